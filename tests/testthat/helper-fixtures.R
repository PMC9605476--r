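# Shared fixture loaders and independent oracles for the test suite.

fx_variants <- function() read_variant_table(ps_fixture("table2_variants.tsv"))
fx_panel <- function() read_panel(ps_fixture("gene_panel.tsv"))
fx_phenotypes <- function() {
  read_phenotype_table(ps_fixture("table34_phenotypes.tsv"))
}
fx_genotypes <- function() {
  read_genotypes(ps_fixture("table34_genotypes.tsv"),
                 panel = fx_panel(), phenotypes = fx_phenotypes())
}
fx_assoc <- function() read_assoc_table(ps_fixture("table5_common.tsv"))

default_cfg <- function() {
  cascade_config(manual_exceptions = variant_key("TP63", "c.1594C>G"))
}

# Printed per-patient missing-teeth counts (Tables 3-4 column), keyed by
# subject. The TA_5 entry is the grid-consistent count (one missing lateral
# incisor plus a peg-shaped one, which is a present tooth).
printed_missing_wnt10a <- c(
  TA_20 = 20, TA_21 = 19, TA_22 = 16, TA_23 = 16, TA_24 = 14, TA_25 = 14,
  TA_26 = 12, TA_27 = 10, TA_28 = 9, TA_29 = 9, TA_30 = 8, TA_31 = 6,
  TA_32 = 5, TA_33 = 5, TA_34 = 4, TA_35 = 3, TA_36 = 2, TA_37 = 2
)

# Build a minimal annotated-variant tibble in memory.
make_variants <- function(gene, dna_change, consequence,
                          af_nfe = NA_real_, cadd = NA_real_,
                          ada = NA_real_, verdicts = NULL,
                          db_pathogenic = FALSE) {
  n <- length(gene)
  if (is.null(verdicts)) {
    empty <- stats::setNames(replicate(16, character(0), simplify = FALSE),
                             prediction_tools())
    verdicts <- replicate(n, empty, simplify = FALSE)
  }
  tibble::tibble(
    gene = gene, rs_id = NA_character_, dna_change = dna_change,
    protein_change = paste0("p.(", dna_change, ")"),
    protein_domain = NA_character_, consequence = consequence,
    af_nfe = rep_len(af_nfe, n), ada = rep_len(ada, n),
    cadd = rep_len(cadd, n), verdicts = verdicts,
    db_pathogenic = rep_len(db_pathogenic, n), db_note = NA_character_,
    key = variant_key(gene, dna_change)
  )
}

# Verdict list with a fixed number of single-token damaging/benign slots.
fixed_verdicts <- function(n_damaging, n_available = 16) {
  stats::setNames(lapply(seq_len(16), function(i) {
    if (i <= n_damaging) "D" else if (i <= n_available) "T" else character(0)
  }), prediction_tools())
}

# Independent brute-force predicate for the cascade retained set: a direct
# conjunction of the printed rules, coded without reference to run_cascade's
# staging machinery.
brute_force_retained <- function(variants, panel, cfg) {
  keep <- vapply(seq_len(nrow(variants)), function(i) {
    if (variants$key[i] %in% cfg$manual_exceptions) return(TRUE)
    cons <- variants$consequence[i]
    if (cons %in% c("synonymous", "other")) return(FALSE)
    gene <- variants$gene[i]
    exempt <- gene %in% cfg$exempt_genes
    rare <- exempt || is.na(variants$af_nfe[i]) ||
      variants$af_nfe[i] < cfg$maf_threshold
    n_dmg <- sum(vapply(variants$verdicts[[i]],
                        function(v) any(v %in% c("D", "Dc", "P")), logical(1)))
    n_av <- sum(lengths(variants$verdicts[[i]]) > 0)
    lgd <- cons %in% c("stop_gain", "stop_loss", "frameshift") ||
      (cons == "splicing" && !is.na(variants$ada[i]) &&
         variants$ada[i] >= cfg$ada_threshold) ||
      (cons == "missense" && !is.na(variants$cadd[i]) &&
         variants$cadd[i] > cfg$cadd_threshold &&
         n_av > 0 && n_dmg >= cfg$vote_rule * n_av)
    j <- match(gene, panel$gene)
    pri <- panel$category[j] %in% c("known_ta", "odontogenesis") ||
      (!is.na(panel$pli[j]) && panel$pli[j] >= cfg$pli_threshold)
    (rare && lgd && pri) || exempt ||
      variants$key[i] %in% cfg$manual_exceptions
  }, logical(1))
  sort(variants$key[keep])
}

# Random variant table over the panel genes, for property tests.
random_variants <- function(n, panel) {
  cons <- sample(c("missense", "stop_gain", "frameshift", "splicing",
                   "synonymous"), n, replace = TRUE,
                 prob = c(0.5, 0.1, 0.1, 0.15, 0.15))
  verdicts <- lapply(seq_len(n), function(i) {
    verdict_profile_sampler(stats::runif(1),
                            n_absent = sample(0:8, 1), dual_rate = 0.2)
  })
  make_variants(
    gene = sample(panel$gene, n, replace = TRUE),
    dna_change = paste0("c.", seq_len(n), "A>G"),
    consequence = cons,
    af_nfe = ifelse(stats::runif(n) < 0.3, NA,
                    stats::runif(n, 0, 0.01)),
    cadd = ifelse(stats::runif(n) < 0.2, NA, stats::runif(n, 5, 40)),
    ada = ifelse(stats::runif(n) < 0.3, NA, stats::runif(n)),
    verdicts = verdicts
  )
}

# Permutation oracle for the trend test: fixes the genotype margin and
# permutes case labels, recomputing the trend statistic each draw. Because
# the permutation distribution is a lattice with large atoms, the mid-p
# (half weight on ties at the observed statistic) is returned: it is the
# quantity the continuous chi-square upper tail estimates.
permutation_p <- function(r, s, n_draws = 20000, scores = c(0, 1, 2)) {
  pool <- rep(scores, r + s)
  R <- sum(r)
  n <- r + s
  N <- sum(n)
  A <- sum(scores * n)
  B2 <- sum(scores^2 * n)
  var_term <- N * B2 - A^2
  chi2_of <- function(Tsum) N * (N * Tsum - R * A)^2 /
    (R * (N - R) * var_term)
  obs <- chi2_of(sum(scores * r))
  perm <- vapply(seq_len(n_draws), function(b) {
    chi2_of(sum(sample(pool, R)))
  }, numeric(1))
  mean(perm > obs + 1e-9) + 0.5 * mean(abs(perm - obs) <= 1e-9)
}

random_count_table <- function(max_n = 40) {
  repeat {
    n_subj <- sample(10:max_n, 1)
    maf <- stats::runif(1, 0.1, 0.5)
    copies <- stats::rbinom(n_subj, 2, maf)
    case <- stats::runif(n_subj) < 0.5
    r <- c(sum(copies[case] == 0), sum(copies[case] == 1),
           sum(copies[case] == 2))
    s <- c(sum(copies[!case] == 0), sum(copies[!case] == 1),
           sum(copies[!case] == 2))
    if (sum(r) > 0 && sum(s) > 0) return(list(r = r, s = s))
  }
}
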