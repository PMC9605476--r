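.default_rare_spec <- function() {
  tibble::tibble(
    gene = c("MSX1", "PAX9", "WNT10A", "EDA", "LRP6", "CREBBP", "LAMA3",
             "AXIN2", "IRF6", "TP63", "EDAR", "ROR2", "OTHERG"),
    dna_change = c("c.101dupA", "c.250C>T", "c.337C>T", "c.500G>A",
                   "c.1418G>C", "c.1030C>T", "c.900+2T>C", "c.300C>T",
                   "c.120A>G", "c.700C>G", "c.256A>C", "c.1000+5G>A",
                   "c.10A>G"),
    consequence = c("frameshift", "stop_gain", "missense", "missense",
                    "missense", "missense", "splicing", "synonymous",
                    "missense", "missense", "missense", "splicing",
                    "missense"),
    af_nfe = c(NA, 5e-5, 2.65e-4, 0, NA, NA, NA, 4e-4, 0.005, NA, NA, NA, NA),
    cadd = c(NA, NA, 16.2, 24, 21.1, 28, NA, NA, 25, 18.5, 25, NA, 30),
    ada = c(NA, NA, NA, NA, NA, NA, 0.95, NA, NA, NA, NA, 0.5, NA),
    target_vote = c(NA, NA, 0.3, 0.8, 0.5, 0.75, NA, NA, 0.8, 0.44, 0.3,
                    NA, 0.9),
    n_absent = c(16L, 16L, 0L, 4L, 0L, 0L, 16L, 16L, 0L, 0L, 0L, 16L, 0L),
    db_pathogenic = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                      FALSE, FALSE, FALSE, FALSE, FALSE),
    carriers_cases = c(2L, 1L, 3L, 2L, 2L, 1L, 2L, 2L, 2L, 1L, 2L, 1L, 1L),
    carriers_controls = rep(0L, 13)
  )
}

.default_background_spec <- function() {
  genes <- c("AXIN2", "EDAR", "EVC", "IRF6", "LAMA3", "LRP6", "MSX1",
             "PAX9", "ROR2", "CHD7", "CREBBP", "LEF1", "TP63", "WNT10A")
  g <- rep(genes, length.out = 28)
  tibble::tibble(
    gene = g,
    dna_change = paste0("c.", 3 * seq_len(28), "C>T"),
    maf = round(seq(0.10, 0.45, length.out = 28), 3)
  )
}

.sim_panel <- function() {
  panel <- read_panel(ps_fixture("gene_panel.tsv"))
  rbind(panel, tibble::tibble(gene = "OTHERG", chromosome = "5",
                              x_linked = FALSE, category = "other",
                              pli = 0.5))
}

#' Synthetic cohort configuration
#'
#' Parameters of the seeded case/control cohort generator. The defaults
#' emulate the study conditions this package reproduces: 65 cases and 127
#' controls; a set of rare variants planted in cases by exact carrier counts
#' (absent from controls), including likely-gene-disrupting passes, an
#' allowlisted-gene rescue and decoys that must fail each cascade stage; one
#' recurrent focal missense variant (WNT10A c.682T>A) strongly enriched in
#' cases (minor allele frequency 0.16 in cases vs 0.004 in controls); 28
#' common background markers sampled under Hardy-Weinberg at identical
#' frequencies in both groups; and dentition phenotypes drawn conditional on
#' carrier class from truncated negative binomial distributions, with tooth
#' positions weighted towards second premolars and lateral incisors.
#'
#' @param n_cases number of case subjects (default 65).
#' @param n_controls number of control subjects (default 127).
#' @param seed mandatory integer seed; the generator is a pure function of
#'   the configuration.
#' @param rare_spec tibble describing planted rare variants (gene,
#'   dna_change, consequence, af_nfe, cadd, ada, target_vote, n_absent,
#'   db_pathogenic, carriers_cases, carriers_controls).
#' @param focal list with gene, dna_change, maf_cases, maf_controls for the
#'   recurrent focal variant.
#' @param background tibble of common background markers (gene, dna_change,
#'   maf), sampled identically in cases and controls.
#' @param phenotype_model per-carrier-class missing-teeth model: negative
#'   binomial mean (`mu`) and dispersion (`size`) for severe carriers
#'   (biallelic focal or truncating-variant carriers), other carriers, and
#'   non-carrier cases; counts clamped to 1..28.
#' @param oligogenic_rate probability that a planted rare carrier is drawn
#'   from cases that already carry a retained variant, creating multilocus
#'   carriers (default 0.1).
#' @return an object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(seed = 1)
#' cfg$n_cases
#' @export
simulation_config <- function(n_cases = 65, n_controls = 127, seed,
                              rare_spec = .default_rare_spec(),
                              focal = list(gene = "WNT10A",
                                           dna_change = "c.682T>A",
                                           maf_cases = 0.16,
                                           maf_controls = 0.004),
                              background = .default_background_spec(),
                              phenotype_model = list(
                                severe = list(mu = 12, size = 8),
                                carrier = list(mu = 8, size = 5),
                                noncarrier = list(mu = 4, size = 3)
                              ),
                              oligogenic_rate = 0.1) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_cases >= 1, n_controls >= 1,
            focal$maf_cases >= 0, focal$maf_cases <= 1,
            focal$maf_controls >= 0, focal$maf_controls <= 1,
            all(background$maf >= 0 & background$maf <= 1),
            oligogenic_rate >= 0, oligogenic_rate <= 1)
  if (any(rare_spec$carriers_cases > n_cases) ||
      any(rare_spec$carriers_controls > n_controls)) {
    stop("infeasible carrier counts: more carriers than subjects",
         call. = FALSE)
  }
  structure(
    list(n_cases = n_cases, n_controls = n_controls, seed = as.integer(seed),
         rare_spec = rare_spec, focal = focal, background = background,
         phenotype_model = phenotype_model,
         oligogenic_rate = oligogenic_rate),
    class = "simulation_config"
  )
}

#' Sample a 16-slot verdict profile
#'
#' Generates a list of 16 per-tool verdict token sets realizing a target
#' damaging fraction: `round(target_vote * n_available)` tools vote damaging
#' (tokens from \{D, Dc, P\}) and the rest benign (\{B, N, T\}); `n_absent`
#' slots carry no verdict. A fraction of damaging slots receive a dual token
#' set such as \{T, D\} to exercise the any-damaging counting rule (a dual
#' entry never changes a slot's damaging status).
#'
#' @param target_vote target damaging fraction in \[0, 1\].
#' @param n_absent number of empty verdict slots (default 0).
#' @param dual_rate probability a damaging slot gets a dual token (default 0.1).
#' @return a 16-element named list of character token sets, as stored in the
#'   `verdicts` column of [read_variant_table()] output.
#' @export
verdict_profile_sampler <- function(target_vote, n_absent = 0,
                                    dual_rate = 0.1) {
  stopifnot(target_vote >= 0, target_vote <= 1, n_absent >= 0, n_absent <= 16)
  tools <- prediction_tools()
  slots <- vector("list", 16)
  names(slots) <- tools
  absent <- if (n_absent > 0) sample(16, n_absent) else integer(0)
  avail <- setdiff(seq_len(16), absent)
  k <- round(target_vote * length(avail))
  damaging <- if (k > 0) sample(avail, k) else integer(0)
  for (i in seq_len(16)) {
    if (i %in% absent) {
      slots[[i]] <- character(0)
    } else if (i %in% damaging) {
      tok <- sample(c("D", "Dc", "P"), 1)
      if (stats::runif(1) < dual_rate) {
        slots[[i]] <- c(sample(c("T", "N", "B"), 1), tok)
      } else {
        slots[[i]] <- tok
      }
    } else {
      slots[[i]] <- sample(c("B", "N", "T"), 1)
    }
  }
  slots
}

# Expected cascade fate of a planted rare variant, derived from the
# configured parameters (not from the cascade implementation): used to
# write the truth record the pipeline is later checked against.
.expected_retained <- function(spec, panel, cfg = cascade_config()) {
  vapply(seq_len(nrow(spec)), function(i) {
    cons <- spec$consequence[i]
    if (cons %in% c("synonymous", "other")) return(FALSE)
    exempt <- spec$gene[i] %in% cfg$exempt_genes
    rare_ok <- exempt || is.na(spec$af_nfe[i]) ||
      spec$af_nfe[i] < cfg$maf_threshold
    n_avail <- 16 - spec$n_absent[i]
    lgd <- cons %in% c("stop_gain", "stop_loss", "frameshift") ||
      (cons == "splicing" && !is.na(spec$ada[i]) &&
         spec$ada[i] >= cfg$ada_threshold) ||
      (cons == "missense" && !is.na(spec$cadd[i]) &&
         spec$cadd[i] > cfg$cadd_threshold && n_avail > 0 &&
         round(spec$target_vote[i] * n_avail) >= cfg$vote_rule * n_avail)
    cat_ok <- panel$category[match(spec$gene[i], panel$gene)] %in%
      c("known_ta", "odontogenesis")
    pli <- panel$pli[match(spec$gene[i], panel$gene)]
    pri <- cat_ok || (!is.na(pli) && pli >= cfg$pli_threshold)
    (rare_ok && lgd && pri) || exempt
  }, logical(1))
}

.hw_copies <- function(n, maf) {
  stats::rbinom(n, size = 2, prob = maf)
}

.copies_to_calls <- function(subjects, copies, gene, dna_change) {
  carrier <- copies > 0
  if (!any(carrier)) {
    return(tibble::tibble(subject_id = character(), gene = character(),
                          dna_change = character(), zygosity = character(),
                          key = character()))
  }
  tibble::tibble(
    subject_id = subjects[carrier],
    gene = gene,
    dna_change = dna_change,
    zygosity = ifelse(copies[carrier] == 2, "HOM", "HET"),
    key = variant_key(gene, dna_change)
  )
}

.tooth_weights <- function() {
  class_w <- c(central_incisor = 0.10, lateral_incisor = 0.23, canine = 0.10,
               first_premolar = 0.14, second_premolar = 0.27,
               first_molar = 0.06, second_molar = 0.10)
  teeth <- as.vector(outer(1:4 * 10, 1:7, `+`))
  w <- class_w[tooth_class(teeth)] / 4
  stats::setNames(w, teeth)
}

.rnbinom_clamped <- function(n, mu, size, lo = 1, hi = 28) {
  pmin(pmax(stats::rnbinom(n, mu = mu, size = size), lo), hi)
}

#' Generate a synthetic case/control cohort
#'
#' Produces the four pipeline inputs (annotated variant table, genotype
#' calls, dentition phenotypes, gene panel) plus a truth record, with the
#' statistical structure described in [simulation_config()]. The output is a
#' deterministic function of the configuration (including its seed): rare
#' variants are planted by exact carrier counts, the focal and background
#' common variants are sampled under Hardy-Weinberg per group, and each
#' case's missing teeth are drawn conditional on its carrier class. Controls
#' carry no rare planted variants (unless configured) and have no missing
#' teeth.
#'
#' @param cfg a [simulation_config()].
#' @param out_dir optional directory; when given, the five outputs are
#'   written as `variants.tsv`, `genotypes.tsv`, `phenotypes.tsv`,
#'   `panel.tsv` and `truth.json`.
#' @return list with tibbles `variants`, `genotypes`, `phenotypes`, `panel`
#'   and the `truth` list (planted carriers, expected retained keys, focal
#'   and background allele frequencies).
#' @examples
#' sim <- simulate_cohort(simulation_config(seed = 7))
#' sim$truth$expected_retained
#' @export
simulate_cohort <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  panel <- .sim_panel()
  cases <- sprintf("CASE_%03d", seq_len(cfg$n_cases))
  controls <- sprintf("CTRL_%03d", seq_len(cfg$n_controls))
  sex <- c(
    ifelse(stats::runif(cfg$n_cases) < 0.49, "male", "female"),
    ifelse(stats::runif(cfg$n_controls) < 0.46, "male", "female")
  )
  names(sex) <- c(cases, controls)

  ## --- annotated variant table -------------------------------------------
  spec <- cfg$rare_spec
  rare_variants <- tibble::tibble(
    gene = spec$gene,
    rs_id = NA_character_,
    dna_change = spec$dna_change,
    protein_change = paste0("p.(", spec$dna_change, ")"),
    protein_domain = NA_character_,
    consequence = spec$consequence,
    af_nfe = spec$af_nfe,
    ada = spec$ada,
    cadd = spec$cadd,
    verdicts = lapply(seq_len(nrow(spec)), function(i) {
      if (is.na(spec$target_vote[i])) {
        verdict_profile_sampler(0, n_absent = 16)
      } else {
        verdict_profile_sampler(spec$target_vote[i], spec$n_absent[i])
      }
    }),
    db_pathogenic = spec$db_pathogenic,
    db_note = NA_character_,
    key = variant_key(spec$gene, spec$dna_change)
  )
  focal_variant <- tibble::tibble(
    gene = cfg$focal$gene, rs_id = NA_character_,
    dna_change = cfg$focal$dna_change,
    protein_change = paste0("p.(", cfg$focal$dna_change, ")"),
    protein_domain = NA_character_, consequence = "missense",
    af_nfe = 0.0223, ada = NA_real_, cadd = 28.4,
    verdicts = list(verdict_profile_sampler(0.8, 0)),
    db_pathogenic = TRUE, db_note = "recurrent focal variant",
    key = variant_key(cfg$focal$gene, cfg$focal$dna_change)
  )
  bg <- cfg$background
  bg_variants <- tibble::tibble(
    gene = bg$gene, rs_id = NA_character_, dna_change = bg$dna_change,
    protein_change = paste0("p.(", bg$dna_change, ")"),
    protein_domain = NA_character_, consequence = "synonymous",
    af_nfe = bg$maf, ada = NA_real_, cadd = NA_real_,
    verdicts = lapply(seq_len(nrow(bg)), function(i) {
      verdict_profile_sampler(0, n_absent = 16)
    }),
    db_pathogenic = FALSE, db_note = NA_character_,
    key = variant_key(bg$gene, bg$dna_change)
  )
  variants <- rbind(rare_variants, focal_variant, bg_variants)

  ## --- genotypes ----------------------------------------------------------
  expected <- .expected_retained(spec, panel)
  planted <- list()
  carrier_pool <- character(0)  # cases already carrying a retained variant
  x_genes <- panel$gene[panel$x_linked]
  for (i in seq_len(nrow(spec))) {
    n_c <- spec$carriers_cases[i]
    pick <- character(0)
    if (n_c > 0) {
      n_from_pool <- sum(stats::runif(n_c) < cfg$oligogenic_rate &
                           length(carrier_pool) > 0)
      n_from_pool <- min(n_from_pool, length(carrier_pool))
      pick <- c(
        if (n_from_pool > 0) sample(carrier_pool, n_from_pool) else character(0),
        sample(setdiff(cases, carrier_pool), n_c - n_from_pool)
      )
    }
    pick_ctrl <- if (spec$carriers_controls[i] > 0) {
      sample(controls, spec$carriers_controls[i])
    } else character(0)
    subj <- c(pick, pick_ctrl)
    if (length(subj) > 0) {
      zyg <- ifelse(spec$gene[i] %in% x_genes & sex[subj] == "male",
                    "HEMI", "HET")
      planted[[length(planted) + 1]] <- tibble::tibble(
        subject_id = subj, gene = spec$gene[i],
        dna_change = spec$dna_change[i], zygosity = unname(zyg),
        key = variant_key(spec$gene[i], spec$dna_change[i])
      )
      if (expected[i]) carrier_pool <- union(carrier_pool, pick)
    }
  }
  planted <- if (length(planted) > 0) dplyr::bind_rows(planted) else
    tibble::tibble(subject_id = character(), gene = character(),
                   dna_change = character(), zygosity = character(),
                   key = character())

  focal_case_copies <- .hw_copies(cfg$n_cases, cfg$focal$maf_cases)
  focal_ctrl_copies <- .hw_copies(cfg$n_controls, cfg$focal$maf_controls)
  focal_calls <- rbind(
    .copies_to_calls(cases, focal_case_copies, cfg$focal$gene,
                     cfg$focal$dna_change),
    .copies_to_calls(controls, focal_ctrl_copies, cfg$focal$gene,
                     cfg$focal$dna_change)
  )
  bg_calls <- dplyr::bind_rows(lapply(seq_len(nrow(bg)), function(i) {
    rbind(
      .copies_to_calls(cases, .hw_copies(cfg$n_cases, bg$maf[i]),
                       bg$gene[i], bg$dna_change[i]),
      .copies_to_calls(controls, .hw_copies(cfg$n_controls, bg$maf[i]),
                       bg$gene[i], bg$dna_change[i])
    )
  }))
  genotypes <- rbind(planted, focal_calls, bg_calls)

  ## --- phenotypes ---------------------------------------------------------
  retained_truth <- sort(c(variant_key(spec$gene, spec$dna_change)[expected],
                           focal_variant$key))
  truncating <- variant_key(spec$gene, spec$dna_change)[
    expected & spec$consequence %in% c("stop_gain", "stop_loss", "frameshift")]
  focal_hom <- cases[focal_case_copies == 2]
  retained_carrier <- unique(genotypes$subject_id[
    genotypes$key %in% retained_truth &
      genotypes$subject_id %in% cases])
  severe <- union(focal_hom, unique(
    genotypes$subject_id[genotypes$key %in% truncating]))
  severe <- intersect(severe, cases)
  pm <- cfg$phenotype_model
  n_missing <- stats::setNames(integer(cfg$n_cases), cases)
  for (s in cases) {
    par <- if (s %in% severe) pm$severe else
      if (s %in% retained_carrier) pm$carrier else pm$noncarrier
    n_missing[[s]] <- .rnbinom_clamped(1, par$mu, par$size)
  }
  w <- .tooth_weights()
  teeth_codes <- as.integer(names(w))
  missing_sets <- lapply(cases, function(s) {
    sort(sample(teeth_codes, n_missing[[s]], prob = w))
  })
  fh <- vapply(cases, function(s) {
    u <- stats::runif(1)
    if (u < 0.10) "unknown" else if (s %in% retained_carrier) {
      if (stats::runif(1) < 0.6) "yes" else "no"
    } else {
      if (stats::runif(1) < 0.4) "yes" else "no"
    }
  }, character(1))
  ecto <- vapply(cases, function(s) {
    n_missing[[s]] >= 6 && stats::runif(1) < 0.2
  }, logical(1))
  phenotypes <- tibble::tibble(
    subject_id = c(cases, controls),
    status = c(rep("case", cfg$n_cases), rep("control", cfg$n_controls)),
    sex = unname(sex),
    family_history = c(unname(fh), rep("no", cfg$n_controls)),
    ectodermal_features = c(unname(ecto), rep(FALSE, cfg$n_controls)),
    missing_teeth = c(missing_sets,
                      replicate(cfg$n_controls, integer(0), simplify = FALSE)),
    peg_shaped = replicate(cfg$n_cases + cfg$n_controls, integer(0),
                           simplify = FALSE)
  )

  truth <- list(
    seed = cfg$seed,
    n_cases = cfg$n_cases,
    n_controls = cfg$n_controls,
    planted_carriers = planted,
    expected_retained = retained_truth,
    focal = list(key = focal_variant$key,
                 maf_cases = cfg$focal$maf_cases,
                 maf_controls = cfg$focal$maf_controls,
                 realized_maf_cases = mean(focal_case_copies) / 2,
                 realized_maf_controls = mean(focal_ctrl_copies) / 2),
    background = stats::setNames(bg$maf, variant_key(bg$gene, bg$dna_change)),
    phenotype_model = cfg$phenotype_model
  )
  out <- list(variants = variants, genotypes = genotypes,
              phenotypes = phenotypes, panel = panel, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_variant_table(variants, file.path(out_dir, "variants.tsv"))
    write_tsv_plain(genotypes, file.path(out_dir, "genotypes.tsv"))
    ph <- phenotypes
    ph$missing_teeth <- vapply(ph$missing_teeth, paste, character(1),
                               collapse = ",")
    ph$peg_shaped <- vapply(ph$peg_shaped, paste, character(1),
                            collapse = ",")
    write_tsv_plain(ph, file.path(out_dir, "phenotypes.tsv"))
    write_tsv_plain(panel, file.path(out_dir, "panel.tsv"))
    tr <- truth
    tr$planted_carriers <- as.data.frame(tr$planted_carriers)
    jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
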