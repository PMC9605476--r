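test_that("consensus vote counts damaging tools over available verdicts", {
  v <- fx_variants()
  vote_of <- function(prot) {
    consensus_vote(v$verdicts[[which(v$protein_change == prot)]])
  }
  # TP63 p.Pro532Ala: 7 of 16 tools vote damaging
  expect_equal(vote_of("p.Pro532Ala"),
               c(n_damaging = 7L, n_available = 16L))
  # LEF1 p.Lys95Asn: dual "D,T" entry counts damaging -> 13/16
  expect_equal(vote_of("p.Lys95Asn"),
               c(n_damaging = 13L, n_available = 16L))
  # LRP6 p.Asp543Glu: exactly half with any-damaging dual handling
  expect_equal(vote_of("p.Asp543Glu"),
               c(n_damaging = 8L, n_available = 16L))
  # frameshift row with no verdicts
  expect_equal(consensus_vote(v$verdicts[[which(v$gene == "EVC")]]),
               c(n_damaging = 0L, n_available = 0L))
  # rows with partial verdict coverage use the available denominator
  expect_equal(vote_of("p.Asn280Lys")[["n_available"]], 12L)
})

test_that("vote rule is 'at least half of available', vacuous input fails", {
  expect_true(vote_passes(8, 16))    # exactly half passes
  expect_false(vote_passes(7, 16))
  expect_true(vote_passes(6, 12))
  expect_false(vote_passes(5, 12))
  expect_false(vote_passes(0, 0))
  expect_true(vote_passes(1, 16, vote_rule = 1 / 16))
})

test_that("rarity stage applies strict MAF cut-off with gene allowlist", {
  cfg <- cascade_config()
  v <- make_variants(
    gene = c("EVC", "WNT10A", "AXIN2", "PAX9", "MSX1"),
    dna_change = paste0("c.", 1:5, "A>G"),
    consequence = c("frameshift", "missense", "synonymous", "missense",
                    "missense"),
    af_nfe = c(7.35e-5, 2.23e-2, 1e-5, 0.001, NA)
  )
  st <- is_rare_nonsynonymous(v, cfg)
  expect_equal(st$status,
               c("pass", "exempt", "fail", "fail", "pass"))
  # synonymous fails irrespective of frequency; 0.001 fails the strict '<'
  expect_match(st$detail[3], "excluded consequence")
  expect_match(st$detail[4], ">=")
  # absent frequency means "not observed" and passes
  expect_match(st$detail[5], "absent")
})

test_that("likely-gene-disrupting stage honors class rules and boundaries", {
  cfg <- cascade_config()
  v <- make_variants(
    gene = rep("PAX9", 6),
    dna_change = paste0("c.", 1:6, "A>G"),
    consequence = c("stop_gain", "splicing", "splicing", "missense",
                    "missense", "missense"),
    cadd = c(NA, NA, NA, 28, 18.8, 25),
    ada = c(NA, 0.85, 0.90, NA, NA, NA),
    verdicts = list(fixed_verdicts(0, 0), fixed_verdicts(0, 0),
                    fixed_verdicts(0, 0), fixed_verdicts(12),
                    fixed_verdicts(12), fixed_verdicts(7))
  )
  st <- is_likely_gene_disrupting(v, cfg)
  # truncating variants pass regardless of scores
  expect_equal(st$status[1], "pass")
  # ADA threshold is >= 0.9
  expect_equal(st$status[2:3], c("fail", "pass"))
  # missense needs CADD > 20 AND a passing vote
  expect_equal(st$status[4:6], c("pass", "fail", "fail"))
})

test_that("prioritization passes by category or pLi and flags panel gaps", {
  cfg <- cascade_config()
  panel <- tibble::tibble(
    gene = c("LAMA3", "GENEA", "GENEB"),
    chromosome = c("18", "1", "2"),
    x_linked = FALSE,
    category = c("known_ta", "other", "other"),
    pli = c(0.00, 0.97, 0.50)
  )
  v <- make_variants(gene = c("LAMA3", "GENEA", "GENEB"),
                     dna_change = paste0("c.", 1:3, "A>G"),
                     consequence = "missense")
  st <- prioritize(v, panel, cfg)
  # known gene passes via category despite pLi 0.00; pLi >= 0.95 suffices
  expect_equal(st$status, c("pass", "pass", "fail"))
  v2 <- make_variants("ABSENT", "c.9A>G", "missense")
  expect_error(prioritize(v2, panel, cfg), "absent from the panel")
})

test_that("pathogenicity label follows database annotation", {
  v <- fx_variants()
  lab <- label_pathogenicity(v)
  names(lab) <- v$protein_change
  expect_equal(unname(lab["p.Cys107Ter"]), "pathogenic")   # ClinVar
  expect_equal(unname(lab["p.Arg69Pro"]), "pathogenic")    # HGMD
  expect_equal(unname(lab["p.Glu1856Gln"]), "likely_pathogenic")  # novel
  # ClinVar VUS does not set the pathogenic label
  expect_equal(unname(lab["p.Glu306Ter"]), "likely_pathogenic")
})

test_that("full cascade on the 27-variant fixture matches the study result", {
  res <- run_cascade(fx_variants(), fx_panel(), default_cfg())
  cl <- res$classified
  expect_equal(sum(cl$retained), 27)
  expect_equal(sum(cl$passed_strict), 25)
  exempt <- cl[cl$retained & cl$exemption != "none", ]
  expect_setequal(exempt$key,
                  c(variant_key("TP63", "c.1594C>G"),
                    variant_key("WNT10A", "c.337C>T")))
  expect_equal(exempt$exemption[exempt$gene == "TP63"], "manual_exception")
  expect_equal(exempt$exemption[exempt$gene == "WNT10A"], "gene_allowlist")
  # stage counts are monotonically non-increasing
  sc <- res$stage_counts
  expect_true(all(diff(sc[c("input", "rare_nonsynonymous",
                            "likely_gene_disrupting", "prioritized")]) <= 0))
  # every retained variant carries a label; audit has 3 entries per variant
  expect_false(anyNA(cl$label[cl$retained]))
  expect_equal(nrow(res$audit), 3 * 27)
  expect_true(all(table(res$audit$key) == 3))
})

test_that("cascade handles degenerate configurations", {
  v <- fx_variants()
  panel <- fx_panel()
  # empty input
  res0 <- run_cascade(v[0, ], panel, cascade_config())
  expect_equal(unname(res0$stage_counts), rep(0L, 5))
  # maf_threshold = 0 and no exemptions: only absent or zero frequencies
  # survive the rarity stage
  cfg0 <- cascade_config(maf_threshold = 0, exempt_genes = character())
  st <- is_rare_nonsynonymous(v, cfg0)
  nonsyn <- !v$consequence %in% c("synonymous", "other")
  expect_equal(st$status == "pass", nonsyn & is.na(v$af_nfe))
})

test_that("retained set is reconstructible from the audit trail", {
  res <- run_cascade(fx_variants(), fx_panel(), default_cfg())
  audit_pass <- tapply(
    res$audit$status %in% c("pass", "exempt"), res$audit$key, all)
  strict_from_audit <- sort(names(audit_pass)[audit_pass])
  expect_equal(strict_from_audit,
               sort(res$classified$key[res$classified$passed_strict]))
})

test_that("cascade equals a brute-force rule conjunction on random tables", {
  set.seed(41)
  panel <- fx_panel()
  for (rep in 1:8) {
    v <- random_variants(50, panel)
    cfg <- cascade_config(
      maf_threshold = sample(c(0.0005, 0.001, 0.005), 1),
      cadd_threshold = sample(c(15, 20, 25), 1),
      vote_rule = sample(c(0.25, 0.5, 0.75), 1),
      manual_exceptions = sample(v$key, 2)
    )
    res <- run_cascade(v, panel, cfg)
    expect_equal(retained_keys(res), brute_force_retained(v, panel, cfg))
  }
})

test_that("tightening any threshold never grows the strictly retained set", {
  set.seed(17)
  panel <- fx_panel()
  strict_keys <- function(v, cfg) {
    cl <- run_cascade(v, panel, cfg)$classified
    cl$key[cl$passed_strict]
  }
  tighter <- list(
    function(cfg) cascade_config(maf_threshold = cfg$maf_threshold / 10,
                                 exempt_genes = cfg$exempt_genes),
    function(cfg) cascade_config(cadd_threshold = cfg$cadd_threshold + 5,
                                 exempt_genes = cfg$exempt_genes),
    function(cfg) cascade_config(ada_threshold = min(1, cfg$ada_threshold + 0.05),
                                 exempt_genes = cfg$exempt_genes),
    function(cfg) cascade_config(vote_rule = min(1, cfg$vote_rule + 0.25),
                                 exempt_genes = cfg$exempt_genes)
  )
  tables <- c(list(fx_variants()),
              lapply(1:4, function(i) random_variants(40, panel)))
  base <- cascade_config()
  for (v in tables) {
    s0 <- strict_keys(v, base)
    for (f in tighter) {
      expect_true(all(strict_keys(v, f(base)) %in% s0))
    }
  }
})

test_that("cascade is a pure function of its inputs", {
  v <- fx_variants()
  panel <- fx_panel()
  cfg <- default_cfg()
  r1 <- run_cascade(v, panel, cfg)
  r2 <- run_cascade(v, panel, cfg)
  expect_identical(r1$classified, r2$classified)
  expect_identical(r1$audit, r2$audit)
})

test_that("control screen counts carriers and runs the reciprocal scan", {
  res <- run_cascade(fx_variants(), fx_panel(), default_cfg())
  ctrl_g <- read_genotypes(ps_fixture("control_genotypes.tsv"))
  ctrl_v <- read_variant_table(ps_fixture("control_variants_synthetic.tsv"))
  scr <- control_screen(res, ctrl_g, ctrl_v, fx_panel())
  # exactly one retained variant (the recurrent focal one) has a control
  # carrier, with one carrier
  hits <- scr$carriers[scr$carriers$n_control_carriers > 0, ]
  expect_equal(hits$key, variant_key("WNT10A", "c.682T>A"))
  expect_equal(hits$n_control_carriers, 1L)
  # the control-only high-CADD LAMA3 missense variant passes the cascade
  expect_equal(scr$reciprocal$key, variant_key("LAMA3", "c.7298A>C"))
  # no control genotypes -> empty report
  scr0 <- control_screen(res, NULL)
  expect_true(all(scr0$carriers$n_control_carriers == 0))
  expect_equal(nrow(scr0$reciprocal), 0)
})
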