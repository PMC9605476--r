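test_that("missing-teeth counts exclude third molars by default", {
  ph <- fx_phenotypes()
  expect_equal(count_missing(ph[ph$subject_id == "TA_20", ]), 20L)
  expect_equal(count_missing(ph[ph$subject_id == "TA_33", ]), 5L)
  # a record missing only wisdom teeth counts zero by default
  rec <- tibble::tibble(
    subject_id = "w", status = "case", sex = "male", family_history = "no",
    ectodermal_features = FALSE,
    missing_teeth = list(c(18L, 28L, 38L, 48L)), peg_shaped = list(integer(0))
  )
  expect_equal(count_missing(rec), 0L)
  expect_equal(count_missing(rec, exclude_third_molars = FALSE), 4L)
})

test_that("agenesis classes follow the 1-5 / >=6 boundaries", {
  expect_equal(classify_agenesis(c(0, 1, 5, 6, 24)),
               c("none", "hypodontia", "hypodontia", "oligodontia",
                 "oligodontia"))
  expect_error(classify_agenesis(-1))
})

test_that("case cohorts partition into hypodontia and oligodontia", {
  ph <- fx_phenotypes()
  cls <- classify_agenesis(count_missing(ph))
  expect_false(any(cls == "none"))
  expect_equal(sum(cls == "hypodontia") + sum(cls == "oligodontia"), nrow(ph))
})

test_that("tooth-class distribution conserves counts and pools quadrants", {
  ph <- fx_phenotypes()
  ds <- tooth_class_distribution(ph)
  expect_equal(ds$n_subjects, 37)
  expect_equal(ds$total_missing, sum(count_missing(ph)))
  expect_equal(sum(ds$per_tooth_class$n), ds$total_missing)
  expect_equal(sum(ds$per_jaw$n), ds$total_missing)
  expect_equal(sum(ds$per_tooth_class$fraction), 1)
  # one subject missing both upper lateral incisors
  single <- ph[ph$subject_id == "TA_4", ]
  ds1 <- tooth_class_distribution(single)
  li <- ds1$per_tooth_class[ds1$per_tooth_class$tooth_class ==
                              "lateral_incisor", ]
  expect_equal(li$n, 2L)
  expect_equal(li$fraction, 1)
})

test_that("carrier summaries reproduce the printed dentition statistics", {
  ph <- fx_phenotypes()
  g <- fx_genotypes()
  w <- carrier_phenotype_summary(ph, g, genes = "WNT10A")
  expect_equal(w$n_subjects, 18)
  expect_equal(w$total_missing, 174)
  expect_equal(round(w$mean_missing, 2), 9.67)
  expect_equal(c(w$min_missing, w$max_missing), c(2L, 20L))
  # exclusive recurrent-variant carriers
  ex <- carrier_phenotype_summary(
    ph, g, variants = variant_key("WNT10A", "c.682T>A"), exclusive = TRUE)
  expect_equal(ex$n_subjects, 9)
  expect_equal(ex$total_missing, 104)
  expect_equal(round(ex$mean_missing, 1), 11.6)
  expect_equal(c(ex$min_missing, ex$max_missing), c(3L, 20L))
  # empty selection gives an explicit empty summary, not an error
  none <- carrier_phenotype_summary(ph, g, genes = "NOSUCHGENE")
  expect_equal(none$n_subjects, 0)
  expect_equal(none$total_missing, 0)
})

test_that("exclusive summaries are sub-summaries of inclusive ones", {
  ph <- fx_phenotypes()
  g <- fx_genotypes()
  for (gene in c("WNT10A", "EDA", "LRP6")) {
    inc <- carrier_phenotype_summary(ph, g, genes = gene)
    exc <- carrier_phenotype_summary(ph, g, genes = gene, exclusive = TRUE)
    expect_lte(exc$n_subjects, inc$n_subjects)
    expect_lte(exc$total_missing, inc$total_missing)
  }
})

test_that("family-history rate keeps unknowns in the denominator", {
  ph <- fx_phenotypes()
  g <- fx_genotypes()
  wnt <- ph[ph$subject_id %in% unique(g$subject_id[g$gene == "WNT10A"]), ]
  fh <- family_history_rate(wnt)
  expect_equal(fh$n_yes, 11)
  expect_equal(fh$n_subjects, 18)
  expect_equal(round(100 * fh$fraction, 2), 61.11)
  # known-risk-gene carriers outside WNT10A
  known <- ph[ph$subject_id %in% paste0("TA_", 6:19), ]
  fh2 <- family_history_rate(known)
  expect_equal(round(100 * fh2$fraction, 2), 64.29)
  # all-unknown cohort: zero rate
  allunk <- wnt
  allunk$family_history <- "unknown"
  expect_equal(family_history_rate(allunk)$fraction, 0)
})

test_that("oligogenic detection finds the printed co-occurrences", {
  g <- fx_genotypes()
  og <- detect_oligogenic(unique(g$key), g)
  cross <- og$subject_id[og$kind == "cross_gene"]
  same <- og$subject_id[og$kind == "same_gene_multi"]
  expect_setequal(cross, c("TA_33", "TA_34", "TA_36"))
  expect_setequal(same, c("TA_21", "TA_22", "TA_28", "TA_37"))
  # restricting the retained set restricts the report
  og2 <- detect_oligogenic(variant_key("WNT10A", "c.682T>A"), g)
  expect_equal(nrow(og2), 0)
  # single-variant-per-subject cohort yields an empty report
  g1 <- g[!duplicated(g$subject_id), ]
  expect_equal(nrow(detect_oligogenic(unique(g1$key), g1)), 0)
})

test_that("carrier rate counts distinct subjects against the cohort size", {
  g <- fx_genotypes()
  cr <- carrier_rate(g, 65)
  expect_equal(cr$n_carriers, 37)
  expect_equal(round(100 * cr$fraction, 2), 56.92)
  cw <- carrier_rate(g, 65, keys = g$key[g$gene == "WNT10A"])
  expect_equal(cw$n_carriers, 18)
  expect_equal(round(100 * cw$fraction, 2), 27.69)
})
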