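test_that("allele frequency from genotype counts, with hemizygotes", {
  # 8 HET + 7 HOM among 65 cases -> 22/130
  expect_equal(allele_frequency(c(50, 8, 7)), 22 / 130)
  expect_equal(allele_frequency(c(126, 1, 0)), 1 / 254)
  expect_equal(allele_frequency(c(10, 0, 0)), 0)
  # X-linked: hemizygous males add one allele each
  expect_equal(allele_frequency(c(30, 5, 0), hemi_carriers = 2,
                                hemi_total = 10), 7 / 80)
  expect_error(allele_frequency(c(0, 0, 0)), "empty group")
})

test_that("trend test matches its closed form and known identities", {
  # identical genotype proportions give a null result
  null <- cochran_armitage(c(30, 15, 5), c(60, 30, 10))
  expect_equal(null$chi2, 0, tolerance = 1e-12)
  expect_equal(null$p, 1)
  # degenerate variance (single genotype class) returns chi2 0, p 1
  degen <- cochran_armitage(c(20, 0, 0), c(30, 0, 0))
  expect_equal(degen$chi2, 0)
  expect_equal(degen$p, 1)
  expect_error(cochran_armitage(c(-1, 2, 3), c(1, 2, 3)), "non-negative")
  # affine score transforms leave the statistic unchanged
  set.seed(11)
  for (i in 1:5) {
    tb <- random_count_table()
    c1 <- cochran_armitage(tb$r, tb$s, scores = c(0, 1, 2))
    c2 <- cochran_armitage(tb$r, tb$s, scores = 3 + 2 * c(0, 1, 2))
    expect_equal(c1$chi2, c2$chi2, tolerance = 1e-9)
  }
  # label swap leaves chi2 invariant
  tb <- random_count_table()
  expect_equal(cochran_armitage(tb$r, tb$s)$chi2,
               cochran_armitage(tb$s, tb$r)$chi2, tolerance = 1e-9)
})

test_that("trend test agrees with the base-R trend test cross-check", {
  set.seed(23)
  for (i in 1:10) {
    tb <- random_count_table()
    mine <- cochran_armitage(tb$r, tb$s)
    ref <- suppressWarnings(
      stats::prop.trend.test(tb$r, tb$r + tb$s, score = c(0, 1, 2)))
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("allelic odds ratio, Woolf interval and zero-cell correction", {
  # symmetric table: OR 1, CI spans 1
  sym <- allelic_odds_ratio(10, 90, 10, 90)
  expect_equal(sym$or, 1)
  expect_lt(sym$ci_low, 1)
  expect_gt(sym$ci_high, 1)
  expect_false(sym$corrected)
  # direct formula arithmetic
  or <- allelic_odds_ratio(21, 109, 1, 253)
  expect_equal(round(or$or, 2), 48.74)
  # independent log-scale recomputation of the interval
  se <- sqrt(1 / 21 + 1 / 109 + 1 / 1 + 1 / 253)
  expect_equal(or$ci_low, exp(log(21 * 253 / 109) - 1.96 * se),
               tolerance = 1e-3)
  expect_true(or$ci_low <= or$or && or$or <= or$ci_high)
  # Haldane-Anscombe correction on a zero cell
  hc <- allelic_odds_ratio(5, 95, 0, 100)
  expect_true(hc$corrected)
  expect_equal(hc$or, (5.5 * 100.5) / (95.5 * 0.5))
  expect_error(allelic_odds_ratio(0, 0, 1, 1), "at least one")
})

test_that("odds ratio inverts under case/control label swap", {
  set.seed(5)
  for (i in 1:5) {
    a <- sample(1:30, 1); b <- sample(50:200, 1)
    c <- sample(1:30, 1); d <- sample(50:200, 1)
    expect_equal(allelic_odds_ratio(a, b, c, d)$or,
                 1 / allelic_odds_ratio(c, d, a, b)$or, tolerance = 1e-12)
  }
})

test_that("multiplicity plan and significance flags", {
  plan <- multiplicity_plan(0.05, 29)
  expect_equal(plan$threshold, 0.05 / 29)
  expect_equal(signif(plan$threshold, 3), 1.72e-3)
  expect_equal(multiplicity_plan(0.05, 1)$threshold, 0.05)
  expect_equal(multiplicity_plan(0.01, 10)$threshold, 0.001)
  sig <- flag_significance(c(0.03, 0.001, 0.2), plan)
  expect_equal(sig$significant_nominal, c(TRUE, TRUE, FALSE))
  expect_equal(sig$significant_bonferroni, c(FALSE, TRUE, FALSE))
  # bonferroni significance implies nominal significance
  expect_true(all(!sig$significant_bonferroni | sig$significant_nominal))
})

test_that("common-variant selection applies the case-MAF >= 0.1 rule", {
  subjects <- c(sprintf("CA%02d", 1:20), sprintf("CO%02d", 1:20))
  ph <- tibble::tibble(
    subject_id = subjects,
    status = rep(c("case", "control"), each = 20),
    sex = "female", family_history = "no", ectodermal_features = FALSE,
    missing_teeth = c(replicate(20, 12L, simplify = FALSE),
                      replicate(20, integer(0), simplify = FALSE)),
    peg_shaped = replicate(40, integer(0), simplify = FALSE)
  )
  geno <- function(gene, dna, carriers) {
    tibble::tibble(subject_id = carriers, gene = gene, dna_change = dna,
                   zygosity = "HET", key = variant_key(gene, dna))
  }
  # 4 HET / 40 case alleles = 0.1 exactly -> included; 3/40 -> excluded
  g <- rbind(geno("PAX9", "c.1C>T", sprintf("CA%02d", 1:4)),
             geno("MSX1", "c.2C>T", sprintf("CA%02d", 1:3)))
  sel <- select_common(g, ph)
  expect_equal(sel$key, variant_key("PAX9", "c.1C>T"))
  expect_equal(sel$maf_cases, 0.1)
})

test_that("trend scan flags the case-enriched variant and excludes X markers", {
  sim <- simulate_cohort(simulation_config(seed = 302))
  expect_warning(
    scan <- trend_scan(sim$genotypes, sim$phenotypes, sim$panel),
    "X-linked"
  )
  focal <- scan[scan$key == sim$truth$focal$key, ]
  expect_equal(nrow(focal), 1)
  expect_gt(focal$maf_cases, focal$maf_controls)
  expect_equal(focal$risk_allele, "alt")
  expect_true(focal$significant_bonferroni)
  expect_true(all(scan$ci_low <= scan$odds_ratio &
                    scan$odds_ratio <= scan$ci_high))
  expect_true(all(scan$p_trend > 0 & scan$p_trend <= 1))
  expect_true(all(!scan$significant_bonferroni | scan$significant_nominal))
  # no X-linked marker slipped through
  xg <- sim$panel$gene[sim$panel$x_linked]
  expect_false(any(sub(":.*", "", scan$key) %in% xg))
  # empty input gives an empty result
  empty <- trend_scan(sim$genotypes[0, ], sim$phenotypes)
  expect_equal(nrow(empty), 0)
})

test_that("diluting both groups with non-carriers never inflates a null chi2", {
  set.seed(9)
  for (i in 1:5) {
    base <- c(sample(10:40, 1), sample(5:20, 1), sample(1:8, 1))
    r <- base; s <- base              # identical groups -> null
    chi0 <- cochran_armitage(r, s)$chi2
    rd <- r + c(50, 0, 0); sd <- s + c(50, 0, 0)
    expect_lte(cochran_armitage(rd, sd)$chi2, chi0 + 1e-9)
  }
})
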