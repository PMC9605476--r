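#' Minor allele frequency from genotype counts
#'
#' For an autosomal marker with genotype counts `g = c(n0, n1, n2)` (0, 1, 2
#' copies of the counted allele) the allele frequency is
#' `(n1 + 2 n2) / (2 N)`. Hemizygous male carriers of an X-linked marker
#' contribute a single allele to both numerator and denominator via
#' `hemi_carriers` (carriers of the counted allele) and `hemi_total`
#' (hemizygous subjects).
#'
#' @param g integer vector `c(n0, n1, n2)` of genotype counts.
#' @param hemi_carriers hemizygous carriers of the counted allele (default 0).
#' @param hemi_total hemizygous subjects in the group (default 0).
#' @return allele frequency in \[0, 1\].
#' @examples
#' allele_frequency(c(50, 8, 7))   # 22/130
#' @export
allele_frequency <- function(g, hemi_carriers = 0, hemi_total = 0) {
  stopifnot(length(g) == 3, all(g >= 0), hemi_carriers >= 0,
            hemi_carriers <= hemi_total)
  denom <- 2 * sum(g) + hemi_total
  if (denom == 0) stop("empty group: allele frequency undefined", call. = FALSE)
  (g[2] + 2 * g[3] + hemi_carriers) / denom
}

#' Genotype counts of one variant from genotype calls
#'
#' Tallies case and control genotype classes (0/1/2 copies) for one variant
#' from a genotype-call table; subjects without a call carry zero copies.
#' HEMI calls are tallied separately.
#'
#' @param key a [variant_key()].
#' @param genotypes genotype tibble.
#' @param phenotypes phenotype tibble giving case/control status.
#' @return list with `cases` and `controls` (each `c(n0, n1, n2)`),
#'   `hemi_cases`, `hemi_controls`.
#' @export
genotype_counts <- function(key, genotypes, phenotypes) {
  g <- genotypes[genotypes$key == key, , drop = FALSE]
  copies <- stats::setNames(
    ifelse(g$zygosity == "HOM", 2L, 1L)[g$zygosity != "HEMI"],
    g$subject_id[g$zygosity != "HEMI"]
  )
  hemi <- g$subject_id[g$zygosity == "HEMI"]
  tally <- function(status) {
    subj <- phenotypes$subject_id[phenotypes$status == status]
    subj <- setdiff(subj, hemi)
    cp <- copies[subj]
    cp[is.na(cp)] <- 0L
    c(sum(cp == 0), sum(cp == 1), sum(cp == 2))
  }
  list(
    cases = tally("case"),
    controls = tally("control"),
    hemi_cases = sum(hemi %in% phenotypes$subject_id[phenotypes$status == "case"]),
    hemi_controls = sum(hemi %in% phenotypes$subject_id[phenotypes$status == "control"])
  )
}

#' Select common variants by case-group frequency
#'
#' Keeps variants whose minor allele frequency in the case group is at least
#' `maf_min` (default 0.1); the selected count feeds the multiplicity plan.
#'
#' @param genotypes genotype tibble.
#' @param phenotypes phenotype tibble.
#' @param maf_min case-group frequency threshold, `>=` (default 0.1).
#' @param keys candidate variant keys (default: all in `genotypes`).
#' @return tibble with columns `key` and `maf_cases` for selected variants.
#' @export
select_common <- function(genotypes, phenotypes, maf_min = 0.1, keys = NULL) {
  if (is.null(keys)) keys <- sort(unique(genotypes$key))
  maf <- vapply(keys, function(k) {
    ct <- genotype_counts(k, genotypes, phenotypes)
    allele_frequency(ct$cases, ct$hemi_cases, ct$hemi_cases)
  }, numeric(1))
  keep <- maf >= maf_min
  tibble::tibble(key = keys[keep], maf_cases = unname(maf[keep]))
}

#' Cochran-Armitage trend test
#'
#' Closed-form one-degree-of-freedom chi-square test for a linear trend in
#' case proportion across ordered genotype classes. With case counts
#' `r = (r0, r1, r2)`, control counts `s`, column totals `n_i = r_i + s_i`,
#' `R = sum(r)`, `N = R + S` and scores `w`:
#' \deqn{\chi^2 = \frac{N\,(N \sum_i w_i r_i - R \sum_i w_i n_i)^2}
#'   {R\,(N-R)\,(N \sum_i w_i^2 n_i - (\sum_i w_i n_i)^2)}}
#' The p-value is the upper tail of the chi-square distribution with 1 df.
#' The statistic is invariant under affine transformations of the scores and
#' under swapping the case/control labels. A degenerate table (all subjects
#' in one genotype class) has zero trend variance and returns chi2 = 0,
#' p = 1.
#'
#' @param r case genotype counts `c(r0, r1, r2)`.
#' @param s control genotype counts `c(s0, s1, s2)`.
#' @param scores genotype scores (default additive `c(0, 1, 2)`).
#' @return list with `chi2` and `p`.
#' @examples
#' cochran_armitage(c(50, 8, 7), c(126, 1, 0))
#' @export
cochran_armitage <- function(r, s, scores = c(0, 1, 2)) {
  stopifnot(length(r) == length(s), length(r) == length(scores))
  if (any(r < 0) || any(s < 0)) {
    stop("genotype counts must be non-negative", call. = FALSE)
  }
  R <- sum(r)
  S <- sum(s)
  if (R == 0 || S == 0) stop("both groups must be non-empty", call. = FALSE)
  n <- r + s
  N <- R + S
  num <- N * sum(scores * r) - R * sum(scores * n)
  var_term <- N * sum(scores^2 * n) - sum(scores * n)^2
  if (var_term <= 0) return(list(chi2 = 0, p = 1))
  chi2 <- N * num^2 / (R * (N - R) * var_term)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Allelic odds ratio with Woolf confidence interval
#'
#' For the 2x2 allele table (a = minor, b = major alleles in cases; c, d in
#' controls) the odds ratio is `(a d)/(b c)` with the Woolf log-scale
#' interval `exp(log(OR) +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell
#' triggers the Haldane-Anscombe correction (0.5 added to all four cells),
#' flagged in the output.
#'
#' @param a,b minor/major allele counts in cases.
#' @param c,d minor/major allele counts in controls.
#' @param conf confidence level (default 0.95).
#' @return list with `or`, `ci_low`, `ci_high`, `corrected` (logical) and
#'   `method`.
#' @examples
#' allelic_odds_ratio(21, 109, 1, 253)
#' @export
allelic_odds_ratio <- function(a, b, c, d, conf = 0.95) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b == 0 || c + d == 0) {
    stop("both groups need at least one counted allele", call. = FALSE)
  }
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       corrected = corrected,
       method = "Woolf log-scale CI; Haldane-Anscombe 0.5 correction on zero cells")
}

#' Bonferroni multiplicity plan
#'
#' @param alpha family-wise significance level (default 0.05).
#' @param m number of tests.
#' @return list with `alpha`, `m` and the per-test `threshold = alpha / m`.
#' @examples
#' multiplicity_plan(0.05, 29)$threshold
#' @export
multiplicity_plan <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  list(alpha = alpha, m = as.integer(m), threshold = alpha / m)
}

#' Flag nominal and Bonferroni significance
#'
#' @param p vector of p-values.
#' @param plan a [multiplicity_plan()].
#' @return tibble with `significant_nominal` (`p < alpha`) and
#'   `significant_bonferroni` (`p < alpha/m`).
#' @export
flag_significance <- function(p, plan) {
  tibble::tibble(
    significant_nominal = p < plan$alpha,
    significant_bonferroni = p < plan$threshold
  )
}

#' Common-variant case-control scan
#'
#' For every common variant (case MAF at or above `maf_min`): genotype
#' counts per group, Cochran-Armitage trend test, allelic odds ratio with
#' confidence interval, the case-enriched risk allele, and nominal plus
#' Bonferroni significance flags (the Bonferroni denominator is the number
#' of tested variants). X-linked markers are excluded with a warning when a
#' panel is supplied: additive genotype scores are ill-defined for
#' hemizygotes.
#'
#' @param genotypes genotype tibble.
#' @param phenotypes phenotype tibble.
#' @param panel optional panel tibble used to drop X-linked markers.
#' @param alpha family-wise significance level (default 0.05).
#' @param maf_min case-group frequency threshold (default 0.1).
#' @param keys candidate variant keys (default: all in `genotypes`).
#' @return tibble with one row per tested variant: `key`, `maf_cases`,
#'   `maf_controls`, `risk_allele` (`"alt"` when the called allele is
#'   case-enriched, else `"ref"`), `chi2`, `p_trend`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `or_corrected`, `significant_nominal`,
#'   `significant_bonferroni`; the multiplicity plan is attached as the
#'   `"plan"` attribute.
#' @export
trend_scan <- function(genotypes, phenotypes, panel = NULL, alpha = 0.05,
                       maf_min = 0.1, keys = NULL) {
  if (is.null(keys)) keys <- sort(unique(genotypes$key))
  if (!is.null(panel)) {
    gene_of <- sub(":.*$", "", keys)
    xg <- panel$gene[panel$x_linked]
    drop <- gene_of %in% xg
    if (any(drop)) {
      warning(sum(drop), " X-linked marker(s) excluded from the trend scan ",
              "(genotype scores are ill-defined for hemizygotes)",
              call. = FALSE)
      keys <- keys[!drop]
    }
  }
  rows <- lapply(keys, function(k) {
    ct <- genotype_counts(k, genotypes, phenotypes)
    maf_ca <- allele_frequency(ct$cases)
    maf_co <- allele_frequency(ct$controls)
    if (maf_ca < maf_min) return(NULL)
    tt <- cochran_armitage(ct$cases, ct$controls)
    a <- ct$cases[2] + 2 * ct$cases[3]
    b <- 2 * sum(ct$cases) - a
    cc <- ct$controls[2] + 2 * ct$controls[3]
    dd <- 2 * sum(ct$controls) - cc
    or <- allelic_odds_ratio(a, b, cc, dd)
    tibble::tibble(
      key = k, maf_cases = maf_ca, maf_controls = maf_co,
      risk_allele = ifelse(maf_ca >= maf_co, "alt", "ref"),
      chi2 = tt$chi2, p_trend = tt$p,
      odds_ratio = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
      or_corrected = or$corrected
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0) {
    tibble::tibble(key = character(), maf_cases = numeric(),
                   maf_controls = numeric(), risk_allele = character(),
                   chi2 = numeric(), p_trend = numeric(),
                   odds_ratio = numeric(), ci_low = numeric(),
                   ci_high = numeric(), or_corrected = logical())
  } else {
    dplyr::bind_rows(rows)
  }
  plan <- multiplicity_plan(alpha, max(1L, nrow(out)))
  sig <- flag_significance(out$p_trend, plan)
  out$significant_nominal <- sig$significant_nominal
  out$significant_bonferroni <- sig$significant_bonferroni
  attr(out, "plan") <- plan
  out
}
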