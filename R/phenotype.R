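#' Count a subject's missing permanent teeth
#'
#' Counts the missing-teeth set of each phenotype record, by default
#' excluding third molars (positions 18/28/38/48) as every cohort summary in
#' this package does. Peg-shaped teeth are present teeth and never counted.
#'
#' @param phenotypes phenotype tibble ([read_phenotype_table()]).
#' @param exclude_third_molars drop positions 8 before counting (default TRUE).
#' @return integer vector, one count per record.
#' @examples
#' ph <- read_phenotype_table(ps_fixture("table34_phenotypes.tsv"))
#' count_missing(ph)[ph$subject_id == "TA_20"]
#' @export
count_missing <- function(phenotypes, exclude_third_molars = TRUE) {
  vapply(phenotypes$missing_teeth, function(teeth) {
    if (exclude_third_molars && length(teeth) > 0) {
      teeth <- teeth[!is_third_molar(teeth)]
    }
    length(teeth)
  }, integer(1))
}

#' Classify agenesis severity
#'
#' Hypodontia is agenesis of 1-5 permanent teeth and oligodontia of 6 or
#' more, third molars excluded in the count; a count of zero is no agenesis.
#'
#' @param count third-molar-excluded missing-teeth count(s).
#' @return character vector over \{none, hypodontia, oligodontia\}.
#' @examples
#' classify_agenesis(c(0, 5, 6))
#' @export
classify_agenesis <- function(count) {
  stopifnot(all(count >= 0))
  ifelse(count == 0, "none", ifelse(count <= 5, "hypodontia", "oligodontia"))
}

.empty_summary <- function() {
  structure(
    list(n_subjects = 0L, total_missing = 0L, mean_missing = NA_real_,
         min_missing = NA_integer_, max_missing = NA_integer_,
         n_hypodontia = 0L, n_oligodontia = 0L,
         per_tooth_class = tibble::tibble(tooth_class = character(),
                                          n = integer(), fraction = numeric()),
         per_jaw = tibble::tibble(jaw = character(), n = integer())),
    class = "phenotype_summary"
  )
}

.summarize_phenotypes <- function(phenotypes, exclude_third_molars = TRUE) {
  if (nrow(phenotypes) == 0) return(.empty_summary())
  counts <- count_missing(phenotypes, exclude_third_molars)
  teeth <- unlist(phenotypes$missing_teeth, use.names = FALSE)
  if (exclude_third_molars && length(teeth) > 0) {
    teeth <- teeth[!is_third_molar(teeth)]
  }
  cls <- factor(tooth_class(teeth), levels = .tooth_classes)
  tab <- table(cls)
  per_class <- tibble::tibble(
    tooth_class = names(tab),
    n = as.integer(tab),
    fraction = if (sum(tab) > 0) as.integer(tab) / sum(tab) else
      rep(0, length(tab))
  )
  jaw <- ifelse(is_maxillary(teeth), "maxillary", "mandibular")
  jtab <- table(factor(jaw, levels = c("maxillary", "mandibular")))
  structure(
    list(n_subjects = nrow(phenotypes),
         total_missing = sum(counts),
         mean_missing = mean(counts),
         min_missing = min(counts),
         max_missing = max(counts),
         n_hypodontia = sum(classify_agenesis(counts) == "hypodontia"),
         n_oligodontia = sum(classify_agenesis(counts) == "oligodontia"),
         per_tooth_class = per_class,
         per_jaw = tibble::tibble(jaw = names(jtab), n = as.integer(jtab))),
    class = "phenotype_summary"
  )
}

#' @export
print.phenotype_summary <- function(x, ...) {
  cat(sprintf("Dentition summary over %d subject(s)\n", x$n_subjects))
  if (x$n_subjects > 0) {
    cat(sprintf("  total missing %d; mean %.2f; range %d-%d\n",
                x$total_missing, x$mean_missing, x$min_missing, x$max_missing))
    cat(sprintf("  hypodontia %d; oligodontia %d\n",
                x$n_hypodontia, x$n_oligodontia))
  }
  invisible(x)
}

#' Cohort tooth-class distribution
#'
#' Pools missing teeth over all case records and tallies them per tooth
#' class (quadrants mirrored: 12, 22, 32 and 42 all count as lateral
#' incisors), with fractions of the total. The maxillary/mandibular split is
#' exposed alongside but the class counts pool both jaws.
#'
#' @param phenotypes phenotype tibble; control records (empty sets)
#'   contribute nothing.
#' @param exclude_third_molars drop third molars first (default TRUE).
#' @return a `phenotype_summary` (see [carrier_phenotype_summary()]).
#' @examples
#' ph <- read_phenotype_table(ps_fixture("table34_phenotypes.tsv"))
#' tooth_class_distribution(ph)
#' @export
tooth_class_distribution <- function(phenotypes, exclude_third_molars = TRUE) {
  .summarize_phenotypes(phenotypes[phenotypes$status == "case", , drop = FALSE],
                        exclude_third_molars)
}

#' Dentition summary of variant carriers
#'
#' Summarizes the missing-teeth phenotype over subjects carrying any variant
#' selected by gene symbol(s) or variant key(s). In `exclusive` mode the
#' summary is restricted to subjects whose *only* retained variants match
#' the selector (e.g. subjects carrying one recurrent variant and nothing
#' else); supply `retained` to define the retained universe, which defaults
#' to every key present in `genotypes`. An empty selection returns an
#' explicit empty summary, not an error.
#'
#' @param phenotypes phenotype tibble.
#' @param genotypes genotype tibble.
#' @param genes character vector of gene symbols to select (optional).
#' @param variants character vector of [variant_key()]s to select (optional).
#' @param exclusive restrict to subjects all of whose retained variants match
#'   the selector (default FALSE).
#' @param retained character vector of retained keys defining the universe
#'   for `exclusive` mode.
#' @param exclude_third_molars drop third molars from counts (default TRUE).
#' @return a `phenotype_summary`: subject count, total/mean/min/max missing
#'   teeth, hypodontia/oligodontia tallies, per-tooth-class counts and
#'   fractions and the per-jaw split.
#' @examples
#' ph <- read_phenotype_table(ps_fixture("table34_phenotypes.tsv"))
#' g <- read_genotypes(ps_fixture("table34_genotypes.tsv"))
#' carrier_phenotype_summary(ph, g, genes = "WNT10A")
#' @export
carrier_phenotype_summary <- function(phenotypes, genotypes, genes = NULL,
                                      variants = NULL, exclusive = FALSE,
                                      retained = NULL,
                                      exclude_third_molars = TRUE) {
  sel <- rep(FALSE, nrow(genotypes))
  if (!is.null(genes)) sel <- sel | genotypes$gene %in% genes
  if (!is.null(variants)) sel <- sel | genotypes$key %in% variants
  carriers <- unique(genotypes$subject_id[sel])
  if (exclusive) {
    universe <- if (is.null(retained)) unique(genotypes$key) else retained
    rg <- genotypes[genotypes$key %in% universe, , drop = FALSE]
    only_sel <- vapply(carriers, function(s) {
      subj_keys <- rg$key[rg$subject_id == s]
      all(subj_keys %in% genotypes$key[sel])
    }, logical(1))
    carriers <- carriers[only_sel]
  }
  .summarize_phenotypes(
    phenotypes[phenotypes$subject_id %in% carriers, , drop = FALSE],
    exclude_third_molars
  )
}

#' Family-history rate
#'
#' Fraction of subjects reporting a positive family history of tooth
#' agenesis. Subjects with unknown family history remain in the denominator
#' (the rate is yes / all subjects, not yes / known).
#'
#' @param phenotypes phenotype tibble (or a subset of its rows).
#' @return list with `n_yes`, `n_known`, `n_subjects` and `fraction`.
#' @examples
#' ph <- read_phenotype_table(ps_fixture("table34_phenotypes.tsv"))
#' family_history_rate(ph)
#' @export
family_history_rate <- function(phenotypes) {
  n_yes <- sum(phenotypes$family_history == "yes")
  n_known <- sum(phenotypes$family_history != "unknown")
  n <- nrow(phenotypes)
  list(n_yes = n_yes, n_known = n_known, n_subjects = n,
       fraction = if (n > 0) n_yes / n else 0)
}

#' Fraction of subjects carrying any listed variant
#'
#' @param genotypes genotype tibble.
#' @param n_total cohort size used as the denominator.
#' @param keys restrict to these variant keys (default: all calls).
#' @return list with `n_carriers`, `n_total`, `fraction`.
#' @export
carrier_rate <- function(genotypes, n_total, keys = NULL) {
  g <- if (is.null(keys)) genotypes else
    genotypes[genotypes$key %in% keys, , drop = FALSE]
  n_car <- length(unique(g$subject_id))
  list(n_carriers = n_car, n_total = n_total, fraction = n_car / n_total)
}

#' Detect oligogenic variant co-occurrence
#'
#' Reports every subject carrying two or more retained variants, the
#' defining signature of a possible oligogenic (multilocus) contribution.
#' Co-occurrence across two or more distinct genes is `cross_gene`; several
#' variants of a single gene (e.g. compound heterozygotes) are
#' `same_gene_multi`.
#'
#' @param retained character vector of retained [variant_key()]s (see
#'   [retained_keys()]).
#' @param genotypes genotype tibble.
#' @return tibble with columns subject_id, n_variants, n_genes, `variants`
#'   (list-column of keys) and `kind`.
#' @examples
#' g <- read_genotypes(ps_fixture("table34_genotypes.tsv"))
#' detect_oligogenic(unique(g$key), g)
#' @export
detect_oligogenic <- function(retained, genotypes) {
  rg <- genotypes[genotypes$key %in% retained, , drop = FALSE]
  if (nrow(rg) == 0) {
    return(tibble::tibble(subject_id = character(), n_variants = integer(),
                          n_genes = integer(), variants = list(),
                          kind = character()))
  }
  per_subject <- split(rg, rg$subject_id)
  multi <- per_subject[vapply(per_subject, nrow, integer(1)) >= 2]
  out <- tibble::tibble(
    subject_id = names(multi),
    n_variants = vapply(multi, nrow, integer(1)),
    n_genes = vapply(multi, function(d) length(unique(d$gene)), integer(1)),
    variants = lapply(multi, function(d) sort(d$key)),
    kind = vapply(multi, function(d) {
      if (length(unique(d$gene)) >= 2) "cross_gene" else "same_gene_multi"
    }, character(1))
  )
  out[order(out$subject_id), ]
}
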