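#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

#' Prediction tools scored by the consensus vote
#'
#' The fixed, ordered set of 16 in-silico pathogenicity predictors whose
#' verdicts the annotated variant table carries, in the order used
#' throughout: MutationTaster, FATHMM, FATHMM-MKL, FATHMM-XF, LRT, DEOGEN2,
#' EIGEN, EIGEN PC, SIFT, SIFT4G, PROVEAN, MVP, REVEL, PrimateAI, MetaSVM,
#' MetaLR.
#'
#' @return character vector of length 16 (column names in variant tables).
#' @export
prediction_tools <- function() {
  c("MutationTaster", "FATHMM", "FATHMM_MKL", "FATHMM_XF", "LRT", "DEOGEN2",
    "EIGEN", "EIGEN_PC", "SIFT", "SIFT4G", "PROVEAN", "MVP", "REVEL",
    "PrimateAI", "MetaSVM", "MetaLR")
}

.verdict_tokens <- c("B", "D", "Dc", "N", "P", "T")
.consequences <- c("missense", "stop_gain", "stop_loss", "frameshift",
                   "splicing", "synonymous", "other")

#' Path to a packaged fixture table
#'
#' The package ships plain-text TSV encodings of the study tables it
#' reproduces: the 27-variant annotation table (`table2_variants.tsv`), the
#' case dentition grids and genotype calls (`table34_phenotypes.tsv`,
#' `table34_genotypes.tsv`), the gene panel metadata (`gene_panel.tsv`), the
#' control-screen inputs (`control_genotypes.tsv`,
#' `control_variants_synthetic.tsv`), the common-variant scan
#' (`table5_common.tsv`) and the cohort characteristics summary
#' (`table1_characteristics.tsv`).
#'
#' @param file fixture file name; with no argument, lists available fixtures.
#' @return an absolute path (or a character vector of file names).
#' @examples
#' ps_fixture()
#' head(readLines(ps_fixture("gene_panel.tsv")), 3)
#' @export
ps_fixture <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "panelscreen")))
  }
  path <- system.file("extdata", file, package = "panelscreen")
  if (identical(path, "")) {
    stop("no packaged fixture named '", file, "'", call. = FALSE)
  }
  path
}

#' Compose the canonical variant key
#'
#' Variants are identified throughout by the pair (gene symbol, HGVS DNA
#' change), collapsed into a single string for joins and set operations.
#'
#' @param gene gene symbol.
#' @param dna_change HGVS c. description.
#' @return character vector of keys, `"GENE:c.change"`.
#' @export
variant_key <- function(gene, dna_change) {
  paste(gene, dna_change, sep = ":")
}

.read_tsv <- function(path, ...) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character(), progress = FALSE, ...)
}

.parse_num <- function(x, what, lo = -Inf, hi = Inf) {
  out <- rep(NA_real_, length(x))
  has <- !is.na(x) & x != ""
  val <- suppressWarnings(as.numeric(x[has]))
  if (anyNA(val)) {
    bad <- which(has)[which(is.na(val))[1]]
    stop("malformed ", what, " value '", x[bad], "' in row ", bad, call. = FALSE)
  }
  if (any(val < lo | val > hi)) {
    bad <- which(has)[which(val < lo | val > hi)[1]]
    stop(what, " out of range [", lo, ",", hi, "] in row ", bad, call. = FALSE)
  }
  out[has] <- val
  out
}

.parse_verdict_cell <- function(cell, row, col) {
  if (is.na(cell) || cell == "") return(character(0))
  tokens <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
  bad <- setdiff(tokens, .verdict_tokens)
  if (length(bad) > 0) {
    stop("unknown verdict token '", bad[1], "' in row ", row,
         ", column ", col, call. = FALSE)
  }
  tokens
}

#' Read an annotated variant table
#'
#' Reads a TSV with one row per panel variant carrying the annotations the
#' filtering cascade consumes: gene, HGVS c./p., consequence class, gnomAD
#' non-Finnish-European allele frequency (`af_nfe`), CADD phred score, ADA
#' splice score, the 16 per-tool pathogenicity verdicts (one column per tool,
#' see [prediction_tools()]) and the ClinVar/HGMD annotation flags. Empty
#' cells are a distinct *absent* state (`NA` scalar / empty verdict set) and
#' are never coerced to 0 -- the filter stage decides what absence means.
#' Verdict cells may hold several comma-separated tokens ("T, D"); these
#' become token sets.
#'
#' @param path TSV file path.
#' @return a tibble with one row per variant; scalar annotation columns plus
#'   a `verdicts` list-column of 16-element token-set lists and a `key`
#'   column from [variant_key()].
#' @examples
#' v <- read_variant_table(ps_fixture("table2_variants.tsv"))
#' nrow(v)
#' v$verdicts[[1]][1:3]
#' @export
read_variant_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- .read_tsv(path)
  tools <- prediction_tools()
  need <- c("gene", "dna_change", "protein_change", "consequence", tools)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("variant table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_cons <- setdiff(unique(raw$consequence), .consequences)
  if (length(bad_cons) > 0) {
    stop("unknown consequence class '", bad_cons[1], "'", call. = FALSE)
  }
  opt <- function(col) if (col %in% names(raw)) raw[[col]] else rep("", nrow(raw))
  verdicts <- lapply(seq_len(nrow(raw)), function(i) {
    vr <- lapply(tools, function(tl) .parse_verdict_cell(raw[[tl]][i], i, tl))
    names(vr) <- tools
    vr
  })
  tibble(
    gene = raw$gene,
    rs_id = ifelse(opt("rs_id") == "", NA_character_, opt("rs_id")),
    dna_change = raw$dna_change,
    protein_change = raw$protein_change,
    protein_domain = ifelse(opt("protein_domain") == "", NA_character_,
                            opt("protein_domain")),
    consequence = raw$consequence,
    af_nfe = .parse_num(opt("af_nfe"), "frequency", 0, 1),
    ada = .parse_num(opt("ada"), "ADA score", 0, 1),
    cadd = .parse_num(opt("cadd"), "CADD score", 0),
    verdicts = verdicts,
    db_pathogenic = toupper(opt("db_pathogenic")) %in% c("TRUE", "T", "1", "YES"),
    db_note = ifelse(opt("db_note") == "", NA_character_, opt("db_note")),
    key = variant_key(raw$gene, raw$dna_change)
  )
}

#' Write an annotated variant table
#'
#' Inverse of [read_variant_table()]: absent values become empty cells and
#' verdict token sets are re-joined with `","`, so a read/write round trip is
#' cell-for-cell lossless.
#'
#' @param variants tibble as returned by [read_variant_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  tools <- prediction_tools()
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  out <- data.frame(
    gene = variants$gene,
    rs_id = fmt(variants$rs_id),
    dna_change = variants$dna_change,
    protein_change = variants$protein_change,
    protein_domain = fmt(variants$protein_domain),
    consequence = variants$consequence,
    af_nfe = fmt(variants$af_nfe),
    ada = fmt(variants$ada),
    cadd = fmt(variants$cadd),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (tl in tools) {
    out[[tl]] <- vapply(variants$verdicts, function(v) {
      paste(v[[tl]], collapse = ",")
    }, character(1))
  }
  out$db_pathogenic <- ifelse(variants$db_pathogenic, "TRUE", "FALSE")
  out$db_note <- fmt(variants$db_note)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

.parse_teeth <- function(cell, subject) {
  if (is.na(cell) || cell == "") return(integer(0))
  codes <- suppressWarnings(as.integer(trimws(strsplit(cell, ",")[[1]])))
  if (anyNA(codes) || !all(fdi_valid(codes))) {
    stop("invalid FDI tooth code in record '", subject, "': ", cell,
         call. = FALSE)
  }
  if (anyDuplicated(codes)) {
    warning("duplicate FDI codes for subject '", subject,
            "' collapsed", call. = FALSE)
    codes <- unique(codes)
  }
  sort(codes)
}

#' Read a cohort dentition/phenotype table
#'
#' One row per subject: case/control status, sex, family history
#' (yes/no/unknown), ectodermal-feature flag, and the missing and peg-shaped
#' teeth as comma-separated FDI codes. Enforced invariants: FDI codes are
#' valid, duplicates collapse with a warning, peg-shaped teeth are present
#' teeth (never also listed missing), cases have at least one missing
#' permanent tooth and controls none.
#'
#' @param path TSV file path.
#' @return tibble with list-columns `missing_teeth` and `peg_shaped`
#'   (sorted integer FDI vectors).
#' @examples
#' ph <- read_phenotype_table(ps_fixture("table34_phenotypes.tsv"))
#' ph$missing_teeth[[1]]
#' @export
read_phenotype_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- .read_tsv(path)
  need <- c("subject_id", "status", "sex", "family_history", "missing_teeth")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("phenotype table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(raw$status %in% c("case", "control"))) {
    stop("status must be 'case' or 'control'", call. = FALSE)
  }
  if (!all(raw$family_history %in% c("yes", "no", "unknown"))) {
    stop("family_history must be yes/no/unknown", call. = FALSE)
  }
  peg_col <- if ("peg_shaped" %in% names(raw)) raw$peg_shaped else
    rep("", nrow(raw))
  ecto <- if ("ectodermal_features" %in% names(raw)) {
    toupper(raw$ectodermal_features) %in% c("TRUE", "T", "1", "YES")
  } else rep(FALSE, nrow(raw))
  missing_teeth <- mapply(.parse_teeth, raw$missing_teeth, raw$subject_id,
                          SIMPLIFY = FALSE, USE.NAMES = FALSE)
  peg_shaped <- mapply(.parse_teeth, peg_col, raw$subject_id,
                       SIMPLIFY = FALSE, USE.NAMES = FALSE)
  for (i in seq_len(nrow(raw))) {
    overlap <- intersect(missing_teeth[[i]], peg_shaped[[i]])
    if (length(overlap) > 0) {
      stop("subject '", raw$subject_id[i], "' lists tooth ", overlap[1],
           " as both missing and peg-shaped (a peg-shaped tooth is present)",
           call. = FALSE)
    }
    n_excl <- sum(!is_third_molar(missing_teeth[[i]]))
    if (raw$status[i] == "case" && n_excl == 0) {
      stop("case '", raw$subject_id[i], "' has no missing permanent teeth ",
           "(inclusion requires agenesis of at least one, third molars excluded)",
           call. = FALSE)
    }
    if (raw$status[i] == "control" && length(missing_teeth[[i]]) > 0) {
      stop("control '", raw$subject_id[i], "' has missing teeth; controls ",
           "must have all permanent teeth present", call. = FALSE)
    }
    if (n_excl > 28) {
      stop("subject '", raw$subject_id[i],
           "' has more than 28 non-third-molar missing teeth", call. = FALSE)
    }
  }
  tibble(
    subject_id = raw$subject_id,
    status = raw$status,
    sex = raw$sex,
    family_history = raw$family_history,
    ectodermal_features = ecto,
    missing_teeth = missing_teeth,
    peg_shaped = peg_shaped
  )
}

#' Read the gene-panel metadata table
#'
#' Gene symbol, chromosome, prioritization category (`known_ta` for
#' established tooth-agenesis risk genes, `odontogenesis` for genes with a
#' documented role in tooth development, `other`) and the gnomAD pLi score
#' where available. X-linkage is derived from the chromosome column.
#'
#' @param path TSV file path.
#' @return tibble with columns gene, chromosome, x_linked, category, pli.
#' @export
read_panel <- function(path) {
  stopifnot(file.exists(path))
  raw <- .read_tsv(path)
  need <- c("gene", "chromosome", "category")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("panel table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(raw$category %in% c("known_ta", "odontogenesis", "other"))) {
    stop("panel category must be known_ta/odontogenesis/other", call. = FALSE)
  }
  pli <- if ("pli" %in% names(raw)) {
    .parse_num(raw$pli, "pLi score", 0, 1)
  } else rep(NA_real_, nrow(raw))
  tibble(
    gene = raw$gene,
    chromosome = raw$chromosome,
    x_linked = raw$chromosome == "X",
    category = raw$category,
    pli = pli
  )
}

#' Read a genotype-call table
#'
#' One row per (subject, variant) with zygosity HET, HOM or HEMI. When panel
#' and phenotype tables are supplied, hemizygous calls are validated: HEMI is
#' only legal for X-linked genes in male subjects, and duplicated
#' (subject, variant) pairs are an error.
#'
#' @param path TSV file path.
#' @param panel optional panel tibble from [read_panel()] for X-linkage checks.
#' @param phenotypes optional phenotype tibble from [read_phenotype_table()]
#'   supplying subject sex.
#' @return tibble with columns subject_id, gene, dna_change, zygosity, key.
#' @examples
#' g <- read_genotypes(ps_fixture("table34_genotypes.tsv"),
#'                     panel = read_panel(ps_fixture("gene_panel.tsv")),
#'                     phenotypes = read_phenotype_table(
#'                       ps_fixture("table34_phenotypes.tsv")))
#' head(g, 3)
#' @export
read_genotypes <- function(path, panel = NULL, phenotypes = NULL) {
  stopifnot(file.exists(path))
  raw <- .read_tsv(path)
  need <- c("subject_id", "gene", "dna_change", "zygosity")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("genotype table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(raw$zygosity %in% c("HET", "HOM", "HEMI"))) {
    stop("zygosity must be HET, HOM or HEMI", call. = FALSE)
  }
  out <- tibble(
    subject_id = raw$subject_id,
    gene = raw$gene,
    dna_change = raw$dna_change,
    zygosity = raw$zygosity,
    key = variant_key(raw$gene, raw$dna_change)
  )
  dup <- duplicated(paste(out$subject_id, out$key))
  if (any(dup)) {
    stop("duplicate genotype call for subject '", out$subject_id[dup][1],
         "', variant ", out$key[dup][1], call. = FALSE)
  }
  validate_genotypes(out, panel, phenotypes)
  out
}

#' Validate hemizygous genotype calls
#'
#' @param genotypes genotype tibble.
#' @param panel optional panel tibble (X-linkage).
#' @param phenotypes optional phenotype tibble (subject sex).
#' @return `genotypes`, invisibly; errors on an illegal HEMI call.
#' @export
validate_genotypes <- function(genotypes, panel = NULL, phenotypes = NULL) {
  hemi <- genotypes[genotypes$zygosity == "HEMI", , drop = FALSE]
  if (nrow(hemi) == 0) return(invisible(genotypes))
  if (!is.null(panel)) {
    xg <- panel$gene[panel$x_linked]
    bad <- setdiff(unique(hemi$gene), xg)
    if (length(bad) > 0) {
      stop("HEMI call for autosomal gene '", bad[1],
           "' (hemizygosity requires X-linkage)", call. = FALSE)
    }
  }
  if (!is.null(phenotypes)) {
    sex <- stats::setNames(phenotypes$sex, phenotypes$subject_id)
    subj_sex <- sex[hemi$subject_id]
    bad <- which(!is.na(subj_sex) & subj_sex != "male")
    if (length(bad) > 0) {
      stop("HEMI call for non-male subject '", hemi$subject_id[bad[1]], "'",
           call. = FALSE)
    }
  }
  invisible(genotypes)
}

#' Read a common-variant association table
#'
#' Reads the printed common-variant scan: per variant the case/control minor
#' allele frequencies (with their minor alleles, which can differ between
#' groups), the trend-test p-value and the allelic odds ratio with its 95%
#' confidence interval. The risk allele is derived as the allele enriched in
#' cases.
#'
#' @param path TSV file path.
#' @return tibble with one row per tested common variant.
#' @export
read_assoc_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- .read_tsv(path)
  need <- c("gene", "rs_id", "maf_cases", "maf_controls", "p_trend")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("association table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  opt <- function(col) if (col %in% names(raw)) raw[[col]] else
    rep("", nrow(raw))
  maf_cases <- .parse_num(raw$maf_cases, "frequency", 0, 1)
  maf_controls <- .parse_num(raw$maf_controls, "frequency", 0, 1)
  a_cases <- opt("minor_allele_cases")
  a_controls <- opt("minor_allele_controls")
  # The risk allele is the case-enriched allele. If both groups share a minor
  # allele, it is that allele when cases carry it more often, otherwise the
  # other one; when the minor allele differs between groups, the case minor
  # allele is the enriched one.
  risk <- ifelse(
    a_cases == a_controls,
    ifelse(maf_cases >= maf_controls, a_cases,
           ifelse(opt("allele1") == a_cases, opt("allele2"), opt("allele1"))),
    a_cases
  )
  tibble(
    gene = raw$gene,
    rs_id = raw$rs_id,
    protein_effect = opt("protein_effect"),
    maf_cases = maf_cases,
    maf_controls = maf_controls,
    risk_allele = risk,
    p_trend = .parse_num(raw$p_trend, "p-value", 0, 1),
    odds_ratio = .parse_num(opt("odds_ratio"), "odds ratio", 0),
    ci_low = .parse_num(opt("ci_low"), "CI bound", 0),
    ci_high = .parse_num(opt("ci_high"), "CI bound", 0)
  )
}

#' Write a plain tibble as TSV (absent values as empty cells)
#'
#' @param x data frame without list columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_plain <- function(x, path) {
  x <- as.data.frame(x)
  for (col in names(x)) {
    if (is.list(x[[col]])) {
      x[[col]] <- vapply(x[[col]], function(v) paste(v, collapse = ","),
                         character(1))
    }
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
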