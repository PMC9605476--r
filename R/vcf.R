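#' Import variants and genotypes from an annotated VCF
#'
#' Reads a VCF 4.x file whose INFO field carries per-variant annotations and
#' whose genotype columns carry GT calls, and converts it to the annotated
#' variant table and genotype-call table the pipeline consumes. Only
#' normalized bi-allelic records are accepted; multi-allelic records are an
#' error instructing the caller to pre-split them. 1-based VCF coordinates
#' are preserved as `chrom`/`pos` metadata columns. Diploid GT 0/1 (or 0|1)
#' maps to HET and 1/1 to HOM; a haploid GT of 1, or 1/1 on the X chromosome
#' in a male subject, maps to HEMI. Verdict columns are absent (VCFs do not
#' carry the per-tool token sets).
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @param field_map named list mapping variant-table columns (`gene`,
#'   `consequence`, `dna_change`, `protein_change`, `af_nfe`, `cadd`, `ada`,
#'   `rs_id`) to INFO keys; a mapped key missing from a record yields a
#'   warning and an absent value.
#' @param sex optional named character vector (`subject -> "male"/"female"`)
#'   used to call hemizygosity on the X chromosome.
#' @return list with `variants` (annotated variant tibble, plus
#'   `chrom`/`pos`) and `genotypes` (genotype-call tibble).
#' @export
from_vcf <- function(path,
                     field_map = list(gene = "GENE", consequence = "CSQ_CLASS",
                                      dna_change = "HGVSC",
                                      protein_change = "HGVSP",
                                      af_nfe = "AF_NFE", cadd = "CADD",
                                      ada = "ADA", rs_id = NULL),
                     sex = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("from_vcf() requires the vcfR package", call. = FALSE)
  }
  stopifnot(file.exists(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic VCF record found; pre-split records ",
         "(e.g. `bcftools norm -m -`) before import", call. = FALSE)
  }
  info_get <- function(key) {
    if (is.null(key)) return(rep(NA_character_, nrow(fix)))
    val <- vcfR::extract.info(vcf, element = key)
    if (all(is.na(val))) {
      warning("INFO field '", key, "' absent from VCF; values set absent",
              call. = FALSE)
    }
    val
  }
  gene <- info_get(field_map$gene)
  if (anyNA(gene)) {
    gene[is.na(gene)] <- paste0(fix$CHROM[is.na(gene)], "_",
                                fix$POS[is.na(gene)])
  }
  dna_change <- info_get(field_map$dna_change)
  if (anyNA(dna_change)) {
    i <- is.na(dna_change)
    dna_change[i] <- paste0("g.", fix$POS[i], fix$REF[i], ">", fix$ALT[i])
  }
  cons <- info_get(field_map$consequence)
  cons[is.na(cons) | !cons %in% .consequences] <- "other"
  num_info <- function(key, lo, hi) {
    v <- suppressWarnings(as.numeric(info_get(key)))
    v[!is.na(v) & (v < lo | v > hi)] <- NA_real_
    v
  }
  empty_verdicts <- stats::setNames(
    replicate(16, character(0), simplify = FALSE), prediction_tools())
  variants <- tibble::tibble(
    gene = gene,
    rs_id = ifelse(is.na(fix$ID) | fix$ID == ".", NA_character_, fix$ID),
    dna_change = dna_change,
    protein_change = ifelse(is.na(info_get(field_map$protein_change)), "",
                            info_get(field_map$protein_change)),
    protein_domain = NA_character_,
    consequence = cons,
    af_nfe = num_info(field_map$af_nfe, 0, 1),
    ada = num_info(field_map$ada, 0, 1),
    cadd = num_info(field_map$cadd, 0, Inf),
    verdicts = replicate(nrow(fix), empty_verdicts, simplify = FALSE),
    db_pathogenic = FALSE,
    db_note = NA_character_,
    key = variant_key(gene, dna_change),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS)
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")
  calls <- list()
  on_x <- sub("^chr", "", fix$CHROM) == "X"
  for (j in seq_len(ncol(gt))) {
    subj <- colnames(gt)[j]
    male <- !is.null(sex) && identical(unname(sex[subj]), "male")
    for (i in seq_len(nrow(gt))) {
      g <- gt[i, j]
      if (is.na(g)) next
      alleles <- strsplit(g, "[/|]")[[1]]
      n_alt <- sum(alleles == "1")
      if (n_alt == 0) next
      zyg <- if (length(alleles) == 1) {
        "HEMI"
      } else if (on_x[i] && male) {
        "HEMI"
      } else if (n_alt == 2) "HOM" else "HET"
      calls[[length(calls) + 1]] <- tibble::tibble(
        subject_id = subj, gene = variants$gene[i],
        dna_change = variants$dna_change[i], zygosity = zyg,
        key = variants$key[i]
      )
    }
  }
  genotypes <- if (length(calls) > 0) dplyr::bind_rows(calls) else
    tibble::tibble(subject_id = character(), gene = character(),
                   dna_change = character(), zygosity = character(),
                   key = character())
  list(variants = variants, genotypes = genotypes)
}
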