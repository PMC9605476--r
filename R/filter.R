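#' Configuration of the rare-variant filtering cascade
#'
#' Bundles every tunable threshold of the filtering/prioritization cascade.
#' Defaults encode the screening rules as applied in the study design this
#' package reproduces: variants are kept when rarer than `maf_threshold` in
#' the gnomAD non-Finnish-European population (strict `<`), genes in
#' `exempt_genes` bypass the strict criteria entirely (all their
#' non-synonymous variants are evaluated regardless of frequency or score,
#' flagged as allowlist retentions when they fail the strict rules), missense
#' variants are likely gene disrupting when CADD exceeds `cadd_threshold`
#' (strict `>`) *and* at least `vote_rule` of the available in-silico
#' verdicts call them damaging, splice variants when the ADA score reaches
#' `ada_threshold` (`>=`), and genes are prioritized by category or a pLi of
#' at least `pli_threshold`. `manual_exceptions` lists variant keys retained
#' by expert judgement despite failing the strict rules; they are flagged,
#' never silently mixed with strict passes.
#'
#' @param maf_threshold population-frequency cut-off, strict `<` (default 0.001).
#' @param exempt_genes character vector of allowlisted genes (default "WNT10A").
#' @param cadd_threshold CADD phred cut-off for missense variants, strict `>`
#'   (default 20).
#' @param ada_threshold ADA splice-score cut-off, `>=` (default 0.9).
#' @param vote_rule fraction of available verdicts that must be damaging,
#'   "at least" (default 1/2).
#' @param pli_threshold pLi prioritization cut-off, `>=` (default 0.95).
#' @param manual_exceptions character vector of [variant_key()] strings.
#' @return an object of class `cascade_config`.
#' @examples
#' cascade_config(manual_exceptions = variant_key("TP63", "c.1594C>G"))
#' @export
cascade_config <- function(maf_threshold = 0.001,
                           exempt_genes = "WNT10A",
                           cadd_threshold = 20,
                           ada_threshold = 0.9,
                           vote_rule = 0.5,
                           pli_threshold = 0.95,
                           manual_exceptions = character()) {
  stopifnot(
    is.numeric(maf_threshold), maf_threshold >= 0, maf_threshold <= 1,
    is.numeric(cadd_threshold), cadd_threshold >= 0,
    is.numeric(ada_threshold), ada_threshold >= 0, ada_threshold <= 1,
    is.numeric(vote_rule), vote_rule > 0, vote_rule <= 1,
    is.numeric(pli_threshold), pli_threshold >= 0, pli_threshold <= 1
  )
  structure(
    list(maf_threshold = maf_threshold,
         exempt_genes = as.character(exempt_genes),
         cadd_threshold = cadd_threshold,
         ada_threshold = ada_threshold,
         vote_rule = vote_rule,
         pli_threshold = pli_threshold,
         manual_exceptions = as.character(manual_exceptions)),
    class = "cascade_config"
  )
}

#' @export
print.cascade_config <- function(x, ...) {
  cat("Rare-variant cascade configuration\n")
  cat(sprintf("  MAF < %g (allowlist: %s)\n", x$maf_threshold,
              paste(x$exempt_genes, collapse = ", ")))
  cat(sprintf("  missense: CADD > %g and damaging vote >= %.3g of available tools\n",
              x$cadd_threshold, x$vote_rule))
  cat(sprintf("  splicing: ADA >= %g\n", x$ada_threshold))
  cat(sprintf("  prioritize: known_ta/odontogenesis category or pLi >= %g\n",
              x$pli_threshold))
  if (length(x$manual_exceptions) > 0) {
    cat("  manual exceptions:", paste(x$manual_exceptions, collapse = ", "), "\n")
  }
  invisible(x)
}

.damaging_tokens <- c("D", "Dc", "P")

#' Consensus vote over the 16 in-silico verdicts
#'
#' A tool's verdict counts as damaging when *any* of its tokens is in
#' {D, Dc, P} (damaging/deleterious, disease causing, pathogenic); B, N and T
#' (benign, neutral, tolerated) do not count. Tools without a verdict are
#' excluded from the denominator, so the vote is taken over the available
#' verdicts.
#'
#' @param verdicts a 16-element list of token sets (one per tool), as stored
#'   in the `verdicts` list-column of [read_variant_table()] output.
#' @return named integer vector `c(n_damaging, n_available)`.
#' @examples
#' v <- read_variant_table(ps_fixture("table2_variants.tsv"))
#' consensus_vote(v$verdicts[[which(v$protein_change == "p.Pro532Ala")]])
#' @export
consensus_vote <- function(verdicts) {
  stopifnot(is.list(verdicts), length(verdicts) == length(prediction_tools()))
  avail <- vapply(verdicts, function(v) length(v) > 0, logical(1))
  damaging <- vapply(verdicts, function(v) any(v %in% .damaging_tokens),
                     logical(1))
  c(n_damaging = sum(damaging & avail), n_available = sum(avail))
}

#' Does a damaging vote pass the consensus rule?
#'
#' Passes when at least `vote_rule` of the available verdicts are damaging;
#' with no available verdicts the vote cannot pass (missense variants without
#' predictions are not called likely gene disrupting by vote).
#'
#' @param n_damaging,n_available counts from [consensus_vote()].
#' @param vote_rule required fraction, "at least" (default 1/2).
#' @return logical scalar.
#' @examples
#' vote_passes(8, 16)  # exactly half passes "at least half"
#' vote_passes(7, 16)
#' @export
vote_passes <- function(n_damaging, n_available, vote_rule = 0.5) {
  n_available > 0 && n_damaging >= vote_rule * n_available
}

.stage_tbl <- function(status, detail) {
  tibble::tibble(status = status, detail = detail)
}

#' Cascade stage 1: rare, non-synonymous
#'
#' Synonymous and "other" consequence classes always fail. Non-synonymous
#' variants pass when the gene is allowlisted (status `"exempt"`: evaluated
#' regardless of frequency) or when the gnomAD non-Finnish-European frequency
#' is absent (never observed) or strictly below the threshold.
#'
#' @param variants variant tibble ([read_variant_table()]).
#' @param cfg a [cascade_config()].
#' @return tibble with columns `status` (`pass`/`fail`/`exempt`) and `detail`,
#'   one row per variant.
#' @export
is_rare_nonsynonymous <- function(variants, cfg = cascade_config()) {
  status <- character(nrow(variants))
  detail <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    cons <- variants$consequence[i]
    af <- variants$af_nfe[i]
    if (cons %in% c("synonymous", "other")) {
      status[i] <- "fail"
      detail[i] <- paste0("excluded consequence class: ", cons)
    } else if (variants$gene[i] %in% cfg$exempt_genes) {
      status[i] <- "exempt"
      detail[i] <- paste0("gene allowlist (af_nfe=",
                          ifelse(is.na(af), "absent", format(af)), ")")
    } else if (is.na(af)) {
      status[i] <- "pass"
      detail[i] <- "af_nfe absent (not observed)"
    } else if (af < cfg$maf_threshold) {
      status[i] <- "pass"
      detail[i] <- sprintf("af_nfe=%g < %g", af, cfg$maf_threshold)
    } else {
      status[i] <- "fail"
      detail[i] <- sprintf("af_nfe=%g >= %g", af, cfg$maf_threshold)
    }
  }
  .stage_tbl(status, detail)
}

#' Cascade stage 2: likely gene disrupting
#'
#' Stop-gain, stop-loss and frameshift variants qualify unconditionally.
#' Splice variants qualify when the ADA score is present and at least the
#' threshold. Missense variants qualify when the CADD score is present and
#' strictly above the threshold *and* the consensus vote passes. Everything
#' else fails.
#'
#' @inheritParams is_rare_nonsynonymous
#' @return tibble with columns `status` and `detail`.
#' @export
is_likely_gene_disrupting <- function(variants, cfg = cascade_config()) {
  status <- character(nrow(variants))
  detail <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    cons <- variants$consequence[i]
    if (cons %in% c("stop_gain", "stop_loss", "frameshift")) {
      status[i] <- "pass"
      detail[i] <- paste0("protein truncating (", cons, ")")
    } else if (cons == "splicing") {
      ada <- variants$ada[i]
      if (!is.na(ada) && ada >= cfg$ada_threshold) {
        status[i] <- "pass"
        detail[i] <- sprintf("ADA=%g >= %g", ada, cfg$ada_threshold)
      } else {
        status[i] <- "fail"
        detail[i] <- sprintf("ADA=%s < %g",
                             ifelse(is.na(ada), "absent", format(ada)),
                             cfg$ada_threshold)
      }
    } else if (cons == "missense") {
      cadd <- variants$cadd[i]
      vote <- consensus_vote(variants$verdicts[[i]])
      voted <- vote_passes(vote[["n_damaging"]], vote[["n_available"]],
                           cfg$vote_rule)
      if (!is.na(cadd) && cadd > cfg$cadd_threshold && voted) {
        status[i] <- "pass"
        detail[i] <- sprintf("CADD=%g > %g; vote %d/%d", cadd,
                             cfg$cadd_threshold, vote[["n_damaging"]],
                             vote[["n_available"]])
      } else {
        status[i] <- "fail"
        detail[i] <- sprintf("CADD=%s, vote %d/%d",
                             ifelse(is.na(cadd), "absent", format(cadd)),
                             vote[["n_damaging"]], vote[["n_available"]])
      }
    } else {
      status[i] <- "fail"
      detail[i] <- paste0("consequence class not gene disrupting: ", cons)
    }
  }
  .stage_tbl(status, detail)
}

#' Cascade stage 3: gene-level prioritization
#'
#' A variant is prioritized when its gene is an established tooth-agenesis
#' risk gene or has a documented role in odontogenesis, or when the gene's
#' pLi score is present and at least the threshold. A variant in a gene
#' absent from the panel is a cohort/panel mismatch and an error.
#'
#' @inheritParams is_rare_nonsynonymous
#' @param panel panel tibble ([read_panel()]).
#' @return tibble with columns `status` and `detail`.
#' @export
prioritize <- function(variants, panel, cfg = cascade_config()) {
  idx <- match(variants$gene, panel$gene)
  if (anyNA(idx)) {
    stop("gene '", variants$gene[which(is.na(idx))[1]],
         "' is absent from the panel table", call. = FALSE)
  }
  category <- panel$category[idx]
  pli <- panel$pli[idx]
  by_cat <- category %in% c("known_ta", "odontogenesis")
  by_pli <- !is.na(pli) & pli >= cfg$pli_threshold
  status <- ifelse(by_cat | by_pli, "pass", "fail")
  detail <- ifelse(by_cat, paste0("category=", category),
                   ifelse(by_pli, sprintf("pLi=%g >= %g", pli, cfg$pli_threshold),
                          sprintf("category=other, pLi=%s",
                                  ifelse(is.na(pli), "absent", format(pli)))))
  .stage_tbl(status, detail)
}

#' Pathogenicity label for retained variants
#'
#' Retained variants are labelled `pathogenic` when annotated
#' pathogenic/likely-pathogenic in ClinVar or as a disease mutation in HGMD
#' (`db_pathogenic`), and `likely_pathogenic` otherwise. A ClinVar
#' uncertain-significance record does not set `db_pathogenic`; such evidence
#' conflicts are carried in `db_note` rather than resolved.
#'
#' @param variants variant tibble.
#' @return character vector of labels.
#' @export
label_pathogenicity <- function(variants) {
  ifelse(variants$db_pathogenic, "pathogenic", "likely_pathogenic")
}

#' Run the full filtering/prioritization cascade
#'
#' Evaluates the three stages (rare non-synonymous, likely gene disrupting,
#' gene prioritization) for every variant and assembles the retained set:
#' variants passing all stages strictly; allowlisted-gene variants that fail
#' a downstream stage are retained with `exemption = "gene_allowlist"`
#' (their rarity-stage allowlist pass is part of the printed criteria and
#' still counts as strict); configured manual exceptions are retained with
#' `exemption = "manual_exception"`. Every retained variant carries a
#' pathogenic/likely-pathogenic label, and an audit trail records one entry
#' per stage per variant in execution order, so retained-set membership is
#' exactly reconstructible from the audit.
#'
#' @param variants variant tibble ([read_variant_table()]).
#' @param panel panel tibble ([read_panel()]).
#' @param cfg a [cascade_config()].
#' @return an object of class `cascade_result`: a list with `classified`
#'   (one row per input variant: stage verdicts, `passed_strict`,
#'   `exemption`, `retained`, `label`), `audit` (long per-stage trail) and
#'   `stage_counts` (variants surviving after each stage, then retained).
#' @examples
#' variants <- read_variant_table(ps_fixture("table2_variants.tsv"))
#' panel <- read_panel(ps_fixture("gene_panel.tsv"))
#' cfg <- cascade_config(manual_exceptions = variant_key("TP63", "c.1594C>G"))
#' res <- run_cascade(variants, panel, cfg)
#' res$stage_counts
#' @export
run_cascade <- function(variants, panel, cfg = cascade_config()) {
  stages <- list(
    rare_nonsynonymous = is_rare_nonsynonymous(variants, cfg),
    likely_gene_disrupting = is_likely_gene_disrupting(variants, cfg),
    prioritized = prioritize(variants, panel, cfg)
  )
  n <- nrow(variants)
  s1_ok <- stages[[1]]$status %in% c("pass", "exempt")
  s2_ok <- stages[[2]]$status == "pass"
  s3_ok <- stages[[3]]$status == "pass"
  passed_strict <- s1_ok & s2_ok & s3_ok
  eligible <- !variants$consequence %in% c("synonymous", "other")
  allowlisted <- eligible & variants$gene %in% cfg$exempt_genes & !passed_strict
  manual <- variants$key %in% cfg$manual_exceptions & !passed_strict &
    !allowlisted
  retained <- passed_strict | allowlisted | manual
  exemption <- ifelse(allowlisted, "gene_allowlist",
                      ifelse(manual, "manual_exception", "none"))
  label <- ifelse(retained, label_pathogenicity(variants), NA_character_)
  classified <- tibble::tibble(
    gene = variants$gene,
    dna_change = variants$dna_change,
    protein_change = variants$protein_change,
    key = variants$key,
    stage_rare = stages[[1]]$status,
    stage_lgd = stages[[2]]$status,
    stage_prioritized = stages[[3]]$status,
    passed_strict = passed_strict,
    exemption = exemption,
    retained = retained,
    label = label
  )
  classified <- classified[order(classified$gene, classified$dna_change), ]
  audit <- do.call(rbind, lapply(seq_along(stages), function(k) {
    tibble::tibble(
      key = variants$key,
      stage = names(stages)[k],
      order = k,
      status = stages[[k]]$status,
      detail = stages[[k]]$detail
    )
  }))
  audit <- audit[order(match(audit$key, classified$key), audit$order), ]
  stage_counts <- c(
    input = n,
    rare_nonsynonymous = sum(s1_ok),
    likely_gene_disrupting = sum(s1_ok & s2_ok),
    prioritized = sum(passed_strict),
    retained = sum(retained)
  )
  structure(
    list(classified = classified, audit = audit, stage_counts = stage_counts,
         config = cfg),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Variant filtering cascade\n")
  cat(sprintf("  %d variants in; %d pass strictly; %d retained (%d exempt)\n",
              x$stage_counts[["input"]], x$stage_counts[["prioritized"]],
              x$stage_counts[["retained"]],
              sum(x$classified$exemption != "none" & x$classified$retained)))
  by_label <- table(x$classified$label[x$classified$retained])
  for (lb in names(by_label)) cat(sprintf("    %s: %d\n", lb, by_label[[lb]]))
  invisible(x)
}

#' Retained variant keys of a cascade result
#'
#' @param result a `cascade_result`.
#' @return character vector of retained [variant_key()]s, sorted.
#' @export
retained_keys <- function(result) {
  stopifnot(inherits(result, "cascade_result"))
  sort(result$classified$key[result$classified$retained])
}

#' Screen the control cohort against the retained variants
#'
#' Two-part control screen: (i) for every retained case variant, the number
#' of distinct control carriers; (ii) a reciprocal scan that runs the same
#' cascade over control-only variants found in the retained genes and lists
#' any that would themselves have been retained.
#'
#' @param result a `cascade_result` from the case cohort.
#' @param control_genotypes control genotype tibble ([read_genotypes()]); may
#'   be `NULL` or empty, giving an empty report.
#' @param control_variants optional annotated-variant tibble for variants
#'   observed only in controls (input to the reciprocal scan).
#' @param panel panel tibble (required when `control_variants` is given).
#' @param cfg the cascade configuration; defaults to the one stored in
#'   `result`.
#' @return list with `carriers` (key, n_control_carriers) and `reciprocal`
#'   (control-only variants in retained genes that pass the cascade).
#' @export
control_screen <- function(result, control_genotypes,
                           control_variants = NULL, panel = NULL,
                           cfg = result$config) {
  keys <- retained_keys(result)
  empty_rec <- tibble::tibble(gene = character(), dna_change = character(),
                              key = character(), label = character())
  if (is.null(control_genotypes) || nrow(control_genotypes) == 0) {
    return(list(
      carriers = tibble::tibble(key = keys,
                                n_control_carriers = integer(length(keys))),
      reciprocal = empty_rec
    ))
  }
  hits <- control_genotypes[control_genotypes$key %in% keys, , drop = FALSE]
  n_car <- vapply(keys, function(k) {
    length(unique(hits$subject_id[hits$key == k]))
  }, integer(1))
  carriers <- tibble::tibble(key = keys, n_control_carriers = unname(n_car))
  reciprocal <- empty_rec
  if (!is.null(control_variants) && nrow(control_variants) > 0) {
    if (is.null(panel)) {
      stop("panel is required for the reciprocal control scan", call. = FALSE)
    }
    retained_genes <- unique(result$classified$gene[result$classified$retained])
    cand <- control_variants[control_variants$gene %in% retained_genes &
                               !control_variants$key %in% keys, , drop = FALSE]
    if (nrow(cand) > 0) {
      rec <- run_cascade(cand, panel, cfg)
      rc <- rec$classified[rec$classified$retained & rec$classified$passed_strict,
                           , drop = FALSE]
      reciprocal <- tibble::tibble(gene = rc$gene, dna_change = rc$dna_change,
                                   key = rc$key, label = rc$label)
    }
  }
  list(carriers = carriers, reciprocal = reciprocal)
}
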