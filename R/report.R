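.load_input <- function(x, reader, stage) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) {
      stop("[", stage, "] input file not found: ", x, call. = FALSE)
    }
    reader(x)
  } else x
}

#' Run the full panel-screening pipeline
#'
#' Orchestrates filter -> control screen -> phenotype -> association ->
#' report over one cohort. Inputs may be tibbles or TSV paths (read with the
#' package readers). Outputs written to `out_dir`: `retained.tsv`,
#' `audit.tsv`, `control_screen.tsv`, `carrier_summaries.tsv`,
#' `oligogenic.tsv`, `association.tsv` (when genotype-based association is
#' possible or a printed association table is supplied), `report.md`,
#' `summary.json` and `manifest.json` (input/output checksums, stage
#' timings, package version). Any stage error aborts with the stage name.
#' Reruns on identical inputs and configuration produce byte-identical
#' outputs except for the timing fields of the manifest.
#'
#' @param variants annotated variant table (tibble or path).
#' @param genotypes case genotype calls (tibble or path).
#' @param phenotypes cohort phenotype table (tibble or path).
#' @param panel gene panel table (tibble or path).
#' @param cfg a [cascade_config()].
#' @param control_genotypes optional control genotype calls (tibble or path).
#' @param control_variants optional control-only annotated variants for the
#'   reciprocal screen (tibble or path).
#' @param assoc optional printed common-variant association table (tibble or
#'   path, [read_assoc_table()] layout); when absent, association is computed
#'   from the genotype calls with [trend_scan()].
#' @param n_cases cohort case count for carrier rates (default: cases in
#'   `phenotypes`).
#' @param alpha family-wise significance level (default 0.05).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all stage objects and the output paths.
#' @export
run_all <- function(variants, genotypes, phenotypes, panel,
                    cfg = cascade_config(),
                    control_genotypes = NULL, control_variants = NULL,
                    assoc = NULL, n_cases = NULL, alpha = 0.05,
                    out_dir = tempfile("panelscreen_run_")) {
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    out
  }
  inputs <- stage("input", {
    list(
      variants = .load_input(variants, read_variant_table, "input"),
      genotypes = .load_input(genotypes, read_genotypes, "input"),
      phenotypes = .load_input(phenotypes, read_phenotype_table, "input"),
      panel = .load_input(panel, read_panel, "input"),
      control_genotypes = if (is.null(control_genotypes)) NULL else
        .load_input(control_genotypes, read_genotypes, "input"),
      control_variants = if (is.null(control_variants)) NULL else
        .load_input(control_variants, read_variant_table, "input"),
      assoc = if (is.null(assoc)) NULL else
        .load_input(assoc, read_assoc_table, "input")
    )
  })
  if (is.null(n_cases)) {
    n_cases <- sum(inputs$phenotypes$status == "case")
  }

  cascade <- stage("filter", run_cascade(inputs$variants, inputs$panel, cfg))
  keys <- retained_keys(cascade)
  screen <- stage("control_screen", control_screen(
    cascade, inputs$control_genotypes, inputs$control_variants,
    inputs$panel, cfg))

  pheno <- stage("phenotype", {
    cases <- inputs$phenotypes[inputs$phenotypes$status == "case", ,
                               drop = FALSE]
    carried_genes <- sort(unique(
      inputs$genotypes$gene[inputs$genotypes$key %in% keys]))
    per_gene <- lapply(carried_genes, function(g) {
      carrier_phenotype_summary(cases, inputs$genotypes, genes = g,
                                retained = keys)
    })
    names(per_gene) <- carried_genes
    list(
      cohort = tooth_class_distribution(cases),
      family_history = family_history_rate(cases),
      carrier = carrier_rate(
        inputs$genotypes[inputs$genotypes$subject_id %in% cases$subject_id, ,
                         drop = FALSE],
        n_cases, keys = keys),
      per_gene = per_gene,
      oligogenic = detect_oligogenic(keys, inputs$genotypes)
    )
  })

  assoc_res <- stage("association", {
    if (!is.null(inputs$assoc)) {
      plan <- multiplicity_plan(alpha, nrow(inputs$assoc))
      sig <- flag_significance(inputs$assoc$p_trend, plan)
      out <- cbind(inputs$assoc, sig)
      attr(out, "plan") <- plan
      out
    } else {
      if (nrow(inputs$genotypes) == 0) NULL else
        suppressWarnings(
          trend_scan(inputs$genotypes, inputs$phenotypes, inputs$panel,
                     alpha = alpha))
    }
  })

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv_plain(df, p)
    paths[[name]] <<- p
  }
  emit(cascade$classified[cascade$classified$retained, , drop = FALSE],
       "retained.tsv")
  emit(cascade$audit, "audit.tsv")
  emit(screen$carriers, "control_screen.tsv")
  per_gene_tbl <- dplyr::bind_rows(lapply(names(pheno$per_gene), function(g) {
    s <- pheno$per_gene[[g]]
    tibble::tibble(gene = g, n_subjects = s$n_subjects,
                   total_missing = s$total_missing,
                   mean_missing = round(s$mean_missing, 2),
                   min_missing = s$min_missing, max_missing = s$max_missing)
  }))
  emit(per_gene_tbl, "carrier_summaries.tsv")
  emit(pheno$oligogenic, "oligogenic.tsv")
  if (!is.null(assoc_res)) emit(as.data.frame(assoc_res), "association.tsv")

  stages <- list(inputs = inputs, cascade = cascade, screen = screen,
                 phenotype = pheno, association = assoc_res,
                 n_cases = n_cases, alpha = alpha)
  report <- build_report(stages)
  writeLines(report, file.path(out_dir, "report.md"))
  paths[["report.md"]] <- file.path(out_dir, "report.md")

  summary <- list(
    n_variants_in = nrow(inputs$variants),
    n_retained = length(keys),
    n_retained_strict = sum(cascade$classified$passed_strict),
    n_exempt = sum(cascade$classified$retained &
                     cascade$classified$exemption != "none"),
    n_cases = n_cases,
    carrier_fraction = pheno$carrier$fraction,
    n_oligogenic_subjects = nrow(pheno$oligogenic),
    n_association_tests = if (is.null(assoc_res)) 0L else nrow(assoc_res),
    n_bonferroni_significant = if (is.null(assoc_res)) 0L else
      sum(assoc_res$significant_bonferroni)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths[["summary.json"]] <- file.path(out_dir, "summary.json")

  manifest <- list(
    package = "panelscreen",
    version = as.character(utils::packageVersion("panelscreen")),
    config = unclass(cfg),
    outputs = lapply(paths, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    stage_seconds = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(c(stages, list(report = report, out_dir = out_dir,
                           paths = paths, summary = summary)))
}

.fmt_pct <- function(x) sprintf("%.2f%%", 100 * x)

#' Assemble the human-readable run report
#'
#' Renders the stage outputs of [run_all()] as a Markdown document: cohort
#' characteristics, the retained-variant classification, control-screen
#' findings, per-gene carrier dentition summaries, oligogenic co-occurrence
#' and the common-variant association scan. Every number is taken from the
#' stage objects; nothing is recomputed at report time.
#'
#' @param stages list of stage outputs as assembled by [run_all()].
#' @return character vector of Markdown lines.
#' @export
build_report <- function(stages) {
  cascade <- stages$cascade
  pheno <- stages$phenotype
  keys <- retained_keys(cascade)
  out <- c(
    "# Candidate-gene panel screen",
    "",
    "## Cohort",
    "",
    sprintf("- %d cases, %d controls",
            stages$n_cases,
            sum(stages$inputs$phenotypes$status == "control")),
    sprintf("- hypodontia %d / oligodontia %d among summarized cases",
            pheno$cohort$n_hypodontia, pheno$cohort$n_oligodontia),
    sprintf("- positive family history: %d/%d (%s)",
            pheno$family_history$n_yes, pheno$family_history$n_subjects,
            .fmt_pct(pheno$family_history$fraction)),
    "",
    "## Retained variants",
    ""
  )
  if (length(keys) == 0) {
    out <- c(out, "No variants retained by the cascade.")
  } else {
    cl <- cascade$classified[cascade$classified$retained, , drop = FALSE]
    out <- c(out,
      sprintf("- %d variants retained (%d strict, %d exempt)",
              nrow(cl), sum(cl$passed_strict),
              sum(cl$exemption != "none")),
      sprintf("- pathogenic: %d; likely pathogenic: %d",
              sum(cl$label == "pathogenic"),
              sum(cl$label == "likely_pathogenic")),
      sprintf("- carriers: %d/%d cases (%s)",
              pheno$carrier$n_carriers, pheno$carrier$n_total,
              .fmt_pct(pheno$carrier$fraction)),
      "",
      "| gene | DNA change | protein | label | exemption |",
      "|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %s | %s |", cl$gene, cl$dna_change,
              cl$protein_change, cl$label, cl$exemption)
    )
  }
  out <- c(out, "", "## Control screen", "")
  hits <- stages$screen$carriers[stages$screen$carriers$n_control_carriers > 0,
                                 , drop = FALSE]
  if (nrow(hits) == 0) {
    out <- c(out, "No retained variant was observed in the control group.")
  } else {
    out <- c(out, sprintf("- %s: %d control carrier(s)", hits$key,
                          hits$n_control_carriers))
  }
  if (nrow(stages$screen$reciprocal) > 0) {
    out <- c(out, "",
             "Control-only variants in retained genes passing the cascade:",
             sprintf("- %s (%s)", stages$screen$reciprocal$key,
                     stages$screen$reciprocal$label))
  }
  out <- c(out, "", "## Carrier dentition summaries", "")
  if (length(pheno$per_gene) == 0) {
    out <- c(out, "No carriers to summarize.")
  } else {
    out <- c(out, "| gene | carriers | total missing | mean | range |",
             "|---|---|---|---|---|")
    for (g in names(pheno$per_gene)) {
      s <- pheno$per_gene[[g]]
      out <- c(out, sprintf("| %s | %d | %d | %.2f | %d-%d |", g,
                            s$n_subjects, s$total_missing, s$mean_missing,
                            s$min_missing, s$max_missing))
    }
  }
  out <- c(out, "", "## Oligogenic co-occurrence", "")
  og <- pheno$oligogenic
  if (nrow(og) == 0) {
    out <- c(out, "No subject carries more than one retained variant.")
  } else {
    out <- c(out, sprintf("- %s [%s]: %s", og$subject_id, og$kind,
                          vapply(og$variants, paste, character(1),
                                 collapse = " + ")))
  }
  out <- c(out, "", "## Common-variant association", "")
  assoc <- stages$association
  if (is.null(assoc) || nrow(assoc) == 0) {
    out <- c(out, "No common-variant scan was performed.")
  } else {
    plan <- attr(assoc, "plan")
    out <- c(out,
      sprintf("- %d variants tested; Bonferroni threshold %.3g (alpha %.3g)",
              plan$m, plan$threshold, plan$alpha),
      sprintf("- nominally significant: %d; Bonferroni-significant: %d",
              sum(assoc$significant_nominal),
              sum(assoc$significant_bonferroni))
    )
    sig <- assoc[assoc$significant_nominal, , drop = FALSE]
    if (nrow(sig) > 0) {
      lab <- if ("key" %in% names(sig)) sig$key else
        paste(sig$gene, sig$rs_id)
      out <- c(out, sprintf("  - %s: p_trend = %.3g, OR = %.2f (%.2f-%.2f)",
                            lab, sig$p_trend, sig$odds_ratio, sig$ci_low,
                            sig$ci_high))
    }
  }
  out
}
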