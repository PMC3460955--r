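## Umbrella pipeline: simulate (or load) a cohort, call events, aggregate
## recurrence, run the dosage screen, stratify survival, and tabulate
## array-vs-iFISH concordance, writing every stage output plus a manifest.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] used when the cohort is simulated.
#' @param thresholds A [calling_thresholds()].
#' @param filter A [filter_config()].
#' @param out_dir Output directory for stage reports.
#' @param risk_gene Symbol of the gene whose amplification stratifies
#'   survival. Default `"PDGFRA"`.
#' @param min_cases Minimum cases for minimal-common-region reporting.
#' @param expression_samples Number of samples with paired expression
#'   (the remainder are CN-only). Default 23.
#' @param quiet Suppress progress messages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            thresholds = calling_thresholds(),
                            filter = filter_config(),
                            out_dir = tempfile("gbmcna_run_"),
                            risk_gene = "PDGFRA", min_cases = 2,
                            expression_samples = 23, quiet = FALSE) {
  structure(
    list(cohort = cohort, thresholds = thresholds, filter = filter,
         out_dir = out_dir, risk_gene = risk_gene, min_cases = min_cases,
         expression_samples = expression_samples, quiet = quiet),
    class = "pipeline_config"
  )
}

pipeline_log <- function(config, stage, msg) {
  if (!isTRUE(config$quiet)) {
    message(sprintf("[%s] %s", stage, msg))
  }
}

run_stage <- function(config, stage, expr) {
  tryCatch(force(expr), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> call -> recurrence -> dosage -> survival -> iFISH
#' concordance. All stage outputs are written under `config$out_dir`
#' together with a JSON run manifest (package version, seed, thresholds);
#' a rerun with the same configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results (`cohort`, `events`,
#'   `regions`, `dosage`, `survival`, `ifish`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cc <- config$cohort
  genes <- load_gene_models()

  pipeline_log(config, "simulate", sprintf(
    "generating %d samples (seed %d)", cc$n_samples, cc$seed))
  cohort <- run_stage(config, "simulate", generate_cohort(cc))

  genes_covered <- genes[genes$chrom %in% unique(cohort$probes$chrom), ]
  coupled <- with_seed(cc$seed + 2L, {
    sample(genes_covered$symbol,
           max(1, round(cc$dosage_coupled_fraction * nrow(genes_covered))))
  })
  expr_samples <- head(sample_columns(cohort$cn),
                       config$expression_samples)
  expr <- run_stage(config, "simulate", generate_expression(
    cohort$cn[, c("probe_id", "chrom", "pos", expr_samples)],
    genes_covered, coupled, noise_sd = cc$expression_noise_sd,
    seed = cc$seed + 3L
  ))
  clinical <- run_stage(config, "simulate",
                        generate_survival(cohort$truth, cc))

  pipeline_log(config, "call", "smoothing and segmenting profiles")
  events <- run_stage(config, "call",
                      call_events(cohort$cn, config$thresholds))

  pipeline_log(config, "recur", "delineating minimal common regions")
  regions <- run_stage(config, "recur", {
    dplyr::bind_rows(
      minimal_common_region(events, "amplification", config$min_cases,
                            cohort_size = cc$n_samples),
      minimal_common_region(events, "homozygous_deletion",
                            config$min_cases, cohort_size = cc$n_samples)
    ) |>
      annotate_regions(genes_covered)
  })

  pipeline_log(config, "dosage", "screening CN-expression correlations")
  dosage <- run_stage(config, "dosage", {
    gene_cn <- summarize_gene_cn(
      cohort$cn[, c("probe_id", "chrom", "pos", expr_samples)],
      genes_covered
    )
    dosage_screen(gene_cn, expr, config$filter)
  })

  pipeline_log(config, "survival", sprintf(
    "stratifying by %s amplification", config$risk_gene))
  surv <- run_stage(config, "survival", {
    gene_row <- genes[genes$symbol == config$risk_gene, ]
    if (nrow(gene_row) == 0) {
      abort(sprintf("risk gene %s not in gene models", config$risk_gene))
    }
    groups <- stratify_by_event(clinical, events, gene = gene_row)
    km_pos <- if (nrow(groups$positive) > 0) {
      km_estimate(groups$positive)
    } else {
      NULL
    }
    km_neg <- km_estimate(groups$negative)
    lr <- if (nrow(groups$positive) > 0) {
      logrank_test(groups$positive, groups$negative)
    } else {
      NULL
    }
    list(groups = groups, km_positive = km_pos, km_negative = km_neg,
         logrank = lr)
  })

  pipeline_log(config, "ifish", "simulating confirmatory iFISH")
  ifish <- run_stage(config, "ifish", {
    loci <- tibble::tibble(
      locus = c("EGFR", "CDKN2A"), chrom = c("chr7", "chr9"),
      start = c(55054000, 21957751), end = c(55242000, 21984490)
    )
    ids <- sample_columns(cohort$cn)
    array_calls <- purrr::pmap_dfr(loci, function(locus, chrom, start, end) {
      hits <- events |>
        dplyr::filter(.data$chrom == !!chrom,
                      intervals_overlap(.data$start, .data$end,
                                        !!start, !!end))
      state <- vapply(ids, function(id) {
        k <- hits$kind[hits$sample_id == id]
        if (length(k) > 0) k[1] else "normal"
      }, character(1))
      tibble::tibble(case_id = ids, locus = locus, state = unname(state))
    })
    counts <- simulate_ifish_counts(array_calls, seed = cc$seed + 4L)
    ifish_calls <- classify_ifish(counts)
    list(array_calls = array_calls, ifish_calls = ifish_calls,
         concordance = concordance_table(array_calls, ifish_calls))
  })

  manifest <- list(
    package = "gbmcna",
    version = as.character(utils::packageVersion("gbmcna")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cc$seed, n_samples = cc$n_samples,
    thresholds = unclass(config$thresholds),
    filter = unclass(config$filter)
  )

  pipeline_log(config, "write", paste("writing outputs to",
                                      config$out_dir))
  run_stage(config, "write", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_probe_table(cohort$cn, file.path(config$out_dir, "cn_probes.tsv"))
    write_events(events, file.path(config$out_dir, "events.tsv"))
    write_events_bed(events, file.path(config$out_dir, "events.bed"))
    write_clinical(clinical, file.path(config$out_dir, "clinical.tsv"))
    write_report(
      list(
        regions = dplyr::mutate(regions,
                                length_kb = .data$length_bp / 1000),
        dosage = dosage,
        ifish_concordance = ifish$concordance$by_locus
      ),
      config$out_dir
    )
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(list(cohort = cohort, expression = expr, clinical = clinical,
                 events = events, regions = regions, dosage = dosage,
                 survival = surv, ifish = ifish, manifest = manifest))
}
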