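## Gene-level CN summarization and CN-expression dosage correlation.
##
## The dosage screen mirrors the published filter: per-gene Pearson
## correlation between DNA CN values and RMA expression across paired
## samples, kept when R-squared > 0.70 and the two-sided p-value (from the
## t transform) < 5e-7. No multiple-testing correction is applied, by
## design: the published screen applies the fixed dual cutoff across all
## genes, and at n = 23 the two conditions nearly coincide.

#' Dosage-filter configuration
#'
#' Both conditions are strict inequalities: `r_squared > r2_min` and
#' `p_value < p_max`.
#'
#' @param r2_min Minimum R-squared (exclusive). Default 0.70.
#' @param p_max Maximum two-sided p-value (exclusive). Default 5e-7.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(r2_min = 0.70, p_max = 5e-7) {
  stopifnot_scalar_number(r2_min, "r2_min", 0, 1)
  if (!is.numeric(p_max) || length(p_max) != 1 || p_max <= 0 || p_max >= 1) {
    abort("`p_max` must be in (0, 1)")
  }
  structure(list(r2_min = r2_min, p_max = p_max), class = "filter_config")
}

#' Gene-level CN summary from probe values
#'
#' For each gene, the CN value is the mean (or median) of probes
#' overlapping the gene interval extended by `flank` on both sides. If no
#' probe overlaps, the nearest probe's value is used and the gene is
#' flagged (`nearest_fallback`). Genes on chromosomes absent from the
#' profile raise an error.
#'
#' @param profiles Wide CN probe table (`probe_id`, `chrom`, `pos` plus
#'   sample columns).
#' @param genes Gene model tibble: `symbol`, `chrom`, `start`, `end`.
#' @param flank Flank in bp added to each side of the gene. Default 10 kb.
#' @param method `"mean"` (default) or `"median"` across probes.
#' @return Tibble: `symbol`, `chrom`, `start`, `end`, `n_probes_used`,
#'   `nearest_fallback`, plus one CN column per sample.
#' @export
summarize_gene_cn <- function(profiles, genes, flank = 1e4,
                              method = c("mean", "median")) {
  method <- match.arg(method)
  agg <- if (method == "mean") colMeans else function(m) apply(m, 2, median)
  samples <- sample_columns(profiles)
  absent <- setdiff(unique(genes$chrom), unique(profiles$chrom))
  if (length(absent) > 0) {
    abort(paste0("no probes on chromosome(s): ",
                 paste(absent, collapse = ", ")))
  }
  rows <- purrr::pmap(
    genes[, c("symbol", "chrom", "start", "end")],
    function(symbol, chrom, start, end) {
      on_chrom <- profiles[profiles$chrom == chrom, , drop = FALSE]
      idx <- which(on_chrom$pos >= start - flank &
                     on_chrom$pos <= end + flank)
      fallback <- length(idx) == 0
      if (fallback) {
        dist <- pmax(start - on_chrom$pos, on_chrom$pos - end, 0)
        idx <- which.min(dist)
      }
      vals <- agg(as.matrix(on_chrom[idx, samples, drop = FALSE]))
      dplyr::bind_cols(
        tibble::tibble(symbol = symbol, chrom = chrom, start = start,
                       end = end, n_probes_used = length(idx),
                       nearest_fallback = fallback),
        tibble::as_tibble(as.list(vals))
      )
    }
  )
  dplyr::bind_rows(rows)
}

#' Pearson dosage correlation for one gene
#'
#' Standard Pearson r between paired CN and expression values; the
#' two-sided p-value comes from the t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against the t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param cn,expr Paired numeric vectors (same length, n >= 3, both with
#'   non-zero variance).
#' @param symbol,cytoband Optional labels carried into the result.
#' @param config A [filter_config()] used to set `passes_filter`.
#' @return One-row tibble: `symbol`, `cytoband`, `n`, `r`, `r_squared`,
#'   `p_value`, `passes_filter`.
#' @examples
#' pearson_dosage(1:10, 2 * (1:10) + rnorm(10, sd = 0.1))
#' @export
pearson_dosage <- function(cn, expr, symbol = NA_character_,
                           cytoband = NA_character_,
                           config = filter_config()) {
  n <- length(cn)
  if (length(expr) != n) abort("`cn` and `expr` must have equal length")
  if (n < 3) abort("need at least 3 paired samples")
  if (stats::sd(cn) == 0 || stats::sd(expr) == 0) {
    abort(class = "gbmcna_zero_variance",
          message = sprintf("zero variance for gene %s", symbol))
  }
  r <- cor(cn, expr)
  r2 <- r^2
  p <- if (r2 >= 1) {
    .Machine$double.xmin
  } else {
    t_stat <- abs(r) * sqrt(n - 2) / sqrt(1 - r2)
    max(2 * pt(t_stat, df = n - 2, lower.tail = FALSE),
        .Machine$double.xmin)
  }
  tibble::tibble(
    symbol = symbol, cytoband = cytoband, n = as.integer(n), r = r,
    r_squared = r2, p_value = p,
    passes_filter = r2 > config$r2_min & p < config$p_max
  )
}

#' Screen all shared genes for CN-expression dosage correlation
#'
#' Runs [pearson_dosage()] for every gene present in both the gene-level CN
#' summary and the expression matrix, over their shared samples. The screen
#' deliberately covers all shared genes, not only genes inside called
#' events. Genes without expression values are excluded and reported in the
#' `skipped` attribute with reason `"no_expression"`; zero-variance genes
#' with reason `"zero_variance"`.
#'
#' @param gene_cn Gene-level CN tibble from [summarize_gene_cn()] (or any
#'   tibble with `symbol` plus sample columns).
#' @param expr Expression tibble: `symbol` plus sample columns (RMA-like
#'   values).
#' @param config A [filter_config()].
#' @param cytobands Optional tibble (`symbol`, `cytoband`) for labeling.
#' @return Tibble of per-gene results sorted by `r_squared` descending,
#'   with attribute `skipped` (tibble: `symbol`, `reason`).
#' @export
dosage_screen <- function(gene_cn, expr, config = filter_config(),
                          cytobands = NULL) {
  cn_samples <- setdiff(sample_columns(gene_cn),
                        c("symbol", "n_probes_used", "nearest_fallback",
                          "start", "end"))
  cn_samples <- intersect(cn_samples, names(expr))
  if (length(cn_samples) < 3) {
    abort("need at least 3 shared samples between CN and expression")
  }
  shared <- intersect(gene_cn$symbol, expr$symbol)
  skipped <- tibble::tibble(
    symbol = setdiff(gene_cn$symbol, expr$symbol),
    reason = if (length(setdiff(gene_cn$symbol, expr$symbol)) > 0) {
      "no_expression"
    } else {
      character(0)
    }
  )
  band_for <- function(sym) {
    if (is.null(cytobands)) return(NA_character_)
    hit <- cytobands$cytoband[match(sym, cytobands$symbol)]
    if (length(hit) == 0) NA_character_ else hit
  }
  results <- list()
  for (sym in shared) {
    cn_v <- as.numeric(gene_cn[match(sym, gene_cn$symbol), cn_samples])
    ex_v <- as.numeric(expr[match(sym, expr$symbol), cn_samples])
    res <- tryCatch(
      pearson_dosage(cn_v, ex_v, symbol = sym, cytoband = band_for(sym),
                     config = config),
      gbmcna_zero_variance = function(e) NULL
    )
    if (is.null(res)) {
      inform(sprintf("dosage_screen: skipping %s (zero variance)", sym))
      skipped <- dplyr::bind_rows(
        skipped, tibble::tibble(symbol = sym, reason = "zero_variance")
      )
    } else {
      results[[length(results) + 1]] <- res
    }
  }
  out <- dplyr::bind_rows(results) |>
    dplyr::arrange(dplyr::desc(.data$r_squared), .data$symbol)
  attr(out, "skipped") <- skipped
  out
}

#' Apply the dosage filter to a table of correlation results
#'
#' Recomputes `passes_filter` on any tibble carrying an `r_squared` column
#' (and optionally `p_value`), using strict inequalities. When no `p_value`
#' column is present (e.g. a published table of R-squared values alone),
#' only the R-squared condition is applied.
#'
#' @param results Tibble with `r_squared` and optionally `p_value`.
#' @param config A [filter_config()].
#' @return `results` with a logical `passes_filter` column.
#' @export
apply_dosage_filter <- function(results, config = filter_config()) {
  pass <- results$r_squared > config$r2_min
  if ("p_value" %in% names(results)) {
    pass <- pass & results$p_value < config$p_max
  }
  results$passes_filter <- pass
  results
}

#' Spearman rank correlation (validation utility)
#'
#' Rank correlation with average ranks for ties, as used to validate
#' microarray expression against quantitative RT-PCR.
#'
#' @param values_a,values_b Paired numeric vectors, n >= 3.
#' @return The rank correlation coefficient (scalar).
#' @export
spearman_validation <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    abort("inputs must have equal length")
  }
  if (length(values_a) < 3) abort("need at least 3 paired values")
  if (stats::sd(values_a) == 0 || stats::sd(values_b) == 0) {
    abort("constant input: rank correlation undefined")
  }
  cor(values_a, values_b, method = "spearman")
}
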