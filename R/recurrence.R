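## Cross-sample aggregation of CN events: recurrence frequencies, minimal
## common regions (MCRs) via base-pair coverage pileup, gene annotation and
## per-case co-occurrence.

#' Recurrence frequency of a kind of event over a region
#'
#' A case counts once if it has at least one event of the given kind
#' overlapping the query region by >= 1 bp. The percent is rounded
#' half-away-from-zero to an integer, the convention that reproduces the
#' printed cohort frequencies (24/46 -> 52%, 21/46 -> 46%, 3/46 -> 7%).
#'
#' @param events Event tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `kind`).
#' @param region List or one-row tibble with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param kind Event kind to count.
#' @param cohort_size Denominator (>= 1); explicit because event-free cases
#'   must count in it.
#' @return One-row tibble: `n_cases`, `frequency_pct`.
#' @examples
#' ev <- tibble::tibble(sample_id = c("a", "b"), chrom = "chr7",
#'                      start = 1e6, end = 2e6, kind = "amplification")
#' recurrence_frequency(ev, list(chrom = "chr7", start = 1.5e6, end = 3e6),
#'                      "amplification", cohort_size = 46)
#' @export
recurrence_frequency <- function(events, region, kind, cohort_size) {
  if (length(cohort_size) != 1 || is.na(cohort_size) || cohort_size < 1) {
    abort("`cohort_size` must be a positive count")
  }
  hits <- events |>
    dplyr::filter(.data$kind == !!kind, .data$chrom == region$chrom,
                  intervals_overlap(.data$start, .data$end,
                                    region$start, region$end))
  n_cases <- dplyr::n_distinct(hits$sample_id)
  tibble::tibble(
    n_cases = n_cases,
    frequency_pct = as.integer(round_half_up(100 * n_cases / cohort_size))
  )
}

## Union of possibly-overlapping 1-based inclusive intervals (per sample).
merge_intervals <- function(df) {
  df <- df[order(df$start), ]
  out_start <- numeric(0); out_end <- numeric(0)
  for (i in seq_len(nrow(df))) {
    if (length(out_end) > 0 && df$start[i] <= out_end[length(out_end)] + 1) {
      out_end[length(out_end)] <- max(out_end[length(out_end)], df$end[i])
    } else {
      out_start <- c(out_start, df$start[i])
      out_end <- c(out_end, df$end[i])
    }
  }
  tibble::tibble(start = out_start, end = out_end)
}

#' Minimal common regions of recurrent events
#'
#' Computes the per-base pileup of per-case event coverage on each
#' chromosome (a case contributes at most 1 per base), finds maximal
#' intervals where coverage >= `min_cases`, and within each reports the
#' maximal sub-interval(s) at the local coverage maximum as minimal common
#' regions. Tied maxima contributed by different case sets are reported as
#' separate regions, in coordinate order. Every reported MCR is contained
#' in an event of every contributing case.
#'
#' @param events Event tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `kind`).
#' @param kind Event kind to aggregate.
#' @param min_cases Minimum number of contributing cases (>= 2).
#' @param cohort_size Optional denominator for `frequency_pct`.
#' @return Tibble of regions: `chrom`, `start`, `end`, `kind`, `n_cases`,
#'   `case_ids` (list column), `frequency_pct`, `length_bp`
#'   (`end - start`).
#' @examples
#' ev <- tibble::tibble(sample_id = c("a", "b"), chrom = "chr9",
#'                      start = c(100, 300), end = c(500, 900),
#'                      kind = "homozygous_deletion")
#' minimal_common_region(ev, "homozygous_deletion", min_cases = 2)
#' @export
minimal_common_region <- function(events, kind, min_cases = 2,
                                  cohort_size = NULL) {
  if (min_cases < 2) abort("`min_cases` must be >= 2")
  empty <- tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    kind = character(), n_cases = integer(), case_ids = list(),
    frequency_pct = integer(), length_bp = numeric()
  )
  ev <- events[events$kind == kind, , drop = FALSE]
  if (nrow(ev) == 0) return(empty)

  per_chrom <- function(chrom_name) {
    ## one coverage unit per case: union each case's events first
    iv <- ev |>
      dplyr::filter(.data$chrom == chrom_name) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::group_modify(~ merge_intervals(.x)) |>
      dplyr::ungroup()
    ## elementary segments between breakpoints
    bp <- sort(unique(c(iv$start, iv$end + 1)))
    if (length(bp) < 2) return(empty)
    seg_start <- bp[-length(bp)]
    seg_end <- bp[-1] - 1
    seg_sets <- purrr::map2(seg_start, seg_end, function(s, e) {
      sort(unique(iv$sample_id[iv$start <= s & iv$end >= e]))
    })
    cov <- lengths(seg_sets)
    ## maximal runs with coverage >= min_cases (support intervals)
    above <- cov >= min_cases
    if (!any(above)) return(empty)
    r <- rle(above)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1
    out <- list()
    for (i in which(r$values)) {
      segs <- run_start[i]:run_end[i]
      m <- max(cov[segs])
      at_max <- segs[cov[segs] == m]
      ## merge adjacent max-coverage segments only when the contributing
      ## case set is identical (a plateau of equal coverage can still swap
      ## cases at a breakpoint)
      grp <- cumsum(c(1, vapply(seq_along(at_max)[-1], function(j) {
        non_adjacent <- at_max[j] != at_max[j - 1] + 1
        set_change <- !identical(seg_sets[[at_max[j]]],
                                 seg_sets[[at_max[j - 1]]])
        as.numeric(non_adjacent || set_change)
      }, numeric(1))))
      for (g in unique(grp)) {
        members <- at_max[grp == g]
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = chrom_name,
          start = seg_start[members[1]],
          end = seg_end[members[length(members)]],
          kind = kind,
          n_cases = as.integer(m),
          case_ids = list(seg_sets[[members[1]]])
        )
      }
    }
    dplyr::bind_rows(out)
  }

  res <- purrr::map_dfr(unique(ev$chrom), per_chrom)
  if (nrow(res) == 0) return(empty)
  res |>
    dplyr::mutate(
      frequency_pct = if (is.null(cohort_size)) NA_integer_ else {
        as.integer(round_half_up(100 * .data$n_cases / cohort_size))
      },
      length_bp = .data$end - .data$start
    ) |>
    dplyr::arrange(chrom_rank(.data$chrom), .data$start)
}

#' Gene symbols overlapping a region
#'
#' Returns, in genomic order, the symbols of gene models overlapping the
#' query region by >= 1 bp.
#'
#' @param region List or one-row tibble with `chrom`, `start`, `end`.
#' @param genes Gene model tibble: `symbol`, `chrom`, `start`, `end`.
#' @return Character vector of symbols.
#' @export
annotate_genes <- function(region, genes) {
  hit <- genes |>
    dplyr::filter(.data$chrom == region$chrom,
                  intervals_overlap(.data$start, .data$end,
                                    region$start, region$end)) |>
    dplyr::arrange(.data$start, .data$end)
  hit$symbol
}

#' Annotate a table of regions with overlapping genes
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, ...), e.g. from
#'   [minimal_common_region()].
#' @param genes Gene model tibble.
#' @return `regions` with a `genes` list column of symbols in genomic
#'   order.
#' @export
annotate_regions <- function(regions, genes) {
  regions$genes <- purrr::pmap(
    regions[, c("chrom", "start", "end")],
    function(chrom, start, end) {
      annotate_genes(list(chrom = chrom, start = start, end = end), genes)
    }
  )
  regions
}

#' Case-by-region co-occurrence incidence table
#'
#' Binary incidence of cases versus query regions: 1 if the case has at
#' least one event (of the region's kind, when given) overlapping the
#' region. Row sums give per-case alteration multiplicity.
#'
#' @param events Event tibble.
#' @param regions Region tibble with `chrom`, `start`, `end`, optionally
#'   `kind` and `region_id`.
#' @param cases Optional character vector of case ids to report (defaults
#'   to all cases appearing in `events`).
#' @return Tibble: `case_id` plus one 0/1 integer column per region.
#' @export
cooccurrence_matrix <- function(events, regions, cases = NULL) {
  cases <- cases %||% sort(unique(events$sample_id))
  if (!"region_id" %in% names(regions)) {
    regions$region_id <- sprintf("%s:%s-%s", regions$chrom,
                                 format(regions$start, scientific = FALSE,
                                        trim = TRUE),
                                 format(regions$end, scientific = FALSE,
                                        trim = TRUE))
  }
  out <- tibble::tibble(case_id = cases)
  for (i in seq_len(nrow(regions))) {
    ev <- events |>
      dplyr::filter(.data$chrom == regions$chrom[i],
                    intervals_overlap(.data$start, .data$end,
                                      regions$start[i], regions$end[i]))
    if ("kind" %in% names(regions) && !is.na(regions$kind[i])) {
      ev <- ev[ev$kind == regions$kind[i], ]
    }
    out[[regions$region_id[i]]] <- as.integer(cases %in% ev$sample_id)
  }
  out
}
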