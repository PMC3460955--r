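## Probe-level CN state classification and per-sample segmentation.
##
## CN values are tumor-vs-paired-normal ratios in arbitrary units with
## diploid ~ 2. The five-state classification uses fixed cutoffs:
## loss <= 1.30, gain >= 2.50 (inclusive), amplification > 5 and
## homozygous deletion < 0.8 (exclusive), applied verbatim to input values.

#' Calling thresholds for CN state classification
#'
#' Bundles the CN cutoffs and segmentation parameters used throughout the
#' pipeline. Defaults are the published cutoffs on the arbitrary-unit
#' tumor/normal scale: values `<= loss_max` are losses, `>= gain_min` gains,
#' strictly above `amp_min` amplifications and strictly below `homdel_max`
#' homozygous deletions.
#'
#' @param loss_max Upper bound (inclusive) for a loss call. Default 1.30.
#' @param gain_min Lower bound (inclusive) for a gain call. Default 2.50.
#' @param amp_min Exclusive lower bound for amplification. Default 5.
#' @param homdel_max Exclusive upper bound for homozygous deletion.
#'   Default 0.8.
#' @param min_probes_per_event Minimum run length (in probes) for a
#'   segmented event; shorter runs are discarded as noise. Default 5.
#' @param smoothing_window Odd window (probe count) for the running-median
#'   smoother applied before classification; 1 disables smoothing.
#'   Default 3.
#' @return A list of class `cna_thresholds`.
#' @examples
#' calling_thresholds()
#' @export
calling_thresholds <- function(loss_max = 1.30, gain_min = 2.50,
                               amp_min = 5, homdel_max = 0.8,
                               min_probes_per_event = 5,
                               smoothing_window = 3) {
  stopifnot_scalar_number(loss_max, "loss_max", 0)
  stopifnot_scalar_number(gain_min, "gain_min", 0)
  stopifnot_scalar_number(amp_min, "amp_min", 0)
  stopifnot_scalar_number(homdel_max, "homdel_max", 0)
  if (!(homdel_max < loss_max && loss_max < gain_min && gain_min < amp_min)) {
    abort("thresholds must satisfy homdel_max < loss_max < gain_min < amp_min")
  }
  stopifnot_scalar_number(min_probes_per_event, "min_probes_per_event", 1)
  stopifnot_scalar_number(smoothing_window, "smoothing_window", 1)
  if (smoothing_window %% 2 != 1) {
    abort("`smoothing_window` must be odd")
  }
  structure(
    list(loss_max = loss_max, gain_min = gain_min, amp_min = amp_min,
         homdel_max = homdel_max,
         min_probes_per_event = as.integer(min_probes_per_event),
         smoothing_window = as.integer(smoothing_window)),
    class = "cna_thresholds"
  )
}

#' Classify CN values into five states
#'
#' Maps each non-negative CN value (arbitrary units, diploid ~ 2) to exactly
#' one of `homozygous_deletion`, `loss`, `neutral`, `gain`, `amplification`.
#' Boundary semantics follow the cutoffs literally: a value equal to
#' `loss_max` is a loss, equal to `gain_min` a gain, equal to `homdel_max` a
#' loss (not a homozygous deletion), and equal to `amp_min` a gain (not an
#' amplification).
#'
#' @param cn Numeric vector of CN values, all `>= 0`.
#' @param thresholds A [calling_thresholds()] object.
#' @return Character vector of states, same length as `cn`.
#' @examples
#' classify_cn_value(c(0.5, 1.3, 2, 2.5, 5.2))
#' @export
classify_cn_value <- function(cn, thresholds = calling_thresholds()) {
  if (any(is.na(cn))) abort("`cn` contains missing values")
  if (any(cn < 0)) abort("`cn` must be non-negative")
  dplyr::case_when(
    cn < thresholds$homdel_max ~ "homozygous_deletion",
    cn <= thresholds$loss_max ~ "loss",
    cn < thresholds$gain_min ~ "neutral",
    cn <= thresholds$amp_min ~ "gain",
    TRUE ~ "amplification"
  )
}

## Running median with endrule = "median"; shrinks the window on short runs.
running_median <- function(x, window) {
  n <- length(x)
  k <- min(window, if (n %% 2 == 1) n else n - 1)
  if (k <= 1 || n <= 2) return(x)
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

#' Smooth CN profiles with a per-chromosome running median
#'
#' Applies a running median (window in probes, odd) independently per
#' chromosome and per sample column. A window of 1 is the identity. The
#' running median removes isolated probe-level spikes while preserving the
#' step edges of true segmental events.
#'
#' @param profiles Probe table: tibble with columns `probe_id`, `chrom`,
#'   `pos` and one numeric CN column per sample, sorted by (chrom, pos).
#' @param window Odd integer window size in probes.
#' @return A tibble with the same shape and coordinates, smoothed values.
#' @export
smooth_profile <- function(profiles, window = 3) {
  stopifnot_scalar_number(window, "window", 1)
  if (window %% 2 != 1) abort("`window` must be odd")
  if (window == 1) return(profiles)
  samples <- sample_columns(profiles)
  profiles |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(samples),
                                ~ running_median(.x, window))) |>
    dplyr::ungroup()
}

#' Segment CN profiles into contiguous alteration events
#'
#' Classifies every probe and collapses maximal runs of consecutive probes
#' sharing one non-neutral state on one chromosome into events. Runs shorter
#' than `min_probes_per_event` are discarded. Event `start`/`end` are the
#' first and last probe positions of the run (1-based inclusive). Values are
#' segmented as given; apply [smooth_profile()] first (or use
#' [call_events()]) for the default smoothed calling.
#'
#' @param profiles Probe table (see [smooth_profile()]); may contain any
#'   number of sample columns.
#' @param thresholds A [calling_thresholds()] object.
#' @param samples Optional character vector restricting which sample columns
#'   to segment.
#' @return Tibble of events: `sample_id`, `chrom`, `start`, `end`, `kind`,
#'   `n_probes`, `mean_cn`, sorted by sample then coordinate.
#' @examples
#' probes <- tibble::tibble(
#'   probe_id = sprintf("p%02d", 1:12), chrom = "chr7",
#'   pos = seq(1e6, 12e6, by = 1e6),
#'   S1 = c(2, 2, 2, 8, 8, 8, 8, 8, 2, 2, 2, 2)
#' )
#' segment_profile(probes, calling_thresholds(min_probes_per_event = 3))
#' @export
segment_profile <- function(profiles, thresholds = calling_thresholds(),
                            samples = NULL) {
  samples <- samples %||% sample_columns(profiles)
  empty <- tibble::tibble(
    sample_id = character(), chrom = character(),
    start = numeric(), end = numeric(), kind = character(),
    n_probes = integer(), mean_cn = numeric()
  )
  if (nrow(profiles) == 0 || length(samples) == 0) return(empty)
  ord <- order(chrom_rank(profiles$chrom), profiles$pos)
  profiles <- profiles[ord, ]

  one_sample <- function(sid) {
    cn <- profiles[[sid]]
    state <- classify_cn_value(cn, thresholds)
    ## break runs at chromosome boundaries
    run_key <- paste(profiles$chrom, state, sep = "\r")
    r <- rle(run_key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    st <- sub("^.*\r", "", r$values)
    keep <- st != "neutral" & r$lengths >= thresholds$min_probes_per_event
    if (!any(keep)) return(empty)
    purrr::map_dfr(which(keep), function(i) {
      idx <- starts[i]:ends[i]
      tibble::tibble(
        sample_id = sid,
        chrom = profiles$chrom[starts[i]],
        start = profiles$pos[starts[i]],
        end = profiles$pos[ends[i]],
        kind = st[i],
        n_probes = r$lengths[i],
        mean_cn = mean(cn[idx])
      )
    })
  }

  purrr::map_dfr(samples, one_sample) |>
    dplyr::arrange(.data$sample_id, chrom_rank(.data$chrom), .data$start)
}

#' Smooth and segment a cohort's CN profiles
#'
#' Convenience wrapper running the default calling pipeline: running-median
#' smoothing with `thresholds$smoothing_window`, then [segment_profile()].
#'
#' @inheritParams segment_profile
#' @return Event tibble as from [segment_profile()].
#' @export
call_events <- function(profiles, thresholds = calling_thresholds(),
                        samples = NULL) {
  smoothed <- smooth_profile(profiles, thresholds$smoothing_window)
  segment_profile(smoothed, thresholds, samples = samples)
}

#' Intersect two probe maps by probe id
#'
#' Harmonizes two array dialects before calling by keeping only probes
#' present (by id) in both maps. Coordinates must agree for shared ids.
#'
#' @param map_a,map_b Probe maps: tibbles with `probe_id`, `chrom`, `pos`.
#' @return The common probe map, sorted by (chrom, pos).
#' @export
intersect_probe_maps <- function(map_a, map_b) {
  shared <- dplyr::inner_join(
    map_a[, c("probe_id", "chrom", "pos")],
    map_b[, c("probe_id", "chrom", "pos")],
    by = "probe_id", suffix = c("", ".b")
  )
  bad <- shared$chrom != shared$chrom.b | shared$pos != shared$pos.b
  if (any(bad)) {
    abort(sprintf(
      "coordinate disagreement for %d shared probe id(s), e.g. %s",
      sum(bad), shared$probe_id[which(bad)[1]]
    ))
  }
  shared |>
    dplyr::select("probe_id", "chrom", "pos") |>
    dplyr::arrange(chrom_rank(.data$chrom), .data$pos)
}
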