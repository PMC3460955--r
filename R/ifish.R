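## iFISH spot-count classification and array-vs-iFISH concordance.
##
## Per-case spot-count distributions are summarized as fractions of nuclei
## per signal class; classification uses percent-of-nuclei cutoffs: gain
## when >= 5% of nuclei show increased signals, loss when >= 10% show
## decreased signals, amplification when > 10% show a locus:centromere
## ratio > 2 or tight signal clusters, homozygous deletion when >= 5% show
## centromeric but no locus signal. Criteria are combined with a fixed
## precedence: amplification > homozygous deletion > gain > loss > normal.

IFISH_STATES <- c("amplification", "homozygous_deletion", "gain", "loss",
                  "normal")

#' Classify iFISH spot-count fractions into CN states
#'
#' @param counts Tibble with columns `fraction_increased`,
#'   `fraction_decreased`, `fraction_no_locus_with_cep`,
#'   `fraction_ratio_gt2_or_clusters` (all in \[0, 1\]) and optionally
#'   `n_nuclei` (a warning flags rows with fewer than `min_nuclei` scored
#'   nuclei). Mutually exclusive classes must be plausible:
#'   `fraction_increased + fraction_decreased <= 1`.
#' @param min_nuclei Minimum nuclei per slide before a row is flagged.
#'   Default 200.
#' @return `counts` with a `state` column (`amplification`,
#'   `homozygous_deletion`, `gain`, `loss` or `normal`).
#' @examples
#' classify_ifish(tibble::tibble(
#'   fraction_increased = 0.06, fraction_decreased = 0,
#'   fraction_no_locus_with_cep = 0, fraction_ratio_gt2_or_clusters = 0
#' ))$state
#' @export
classify_ifish <- function(counts, min_nuclei = 200) {
  fr <- counts[, c("fraction_increased", "fraction_decreased",
                   "fraction_no_locus_with_cep",
                   "fraction_ratio_gt2_or_clusters")]
  if (any(as.matrix(fr) < 0 | as.matrix(fr) > 1, na.rm = FALSE)) {
    abort("all fractions must lie in [0, 1]")
  }
  if (any(counts$fraction_increased + counts$fraction_decreased > 1)) {
    abort("implausible fractions: increased + decreased exceeds 1")
  }
  if ("n_nuclei" %in% names(counts) &&
      any(counts$n_nuclei < min_nuclei)) {
    warn(sprintf("%d row(s) scored fewer than %d nuclei",
                 sum(counts$n_nuclei < min_nuclei), min_nuclei))
  }
  counts$state <- dplyr::case_when(
    counts$fraction_ratio_gt2_or_clusters > 0.10 ~ "amplification",
    counts$fraction_no_locus_with_cep >= 0.05 ~ "homozygous_deletion",
    counts$fraction_increased >= 0.05 ~ "gain",
    counts$fraction_decreased >= 0.10 ~ "loss",
    TRUE ~ "normal"
  )
  counts
}

#' Concordance between array-based and iFISH-based CN calls
#'
#' Joins the two call sets on (case, locus) and tabulates agreement: a
#' contingency table of array state vs iFISH state, per-locus agreement
#' percentages, and the overall percent agreement.
#'
#' @param array_calls Tibble with `case_id`, `locus`, `state`.
#' @param ifish_calls Tibble with `case_id`, `locus`, `state` (e.g. from
#'   [classify_ifish()]).
#' @return List: `contingency` (tibble `locus`, `array_state`,
#'   `ifish_state`, `n`), `by_locus` (tibble `locus`, `n_cases`,
#'   `n_agree`, `agreement_pct`), `overall_pct` (scalar percent).
#' @export
concordance_table <- function(array_calls, ifish_calls) {
  joined <- dplyr::inner_join(
    array_calls[, c("case_id", "locus", "state")],
    ifish_calls[, c("case_id", "locus", "state")],
    by = c("case_id", "locus"), suffix = c("_array", "_ifish")
  )
  if (nrow(joined) == 0) abort("no shared (case, locus) pairs")
  ## an array "neutral" call and an iFISH "normal" call agree
  norm <- function(s) ifelse(s == "neutral", "normal", s)
  joined <- joined |>
    dplyr::mutate(array_state = norm(.data$state_array),
                  ifish_state = norm(.data$state_ifish),
                  agree = .data$array_state == .data$ifish_state)
  contingency <- joined |>
    dplyr::count(.data$locus, .data$array_state, .data$ifish_state,
                 name = "n")
  by_locus <- joined |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(n_cases = dplyr::n(), n_agree = sum(.data$agree),
                     agreement_pct = 100 * mean(.data$agree),
                     .groups = "drop")
  list(contingency = contingency, by_locus = by_locus,
       overall_pct = 100 * mean(joined$agree))
}
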