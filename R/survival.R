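## Kaplan-Meier estimation, median survival and log-rank comparison of
## carrier vs non-carrier groups. Product-limit curves and the log-rank
## statistic come from the survival package; the median rule (smallest
## event time with S(t) <= 0.5) and group stratification are applied here.

## Normalize a clinical tibble to (case_id, time, status) with status 1 =
## death, 0 = censored. Accepts `survival_months`/`time` and
## `vital_status` ("deceased"/"alive") or `event` ("deceased"/"censored").
as_survival_records <- function(clinical) {
  col <- function(...) {
    nm <- intersect(c(...), names(clinical))
    if (length(nm) > 0) clinical[[nm[1]]] else NULL
  }
  time <- col("time", "survival_months")
  if (is.null(time)) abort("no `time` or `survival_months` column")
  status_col <- col("event", "vital_status", "status")
  status <- if (is.null(status_col)) {
    rep(1L, length(time))
  } else if (is.numeric(status_col)) {
    as.integer(status_col)
  } else {
    as.integer(status_col %in% c("deceased", "dead", "death"))
  }
  if (any(is.na(time)) || any(time < 0)) {
    abort("survival times must be non-negative and non-missing")
  }
  tibble::tibble(
    case_id = col("case_id") %||% as.character(seq_along(time)),
    time = as.numeric(time), status = status
  )
}

## Zero-month follow-up handling: such cases are valid deaths at t = 0 and
## are retained by default, but published survival figures sometimes drop
## them (a 46-case table plotted as n = 45). `drop_zero_followup = TRUE`
## reproduces that convention.
handle_zero_followup <- function(rec, drop_zero_followup) {
  zero <- rec$time == 0
  if (!any(zero)) return(rec)
  if (drop_zero_followup) {
    rec[!zero, , drop = FALSE]
  } else {
    warn(sprintf(
      "%d record(s) with zero follow-up retained as deaths at t = 0; set drop_zero_followup = TRUE to exclude them",
      sum(zero)
    ))
    rec
  }
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function. Censored times reduce
#' the at-risk count without introducing a step; ties between deaths and
#' censorings at the same time are resolved deaths-first (the standard
#' convention). Deaths at time 0 are retained (the curve then drops at 0).
#'
#' @param records Clinical tibble with `case_id`, a time column
#'   (`survival_months` or `time`, months) and a status column
#'   (`vital_status` with `"deceased"`/`"alive"`, or `event`, or numeric
#'   0/1).
#' @param drop_zero_followup Exclude records with zero follow-up time
#'   instead of keeping them as deaths at t = 0 (the default warns when
#'   such records are present).
#' @return A tibble of class `cna_km` with one row per distinct time
#'   (plus t = 0): `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @examples
#' km <- km_estimate(tibble::tibble(case_id = letters[1:4],
#'                                  time = c(1, 2, 4, 8), event = 1))
#' km_median(km)
#' @export
km_estimate <- function(records, drop_zero_followup = FALSE) {
  rec <- handle_zero_followup(as_survival_records(records),
                              drop_zero_followup)
  if (nrow(rec) == 0) abort("no survival records")
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = rec)
  curve <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv
  )
  if (!any(curve$time == 0)) {
    curve <- dplyr::bind_rows(
      tibble::tibble(time = 0, n_risk = nrow(rec), n_event = 0L,
                     n_censor = 0L, surv = 1),
      curve
    )
  }
  structure(curve, class = c("cna_km", class(curve)),
            n = nrow(rec), n_event = sum(rec$status))
}

#' Kaplan-Meier median survival
#'
#' The smallest event time t with S(t) <= 0.5; `NA` when the curve never
#' reaches 0.5 (e.g. all records censored).
#'
#' @param curve A `cna_km` curve from [km_estimate()], or any tibble with
#'   `time`, `surv` and `n_event` columns.
#' @return Median survival in months, or `NA_real_` if undefined.
#' @export
km_median <- function(curve) {
  drops <- curve[curve$n_event > 0 & curve$surv <= 0.5, ]
  if (nrow(drops) == 0) return(NA_real_)
  min(drops$time)
}

#' @export
glance.cna_km <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), n_event = attr(x, "n_event"),
                 median = km_median(x))
}

#' @export
tidy.cna_km <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Log-rank test between two survival groups
#'
#' Standard observed-vs-expected log-rank statistic over the pooled event
#' times, with p from the chi-square distribution with 1 df.
#'
#' @param group_a,group_b Clinical tibbles (see [km_estimate()] for
#'   accepted columns); both non-empty.
#' @inheritParams km_estimate
#' @return A one-row tibble of class `cna_logrank`: `chisq`, `df`,
#'   `p_value`, `n_a`, `n_b`.
#' @export
logrank_test <- function(group_a, group_b, drop_zero_followup = FALSE) {
  a <- handle_zero_followup(as_survival_records(group_a),
                            drop_zero_followup)
  b <- handle_zero_followup(as_survival_records(group_b),
                            drop_zero_followup)
  if (nrow(a) == 0 || nrow(b) == 0) abort("both groups must be non-empty")
  if (sum(a$status) == 0 || sum(b$status) == 0) {
    warn("a group has zero observed events; the log-rank statistic is still defined")
  }
  pooled <- dplyr::bind_rows(
    dplyr::mutate(a, group = "a"), dplyr::mutate(b, group = "b")
  )
  if (sum(pooled$status) == 0) {
    res <- tibble::tibble(chisq = 0, df = 1L, p_value = 1,
                          n_a = nrow(a), n_b = nrow(b))
    return(structure(res, class = c("cna_logrank", class(res))))
  }
  sd <- survival::survdiff(survival::Surv(time, status) ~ group,
                           data = pooled)
  chisq <- unname(sd$chisq)
  res <- tibble::tibble(
    chisq = chisq, df = 1L,
    p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
    n_a = nrow(a), n_b = nrow(b)
  )
  structure(res, class = c("cna_logrank", class(res)))
}

#' @export
glance.cna_logrank <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
tidy.cna_logrank <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Stratify a clinical table by event-carrier status
#'
#' Splits cases into a positive group (at least one qualifying event
#' overlapping the query gene or region) and a negative group (all
#' others). Event case ids must all be present in the clinical table.
#'
#' @param clinical Clinical tibble with `case_id`.
#' @param events Event tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `kind`); ignored when `positive_ids` is given.
#' @param region List with `chrom`, `start`, `end` defining the query
#'   locus; alternatively supply `gene` (a one-row gene model).
#' @param gene One-row tibble/list with `chrom`, `start`, `end` (e.g. a
#'   gene model row); used as the region.
#' @param kind Qualifying event kind. Default `"amplification"`.
#' @param positive_ids Explicit carrier case ids (bypasses `events`).
#' @return List with `positive` and `negative` clinical tibbles.
#' @export
stratify_by_event <- function(clinical, events = NULL, region = NULL,
                              gene = NULL, kind = "amplification",
                              positive_ids = NULL) {
  if (is.null(positive_ids)) {
    region <- region %||% gene
    if (is.null(events) || is.null(region)) {
      abort("supply either `positive_ids` or `events` plus a `region`/`gene`")
    }
    unmatched <- setdiff(unique(events$sample_id), clinical$case_id)
    if (length(unmatched) > 0) {
      abort(paste0("event case ids missing from clinical table: ",
                   paste(unmatched, collapse = ", ")))
    }
    hits <- events |>
      dplyr::filter(.data$kind == !!kind, .data$chrom == region$chrom,
                    intervals_overlap(.data$start, .data$end,
                                      region$start, region$end))
    positive_ids <- unique(hits$sample_id)
  } else {
    unmatched <- setdiff(positive_ids, clinical$case_id)
    if (length(unmatched) > 0) {
      abort(paste0("carrier case ids missing from clinical table: ",
                   paste(unmatched, collapse = ", ")))
    }
  }
  list(
    positive = clinical[clinical$case_id %in% positive_ids, , drop = FALSE],
    negative = clinical[!clinical$case_id %in% positive_ids, , drop = FALSE]
  )
}
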