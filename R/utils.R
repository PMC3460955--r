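## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Integer rounding where exact halves move away from zero, the convention
#' used for percent frequencies in cohort reports (e.g. 24/46 -> 52%,
#' 21/46 -> 46%). Base `round()` rounds halves to even and would disagree on
#' x.5 inputs.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4, -0.5))
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## Rank used to order chromosome names naturally: chr1 < chr2 < ... < chr22
## < chrX < chrY; unknown names sort after, alphabetically.
chrom_rank <- function(chrom) {
  base <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(base))
  num[base == "X"] <- 23
  num[base == "Y"] <- 24
  num[base == "M" | base == "MT"] <- 25
  ifelse(is.na(num), 1000 + as.numeric(factor(base)), num)
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

## Column names of a probe table that hold per-sample CN values.
sample_columns <- function(profiles) {
  setdiff(names(profiles), c("probe_id", "chrom", "pos"))
}

## 1-based inclusive interval overlap (>= 1 bp).
intervals_overlap <- function(start1, end1, start2, end2) {
  start1 <= end2 & end1 >= start2
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(min), format(max)))
  }
  invisible(x)
}
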