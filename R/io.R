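## Readers and writers for the pipeline's tabular formats.
##
## Native tables are TSV whose header line starts with `#`; doubles are
## written with 6 significant digits so writers are deterministic.
## Coordinates are 1-based inclusive everywhere in memory; BED files
## (0-based half-open) are converted on the way in and out.

format_native <- function(x) {
  if (is.double(x)) {
    ## whole numbers (genomic positions) keep full precision; fractional
    ## values are fixed at 6 significant digits for stable output
    ifelse(is.finite(x) & x == round(x),
           sprintf("%.0f", x), sprintf("%.6g", x))
  } else {
    as.character(x)
  }
}

#' Write a native TSV table (commented header, 6-significant-digit floats)
#'
#' @param tbl A data frame; list columns are collapsed with `;`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cna_tsv <- function(tbl, path) {
  tbl <- dplyr::mutate(tbl, dplyr::across(
    dplyr::where(is.list), ~ purrr::map_chr(.x, paste, collapse = ";")
  ))
  cols <- lapply(tbl, format_native)
  lines <- c(
    paste0("#", paste(names(tbl), collapse = "\t")),
    if (nrow(tbl) > 0) do.call(paste, c(cols, sep = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a native TSV table written by [write_cna_tsv()]
#'
#' @param path Input path.
#' @param col_types Optional readr column specification.
#' @return A tibble.
#' @export
read_cna_tsv <- function(path, col_types = NULL) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#")) {
    abort(sprintf("%s: expected a '#'-prefixed header line", path))
  }
  nms <- strsplit(sub("^#", "", header), "\t")[[1]]
  readr::read_tsv(path, skip = 1, col_names = nms,
                  col_types = col_types %||% readr::cols(),
                  progress = FALSE, show_col_types = FALSE)
}

#' Read a probe-level CN table
#'
#' Native TSV with columns `probe_id`, `chrom`, `pos` and one CN column per
#' sample. Rows are returned sorted by (chrom, pos); malformed coordinate
#' values raise an error naming the offending line.
#'
#' @param path Input path.
#' @return Wide CN profile tibble.
#' @export
read_probe_table <- function(path) {
  tbl <- read_cna_tsv(path)
  required <- c("probe_id", "chrom", "pos")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tbl) > 0) {
    bad <- which(is.na(tbl$pos) | tbl$pos < 1)
    if (length(bad) > 0) {
      abort(sprintf("%s: invalid position at data line %d", path, bad[1]))
    }
  }
  dplyr::arrange(tbl, chrom_rank(.data$chrom), .data$pos)
}

#' @rdname read_probe_table
#' @param profiles Wide CN profile tibble.
#' @export
write_probe_table <- function(profiles, path) {
  write_cna_tsv(profiles, path)
}

#' Read gene models from BED
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention (`start = start0 + 1`, `end = end0`). A
#' line like `chr9 21978442 22119128` therefore becomes the interval
#' 21,978,443-22,119,128.
#'
#' @param path BED path (3+ columns; 4th column taken as the symbol).
#' @return Gene model tibble: `symbol`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t")
  rows <- purrr::imap(fields, function(f, i) {
    if (length(f) < 3) {
      abort(sprintf("%s: malformed BED line %d (fewer than 3 fields)",
                    path, i))
    }
    start0 <- suppressWarnings(as.numeric(f[2]))
    end0 <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start0) || is.na(end0) || start0 < 0 || end0 <= start0) {
      abort(sprintf("%s: invalid 0-based half-open coordinates at line %d",
                    path, i))
    }
    tibble::tibble(
      symbol = if (length(f) >= 4) f[4] else sprintf("feature_%d", i),
      chrom = f[1], start = start0 + 1, end = end0
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(chrom_rank(.data$chrom), .data$start)
}

#' Write CN events
#'
#' `write_events` writes the native 1-based TSV report;
#' `write_events_bed` exports BED6-like lines (0-based half-open) for
#' genome browsers, with the sample id as the name field and the mean CN in
#' the score slot.
#'
#' @param events Event tibble from [segment_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  write_cna_tsv(events, path)
}

#' @rdname write_events
#' @export
write_events_bed <- function(events, path) {
  lines <- sprintf(
    "%s\t%.0f\t%.0f\t%s\t%s\t%s",
    events$chrom, events$start - 1, events$end,
    events$sample_id, format_native(events$mean_cn), events$kind
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read_cna_tsv(path, readr::cols(
    sample_id = "c", chrom = "c", start = "d", end = "d", kind = "c",
    n_probes = "i", mean_cn = "d"
  ))
}

#' Read / write a clinical table
#'
#' Plain TSV with at least `case_id`, `survival_months` and `vital_status`
#' columns (the packaged clinical fixture's schema).
#'
#' @param path File path.
#' @return Clinical tibble.
#' @export
read_clinical <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  required <- c("case_id", "survival_months", "vital_status")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl
}

#' @rdname read_clinical
#' @param clinical Clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_tsv(clinical, path, progress = FALSE)
  invisible(path)
}

#' Write a named list of report tables
#'
#' Each table goes to `<dir>/<name>.tsv` in the native format (list
#' columns, e.g. MCR case and gene lists, are `;`-collapsed).
#'
#' @param tables Named list of tibbles.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::imap_chr(tables, function(tbl, name) {
    write_cna_tsv(tbl, file.path(dir, paste0(name, ".tsv")))
  })
  invisible(paths)
}
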