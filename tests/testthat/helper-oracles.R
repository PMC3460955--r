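# Independent reference implementations used as oracles. These stay
# deliberately naive (per-probe loops, per-base counting, explicit 2x2
# tables) and share no code with the package internals they check.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Five-state classification as an explicit if-chain.
oracle_classify <- function(cn) {
  vapply(cn, function(x) {
    if (x < 0.8) {
      "homozygous_deletion"
    } else if (x <= 1.30) {
      "loss"
    } else if (x < 2.50) {
      "neutral"
    } else if (x <= 5) {
      "gain"
    } else {
      "amplification"
    }
  }, character(1))
}

# Run-length scan over per-probe states for a single sample on one table
# of probes sorted by (chrom, pos).
oracle_segment <- function(probes, cn, sample_id, min_probes = 5) {
  states <- oracle_classify(cn)
  out <- list()
  i <- 1
  n <- length(cn)
  while (i <= n) {
    j <- i
    while (j < n && states[j + 1] == states[i] &&
             probes$chrom[j + 1] == probes$chrom[i]) {
      j <- j + 1
    }
    if (states[i] != "neutral" && (j - i + 1) >= min_probes) {
      out[[length(out) + 1]] <- tibble::tibble(
        sample_id = sample_id, chrom = probes$chrom[i],
        start = probes$pos[i], end = probes$pos[j], kind = states[i],
        n_probes = as.integer(j - i + 1), mean_cn = mean(cn[i:j])
      )
    }
    i <- j + 1
  }
  dplyr::bind_rows(out)
}

# Per-base coverage scan for minimal common regions on small coordinates.
# Returns regions (start, end, n_cases, case_ids) per chromosome.
oracle_mcr <- function(events, kind, min_cases) {
  ev <- events[events$kind == kind, ]
  out <- list(tibble::tibble(chrom = character(), start = integer(),
                             end = integer(), n_cases = integer(),
                             case_ids = list()))
  for (chrom in sort(unique(ev$chrom))) {
    evc <- ev[ev$chrom == chrom, ]
    max_pos <- max(evc$end)
    samples <- sort(unique(evc$sample_id))
    covered <- sapply(samples, function(s) {
      v <- rep(FALSE, max_pos)
      rows <- evc[evc$sample_id == s, ]
      for (r in seq_len(nrow(rows))) {
        v[rows$start[r]:rows$end[r]] <- TRUE
      }
      v
    })
    covered <- matrix(covered, ncol = length(samples))
    cov <- rowSums(covered)
    above <- cov >= min_cases
    base <- 1
    while (base <= max_pos) {
      if (!above[base]) {
        base <- base + 1
        next
      }
      run_end <- base
      while (run_end < max_pos && above[run_end + 1]) run_end <- run_end + 1
      m <- max(cov[base:run_end])
      sets <- apply(covered[base:run_end, , drop = FALSE], 1, function(row) {
        paste(samples[row], collapse = ",")
      })
      at_max <- (base:run_end)[cov[base:run_end] == m]
      k <- 1
      while (k <= length(at_max)) {
        l <- k
        while (l < length(at_max) && at_max[l + 1] == at_max[l] + 1 &&
                 sets[at_max[l + 1] - base + 1] == sets[at_max[l] - base + 1]) {
          l <- l + 1
        }
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = chrom, start = at_max[k], end = at_max[l],
          n_cases = as.integer(m),
          case_ids = list(strsplit(sets[at_max[k] - base + 1], ",")[[1]])
        )
        k <- l + 1
      }
      base <- run_end + 1
    }
  }
  dplyr::bind_rows(out)
}

# Explicit observed-vs-expected log-rank over pooled event times.
oracle_logrank <- function(time_a, status_a, time_b, status_b) {
  times <- sort(unique(c(time_a[status_a == 1], time_b[status_b == 1])))
  O_A <- 0; E_A <- 0; V <- 0
  for (t in times) {
    nA <- sum(time_a >= t); nB <- sum(time_b >= t)
    dA <- sum(time_a == t & status_a == 1)
    dB <- sum(time_b == t & status_b == 1)
    n <- nA + nB; d <- dA + dB
    if (n < 1 || d < 1) next
    O_A <- O_A + dA
    E_A <- E_A + d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (nB / n) * (n - d) / (n - 1)
  }
  (O_A - E_A)^2 / V
}

# Small random event tables on compact coordinates (for MCR tests).
random_small_events <- function(n_events, n_samples = 6, max_pos = 400,
                                kind = "homozygous_deletion") {
  start <- sample(seq_len(max_pos - 20), n_events, replace = TRUE)
  len <- sample(5:80, n_events, replace = TRUE)
  tibble::tibble(
    sample_id = sample(sprintf("s%d", seq_len(n_samples)), n_events,
                       replace = TRUE),
    chrom = "chr9", start = start, end = pmin(start + len, max_pos),
    kind = kind
  )
}

# Tiny single-chromosome probe table builder.
make_probes <- function(cn_by_sample, chrom = "chr7", spacing = 1e5) {
  n <- length(cn_by_sample[[1]])
  dplyr::bind_cols(
    tibble::tibble(
      probe_id = sprintf("%s_p%04d", chrom, seq_len(n)),
      chrom = chrom, pos = seq(spacing, n * spacing, by = spacing)
    ),
    tibble::as_tibble(cn_by_sample)
  )
}
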