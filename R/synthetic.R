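## Synthetic GBM-like cohort generator.
##
## Emulates the statistical structure the downstream analysis assumes:
## per-sample probe-level CN profiles with a diploid baseline near 2,
## segmental amplicons / homozygous deletions implanted at configurable
## per-region prevalences, expression linearly coupled to gene-level CN for
## a chosen gene subset, exponential survival with an amplification-
## dependent hazard, and iFISH spot-count fractions drawn from the true
## per-case states. Every generator is fully determined by its seed.

#' Specify one implantable segmental CN event
#'
#' @param chrom,start,end Genomic interval (1-based inclusive) on which the
#'   event is implanted.
#' @param kind One of `amplification`, `homozygous_deletion`, `gain`,
#'   `loss`.
#' @param prevalence Probability that a given sample carries the event.
#' @param cn_level (low, high) bounds of the uniform draw for the event's
#'   CN level, in arbitrary units. Bounds must be consistent with the
#'   calling cutoff for `kind` (amplification > 5, homozygous deletion
#'   < 0.8, gain in (2.5, 5], loss in [0.8, 1.3]).
#' @param boundary_jitter Half-width (bp) of the uniform jitter applied
#'   independently to each event boundary per carrier sample.
#' @return One-row tibble describing the event spec.
#' @export
event_spec <- function(chrom, start, end, kind, prevalence,
                       cn_level = NULL, boundary_jitter = 1e5) {
  kind <- match.arg(kind, CNA_KINDS)
  stopifnot_scalar_number(prevalence, "prevalence", 0, 1)
  stopifnot_scalar_number(start, "start", 1)
  stopifnot_scalar_number(end, "end", start)
  cn_level <- cn_level %||% switch(kind,
    amplification = c(6, 9),
    homozygous_deletion = c(0.1, 0.5),
    gain = c(2.8, 4),
    loss = c(0.9, 1.2)
  )
  lo <- cn_level[1]; hi <- cn_level[2]
  ok <- switch(kind,
    amplification = lo > 5,
    homozygous_deletion = hi < 0.8 && lo >= 0,
    gain = lo > 2.5 && hi <= 5,
    loss = lo >= 0.8 && hi <= 1.3
  )
  if (!isTRUE(ok) || lo > hi) {
    abort(sprintf("cn_level bounds (%g, %g) inconsistent with kind '%s'",
                  lo, hi, kind))
  }
  tibble::tibble(
    chrom = chrom, start = start, end = end, kind = kind,
    prevalence = prevalence, cn_low = lo, cn_high = hi,
    boundary_jitter = boundary_jitter
  )
}

#' Default chromosome models for the synthetic genome
#'
#' The eight chromosomes recurrently altered in the emulated cohort, with
#' approximate hg17-scale lengths.
#'
#' @return Tibble with `chrom` and `length_bp`.
#' @export
default_chromosomes <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr4", "chr7", "chr9", "chr10", "chr11", "chr12",
              "chr17"),
    length_bp = c(245.5e6, 191.4e6, 158.6e6, 138.4e6, 135.4e6, 134.5e6,
                  132.4e6, 78.8e6)
  )
}

#' Default event table: recurrent GBM amplicons and homozygous deletions
#'
#' One spec per recurrently altered region, with prevalences matching the
#' reported cohort frequencies: amplicons on chromosomes 7 (50%), 12 (22%),
#' 1 (11%), 4 (9%), 11 (4%) and 17 (4%), homozygous deletions at 9p21 (52%)
#' and 10q (22%). Regions are placed at hg17-like coordinates around the
#' loci the events target (EGFR at 7p11.2, the 12q13-15 cluster, MDM4 at
#' 1q32.1, PDGFRA at 4q12, CDKN2A/MTAP at 9p21.3, PTEN at 10q23.31).
#'
#' @return Tibble of event specs (one row per region).
#' @export
default_event_specs <- function() {
  dplyr::bind_rows(
    event_spec("chr7", 54.0e6 + 1, 56.5e6, "amplification", 0.50,
               cn_level = c(6, 10)),
    event_spec("chr12", 56.0e6 + 1, 58.5e6, "amplification", 0.22),
    event_spec("chr1", 202.0e6 + 1, 204.5e6, "amplification", 0.11),
    event_spec("chr4", 53.5e6 + 1, 56.0e6, "amplification", 0.09),
    event_spec("chr11", 32.0e6 + 1, 34.5e6, "amplification", 0.04),
    event_spec("chr17", 57.0e6 + 1, 59.5e6, "amplification", 0.04),
    event_spec("chr9", 20.5e6 + 1, 23.0e6, "homozygous_deletion", 0.52),
    event_spec("chr10", 88.5e6 + 1, 91.0e6, "homozygous_deletion", 0.22)
  )
}

#' Cohort generator configuration
#'
#' Collects every knob of the synthetic cohort. Defaults emulate the
#' 46-tumor study cohort: the event table of [default_event_specs()],
#' Gaussian baseline noise around a diploid CN of 2, expression coupling on
#' an RMA-like log2 scale, exponential survival with median 13 months and a
#' 6.5-fold hazard for carriers of the flagged amplicon, and a single-case
#' censoring rate (1/46).
#'
#' @param n_samples Number of tumors (>= 2). Default 46.
#' @param probe_spacing Distance between consecutive probes, bp.
#'   Default 100 kb.
#' @param chromosomes Tibble (`chrom`, `length_bp`); default
#'   [default_chromosomes()].
#' @param event_specs Tibble of event specs; default
#'   [default_event_specs()].
#' @param baseline_cn Diploid baseline CN in arbitrary units. Default 2.
#' @param baseline_noise_sd Gaussian probe noise sd, CN units. Default 0.15.
#' @param dosage_coupled_fraction Fraction of genes whose expression is
#'   coupled to CN when no explicit coupled set is given. Default 0.5.
#' @param expression_noise_sd Residual sd of expression around the linear
#'   CN coupling, RMA units. Default 0.5.
#' @param hazard_ratio_amplified Hazard ratio for carriers of the flagged
#'   event. Default 6.5 (13-month baseline median vs 2 months).
#' @param baseline_median_survival Median survival of non-carriers, months.
#'   Default 13.
#' @param censoring_rate Per-case probability of censoring. Default 1/46.
#' @param seed Integer seed; fully determines all generator output.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 46, probe_spacing = 1e5,
                          chromosomes = default_chromosomes(),
                          event_specs = default_event_specs(),
                          baseline_cn = 2, baseline_noise_sd = 0.15,
                          dosage_coupled_fraction = 0.5,
                          expression_noise_sd = 0.5,
                          hazard_ratio_amplified = 6.5,
                          baseline_median_survival = 13,
                          censoring_rate = 1 / 46,
                          seed = 1L) {
  stopifnot_scalar_number(n_samples, "n_samples", 2)
  stopifnot_scalar_number(probe_spacing, "probe_spacing", 1)
  stopifnot_scalar_number(baseline_cn, "baseline_cn", 0)
  stopifnot_scalar_number(baseline_noise_sd, "baseline_noise_sd", 0)
  stopifnot_scalar_number(dosage_coupled_fraction,
                          "dosage_coupled_fraction", 0, 1)
  stopifnot_scalar_number(expression_noise_sd, "expression_noise_sd", 0)
  stopifnot_scalar_number(hazard_ratio_amplified, "hazard_ratio_amplified",
                          min = .Machine$double.eps)
  stopifnot_scalar_number(baseline_median_survival,
                          "baseline_median_survival",
                          min = .Machine$double.eps)
  stopifnot_scalar_number(censoring_rate, "censoring_rate", 0, 1)
  if (nrow(event_specs) > 0 &&
      any(event_specs$prevalence < 0 | event_specs$prevalence > 1)) {
    abort("event prevalences must lie in [0, 1]")
  }
  ## reject contradictory overlapping specs (same interval, different kind)
  if (nrow(event_specs) > 1) {
    for (i in seq_len(nrow(event_specs) - 1)) {
      for (j in seq(i + 1, nrow(event_specs))) {
        same_chrom <- event_specs$chrom[i] == event_specs$chrom[j]
        if (same_chrom &&
            intervals_overlap(event_specs$start[i], event_specs$end[i],
                              event_specs$start[j], event_specs$end[j]) &&
            event_specs$kind[i] != event_specs$kind[j]) {
          abort(sprintf(
            "event specs %d and %d overlap on %s with contradictory kinds",
            i, j, event_specs$chrom[i]
          ))
        }
      }
    }
  }
  structure(
    list(n_samples = as.integer(n_samples), probe_spacing = probe_spacing,
         chromosomes = chromosomes, event_specs = event_specs,
         baseline_cn = baseline_cn, baseline_noise_sd = baseline_noise_sd,
         dosage_coupled_fraction = dosage_coupled_fraction,
         expression_noise_sd = expression_noise_sd,
         hazard_ratio_amplified = hazard_ratio_amplified,
         baseline_median_survival = baseline_median_survival,
         censoring_rate = censoring_rate, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

sample_ids_for <- function(n) sprintf("S%02d", seq_len(n))

#' Generate a synthetic cohort of CN profiles
#'
#' Draws each sample's probe-level profile as Gaussian noise around the
#' diploid baseline, then implants each event spec independently per sample
#' with its prevalence: carriers get a per-event CN level drawn uniformly
#' from the spec's bounds, written (plus the same probe noise) over all
#' probes inside the per-sample jittered interval. The returned truth table
#' records the exact implanted intervals.
#'
#' @param config A [cohort_config()].
#' @return List with `probes` (probe map tibble: `probe_id`, `chrom`,
#'   `pos`), `cn` (wide tibble: probe map columns plus one CN column per
#'   sample) and `truth` (tibble: `chrom`, `start`, `end`, `sample_id`,
#'   `kind`, `cn_level`).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_samples = 4, seed = 7))
#' dim(cohort$cn)
#' @export
generate_cohort <- function(config = cohort_config()) {
  probes <- config$chromosomes |>
    dplyr::mutate(chrom = as.character(.data$chrom)) |>
    purrr::pmap_dfr(function(chrom, length_bp) {
      pos <- seq(config$probe_spacing, length_bp, by = config$probe_spacing)
      tibble::tibble(
        probe_id = sprintf("%s_p%06d", chrom, seq_along(pos)),
        chrom = chrom, pos = pos
      )
    }) |>
    dplyr::arrange(chrom_rank(.data$chrom), .data$pos)

  ids <- sample_ids_for(config$n_samples)
  n_probes <- nrow(probes)
  specs <- config$event_specs

  with_seed(config$seed, {
    cn_cols <- vector("list", length(ids))
    names(cn_cols) <- ids
    truth <- list()
    for (s in seq_along(ids)) {
      cn <- rnorm(n_probes, mean = config$baseline_cn,
                  sd = config$baseline_noise_sd)
      if (nrow(specs) > 0) {
        for (k in seq_len(nrow(specs))) {
          carrier <- runif(1) < specs$prevalence[k]
          if (!carrier) next
          j <- specs$boundary_jitter[k]
          start_j <- max(1, round(specs$start[k] + runif(1, -j, j)))
          end_j <- round(specs$end[k] + runif(1, -j, j))
          if (end_j < start_j) end_j <- start_j
          level <- runif(1, specs$cn_low[k], specs$cn_high[k])
          idx <- which(probes$chrom == specs$chrom[k] &
                         probes$pos >= start_j & probes$pos <= end_j)
          if (length(idx) > 0) {
            cn[idx] <- pmax(0, level + rnorm(length(idx),
                                             sd = config$baseline_noise_sd))
          }
          truth[[length(truth) + 1]] <- tibble::tibble(
            chrom = specs$chrom[k], start = start_j, end = end_j,
            sample_id = ids[s], kind = specs$kind[k], cn_level = level
          )
        }
      }
      cn_cols[[s]] <- pmax(0, cn)
    }
    truth <- if (length(truth) > 0) {
      dplyr::bind_rows(truth) |>
        dplyr::arrange(.data$sample_id, chrom_rank(.data$chrom), .data$start)
    } else {
      tibble::tibble(chrom = character(), start = numeric(),
                     end = numeric(), sample_id = character(),
                     kind = character(), cn_level = numeric())
    }
    list(probes = probes,
         cn = dplyr::bind_cols(probes, tibble::as_tibble(cn_cols)),
         truth = truth)
  })
}

#' Generate expression coupled to gene-level CN
#'
#' For genes in `coupled_genes`, expression is `intercept + slope * CN +
#' N(0, noise_sd)` with positive slope, where the gene's CN is the mean of
#' probes overlapping its (flanked) interval, as in
#' [summarize_gene_cn()]. Uncoupled genes get expression independent of CN
#' (Gaussian around the diploid-coupled mean). Values are on an RMA-like
#' log2 scale.
#'
#' @param profiles Wide CN probe table (as `generate_cohort()$cn`).
#' @param genes Gene models: tibble `symbol`, `chrom`, `start`, `end`.
#' @param coupled_genes Character vector of coupled gene symbols
#'   (non-empty; must lie on chromosomes covered by probes).
#' @param intercept,slope Linear coupling coefficients (slope > 0).
#' @param noise_sd Residual sd (RMA units) around the coupling line.
#' @param uncoupled_sd Sd of uncoupled genes' expression. Default 0.8.
#' @param seed Integer seed.
#' @return Wide expression tibble: `symbol` plus one column per sample.
#' @export
generate_expression <- function(profiles, genes, coupled_genes,
                                intercept = 6, slope = 1, noise_sd = 0.5,
                                uncoupled_sd = 0.8, seed = 1L) {
  if (length(coupled_genes) == 0) abort("`coupled_genes` must be non-empty")
  if (slope <= 0) abort("`slope` must be positive")
  missing_genes <- setdiff(coupled_genes, genes$symbol)
  if (length(missing_genes) > 0) {
    abort(paste0("coupled genes absent from gene models: ",
                 paste(missing_genes, collapse = ", ")))
  }
  covered <- genes$symbol[genes$chrom %in% unique(profiles$chrom)]
  off <- setdiff(coupled_genes, covered)
  if (length(off) > 0) {
    abort(paste0("coupled genes on chromosomes without probes: ",
                 paste(off, collapse = ", ")))
  }
  samples <- sample_columns(profiles)
  gene_cn <- summarize_gene_cn(profiles, genes[genes$symbol %in% covered, ])
  cn_mat <- as.matrix(gene_cn[, samples])
  rownames(cn_mat) <- gene_cn$symbol

  with_seed(seed, {
    expr <- matrix(NA_real_, nrow = nrow(genes), ncol = length(samples),
                   dimnames = list(genes$symbol, samples))
    for (g in genes$symbol) {
      if (g %in% coupled_genes) {
        mu <- intercept + slope * cn_mat[g, ]
        expr[g, ] <- mu + rnorm(length(samples), sd = noise_sd)
      } else {
        expr[g, ] <- rnorm(length(samples), mean = intercept + 2 * slope,
                           sd = uncoupled_sd)
      }
    }
    dplyr::bind_cols(tibble::tibble(symbol = genes$symbol),
                     tibble::as_tibble(expr))
  })
}

#' Generate survival with an amplification-dependent hazard
#'
#' Exponential survival: non-carriers have median
#' `baseline_median_survival`; carriers of an event of `risk_kind`
#' overlapping `risk_region` have their hazard multiplied by
#' `hazard_ratio_amplified` (exponential median divides by the hazard
#' ratio). Censored cases get a uniform administrative censoring time below
#' their latent event time.
#'
#' @param truth Truth table from [generate_cohort()] (or any event tibble
#'   with `sample_id`, `chrom`, `start`, `end`, `kind`).
#' @param config A [cohort_config()]; supplies cohort size, hazard ratio,
#'   baseline median and censoring rate.
#' @param risk_region List/tibble row with `chrom`, `start`, `end` defining
#'   the high-risk locus. Default: the 4q12 (PDGFRA) amplicon region of
#'   [default_event_specs()].
#' @param risk_kind Event kind conferring risk. Default `amplification`.
#' @param seed Integer seed; defaults to `config$seed + 1` so the clinical
#'   draw is distinct from, but still determined by, the cohort seed.
#' @return Clinical tibble: `case_id`, `survival_months`, `vital_status`
#'   (`deceased`/`alive`).
#' @export
generate_survival <- function(truth, config = cohort_config(),
                              risk_region = NULL,
                              risk_kind = "amplification", seed = NULL) {
  risk_region <- risk_region %||%
    list(chrom = "chr4", start = 53.5e6 + 1, end = 56.0e6)
  ids <- sample_ids_for(config$n_samples)
  carriers <- truth |>
    dplyr::filter(.data$kind == risk_kind,
                  .data$chrom == risk_region$chrom,
                  intervals_overlap(.data$start, .data$end,
                                    risk_region$start, risk_region$end)) |>
    dplyr::pull(.data$sample_id) |>
    unique()
  rate0 <- log(2) / config$baseline_median_survival
  with_seed(seed %||% (config$seed + 1L), {
    rate <- ifelse(ids %in% carriers,
                   rate0 * config$hazard_ratio_amplified, rate0)
    t_event <- rexp(length(ids), rate = rate)
    censored <- runif(length(ids)) < config$censoring_rate
    t_obs <- ifelse(censored, t_event * runif(length(ids)), t_event)
    tibble::tibble(
      case_id = ids,
      survival_months = round(t_obs, 1),
      vital_status = ifelse(censored, "alive", "deceased")
    )
  })
}

## Per-state signal-fraction probabilities used by the iFISH simulator.
## Chosen well clear of the 5%/10% calling cutoffs so that, at >= 200
## nuclei, binomial noise rarely crosses a cutoff.
IFISH_STATE_PROBS <- list(
  normal = c(inc = 0.01, dec = 0.02, nolocus = 0.005, ratio = 0.002),
  gain = c(inc = 0.30, dec = 0.02, nolocus = 0.005, ratio = 0.02),
  loss = c(inc = 0.01, dec = 0.35, nolocus = 0.01, ratio = 0.002),
  amplification = c(inc = 0.30, dec = 0.02, nolocus = 0.005, ratio = 0.40),
  homozygous_deletion = c(inc = 0.01, dec = 0.30, nolocus = 0.40,
                          ratio = 0.002)
)

#' Simulate iFISH spot-count fractions from true CN states
#'
#' For each (case, locus, state) row, draws the four per-nucleus signal
#' fractions from binomial counts over `n_nuclei` nuclei, with per-state
#' success probabilities placed well away from the classification cutoffs.
#'
#' @param states Tibble with `case_id`, `locus`, `state` (a CN state name;
#'   `neutral` is treated as `normal`).
#' @param n_nuclei Nuclei scored per slide (>= 200 by convention).
#' @param seed Integer seed.
#' @return Tibble of iFISH counts: `case_id`, `locus`,
#'   `fraction_increased`, `fraction_decreased`,
#'   `fraction_no_locus_with_cep`, `fraction_ratio_gt2_or_clusters`,
#'   `n_nuclei`.
#' @export
simulate_ifish_counts <- function(states, n_nuclei = 200, seed = 1L) {
  state <- ifelse(states$state == "neutral", "normal", states$state)
  bad <- !state %in% names(IFISH_STATE_PROBS)
  if (any(bad)) {
    abort(paste0("unknown state(s): ", paste(unique(state[bad]),
                                             collapse = ", ")))
  }
  with_seed(seed, {
    draw <- function(which_p) {
      p <- vapply(state, function(s) IFISH_STATE_PROBS[[s]][[which_p]],
                  numeric(1))
      rbinom(length(p), n_nuclei, p) / n_nuclei
    }
    tibble::tibble(
      case_id = states$case_id,
      locus = states$locus,
      fraction_increased = draw("inc"),
      fraction_decreased = draw("dec"),
      fraction_no_locus_with_cep = draw("nolocus"),
      fraction_ratio_gt2_or_clusters = draw("ratio"),
      n_nuclei = n_nuclei
    )
  })
}
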