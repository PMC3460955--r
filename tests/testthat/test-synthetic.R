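# Synthetic cohort generator: determinism, implantation frequencies,
# expression coupling and survival structure.

small_config <- function(n_samples = 10, seed = 9) {
  cohort_config(
    n_samples = n_samples,
    chromosomes = tibble::tibble(chrom = "chr7", length_bp = 5e6),
    event_specs = event_spec("chr7", 1e6, 4e6, "amplification", 0.5,
                             boundary_jitter = 0),
    seed = seed
  )
}

test_that("equal seeds give bit-identical cohorts", {
  a <- generate_cohort(small_config())
  b <- generate_cohort(small_config())
  expect_identical(a, b)
  c <- generate_cohort(small_config(seed = 10))
  expect_false(identical(a$cn, c$cn))
})

test_that("prevalence 0 and 1 behave as certainty bounds", {
  cfg0 <- small_config()
  cfg0$event_specs$prevalence <- 0
  none <- generate_cohort(cfg0)
  expect_equal(nrow(none$truth), 0)
  expect_equal(nrow(call_events(none$cn)), 0) # all-neutral profiles

  cfg1 <- small_config()
  cfg1$event_specs$prevalence <- 1
  all_in <- generate_cohort(cfg1)
  expect_equal(nrow(all_in$truth), 10)
  expect_true(all(all_in$truth$kind == "amplification"))
})

test_that("default cohort hits the chromosome-7 amplicon rate within binomial error", {
  cohort <- generate_cohort(cohort_config(seed = 20))
  carriers <- cohort$truth |>
    dplyr::filter(kind == "amplification", chrom == "chr7") |>
    dplyr::pull(sample_id) |>
    unique()
  frac <- length(carriers) / 46
  # 3 binomial SEs around 0.50 at n = 46
  expect_lt(abs(frac - 0.50), 3 * sqrt(0.5 * 0.5 / 46))
})

test_that("implantation frequency converges to the spec prevalence", {
  p <- 0.3
  carriers <- 0
  n_total <- 0
  for (s in 1:30) {
    cfg <- cohort_config(
      n_samples = 20,
      chromosomes = tibble::tibble(chrom = "chr1", length_bp = 2e6),
      event_specs = event_spec("chr1", 2e5, 1.8e6, "gain", p),
      seed = 100 + s
    )
    tr <- generate_cohort(cfg)$truth
    carriers <- carriers + length(unique(tr$sample_id))
    n_total <- n_total + 20
  }
  expect_gt(stats::binom.test(carriers, n_total, p)$p.value, 0.01)
})

test_that("contradictory overlapping event specs are rejected", {
  specs <- dplyr::bind_rows(
    event_spec("chr7", 1e6, 3e6, "amplification", 0.5),
    event_spec("chr7", 2e6, 4e6, "homozygous_deletion", 0.5)
  )
  expect_error(cohort_config(event_specs = specs), "contradictory")
  expect_error(event_spec("chr7", 1e6, 2e6, "amplification", 0.5,
                          cn_level = c(3, 8)),
               "inconsistent")
  expect_error(event_spec("chr9", 1e6, 2e6, "homozygous_deletion", 0.5,
                          cn_level = c(0.1, 0.9)),
               "inconsistent")
})

test_that("noiseless coupling gives a perfect dosage correlation", {
  cfg <- small_config(n_samples = 12)
  cfg$event_specs$prevalence <- 0.5
  cohort <- generate_cohort(cfg)
  genes <- tibble::tibble(symbol = c("IN_AMP", "ELSEWHERE"),
                          chrom = "chr7",
                          start = c(2e6, 4.5e6), end = c(2.5e6, 4.8e6))
  expr <- generate_expression(cohort$cn, genes, "IN_AMP", noise_sd = 0,
                              seed = 3)
  gene_cn <- summarize_gene_cn(cohort$cn, genes)
  samples <- sprintf("S%02d", 1:12)
  res <- pearson_dosage(as.numeric(gene_cn[1, samples]),
                        as.numeric(expr[1, samples]))
  expect_equal(res$r_squared, 1)
  expect_true(res$passes_filter)
  # uncoupled gene: expression independent of CN
  res2 <- pearson_dosage(as.numeric(gene_cn[2, samples]),
                         as.numeric(expr[2, samples]))
  expect_lt(res2$r_squared, 0.70)
  expect_error(generate_expression(cohort$cn, genes, character(0)),
               "non-empty")
})

test_that("noise tuned by the variance decomposition yields the target R^2", {
  # R^2 = b^2 var(CN) / (b^2 var(CN) + sd^2): pick sd for R^2 = 0.85 from
  # the realized CN variance, then check the empirical R^2 at n = 200
  n <- 200
  withr::local_seed(77)
  cn_per_sample <- pmax(0.2, rnorm(n, mean = 2, sd = 1))
  cn_cols <- setNames(
    lapply(cn_per_sample, function(v) rep(v, 5)),
    sprintf("S%03d", seq_len(n))
  )
  probes <- make_probes(cn_cols)
  genes <- tibble::tibble(symbol = "G1", chrom = "chr7", start = 1e5,
                          end = 5e5)
  b <- 1
  target <- 0.85
  v <- stats::var(cn_per_sample)
  sd_needed <- sqrt(b^2 * v * (1 - target) / target)
  expr <- generate_expression(probes, genes, "G1", slope = b,
                              noise_sd = sd_needed, seed = 5)
  res <- pearson_dosage(cn_per_sample,
                        as.numeric(expr[1, names(cn_cols)]))
  expect_lt(abs(res$r_squared - target), 0.08)
  # the fitted slope recovers b within 3 standard errors
  fit <- summary(stats::lm(as.numeric(expr[1, names(cn_cols)]) ~
                             cn_per_sample))
  expect_lt(abs(fit$coefficients[2, 1] - b),
            3 * fit$coefficients[2, 2])
})

test_that("survival generator reproduces the exponential group medians", {
  # 600 cases, half carrying the flagged 4q12 amplicon; hazard ratio 6.5
  # on a 13-month baseline gives carrier median 13 / 6.5 = 2
  n <- 600
  ids <- sprintf("S%02d", seq_len(n))
  carriers <- ids[seq_len(n / 2)]
  truth <- tibble::tibble(
    chrom = "chr4", start = 54e6, end = 55e6, sample_id = carriers,
    kind = "amplification", cn_level = 7
  )
  cfg <- cohort_config(n_samples = n, censoring_rate = 0, seed = 12)
  clin <- generate_survival(truth, cfg)
  expect_true(all(clin$vital_status == "deceased")) # censoring_rate 0
  grp <- stratify_by_event(clin, positive_ids = carriers)
  # a handful of draws round to 0.0 months; retained with a warning
  m_amp <- km_median(suppressWarnings(km_estimate(grp$positive)))
  m_rest <- km_median(suppressWarnings(km_estimate(grp$negative)))
  expect_lt(abs(m_amp - 2), 0.5)
  expect_lt(abs(m_rest - 13), 2.5)

  # null hazard ratio: medians differ only by sampling error
  cfg1 <- cohort_config(n_samples = n, censoring_rate = 0,
                        hazard_ratio_amplified = 1, seed = 13)
  clin1 <- generate_survival(truth, cfg1)
  grp1 <- stratify_by_event(clin1, positive_ids = carriers)
  m1 <- km_median(suppressWarnings(km_estimate(grp1$positive)))
  m2 <- km_median(suppressWarnings(km_estimate(grp1$negative)))
  expect_lt(abs(log(m1 / m2)), 0.35)

  # censoring produces 'alive' records at the configured rate
  cfg2 <- cohort_config(n_samples = n, censoring_rate = 0.3, seed = 14)
  clin2 <- generate_survival(truth, cfg2)
  expect_gt(stats::binom.test(sum(clin2$vital_status == "alive"), n,
                              0.3)$p.value, 0.01)
})

test_that("packaged fixtures load verbatim", {
  t1 <- load_table1_fixture()
  expect_equal(nrow(t1), 46)
  expect_equal(t1$survival_months[t1$case_id == "G12"], 1)
  expect_equal(t1$vital_status[t1$case_id == "G93"], "alive")
  expect_equal(sum(t1$vital_status == "deceased"), 45)

  t2 <- load_table2_fixture()
  expect_equal(nrow(t2), 46)
  expect_equal(t2$r_squared[t2$symbol == "RAP1B"], 0.97)
  expect_true(all(t2$r_squared > 0.70))
  expect_setequal(t2$symbol[t2$not_amplified_or_deleted],
                  c("IMMP1L", "XIST"))

  genes <- load_gene_models()
  expect_true(all(c("EGFR", "PDGFRA", "CDKN2A", "MTAP") %in% genes$symbol))
  expect_true(all(genes$start <= genes$end))
})

test_that("iFISH count simulation is deterministic and in range", {
  states <- tibble::tibble(
    case_id = sprintf("c%d", 1:10), locus = "EGFR",
    state = rep(c("amplification", "normal"), 5)
  )
  a <- simulate_ifish_counts(states, seed = 4)
  b <- simulate_ifish_counts(states, seed = 4)
  expect_identical(a, b)
  fr <- as.matrix(a[, grep("^fraction", names(a))])
  expect_true(all(fr >= 0 & fr <= 1))
  expect_error(simulate_ifish_counts(
    tibble::tibble(case_id = "c", locus = "x", state = "weird")
  ), "unknown state")
})
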