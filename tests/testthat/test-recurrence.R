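# Cohort-level recurrence: frequencies, minimal common regions, gene
# annotation and co-occurrence.

# n cases with an event of `kind` exactly on `region`, ids e1, e2, ...
events_at <- function(n, region, kind, prefix = "e") {
  if (n == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          kind = character()))
  }
  tibble::tibble(
    sample_id = sprintf("%s%02d", prefix, seq_len(n)),
    chrom = region$chrom, start = region$start, end = region$end,
    kind = kind
  )
}

cdkn2a <- list(chrom = "chr9", start = 21957751, end = 21984490)

test_that("recurrence frequency reproduces the printed count/percent pairs", {
  cases <- list(
    list(n = 24, kind = "homozygous_deletion", region = cdkn2a, pct = 52L),
    list(n = 12, kind = "homozygous_deletion",
         region = list(chrom = "chr9", start = 21802635, end = 21867763),
         pct = 26L),
    list(n = 4, kind = "amplification",
         region = list(chrom = "chr4", start = 54e6, end = 55e6),
         pct = 9L),
    list(n = 3, kind = "amplification",
         region = list(chrom = "chr1", start = 202.5e6, end = 203.4e6),
         pct = 7L),
    list(n = 21, kind = "amplification",
         region = list(chrom = "chr7", start = 55e6, end = 55.3e6),
         pct = 46L)
  )
  for (cs in cases) {
    ev <- events_at(cs$n, cs$region, cs$kind)
    got <- recurrence_frequency(ev, cs$region, cs$kind, cohort_size = 46)
    expect_equal(got$n_cases, cs$n)
    expect_equal(got$frequency_pct, cs$pct)
  }
  none <- recurrence_frequency(events_at(0, cdkn2a, "loss"), cdkn2a,
                               "loss", 46)
  expect_equal(unlist(none), c(n_cases = 0, frequency_pct = 0))
  expect_error(recurrence_frequency(events_at(1, cdkn2a, "loss"), cdkn2a,
                                    "loss", 0), "positive")
})

test_that("percent rounding is half-away-from-zero", {
  expect_equal(round_half_up(c(52.17, 45.65, 6.52, 0.5, 1.5, 2.5)),
               c(52, 46, 7, 1, 2, 3))
  expect_equal(round_half_up(-0.5), -1)
})

test_that("a case counts once regardless of how many events overlap", {
  ev <- dplyr::bind_rows(
    events_at(2, cdkn2a, "homozygous_deletion"),
    events_at(1, cdkn2a, "homozygous_deletion") # duplicate id e01
  )
  got <- recurrence_frequency(ev, cdkn2a, "homozygous_deletion", 46)
  expect_equal(got$n_cases, 2)
})

test_that("enlarging a query region never decreases the case count", {
  withr::local_seed(5)
  ev <- random_small_events(25, kind = "gain")
  region <- list(chrom = "chr9", start = 100, end = 150)
  wider <- list(chrom = "chr9", start = 50, end = 300)
  n1 <- recurrence_frequency(ev, region, "gain", 46)$n_cases
  n2 <- recurrence_frequency(ev, wider, "gain", 46)$n_cases
  expect_gte(n2, n1)
})

test_that("pairwise minimal common region is the intersection", {
  ev <- tibble::tibble(
    sample_id = c("a", "b"), chrom = "chr9",
    start = c(100, 300), end = c(500, 900), kind = "homozygous_deletion"
  )
  mcr <- minimal_common_region(ev, "homozygous_deletion", min_cases = 2)
  expect_equal(nrow(mcr), 1)
  expect_equal(c(mcr$start, mcr$end), c(300, 500))
  expect_equal(mcr$case_ids[[1]], c("a", "b"))
  expect_equal(mcr$length_bp, 200)
  # one sample only: below min_cases
  expect_equal(nrow(minimal_common_region(ev[1, ], "homozygous_deletion",
                                          min_cases = 2)), 0)
  expect_equal(nrow(minimal_common_region(ev[0, ], "homozygous_deletion",
                                          min_cases = 2)), 0)
})

test_that("minimal common regions match a per-base coverage scan", {
  withr::local_seed(33)
  for (rep in 1:10) {
    ev <- random_small_events(sample(3:20, 1))
    got <- minimal_common_region(ev, "homozygous_deletion", min_cases = 2)
    want <- oracle_mcr(ev, "homozygous_deletion", min_cases = 2)
    expect_equal(
      as.data.frame(got[, c("chrom", "start", "end", "n_cases")]),
      as.data.frame(want[, c("chrom", "start", "end", "n_cases")])
    )
    expect_equal(got$case_ids, want$case_ids)
  }
})

test_that("every region is contained in each contributing case's coverage", {
  withr::local_seed(8)
  ev <- random_small_events(30)
  mcr <- minimal_common_region(ev, "homozygous_deletion", min_cases = 3)
  expect_gt(nrow(mcr), 0)
  for (i in seq_len(nrow(mcr))) {
    for (case in mcr$case_ids[[i]]) {
      covered <- rep(FALSE, mcr$end[i])
      rows <- ev[ev$sample_id == case, ]
      for (r in seq_len(nrow(rows))) {
        idx <- max(1, rows$start[r]):min(mcr$end[i], rows$end[r])
        covered[idx] <- TRUE
      }
      expect_true(all(covered[mcr$start[i]:mcr$end[i]]))
    }
  }
})

test_that("gene annotation uses >= 1 bp overlap in genomic order", {
  genes <- load_gene_models()
  # the recurrent 9p21.3 deletion interval spans CDKN2A and CDKN2B
  mcr9 <- list(chrom = "chr9", start = 21978443, end = 22119128)
  expect_equal(annotate_genes(mcr9, genes), c("CDKN2A", "CDKN2B"))
  # strictly between two genes
  gap <- list(chrom = "chr9", start = 21985000, end = 21990000)
  expect_equal(annotate_genes(gap, genes), character(0))
  # fully spanning a gene
  expect_true("MTAP" %in% annotate_genes(
    list(chrom = "chr9", start = 21.5e6, end = 22.2e6), genes))
  # annotate_regions adds the same lists as a column
  regions <- tibble::tibble(chrom = "chr9", start = 21978443,
                            end = 22119128)
  expect_equal(annotate_regions(regions, genes)$genes[[1]],
               c("CDKN2A", "CDKN2B"))
})

test_that("co-occurrence rows mirror per-case amplicon multiplicity", {
  regions <- tibble::tibble(
    region_id = c("chr4q12", "chr7p11", "chr12q14"),
    chrom = c("chr4", "chr7", "chr12"),
    start = c(54e6, 55e6, 56e6), end = c(55.5e6, 55.5e6, 58e6),
    kind = "amplification"
  )
  # G82 carries amplicons on chromosomes 4, 7 and 12
  ev <- tibble::tibble(
    sample_id = c("G82", "G82", "G82", "G88", "G88"),
    chrom = c("chr4", "chr7", "chr12", "chr4", "chr12"),
    start = c(54.2e6, 55.1e6, 56.5e6, 54.3e6, 57e6),
    end = c(55.2e6, 55.3e6, 57.5e6, 55.4e6, 57.8e6),
    kind = "amplification"
  )
  inc <- cooccurrence_matrix(ev, regions)
  g82 <- inc[inc$case_id == "G82", -1]
  expect_equal(sum(unlist(g82)), 3)
  g88 <- inc[inc$case_id == "G88", -1]
  expect_equal(unlist(g88, use.names = FALSE), c(1L, 0L, 1L))
  # no events: all-zero table
  empty <- cooccurrence_matrix(ev[0, ], regions, cases = c("G1", "G2"))
  expect_equal(sum(unlist(empty[, -1])), 0)
  # row sums equal independent per-case recounts
  withr::local_seed(2)
  rev <- random_small_events(15, kind = "amplification")
  reg <- tibble::tibble(chrom = "chr9", start = c(1, 200), end = c(199, 400),
                        kind = "amplification")
  inc2 <- cooccurrence_matrix(rev, reg)
  for (i in seq_len(nrow(inc2))) {
    case <- inc2$case_id[i]
    manual <- vapply(seq_len(nrow(reg)), function(j) {
      any(rev$sample_id == case & rev$start <= reg$end[j] &
            rev$end >= reg$start[j])
    }, logical(1))
    expect_equal(unlist(inc2[i, -1], use.names = FALSE),
                 as.integer(manual))
  }
})
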