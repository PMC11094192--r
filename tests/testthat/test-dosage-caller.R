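test_that("segmentation handles constant series, clean steps and huge penalties", {
  expect_equal(segment_series(rep(0, 12), penalty = 1), integer(0))

  x <- c(rep(0, 6), rep(-1, 6))
  expect_equal(segment_series(x, penalty = 0.5, min_seg_bins = 2), 6L)
  expect_equal(oracle_segment(x, 0.5, 2), 6L)

  # penalty larger than any possible SSE reduction: one segment
  expect_equal(segment_series(x, penalty = 1e9), integer(0))

  expect_error(segment_series(x, penalty = 0), "penalty")
  # series shorter than two minimum segments cannot split
  expect_equal(segment_series(c(0, 5), penalty = 0.1, min_seg_bins = 3),
               integer(0))
})

test_that("DP segmentation equals the exhaustive-search oracle on random series", {
  set.seed(1234)
  n_cases <- 120
  for (i in seq_len(n_cases)) {
    n <- sample(4:12, 1)
    m <- sample(1:3, 1)
    # mix of pure noise and noise + a planted step
    x <- rnorm(n, sd = 0.4)
    if (i %% 2 == 0) {
      k <- sample(seq_len(n - 1), 1)
      x[(k + 1):n] <- x[(k + 1):n] - sample(c(0.5, 1, 2), 1)
    }
    pen <- runif(1, 0.1, 3)
    expect_identical(segment_series(x, pen, m), oracle_segment(x, pen, m),
                     info = sprintf("case %d: n=%d m=%d pen=%.3f", i, n, m, pen))
  }
})

test_that("re-segmenting piecewise-constant series recovers true breakpoints", {
  # exact recovery expected when penalty < step^2 * min_seg_bins / 2
  set.seed(7)
  for (i in 1:30) {
    m <- sample(2:3, 1)
    lens <- sample(m:5, sample(2:3, 1), replace = TRUE)
    steps <- cumsum(c(0, sample(c(-1, 1), length(lens) - 1, replace = TRUE)))
    x <- rep(steps, lens)
    pen <- 0.9 * min(1^2 * m / 2, 1)
    bp <- segment_series(x, pen, m)
    expect_equal(bp, cumsum(lens)[-length(lens)],
                 info = paste("lens:", paste(lens, collapse = ",")))
  }
})

test_that("copy-number assignment rounds 2*2^r with boundaries going down", {
  expect_equal(assign_copy_number(0), 2L)
  expect_equal(assign_copy_number(-1), 1L)
  expect_equal(assign_copy_number(-5), 0L)
  expect_equal(assign_copy_number(0.585), 3L)
  expect_equal(assign_copy_number(1), 4L)
  expect_equal(assign_copy_number(2), 4L)       # capped at 4
  expect_equal(assign_copy_number(-Inf), 0L)
  # exact boundaries round toward fewer copies
  bounds <- log2(c(0.25, 0.75, 1.25, 1.75))
  expect_equal(assign_copy_number(bounds), c(0L, 1L, 2L, 3L))
  expect_equal(assign_copy_number(bounds + 1e-9), c(1L, 2L, 3L, 4L))
})

test_that("copy-number assignment is non-decreasing in the log2 ratio", {
  r <- seq(-6, 2, by = 0.01)
  cn <- assign_copy_number(r)
  expect_true(all(diff(cn) >= 0))
  expect_true(all(cn >= 0 & cn <= 4))
})

test_that("chromosome classification covers the karyotype vocabulary", {
  seg <- function(start, end, cn, n_bins = (end - start) / 1e6) {
    tibble::tibble(start = start, end = end, mean_log2 = log2(pmax(cn, 0.1) / 2),
                   copy_number = as.integer(cn), n_bins = n_bins)
  }
  cen <- 5e6; len <- 12e6; bnd <- 6e6; w <- 1e6

  # disomic chromosome: no event
  r <- classify_chromosome(seg(0, len, 2), cen, len, bnd, w)
  expect_equal(nrow(r$events), 0)
  expect_equal(c(r$cn_S, r$cn_L), c(2L, 2L))

  # uniform aneuploidies
  for (case in list(c(0, "nullisomic"), c(1, "monosomic"),
                    c(3, "trisomic"), c(4, "tetrasomic"))) {
    r <- classify_chromosome(seg(0, len, as.numeric(case[1])), cen, len, bnd, w)
    expect_equal(r$events$label, case[2])
  }

  # S arm kept at 2, L arm at 0: ditelosomic for the short arm
  r <- classify_chromosome(dplyr::bind_rows(seg(0, bnd, 2), seg(bnd, len, 0)),
                           cen, len, bnd, w)
  expect_equal(r$events$label, "ditelosomic:S")
  expect_equal(c(r$cn_S, r$cn_L), c(2L, 0L))

  # one homolog lost entirely plus the other's L arm: monotelosomic
  r <- classify_chromosome(dplyr::bind_rows(seg(0, bnd, 1), seg(bnd, len, 0)),
                           cen, len, bnd, w)
  expect_equal(r$events$label, "monotelosomic:S")

  # whole-arm copy context (2,1): monotelosomic on the retained arm
  r <- classify_chromosome(dplyr::bind_rows(seg(0, bnd, 2), seg(bnd, len, 1)),
                           cen, len, bnd, w)
  expect_equal(r$events$label, "monotelosomic:S")
  expect_equal(c(r$events$cn_S, r$events$cn_L), c(2L, 1L))

  # distal CN1 segment on an otherwise disomic L arm: terminal deletion
  r <- classify_chromosome(dplyr::bind_rows(seg(0, 9e6, 2), seg(9e6, len, 1)),
                           cen, len, bnd, w)
  expect_equal(r$events$label, "terminal_deletion:L")
  expect_equal(c(r$cn_S, r$cn_L), c(2L, 2L))

  # deletion spanning the centromere bin: pericentric
  r <- classify_chromosome(
    dplyr::bind_rows(seg(0, 4e6, 2), seg(4e6, 7e6, 1), seg(7e6, len, 2)),
    cen, len, bnd, w)
  expect_equal(r$events$label, "pericentric_deletion")

  # internal deletion away from ends and centromere: interstitial
  r <- classify_chromosome(
    dplyr::bind_rows(seg(0, 8e6, 2), seg(8e6, 11e6, 0), seg(11e6, len, 2)),
    cen, len, bnd, w)
  expect_equal(r$events$label, "interstitial_deletion")
})

test_that("locus dosage is the minimum copy number over overlapping segments", {
  segs <- tibble::tibble(
    sample = "s", chrom = "6A",
    start = c(0, 20e6), end = c(20e6, 30e6),
    mean_log2 = c(0, -1), copy_number = c(2L, 1L), n_bins = c(20, 10))
  inside <- loci_table("in2", "6A", 5e6, 6e6, "S")
  strad <- loci_table("strad", "6A", 19e6, 21e6, "L")
  res <- locus_dosage(segs, dplyr::bind_rows(inside, strad))
  expect_equal(res$copy_number[res$name == "in2"], 2L)
  expect_equal(res$copy_number[res$name == "strad"], 1L)
  expect_true(all(res$present))

  # terminal CN0 segment containing the locus: absent
  segs0 <- dplyr::mutate(segs, copy_number = c(2L, 0L))
  res0 <- locus_dosage(segs0, loci_table("eml", "6A", 25e6, 30e6, "L"))
  expect_equal(res0$copy_number, 0L)
  expect_false(res0$present)

  expect_error(locus_dosage(segs, loci_table("x", "9Z", 0, 1e6, "S")),
               "no called segments")
})

test_that("called segments are sorted, disjoint and cover unmasked bins", {
  sim <- simulate_cohort(mini_cohort())
  nm <- normalize_gbs(sim$counts, sim$samplesheet)
  calls <- call_dosage(nm, mini_genome())
  segs <- calls$segments
  for (key in split(segs, paste(segs$sample, segs$chrom))) {
    key <- key[order(key$start), ]
    if (nrow(key) > 1) {
      expect_true(all(key$start[-1] >= key$end[-nrow(key)]))
    }
  }
  # per sample+chrom, bins covered = unmasked bins of that chromosome
  cov <- segs |>
    dplyr::group_by(sample, chrom) |>
    dplyr::summarise(n = sum(n_bins), .groups = "drop")
  unm <- tibble::as_tibble(nm) |>
    dplyr::filter(!masked) |>
    dplyr::count(sample, chrom, name = "n")
  expect_equal(dplyr::arrange(cov, sample, chrom),
               dplyr::arrange(unm, sample, chrom), ignore_attr = TRUE)
})

test_that("planted events in a small cohort are called with exact copy number", {
  sim <- simulate_cohort(mini_cohort())
  nm <- normalize_gbs(sim$counts, sim$samplesheet)
  calls <- call_dosage(nm, mini_genome(), loci = NULL)
  ev <- calls$events
  expect_equal(ev$label[ev$sample == "mono1A"], "monosomic")
  expect_equal(ev$chrom[ev$sample == "mono1A"], "1A")
  expect_equal(ev$label[ev$sample == "dt1B"], "ditelosomic:S")
  expect_equal(nrow(ev[grepl("ctrl", ev$sample), ]), 0)
})
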