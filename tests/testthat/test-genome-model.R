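test_that("make_bins tiles chromosomes exactly, truncating the final bin", {
  g1 <- genome_model("1A", "A", 5e6, 2e6)
  b1 <- make_bins(g1, 1e6)
  expect_equal(nrow(b1), 5)
  expect_equal(b1$start, seq(0, 4e6, by = 1e6))
  expect_equal(b1$end, seq(1e6, 5e6, by = 1e6))

  g2 <- genome_model("1A", "A", 5.5e6, 2e6)
  b2 <- make_bins(g2, 1e6)
  expect_equal(nrow(b2), 6)
  expect_equal(b2$end[6], 5.5e6)
  expect_equal(b2$start[6], 5e6)

  # two chromosomes, 3 Mb and 2 Mb: 5 bins in chromosome order
  g3 <- genome_model(c("1A", "1B"), c("A", "B"), c(3e6, 2e6), c(1e6, 1e6))
  b3 <- make_bins(g3, 1e6)
  expect_equal(nrow(b3), 5)
  expect_equal(b3$chrom, c("1A", "1A", "1A", "1B", "1B"))
  expect_equal(b3$start, c(0, 1e6, 2e6, 0, 1e6))
  expect_equal(b3$end, c(1e6, 2e6, 3e6, 1e6, 2e6))

  expect_error(make_bins(g1, 0), "width")
})

test_that("bin grids tile every chromosome without gaps or overlaps", {
  for (w in c(7e5, 1e6, 2.5e6)) {
    bins <- make_bins(default_genome(), w)
    per_chrom <- split(bins, bins$chrom)
    g <- default_genome()
    for (chrom in g$chrom) {
      b <- per_chrom[[chrom]]
      b <- b[order(b$start), ]
      expect_equal(b$start[1], 0)
      expect_equal(b$end[nrow(b)], g$length[g$chrom == chrom])
      if (nrow(b) > 1) expect_equal(b$start[-1], b$end[-nrow(b)])
      expect_equal(nrow(b), ceiling(g$length[g$chrom == chrom] / w))
    }
  }
})

test_that("genome TSVs round-trip and invalid rows are rejected by name", {
  g <- default_genome()
  expect_equal(nrow(g), 28)
  expect_setequal(unique(g$subgenome), c("A", "B", "D", "R"))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_genome(g, path)
  expect_equal(read_genome(path), g)

  expect_error(genome_model("1A", "A", 5e6, 5e6), "1A")
  expect_error(genome_model(c("1A", "1A"), c("A", "A"), c(1e6, 1e6),
                            c(5e5, 5e5)), "duplicate")
  expect_error(genome_model("1A", "Q", 5e6, 1e6), "subgenome")
})

test_that("read_counts demands exact grid agreement and keeps sample order", {
  g <- genome_model("1A", "A", 3e6, 1e6)
  bins <- make_bins(g, 1e6)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "s1.tsv")
  writeLines(c("1A\t0\t1000000\t10", "1A\t1000000\t2000000\t20",
               "1A\t2000000\t3000000\t30"), p1)
  cm <- read_counts(c(s1 = p1), bins)
  expect_equal(sum(cm$count), 60)
  expect_equal(cm$count, c(10, 20, 30))

  # wrong interval width: rejected, not silently zeroed
  p2 <- file.path(dir, "bad.tsv")
  writeLines(c("1A\t0\t2000000\t10", "1A\t2000000\t3000000\t5"), p2)
  expect_error(read_counts(c(bad = p2), bins), "grid")

  p3 <- file.path(dir, "s2.tsv")
  writeLines(c("1A\t2000000\t3000000\t3", "1A\t0\t1000000\t1",
               "1A\t1000000\t2000000\t2"), p3)
  cm2 <- read_counts(c(zz = p3, s1 = p1), bins)
  expect_equal(unique(cm2$sample), c("zz", "s1"))
  # rows reordered into grid order regardless of file order
  expect_equal(cm2$count[cm2$sample == "zz"], c(1, 2, 3))

  # counts round-trip through write_counts
  out <- write_counts(cm2, file.path(dir, "counts"))
  back <- read_counts(out, bins)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(cm2))
})

test_that("count_from_alignments honours flags, MAPQ and half-open bins", {
  g <- genome_model(c("1A", "1B"), c("A", "B"), c(2e6, 1e6), c(1e6, 5e5))
  bins <- make_bins(g, 1e6)
  rec <- tibble::tibble(
    rname = c("1A", "1A", "1A", "1A", "1A", "chrUn"),
    pos = c(10, 1000000, 1000001, 50, 60, 5),
    flag = c(0L, 0L, 0L, 256L, 0L, 0L),
    mapq = c(60L, 60L, 60L, 60L, 5L, 60L))
  res <- count_from_alignments(rec, bins, mapq_min = 20)
  # SAM pos 1,000,000 (1-based) is the last base of the half-open bin 0;
  # pos 1,000,001 opens bin 1
  expect_equal(res$counts$count[res$counts$chrom == "1A"], c(2, 1))
  expect_equal(res$unplaced, 1)
  # secondary (flag 256) and low-MAPQ records are never counted
  expect_equal(sum(res$counts$count) + res$unplaced, 3 + 1)
})

test_that("alignment counting matches a hand-looped oracle on random records", {
  g <- mini_genome()
  bins <- make_bins(g, 1e6)
  set.seed(42)
  n <- 100
  rec <- tibble::tibble(
    rname = sample(g$chrom, n, replace = TRUE),
    pos = NA_real_, flag = 0L,
    mapq = sample(c(0L, 60L), n, replace = TRUE))
  rec$pos <- floor(stats::runif(n, 1, g$length[match(rec$rname, g$chrom)]))
  res <- count_from_alignments(rec, bins, mapq_min = 20)
  # independent loop over records
  expected <- rep(0L, nrow(bins))
  for (i in seq_len(n)) {
    if (rec$mapq[i] < 20) next
    hit <- which(bins$chrom == rec$rname[i] & bins$start <= rec$pos[i] - 1 &
                   rec$pos[i] - 1 < bins$end)
    expected[hit] <- expected[hit] + 1L
  }
  expect_equal(res$counts$count, expected)
  expect_equal(sum(res$counts$count), sum(rec$mapq >= 20) - res$unplaced)
})

test_that("SAM text input is counted through the same path", {
  skip_if_not_installed("Rsamtools")
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:1A\tLN:2000000",
    "r1\t0\t1A\t10\t60\t50M\t*\t0\t0\t*\t*",
    "r2\t0\t1A\t1000001\t60\t50M\t*\t0\t0\t*\t*",
    "r3\t256\t1A\t20\t60\t50M\t*\t0\t0\t*\t*",
    "r4\t0\t1A\t30\t3\t50M\t*\t0\t0\t*\t*"), sam)
  bins <- make_bins(genome_model("1A", "A", 2e6, 1e6), 1e6)
  res <- count_from_alignments(sam, bins, mapq_min = 20)
  expect_equal(res$counts$count, c(1, 1))
  expect_equal(res$unplaced, 0)
})

test_that("loci validate against the genome and round-trip as BED6", {
  g <- default_genome()
  loci <- default_loci(g)
  expect_setequal(loci$name, c("Eml-A1", "Eml-R1b"))
  expect_true(all(loci$arm == "L"))
  # Eml-A1 is terminal on 6AL: reaches the chromosome end
  expect_equal(loci$end[loci$name == "Eml-A1"],
               g$length[g$chrom == "6A"])
  # Eml-R1b is interstitial on 6RL: strictly inside the arm
  r <- loci[loci$name == "Eml-R1b", ]
  expect_gt(r$start, g$centromere[g$chrom == "6R"])
  expect_lt(r$end, g$length[g$chrom == "6R"])

  path <- withr::local_tempfile(fileext = ".bed")
  write_loci(loci, path)
  expect_equal(read_loci(path, g), loci)

  expect_error(loci_table("x", "9Z", 0, 10, "S", g), "absent")
  expect_error(loci_table("x", "6A", 0, 1e6, "L", g), "arm")
})

test_that("sample sheets require a control and round-trip", {
  s <- tibble::tibble(sample = c("a", "b"), role = c("control", "test"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_samplesheet(s, path)
  back <- read_samplesheet(path)
  expect_equal(back$sample, s$sample)
  expect_equal(back$role, s$role)
  expect_error(
    write_samplesheet(tibble::tibble(sample = "a", role = "test"), path),
    "control")
})
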