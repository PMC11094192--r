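#' Penalized least-squares segmentation of a log2-ratio series
#'
#' Finds the changepoints that minimize the within-segment sum of squared
#' deviations plus `penalty` per additional segment, over all segmentations
#' whose segments have at least `min_seg_bins` bins (a series shorter than
#' `min_seg_bins` stays one segment). Solved exactly by dynamic programming
#' (O(n^2) per series; chromosomes have tens of bins). Ties are broken
#' toward fewer segments, then toward leftmost breakpoints.
#'
#' @param x Numeric series (one chromosome's per-bin log2 ratios, masked
#'   bins already removed).
#' @param penalty Positive penalty per additional segment.
#' @param min_seg_bins Minimum bins per segment (default 3).
#' @return Integer vector of breakpoints: `b` means a boundary between
#'   positions `b` and `b + 1`. Empty when the series is one segment.
#' @export
#' @examples
#' segment_series(c(rep(0, 6), rep(-1, 6)), penalty = 0.5, min_seg_bins = 2)
segment_series <- function(x, penalty, min_seg_bins = 3) {
  if (!is.numeric(penalty) || length(penalty) != 1 || !is.finite(penalty) ||
      penalty <= 0) {
    stop("`penalty` must be a single positive number", call. = FALSE)
  }
  if (min_seg_bins < 1) stop("`min_seg_bins` must be >= 1", call. = FALSE)
  n <- length(x)
  if (n == 0) return(integer(0))
  if (n < 2 * min_seg_bins) return(integer(0))
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  sse <- function(i, j) { # segment x[i..j], 1-based inclusive
    m <- j - i + 1
    s2[j + 1] - s2[i] - (s1[j + 1] - s1[i])^2 / m
  }
  eps <- 1e-9
  # F[j+1]: best (cost, nseg, breakpoints) for prefix x[1..j]
  cost <- rep(Inf, n + 1); cost[1] <- 0
  nseg <- rep(0L, n + 1)
  bps <- vector("list", n + 1); bps[[1]] <- integer(0)
  for (j in seq_len(n)) {
    for (i in seq_len(j)) { # last segment x[i..j]
      if (j - i + 1 < min_seg_bins) next
      if (i > 1 && (i - 1) < min_seg_bins) next
      if (!is.finite(cost[i])) next
      cand_cost <- cost[i] + sse(i, j) + if (i > 1) penalty else 0
      cand_nseg <- nseg[i] + 1L
      cand_bps <- if (i > 1) c(bps[[i]], i - 1L) else integer(0)
      if (!is.finite(cost[j + 1])) {
        cost[j + 1] <- cand_cost
        nseg[j + 1] <- cand_nseg
        bps[[j + 1]] <- cand_bps
        next
      }
      tol <- eps * max(1, abs(cand_cost), abs(cost[j + 1]))
      better <- cand_cost < cost[j + 1] - tol
      if (!better && abs(cand_cost - cost[j + 1]) <= tol) {
        if (cand_nseg < nseg[j + 1]) {
          better <- TRUE
        } else if (cand_nseg == nseg[j + 1]) {
          better <- lex_less(cand_bps, bps[[j + 1]])
        }
      }
      if (better) {
        cost[j + 1] <- cand_cost
        nseg[j + 1] <- cand_nseg
        bps[[j + 1]] <- cand_bps
      }
    }
  }
  bps[[n + 1]]
}

# TRUE if breakpoint vector a is lexicographically smaller than b.
lex_less <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0) {
    d <- which(a[seq_len(k)] != b[seq_len(k)])
    if (length(d) > 0) return(a[d[1]] < b[d[1]])
  }
  length(a) < length(b)
}

#' Convert a mean log2 ratio to an integer copy number
#'
#' The copy number is the integer in 0..4 nearest to `2 * 2^mean_log2`
#' (the dosage a log2 ratio against a disomic reference implies), with
#' exact boundary values rounding down (toward fewer copies). The class
#' boundaries fall at log2 ratios -2.000, -0.415, +0.322 and +0.807
#' (log2 of 0.25, 0.75, 1.25 and 1.75).
#'
#' @param mean_log2 Numeric vector of segment mean log2 ratios; `-Inf` or
#'   floored values map to 0.
#' @return Integer vector of copy numbers in 0..4.
#' @export
#' @examples
#' assign_copy_number(c(-5, -1, 0, 0.585, 1))  # 0 1 2 3 4
assign_copy_number <- function(mean_log2) {
  dosage <- 2 * 2^mean_log2
  dosage[is.infinite(mean_log2) & mean_log2 < 0] <- 0
  cn <- ceiling(dosage - 0.5)
  as.integer(pmin(4, pmax(0, cn)))
}

# Per-bin noise variance of the log2-ratio series, for penalty = "auto".
# Uses the robust first-difference estimator (MAD of within-chromosome
# lag-1 differences, squared, halved): differences cancel the piecewise-
# constant signal, so planted events do not inflate the estimate. Measured
# on test samples when any exist — a control's residual against a mean that
# includes itself understates the noise a test sample sees — with the
# median across samples guarding against single odd libraries.
estimate_noise <- function(normalized) {
  controls <- attr(normalized, "controls") %||% character()
  floor_val <- (attr(normalized, "params") %||% list())$ratio_floor %||% -5
  x <- dplyr::filter(normalized, !.data$masked, is.finite(.data$log2ratio),
                     # floored (nullisomic) bins sit at a constant and would
                     # deflate the difference-based noise estimate
                     .data$log2ratio > floor_val + 1e-8)
  test <- dplyr::filter(x, !.data$sample %in% controls)
  if (nrow(test) >= 20) x <- test
  per_sample <- x |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::summarise(d = list(diff(.data$log2ratio[order(.data$start)])),
                     .groups = "drop") |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(sigma2 = stats::mad(unlist(.data$d))^2 / 2,
                     .groups = "drop")
  s2 <- stats::median(per_sample$sigma2)
  if (!is.finite(s2) || s2 <= 0) {
    stop("could not estimate per-bin noise; give a numeric `penalty`",
         call. = FALSE)
  }
  s2
}

# Baseline (euploid) shift of one sample's log2-ratio series: an iterated
# trimmed median that converges on the dominant dosage state. A plain
# median is biased when a large genome fraction sits at the ratio floor
# (e.g. a whole eliminated subgenome drags it below the euploid level);
# re-taking the median inside a +-0.5 window (half the 1-vs-2-copy
# spacing) sheds the other dosage states in a few iterations.
baseline_shift <- function(x, window = 0.5, iterations = 3) {
  m <- stats::median(x)
  for (k in seq_len(iterations)) {
    inside <- x[abs(x - m) <= window]
    if (length(inside) < 10) break
    m <- stats::median(inside)
  }
  m
}

#' Segment a normalized cohort and call copy-number states
#'
#' Runs changepoint segmentation on every (sample, chromosome) log2-ratio
#' series, assigns each segment an integer copy number (0-4), aggregates
#' arm copy numbers, and classifies events into the karyotype vocabulary
#' (nullisomic/monosomic/trisomic/tetrasomic, mono-/ditelosomic, terminal/
#' interstitial/pericentric deletions). Calling is done on the fine
#' (counting) grid, not the coarse display grid.
#'
#' @param normalized A `gbs_normalized` tibble from [normalize_gbs()].
#' @param genome The `gbs_genome` model.
#' @param penalty `"auto"` (10x the per-bin noise variance estimated from
#'   control residuals) or a positive number.
#' @param min_seg_bins Minimum segment length in bins (default 3; smaller
#'   events are below the method's resolution).
#' @param loci Optional loci tibble; when given, per-sample locus dosages
#'   are reported.
#' @param recenter Subtract each sample's median log2 ratio before
#'   segmentation (default `TRUE`). CPM scaling is compositional: a sample
#'   that has lost (or gained) a large genome fraction redistributes its
#'   reads over the remaining bins, shifting every log2 ratio. Recentering
#'   on the median restores the euploid baseline to 0 under the standard
#'   read-depth assumption that most of the genome is at baseline dosage.
#' @return An object of class `gbs_calls`: list with `segments`, `events`,
#'   `arms`, `loci` tibbles and `params`. `tidy()` returns the segments.
#' @export
call_dosage <- function(normalized, genome, penalty = "auto",
                        min_seg_bins = 3, loci = NULL, recenter = TRUE) {
  genome <- validate_genome(genome)
  if (identical(penalty, "auto")) {
    penalty <- 10 * estimate_noise(normalized)
  }
  width <- bin_width(attr(normalized, "bins") %||% normalized)
  bnd <- stats::setNames(arm_boundary(genome, width), genome$chrom)

  per <- normalized |>
    dplyr::filter(!.data$masked, is.finite(.data$log2ratio))
  if (recenter) {
    per <- per |>
      dplyr::group_by(.data$sample) |>
      dplyr::mutate(log2ratio = .data$log2ratio -
                      baseline_shift(.data$log2ratio)) |>
      dplyr::ungroup()
  }
  per <- per |>
    dplyr::group_by(.data$sample, .data$chrom)
  keys <- dplyr::group_keys(per)
  missing_chrom <- setdiff(genome$chrom, unique(keys$chrom))
  if (length(missing_chrom) > 0) {
    stop("no unmasked bins on chromosome(s): ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  segments <- per |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$start)
      bp <- segment_series(d$log2ratio, penalty, min_seg_bins)
      seg_id <- cumsum(seq_len(nrow(d)) %in% (bp + 1))
      d |>
        dplyr::mutate(.seg = seg_id) |>
        dplyr::group_by(.data$.seg) |>
        dplyr::summarise(start = min(.data$start), end = max(.data$end),
                         n_bins = dplyr::n(),
                         mean_log2 = mean(.data$log2ratio),
                         .groups = "drop") |>
        dplyr::select(-".seg")
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(copy_number = assign_copy_number(.data$mean_log2)) |>
    dplyr::arrange(match(.data$sample, unique(normalized$sample)),
                   match(.data$chrom, genome$chrom), .data$start)

  cls <- segments |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::group_map(function(d, key) {
      g <- genome[genome$chrom == key$chrom, ]
      res <- classify_chromosome(d, centromere = g$centromere,
                                 chrom_length = g$length,
                                 boundary = bnd[[key$chrom]], width = width)
      list(events = dplyr::mutate(res$events, sample = key$sample,
                                  chrom = key$chrom, .before = 1),
           arms = tibble::tibble(sample = key$sample, chrom = key$chrom,
                                 cn_S = res$cn_S, cn_L = res$cn_L))
    })
  events <- dplyr::bind_rows(purrr::map(cls, "events"))
  if (nrow(events) == 0) {
    events <- tibble::tibble(sample = character(), chrom = character(),
                             label = character(), start = numeric(),
                             end = numeric(), copy_number = integer(),
                             cn_S = integer(), cn_L = integer())
  }
  arms <- dplyr::bind_rows(purrr::map(cls, "arms")) |>
    dplyr::arrange(match(.data$sample, unique(normalized$sample)),
                   match(.data$chrom, genome$chrom))

  loci_res <- NULL
  if (!is.null(loci) && nrow(loci) > 0) {
    loci_res <- locus_dosage(segments, loci)
  }
  structure(list(segments = segments, events = events, arms = arms,
                 loci = loci_res,
                 params = list(penalty = penalty, min_seg_bins = min_seg_bins,
                               width = width, recenter = recenter),
                 genome = genome),
            class = "gbs_calls")
}

#' Classify one chromosome's segments into karyotype events
#'
#' Arm copy numbers are the length-weighted modal copy number of the
#' segments overlapping each arm (the bin containing the centromere belongs
#' to the short arm; ties go to the lower copy number). Equal arms give
#' whole-chromosome states (disomic emits no event; 0/1/3/4 copies emit
#' nullisomic/monosomic/trisomic/tetrasomic). Unequal arms give telosomic
#' calls named for the retained (higher) arm: `ditelosomic:S` means both
#' homologs kept only the short arm. Segments below their arm's copy number
#' are deletions: `terminal` if they touch a chromosome end, `pericentric`
#' if they span or abut the centromere bin, else `interstitial`.
#'
#' @param segments Tibble of one sample's segments on one chromosome
#'   (`start`, `end`, `mean_log2`, `copy_number`, `n_bins`), covering the
#'   chromosome's unmasked extent.
#' @param centromere,chrom_length Centromere position and chromosome
#'   length in bp.
#' @param boundary Bin-aligned arm boundary in bp (end of the bin holding
#'   the centromere); defaults to the centromere itself if not supplied.
#' @return List with `cn_S`, `cn_L` (integer arm copy numbers) and
#'   `events` (tibble `label`, `start`, `end`, `copy_number`, `cn_S`,
#'   `cn_L`).
#' @export
classify_chromosome <- function(segments, centromere, chrom_length,
                                boundary = NULL, width = NULL) {
  if (nrow(segments) == 0) {
    stop("no segments supplied for classification", call. = FALSE)
  }
  boundary <- boundary %||% centromere
  cen_bin_start <- if (!is.null(width)) max(0, boundary - width) else centromere
  arm_cn <- function(a_start, a_end) {
    ov <- pmin(segments$end, a_end) - pmax(segments$start, a_start)
    ov <- pmax(ov, 0)
    if (sum(ov) == 0) return(NA_integer_)
    w <- tapply(ov, segments$copy_number, sum)
    w <- w[w > 0]
    cns <- as.integer(names(w))
    # ties (e.g. a deletion covering exactly half the arm) resolve toward
    # the euploid state, then toward fewer copies, so sub-arm deletions do
    # not shift the arm's baseline
    cns[order(-w, abs(cns - 2L), cns)][1]
  }
  cn_S <- arm_cn(0, boundary)
  cn_L <- arm_cn(boundary, chrom_length)
  # A chromosome entirely on one side (unmasked extent) inherits the other
  # arm's state rather than reporting NA.
  if (is.na(cn_S)) cn_S <- cn_L
  if (is.na(cn_L)) cn_L <- cn_S
  events <- list()
  add <- function(label, start, end, cn) {
    events[[length(events) + 1]] <<- tibble::tibble(
      label = label, start = start, end = end, copy_number = as.integer(cn),
      cn_S = cn_S, cn_L = cn_L)
  }
  if (cn_S == cn_L) {
    lab <- unname(c(`0` = "nullisomic", `1` = "monosomic", `2` = "disomic",
                    `3` = "trisomic", `4` = "tetrasomic")[as.character(cn_S)])
    if (lab != "disomic") add(lab, 0, chrom_length, cn_S)
  } else {
    lo <- min(cn_S, cn_L); hi <- max(cn_S, cn_L)
    retained <- if (cn_S > cn_L) "S" else "L"
    lost_int <- if (retained == "S") c(boundary, chrom_length) else c(0, boundary)
    lab <- if (lo == 0 && hi == 2) {
      paste0("ditelosomic:", retained)
    } else {
      paste0("monotelosomic:", retained)
    }
    add(lab, lost_int[1], lost_int[2], lo)
  }
  # Sub-arm deletions: segments below their arm's modal copy number.
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    arm <- if (s$start < boundary) "S" else "L"
    arm_base <- if (arm == "S") cn_S else cn_L
    # segments spanning the boundary count against the arm holding most of them
    if (s$start < boundary && s$end > boundary) {
      arm <- if ((boundary - s$start) >= (s$end - boundary)) "S" else "L"
      arm_base <- if (arm == "S") cn_S else cn_L
    }
    if (s$copy_number >= arm_base) next
    # skip segments that are the arm loss itself (cover >= half the arm)
    a_int <- if (arm == "S") c(0, boundary) else c(boundary, chrom_length)
    ov <- min(s$end, a_int[2]) - max(s$start, a_int[1])
    if (ov > 0.5 * (a_int[2] - a_int[1])) next
    touches_start <- s$start <= 0
    touches_end <- s$end >= chrom_length
    if (touches_start || touches_end) {
      add(paste0("terminal_deletion:", if (touches_start) "S" else "L"),
          s$start, s$end, s$copy_number)
    } else if (s$start <= boundary && s$end >= cen_bin_start) {
      add("pericentric_deletion", s$start, s$end, s$copy_number)
    } else {
      add("interstitial_deletion", s$start, s$end, s$copy_number)
    }
  }
  list(cn_S = cn_S, cn_L = cn_L,
       events = if (length(events) > 0) dplyr::bind_rows(events) else
         tibble::tibble(label = character(), start = numeric(),
                        end = numeric(), copy_number = integer(),
                        cn_S = integer(), cn_L = integer()))
}

#' Copy number of a named locus
#'
#' The locus copy number is the minimum copy number over all segments
#' overlapping the locus interval (a locus straddling a breakpoint is only
#' as present as its most-deleted part); `present` means copy number >= 1.
#'
#' @param segments Segment tibble (from `call_dosage()$segments`) for one
#'   or more samples.
#' @param loci Loci tibble (e.g. [default_loci()]).
#' @return Tibble with `sample`, `name`, `chrom`, `copy_number`, `present`.
#' @export
locus_dosage <- function(segments, loci) {
  samples <- unique(segments$sample)
  out <- tidyr::expand_grid(sample = samples,
                            loci[, c("name", "chrom", "start", "end")]) |>
    dplyr::rowwise() |>
    dplyr::mutate(copy_number = {
      seg <- segments[segments$sample == .data$sample &
                        segments$chrom == .data$chrom &
                        segments$start < .data$end &
                        segments$end > .data$start, ]
      if (nrow(seg) == 0) {
        stop("locus '", .data$name, "': chromosome ", .data$chrom,
             " has no called segments for sample ", .data$sample,
             call. = FALSE)
      }
      min(seg$copy_number)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(present = .data$copy_number >= 1) |>
    dplyr::select("sample", "name", "chrom", "copy_number", "present")
  out
}

#' Write dosage calls to disk
#'
#' Writes `segments.bed` (chrom, start, end, sample, copy number, mean
#' log2) and `events.tsv` (plus `loci.tsv` when locus dosages were
#' computed) under `dir`.
#'
#' @param calls A `gbs_calls` object.
#' @param dir Output directory.
#' @export
write_calls <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg <- tibble::tibble(chrom = calls$segments$chrom,
                        start = calls$segments$start,
                        end = calls$segments$end,
                        sample = calls$segments$sample,
                        copy_number = calls$segments$copy_number,
                        mean_log2 = calls$segments$mean_log2)
  readr::write_tsv(seg, file.path(dir, "segments.bed"))
  readr::write_tsv(calls$events, file.path(dir, "events.tsv"))
  readr::write_tsv(calls$arms, file.path(dir, "arms.tsv"))
  if (!is.null(calls$loci)) {
    readr::write_tsv(calls$loci, file.path(dir, "loci.tsv"))
  }
  invisible(dir)
}
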