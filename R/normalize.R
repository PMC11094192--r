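#' Counts-per-million scaling
#'
#' First normalization step: each sample's raw bin counts are divided by
#' that sample's total and multiplied by 1e6, removing library-size
#' differences between GBS libraries.
#'
#' @param counts A long count tibble (`sample`, `chrom`, `start`, `end`,
#'   `count`), e.g. from [read_counts()] or [simulate_cohort()].
#' @return The same tibble with a `cpm` column appended; per sample the
#'   `cpm` values sum to 1e6.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 1))
#' head(scale_cpm(sim$counts))
scale_cpm <- function(counts) {
  totals <- counts |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals$sample[totals$total <= 0]
  if (length(zero) > 0) {
    stop("sample(s) with zero total counts cannot be scaled: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  counts |>
    dplyr::left_join(totals, by = "sample") |>
    dplyr::mutate(cpm = .data$count / .data$total * 1e6) |>
    dplyr::select(-"total")
}

#' Per-bin euploid control reference
#'
#' Second-step reference: the arithmetic mean of the scaled (CPM) values of
#' the euploid control samples, per bin. Bins whose control mean falls
#' below `min_control_cpm` are masked — these are GBS target deserts where
#' a ratio would be dominated by noise (or undefined at 0).
#'
#' @param scaled Output of [scale_cpm()].
#' @param samplesheet Sample sheet with at least one `control` row.
#' @param min_control_cpm Masking threshold in CPM (default 1).
#' @return Tibble with one row per bin: `chrom`, `start`, `end`,
#'   `control_mean`, `masked`.
#' @export
control_reference <- function(scaled, samplesheet, min_control_cpm = 1) {
  samplesheet <- validate_samplesheet(samplesheet)
  controls <- samplesheet$sample[samplesheet$role == "control"]
  controls <- intersect(controls, unique(scaled$sample))
  if (length(controls) == 0) {
    stop("no control sample from the sample sheet is present in the data",
         call. = FALSE)
  }
  scaled |>
    dplyr::filter(.data$sample %in% controls) |>
    dplyr::group_by(.data$chrom, .data$start, .data$end) |>
    dplyr::summarise(control_mean = mean(.data$cpm), .groups = "drop") |>
    dplyr::mutate(masked = .data$control_mean < min_control_cpm) |>
    dplyr::arrange(match(paste(.data$chrom, .data$start),
                         unique(paste(scaled$chrom, scaled$start))))
}

#' Per-bin log2 coverage ratios against the control reference
#'
#' For each unmasked bin, `log2((cpm + pseudo) / (control_mean + pseudo))`,
#' floored at `ratio_floor`. A log2 ratio of 0 means balanced dosage, -1
#' half dosage (monosomic), and the floor is where nullisomic bins land.
#' Masked bins carry `log2ratio = NA` and `masked = TRUE`, never a silent 0.
#'
#' @param scaled Output of [scale_cpm()].
#' @param reference Output of [control_reference()].
#' @param pseudo Pseudocount in CPM added to numerator and denominator
#'   (default 0.5); keeps zero-count bins finite. Must be >= 0.
#' @param ratio_floor Lower bound applied to the ratios (default -5).
#' @return `scaled` with `log2ratio` and `masked` columns appended.
#' @export
log2_ratio <- function(scaled, reference, pseudo = 0.5, ratio_floor = -5) {
  if (pseudo < 0) stop("`pseudo` must be >= 0", call. = FALSE)
  out <- scaled |>
    dplyr::left_join(
      dplyr::select(reference, "chrom", "start", "control_mean", "masked"),
      by = c("chrom", "start")) |>
    dplyr::mutate(
      log2ratio = dplyr::if_else(
        .data$masked, NA_real_,
        pmax(log2((.data$cpm + pseudo) / (.data$control_mean + pseudo)),
             ratio_floor))) |>
    dplyr::select(-"control_mean")
  out
}

#' Normalize a GBS count table against euploid controls
#'
#' The two-step normalization in one call: CPM scaling per sample, then
#' per-bin log2 ratios against the mean of the euploid control samples.
#'
#' @inheritParams scale_cpm
#' @inheritParams control_reference
#' @inheritParams log2_ratio
#' @return A tibble of class `gbs_normalized` (`sample`, `chrom`, `start`,
#'   `end`, `count`, `cpm`, `log2ratio`, `masked`) with the control
#'   reference, control sample ids and parameters stored as attributes.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(
#'   genotypes = list(c1 = NULL, c2 = NULL,
#'                    mono1A = dosage_event("1A", "whole_chromosome", 1)),
#'   seed = 2))
#' nm <- normalize_gbs(sim$counts, sim$samplesheet)
#' dplyr::filter(nm, sample == "mono1A", chrom == "1A")  # log2 ratios near -1
normalize_gbs <- function(counts, samplesheet, pseudo = 0.5,
                          min_control_cpm = 1, ratio_floor = -5) {
  scaled <- scale_cpm(counts)
  reference <- control_reference(scaled, samplesheet, min_control_cpm)
  out <- log2_ratio(scaled, reference, pseudo, ratio_floor)
  samplesheet <- validate_samplesheet(samplesheet)
  structure(out,
            reference = reference,
            bins = attr(counts, "bins"),
            controls = samplesheet$sample[samplesheet$role == "control"],
            params = list(pseudo = pseudo, min_control_cpm = min_control_cpm,
                          ratio_floor = ratio_floor),
            class = unique(c("gbs_normalized", class(tibble::tibble()))))
}

#' Re-bin per-bin values onto a coarser grid
#'
#' Collapses fine bins (e.g. the 1 Mb counting grid) into coarse bins (e.g.
#' the 5 Mb display grid). `mode = "sum"` conserves totals and is right for
#' raw counts; `mode = "mean"` averages over unmasked fine bins and is
#' right for log2 ratios. A coarse bin is masked only when all its members
#' are masked. The coarse width must be a multiple of the fine width; the
#' last group on each chromosome may be partial.
#'
#' @param x A long tibble with `chrom`, `start`, `end`, a value column, and
#'   optionally `sample` and `masked` columns.
#' @param value Name of the value column (string), e.g. `"count"` or
#'   `"log2ratio"`.
#' @param width Target coarse width in bp (default 5 Mb).
#' @param mode `"sum"` or `"mean"`.
#' @return Coarse-grid tibble with columns `sample` (if present), `chrom`,
#'   `start`, `end`, `<value>`, `masked`.
#' @export
#' @examples
#' bins <- make_bins(genome_model("1A", "A", 7e6, 3e6), 1e6)
#' x <- dplyr::mutate(bins, count = 1:7)
#' rebin(x, "count", 5e6, "sum")   # groups of 5 and 2 bins: 15 and 13
rebin <- function(x, value, width = 5e6, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  fine <- sort(unique(x$end - x$start), decreasing = TRUE)[1]
  if (width <= 0 || (width %% fine) != 0) {
    stop("coarse width (", width, ") must be a positive multiple of the ",
         "fine bin width (", fine, ")", call. = FALSE)
  }
  if (!value %in% names(x)) {
    stop("no column named '", value, "' to rebin", call. = FALSE)
  }
  if (!("masked" %in% names(x))) x$masked <- FALSE
  grp <- c()
  if ("sample" %in% names(x)) grp <- "sample"
  out <- x |>
    dplyr::mutate(.coarse = floor(.data$start / width) * width) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "chrom", ".coarse")))) |>
    dplyr::summarise(
      end = max(.data$end),
      .value = if (mode == "sum") {
        sum(.data[[value]])
      } else if (all(.data$masked)) {
        NA_real_
      } else {
        mean(.data[[value]][!.data$masked])
      },
      masked = all(.data$masked),
      .groups = "drop") |>
    dplyr::rename(start = ".coarse")
  names(out)[names(out) == ".value"] <- value
  out <- dplyr::relocate(
    out, dplyr::all_of(c(grp, "chrom", "start", "end", value, "masked")))
  if ("sample" %in% names(out)) {
    dplyr::arrange(out, match(.data$sample, unique(x$sample)),
                   match(.data$chrom, unique(x$chrom)), .data$start)
  } else {
    dplyr::arrange(out, match(.data$chrom, unique(x$chrom)), .data$start)
  }
}

#' Write / read a normalized table
#'
#' Long-format TSV with columns `sample`, `chrom`, `start`, `end`, `count`,
#' `cpm`, `log2ratio`, `masked` — the interchange format between the
#' normalization and calling stages.
#'
#' @param normalized A `gbs_normalized` tibble.
#' @param path TSV path.
#' @export
write_normalized <- function(normalized, path) {
  readr::write_tsv(tibble::as_tibble(normalized), path)
  invisible(path)
}

#' @rdname write_normalized
#' @param controls Control sample ids (recorded so `penalty = "auto"` in
#'   [call_dosage()] still works after a round trip).
#' @export
read_normalized <- function(path, controls = character()) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         sample = readr::col_character(),
                         chrom = readr::col_character(),
                         masked = readr::col_logical(),
                         .default = readr::col_double()))
  x <- strip_readr_attrs(x)
  structure(x, controls = controls,
            class = unique(c("gbs_normalized", class(tibble::tibble()))))
}
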