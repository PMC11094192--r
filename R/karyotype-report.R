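#' Somatic chromosome number from arm copy numbers
#'
#' The somatic chromosome number 2n counts chromosome *bodies*: each
#' chromosome contributes `max(cn_S, cn_L)`, so a telocentric (one arm
#' lost on one or both homologs) still contributes the homolog(s) carrying
#' the retained arm. A euploid wheat x rye amphidiploid (28 chromosome
#' pairs) gives 2n = 56; loss of the whole rye genome gives 42.
#'
#' @param arms Tibble with `chrom`, `cn_S`, `cn_L`, and optionally
#'   `sample` (then a per-sample result is returned).
#' @param genome Optional `gbs_genome`; when given, every chromosome of the
#'   genome must be present per sample (missing ones are an error).
#' @return Tibble with `inferred_2n` (and `sample` when present in input).
#' @export
#' @examples
#' arms <- tibble::tibble(chrom = c("1A", "1B"), cn_S = c(2, 2), cn_L = c(2, 0))
#' count_2n(arms)  # 4: the telosome still counts as a body
count_2n <- function(arms, genome = NULL) {
  if (any(is.na(arms$cn_S) | is.na(arms$cn_L))) {
    stop("arm copy numbers contain NA", call. = FALSE)
  }
  if (!("sample" %in% names(arms))) {
    arms <- dplyr::mutate(arms, sample = ".")
    drop_sample <- TRUE
  } else {
    drop_sample <- FALSE
  }
  if (!is.null(genome)) {
    genome <- validate_genome(genome)
    miss <- arms |>
      dplyr::group_by(.data$sample) |>
      dplyr::summarise(missing = list(setdiff(genome$chrom, .data$chrom)),
                       .groups = "drop") |>
      dplyr::filter(lengths(.data$missing) > 0)
    if (nrow(miss) > 0) {
      stop("sample '", miss$sample[1], "' is missing arm calls for: ",
           paste(miss$missing[[1]], collapse = ", "), call. = FALSE)
    }
  }
  out <- arms |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(inferred_2n = sum(pmax(.data$cn_S, .data$cn_L)),
                     .groups = "drop")
  if (drop_sample) dplyr::select(out, -"sample") else out
}

#' Per-plant karyotype reports
#'
#' Aggregates dosage calls into one report per sample: per-chromosome arm
#' copy numbers and labels, the inferred somatic chromosome number 2n
#' (chromosome bodies, telocentrics included), chromosome tallies per
#' subgenome, locus presence flags, and the event list. Samples with no
#' events are labelled `"euploid, no major rearrangements"`.
#'
#' @param calls A `gbs_calls` object from [call_dosage()].
#' @param samplesheet Optional sample sheet (adds the `role` column).
#' @return An object of class `gbs_karyotype`: list of tibbles `summary`
#'   (one row per sample), `chromosomes`, `events`, `loci`. `glance()`
#'   returns the summary, `tidy()` the per-chromosome table.
#' @export
karyotype_report <- function(calls, samplesheet = NULL) {
  stopifnot(inherits(calls, "gbs_calls"))
  genome <- calls$genome
  arms <- calls$arms
  two_n <- count_2n(arms, genome)

  chrom_tbl <- arms |>
    dplyr::left_join(
      dplyr::summarise(
        dplyr::group_by(calls$events, .data$sample, .data$chrom),
        label = paste(.data$label, collapse = ";"), .groups = "drop"),
      by = c("sample", "chrom")) |>
    dplyr::mutate(label = dplyr::coalesce(.data$label, "disomic"),
                  bodies = pmax(.data$cn_S, .data$cn_L))

  tallies <- chrom_tbl |>
    dplyr::left_join(genome[, c("chrom", "subgenome")], by = "chrom") |>
    dplyr::group_by(.data$sample, .data$subgenome) |>
    dplyr::summarise(bodies = sum(.data$bodies), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "subgenome", values_from = "bodies",
                       names_prefix = "n_", values_fill = 0L)

  n_events <- calls$events |>
    dplyr::count(.data$sample, name = "n_events")

  summary <- two_n |>
    dplyr::left_join(tallies, by = "sample") |>
    dplyr::left_join(n_events, by = "sample") |>
    dplyr::mutate(
      n_events = tidyr::replace_na(.data$n_events, 0L),
      status = dplyr::if_else(.data$n_events == 0,
                              "euploid, no major rearrangements",
                              "rearranged"))
  if (!is.null(samplesheet)) {
    samplesheet <- validate_samplesheet(samplesheet)
    summary <- dplyr::left_join(summary,
                                samplesheet[, c("sample", "role")],
                                by = "sample") |>
      dplyr::relocate("role", .after = "sample")
  }
  summary <- dplyr::arrange(summary,
                            match(.data$sample, unique(arms$sample)))

  structure(list(summary = summary,
                 chromosomes = dplyr::select(chrom_tbl, "sample", "chrom",
                                             "cn_S", "cn_L", "label"),
                 events = calls$events,
                 loci = calls$loci),
            class = "gbs_karyotype")
}

#' Percentage of plants showing somatic karyotype changes
#'
#' Cohort-level rate of somatic (pre-meiotic) structural change: the share
#' of plants whose karyotype differs from euploid, as a percentage.
#'
#' @param n_changed Number of plants with somatic structural changes.
#' @param n_total Total number of plants screened.
#' @return Percentage (0-100).
#' @export
#' @examples
#' somatic_change_rate(8, 229)
somatic_change_rate <- function(n_changed, n_total) {
  if (n_total <= 0 || n_changed < 0 || n_changed > n_total) {
    stop("need 0 <= n_changed <= n_total and n_total > 0", call. = FALSE)
  }
  100 * n_changed / n_total
}

#' Genome-wide coverage profile plot
#'
#' Plots one sample's log2 coverage ratios along the genome in coarse
#' display bins (default 5 Mb), split into a wheat panel (A/B/D
#' subgenomes) and a rye panel (R), with horizontal guides at the
#' monosomic (log2 0.5) and trisomic (log2 1.5) levels. Values are clipped
#' at the ratio floor, so nullisomic chromosomes render as a flat floor
#' band.
#'
#' @param normalized A `gbs_normalized` tibble.
#' @param sample Sample identifier to plot.
#' @param genome The `gbs_genome` model.
#' @param display_width Display bin width in bp (default 5 Mb).
#' @param path Optional output file (png/pdf via [ggplot2::ggsave()]).
#' @return The ggplot object (invisibly when `path` is given).
#' @export
plot_genome <- function(normalized, sample, genome, display_width = 5e6,
                        path = NULL) {
  genome <- validate_genome(genome)
  if (!sample %in% unique(normalized$sample)) {
    stop("unknown sample: ", sample, call. = FALSE)
  }
  d <- rebin_sample(normalized, sample, display_width)
  d <- dplyr::left_join(d, genome[, c("chrom", "subgenome")], by = "chrom") |>
    dplyr::mutate(panel = dplyr::if_else(.data$subgenome == "R",
                                         "rye (R)", "wheat (A/B/D)"),
                  chrom = factor(.data$chrom, levels = genome$chrom),
                  mid = (.data$start + .data$end) / 2e6)
  floor_y <- attr(normalized, "params")$ratio_floor %||% -5
  p <- ggplot2::ggplot(dplyr::filter(d, !d$masked),
                       ggplot2::aes(x = .data$mid, y = .data$log2ratio)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_hline(yintercept = log2(c(0.5, 1.5)), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(size = 0.6, colour = "#2166ac") +
    ggplot2::facet_grid(panel ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::coord_cartesian(ylim = c(floor_y, 2)) +
    ggplot2::labs(x = "position (Mb)", y = "log2 coverage ratio",
                  title = sample) +
    ggplot2::theme_bw(base_size = 9) +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(0.5, "pt"),
                   axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 10, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}

rebin_sample <- function(normalized, sample, display_width) {
  normalized |>
    dplyr::filter(.data$sample == !!sample) |>
    rebin("log2ratio", display_width, "mean")
}

#' @export
autoplot.gbs_normalized <- function(object, sample = NULL, genome = NULL,
                                    display_width = 5e6, ...) {
  genome <- genome %||% attr(attr(object, "bins"), "genome")
  if (is.null(genome)) {
    stop("supply `genome` (not recoverable from this object)", call. = FALSE)
  }
  sample <- sample %||% unique(object$sample)[1]
  plot_genome(object, sample, genome, display_width)
}

#' Run the full GBS karyotyping pipeline
#'
#' Simulate (or read) bin counts, normalize against euploid controls,
#' segment and call copy-number events, and write per-plant karyotype
#' reports plus a JSON manifest recording package version, seed and
#' parameters. With `truth` available (simulation input), a recovery table
#' comparing calls with the planted truth is also written.
#'
#' @param config Either a `gbs_sim_config` (simulate a cohort), a
#'   `gbs_simulation`, or a list with elements `counts` (`gbs_counts`),
#'   `samplesheet`, `genome` and optionally `loci`.
#' @param out_dir Output directory.
#' @param loci Loci tibble; defaults to [default_loci()] of the genome.
#' @param penalty,min_seg_bins Passed to [call_dosage()].
#' @param pseudo,min_control_cpm,ratio_floor Passed to [normalize_gbs()].
#' @param plots Number of per-sample genome plots to write (default 0).
#' @return Invisibly, a list with `normalized`, `calls`, `report`, and
#'   (when simulated) `truth` and `recovery`.
#' @export
run_pipeline <- function(config, out_dir, loci = NULL, penalty = "auto",
                         min_seg_bins = 3, pseudo = 0.5, min_control_cpm = 1,
                         ratio_floor = -5, plots = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- tryCatch({
    if (inherits(config, "gbs_sim_config")) {
      stage <- "simulate"
      sim <- simulate_cohort(config)
    } else if (inherits(config, "gbs_simulation")) {
      sim <- config
    } else {
      sim <- list(counts = config$counts, samplesheet = config$samplesheet,
                  truth = NULL,
                  config = list(genome = config$genome, seed = NA))
    }
    genome <- if (!is.null(sim$config$genome)) sim$config$genome else config$genome
    loci <- loci %||% default_loci(genome)

    stage <- "normalize"
    nm <- normalize_gbs(sim$counts, sim$samplesheet, pseudo = pseudo,
                        min_control_cpm = min_control_cpm,
                        ratio_floor = ratio_floor)
    write_normalized(nm, file.path(out_dir, "normalized.tsv"))

    stage <- "call"
    calls <- call_dosage(nm, genome, penalty = penalty,
                         min_seg_bins = min_seg_bins, loci = loci)
    write_calls(calls, out_dir)

    stage <- "report"
    report <- karyotype_report(calls, sim$samplesheet)
    readr::write_tsv(report$summary, file.path(out_dir, "karyotype.tsv"))
    readr::write_tsv(report$chromosomes, file.path(out_dir, "chromosomes.tsv"))

    recovery <- NULL
    if (!is.null(sim$truth)) {
      write_truth(sim$truth, out_dir)
      recovery <- compare_to_truth(report, calls, sim$truth)
      readr::write_tsv(recovery, file.path(out_dir, "recovery.tsv"))
    }

    if (plots > 0) {
      stage <- "plot"
      for (s in utils::head(unique(nm$sample), plots)) {
        plot_genome(nm, s, genome,
                    path = file.path(out_dir, paste0(s, ".genome.png")))
      }
    }

    manifest <- list(
      package = "gbskaryo",
      version = as.character(utils::packageVersion("gbskaryo")),
      seed = sim$config$seed,
      parameters = list(penalty = calls$params$penalty,
                        min_seg_bins = min_seg_bins, pseudo = pseudo,
                        min_control_cpm = min_control_cpm,
                        ratio_floor = ratio_floor))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(normalized = nm, calls = calls, report = report,
         truth = sim$truth, recovery = recovery)
  }, error = function(e) {
    failed <- file.path(out_dir, "failed")
    dir.create(failed, showWarnings = FALSE, recursive = TRUE)
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(failed, "error.txt"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Compare called karyotypes with a simulation truth set
#'
#' Per genotype: does the inferred 2n match the expected 2n, and how many
#' planted events were recovered with the exact copy number (an event is
#' recovered when a called segment or whole-chromosome/arm state of the
#' same copy number covers at least half of the planted interval)?
#'
#' @param report A `gbs_karyotype` from [karyotype_report()].
#' @param calls The `gbs_calls` the report was built from.
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @return Tibble with one row per genotype: `sample`, `expected_2n`,
#'   `inferred_2n`, `match_2n`, `n_planted`, `n_recovered`,
#'   `arms_correct` (all arm copy numbers exact), `false_call_bins`
#'   (bins asserted at non-baseline copy number with no planted event).
#' @export
compare_to_truth <- function(report, calls, truth) {
  width <- calls$params$width
  per_sample <- purrr::map_dfr(report$summary$sample, function(s) {
    planted <- dplyr::filter(truth$events, .data$genotype == s)
    segs <- dplyr::filter(calls$segments, .data$sample == s)
    recovered <- 0L
    if (nrow(planted) > 0) {
      for (i in seq_len(nrow(planted))) {
        p <- planted[i, ]
        ov <- segs |>
          dplyr::filter(.data$chrom == p$chrom,
                        .data$copy_number == p$copy_number) |>
          dplyr::mutate(ov = pmax(0, pmin(.data$end, p$end) -
                                    pmax(.data$start, p$start)))
        if (sum(ov$ov) >= 0.5 * (p$end - p$start)) {
          recovered <- recovered + 1L
        }
      }
    }
    true_arms <- dplyr::filter(truth$arms, .data$genotype == s)
    called_arms <- dplyr::filter(calls$arms, .data$sample == s)
    j <- dplyr::inner_join(true_arms, called_arms, by = "chrom",
                           suffix = c("_true", "_called"))
    arms_correct <- all(j$cn_S_true == j$cn_S_called &
                          j$cn_L_true == j$cn_L_called)
    # bins called away from copy 2 outside any planted interval
    fc <- segs |>
      dplyr::filter(.data$copy_number != 2L) |>
      dplyr::rowwise() |>
      dplyr::mutate(extra = {
        pl <- planted[planted$chrom == .data$chrom, ]
        ov <- if (nrow(pl) == 0) 0 else
          sum(pmax(0, pmin(pl$end, .data$end) - pmax(pl$start, .data$start)))
        max(0, (.data$end - .data$start) - ov)
      }) |>
      dplyr::ungroup()
    tibble::tibble(sample = s, n_planted = nrow(planted),
                   n_recovered = recovered, arms_correct = arms_correct,
                   false_call_bins = round(sum(fc$extra) / width))
  })
  report$summary |>
    dplyr::select("sample", "inferred_2n") |>
    dplyr::left_join(truth$expected_2n, by = c(sample = "genotype")) |>
    dplyr::mutate(match_2n = .data$inferred_2n == .data$expected_2n) |>
    dplyr::left_join(per_sample, by = "sample") |>
    dplyr::relocate("sample", "expected_2n", "inferred_2n", "match_2n")
}
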