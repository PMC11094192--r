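#' @importFrom rlang .data %||%
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Drop readr's spec/problems metadata so read-back tables compare clean.
strip_readr_attrs <- function(x) {
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  x
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so simulation substreams never leak into user code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
tidy.gbs_calls <- function(x, ...) x$segments

#' @export
glance.gbs_calls <- function(x, ...) {
  x$segments |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_segments = dplyr::n(),
                     n_chromosomes = dplyr::n_distinct(.data$chrom),
                     .groups = "drop") |>
    dplyr::left_join(
      dplyr::count(x$events, .data$sample, name = "n_events"),
      by = "sample") |>
    dplyr::mutate(n_events = tidyr::replace_na(.data$n_events, 0L),
                  penalty = x$params$penalty)
}

#' @export
tidy.gbs_karyotype <- function(x, ...) x$chromosomes

#' @export
glance.gbs_karyotype <- function(x, ...) x$summary

#' @export
print.gbs_sim_config <- function(x, ...) {
  cat("<gbs_sim_config>\n")
  cat("  genome:", nrow(x$genome), "chromosomes;",
      sum(x$genome$length) / 1e6, "Mb total\n")
  cat("  bin width:", x$bin_width, "bp; genotypes:", length(x$genotypes),
      sprintf("(%d event-free)\n",
              sum(purrr::map_int(x$genotypes, nrow) == 0)))
  cat("  lib size ~ lognormal(mean ", x$lib_size_mean, ", sigma ",
      x$lib_size_sigma, "); dispersion ", x$dispersion,
      "; floor ", x$cross_mapping_floor, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
print.gbs_karyotype <- function(x, ...) {
  cat("<gbs_karyotype> ", nrow(x$summary), " sample(s)\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}

#' @export
print.gbs_calls <- function(x, ...) {
  cat("<gbs_calls> ", dplyr::n_distinct(x$segments$sample), " sample(s), ",
      nrow(x$segments), " segments, ", nrow(x$events), " event call(s); ",
      "penalty ", signif(x$params$penalty, 3), "\n", sep = "")
  invisible(x)
}
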