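#' Describe a planted dosage event
#'
#' An event sets the copy number of a whole chromosome, one arm, or a
#' segment of a simulated genotype. Copy numbers run 0 (nullisomic) to 4
#' (tetrasomic); the euploid baseline is 2. Events within one genotype may
#' not overlap.
#'
#' @param chrom Chromosome name.
#' @param scope One of `"whole_chromosome"`, `"arm:S"`, `"arm:L"`,
#'   `"segment"`.
#' @param copy_number Integer in 0..4.
#' @param start,end Segment bounds in bp (required when
#'   `scope = "segment"`).
#' @return One-row tibble describing the event.
#' @export
#' @examples
#' dosage_event("6A", "arm:L", 0)              # ditelosomic 6AS genotype
#' dosage_event("1B", "segment", 1, 10e6, 18e6)
dosage_event <- function(chrom, scope, copy_number, start = NA, end = NA) {
  scope <- match.arg(scope, c("whole_chromosome", "arm:S", "arm:L", "segment"))
  if (!copy_number %in% 0:4) {
    stop("copy_number must be an integer in 0..4", call. = FALSE)
  }
  if (scope == "segment" && (is.na(start) || is.na(end) || start >= end)) {
    stop("segment events need start < end", call. = FALSE)
  }
  tibble::tibble(chrom = as.character(chrom), scope = scope,
                 copy_number = as.integer(copy_number),
                 start = as.numeric(start), end = as.numeric(end))
}

#' Simulation configuration for a GBS cohort
#'
#' Captures the statistical structure of GBS bin counts: a per-bin target
#' density shared by every sample (GBS restriction targets are unevenly
#' distributed but reproducibly so), a per-sample library size, and
#' negative-binomial count noise. A small cross-mapping floor keeps deleted
#' regions from reading exactly zero, as residual homeolog mis-mapping does
#' in real allopolyploid data.
#'
#' @param genome A `gbs_genome` model (default [default_genome()]).
#' @param bin_width Bin width in bp, default 1 Mb.
#' @param genotypes Named list; each element is a tibble of
#'   [dosage_event()] rows (possibly empty = euploid). Event-free genotypes
#'   are marked `control` in the emitted sample sheet.
#' @param density_sigma Log-normal sigma of the shared per-bin target
#'   density multipliers (default 0.7).
#' @param lib_size_mean Mean per-sample library size in reads
#'   (default 2e5, about 180 reads per 1 Mb bin on the default genome).
#' @param lib_size_sigma Log-normal sigma of library sizes (default 0.2).
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts. Default 0.05.
#' @param cross_mapping_floor Fraction of the baseline rate still observed
#'   at copy number 0; must be in `[0, 0.25)`. Default 0.02.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the config including this seed.
#' @return A list of class `gbs_sim_config`.
#' @export
sim_config <- function(genome = default_genome(), bin_width = 1e6,
                       genotypes = list(control_1 = NULL),
                       density_sigma = 0.7, lib_size_mean = 2e5,
                       lib_size_sigma = 0.2, dispersion = 0.05,
                       cross_mapping_floor = 0.02, seed = 1) {
  genome <- validate_genome(genome)
  if (cross_mapping_floor < 0 || cross_mapping_floor >= 0.25) {
    stop("cross_mapping_floor must be in [0, 0.25)", call. = FALSE)
  }
  if (lib_size_mean <= 0) stop("lib_size_mean must be > 0", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (density_sigma < 0) stop("density_sigma must be >= 0", call. = FALSE)
  if (is.null(names(genotypes)) || any(names(genotypes) == "") ||
      anyDuplicated(names(genotypes)) > 0) {
    stop("genotypes must be a uniquely named list", call. = FALSE)
  }
  genotypes <- purrr::map(genotypes, function(ev) {
    if (is.null(ev) || (is.data.frame(ev) && nrow(ev) == 0)) {
      return(dosage_event("none", "whole_chromosome", 2)[0, ])
    }
    tibble::as_tibble(ev)
  })
  structure(list(genome = genome, bin_width = bin_width,
                 genotypes = genotypes, density_sigma = density_sigma,
                 lib_size_mean = lib_size_mean, lib_size_sigma = lib_size_sigma,
                 dispersion = dispersion,
                 cross_mapping_floor = cross_mapping_floor,
                 seed = as.integer(seed)),
            class = "gbs_sim_config")
}

# Deterministic, order-invariant substream seed for one genotype: a
# polynomial hash of the genotype name mixed with the cohort seed, kept
# inside the 32-bit signed range. Keying by name (not list position) means
# adding genotypes to a cohort never perturbs existing samples.
substream_seed <- function(seed, name) {
  m <- 2147483647
  h <- 7
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  as.integer((h + (seed %% m) * 31) %% m)
}

# Expand events to per-bin copy numbers on the grid. Arm events use the
# bin-aligned arm boundary (the centromere-containing bin belongs to S) so
# simulator truth and caller aggregation share one convention.
events_to_bin_copy <- function(events, genome, bins, genotype = "genotype") {
  width <- bin_width(bins)
  copy <- rep(2L, nrow(bins))
  if (nrow(events) == 0) return(copy)
  m <- match(events$chrom, genome$chrom)
  if (anyNA(m)) {
    stop("genotype '", genotype, "': event chromosome(s) not in genome: ",
         paste(unique(events$chrom[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  bnd <- arm_boundary(genome, width)[m]
  len <- genome$length[m]
  ev_start <- dplyr::case_when(
    events$scope == "whole_chromosome" ~ 0,
    events$scope == "arm:S" ~ 0,
    events$scope == "arm:L" ~ bnd,
    TRUE ~ events$start
  )
  ev_end <- dplyr::case_when(
    events$scope == "whole_chromosome" ~ len,
    events$scope == "arm:S" ~ bnd,
    events$scope == "arm:L" ~ len,
    TRUE ~ events$end
  )
  if (any(ev_start < 0 | ev_end > len | ev_start >= ev_end)) {
    stop("genotype '", genotype, "': event outside chromosome bounds",
         call. = FALSE)
  }
  touched <- rep(FALSE, nrow(bins))
  for (i in seq_len(nrow(events))) {
    hit <- bins$chrom == events$chrom[i] &
      bins$start < ev_end[i] & bins$end > ev_start[i]
    if (any(touched & hit)) {
      stop("genotype '", genotype, "': overlapping events on ",
           events$chrom[i], call. = FALSE)
    }
    touched <- touched | hit
    copy[hit] <- events$copy_number[i]
  }
  copy
}

# Truth intervals (bp) for one genotype's events.
events_to_intervals <- function(events, genome, width) {
  if (nrow(events) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), scope = character(),
                          copy_number = integer()))
  }
  m <- match(events$chrom, genome$chrom)
  bnd <- arm_boundary(genome, width)[m]
  len <- genome$length[m]
  tibble::tibble(
    chrom = events$chrom,
    start = dplyr::case_when(events$scope %in% c("whole_chromosome", "arm:S") ~ 0,
                             events$scope == "arm:L" ~ bnd,
                             TRUE ~ events$start),
    end = dplyr::case_when(events$scope == "arm:S" ~ bnd,
                           events$scope %in% c("whole_chromosome", "arm:L") ~ len,
                           TRUE ~ events$end),
    scope = events$scope,
    copy_number = events$copy_number
  )
}

#' Simulate a GBS cohort with planted dosage events
#'
#' Draws, for bin *b* of sample *s*, a count with mean
#' `libsize_s * density_b * binlen_b / width * max(copy_b / 2, floor)` from a
#' negative binomial (Poisson when `dispersion = 0`). The density
#' multipliers are drawn once per cohort (log-normal, normalized so the
#' euploid expected total equals the library size) and shared across
#' samples; per-genotype RNG substreams are keyed by genotype name, so the
#' same genotype gets the same counts regardless of cohort composition.
#'
#' @param config A [sim_config()].
#' @return A list of class `gbs_simulation` with elements `counts`
#'   (`gbs_counts` tibble), `samplesheet` (event-free genotypes are
#'   controls), and `truth` (list with `events`, `arms`, `expected_2n`
#'   tibbles; `expected_2n` is the chromosome-body count
#'   `sum(pmax(cn_S, cn_L))`).
#' @export
#' @examples
#' cfg <- sim_config(genotypes = list(ctrl = NULL,
#'                                    null6A = dosage_event("6A", "whole_chromosome", 0)),
#'                   seed = 7)
#' sim <- simulate_cohort(cfg)
#' head(sim$counts)
#' sim$truth$expected_2n
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "gbs_sim_config"))
  genome <- config$genome
  bins <- make_bins(genome, config$bin_width)
  width <- config$bin_width
  lenfrac <- (bins$end - bins$start) / width

  # Shared per-bin density: depends only on (seed, grid), not on genotypes.
  mult <- with_seed(substream_seed(config$seed, "..density.."),
                    stats::rlnorm(nrow(bins), 0, config$density_sigma))
  density <- mult / sum(mult * lenfrac)

  sim_one <- function(name, events) {
    copy <- events_to_bin_copy(events, genome, bins, name)
    with_seed(substream_seed(config$seed, name), {
      lib <- stats::rlnorm(1, log(config$lib_size_mean), config$lib_size_sigma)
      mu <- lib * density * lenfrac *
        pmax(copy / 2, config$cross_mapping_floor)
      if (config$dispersion > 0) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
      } else {
        stats::rpois(length(mu), mu)
      }
    })
  }

  rows <- purrr::imap(config$genotypes, function(events, name) {
    tibble::tibble(sample = name, chrom = bins$chrom, start = bins$start,
                   end = bins$end, count = sim_one(name, events))
  })
  counts <- as_gbs_counts(dplyr::bind_rows(rows), bins)

  samplesheet <- tibble::tibble(
    sample = names(config$genotypes),
    role = ifelse(purrr::map_int(config$genotypes, nrow) == 0,
                  "control", "test"),
    pedigree = NA_character_
  )

  truth_events <- purrr::imap_dfr(config$genotypes, function(ev, name) {
    dplyr::mutate(events_to_intervals(ev, genome, width),
                  genotype = name, .before = 1)
  })
  arms <- purrr::imap_dfr(config$genotypes, function(ev, name) {
    copy <- events_to_bin_copy(ev, genome, bins, name)
    true_arms_from_bins(copy, bins, genome) |>
      dplyr::mutate(genotype = name, .before = 1)
  })
  expected_2n <- arms |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(expected_2n = sum(pmax(.data$cn_S, .data$cn_L)),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$genotype, names(config$genotypes)))

  structure(list(counts = counts, samplesheet = samplesheet,
                 truth = list(events = truth_events, arms = arms,
                              expected_2n = expected_2n),
                 config = config),
            class = "gbs_simulation")
}

# Length-weighted modal copy number per arm from per-bin truth.
true_arms_from_bins <- function(copy, bins, genome) {
  width <- bin_width(bins)
  bnd <- arm_boundary(genome, width)
  bnd_of <- bnd[match(bins$chrom, genome$chrom)]
  arm <- ifelse(bins$start < bnd_of, "S", "L")
  df <- tibble::tibble(chrom = bins$chrom, arm = arm,
                       len = bins$end - bins$start, cn = copy)
  df |>
    dplyr::group_by(.data$chrom, .data$arm, .data$cn) |>
    dplyr::summarise(len = sum(.data$len), .groups = "drop_last") |>
    dplyr::slice_max(.data$len, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", "arm", "cn") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "cn",
                       names_prefix = "cn_") |>
    dplyr::select("chrom", "cn_S", "cn_L") |>
    dplyr::arrange(match(.data$chrom, genome$chrom))
}

#' Write / read a simulation truth set
#'
#' The truth set is written as two plain-text files under `dir`: a BED-like
#' events file (`truth_events.bed`: chrom, start, end, genotype, copy
#' number, scope) and a per-genotype summary TSV (`truth_summary.tsv`: arm
#' copy numbers and expected 2n). Reading the pair back reproduces the
#' truth tables exactly.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param dir Output directory.
#' @return `write_truth()` returns `dir` invisibly; `read_truth()` returns
#'   a truth list (`events`, `arms`, `expected_2n`).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- tibble::tibble(chrom = truth$events$chrom, start = truth$events$start,
                       end = truth$events$end, genotype = truth$events$genotype,
                       copy_number = truth$events$copy_number,
                       scope = truth$events$scope)
  readr::write_tsv(ev, file.path(dir, "truth_events.bed"))
  summary <- dplyr::left_join(truth$arms, truth$expected_2n, by = "genotype")
  readr::write_tsv(summary, file.path(dir, "truth_summary.tsv"))
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  ev <- readr::read_tsv(file.path(dir, "truth_events.bed"),
                        show_col_types = FALSE, col_types = "cddcic")
  summary <- strip_readr_attrs(
    readr::read_tsv(file.path(dir, "truth_summary.tsv"),
                    show_col_types = FALSE))
  events <- tibble::tibble(genotype = ev$genotype, chrom = ev$chrom,
                           start = ev$start, end = ev$end, scope = ev$scope,
                           copy_number = as.integer(ev$copy_number))
  arms <- dplyr::select(summary, "genotype", "chrom", "cn_S", "cn_L") |>
    dplyr::mutate(cn_S = as.integer(.data$cn_S), cn_L = as.integer(.data$cn_L))
  expected_2n <- dplyr::distinct(summary, .data$genotype, .data$expected_2n)
  list(events = events, arms = arms, expected_2n = expected_2n)
}

#' Default demonstration cohort configuration
#'
#' Thirty genotypes on the default amphidiploid genome: six event-free
#' controls and twenty-four genotypes each carrying one planted event drawn
#' deterministically from the seed — whole-chromosome losses and gains
#' (copy 0, 1, 3, 4), arm losses (telosomics), and segmental deletions of
#' at least 5 bins. This is the cohort used for parameter-recovery checks.
#'
#' @param seed Integer seed.
#' @param n_genotypes Total genotypes (default 30).
#' @param n_controls Event-free control genotypes among them (default 6).
#' @param genome Genome model.
#' @param ... Passed to [sim_config()] (e.g. `dispersion`).
#' @return A `gbs_sim_config`.
#' @export
demo_cohort_config <- function(seed = 1, n_genotypes = 30, n_controls = 6,
                               genome = default_genome(), ...) {
  stopifnot(n_controls >= 1, n_genotypes > n_controls)
  width <- 1e6
  n_events <- n_genotypes - n_controls
  kinds <- rep(c("whole", "arm", "segment"), length.out = n_events)
  genotypes <- with_seed(substream_seed(seed, "..demo.."),
                         purrr::map(seq_len(n_events), function(i) {
    chrom <- sample(genome$chrom, 1)
    g <- genome[genome$chrom == chrom, ]
    if (kinds[i] == "whole") {
      dosage_event(chrom, "whole_chromosome", sample(c(0L, 1L, 3L, 4L), 1))
    } else if (kinds[i] == "arm") {
      dosage_event(chrom, sample(c("arm:S", "arm:L"), 1), sample(0:1, 1))
    } else {
      # segmental deletion, >= 5 bins, bin-aligned, away from both ends
      nb <- floor(g$length / width)
      len_bins <- sample(5:min(10, nb - 2), 1)
      s <- sample(seq_len(nb - len_bins - 1), 1) * width
      dosage_event(chrom, "segment", sample(0:1, 1), s, s + len_bins * width)
    }
  }))
  names(genotypes) <- sprintf("G%02d", seq_len(n_events))
  controls <- stats::setNames(vector("list", n_controls),
                              sprintf("CTRL%02d", seq_len(n_controls)))
  sim_config(genome = genome, bin_width = width,
             genotypes = c(controls, genotypes), seed = seed, ...)
}

#' Read / write a simulation config as YAML
#'
#' @param config A `gbs_sim_config`.
#' @param path YAML file path.
#' @return `read_sim_config()` returns a `gbs_sim_config`.
#' @export
write_sim_config <- function(config, path) {
  lst <- list(
    bin_width = config$bin_width, density_sigma = config$density_sigma,
    lib_size_mean = config$lib_size_mean,
    lib_size_sigma = config$lib_size_sigma,
    dispersion = config$dispersion,
    cross_mapping_floor = config$cross_mapping_floor, seed = config$seed,
    genome = purrr::pmap(config$genome, list),
    genotypes = purrr::map(config$genotypes, function(ev) {
      purrr::pmap(ev, function(chrom, scope, copy_number, start, end) {
        x <- list(chrom = chrom, scope = scope, copy_number = copy_number)
        if (!is.na(start)) { x$start <- start; x$end <- end }
        x
      })
    })
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  g <- dplyr::bind_rows(purrr::map(lst$genome, tibble::as_tibble))
  genome <- genome_model(g$chrom, g$subgenome, g$length, g$centromere)
  genotypes <- purrr::map(lst$genotypes, function(evs) {
    if (length(evs) == 0) return(NULL)
    dplyr::bind_rows(purrr::map(evs, function(e) {
      dosage_event(e$chrom, e$scope, e$copy_number,
                   e$start %||% NA, e$end %||% NA)
    }))
  })
  sim_config(genome = genome, bin_width = lst$bin_width,
             genotypes = genotypes, density_sigma = lst$density_sigma,
             lib_size_mean = lst$lib_size_mean,
             lib_size_sigma = lst$lib_size_sigma,
             dispersion = lst$dispersion,
             cross_mapping_floor = lst$cross_mapping_floor, seed = lst$seed)
}
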