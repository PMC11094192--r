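#' Construct a genome model
#'
#' A genome model describes the combined multi-subgenome genome on which all
#' coordinates live: one row per chromosome with its subgenome label, length
#' and centromere position. For a wheat x rye amphidiploid this is the 21
#' wheat chromosomes (A, B, D subgenomes) plus the 7 rye chromosomes (R).
#'
#' @param chrom Character vector of unique chromosome names (e.g. `"1A"`,
#'   `"6R"`).
#' @param subgenome Character vector of subgenome labels, one of
#'   `"A"`, `"B"`, `"D"`, `"R"`.
#' @param length Integer vector of chromosome lengths in bp (> 0).
#' @param centromere Integer vector of centromere offsets in bp, strictly
#'   inside `(0, length)`.
#'
#' @return A tibble of class `gbs_genome` with columns `chrom`, `subgenome`,
#'   `length`, `centromere`, in the order given.
#' @export
#' @examples
#' genome_model("1A", "A", 5e6, 2e6)
genome_model <- function(chrom, subgenome, length, centromere) {
  g <- tibble::tibble(
    chrom = as.character(chrom),
    subgenome = as.character(subgenome),
    length = as.numeric(length),
    centromere = as.numeric(centromere)
  )
  validate_genome(g)
}

validate_genome <- function(g) {
  required <- c("chrom", "subgenome", "length", "centromere")
  missing <- setdiff(required, names(g))
  if (length(missing) > 0) {
    stop("genome model is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- g$chrom[duplicated(g$chrom)]
  if (length(dup) > 0) {
    stop("duplicate chromosome name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_sub <- setdiff(unique(g$subgenome), c("A", "B", "D", "R"))
  if (length(bad_sub) > 0) {
    stop("unknown subgenome label(s): ", paste(bad_sub, collapse = ", "),
         " (expected A, B, D or R)", call. = FALSE)
  }
  bad_len <- g$chrom[!is.finite(g$length) | g$length <= 0]
  if (length(bad_len) > 0) {
    stop("non-positive length for chromosome(s): ",
         paste(bad_len, collapse = ", "), call. = FALSE)
  }
  bad_cen <- g$chrom[!is.finite(g$centromere) |
                       g$centromere <= 0 | g$centromere >= g$length]
  if (length(bad_cen) > 0) {
    stop("centromere outside (0, length) for chromosome(s): ",
         paste(bad_cen, collapse = ", "), call. = FALSE)
  }
  class(g) <- unique(c("gbs_genome", class(tibble::tibble())))
  g
}

#' Default synthetic amphidiploid genome
#'
#' A deterministic 28-chromosome genome model: 21 wheat chromosomes
#' (1A-7A, 1B-7B, 1D-7D) and 7 rye chromosomes (1R-7R). Lengths cycle over
#' 20-60 Mb and centromeres sit at 35-45% of each chromosome, so the whole
#' pipeline runs in seconds; assembly-scale models are read with
#' [read_genome()]. These are deliberately not real assembly sizes.
#'
#' @param subgenomes Subgenomes to keep (default all four). Restricting to
#'   `c("A","B","D")` gives a hexaploid wheat parent model; `"R"` gives the
#'   diploid rye parent.
#' @return A `gbs_genome` tibble.
#' @export
#' @examples
#' default_genome()
#' default_genome(subgenomes = "R")   # rye parent, 7 chromosomes
default_genome <- function(subgenomes = c("A", "B", "D", "R")) {
  sub <- rep(c("A", "B", "D", "R"), each = 7)
  num <- rep(1:7, times = 4)
  idx <- seq_along(sub)
  len <- (20 + ((idx * 5 + num * 3) %% 41)) * 1e6
  cen <- round(len * (0.35 + 0.02 * (idx %% 6)))
  g <- genome_model(paste0(num, sub), sub, len, cen)
  g <- g[g$subgenome %in% subgenomes, ]
  validate_genome(g)
}

#' Tile a genome into non-overlapping bins
#'
#' Bins are 0-based half-open `[start, end)` intervals of fixed width that
#' tile each chromosome without gaps or overlaps; the last bin of a
#' chromosome is truncated to the chromosome length. Counting is done on
#' this grid (typically 1 Mb); plotting typically re-bins to 5 Mb with
#' [rebin()].
#'
#' @param genome A `gbs_genome` model.
#' @param width Bin width in bp (> 0). Default 1 Mb.
#' @return A tibble of class `gbs_bins` with columns `chrom`, `start`, `end`
#'   in chromosome order, and attributes `width` and `genome`.
#' @export
#' @examples
#' make_bins(genome_model("1A", "A", 5.5e6, 2e6), width = 1e6)
make_bins <- function(genome, width = 1e6) {
  genome <- validate_genome(genome)
  if (!is.numeric(width) || length(width) != 1 || !is.finite(width) ||
      width <= 0) {
    stop("`width` must be a single positive number of bp", call. = FALSE)
  }
  bins <- purrr::pmap_dfr(
    list(genome$chrom, genome$length),
    function(chrom, len) {
      start <- seq(0, len - 1, by = width)
      tibble::tibble(chrom = chrom, start = start,
                     end = pmin(start + width, len))
    }
  )
  structure(bins, width = width, genome = genome,
            class = unique(c("gbs_bins", class(bins))))
}

bin_width <- function(bins) {
  w <- attr(bins, "width")
  if (is.null(w)) w <- stats::median(bins$end - bins$start)
  w
}

# End (bp) of the bin containing the centromere: the arm boundary used for
# all arm aggregation (the centromere bin belongs to the short arm).
arm_boundary <- function(genome, width) {
  pmin((floor(genome$centromere / width) + 1) * width, genome$length)
}

#' Read / write a genome model TSV
#'
#' The file is a TSV with header columns `chrom`, `subgenome`, `length`,
#' `centromere`. `read_genome()` validates every invariant (unique names,
#' positive lengths, centromere strictly inside the chromosome) and names the
#' offending row on failure. Writing then reading gives back an identical
#' model.
#'
#' @param path File path.
#' @return `read_genome()` returns a `gbs_genome` tibble; `write_genome()`
#'   returns `path` invisibly.
#' @export
read_genome <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         subgenome = readr::col_character(),
                         length = readr::col_double(),
                         centromere = readr::col_double()
                       ))
  validate_genome(strip_readr_attrs(g))
}

#' @rdname read_genome
#' @param genome A `gbs_genome` model.
#' @export
write_genome <- function(genome, path) {
  genome <- validate_genome(genome)
  readr::write_tsv(genome, path)
  invisible(path)
}

#' Read per-sample bin-count files into a count table
#'
#' Each per-sample file is a BED-like TSV (`chrom`, `start`, `end`, `count`,
#' no header) whose intervals must match the bin grid exactly; a missing or
#' mismatched bin is an error, never a silent zero. Counts from all samples
#' are assembled into one long tibble in grid order, preserving the sample
#' order given.
#'
#' @param paths Named character vector of file paths; names are sample
#'   identifiers (unnamed paths use the file base name).
#' @param bins A `gbs_bins` grid from [make_bins()].
#' @return A tibble of class `gbs_counts` with columns `sample`, `chrom`,
#'   `start`, `end`, `count`, ordered by sample then grid.
#' @export
read_counts <- function(paths, bins) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    nm <- names(paths)
    if (is.null(nm)) nm <- rep("", length(paths))
    nm[nm == ""] <- sub("\\.[^.]*$", "", basename(paths[nm == ""]))
    names(paths) <- nm
  }
  per_sample <- purrr::imap(paths, function(p, sample) {
    x <- readr::read_tsv(p, col_names = c("chrom", "start", "end", "count"),
                         show_col_types = FALSE,
                         col_types = "cddd")
    if (any(!is.finite(x$count) | x$count < 0 | x$count != floor(x$count))) {
      stop("sample '", sample, "': counts must be non-negative integers",
           call. = FALSE)
    }
    key_grid <- paste(bins$chrom, bins$start, bins$end)
    key_file <- paste(x$chrom, x$start, x$end)
    if (length(key_file) != length(key_grid) || !setequal(key_file, key_grid) ||
        anyDuplicated(key_file) > 0) {
      off <- c(setdiff(key_file, key_grid), setdiff(key_grid, key_file))
      stop("sample '", sample, "': bin intervals do not match the grid ",
           "(first mismatch: ", off[1], ")", call. = FALSE)
    }
    tibble::tibble(sample = sample, chrom = bins$chrom, start = bins$start,
                   end = bins$end,
                   count = x$count[match(key_grid, key_file)])
  })
  counts <- dplyr::bind_rows(per_sample)
  as_gbs_counts(counts, bins)
}

as_gbs_counts <- function(counts, bins) {
  structure(counts, bins = bins,
            samples = unique(counts$sample),
            class = unique(c("gbs_counts", class(tibble::tibble()))))
}

#' Write a count table
#'
#' Writes one BED4-like TSV per sample (`<sample>.counts.tsv` under `dir`),
#' the format [read_counts()] reads back bit-identically.
#'
#' @param counts A `gbs_counts` tibble.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- unique(counts$sample)
  paths <- vapply(samples, function(s) {
    p <- file.path(dir, paste0(s, ".counts.tsv"))
    readr::write_tsv(
      dplyr::select(dplyr::filter(counts, .data$sample == s),
                    "chrom", "start", "end", "count"),
      p, col_names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read / write a sample sheet
#'
#' A sample sheet assigns each sample a role: `control` (assumed euploid,
#' used to build the per-bin reference coverage) or `test`. TSV columns:
#' `sample`, `role`, optional `pedigree`.
#'
#' @param path File path.
#' @return A tibble with columns `sample`, `role`, `pedigree`.
#' @export
read_samplesheet <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  validate_samplesheet(strip_readr_attrs(s))
}

validate_samplesheet <- function(s) {
  if (!all(c("sample", "role") %in% names(s))) {
    stop("sample sheet needs columns `sample` and `role`", call. = FALSE)
  }
  bad <- setdiff(unique(s$role), c("control", "test"))
  if (length(bad) > 0) {
    stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!any(s$role == "control")) {
    stop("sample sheet designates no control sample", call. = FALSE)
  }
  if (!("pedigree" %in% names(s))) s$pedigree <- NA_character_
  tibble::as_tibble(s)
}

#' @rdname read_samplesheet
#' @param samplesheet Sample sheet tibble.
#' @export
write_samplesheet <- function(samplesheet, path) {
  readr::write_tsv(validate_samplesheet(samplesheet), path)
  invisible(path)
}

#' Named loci: construction and I/O
#'
#' Loci are named genomic intervals whose copy number the caller reports —
#' here typically the incompatibility alleles *Eml-A1* (terminal 6AL) and
#' *Eml-R1b* (interstitial 6RL). Files are BED6-like TSVs without header:
#' `chrom`, `start`, `end`, `name`, `score` (written as `.`), `arm`
#' (`S` or `L`).
#'
#' @param chrom,start,end,name,arm Locus fields; the interval must lie
#'   within the chromosome and on the stated side of the centromere.
#' @param genome A `gbs_genome` used for validation.
#' @return A tibble with columns `name`, `chrom`, `start`, `end`, `arm`.
#' @export
loci_table <- function(name, chrom, start, end, arm, genome = NULL) {
  l <- tibble::tibble(name = as.character(name), chrom = as.character(chrom),
                      start = as.numeric(start), end = as.numeric(end),
                      arm = as.character(arm))
  if (!is.null(genome)) {
    genome <- validate_genome(genome)
    m <- match(l$chrom, genome$chrom)
    if (anyNA(m)) {
      stop("locus chromosome(s) absent from genome: ",
           paste(unique(l$chrom[is.na(m)]), collapse = ", "), call. = FALSE)
    }
    if (any(l$start < 0 | l$end > genome$length[m] | l$start >= l$end)) {
      stop("locus interval outside chromosome bounds", call. = FALSE)
    }
    cen <- genome$centromere[m]
    side <- ifelse(l$end <= cen, "S", ifelse(l$start >= cen, "L", NA))
    bad <- !is.na(side) & side != l$arm
    if (any(bad)) {
      stop("locus arm label inconsistent with centromere side: ",
           paste(l$name[bad], collapse = ", "), call. = FALSE)
    }
  }
  l
}

#' @rdname loci_table
#' @param path File path.
#' @export
read_loci <- function(path, genome = NULL) {
  x <- readr::read_tsv(path,
                       col_names = c("chrom", "start", "end", "name", "score", "arm"),
                       show_col_types = FALSE, col_types = "cddccc")
  loci_table(x$name, x$chrom, x$start, x$end, x$arm, genome)
}

#' @rdname loci_table
#' @param loci Loci tibble.
#' @export
write_loci <- function(loci, path) {
  out <- tibble::tibble(chrom = loci$chrom, start = loci$start, end = loci$end,
                        name = loci$name, score = ".", arm = loci$arm)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Default Eml incompatibility loci for a genome model
#'
#' Places *Eml-A1* in the terminal region of the long arm of chromosome 6A
#' and *Eml-R1b* in an interstitial region of the long arm of 6R (both as in
#' the wheat-rye embryo-lethality system). Coordinates are expressed as
#' fractions of the arm so they adapt to any genome model carrying 6A/6R.
#'
#' @param genome A `gbs_genome` model.
#' @return Loci tibble (possibly with fewer rows if 6A or 6R is absent).
#' @export
default_loci <- function(genome) {
  genome <- validate_genome(genome)
  out <- list()
  if ("6A" %in% genome$chrom) {
    g <- genome[genome$chrom == "6A", ]
    out$a <- loci_table("Eml-A1", "6A",
                        round(g$length - 0.05 * (g$length - g$centromere)) ,
                        g$length, "L", genome)
  }
  if ("6R" %in% genome$chrom) {
    g <- genome[genome$chrom == "6R", ]
    mid <- g$centromere + 0.5 * (g$length - g$centromere)
    out$r <- loci_table("Eml-R1b", "6R", round(mid - 1e6), round(mid + 1e6),
                        "L", genome)
  }
  dplyr::bind_rows(out)
}

#' Count uniquely mapped alignment records into bins
#'
#' Optional adapter from alignment records (SAM convention) to per-bin
#' counts. "Uniquely mapped" is operationalized as mapping quality >=
#' `mapq_min` with secondary and supplementary records excluded. Each
#' passing record increments exactly one bin, chosen by its leftmost aligned
#' position; records on chromosomes absent from the grid go to an
#' `unplaced` tally rather than failing.
#'
#' @param alignments Either a path to a SAM file (read via Rsamtools) or a
#'   data frame with columns `rname`, `pos` (1-based leftmost position),
#'   `flag`, `mapq`.
#' @param bins A `gbs_bins` grid.
#' @param mapq_min Minimum mapping quality (default 20).
#' @return A list with `counts` (tibble `chrom`, `start`, `end`, `count`)
#'   and `unplaced` (number of passing records on unknown chromosomes).
#' @export
count_from_alignments <- function(alignments, bins, mapq_min = 20) {
  if (is.character(alignments) && length(alignments) == 1) {
    alignments <- read_sam_records(alignments)
  }
  stopifnot(all(c("rname", "pos", "flag", "mapq") %in% names(alignments)))
  flag <- as.integer(alignments$flag)
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L
  supplementary <- bitwAnd(flag, 2048L) != 0L
  pass <- !unmapped & !secondary & !supplementary &
    !is.na(alignments$mapq) & alignments$mapq >= mapq_min
  rec <- alignments[pass, , drop = FALSE]
  known <- rec$rname %in% unique(bins$chrom)
  unplaced <- sum(!known)
  rec <- rec[known, , drop = FALSE]
  width <- bin_width(bins)
  # 1-based SAM pos -> 0-based coordinate -> bin index within chromosome
  key <- paste(rec$rname, floor((rec$pos - 1) / width))
  bin_key <- paste(bins$chrom, floor(bins$start / width))
  tab <- table(factor(key, levels = bin_key))
  counts <- tibble::tibble(chrom = bins$chrom, start = bins$start,
                           end = bins$end, count = as.integer(tab))
  list(counts = counts, unplaced = unplaced)
}

read_sam_records <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading SAM files requires the Rsamtools package", call. = FALSE)
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(what = c("rname", "pos", "flag", "mapq"))
  )[[1]]
  tibble::tibble(rname = as.character(res$rname), pos = res$pos,
                 flag = res$flag, mapq = res$mapq)
}
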