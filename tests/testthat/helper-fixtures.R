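# Small fixtures built in code, shared across test files.

# Four-chromosome mini genome: quick to simulate, still has two subgenomes.
mini_genome <- function() {
  genome_model(chrom = c("1A", "2A", "1B", "1R"),
               subgenome = c("A", "A", "B", "R"),
               length = c(12e6, 10e6, 8e6, 9e6),
               centromere = c(5e6, 4e6, 3.5e6, 4.5e6))
}

# Exhaustive-search oracle for penalized least-squares segmentation:
# enumerates every breakpoint subset of a series (n <= ~14), drops those
# violating the minimum segment length, scores cost = SSE + penalty * (k-1),
# and applies the same tie-breaks as the implementation under test
# (fewer segments, then leftmost breakpoints). Independent of the DP.
oracle_segment <- function(x, penalty, min_seg_bins) {
  n <- length(x)
  if (n < 2 * min_seg_bins) return(integer(0))
  seg_cost <- function(v) sum((v - mean(v))^2)
  best <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    bp <- which(bitwAnd(mask, 2^(0:(n - 2))) != 0)
    bounds <- c(0, bp, n)
    lens <- diff(bounds)
    if (any(lens < min_seg_bins)) next
    cost <- penalty * length(bp) +
      sum(vapply(seq_along(lens), function(k) {
        seg_cost(x[(bounds[k] + 1):bounds[k + 1]])
      }, numeric(1)))
    cand <- list(cost = cost, bp = bp)
    if (is.null(best)) { best <- cand; next }
    tol <- 1e-9 * max(1, abs(cost), abs(best$cost))
    if (cost < best$cost - tol) {
      best <- cand
    } else if (abs(cost - best$cost) <= tol) {
      if (length(bp) < length(best$bp)) {
        best <- cand
      } else if (length(bp) == length(best$bp) &&
                 lexico_less(bp, best$bp)) {
        best <- cand
      }
    }
  }
  as.integer(best$bp)
}

lexico_less <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0) {
    d <- which(a[seq_len(k)] != b[seq_len(k)])
    if (length(d) > 0) return(a[d[1]] < b[d[1]])
  }
  length(a) < length(b)
}

# A small cohort on the mini genome with one planted event per kind.
mini_cohort <- function(seed = 11, dispersion = 0.05, ...) {
  sim_config(
    genome = mini_genome(), bin_width = 1e6,
    genotypes = list(
      ctrlA = NULL, ctrlB = NULL, ctrlC = NULL,
      mono1A = dosage_event("1A", "whole_chromosome", 1),
      dt1B = dosage_event("1B", "arm:L", 0)),
    dispersion = dispersion, seed = seed, ...)
}
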