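#' Build a Rank Occupancy-Abundance Profile (ROAP)
#'
#' Sorts per-cell abundances in descending order and assigns relative rank
#' `k / n_cells` to the k-th largest value, so the X axis runs over (0, 1]
#' and the Y axis is absolute abundance. `n_cells` is the rank denominator
#' (the number of ever-occupied cells in the study grid) and may exceed the
#' number of abundances supplied. Ties keep their input order (the area
#' under the profile is unaffected by tie order).
#'
#' @param abundances non-negative per-cell counts (at least one).
#' @param n_cells rank denominator, `>= length(abundances)`.
#' @return Object of class `roap`: list with `points` (data.frame
#'   `relative_rank`, `abundance`) and `n_cells`.
#' @export
build_roap <- function(abundances, n_cells = length(abundances)) {
  if (length(abundances) == 0L) stop("empty abundance vector")
  if (anyNA(abundances) || any(abundances < 0))
    stop("abundances must be non-negative")
  if (n_cells < length(abundances))
    stop("n_cells must be >= length(abundances)")
  a <- abundances[order(-abundances)]   # radix order: stable in ties
  structure(list(points = data.frame(
    relative_rank = seq_along(a) / n_cells,
    abundance = as.numeric(a)), n_cells = n_cells), class = "roap")
}

#' @export
print.roap <- function(x, ...) {
  cat("ROAP:", nrow(x$points), "ranked cells of", x$n_cells,
      "; max abundance", max(x$points$abundance),
      "; area", signif(roap_auc(x), 4), "\n")
  invisible(x)
}

#' Area under a ROAP
#'
#' Trapezoidal area under the (relative rank, abundance) polyline, from the
#' first to the last ranked point. A single-point profile uses the
#' rectangle convention `abundance * relative_rank`.
#'
#' @param p a [build_roap()] profile.
#' @return non-negative scalar.
#' @export
roap_auc <- function(p) {
  stopifnot(inherits(p, "roap"))
  r <- p$points$relative_rank
  a <- p$points$abundance
  if (length(r) == 1L) return(a * r)
  sum(diff(r) * (a[-length(a)] + a[-1L]) / 2)
}

#' D* statistic comparing two ROAPs
#'
#' The ratio of the smaller to the larger area under the two profiles:
#' 1 means identical areas (indistinguishable occupancy-abundance
#' distributions), values near 0 mean strong divergence. Symmetric in its
#' arguments and bounded in (0, 1]. Both profiles must share the rank
#' denominator `n_cells`.
#'
#' @param a,b [build_roap()] profiles on the same `n_cells`.
#' @return scalar in (0, 1].
#' @export
dstar <- function(a, b) {
  stopifnot(inherits(a, "roap"), inherits(b, "roap"))
  if (a$n_cells != b$n_cells)
    stop("profiles must be built on the same n_cells")
  aa <- roap_auc(a); ab <- roap_auc(b)
  if (aa == 0 && ab == 0)
    stop("both profiles have zero area; D* is undefined")
  min(aa, ab) / max(aa, ab)
}

#' Permutation test of temporal stability between two census years
#'
#' Computes the observed D* between the ROAPs of two census years, then
#' builds a null distribution by relabelling years and recomputing D*.
#' Two relabelling schemes are available: `"per_cell"` (default) randomly
#' reassigns, independently within each cell, that cell's observed counts
#' to the year labels, preserving each cell's multiset of counts;
#' `"pooled"` pools all counts of both years across cells and splits them
#' at random into two pseudo-years. The one-sided lower-tail p-value
#' `(1 + #\{D*_null <= D*_obs\}) / (1 + n_iter)` treats small D* as
#' evidence of divergence; `stable = (p >= alpha)`.
#'
#' @param x a [census_table()] (typically after [filter_ever_present()]).
#' @param year_a,year_b two census years present in `x`.
#' @param n_iter number of relabelling iterations (default 999; values
#'   below 19 cannot resolve alpha = 0.05 and trigger a warning).
#' @param alpha significance level for the `stable` flag (default 0.05).
#' @param seed optional integer seed.
#' @param scheme `"per_cell"` or `"pooled"` relabelling (see above).
#' @return Object of class `dstar_test`: list with `d_star_observed`,
#'   `null_distribution`, `p_value`, `stable`, `n_iterations`, `alpha`,
#'   `years`, `scheme`, `seed`.
#' @export
dstar_permutation_test <- function(x, year_a, year_b, n_iter = 999,
                                   alpha = 0.05, seed = NULL,
                                   scheme = c("per_cell", "pooled")) {
  stopifnot(inherits(x, "census_table"))
  scheme <- match.arg(scheme)
  for (y in c(year_a, year_b))
    if (!y %in% x$years) stop("year ", y, " not present in census")
  if (n_iter < 19L)
    warning("n_iter < 19: alpha = 0.05 is unreachable at this granularity")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x$counts)
  ca <- as.numeric(x$counts[, as.character(year_a)])
  cb <- as.numeric(x$counts[, as.character(year_b)])
  obs <- dstar(build_roap(ca, n), build_roap(cb, n))
  null <- numeric(n_iter)
  pooled <- c(ca, cb)
  for (i in seq_len(n_iter)) {
    if (scheme == "per_cell") {
      swap <- stats::runif(n) < 0.5
      pa <- ifelse(swap, cb, ca)
      pb <- ifelse(swap, ca, cb)
    } else {
      idx <- sample.int(2L * n, n)
      pa <- pooled[idx]
      pb <- pooled[-idx]
    }
    null[i] <- dstar(build_roap(pa, n), build_roap(pb, n))
  }
  p <- (1 + sum(null <= obs)) / (1 + n_iter)
  structure(list(d_star_observed = obs, null_distribution = null,
                 p_value = p, stable = p >= alpha, n_iterations = n_iter,
                 alpha = alpha, years = c(year_a, year_b), scheme = scheme,
                 seed = seed),
            class = "dstar_test")
}

#' @export
print.dstar_test <- function(x, ...) {
  cat(sprintf("D* temporal-stability test (%d vs %d, %s relabelling)\n",
              x$years[1L], x$years[2L], x$scheme))
  cat(sprintf("  D* = %.3f, p = %.3f (%d iterations): %s\n",
              x$d_star_observed, x$p_value, x$n_iterations,
              if (x$stable) "no evidence of change (stable)"
              else "distributions differ"))
  invisible(x)
}
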