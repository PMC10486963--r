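#' Distance-based spatial weights between grid-cell centroids
#'
#' Builds a symmetric weight matrix from the pairwise centroid distances.
#' `style = "binary"` sets `w_ij = 1` for `0 < d_ij <= band_km`;
#' `style = "inverse"` sets `w_ij = 1 / d_ij` within the same band.
#' Optional row standardisation divides each row by its sum (islands keep
#' zero rows); note that the LISA additivity identity
#' `sum(I_i) = S0 * I` is stated for unstandardised weights.
#' Cells with no neighbour inside the band are flagged as islands; if every
#' cell is an island the weights are unusable and an error is raised.
#'
#' @param cells data.frame with `cell_id`, `x_km`, `y_km`.
#' @param style `"binary"` (default) or `"inverse"` distance weighting.
#' @param band_km neighbourhood distance threshold in km (default 20, two
#'   lattice steps on a 10-km grid).
#' @param row_standardize divide rows by their sums (default `FALSE`).
#' @return Object of class `spatial_weights`: list with `W` (dense matrix),
#'   `n`, `S0`, `style`, `band_km`, `row_standardized`, `islands` (logical),
#'   `cell_id`.
#' @export
build_weights <- function(cells, style = c("binary", "inverse"),
                          band_km = 20, row_standardize = FALSE) {
  style <- match.arg(style)
  stopifnot(is.data.frame(cells), nrow(cells) >= 2L,
            all(c("cell_id", "x_km", "y_km") %in% names(cells)),
            band_km > 0)
  d <- as.matrix(stats::dist(cells[, c("x_km", "y_km")]))
  if (any(d[upper.tri(d)] == 0)) stop("duplicate cell centroids")
  W <- matrix(0, nrow(d), ncol(d))
  in_band <- d > 0 & d <= band_km
  W[in_band] <- if (style == "binary") 1 else 1 / d[in_band]
  islands <- rowSums(W) == 0
  if (all(islands))
    stop("all cells are islands at band_km = ", band_km,
         "; increase the band")
  if (row_standardize) {
    rs <- rowSums(W)
    W[!islands, ] <- W[!islands, , drop = FALSE] / rs[!islands]
  }
  structure(list(W = W, n = nrow(W), S0 = sum(W), style = style,
                 band_km = band_km, row_standardized = row_standardize,
                 islands = islands,
                 cell_id = as.character(cells$cell_id)),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("Spatial weights: %d cells, %s style, band %g km, S0 = %g",
              x$n, x$style, x$band_km, x$S0),
      if (x$row_standardized) "(row-standardized)" else "", "\n")
  if (any(x$islands)) cat("  islands:", sum(x$islands), "cells\n")
  invisible(x)
}

moran_statistic <- function(z, W, S0) {
  n <- length(z)
  (n / S0) * drop(crossprod(z, W %*% z)) / sum(z^2)
}

#' Global Moran's I
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z_i = x_i - mean(x)`. Values near +1 indicate spatial aggregation,
#' values near -1 regular spacing; the null expectation under random
#' permutation is `-1 / (n - 1)`. A constant field has no defined I.
#'
#' @param x numeric per-cell values, in the cell order of `w`.
#' @param w a [build_weights()] object.
#' @return Object of class `moran`: list with `I`, `expected_I`, `n`, `S0`.
#' @export
global_moran <- function(x, w) {
  stopifnot(inherits(w, "spatial_weights"), length(x) == w$n)
  if (anyNA(x)) stop("missing values in x")
  z <- x - mean(x)
  if (sum(z^2) == 0) stop("constant field: Moran's I is undefined")
  structure(list(I = moran_statistic(z, w$W, w$S0),
                 expected_I = -1 / (w$n - 1), n = w$n, S0 = w$S0),
            class = "moran")
}

#' @export
print.moran <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (null expectation %.4f, n = %d)\n",
              x$I, x$expected_I, x$n))
  if (!is.null(x$p_value))
    cat(sprintf("  Monte-Carlo p = %.4g (%d permutations, %s)\n",
                x$p_value, x$n_perm, x$alternative))
  invisible(x)
}

#' Monte-Carlo test for global Moran's I
#'
#' Recomputes I after randomly permuting the values over the cells,
#' `n_perm` times, and reports
#' `p = (1 + #\{I_perm >= I_obs\}) / (1 + n_perm)` for the default
#' one-sided alternative `"greater"` (spatial aggregation); `"two.sided"`
#' doubles the smaller tail.
#'
#' @inheritParams global_moran
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A `moran` object with `p_value`, `n_perm`, `permuted_I`,
#'   `alternative`, `seed` added.
#' @export
moran_montecarlo <- function(x, w, n_perm = 999, seed = NULL,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  res <- global_moran(x, w)
  if (!is.null(seed)) set.seed(seed)
  z <- x - mean(x)
  # all permutations at once: I_perm = (n/S0) t(zp) W zp / sum z^2
  Zp <- vapply(seq_len(n_perm), function(i) z[sample.int(w$n)],
               numeric(w$n))
  Ip <- (w$n / w$S0) * colSums(Zp * (w$W %*% Zp)) / sum(z^2)
  hi <- sum(Ip >= res$I)
  p <- if (alternative == "greater") (1 + hi) / (1 + n_perm)
  else min(1, 2 * (1 + min(hi, sum(Ip <= res$I))) / (1 + n_perm))
  res$p_value <- p
  res$n_perm <- n_perm
  res$permuted_I <- Ip
  res$alternative <- alternative
  res$seed <- seed
  res
}

#' Moran's I correlogram over distance lags
#'
#' For each distance bin `(edge_{k-1}, edge_k]`, restricts binary weights
#' to the centroid pairs whose distance falls in the bin and computes
#' Moran's I with a Monte-Carlo permutation p-value. Bins containing no
#' pair are flagged empty and carry no statistic.
#'
#' @param x per-cell values.
#' @param cells data.frame with `cell_id`, `x_km`, `y_km`.
#' @param lag_edges_km increasing numeric bin edges (default multiples of
#'   10 km up to 100 km).
#' @param n_perm permutations per bin (default 199).
#' @param seed optional integer seed.
#' @param alpha significance level for the per-bin flag (default 0.05).
#' @return Object of class `correlogram`: data.frame with `lag_lo_km`,
#'   `lag_hi_km`, `n_pairs`, `I`, `p_value`, `significant`, `empty`.
#' @export
correlogram <- function(x, cells, lag_edges_km = seq(0, 100, by = 10),
                        n_perm = 199, seed = NULL, alpha = 0.05) {
  stopifnot(length(lag_edges_km) >= 3L, !is.unsorted(lag_edges_km,
                                                     strictly = TRUE))
  if (!is.null(seed)) set.seed(seed)
  d <- as.matrix(stats::dist(cells[, c("x_km", "y_km")]))
  z <- x - mean(x)
  if (sum(z^2) == 0) stop("constant field: correlogram is undefined")
  nb <- length(lag_edges_km) - 1L
  out <- data.frame(lag_lo_km = lag_edges_km[-(nb + 1L)],
                    lag_hi_km = lag_edges_km[-1L],
                    n_pairs = NA_integer_, I = NA_real_,
                    p_value = NA_real_, significant = NA, empty = TRUE)
  n <- length(x)
  for (k in seq_len(nb)) {
    sel <- d > out$lag_lo_km[k] & d <= out$lag_hi_km[k]
    diag(sel) <- FALSE
    npairs <- sum(sel) / 2
    out$n_pairs[k] <- npairs
    if (npairs == 0) next
    W <- matrix(0, n, n); W[sel] <- 1
    S0 <- sum(W)
    Iobs <- moran_statistic(z, W, S0)
    Zp <- vapply(seq_len(n_perm), function(i) z[sample.int(n)], numeric(n))
    Ip <- (n / S0) * colSums(Zp * (W %*% Zp)) / sum(z^2)
    p <- (1 + sum(Ip >= Iobs)) / (1 + n_perm)
    out$I[k] <- Iobs; out$p_value[k] <- p
    out$significant[k] <- p < alpha; out$empty[k] <- FALSE
  }
  if (all(out$empty)) stop("all distance bins are empty")
  class(out) <- c("correlogram", "data.frame")
  out
}

#' Local Moran (LISA) with conditional permutation
#'
#' Per-cell local Moran statistics
#' `I_i = z_i * sum_j w_ij z_j / (sum_k z_k^2 / n)`, the Moran-scatterplot
#' quadrant of each cell (HH, LL, HL, LH from the signs of `z_i` and its
#' spatial lag), and a conditional-permutation p-value: holding `x_i`
#' fixed, the remaining values are randomly reassigned to the other cells
#' `n_perm` times and the two-sided tail probability of `I_i` is taken.
#' With unstandardised weights the identity `sum_i I_i = S0 * I` holds
#' exactly. Island cells get `I_i = 0` and class `NS`.
#'
#' @inheritParams global_moran
#' @param n_perm conditional permutations per cell (default 999).
#' @param alpha significance level (default 0.05).
#' @param seed optional integer seed.
#' @param adjust p-value adjustment across cells passed to
#'   [stats::p.adjust()] (default `"none"`, i.e. each cell at `alpha`;
#'   `"fdr"` available).
#' @return Object of class `lisa`: data.frame with `cell_id`, `I_i`,
#'   `z`, `lag_z`, `quadrant`, `p_value`, `significant`, plus attributes
#'   `S0`, `global_I`, `alpha`.
#' @export
local_moran <- function(x, w, n_perm = 999, alpha = 0.05, seed = NULL,
                        adjust = "none") {
  stopifnot(inherits(w, "spatial_weights"), length(x) == w$n)
  if (anyNA(x)) stop("missing values in x")
  if (!is.null(seed)) set.seed(seed)
  n <- w$n
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  if (m2 == 0) stop("constant field: local Moran is undefined")
  lag <- drop(w$W %*% z)
  Ii <- z * lag / m2
  quadrant <- ifelse(z >= 0,
                     ifelse(lag >= 0, "HH", "HL"),
                     ifelse(lag >= 0, "LH", "LL"))
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (w$islands[i]) next
    wi <- w$W[i, ]
    nz <- which(wi != 0)
    wnz <- wi[nz]
    zmi <- z[-i]
    k <- length(nz)
    lag_perm <- vapply(seq_len(n_perm),
                       function(r) sum(wnz * zmi[sample.int(n - 1L, k)]),
                       numeric(1))
    Ip <- z[i] * lag_perm / m2
    hi <- sum(Ip >= Ii[i]); lo <- sum(Ip <= Ii[i])
    p[i] <- min(1, 2 * (1 + min(hi, lo)) / (1 + n_perm))
  }
  Ii[w$islands] <- 0
  quadrant[w$islands] <- NA_character_
  padj <- p
  padj[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = adjust)
  sig <- !is.na(padj) & padj < alpha
  out <- data.frame(cell_id = w$cell_id, I_i = Ii, z = z, lag_z = lag,
                    quadrant = quadrant, p_value = padj, significant = sig)
  attr(out, "S0") <- w$S0
  attr(out, "global_I") <- moran_statistic(z, w$W, w$S0)
  attr(out, "alpha") <- alpha
  class(out) <- c("lisa", "data.frame")
  out
}

#' Merge LISA quadrants into High / Low / NS classes
#'
#' Significant HH and HL cells become `"High"` (abundance above the
#' neighbourhood), significant LL and LH cells become `"Low"`; everything
#' else (non-significant cells, islands) is `"NS"`. High and Low are
#' disjoint by construction.
#'
#' @param l a [local_moran()] result.
#' @return character vector of classes, one per cell, named by `cell_id`.
#' @export
classify_high_low <- function(l) {
  stopifnot(inherits(l, "lisa"))
  cls <- rep("NS", nrow(l))
  cls[l$significant & l$quadrant %in% c("HH", "HL")] <- "High"
  cls[l$significant & l$quadrant %in% c("LL", "LH")] <- "Low"
  stats::setNames(cls, l$cell_id)
}

#' Summarise abundance by LISA class
#'
#' Per class: number of cells, mean count, standard error of the mean,
#' total count, the class's share of total abundance (percent), and the
#' area covered (cells times cell area).
#'
#' @param counts per-cell counts (one census year).
#' @param classes per-cell classes from [classify_high_low()] (same order).
#' @param cell_area_km2 area of one grid cell in km2 (default 100).
#' @return data.frame with one row per class present.
#' @export
lisa_class_summary <- function(counts, classes, cell_area_km2 = 100) {
  stopifnot(length(counts) == length(classes))
  total <- sum(counts)
  cls <- factor(classes, levels = c("High", "Low", "NS"))
  agg <- lapply(levels(cls), function(g) {
    v <- counts[cls == g]
    if (length(v) == 0L) return(NULL)
    data.frame(class = g, n_cells = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)), total = sum(v),
               share_pct = 100 * sum(v) / total,
               area_km2 = length(v) * cell_area_km2)
  })
  do.call(rbind, agg)
}
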