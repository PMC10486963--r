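#' Kruskal-Wallis rank test on a list of groups
#'
#' Thin wrapper around [stats::kruskal.test()] returning the tie-corrected
#' H statistic and its chi-square p-value (df = groups - 1). If all pooled
#' values are identical the test degenerates to H = 0, p = 1 and the result
#' is flagged.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return list with `H`, `p_value`, `df`, `degenerate`.
#' @export
kw_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 1L))
  pooled <- unlist(groups, use.names = FALSE)
  if (length(pooled) < 3L) stop("need at least 3 values in total")
  if (length(unique(pooled)) == 1L)
    return(list(H = 0, p_value = 1, df = length(groups) - 1L,
                degenerate = TRUE))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), degenerate = FALSE)
}

#' Compare covariates between High and Low cells
#'
#' Runs one Kruskal-Wallis test per covariate, High versus Low cells, and
#' applies a Bonferroni-adjusted significance threshold `alpha / m` where
#' `m` is the number of variables tested. Group means with t-based 95%
#' confidence intervals are reported for description only (they play no
#' role in the test). Results are sorted by p-value.
#'
#' @param cov covariate data.frame with `cell_id` plus the variables.
#' @param classes per-cell classes (`"High"`/`"Low"`/`"NS"`) named by
#'   `cell_id`, e.g. from [classify_high_low()]; or an unnamed vector in
#'   the row order of `cov`.
#' @param alpha family-wise significance level (default 0.05).
#' @param variables covariates to test (default the 16 standard acronyms).
#' @param conf_level confidence level of the descriptive CIs (default 0.95).
#' @return Object of class `group_comparison`: data.frame with `variable`,
#'   `H`, `p_value`, `threshold`, `significant`, `mean_high`, `mean_low`,
#'   CI bounds; attributes `m`, `alpha`, `n_high`, `n_low`.
#' @export
compare_high_low <- function(cov, classes, alpha = 0.05,
                             variables = covariate_acronyms(),
                             conf_level = 0.95) {
  stopifnot(is.data.frame(cov))
  miss <- setdiff(variables, names(cov))
  if (length(miss) > 0L)
    stop("covariate table is missing: ", paste(miss, collapse = ", "))
  if (!is.null(names(classes)) && "cell_id" %in% names(cov))
    classes <- classes[match(as.character(cov$cell_id), names(classes))]
  if (length(classes) != nrow(cov))
    stop("classes do not match the covariate rows")
  hi <- which(classes == "High")
  lo <- which(classes == "Low")
  if (length(hi) < 2L || length(lo) < 2L)
    stop("need at least 2 High and 2 Low cells; check classify_high_low ",
         "output (", length(hi), " High, ", length(lo), " Low)")
  m <- length(variables)
  thr <- alpha / m
  ci <- function(v) {
    if (length(v) < 2L || stats::sd(v) == 0) return(c(mean(v), mean(v)))
    tt <- stats::t.test(v, conf.level = conf_level)
    as.numeric(tt$conf.int)
  }
  rows <- lapply(variables, function(v) {
    kt <- kw_test(list(cov[[v]][hi], cov[[v]][lo]))
    ch <- ci(cov[[v]][hi]); cl <- ci(cov[[v]][lo])
    data.frame(variable = v, H = kt$H, p_value = kt$p_value,
               threshold = thr, significant = kt$p_value < thr,
               mean_high = mean(cov[[v]][hi]), mean_low = mean(cov[[v]][lo]),
               ci_high_lo = ch[1L], ci_high_hi = ch[2L],
               ci_low_lo = cl[1L], ci_low_hi = cl[2L])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  attr(out, "n_high") <- length(hi)
  attr(out, "n_low") <- length(lo)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Kruskal-Wallis High vs Low screen: %d variables, %d High / %d Low cells\n",
    attr(x, "m"), attr(x, "n_high"), attr(x, "n_low")))
  cat(sprintf("Bonferroni threshold: alpha/m = %.6g\n", x$threshold[1L]))
  df <- as.data.frame(x)[, c("variable", "H", "p_value", "significant",
                             "mean_high", "mean_low")]
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}
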