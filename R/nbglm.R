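#' The trend-surface term pool
#'
#' The nine non-constant monomials of total degree <= 3 in the standardized
#' centroid coordinates: X, Y, X2, Y2, X3, Y3, XY, X2Y, XY2.
#'
#' @return character vector of length 9.
#' @export
spatial_terms <- function() {
  c("X", "Y", "X2", "Y2", "X3", "Y3", "XY", "X2Y", "XY2")
}

#' Assemble the modelling frame for the abundance GLMs
#'
#' Builds one data.frame holding the response (counts in `response_year`),
#' every covariate z-score standardized, the temporal term (counts of
#' `temporal_year`, standardized, named `NP` plus the two final year
#' digits, e.g. `NP08`), and the nine third-degree trend-surface monomials
#' computed from the standardized centroid coordinates (coordinates are
#' standardized before raising to powers). Zero-variance predictors are
#' dropped with a message.
#'
#' @param census a [census_table()].
#' @param cov covariate data.frame with `cell_id` (rows matched to the
#'   census cells).
#' @param response_year year whose counts are the response (default the
#'   last census year).
#' @param temporal_year earlier census year providing the temporal term.
#' @return data.frame with column `y` plus standardized predictors;
#'   attributes `temporal_term`, `dropped`.
#' @export
design_frame <- function(census, cov, response_year = max(census$years),
                         temporal_year) {
  stopifnot(inherits(census, "census_table"))
  for (yy in c(response_year, temporal_year))
    if (!yy %in% census$years) stop("year ", yy, " not in census")
  if (temporal_year >= response_year)
    stop("temporal_year must precede response_year")
  cov <- cov[match(census$cells$cell_id, as.character(cov$cell_id)), ,
             drop = FALSE]
  if (anyNA(cov$cell_id)) stop("covariates do not cover all census cells")
  zstd <- function(v) {
    s <- stats::sd(v)
    if (s == 0) return(NULL)
    (v - mean(v)) / s
  }
  d <- data.frame(y = as.numeric(census$counts[, as.character(response_year)]))
  dropped <- character(0)
  for (v in setdiff(names(cov), "cell_id")) {
    z <- zstd(cov[[v]])
    if (is.null(z)) dropped <- c(dropped, v) else d[[v]] <- z
  }
  np_name <- paste0("NP", substr(as.character(temporal_year),
                                 nchar(as.character(temporal_year)) - 1L,
                                 nchar(as.character(temporal_year))))
  znp <- zstd(as.numeric(census$counts[, as.character(temporal_year)]))
  if (is.null(znp)) stop("temporal term has zero variance")
  d[[np_name]] <- znp
  X <- zstd(census$cells$x_km)
  Y <- zstd(census$cells$y_km)
  if (is.null(X) || is.null(Y))
    stop("degenerate grid: a coordinate has zero variance")
  d$X <- X; d$Y <- Y
  d$X2 <- X^2; d$Y2 <- Y^2; d$X3 <- X^3; d$Y3 <- Y^3
  d$XY <- X * Y; d$X2Y <- X^2 * Y; d$XY2 <- X * Y^2
  if (length(dropped) > 0)
    message("dropped zero-variance predictor(s): ",
            paste(dropped, collapse = ", "))
  attr(d, "temporal_term") <- np_name
  attr(d, "dropped") <- dropped
  d
}

#' Build one response/design pair from a term set
#'
#' Selects the requested terms from a [design_frame()] and returns the
#' response vector and the design matrix (with intercept).
#'
#' @param frame a [design_frame()].
#' @param terms character vector of predictor names in `frame`.
#' @return list with `y`, `X` (matrix incl. `(Intercept)`), `terms`,
#'   `formula`.
#' @export
build_design <- function(frame, terms) {
  miss <- setdiff(terms, names(frame))
  if (length(miss) > 0L)
    stop("unknown design term(s): ", paste(miss, collapse = ", "))
  f <- if (length(terms) == 0L) stats::as.formula("y ~ 1") else
    stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(f, frame)
  list(y = frame$y, X = X, terms = terms, formula = f)
}

#' Fit a negative-binomial abundance GLM
#'
#' Negative-binomial regression with log link: mean `mu = exp(X beta)`,
#' variance `mu + mu^2 / theta`. By default `theta` is estimated by
#' maximum likelihood jointly with `beta` (alternating IRLS and univariate
#' theta scoring, via [MASS::glm.nb()]); a fixed `theta` may be supplied
#' instead (large values approach a Poisson fit). The parameter count `k`
#' used for AICc always includes theta, matching the df convention of the
#' candidate tables.
#'
#' @param terms character vector of predictor columns in `frame`
#'   (empty = intercept-only).
#' @param frame a [design_frame()] (any data.frame with `y` and the terms).
#' @param theta optional fixed dispersion; `NULL` (default) estimates it.
#' @return Object of class `nbglm`: list with `coefficients`, `theta`,
#'   `theta_fixed`, `loglik`, `k`, `n`, `aicc`, `null_deviance`,
#'   `deviance`, `pseudo_r2`, `converged`, `terms`, `fit` (the underlying
#'   glm object).
#' @export
fit_nb_glm <- function(terms, frame, theta = NULL) {
  stopifnot(is.data.frame(frame), "y" %in% names(frame))
  y <- frame$y
  if (any(y < 0) || any(y != round(y))) stop("response must be counts")
  des <- build_design(frame, terms)
  n <- length(y)
  p <- ncol(des$X)
  if (n <= p + 2L) stop("too few observations for this model")
  fit <- if (is.null(theta)) {
    suppressWarnings(MASS::glm.nb(des$formula, data = frame,
                                  control = stats::glm.control(maxit = 100)))
  } else {
    stats::glm(des$formula, data = frame,
               family = MASS::negative.binomial(theta),
               control = stats::glm.control(maxit = 100))
  }
  th <- if (is.null(theta)) fit$theta else theta
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit)) + 1L   # + dispersion
  conv <- isTRUE(fit$converged) &&
    (is.null(theta) || isTRUE(fit$converged))
  if (is.null(theta) && !is.null(fit$th.warn)) conv <- FALSE
  structure(list(coefficients = stats::coef(fit), theta = th,
                 theta_fixed = !is.null(theta), loglik = ll, k = k, n = n,
                 aicc = aicc(ll, k, n),
                 null_deviance = fit$null.deviance,
                 deviance = fit$deviance,
                 pseudo_r2 = 1 - fit$deviance / fit$null.deviance,
                 converged = conv, terms = terms, fit = fit),
            class = "nbglm")
}

#' @export
print.nbglm <- function(x, digits = 4, ...) {
  cat("Negative-binomial GLM (log link):",
      if (length(x$terms) == 0L) "intercept only"
      else paste(x$terms, collapse = " + "), "\n")
  cat(sprintf("  n = %d, theta = %.4g%s, logLik = %.2f, k = %d, AICc = %.2f\n",
              x$n, x$theta, if (x$theta_fixed) " (fixed)" else "",
              x$loglik, x$k, x$aicc))
  cat(sprintf("  pseudo-R2 (deviance) = %.3f%s\n", x$pseudo_r2,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.nbglm <- function(object, ...) object$coefficients

#' @export
logLik.nbglm <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
predict.nbglm <- function(object, newdata = NULL,
                          type = c("response", "link"), ...) {
  type <- match.arg(type)
  stats::predict(object$fit, newdata = newdata, type = type)
}

#' @export
residuals.nbglm <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
summary.nbglm <- function(object, ...) summary(object$fit, ...)

#' Standard errors of an `nbglm` fit
#' @param fit an [fit_nb_glm()] object.
#' @return named numeric vector of coefficient standard errors.
#' @export
nbglm_se <- function(fit) {
  stopifnot(inherits(fit, "nbglm"))
  sqrt(diag(stats::vcov(fit$fit)))
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1)`; requires `n > k + 1`.
#' The correction vanishes as `n` grows, recovering the plain AIC.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (including dispersion).
#' @param n number of observations.
#' @return scalar AICc.
#' @export
aicc <- function(loglik, k, n) {
  stopifnot(is.finite(loglik), k >= 1, n > 0)
  if (n - k - 1 <= 0) stop("AICc undefined: need n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Pseudo-R2 of a negative-binomial GLM
#'
#' Default `"deviance"` convention: `1 - residual / null deviance`
#' (fraction of deviance explained). `"mcfadden"` uses
#' `1 - loglik / loglik_null`; `"nagelkerke"` rescales the likelihood-ratio
#' R2 by its attainable maximum. The flavours differ numerically but rank
#' nested models identically.
#'
#' @param fit an [fit_nb_glm()] object.
#' @param method one of `"deviance"`, `"mcfadden"`, `"nagelkerke"`.
#' @return scalar in (-Inf, 1\].
#' @export
pseudo_r2 <- function(fit, method = c("deviance", "mcfadden", "nagelkerke")) {
  stopifnot(inherits(fit, "nbglm"))
  method <- match.arg(method)
  if (method == "deviance") {
    if (fit$null_deviance == 0) stop("null deviance is zero")
    return(1 - fit$deviance / fit$null_deviance)
  }
  y <- fit$fit$y
  ll0 <- sum(stats::dnbinom(y, mu = mean(y), size = fit$theta, log = TRUE))
  if (method == "mcfadden") return(1 - fit$loglik / ll0)
  n <- fit$n
  (1 - exp(-2 * (fit$loglik - ll0) / n)) / (1 - exp(2 * ll0 / n))
}

#' Enumerate candidate model term sets
#'
#' All subsets of the covariate pool crossed with all subsets of the
#' trend-surface pool of size at most `max_spatial_terms`; the temporal
#' term is mandatory in every candidate. The default pools are the five
#' covariates that pass the High/Low screen and the nine third-degree
#' monomials.
#'
#' @param covariate_pool covariate term names (default
#'   `c("COW", "DEH", "SFS", "GF", "WTG")`).
#' @param temporal_term the mandatory temporal term, e.g. `"NP08"`.
#' @param spatial_pool trend-surface terms (default [spatial_terms()]).
#' @param max_spatial_terms cap on spatial terms per candidate (default 4).
#' @param max_models error if the candidate count exceeds this (default
#'   20000).
#' @return list of character term vectors (temporal term included).
#' @export
enumerate_models <- function(covariate_pool = c("COW", "DEH", "SFS", "GF",
                                                "WTG"),
                             temporal_term = "NP08",
                             spatial_pool = spatial_terms(),
                             max_spatial_terms = 4,
                             max_models = 20000) {
  stopifnot(length(covariate_pool) >= 1L, length(spatial_pool) >= 1L,
            length(temporal_term) == 1L)
  subsets <- function(pool, kmax = length(pool)) {
    out <- list(character(0))
    for (k in seq_len(min(kmax, length(pool))))
      out <- c(out, utils::combn(pool, k, simplify = FALSE))
    out
  }
  cs <- subsets(covariate_pool)
  ss <- subsets(spatial_pool, max_spatial_terms)
  n_cand <- length(cs) * length(ss)
  if (n_cand > max_models)
    stop(n_cand, " candidate models exceed max_models = ", max_models,
         "; constrain the pools or max_spatial_terms")
  out <- vector("list", n_cand)
  i <- 0L
  for (a in cs) for (b in ss) {
    i <- i + 1L
    out[[i]] <- c(a, temporal_term, b)
  }
  unique(out)
}

#' Fit every candidate model
#'
#' Fits [fit_nb_glm()] for each term set; candidates that fail or do not
#' converge are dropped with a warning and excluded from selection.
#'
#' @param specs list of term vectors (e.g. [enumerate_models()]).
#' @param frame a [design_frame()].
#' @param theta optional fixed dispersion passed to [fit_nb_glm()].
#' @return list of `nbglm` fits (converged only).
#' @export
fit_candidates <- function(specs, frame, theta = NULL) {
  fits <- lapply(specs, function(tr)
    tryCatch(fit_nb_glm(tr, frame, theta = theta),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  conv <- ok
  conv[ok] <- vapply(fits[ok], function(f) f$converged, logical(1))
  if (any(!conv))
    warning(sum(!conv), " candidate(s) failed or did not converge and ",
            "were excluded")
  fits[conv]
}

#' Rank candidates by AICc and average the top model set
#'
#' Ranks converged fits by AICc, computes `delta = AICc - min(AICc)` and
#' Akaike weights `exp(-delta/2)` normalized over the full candidate set,
#' then averages coefficients over the models with `delta <
#' delta_threshold` using weights renormalized within that set. Both
#' full-model averaging (a term absent from a model contributes 0) and
#' conditional averaging (over the models containing the term) are
#' reported, along with per-term importance (sum of full-set weights of
#' the models containing the term).
#'
#' @param fits list of `nbglm` fits ([fit_candidates()]).
#' @param delta_threshold AICc window for the averaging set (default 2).
#' @return Object of class `model_selection`: list with `table`
#'   (data.frame: `model`, `df`, `loglik`, `AICc`, `delta`, `weight`,
#'   `averaged`), `coef_full`, `coef_conditional`, `importance`,
#'   `delta_threshold`, `n_models`, `fits` (ranked).
#' @export
select_and_average <- function(fits, delta_threshold = 2) {
  stopifnot(length(fits) >= 1L)
  ai <- vapply(fits, function(f) f$aicc, numeric(1))
  ord <- order(ai)
  fits <- fits[ord]
  ai <- ai[ord]
  delta <- ai - ai[1L]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  in_set <- delta < delta_threshold
  wa <- w[in_set] / sum(w[in_set])
  avg_fits <- fits[in_set]
  all_terms <- unique(unlist(lapply(avg_fits, function(f)
    names(f$coefficients))))
  coef_mat <- vapply(avg_fits, function(f) {
    v <- stats::setNames(rep(0, length(all_terms)), all_terms)
    v[names(f$coefficients)] <- f$coefficients
    v
  }, numeric(length(all_terms)))
  coef_mat <- matrix(coef_mat, nrow = length(all_terms),
                     dimnames = list(all_terms, NULL))
  coef_full <- drop(coef_mat %*% wa)
  present <- vapply(avg_fits, function(f)
    all_terms %in% names(f$coefficients), logical(length(all_terms)))
  present <- matrix(present, nrow = length(all_terms))
  coef_cond <- vapply(seq_along(all_terms), function(j) {
    sel <- present[j, ]
    sum(coef_mat[j, sel] * wa[sel]) / sum(wa[sel])
  }, numeric(1))
  names(coef_cond) <- all_terms
  terms_all <- unique(unlist(lapply(fits, function(f) f$terms)))
  importance <- vapply(terms_all, function(tr)
    sum(w[vapply(fits, function(f) tr %in% f$terms, logical(1))]),
    numeric(1))
  tab <- data.frame(
    model = vapply(fits, function(f)
      if (length(f$terms) == 0L) "(intercept)"
      else paste(f$terms, collapse = " + "), character(1)),
    df = vapply(fits, function(f) f$k, integer(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    AICc = ai, delta = delta, weight = w, averaged = in_set)
  structure(list(table = tab, coef_full = coef_full,
                 coef_conditional = coef_cond,
                 importance = sort(importance, decreasing = TRUE),
                 delta_threshold = delta_threshold,
                 n_models = length(fits), fits = fits),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, n = 10, digits = 4, ...) {
  cat(sprintf("Model selection over %d candidates (AICc, delta < %g ",
              x$n_models, x$delta_threshold))
  cat(sprintf("averaging set: %d models)\n", sum(x$table$averaged)))
  top <- utils::head(x$table[, c("model", "df", "loglik", "AICc", "delta",
                                 "weight")], n)
  top$loglik <- round(top$loglik, 2)
  top$AICc <- round(top$AICc, 2)
  top$delta <- round(top$delta, 3)
  top$weight <- signif(top$weight, 2)
  print(top, row.names = FALSE)
  cat("Averaged coefficients (full-model):\n")
  print(signif(x$coef_full, digits))
  invisible(x)
}

#' @export
coef.model_selection <- function(object, full = TRUE, ...) {
  if (full) object$coef_full else object$coef_conditional
}
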