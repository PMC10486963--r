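#' Configuration for the synthetic census generator
#'
#' Bundles every knob of the generator. Defaults emulate the structure of a
#' national raptor breeding census on a 10 x 10 km grid: roughly a thousand
#' ever-occupied cells, small overdispersed counts (most cells 0-3 pairs,
#' maxima near 8), positive spatial autocorrelation decaying within about
#' two lattice steps, and three census years with strong year-to-year
#' persistence.
#'
#' The latent field is a zero-mean Gaussian process with exponential
#' covariance `sill * exp(-d / range_km)` over centroid distances `d`,
#' coupled across years as a stationary AR(1) with coefficient `rho`.
#' Counts are negative binomial with mean
#' `exp(beta0 + sum(beta_j * z_j) + field)` (covariates z-scored) and
#' variance `mu + mu^2 / theta`.
#'
#' @param nx,ny lattice dimensions in cells (default 40 x 26 = 1040 cells).
#' @param cell_size_km cell side in km (default 10).
#' @param range_km spatial correlation range of the latent field (default
#'   20, i.e. two lattice steps).
#' @param sill marginal variance of the latent field (default 0.5).
#' @param beta named log-scale coefficient vector; the name `intercept` is
#'   the baseline log mean, other names must be covariate columns. Default
#'   encodes positive cattle, griffon, feeding-station and wood-pasture
#'   effects and a negative wind-turbine effect, with the intercept set so
#'   the mean count per ever-occupied cell is about 1.3.
#' @param theta negative-binomial dispersion (> 0; variance
#'   `mu + mu^2/theta`); `Inf` gives Poisson counts. Default 2.
#' @param rho year-to-year AR(1) persistence of the latent field in
#'   \[0, 1\] (default 0.9).
#' @param years census years (default 2000, 2008, 2018).
#' @param never_occupied_frac fraction of cells forced structurally empty in
#'   all years (default 0).
#' @param seed integer seed; the same config yields bit-identical output.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(nx = 40L, ny = 26L, cell_size_km = 10,
                         range_km = 20, sill = 0.5,
                         beta = c(intercept = -0.15, COW = 0.3, GF = 0.3,
                                  SFS = 0.2, DEH = 0.2, WTG = -0.3),
                         theta = 2, rho = 0.9,
                         years = c(2000L, 2008L, 2018L),
                         never_occupied_frac = 0, seed = 1L) {
  stopifnot(nx >= 1L, ny >= 1L, cell_size_km > 0, range_km > 0,
            sill >= 0, theta > 0, rho >= 0, rho <= 1,
            never_occupied_frac >= 0, never_occupied_frac <= 1,
            length(years) >= 1L)
  if (is.null(names(beta)) || !"intercept" %in% names(beta))
    stop("beta must be a named vector including 'intercept'")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 cell_size_km = cell_size_km, range_km = range_km,
                 sill = sill, beta = beta, theta = theta, rho = rho,
                 years = as.integer(years),
                 never_occupied_frac = never_occupied_frac,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# centroid grid for a config: cell (i, j) centred at ((i-1/2)s, (j-1/2)s)
synth_cells <- function(cfg) {
  s <- cfg$cell_size_km
  g <- expand.grid(ix = seq_len(cfg$nx), iy = seq_len(cfg$ny))
  data.frame(cell_id = sprintf("c%04d", seq_len(nrow(g))),
             x_km = (g$ix - 0.5) * s, y_km = (g$iy - 0.5) * s)
}

# Cholesky factor of the exponential covariance over given centroids.
# A small diagonal jitter keeps the factorisation stable for near-duplicate
# distances; failure after jitter is a genuine non-PD input.
exp_cov_chol <- function(cells, sill, range_km, jitter = 1e-10) {
  d <- as.matrix(stats::dist(cells[, c("x_km", "y_km")]))
  S <- sill * exp(-d / range_km)
  diag(S) <- diag(S) + jitter
  L <- tryCatch(chol(S), error = function(e)
    stop("latent-field covariance is not positive definite: ",
         conditionMessage(e)))
  L
}

#' Simulate the latent spatial field for every census year
#'
#' Draws a zero-mean Gaussian field with exponential covariance
#' `sill * exp(-d / range_km)` over the cell centroids, then couples years
#' as a stationary AR(1): `f_t = rho * f_{t-1} + sqrt(1 - rho^2) * e_t`
#' with `e_t` an independent draw from the same field, so every year has
#' marginal variance `sill`. `rho = 1` repeats the first year exactly;
#' `sill = 0` gives all-zero fields.
#'
#' @param cfg a [synth_config()].
#' @param cells optional centroid data.frame (default: the config's grid).
#' @return numeric matrix, cells x years.
#' @export
simulate_latent_field <- function(cfg, cells = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(cells)) cells <- synth_cells(cfg)
  n <- nrow(cells)
  ny <- length(cfg$years)
  f <- matrix(0, n, ny, dimnames = list(cells$cell_id, cfg$years))
  if (cfg$sill == 0) return(f)
  L <- exp_cov_chol(cells, cfg$sill, cfg$range_km)
  draw <- function() drop(crossprod(L, stats::rnorm(n)))
  f[, 1L] <- draw()
  if (ny > 1L) {
    for (t in 2L:ny) {
      innov <- if (cfg$rho < 1) draw() else 0
      f[, t] <- cfg$rho * f[, t - 1L] + sqrt(1 - cfg$rho^2) * innov
    }
  }
  f
}

# Smooth covariate surfaces plus sparse point-process covariates, so the
# High/Low screen sees realistic contrast. Percent covers go through a
# probit squash to [0, 100]; livestock and griffons are log-normal fields;
# turbines / feeding stations / landfills / poisonings are Poisson counts
# with spatially smooth log intensity.
simulate_covariates <- function(cfg, cells) {
  n <- nrow(cells)
  L <- exp_cov_chol(cells, 1, cfg$range_km * 1.5)
  field <- function() drop(crossprod(L, stats::rnorm(n)))
  pct <- function() 100 * stats::pnorm(field())
  counts <- function(log_mean, sd = 1) stats::rpois(n, exp(log_mean + sd * field()))
  d <- data.frame(
    cell_id = cells$cell_id,
    ALT = pmax(0, 600 + 300 * field()),
    NIC = pct(), IRR = pct(), TREE = pct(), DEH = pct(),
    ROC = pct() / 5, FOR = pct(), PAS = pct(),
    COW = counts(log(800), 1), SHEEP = counts(log(2000), 1),
    LAND = stats::rpois(n, 0.2), SFS = counts(log(0.3), 0.8),
    URB = pct() / 10, WTG = counts(log(1.5), 1.2),
    POIS = stats::rpois(n, 0.1), GF = counts(log(15), 1.5)
  )
  validate_covariates(d, covariate_acronyms())
}

#' Simulate a multi-year gridded census with known ground truth
#'
#' Generates (or takes) a per-cell covariate table, draws the latent
#' spatial field ([simulate_latent_field()]), and samples counts
#' `NB(mean = exp(beta0 + X_z beta + field), dispersion = theta)` per cell
#' and year, where `X_z` are the z-scored covariates named in `cfg$beta`.
#' A `never_occupied_frac` fraction of cells is forced to zero in all years
#' (structurally unsuitable habitat). The returned truth record stores
#' everything needed to verify recovery: coefficients, dispersion, the
#' latent field, and the forced-empty cells.
#'
#' @param cfg a [synth_config()].
#' @param covariates optional covariate data.frame (cell_id + columns
#'   covering `names(cfg$beta)` minus `intercept`); generated if `NULL`.
#' @return list of class `synthetic_census` with elements `census`
#'   (a [census_table()]), `covariates` (data.frame) and `truth` (list with
#'   `beta`, `theta`, `field`, `never_occupied`, `seed`).
#' @export
simulate_census <- function(cfg, covariates = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  cells <- synth_cells(cfg)
  n <- nrow(cells)
  if (is.null(covariates)) covariates <- simulate_covariates(cfg, cells)
  covariates$cell_id <- as.character(covariates$cell_id)
  if (!identical(covariates$cell_id, cells$cell_id))
    covariates <- covariates[match(cells$cell_id, covariates$cell_id), ]
  if (anyNA(covariates$cell_id)) stop("covariates do not cover all cells")
  b_cov <- cfg$beta[setdiff(names(cfg$beta), "intercept")]
  miss <- setdiff(names(b_cov), names(covariates))
  if (length(miss) > 0L)
    stop("beta names not in covariates: ", paste(miss, collapse = ", "))
  eta0 <- rep(cfg$beta[["intercept"]], n)
  for (v in names(b_cov)) {
    z <- covariates[[v]]
    s <- stats::sd(z)
    z <- if (s > 0) (z - mean(z)) / s else z * 0
    eta0 <- eta0 + b_cov[[v]] * z
  }
  field <- simulate_latent_field(cfg, cells)
  counts <- matrix(0L, n, length(cfg$years))
  for (t in seq_along(cfg$years)) {
    eta <- eta0 + field[, t]
    if (any(eta > 20))
      stop("log-mean exceeds 20; choose smaller beta / sill")
    mu <- exp(eta)
    counts[, t] <- if (is.finite(cfg$theta))
      stats::rnbinom(n, mu = mu, size = cfg$theta)
    else stats::rpois(n, mu)
  }
  k <- floor(cfg$never_occupied_frac * n)
  never <- if (k > 0) sample.int(n, k) else integer(0)
  counts[never, ] <- 0L
  list(census = census_table(cells, cfg$years, counts),
       covariates = covariates,
       truth = list(beta = cfg$beta, theta = cfg$theta, field = field,
                    never_occupied = cells$cell_id[never], seed = cfg$seed)) |>
    structure(class = "synthetic_census")
}

#' @export
print.synthetic_census <- function(x, ...) {
  cat("Synthetic gridded census (seed", x$truth$seed, ")\n")
  print(x$census)
  cat("Truth: theta =", x$truth$theta, "; beta:",
      paste(names(x$truth$beta), signif(x$truth$beta, 3), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
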