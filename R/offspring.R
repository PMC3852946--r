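#' Ratio of effective to census population size implied by family-size variance
#'
#' Under random mating with mean two offspring per mating and family-size
#' variance `vk`, the effective size of a constant population relates to its
#' census size approximately as `Ne/Nc = 4/(vk + 2)`.  Poisson family sizes
#' (`vk = 2`) give `Ne/Nc = 1`; sweepstakes-like variance drives the ratio
#' toward zero.
#'
#' @param vk Variance in reproductive success (variance of family sizes),
#'   non-negative.
#' @return `4 / (vk + 2)`.  Note the formula exceeds 1 for `vk < 2`; such
#'   values lie outside the regime the simulator supports.
#' @examples
#' ne_nc_ratio(2)    # 1
#' ne_nc_ratio(400)  # ~0.01
#' @export
ne_nc_ratio <- function(vk) {
  if (!is.numeric(vk) || anyNA(vk) || any(vk < 0))
    stop("'vk' must be a non-negative number")
  4 / (vk + 2)
}

#' Census size required for a target effective size
#'
#' Inverts [ne_nc_ratio()]: `Nc = Ne * (vk + 2) / 4`, rounded to the nearest
#' integer and then forced even (the mating scheme pairs individuals), with a
#' floor of 2.
#'
#' @param ne Target effective population size (individuals).
#' @param vk Variance in reproductive success.
#' @return Integer census size.
#' @examples
#' census_size(500, 400)  # 50250
#' census_size(50, 2)     # 50
#' @export
census_size <- function(ne, vk) {
  if (!is.numeric(ne) || any(ne <= 0)) stop("'ne' must be positive")
  if (!is.numeric(vk) || any(vk < 0)) stop("'vk' must be non-negative")
  nc <- round(ne * (vk + 2) / 4)
  nc <- nc + nc %% 2
  as.integer(pmax(nc, 2))
}

# Calibrated models memoised by (vk, tolerance); calibration is deterministic.
.model_cache <- new.env(parent = emptyenv())

# Mean/variance (and total mass) of X = floor(Gamma(shape, scale)) by analytic
# summation of the discretised mass function P(X = k) = F(k+1) - F(k),
# truncated where the right tail mass drops below `tail`.
floored_gamma_moments <- function(shape, scale, tail = 1e-12) {
  kmax <- ceiling(stats::qgamma(1 - tail, shape = shape, scale = scale)) + 1
  m1 <- m2 <- mass <- 0
  chunk <- 1e6
  lo <- 0
  while (lo <= kmax) {
    hi <- min(lo + chunk - 1, kmax)
    cdf <- stats::pgamma(lo:(hi + 1), shape = shape, scale = scale)
    p <- diff(cdf)
    k <- lo:hi
    m1 <- m1 + sum(k * p)
    m2 <- m2 + sum(k^2 * p)
    mass <- mass + sum(p)
    lo <- hi + 1
  }
  list(mean = m1, variance = m2 - m1^2, mass = mass, support_max = kmax)
}

#' Calibrate a floored-gamma family-size distribution
#'
#' Finds gamma parameters (shape, scale) such that `X = floor(Gamma)` has mean
#' 2 and variance `target_variance`.  Flooring a continuous gamma yields a
#' discrete, long-right-tailed distribution (approximately negative binomial)
#' in which most matings produce few or no offspring and a few produce very
#' many -- the sweepstakes pattern.  Moments are computed by analytic summation
#' of the discretised mass function, so calibration is deterministic.
#'
#' The search is nested: for a trial shape, the scale achieving mean 2 is
#' found by bisection (the floored mean is increasing in scale); the variance
#' at that mean is then matched by an outer bisection over shape (variance is
#' decreasing in shape at fixed mean).
#'
#' @param target_variance Target family-size variance `vk`, must exceed 2.
#' @param tolerance Relative tolerance on both realized moments; the root
#'   search itself converges far tighter.  `tolerance = 0` is unattainable and
#'   raises an error.
#' @return An object of class `offspring_model` with fields `kind`
#'   (`"floored_gamma"`), `shape_param`, `scale_param`, `realized_mean`,
#'   `realized_variance`.
#' @export
calibrate_floored_gamma <- function(target_variance, tolerance = 0.01) {
  if (!is.numeric(target_variance) || length(target_variance) != 1 ||
      target_variance <= 2)
    stop("'target_variance' must be a single number > 2")
  if (tolerance <= 0)
    stop("calibration error: tolerance must be > 0 (exact moment matching of ",
         "a discretised distribution is unattainable)")

  scale_for_mean2 <- function(shape) {
    f <- function(log_scale) {
      floored_gamma_moments(shape, exp(log_scale))$mean - 2
    }
    guess <- 2.5 / shape  # continuous-gamma mean 2.5 loses ~0.5 to flooring
    r <- stats::uniroot(f, lower = log(guess / 20), upper = log(guess * 20),
                        tol = 1e-12, extendInt = "yes")
    exp(r$root)
  }
  var_at_shape <- function(log_shape) {
    shape <- exp(log_shape)
    scale <- scale_for_mean2(shape)
    floored_gamma_moments(shape, scale)$variance - target_variance
  }
  # continuous-gamma guess shape = mean^2/variance = 4/vk brackets the root
  r <- tryCatch(
    stats::uniroot(var_at_shape, lower = log(0.4 / target_variance),
                   upper = log(40 / target_variance), tol = 1e-10,
                   extendInt = "yes"),
    error = function(e) stop("calibration error for vk = ", target_variance,
                             ": ", conditionMessage(e)))
  shape <- exp(r$root)
  scale <- scale_for_mean2(shape)
  mom <- floored_gamma_moments(shape, scale)
  # discrete CDF of the floored distribution, used for O(log k) sampling
  cdf <- stats::pgamma(seq_len(mom$support_max + 1), shape = shape,
                       scale = scale)
  if (abs(mom$mean - 2) > 2 * tolerance ||
      abs(mom$variance - target_variance) > tolerance * target_variance)
    stop("calibration error for vk = ", target_variance,
         ": realized mean ", signif(mom$mean, 6), ", variance ",
         signif(mom$variance, 6))
  structure(list(kind = "floored_gamma",
                 family_mean = 2,
                 family_variance = target_variance,
                 shape_param = shape,
                 scale_param = scale,
                 realized_mean = mom$mean,
                 realized_variance = mom$variance,
                 cdf = cdf),
            class = "offspring_model")
}

#' Construct a family-size (offspring-number) model
#'
#' `vk = 2` gives Poisson(2) family sizes (the Wright-Fisher assumption);
#' `vk > 2` gives a calibrated floored-gamma distribution with mean 2 and
#' variance `vk` (see [calibrate_floored_gamma()]).  Values below 2 are not
#' supported: the `Ne/Nc = 4/(vk + 2)` relationship would exceed 1.
#'
#' @param vk Variance in reproductive success.
#' @param tolerance Passed to [calibrate_floored_gamma()] when `vk > 2`.
#' @return An `offspring_model` object.
#' @export
offspring_model <- function(vk, tolerance = 0.01) {
  if (!is.numeric(vk) || length(vk) != 1 || is.na(vk))
    stop("'vk' must be a single number")
  if (vk < 2) stop("vk < 2 is not supported (Ne/Nc would exceed 1)")
  if (vk == 2) {
    return(structure(list(kind = "poisson",
                          family_mean = 2,
                          family_variance = 2,
                          shape_param = NA_real_,
                          scale_param = NA_real_,
                          realized_mean = 2,
                          realized_variance = 2),
                     class = "offspring_model"))
  }
  key <- paste(vk, tolerance, sep = "_")  # calibration is deterministic
  if (is.null(.model_cache[[key]]))
    .model_cache[[key]] <- calibrate_floored_gamma(vk, tolerance = tolerance)
  .model_cache[[key]]
}

#' @export
print.offspring_model <- function(x, ...) {
  cat("Offspring model:", x$kind, "\n")
  cat(sprintf("  target mean/variance: 2 / %g\n", x$family_variance))
  cat(sprintf("  realized mean/variance: %.4f / %.4f\n",
              x$realized_mean, x$realized_variance))
  if (x$kind == "floored_gamma")
    cat(sprintf("  gamma shape/scale: %.6g / %.6g\n",
                x$shape_param, x$scale_param))
  invisible(x)
}

#' Draw family sizes from an offspring model
#'
#' @param model An `offspring_model`.
#' @param n_families Number of independent families to draw.
#' @return Integer vector of non-negative family sizes (empty for
#'   `n_families = 0`).
#' @export
draw_family_sizes <- function(model, n_families) {
  stopifnot(inherits(model, "offspring_model"))
  if (n_families < 0) stop("'n_families' must be >= 0")
  if (n_families == 0) return(integer(0))
  if (model$kind == "poisson") {
    stats::rpois(n_families, 2)
  } else {
    # inverse-CDF draw from the discretised distribution (cdf[k+1] = P(X<=k))
    findInterval(stats::runif(n_families), model$cdf)
  }
}

#' Demography configuration for one simulated scenario
#'
#' Bundles the target effective size, reproductive-success variance, derived
#' census size, marker model and sampling design of one grid cell.
#'
#' @param ne Target effective population size.
#' @param vk Variance in reproductive success (>= 2).
#' @param n_loci Number of unlinked loci (microsatellite modes; a sequence
#'   dataset carries a single 500-bp locus).
#' @param mu Mutation rate: per locus per generation for microsatellites
#'   (default 5e-4), per site per generation for sequences (default 1e-7).
#' @param sample_size Individuals sampled per dataset (default 50).
#' @param marker_type `"microsat"`, `"microsat_constrained"` (alleles confined
#'   to a window of 5 adjacent repeat states) or `"sequence"` (one 500-bp
#'   infinite-sites locus).
#' @param n_sites Sites per sequence locus (sequence mode only).
#' @return A `demography_config` object with derived `nc = census_size(ne, vk)`
#'   and `theta`, the per-locus population mutation parameter `4*ne*mu`
#'   (`4*ne*mu*n_sites` for sequences).
#' @export
demography_config <- function(ne, vk, n_loci = 15, mu = NULL, sample_size = 50,
                              marker_type = c("microsat",
                                              "microsat_constrained",
                                              "sequence"),
                              n_sites = 500) {
  marker_type <- match.arg(marker_type)
  if (is.null(mu)) mu <- if (marker_type == "sequence") 1e-7 else 5e-4
  stopifnot(ne > 0, vk >= 2, n_loci >= 1, mu >= 0, sample_size >= 1)
  if (marker_type == "sequence") n_loci <- 1L
  nc <- census_size(ne, vk)
  if (sample_size > nc)
    stop("sample_size (", sample_size, ") exceeds census size (", nc, ")")
  theta <- if (marker_type == "sequence") 4 * ne * mu * n_sites else
    4 * ne * mu
  structure(list(ne = ne, vk = vk, nc = nc, n_loci = as.integer(n_loci),
                 mu = mu, sample_size = as.integer(sample_size),
                 marker_type = marker_type, n_sites = as.integer(n_sites),
                 theta = theta),
            class = "demography_config")
}

#' @export
print.demography_config <- function(x, ...) {
  cat(sprintf("Demography: Ne = %g, Vk = %g, Nc = %d (Ne/Nc = %.4g)\n",
              x$ne, x$vk, x$nc, ne_nc_ratio(x$vk)))
  cat(sprintf("  marker: %s, %d loci, mu = %g, theta = %g, sample = %d\n",
              x$marker_type, x$n_loci, x$mu, x$theta, x$sample_size))
  invisible(x)
}

#' Expected heterozygosity at stepwise-mutation equilibrium
#'
#' Closed-form equilibrium heterozygosity of the strict stepwise mutation
#' model, `1 - 1/sqrt(1 + 2*theta)`, used both as an initialisation target and
#' as the theoretical check on the forward simulator.
#'
#' @param theta Population mutation parameter `4*Ne*mu`.
#' @return Expected heterozygosity in `[0, 1)`.
#' @export
smm_equilibrium_he <- function(theta) {
  stopifnot(theta >= 0)
  1 - 1 / sqrt(1 + 2 * theta)
}
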