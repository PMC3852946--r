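# The four bottleneck-detection procedures.  Each consumes an `srs_dataset`
# and returns a boolean call plus supporting values; all assume a stable
# Wright-Fisher (Vk = 2) population as the null.

#' Fixed-threshold M-ratio test
#'
#' The conservation-genetics rule of thumb: a bottleneck is called when the
#' dataset-mean M-ratio falls strictly below 0.68.
#'
#' @param dataset Microsatellite `srs_dataset`.
#' @param threshold Decision threshold (default 0.68).
#' @return List with `m_mean`, `threshold`, `call`.
#' @export
m_ratio_ft_test <- function(dataset, threshold = 0.68) {
  stopifnot(inherits(dataset, "srs_dataset"),
            dataset$marker_type != "sequence")
  m <- summary_stats(dataset)$m
  list(test = "m_ratio_ft", m_mean = m, threshold = threshold,
       call = m < threshold)
}

#' M-ratio test with a simulated critical value
#'
#' Reconstructs the null distribution of the dataset-mean M-ratio from
#' `n_sims` Kingman-coalescent stepwise-mutation simulations at the true Ne
#' and mu of the data-generating process (theta = 4*Ne*mu), and calls a
#' bottleneck when the observed mean M falls below the empirical alpha
#' quantile (lower-tail order statistic, no interpolation).
#'
#' @param dataset Microsatellite `srs_dataset`.
#' @param true_ne,true_mu Parameters used to generate the data.
#' @param n_sims Coalescent simulations for the null (default 1000).
#' @param alpha Significance level.
#' @param seed Optional private seed for the null simulations.
#' @param null_M Optional precomputed [null_M_distribution()] (the null
#'   depends only on theta, sample size and locus count, so it can be shared
#'   across replicates of one scenario).
#' @return List with `m_mean`, `critical_value`, `call`.
#' @export
m_ratio_sim_test <- function(dataset, true_ne, true_mu, n_sims = 1000,
                             alpha = 0.05, seed = NULL, null_M = NULL) {
  stopifnot(inherits(dataset, "srs_dataset"),
            dataset$marker_type != "sequence")
  if (is.null(null_M))
    null_M <- null_M_distribution(4 * true_ne * true_mu,
                                  n_genes = 2L * dataset$n_ind,
                                  n_loci = dataset$n_loci,
                                  n_sims = n_sims, seed = seed)
  crit <- sort(null_M)[max(1L, floor(alpha * length(null_M)))]
  m <- summary_stats(dataset)$m
  list(test = "m_ratio_sim", m_mean = m, critical_value = crit,
       call = m < crit)
}

# One-tailed Wilcoxon signed-rank p-value for "x tends to be positive".
# Zero differences are dropped (standard practice); base wilcox.test provides
# the exact distribution for small samples without ties and the
# continuity-corrected normal approximation otherwise.
signed_rank_p <- function(x, alternative = "greater") {
  x <- x[!is.na(x) & x != 0]
  if (!length(x)) return(1)
  suppressWarnings(
    stats::wilcox.test(x, alternative = alternative)$p.value)
}

#' Heterozygosity-excess test
#'
#' For each polymorphic locus the unbiased expected heterozygosity He is
#' compared with the equilibrium heterozygosity Heq expected under the
#' Wright-Fisher stepwise-mutation model given the observed allele count
#' ([estimate_Heq()], computed by coalescent simulation).  A one-tailed
#' Wilcoxon signed-rank test on the per-locus differences He - Heq calls a
#' bottleneck when heterozygosity is significantly in excess.
#'
#' @param dataset Microsatellite `srs_dataset`.
#' @param alpha Significance level.
#' @param min_accepted Accepted simulations per Heq value.
#' @return List with per-locus table (`He`, `K`, `Heq`, `delta`), `p`,
#'   `call`, and `applicable` (FALSE, with no call, when fewer than 4
#'   polymorphic loci are available to rank).
#' @export
het_excess_test <- function(dataset, alpha = 0.05, min_accepted = 500) {
  stopifnot(inherits(dataset, "srs_dataset"),
            dataset$marker_type != "sequence")
  ss <- summary_stats(dataset)
  loc <- ss$locus
  poly <- which(loc$K >= 2)
  if (length(poly) < 4) {
    return(list(test = "het_excess", applicable = FALSE, p = NA_real_,
                call = FALSE, loci = NULL))
  }
  n_genes <- 2L * dataset$n_ind
  heq <- vapply(loc$K[poly],
                function(k) estimate_Heq(n_genes, k, min_accepted),
                numeric(1))
  delta <- loc$He[poly] - heq
  p <- signed_rank_p(delta, alternative = "greater")
  list(test = "het_excess", applicable = TRUE,
       loci = data.frame(locus = poly, He = loc$He[poly], K = loc$K[poly],
                         Heq = heq, delta = delta),
       p = p, alpha = alpha, call = p < alpha)
}

#' Tajima's D test for population decline
#'
#' Computes D for the sequence sample and a one-tailed p-value (positive
#' side: decline / balancing-selection signal) from `n_sims` constant-size
#' infinite-sites coalescent simulations at theta estimated from the observed
#' mean pairwise difference pi.  Simulated samples with S = 0 contribute
#' D = 0 (no deviation).
#'
#' @param dataset Sequence `srs_dataset`.
#' @param alpha Significance level.
#' @param n_sims Coalescent simulations for the null.
#' @param seed Optional private seed for the null simulations.
#' @return List with `S`, `pi`, `D`, `p`, `call`, and `applicable` (FALSE when
#'   S = 0, where D is undefined).
#' @export
tajima_test <- function(dataset, alpha = 0.05, n_sims = 1000, seed = NULL) {
  stopifnot(inherits(dataset, "srs_dataset"),
            dataset$marker_type == "sequence")
  obs <- tajimas_d(dataset$seq)
  if (obs["S"] == 0) {
    return(list(test = "tajima", applicable = FALSE, S = 0, pi = 0,
                D = NA_real_, p = NA_real_, call = FALSE))
  }
  n <- nrow(dataset$seq)
  theta_hat <- obs[["pi"]]
  d_null <- with_rng_scope(seed, {
    vapply(seq_len(n_sims), function(i) {
      sp <- sim_infsites_spi(n, theta_hat)
      d <- tajima_d_from_counts(n, sp[["S"]], sp[["pi"]])
      if (is.na(d)) 0 else d
    }, numeric(1))
  })
  p <- mean(d_null >= obs[["D"]])
  list(test = "tajima", applicable = TRUE, S = unname(obs["S"]),
       pi = unname(obs["pi"]), D = unname(obs["D"]), p = p, alpha = alpha,
       call = p < alpha)
}

#' Run the applicable battery of bottleneck tests on one dataset
#'
#' Microsatellite datasets get the fixed-threshold M-ratio, simulated-critical
#' M-ratio and heterozygosity-excess tests; sequence datasets get Tajima's D.
#'
#' @param dataset An `srs_dataset`.
#' @param true_ne,true_mu Data-generating parameters (microsatellite modes;
#'   default taken from the dataset provenance where available).
#' @param alpha Significance level for every test.
#' @param null_M Optional shared null for [m_ratio_sim_test()].
#' @param tests Character subset of
#'   `c("m_ratio_ft", "m_ratio_sim", "het_excess", "tajima")`.
#' @param ... Passed through to the individual tests.
#' @return List of class `srs_battery` with one entry per test run.
#' @export
test_battery <- function(dataset, true_ne = NULL, true_mu = NULL,
                         alpha = 0.05, null_M = NULL, tests = NULL, ...) {
  stopifnot(inherits(dataset, "srs_dataset"))
  if (is.null(true_ne)) true_ne <- dataset$provenance$ne
  if (is.null(tests)) {
    tests <- if (dataset$marker_type == "sequence") "tajima" else
      c("m_ratio_ft", "m_ratio_sim", "het_excess")
  }
  out <- list()
  if ("m_ratio_ft" %in% tests)
    out$m_ratio_ft <- m_ratio_ft_test(dataset)
  if ("m_ratio_sim" %in% tests)
    out$m_ratio_sim <- m_ratio_sim_test(dataset, true_ne, true_mu,
                                        alpha = alpha, null_M = null_M, ...)
  if ("het_excess" %in% tests)
    out$het_excess <- het_excess_test(dataset, alpha = alpha)
  if ("tajima" %in% tests)
    out$tajima <- tajima_test(dataset, alpha = alpha)
  class(out) <- "srs_battery"
  out
}

#' @export
print.srs_battery <- function(x, ...) {
  for (t in x) {
    cat(sprintf("%-12s call = %-5s", t$test, t$call))
    if (!is.null(t$p) && !is.na(t$p)) cat(sprintf("  p = %.4g", t$p))
    if (!is.null(t$m_mean)) cat(sprintf("  M = %.3f", t$m_mean))
    if (!is.null(t$D) && !is.na(t$D)) cat(sprintf("  D = %.3f", t$D))
    cat("\n")
  }
  invisible(x)
}
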