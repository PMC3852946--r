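# Orchestration: replicate simulation + test battery over an Ne x Vk grid,
# aggregated into a single false-positive-rate results table.

#' Specification of an Ne x Vk simulation grid
#'
#' Defaults define the package's reference study design: Ne in {50, 500, 2500, 5000}, Vk in
#' {2, 40, 400, 2000}, 100 replicates per cell, 15 microsatellite loci,
#' samples of 50 individuals, alpha = 0.05.  Unless `full = TRUE`, cells with
#' Ne in {2500, 5000} and Vk in {400, 2000} are dropped from the default
#' profile: their census sizes (up to 2.5 million forward-simulated
#' individuals) are cluster-scale, not desk-scale.
#'
#' @param ne_values,vk_values Grid margins.
#' @param replicates Replicates per cell.
#' @param marker_type Passed to [demography_config()].
#' @param alpha Significance level.
#' @param seed Master seed; every cell and replicate seed derives from it.
#' @param full Keep the large-census cells.
#' @return A `grid_spec` object (data frame of cells plus settings).
#' @export
grid_spec <- function(ne_values = c(50, 500, 2500, 5000),
                      vk_values = c(2, 40, 400, 2000),
                      replicates = 100, marker_type = "microsat",
                      alpha = 0.05, seed = 1, full = FALSE) {
  cells <- expand.grid(ne = ne_values, vk = vk_values)
  if (!full)
    cells <- cells[!(cells$ne %in% c(2500, 5000) &
                       cells$vk %in% c(400, 2000)), , drop = FALSE]
  cells <- cells[order(cells$ne, cells$vk), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(cells = cells, replicates = replicates,
                 marker_type = marker_type, alpha = alpha, seed = seed),
            class = "grid_spec")
}

# Clopper-Pearson interval for a false-positive count.
fpr_ci <- function(x, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(stats::binom.test(x, n)$conf.int)
}

#' Simulate and test one grid cell
#'
#' Runs `replicates` independent forward simulations at the given Ne and Vk
#' (calibrated offspring model, burn-in to equilibrium, sample of
#' `sample_size` individuals), applies the requested bottleneck tests to each
#' dataset, and aggregates summary-statistic means/SDs and per-test false
#' positive rates (all populations are demographically stable, so every call
#' is a false positive).
#'
#' The null M distribution for the simulated-critical-value test is computed
#' once per cell and shared across replicates; equilibrium heterozygosities
#' are memoised by (sample size, allele count) across the whole session.
#'
#' @param ne,vk Cell coordinates.
#' @param replicates Number of replicate datasets (>= 1).
#' @param marker_type Passed to [demography_config()].
#' @param seed Cell seed; replicate seeds are spawned from it.
#' @param alpha Significance level.
#' @param tests Subset of tests to run (`NULL` = all applicable; see
#'   [test_battery()]).
#' @param n_loci,sample_size,mu Passed to [demography_config()].
#' @param n_null_sims Simulations behind the M-ratio critical value and the
#'   Tajima p-value.
#' @param heq_min_accepted Accepted simulations per Heq value.
#' @param burnin_generations Passed to [run_to_equilibrium()].
#' @param verbose Print progress.
#' @return List of class `srs_cell`: `summary` (one-row data frame),
#'   `replicates` (per-replicate statistics and calls), `n_excluded`
#'   (sequence replicates with S = 0 or batteries not applicable).
#' @export
run_cell <- function(ne, vk, replicates, marker_type = "microsat", seed = 1,
                     alpha = 0.05, tests = NULL, n_loci = 15,
                     sample_size = 50, mu = NULL, n_null_sims = 1000,
                     heq_min_accepted = 500, burnin_generations = NULL,
                     verbose = FALSE) {
  if (replicates < 1) stop("'replicates' must be >= 1")
  config <- demography_config(ne, vk, n_loci = n_loci, mu = mu,
                              sample_size = sample_size,
                              marker_type = marker_type)
  model <- offspring_model(vk)
  if (is.null(tests))
    tests <- if (marker_type == "sequence") "tajima" else
      c("m_ratio_ft", "m_ratio_sim", "het_excess")
  rep_seeds <- spawn_seeds(seed, replicates + 1L)
  null_M <- NULL
  if ("m_ratio_sim" %in% tests)
    null_M <- null_M_distribution(config$theta, n_genes = 2L * sample_size,
                                  n_loci = config$n_loci,
                                  n_sims = n_null_sims,
                                  seed = rep_seeds[replicates + 1L])

  rows <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    set.seed(rep_seeds[i])
    eq <- run_to_equilibrium(config, model,
                             burnin_generations = burnin_generations)
    ds <- sample_individuals(eq$population)
    ds$provenance$replicate <- i
    ss <- summary_stats(ds)
    if (marker_type == "sequence") {
      tj <- tajima_test(ds, alpha = alpha, n_sims = n_null_sims)
      rows[[i]] <- data.frame(replicate = i, S = ss$S, pi = ss$pi, D = ss$D,
                              tajima_p = tj$p, tajima = tj$call,
                              applicable = tj$applicable,
                              converged = isTRUE(eq$converged))
    } else {
      bt <- test_battery(ds, true_ne = ne, true_mu = config$mu,
                         alpha = alpha, null_M = null_M, tests = tests)
      row <- data.frame(replicate = i, He = ss$he, K = ss$k, Fis = ss$fis,
                        M = ss$m, pct_P = ss$pct_polymorphic,
                        converged = isTRUE(eq$converged))
      if (!is.null(bt$m_ratio_ft)) row$m_ratio_ft <- bt$m_ratio_ft$call
      if (!is.null(bt$m_ratio_sim)) row$m_ratio_sim <- bt$m_ratio_sim$call
      if (!is.null(bt$het_excess)) {
        row$het_excess <- bt$het_excess$call
        row$het_applicable <- bt$het_excess$applicable
      }
      rows[[i]] <- row
    }
    if (verbose) message(sprintf("  cell (Ne=%g, Vk=%g) replicate %d/%d",
                                 ne, vk, i, replicates))
  }
  reps <- do.call(rbind, rows)

  summ <- data.frame(ne = ne, vk = vk, ne_nc = ne_nc_ratio(vk),
                     nc = config$nc, marker_type = marker_type,
                     replicates = replicates)
  n_excluded <- 0L
  if (marker_type == "sequence") {
    valid <- reps$applicable
    n_excluded <- sum(!valid)
    summ$S_mean <- mean(reps$S)
    summ$D_mean <- mean(reps$D[valid])
    summ$D_sd <- stats::sd(reps$D[valid])
    x <- sum(reps$tajima[valid]); n <- sum(valid)
    ci <- fpr_ci(x, n)
    summ$fpr_tajima <- if (n) x / n else NA_real_
    summ$fpr_tajima_lo <- ci[1]; summ$fpr_tajima_hi <- ci[2]
    summ$n_valid <- n
  } else {
    summ$He_mean <- mean(reps$He); summ$He_sd <- stats::sd(reps$He)
    summ$K_mean <- mean(reps$K); summ$K_sd <- stats::sd(reps$K)
    summ$Fis_mean <- mean(reps$Fis, na.rm = TRUE)
    summ$Fis_sd <- stats::sd(reps$Fis, na.rm = TRUE)
    summ$M_mean <- mean(reps$M); summ$M_sd <- stats::sd(reps$M)
    summ$pct_P <- mean(reps$pct_P)
    for (t in intersect(c("m_ratio_ft", "m_ratio_sim", "het_excess"),
                        names(reps))) {
      valid <- if (t == "het_excess") reps$het_applicable else
        rep(TRUE, nrow(reps))
      x <- sum(reps[[t]][valid]); n <- sum(valid)
      ci <- fpr_ci(x, n)
      summ[[paste0("fpr_", t)]] <- if (n) x / n else NA_real_
      summ[[paste0("fpr_", t, "_lo")]] <- ci[1]
      summ[[paste0("fpr_", t, "_hi")]] <- ci[2]
      if (t == "het_excess") n_excluded <- sum(!valid)
    }
  }
  structure(list(summary = summ, replicates = reps, n_excluded = n_excluded,
                 seed = seed, alpha = alpha),
            class = "srs_cell")
}

#' @export
print.srs_cell <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run a full grid of scenarios
#'
#' Maps [run_cell()] over every cell of a [grid_spec()]; cell seeds derive
#' deterministically from the master seed, so the aggregate table is
#' bit-reproducible.
#'
#' @param spec A `grid_spec`.
#' @param ... Passed to [run_cell()].
#' @return A data frame of class `fpr_table`, one row per cell, carrying the
#'   per-cell results as the `cells` attribute.
#' @export
run_grid <- function(spec, ...) {
  stopifnot(inherits(spec, "grid_spec"))
  cell_seeds <- spawn_seeds(spec$seed, nrow(spec$cells))
  cells <- vector("list", nrow(spec$cells))
  for (i in seq_len(nrow(spec$cells))) {
    cells[[i]] <- run_cell(spec$cells$ne[i], spec$cells$vk[i],
                           replicates = spec$replicates,
                           marker_type = spec$marker_type,
                           seed = cell_seeds[i], alpha = spec$alpha, ...)
  }
  tab <- do.call(rbind, lapply(cells, function(c) c$summary))
  class(tab) <- c("fpr_table", "data.frame")
  attr(tab, "cells") <- cells
  attr(tab, "spec") <- spec
  tab
}

#' @export
print.fpr_table <- function(x, digits = 3, ...) {
  cat("False positive rates of bottleneck tests in stable populations\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an FPR table to TSV
#' @param x An `fpr_table` (or any data frame).
#' @param path Output path.
#' @export
write_fpr_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
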