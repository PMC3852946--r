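# Forward-in-time individual-based simulation: population state, one-generation
# advance (Rcpp kernel), burn-in to mutation-drift equilibrium, and sampling.

#' Initialize a population
#'
#' Microsatellite modes: per locus, allele frequencies are drawn from a
#' symmetric Dirichlet over `n_init_alleles` adjacent repeat states centred at
#' `ref_state`, and genotypes are drawn multinomially at those frequencies.
#' By default the Dirichlet concentration is chosen so the expected initial
#' homozygosity equals the stepwise-mutation equilibrium value
#' `1/sqrt(1 + 2*theta)`; the burn-in then only has to relax the allele-count
#' and frequency-spectrum shape, which is what makes an `Ne`-generation
#' burn-in sufficient (see the methods vignette).
#'
#' Sequence mode starts monomorphic (all-ancestral haplotypes); diversity is
#' built up during a longer burn-in.
#'
#' @param config A [demography_config()].
#' @param n_init_alleles Number of adjacent initial repeat states (capped at 5
#'   for constrained loci).  `NULL` keeps the default of 10 (or the window
#'   width).
#' @param dirichlet_conc Symmetric Dirichlet concentration; `NULL` (default)
#'   auto-calibrates to the equilibrium homozygosity as described above.
#' @param ref_state Reference repeat count at the centre of the initial allele
#'   range (and of the 5-state window for constrained loci).
#' @return An object of class `srs_population`.
#' @export
initialize_population <- function(config, n_init_alleles = NULL,
                                  dirichlet_conc = NULL, ref_state = 20L) {
  stopifnot(inherits(config, "demography_config"))
  nc <- config$nc

  if (config$marker_type == "sequence") {
    pop <- list(config = config,
                hap = matrix(1L, nrow = nc, ncol = 2),
                hap_sites = list(integer(0)),  # haplotype id -> derived sites
                next_hap_id = 2L,
                active_sites = integer(0),
                generation = 0L)
    class(pop) <- "srs_population"
    return(pop)
  }

  constrained <- config$marker_type == "microsat_constrained"
  win <- if (constrained) c(ref_state - 2L, ref_state + 2L) else c(NA, NA)
  m <- if (is.null(n_init_alleles)) {
    # start near the SMM equilibrium allele count (~1.5 at theta = 0.1,
    # ~3 at theta = 1) so the Ne-generation burn-in only has to refine the
    # spectrum, not shed excess alleles (which takes >> Ne generations and
    # would leave bottleneck-like gaps in the allele range)
    as.integer(max(1, round(1 + 2 * sqrt(config$theta))))
  } else {
    if (n_init_alleles < 1) stop("'n_init_alleles' must be >= 1")
    as.integer(n_init_alleles)
  }
  if (constrained) m <- min(m, 5L)
  if (is.null(dirichlet_conc)) {
    # match E[sum p^2] = (conc + 1)/(m*conc + 1) to the SMM equilibrium value
    f_eq <- 1 - smm_equilibrium_he(config$theta)
    dirichlet_conc <- if (m * f_eq > 1) (1 - f_eq) / (m * f_eq - 1) else 100
    dirichlet_conc <- min(max(dirichlet_conc, 1e-4), 100)
  }
  states <- as.integer(ref_state - (m %/% 2L) + seq_len(m) - 1L)
  if (constrained) states <- pmin(pmax(states, win[1]), win[2])

  geno <- matrix(0L, nrow = nc, ncol = 2L * config$n_loci)
  for (l in seq_len(config$n_loci)) {
    if (m == 1L) {
      geno[, c(2 * l - 1, 2 * l)] <- states
      next
    }
    w <- stats::rgamma(m, shape = dirichlet_conc)
    if (sum(w) == 0) w[sample.int(m, 1)] <- 1
    freqs <- w / sum(w)
    draws <- sample(states, size = 2L * nc, replace = TRUE, prob = freqs)
    geno[, 2 * l - 1] <- draws[seq_len(nc)]
    geno[, 2 * l] <- draws[nc + seq_len(nc)]
  }
  pop <- list(config = config, geno = geno, window = win, generation = 0L)
  class(pop) <- "srs_population"
  pop
}

#' @export
print.srs_population <- function(x, ...) {
  cat(sprintf("Population of %d individuals (%s), generation %d\n",
              x$config$nc, x$config$marker_type, x$generation))
  invisible(x)
}

# Prune lost haplotypes; free sites whose derived allele has been lost and
# re-polarise (and free) sites fixed for the derived allele.  Keeping only
# currently segregating sites occupied is what lets 500 physical sites host an
# unbounded number of mutation events over the run while every *segregating*
# site still traces back to a single mutation origin.
seq_cleanup <- function(pop) {
  counts <- seq_site_counts(pop)
  total <- 2L * nrow(pop$hap)
  seg <- which(counts > 0L & counts < total)
  ids <- unique(as.vector(pop$hap))
  new_sites <- vector("list", length(pop$hap_sites))
  for (id in ids) {
    s <- pop$hap_sites[[id]]
    new_sites[[id]] <- s[s %in% seg]
  }
  pop$hap_sites <- new_sites
  pop$active_sites <- seg
  pop
}

# Population-wide derived-allele count per physical site.
seq_site_counts <- function(pop) {
  cnt <- tabulate(pop$hap, nbins = length(pop$hap_sites))
  counts <- integer(pop$config$n_sites)
  for (id in which(cnt > 0L)) {
    s <- pop$hap_sites[[id]]
    if (length(s)) counts[s] <- counts[s] + cnt[id]
  }
  counts
}

#' Advance a population by one generation
#'
#' Random mating with the configured family-size model, Mendelian inheritance,
#' and mutation: strict stepwise (+-1 repeat) for microsatellites, reflected
#' inside the 5-state window for constrained loci, infinite-sites for
#' sequences.  The census size is constant by construction.
#'
#' @param pop An `srs_population`.
#' @param model An [offspring_model()]; its variance should match
#'   `pop$config$vk`.
#' @param mu Mutation rate override (defaults to the configured rate).
#' @return The population one generation later.
#' @export
advance_generation <- function(pop, model, mu = NULL) {
  stopifnot(inherits(pop, "srs_population"), inherits(model, "offspring_model"))
  cfg <- pop$config
  if (is.null(mu)) mu <- cfg$mu
  poisson <- model$kind == "poisson"
  fam_cdf <- if (poisson) numeric(0) else model$cdf

  if (cfg$marker_type == "sequence") {
    pop$hap <- cpp_advance_one(pop$hap, fam_cdf, poisson, 0, 0L, 0L, 0L)
    n_mut <- stats::rpois(1, mu * cfg$n_sites * 2 * cfg$nc)
    if (n_mut > 0) {
      for (i in seq_len(n_mut)) {
        if (length(pop$active_sites) > cfg$n_sites - 5L)
          pop <- seq_cleanup(pop)
        free <- setdiff(seq_len(cfg$n_sites), pop$active_sites)
        if (!length(free))
          stop("infinite-sites violation: all ", cfg$n_sites,
               " sites are simultaneously segregating")
        slot <- sample.int(2L * cfg$nc, 1)
        row <- (slot - 1L) %% cfg$nc + 1L
        col <- (slot - 1L) %/% cfg$nc + 1L
        site <- if (length(free) == 1L) free else sample(free, 1)
        parent_id <- pop$hap[row, col]
        new_id <- pop$next_hap_id
        pop$hap_sites[[new_id]] <- c(pop$hap_sites[[parent_id]], site)
        pop$next_hap_id <- new_id + 1L
        pop$active_sites <- c(pop$active_sites, site)
        pop$hap[row, col] <- new_id
      }
    }
    if (pop$generation %% 50L == 49L) pop <- seq_cleanup(pop)
  } else {
    mode <- if (cfg$marker_type == "microsat_constrained") 2L else 1L
    win <- if (mode == 2L) pop$window else c(0L, 0L)
    pop$geno <- cpp_advance_one(pop$geno, fam_cdf, poisson,
                                mu, mode, win[1], win[2])
  }
  pop$generation <- pop$generation + 1L
  pop
}

# Population-level summaries tracked during burn-in.
pop_diagnostics <- function(pop) {
  cfg <- pop$config
  if (cfg$marker_type == "sequence") {
    counts <- seq_site_counts(pop)
    n <- 2 * cfg$nc
    seg <- counts > 0L & counts < n
    s_pop <- sum(seg)
    pi_pop <- sum(2 * counts[seg] * (n - counts[seg])) / (n * (n - 1))
    return(c(K = s_pop, He = pi_pop, Fis = NA_real_))
  }
  L <- cfg$n_loci
  he <- ho <- k <- numeric(L)
  for (l in seq_len(L)) {
    a1 <- pop$geno[, 2 * l - 1]
    a2 <- pop$geno[, 2 * l]
    p <- tabulate(c(a1, a2) - min(a1, a2) + 1L)
    p <- p[p > 0] / (2 * length(a1))
    k[l] <- length(p)
    he[l] <- 1 - sum(p^2)
    ho[l] <- mean(a1 != a2)
  }
  poly <- k >= 2
  fis <- if (any(poly)) 1 - sum(ho[poly]) / sum(he[poly]) else NA_real_
  c(K = mean(k), He = mean(he), Fis = fis)
}

#' Run a population to mutation-drift equilibrium
#'
#' Advances the population for `burnin_generations`, recording population-level
#' allele counts (K), expected heterozygosity (He) and inbreeding coefficient
#' (Fis) every `check_interval` generations.  Convergence is declared when the
#' least-squares slope of the second half of the He trajectory is below
#' `slope_tol` in absolute value; non-convergence is reported, not fatal.
#'
#' @param config A [demography_config()].
#' @param model An [offspring_model()] (defaults to `offspring_model(vk)`).
#' @param burnin_generations Number of generations; `NULL` uses `ne` for
#'   microsatellite modes and `10 * ne` for sequences (which start
#'   monomorphic).  `0` returns the initial population unchanged.
#' @param check_interval Generations between diagnostic records (`NULL`:
#'   `burnin/25`).
#' @param pop Optional starting population ([initialize_population()] default).
#' @param slope_tol Convergence threshold on the He slope per generation.
#' @return A list with `population`, `diagnostics` (data frame of generation,
#'   K, He, Fis), and `converged`.
#' @export
run_to_equilibrium <- function(config, model = NULL, burnin_generations = NULL,
                               check_interval = NULL, pop = NULL,
                               slope_tol = 5e-5) {
  stopifnot(inherits(config, "demography_config"))
  if (is.null(model)) model <- offspring_model(config$vk)
  if (is.null(burnin_generations))
    burnin_generations <- if (config$marker_type == "sequence")
      10L * ceiling(config$ne) else ceiling(config$ne)
  if (is.null(pop)) pop <- initialize_population(config)
  if (burnin_generations == 0)
    return(list(population = pop,
                diagnostics = data.frame(generation = integer(0),
                                         K = numeric(0), He = numeric(0),
                                         Fis = numeric(0)),
                converged = NA))
  if (is.null(check_interval))
    check_interval <- max(1L, burnin_generations %/% 25L)

  n_checks <- burnin_generations %/% check_interval
  diag <- matrix(NA_real_, nrow = n_checks, ncol = 3,
                 dimnames = list(NULL, c("K", "He", "Fis")))
  gens <- integer(n_checks)
  ci <- 0L
  for (g in seq_len(burnin_generations)) {
    pop <- advance_generation(pop, model)
    if (g %% check_interval == 0L && ci < n_checks) {
      ci <- ci + 1L
      diag[ci, ] <- pop_diagnostics(pop)
      gens[ci] <- pop$generation
    }
  }
  diag <- data.frame(generation = gens[seq_len(ci)], diag[seq_len(ci), ,
                                                         drop = FALSE])
  converged <- NA
  half <- diag[diag$generation > max(diag$generation) / 2, , drop = FALSE]
  if (nrow(half) >= 3 && stats::sd(half$He) > 0) {
    slope <- stats::coef(stats::lm(He ~ generation, data = half))[2]
    converged <- abs(slope) < slope_tol
  } else if (nrow(half) >= 3) {
    converged <- TRUE  # flat trajectory
  }
  list(population = pop, diagnostics = diag, converged = converged)
}

# Binary (copies x sites) matrix over the full physical locus for given
# haplotype ids.
seq_site_matrix <- function(hap, hap_sites, n_sites) {
  ids <- as.vector(t(hap))  # copies ordered (ind1 copy1, ind1 copy2, ...)
  mat <- matrix(0L, nrow = length(ids), ncol = n_sites)
  for (i in seq_along(ids)) {
    s <- hap_sites[[ids[i]]]
    if (length(s)) mat[i, s] <- 1L
  }
  mat
}

#' Sample individuals from a population
#'
#' Uniform sampling without replacement; genotypes are copied into a
#' free-standing dataset, the unit consumed by summary statistics and
#' bottleneck tests.
#'
#' @param pop An `srs_population`.
#' @param n Number of individuals (defaults to the configured sample size).
#' @return An object of class `srs_dataset`: for microsatellite modes a
#'   genotype matrix `n x 2*n_loci` of repeat counts; for sequence mode a
#'   binary haplotype matrix `2n x n_sites`.
#' @export
sample_individuals <- function(pop, n = NULL) {
  stopifnot(inherits(pop, "srs_population"))
  cfg <- pop$config
  if (is.null(n)) n <- cfg$sample_size
  if (n > cfg$nc)
    stop("cannot sample ", n, " individuals from a census of ", cfg$nc)
  idx <- sample.int(cfg$nc, n)
  prov <- list(ne = cfg$ne, vk = cfg$vk, generation = pop$generation)
  if (cfg$marker_type == "sequence") {
    pop <- seq_cleanup(pop)
    seq <- seq_site_matrix(pop$hap[idx, , drop = FALSE], pop$hap_sites,
                           cfg$n_sites)
    ds <- list(marker_type = cfg$marker_type, n_ind = n, n_loci = 1L,
               n_sites = cfg$n_sites, seq = seq, provenance = prov)
  } else {
    ds <- list(marker_type = cfg$marker_type, n_ind = n,
               n_loci = cfg$n_loci,
               genotypes = pop$geno[idx, , drop = FALSE], provenance = prov)
  }
  class(ds) <- "srs_dataset"
  ds
}

#' @export
print.srs_dataset <- function(x, ...) {
  cat(sprintf("Dataset: %d individuals, %s, %d loc%s\n", x$n_ind,
              x$marker_type, x$n_loci, if (x$n_loci == 1) "us" else "i"))
  invisible(x)
}

#' Simulate one equilibrium dataset
#'
#' Convenience wrapper: build the offspring model, burn the population in to
#' mutation-drift equilibrium, and sample `sample_size` individuals.
#'
#' @param config A [demography_config()].
#' @param seed Optional integer seed (sets the session RNG).
#' @param ... Passed to [run_to_equilibrium()].
#' @return An `srs_dataset` with provenance (`ne`, `vk`, `seed`, generation).
#' @export
simulate_dataset <- function(config, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  eq <- run_to_equilibrium(config, ...)
  ds <- sample_individuals(eq$population)
  ds$provenance$seed <- seed
  ds$provenance$converged <- eq$converged
  ds
}
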