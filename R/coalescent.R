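# Kingman coalescent simulator: the Wright-Fisher (Vk = 2) null model behind
# the simulated M-ratio critical value, the equilibrium heterozygosity of the
# heterozygosity-excess test, and Tajima's D p-values.

#' Simulate a Kingman genealogy
#'
#' Standard neutral coalescent for `n_genes` sampled gene copies: while `k`
#' lineages remain, the waiting time to the next coalescence is
#' Exponential(k(k-1)/2) in coalescent units (2Ne generations) and a uniformly
#' chosen pair merges.
#'
#' @param n_genes Number of sampled gene copies (>= 2).
#' @return An object of class `srs_genealogy` recording epoch durations, the
#'   merge sequence, per-node descendant tip sets and the active lineages of
#'   each epoch.
#' @export
simulate_genealogy <- function(n_genes) {
  stopifnot(n_genes >= 2)
  n <- as.integer(n_genes)
  n_ep <- n - 1L
  times <- numeric(n_ep)
  merges <- matrix(0L, nrow = n_ep, ncol = 2)
  active <- vector("list", n_ep)
  tipsets <- vector("list", 2L * n - 1L)
  tipsets[seq_len(n)] <- as.list(seq_len(n))
  act <- seq_len(n)
  for (j in seq_len(n_ep)) {
    k <- n - j + 1L
    times[j] <- stats::rexp(1, rate = k * (k - 1) / 2)
    active[[j]] <- act
    pick <- sample.int(k, 2)
    a <- act[pick[1]]; b <- act[pick[2]]
    new_id <- n + j
    tipsets[[new_id]] <- c(tipsets[[a]], tipsets[[b]])
    act <- c(act[-pick], new_id)
    merges[j, ] <- c(a, b)
  }
  structure(list(n = n, times = times, merges = merges, active = active,
                 tipsets = tipsets),
            class = "srs_genealogy")
}

#' Height of a genealogy (time to the MRCA, coalescent units)
#' @param tree An `srs_genealogy`.
#' @export
genealogy_height <- function(tree) sum(tree$times)

#' Total branch length of a genealogy (coalescent units)
#' @param tree An `srs_genealogy`.
#' @export
genealogy_total_length <- function(tree) {
  k <- tree$n - seq_along(tree$times) + 1L
  sum(k * tree$times)
}

#' Drop mutations on a genealogy
#'
#' The number of mutations during an epoch with `k` lineages of duration `t`
#' is Poisson(k * t * theta/2); each mutation strikes a uniformly chosen
#' lineage and affects all its descendant tips.
#'
#' Under `"smm"` each mutation shifts the repeat count of the subtended tips
#' by +-1 from the ancestral state 0 (relative coding).  Under
#' `"infinite_sites"` each mutation creates a new segregating site.
#'
#' @param tree An `srs_genealogy`.
#' @param theta Population mutation parameter `4*Ne*mu` for the locus.
#' @param mutation_mode `"smm"` or `"infinite_sites"`.
#' @return For `"smm"`, an integer vector of repeat counts (one per tip).  For
#'   `"infinite_sites"`, a binary tips x sites matrix (zero columns when no
#'   mutation occurred).
#' @export
drop_mutations <- function(tree, theta,
                           mutation_mode = c("smm", "infinite_sites")) {
  mutation_mode <- match.arg(mutation_mode)
  stopifnot(inherits(tree, "srs_genealogy"), theta >= 0)
  n <- tree$n
  k <- n - seq_along(tree$times) + 1L
  m <- stats::rpois(length(tree$times), tree$times * k * theta / 2)
  if (mutation_mode == "smm") {
    x <- integer(n)
    for (j in which(m > 0L)) {
      for (i in seq_len(m[j])) {
        lin <- tree$active[[j]][sample.int(k[j], 1)]
        x[tree$tipsets[[lin]]] <- x[tree$tipsets[[lin]]] +
          sample(c(-1L, 1L), 1)
      }
    }
    x
  } else {
    cols <- vector("list", sum(m))
    ci <- 0L
    for (j in which(m > 0L)) {
      for (i in seq_len(m[j])) {
        lin <- tree$active[[j]][sample.int(k[j], 1)]
        col <- integer(n)
        col[tree$tipsets[[lin]]] <- 1L
        ci <- ci + 1L
        cols[[ci]] <- col
      }
    }
    if (ci == 0L) matrix(0L, nrow = n, ncol = 0) else
      matrix(unlist(cols), nrow = n, ncol = ci)
  }
}

# Fast path for significance simulations: (S, pi) of one infinite-sites
# coalescent sample without building a tree object.  Tracks lineage sizes
# only; a mutation on a lineage subtending i tips contributes 2*i*(n-i)/
# (n*(n-1)) to pi.
sim_infsites_spi <- function(n, theta) {
  sizes <- rep(1L, n)
  k <- n
  s <- 0L
  pi <- 0
  denom <- n * (n - 1)
  while (k > 1L) {
    t <- stats::rexp(1, rate = k * (k - 1) / 2)
    m <- stats::rpois(1, t * k * theta / 2)
    if (m > 0L) {
      hit <- sample.int(k, m, replace = TRUE)
      i <- sizes[hit]
      s <- s + m
      pi <- pi + sum(2 * i * (n - i)) / denom
    }
    pick <- sample.int(k, 2)
    sizes[pick[1]] <- sizes[pick[1]] + sizes[pick[2]]
    sizes[pick[2]] <- sizes[k]
    k <- k - 1L
  }
  c(S = s, pi = pi)
}

#' Null distribution of the dataset-mean M-ratio under the Kingman coalescent
#'
#' Each simulated dataset consists of `n_loci` independent stepwise-mutation
#' loci of `n_genes` gene copies at the supplied theta; the per-locus M-ratios
#' are averaged.  This is the Wright-Fisher (Vk = 2) null used to set the
#' critical value of the simulated M-ratio test.
#'
#' @param theta Per-locus `4*Ne*mu`.
#' @param n_genes Sampled gene copies per locus (default 100 = 50 diploids).
#' @param n_loci Loci per dataset.
#' @param n_sims Number of simulated datasets.
#' @param seed Optional seed applied in a private RNG scope (the caller's
#'   stream is left untouched).
#' @return Numeric vector of `n_sims` dataset-mean M values.
#' @export
null_M_distribution <- function(theta, n_genes = 100, n_loci = 15,
                                n_sims = 1000, seed = NULL) {
  stopifnot(theta >= 0, n_sims >= 1)
  with_rng_scope(seed, {
    vapply(seq_len(n_sims), function(i) {
      mean(vapply(seq_len(n_loci), function(l) {
        x <- drop_mutations(simulate_genealogy(n_genes), theta, "smm")
        m_ratio(x)
      }, numeric(1)))
    }, numeric(1))
  })
}

# Memo store for simulated equilibrium heterozygosities.
.heq_cache <- new.env(parent = emptyenv())

#' Equilibrium heterozygosity expected for an observed allele count
#'
#' Simulation-based analogue of the quantity the heterozygosity-excess test
#' compares sample heterozygosity against: coalescent stepwise-mutation loci
#' are simulated across a logarithmic theta grid, loci whose allele count
#' equals `k_observed` are accepted (simulation effort is steered toward
#' accepting theta values), and the mean unbiased expected heterozygosity of
#' accepted loci is returned.
#'
#' Results are memoised by `(n_genes, k_observed, min_accepted)` with a seed
#' derived from that key, so the value is a fixed deterministic function of
#' its arguments.
#'
#' @param n_genes Gene copies in the sample.
#' @param k_observed Observed allele count (1 to `n_genes`).
#' @param min_accepted Minimum number of accepted loci.
#' @param theta_grid Theta values searched.
#' @return Expected equilibrium heterozygosity given `k_observed` alleles
#'   (0 for `k_observed = 1`, without simulation).
#' @export
estimate_Heq <- function(n_genes, k_observed, min_accepted = 500,
                         theta_grid = exp(seq(log(0.05), log(50),
                                              length.out = 24))) {
  stopifnot(k_observed >= 1, k_observed <= n_genes, min_accepted >= 1)
  if (k_observed == 1) return(0)
  key <- paste(n_genes, k_observed, min_accepted, sep = "_")
  if (!is.null(.heq_cache[[key]])) return(.heq_cache[[key]])

  val <- with_rng_scope(key_seed("heq", n_genes, k_observed, min_accepted), {
    ng <- length(theta_grid)
    acc_he <- numeric(0)
    tried <- accepted <- rep(0L, ng)
    total <- 0L
    max_sims <- 400000L
    while (length(acc_he) < min_accepted) {
      if (total >= max_sims)
        stop("estimation error: allele count k = ", k_observed,
             " not attainable within the simulation budget")
      # steer effort toward theta values that accept, keeping exploration alive
      w <- (accepted + 1) / (tried + 2)
      batch <- pmax(2L, as.integer(round(40 * w / sum(w))))
      for (g in seq_len(ng)) {
        for (b in seq_len(batch[g])) {
          x <- drop_mutations(simulate_genealogy(n_genes), theta_grid[g],
                              "smm")
          tried[g] <- tried[g] + 1L
          total <- total + 1L
          if (length(unique(x)) == k_observed) {
            accepted[g] <- accepted[g] + 1L
            acc_he <- c(acc_he, expected_heterozygosity(x))
          }
        }
      }
    }
    mean(acc_he)
  })
  .heq_cache[[key]] <- val
  val
}
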