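# Independent oracles used across the suite.  These deliberately use naive
# enumeration / direct formulas, not the package's own code paths.

# Tajima's D by brute force: explicit pairwise difference count and the 1989
# constants computed from scratch.
oracle_tajima_d <- function(seqmat) {
  n <- nrow(seqmat)
  diffs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) diffs <- diffs + sum(seqmat[i, ] != seqmat[j, ])
  }
  pi <- diffs / choose(n, 2)
  d <- colSums(seqmat)
  s <- sum(d > 0 & d < n)
  if (s == 0) return(c(S = 0, pi = pi, D = NA_real_))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  c(S = s, pi = pi, D = (pi - s / a1) / sqrt(e1 * s + e2 * s * (s - 1)))
}

# Exact one-tailed (greater) Wilcoxon signed-rank p-value by enumerating all
# 2^n sign assignments of the absolute values (no ties assumed).
oracle_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  mean(w_all >= w_obs)
}

# Expected number of distinct parents of one offspring generation, from the
# family-size distribution alone: replay the pairing/truncation process
# without any genetics.
oracle_distinct_parents <- function(model, nc, reps) {
  mean(replicate(reps, {
    filled <- 0
    parents <- integer(0)
    pool <- sample.int(nc)
    pos <- 1
    while (filled < nc) {
      if (pos + 1 > nc) { pool <- sample.int(nc); pos <- 1 }
      fam <- draw_family_sizes(model, 1)
      if (fam > 0) {
        parents <- c(parents, pool[pos], pool[pos + 1])
        filled <- filled + min(fam, nc - filled)
      }
      pos <- pos + 2
    }
    length(unique(parents))
  }))
}

# Tiny microsatellite dataset built by hand from a genotype matrix
# (individuals x 2*loci).
make_ms_dataset <- function(geno, marker_type = "microsat") {
  ds <- list(marker_type = marker_type, n_ind = nrow(geno),
             n_loci = ncol(geno) / 2L, genotypes = geno,
             provenance = list(ne = NA, vk = NA))
  class(ds) <- "srs_dataset"
  ds
}

make_seq_dataset <- function(seqmat) {
  ds <- list(marker_type = "sequence", n_ind = nrow(seqmat) %/% 2L,
             n_loci = 1L, n_sites = ncol(seqmat), seq = seqmat,
             provenance = list(ne = NA, vk = NA))
  class(ds) <- "srs_dataset"
  ds
}
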