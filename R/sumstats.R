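# Per-dataset summary statistics: He, Ho, K, Fis, M-ratio, %P for
# microsatellites; S, pi and Tajima's D for sequences.

#' Unbiased expected heterozygosity of one locus
#'
#' Nei's unbiased estimator `(n/(n-1)) * (1 - sum(p_i^2))` over `n` gene
#' copies.
#'
#' @param alleles Vector of allelic states (one entry per gene copy).
#' @return Expected heterozygosity in `[0, 1]` (0 for a monomorphic or
#'   single-copy locus).
#' @export
expected_heterozygosity <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  n <- length(alleles)
  if (n < 2) return(0)
  p <- as.vector(table(alleles)) / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' M-ratio (occupied over possible allelic states) of one microsatellite locus
#'
#' Garza-Williamson convention: the number of distinct repeat states divided
#' by the inclusive allele-size range `max - min + 1`.  Gaps in the range pull
#' M below 1; a monomorphic locus has M = 1 (no evidence of gaps).
#'
#' @param alleles Integer repeat counts (one entry per gene copy).
#' @return M in `(0, 1]`.
#' @export
m_ratio <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  u <- unique(alleles)
  if (length(u) <= 1) return(1)
  length(u) / (max(u) - min(u) + 1)
}

#' Multilocus inbreeding coefficient
#'
#' `Fis = 1 - sum(Ho)/sum(He)` over polymorphic loci (ratio of averages, for
#' stability at low polymorphism), with He the unbiased estimator.  Negative
#' values indicate heterozygote excess, the Hardy-Weinberg deviation produced
#' by sib-dominated generations under sweepstakes reproduction.
#'
#' @param dataset A microsatellite `srs_dataset`.
#' @return Fis in `[-1, 1]`, or `NA` (flagged via a warning) when all loci are
#'   monomorphic.
#' @export
f_is <- function(dataset) {
  ss <- summary_stats(dataset)
  if (is.na(ss$fis)) warning("Fis undefined: all loci monomorphic")
  ss$fis
}

# Tajima (1989) constants for sample size n (number of sequences).
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# D from (n, S, pi); NA when S = 0.
tajima_d_from_counts <- function(n, s, pi) {
  if (s == 0) return(NA_real_)
  k <- tajima_constants(n)
  v <- k$e1 * s + k$e2 * s * (s - 1)
  if (v <= 0) return(NA_real_)  # n = 2: pi == S/a1 by construction
  (pi - s / k$a1) / sqrt(v)
}

#' Tajima's D of a haplotype sample
#'
#' Compares the mean pairwise difference (pi) with the scaled number of
#' segregating sites (S/a1); positive values indicate a deficit of rare
#' variants, the pattern expected after a population decline -- or, as
#' simulated here, under high variance in reproductive success.
#'
#' @param seqmat Binary matrix, one row per sequence, one column per site
#'   (0 ancestral / 1 derived).
#' @return Named vector `c(S, pi, D)`; `D` is `NA` when `S = 0` (the statistic
#'   is undefined and such samples are excluded from means).
#' @export
tajimas_d <- function(seqmat) {
  stopifnot(is.matrix(seqmat), nrow(seqmat) >= 2)
  n <- nrow(seqmat)
  d <- colSums(seqmat)
  seg <- d > 0 & d < n
  s <- sum(seg)
  pi <- if (s) sum(2 * d[seg] * (n - d[seg])) / (n * (n - 1)) else 0
  c(S = s, pi = pi, D = tajima_d_from_counts(n, s, pi))
}

# Gene copies of locus l as a single vector.
locus_alleles <- function(dataset, l) {
  c(dataset$genotypes[, 2 * l - 1], dataset$genotypes[, 2 * l])
}

#' Summary statistics of a dataset
#'
#' Microsatellite modes: per-locus and dataset-mean He (unbiased), Ho, allele
#' count K, M-ratio, multilocus Fis and the percentage of polymorphic loci
#' (K >= 2).  Sequence mode: segregating sites S, mean pairwise difference pi,
#' and Tajima's D.
#'
#' @param dataset An `srs_dataset`.
#' @return A list of class `srs_sumstats`.
#' @export
summary_stats <- function(dataset) {
  stopifnot(inherits(dataset, "srs_dataset"))
  if (dataset$marker_type == "sequence") {
    td <- tajimas_d(dataset$seq)
    out <- list(marker_type = "sequence", S = unname(td["S"]),
                pi = unname(td["pi"]), D = unname(td["D"]))
    class(out) <- "srs_sumstats"
    return(out)
  }
  L <- dataset$n_loci
  he <- ho <- k <- m <- numeric(L)
  for (l in seq_len(L)) {
    a <- locus_alleles(dataset, l)
    he[l] <- expected_heterozygosity(a)
    ho[l] <- mean(dataset$genotypes[, 2 * l - 1] != dataset$genotypes[, 2 * l])
    k[l] <- length(unique(a))
    m[l] <- m_ratio(a)
  }
  poly <- k >= 2
  fis <- if (any(poly)) 1 - sum(ho[poly]) / sum(he[poly]) else NA_real_
  out <- list(marker_type = dataset$marker_type,
              locus = data.frame(He = he, Ho = ho, K = k, M = m),
              he = mean(he), ho = mean(ho), k = mean(k), fis = fis,
              m = mean(m), pct_polymorphic = 100 * mean(poly))
  class(out) <- "srs_sumstats"
  out
}

#' @export
print.srs_sumstats <- function(x, ...) {
  if (x$marker_type == "sequence") {
    cat(sprintf("Sequence sample: S = %d, pi = %.4f, Tajima's D = %s\n",
                x$S, x$pi, ifelse(is.na(x$D), "NA (S = 0)",
                                  sprintf("%.3f", x$D))))
  } else {
    cat(sprintf(
      "Microsatellite sample (%d loci): He = %.3f, K = %.2f, Fis = %s, M = %.3f, %%P = %.0f\n",
      nrow(x$locus), x$he, x$k,
      ifelse(is.na(x$fis), "NA", sprintf("%.3f", x$fis)), x$m,
      x$pct_polymorphic))
  }
  invisible(x)
}

#' Write one dataset's summary statistics as a TSV table row
#'
#' One row per dataset, columns He, K, Fis, M, %P (plus S, pi, D for
#' sequences); appends when the file exists.
#'
#' @param stats An `srs_sumstats`.
#' @param path Output TSV path.
#' @export
write_sumstats_tsv <- function(stats, path) {
  stopifnot(inherits(stats, "srs_sumstats"))
  row <- if (stats$marker_type == "sequence") {
    data.frame(S = stats$S, pi = stats$pi, D = stats$D)
  } else {
    data.frame(He = stats$he, K = stats$k, Fis = stats$fis, M = stats$m,
               pct_P = stats$pct_polymorphic)
  }
  utils::write.table(row, path, sep = "\t", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path),
                     quote = FALSE)
  invisible(path)
}
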