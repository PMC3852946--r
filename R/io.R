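# File interchange: Genepop for microsatellite datasets (so real data can be
# fed to the test battery) and FASTA for sequence haplotypes.

#' Write a microsatellite dataset in Genepop format
#'
#' Repeat counts are written as 3-digit alleles, both copies concatenated
#' (6 digits per locus), one population block.
#'
#' @param dataset Microsatellite `srs_dataset`.
#' @param path Output file.
#' @param title First (comment) line of the file.
#' @export
write_genepop <- function(dataset, path, title = "srsfpr simulated dataset") {
  stopifnot(inherits(dataset, "srs_dataset"),
            dataset$marker_type != "sequence")
  g <- dataset$genotypes
  if (any(g < 0 | g > 999)) stop("repeat counts outside 3-digit coding")
  lines <- c(title, paste0("locus", seq_len(dataset$n_loci)), "Pop")
  for (i in seq_len(dataset$n_ind)) {
    loci <- vapply(seq_len(dataset$n_loci), function(l)
      sprintf("%03d%03d", g[i, 2 * l - 1], g[i, 2 * l]), character(1))
    lines <- c(lines, paste0("ind", i, " , ", paste(loci, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Genepop file into a dataset
#'
#' Accepts the 2- or 3-digit-per-allele diploid encoding with loci on
#' separate lines or one comma-separated line; multiple `Pop` blocks are
#' pooled.
#'
#' @param path Genepop file.
#' @return A microsatellite `srs_dataset`.
#' @export
read_genepop <- function(path) {
  raw <- trimws(readLines(path))
  raw <- raw[nzchar(raw)]
  pop_idx <- grep("^pop$", raw, ignore.case = TRUE)
  if (!length(pop_idx)) stop("not a Genepop file: no 'Pop' line")
  header <- raw[2:(pop_idx[1] - 1)]
  loci <- unlist(strsplit(paste(header, collapse = ","), ","))
  loci <- trimws(loci[nzchar(trimws(loci))])
  L <- length(loci)
  ind_lines <- raw[-seq_len(pop_idx[1])]
  ind_lines <- ind_lines[!grepl("^pop$", ind_lines, ignore.case = TRUE)]
  n <- length(ind_lines)
  geno <- matrix(NA_integer_, nrow = n, ncol = 2L * L)
  for (i in seq_len(n)) {
    parts <- strsplit(ind_lines[i], ",")[[1]]
    if (length(parts) < 2) stop("malformed Genepop individual line: ",
                                ind_lines[i])
    fields <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                       "[[:space:]]+")[[1]]
    if (length(fields) != L) stop("expected ", L, " loci, got ",
                                  length(fields))
    w <- nchar(fields[1]) / 2
    if (!w %in% c(2, 3)) stop("unsupported allele coding width: ", w * 2)
    geno[i, seq(1, 2 * L, by = 2)] <-
      as.integer(substr(fields, 1, w))
    geno[i, seq(2, 2 * L, by = 2)] <-
      as.integer(substr(fields, w + 1, 2 * w))
  }
  ds <- list(marker_type = "microsat", n_ind = n, n_loci = L,
             genotypes = geno,
             provenance = list(source = path))
  class(ds) <- "srs_dataset"
  ds
}

#' Write sequence haplotypes as FASTA
#'
#' Binary states are encoded as nucleotides (0 = A, 1 = T).
#'
#' @param dataset Sequence `srs_dataset`.
#' @param path Output file.
#' @export
write_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "srs_dataset"),
            dataset$marker_type == "sequence")
  chars <- matrix(c("a", "t")[dataset$seq + 1L], nrow = nrow(dataset$seq))
  rownames(chars) <- sprintf("hap%03d", seq_len(nrow(chars)))
  ape::write.dna(chars, path, format = "fasta", colsep = "")
  invisible(path)
}

#' Read FASTA haplotypes into a sequence dataset
#'
#' Inverse of [write_fasta()]: A is read as ancestral (0), anything else as
#' derived (1).
#'
#' @param path FASTA file of equal-length haplotypes.
#' @return A sequence `srs_dataset` (two haplotypes per individual).
#' @export
read_fasta_dataset <- function(path) {
  dna <- ape::read.FASTA(path)
  mat <- as.character(as.matrix(dna))
  seq <- matrix(as.integer(tolower(mat) != "a"), nrow = nrow(mat))
  ds <- list(marker_type = "sequence", n_ind = nrow(seq) %/% 2L,
             n_loci = 1L, n_sites = ncol(seq), seq = seq,
             provenance = list(source = path))
  class(ds) <- "srs_dataset"
  ds
}
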