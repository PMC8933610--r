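#' Allele frequency table
#'
#' Populations x loci table of counted-allele frequencies together with the
#' per-cell allele-copy denominators. Frequencies are only defined where
#' `n_alleles > 0`.
#'
#' @param freq Numeric matrix, populations x loci, values in `[0, 1]` or
#'   `NA`.
#' @param n_alleles Integer matrix of the same shape: number of sampled
#'   allele copies (2 x individuals with data). If a single number, it is
#'   recycled.
#' @param population_ids,locus_ids Optional dimnames overrides.
#' @param flipped Optional logical vector marking loci whose orientation
#'   was flipped by [minor_allele_orientation()].
#' @return An object of class `allele_freq_table` with fields `freq`,
#'   `n_alleles`, `population_ids`, `locus_ids`, `flipped`.
#' @export
allele_freq_table <- function(freq, n_alleles, population_ids = NULL,
                              locus_ids = NULL, flipped = NULL) {
  freq <- as.matrix(freq)
  if (length(n_alleles) == 1) {
    n_alleles <- matrix(as.integer(n_alleles), nrow(freq), ncol(freq))
  }
  n_alleles <- as.matrix(n_alleles)
  storage.mode(n_alleles) <- "integer"
  if (!all(dim(freq) == dim(n_alleles)))
    stop("`freq` and `n_alleles` must have the same shape")
  if (is.null(population_ids)) {
    population_ids <- rownames(freq)
    if (is.null(population_ids)) population_ids <- paste0("pop", seq_len(nrow(freq)))
  }
  if (is.null(locus_ids)) {
    locus_ids <- colnames(freq)
    if (is.null(locus_ids)) locus_ids <- paste0("loc", seq_len(ncol(freq)))
  }
  v <- freq[!is.na(freq)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) stop("frequencies must lie in [0, 1]")
  if (any(n_alleles < 0, na.rm = TRUE)) stop("`n_alleles` must be nonnegative")
  freq[n_alleles == 0 | is.na(n_alleles)] <- NA_real_
  dimnames(freq) <- dimnames(n_alleles) <- list(population_ids, locus_ids)
  if (is.null(flipped)) flipped <- rep(FALSE, ncol(freq))
  structure(list(freq = freq, n_alleles = n_alleles,
                 population_ids = population_ids, locus_ids = locus_ids,
                 flipped = flipped),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("allele_freq_table:", nrow(x$freq), "populations x", ncol(x$freq),
      "loci;", sum(x$flipped), "loci flipped to minor orientation\n")
  invisible(x)
}

#' Orient loci to the minor allele
#'
#' Flips each locus (`freq -> 1 - freq`) whenever the pooled,
#' sample-size-weighted mean frequency across populations exceeds 0.5, so
#' the counted allele is the pooled minor allele (an ad hoc stand-in for
#' the derived allele when outgroup information is unavailable). A pooled
#' mean of exactly 0.5 keeps the current orientation.
#'
#' @param t An [allele_freq_table()].
#' @return The table with flipped loci and updated `flipped` flags.
#' @export
minor_allele_orientation <- function(t) {
  stopifnot(inherits(t, "allele_freq_table"))
  w <- t$n_alleles
  w[is.na(t$freq)] <- 0L
  num <- colSums(t$freq * w, na.rm = TRUE)
  den <- colSums(w)
  pooled <- ifelse(den > 0, num / den, NA_real_)
  flip <- !is.na(pooled) & pooled > 0.5
  t$freq[, flip] <- 1 - t$freq[, flip, drop = FALSE]
  t$flipped <- unname(xor(t$flipped, flip))
  t
}

#' Write / read a numeric matrix as TSV with a leading id column
#'
#' All tabular outputs of the package are TSV with a header row and a
#' leading id column holding row names (population-major).
#'
#' @param x Numeric matrix with row names.
#' @param path Output path.
#' @param id_name Header of the leading id column.
#' @return `path` (write) or a numeric matrix with row names (read).
#' @export
write_matrix_tsv <- function(x, path, id_name = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE)
  colnames(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write or read an allele frequency table as a TSV pair
#'
#' Writes `<stem>.freq.tsv` and `<stem>.n.tsv` (frequencies and allele-copy
#' denominators), both populations x loci.
#'
#' @param t An [allele_freq_table()].
#' @param stem Path stem.
#' @return The stem (write); an [allele_freq_table()] (read). If the
#'   `.n.tsv` file is absent on read, denominators are taken as `n_default`.
#' @param n_default Denominator to assume when no `.n.tsv` file exists.
#' @export
write_freq_tsv <- function(t, stem) {
  write_matrix_tsv(t$freq, paste0(stem, ".freq.tsv"), "population")
  write_matrix_tsv(t$n_alleles, paste0(stem, ".n.tsv"), "population")
  invisible(stem)
}

#' @rdname write_freq_tsv
#' @export
read_freq_tsv <- function(stem, n_default = 100L) {
  fp <- if (file.exists(stem)) stem else paste0(stem, ".freq.tsv")
  freq <- read_matrix_tsv(fp)
  np <- paste0(sub("\\.freq\\.tsv$", "", fp), ".n.tsv")
  n <- if (file.exists(np)) read_matrix_tsv(np) else
    matrix(n_default, nrow(freq), ncol(freq), dimnames = dimnames(freq))
  allele_freq_table(freq, n)
}
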