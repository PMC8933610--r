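#' Write allele counts in TreeMix input format
#'
#' Produces the whitespace table TreeMix reads: a header of population ids
#' and one row per locus of `countA,countB` pairs, where `countA` is the
#' counted-allele copy number `round(freq * n_alleles)` and `countB` the
#' remainder. Missing cells are written as `0,0`. A `.gz` suffix writes a
#' gzip stream.
#'
#' @param t An [allele_freq_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_treemix_input <- function(t, path) {
  stopifnot(inherits(t, "allele_freq_table"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(t$population_ids, collapse = " "), con)
  cA <- round(t$freq * t$n_alleles)
  cB <- t$n_alleles - cA
  cA[is.na(cA)] <- 0; cB[is.na(cB)] <- 0
  rows <- vapply(seq_len(ncol(t$freq)), function(l)
    paste(paste0(cA[, l], ",", cB[, l]), collapse = " "), "")
  writeLines(rows, con)
  invisible(path)
}

#' Read a TreeMix allele-count input file
#'
#' Inverse of [write_treemix_input()]. Cells with zero total count become
#' missing frequencies.
#'
#' @param path Path to a TreeMix frequency file (optionally `.gz`).
#' @param locus_ids Optional locus identifiers.
#' @return An [allele_freq_table()].
#' @export
read_treemix_input <- function(path, locus_ids = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  pops <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  L <- length(body)
  cA <- matrix(0L, length(pops), L)
  nt <- matrix(0L, length(pops), L)
  for (l in seq_len(L)) {
    cells <- strsplit(trimws(body[l]), "\\s+")[[1]]
    if (length(cells) != length(pops))
      stop("row ", l, ": expected ", length(pops), " populations")
    parts <- matrix(as.integer(unlist(strsplit(cells, ","))), nrow = 2)
    cA[, l] <- parts[1, ]
    nt[, l] <- parts[1, ] + parts[2, ]
  }
  freq <- ifelse(nt > 0, cA / nt, NA_real_)
  rownames(freq) <- rownames(nt) <- pops
  if (!is.null(locus_ids)) colnames(freq) <- colnames(nt) <- locus_ids
  allele_freq_table(freq, nt)
}
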