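#' Genotype matrix container
#'
#' Holds diploid SNP dosages for a set of individuals grouped into
#' populations. Dosage counts copies of the alternate (non-reference)
#' allele, so values are 0, 1, 2 or `NA` for missing genotypes.
#'
#' @param dosage Integer matrix, individuals x loci, entries in
#'   `{0, 1, 2, NA}`.
#' @param population Character or factor of length `nrow(dosage)` assigning
#'   each individual to exactly one population.
#' @param individual_ids Optional individual identifiers (default: row
#'   names of `dosage`, or `ind1..indN`).
#' @param locus_ids Optional locus identifiers (default: column names of
#'   `dosage`, or `loc1..locL`). Must be unique.
#' @param gene_of Optional named character vector mapping locus ids to gene
#'   ids (used by [top_snp_per_gene()]).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, population, individual_ids = NULL,
                            locus_ids = NULL, gene_of = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(individual_ids)) {
    individual_ids <- rownames(dosage)
    if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(dosage)))
  }
  if (is.null(locus_ids)) {
    locus_ids <- colnames(dosage)
    if (is.null(locus_ids)) locus_ids <- paste0("loc", seq_len(ncol(dosage)))
  }
  if (anyDuplicated(locus_ids)) stop("locus ids must be unique")
  if (length(population) != nrow(dosage))
    stop("`population` must assign every individual to one population")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(individual_ids, locus_ids)
  if (!is.null(gene_of)) {
    if (is.null(names(gene_of))) stop("`gene_of` must be named by locus id")
    gene_of <- gene_of[intersect(locus_ids, names(gene_of))]
  }
  structure(list(dosage = dosage,
                 individual_ids = individual_ids,
                 population = as.character(population),
                 locus_ids = locus_ids,
                 gene_of = gene_of),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$individual_ids), "individuals,",
      length(x$locus_ids), "loci,",
      length(unique(x$population)), "populations\n")
  invisible(x)
}

#' Read a Genepop genotype file
#'
#' Parses the Genepop text format (title line, locus names, `POP`-delimited
#' population blocks, 2- or 3-digit diploid allele codes; `0000`/`000000`
#' denotes a missing genotype). Biallelic loci are encoded as dosage of the
#' alternate allele, where the reference allele is the numerically smallest
#' allele code observed at the locus.
#'
#' Populations are labelled `pop1..popK` in block order unless `pop_names`
#' is supplied.
#'
#' @param path Path to a Genepop file.
#' @param drop_multiallelic Drop loci with more than two observed alleles
#'   (with a warning) instead of raising an error.
#' @param pop_names Optional character vector of population labels, one per
#'   `POP` block.
#' @return A [genotype_matrix()].
#' @export
read_genepop <- function(path, drop_multiallelic = FALSE, pop_names = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a Genepop file: fewer than 3 non-empty lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a Genepop file: no POP line found")
  # locus names: lines 2..(first_pop-1), possibly comma-separated
  locus_ids <- trimws(unlist(strsplit(lines[2:(first_pop - 1)], ",")))
  locus_ids <- locus_ids[nzchar(locus_ids)]
  L <- length(locus_ids)
  pop_starts <- which(is_pop)
  K <- length(pop_starts)
  pop_ends <- c(pop_starts[-1] - 1, length(lines))
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(K))
  if (length(pop_names) != K) stop("`pop_names` must have one label per POP block")

  ids <- character(0); pops <- character(0); allele_rows <- list()
  width <- NA_integer_
  for (b in seq_len(K)) {
    rng <- seq(pop_starts[b] + 1, pop_ends[b])
    if (rng[1] > pop_ends[b]) next
    for (li in rng) {
      parts <- strsplit(lines[li], ",")[[1]]
      if (length(parts) < 2)
        stop("malformed Genepop individual line ", li, ": missing comma")
      id <- trimws(parts[1])
      genos <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
      if (length(genos) != L)
        stop("line ", li, ": expected ", L, " genotypes, found ", length(genos))
      nc <- unique(nchar(genos))
      if (length(nc) != 1 || !nc %in% c(4L, 6L))
        stop("line ", li, ": allele codes must be uniformly 2- or 3-digit")
      w <- nc / 2L
      if (is.na(width)) width <- w
      if (w != width) stop("line ", li, ": inconsistent allele code width")
      a1 <- substr(genos, 1L, width)
      a2 <- substr(genos, width + 1L, 2L * width)
      ids <- c(ids, id)
      pops <- c(pops, pop_names[b])
      allele_rows[[length(allele_rows) + 1L]] <- rbind(a1, a2)
    }
  }
  n <- length(ids)
  if (n == 0) stop("Genepop file contains no individuals")
  miss <- strrep("0", width)
  a1m <- t(vapply(allele_rows, function(m) m[1, ], character(L)))
  a2m <- t(vapply(allele_rows, function(m) m[2, ], character(L)))
  if (L == 1) { a1m <- matrix(a1m, ncol = 1); a2m <- matrix(a2m, ncol = 1) }
  dosage <- matrix(NA_integer_, n, L)
  multi <- logical(L)
  for (l in seq_len(L)) {
    al <- c(a1m[, l], a2m[, l])
    ok <- al != miss
    codes <- sort(unique(al[ok]))
    if (length(codes) > 2) {
      if (drop_multiallelic) { multi[l] <- TRUE; next }
      stop("locus '", locus_ids[l], "' has ", length(codes),
           " alleles; rerun with drop_multiallelic = TRUE to drop it")
    }
    alt <- if (length(codes) == 2) codes[2] else NA_character_
    called <- a1m[, l] != miss & a2m[, l] != miss
    d <- rep(NA_integer_, n)
    if (is.na(alt)) {
      d[called] <- 0L
    } else {
      d[called] <- (a1m[called, l] == alt) + (a2m[called, l] == alt)
    }
    dosage[, l] <- d
  }
  if (any(multi)) {
    warning("dropped ", sum(multi), " multiallelic loci")
    dosage <- dosage[, !multi, drop = FALSE]
    locus_ids <- locus_ids[!multi]
  }
  genotype_matrix(dosage, pops, individual_ids = ids, locus_ids = locus_ids)
}

#' Write a genotype matrix in Genepop format
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @param digits Allele code width, 2 (default) or 3. Reference allele is
#'   written as code 1 and the alternate as code 2.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, path, digits = 2, title = "setscape export") {
  stopifnot(inherits(g, "genotype_matrix"), digits %in% c(2, 3))
  fmt <- function(code) formatC(code, width = digits, flag = "0")
  geno_codes <- c(paste0(fmt(1), fmt(1)), paste0(fmt(1), fmt(2)),
                  paste0(fmt(2), fmt(2)))
  miss <- strrep("0", 2 * digits)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(g$locus_ids, con)
  for (p in unique(g$population)) {
    writeLines("POP", con)
    for (i in which(g$population == p)) {
      d <- g$dosage[i, ]
      gstr <- ifelse(is.na(d), miss, geno_codes[d + 1L])
      writeLines(paste0(g$individual_ids[i], " , ", paste(gstr, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Per-population allele frequencies from genotypes
#'
#' Computes the alternate-allele frequency and the number of successfully
#' genotyped allele copies (`2 x` called individuals) for every population
#' and locus. Missing dosages are excluded from numerator and denominator;
#' a population with zero called alleles at a locus gets a missing
#' frequency.
#'
#' @param g A [genotype_matrix()].
#' @return An [allele_freq_table()].
#' @export
frequencies_from_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- unique(g$population)
  L <- length(g$locus_ids)
  freq <- matrix(NA_real_, length(pops), L,
                 dimnames = list(pops, g$locus_ids))
  n_alleles <- matrix(0L, length(pops), L,
                      dimnames = list(pops, g$locus_ids))
  for (p in pops) {
    d <- g$dosage[g$population == p, , drop = FALSE]
    called <- colSums(!is.na(d))
    tot <- colSums(d, na.rm = TRUE)
    n_alleles[p, ] <- 2L * called
    freq[p, ] <- ifelse(called > 0, tot / (2 * called), NA_real_)
  }
  allele_freq_table(freq, n_alleles)
}
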