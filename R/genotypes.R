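#' Construct a diploid genotype table
#'
#' The raw-data surface for codominant markers (allozymes): one row per
#' individual, one column per locus, each non-missing cell an unordered pair
#' of allele labels.  Alleles are short case-sensitive strings; the
#' alphabetical labelling convention of allozyme gels is cosmetic only, no
#' statistic depends on label order.
#'
#' @param calls character matrix (individuals x loci) of cells like `"a/b"`,
#'   `"a/a"`, or `NA` for missing; rownames are individual IDs, colnames locus
#'   names.
#' @param site optional character vector of site labels per individual.
#' @param group optional character vector of a-priori group labels.
#' @return an object of class `genotype_table` with components `individuals`,
#'   `loci`, `allele1`, `allele2` (character matrices, pair stored sorted),
#'   `site`, `group`.
#' @export
genotype_table <- function(calls, site = NULL, group = NULL) {
  if (!is.matrix(calls) || !is.character(calls))
    stop_validation("calls must be a character matrix")
  ids <- rownames(calls)
  loci <- colnames(calls)
  if (is.null(ids) || is.null(loci))
    stop_validation("calls must have individual IDs as rownames and locus names as colnames")
  if (anyDuplicated(ids))
    stop_validation("duplicate individual IDs: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  a1 <- a2 <- matrix(NA_character_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  for (j in seq_len(ncol(calls))) {
    for (i in seq_len(nrow(calls))) {
      cell <- calls[i, j]
      if (is.na(cell) || cell == "" || cell == "?") next
      parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2L || any(!nzchar(parts)))
        stop_parse("malformed genotype '", cell, "' for individual '", ids[i],
                   "' at locus '", loci[j], "': expected two '/'-separated alleles")
      parts <- sort(parts)
      a1[i, j] <- parts[1]; a2[i, j] <- parts[2]
    }
  }
  typed <- rowSums(!is.na(a1))
  if (any(typed == 0L))
    stop_validation("individual(s) with no typed locus: ",
                    paste(ids[typed == 0L], collapse = ", "))
  if (!is.null(site) && length(site) != length(ids))
    stop_validation("site labels must match the number of individuals")
  if (!is.null(group) && length(group) != length(ids))
    stop_validation("group labels must match the number of individuals")
  structure(list(individuals = ids, loci = loci, allele1 = a1, allele2 = a2,
                 site = site %||% rep(NA_character_, length(ids)),
                 group = group %||% rep(NA_character_, length(ids))),
            class = "genotype_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table:", length(x$individuals), "individuals x",
      length(x$loci), "loci\n")
  miss <- mean(is.na(x$allele1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  if (!all(is.na(x$group)))
    cat("  a-priori groups:", paste(unique(stats::na.omit(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype table by individuals
#'
#' @param x a `genotype_table`.
#' @param individuals character vector of individual IDs to keep.
#' @return a `genotype_table` restricted to those individuals.
#' @export
subset_individuals <- function(x, individuals) {
  stopifnot(inherits(x, "genotype_table"))
  keep <- match(individuals, x$individuals)
  if (anyNA(keep))
    stop_validation("unknown individual IDs: ",
                    paste(individuals[is.na(keep)], collapse = ", "))
  structure(list(individuals = x$individuals[keep], loci = x$loci,
                 allele1 = x$allele1[keep, , drop = FALSE],
                 allele2 = x$allele2[keep, , drop = FALSE],
                 site = x$site[keep], group = x$group[keep]),
            class = "genotype_table")
}

#' Read a delimited genotype file
#'
#' Expects columns `id`, `site`, `group` followed by one column per locus;
#' comma- or tab-delimited (auto-detected from the header line).  Cells are
#' `"a/b"`, `"a/a"`, or empty/`"?"` for missing.
#'
#' @param path file path.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                          check.names = FALSE, na.strings = NULL,
                          quote = "\"", comment.char = "#")
  need <- c("id", "site", "group")
  if (!all(need %in% names(df)[1:3]))
    stop_parse("genotype file must start with columns id, site, group; got: ",
               paste(names(df)[1:3], collapse = ", "))
  loci <- setdiff(names(df), need)
  if (!length(loci)) stop_parse("genotype file has no locus columns")
  calls <- as.matrix(df[, loci, drop = FALSE])
  rownames(calls) <- df$id
  grp <- df$group
  grp[grp == ""] <- NA_character_
  genotype_table(calls, site = df$site, group = grp)
}

#' Write a genotype table to a delimited file
#'
#' @param gt a `genotype_table`.
#' @param path output path.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path, sep = "\t") {
  stopifnot(inherits(gt, "genotype_table"))
  calls <- ifelse(is.na(gt$allele1), "",
                  paste(gt$allele1, gt$allele2, sep = "/"))
  dim(calls) <- dim(gt$allele1)
  df <- data.frame(id = gt$individuals,
                   site = ifelse(is.na(gt$site), "", gt$site),
                   group = ifelse(is.na(gt$group), "", gt$group),
                   calls, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", "site", "group", gt$loci)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-group allele frequencies
#'
#' Tabulates allele frequencies and gene-copy counts per group and locus.
#' Missing calls are simply not counted: the gene-copy count `2n` at a locus
#' is twice the number of individuals actually typed there (pairwise-deletion
#' convention), so frequencies at a typed locus always sum to 1.
#'
#' @param gt a [genotype_table()].
#' @param grouping named character vector mapping every individual ID to a
#'   group label; defaults to the table's `group` column.  Use
#'   `grouping = "individual"` to treat each individual as its own group
#'   (the profile used for individual-level distance matrices).
#' @return a named list of `allele_freq_profile` objects, one per group, each
#'   with components `group`, `freqs` (per-locus named numeric vector of
#'   allele frequencies) and `n_copies` (per-locus gene-copy count; 0 flags an
#'   untyped locus).
#' @export
allele_frequencies <- function(gt, grouping = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  if (identical(grouping, "individual")) {
    grouping <- stats::setNames(gt$individuals, gt$individuals)
  } else if (is.null(grouping)) {
    if (all(is.na(gt$group)))
      stop_validation("no grouping supplied and genotype table has no group labels")
    grouping <- stats::setNames(gt$group, gt$individuals)
  }
  if (!all(gt$individuals %in% names(grouping)))
    stop_validation("grouping must cover every individual")
  g <- grouping[gt$individuals]
  if (anyNA(g)) stop_validation("grouping has NA for some individuals")
  lapply(stats::setNames(nm = unique(as.character(g))), function(grp) {
    rows <- which(g == grp)
    freqs <- vector("list", length(gt$loci))
    names(freqs) <- gt$loci
    n_copies <- integer(length(gt$loci))
    names(n_copies) <- gt$loci
    for (j in seq_along(gt$loci)) {
      alleles <- c(gt$allele1[rows, j], gt$allele2[rows, j])
      alleles <- alleles[!is.na(alleles)]
      n_copies[j] <- length(alleles)
      if (length(alleles)) {
        tab <- table(alleles)
        freqs[[j]] <- stats::setNames(as.numeric(tab) / length(alleles), names(tab))
      } else {
        freqs[[j]] <- numeric(0)
      }
    }
    structure(list(group = grp, freqs = freqs, n_copies = n_copies,
                   n_individuals = length(rows)),
              class = "allele_freq_profile")
  })
}

#' @export
print.allele_freq_profile <- function(x, ...) {
  typed <- sum(x$n_copies > 0)
  cat("Allele frequency profile for group '", x$group, "': ", typed, " typed loci, ",
      x$n_individuals, " individuals\n", sep = "")
  invisible(x)
}
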