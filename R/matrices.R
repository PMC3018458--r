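#' Labelled symmetric distance matrix
#'
#' Light wrapper around a square numeric matrix carrying a statistic tag
#' (`"rogers"`, `"nei_unbiased"`, `"p_uncorrected"`, `"corrected"`, or
#' `"other"`) and an optional per-cell support payload (e.g. sites compared).
#' Rogers' distances are bounded by 1; Nei's and model-corrected distances may
#' exceed 1 and may be `Inf` where no identity is shared.
#'
#' @param m square numeric matrix with identical row/col labels.
#' @param statistic statistic tag.
#' @param support optional matrix of the same shape.
#' @return an object of class `dist_matrix` (a numeric matrix with attributes).
#' @export
dist_matrix <- function(m, statistic = c("other", "rogers", "nei_unbiased",
                                         "p_uncorrected", "corrected"),
                        support = NULL) {
  statistic <- match.arg(statistic)
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_validation("distance matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop_validation("distance matrix must have identical row and column labels")
  fin <- is.finite(m)
  if (any(abs(m[fin] - t(m)[fin]) > 1e-12))
    stop_validation("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stop_validation("distance matrix must have a zero diagonal")
  if (any(m[fin] < 0)) stop_validation("distances must be non-negative")
  if (statistic == "rogers" && any(m[fin] > 1 + 1e-12))
    stop_validation("Rogers' distances must be <= 1")
  structure(m, statistic = statistic, support = support,
            class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("Distance matrix (", attr(x, "statistic"), "), ", nrow(x), " labels\n", sep = "")
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Write / read a labelled distance matrix as TSV
#'
#' Layout: an optional `# statistic: <tag>` comment, a header of labels, then
#' one row per label with the label in the first column.  Values are written
#' at full double precision so write-read round-trips are exact to 1e-12.
#'
#' @param m a [dist_matrix()].
#' @param path file path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` a `dist_matrix`.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "dist_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# statistic: ", attr(m, "statistic")), con)
  writeLines(paste(c("label", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], format(m[i, ], digits = 17, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  lines <- readLines(path)
  statistic <- "other"
  stat_line <- grep("^#\\s*statistic:", lines)
  if (length(stat_line)) {
    statistic <- trimws(sub("^#\\s*statistic:", "", lines[stat_line[1]]))
  }
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop_parse("matrix file too short: ", path)
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  labels <- df[[1]]
  vals <- suppressWarnings(vapply(df[-1], as.numeric, numeric(nrow(df))))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(df))
  if (anyNA(vals)) stop_parse("non-numeric cell in matrix file: ", path)
  rownames(vals) <- labels
  colnames(vals) <- names(df)[-1]
  if (!identical(rownames(vals), colnames(vals)))
    stop_parse("matrix file labels disagree between header and rows: ", path)
  dist_matrix(vals, statistic = if (statistic %in% c("rogers", "nei_unbiased",
                                                     "p_uncorrected", "corrected"))
                                  statistic else "other")
}

#' Read a FASTA alignment
#'
#' Thin wrapper over [ape::read.FASTA()] that enforces equal sequence lengths
#' and unique IDs, returning an uppercase character matrix (sequences x sites).
#'
#' @param path FASTA file.
#' @return character matrix with sequence IDs as rownames; class
#'   `sequence_alignment`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (!length(dna)) stop_parse("no sequences in FASTA file: ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop_validation("ragged alignment: sequence lengths ",
                    paste(sort(unique(lens)), collapse = ", "))
  if (anyDuplicated(names(dna)))
    stop_validation("duplicate sequence IDs in FASTA: ", path)
  m <- toupper(as.character(as.matrix(dna)))
  structure(m, class = c("sequence_alignment", "matrix", "array"))
}

#' Write an alignment to FASTA
#'
#' @param aln character matrix (sequences x sites) with rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop_parse("could not parse Newick file: ", path)
  tr
}
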