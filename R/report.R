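#' Read a combined allozyme summary table
#'
#' Parses the customary combined layout of allozyme species-delimitation
#' summaries: one row per taxon, fixed-difference counts with display
#' percentages (`"10 (24%)"`) below the diagonal and Nei unbiased distances
#' above it.
#'
#' @param path TSV file; first column taxon labels (optionally numbered like
#'   `"1. South-West"`), remaining columns the taxon cells, `-` or `_` on the
#'   diagonal.
#' @return list with `fd_counts`, `fd_percent` and `nei` (symmetric
#'   [dist_matrix()] objects; the FD matrices carry statistic `"other"`).
#' @export
read_allozyme_summary <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", comment.char = "#")
  labs <- sub("^[0-9]+\\.\\s*", "", df[[1]])
  n <- length(labs)
  if (ncol(df) != n + 1) stop_parse("allozyme summary must be square: ", path)
  counts <- pct <- nei <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cell <- trimws(df[i, j + 1])
    if (i > j) {                                 # lower triangle: "10 (24%)"
      m <- regmatches(cell, regexec("^([0-9]+)\\s*\\(([0-9]+)%\\)$", cell))[[1]]
      if (length(m) != 3) stop_parse("bad FD cell '", cell, "' at row ", i,
                                     ", column ", j)
      counts[i, j] <- counts[j, i] <- as.numeric(m[2])
      pct[i, j] <- pct[j, i] <- as.numeric(m[3])
    } else {                                     # upper triangle: Nei's D
      v <- suppressWarnings(as.numeric(cell))
      if (is.na(v)) stop_parse("bad Nei cell '", cell, "' at row ", i,
                               ", column ", j)
      nei[i, j] <- nei[j, i] <- v
    }
  }
  list(fd_counts = dist_matrix(counts, "other"),
       fd_percent = dist_matrix(pct, "other"),
       nei = dist_matrix(nei, "nei_unbiased"))
}

#' Read a combined divergence table
#'
#' Parses the customary mitochondrial divergence layout: a per-taxon sample
#' size column `N`, uncorrected p-distances above the diagonal and
#' model-corrected distances below it.
#'
#' @param path TSV file.
#' @return list with `n` (named sample sizes), `uncorrected` and `corrected`
#'   ([dist_matrix()] objects).
#' @export
read_divergence_table <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", comment.char = "#")
  labs <- sub("^[0-9]+\\.\\s*", "", df[[1]])
  if (!identical(toupper(names(df)[2]), "N"))
    stop_parse("divergence table must have an N column: ", path)
  n <- length(labs)
  if (ncol(df) != n + 2) stop_parse("divergence table must be square: ", path)
  sizes <- stats::setNames(as.integer(df[[2]]), labs)
  un <- co <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- suppressWarnings(as.numeric(trimws(df[i, j + 2])))
    if (is.na(v)) stop_parse("bad cell at row ", i, ", column ", j, ": ", path)
    if (i < j) un[i, j] <- un[j, i] <- v else co[i, j] <- co[j, i] <- v
  }
  list(n = sizes, uncorrected = dist_matrix(un, "p_uncorrected"),
       corrected = dist_matrix(co, "corrected"))
}

#' Headline statistics of a fixed-difference summary
#'
#' @param fd_counts,fd_percent,nei symmetric matrices over the same labels
#'   (e.g. from [read_allozyme_summary()] or recomputed by the pipeline).
#' @return an object of class `summary_table`: the input matrices plus
#'   `headline` (min/mean/max %FD, min/max FD count, min/max Nei D over all
#'   taxon pairs).
#' @export
summarize_fd_matrix <- function(fd_counts, fd_percent, nei = NULL) {
  if (!identical(rownames(fd_counts), rownames(fd_percent)) ||
      (!is.null(nei) && !identical(rownames(fd_counts), rownames(nei))))
    stop_validation("label mismatch between summary matrices")
  up <- upper.tri(fd_counts)
  headline <- list(
    min_pct_fd = min(fd_percent[up]), max_pct_fd = max(fd_percent[up]),
    mean_pct_fd = mean(fd_percent[up]),
    min_fd = min(fd_counts[up]), max_fd = max(fd_counts[up]))
  if (!is.null(nei)) {
    headline$min_nei <- min(nei[up]); headline$max_nei <- max(nei[up])
  }
  structure(list(fd_counts = fd_counts, fd_percent = fd_percent, nei = nei,
                 headline = headline),
            class = "summary_table")
}

#' Headline statistics of a divergence summary
#'
#' @param uncorrected,corrected symmetric [dist_matrix()] objects over the
#'   same labels.
#' @param grouping optional named map label -> group; defaults to every label
#'   its own group (between-group values only, within not assessable).
#' @return a `summary_table` with `headline` carrying the minimum
#'   between-group uncorrected and corrected divergences, the maxima, and the
#'   maximum within-group divergences (NA when no group has 2+ members).
#' @export
summarize_divergence_matrix <- function(uncorrected, corrected, grouping = NULL) {
  if (!identical(rownames(uncorrected), rownames(corrected)))
    stop_validation("label mismatch between divergence matrices")
  labs <- rownames(uncorrected)
  if (is.null(grouping)) grouping <- stats::setNames(labs, labs)
  su <- group_divergence_summary(uncorrected, grouping)
  sc <- group_divergence_summary(corrected, grouping)
  headline <- list(
    min_between_uncorrected = su$min_between,
    max_between_uncorrected = if (is.null(su$between)) NA_real_ else max(su$between$max),
    min_between_corrected = sc$min_between,
    max_between_corrected = if (is.null(sc$between)) NA_real_ else max(sc$between$max),
    max_within_uncorrected = su$max_within,
    max_within_corrected = sc$max_within)
  structure(list(uncorrected = su, corrected = sc, headline = headline),
            class = "summary_table")
}

#' @export
print.summary_table <- function(x, ...) {
  cat("Summary table headline statistics:\n")
  for (nm in names(x$headline))
    cat(sprintf("  %-26s %s\n", nm,
                format(x$headline[[nm]], digits = 4)))
  invisible(x)
}

#' Run the full delimitation pipeline
#'
#' End-to-end driver: reads the genotype table (and, when provided, the
#' sequence alignment and gene tree), runs stepwise PCO delimitation,
#' computes per-cluster distance matrices and the candidate-species report,
#' and writes all artifacts (matrices as TSV, report and config echo as JSON,
#' a structured per-stage log) into `out_dir`.  Rerunning with identical
#' inputs and seed reproduces the outputs byte-for-byte.
#'
#' @param config a named list or path to a JSON file with fields `genotypes`
#'   (path, required), optional `fasta`, `tree`, and parameters `min_fd`
#'   (default 3), `tolerance` (0.10), `model` ("GTR+G"), `seed` (1),
#'   `out_dir` (required).
#' @return invisibly, a list with `clusters`, `report`, `summary`, and the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_validation("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (field in c("genotypes", "out_dir"))
    if (is.null(config[[field]]))
      stop_validation("config is missing required field '", field, "'")
  min_fd <- config$min_fd %||% 3
  tolerance <- config$tolerance %||% 0.10
  model <- config$model %||% "GTR+G"
  seed <- config$seed %||% 1
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  log_lines <- character(0)
  t0 <- as.numeric(Sys.time())

  gt <- read_genotypes(config$genotypes)
  log_lines <- log_stage(log_lines, "read_genotypes", file = config$genotypes,
                         md5 = unname(tools::md5sum(config$genotypes)),
                         n = length(gt$individuals), loci = length(gt$loci), t0 = t0)

  tree_node <- stepwise_pco(gt, min_fd = min_fd, tolerance = tolerance)
  clusters <- terminal_clusters(tree_node)
  log_lines <- log_stage(log_lines, "stepwise_pco", min_fd = min_fd,
                         tolerance = tolerance,
                         clusters = length(unique(clusters)), t0 = t0)

  prof <- allele_frequencies(gt, grouping = clusters)
  rogers <- allozyme_distance_matrix(prof, "rogers")
  nei <- allozyme_distance_matrix(prof, "nei_unbiased")
  fd_counts <- allozyme_distance_matrix(prof, "fd_count", tolerance = tolerance)
  fd_pct <- allozyme_distance_matrix(prof, "fd_percent", tolerance = tolerance)
  summary_fd <- summarize_fd_matrix(fd_counts, fd_pct, nei)
  log_lines <- log_stage(log_lines, "allozyme_matrices", t0 = t0)

  mt_un <- mt_co <- mt_tree <- NULL
  if (!is.null(config$fasta)) {
    aln <- read_fasta(config$fasta)
    mt_un <- dna_distance_matrix(aln, model = "p")
    mt_co <- dna_distance_matrix(aln, model = model)
    log_lines <- log_stage(log_lines, "sequence_divergence", file = config$fasta,
                           md5 = unname(tools::md5sum(config$fasta)),
                           model = model, n = nrow(aln), t0 = t0)
  }
  if (!is.null(config$tree)) {
    mt_tree <- read_newick(config$tree)
    log_lines <- log_stage(log_lines, "read_tree", file = config$tree,
                           md5 = unname(tools::md5sum(config$tree)), t0 = t0)
  }

  report <- assess_candidates(tree_node, gt, mt_uncorrected = mt_un,
                              mt_corrected = mt_co, mt_tree = mt_tree,
                              min_fd = min_fd, tolerance = tolerance)
  log_lines <- log_stage(log_lines, "assess_candidates",
                         candidates = sum(report$candidate), t0 = t0)

  paths <- list(
    rogers = file.path(out_dir, "rogers.tsv"),
    nei = file.path(out_dir, "nei.tsv"),
    fd_counts = file.path(out_dir, "fd_counts.tsv"),
    report = file.path(out_dir, "report.json"),
    clusters = file.path(out_dir, "clusters.tsv"),
    log = file.path(out_dir, "pipeline.log"))
  write_matrix(rogers, paths$rogers)
  write_matrix(nei, paths$nei)
  write_matrix(fd_counts, paths$fd_counts)
  utils::write.table(data.frame(id = names(clusters), cluster = unname(clusters)),
                     paths$clusters, sep = "\t", quote = FALSE, row.names = FALSE)
  report_json <- list(
    parameters = list(min_fd = min_fd, tolerance = tolerance, model = model,
                      seed = seed),
    n_individuals = length(gt$individuals),
    clusters = lapply(split(names(clusters), clusters), as.list),
    candidates = report,
    headline = summary_fd$headline)
  jsonlite::write_json(report_json, paths$report, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  writeLines(log_lines, paths$log)
  invisible(list(clusters = clusters, report = report, summary = summary_fd,
                 tree = tree_node, paths = paths))
}
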