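#' Assess terminal clusters as candidate species
#'
#' Combines the lines of evidence into a per-cluster congruence report: the
#' minimum fixed-difference support against all other clusters, the number of
#' fixed loci involving private alleles, minimum between-cluster and maximum
#' within-cluster mitochondrial divergence (uncorrected and corrected),
#' and reciprocal monophyly on the mitochondrial gene tree.  A cluster is
#' nominated as a candidate species when its minimum FD support is at least
#' `min_fd`, it is monophyletic (or monophyly is not assessable), and its
#' minimum between-cluster mitochondrial divergence exceeds its maximum
#' within-cluster divergence wherever both are computable.  Clusters with no
#' sequenced member fall back to allozyme-only evidence, with a warning.
#'
#' @param node a `cluster_node` tree from [stepwise_pco()].
#' @param gt the [genotype_table()] the tree was built from.
#' @param mt_uncorrected,mt_corrected [dist_matrix()] objects over sequenced
#'   individual IDs (a subset of the genotyped individuals); either may be
#'   `NULL`.
#' @param mt_tree optional `phylo` gene tree over the sequenced individuals.
#' @param min_fd minimum fixed-difference support (default 3).
#' @param tolerance shared-allele tolerance for the reported %FD (default
#'   0.10); the FD support count itself uses the strict rule.
#' @return a data.frame of class `candidate_species_report`, one row per
#'   terminal cluster.
#' @export
assess_candidates <- function(node, gt, mt_uncorrected = NULL,
                              mt_corrected = NULL, mt_tree = NULL,
                              min_fd = 3, tolerance = 0.10) {
  stopifnot(inherits(node, "cluster_node"), inherits(gt, "genotype_table"))
  clusters <- terminal_clusters(node)
  labs <- unique(clusters)
  prof <- allele_frequencies(gt, grouping = clusters)
  strict <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  pct <- strict
  if (length(labs) > 1) {
    for (i in seq_along(labs)[-length(labs)]) for (j in (i + 1):length(labs)) {
      s <- fixed_differences(prof[[labs[i]]], prof[[labs[j]]], 0)
      t <- fixed_differences(prof[[labs[i]]], prof[[labs[j]]], tolerance)
      strict[i, j] <- strict[j, i] <- s$count
      pct[i, j] <- pct[j, i] <- t$percent
    }
  }
  priv <- if (length(labs) > 1) private_allele_diagnosis(prof, 0) else
    stats::setNames(NA_integer_, labs)

  mono <- stats::setNames(rep("not_assessable", length(labs)), labs)
  if (!is.null(mt_tree)) {
    seq_ids <- mt_tree$tip.label
    grouping <- clusters[seq_ids]
    if (anyNA(grouping))
      stop_validation("mt tree tips not in genotype table: ",
                      paste(seq_ids[is.na(grouping)], collapse = ", "))
    flags <- is_reciprocally_monophyletic(mt_tree, grouping)
    mono[names(flags)] <- flags
  }

  summarize_mt <- function(m) {
    if (is.null(m)) return(list(min_between = rep(NA_real_, length(labs)),
                                max_within = rep(NA_real_, length(labs))))
    ids <- rownames(m)
    grouping <- clusters[ids]
    if (anyNA(grouping))
      stop_validation("divergence matrix labels not in genotype table: ",
                      paste(ids[is.na(grouping)], collapse = ", "))
    mb <- mw <- stats::setNames(rep(NA_real_, length(labs)), labs)
    for (cl in labs) {
      inside <- which(grouping == cl)
      outside <- which(grouping != cl)
      if (length(inside) && length(outside))
        mb[cl] <- min(m[inside, outside])
      if (length(inside) >= 2) {
        v <- m[inside, inside][upper.tri(diag(length(inside)))]
        mw[cl] <- max(v)
      }
    }
    list(min_between = mb, max_within = mw)
  }
  un <- summarize_mt(mt_uncorrected)
  co <- summarize_mt(mt_corrected)

  n_seq <- vapply(labs, function(cl) {
    ids <- character(0)
    if (!is.null(mt_uncorrected)) ids <- rownames(mt_uncorrected)
    else if (!is.null(mt_corrected)) ids <- rownames(mt_corrected)
    else if (!is.null(mt_tree)) ids <- mt_tree$tip.label
    sum(clusters[ids] == cl, na.rm = TRUE)
  }, numeric(1))

  verdict <- logical(length(labs))
  for (i in seq_along(labs)) {
    fd_ok <- if (length(labs) == 1) FALSE else min(strict[i, -i]) >= min_fd
    mono_ok <- mono[i] %in% c("yes", "not_assessable")
    mt_ok <- TRUE
    if (is.finite(un$min_between[i]) && is.finite(un$max_within[i]))
      mt_ok <- mt_ok && un$min_between[i] > un$max_within[i]
    if (is.finite(co$min_between[i]) && is.finite(co$max_within[i]))
      mt_ok <- mt_ok && co$min_between[i] > co$max_within[i]
    if (n_seq[i] == 0 && (!is.null(mt_uncorrected) || !is.null(mt_tree)))
      warning("cluster '", labs[i], "' has no sequenced member; ",
              "verdict based on allozyme evidence only")
    verdict[i] <- fd_ok && mono_ok && mt_ok
  }

  out <- data.frame(
    cluster = labs,
    n = as.integer(table(factor(clusters, levels = labs))),
    n_sequenced = as.integer(n_seq),
    min_fd = if (length(labs) == 1) NA_integer_ else
      vapply(seq_along(labs), function(i) as.integer(min(strict[i, -i])), integer(1)),
    min_pct_fd = if (length(labs) == 1) NA_real_ else
      vapply(seq_along(labs), function(i) min(pct[i, -i]), numeric(1)),
    private_fd_loci = as.integer(priv[labs]),
    min_between_uncorrected = un$min_between,
    max_within_uncorrected = un$max_within,
    min_between_corrected = co$min_between,
    max_within_corrected = co$max_within,
    monophyly = unname(mono),
    candidate = verdict,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("candidate_species_report", "data.frame")
  attr(out, "fd_matrix") <- strict
  attr(out, "pct_fd_matrix") <- pct
  attr(out, "clusters") <- clusters
  out
}

#' @export
print.candidate_species_report <- function(x, ...) {
  cat("Candidate-species report:", nrow(x), "terminal clusters,",
      sum(x$candidate), "nominated\n\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
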