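#' Detect fixed-difference-validated clusters in PCO space
#'
#' Automates the scatterplot assessment of a PCO: candidate partitions are
#' proposed by average-linkage agglomerative clustering on the first two PCO
#' axes for k = 2..`kmax`, and a partition is accepted only if every pair of
#' its groups is separated by at least `min_fd` fixed differences (at
#' `tolerance`, strict by default).  The accepted partition with the largest
#' k wins; if none validates, the single-group partition is returned.
#'
#' @param p a `pco_result` computed from the individuals in `gt`.
#' @param gt the [genotype_table()] restricted to those individuals.
#' @param min_fd minimum fixed differences between every pair of accepted
#'   groups (default 3: groups differing by fewer are treated as
#'   non-distinct).
#' @param tolerance shared-allele tolerance used for validation (default 0,
#'   the strict no-shared-alleles rule).
#' @param kmax largest number of groups scanned; default `min(8, n)`, so the
#'   all-singletons partition is considered for nodes of up to 8 individuals
#'   (two singleton taxa isolated in a pair-node must remain delimitable).
#' @return named integer vector: individual ID -> cluster id (1..k).
#' @export
detect_clusters <- function(p, gt, min_fd = 3, tolerance = 0, kmax = NULL) {
  stopifnot(inherits(p, "pco_result"), inherits(gt, "genotype_table"))
  if (min_fd < 1) stop_validation("min_fd must be >= 1")
  n <- length(p$labels)
  trivial <- stats::setNames(rep(1L, n), p$labels)
  if (n < 2) return(trivial)
  if (!setequal(p$labels, gt$individuals))
    stop_validation("PCO labels and genotype table individuals differ")
  coords <- p$coordinates[, seq_len(min(2, ncol(p$coordinates))), drop = FALSE]
  hc <- stats::hclust(stats::dist(coords), method = "average")
  if (is.null(kmax)) kmax <- min(8L, n)
  kmax <- min(kmax, n)
  for (k in rev(seq(2, kmax))) {
    part <- stats::cutree(hc, k = k)
    if (partition_validated(part, gt, min_fd, tolerance))
      return(stats::setNames(part[p$labels], p$labels))
  }
  trivial
}

## every pair of groups in the partition must show >= min_fd fixed differences
partition_validated <- function(part, gt, min_fd, tolerance) {
  prof <- allele_frequencies(gt, grouping = stats::setNames(as.character(part), names(part)))
  ids <- names(prof)
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
    fd <- tryCatch(fixed_differences(prof[[i]], prof[[j]], tolerance),
                   crenadelim_validation_error = function(e) NULL)
    if (is.null(fd) || fd$count < min_fd) return(FALSE)
  }
  TRUE
}

#' Stepwise PCO species delimitation
#'
#' Recursive cluster detection: a PCO of individual-level Rogers' distances
#' is scanned for fixed-difference-validated clusters
#' ([detect_clusters()]), and each validated cluster is re-analysed by its
#' own PCO round, until no further validated split is found or `max_rounds`
#' rounds have been spent along a branch.  Terminal clusters are the proposed
#' taxa.
#'
#' @param gt a [genotype_table()] (>= 2 individuals).
#' @param min_fd,tolerance,kmax see [detect_clusters()].
#' @param max_rounds maximum PCO rounds along any root-to-leaf path
#'   (default 3: full dataset, regional groups, subgroups).
#' @return a `cluster_node` tree: list with `members`, `depth`, `pco`,
#'   `children` (list of `cluster_node`), `child_fd` (FD support for each
#'   child pair), `terminal`.
#' @export
stepwise_pco <- function(gt, min_fd = 3, tolerance = 0, max_rounds = 3, kmax = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  if (length(gt$individuals) < 2) stop_validation("need at least 2 individuals")
  stepwise_node(gt, depth = 1L, min_fd = min_fd, tolerance = tolerance,
                max_rounds = max_rounds, kmax = kmax)
}

stepwise_node <- function(gt, depth, min_fd, tolerance, max_rounds, kmax) {
  node <- structure(list(members = gt$individuals, depth = depth, pco = NULL,
                         children = list(), child_fd = list(), terminal = TRUE),
                    class = "cluster_node")
  if (length(gt$individuals) < 2 || depth > max_rounds) return(node)
  m <- individual_rogers_matrix(gt)
  ## genetically uniform members (all-zero distances) carry no structure
  node$pco <- tryCatch(pco(m, k = 2),
                       crenadelim_validation_error = function(e) NULL)
  if (is.null(node$pco)) return(node)
  part <- detect_clusters(node$pco, gt, min_fd = min_fd, tolerance = tolerance,
                          kmax = kmax)
  if (length(unique(part)) < 2) return(node)
  node$terminal <- FALSE
  prof <- allele_frequencies(gt, grouping = stats::setNames(as.character(part), names(part)))
  ids <- sort(unique(part))
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
    node$child_fd[[paste(ids[i], ids[j], sep = "-")]] <-
      fixed_differences(prof[[as.character(ids[i])]], prof[[as.character(ids[j])]],
                        tolerance)
  }
  node$children <- lapply(ids, function(id) {
    stepwise_node(subset_individuals(gt, names(part)[part == id]),
                  depth = depth + 1L, min_fd = min_fd, tolerance = tolerance,
                  max_rounds = max_rounds, kmax = kmax)
  })
  node
}

#' Terminal clusters of a stepwise-PCO tree
#'
#' @param node a `cluster_node` (from [stepwise_pco()]).
#' @param prefix label prefix used while recursing (internal).
#' @return named character vector: individual ID -> terminal cluster label
#'   (labels like `"C1"`, `"C2.1"` encode the split path).
#' @export
terminal_clusters <- function(node, prefix = "C") {
  stopifnot(inherits(node, "cluster_node"))
  if (node$terminal)
    return(stats::setNames(rep(prefix, length(node$members)), node$members))
  out <- lapply(seq_along(node$children), function(i)
    terminal_clusters(node$children[[i]], paste0(prefix, if (prefix == "C") "" else ".", i)))
  do.call(c, out)
}

#' @export
print.cluster_node <- function(x, indent = "", ...) {
  status <- if (x$terminal) "terminal" else paste0(length(x$children), " children")
  cat(indent, "round ", x$depth, ": ", length(x$members), " individuals (",
      status, ")\n", sep = "")
  for (ch in x$children) print(ch, indent = paste0(indent, "  "))
  invisible(x)
}

#' Count fixed-difference loci involving private alleles
#'
#' For each group, the number of loci that are strict fixed differences
#' against every other group and at which the group carries at least one
#' "private" allele (an allele found in no other profiled group).
#'
#' @param profiles list of `allele_freq_profile` objects (>= 2).
#' @param tolerance shared-allele tolerance for the FD condition (default 0).
#' @return named integer vector of per-group counts.
#' @export
private_allele_diagnosis <- function(profiles, tolerance = 0) {
  if (length(profiles) < 2) stop_validation("need at least 2 profiles")
  labs <- vapply(profiles, function(p) p$group, character(1))
  names(profiles) <- labs
  loci <- names(profiles[[1]]$n_copies)
  counts <- stats::setNames(integer(length(labs)), labs)
  for (g in labs) {
    others <- setdiff(labs, g)
    for (l in loci) {
      if (profiles[[g]]$n_copies[[l]] == 0) next
      mine <- names(profiles[[g]]$freqs[[l]])
      elsewhere <- unique(unlist(lapply(others, function(h) names(profiles[[h]]$freqs[[l]]))))
      if (!length(setdiff(mine, elsewhere))) next   # no private allele here
      fd_all <- all(vapply(others, function(h) {
        if (profiles[[h]]$n_copies[[l]] == 0) return(FALSE)
        shared <- intersect(mine, names(profiles[[h]]$freqs[[l]]))
        mass <- sum((profiles[[g]]$freqs[[l]][shared] +
                     profiles[[h]]$freqs[[l]][shared]) / 2)
        mass <= tolerance
      }, logical(1)))
      if (fd_all) counts[g] <- counts[g] + 1L
    }
  }
  counts
}

#' Reciprocal monophyly of groups on a gene tree
#'
#' Tests, on the unrooted topology, whether each group's tips are separated
#' from all other tips by a single edge (i.e. the group is a clade under some
#' rooting).  Groups with a single tip are "not assessable".
#'
#' @param tree an `ape` `phylo` object (rooted or unrooted).
#' @param grouping named character vector: tip label -> group.  Tips of the
#'   tree absent from `grouping` are an error, as are grouped names absent
#'   from the tree.
#' @return named character vector per group: `"yes"`, `"no"`, or
#'   `"not_assessable"`.
#' @export
is_reciprocally_monophyletic <- function(tree, grouping) {
  if (!inherits(tree, "phylo")) stop_validation("tree must be a phylo object")
  missing_tips <- setdiff(tree$tip.label, names(grouping))
  missing_names <- setdiff(names(grouping), tree$tip.label)
  if (length(missing_tips) || length(missing_names))
    stop_validation("tip/grouping mismatch; offenders: ",
                    paste(c(missing_tips, missing_names), collapse = ", "))
  g <- grouping[tree$tip.label]
  groups <- unique(as.character(g))
  utree <- ape::unroot(tree)
  out <- stats::setNames(character(length(groups)), groups)
  for (grp in groups) {
    tips <- tree$tip.label[g == grp]
    if (length(tips) < 2) { out[grp] <- "not_assessable"; next }
    if (length(tips) == length(tree$tip.label)) { out[grp] <- "yes"; next }
    ## on an unrooted tree a group is a clade under some rooting iff either
    ## the group or its complement is monophyletic in an arbitrary rooted view
    rooted <- ape::root(utree, outgroup = setdiff(tree$tip.label, tips)[1],
                        resolve.root = TRUE)
    ok <- ape::is.monophyletic(rooted, tips) ||
      ape::is.monophyletic(rooted, setdiff(tree$tip.label, tips))
    out[grp] <- if (ok) "yes" else "no"
  }
  out
}
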