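## Synthetic data with planted truth.
##
## Fixed differences are planted through per-locus "allele block" partitions
## of the groups: all groups in a block are fixed for (or share) that block's
## allele(s), so a pair of groups is a strict fixed difference at a locus iff
## the locus partition separates them.  Planted FD counts are therefore
## Hamming distances over the locus plan and exact by construction; sampling
## can neither create sharing between blocks nor (except with vanishingly
## small probability at tiny sample sizes) destroy sharing within one.

## Greedy realization of a target FD-count matrix as locus partitions.
## Each round starts from the finest partition that keeps exhausted pairs
## together (must-link components over zero-demand pairs) and decrements
## every separated pair.  If the full decrement would leave a residual that
## violates the triangle inequality -- i.e. some demand would become
## unreachable -- blocks of the offending exhausted pair are fused and the
## round retried with the coarser partition, so asymmetric demands (e.g. one
## pair needing many more loci than its neighbours) are expressed through
## partitions that keep the nearly-done pair in one block.  A round with no
## separable positive pair, or exceeding the locus budget, means the target
## is not realizable and is reported before any sampling.
plant_fd_partitions <- function(target, n_loci) {
  if (!is.matrix(target) || nrow(target) != ncol(target))
    stop_validation("fd target must be a square matrix")
  groups <- rownames(target)
  if (is.null(groups)) stop_validation("fd target needs group dimnames")
  if (any(target != t(target)) || any(diag(target) != 0) || any(target < 0))
    stop_validation("fd target must be symmetric, non-negative, zero diagonal")
  G <- length(groups)
  triangle_ok <- function(R) {
    for (i in seq_len(G)) for (j in seq_len(G)) for (k in seq_len(G))
      if (R[i, j] > R[i, k] + R[k, j]) return(c(i, j, k))
    NULL
  }
  if (!is.null(triangle_ok(target)))
    stop_validation("infeasible FD plan: target violates the triangle inequality ",
                    "of Hamming distances")
  R <- target
  partitions <- list()
  while (sum(R) > 0) {
    ## must-link components over pairs with exhausted demand
    comp <- seq_len(G)
    fuse <- function(comp, i, j) { comp[comp == comp[j]] <- comp[i]; comp }
    repeat {
      changed <- FALSE
      for (i in seq_len(G - 1)) for (j in (i + 1):G) {
        if (R[i, j] == 0 && comp[i] != comp[j]) { comp <- fuse(comp, i, j); changed <- TRUE }
      }
      if (!changed) break
    }
    repeat {
      blocks <- match(comp, unique(comp))
      sep <- outer(blocks, blocks, `!=`)
      if (!any(sep & R > 0))
        stop_validation("infeasible FD plan: positive demand not realizable ",
                        "by allele-block partitions")
      Rnext <- R
      Rnext[sep] <- Rnext[sep] - 1
      bad <- triangle_ok(Rnext)
      if (is.null(bad)) break
      ## fuse the blocks of the tighter side of the violated triple so its
      ## remaining demand is preserved for later, coarser rounds
      i <- bad[1]; j <- bad[2]; k <- bad[3]
      side <- if (Rnext[i, k] <= Rnext[k, j]) c(i, k) else c(k, j)
      comp <- fuse(comp, side[1], side[2])
    }
    R <- Rnext
    partitions[[length(partitions) + 1L]] <- stats::setNames(blocks, groups)
    if (length(partitions) > n_loci)
      stop_validation("infeasible FD plan: needs more than ", n_loci, " loci")
  }
  partitions
}

## planted strict-FD counts implied by a locus partition plan
partitions_to_fd <- function(partitions, groups) {
  G <- length(groups)
  fd <- matrix(0L, G, G, dimnames = list(groups, groups))
  for (p in partitions) {
    if (is.null(p)) next
    b <- p[groups]
    fd <- fd + outer(b, b, `!=`)
  }
  fd
}

#' Specify a synthetic delimitation scenario
#'
#' Describes the study design to emulate: group sizes, an allozyme locus plan
#' that plants exact strict fixed-difference counts, loci exercising the
#' shared-allele tolerance rule, a missing-data rate, and (optionally) a tree
#' plus substitution-model parameters for sequence simulation.
#'
#' @param group_sizes named integer vector of individuals per group.
#' @param n_loci total allozyme loci.
#' @param fd_target optional symmetric matrix of planted strict FD counts per
#'   group pair; realized exactly via [plant_fd_partitions()] (a validation
#'   error is raised before sampling if the plan is infeasible).
#' @param partitions optional explicit locus plan: a list of length `n_loci`
#'   whose entries are named integer block assignments (or `NULL` for a
#'   monomorphic locus).  Overrides `fd_target`.
#' @param tolerant_loci indices of loci (outside the FD plan) where the groups
#'   split into two allele blocks but share a rare allele at frequency
#'   `shared_freq`, so that the locus is a fixed difference under the 10%
#'   cumulative tolerance but not under the strict rule.
#' @param shared_freq frequency of the injected shared allele (default 0.05).
#' @param block_poly_freq frequency of a secondary, within-block-shared allele
#'   at plan loci whose block holds 2+ groups (mild realistic polymorphism
#'   that cannot disturb planted FDs); default 0.15.
#' @param missing_rate per-call missing-data probability.
#' @param tree Newick string for sequence simulation (tip labels must be
#'   individual IDs of the sequenced subset).
#' @param seq_grouping named character vector tip label -> group.
#' @param model list with `rates` (6 GTR exchangeabilities), `base_freqs`
#'   (A,C,G,T), `gamma_shape` (`NULL` for rate homogeneity), `p_inv`.
#' @param aln_length alignment length in sites.
#' @param seed integer seed; mandatory, all outputs are deterministic in it.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(group_sizes, n_loci, fd_target = NULL,
                          partitions = NULL, tolerant_loci = integer(0),
                          shared_freq = 0.05, block_poly_freq = 0.15,
                          missing_rate = 0, tree = NULL, seq_grouping = NULL,
                          model = list(rates = rep(1, 6),
                                       base_freqs = rep(0.25, 4),
                                       gamma_shape = NULL, p_inv = 0),
                          aln_length = 828, seed) {
  if (missing(seed) || !is.numeric(seed))
    stop_validation("a numeric seed is mandatory")
  if (is.null(names(group_sizes)) || any(group_sizes < 1))
    stop_validation("group_sizes must be a named vector of sizes >= 1")
  groups <- names(group_sizes)
  if (is.null(partitions)) {
    planned <- if (is.null(fd_target)) list() else plant_fd_partitions(fd_target, n_loci)
    partitions <- c(planned, vector("list", n_loci - length(planned)))
  }
  if (length(partitions) != n_loci)
    stop_validation("partitions must have one entry per locus")
  plan_loci <- which(!vapply(partitions, is.null, logical(1)))
  if (length(intersect(tolerant_loci, plan_loci)))
    stop_validation("tolerant loci must not overlap the FD plan loci")
  if (any(tolerant_loci > n_loci)) stop_validation("tolerant locus index out of range")
  fd_planted <- partitions_to_fd(partitions, groups)
  if (!is.null(fd_target) && !all(fd_planted == fd_target))
    stop_validation("internal: realized plan does not match fd_target")
  if (!is.null(model$base_freqs) &&
      abs(sum(model$base_freqs) - 1) > 1e-8)
    stop_validation("base frequencies must sum to 1")
  if (!is.null(model$p_inv) && (model$p_inv < 0 || model$p_inv >= 1))
    stop_validation("p_inv must be in [0, 1)")
  structure(list(group_sizes = group_sizes, n_loci = n_loci,
                 partitions = partitions, tolerant_loci = tolerant_loci,
                 shared_freq = shared_freq, block_poly_freq = block_poly_freq,
                 missing_rate = missing_rate, tree = tree,
                 seq_grouping = seq_grouping, model = model,
                 aln_length = aln_length, fd_planted = fd_planted,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario:", length(x$group_sizes), "groups,", sum(x$group_sizes),
      "individuals,", x$n_loci, "loci, seed", x$seed, "\n")
  off <- x$fd_planted[upper.tri(x$fd_planted)]
  if (length(off))
    cat("  planted strict FDs per pair:", min(off), "-", max(off), "\n")
  if (!is.null(x$tree))
    cat("  sequences:", length(x$seq_grouping), "tips x", x$aln_length, "sites\n")
  invisible(x)
}

## per-group, per-locus allele frequency vectors implied by the spec
spec_frequencies <- function(spec) {
  groups <- names(spec$group_sizes)
  G <- length(groups)
  lapply(seq_len(spec$n_loci), function(l) {
    part <- spec$partitions[[l]]
    if (l %in% spec$tolerant_loci) {
      ## two main blocks plus a universal rare shared allele
      blocks <- stats::setNames(1L + (seq_len(G) > G / 2), groups)
      return(lapply(stats::setNames(nm = groups), function(g) {
        main <- c("a", "b")[blocks[g]]
        stats::setNames(c(1 - spec$shared_freq, spec$shared_freq), c(main, "s"))
      }))
    }
    if (is.null(part)) {
      return(lapply(stats::setNames(nm = groups), function(g) c(a = 1)))
    }
    blocks <- part[groups]
    counts <- table(blocks)
    lapply(stats::setNames(nm = groups), function(g) {
      b <- blocks[[g]]
      main <- letters[2 * b - 1]
      if (counts[[as.character(b)]] >= 2 && spec$block_poly_freq > 0) {
        stats::setNames(c(1 - spec$block_poly_freq, spec$block_poly_freq),
                        c(main, letters[2 * b]))
      } else stats::setNames(1, main)
    })
  })
}

#' Simulate an allozyme genotype table with planted structure
#'
#' Draws Hardy-Weinberg genotypes from the group/locus allele frequencies
#' implied by the scenario's locus plan, applies the missing-data rate, and
#' records the truth: the individual-to-group map, the planted strict FD
#' counts, and the realized (post-sampling) strict and tolerant FD matrices,
#' recomputed from the emitted table itself.
#'
#' @param spec a [scenario_spec()].
#' @return list with `genotypes` (a [genotype_table()]) and `truth` (list:
#'   `grouping`, `fd_planted`, `fd_strict`, `fd_tolerant`).
#' @export
simulate_allozymes <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  groups <- names(spec$group_sizes)
  ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", g, seq_len(spec$group_sizes[[g]]))))
  grouping <- stats::setNames(rep(groups, spec$group_sizes), ids)
  freqs <- spec_frequencies(spec)
  loci <- sprintf("L%02d", seq_len(spec$n_loci))
  calls <- matrix(NA_character_, length(ids), spec$n_loci,
                  dimnames = list(ids, loci))
  for (l in seq_len(spec$n_loci)) {
    for (i in seq_along(ids)) {
      if (spec$missing_rate > 0 && stats::runif(1) < spec$missing_rate) next
      f <- freqs[[l]][[grouping[[ids[i]]]]]
      pair <- sample(names(f), 2, replace = TRUE, prob = f)
      calls[i, l] <- paste(sort(pair), collapse = "/")
    }
  }
  gt <- genotype_table(calls, site = unname(grouping), group = unname(grouping))
  prof <- allele_frequencies(gt, grouping)
  truth <- list(
    grouping = grouping,
    fd_planted = spec$fd_planted,
    fd_strict = unclass(allozyme_distance_matrix(prof, "fd_count", tolerance = 0)),
    fd_tolerant = unclass(allozyme_distance_matrix(prof, "fd_count", tolerance = 0.10)))
  list(genotypes = gt, truth = truth)
}

## expected p-distance between two sequences separated by path length d
## under the scenario's substitution model (used to calibrate tree depths)
expected_p_distance <- function(d, model) {
  freqs <- model$base_freqs / sum(model$base_freqs)
  Q <- gtr_rate_matrix(model$rates, freqs)
  rates <- if (is.null(model$gamma_shape) || !is.finite(model$gamma_shape)) 1
           else discrete_gamma_rates(model$gamma_shape, 4)
  p_var <- mean(vapply(rates, function(r) {
    P <- transition_probs(Q, d * r)
    sum(freqs * (1 - diag(P)))
  }, numeric(1)))
  (1 - (model$p_inv %||% 0)) * p_var
}

## path length d with expected p-distance p under the model
invert_p_distance <- function(p, model) {
  pmax_attainable <- expected_p_distance(50, model)
  if (p >= pmax_attainable)
    stop_validation("target p-distance ", p, " not attainable under the model")
  stats::uniroot(function(d) expected_p_distance(d, model) - p,
                 lower = 1e-6, upper = 50, tol = 1e-10)$root
}

#' Simulate sequences along the scenario tree
#'
#' Evolves `aln_length` sites independently down the scenario's tree under
#' GTR with optional discrete-gamma (4 category) rate heterogeneity and a
#' proportion of invariant sites; the root state is drawn from the stationary
#' base frequencies.
#'
#' @param spec a [scenario_spec()] with a `tree`.
#' @return list with `alignment` (character matrix, class
#'   `sequence_alignment`), and `truth` (list: `grouping`, `tree`,
#'   `p_distances` realized uncorrected divergence matrix).
#' @export
simulate_sequences <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(spec$tree)) stop_validation("scenario has no tree")
  set.seed(spec$seed)
  model <- spec$model
  freqs <- model$base_freqs / sum(model$base_freqs)
  tree <- ape::read.tree(text = spec$tree)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop_validation("tree must have non-negative branch lengths")
  n_sites <- spec$aln_length
  p_inv <- model$p_inv %||% 0
  gam <- if (is.null(model$gamma_shape) || !is.finite(model$gamma_shape)) 1
         else discrete_gamma_rates(model$gamma_shape, 4)
  site_rate <- sample(gam, n_sites, replace = TRUE)
  if (p_inv > 0) site_rate[stats::runif(n_sites) < p_inv] <- 0
  Q <- gtr_rate_matrix(model$rates, freqs)
  bases <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  states <- matrix(0L, n_tip + tree$Nnode, n_sites)
  root <- n_tip + 1L
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE, prob = freqs)
  edges <- ape::reorder.phylo(tree, "cladewise")
  rate_vals <- sort(unique(site_rate[site_rate > 0]))
  for (e in seq_len(nrow(edges$edge))) {
    parent <- edges$edge[e, 1]; child <- edges$edge[e, 2]
    len <- edges$edge.length[e]
    child_states <- states[parent, ]
    if (len > 0) {
      for (r in rate_vals) {
        P <- transition_probs(Q, len * r)
        for (s in 1:4) {
          idx <- which(site_rate == r & states[parent, ] == s)
          if (length(idx))
            child_states[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                            prob = P[s, ])
        }
      }
    }
    states[child, ] <- child_states
  }
  aln <- matrix(bases[states[seq_len(n_tip), ]], nrow = n_tip,
                dimnames = list(tree$tip.label, NULL))
  aln <- structure(aln, class = c("sequence_alignment", "matrix", "array"))
  truth <- list(grouping = spec$seq_grouping, tree = tree,
                p_distances = dna_distance_matrix(aln, model = "p"))
  list(alignment = aln, truth = truth)
}

#' Scenario emulating the Crenadactylus study design
#'
#' A deterministic two-level scenario: 94 individuals in 10 groups over 42
#' allozyme loci -- six primary regional groups, one of which (the Kimberley)
#' comprises five subgroups, three of them singletons.  The locus plan plants
#' pairwise strict FD counts of 5-9 among the Kimberley subgroups and 8-20
#' between primary regions; two loci carry a rare shared allele exercising
#' the 10% tolerance rule.  A 53-tip ultrametric tree with GTR+I+G parameters
#' is calibrated so expected between-group uncorrected divergences lie in
#' 0.17-0.26 (within the 0.14-0.29 construction envelope) and within-group
#' divergences stay near 1%.
#'
#' @param seed integer seed passed into the [scenario_spec()].
#' @return a `scenario_spec`.
#' @export
make_paper_like_scenario <- function(seed = 1) {
  groups <- c("SouthWest", "Carnarvon", "CapeRange", "Pilbara",
              "KimberleyA", "KimberleyB", "KimberleyC", "KimberleyD",
              "KimberleyE", "CentralRanges")
  sizes <- stats::setNames(c(20L, 14L, 10L, 17L, 1L, 3L, 1L, 1L, 7L, 20L), groups)
  part <- function(...) stats::setNames(c(...), groups)
  one_vs_rest <- function(i) { b <- rep(2L, 10); b[i] <- 1L; part(b) }
  plan <- c(
    rep(list(part(1, 2, 3, 4, 5, 5, 5, 5, 5, 6)), 4),   # full primary split
    rep(list(part(1, 1, 1, 2, 2, 2, 2, 2, 2, 2)), 3),   # south vs north clade
    rep(list(one_vs_rest(1)), 2),                        # SouthWest private
    rep(list(one_vs_rest(2)), 2),                        # Carnarvon private
    rep(list(one_vs_rest(3)), 2),                        # CapeRange private
    rep(list(one_vs_rest(4)), 2),                        # Pilbara private
    rep(list(one_vs_rest(10)), 2),                       # CentralRanges private
    rep(list(part(2, 2, 2, 2, 1, 1, 1, 1, 1, 2)), 2),   # Kimberley clade private
    rep(list(part(2, 2, 2, 1, 2, 2, 2, 2, 2, 1)), 2),   # Pilbara+Central
    rep(list(part(2, 1, 1, 2, 2, 2, 2, 2, 2, 2)), 2),   # Carnarvon+CapeRange
    rep(list(part(6, 6, 6, 6, 1, 2, 3, 4, 5, 6)), 3),   # full Kimberley split
    rep(list(one_vs_rest(5)), 2),                        # Kimberley A private
    rep(list(one_vs_rest(6)), 2),                        # Kimberley B private
    rep(list(one_vs_rest(7)), 2),                        # Kimberley C private
    rep(list(one_vs_rest(8)), 1),                        # Kimberley D private
    rep(list(one_vs_rest(9)), 1),                        # Kimberley E private
    rep(list(part(2, 2, 2, 2, 2, 1, 1, 2, 2, 2)), 2),   # Kimberley B+C
    vector("list", 6))                                   # 2 tolerant + 4 common
  model <- list(rates = c(1, 8, 1, 1, 8, 1),
                base_freqs = c(0.35, 0.30, 0.10, 0.25),
                gamma_shape = 0.8, p_inv = 0.35)
  seq_counts <- stats::setNames(c(7L, 10L, 4L, 10L, 1L, 2L, 1L, 1L, 6L, 11L), groups)
  tree <- paper_like_tree(groups, seq_counts, model)
  seq_ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", g, seq_len(seq_counts[[g]]))))
  seq_grouping <- stats::setNames(rep(groups, seq_counts), seq_ids)
  scenario_spec(group_sizes = sizes, n_loci = 42, partitions = plan,
                tolerant_loci = c(37L, 38L), missing_rate = 0.02,
                tree = tree, seq_grouping = seq_grouping, model = model,
                aln_length = 828, seed = seed)
}

## ultrametric 53-tip tree; node heights are d/2 values whose implied expected
## p-distances hit the stated between-group targets
paper_like_tree <- function(groups, seq_counts, model) {
  h <- function(p) invert_p_distance(p, model) / 2   # height for total path p
  hw <- h(0.010)                                     # within-group mrca height
  tipset <- function(g, parent_h) {
    n <- seq_counts[[g]]
    ids <- sprintf("%s_%02d", g, seq_len(n))
    if (n == 1) return(sprintf("%s:%.8f", ids, parent_h))
    inner <- paste(sprintf("%s:%.8f", ids, hw), collapse = ",")
    sprintf("(%s):%.8f", inner, parent_h - hw)
  }
  clade <- function(children_str, parent_h, own_h)
    sprintf("(%s):%.8f", paste(children_str, collapse = ","), parent_h - own_h)
  h_root <- h(0.26)
  h_sw <- h(0.23); h_cbcr <- h(0.20)
  h_north <- h(0.24); h_pc <- h(0.21)
  h_k1 <- h(0.20); h_k2 <- h(0.19); h_k3 <- h(0.18); h_k4 <- h(0.17)
  south <- clade(c(tipset("SouthWest", h_sw),
                   clade(c(tipset("Carnarvon", h_cbcr), tipset("CapeRange", h_cbcr)),
                         h_sw, h_cbcr)),
                 h_root, h_sw)
  kim <- clade(c(tipset("KimberleyA", h_k1),
                 clade(c(tipset("KimberleyB", h_k2),
                         clade(c(tipset("KimberleyC", h_k3),
                                 clade(c(tipset("KimberleyD", h_k4),
                                         tipset("KimberleyE", h_k4)),
                                       h_k3, h_k4)),
                               h_k2, h_k3)),
                       h_k1, h_k2)),
               h_north, h_k1)
  north <- clade(c(clade(c(tipset("Pilbara", h_pc), tipset("CentralRanges", h_pc)),
                         h_north, h_pc),
                   kim),
                 h_root, h_north)
  sprintf("(%s,%s);", south, north)
}
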