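## Between-taxon allozyme statistics.  All statistics use pairwise deletion:
## only loci typed (gene-copy count > 0) in BOTH profiles enter a comparison,
## so denominators vary between pairs, as in gel-based datasets where not
## every locus resolves in every taxon.

joint_loci <- function(A, B) {
  names(A$n_copies)[A$n_copies > 0 & B$n_copies > 0]
}

## allele frequency vectors of A and B at locus l over the union of alleles
aligned_freqs <- function(A, B, l) {
  fa <- A$freqs[[l]]; fb <- B$freqs[[l]]
  alleles <- union(names(fa), names(fb))
  pa <- stats::setNames(numeric(length(alleles)), alleles)
  pb <- pa
  pa[names(fa)] <- fa
  pb[names(fb)] <- fb
  list(alleles = alleles, pa = pa, pb = pb)
}

#' Rogers' genetic distance between two allele-frequency profiles
#'
#' Mean over jointly typed loci of the per-locus Euclidean distance between
#' allele-frequency vectors, scaled so a locus with no shared alleles
#' contributes exactly 1: `sqrt(0.5 * sum((pA - pB)^2))`.  Bounded in
#' `[0, 1]` and metric.
#'
#' @param A,B `allele_freq_profile` objects (see [allele_frequencies()]).
#' @return numeric scalar in `[0, 1]`.
#' @export
rogers_distance <- function(A, B) {
  loci <- joint_loci(A, B)
  if (!length(loci)) stop_validation("no comparable loci between groups '",
                                     A$group, "' and '", B$group, "'")
  d <- vapply(loci, function(l) {
    f <- aligned_freqs(A, B, l)
    sqrt(0.5 * sum((f$pa - f$pb)^2))
  }, numeric(1))
  mean(d)
}

#' Nei's (1978) unbiased genetic distance
#'
#' `D = -log(Jxy / sqrt(Jx * Jy))` where `Jxy` is the mean across jointly
#' typed loci of the between-group gene identity `sum(pA * pB)`, and `Jx`,
#' `Jy` are means of the small-sample-corrected within-group identities
#' `(2n * sum(p^2) - 1) / (2n - 1)`.  The correction can overshoot for very
#' similar groups, giving a slightly negative distance; such values are
#' clamped to 0 (attribute `clamped`).  Groups sharing no allele at any
#' jointly typed locus have zero between-identity and the distance is `Inf`
#' (with a warning).  Loci with fewer than 2 gene copies in either group are
#' excluded (with a warning), since the unbiased correction is undefined there.
#'
#' @param A,B `allele_freq_profile` objects.
#' @return non-negative numeric scalar, possibly `Inf`.
#' @export
nei_unbiased_distance <- function(A, B) {
  loci <- joint_loci(A, B)
  if (!length(loci)) stop_validation("no comparable loci between groups '",
                                     A$group, "' and '", B$group, "'")
  usable <- loci[A$n_copies[loci] >= 2 & B$n_copies[loci] >= 2]
  if (length(usable) < length(loci))
    warning("excluding ", length(loci) - length(usable),
            " locus/loci with < 2 gene copies from Nei's D")
  if (!length(usable)) stop_validation("no locus with >= 2 gene copies in both groups")
  jxy <- jx <- jy <- numeric(length(usable))
  for (i in seq_along(usable)) {
    l <- usable[i]
    f <- aligned_freqs(A, B, l)
    jxy[i] <- sum(f$pa * f$pb)
    nx <- A$n_copies[[l]]; ny <- B$n_copies[[l]]
    jx[i] <- (nx * sum(f$pa^2) - 1) / (nx - 1)
    jy[i] <- (ny * sum(f$pb^2) - 1) / (ny - 1)
  }
  if (mean(jxy) == 0) {
    warning("groups '", A$group, "' and '", B$group,
            "' share no alleles at any locus: Nei's D is infinite")
    return(Inf)
  }
  d <- -log(mean(jxy) / sqrt(mean(jx) * mean(jy)))
  clamped <- FALSE
  if (is.finite(d) && d < 0) { d <- 0; clamped <- TRUE }
  structure(d, clamped = clamped)
}

#' Fixed differences between two allele-frequency profiles
#'
#' A locus is a fixed difference when the two groups share (essentially) no
#' alleles there.  The shared-allele mass at a locus is
#' `m = sum over alleles present in both groups of (pA + pB) / 2`; the locus
#' counts as fixed iff `m <= tolerance`.  `tolerance = 0` is the strict
#' definition (no shared alleles at all); the customary 10% cumulative
#' tolerance (`tolerance = 0.1`) lets loci through where rare alleles leak
#' across otherwise-diagnostic groups.  The denominator for the percentage is
#' the number of loci scorable in both groups, not the panel size.
#'
#' @param A,B `allele_freq_profile` objects.
#' @param tolerance maximum shared-allele mass for a locus to count, in
#'   `[0, 0.5)`.
#' @return an object of class `fd_result`: list with `count`, `denominator`,
#'   `percent` (unrounded), `percent_display` (rounded half away from zero),
#'   `fd_loci`, `shared_mass` (named, all jointly typed loci), `tolerance`.
#' @export
fixed_differences <- function(A, B, tolerance = 0.10) {
  if (!is.numeric(tolerance) || length(tolerance) != 1 ||
      tolerance < 0 || tolerance >= 0.5)
    stop_validation("tolerance must be a single value in [0, 0.5)")
  loci <- joint_loci(A, B)
  if (!length(loci)) stop_validation("no comparable loci between groups '",
                                     A$group, "' and '", B$group, "'")
  shared <- vapply(loci, function(l) {
    f <- aligned_freqs(A, B, l)
    both <- f$pa > 0 & f$pb > 0
    sum((f$pa[both] + f$pb[both]) / 2)
  }, numeric(1))
  fd <- shared <= tolerance
  pct <- 100 * sum(fd) / length(loci)
  structure(list(count = sum(fd), denominator = length(loci),
                 percent = pct, percent_display = round_half_away(pct),
                 fd_loci = loci[fd], shared_mass = shared,
                 tolerance = tolerance),
            class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("%d fixed differences over %d comparable loci (%d%%), tolerance %.2f\n",
              x$count, x$denominator, x$percent_display, x$tolerance))
  invisible(x)
}

#' Pairwise allozyme distance matrix over groups
#'
#' @param profiles list of `allele_freq_profile` objects (see
#'   [allele_frequencies()]).
#' @param statistic `"rogers"`, `"nei_unbiased"`, `"fd_count"` or `"fd_percent"`.
#' @param tolerance shared-allele tolerance for the FD statistics.
#' @return a [dist_matrix()] over the profile group labels.
#' @export
allozyme_distance_matrix <- function(profiles,
                                     statistic = c("rogers", "nei_unbiased",
                                                   "fd_count", "fd_percent"),
                                     tolerance = 0.10) {
  statistic <- match.arg(statistic)
  if (length(profiles) < 2) stop_validation("need at least 2 profiles")
  labs <- vapply(profiles, function(p) p$group, character(1))
  n <- length(labs)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- switch(statistic,
      rogers = rogers_distance(profiles[[i]], profiles[[j]]),
      nei_unbiased = as.numeric(nei_unbiased_distance(profiles[[i]], profiles[[j]])),
      fd_count = fixed_differences(profiles[[i]], profiles[[j]], tolerance)$count,
      fd_percent = fixed_differences(profiles[[i]], profiles[[j]], tolerance)$percent)
    m[i, j] <- m[j, i] <- v
  }
  dist_matrix(m, statistic = switch(statistic, rogers = "rogers",
                                    nei_unbiased = "nei_unbiased", "other"))
}

## Fast individual-level Rogers matrix used by the stepwise clustering: one
## dist() per locus over the individuals-x-alleles frequency matrix, averaged
## over the loci typed in both members of each pair.  Equivalent to calling
## rogers_distance() on single-individual profiles (checked by test).
individual_rogers_matrix <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  n <- length(gt$individuals)
  acc <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  for (j in seq_along(gt$loci)) {
    typed <- which(!is.na(gt$allele1[, j]))
    if (length(typed) < 2) next
    alleles <- sort(unique(c(gt$allele1[typed, j], gt$allele2[typed, j])))
    X <- matrix(0, length(typed), length(alleles),
                dimnames = list(NULL, alleles))
    X[cbind(seq_along(typed), match(gt$allele1[typed, j], alleles))] <-
      X[cbind(seq_along(typed), match(gt$allele1[typed, j], alleles))] + 0.5
    X[cbind(seq_along(typed), match(gt$allele2[typed, j], alleles))] <-
      X[cbind(seq_along(typed), match(gt$allele2[typed, j], alleles))] + 0.5
    dl <- sqrt(0.5) * as.matrix(stats::dist(X))
    acc[typed, typed] <- acc[typed, typed] + dl
    cnt[typed, typed] <- cnt[typed, typed] + 1L
  }
  if (any(cnt[upper.tri(cnt)] == 0))
    stop_validation("some individual pairs share no typed locus")
  m <- acc / pmax(cnt, 1L)
  diag(m) <- 0
  dimnames(m) <- list(gt$individuals, gt$individuals)
  dist_matrix((m + t(m)) / 2, statistic = "rogers")
}
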