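## Builders and independent oracles shared across tests.  Oracles here are
## deliberately naive (loops, enumeration) and written against the
## definitions, not against the package code paths they check.

## construct an allele_freq_profile directly from planted frequencies
profile <- function(group, freqs, n = 20) {
  n_copies <- vapply(freqs, function(f) if (length(f)) n else 0L, numeric(1))
  freqs <- lapply(freqs, function(f) if (length(f)) f / sum(f) else numeric(0))
  structure(list(group = group, freqs = freqs,
                 n_copies = stats::setNames(n_copies, names(freqs)),
                 n_individuals = n / 2),
            class = "allele_freq_profile")
}

## random profile over n_loci loci with alleles drawn from a small pool
random_profile <- function(group, n_loci = 6, pool = letters[1:4], n = 20) {
  freqs <- lapply(seq_len(n_loci), function(l) {
    k <- sample(1:3, 1)
    a <- sample(pool, k)
    w <- as.numeric(stats::rmultinom(1, n, rep(1, k)))
    keep <- w > 0
    stats::setNames(w[keep] / sum(w), a[keep])
  })
  names(freqs) <- sprintf("L%02d", seq_len(n_loci))
  profile(group, freqs, n = n)
}

## brute-force strict fixed differences: loci with empty allele-set overlap
fd_strict_oracle <- function(A, B) {
  loci <- names(A$n_copies)[A$n_copies > 0 & B$n_copies > 0]
  sum(vapply(loci, function(l)
    length(intersect(names(A$freqs[[l]]), names(B$freqs[[l]]))) == 0, logical(1)))
}

## straight-line Nei (1978) unbiased distance for aligned frequency vectors
nei_oracle <- function(pA, pB, nA, nB) {
  jxy <- jx <- jy <- numeric(length(pA))
  for (l in seq_along(pA)) {
    jxy[l] <- sum(pA[[l]] * pB[[l]])
    jx[l] <- (nA * sum(pA[[l]]^2) - 1) / (nA - 1)
    jy[l] <- (nB * sum(pB[[l]]^2) - 1) / (nB - 1)
  }
  -log(mean(jxy) / sqrt(mean(jx) * mean(jy)))
}

## naive per-character p-distance with pairwise deletion
p_distance_oracle <- function(x, y) {
  x <- strsplit(toupper(x), "")[[1]]; y <- strsplit(toupper(y), "")[[1]]
  good <- c("A", "C", "G", "T")
  n <- 0L; mism <- 0L
  for (i in seq_along(x)) {
    if (x[i] %in% good && y[i] %in% good) {
      n <- n + 1L
      if (x[i] != y[i]) mism <- mism + 1L
    }
  }
  mism / n
}

## all bipartitions of an unrooted tree, as sorted tip-label sets
tree_bipartitions <- function(tr) {
  tr <- ape::unroot(tr)
  n <- length(tr$tip.label)
  below <- function(node) {
    if (node <= n) return(node)
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  lapply(tr$edge[, 2], function(nd) sort(tr$tip.label[below(nd)]))
}

## brute-force monophyly on the unrooted topology by bipartition enumeration
mono_oracle <- function(tr, tips) {
  tips <- sort(tips)
  comp <- sort(setdiff(tr$tip.label, tips))
  any(vapply(tree_bipartitions(tr),
             function(p) identical(p, tips) || identical(p, comp), logical(1)))
}

## random nucleotide string
random_seq <- function(n, gap_rate = 0) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (gap_rate > 0) s[stats::runif(n) < gap_rate] <- sample(c("-", "N"), 1)
  paste(s, collapse = "")
}

## tiny two-group genotype table with `fd` planted strict fixed differences
## and `shared` extra loci where both groups are fixed for the same allele
two_group_gt <- function(n_per = 10, fd = 4, shared = 6, seed = 1) {
  set.seed(seed)
  spec <- scenario_spec(
    group_sizes = c(g1 = n_per, g2 = n_per), n_loci = fd + shared,
    fd_target = matrix(c(0, fd, fd, 0), 2, 2,
                       dimnames = list(c("g1", "g2"), c("g1", "g2"))),
    seed = seed)
  simulate_allozymes(spec)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "crenadelim", mustWork = TRUE)
}
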