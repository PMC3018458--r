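## Pairwise nucleotide divergences.  Sites where either sequence is not an
## unambiguous A/C/G/T (gaps, N, IUPAC ambiguity codes) are excluded from the
## comparison ("pairwise deletion"); ambiguity codes are never partially
## matched.

comparable_sites <- function(x, y) {
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  list(x = x[ok], y = y[ok], n = sum(ok))
}

as_char_seq <- function(s) {
  if (length(s) == 1L && is.character(s)) strsplit(toupper(s), "")[[1]] else toupper(s)
}

#' Uncorrected pairwise distance (p-distance)
#'
#' Proportion of mismatching sites among sites where both sequences carry an
#' unambiguous base.
#'
#' @param x,y nucleotide sequences: single strings or character vectors, equal
#'   length.
#' @return numeric in `[0, 1]`, with attribute `sites` (number compared).
#' @export
p_distance <- function(x, y) {
  x <- as_char_seq(x); y <- as_char_seq(y)
  if (length(x) != length(y)) stop_validation("sequences must have equal length")
  cs <- comparable_sites(x, y)
  if (cs$n == 0) stop_validation("no comparable sites between sequences")
  structure(sum(cs$x != cs$y) / cs$n, sites = cs$n)
}

## pooled empirical base frequencies of the comparable sites of a pair
pair_base_freqs <- function(x, y) {
  tab <- table(factor(c(x, y), levels = c("A", "C", "G", "T")))
  f <- as.numeric(tab) / sum(tab)
  stats::setNames(f, c("A", "C", "G", "T"))
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Model-corrected pairwise distance
#'
#' Estimated substitutions per site between two sequences under a nucleotide
#' substitution model.  JC69, K2P and TN93 use their closed forms; GTR+G
#' (the default model of the pipeline, closest to a GTR+I+G tree analysis)
#' maximises the likelihood of the pairwise site-pattern counts over the
#' branch length numerically, with empirical base frequencies from the pair
#' unless supplied.  Saturated pairs for which a closed-form logarithm has a
#' non-positive argument return `Inf` with a warning.
#'
#' @param x,y nucleotide sequences (strings or character vectors).
#' @param model `"JC69"`, `"K2P"`, `"TN93"` or `"GTR+G"`.
#' @param rates for GTR+G: exchangeability rates `c(AC, AG, AT, CG, CT, GT)`
#'   (default all 1; GT is the reference rate).
#' @param base_freqs for GTR+G: stationary base frequencies A,C,G,T; default
#'   empirical from the pair.
#' @param gamma_shape gamma rate-heterogeneity shape for GTR+G (4 discrete
#'   categories); default 1.
#' @return non-negative numeric scalar (possibly `Inf`).
#' @export
corrected_distance <- function(x, y, model = c("GTR+G", "JC69", "K2P", "TN93"),
                               rates = rep(1, 6), base_freqs = NULL,
                               gamma_shape = 1) {
  model <- match.arg(model)
  x <- as_char_seq(x); y <- as_char_seq(y)
  if (length(x) != length(y)) stop_validation("sequences must have equal length")
  cs <- comparable_sites(x, y)
  if (cs$n == 0) stop_validation("no comparable sites between sequences")
  p <- sum(cs$x != cs$y) / cs$n
  if (p == 0) return(0)
  saturated <- function() {
    warning("correction undefined (saturated divergence) under ", model)
    Inf
  }
  if (model == "JC69") {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) return(saturated())
    return(-0.75 * log(arg))
  }
  if (model == "K2P") {
    ts <- is_transition(cs$x, cs$y)
    P <- sum(ts) / cs$n
    Q <- p - P
    a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
    if (a1 <= 0 || a2 <= 0) return(saturated())
    return(-0.5 * log(a1) - 0.25 * log(a2))
  }
  if (model == "TN93") {
    f <- pair_base_freqs(cs$x, cs$y)
    gR <- f["A"] + f["G"]; gY <- f["C"] + f["T"]
    diffs <- cs$x != cs$y
    P1 <- sum(diffs & ((cs$x == "A" & cs$y == "G") | (cs$x == "G" & cs$y == "A"))) / cs$n
    P2 <- sum(diffs & ((cs$x == "C" & cs$y == "T") | (cs$x == "T" & cs$y == "C"))) / cs$n
    Q <- p - P1 - P2
    k1 <- 2 * f["A"] * f["G"] / gR
    k2 <- 2 * f["C"] * f["T"] / gY
    k3 <- 2 * (gR * gY - f["A"] * f["G"] * gY / gR - f["C"] * f["T"] * gR / gY)
    a1 <- 1 - P1 / k1 - Q / (2 * gR)
    a2 <- 1 - P2 / k2 - Q / (2 * gY)
    a3 <- 1 - Q / (2 * gR * gY)
    if (a1 <= 0 || a2 <= 0 || a3 <= 0) return(saturated())
    return(as.numeric(-k1 * log(a1) - k2 * log(a2) - k3 * log(a3)))
  }
  ## GTR+G: discrete-gamma mixture likelihood of the 4x4 pattern counts,
  ## branch length optimised numerically.
  if (is.null(base_freqs)) base_freqs <- pair_base_freqs(cs$x, cs$y)
  base_freqs <- base_freqs / sum(base_freqs)
  if (any(base_freqs <= 0)) {
    ## a base absent from both sequences cannot inform the rate matrix
    base_freqs <- (base_freqs + 1e-4) / sum(base_freqs + 1e-4)
  }
  Q <- gtr_rate_matrix(rates, base_freqs)
  counts <- table(factor(cs$x, levels = c("A", "C", "G", "T")),
                  factor(cs$y, levels = c("A", "C", "G", "T")))
  gr <- discrete_gamma_rates(gamma_shape, 4)
  negll <- function(t) {
    ll <- 0
    M <- matrix(0, 4, 4)
    for (r in gr) M <- M + 0.25 * transition_probs(Q, t * r)
    joint <- base_freqs * M          # pi_i * P[i -> j]
    -sum(counts * log(pmax(joint, 1e-300)))
  }
  opt <- stats::optimize(negll, interval = c(1e-8, 20))
  opt$minimum
}

## GTR generator matrix scaled to one expected substitution per unit time
gtr_rate_matrix <- function(rates, freqs) {
  if (length(rates) != 6 || any(rates <= 0))
    stop_validation("GTR needs 6 positive exchangeability rates")
  R <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  R["A", "C"] <- rates[1]; R["A", "G"] <- rates[2]; R["A", "T"] <- rates[3]
  R["C", "G"] <- rates[4]; R["C", "T"] <- rates[5]; R["G", "T"] <- rates[6]
  R <- R + t(R)
  Q <- R * rep(freqs, each = 4)   # q_ij = r_ij * pi_j
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q / scale
}

## P(t) = exp(Qt) via the symmetrised eigendecomposition of a reversible Q
transition_probs <- function(Q, t) {
  e <- eigen_q(Q)
  P <- e$U %*% (exp(e$values * t) * e$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

eigen_q <- function(Q) {
  key <- paste(format(Q, digits = 15), collapse = ",")
  cached <- .eigen_cache[[key]]
  if (!is.null(cached)) return(cached)
  e <- eigen(Q)
  out <- list(values = Re(e$values), U = Re(e$vectors), Uinv = Re(solve(e$vectors)))
  .eigen_cache[[key]] <- out
  out
}
.eigen_cache <- new.env(parent = emptyenv())

## mean rates of k equal-probability discrete gamma categories (mean 1)
discrete_gamma_rates <- function(shape, k = 4) {
  if (shape <= 0) stop_validation("gamma shape must be positive")
  q <- stats::qgamma((seq_len(k) - 0.5) / k, shape = shape, rate = shape)
  q / mean(q)
}

#' Pairwise DNA distance matrix for an alignment
#'
#' @param aln a `sequence_alignment` (see [read_fasta()]) or character matrix
#'   of aligned sequences with rownames.
#' @param model `"p"` for the uncorrected distance, else a
#'   [corrected_distance()] model.
#' @param ... passed to [corrected_distance()].
#' @return a [dist_matrix()] with the per-pair compared-site counts in its
#'   `support` attribute.
#' @export
dna_distance_matrix <- function(aln, model = "p", ...) {
  if (!is.matrix(aln)) stop_validation("alignment must be a matrix of sequences")
  n <- nrow(aln)
  if (n < 2) stop_validation("need at least 2 sequences")
  labs <- rownames(aln)
  m <- sup <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (model == "p") {
      d <- p_distance(aln[i, ], aln[j, ])
      sup[i, j] <- sup[j, i] <- attr(d, "sites")
      m[i, j] <- m[j, i] <- as.numeric(d)
    } else {
      m[i, j] <- m[j, i] <- corrected_distance(aln[i, ], aln[j, ], model = model, ...)
    }
  }
  dist_matrix(m, statistic = if (model == "p") "p_uncorrected" else "corrected",
              support = sup)
}

#' Between- and within-group divergence summary
#'
#' The quantities a delimitation argument needs from a divergence matrix:
#' for each pair of groups the minimum / mean / maximum between-group value,
#' and for each group with at least 2 members the maximum / mean within-group
#' value (singleton groups get `NA`, not zero).
#'
#' @param m a [dist_matrix()].
#' @param grouping named character vector mapping every matrix label to a group.
#' @return list with `between` (data.frame: group1, group2, min, mean, max)
#'   and `within` (data.frame: group, n, max, mean), plus scalars
#'   `min_between` and `max_within`.
#' @export
group_divergence_summary <- function(m, grouping) {
  labs <- rownames(m)
  if (!all(labs %in% names(grouping)))
    stop_validation("grouping must cover all matrix labels")
  g <- as.character(grouping[labs])
  groups <- unique(g)
  bet <- NULL
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2)
    bet <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      v <- m[g == pairs[1, k], g == pairs[2, k], drop = FALSE]
      data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
                 min = min(v), mean = mean(v), max = max(v))
    }))
  }
  wit <- do.call(rbind, lapply(groups, function(gr) {
    idx <- which(g == gr)
    if (length(idx) < 2)
      return(data.frame(group = gr, n = length(idx), max = NA_real_, mean = NA_real_))
    v <- m[idx, idx][upper.tri(diag(length(idx)))]
    data.frame(group = gr, n = length(idx), max = max(v), mean = mean(v))
  }))
  list(between = bet, within = wit,
       min_between = if (is.null(bet)) NA_real_ else min(bet$min),
       max_within = if (all(is.na(wit$max))) NA_real_ else max(wit$max, na.rm = TRUE))
}

#' Convert a crown divergence to a per-lineage rate
#'
#' A total divergence `d` between two lineages that split `crown_age` million
#' years ago corresponds to `100 * d / (2 * crown_age)` percent sequence
#' change per lineage per million years.
#'
#' @param d divergence (substitutions per site or proportion of sites).
#' @param crown_age age of the split, in millions of years (> 0).
#' @return percent per lineage per million years.
#' @export
divergence_to_rate <- function(d, crown_age) {
  if (!is.numeric(crown_age) || any(crown_age <= 0))
    stop_validation("crown_age must be positive")
  100 * d / (2 * crown_age)
}
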