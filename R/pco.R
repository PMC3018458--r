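#' Principal Co-ordinates Analysis (classical metric scaling)
#'
#' Embeds a distance matrix into Euclidean axes ordered by explained
#' variation: Gower double-centering of `-0.5 * d^2`, eigendecomposition, and
#' coordinates `eigenvector * sqrt(lambda)` for each positive eigenvalue.
#' Negative eigenvalues (which arise when the distances are not Euclidean-
#' embeddable) are discarded from both the coordinates and the variation
#' denominator; their count is reported.  Per-axis sign is fixed by making
#' the largest-magnitude loading positive, so results are reproducible across
#' platforms.
#'
#' @param m a [dist_matrix()] (or plain symmetric labelled matrix).
#' @param k number of axes to keep (capped at the number of positive
#'   eigenvalues); default 2, the scatterplot dimensions of stepwise
#'   delimitation.
#' @return an object of class `pco_result`: `labels`, `coordinates`
#'   (n x k' matrix), `eigenvalues` (all positive ones, descending),
#'   `percent` (percent of total multivariate variation per kept axis),
#'   `n_negative` (count of discarded negative eigenvalues).
#' @export
pco <- function(m, k = 2) {
  m <- unclass(m)
  n <- nrow(m)
  if (is.null(n) || n < 2) stop_validation("PCO needs at least 2 labels")
  if (any(abs(m - t(m)) > 1e-12) || any(diag(m) != 0))
    stop_validation("PCO input must be symmetric with a zero diagonal")
  labs <- rownames(m) %||% as.character(seq_len(n))
  B <- -0.5 * m^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  if (!length(pos)) stop_validation("degenerate configuration: no positive eigenvalue")
  lambda <- e$values[pos]
  n_neg <- sum(e$values < -tol)
  keep <- seq_len(min(k, length(pos)))
  V <- e$vectors[, pos[keep], drop = FALSE]
  for (a in seq_len(ncol(V))) {
    i <- which.max(abs(V[, a]))
    if (V[i, a] < 0) V[, a] <- -V[, a]
  }
  coords <- sweep(V, 2, sqrt(lambda[keep]), `*`)
  dimnames(coords) <- list(labs, paste0("PCO", keep))
  structure(list(labels = labs, coordinates = coords,
                 eigenvalues = lambda,
                 percent = 100 * lambda[keep] / sum(lambda),
                 n_negative = n_neg),
            class = "pco_result")
}

#' @export
print.pco_result <- function(x, ...) {
  cat("PCO of", length(x$labels), "labels:",
      ncol(x$coordinates), "axes kept of", length(x$eigenvalues), "positive\n")
  cat("  % variation:", paste(sprintf("%.1f", x$percent), collapse = ", "), "\n")
  if (x$n_negative)
    cat("  discarded", x$n_negative, "negative eigenvalue(s)\n")
  invisible(x)
}
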