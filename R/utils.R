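#' @keywords internal
"_PACKAGE"

## condition helpers: validation errors (bad inputs/contracts) vs parse errors
## (malformed files) carry distinct classes so callers and the CLI can map
## them to exit codes.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("crenadelim_validation_error", "error")))
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("crenadelim_parse_error", "error")))
}

## round half away from zero (what gets printed next to FD counts);
## base round() rounds half to even, which is not the display convention here.
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items.
#' Returns 1 for identical partitions (up to label renaming), approximately 0
#' for independent ones.
#'
#' @param a,b vectors of cluster labels, same length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_validation("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

## structured one-line stage log used by run_pipeline
log_stage <- function(log_lines, stage, ..., t0 = NULL) {
  kv <- list(...)
  extra <- if (length(kv)) {
    paste(vapply(seq_along(kv), function(i) paste0(names(kv)[i], "=", kv[[i]]),
                 character(1)), collapse = " ")
  } else ""
  elapsed <- if (!is.null(t0)) sprintf(" wall=%.2fs", as.numeric(Sys.time()) - t0) else ""
  c(log_lines, sprintf("[%s] stage=%s %s%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                       stage, extra, elapsed))
}
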