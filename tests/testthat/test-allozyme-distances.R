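test_that("Rogers' distance matches hand-evaluated cases", {
  A <- profile("A", list(L1 = c(a = 1)))
  B <- profile("B", list(L1 = c(b = 1)))
  expect_equal(rogers_distance(A, B), 1)
  expect_equal(rogers_distance(A, A), 0)
  A2 <- profile("A", list(L1 = c(a = 1)))
  B2 <- profile("B", list(L1 = c(a = 0.5, b = 0.5)))
  expect_equal(rogers_distance(A2, B2), 0.5)  # sqrt(0.5 * (0.25 + 0.25))
  # loci typed in only one group are excluded, not counted as zero
  A3 <- profile("A", list(L1 = c(a = 1), L2 = c(a = 1)))
  B3 <- profile("B", list(L1 = c(b = 1), L2 = numeric(0)))
  expect_equal(rogers_distance(A3, B3), 1)
  expect_error(rogers_distance(profile("A", list(L1 = numeric(0))),
                               profile("B", list(L1 = c(a = 1)))),
               "no comparable loci", class = "crenadelim_validation_error")
})

test_that("Nei's unbiased distance agrees with a straight-line oracle", {
  A <- profile("A", list(L1 = c(a = 0.9, b = 0.1)), n = 20)
  B <- profile("B", list(L1 = c(a = 0.1, b = 0.9)), n = 20)
  expect_equal(as.numeric(nei_unbiased_distance(A, B)),
               nei_oracle(list(c(0.9, 0.1)), list(c(0.1, 0.9)), 20, 20),
               tolerance = 1e-12)
  # multi-locus random profiles against the oracle
  set.seed(42)
  for (rep in 1:20) {
    X <- random_profile("X", n_loci = 5)
    Y <- random_profile("Y", n_loci = 5)
    pA <- pB <- vector("list", 5)
    for (l in 1:5) {
      al <- union(names(X$freqs[[l]]), names(Y$freqs[[l]]))
      pA[[l]] <- stats::setNames(numeric(length(al)), al)
      pB[[l]] <- pA[[l]]
      pA[[l]][names(X$freqs[[l]])] <- X$freqs[[l]]
      pB[[l]][names(Y$freqs[[l]])] <- Y$freqs[[l]]
    }
    got <- as.numeric(nei_unbiased_distance(X, Y))
    want <- max(0, nei_oracle(pA, pB, 20, 20))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Nei's distance handles identity, disjoint profiles and clamping", {
  # identical frequencies at large n: D -> 0 (within-identity correction ~ 0)
  A <- profile("A", list(L1 = c(a = 0.5, b = 0.5), L2 = c(a = 1)), n = 1e6)
  expect_equal(as.numeric(nei_unbiased_distance(A, A)), 0, tolerance = 1e-4)
  # no shared allele anywhere: -log(0) = Inf, flagged by a warning
  B <- profile("B", list(L1 = c(c = 1), L2 = c(d = 1)), n = 20)
  expect_warning(d <- nei_unbiased_distance(A, B), "no alleles")
  expect_identical(as.numeric(d), Inf)
  # sampling-correction overshoot is clamped to zero and flagged
  C1 <- profile("C1", list(L1 = c(a = 0.5, b = 0.5)), n = 4)
  d2 <- nei_unbiased_distance(C1, C1)
  expect_equal(as.numeric(d2), 0)
  expect_true(attr(d2, "clamped"))
})

test_that("fixed differences implement the cumulative shared-mass tolerance rule", {
  # shared mass 0.06 <= 0.10: locus still counts as fixed
  A <- profile("A", list(L1 = c(a = 0.94, s = 0.06)))
  B <- profile("B", list(L1 = c(b = 0.94, s = 0.06)))
  expect_equal(fixed_differences(A, B, 0.10)$count, 1)
  expect_equal(fixed_differences(A, B, 0)$count, 0)   # strict rule
  # shared mass 0.2 > 0.10: does not count
  A2 <- profile("A", list(L1 = c(a = 0.8, s = 0.2)))
  B2 <- profile("B", list(L1 = c(b = 0.8, s = 0.2)))
  expect_equal(fixed_differences(A2, B2, 0.10)$count, 0)
  expect_error(fixed_differences(A, B, 0.6), "tolerance",
               class = "crenadelim_validation_error")
  expect_error(fixed_differences(A, B, -0.1), "tolerance",
               class = "crenadelim_validation_error")
})

test_that("strict fixed differences equal brute-force allele-set intersection", {
  set.seed(11)
  for (rep in 1:100) {
    A <- random_profile("A")
    B <- random_profile("B")
    expect_identical(fixed_differences(A, B, 0)$count, fd_strict_oracle(A, B))
  }
})

test_that("FD count is monotone in tolerance and percentages use joint denominators", {
  set.seed(12)
  for (rep in 1:25) {
    A <- random_profile("A", n_loci = 8)
    B <- random_profile("B", n_loci = 8)
    counts <- vapply(c(0, 0.05, 0.1, 0.2, 0.4),
                     function(tol) fixed_differences(A, B, tol)$count, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
  # display percent rounds half away from zero over the joint denominator
  A <- profile("A", c(lapply(1:18, function(i) c(a = 1)),
                      lapply(19:41, function(i) c(c = 1))) |>
                 stats::setNames(sprintf("L%02d", 1:41)))
  B <- profile("B", c(lapply(1:18, function(i) c(b = 1)),
                      lapply(19:41, function(i) c(c = 1))) |>
                 stats::setNames(sprintf("L%02d", 1:41)))
  fd <- fixed_differences(A, B, 0)
  expect_equal(fd$denominator, 41)
  expect_equal(fd$percent_display, 44)  # 100*18/41 = 43.9
})

test_that("Rogers obeys symmetry, bounds and the triangle inequality", {
  set.seed(13)
  for (rep in 1:60) {
    A <- random_profile("A"); B <- random_profile("B"); C <- random_profile("C")
    dab <- rogers_distance(A, B)
    expect_equal(dab, rogers_distance(B, A))
    expect_true(dab >= 0 && dab <= 1)
    expect_lte(dab, rogers_distance(A, C) + rogers_distance(C, B) + 1e-12)
  }
})

test_that("the fast individual-level Rogers matrix matches pairwise profiles", {
  sim <- two_group_gt(n_per = 5, fd = 3, shared = 4, seed = 21)
  gt <- sim$genotypes
  m <- crenadelim:::individual_rogers_matrix(gt)
  prof <- allele_frequencies(gt, grouping = "individual")
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(m[i, j],
                 rogers_distance(prof[[gt$individuals[i]]], prof[[gt$individuals[j]]]),
                 tolerance = 1e-12)
  }
  expect_identical(attr(m, "statistic"), "rogers")
})
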