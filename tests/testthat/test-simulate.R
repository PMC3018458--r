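test_that("planted fixed-difference counts are realized exactly", {
  fdm <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))
  spec <- scenario_spec(group_sizes = c(g1 = 20, g2 = 20), n_loci = 10,
                        fd_target = fdm, seed = 1)
  sim <- simulate_allozymes(spec)
  prof <- allele_frequencies(sim$genotypes, sim$truth$grouping)
  expect_equal(fixed_differences(prof$g1, prof$g2, 0)$count, 4)
  expect_equal(sim$truth$fd_strict["g1", "g2"], 4)
  # three groups with unequal demands
  g3 <- c("a", "b", "c")
  fdm3 <- matrix(c(0, 3, 7, 3, 0, 6, 7, 6, 0), 3, 3, dimnames = list(g3, g3))
  spec3 <- scenario_spec(group_sizes = stats::setNames(rep(6L, 3), g3),
                         n_loci = 12, fd_target = fdm3, seed = 2)
  sim3 <- simulate_allozymes(spec3)
  expect_true(all(sim3$truth$fd_strict[g3, g3] == fdm3))
})

test_that("realized counts equal planted whenever n >= 5 and no missingness", {
  for (s in 1:5) {
    fdm <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
                  dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
    spec <- scenario_spec(group_sizes = c(x = 5, y = 8, z = 5), n_loci = 15,
                          fd_target = fdm, seed = s)
    sim <- simulate_allozymes(spec)
    expect_true(all(sim$truth$fd_strict[rownames(fdm), colnames(fdm)] == fdm),
                info = paste("seed", s))
  }
})

test_that("infeasible FD plans are rejected before sampling", {
  g3 <- c("a", "b", "c")
  # violates the triangle inequality of Hamming distances: 10 > 4 + 4
  bad <- matrix(c(0, 4, 4, 4, 0, 10, 4, 10, 0), 3, 3, dimnames = list(g3, g3))
  expect_error(scenario_spec(group_sizes = stats::setNames(rep(5L, 3), g3),
                             n_loci = 30, fd_target = bad, seed = 1),
               "infeasible", class = "crenadelim_validation_error")
  # demands exceeding the locus budget
  big <- matrix(c(0, 9, 9, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(scenario_spec(group_sizes = c(a = 5, b = 5), n_loci = 5,
                             fd_target = big, seed = 1),
               "loci", class = "crenadelim_validation_error")
})

test_that("no planted differences means no delimitable structure", {
  sim <- two_group_gt(n_per = 8, fd = 0, shared = 10, seed = 4)
  expect_equal(length(unique(terminal_clusters(stepwise_pco(sim$genotypes)))), 1)
})

test_that("identical seeds give byte-identical outputs, different seeds differ", {
  spec_a <- make_paper_like_scenario(seed = 7)
  spec_b <- make_paper_like_scenario(seed = 7)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_genotypes(simulate_allozymes(spec_a)$genotypes, f1)
  write_genotypes(simulate_allozymes(spec_b)$genotypes, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(simulate_sequences(spec_a)$alignment,
                   simulate_sequences(spec_b)$alignment)
  spec_c <- make_paper_like_scenario(seed = 8)
  expect_false(identical(simulate_allozymes(spec_c)$genotypes$allele1,
                         simulate_allozymes(spec_a)$genotypes$allele1))
})

test_that("empirical allele frequencies converge to planted values", {
  spec <- scenario_spec(group_sizes = c(g1 = 500, g2 = 500), n_loci = 6,
                        fd_target = matrix(c(0, 2, 2, 0), 2, 2,
                                           dimnames = list(c("g1", "g2"),
                                                           c("g1", "g2"))),
                        tolerant_loci = 5:6, seed = 10)
  sim <- simulate_allozymes(spec)
  prof <- allele_frequencies(sim$genotypes, sim$truth$grouping)
  planted <- crenadelim:::spec_frequencies(spec)
  for (l in seq_len(6)) {
    for (g in c("g1", "g2")) {
      want <- planted[[l]][[g]]
      got <- prof[[g]]$freqs[[l]]
      for (a in names(want))
        expect_lt(abs(unname(got[a]) - unname(want[a])), 0.03)
    }
  }
})

test_that("tolerant loci are fixed under the 10% rule but not strictly", {
  spec <- make_paper_like_scenario(seed = 11)
  sim <- simulate_allozymes(spec)
  strict <- sim$truth$fd_strict
  tol <- sim$truth$fd_tolerant
  expect_true(all(tol >= strict))
  # the injected shared-allele loci add tolerant-only FDs for cross-half pairs
  expect_gt(max(tol - strict), 0)
})

test_that("sequence simulation matches closed-form expectations", {
  # zero-length tree: all sequences identical
  spec0 <- scenario_spec(group_sizes = c(g1 = 1, g2 = 1), n_loci = 1,
                         tree = "(g1_01:0,g2_01:0);",
                         seq_grouping = c(g1_01 = "g1", g2_01 = "g2"),
                         aln_length = 500, seed = 1)
  aln0 <- simulate_sequences(spec0)$alignment
  expect_identical(aln0[1, ], aln0[2, ])
  # two-taxon JC at total length 0.3: E[p] = (3/4)(1 - exp(-4*0.3/3))
  spec_jc <- scenario_spec(group_sizes = c(g1 = 1, g2 = 1), n_loci = 1,
                           tree = "(g1_01:0.15,g2_01:0.15);",
                           seq_grouping = c(g1_01 = "g1", g2_01 = "g2"),
                           aln_length = 100000, seed = 1)
  p <- simulate_sequences(spec_jc)$truth$p_distances[1, 2]
  expect_equal(p, 0.75 * (1 - exp(-0.4)), tolerance = 0.01)
})

test_that("the study-like scenario matches the published design envelope", {
  spec <- make_paper_like_scenario(seed = 1)
  expect_length(spec$group_sizes, 10)
  expect_equal(sum(spec$group_sizes), 94)
  expect_equal(spec$n_loci, 42)
  expect_equal(spec$aln_length, 828)
  sim <- simulate_allozymes(spec)
  expect_equal(dim(sim$genotypes$allele1), c(94L, 42L))
  fd <- spec$fd_planted
  kim <- paste0("Kimberley", LETTERS[1:5])
  kim_fd <- fd[kim, kim][upper.tri(diag(5))]
  expect_true(all(kim_fd >= 4 & kim_fd <= 14))
  cross <- fd[setdiff(rownames(fd), kim), ]
  cross <- cross[, colnames(cross) != rownames(cross)]
  off <- fd[upper.tri(fd)]
  expect_true(all(off >= 4 & off <= 21))
  primary_pairs <- fd[setdiff(rownames(fd), kim), c(setdiff(rownames(fd), kim), kim)]
  expect_true(all(fd[setdiff(rownames(fd), kim), kim] >= 6))
  # between-group sequence divergences land in the published 0.14-0.29 span
  seqs <- simulate_sequences(spec)
  sm <- group_divergence_summary(seqs$truth$p_distances, spec$seq_grouping)
  expect_true(all(sm$between$min >= 0.14 & sm$between$max <= 0.29))
  expect_lt(sm$max_within, sm$min_between)
})
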