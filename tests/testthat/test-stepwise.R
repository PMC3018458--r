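test_that("two planted populations with ample fixed differences are recovered", {
  sim <- two_group_gt(n_per = 10, fd = 10, shared = 10, seed = 1)
  node <- stepwise_pco(sim$genotypes)
  cl <- terminal_clusters(node)
  expect_equal(length(unique(cl)), 2)
  expect_equal(adjusted_rand_index(cl[names(sim$truth$grouping)],
                                   sim$truth$grouping), 1)
  # split found at round 1, children terminal at round 2
  expect_false(node$terminal)
  expect_equal(node$depth, 1L)
  expect_true(all(vapply(node$children, function(ch) ch$terminal, logical(1))))
})

test_that("a panmictic sample and an under-supported split yield one cluster", {
  sim0 <- two_group_gt(n_per = 10, fd = 0, shared = 12, seed = 2)
  expect_equal(length(unique(terminal_clusters(stepwise_pco(sim0$genotypes)))), 1)
  # 2 fixed loci with min_fd = 3: PCO separation is there but not validated
  sim2 <- two_group_gt(n_per = 10, fd = 2, shared = 12, seed = 3)
  expect_equal(length(unique(terminal_clusters(stepwise_pco(sim2$genotypes,
                                                            min_fd = 3)))), 1)
  expect_equal(length(unique(terminal_clusters(stepwise_pco(sim2$genotypes,
                                                            min_fd = 2)))), 2)
})

test_that("terminal clusters partition the individuals and ignore row order", {
  spec <- make_paper_like_scenario(seed = 4)
  sim <- simulate_allozymes(spec)
  gt <- sim$genotypes
  cl <- terminal_clusters(stepwise_pco(gt))
  expect_setequal(names(cl), gt$individuals)
  expect_false(anyDuplicated(names(cl)) > 0)
  # permuted input rows give the same partition
  set.seed(99)
  perm <- sample(length(gt$individuals))
  calls <- ifelse(is.na(gt$allele1), NA_character_,
                  paste(gt$allele1, gt$allele2, sep = "/"))
  dim(calls) <- dim(gt$allele1); dimnames(calls) <- dimnames(gt$allele1)
  gt_perm <- genotype_table(calls[perm, ], site = gt$site[perm],
                            group = gt$group[perm])
  cl_perm <- terminal_clusters(stepwise_pco(gt_perm))
  expect_equal(adjusted_rand_index(cl[gt$individuals], cl_perm[gt$individuals]), 1)
})

test_that("raising min_fd never increases the number of terminal clusters", {
  sim <- simulate_allozymes(make_paper_like_scenario(seed = 5))
  k <- vapply(c(2, 3, 6, 10),
              function(mf) length(unique(terminal_clusters(
                stepwise_pco(sim$genotypes, min_fd = mf)))), numeric(1))
  expect_true(all(diff(k) <= 0))
})

test_that("reported split support equals an independent FD recomputation", {
  sim <- two_group_gt(n_per = 8, fd = 5, shared = 8, seed = 6)
  node <- stepwise_pco(sim$genotypes)
  expect_length(node$child_fd, 1)
  members <- lapply(node$children, function(ch) ch$members)
  prof <- allele_frequencies(sim$genotypes,
    grouping = stats::setNames(rep(c("1", "2"), lengths(members)), unlist(members)))
  fd_again <- fixed_differences(prof[["1"]], prof[["2"]], 0)
  expect_identical(node$child_fd[[1]]$count, fd_again$count)
  expect_identical(sort(node$child_fd[[1]]$fd_loci), sort(fd_again$fd_loci))
})

test_that("private-allele diagnosis counts loci fixed via unique alleles", {
  loci <- sprintf("L%d", 1:4)
  A <- profile("A", stats::setNames(list(c(z = 1), c(a = 1), c(m = 1), c(c = 1)), loci))
  B <- profile("B", stats::setNames(list(c(x = 1), c(b = 1), c(m = 1), c(c = 1)), loci))
  C <- profile("C", stats::setNames(list(c(y = 1), c(b = 1), c(n = 1), c(c = 1)), loci))
  counts <- private_allele_diagnosis(list(A, B, C))
  # A: L1 private z fixed vs both; L2 private a fixed vs both -> 2
  # B: L1 private x -> 1 (L2 'b' shared with C); C: L1 y + L3 n -> 2
  expect_equal(counts, c(A = 2L, B = 1L, C = 2L))
  same <- profile("D", stats::setNames(list(c(z = 1), c(a = 1), c(m = 1), c(c = 1)), loci))
  expect_equal(unname(private_allele_diagnosis(list(A, same))), c(0L, 0L))
})

test_that("private-fixed loci planted in a Kimberley-like scenario are recovered", {
  # five subgroups, each with 1-4 loci fixed for an allele seen nowhere else
  groups <- paste0("K", LETTERS[1:5])
  planted <- c(KA = 1L, KB = 2L, KC = 3L, KD = 4L, KE = 2L)
  n_loci <- sum(planted) + 3
  part <- vector("list", n_loci)
  idx <- 1
  for (g in seq_along(groups)) {
    for (r in seq_len(planted[g])) {
      b <- rep(2L, 5); b[g] <- 1L
      part[[idx]] <- stats::setNames(b, groups); idx <- idx + 1
    }
  }
  spec <- scenario_spec(group_sizes = stats::setNames(rep(6L, 5), groups),
                        n_loci = n_loci, partitions = part,
                        block_poly_freq = 0, seed = 8)
  sim <- simulate_allozymes(spec)
  prof <- allele_frequencies(sim$genotypes, sim$truth$grouping)
  counts <- private_allele_diagnosis(prof)
  expect_equal(counts[groups], stats::setNames(planted, groups))
})

test_that("paper-like scenario delimits the ten planted taxa", {
  sim <- simulate_allozymes(make_paper_like_scenario(seed = 1))
  node <- stepwise_pco(sim$genotypes)
  cl <- terminal_clusters(node)
  expect_equal(length(unique(cl)), 10)
  expect_equal(adjusted_rand_index(cl[names(sim$truth$grouping)],
                                   sim$truth$grouping), 1)
})

test_that("monophyly flags agree with hand cases and bipartition enumeration", {
  tr <- ape::read.tree(text = "((a1,a2),(b1,b2));")
  g <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  expect_equal(unname(is_reciprocally_monophyletic(tr, g)[c("A", "B")]),
               c("yes", "yes"))
  tr2 <- ape::read.tree(text = "((a1,b1),(a2,b2));")
  expect_equal(unname(is_reciprocally_monophyletic(tr2, g)[c("A", "B")]),
               c("no", "no"))
  # singletons are not assessable; name mismatches are errors
  tr3 <- ape::read.tree(text = "((a1,a2),c1);")
  g3 <- c(a1 = "A", a2 = "A", c1 = "C")
  expect_equal(unname(is_reciprocally_monophyletic(tr3, g3)["C"]), "not_assessable")
  expect_error(is_reciprocally_monophyletic(tr3, g3[1:2]), "c1",
               class = "crenadelim_validation_error")
  set.seed(51)
  for (rep in 1:30) {
    tr <- ape::rtree(20)
    grouping <- stats::setNames(sample(c("G1", "G2", "G3"), 20, replace = TRUE),
                                tr$tip.label)
    flags <- is_reciprocally_monophyletic(tr, grouping)
    for (grp in names(flags)) {
      tips <- names(grouping)[grouping == grp]
      if (length(tips) < 2) next
      expect_identical(flags[[grp]] == "yes", mono_oracle(tr, tips),
                       info = paste("seed rep", rep, "group", grp))
    }
  }
})

test_that("candidate assessment applies the congruence rule", {
  spec <- make_paper_like_scenario(seed = 2)
  sim <- simulate_allozymes(spec)
  seqs <- simulate_sequences(spec)
  node <- stepwise_pco(sim$genotypes)
  mt_un <- seqs$truth$p_distances
  report <- assess_candidates(node, sim$genotypes, mt_uncorrected = mt_un,
                              mt_tree = seqs$truth$tree)
  expect_s3_class(report, "candidate_species_report")
  expect_equal(nrow(report), 10)
  expect_true(all(report$candidate))
  # singleton clusters: monophyly not assessable but allozyme verdict stands
  singletons <- report$n == 1
  expect_true(any(singletons))
  expect_true(all(report$monophyly[singletons] == "not_assessable"))
  expect_true(all(report$min_fd >= 3))
  # min-between exceeds max-within wherever both are computable
  both <- is.finite(report$min_between_uncorrected) &
    is.finite(report$max_within_uncorrected)
  expect_true(any(both))
  expect_true(all(report$min_between_uncorrected[both] >
                  report$max_within_uncorrected[both]))
})

test_that("planted mitochondrial introgression vetoes the verdict", {
  sim <- two_group_gt(n_per = 6, fd = 6, shared = 6, seed = 9)
  node <- stepwise_pco(sim$genotypes)
  cl <- terminal_clusters(node)
  expect_equal(length(unique(cl)), 2)
  # gene tree interleaves the two clusters: monophyly fails for both
  ids <- names(sort(cl))
  tr <- ape::read.tree(text = sprintf("((%s,%s),(%s,%s));",
                                      ids[1], ids[7], ids[2], ids[8]))
  report <- assess_candidates(node, sim$genotypes, mt_tree = tr)
  expect_true(all(report$monophyly == "no"))
  expect_false(any(report$candidate))
})
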