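test_that("mfe_fold handles trivial and textbook cases", {
  f <- mfe_fold("GGGAAACCC")
  expect_identical(f$structure, "(((...)))")
  # 3 CG pairs, two of them stacked on a neighbour
  expect_equal(f$energy, 3 * -3 + 2 * -1)

  expect_identical(mfe_fold("AAAAAA")$structure, "......")
  expect_equal(mfe_fold("AAAAAA")$energy, 0)
  expect_identical(mfe_fold("ACG")$structure, "...")
})

test_that("mfe_fold matches brute-force enumeration (lengths <= 12)", {
  set.seed(21)
  for (rep in 1:40) {
    s <- if (rep %% 2) random_rna_pairy(sample(5:12, 1))
         else random_rna(sample(5:12, 1))
    f <- mfe_fold(s)
    expect_equal(f$energy, oracle_mfe(s), info = s)
    # rescoring law
    expect_equal(f$energy, energy_of_structure(s, f$pairs), info = s)
  }
})

test_that("constrained_fold obeys its laws", {
  s <- "GGGAAACCCAAAGGGAAACCC"
  mfe <- mfe_fold(s)
  # empty constraints reduce to mfe_fold
  expect_identical(constrained_fold(s, NULL), mfe)
  # constraining with the full MFE structure returns it
  again <- constrained_fold(s, mfe$pairs)
  expect_identical(again$structure, mfe$structure)
  expect_equal(again$energy, mfe$energy)

  # one outer pair of the first helix as mandatory constraint
  con <- rbind(c(1L, 9L))
  cf <- constrained_fold(s, con)
  expect_true(all(paste(con[, 1], con[, 2]) %in%
                    paste(cf$pairs[, 1], cf$pairs[, 2])))
  expect_true(cf$energy <= energy_of_structure(s, con))
  expect_true(cf$energy >= mfe$energy)
  expect_equal(cf$energy, oracle_constrained_mfe(s, con))
  expect_equal(cf$energy, energy_of_structure(s, cf$pairs))

  expect_error(constrained_fold("AAAAAAA", rbind(c(1L, 7L))),
               "non-canonical")
  expect_error(constrained_fold("GGGGAAAACCCC",
                                rbind(c(1L, 9L), c(2L, 11L))), "crossing")
})

test_that("constrained_fold matches the constrained oracle on random cases", {
  set.seed(31)
  done <- 0
  while (done < 12) {
    s <- random_rna_pairy(sample(8:14, 1))
    f <- mfe_fold(s)
    if (f$npairs == 0) next
    # constrain a random subset of the MFE pairs (always satisfiable)
    keep <- sort(sample(f$npairs, sample(f$npairs, 1)))
    con <- f$pairs[keep, , drop = FALSE]
    cf <- constrained_fold(s, con)
    expect_equal(cf$energy, oracle_constrained_mfe(s, con), info = s)
    expect_true(all(paste(con[, 1], con[, 2]) %in%
                      paste(cf$pairs[, 1], cf$pairs[, 2])), info = s)
    expect_true(cf$energy >= f$energy, info = s)
    done <- done + 1
  }
})

test_that("alifold degenerates to mfe_fold on identical rows", {
  aln <- msa(c("a", "b", "c"), rep("GGGAAACCC", 3))
  cons <- alifold(aln)
  f <- mfe_fold("GGGAAACCC")
  expect_identical(cons$structure, f$structure)
  expect_equal(cons$energy, f$energy)
  expect_true(all(cons$covariance == 0))
  expect_error(alifold(msa("a", "ACGU")), "at least 2")
})

test_that("compensatory columns score better than pair-breaking ones", {
  model <- energy_model()
  # CG in one row, AU in the other at a helix position
  comp <- alifold(msa(c("a", "b"), c("GGGCAAAGCCC", "GGGAAAAUCCC")))
  # same alignment but the second row cannot pair at that position
  broke <- alifold(msa(c("a", "b"), c("GGGCAAAGCCC", "GGGAAAACCCC")))
  s_comp <- comp$score_matrix[4, 8]
  s_broke <- broke$score_matrix[4, 8]
  expect_true(is.finite(s_comp))
  expect_true(s_comp < s_broke || !is.finite(s_broke))
})

test_that("the shifted-gap toy alignment loses the inner pair", {
  # the pathological sequence alignment: mismatch first, then the gap, for
  # both helix arms; joint folding cannot form the upper inner pair as its
  # partner columns now carry the lower sequence's bases
  aln <- msa(c("up", "lo"), c("AAGGAAAACCAA", "AAC-AAAAG-AA"))
  cons <- alifold(aln)
  up_pairs <- mfe_fold("AAGGAAAACCAA")$pairs   # (3,10) and (4,9)
  have <- paste(cons$pairs[, 1], cons$pairs[, 2])
  expect_false(all(paste(up_pairs[, 1], up_pairs[, 2]) %in% have))
})

test_that("project_consensus projects, filters and re-indexes", {
  aln <- msa(c("a", "b"), c("AAGGAAAACCAA", "AAC-AAAAG-AA"))
  cons_pairs <- rbind(c(3L, 10L), c(4L, 9L))
  # ungapped row: pure coordinate copy (both pairs canonical)
  p1 <- project_consensus(cons_pairs, aln, 1)
  expect_equal(unname(p1), unname(cons_pairs), ignore_attr = TRUE)
  # gapped row: both pairs touch a gap column -> dropped
  p2 <- project_consensus(cons_pairs, aln, 2)
  expect_identical(nrow(p2), 0L)

  # re-indexing by preceding gaps, and canonical filtering
  aln2 <- msa(c("a", "b"), c("GGGAAACCCC", "G-GAAAC-CC"))
  pp <- rbind(c(1L, 9L), c(2L, 8L), c(3L, 7L))
  pr <- project_consensus(pp, aln2, 2)
  # row b: cols 2 and 8 are gaps, so (2,8) is dropped; (1,9) -> (1,7) and
  # (3,7) -> (2,6) by the number of preceding gaps
  expect_equal(unname(pr), rbind(c(1, 7), c(2, 6)), ignore_attr = TRUE)

  # projected pairs, mapped back to columns, are a subset of the consensus
  fam <- generate_family(family_spec(seed = 6, indel_rate = 0.08))
  cons <- alifold(fam$ref_alignment)
  for (r in seq_along(fam$seqs)) {
    pr <- project_consensus(cons, fam$ref_alignment, r)
    ch <- strsplit(fam$ref_alignment$rows[r], "")[[1]]
    colmap <- which(ch != "-")
    back <- cbind(colmap[pr[, 1]], colmap[pr[, 2]])
    expect_true(all(paste(back[, 1], back[, 2]) %in%
                      paste(cons$pairs[, 1], cons$pairs[, 2])))
  }
})
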