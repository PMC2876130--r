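test_that("forest encoding round trips and satisfies the node-count law", {
  cases <- list(c(TOY_UPPER_SEQ, TOY_UPPER_DB),
                c("AC", ".."),
                c("GGGAAACCC", "(((...)))"),
                c("AAAAA", "....."))
  for (cs in cases) {
    f <- forest_from_structure(cs[1], cs[2])
    back <- structure_from_forest(f)
    expect_identical(back$seq, cs[1])
    expect_identical(back$structure, cs[2])
    n_unpaired <- sum(f$kind == 0)
    n_pair <- sum(f$kind == 1)
    expect_identical(n_unpaired + 2L * n_pair, nchar(cs[1]))
  }
  # the toy forest: 2 unpaired, nested pair of pairs with 4 leaves, 2 more
  f <- forest_from_structure(TOY_UPPER_SEQ, TOY_UPPER_DB)
  expect_identical(length(f$top), 5L)          # U U P U U
  expect_identical(f$kind[f$top], c(0L, 0L, 1L, 0L, 0L))
  outer <- f$top[3]
  expect_identical(length(f$kids[[outer]]), 1L)
  inner <- f$kids[[outer]][1]
  expect_identical(f$kind[inner], 1L)
  expect_identical(length(f$kids[[inner]]), 4L)
  expect_error(forest_from_structure("ACG", "...."), "length")
})

test_that("the toy structure alignment has 2 gaps and a pair-pair match", {
  tf <- toy_forests()
  y <- pairwise_forest_align(tf$f1, tf$f2)
  aln <- implied_sequence_alignment(y)
  expect_identical(count_gaps(aln), 2L)
  expect_identical(unname(msa_sequences(aln)),
                   c(TOY_UPPER_SEQ, TOY_LOWER_SEQ))
  # the shared pair is aligned pair-to-pair: some merged PAIR node has
  # residues from both rows
  f <- y$forest
  shared <- any(f$kind == 1L & f$left[, 1] > 0 & f$left[, 2] > 0)
  expect_true(shared)
  # score: 8 base matches + 1 pair match + 1 pair gap under the defaults
  expect_equal(y$score, 8 * 1 + 4 - 2)
})

test_that("self-alignment is an all-match maximum and score is symmetric", {
  set.seed(13)
  for (rep in 1:8) {
    s1 <- random_rna_pairy(sample(6:14, 1))
    s2 <- random_rna_pairy(sample(6:14, 1))
    f1 <- forest_from_structure(s1, mfe_fold(s1)$structure, "a")
    f1b <- forest_from_structure(s1, mfe_fold(s1)$structure, "a2")
    f2 <- forest_from_structure(s2, mfe_fold(s2)$structure, "b")
    self <- pairwise_forest_align(f1, f1b)
    expect_identical(count_gaps(implied_sequence_alignment(self)), 0L)
    expect_equal(forest_align_score(f1, f2), forest_align_score(f2, f1))
    expect_true(forest_align_score(f1, f2) <= forest_align_score(f1, f1))
  }
})

test_that("pairwise_forest_align matches the exhaustive oracle (size <= 8)", {
  cases <- list(
    list("AAA", "...", "AA", ".."),
    list("GAAAC", "(...)", "AAA", "..."),
    list("GAAAC", "(...)", "CAAAG", "(...)"),
    list("GGAAACC", "((...))", "GAAAC", "(...)"),
    list("AGAAACA", ".(...).", "GAAAC", "(...)"),
    list("GAAACAAA", "(...)...", "AAAGAAAC", "...(...)"))
  for (cs in cases) {
    f1 <- forest_from_structure(cs[[1]], cs[[2]], "a")
    f2 <- forest_from_structure(cs[[3]], cs[[4]], "b")
    got <- forest_align_score(f1, f2)
    want <- oracle_forest_score(oracle_forest(cs[[1]], cs[[2]]),
                                oracle_forest(cs[[3]], cs[[4]]))
    expect_equal(got, want, info = paste(cs[[2]], cs[[4]]))
  }
})

test_that("multiple_structure_align reduces, projects and degaps", {
  rec <- function(seq, id) list(id = id, seq = seq,
                                structure = mfe_fold(seq)$structure)
  # n identical folds -> ungapped alignment
  same <- lapply(c("a", "b", "c"), function(i) rec("GGGAAACCC", i))
  aln <- implied_sequence_alignment(multiple_structure_align(same))
  expect_identical(count_gaps(aln), 0L)
  expect_identical(aln$rows, rep("GGGAAACCC", 3))

  # n = 2 equals pairwise_forest_align
  tf <- toy_forests()
  y2 <- multiple_structure_align(list(
    list(id = "upper", seq = TOY_UPPER_SEQ, structure = TOY_UPPER_DB),
    list(id = "lower", seq = TOY_LOWER_SEQ, structure = TOY_LOWER_DB)))
  expect_equal(y2$score, pairwise_forest_align(tf$f1, tf$f2)$score)
  expect_error(multiple_structure_align(list(rec("ACGU", "x"))), "at least 2")

  # synthetic family: degapping law and row order on every member
  fam <- generate_family(family_spec(seed = 8))
  folds <- lapply(seq_along(fam$seqs), function(i)
    list(id = names(fam$seqs)[i], seq = fam$seqs[[i]],
         structure = mfe_fold(fam$seqs[[i]])$structure))
  y <- multiple_structure_align(folds)
  aln <- implied_sequence_alignment(y)
  expect_identical(aln$ids, names(fam$seqs))
  expect_identical(msa_sequences(aln), fam$seqs)
})

test_that("pair columns of a shared shape are aligned across all rows", {
  # five members folding into the same two-helix shape
  fam <- generate_family(family_spec(seed = 15, loop_sub_rate = 0.2,
                                     compensatory_rate = 0.6,
                                     indel_rate = 0))
  folds <- lapply(seq_along(fam$seqs), function(i)
    list(id = names(fam$seqs)[i], seq = fam$seqs[[i]],
         structure = fam$ref_alignment$ss_cons))
  y <- multiple_structure_align(folds)
  f <- y$forest
  # every PAIR node of the merged forest is supported by every row
  pairs_full <- f$kind == 1L
  expect_true(any(pairs_full))
  expect_true(all(f$left[pairs_full, ] > 0))
})

test_that("compensatory changes keep the score, pair-breaking lowers it", {
  set.seed(17)
  done <- 0
  while (done < 6) {
    s <- random_rna_pairy(sample(10:16, 1))
    f <- mfe_fold(s)
    if (f$npairs == 0) next
    fa <- forest_from_structure(s, f$structure, "a")
    base <- forest_align_score(fa, fa)
    # compensatory: swap one pair to a different canonical pair type
    ch <- strsplit(s, "")[[1]]
    k <- sample(f$npairs, 1)
    i <- f$pairs[k, 1]; j <- f$pairs[k, 2]
    other <- setdiff(c("AU", "UA", "CG", "GC", "GU", "UG"),
                     paste0(ch[i], ch[j]))[1]
    ch2 <- ch
    ch2[i] <- substr(other, 1, 1); ch2[j] <- substr(other, 2, 2)
    fb <- forest_from_structure(paste(ch2, collapse = ""), f$structure, "b")
    expect_equal(forest_align_score(fa, fb), base)
    # one-sided break: the pair disappears from the partner's structure
    ch3 <- ch
    bad <- c("A", "C", "G", "U")
    bad <- bad[!vapply(bad, function(b) is_canonical_pair(b, ch[j]),
                       logical(1))]
    ch3[i] <- bad[1]
    broken <- f$pairs[-k, , drop = FALSE]
    fc <- forest_from_structure(paste(ch3, collapse = ""),
                                write_dotbracket(broken, nchar(s)), "c")
    expect_true(forest_align_score(fa, fc) < base)
    done <- done + 1
  }
})
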