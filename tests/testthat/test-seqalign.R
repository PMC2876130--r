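test_that("pairwise_align basics and degapping", {
  pw <- pairwise_align("ACGU", "ACGU")
  expect_identical(pw$alignment$rows, c("ACGU", "ACGU"))
  expect_equal(pw$score, 4 * scoring_scheme()$match)
  expect_error(pairwise_align("A", ""), "empty")

  # degapped rows equal the inputs
  pw <- pairwise_align("GGCAAUCC", "GACU")
  expect_identical(unname(msa_sequences(pw$alignment)),
                   c("GGCAAUCC", "GACU"))
})

test_that("pairwise_align matches the alignment-enumeration oracle", {
  # the in-text example pair
  pw <- pairwise_align("AAGGAAAACCAA", "AACAAAAGA")
  expect_equal(pw$score, oracle_align_score("AAGGAAAACCAA", "AACAAAAGA"))

  set.seed(11)
  for (rep in 1:12) {
    a <- random_rna(sample(3:8, 1))
    b <- random_rna(sample(3:8, 1))
    pw <- pairwise_align(a, b)
    expect_equal(pw$score, oracle_align_score(a, b), info = paste(a, b))
    # reported score equals the score of the returned alignment
    m <- planacstar:::msa_matrix(pw$alignment)
    resc <- 0
    run <- c(0, 0)
    sch <- scoring_scheme()
    for (k in seq_len(ncol(m))) {
      if (m[1, k] == "-") {
        resc <- resc + if (run[1] > 0) sch$gap_extend else sch$gap_open
        run <- c(run[1] + 1, 0)
      } else if (m[2, k] == "-") {
        resc <- resc + if (run[2] > 0) sch$gap_extend else sch$gap_open
        run <- c(0, run[2] + 1)
      } else {
        resc <- resc + if (m[1, k] == m[2, k]) sch$match else sch$mismatch
        run <- c(0, 0)
      }
    }
    expect_equal(pw$score, resc, info = paste(a, b))
  }
})

test_that("tie-breaking prefers diagonal then pushes gaps right", {
  # score-neutral gap placement: the fixed rule takes the mismatch first
  # and the gap after it, which is what buries the covariance signal
  pw <- pairwise_align("GG", "C")
  expect_identical(pw$alignment$rows, c("GG", "C-"))
  pw <- pairwise_align("AAGG", "AAC")
  expect_identical(pw$alignment$rows, c("AAGG", "AAC-"))
})

test_that("progressive_align reduces, degaps and stays consistent", {
  seqs <- c(a = "GACUCG", b = "GACUCG", c = "GACUCG")
  aln <- progressive_align(seqs)
  expect_identical(aln$rows, unname(seqs))

  # n = 2 reduces to pairwise_align
  two <- c(x = "GGCAAUCC", y = "GACU")
  expect_identical(progressive_align(two)$rows,
                   pairwise_align(two[[1]], two[[2]], ids = names(two)
                                  )$alignment$rows)
  expect_error(progressive_align(c(a = "ACGU")), "at least 2")

  # synthetic families: row order preserved, degapping recovers inputs
  for (seed in c(2, 9)) {
    fam <- generate_family(family_spec(seed = seed))
    aln <- progressive_align(fam$seqs)
    expect_identical(aln$ids, names(fam$seqs))
    expect_identical(msa_sequences(aln), fam$seqs)
  }
})

test_that("percent_identity implements the per-pair denominator", {
  expect_equal(percent_identity(msa(c("a", "b"), c("ACGU", "ACGU"))), 1)
  expect_equal(percent_identity(msa(c("a", "b"), c("AAAA", "CCCC"))), 0)
  # 3 identical residue pairs / 4 scored columns (the gap-residue column
  # counts in the denominator only)
  expect_equal(percent_identity(msa(c("a", "b"), c("AC-G", "ACAG"))), 0.75)

  # brute-force per-pair counter on random gapped alignments + symmetry
  set.seed(3)
  for (rep in 1:10) {
    fam <- generate_family(family_spec(seed = rep, indel_rate = 0.1))
    aln <- fam$ref_alignment
    m <- planacstar:::msa_matrix(aln)
    n <- nrow(m)
    vals <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      num <- 0; den <- 0
      for (k in seq_len(ncol(m))) {
        if (m[i, k] == "-" && m[j, k] == "-") next
        den <- den + 1
        if (m[i, k] != "-" && m[i, k] == m[j, k]) num <- num + 1
      }
      vals <- c(vals, num / den)
    }
    expect_equal(percent_identity(aln), mean(vals))
    perm <- msa(rev(aln$ids), rev(aln$rows))
    expect_equal(percent_identity(perm), percent_identity(aln))
  }
})

test_that("gap_content counts gaps over cells", {
  expect_equal(gap_content(msa(c("a", "b"), c("ACGU", "ACGU"))), 0)
  expect_equal(gap_content(msa(c("a", "b"), c("AC-G", "A-CG"))), 0.25)
  fam <- generate_family(family_spec(seed = 4, indel_rate = 0.08))
  g <- gap_content(fam$ref_alignment)
  expect_true(g >= 0 && g < 1)
})

test_that("compare_alignments measures shared aligned pairs", {
  a <- msa(c("x", "y"), c("AC-G", "ACAG"))
  expect_equal(compare_alignments(a, a), 1)
  # no shared residue pair
  b1 <- msa(c("x", "y"), c("AA--", "--AA"))
  b2 <- msa(c("x", "y"), c("AA", "AA"))
  expect_equal(compare_alignments(b1, b2), 0)
  expect_error(compare_alignments(a, b1), "same sequence set")

  # brute-force pair enumeration on a small case
  c1 <- msa(c("x", "y"), c("ACG-", "A-GU"))
  c2 <- msa(c("x", "y"), c("ACG-", "AG-U"))
  # c1 pairs: x1:y1, x3:y2 ; c2 pairs: x1:y1, x2:y2 -> overlap 1 of 2+2
  expect_equal(compare_alignments(c1, c2), 2 * 1 / (2 + 2))
})
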