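test_that("zero rates give identical ungapped copies of the ancestor", {
  sp <- family_spec(loop_sub_rate = 0, compensatory_rate = 0,
                    indel_rate = 0, seed = 2)
  fam <- generate_family(sp)
  expect_identical(length(unique(fam$seqs)), 1L)
  expect_false(any(grepl("-", fam$ref_alignment$rows)))
  expect_identical(unname(nchar(fam$seqs[1])), nchar(sp$consensus))
})

test_that("compensatory-only families vary only at paired sites", {
  sp <- family_spec(loop_sub_rate = 0, compensatory_rate = 1,
                    indel_rate = 0, seed = 3)
  fam <- generate_family(sp)
  m <- planacstar:::msa_matrix(fam$ref_alignment)
  paired_cols <- sort(as.vector(fam$ref_consensus))
  for (col in seq_len(ncol(m))) {
    if (col %in% paired_cols) next
    expect_identical(length(unique(m[, col])), 1L)
  }
  # every reference pair canonical in every row
  for (k in seq_len(nrow(fam$ref_consensus)))
    expect_true(all(is_canonical_pair(m[, fam$ref_consensus[k, 1]],
                                      m[, fam$ref_consensus[k, 2]])))
})

test_that("reference pairs stay canonical per row whenever breaking is off", {
  for (seed in c(1, 12, 31)) {
    fam <- generate_family(family_spec(seed = seed, indel_rate = 0.08))
    m <- planacstar:::msa_matrix(fam$ref_alignment)
    pp <- fam$ref_consensus
    for (k in seq_len(nrow(pp))) {
      expect_true(all(m[, pp[k, 1]] != "-"))
      expect_true(all(is_canonical_pair(m[, pp[k, 1]], m[, pp[k, 2]])))
    }
    # degapping the reference reproduces the emitted sequences
    expect_identical(msa_sequences(fam$ref_alignment), fam$seqs)
  }
})

test_that("defaults land in the twilight identity band, deterministically", {
  sp <- family_spec(seed = 11)
  fam <- generate_family(sp)
  id <- percent_identity(fam$ref_alignment)
  expect_true(id >= 0.30 && id <= 0.55)
  expect_identical(fam, generate_family(sp))
  # different seed, different family
  expect_false(identical(fam$seqs,
                         generate_family(family_spec(seed = 12))$seqs))
})

test_that("pathology families include the literal member and improve", {
  pf <- make_twilight_pathology(5)
  expect_true("AAGGAAAACCAA" %in% pf)
  expect_identical(pf, make_twilight_pathology(5))
  expect_false(identical(unname(pf), unname(make_twilight_pathology(6))))
  res <- run_planacstar(pf)
  expect_true(res$sci$sci > res$trace[[1]]$sci$sci + 1e-9)
})

test_that("sweep hits targets, reproducibly and monotonically", {
  targets <- c(0.35, 0.5, 0.65, 0.8)
  sw <- sweep_families(targets, n_families = 1, seed = 9)
  ids <- vapply(sw, `[[`, numeric(1), "identity")
  expect_true(all(abs(ids - targets) <= 0.05))
  expect_true(!is.unsorted(ids))
  sw2 <- sweep_families(targets, n_families = 1, seed = 9)
  expect_identical(ids, vapply(sw2, `[[`, numeric(1), "identity"))
  expect_error(sweep_families(c(0, 0.5)), "in \\(0, 1\\)")
})

test_that("family_spec validates its invariants", {
  expect_error(family_spec(loop_sub_rate = 1.2), "rates")
  expect_error(family_spec(n_sequences = 1), "n_sequences")
  expect_error(family_spec(consensus = "((..))"), "hairpin")
})
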