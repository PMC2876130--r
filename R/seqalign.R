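# Initial multiple sequence alignment (progressive, UPGMA guide tree,
# affine-gap profile alignment) and alignment metrics.

#' Affine-gap scoring scheme
#'
#' @param match,mismatch,gap_open,gap_extend scores; a length-k gap costs
#'   `gap_open + (k - 1) * gap_extend`. Invariants: `gap_open <= gap_extend
#'   <= 0 < match`, `mismatch < match`.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -1, gap_open = -5,
                           gap_extend = -1) {
  if (!(gap_open <= gap_extend && gap_extend <= 0 && match > 0))
    stop("need gap_open <= gap_extend <= 0 < match")
  if (!(mismatch < match)) stop("need mismatch < match")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

codes_of <- function(x) {
  # gapped or ungapped string -> integer codes (0 gap, 1..4 ACGU)
  m <- match(strsplit(x, "")[[1]], c("A", "C", "G", "U"))
  m[is.na(m)] <- 0L
  as.integer(m)
}

profile_of <- function(rows) {
  do.call(rbind, lapply(rows, codes_of))
}

codes_to_row <- function(codes) {
  paste(c("-", "A", "C", "G", "U")[codes + 1L], collapse = "")
}

#' Optimal global pairwise alignment
#'
#' Affine-gap Gotoh alignment with deterministic tie-breaking: prefer the
#' diagonal (match/mismatch) move, then a gap in the shorter sequence, then
#' a gap in the longer, resolved left-to-right. The fixed rule makes
#' score-neutral gap placements reproducible (and deliberately reproduces
#' the mismatch-then-gap placement that obscures covariance in downstream
#' consensus folding).
#'
#' @param a,b RNA sequences (single strings; names are used as ids).
#' @param scheme a [scoring_scheme()].
#' @param ids length-2 ids for the rows.
#' @return list with `alignment` (a 2-row `rna_msa`) and `score`.
#' @export
pairwise_align <- function(a, b, scheme = scoring_scheme(),
                           ids = c("seq1", "seq2")) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  a <- normalize_residues(a)
  b <- normalize_residues(b)
  pa <- matrix(codes_of(a), nrow = 1)
  pb <- matrix(codes_of(b), nrow = 1)
  res <- gotoh_align_cpp(pa, pb, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend,
                         prefer_gap_in_B = nchar(b) <= nchar(a))
  rowa <- ifelse(res$ai == 0, "-", strsplit(a, "")[[1]][pmax(res$ai, 1)])
  rowb <- ifelse(res$bi == 0, "-", strsplit(b, "")[[1]][pmax(res$bi, 1)])
  list(alignment = msa(ids, c(paste(rowa, collapse = ""),
                              paste(rowb, collapse = ""))),
       score = res$score)
}

align_profiles <- function(A, B, scheme) {
  res <- gotoh_align_cpp(A, B, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend,
                         prefer_gap_in_B = ncol(B) <= ncol(A))
  nc <- length(res$ai)
  out <- matrix(0L, nrow(A) + nrow(B), nc)
  for (k in seq_len(nc)) {
    if (res$ai[k] > 0) out[seq_len(nrow(A)), k] <- A[, res$ai[k]]
    if (res$bi[k] > 0) out[nrow(A) + seq_len(nrow(B)), k] <- B[, res$bi[k]]
  }
  out
}

upgma_merge_order <- function(d, labels) {
  # average-linkage tree; returns hclust merge matrix plus labels
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  hc
}

#' Progressive multiple sequence alignment
#'
#' Guide tree: UPGMA (average linkage) on pairwise distances
#' `1 - percent_identity`; profiles are merged leaf-to-root by affine-gap
#' profile-profile alignment with sum-of-pairs column scores. For two
#' sequences this reduces exactly to [pairwise_align()]. Output rows keep
#' the input order and degap to the input sequences.
#'
#' @param seqs named character vector (n >= 2).
#' @param scheme a [scoring_scheme()].
#' @return an `rna_msa`.
#' @export
progressive_align <- function(seqs, scheme = scoring_scheme()) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  seqs <- normalize_residues(seqs)
  validate_sequences(seqs)
  n <- length(seqs)
  if (n == 2) {
    return(pairwise_align(seqs[[1]], seqs[[2]], scheme,
                          ids = names(seqs))$alignment)
  }
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pw <- pairwise_align(seqs[[i]], seqs[[j]], scheme)
    d[i, j] <- d[j, i] <- 1 - percent_identity(pw$alignment)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  profiles <- list()   # by cluster key
  members <- list()
  get_leaf <- function(i) {
    list(profile = matrix(codes_of(seqs[[i]]), nrow = 1), members = i)
  }
  nodes <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    l <- hc$merge[k, 1]
    r <- hc$merge[k, 2]
    L <- if (l < 0) get_leaf(-l) else nodes[[l]]
    R <- if (r < 0) get_leaf(-r) else nodes[[r]]
    prof <- align_profiles(L$profile, R$profile, scheme)
    nodes[[k]] <- list(profile = prof, members = c(L$members, R$members))
  }
  final <- nodes[[nrow(hc$merge)]]
  ord <- order(final$members)
  prof <- final$profile[ord, , drop = FALSE]
  rows <- apply(prof, 1, codes_to_row)
  msa(names(seqs), rows)
}

#' Mean pairwise percent identity of an alignment
#'
#' For each pair of rows, identical aligned residue pairs divided by the
#' number of columns where at least one of the two rows has a residue
#' (gap-gap columns are excluded from that pair's denominator); the mean
#' over all row pairs is returned. This per-pair denominator follows the
#' improved identity calculation used for twilight-zone benchmarking.
#'
#' @param aln an `rna_msa` with >= 2 rows.
#' @return fraction in `[0, 1]`.
#' @export
percent_identity <- function(aln) {
  m <- msa_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 rows")
  tot <- 0
  cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    gi <- m[i, ] == "-"
    gj <- m[j, ] == "-"
    scored <- !(gi & gj)
    ident <- sum(!gi & !gj & m[i, ] == m[j, ])
    tot <- tot + if (sum(scored) == 0) 0 else ident / sum(scored)
    cnt <- cnt + 1
  }
  tot / cnt
}

#' Gap content of an alignment
#'
#' @param aln an `rna_msa`.
#' @return fraction of gap characters, `(# gaps) / (rows * columns)`.
#' @export
gap_content <- function(aln) {
  m <- msa_matrix(aln)
  mean(m == "-")
}

aligned_pair_keys <- function(aln) {
  m <- msa_matrix(aln)
  ord <- order(aln$ids)
  m <- m[ord, , drop = FALSE]
  ids <- aln$ids[ord]
  n <- nrow(m)
  pos <- apply(m != "-", 1, cumsum)          # n_cols x n
  keys <- character()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    both <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(both)) next
    keys <- c(keys, paste(ids[i], pos[both, i], ids[j], pos[both, j],
                          sep = ":"))
  }
  keys
}

#' Similarity of two alignments of the same sequences
#'
#' The sets of aligned residue pairs (which residue of row *i* sits in the
#' same column as which residue of row *j*) are compared; the similarity is
#' the Dice overlap `2|A & B| / (|A| + |B|)`: 1 for identical alignments, 0
#' when no residue pair is shared.
#'
#' @param a,b `rna_msa` objects over the same sequence set.
#' @return similarity in `[0, 1]`.
#' @export
compare_alignments <- function(a, b) {
  sa <- msa_sequences(a)
  sb <- msa_sequences(b)
  if (!setequal(names(sa), names(sb)) ||
      !identical(sa[sort(names(sa))], sb[sort(names(sb))]))
    stop("alignments are not over the same sequence set")
  ka <- aligned_pair_keys(a)
  kb <- aligned_pair_keys(b)
  if (length(ka) + length(kb) == 0) return(1)
  2 * length(intersect(ka, kb)) / (length(ka) + length(kb))
}
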