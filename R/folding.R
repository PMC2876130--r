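# Single-sequence MFE folding, constrained folding and consensus folding of
# an alignment with covariance pseudo-energies, under a pluggable simplified
# energy model. All three share one nested-structure DP (src/fold.cpp) over
# a pair-score matrix; what differs is how the matrix is built.

#' Simplified RNA energy model
#'
#' A nearest-neighbour surrogate rather than full thermodynamic parameter
#' tables: canonical pairs carry a flat pairing energy (CG/GC -3, AU/UA -2,
#' GU/UG -1 kcal/mol-like units), directly stacked pairs get a stacking
#' bonus (-1), hairpin loops need at least `min_hairpin` unpaired bases.
#' The closed form admits exact brute-force oracles; the folding pipeline is
#' model-agnostic, so richer models can be dropped in through this object.
#'
#' @param cg,au,gu pairing energies (negative) for the canonical pair
#'   classes.
#' @param stack_bonus energy added per directly stacked pair (<= 0).
#' @param min_hairpin minimum number of unpaired bases in a hairpin loop.
#' @return an object of class `energy_model` with a 4x4 `pair_mat`
#'   (NA = forbidden pair).
#' @export
energy_model <- function(cg = -3, au = -2, gu = -1, stack_bonus = -1,
                         min_hairpin = 3L) {
  if (any(c(cg, au, gu) >= 0)) stop("pair energies must be negative")
  if (stack_bonus > 0) stop("stack_bonus must be <= 0")
  if (min_hairpin < 3) stop("min_hairpin must be >= 3")
  pm <- matrix(NA_real_, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  pm["C", "G"] <- pm["G", "C"] <- cg
  pm["A", "U"] <- pm["U", "A"] <- au
  pm["G", "U"] <- pm["U", "G"] <- gu
  structure(list(pair_mat = pm, stack_bonus = stack_bonus,
                 min_hairpin = as.integer(min_hairpin)),
            class = "energy_model")
}

#' Is a base pair canonical?
#' @param b1,b2 bases (characters among ACGU, vectorized).
#' @param model an [energy_model()].
#' @return logical vector.
#' @export
is_canonical_pair <- function(b1, b2, model = energy_model()) {
  !is.na(model$pair_mat[cbind(b1, b2)])
}

# pair-score matrix for a single sequence: S[i,j] = pairing energy where
# (i,j) may pair, NA elsewhere
pair_score_matrix <- function(codes, model) {
  n <- length(codes)
  pm <- model$pair_mat
  S <- matrix(pm[codes, codes], n, n)
  ij <- outer(seq_len(n), seq_len(n), function(i, j) j - i - 1)
  S[ij < model$min_hairpin] <- NA_real_
  S
}

new_fold_result <- function(seq, pairs, energy, id = NULL) {
  pairs <- as_pairs(pairs)
  structure(list(id = id, seq = seq, pairs = pairs,
                 structure = write_dotbracket(pairs, nchar(seq)),
                 energy = energy, npairs = nrow(pairs)),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  if (!is.null(x$id)) cat(">", x$id, "\n", sep = "")
  cat(x$seq, "\n", x$structure, sprintf(" (%.2f)\n", x$energy), sep = "")
  invisible(x)
}

#' Minimum free energy folding
#'
#' Dynamic-programming MFE folding of one sequence under the simplified
#' model: pseudoknot-free structures, canonical pairs only, hairpin loops of
#' at least `model$min_hairpin` bases, stacking bonus for adjacent pairs.
#' Ties in energy are broken towards fewer pairs, then by a fixed traceback
#' order, so the result is deterministic.
#'
#' @param seq RNA sequence (single string).
#' @param model an [energy_model()].
#' @return a `fold_result`: `pairs` (2-column matrix), `structure`
#'   (dot-bracket), `energy`, `npairs`. An empty structure with energy 0 is
#'   a valid answer.
#' @export
mfe_fold <- function(seq, model = energy_model()) {
  seq <- normalize_residues(seq)
  codes <- codes_of(seq)
  S <- pair_score_matrix(codes, model)
  res <- fold_dp_cpp(S, rep(TRUE, length(codes)), model$stack_bonus)
  new_fold_result(seq, res$pairs, res$energy)
}

validate_constraints <- function(pairs, seq, model) {
  pairs <- as_pairs(pairs)
  n <- nchar(seq)
  if (nrow(pairs) == 0) return(pairs)
  if (any(pairs < 1) || any(pairs > n)) stop("constraint pair out of range")
  if (any(pairs[, 1] >= pairs[, 2])) stop("constraint pairs need i < j")
  if (anyDuplicated(as.vector(pairs)))
    stop("constraints assign a position to two pairs")
  if (pairs_cross(pairs)) stop("constraints are internally crossing")
  if (any(pairs[, 2] - pairs[, 1] - 1 < model$min_hairpin))
    stop("constraint hairpin loop shorter than min_hairpin")
  ch <- strsplit(seq, "")[[1]]
  canon <- is_canonical_pair(ch[pairs[, 1]], ch[pairs[, 2]], model)
  if (!all(canon))
    stop("non-canonical mandatory pair(s) at: ",
         paste(sprintf("(%d,%d)", pairs[!canon, 1], pairs[!canon, 2]),
               collapse = " "))
  pairs
}

#' Constrained MFE folding
#'
#' Folds a sequence under mandatory base-pair constraints: the result always
#' contains every constraint pair, all added pairs are nested relative to
#' them, and the energy is minimal among such structures. With empty
#' constraints this is exactly [mfe_fold()]. This mirrors constrained
#' folding a la `RNAfold -C`: the projection of a consensus onto a sequence
#' is "unsaturated", and refolding may add compatible pairs.
#'
#' @param seq RNA sequence.
#' @param constraints 2-column matrix of mandatory pairs (1-based, on the
#'   ungapped sequence), e.g. from [project_consensus()].
#' @param model an [energy_model()].
#' @return a `fold_result` whose `pairs` are a superset of `constraints`.
#' @export
constrained_fold <- function(seq, constraints = NULL,
                             model = energy_model()) {
  seq <- normalize_residues(seq)
  pairs <- validate_constraints(constraints, seq, model)
  if (nrow(pairs) == 0) return(mfe_fold(seq, model))
  codes <- codes_of(seq)
  n <- length(codes)
  S <- pair_score_matrix(codes, model)
  constrained_pos <- as.vector(pairs)
  # a constrained position may only pair with its mandated partner
  S[constrained_pos, ] <- NA_real_
  S[, constrained_pos] <- NA_real_
  pm <- model$pair_mat
  ch <- strsplit(seq, "")[[1]]
  for (k in seq_len(nrow(pairs)))
    S[pairs[k, 1], pairs[k, 2]] <- pm[ch[pairs[k, 1]], ch[pairs[k, 2]]]
  # no added pair may cross a mandatory pair
  idx <- which(!is.na(S), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    cross <- (idx[, 1] < a & idx[, 2] >= a & idx[, 2] < b) |
             (idx[, 1] > a & idx[, 1] <= b & idx[, 2] > b)
    if (any(cross)) {
      drop <- idx[cross, , drop = FALSE]
      keep <- !(drop[, 1] %in% pairs[, 1] & drop[, 2] %in% pairs[, 2])
      # mandated pairs themselves never cross (validated), but guard anyway
      S[drop[keep, , drop = FALSE]] <- NA_real_
      idx <- which(!is.na(S), arr.ind = TRUE)
    }
  }
  unp <- rep(TRUE, n)
  unp[constrained_pos] <- FALSE
  res <- fold_dp_cpp(S, unp, model$stack_bonus)
  new_fold_result(seq, res$pairs, res$energy)
}

#' Recompute the model energy of a given structure
#'
#' Used for the rescoring law: the energy reported by the folding routines
#' must equal the energy of the returned structure recomputed from the
#' model.
#'
#' @param seq RNA sequence.
#' @param pairs 2-column pair matrix.
#' @param model an [energy_model()].
#' @return energy (sum of pairing energies plus stacking bonuses).
#' @export
energy_of_structure <- function(seq, pairs, model = energy_model()) {
  pairs <- as_pairs(pairs)
  if (nrow(pairs) == 0) return(0)
  ch <- strsplit(normalize_residues(seq), "")[[1]]
  e <- sum(model$pair_mat[cbind(ch[pairs[, 1]], ch[pairs[, 2]])])
  key <- paste(pairs[, 1], pairs[, 2])
  stacked <- sum(paste(pairs[, 1] + 1, pairs[, 2] - 1) %in% key)
  e + stacked * model$stack_bonus
}

# ---- consensus folding ------------------------------------------------------

#' Consensus folding of an alignment with covariance pseudo-energies
#'
#' RNAalifold-style: two columns may pair if at least a fraction `q` of the
#' rows without a gap in either column can form a canonical pair there
#' (rows gapped in either column are neutral, and at least one row must
#' pair). The column pseudo-energy is the sum of the pairing rows' pair
#' energies divided by the *total* number of rows — rows that cannot
#' support a pair dilute it — plus a covariance term: a bonus of -1 per
#' additional distinct pair type among the pairing rows and a penalty of
#' `mismatch_penalty` per gap-free row unable to pair, weighted by
#' `cov_weight`. The DP then finds the minimum-energy nested set of column
#' pairs, with the model's stacking bonus for adjacent column pairs, giving
#' the consensus energy `E_A` that enters the SCI numerator.
#'
#' @param aln an `rna_msa` with >= 2 rows.
#' @param model an [energy_model()].
#' @param cov_weight weight of the covariance pseudo-energy (default 1).
#' @param q minimum fraction of gap-free rows that must pair (default 0.5).
#' @param mismatch_penalty pseudo-energy per gap-free non-pairing row.
#' @return an object of class `consensus_structure`: `pairs` (on alignment
#'   columns), `energy` (`E_A`), `structure` (dot-bracket), `covariance`
#'   (per-pair covariance credit), `n_cols`.
#' @export
alifold <- function(aln, model = energy_model(), cov_weight = 1,
                    q = 0.5, mismatch_penalty = 1) {
  if (length(aln$ids) < 2) stop("need at least 2 rows")
  if (aln$n_cols == 0) stop("alignment has zero columns")
  cm <- do.call(rbind, lapply(aln$rows, codes_of))
  n <- nrow(cm)
  C <- ncol(cm)
  pm <- model$pair_mat
  S <- matrix(NA_real_, C, C)
  cov <- matrix(NA_real_, C, C)
  for (i in seq_len(C)) {
    jmin <- i + model$min_hairpin + 1
    if (jmin > C) break
    li <- cm[, i]
    for (j in jmin:C) {
      lj <- cm[, j]
      gapfree <- li > 0L & lj > 0L
      if (!any(gapfree)) next
      pe <- rep(NA_real_, n)
      pe[gapfree] <- pm[cbind(li[gapfree], lj[gapfree])]
      pairing <- !is.na(pe)
      npair <- sum(pairing)
      if (npair == 0 || npair / sum(gapfree) < q) next
      ntypes <- length(unique(paste(li[pairing], lj[pairing])))
      credit <- -(ntypes - 1) + mismatch_penalty * (sum(gapfree) - npair)
      S[i, j] <- sum(pe[pairing]) / n + cov_weight * credit
      cov[i, j] <- credit
    }
  }
  res <- fold_dp_cpp(S, rep(TRUE, C), model$stack_bonus)
  pairs <- as_pairs(res$pairs)
  structure(list(pairs = pairs, energy = res$energy,
                 structure = write_dotbracket(pairs, C),
                 covariance = if (nrow(pairs)) cov[pairs] else numeric(0),
                 n_cols = C, score_matrix = S),
            class = "consensus_structure")
}

#' @export
print.consensus_structure <- function(x, ...) {
  cat(x$structure, sprintf(" (%.2f)\n", x$energy), sep = "")
  invisible(x)
}

#' Project a consensus structure onto one row
#'
#' Takes the consensus base pairs (defined on alignment columns), removes
#' the gaps with respect to the chosen row, and returns the "unsaturated"
#' constraint structure for that sequence: a pair is kept only when the row
#' has residues at both columns *and* they form a canonical pair (pairs
#' that the sequence cannot form are dropped, not forced). Kept pairs are
#' re-indexed to ungapped sequence coordinates.
#'
#' @param consensus a `consensus_structure` (or bare 2-column pair matrix on
#'   columns).
#' @param aln the `rna_msa` the consensus was computed on.
#' @param row_index which row to project onto.
#' @param model an [energy_model()] (for the canonical-pair check).
#' @return 2-column matrix of constraint pairs in sequence coordinates
#'   (possibly empty).
#' @export
project_consensus <- function(consensus, aln, row_index,
                              model = energy_model()) {
  pairs <- if (inherits(consensus, "consensus_structure"))
    consensus$pairs else as_pairs(consensus)
  if (row_index < 1 || row_index > length(aln$ids))
    stop("row_index out of range")
  ch <- strsplit(aln$rows[row_index], "")[[1]]
  if (!is.null(dim(pairs)) && nrow(pairs) > 0 &&
      max(pairs) > length(ch)) stop("consensus does not fit the alignment")
  resid <- ch != "-"
  pos <- cumsum(resid)
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    keep[k] <- resid[i] && resid[j] &&
      is_canonical_pair(ch[i], ch[j], model) &&
      (pos[j] - pos[i] - 1 >= model$min_hairpin)
  }
  out <- cbind(pos[pairs[keep, 1]], pos[pairs[keep, 2]])
  as_pairs(out)
}
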