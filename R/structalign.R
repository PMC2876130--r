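# Sequence-agnostic alignment of RNA secondary structures as ordered
# forests, progressive multiple structure alignment, and extraction of the
# sequence alignment implied by a structure alignment.

#' Forest alignment scores
#'
#' Pair nodes align only to pair nodes, unpaired bases only to unpaired
#' bases. A pair-to-pair alignment scores `pair_match` regardless of the
#' residues — this is what recovers compensatory base changes — plus
#' `pair_ident_bonus` when both residue pairs are identical (default 0, so
#' that a compensatory double substitution leaves the score unchanged;
#' configure a small positive bonus to prefer residue-identical pairings).
#'
#' @param pair_match score for aligning two pair nodes.
#' @param pair_ident_bonus extra score when the two residue pairs are
#'   identical.
#' @param base_match,base_mismatch scores for aligned unpaired bases.
#' @param pair_gap,base_gap scores for nodes aligned to a gap.
#' @return an object of class `forest_score`.
#' @export
forest_score <- function(pair_match = 4, pair_ident_bonus = 0,
                         base_match = 1, base_mismatch = 0,
                         pair_gap = -2, base_gap = -1) {
  if (!(pair_match > pair_gap)) stop("need pair_match > pair_gap")
  if (!(base_match >= base_mismatch && base_mismatch >= base_gap))
    stop("need base_match >= base_mismatch >= base_gap")
  if (pair_ident_bonus < 0) stop("pair_ident_bonus must be >= 0")
  structure(list(pair_match = pair_match,
                 pair_ident_bonus = pair_ident_bonus,
                 base_match = base_match, base_mismatch = base_mismatch,
                 pair_gap = pair_gap, base_gap = base_gap),
            class = "forest_score")
}

new_forest <- function(kind, kids, top, left, right, rows) {
  structure(list(kind = kind, kids = kids, top = top,
                 left = left, right = right, rows = rows),
            class = "structure_forest")
}

#' Encode a folded sequence as an ordered structure forest
#'
#' PAIR nodes carry the two paired residues and the subforest they enclose;
#' UNPAIRED nodes are leaves carrying one residue. The in-order traversal
#' reconstructs `(seq, structure)` exactly, and
#' `#UNPAIRED + 2 * #PAIR == nchar(seq)`.
#'
#' @param seq RNA sequence.
#' @param structure dot-bracket string or 2-column pair matrix.
#' @param id row id stored with the forest.
#' @return an object of class `structure_forest`.
#' @export
forest_from_structure <- function(seq, structure, id = "seq") {
  seq <- normalize_residues(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  pairs <- if (is.character(structure)) {
    if (nchar(structure) != n)
      stop("structure length differs from sequence length")
    parse_dotbracket(structure)
  } else as_pairs(structure)
  partner <- integer(n)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  code <- codes_of(seq)

  kind <- integer(0)
  kidsl <- list()
  leftv <- integer(0)
  rightv <- integer(0)
  build <- function(lo, hi) {
    ids <- integer(0)
    k <- lo
    while (k <= hi) {
      if (partner[k] == 0L) {
        kind[[length(kind) + 1]] <<- 0L
        kidsl[[length(kidsl) + 1]] <<- integer(0)
        leftv[[length(leftv) + 1]] <<- code[k]
        rightv[[length(rightv) + 1]] <<- 0L
        ids <- c(ids, length(kind))
        k <- k + 1
      } else {
        j <- partner[k]
        kind[[length(kind) + 1]] <<- 1L
        me <- length(kind)
        kidsl[[me]] <<- integer(0)
        leftv[[me]] <<- code[k]
        rightv[[me]] <<- code[j]
        ids <- c(ids, me)
        kidsl[[me]] <<- build(k + 1, j - 1)
        k <- j + 1
      }
    }
    ids
  }
  top <- build(1L, n)
  new_forest(kind, kidsl, top,
             matrix(leftv, ncol = 1), matrix(rightv, ncol = 1), rows = id)
}

# in-order traversal: matrix with one row per alignment column, columns
# (node, side) where side 1 = left/opening, 2 = right/closing
forest_inorder <- function(forest) {
  out <- matrix(integer(), 0, 2)
  walk <- function(ids) {
    for (v in ids) {
      if (forest$kind[v] == 0L) {
        out <<- rbind(out, c(v, 1L))
      } else {
        out <<- rbind(out, c(v, 1L))
        walk(forest$kids[[v]])
        out <<- rbind(out, c(v, 2L))
      }
    }
  }
  walk(forest$top)
  out
}

#' Decode a single-row forest back to sequence and structure
#'
#' Inverse of [forest_from_structure()] (for row `row` of a profile
#' forest, gap entries are dropped).
#'
#' @param forest a `structure_forest`.
#' @param row which profile row to decode.
#' @return list with `seq` and `structure` (dot-bracket).
#' @export
structure_from_forest <- function(forest, row = 1L) {
  ord <- forest_inorder(forest)
  lets <- c("-", "A", "C", "G", "U")
  chs <- character(0)
  brk <- character(0)
  for (k in seq_len(nrow(ord))) {
    v <- ord[k, 1]; side <- ord[k, 2]
    codev <- if (side == 1L) forest$left[v, row] else forest$right[v, row]
    if (codev == 0L) next
    chs <- c(chs, lets[codev + 1L])
    brk <- c(brk, if (forest$kind[v] == 0L) "."
             else if (side == 1L) "(" else ")")
  }
  list(seq = paste(chs, collapse = ""),
       structure = paste(brk, collapse = ""))
}

forest_to_cpp <- function(f) {
  list(kind = as.integer(f$kind), kids = f$kids, top = as.integer(f$top),
       left = f$left, right = f$right)
}

forest_from_cpp <- function(res, rows) {
  n <- length(res$kind)
  kids <- rep(list(integer(0)), n)
  top <- integer(0)
  for (v in seq_len(n)) {
    p <- res$parent[v]
    if (p == 0L) top <- c(top, v) else kids[[p]] <- c(kids[[p]], v)
  }
  new_forest(as.integer(res$kind), kids, top, res$left, res$right, rows)
}

#' Pairwise global forest alignment
#'
#' Optimal global alignment of two ordered structure forests under a
#' [forest_score()]: pair nodes align to pair nodes or gaps, base nodes to
#' base nodes or gaps, children alignments nested within parent alignments
#' (a gapped pair node has its children promoted). Because pair alignment
#' is scored irrespective of residues, compensatory base changes align
#' pair-to-pair at full score. Deterministic tie-breaking.
#'
#' @param f1,f2 `structure_forest` objects (single or profile).
#' @param score a [forest_score()].
#' @return an object of class `structure_alignment`: `forest` (the merged
#'   profile forest over the union of rows), `score`, `ids`.
#' @export
pairwise_forest_align <- function(f1, f2, score = forest_score()) {
  res <- forest_align_cpp(forest_to_cpp(f1), forest_to_cpp(f2),
                          unclass(score))
  merged <- forest_from_cpp(res, rows = c(f1$rows, f2$rows))
  structure(list(forest = merged, score = res$score,
                 ids = c(f1$rows, f2$rows)),
            class = "structure_alignment")
}

#' Forest alignment score only
#' @inheritParams pairwise_forest_align
#' @return numeric score of the optimal alignment.
#' @export
forest_align_score <- function(f1, f2, score = forest_score()) {
  forest_align_cpp(forest_to_cpp(f1), forest_to_cpp(f2),
                   unclass(score))$score
}

#' Progressive multiple structure alignment
#'
#' Aligns n folded sequences as ordered forests along a UPGMA guide tree
#' built from pairwise forest-alignment scores (converted to distances by
#' max-self-score normalization), merging profile forests leaf-to-root.
#' Every input is recoverable from the result by projection.
#'
#' @param folds list of records with fields `id`, `seq` and `structure`
#'   (dot-bracket), e.g. [read_vienna()] output or `fold_result`s carrying
#'   an `id`.
#' @param score a [forest_score()].
#' @return a `structure_alignment` whose profile rows follow the input
#'   order.
#' @export
multiple_structure_align <- function(folds, score = forest_score()) {
  n <- length(folds)
  if (n < 2) stop("need at least 2 structures")
  forests <- lapply(folds, function(r)
    forest_from_structure(r$seq, r$structure, id = r$id %||% "seq"))
  ids <- vapply(forests, function(f) f$rows[1], character(1))
  if (anyDuplicated(ids)) stop("duplicate structure ids")
  if (n == 2) {
    y <- pairwise_forest_align(forests[[1]], forests[[2]], score)
    return(y)
  }
  self <- vapply(forests, function(f) forest_align_score(f, f, score),
                 numeric(1))
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- forest_align_score(forests[[i]], forests[[j]], score)
    d[i, j] <- d[j, i] <- max(0, 1 - s / max(self[i], self[j]))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  nodes <- vector("list", nrow(hc$merge))
  get_leaf <- function(i) forests[[i]]
  last <- NULL
  for (k in seq_len(nrow(hc$merge))) {
    l <- hc$merge[k, 1]; r <- hc$merge[k, 2]
    L <- if (l < 0) get_leaf(-l) else nodes[[l]]$forest
    R <- if (r < 0) get_leaf(-r) else nodes[[r]]$forest
    nodes[[k]] <- pairwise_forest_align(L, R, score)
    last <- nodes[[k]]
  }
  # reorder profile rows back to input order
  f <- last$forest
  ord <- match(ids, f$rows)
  f$left <- f$left[, ord, drop = FALSE]
  f$right <- f$right[, ord, drop = FALSE]
  f$rows <- f$rows[ord]
  structure(list(forest = f, score = last$score, ids = ids),
            class = "structure_alignment")
}

#' Sequence alignment implied by a structure alignment
#'
#' Reads the residue-level alignment off the in-order traversal of the
#' aligned forest: an UNPAIRED node contributes one column, a PAIR node two
#' (at its opening and closing positions); gap entries become `-`.
#' Degapping row i returns sequence i exactly. The consensus of the aligned
#' pair nodes is attached as `ss_cons` (columns where the pair node has at
#' least one non-gap row).
#'
#' @param y a `structure_alignment`.
#' @return an `rna_msa`.
#' @export
implied_sequence_alignment <- function(y) {
  f <- y$forest
  ord <- forest_inorder(f)
  r <- length(f$rows)
  nc <- nrow(ord)
  lets <- c("-", "A", "C", "G", "U")
  m <- matrix("-", r, nc)
  ss <- rep(".", nc)
  for (k in seq_len(nc)) {
    v <- ord[k, 1]; side <- ord[k, 2]
    codev <- if (side == 1L) f$left[v, ] else f$right[v, ]
    m[, k] <- lets[codev + 1L]
    if (f$kind[v] == 1L) ss[k] <- if (side == 1L) "(" else ")"
  }
  msa(f$rows, apply(m, 1, paste, collapse = ""),
      ss_cons = paste(ss, collapse = ""))
}
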