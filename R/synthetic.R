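# Seeded generator of RNA families with a known consensus structure,
# compensatory mutations and loop-confined indels: the test and evaluation
# substrate. The stated world: families of 5 homologous sequences sharing a
# consensus structure, compensatory substitutions at paired sites, neutral
# substitutions in loops, indels tuned so pairwise identity falls in a
# target band.

PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")
# canonical pair frequencies loosely following helix composition in
# structured RNAs: wobble pairs are rare
PAIR_TYPE_W <- c(AU = 0.24, UA = 0.24, CG = 0.22, GC = 0.22,
                 GU = 0.04, UG = 0.04)

# ~51 nt, three helices in a multiloop: small enough for fast sweeps,
# long enough to carry a real covariance signal
DEFAULT_CONSENSUS <-
  "....((((....((((.....))))..((((.....))))...))))...."

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, k) {
  ((as.numeric(seed) %% 1000003) * 2039 + k * 7919) %% 2147483629
}

#' Specification of a synthetic RNA family
#'
#' @param consensus dot-bracket consensus structure the family shares.
#' @param n_sequences number of family members (>= 2; benchmark
#'   subalignments have 5).
#' @param loop_sub_rate per-site substitution probability at unpaired
#'   sites.
#' @param compensatory_rate per-pair probability of a compensatory double
#'   substitution (both partners replaced by another canonical pair).
#' @param pair_break_rate per-pair probability of a one-sided,
#'   pair-breaking substitution.
#' @param indel_rate per-loop-site indel probability (split evenly between
#'   insertion and deletion; paired sites are never touched so the
#'   reference consensus stays well-defined in every row).
#' @param indel_mean_len mean indel length.
#' @param seed integer; fixes all randomness of the family.
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(consensus = DEFAULT_CONSENSUS, n_sequences = 5L,
                        loop_sub_rate = 0.35, compensatory_rate = 0.35,
                        pair_break_rate = 0, indel_rate = 0.03,
                        indel_mean_len = 2, seed = 1L) {
  rates <- c(loop_sub_rate, compensatory_rate, pair_break_rate, indel_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (compensatory_rate + pair_break_rate > 1)
    stop("compensatory_rate + pair_break_rate must be <= 1")
  if (n_sequences < 2) stop("n_sequences must be >= 2")
  pairs <- parse_dotbracket(consensus)
  if (nrow(pairs) && any(pairs[, 2] - pairs[, 1] - 1 < 3)) {
    inner <- innermost_pairs(pairs)
    if (any(pairs[inner, 2] - pairs[inner, 1] - 1 < 3))
      stop("consensus hairpin loop shorter than 3")
  }
  structure(list(consensus = consensus, n_sequences = as.integer(n_sequences),
                 loop_sub_rate = loop_sub_rate,
                 compensatory_rate = compensatory_rate,
                 pair_break_rate = pair_break_rate,
                 indel_rate = indel_rate, indel_mean_len = indel_mean_len,
                 seed = as.integer(seed)),
            class = "family_spec")
}

innermost_pairs <- function(pairs) {
  vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    !any(pairs[, 1] > i & pairs[, 2] < j)
  }, logical(1))
}

sample_other <- function(current, pool) {
  opts <- setdiff(pool, current)
  opts[sample.int(length(opts), 1)]
}

#' Generate a synthetic RNA family
#'
#' Samples an ancestor compatible with the consensus (paired sites get
#' canonical pairs, loops uniform bases), then mutates each descendant
#' independently: compensatory events replace both partners of a pair by
#' another canonical pair, pair-breaking events mutate one partner to a
#' non-pairing base, loop sites substitute freely, and indels are confined
#' to unpaired regions (hairpin loops never shrink below 3). The reference
#' alignment tracks every event, so degapping it reproduces the emitted
#' sequences and, with `pair_break_rate = 0`, every reference consensus
#' pair is canonical in every row. The same seed gives identical output.
#'
#' @param spec a [family_spec()].
#' @return list with `seqs` (named character vector), `ref_alignment`
#'   (`rna_msa` with the consensus as `ss_cons`) and `ref_consensus`
#'   (pair matrix on the reference-alignment columns).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  pairs <- parse_dotbracket(spec$consensus)
  L <- nchar(spec$consensus)
  partner <- integer(L)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  loops <- which(partner == 0L)
  # hairpin runs: unpaired stretch directly inside an innermost pair
  hairpin_run <- integer(0)
  if (nrow(pairs)) {
    for (k in which(innermost_pairs(pairs)))
      hairpin_run <- c(hairpin_run, (pairs[k, 1] + 1):(pairs[k, 2] - 1))
  }

  with_seed(spec$seed, {
    anc <- character(L)
    anc[loops] <- sample(RNA_BASES, length(loops), replace = TRUE)
    for (k in seq_len(nrow(pairs))) {
      pt <- sample(PAIR_TYPES, 1, prob = PAIR_TYPE_W)
      anc[pairs[k, 1]] <- substr(pt, 1, 1)
      anc[pairs[k, 2]] <- substr(pt, 2, 2)
    }
    n <- spec$n_sequences
    chars <- matrix(rep(anc, n), nrow = n, byrow = TRUE)  # '' = deleted
    inserts <- vector("list", n)  # per row: named list pos -> string
    for (r in seq_len(n)) {
      for (k in seq_len(nrow(pairs))) {
        u <- runif(1)
        i <- pairs[k, 1]; j <- pairs[k, 2]
        if (u < spec$compensatory_rate) {
          pt <- sample_other(paste0(chars[r, i], chars[r, j]), PAIR_TYPES)
          chars[r, i] <- substr(pt, 1, 1)
          chars[r, j] <- substr(pt, 2, 2)
        } else if (u < spec$compensatory_rate + spec$pair_break_rate) {
          side <- if (runif(1) < 0.5) i else j
          other <- if (side == i) j else i
          bad <- RNA_BASES[vapply(RNA_BASES, function(b) {
            if (side == i) !is_canonical_pair(b, chars[r, other])
            else !is_canonical_pair(chars[r, other], b)
          }, logical(1))]
          chars[r, side] <- bad[sample.int(length(bad), 1)]
        }
      }
      sub <- loops[runif(length(loops)) < spec$loop_sub_rate]
      for (p in sub) chars[r, p] <- sample_other(chars[r, p], RNA_BASES)
      # indels, loop sites only
      ins <- list()
      for (p in loops) {
        if (runif(1) >= spec$indel_rate) next
        if (runif(1) < 0.5) {
          len <- 1L + stats::rgeom(1, 1 / max(spec$indel_mean_len, 1))
          ins[[as.character(p)]] <- paste(
            sample(RNA_BASES, len, replace = TRUE), collapse = "")
        } else {
          if (p %in% hairpin_run) {
            # keep every hairpin loop at length >= 3 for this row
            k <- which(innermost_pairs(pairs) &
                         pairs[, 1] < p & pairs[, 2] > p)[1]
            run <- (pairs[k, 1] + 1):(pairs[k, 2] - 1)
            if (sum(chars[r, run] != "") <= 3) next
          }
          chars[r, p] <- ""
        }
      }
      inserts[[r]] <- ins
    }

    # build the reference alignment column by column
    cols <- list()
    colof <- integer(L)   # ancestor position -> final column index
    for (p in seq_len(L)) {
      col <- ifelse(chars[, p] == "", "-", chars[, p])
      cols[[length(cols) + 1]] <- col
      colof[p] <- length(cols)
      for (r in seq_len(n)) {
        insstr <- inserts[[r]][[as.character(p)]]
        if (is.null(insstr)) next
        for (b in strsplit(insstr, "")[[1]]) {
          col <- rep("-", n)
          col[r] <- b
          cols[[length(cols) + 1]] <- col
        }
      }
    }
    m <- do.call(cbind, cols)
    keep <- colSums(m != "-") > 0
    newidx <- cumsum(keep)
    m <- m[, keep, drop = FALSE]
    ref_pairs <- cbind(newidx[colof[pairs[, 1]]], newidx[colof[pairs[, 2]]])
    rows <- apply(m, 1, paste, collapse = "")
    ids <- sprintf("seq%02d", seq_len(n))
    aln <- msa(ids, rows,
               ss_cons = write_dotbracket(as_pairs(ref_pairs), ncol(m)))
    list(seqs = msa_sequences(aln), ref_alignment = aln,
         ref_consensus = as_pairs(ref_pairs))
  })
}

#' The gap-shift pathology family
#'
#' A five-member family built around the score-neutral gap-placement trap:
#' three long members share a two-pair helix (with compensatory variation
#' between them) flanked by homopolymer loops, two short members carry a
#' one-sided deletion inside the helix so only a single pair remains.
#' Sequence alignment places the short members' pairing bases under the
#' wrong helix column (the tie-break inserts the gap to the right of the
#' mismatch), which obscures the covariance signal; structure alignment
#' recovers it. The literal member `"AAGGAAAACCAA"` (structure
#' `..((....))..`) is always included; the paired bases of the remaining
#' members vary with the seed.
#'
#' @param seed integer seed.
#' @return named character vector of 5 sequences.
#' @export
make_twilight_pathology <- function(seed = 1L) {
  with_seed(seed, {
    mk_long <- function(outer, inner)
      paste0("AA", substr(outer, 1, 1), substr(inner, 1, 1), "CAAU",
             substr(inner, 2, 2), substr(outer, 2, 2), "AA")
    # short members carry a one-sided deletion in each helix arm plus a
    # compensatory switch of the remaining pair to A-U, a pair type no long
    # member uses: their pairing bases match nothing in the helix columns,
    # so every sequence-alignment placement is score-neutral there and the
    # deterministic tie-break parks them on non-supporting columns --
    # obscuring a covariance signal that structure alignment recovers
    short_templates <- c("AAUCAAUAAA",    # U...A single pair
                         "AAACAAUUAA")    # A...U (folds into two A-U pairs)
    longs <- c("AAGGAAAACCAA",            # the literal toy member
               mk_long("CG", "GC"),
               mk_long("GC", "CG"))
    if (runif(1) < 0.5) longs[2:3] <- longs[c(3, 2)]
    shorts <- sample(short_templates, 2, replace = TRUE)
    s <- c(longs, shorts)
    names(s) <- sprintf("p%d", 1:5)
    s
  })
}

#' Seeded family sweep across identity targets
#'
#' For each identity target, tunes a single divergence scalar (scaling the
#' substitution, compensatory and indel rates of a base [family_spec()]) by
#' bisection until the reference alignment's [percent_identity()] is within
#' 0.05 of the target, and emits `n_families` seeded families per target.
#'
#' @param identity_targets numeric vector in (0, 1).
#' @param n_families families per target.
#' @param seed master seed; each family derives its own stream.
#' @param base base [family_spec()] providing the consensus and untuned
#'   parameters.
#' @param tol acceptable deviation from the target (default 0.05).
#' @return list of lists with `spec`, `family` (a [generate_family()]
#'   result) and `identity` (the measured reference identity).
#' @export
sweep_families <- function(identity_targets, n_families = 1L, seed = 1L,
                           base = family_spec(), tol = 0.05) {
  if (any(identity_targets <= 0 | identity_targets >= 1))
    stop("identity targets must be in (0, 1)")
  out <- list()
  k <- 0L
  for (ti in seq_along(identity_targets)) {
    target <- identity_targets[ti]
    for (fi in seq_len(n_families)) {
      k <- k + 1L
      fam_seed <- derive_seed(seed, k)
      lo <- 0
      hi <- 1
      best <- NULL
      for (it in 1:14) {
        d <- (lo + hi) / 2
        sp <- family_spec(consensus = base$consensus,
                          n_sequences = base$n_sequences,
                          loop_sub_rate = min(0.8 * d, 1),
                          compensatory_rate = min(0.8 * d, 1),
                          pair_break_rate = base$pair_break_rate,
                          indel_rate = min(0.12 * d, 1),
                          indel_mean_len = base$indel_mean_len,
                          seed = fam_seed)
        fam <- generate_family(sp)
        id <- percent_identity(fam$ref_alignment)
        if (is.null(best) || abs(id - target) < abs(best$identity - target))
          best <- list(spec = sp, family = fam, identity = id)
        if (abs(id - target) <= tol) break
        if (id > target) lo <- d else hi <- d
      }
      if (abs(best$identity - target) > tol)
        stop(sprintf("identity target %.2f unreachable (closest %.2f)",
                     target, best$identity))
      out[[k]] <- best
    }
  }
  out
}
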