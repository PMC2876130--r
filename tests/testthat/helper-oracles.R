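# Independent brute-force oracles. These deliberately avoid the package's
# DP code paths: structures are enumerated and rescored, alignments are
# enumerated over aligned-column sets with closed-form gap-run costs, and
# forest alignments are explored by plain recursion over list-structured
# forests.

# ---- all nested structures of a sequence -----------------------------------

enum_structures <- function(seq, model = energy_model()) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  ok_pair <- function(i, j)
    j - i - 1 >= model$min_hairpin && is_canonical_pair(ch[i], ch[j], model)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return(list(matrix(integer(), 0, 2)))
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- rec(i + 1, j)                      # i unpaired
    for (k in if (j > i) (i + 1):j else integer(0)) {
      if (!ok_pair(i, k)) next
      for (s1 in rec(i + 1, k - 1))
        for (s2 in rec(k + 1, j))
          out[[length(out) + 1]] <- rbind(c(i, k), s1, s2)
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

oracle_mfe <- function(seq, model = energy_model()) {
  min(vapply(enum_structures(seq, model), energy_of_structure,
             numeric(1), seq = seq, model = model))
}

oracle_constrained_mfe <- function(seq, constraints, model = energy_model()) {
  constraints <- planacstar:::as_pairs(constraints)
  want <- paste(constraints[, 1], constraints[, 2])
  ok <- vapply(enum_structures(seq, model), function(s) {
    all(want %in% paste(s[, 1], s[, 2]))
  }, logical(1))
  structs <- enum_structures(seq, model)[ok]
  if (!length(structs)) stop("oracle: no structure satisfies constraints")
  min(vapply(structs, energy_of_structure, numeric(1),
             seq = seq, model = model))
}

# ---- global pairwise alignment oracle --------------------------------------

# decomposes an alignment by its aligned (residue-residue) columns; the
# unaligned stretch between two consecutive aligned columns is a pure gap
# run in each sequence, costed in closed form. Since gap_open <= gap_extend
# <= 0, interleaving gap runs is never better than keeping them contiguous,
# so this search space contains an optimum.
oracle_align_score <- function(a, b, scheme = scoring_scheme()) {
  c1 <- strsplit(a, "")[[1]]
  c2 <- strsplit(b, "")[[1]]
  n <- length(c1)
  m <- length(c2)
  gcost <- function(k) if (k == 0) 0 else
    scheme$gap_open + (k - 1) * scheme$gap_extend
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- gcost(n - i + 1) + gcost(m - j + 1)   # no further aligned column
    if (i <= n && j <= m) {
      for (k in i:n) for (l in j:m) {
        s <- gcost(k - i) + gcost(l - j) +
          (if (c1[k] == c2[l]) scheme$match else scheme$mismatch) +
          rec(k + 1, l + 1)
        if (s > best) best <- s
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1)
}

# ---- forest alignment oracle ------------------------------------------------

oracle_forest <- function(seq, db) {
  pairs <- parse_dotbracket(db)
  ch <- strsplit(seq, "")[[1]]
  partner <- integer(length(ch))
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  build <- function(lo, hi) {
    out <- list()
    k <- lo
    while (k <= hi) {
      if (partner[k] == 0) {
        out[[length(out) + 1]] <- list(kind = "U", left = ch[k],
                                       right = NULL, children = list())
        k <- k + 1
      } else {
        j <- partner[k]
        out[[length(out) + 1]] <- list(kind = "P", left = ch[k],
                                       right = ch[j],
                                       children = build(k + 1, j - 1))
        k <- j + 1
      }
    }
    out
  }
  build(1, length(ch))
}

ogap1 <- function(t, sc) if (t$kind == "P") sc$pair_gap else sc$base_gap

ogap_all <- function(F, sc) {
  if (!length(F)) return(0)
  sum(vapply(F, function(t) ogap1(t, sc) + ogap_all(t$children, sc),
             numeric(1)))
}

osigma <- function(a, b, sc) {
  if (a$kind != b$kind) return(-Inf)
  if (a$kind == "U") {
    if (a$left == b$left) sc$base_match else sc$base_mismatch
  } else {
    sc$pair_match +
      (if (a$left == b$left && a$right == b$right) sc$pair_ident_bonus else 0)
  }
}

oracle_forest_score <- function(F, G, sc = forest_score()) {
  if (!length(F) && !length(G)) return(0)
  if (!length(F)) return(ogap_all(G, sc))
  if (!length(G)) return(ogap_all(F, sc))
  a <- F[[1]]
  b <- G[[1]]
  best <- -Inf
  if (a$kind == b$kind) {
    best <- osigma(a, b, sc) +
      oracle_forest_score(a$children, b$children, sc) +
      oracle_forest_score(F[-1], G[-1], sc)
  }
  for (k in 0:length(G)) {
    head <- if (k > 0) G[1:k] else list()
    rest <- if (k < length(G)) G[(k + 1):length(G)] else list()
    v <- ogap1(a, sc) + oracle_forest_score(a$children, head, sc) +
      oracle_forest_score(F[-1], rest, sc)
    if (v > best) best <- v
  }
  for (k in 0:length(F)) {
    head <- if (k > 0) F[1:k] else list()
    rest <- if (k < length(F)) F[(k + 1):length(F)] else list()
    v <- ogap1(b, sc) + oracle_forest_score(head, b$children, sc) +
      oracle_forest_score(rest, G[-1], sc)
    if (v > best) best <- v
  }
  best
}

# ---- misc -------------------------------------------------------------------

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# structured random sequences: fold-worthy (biased composition)
random_rna_pairy <- function(n) {
  half <- sample(c("G", "C", "A", "U"), ceiling(n / 2), replace = TRUE,
                 prob = c(0.35, 0.15, 0.3, 0.2))
  rest <- sample(c("G", "C", "A", "U"), floor(n / 2), replace = TRUE,
                 prob = c(0.15, 0.35, 0.2, 0.3))
  paste(c(half, rest), collapse = "")
}
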