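#' @useDynLib planacstar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats as.dist hclust runif rbinom rgeom
#' @importFrom utils head tail
NULL

RNA_BASES <- c("A", "C", "G", "U")

# first concrete base of each IUPAC ambiguity set, used only on opt-in
IUPAC_FIRST <- c(R = "A", Y = "C", S = "G", W = "A", K = "G", M = "A",
                 B = "C", D = "A", H = "A", V = "A", N = "A")

#' Normalize RNA residues
#'
#' Uppercases, maps T to U and optionally resolves IUPAC ambiguity codes to
#' the first concrete base of their set. Ambiguity codes are rejected by
#' default: downstream structure alignment requires concrete sequences, so
#' the full IUPAC alphabet is not supported.
#'
#' @param x character vector of residue strings (no gaps).
#' @param allow_ambiguity if `TRUE`, ambiguity codes are mapped to the first
#'   concrete base of their IUPAC set instead of raising an error.
#' @return character vector over the alphabet ACGU.
#' @export
normalize_residues <- function(x, allow_ambiguity = FALSE) {
  x <- chartr("t", "T", toupper(x))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(gsub("[ACGU]", "", x[bad]), "")))
    amb <- chars[chars %in% names(IUPAC_FIRST)]
    other <- setdiff(chars, names(IUPAC_FIRST))
    if (length(other))
      stop("invalid residue character(s): ", paste(other, collapse = ", "))
    if (!allow_ambiguity)
      stop("IUPAC ambiguity code(s) ", paste(amb, collapse = ", "),
           " found; only concrete RNA sequences (ACGU) are supported. ",
           "Set allow_ambiguity = TRUE to map each code to the first ",
           "concrete base of its set.")
    for (a in amb) x <- gsub(a, IUPAC_FIRST[[a]], x, fixed = TRUE)
  }
  x
}

validate_sequences <- function(seqs) {
  if (length(seqs) == 0) stop("no sequences")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence needs a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs))) stop("empty sequence(s)")
  if (any(grepl("[^ACGU]", seqs)))
    stop("sequences must be over the alphabet ACGU")
  invisible(seqs)
}

as_text_input <- function(path_or_text) {
  # a multi-line string or one starting with '>'/'CLUSTAL'/'# STOCKHOLM'
  # is treated as literal content, anything else as a file path
  if (length(path_or_text) > 1)
    return(paste(path_or_text, collapse = "\n"))
  if (grepl("\n", path_or_text) || grepl("^\\s*(>|CLUSTAL|# STOCKHOLM)",
                                         path_or_text))
    return(path_or_text)
  if (!file.exists(path_or_text)) stop("file not found: ", path_or_text)
  paste(readLines(path_or_text, warn = FALSE), collapse = "\n")
}

#' Read RNA sequences from FASTA
#'
#' Accepts a file path or the FASTA text itself. T is converted to U;
#' lowercase is uppercased; IUPAC ambiguity codes are rejected unless
#' `allow_ambiguity = TRUE` (see [normalize_residues()]). Ids are the header
#' up to the first whitespace; order is preserved.
#'
#' @param path_or_text FASTA file path or text.
#' @param allow_ambiguity passed to [normalize_residues()].
#' @return named character vector of RNA sequences.
#' @export
read_fasta <- function(path_or_text, allow_ambiguity = FALSE) {
  txt <- as_text_input(path_or_text)
  if (!grepl("\\S", txt)) stop("empty FASTA input")
  tf <- tempfile(fileext = ".fa")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  bs <- Biostrings::readBStringSet(tf)
  if (length(bs) == 0) stop("empty FASTA input")
  ids <- sub("\\s.*$", "", names(bs))
  seqs <- normalize_residues(as.character(bs), allow_ambiguity)
  names(seqs) <- ids
  validate_sequences(seqs)
  seqs
}

#' Write RNA sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path optional file path; if `NULL` the text is returned invisibly
#'   only.
#' @param width line-wrap width.
#' @return the FASTA text, invisibly when writing to a file.
#' @export
write_fasta <- function(seqs, path = NULL, width = 60L) {
  if (length(seqs) == 0) {
    txt <- ""
  } else {
    validate_sequences(seqs)
    rec <- vapply(seq_along(seqs), function(i) {
      s <- seqs[[i]]
      chunks <- substring(s, seq(1, nchar(s), width),
                          pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
      paste0(">", names(seqs)[i], "\n", paste(chunks, collapse = "\n"))
    }, character(1))
    txt <- paste0(paste(rec, collapse = "\n"), "\n")
  }
  if (!is.null(path)) {
    cat(txt, file = path)
    return(invisible(txt))
  }
  txt
}

# ---- multiple alignment container ------------------------------------------

#' Construct a multiple alignment
#'
#' Rows are gapped strings over ACGU-; `.` and `~` are accepted as gap
#' characters on input and normalized to `-`. All-gap columns are removed.
#'
#' @param ids row ids.
#' @param rows gapped row strings, same length each.
#' @param ss_cons optional consensus structure (dot-bracket on the columns).
#' @return an object of class `rna_msa` with fields `ids`, `rows`, `n_cols`
#'   and optionally `ss_cons`.
#' @export
msa <- function(ids, rows, ss_cons = NULL) {
  rows <- unname(chartr(".~", "--", toupper(rows)))
  rows <- chartr("T", "U", rows)
  if (length(ids) != length(rows)) stop("ids/rows length mismatch")
  nc <- unique(nchar(rows))
  if (length(nc) != 1) stop("ragged alignment rows")
  if (any(grepl("[^ACGU-]", rows)))
    stop("alignment rows must be over the alphabet ACGU-")
  m <- do.call(rbind, strsplit(rows, ""))
  allgap <- colSums(m != "-") == 0
  if (any(allgap)) {
    m <- m[, !allgap, drop = FALSE]
    rows <- apply(m, 1, paste, collapse = "")
    if (!is.null(ss_cons)) ss_cons <- NULL  # columns changed, drop annotation
  }
  seqs <- degap(rows)
  names(seqs) <- ids
  validate_sequences(seqs)
  structure(list(ids = as.character(ids), rows = unname(rows),
                 n_cols = unname(nchar(rows[1])), ss_cons = ss_cons),
            class = "rna_msa")
}

#' @export
print.rna_msa <- function(x, ...) {
  cat(sprintf("RNA multiple alignment: %d rows x %d columns\n",
              length(x$ids), x$n_cols))
  w <- max(nchar(x$ids))
  for (i in seq_along(x$ids))
    cat(sprintf("%-*s %s\n", w, x$ids[i], x$rows[i]))
  if (!is.null(x$ss_cons))
    cat(sprintf("%-*s %s\n", w, "SS_cons", x$ss_cons))
  invisible(x)
}

#' Remove gaps from gapped strings
#' @param x character vector of gapped strings.
#' @return ungapped strings.
#' @export
degap <- function(x) gsub("[-.~]", "", x)

#' Extract the ungapped sequences of an alignment
#' @param aln an `rna_msa`.
#' @return named character vector of sequences, in row order.
#' @export
msa_sequences <- function(aln) {
  s <- degap(aln$rows)
  names(s) <- aln$ids
  s
}

msa_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, ""))
  rownames(m) <- aln$ids
  m
}

#' Read a multiple alignment
#'
#' Supported dialects: `clustal`, `stockholm` and `aligned-fasta`. For
#' Stockholm input a `#=GC SS_cons` line, if present, is returned in the
#' `ss_cons` field with WUSS brackets `<>`, `[]`, `{}` normalized to `()`
#' and all other WUSS symbols to `.`.
#'
#' @param path_or_text file path or alignment text.
#' @param dialect one of `"clustal"`, `"stockholm"`, `"aligned-fasta"`.
#' @return an `rna_msa`.
#' @export
read_alignment <- function(path_or_text,
                           dialect = c("clustal", "stockholm",
                                       "aligned-fasta")) {
  dialect <- match.arg(dialect)
  txt <- as_text_input(path_or_text)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (dialect == "aligned-fasta") {
    tf <- tempfile(fileext = ".fa")
    on.exit(unlink(tf))
    writeLines(txt, tf)
    bs <- Biostrings::readBStringSet(tf)
    return(msa(sub("\\s.*$", "", names(bs)), as.character(bs)))
  }
  ss <- NULL
  ids <- character()
  blocks <- list()
  for (ln in lines) {
    if (dialect == "clustal" && grepl("^CLUSTAL", ln)) next
    if (dialect == "stockholm") {
      if (grepl("^# STOCKHOLM", ln) || ln == "//") next
      if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
        part <- sub("^#=GC\\s+SS_cons\\s+", "", ln)
        ss <- paste0(ss %||% "", part)
        next
      }
      if (grepl("^#", ln)) next
    }
    if (!grepl("\\S", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2) next
    if (dialect == "clustal" && length(parts) == 2 &&
        grepl("^[.:* ]+$", parts[2])) next  # conservation line
    id <- parts[1]
    chunk <- parts[2]
    if (!(id %in% ids)) {
      ids <- c(ids, id)
      blocks[[id]] <- chunk
    } else {
      blocks[[id]] <- paste0(blocks[[id]], chunk)
    }
  }
  if (length(ids) == 0) stop("no alignment rows found")
  rows <- unlist(blocks[ids], use.names = FALSE)
  if (length(unique(nchar(rows))) != 1) stop("ragged alignment rows")
  if (!is.null(ss)) {
    ss <- chartr("<>[]{}", "()()()", ss)
    ss <- gsub("[^().]", ".", ss)
  }
  msa(ids, rows, ss_cons = ss)
}

#' Write a multiple alignment
#'
#' @param aln an `rna_msa`.
#' @param dialect `"clustal"`, `"stockholm"` or `"aligned-fasta"`.
#' @param path optional output file.
#' @param ss_cons optional dot-bracket consensus to emit as `#=GC SS_cons`
#'   (Stockholm only; defaults to `aln$ss_cons`).
#' @return the text, invisibly when writing to a file.
#' @export
write_alignment <- function(aln,
                            dialect = c("clustal", "stockholm",
                                        "aligned-fasta"),
                            path = NULL, ss_cons = NULL) {
  dialect <- match.arg(dialect)
  ss_cons <- ss_cons %||% aln$ss_cons
  w <- max(nchar(aln$ids), if (dialect == "stockholm") 12L else 0L)
  body <- switch(dialect,
    "aligned-fasta" = paste0(paste0(">", aln$ids, "\n", aln$rows,
                                    collapse = "\n"), "\n"),
    "clustal" = paste0("CLUSTAL W multiple sequence alignment\n\n",
                       paste(sprintf("%-*s %s", w, aln$ids, aln$rows),
                             collapse = "\n"), "\n"),
    "stockholm" = {
      ss_line <- if (!is.null(ss_cons))
        sprintf("%-*s %s\n", w, "#=GC SS_cons", ss_cons) else ""
      paste0("# STOCKHOLM 1.0\n",
             paste(sprintf("%-*s %s", w, aln$ids, aln$rows),
                   collapse = "\n"),
             "\n", ss_line, "//\n")
    })
  if (!is.null(path)) {
    cat(body, file = path)
    return(invisible(body))
  }
  body
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- dot-bracket ------------------------------------------------------------

#' Parse dot-bracket notation
#'
#' @param text a string over `.`, `(`, `)`.
#' @return integer matrix with columns `i`, `j` (1-based, `i < j`), one row
#'   per base pair, ordered by `i`. Pairs are mutually nested by
#'   construction.
#' @export
parse_dotbracket <- function(text) {
  chars <- strsplit(text, "")[[1]]
  if (any(!chars %in% c(".", "(", ")")))
    stop("dot-bracket may only contain '.', '(' and ')'")
  stack <- integer()
  pairs <- NULL
  for (k in seq_along(chars)) {
    if (chars[k] == "(") stack <- c(stack, k)
    else if (chars[k] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket: unmatched ')'")
      pairs <- rbind(pairs, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '('")
  if (is.null(pairs)) pairs <- matrix(integer(), 0, 2)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  pairs
}

pairs_cross <- function(pairs) {
  if (nrow(pairs) < 2) return(FALSE)
  for (a in seq_len(nrow(pairs) - 1)) {
    for (b in (a + 1):nrow(pairs)) {
      i <- pairs[a, 1]; j <- pairs[a, 2]
      k <- pairs[b, 1]; l <- pairs[b, 2]
      if ((i < k && k < j && j < l) || (k < i && i < l && l < j))
        return(TRUE)
    }
  }
  FALSE
}

#' Serialize base pairs to dot-bracket
#'
#' The inverse of [parse_dotbracket()]. Crossing (pseudoknotted) pair sets
#' are rejected: non-nested base pairing is not representable here, matching
#' the folding model.
#'
#' @param pairs 2-column matrix of 1-based pairs.
#' @param length length of the annotated sequence.
#' @return dot-bracket string.
#' @export
write_dotbracket <- function(pairs, length) {
  pairs <- as_pairs(pairs)
  if (nrow(pairs)) {
    if (any(pairs < 1) || any(pairs > length))
      stop("pair index out of range")
    if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy i < j")
    if (anyDuplicated(as.vector(pairs)))
      stop("a position may occur in at most one pair")
    if (pairs_cross(pairs))
      stop("crossing pairs would create non-nested base pairing")
  }
  out <- rep(".", length)
  out[pairs[, 1]] <- "("
  out[pairs[, 2]] <- ")"
  paste(out, collapse = "")
}

as_pairs <- function(pairs) {
  if (is.null(pairs) || length(pairs) == 0)
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j"))))
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  pairs[order(pairs[, 1]), , drop = FALSE]
}

# ---- Vienna two-line records ------------------------------------------------

#' Read Vienna-style fold records
#'
#' Records of the form `>id`, sequence line, structure line with an optional
#' trailing energy in parentheses, e.g. `"((...)) (-3.00)"`.
#'
#' @param path_or_text file path or text.
#' @return list of lists with fields `id`, `seq`, `structure` (dot-bracket)
#'   and `energy` (`NA` if absent).
#' @export
read_vienna <- function(path_or_text) {
  txt <- as_text_input(path_or_text)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  k <- 1
  while (k <= length(lines)) {
    if (!grepl("^>", lines[k])) stop("expected '>' header at line ", k)
    id <- sub("\\s.*$", "", sub("^>", "", lines[k]))
    seq <- normalize_residues(trimws(lines[k + 1]))
    sl <- trimws(lines[k + 2])
    en <- NA_real_
    m <- regmatches(sl, regexec("^([.()]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)$", sl))[[1]]
    if (length(m)) {
      struct <- m[2]
      en <- as.numeric(m[3])
    } else struct <- sl
    if (nchar(struct) != nchar(seq))
      stop("structure length differs from sequence length for ", id)
    out[[length(out) + 1]] <- list(id = id, seq = seq, structure = struct,
                                   energy = en)
    k <- k + 3
  }
  out
}

#' Write Vienna-style fold records
#'
#' @param records list as returned by [read_vienna()], or a list of
#'   `fold_result` objects with an added `id`/`seq`.
#' @param path optional output file.
#' @return the text.
#' @export
write_vienna <- function(records, path = NULL) {
  txt <- paste(vapply(records, function(r) {
    en <- if (!is.null(r$energy) && !is.na(r$energy))
      sprintf(" (%.2f)", r$energy) else ""
    paste0(">", r$id, "\n", r$seq, "\n", r$structure, en)
  }, character(1)), collapse = "\n")
  txt <- paste0(txt, "\n")
  if (!is.null(path)) {
    cat(txt, file = path)
    return(invisible(txt))
  }
  txt
}
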