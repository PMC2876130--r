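# The fine-tuning driver: SCI scoring, the align -> fold -> project ->
# refold -> structure-align -> re-fold iteration with accept-if-improved
# termination, plus evaluation utilities.

#' Structure conservation index
#'
#' The SCI is the quotient of the consensus folding energy `E_A` of an
#' alignment and the mean of the individual sequences' MFEs. Values near or
#' above 1 indicate well-conserved structure (covariance pseudo-energies
#' can push `E_A` below the mean MFE). Degenerate case: when the mean MFE
#' is 0 the SCI is 0 by convention if `E_A` is 0 too, and undefined
#' (an error) otherwise.
#'
#' @param consensus_energy consensus energy `E_A`.
#' @param individual_mfes numeric vector of single-sequence MFEs (>= 1).
#' @return an object of class `sci_report`: `consensus_energy`,
#'   `individual_mfes`, `mean_mfe`, `sci` (full precision; printed to 4
#'   decimals).
#' @export
sci <- function(consensus_energy, individual_mfes) {
  if (length(individual_mfes) < 1) stop("need at least one individual MFE")
  mean_mfe <- mean(individual_mfes)
  if (mean_mfe == 0) {
    if (consensus_energy != 0)
      stop("SCI undefined: mean individual MFE is 0 but E_A is not")
    val <- 0
  } else {
    val <- consensus_energy / mean_mfe
  }
  structure(list(consensus_energy = consensus_energy,
                 individual_mfes = individual_mfes,
                 mean_mfe = mean_mfe, sci = val),
            class = "sci_report")
}

#' @export
print.sci_report <- function(x, ...) {
  cat(sprintf("SCI %.4f  (E_A %.2f / mean MFE %.2f over %d sequences)\n",
              x$sci, x$consensus_energy, x$mean_mfe,
              length(x$individual_mfes)))
  invisible(x)
}

#' Pipeline configuration
#'
#' @param scheme sequence-alignment [scoring_scheme()].
#' @param model [energy_model()].
#' @param cov_weight,q,mismatch_penalty consensus-folding parameters, see
#'   [alifold()].
#' @param fscore structure-alignment [forest_score()].
#' @param max_iterations upper bound on fine-tuning rounds (>= 1; one round
#'   normally suffices).
#' @param epsilon minimal SCI improvement counted as strict (guards
#'   floating-point ties).
#' @return an object of class `planac_config`.
#' @export
planac_config <- function(scheme = scoring_scheme(), model = energy_model(),
                          cov_weight = 1, q = 0.5, mismatch_penalty = 1,
                          fscore = forest_score(), max_iterations = 10L,
                          epsilon = 1e-9) {
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (epsilon < 0) stop("epsilon must be >= 0")
  structure(list(scheme = scheme, model = model, cov_weight = cov_weight,
                 q = q, mismatch_penalty = mismatch_penalty,
                 fscore = fscore,
                 max_iterations = as.integer(max_iterations),
                 epsilon = epsilon),
            class = "planac_config")
}

consensus_of <- function(aln, config) {
  alifold(aln, config$model, config$cov_weight, config$q,
          config$mismatch_penalty)
}

#' Plan A: align, then fold jointly
#'
#' The baseline the fine-tuning is compared against: progressive sequence
#' alignment followed by consensus folding, nothing else. Identical to the
#' iteration-0 record of [run_planacstar()].
#'
#' @param seqs named character vector of RNA sequences (n >= 2).
#' @param config a [planac_config()].
#' @param aligned optional precomputed `rna_msa` (skips the alignment
#'   stage).
#' @return list with `alignment`, `consensus` and `sci` (a `sci_report`).
#' @export
run_plan_a <- function(seqs, config = planac_config(), aligned = NULL) {
  seqs <- normalize_residues(seqs)
  validate_sequences(seqs)
  if (length(seqs) < 2) stop("need at least 2 sequences")
  aln <- aligned %||% progressive_align(seqs, config$scheme)
  cons <- consensus_of(aln, config)
  mfes <- vapply(seqs, function(s) mfe_fold(s, config$model)$energy,
                 numeric(1))
  list(alignment = aln, consensus = cons,
       sci = sci(cons$energy, mfes))
}

#' Iterative fine-tuning of a structural RNA alignment
#'
#' Runs the full pipeline: (1) progressive sequence alignment (skipped when
#' `aligned` is given); (2) consensus folding and SCI scoring; then rounds
#' of (3) projecting the consensus pairs onto each sequence, (4) refolding
#' each sequence under those mandatory-pair constraints, (5) aligning the
#' refolded structures as forests irrespective of sequence, (6) extracting
#' the implied sequence alignment, (7) re-folding it into a new consensus
#' with SCI `X*`. A round is accepted iff `X* > X + epsilon`; on acceptance
#' the alignment and consensus are replaced and the loop repeats, otherwise
#' it exits with the best state. A round whose implied alignment is
#' identical to the current one is a fixed point and ends the loop without
#' being recorded. The SCI denominator (unconstrained individual MFEs) is
#' alignment-independent and computed once.
#'
#' Consensus pairs are never undone: every projected consensus pair appears
#' in the corresponding constrained refold, so fine-tuning can only realign
#' or augment the structure found initially.
#'
#' @param seqs named character vector of RNA sequences (n >= 2, concrete
#'   ACGU; ambiguity codes are rejected).
#' @param config a [planac_config()].
#' @param aligned optional starting `rna_msa`.
#' @return list with `alignment`, `consensus`, `sci` (best state), `trace`
#'   (list of per-iteration records: `iteration`, `alignment`, `consensus`,
#'   `sci`, `accepted`), and `folds` (the last round's constrained folds).
#' @export
run_planacstar <- function(seqs, config = planac_config(), aligned = NULL) {
  seqs <- normalize_residues(seqs)
  validate_sequences(seqs)
  if (length(seqs) < 2) stop("need at least 2 sequences")
  aln <- aligned %||% progressive_align(seqs, config$scheme)
  cons <- consensus_of(aln, config)
  mfes <- vapply(seqs, function(s) mfe_fold(s, config$model)$energy,
                 numeric(1))
  X <- sci(cons$energy, mfes)
  trace <- list(list(iteration = 0L, alignment = aln, consensus = cons,
                     sci = X, accepted = TRUE))
  folds <- NULL
  for (it in seq_len(config$max_iterations)) {
    constraints <- lapply(seq_along(seqs), function(i)
      project_consensus(cons, aln, i, config$model))
    refolds <- lapply(seq_along(seqs), function(i) {
      fr <- constrained_fold(seqs[[i]], constraints[[i]], config$model)
      fr$id <- names(seqs)[i]
      fr
    })
    y <- multiple_structure_align(lapply(refolds, function(fr)
      list(id = fr$id, seq = fr$seq, structure = fr$structure)),
      config$fscore)
    aln_star <- implied_sequence_alignment(y)
    if (identical(aln_star$rows, aln$rows)) break  # fixed point
    cons_star <- consensus_of(aln_star, config)
    X_star <- sci(cons_star$energy, mfes)
    accepted <- X_star$sci > X$sci + config$epsilon
    trace[[length(trace) + 1]] <- list(iteration = it,
                                       alignment = aln_star,
                                       consensus = cons_star,
                                       sci = X_star, accepted = accepted)
    folds <- refolds
    if (!accepted) break
    aln <- aln_star
    cons <- cons_star
    X <- X_star
  }
  list(alignment = aln, consensus = cons, sci = X, trace = trace,
       folds = folds)
}

# ---- evaluation -------------------------------------------------------------

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with symmetric windows;
#' endpoints are smoothed by evaluating the boundary window's polynomial
#' fit at their positions, so polynomials of degree <= `polyorder` are
#' reproduced exactly everywhere.
#'
#' @param y numeric series.
#' @param window odd window length (`>= polyorder + 1`).
#' @param polyorder polynomial degree.
#' @return smoothed series, same length as `y`.
#' @export
sgolay_filter <- function(y, window = 7L, polyorder = 2L) {
  n <- length(y)
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (n < window) stop("series shorter than window")
  half <- (window - 1L) %/% 2L
  X <- outer(seq(-half, half), 0:polyorder, `^`)
  H <- X %*% solve(crossprod(X)) %*% t(X)   # hat matrix of the window fit
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i <= half) {
      out[i] <- H[i, ] %*% y[1:window]
    } else if (i > n - half) {
      out[i] <- H[window - (n - i), ] %*% y[(n - window + 1):n]
    } else {
      out[i] <- H[half + 1, ] %*% y[(i - half):(i + half)]
    }
  }
  out
}

#' SCI-versus-identity evaluation curve
#'
#' Runs Plan A and the fine-tuning pipeline on each family, tabulates the
#' Plan-A alignment identity and both SCIs, sorts by identity and smooths
#' the SCI series with a Savitzky-Golay filter.
#'
#' @param families list of named character vectors (sequence families).
#' @param config a [planac_config()].
#' @param window,polyorder smoothing parameters (window odd, `>=` number of
#'   families is an error).
#' @return list with `table` (one row per family: `identity`, `sci_plan_a`,
#'   `sci_planacstar`, `gap_content`) and `smoothed` (sorted by identity,
#'   with smoothed SCI columns).
#' @export
evaluate_curve <- function(families, config = planac_config(),
                           window = 7L, polyorder = 2L) {
  if (length(families) < window) stop("need at least `window` families")
  rows <- lapply(families, function(fam) {
    res <- run_planacstar(fam, config)
    plan_a <- res$trace[[1]]
    data.frame(identity = percent_identity(plan_a$alignment),
               sci_plan_a = plan_a$sci$sci,
               sci_planacstar = res$sci$sci,
               gap_content = gap_content(plan_a$alignment))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  sm <- tab[order(tab$identity), ]
  sm$sci_plan_a_smooth <- sgolay_filter(sm$sci_plan_a, window, polyorder)
  sm$sci_planacstar_smooth <- sgolay_filter(sm$sci_planacstar, window,
                                            polyorder)
  list(table = tab, smoothed = sm)
}

#' Summarize a fine-tuning trace
#'
#' @param trace the `trace` component of a [run_planacstar()] result.
#' @return an object of class `planac_report` with `table` (per-iteration
#'   SCI, `E_A`, identity, gap content, accepted flag), `text` and `json`
#'   renderings.
#' @export
report <- function(trace) {
  if (length(trace) == 0) stop("empty trace")
  tab <- do.call(rbind, lapply(trace, function(rec)
    data.frame(iteration = rec$iteration,
               sci = rec$sci$sci,
               E_A = rec$consensus$energy,
               identity = percent_identity(rec$alignment),
               gap_content = gap_content(rec$alignment),
               accepted = rec$accepted)))
  txt <- c(sprintf("%9s %8s %8s %8s %11s %8s",
                   "iteration", "SCI", "E_A", "identity", "gap_content",
                   "accepted"),
           sprintf("%9d %8.4f %8.2f %8.3f %11.3f %8s",
                   tab$iteration, tab$sci, tab$E_A, tab$identity,
                   tab$gap_content, tab$accepted))
  structure(list(table = tab,
                 text = paste(txt, collapse = "\n"),
                 json = jsonlite::toJSON(tab, digits = NA)),
            class = "planac_report")
}

#' @export
print.planac_report <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}
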