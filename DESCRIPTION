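Package: planacstar
Title: Fine-Tuning Structural RNA Alignments by Iterated Refolding and
    Structure Alignment
Version: 0.1.0
Authors@R:
    person("planacstar", "maintainers", email = "planacstar@example.org",
           role = c("aut", "cre"))
Description: Iterative fine-tuning of RNA multiple alignments in the
    30-55% sequence-identity "twilight zone". Starting from a sequence
    alignment, the pipeline folds the alignment into a consensus secondary
    structure with covariance pseudo-energies, projects the consensus onto
    each sequence, refolds every sequence under those constraints, aligns
    the resulting structures as ordered forests irrespective of sequence,
    extracts the sequence alignment implied by the structure alignment,
    and iterates while the structure conservation index (SCI, the ratio of
    the consensus folding energy to the mean single-sequence minimum free
    energy) improves. Includes a simplified pluggable energy model with
    exact brute-force oracles, readers and writers for FASTA, CLUSTAL,
    Stockholm and Vienna dot-bracket formats, and a seeded generator of
    synthetic RNA families with compensatory mutations for evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
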