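# Shared fixtures. The toy pair from the gap-placement pathology: the upper
# sequence/structure is used verbatim; the printed lower sequence (9 nt) is
# one base short of its 10-character structure, so the fixture uses the
# synthetic completion with a trailing A (the structure is authoritative).
TOY_UPPER_SEQ <- "AAGGAAAACCAA"
TOY_UPPER_DB  <- "..((....)).."
TOY_LOWER_SEQ <- "AACAAAAGAA"    # synthetic completion of "AACAAAAGA"
TOY_LOWER_DB  <- "..(....).."

toy_forests <- function() {
  list(f1 = forest_from_structure(TOY_UPPER_SEQ, TOY_UPPER_DB, "upper"),
       f2 = forest_from_structure(TOY_LOWER_SEQ, TOY_LOWER_DB, "lower"))
}

count_gaps <- function(aln) sum(planacstar:::msa_matrix(aln) == "-")
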