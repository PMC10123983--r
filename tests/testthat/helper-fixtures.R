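# Shared fixture, built once per test run. Seed fixed so every expectation
# over it is reproducible.
default_fixture <- sim_fixture(sim_config(seed = 42))

# Shortcut for a sam tibble from parallel vectors.
aln_tbl <- function(qname, flag, pos, cigar, seq = NULL, qual = NULL,
                    rname = "chr1", mapq = 60L) {
  n <- length(cigar)
  if (is.null(seq)) {
    qw <- vapply(cigar, function(cg) {
      sum(as.integer(regmatches(cg, gregexpr("[0-9]+(?=[MIS=X])",
                                             cg, perl = TRUE))[[1]]))
    }, 1L)
    seq <- vapply(qw, function(w) strrep("A", w), "")
    qual <- vapply(qw, function(w) strrep("I", w), "")
  }
  tibble::tibble(
    qname = qname, flag = as.integer(flag), rname = rname,
    pos = as.integer(pos), mapq = mapq, cigar = cigar, seq = seq, qual = qual
  )
}
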