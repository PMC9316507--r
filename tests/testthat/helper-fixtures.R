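# deterministic string generators and toy objects shared by the tests

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# single-"exon" circle wrapping an arbitrary sequence, for scanner tests
toy_circle <- function(seq, id = "toy") {
  L <- nchar(seq)
  circ_rna(id,
           data.frame(exon_index = 1L, seg_start = 0L, seg_end = L),
           seq,
           backsplice_junction(1L, L, 1L, 0L, L, L))
}

# a codon string of n non-stop, non-ATG codons (deterministic)
filler_codons <- function(n, seed = 1) {
  set.seed(seed)
  pool <- c("GCT", "GCC", "GAA", "GAT", "TGC", "CAT", "ATC", "AAA",
            "CTG", "TTT", "CCT", "AGT", "ACG", "TAC", "GTG", "TGG")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# brute-force oracle: number of junction placements (donor_end,
# acceptor_start) on the same model that realise the identical circular
# sequence (cyclic-word equality)
enumerate_placements <- function(circ, model) {
  bsj <- circ$bsj
  segs <- circ$segments
  dlen <- nchar(circaid:::exon_seq(model, bsj$donor_exon_index))
  alen <- nchar(circaid:::exon_seq(model, bsj$acceptor_exon_index))
  # cyclic-word equality: same length + substring of the doubled original
  doubled <- paste0(circ$sequence, circ$sequence)
  count <- 0L
  single <- bsj$donor_exon_index == bsj$acceptor_exon_index
  const <- bsj$donor_end_offset - bsj$acceptor_start_offset
  for (a0 in 0:(alen - 1L)) {
    d0 <- const + a0
    if (d0 < 1L || d0 > dlen) next
    seq <- if (single) {
      substr(circaid:::exon_seq(model, bsj$acceptor_exon_index),
             a0 + 1L, d0)
    } else {
      parts <- vapply(seq_len(nrow(segs)), function(j) {
        ei <- segs$exon_index[j]
        es <- circaid:::exon_seq(model, ei)
        if (ei == bsj$acceptor_exon_index) substr(es, a0 + 1L, nchar(es))
        else if (ei == bsj$donor_exon_index) substr(es, 1L, d0)
        else substr(es, segs$seg_start[j] + 1L, segs$seg_end[j])
      }, character(1))
      paste(parts, collapse = "")
    }
    if (nchar(seq) == circ$length && grepl(seq, doubled, fixed = TRUE)) {
      count <- count + 1L
    }
  }
  count
}

table_oracle_exon_counts <- function(exons_col) {
  idx <- lapply(strsplit(exons_col, ","), function(p) {
    unique(as.integer(sub("^\\s*Exon\\s+(\\d+).*$", "\\1", p)))
  })
  table(unlist(idx))
}
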