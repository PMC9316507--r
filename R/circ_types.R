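#' Construct a back-splice junction record
#'
#' The back-splice junction (BSJ) joins the 3' end of the genomically
#' downstream (donor) exon to the 5' end of the upstream (acceptor)
#' exon. Either junction-facing end may be truncated; offsets are
#' expressed on the exon: `donor_end_offset` is the retained length of
#' the donor exon (in (0, donor length]) and `acceptor_start_offset` the
#' skipped prefix of the acceptor (in [0, acceptor length)).
#'
#' @param donor_exon_index,acceptor_exon_index 1-based exon indices.
#' @param donor_end_offset,acceptor_start_offset junction offsets (see
#'   above).
#' @param donor_exon_length,acceptor_exon_length full exon lengths, used
#'   to set the truncation flags.
#' @param ambiguity_k,ambiguity_string junction-overlap ambiguity (see
#'   [compute_overlap_ambiguity()]); filled by [annotate_bsj_flags()].
#' @param canonical `"canonical"`, `"non_canonical"` or `"unknown"`:
#'   whether the junction-facing genomic dinucleotides are GT (donor
#'   side) and AG (acceptor side).
#' @return object of class `backsplice_junction`.
#' @export
backsplice_junction <- function(donor_exon_index, donor_end_offset,
                                acceptor_exon_index, acceptor_start_offset,
                                donor_exon_length, acceptor_exon_length,
                                ambiguity_k = NA_integer_,
                                ambiguity_string = NA_character_,
                                canonical = "unknown") {
  if (donor_end_offset <= 0L || donor_end_offset > donor_exon_length) {
    stop("donor_end_offset out of (0, donor exon length]", call. = FALSE)
  }
  if (acceptor_start_offset < 0L ||
      acceptor_start_offset >= acceptor_exon_length) {
    stop("acceptor_start_offset out of [0, acceptor exon length)",
         call. = FALSE)
  }
  if (!is.na(ambiguity_k) && !is.na(ambiguity_string) &&
      nchar(ambiguity_string) != ambiguity_k) {
    stop("ambiguity_string length must equal ambiguity_k", call. = FALSE)
  }
  structure(list(donor_exon_index = as.integer(donor_exon_index),
                 donor_end_offset = as.integer(donor_end_offset),
                 acceptor_exon_index = as.integer(acceptor_exon_index),
                 acceptor_start_offset = as.integer(acceptor_start_offset),
                 donor_exon_length = as.integer(donor_exon_length),
                 acceptor_exon_length = as.integer(acceptor_exon_length),
                 donor_truncated = donor_end_offset < donor_exon_length,
                 acceptor_truncated = acceptor_start_offset > 0L,
                 ambiguity_k = as.integer(ambiguity_k),
                 ambiguity_string = ambiguity_string,
                 canonical = canonical),
            class = "backsplice_junction")
}

#' @export
print.backsplice_junction <- function(x, ...) {
  cat(sprintf("BSJ: exon %d (end offset %d%s) -> exon %d (start offset %d%s)\n",
              x$donor_exon_index, x$donor_end_offset,
              if (x$donor_truncated) ", truncated" else "",
              x$acceptor_exon_index, x$acceptor_start_offset,
              if (x$acceptor_truncated) ", truncated" else ""))
  cat(sprintf("  splice sites: %s; overlap ambiguity k=%s%s\n", x$canonical,
              x$ambiguity_k,
              if (!is.na(x$ambiguity_k) && x$ambiguity_k > 0L)
                paste0(" (", as_rna(x$ambiguity_string), ")") else ""))
  invisible(x)
}

#' Construct a circRNA record
#'
#' The circle is stored in canonical rotation: the sequence begins at the
#' acceptor's first retained base, so rotation-invariant identity reduces
#' to plain string equality. Segments are listed in circle order
#' (ascending exon index from the BSJ acceptor to the donor), each with
#' its retained exon interval (0-based half-open on the exon).
#'
#' @param id character id.
#' @param segments data.frame with columns `exon_index`, `seg_start`,
#'   `seg_end`.
#' @param sequence the realised circular sequence (canonical rotation).
#' @param bsj a [backsplice_junction()].
#' @param support character vector of supporting read ids.
#' @param sample optional free-text sample label(s).
#' @return object of class `circ_rna`.
#' @export
circ_rna <- function(id, segments, sequence, bsj, support = character(0),
                     sample = character(0)) {
  sequence <- as_dna(sequence)
  seg_lens <- segments$seg_end - segments$seg_start
  if (any(seg_lens <= 0L)) stop("empty circle segment", call. = FALSE)
  if (sum(seg_lens) != nchar(sequence)) {
    stop("circle length disagrees with segment lengths", call. = FALSE)
  }
  structure(list(id = id, segments = segments, sequence = sequence,
                 length = nchar(sequence), bsj = bsj,
                 support = support, sample = sample),
            class = "circ_rna")
}

#' @export
print.circ_rna <- function(x, ...) {
  cat(sprintf("circ_rna %s: %d nt, %d segment(s): %s\n", x$id, x$length,
              nrow(x$segments), exon_list_string(x)))
  print(x$bsj)
  invisible(x)
}

# Table-style exon list, truncation marked with an asterisk
exon_list_string <- function(circ) {
  segs <- circ$segments
  lab <- vapply(seq_len(nrow(segs)), function(j) {
    idx <- segs$exon_index[j]
    trunc <- (idx == circ$bsj$donor_exon_index && circ$bsj$donor_truncated) ||
      (idx == circ$bsj$acceptor_exon_index && circ$bsj$acceptor_truncated)
    paste0("Exon ", idx, if (trunc) " *" else "")
  }, character(1))
  paste(lab, collapse = ", ")
}
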