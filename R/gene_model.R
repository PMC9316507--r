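#' Construct and validate a gene model
#'
#' A gene model holds the ordered exons of a single gene in transcript
#' orientation: minus-strand input is reverse-complemented once at load
#' time so that all downstream logic is strand-free. Coordinates are
#' 0-based half-open on the transcript-oriented gene sequence; exon
#' indices are 1-based and consecutive.
#'
#' @param gene_id character scalar.
#' @param exons data.frame with columns `genomic_start`, `genomic_end`
#'   (0-based half-open) and optionally `sequence`, `index`. Rows are
#'   sorted by `genomic_start`; indices, when absent, are assigned
#'   1..n in that order.
#' @param gene_sequence optional full transcript-oriented genomic string
#'   (exons plus introns). When present, exon sequences are taken (or
#'   checked) against the corresponding slices and intronic flanking
#'   dinucleotides are recorded.
#' @return an object of class `gene_model` with elements `gene_id`,
#'   `exons` (data.frame: index, genomic_start, genomic_end, sequence,
#'   donor_flank, acceptor_flank) and `gene_sequence` (or NULL).
#' @export
gene_model <- function(gene_id, exons, gene_sequence = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            is.data.frame(exons), nrow(exons) >= 1L)
  exons <- exons[order(exons$genomic_start), , drop = FALSE]
  n <- nrow(exons)
  if (is.null(exons$index)) exons$index <- seq_len(n)
  if (!identical(as.integer(exons$index), seq_len(n))) {
    stop("exon indices must be 1..n, consecutive in genomic order",
         call. = FALSE)
  }
  if (any(exons$genomic_end <= exons$genomic_start)) {
    stop("empty or inverted exon interval", call. = FALSE)
  }
  if (n > 1L && any(exons$genomic_start[-1L] < exons$genomic_end[-n])) {
    stop("overlapping exons", call. = FALSE)
  }
  if (!is.null(gene_sequence)) {
    gene_sequence <- as_dna(gene_sequence)
    if (max(exons$genomic_end) > nchar(gene_sequence)) {
      stop("exon outside contig bounds", call. = FALSE)
    }
    slices <- substring(gene_sequence, exons$genomic_start + 1L,
                        exons$genomic_end)
    if (is.null(exons$sequence)) {
      exons$sequence <- slices
    } else if (!all(toupper(exons$sequence) == slices)) {
      stop("exon sequence does not match gene_sequence slice", call. = FALSE)
    }
  }
  if (is.null(exons$sequence)) {
    stop("exon sequences required (directly or via gene_sequence)",
         call. = FALSE)
  }
  exons$sequence <- vapply(exons$sequence, as_dna, character(1),
                           USE.NAMES = FALSE)
  if (!all(nchar(exons$sequence) ==
           exons$genomic_end - exons$genomic_start)) {
    stop("exon sequence length disagrees with interval length",
         call. = FALSE)
  }
  exons$donor_flank <- "unknown"
  exons$acceptor_flank <- "unknown"
  if (!is.null(gene_sequence)) {
    for (i in seq_len(n)) {
      # donor flank: 2 nt immediately 3' of the exon, inside the gene
      if (exons$genomic_end[i] + 2L <= nchar(gene_sequence) &&
          (i == n || exons$genomic_start[i + 1L] - exons$genomic_end[i] >= 2L)) {
        if (i < n) {
          exons$donor_flank[i] <- substring(gene_sequence,
                                            exons$genomic_end[i] + 1L,
                                            exons$genomic_end[i] + 2L)
        }
      }
      # acceptor flank: 2 nt immediately 5' of the exon
      if (i > 1L && exons$genomic_start[i] - exons$genomic_end[i - 1L] >= 2L) {
        exons$acceptor_flank[i] <- substring(gene_sequence,
                                             exons$genomic_start[i] - 1L,
                                             exons$genomic_start[i])
      }
    }
  }
  rownames(exons) <- NULL
  structure(list(gene_id = gene_id,
                 exons = exons[, c("index", "genomic_start", "genomic_end",
                                   "sequence", "donor_flank",
                                   "acceptor_flank")],
                 gene_sequence = gene_sequence),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", x$gene_id, "\n")
  cat("  exons:", nrow(x$exons), " total exonic nt:",
      sum(nchar(x$exons$sequence)), "\n")
  cat("  gene sequence:",
      if (is.null(x$gene_sequence)) "absent"
      else paste0(nchar(x$gene_sequence), " nt"), "\n")
  invisible(x)
}

n_exons <- function(model) nrow(model$exons)

exon_seq <- function(model, index) {
  if (!index %in% model$exons$index) stop("exon index out of range",
                                          call. = FALSE)
  model$exons$sequence[model$exons$index == index]
}

exon_len <- function(model, index) nchar(exon_seq(model, index))

#' Load a gene model from a BED interval table and a FASTA file
#'
#' The BED file (3+ columns, 0-based half-open) lists the exon intervals
#' of one gene on a single contig; the FASTA file supplies that contig's
#' sequence (exons plus introns, which is how intronic splice-site flanks
#' become available). When a 6th BED column carries strand `-`, the
#' contig is reverse-complemented and intervals are flipped once at load,
#' so the stored model is always transcript-oriented.
#'
#' @param bed_file path to BED file of exon intervals.
#' @param fasta_file path to FASTA with the contig sequence.
#' @return a validated [gene_model()].
#' @export
load_gene_model <- function(bed_file, fasta_file) {
  bed <- utils::read.table(bed_file, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED needs at least 3 columns", call. = FALSE)
  contigs <- unique(bed[[1L]])
  if (length(contigs) != 1L) {
    stop("all exon intervals must name a single contig", call. = FALSE)
  }
  fasta <- Biostrings::readDNAStringSet(fasta_file)
  fa_names <- sub("\\s.*$", "", names(fasta))
  if (!contigs %in% fa_names) {
    stop("contig '", contigs, "' not present in FASTA", call. = FALSE)
  }
  gene_seq <- as.character(fasta[[match(contigs, fa_names)]])
  strand <- if (ncol(bed) >= 6L) bed[[6L]][1L] else "+"
  starts <- as.integer(bed[[2L]])
  ends <- as.integer(bed[[3L]])
  if (strand == "-") {
    gene_seq <- revcomp(gene_seq)
    L <- nchar(gene_seq)
    new_starts <- L - ends
    ends <- L - starts
    starts <- new_starts
  }
  gene_model(gene_id = contigs,
             exons = data.frame(genomic_start = starts, genomic_end = ends),
             gene_sequence = gene_seq)
}

#' Serialise a gene model to a single JSON document
#'
#' @param model a [gene_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  jsonlite::write_json(
    list(gene_id = model$gene_id,
         exons = model$exons,
         gene_sequence = model$gene_sequence),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a gene model from its JSON serialisation
#'
#' @param path path written by [write_gene_model()].
#' @return a validated [gene_model()].
#' @export
read_gene_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  gene_model(gene_id = doc$gene_id,
             exons = as.data.frame(doc$exons),
             gene_sequence = doc$gene_sequence)
}

#' Intronic flanking dinucleotides of one exon
#'
#' Returns the two intronic bases immediately 3' of the exon (the donor
#' side, canonically `GT`) and immediately 5' of it (the acceptor side,
#' canonically `AG`). `"unknown"` is returned for terminal exons or when
#' the model carries exon sequences only.
#'
#' @param model a [gene_model()].
#' @param index 1-based exon index.
#' @return named character vector `c(donor_flank=, acceptor_flank=)`.
#' @export
exon_flanks <- function(model, index) {
  row <- model$exons[model$exons$index == index, , drop = FALSE]
  if (nrow(row) != 1L) stop("exon index out of range", call. = FALSE)
  c(donor_flank = row$donor_flank, acceptor_flank = row$acceptor_flank)
}
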