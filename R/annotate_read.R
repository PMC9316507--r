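# Detect the rolling-circle period of a read by self-overlap: the
# smallest shift p at which the read matches itself (mismatch fraction
# <= max_mm) with at least min_overlap nt of evidence. Candidate shifts
# come from re-occurrences of short anchors, so the scan is linear.
detect_period <- function(read, min_overlap = 25L, max_mm = 0.05,
                          anchor_len = 20L) {
  n <- nchar(read)
  if (n < anchor_len + min_overlap) return(NA_integer_)
  chars <- strsplit(read, "", fixed = TRUE)[[1L]]
  candidates <- integer(0)
  for (off in c(0L, 37L, 74L, 111L)) {
    if (off + anchor_len > n) next
    anchor <- substr(read, off + 1L, off + anchor_len)
    hits <- gregexpr(anchor, read, fixed = TRUE)[[1L]]
    hits <- hits[hits > 0L]
    candidates <- c(candidates, (hits - 1L) - off)
  }
  candidates <- sort(unique(candidates[candidates >= anchor_len]))
  for (p in candidates) {
    ov <- n - p
    if (ov < min_overlap) next
    mm <- sum(chars[seq_len(ov)] != chars[p + seq_len(ov)])
    if (mm / ov <= max_mm) return(p)
  }
  NA_integer_
}

# collapse a read longer than one circle circumference to a single period
collapse_rolling_read <- function(read, min_overlap = 25L) {
  p <- detect_period(read, min_overlap = min_overlap)
  if (is.na(p) || p >= nchar(read)) {
    list(seq = read, period = NA_integer_, collapsed = FALSE)
  } else {
    list(seq = substr(read, 1L, p), period = p, collapsed = TRUE)
  }
}

best_chain_for_read <- function(seq, model, params, index) {
  matches <- find_exon_matches(seq, model, params, index)
  best <- NULL
  best_strand <- NA_character_
  best_cover <- -1
  for (strand in unique(matches$strand)) {
    ch <- chain_segments(matches[matches$strand == strand, , drop = FALSE],
                         nchar(seq), params)
    if (is.null(ch)) next
    attr(ch, "read") <- if (strand == "+") seq else revcomp(seq)
    cov <- attr(ch, "cover")
    if (cov > best_cover) {
      best <- ch
      best_strand <- strand
      best_cover <- cov
    }
  }
  list(chain = best, strand = best_strand, cover = best_cover)
}

# is the junction evidence of a chain weak near the read ends?
junction_flanks_ok <- function(chain, params) {
  d <- attr(chain, "descent")
  if (is.na(d)) return(FALSE)
  don_len <- chain$read_end[d] - chain$read_start[d]
  acc_len <- chain$read_end[d + 1L] - chain$read_start[d + 1L]
  don_len >= params$min_flank && acc_len >= params$min_flank
}

#' Annotate one read against a gene model
#'
#' Runs the full per-read procedure: reads longer than one circle
#' circumference are first collapsed to a single period (rolling-circle
#' reverse transcription can traverse the circle repeatedly), exon
#' matches are found on both orientations, the best near-adjacent chain
#' with at most one backward step is selected, and the back-splice
#' junction is called. When a collapsed read yields no junction or only
#' junction evidence at the read ends, the period is rotated by half a
#' turn and annotation is retried — the junction of a circular read is
#' rotation-invariant.
#'
#' @param read nucleotide string.
#' @param model a [gene_model()].
#' @param params an [annot_params()].
#' @param index optional precomputed exon k-mer index.
#' @param read_id identifier carried into the result.
#' @return object of class `annotation_result`: `read_id`, `strand`,
#'   `chain`, `coverage`, `bsj` (or NULL), `period`, `collapsed`,
#'   `reason` (NA or why annotation failed).
#' @export
annotate_read <- function(read, model, params = annot_params(),
                          index = NULL, read_id = "read") {
  read <- as_dna(read)
  if (is.null(index)) index <- build_exon_index(model, params$min_anchor)
  col <- collapse_rolling_read(read)
  attempt <- function(seq) {
    bc <- best_chain_for_read(seq, model, params, index)
    bc$seq <- seq
    bc
  }
  bc <- attempt(col$seq)
  if (col$collapsed &&
      (is.null(bc$chain) || !junction_flanks_ok(bc$chain, params))) {
    # a collapsed read is a full rotation of the circle, so the junction
    # call is rotation-invariant; retry dyadically spaced rotations
    # (1/2, 1/4, 3/4, 1/8, ...) until every circle junction sits at
    # least one anchor away from the read ends — the coarse-to-fine
    # order finds the usual case in one or two tries while the densest
    # spacing (p/32) still hits the smallest viable window
    p <- nchar(col$seq)
    fracs <- unlist(lapply(c(2L, 4L, 8L, 16L, 32L), function(d) {
      seq(1L, d - 1L, by = 2L) / d
    }))
    for (r in unique(floor(p * fracs))) {
      if (r == 0L) next
      bc2 <- attempt(rotate_str(col$seq, r))
      if (!is.null(bc2$chain) && junction_flanks_ok(bc2$chain, params)) {
        bc <- bc2
        break
      }
      if (is.null(bc$chain) && !is.null(bc2$chain)) bc <- bc2
    }
  }
  res <- list(read_id = read_id, strand = bc$strand, chain = bc$chain,
              coverage = if (is.null(bc$chain)) 0
                         else bc$cover / nchar(bc$seq),
              bsj = NULL, period = col$period, collapsed = col$collapsed,
              reason = NA_character_)
  class(res) <- "annotation_result"
  if (is.null(bc$chain)) {
    res$reason <- "unannotatable"
    return(res)
  }
  bsj <- tryCatch(call_bsj(bc$chain, model), error = function(e) {
    res$reason <<- conditionMessage(e)
    NULL
  })
  res$bsj <- bsj
  if (is.null(bsj) && is.na(res$reason)) res$reason <- "no junction evidence"
  res
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("annotation_result:", x$read_id, "\n")
  if (is.null(x$chain)) {
    cat("  unannotatable (", x$reason, ")\n", sep = "")
  } else {
    cat("  strand", x$strand, " segments:",
        paste(x$chain$exon_index, collapse = ","),
        sprintf(" coverage %.2f\n", x$coverage))
    if (!is.null(x$bsj)) print(x$bsj) else cat("  no BSJ (", x$reason, ")\n")
  }
  invisible(x)
}

#' Confirm a read's circRNA and reconstruct its reference sequence
#'
#' A circRNA call is confirmed only when the read chain covers the
#' back-splice junction with at least `min_flank` aligned nt on each
#' side; reads without junction evidence are rejected, mirroring the
#' confirmation rule of amplicon-sequencing circRNA discovery. On
#' confirmation the canonical circle (rotation starting at the
#' acceptor's first retained base) is reconstructed from the gene model,
#' not from the read, so sequencing errors do not leak into the
#' reference circle.
#'
#' @param result an [annotate_read()] result.
#' @param model a [gene_model()].
#' @param params an [annot_params()].
#' @param sample optional free-text sample label attached to the circle.
#' @return a `circ_rna` on confirmation, otherwise a list of class
#'   `circ_rejection` with elements `read_id` and `reason`.
#' @export
confirm_and_reconstruct <- function(result, model, params = annot_params(),
                                    sample = character(0)) {
  reject <- function(reason) {
    structure(list(read_id = result$read_id, reason = reason),
              class = "circ_rejection")
  }
  if (is.null(result$chain)) return(reject(result$reason))
  if (is.null(result$bsj)) {
    return(reject(if (!is.na(result$reason)) result$reason
                  else "no junction evidence"))
  }
  if (!junction_flanks_ok(result$chain, params)) {
    return(reject("insufficient junction flank"))
  }
  bsj <- result$bsj
  chain <- result$chain
  d <- attr(chain, "descent")
  circle_rows <- rbind(chain[(d + 1L):nrow(chain), , drop = FALSE],
                       chain[seq_len(d), , drop = FALSE])
  ex <- unique(circle_rows$exon_index)
  if (bsj$donor_exon_index == bsj$acceptor_exon_index) {
    segments <- data.frame(exon_index = bsj$acceptor_exon_index,
                           seg_start = bsj$acceptor_start_offset,
                           seg_end = bsj$donor_end_offset)
  } else {
    if (is.unsorted(ex, strictly = TRUE)) {
      return(reject("segment order inconsistent with one junction"))
    }
    segments <- data.frame(
      exon_index = ex,
      seg_start = ifelse(ex == bsj$acceptor_exon_index,
                         bsj$acceptor_start_offset, 0L),
      seg_end = vapply(ex, function(i) {
        if (i == bsj$donor_exon_index) bsj$donor_end_offset
        else exon_len(model, i)
      }, integer(1)))
  }
  seq <- paste(vapply(seq_len(nrow(segments)), function(j) {
    substr(exon_seq(model, segments$exon_index[j]),
           segments$seg_start[j] + 1L, segments$seg_end[j])
  }, character(1)), collapse = "")
  circ_rna(id = result$read_id, segments = segments, sequence = seq,
           bsj = bsj, support = result$read_id, sample = sample)
}

#' Merge identical circles and build a catalog
#'
#' Circles identical under rotation-invariant sequence equality are
#' merged (the canonical rotation makes this a string comparison; a
#' minimal-rotation key guards against residual rotation differences).
#' The catalog mirrors the usual presentation of full-length circRNA
#' inventories: id, sample(s), exon count, exon list with truncation
#' asterisks, and length.
#'
#' @param circs list of `circ_rna` objects (rejections are skipped).
#' @param id_prefix prefix for catalog ids.
#' @return list with `catalog` (data.frame: circ_id, sample, exon_count,
#'   exons, length, n_reads, sequence) and `circs` (merged `circ_rna`
#'   list, one per catalog row).
#' @export
dedupe_and_catalog <- function(circs, id_prefix = "circ") {
  circs <- Filter(function(x) inherits(x, "circ_rna"), circs)
  keys <- vapply(circs, function(x) min_rotation(x$sequence), character(1))
  merged <- list()
  order_seen <- character(0)
  for (i in seq_along(circs)) {
    k <- keys[i]
    if (is.null(merged[[k]])) {
      merged[[k]] <- circs[[i]]
      order_seen <- c(order_seen, k)
    } else {
      merged[[k]]$support <- c(merged[[k]]$support, circs[[i]]$support)
      merged[[k]]$sample <- unique(c(merged[[k]]$sample, circs[[i]]$sample))
    }
  }
  merged <- merged[order_seen]
  rows <- lapply(seq_along(merged), function(i) {
    x <- merged[[i]]
    data.frame(circ_id = paste0(id_prefix, "_", i),
               sample = paste(sort(unique(x$sample)), collapse = "; "),
               exon_count = nrow(x$segments),
               exons = exon_list_string(x),
               length = x$length,
               n_reads = length(x$support),
               sequence = x$sequence)
  })
  catalog <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(circ_id = character(0), sample = character(0),
               exon_count = integer(0), exons = character(0),
               length = integer(0), n_reads = integer(0),
               sequence = character(0))
  for (i in seq_along(merged)) merged[[i]]$id <- catalog$circ_id[i]
  list(catalog = catalog, circs = unname(merged))
}

#' Write a circRNA catalog as TSV
#'
#' @param catalog catalog data.frame from [dedupe_and_catalog()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a circRNA catalog TSV
#'
#' @param path path written by [write_catalog()].
#' @return catalog data.frame.
#' @export
read_catalog <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = character(0))
  for (col in intersect(c("circ_id", "sample", "exons", "sequence"),
                        names(out))) {
    out[[col]] <- as.character(out[[col]])
  }
  out
}
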