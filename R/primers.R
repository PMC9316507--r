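# nearest-neighbour thermodynamic parameters (unified set): dH kcal/mol,
# dS cal/(mol K), for 5'->3' dinucleotide steps on the top strand
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_GC <- c(dh = 0.1, ds = -2.8)
NN_INIT_AT <- c(dh = 2.3, ds = 4.1)

#' Melting temperature and GC content of a primer
#'
#' Nearest-neighbour Tm with the unified dinucleotide parameter set and
#' the entropy salt correction 0.368 (N-1) ln\[Na+\]. Default conditions:
#' 50 mM monovalent cation, 400 nM primer (the primer strand in excess,
#' so the effective duplex concentration is the primer concentration).
#' A Wallace-rule estimate (2 degrees per A/T, 4 per G/C) is available
#' via `method = "wallace"` for quick checks on short oligos.
#'
#' @param primer DNA string, length >= 8.
#' @param na_mM monovalent cation concentration, mM.
#' @param primer_nM primer concentration, nM.
#' @param method `"nn"` (default) or `"wallace"`.
#' @return list `tm` (degrees C) and `gc` (fraction).
#' @export
tm_and_gc <- function(primer, na_mM = 50, primer_nM = 400, method = "nn") {
  primer <- as_dna(primer)
  n <- nchar(primer)
  if (n < 8L) stop("primer must be at least 8 nt", call. = FALSE)
  gc <- gc_fraction(primer)
  if (method == "wallace") {
    chars <- strsplit(primer, "", fixed = TRUE)[[1L]]
    tm <- 2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C"))
    return(list(tm = tm, gc = gc))
  }
  steps <- substring(primer, 1:(n - 1L), 2:n)
  dh <- sum(NN_DH[steps])
  ds <- sum(NN_DS[steps])
  for (endbase in c(substr(primer, 1L, 1L), substr(primer, n, n))) {
    init <- if (endbase %in% c("G", "C")) NN_INIT_GC else NN_INIT_AT
    dh <- dh + init[["dh"]]
    ds <- ds + init[["ds"]]
  }
  ds_salt <- ds + 0.368 * (n - 1L) * log(na_mM / 1000)
  R <- 1.987
  tm <- 1000 * dh / (ds_salt + R * log(primer_nM * 1e-9)) - 273.15
  list(tm = tm, gc = gc)
}

#' Primer design constraints
#'
#' @param length_range primer length bounds, nt.
#' @param gc_range GC-fraction bounds.
#' @param tm_range melting-temperature bounds, degrees C.
#' @return list of class `primer_constraints`.
#' @export
primer_constraints <- function(length_range = c(18L, 25L),
                               gc_range = c(0.40, 0.60),
                               tm_range = c(57, 63)) {
  structure(list(length_range = as.integer(length_range),
                 gc_range = gc_range, tm_range = tm_range),
            class = "primer_constraints")
}

# count perfect occurrences of a primer (either strand) in a sequence
count_matches <- function(primer, seq) {
  hits <- function(p) {
    g <- gregexpr(p, seq, fixed = TRUE)[[1L]]
    sum(g > 0L)
  }
  hits(primer) + hits(revcomp(primer))
}

# enumerate candidate primer sites on one exon: start in [lo, hi) (0-based),
# all lengths in range, meeting GC/Tm, unique in the gene
candidate_sites <- function(exseq, lo, hi, constraints, gene_seq,
                            sense = c("forward", "reverse")) {
  sense <- match.arg(sense)
  out <- list()
  for (len in seq(constraints$length_range[1L], constraints$length_range[2L])) {
    if (hi - len < lo) next
    starts <- seq.int(lo, hi - len)
    for (s in starts) {
      site <- substr(exseq, s + 1L, s + len)
      primer <- if (sense == "forward") site else revcomp(site)
      tg <- tm_and_gc(primer)
      if (tg$gc < constraints$gc_range[1L] ||
          tg$gc > constraints$gc_range[2L]) next
      if (tg$tm < constraints$tm_range[1L] ||
          tg$tm > constraints$tm_range[2L]) next
      if (!is.null(gene_seq) && count_matches(primer, gene_seq) != 1L) next
      out[[length(out) + 1L]] <-
        data.frame(start = s, end = s + len, primer = primer, tm = tg$tm,
                   gc = tg$gc)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

new_primer_pair <- function(exon_index, fwd, rev, round) {
  structure(list(forward = fwd$primer, reverse = rev$primer,
                 target_exon_index = as.integer(exon_index),
                 fwd_start = fwd$start, fwd_end = fwd$end,
                 rev_start = rev$start, rev_end = rev$end,
                 orientation = "outward",
                 tm_forward = fwd$tm, tm_reverse = rev$tm,
                 gc_forward = fwd$gc, gc_reverse = rev$gc,
                 round = round),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("divergent primer pair (round: %s) on exon %d\n", x$round,
              x$target_exon_index))
  cat(sprintf("  forward %s  [%d,%d) Tm %.1f GC %.2f\n", x$forward,
              x$fwd_start, x$fwd_end, x$tm_forward, x$gc_forward))
  cat(sprintf("  reverse %s  [%d,%d) Tm %.1f GC %.2f\n", x$reverse,
              x$rev_start, x$rev_end, x$tm_reverse, x$gc_reverse))
  invisible(x)
}

#' Design an outward-facing (divergent) primer pair on one exon
#'
#' Divergent primers face away from each other on the linear gene — the
#' forward primer points toward the exon 3' end, the reverse toward the
#' 5' end — so they can only converge, and amplify, on a circular
#' template that joins the exon's 3' side back to its 5' side. The pair
#' is placed near the exon middle (reverse site wholly before the
#' forward site) to leave room for an inner second-round pair, and is
#' chosen to maximise Tm balance among candidates that meet the length,
#' GC and Tm constraints and have a unique perfect match in the gene.
#'
#' @param model a [gene_model()].
#' @param exon_index 1-based target exon.
#' @param constraints a [primer_constraints()].
#' @return a `primer_pair` (round `"first"`).
#' @export
design_divergent_pair <- function(model, exon_index,
                                  constraints = primer_constraints()) {
  exseq <- exon_seq(model, exon_index)
  m <- nchar(exseq)
  min_len <- constraints$length_range[1L]
  if (m < 2L * min_len) {
    stop("exon too short to host a non-overlapping divergent pair (",
         m, " nt < 2 x ", min_len, " nt)", call. = FALSE)
  }
  mid <- m %/% 2L
  gene_seq <- model$gene_sequence
  rev_cand <- candidate_sites(exseq, 0L, mid, constraints, gene_seq,
                              "reverse")
  fwd_cand <- candidate_sites(exseq, mid, m, constraints, gene_seq,
                              "forward")
  if (is.null(rev_cand) || is.null(fwd_cand)) {
    side <- if (is.null(rev_cand)) "reverse" else "forward"
    stop("no ", side, " primer on exon ", exon_index,
         " satisfies length ", constraints$length_range[1L], "-",
         constraints$length_range[2L], ", GC ",
         constraints$gc_range[1L], "-", constraints$gc_range[2L],
         ", Tm ", constraints$tm_range[1L], "-",
         constraints$tm_range[2L], " with a unique gene match",
         call. = FALSE)
  }
  # best Tm balance; prefer sites near the exon middle on ties
  best <- NULL
  best_key <- c(Inf, Inf)
  for (i in seq_len(nrow(fwd_cand))) {
    dtm <- abs(fwd_cand$tm[i] - rev_cand$tm)
    j <- which.min(dtm + 1e-6 * (mid - rev_cand$end))
    key <- c(dtm[j], (fwd_cand$start[i] - mid) + (mid - rev_cand$end[j]))
    if (key[1L] < best_key[1L] ||
        (key[1L] == best_key[1L] && key[2L] < best_key[2L])) {
      best <- list(fwd = fwd_cand[i, ], rev = rev_cand[j, ])
      best_key <- key
    }
  }
  new_primer_pair(exon_index, best$fwd, best$rev, "first")
}

#' Design the inner, second-round divergent pair
#'
#' Nested: both primers lie strictly inside the first-round product —
#' on the exon that means the new forward site starts strictly 3' of the
#' first forward start, and the new reverse site ends strictly 5' of the
#' first reverse end. Semi-nested: exactly one first-round primer is
#' reused. Divergent orientation is preserved in both modes.
#'
#' @param first first-round `primer_pair`.
#' @param model a [gene_model()].
#' @param mode `"nested"` or `"semi_nested"`.
#' @param constraints a [primer_constraints()].
#' @return a `primer_pair` with `round` set to the mode.
#' @export
design_second_round <- function(first, model,
                                mode = c("nested", "semi_nested"),
                                constraints = primer_constraints()) {
  mode <- match.arg(mode)
  exon_index <- first$target_exon_index
  exseq <- exon_seq(model, exon_index)
  m <- nchar(exseq)
  gene_seq <- model$gene_sequence
  inner_fwd <- function() {
    cand <- candidate_sites(exseq, first$fwd_start + 1L, m, constraints,
                            gene_seq, "forward")
    if (!is.null(cand)) cand <- cand[cand$start > first$fwd_start, ]
    if (is.null(cand) || nrow(cand) == 0L) {
      stop("interior too short for an inner forward primer", call. = FALSE)
    }
    cand
  }
  inner_rev <- function() {
    cand <- candidate_sites(exseq, 0L, first$rev_end - 1L, constraints,
                            gene_seq, "reverse")
    if (!is.null(cand)) cand <- cand[cand$end < first$rev_end, ]
    if (is.null(cand) || nrow(cand) == 0L) {
      stop("interior too short for an inner reverse primer", call. = FALSE)
    }
    cand
  }
  pick_balanced <- function(cand, target_tm) {
    cand[which.min(abs(cand$tm - target_tm)), ]
  }
  if (mode == "nested") {
    fc <- inner_fwd()
    rc <- inner_rev()
    best <- NULL
    best_d <- Inf
    for (i in seq_len(nrow(fc))) {
      j <- which.min(abs(fc$tm[i] - rc$tm))
      d <- abs(fc$tm[i] - rc$tm[j])
      if (d < best_d) {
        best <- list(fwd = fc[i, ], rev = rc[j, ])
        best_d <- d
      }
    }
    new_primer_pair(exon_index, best$fwd, best$rev, "nested")
  } else {
    # reuse the forward primer, redesign the reverse (fall back to the
    # opposite choice when the reverse interior has no room)
    fwd_keep <- data.frame(start = first$fwd_start, end = first$fwd_end,
                           primer = first$forward, tm = first$tm_forward,
                           gc = first$gc_forward)
    res <- tryCatch({
      rc <- inner_rev()
      new_primer_pair(exon_index, fwd_keep,
                      pick_balanced(rc, first$tm_forward), "semi_nested")
    }, error = function(e) NULL)
    if (!is.null(res)) return(res)
    rev_keep <- data.frame(start = first$rev_start, end = first$rev_end,
                           primer = first$reverse, tm = first$tm_reverse,
                           gc = first$gc_reverse)
    fc <- inner_fwd()
    new_primer_pair(exon_index, pick_balanced(fc, first$tm_reverse),
                    rev_keep, "semi_nested")
  }
}

#' In-silico PCR of a primer pair on a circular or linear template
#'
#' Perfect-match binding only: the forward primer must occur verbatim,
#' the reverse as its reverse complement downstream. On a circle the
#' doubled sequence is scanned and the shortest single-period product is
#' reported; outward primers on a linear template cannot converge, so
#' linear templates yield no product for a divergent pair.
#'
#' @param x a `circ_rna`, or a character template sequence.
#' @param pair a `primer_pair`.
#' @param circular logical; defaults to TRUE for `circ_rna` input.
#' @return list of class `amplicon_prediction` (`circ_id`,
#'   `product_sequence`, `product_length`, `spans_bsj`), or `NULL` when
#'   no product forms.
#' @export
predict_amplicon <- function(x, pair, circular = inherits(x, "circ_rna")) {
  seq <- if (inherits(x, "circ_rna")) x$sequence else as_dna(x)
  id <- if (inherits(x, "circ_rna")) x$id else NA_character_
  L <- nchar(seq)
  template <- if (circular) paste0(seq, seq) else seq
  starts0 <- function(p) {
    g <- gregexpr(p, template, fixed = TRUE)[[1L]]
    g <- g[g > 0L]
    g - 1L
  }
  fhits <- starts0(pair$forward)
  rhits <- starts0(revcomp(pair$reverse))
  if (circular) fhits <- fhits[fhits < L]
  if (length(fhits) == 0L || length(rhits) == 0L) return(NULL)
  best <- NULL
  for (f in fhits) {
    rends <- rhits + nchar(pair$reverse)
    rends <- rends[rhits >= f + nchar(pair$forward)]
    if (circular) rends <- rends[rends - f <= L]
    if (length(rends) == 0L) next
    plen <- min(rends) - f
    if (is.null(best) || plen < best$product_length) {
      best <- list(circ_id = id,
                   product_sequence = substr(template, f + 1L, f + plen),
                   product_length = plen,
                   spans_bsj = circular && (f + plen > L))
    }
  }
  if (is.null(best)) return(NULL)
  structure(best, class = "amplicon_prediction")
}

#' Write a primer table as TSV
#'
#' @param pairs list of `primer_pair` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_primer_table <- function(pairs, path) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    data.frame(name = paste0("pair", i, "_", p$round),
               round = p$round, exon = p$target_exon_index,
               forward = p$forward, fwd_start = p$fwd_start,
               fwd_end = p$fwd_end, tm_forward = round(p$tm_forward, 2),
               gc_forward = round(p$gc_forward, 3),
               reverse = p$reverse, rev_start = p$rev_start,
               rev_end = p$rev_end, tm_reverse = round(p$tm_reverse, 2),
               gc_reverse = round(p$gc_reverse, 3))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
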