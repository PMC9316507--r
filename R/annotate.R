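#' Annotation parameters
#'
#' @param min_anchor exact seed length for exon matching, nt.
#' @param max_mismatch_rate maximum mismatch fraction within one exon
#'   match.
#' @param gap_tol maximum unaligned read gap between chained segments, nt.
#' @param overlap_tol maximum read overlap between chained segments, nt
#'   (junction-overlap ambiguity makes the donor and acceptor matches
#'   claim the same few read bases).
#' @param min_cover_frac minimum fraction of the read a chain must cover.
#' @param min_flank minimum aligned nt required on each side of the BSJ
#'   for confirmation.
#' @return a list of class `annot_params`.
#' @export
annot_params <- function(min_anchor = 18L, max_mismatch_rate = 0.02,
                         gap_tol = 12L, overlap_tol = 12L,
                         min_cover_frac = 0.9, min_flank = 10L) {
  structure(list(min_anchor = as.integer(min_anchor),
                 max_mismatch_rate = max_mismatch_rate,
                 gap_tol = as.integer(gap_tol),
                 overlap_tol = as.integer(overlap_tol),
                 min_cover_frac = min_cover_frac,
                 min_flank = as.integer(min_flank)),
            class = "annot_params")
}

# k-mer index of the model's exon sequences: per exon, a named list
# mapping each k-mer to its 0-based start positions
build_exon_index <- function(model, k) {
  idx <- lapply(seq_len(n_exons(model)), function(i) {
    s <- model$exons$sequence[i]
    m <- nchar(s)
    if (m < k) return(list())
    kmers <- substring(s, 1:(m - k + 1L), k:m)
    split(0:(m - k), kmers)
  })
  names(idx) <- as.character(model$exons$index)
  idx
}

# maximal diagonal matches between a read and one exon along diagonal
# d = read0 - exon0 (0-based). Substitution-only model: matches are
# gap-free. Exact runs >= min_anchor seed a match; neighbouring runs are
# absorbed across single-base mismatches while the overall mismatch
# fraction stays within budget.
diagonal_matches <- function(read_chars, exon_chars, d, min_anchor,
                             max_mm_rate, min_absorb_run = 4L) {
  n <- length(read_chars)
  m <- length(exon_chars)
  r0 <- max(0L, d)
  r1 <- min(n, m + d)  # exclusive
  if (r1 - r0 < min_anchor) return(NULL)
  ri <- (r0 + 1L):r1
  v <- read_chars[ri] == exon_chars[ri - d]
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  true_runs <- which(runs$values)
  seed_runs <- true_runs[runs$lengths[true_runs] >= min_anchor]
  if (length(seed_runs) == 0L) return(NULL)
  out <- list()
  used <- logical(length(runs$lengths))
  for (s in seed_runs[order(-runs$lengths[seed_runs])]) {
    if (used[s]) next
    lo <- s
    hi <- s
    mlen <- runs$lengths[s]
    mm <- 0L
    repeat {
      extended <- FALSE
      # absorb the next TRUE run to the right across a 1-mismatch gap;
      # requiring a decent exact run beyond the mismatch stops the
      # extension from drifting across a junction on chance matches
      if (hi + 2L <= length(runs$lengths) && runs$lengths[hi + 1L] == 1L &&
          !used[hi + 2L] && runs$lengths[hi + 2L] >= min_absorb_run &&
          (mm + 1L) / (mlen + 1L + runs$lengths[hi + 2L]) <= max_mm_rate) {
        mm <- mm + 1L
        mlen <- mlen + 1L + runs$lengths[hi + 2L]
        hi <- hi + 2L
        extended <- TRUE
      }
      if (lo - 2L >= 1L && runs$lengths[lo - 1L] == 1L && !used[lo - 2L] &&
          runs$lengths[lo - 2L] >= min_absorb_run &&
          (mm + 1L) / (mlen + 1L + runs$lengths[lo - 2L]) <= max_mm_rate) {
        mm <- mm + 1L
        mlen <- mlen + 1L + runs$lengths[lo - 2L]
        lo <- lo - 2L
        extended <- TRUE
      }
      if (!extended) break
    }
    used[lo:hi] <- TRUE
    # window trimmed to matching ends by construction (lo/hi are TRUE runs)
    w0 <- r0 + starts[lo] - 1L          # 0-based read start
    w1 <- r0 + ends[hi]                 # exclusive read end
    out[[length(out) + 1L]] <-
      data.frame(read_start = w0, read_end = w1,
                 exon_start = w0 - d, exon_end = w1 - d, mismatches = mm)
  }
  do.call(rbind, out)
}

#' Find exon matches for a read against a gene model
#'
#' Seed-and-extend matching of read substrings to exon substrings:
#' exact k-mer seeds of `min_anchor` nt locate candidate diagonals, which
#' are extended gap-free allowing mismatches up to `max_mismatch_rate`.
#' Both the given orientation and the reverse complement are scanned and
#' flagged; minus-strand matches carry read coordinates on the
#' reverse-complemented read.
#'
#' @param read nucleotide string.
#' @param model a [gene_model()].
#' @param params an [annot_params()].
#' @param index optional precomputed k-mer index (see internals); built
#'   on the fly when absent.
#' @return data.frame of segment matches: `exon_index`, `read_start`,
#'   `read_end`, `exon_start`, `exon_end` (0-based half-open),
#'   `mismatches`, `strand`.
#' @export
find_exon_matches <- function(read, model, params = annot_params(),
                              index = NULL) {
  if (n_exons(model) == 0L) stop("empty gene model", call. = FALSE)
  read <- as_dna(read)
  if (nchar(read) < params$min_anchor) {
    stop("read shorter than min_anchor", call. = FALSE)
  }
  if (is.null(index)) index <- build_exon_index(model, params$min_anchor)
  out <- list()
  for (strand in c("+", "-")) {
    r <- if (strand == "+") read else revcomp(read)
    n <- nchar(r)
    read_chars <- strsplit(r, "", fixed = TRUE)[[1L]]
    k <- params$min_anchor
    read_kmers <- substring(r, 1:(n - k + 1L), k:n)
    for (e in seq_len(n_exons(model))) {
      ex_idx <- model$exons$index[e]
      exidx_kmers <- index[[as.character(ex_idx)]]
      if (length(exidx_kmers) == 0L) next
      hit_i <- which(read_kmers %in% names(exidx_kmers))
      if (length(hit_i) == 0L) next
      diags <- unique(unlist(lapply(hit_i, function(i) {
        (i - 1L) - exidx_kmers[[read_kmers[i]]]
      })))
      exon_chars <- strsplit(model$exons$sequence[e], "", fixed = TRUE)[[1L]]
      for (d in diags) {
        dm <- diagonal_matches(read_chars, exon_chars, d, k,
                               params$max_mismatch_rate)
        if (!is.null(dm) && nrow(dm) > 0L) {
          dm$exon_index <- ex_idx
          dm$strand <- strand
          out[[length(out) + 1L]] <- dm
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(exon_index = integer(0), read_start = integer(0),
                      read_end = integer(0), exon_start = integer(0),
                      exon_end = integer(0), mismatches = integer(0),
                      strand = character(0)))
  }
  res <- do.call(rbind, out)
  res <- unique(res[, c("exon_index", "read_start", "read_end",
                        "exon_start", "exon_end", "mismatches", "strand")])
  rownames(res) <- NULL
  res[order(res$strand, res$read_start, res$exon_index), ]
}

# is the step from chain row a to row b a backward (BSJ-candidate) step?
is_backward_step <- function(a, b) {
  b$exon_index < a$exon_index ||
    (b$exon_index == a$exon_index && b$exon_start < a$exon_start)
}

#' Select the best segment chain for one read
#'
#' Dynamic programme over the matches of a single orientation: picks the
#' chain maximising covered read bases such that consecutive segments
#' are near-adjacent on the read (gap at most `gap_tol`, overlap at most
#' `overlap_tol`) and exon indices are non-decreasing except for at most
#' one backward step — the back-splice junction candidate. Ties are
#' broken by fewer mismatches, then fewer segments.
#'
#' @param matches data.frame from [find_exon_matches()] (one strand).
#' @param read_length read length, nt.
#' @param params an [annot_params()].
#' @return the chain as a data.frame of matches in read order with
#'   attribute `descent` (row index after which the backward step
#'   occurs, or NA), or `NULL` when no chain covers
#'   `min_cover_frac * read_length`.
#' @export
chain_segments <- function(matches, read_length, params = annot_params()) {
  if (nrow(matches) == 0L) return(NULL)
  if (length(unique(matches$strand)) > 1L) {
    stop("chain_segments expects matches of a single orientation",
         call. = FALSE)
  }
  m <- matches[order(matches$read_start, matches$read_end), ]
  rownames(m) <- NULL
  nm <- nrow(m)
  # dp over (row, descent used): best covered bases ending at row
  INF <- -1e18
  cover <- matrix(INF, nm, 2L)
  mmcnt <- matrix(0L, nm, 2L)
  nseg <- matrix(0L, nm, 2L)
  prev <- array(NA_integer_, c(nm, 2L, 2L))  # row, prev descent state
  seglen <- m$read_end - m$read_start
  for (i in seq_len(nm)) {
    cover[i, 1L] <- seglen[i]
    mmcnt[i, 1L] <- m$mismatches[i]
    nseg[i, 1L] <- 1L
    for (j in seq_len(i - 1L)) {
      gap <- m$read_start[i] - m$read_end[j]
      if (gap > params$gap_tol || gap < -params$overlap_tol) next
      add <- seglen[i] - max(0L, -gap)  # overlap bases counted once
      back <- is_backward_step(m[j, ], m[i, ])
      for (s_prev in 1:2) {
        if (cover[j, s_prev] <= INF / 2) next
        s_new <- if (back) s_prev + 1L else s_prev
        if (s_new > 2L) next
        cand_cover <- cover[j, s_prev] + add
        cand_mm <- mmcnt[j, s_prev] + m$mismatches[i]
        cand_ns <- nseg[j, s_prev] + 1L
        better <- cand_cover > cover[i, s_new] ||
          (cand_cover == cover[i, s_new] &&
             (cand_mm < mmcnt[i, s_new] ||
                (cand_mm == mmcnt[i, s_new] && cand_ns < nseg[i, s_new])))
        if (better) {
          cover[i, s_new] <- cand_cover
          mmcnt[i, s_new] <- cand_mm
          nseg[i, s_new] <- cand_ns
          prev[i, s_new, ] <- c(j, s_prev)
        }
      }
    }
  }
  best <- which(cover == max(cover), arr.ind = TRUE)
  if (nrow(best) > 1L) {
    key <- order(mmcnt[best], nseg[best])[1L]
    best <- best[key, , drop = FALSE]
  }
  if (max(cover) < params$min_cover_frac * read_length) return(NULL)
  # backtrack
  path <- integer(0)
  i <- best[1L, 1L]
  s <- best[1L, 2L]
  while (!is.na(i)) {
    path <- c(i, path)
    pi <- prev[i, s, ]
    i <- pi[1L]
    s <- pi[2L]
  }
  chain <- m[path, ]
  rownames(chain) <- NULL
  attr(chain, "cover") <- max(cover)
  descent <- NA_integer_
  if (nrow(chain) > 1L) {
    for (j in seq_len(nrow(chain) - 1L)) {
      if (is_backward_step(chain[j, ], chain[j + 1L, ])) descent <- j
    }
  }
  attr(chain, "descent") <- descent
  chain
}

# junction-facing genomic dinucleotides at a (possibly truncated) BSJ:
# 2 nt just 3' of the retained donor end and 2 nt just 5' of the retained
# acceptor start
junction_dinucs <- function(model, donor, donor_end_offset,
                            acceptor, acceptor_start_offset) {
  dlen <- exon_len(model, donor)
  don <- "unknown"
  acc <- "unknown"
  if (!is.null(model$gene_sequence)) {
    g_d <- model$exons$genomic_end[model$exons$index == donor] -
      (dlen - donor_end_offset)
    g_a <- model$exons$genomic_start[model$exons$index == acceptor] +
      acceptor_start_offset
    if (g_d + 2L <= nchar(model$gene_sequence)) {
      don <- substr(model$gene_sequence, g_d + 1L, g_d + 2L)
    }
    if (g_a - 2L >= 0L) {
      acc <- substr(model$gene_sequence, g_a - 1L, g_a)
    }
  } else {
    dseq <- exon_seq(model, donor)
    aseq <- exon_seq(model, acceptor)
    if (donor_end_offset + 2L <= nchar(dseq)) {
      don <- substr(dseq, donor_end_offset + 1L, donor_end_offset + 2L)
    } else if (donor_end_offset == nchar(dseq)) {
      don <- unname(exon_flanks(model, donor)["donor_flank"])
    }
    if (acceptor_start_offset >= 2L) {
      acc <- substr(aseq, acceptor_start_offset - 1L, acceptor_start_offset)
    } else if (acceptor_start_offset == 0L) {
      acc <- unname(exon_flanks(model, acceptor)["acceptor_flank"])
    }
  }
  c(donor = don, acceptor = acc)
}

#' Quantify junction-overlap ambiguity of a back-splice junction
#'
#' When the retained donor suffix is identical to the genomic bases
#' immediately upstream of the retained acceptor start (and/or the
#' retained acceptor prefix to the bases immediately downstream of the
#' donor end), the junction can be placed at k+1 equivalent positions
#' yielding the same circular sequence; the identical run cannot be
#' assigned to either exon. k is the sum of the leftward (`k_left`) and
#' rightward (`k_right`) extents of that identity.
#'
#' @param bsj a [backsplice_junction()].
#' @param model a [gene_model()] (exon sequences; gene sequence used
#'   when present so the identity may run into intronic bases).
#' @return list `k`, `k_left`, `k_right`, `ambiguity_string` (the
#'   junction-spanning identical run, DNA), `n_equivalent_placements`
#'   (= k + 1).
#' @export
compute_overlap_ambiguity <- function(bsj, model) {
  donor <- bsj$donor_exon_index
  acceptor <- bsj$acceptor_exon_index
  dlen <- exon_len(model, donor)
  alen <- exon_len(model, acceptor)
  dseq <- exon_seq(model, donor)
  aseq <- exon_seq(model, acceptor)
  d_off <- bsj$donor_end_offset
  a_off <- bsj$acceptor_start_offset
  # base at signed offset around the junction, donor side / acceptor side;
  # NA when the base is unavailable (no gene sequence and outside exon)
  gene <- model$gene_sequence
  d_gend <- model$exons$genomic_end[model$exons$index == donor]
  a_gstart <- model$exons$genomic_start[model$exons$index == acceptor]
  donor_base <- function(j) {  # j = 1 is the last retained donor base
    p <- d_off - j + 1L
    if (p >= 1L && p <= dlen) return(substr(dseq, p, p))
    if (!is.null(gene)) {
      g <- d_gend - (dlen - d_off) - j + 1L
      if (g >= 1L && g <= nchar(gene)) return(substr(gene, g, g))
    }
    NA_character_
  }
  donor_after <- function(j) {  # j = 1 is the first base past the donor end
    p <- d_off + j
    if (p <= dlen) return(substr(dseq, p, p))
    if (!is.null(gene)) {
      g <- d_gend - (dlen - d_off) + j
      if (g <= nchar(gene)) return(substr(gene, g, g))
    }
    NA_character_
  }
  acc_base <- function(j) {  # j = 1 is the first retained acceptor base
    p <- a_off + j
    if (p <= alen) return(substr(aseq, p, p))
    NA_character_
  }
  acc_before <- function(j) {  # j = 1 is the base just 5' of the start
    p <- a_off - j + 1L
    if (p >= 1L) return(substr(aseq, p, p))
    if (!is.null(gene)) {
      g <- a_gstart + a_off - j + 1L
      if (g >= 1L) return(substr(gene, g, g))
    }
    NA_character_
  }
  # identity is only counted as far as a legal junction placement can
  # slide: both junction ends must stay inside their exons, so k+1 is
  # exactly the number of equivalent placements
  k_left_max <- min(d_off - 1L, a_off)
  k_right_max <- min(dlen - d_off, alen - 1L - a_off)
  k_left <- 0L
  while (k_left < k_left_max) {
    b1 <- donor_base(k_left + 1L)
    b2 <- acc_before(k_left + 1L)
    if (is.na(b1) || is.na(b2) || b1 != b2) break
    k_left <- k_left + 1L
  }
  k_right <- 0L
  while (k_right < k_right_max) {
    b1 <- acc_base(k_right + 1L)
    b2 <- donor_after(k_right + 1L)
    if (is.na(b1) || is.na(b2) || b1 != b2) break
    k_right <- k_right + 1L
  }
  k <- k_left + k_right
  amb <- ""
  if (k > 0L) {
    left <- vapply(rev(seq_len(k_left)), donor_base, character(1))
    right <- vapply(seq_len(k_right), acc_base, character(1))
    amb <- paste(c(left, right), collapse = "")
  }
  list(k = k, k_left = k_left, k_right = k_right,
       ambiguity_string = amb, n_equivalent_placements = k + 1L)
}

# canonical junction placement: slide the junction as far donor-ward as
# the ambiguity run (and the exon bounds) allow, so the ambiguous bases
# sit at the donor 3' end; then record ambiguity and splice-site flags
annotate_bsj_flags <- function(bsj, model) {
  amb <- compute_overlap_ambiguity(bsj, model)
  if (amb$k_right > 0L) {
    dlen <- exon_len(model, bsj$donor_exon_index)
    alen <- exon_len(model, bsj$acceptor_exon_index)
    shift <- min(amb$k_right, dlen - bsj$donor_end_offset,
                 alen - 1L - bsj$acceptor_start_offset)
    if (shift > 0L) {
      bsj <- backsplice_junction(
        bsj$donor_exon_index, bsj$donor_end_offset + shift,
        bsj$acceptor_exon_index, bsj$acceptor_start_offset + shift,
        dlen, alen)
      amb <- compute_overlap_ambiguity(bsj, model)
    }
  }
  bsj$ambiguity_k <- as.integer(amb$k)
  bsj$ambiguity_string <- amb$ambiguity_string
  dn <- junction_dinucs(model, bsj$donor_exon_index, bsj$donor_end_offset,
                        bsj$acceptor_exon_index, bsj$acceptor_start_offset)
  bsj$canonical <- if (any(dn == "unknown")) {
    "unknown"
  } else if (dn[["donor"]] == "GT" && dn[["acceptor"]] == "AG") {
    "canonical"
  } else {
    "non_canonical"
  }
  bsj
}

#' Call the back-splice junction from a segment chain
#'
#' The single backward step of the chain identifies the junction: the
#' segment before it is the donor, the one after the acceptor. Read
#' bases claimed by both matches (the junction-overlap ambiguity run)
#' are assigned to the donor side, giving one deterministic canonical
#' placement; truncation flags, ambiguity and splice-site class are then
#' annotated against the model.
#'
#' @param chain output of [chain_segments()].
#' @param model a [gene_model()].
#' @param read the read the chain came from (taken from the chain's
#'   `read` attribute when not supplied); used to place the junction
#'   within the overlap claimed by both junction matches.
#' @return a [backsplice_junction()], or `NULL` when the chain has no
#'   backward step.
#' @export
call_bsj <- function(chain, model, read = attr(chain, "read")) {
  if (is.null(chain) || nrow(chain) == 0L) return(NULL)
  backs <- which(vapply(seq_len(max(nrow(chain) - 1L, 0L)), function(j) {
    is_backward_step(chain[j, ], chain[j + 1L, ])
  }, logical(1)))
  if (length(backs) == 0L) return(NULL)
  if (length(backs) > 1L) stop("multiple junctions in chain", call. = FALSE)
  dj <- backs
  don <- chain[dj, ]
  acc <- chain[dj + 1L, ]
  o <- max(0L, don$read_end - acc$read_start)
  donor_end <- don$exon_end
  acc_start <- acc$exon_start + o
  if (!is.null(read) && don$read_end != acc$read_start) {
    # place the junction within the overlap (or error-induced gap)
    # where the read agrees best with the model on both sides
    # (ties donor-ward: canonical form)
    placed <- place_junction(read, don, acc, model)
    donor_end <- placed[["donor_end"]]
    acc_start <- placed[["acc_start"]]
  }
  bsj <- backsplice_junction(
    donor_exon_index = don$exon_index,
    donor_end_offset = donor_end,
    acceptor_exon_index = acc$exon_index,
    acceptor_start_offset = acc_start,
    donor_exon_length = exon_len(model, don$exon_index),
    acceptor_exon_length = exon_len(model, acc$exon_index))
  annotate_bsj_flags(bsj, model)
}

# score every junction placement within the read interval spanned by
# the donor match end and the acceptor match start (an overlap when the
# two matches claim the same bases, a gap when errors trimmed them)
# against the model and return the best (donor-ward on ties), as
# c(donor_end =, acc_start =)
place_junction <- function(read, don, acc, model, window = 12L) {
  dseq <- exon_seq(model, don$exon_index)
  aseq <- exon_seq(model, acc$exon_index)
  rchars <- strsplit(read, "", fixed = TRUE)[[1L]]
  dchars <- strsplit(dseq, "", fixed = TRUE)[[1L]]
  achars <- strsplit(aseq, "", fixed = TRUE)[[1L]]
  best <- NULL
  best_score <- Inf
  lo <- min(acc$read_start, don$read_end)
  hi <- max(acc$read_start, don$read_end)
  for (j in lo:hi) {  # candidate junction (0-based read position)
    donor_end <- don$exon_end - (don$read_end - j)
    acc_start <- acc$exon_start + (j - acc$read_start)
    if (donor_end < 1L || donor_end > length(dchars) ||
        acc_start < 0L || acc_start >= length(achars)) next
    wl <- min(window, j - don$read_start, donor_end)
    wr <- min(window, acc$read_end - j, length(achars) - acc_start)
    score <- 0L
    if (wl > 0L) {
      score <- score + sum(rchars[(j - wl + 1L):j] !=
                             dchars[(donor_end - wl + 1L):donor_end])
    }
    if (wr > 0L) {
      score <- score + sum(rchars[(j + 1L):(j + wr)] !=
                             achars[(acc_start + 1L):(acc_start + wr)])
    }
    if (score < best_score ||
        (score == best_score && !is.null(best))) {
      # strict improvement, or equal score further donor-ward (larger j)
      best <- c(donor_end = donor_end, acc_start = acc_start)
      best_score <- score
    }
  }
  if (is.null(best)) {
    c(donor_end = don$exon_end,
      acc_start = acc$exon_start +
        max(0L, don$read_end - acc$read_start))
  } else {
    best
  }
}
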