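STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' Translate an open reading frame
#'
#' Standard-code translation of an ORF nucleotide sequence. A single
#' trailing stop codon is trimmed; an internal stop violates the ORF
#' contract and is rejected.
#'
#' @param orf_nucleotides DNA/RNA string, length a multiple of 3 after
#'   stop trimming.
#' @return amino-acid string beginning with the encoded first residue.
#' @export
translate_orf <- function(orf_nucleotides) {
  s <- as_dna(orf_nucleotides)
  n <- nchar(s)
  if (n %% 3L != 0L) stop("ORF length not a multiple of 3", call. = FALSE)
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  if (length(codons) > 0L && codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  if (any(codons %in% STOP_CODONS)) {
    stop("internal stop codon in claimed ORF", call. = FALSE)
  }
  tab <- codon_table()
  paste(tab[codons], collapse = "")
}

# walk one frame of a linear string: report maximal ORFs (first ATG after
# the previous stop opens an ORF; a stop closes it); ORFs reaching the
# end without a stop are reported with stop_found = FALSE
walk_frame_orfs <- function(seq, frame, max_codons = Inf) {
  n <- nchar(seq)
  if (n < frame + 3L) return(NULL)
  starts <- seq(frame + 1L, n - 2L, by = 3L)
  if (length(starts) == 0L) return(NULL)
  codons <- substring(seq, starts, starts + 2L)
  out <- list()
  open <- NA_integer_
  for (i in seq_along(codons)) {
    if (is.na(open)) {
      if (codons[i] == "ATG") open <- i
    } else if (codons[i] %in% STOP_CODONS) {
      out[[length(out) + 1L]] <-
        list(start = starts[open] - 1L, n_codons = i - open,
             stop_found = TRUE)
      open <- NA_integer_
    } else if (i - open + 1L > max_codons) {
      out[[length(out) + 1L]] <-
        list(start = starts[open] - 1L, n_codons = max_codons,
             stop_found = FALSE)
      open <- NA_integer_
    }
  }
  if (!is.na(open)) {
    out[[length(out) + 1L]] <-
      list(start = starts[open] - 1L,
           n_codons = min(length(codons) - open + 1L, max_codons),
           stop_found = FALSE)
  }
  out
}

orf_records <- function(hits, seq, mode, L, min_aa, offset = 0L) {
  rows <- lapply(hits, function(h) {
    if (h$n_codons < min_aa) return(NULL)
    nt <- substr(seq, h$start + 1L, h$start + 3L * h$n_codons)
    start_circ <- (h$start + offset) %% L
    span_end <- h$start + 3L * h$n_codons + if (h$stop_found) 3L else 0L
    data.frame(mode = mode, start = start_circ, length_aa = h$n_codons,
               peptide = translate_orf(nt),
               crosses_bsj = (span_end + offset) > L &&
                 (h$start + offset) < L,
               stop_found = h$stop_found)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(mode = character(0), start = integer(0),
                      length_aa = integer(0), peptide = character(0),
                      crosses_bsj = logical(0), stop_found = logical(0)))
  }
  do.call(rbind, rows)
}

#' Find open reading frames on a circRNA
#'
#' Three scanning modes mirror how circles must be handled by linear ORF
#' tools versus a genuinely circular scan:
#' \describe{
#'   \item{`linearized_bsj`}{the circle is cut at the back-splice
#'     junction (the canonical rotation start) and the three forward
#'     frames of the linear string are scanned;}
#'   \item{`linearized_adjacent`}{the cut is placed instead at the splice
#'     site adjacent to the BSJ (the boundary after the acceptor
#'     segment);}
#'   \item{`circular`}{the doubled sequence is scanned, starts are
#'     reported in `[0, L)` in circular coordinates, translation runs
#'     across the junction, and ORFs that find no in-frame stop within
#'     one extra full period are capped at `L/3` codons with
#'     `stop_found = FALSE`.}
#' }
#' ORFs start at ATG and must encode at least `min_aa` residues (the
#' stop codon is excluded from the count).
#'
#' @param circ a `circ_rna`.
#' @param mode one of `"circular"`, `"linearized_bsj"`,
#'   `"linearized_adjacent"`.
#' @param min_aa minimum peptide length, amino acids (default 51: more
#'   than 50).
#' @return data.frame of ORF records: `mode`, `start` (0-based circular
#'   coordinate of the A of ATG), `length_aa`, `peptide`, `crosses_bsj`,
#'   `stop_found`.
#' @export
find_orfs <- function(circ,
                      mode = c("circular", "linearized_bsj",
                               "linearized_adjacent"),
                      min_aa = 51L) {
  mode <- match.arg(mode)
  if (min_aa < 1L) stop("min_aa must be >= 1", call. = FALSE)
  seq <- circ$sequence
  L <- nchar(seq)
  if (L < 3L) stop("circle shorter than one codon", call. = FALSE)
  if (mode == "linearized_bsj") {
    hits <- do.call(c, lapply(0:2, function(f) walk_frame_orfs(seq, f)))
    return(orf_records(hits, seq, mode, L = .Machine$integer.max,
                       min_aa = min_aa))
  }
  if (mode == "linearized_adjacent") {
    cut <- circ$segments$seg_end[1L] - circ$segments$seg_start[1L]
    lin <- rotate_str(seq, cut)
    hits <- do.call(c, lapply(0:2, function(f) walk_frame_orfs(lin, f)))
    rec <- orf_records(hits, lin, mode, L = .Machine$integer.max,
                       min_aa = min_aa)
    # report starts in circular coordinates of the canonical rotation
    rec$start <- (rec$start + cut) %% L
    return(rec)
  }
  doubled <- paste0(seq, seq)
  max_codons <- L %/% 3L
  hits <- do.call(c, lapply(0:2, function(f) {
    walk_frame_orfs(doubled, f, max_codons = max_codons)
  }))
  hits <- Filter(function(h) h$start < L, hits)
  rec <- orf_records(hits, doubled, "circular", L = L, min_aa = min_aa)
  unique(rec)
}

#' Map a circular coordinate to its exon
#'
#' @param circ a `circ_rna`.
#' @param pos 0-based circular coordinate.
#' @return list `exon_index` and `exon_offset` (0-based on the exon).
#' @export
circ_position_to_exon <- function(circ, pos) {
  segs <- circ$segments
  lens <- segs$seg_end - segs$seg_start
  pos <- pos %% sum(lens)
  bounds <- cumsum(lens)
  j <- which(pos < bounds)[1L]
  within <- pos - c(0L, bounds)[j]
  list(exon_index = segs$exon_index[j],
       exon_offset = segs$seg_start[j] + within)
}

#' Built-in methyltransferase peptide motifs
#'
#' The signature arginine-methyltransferase motif I and post-I motifs
#' used to recognise catalytically relevant isoforms.
#'
#' @return named character vector of exact amino-acid motifs.
#' @export
methyltransferase_motifs <- function() {
  c(motif_I = "VLDVGSGTG", post_I = "VIGIE")
}

#' Scan a peptide for exact amino-acid motifs
#'
#' @param peptide amino-acid string.
#' @param motif_set named character vector of exact motifs (default the
#'   built-in methyltransferase motifs).
#' @return data.frame: `motif_name`, `motif`, `position` (1-based).
#' @export
scan_protein_motifs <- function(peptide, motif_set = methyltransferase_motifs()) {
  if (length(motif_set) == 0L) {
    return(data.frame(motif_name = character(0), motif = character(0),
                      position = integer(0)))
  }
  if (any(!nzchar(motif_set))) stop("empty motif", call. = FALSE)
  rows <- lapply(seq_along(motif_set), function(i) {
    mot <- motif_set[[i]]
    # overlapping occurrences
    pos <- integer(0)
    from <- 1L
    repeat {
      p <- regexpr(mot, substr(peptide, from, nchar(peptide)), fixed = TRUE)
      if (p < 0L) break
      pos <- c(pos, from + p - 1L)
      from <- from + p
    }
    if (length(pos) == 0L) return(NULL)
    data.frame(motif_name = names(motif_set)[i], motif = mot, position = pos)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(motif_name = character(0), motif = character(0),
                      position = integer(0)))
  }
  do.call(rbind, rows)
}

#' Scan a circRNA for canonical miRNA seed sites
#'
#' TargetScan-style seed classes on the circular target, 5' to 3':
#' an 8mer site is the reverse complement of miRNA positions 2-8
#' followed by an A opposite position 1; 7mer-m8 drops the A; 7mer-A1
#' matches positions 2-7 plus the A. The doubled sequence is scanned so
#' sites spanning the back-splice junction are found; each seed anchor
#' is reported once with its strongest class. Motifs are rendered as RNA
#' as they read on the target strand.
#'
#' @param circ a `circ_rna`.
#' @param mirnas named character vector of miRNA sequences (RNA or DNA,
#'   5'->3', >= 8 nt) or a FASTA path.
#' @return data.frame: `mirna_id`, `site_type`, `motif` (RNA), `position`
#'   (0-based circular start of the motif), `crosses_bsj`.
#' @export
scan_mirna_sites <- function(circ, mirnas) {
  if (is.character(mirnas) && length(mirnas) == 1L && is.null(names(mirnas))
      && file.exists(mirnas)) {
    mirnas <- read_fasta(mirnas)
  }
  if (is.null(names(mirnas)) || any(!nzchar(names(mirnas)))) {
    stop("miRNAs must be named", call. = FALSE)
  }
  if (anyDuplicated(names(mirnas))) {
    stop("duplicate miRNA ids", call. = FALSE)
  }
  seq <- circ$sequence
  L <- nchar(seq)
  doubled <- paste0(seq, seq)
  dchars <- strsplit(doubled, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (id in names(mirnas)) {
    m <- as_dna(mirnas[[id]])
    if (nchar(m) < 8L) stop("miRNA ", id, " shorter than 8 nt", call. = FALSE)
    seed28 <- revcomp(substr(m, 2L, 8L))   # 7 nt on the target strand
    seed27 <- revcomp(substr(m, 2L, 7L))   # 6 nt
    # anchor q = target position pairing miRNA position 2 (end of seed28)
    hit_starts <- function(pat) {
      g <- gregexpr(pat, doubled, fixed = TRUE)[[1L]]
      g <- g[g > 0L]
      g - 1L
    }
    s28 <- hit_starts(seed28)
    s27 <- hit_starts(seed27)
    anchors <- sort(unique(c(s28 + 6L, s27 + 5L)))
    anchors <- anchors[anchors >= 5L]
    for (q in anchors) {
      m8_match <- q >= 6L && (q - 6L) %in% s28
      a1 <- q + 1L < 2L * L && dchars[q + 2L] == "A"
      if (m8_match && a1) {
        p <- q - 6L
        site <- list(type = "8mer", motif = paste0(seed28, "A"), start = p,
                     len = 8L)
      } else if (m8_match) {
        p <- q - 6L
        site <- list(type = "7mer_m8", motif = seed28, start = p, len = 7L)
      } else if ((q - 5L) %in% s27 && a1) {
        p <- q - 5L
        site <- list(type = "7mer_A1", motif = paste0(seed27, "A"), start = p,
                     len = 7L)
      } else {
        next
      }
      if (site$start >= L) next  # keep one circular copy
      rows[[length(rows) + 1L]] <-
        data.frame(mirna_id = id, site_type = site$type,
                   motif = as_rna(site$motif), position = site$start,
                   crosses_bsj = site$start + site$len > L)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(mirna_id = character(0), site_type = character(0),
                      motif = character(0), position = integer(0),
                      crosses_bsj = logical(0)))
  }
  do.call(rbind, rows)
}

#' Scan a circRNA for DRACH m6A consensus sites
#'
#' Every adenosine whose centred 5-mer matches D-R-A-C-H (D in A/G/U,
#' R in A/G, H in A/C/U) is reported, scanning circularly; the 9-mer
#' context centred on the modified A is rendered as RNA.
#'
#' @param circ a `circ_rna`.
#' @return data.frame: `position` (0-based circular coordinate of the
#'   modified A), `context_9mer` (RNA), `consensus`.
#' @export
scan_m6a <- function(circ) {
  seq <- circ$sequence
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  at <- function(i) chars[((i %% L) + L) %% L + 1L]
  rows <- list()
  for (i in 0:(L - 1L)) {
    if (at(i) != "A") next
    if (at(i - 2L) %in% c("A", "G", "T") &&
        at(i - 1L) %in% c("A", "G") &&
        at(i + 1L) == "C" &&
        at(i + 2L) %in% c("A", "C", "T")) {
      ctx <- paste(vapply((i - 4L):(i + 4L), at, character(1)),
                   collapse = "")
      rows[[length(rows) + 1L]] <-
        data.frame(position = i, context_9mer = as_rna(ctx),
                   consensus = "DRACH_match")
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(position = integer(0), context_9mer = character(0),
                      consensus = character(0)))
  }
  do.call(rbind, rows)
}

# does the DRACH consensus hold for the central A of a context string?
drach_match <- function(context) {
  s <- as_dna(context)
  n <- nchar(s)
  mid <- (n + 1L) %/% 2L
  if (substr(s, mid, mid) != "A" || mid < 3L || mid + 2L > n) return(FALSE)
  five <- substr(s, mid - 2L, mid + 2L)
  c5 <- strsplit(five, "", fixed = TRUE)[[1L]]
  c5[1L] %in% c("A", "G", "T") && c5[2L] %in% c("A", "G") &&
    c5[4L] == "C" && c5[5L] %in% c("A", "C", "T")
}

# Altschul-Erickson dinucleotide-preserving shuffle of a character vector
dinucleotide_shuffle <- function(chars) {
  n <- length(chars)
  if (n < 3L) return(chars)
  verts <- unique(chars)
  if (length(verts) == 1L) return(chars)
  from <- chars[-n]
  to <- chars[-1L]
  sn <- chars[n]
  edge_list <- split(to, factor(from, levels = verts))
  # choose random last edges forming paths to the end vertex
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == sn || length(edge_list[[v]]) == 0L) NA_character_
      else sample(edge_list[[v]], 1L)
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == sn || is.na(last_edge[[v]])) next
      seen <- character(0)
      cur <- v
      while (!is.na(last_edge[[cur]]) && cur != sn && !cur %in% seen) {
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (cur != sn) {
        ok <- FALSE
        break
      }
    }
    if (ok) break
  }
  ordered <- lapply(verts, function(v) {
    e <- edge_list[[v]]
    if (length(e) == 0L) return(e)
    if (is.na(last_edge[[v]])) return(sample(e))
    le <- last_edge[[v]]
    rest <- e[-match(le, e)]
    c(if (length(rest) > 0L) sample(rest) else character(0), le)
  })
  names(ordered) <- verts
  used <- stats::setNames(integer(length(verts)), verts)
  walk <- character(n)
  walk[1L] <- chars[1L]
  cur <- chars[1L]
  for (i in 2:n) {
    used[[cur]] <- used[[cur]] + 1L
    nxt <- ordered[[cur]][used[[cur]]]
    walk[i] <- nxt
    cur <- nxt
  }
  walk
}

#' Count IUPAC motif matches on a circRNA, per RNA-binding protein
#'
#' Circular match counting under IUPAC semantics: the doubled sequence
#' is scanned and match starts are reported once per circular position.
#' An optional empirical p-value compares the observed count with counts
#' on dinucleotide-preserving shuffles of the circle.
#'
#' @param circ a `circ_rna`.
#' @param motif_table data.frame with columns `rbp` and `pattern` (IUPAC,
#'   RNA or DNA spelling).
#' @param n_shuffle number of dinucleotide shuffles for the empirical
#'   p-value; 0 (default) skips it.
#' @return data.frame: `rbp`, `pattern`, `count`, `positions`
#'   (comma-separated 0-based starts), and `p_empirical` when shuffling
#'   is requested.
#' @export
scan_rbp_motifs <- function(circ, motif_table, n_shuffle = 0L) {
  stopifnot(is.data.frame(motif_table),
            all(c("rbp", "pattern") %in% names(motif_table)))
  seq <- circ$sequence
  L <- nchar(seq)
  count_circular <- function(pattern, s) {
    doubled <- Biostrings::DNAString(paste0(s, s))
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                     doubled, fixed = FALSE)
    starts <- Biostrings::start(hits) - 1L
    starts[starts < L & starts + nchar(pattern) <= 2L * L]
  }
  rows <- lapply(seq_len(nrow(motif_table)), function(i) {
    pattern <- check_iupac(motif_table$pattern[i])
    if (nchar(pattern) > L) {
      stop("pattern longer than the circle", call. = FALSE)
    }
    starts <- count_circular(pattern, seq)
    row <- data.frame(rbp = motif_table$rbp[i], pattern = pattern,
                      count = length(starts),
                      positions = paste(starts, collapse = ","))
    if (n_shuffle > 0L) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
      null_counts <- vapply(seq_len(n_shuffle), function(j) {
        length(count_circular(pattern,
                              paste(dinucleotide_shuffle(chars),
                                    collapse = "")))
      }, integer(1))
      row$p_empirical <- (1 + sum(null_counts >= row$count)) /
        (n_shuffle + 1)
    }
    row
  })
  do.call(rbind, rows)
}

#' Full feature report for a set of circRNAs
#'
#' Runs the circular ORF finder (all three modes), peptide motif scan on
#' every circular-mode ORF, DRACH m6A scan, and — when supplied — miRNA
#' seed-site and RBP motif scans.
#'
#' @param circs list of `circ_rna` objects.
#' @param mirnas optional named miRNA vector or FASTA path.
#' @param rbp_motifs optional motif table (see [scan_rbp_motifs()]).
#' @param min_aa ORF length threshold, aa.
#' @return named list (by circ id) of per-circle feature lists.
#' @export
circ_features <- function(circs, mirnas = NULL, rbp_motifs = NULL,
                          min_aa = 51L) {
  out <- lapply(circs, function(circ) {
    orfs <- do.call(rbind, lapply(
      c("circular", "linearized_bsj", "linearized_adjacent"),
      function(mo) find_orfs(circ, mo, min_aa = min_aa)))
    prot <- do.call(rbind, lapply(
      which(orfs$mode == "circular"),
      function(i) {
        hits <- scan_protein_motifs(orfs$peptide[i])
        if (nrow(hits) > 0L) hits$orf_start <- orfs$start[i]
        hits
      }))
    list(id = circ$id, length = circ$length,
         exons = exon_list_string(circ),
         orfs = orfs,
         protein_motifs = prot,
         m6a = scan_m6a(circ),
         mirna_sites = if (!is.null(mirnas)) scan_mirna_sites(circ, mirnas),
         rbp_counts = if (!is.null(rbp_motifs))
           scan_rbp_motifs(circ, rbp_motifs))
  })
  names(out) <- vapply(circs, function(x) x$id, character(1))
  out
}
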