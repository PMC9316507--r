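# run expr with a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic locus / circRNA / read generator.
#' Identical configurations produce byte-identical output. Defaults
#' emulate the study system: a ~10-exon gene, circles of 2-6 exons with
#' the two junction-facing exon ends usually truncated, junction-overlap
#' homology of 3-8 nt planted in about two thirds of circles, and long
#' low-error amplicon reads (700 nt, 0.1% substitutions) that traverse
#' the circle rolling-circle fashion.
#'
#' @param seed integer; master seed (all generator functions derive their
#'   streams from it).
#' @param n_exons number of exons in a simulated gene.
#' @param exon_length_range,intron_length_range integer pairs (min, max) nt.
#' @param gc_fraction target GC content of generated sequence, in (0,1).
#' @param truncation_prob probability that each junction-facing exon end
#'   (donor 3' end, acceptor 5' end) is truncated.
#' @param truncation_range integer pair; truncation lengths drawn
#'   uniformly from this range (capped below exon length).
#' @param overlap_homology_range integer pair; planted junction-homology
#'   lengths, default 3-8 nt.
#' @param homology_prob probability that a simulated circle gets planted
#'   junction homology (default 6/9).
#' @param n_segments_range integer pair; number of distinct exons per
#'   circle, default 2-6.
#' @param read_error_rate substitution probability per base.
#' @param read_length read length in nt.
#' @param flank_length nt of non-genic sequence kept on both sides of the
#'   gene (room for junction-homology planting next to terminal exons).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_exons = 10L,
                       exon_length_range = c(80L, 110L),
                       intron_length_range = c(60L, 300L),
                       gc_fraction = 0.5,
                       truncation_prob = 0.8,
                       truncation_range = c(1L, 30L),
                       overlap_homology_range = c(3L, 8L),
                       homology_prob = 6 / 9,
                       n_segments_range = c(2L, 6L),
                       read_error_rate = 0.001,
                       read_length = 700L,
                       flank_length = 30L) {
  cfg <- list(seed = as.integer(seed), n_exons = as.integer(n_exons),
              exon_length_range = as.integer(exon_length_range),
              intron_length_range = as.integer(intron_length_range),
              gc_fraction = gc_fraction,
              truncation_prob = truncation_prob,
              truncation_range = as.integer(truncation_range),
              overlap_homology_range = as.integer(overlap_homology_range),
              homology_prob = homology_prob,
              n_segments_range = as.integer(n_segments_range),
              read_error_rate = read_error_rate,
              read_length = as.integer(read_length),
              flank_length = as.integer(flank_length))
  ranges <- c("exon_length_range", "intron_length_range",
              "truncation_range", "overlap_homology_range",
              "n_segments_range")
  for (r in ranges) {
    v <- cfg[[r]]
    if (length(v) != 2L || any(is.na(v)) || v[1L] > v[2L] || v[1L] < 0L) {
      stop("degenerate range for ", r, call. = FALSE)
    }
  }
  for (p in c("gc_fraction", "truncation_prob", "homology_prob",
              "read_error_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0,1]",
                                           call. = FALSE)
  }
  if (cfg$n_exons < 1L) stop("n_exons must be >= 1", call. = FALSE)
  if (cfg$exon_length_range[1L] < 1L) stop("exons must be non-empty",
                                           call. = FALSE)
  # introns carry GT...AG, so they need at least 4 nt
  if (cfg$intron_length_range[1L] < 4L) stop("introns must be >= 4 nt",
                                             call. = FALSE)
  if (cfg$read_length < 1L) stop("read_length must be >= 1", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds any subset of the [sim_config()] arguments under their
#' argument names; missing keys take the defaults.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown) > 0L) {
    stop("unknown sim_config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, doc)
}

#' Simulate a multi-exon gene model
#'
#' Generates a single-gene locus: `n_exons` exons separated by introns
#' that begin with the canonical donor dinucleotide `GT` and end with the
#' acceptor `AG`, plus short non-genic flanks on both sides. Output is
#' deterministic under the configuration seed.
#'
#' @param config a [sim_config()].
#' @return a [gene_model()] with gene sequence and intronic flanks.
#' @export
simulate_gene <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_exons
    elen <- sample(seq(config$exon_length_range[1L],
                       config$exon_length_range[2L]), n, replace = TRUE)
    ilen <- if (n > 1L) {
      sample(seq(config$intron_length_range[1L],
                 config$intron_length_range[2L]), n - 1L, replace = TRUE)
    } else integer(0)
    pieces <- character(0)
    starts <- integer(n)
    pos <- config$flank_length
    pieces <- random_dna(config$flank_length, config$gc_fraction)
    for (i in seq_len(n)) {
      starts[i] <- pos
      pieces <- c(pieces, random_dna(elen[i], config$gc_fraction))
      pos <- pos + elen[i]
      if (i < n) {
        mid <- random_dna(ilen[i] - 4L, config$gc_fraction)
        pieces <- c(pieces, paste0("GT", mid, "AG"))
        pos <- pos + ilen[i]
      }
    }
    pieces <- c(pieces, random_dna(config$flank_length, config$gc_fraction))
    gene_model(gene_id = paste0("simgene_seed", config$seed),
               exons = data.frame(genomic_start = starts,
                                  genomic_end = starts + elen),
               gene_sequence = paste(pieces, collapse = ""))
  })
}

# replace gene_sequence characters in [start, end) (0-based half-open)
edit_gene_seq <- function(seq, start, replacement) {
  stopifnot(start >= 0L, start + nchar(replacement) <= nchar(seq))
  paste0(substr(seq, 1L, start), replacement,
         substr(seq, start + nchar(replacement) + 1L, nchar(seq)))
}

# a deterministic base different from every base in `avoid`
other_base <- function(avoid) setdiff(DNA_BASES, avoid)[1L]

#' Simulate a circRNA from a gene model
#'
#' Chooses 2-6 exons (or takes an explicit choice), truncates the two
#' junction-facing exon ends with the configured probability, optionally
#' plants junction-overlap homology of k nt, and emits the circular
#' sequence in canonical rotation (starting at the acceptor's first
#' retained base). Homology planting edits the gene sequence itself —
#' the k bases immediately upstream of the acceptor's retained start are
#' made identical to the retained donor suffix, and the bases that would
#' extend the run are forced to mismatch so the planted k is exact — and
#' the returned model reflects the edited locus, so annotation and
#' ground truth see a self-consistent gene.
#'
#' @param model a [gene_model()] with gene sequence.
#' @param config a [sim_config()].
#' @param exons optional integer vector of exon indices to use (any
#'   order; the smallest becomes the BSJ acceptor, the largest the
#'   donor).
#' @param donor_trunc,acceptor_trunc optional explicit truncation lengths
#'   (nt removed from the donor 3' end / acceptor 5' start); `NULL`
#'   means "draw from config", `0` forces a full exon end.
#' @param homology_k optional explicit planted homology length (0 = no
#'   planting).
#' @return list with elements `circ` (a `circ_rna`), `truth` (a list
#'   recording the planted structure) and `model` (the possibly edited
#'   gene model).
#' @export
simulate_circrna <- function(model, config, exons = NULL,
                             donor_trunc = NULL, acceptor_trunc = NULL,
                             homology_k = NULL) {
  stopifnot(inherits(model, "gene_model"), inherits(config, "sim_config"))
  if (is.null(model$gene_sequence)) {
    stop("simulate_circrna needs a model with gene sequence", call. = FALSE)
  }
  with_seed(config$seed + 1L, {
    if (is.null(exons)) {
      m <- sample(seq(config$n_segments_range[1L],
                      min(config$n_segments_range[2L], n_exons(model))), 1L)
      exons <- sort(sample(model$exons$index, m))
    } else {
      exons <- sort(unique(as.integer(exons)))
      if (!all(exons %in% model$exons$index)) {
        stop("requested exon absent from model", call. = FALSE)
      }
    }
    acceptor <- exons[1L]
    donor <- exons[length(exons)]
    draw_trunc <- function(len) {
      if (stats::runif(1) < config$truncation_prob) {
        min(sample(seq(config$truncation_range[1L],
                       config$truncation_range[2L]), 1L), len - 1L)
      } else 0L
    }
    d_len <- exon_len(model, donor)
    a_len <- exon_len(model, acceptor)
    don_explicit <- !is.null(donor_trunc)
    acc_explicit <- !is.null(acceptor_trunc)
    if (is.null(donor_trunc)) donor_trunc <- draw_trunc(d_len)
    if (is.null(acceptor_trunc)) acceptor_trunc <- draw_trunc(a_len)
    donor_trunc <- as.integer(donor_trunc)
    acceptor_trunc <- as.integer(acceptor_trunc)
    if (donor_trunc >= d_len || donor_trunc < 0L) {
      stop("donor truncation longer than exon", call. = FALSE)
    }
    if (acceptor_trunc >= a_len || acceptor_trunc < 0L) {
      stop("acceptor truncation longer than exon", call. = FALSE)
    }
    k_explicit <- !is.null(homology_k)
    if (is.null(homology_k)) {
      homology_k <- if (stats::runif(1) < config$homology_prob) {
        sample(seq(config$overlap_homology_range[1L],
                   config$overlap_homology_range[2L]), 1L)
      } else 0L
    }
    homology_k <- as.integer(homology_k)
    # the identity run must sit inside the exons on both sides (the
    # acceptor's skipped prefix hosts its copy), or the junction could
    # not slide k placements
    if (homology_k > 0L) {
      if (acceptor_trunc < homology_k) {
        if (acc_explicit && k_explicit) {
          stop("cannot plant homology of length ", homology_k,
               " with acceptor truncation ", acceptor_trunc, call. = FALSE)
        } else if (acc_explicit) {
          # drawn homology yields to an explicitly requested truncation
          homology_k <- acceptor_trunc
        } else {
          acceptor_trunc <- homology_k
        }
      }
      if (d_len - donor_trunc < homology_k + 1L) {
        if (!don_explicit) donor_trunc <- d_len - homology_k - 1L
        else if (!k_explicit) homology_k <- max(0L, d_len - donor_trunc - 1L)
      }
      if (acceptor_trunc >= a_len ||
          d_len - donor_trunc < homology_k + 1L || donor_trunc < 0L) {
        stop("cannot plant homology of length ", homology_k,
             " at this junction", call. = FALSE)
      }
    }

    gseq <- model$gene_sequence
    exrow <- function(i) model$exons[model$exons$index == i, ]
    # gene coordinate just past the last retained donor base
    g_d <- exrow(donor)$genomic_end - donor_trunc
    # gene coordinate of the first retained acceptor base
    g_a <- exrow(acceptor)$genomic_start + acceptor_trunc

    k <- homology_k
    if (g_a - k - 1L < 0L || g_d - k - 1L < 0L ||
        g_d + 1L > nchar(gseq) ||
        (donor == acceptor && g_a > g_d - k)) {
      stop("cannot plant homology of length ", k, " at this junction",
           call. = FALSE)
    }
    if (k > 0L) {
      donor_suffix <- substr(gseq, g_d - k + 1L, g_d)
      gseq <- edit_gene_seq(gseq, g_a - k, donor_suffix)
    }
    # break extension of the identical run on both sides so the planted
    # homology length is exact (also when k = 0: no accidental run)
    left_donor <- substr(gseq, g_d - k, g_d - k)
    if (substr(gseq, g_a - k, g_a - k) == left_donor) {
      gseq <- edit_gene_seq(gseq, g_a - k - 1L, other_base(left_donor))
    }
    acc_first <- substr(gseq, g_a + 1L, g_a + 1L)
    if (substr(gseq, g_d + 1L, g_d + 1L) == acc_first) {
      gseq <- edit_gene_seq(gseq, g_d, other_base(acc_first))
    }
    if (gseq != model$gene_sequence) {
      model <- gene_model(model$gene_id,
                          model$exons[, c("index", "genomic_start",
                                          "genomic_end")],
                          gene_sequence = gseq)
    }

    segments <- data.frame(
      exon_index = exons,
      seg_start = ifelse(exons == acceptor, acceptor_trunc, 0L),
      seg_end = vapply(exons, function(i) {
        if (i == donor) exon_len(model, i) - donor_trunc
        else exon_len(model, i)
      }, integer(1)))
    seq <- paste(vapply(seq_len(nrow(segments)), function(j) {
      substr(exon_seq(model, segments$exon_index[j]),
             segments$seg_start[j] + 1L, segments$seg_end[j])
    }, character(1)), collapse = "")

    bsj <- backsplice_junction(
      donor_exon_index = donor,
      donor_end_offset = d_len - donor_trunc,
      acceptor_exon_index = acceptor,
      acceptor_start_offset = acceptor_trunc,
      donor_exon_length = d_len,
      acceptor_exon_length = a_len)
    bsj <- annotate_bsj_flags(bsj, model)
    circ <- circ_rna(id = paste0("simcirc_seed", config$seed),
                     segments = segments, sequence = seq, bsj = bsj)
    truth <- list(exons = exons, acceptor = acceptor, donor = donor,
                  donor_trunc = donor_trunc,
                  acceptor_trunc = acceptor_trunc,
                  donor_end_offset = d_len - donor_trunc,
                  acceptor_start_offset = acceptor_trunc,
                  homology_k = homology_k,
                  length = nchar(seq), sequence = seq)
    list(circ = circ, truth = truth, model = model)
  })
}

#' Simulate rolling-circle reads from a circRNA
#'
#' Each read starts at a uniform position on the circle and follows it
#' for `read_length` bases, wrapping as often as needed (rolling-circle
#' reverse transcription); substitutions are injected i.i.d. at the
#' configured error rate. Read names record the true start and whether
#' the read spans the back-splice junction.
#'
#' @param circ a `circ_rna`.
#' @param n_reads number of reads (> 0).
#' @param config a [sim_config()].
#' @return named character vector of read sequences; names are
#'   `read<i>|start=<s>|spans_bsj=<0/1>`.
#' @export
simulate_reads <- function(circ, n_reads, config) {
  stopifnot(inherits(config, "sim_config"))
  if (n_reads <= 0L) stop("n_reads must be positive", call. = FALSE)
  L <- nchar(circ$sequence)
  with_seed(config$seed + 2L, {
    starts <- sample.int(L, n_reads, replace = TRUE) - 1L
    reads <- vapply(starts, function(s) {
      circ_substr(circ$sequence, s, config$read_length)
    }, character(1))
    if (config$read_error_rate > 0) {
      reads <- vapply(reads, function(r) {
        chars <- strsplit(r, "", fixed = TRUE)[[1L]]
        hit <- which(stats::runif(length(chars)) < config$read_error_rate)
        for (i in hit) chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
        paste(chars, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    # the junction sits between circle positions L-1 and 0; a read from
    # start s covers it iff it walks past the wrap point at least once
    spans <- as.integer(starts + config$read_length > L)
    names(reads) <- sprintf("read%d|start=%d|spans_bsj=%d",
                            seq_len(n_reads), starts, spans)
    reads
  })
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector, uppercase DNA (U converted to T).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  vapply(out, as_dna, character(1))
}
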