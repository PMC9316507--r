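test_that("exon matching finds identities, tolerates substitutions, rejects noise", {
  cfg <- sim_config(seed = 21)
  m <- simulate_gene(cfg)
  idx <- circaid:::build_exon_index(m, 18L)

  # a read that is exactly exon 4
  r <- circaid:::exon_seq(m, 4)
  hits <- find_exon_matches(r, m, index = idx)
  fwd <- hits[hits$strand == "+" & hits$exon_index == 4, ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$read_start, 0L)
  expect_equal(fwd$read_end, nchar(r))
  expect_equal(fwd$mismatches, 0L)

  # exon5 + exon6 with one substitution inside exon 6
  e5 <- circaid:::exon_seq(m, 5)
  e6 <- circaid:::exon_seq(m, 6)
  pos <- 40L
  bad <- paste0(substr(e6, 1, pos - 1),
                setdiff(c("A", "C", "G", "T"),
                        substr(e6, pos, pos))[1],
                substr(e6, pos + 1, nchar(e6)))
  hits2 <- find_exon_matches(paste0(e5, bad), m, index = idx)
  hits2 <- hits2[hits2$strand == "+" & hits2$exon_index %in% c(5, 6), ]
  expect_equal(sort(unique(hits2$exon_index)), c(5L, 6L))
  expect_equal(hits2$mismatches[hits2$exon_index == 6], 1L)

  # a random 50-mer absent from the gene yields nothing on either strand
  set.seed(99)
  repeat {
    probe <- random_seq(50)
    if (!grepl(probe, m$gene_sequence, fixed = TRUE) &&
        !grepl(revcomp(probe), m$gene_sequence, fixed = TRUE)) break
  }
  expect_equal(nrow(find_exon_matches(probe, m, index = idx)), 0L)

  # reverse-complement reads are found and flagged
  rc_hits <- find_exon_matches(revcomp(r), m, index = idx)
  expect_true(any(rc_hits$strand == "-" & rc_hits$exon_index == 4))
})

test_that("chains allow exactly one backward step and report it", {
  cfg <- sim_config(seed = 22)
  m <- simulate_gene(cfg)
  sim <- simulate_circrna(m, cfg, exons = c(1, 4, 5, 6, 7),
                          donor_trunc = 20, acceptor_trunc = 0,
                          homology_k = 0)
  read <- circaid:::rotate_str(sim$circ$sequence, 150L)
  matches <- find_exon_matches(read, m2 <- sim$model)
  ch <- chain_segments(matches[matches$strand == "+", ], nchar(read))
  expect_false(is.null(ch))
  d <- attr(ch, "descent")
  expect_false(is.na(d))
  expect_equal(ch$exon_index[d], 7L)
  expect_equal(ch$exon_index[d + 1L], 1L)

  # a single full-exon read chains without any junction candidate
  single <- find_exon_matches(circaid:::exon_seq(m, 3), m)
  ch1 <- chain_segments(single[single$strand == "+", ],
                        nchar(circaid:::exon_seq(m, 3)))
  expect_equal(nrow(ch1), 1L)
  expect_true(is.na(attr(ch1, "descent")))
  expect_null(call_bsj(ch1, m))
})

test_that("junction calls recover planted truncation offsets exactly", {
  for (s in 1:20) {
    cfg <- sim_config(seed = 300 + s, read_error_rate = 0)
    m <- simulate_gene(cfg)
    dt <- (s * 7L) %% 30L + 1L
    at <- (s * 11L) %% 30L
    sim <- simulate_circrna(m, cfg, donor_trunc = dt, acceptor_trunc = at)
    reads <- simulate_reads(sim$circ, 1, cfg)
    res <- annotate_read(reads[[1]], sim$model, read_id = "r")
    expect_false(is.null(res$bsj))
    expect_equal(res$bsj$donor_exon_index, sim$truth$donor)
    expect_equal(res$bsj$acceptor_exon_index, sim$truth$acceptor)
    expect_equal(res$bsj$donor_end_offset, sim$truth$donor_end_offset)
    expect_equal(res$bsj$acceptor_start_offset,
                 sim$truth$acceptor_start_offset)
    expect_equal(res$bsj$donor_truncated, dt > 0L)
    expect_equal(res$bsj$acceptor_truncated, at > 0L)
  }
})

test_that("a single-exon circle yields a degenerate donor == acceptor junction", {
  cfg <- sim_config(seed = 23, n_segments_range = c(1L, 1L))
  m <- simulate_gene(cfg)
  sim <- simulate_circrna(m, cfg, exons = 5, donor_trunc = 0,
                          acceptor_trunc = 0, homology_k = 0)
  read <- circaid:::rotate_str(sim$circ$sequence, 30L)
  res <- annotate_read(read, sim$model, read_id = "r")
  expect_equal(res$bsj$donor_exon_index, 5L)
  expect_equal(res$bsj$acceptor_exon_index, 5L)
  expect_equal(res$bsj$donor_end_offset, sim$circ$length)
  expect_equal(res$bsj$acceptor_start_offset, 0L)
})

test_that("overlap ambiguity equals the brute-force placement enumeration", {
  agree <- 0L
  n_cases <- 60L
  for (s in seq_len(n_cases)) {
    cfg <- sim_config(seed = 500 + s)
    m <- simulate_gene(cfg)
    sim <- simulate_circrna(m, cfg)
    amb <- compute_overlap_ambiguity(sim$circ$bsj, sim$model)
    oracle <- enumerate_placements(sim$circ, sim$model)
    expect_equal(amb$n_equivalent_placements, oracle)
    expect_equal(nchar(amb$ambiguity_string), amb$k)
    if (amb$k == sim$truth$homology_k) agree <- agree + 1L
  }
  expect_equal(agree, n_cases)
})

test_that("splice-site class reflects the junction-facing dinucleotides", {
  cfg <- sim_config(seed = 25)
  m <- simulate_gene(cfg)
  # truncated junction ends sit inside exons: non-canonical by construction
  sim <- simulate_circrna(m, cfg, donor_trunc = 10, acceptor_trunc = 10,
                          homology_k = 0)
  expect_equal(sim$circ$bsj$canonical, "non_canonical")
  # a model without gene sequence and full exon ends: flanks unknown
  m2 <- gene_model("bare", m$exons[, c("index", "genomic_start",
                                       "genomic_end", "sequence")])
  bsj <- backsplice_junction(3L, nchar(circaid:::exon_seq(m2, 3)), 2L, 0L,
                             nchar(circaid:::exon_seq(m2, 3)),
                             nchar(circaid:::exon_seq(m2, 2)))
  expect_equal(circaid:::annotate_bsj_flags(bsj, m2)$canonical, "unknown")
})

test_that("annotation is rotation-invariant for error-free reads", {
  cfg <- sim_config(seed = 26, read_error_rate = 0)
  m <- simulate_gene(cfg)
  sim <- simulate_circrna(m, cfg)
  L <- sim$circ$length
  seqs <- character(0)
  for (r in c(0L, 13L, L %/% 3L, L %/% 2L, L - 7L)) {
    read <- circaid:::circ_substr(sim$circ$sequence, r, 700L)
    res <- annotate_read(read, sim$model, read_id = paste0("rot", r))
    cc <- confirm_and_reconstruct(res, sim$model)
    expect_s3_class(cc, "circ_rna")
    seqs <- c(seqs, cc$sequence)
  }
  expect_equal(length(unique(seqs)), 1L)
  expect_equal(seqs[1L], sim$truth$sequence)
})

test_that("confirmation requires junction evidence and reconstructs from the model", {
  cfg <- sim_config(seed = 27, read_error_rate = 0)
  m <- simulate_gene(cfg)
  sim <- simulate_circrna(m, cfg)

  # a read entirely inside one exon has no junction evidence
  inside <- substr(circaid:::exon_seq(sim$model, 6), 5, 90)
  res <- annotate_read(inside, sim$model, read_id = "linear")
  rej <- confirm_and_reconstruct(res, sim$model)
  expect_s3_class(rej, "circ_rejection")
  expect_match(rej$reason, "no junction evidence")

  # read errors must not leak into the reconstructed reference circle
  cfg_err <- sim_config(seed = 27, read_error_rate = 0.005)
  reads <- simulate_reads(sim$circ, 6, cfg_err)
  for (i in seq_along(reads)) {
    res <- annotate_read(reads[[i]], sim$model, read_id = names(reads)[i])
    cc <- confirm_and_reconstruct(res, sim$model)
    if (inherits(cc, "circ_rna")) {
      expect_equal(cc$length, sum(cc$segments$seg_end -
                                    cc$segments$seg_start))
      expect_true(all(strsplit(cc$sequence, "")[[1]] %in%
                        c("A", "C", "G", "T")))
      expect_equal(cc$sequence, sim$truth$sequence)
    }
  }
})

test_that("rotated duplicate reads merge into one catalog entry", {
  cfg <- sim_config(seed = 28, read_error_rate = 0)
  m <- simulate_gene(cfg)
  sim1 <- simulate_circrna(m, cfg)
  m <- sim1$model
  cfg2 <- sim_config(seed = 29, read_error_rate = 0)
  sim2 <- simulate_circrna(m, cfg2)
  m <- sim2$model

  circs <- list()
  for (sim in list(sim1, sim2)) {
    circ <- circaid:::rebuild_circ(sim$circ, m)
    for (r in c(11L, 101L)) {
      read <- circaid:::circ_substr(circ$sequence, r, 700L)
      res <- annotate_read(read, m, read_id = paste0(circ$id, "_rot", r))
      cc <- confirm_and_reconstruct(res, m)
      expect_s3_class(cc, "circ_rna")
      circs[[length(circs) + 1L]] <- cc
    }
  }
  dd <- dedupe_and_catalog(circs)
  expect_equal(nrow(dd$catalog), 2L)
  expect_equal(dd$catalog$n_reads, c(2L, 2L))
  expect_equal(sum(dd$catalog$n_reads), length(circs))
})
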