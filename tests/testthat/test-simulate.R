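test_that("identical configurations give byte-identical output", {
  cfg <- sim_config(seed = 1, n_exons = 10)
  m1 <- simulate_gene(cfg)
  m2 <- simulate_gene(cfg)
  expect_identical(m1, m2)
  s1 <- simulate_circrna(m1, cfg)
  s2 <- simulate_circrna(m2, cfg)
  expect_identical(s1$circ$sequence, s2$circ$sequence)
  r1 <- simulate_reads(s1$circ, 20, cfg)
  r2 <- simulate_reads(s2$circ, 20, cfg)
  expect_identical(r1, r2)
})

test_that("simulated introns are canonical GT...AG and GC tracks its target", {
  cfg <- sim_config(seed = 2, n_exons = 10)
  m <- simulate_gene(cfg)
  n <- nrow(m$exons)
  expect_equal(n, 10L)
  for (i in seq_len(n - 1L)) {
    intron <- substr(m$gene_sequence, m$exons$genomic_end[i] + 1L,
                     m$exons$genomic_start[i + 1L])
    expect_equal(substr(intron, 1, 2), "GT")
    expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
  }
  # binomial oracle: observed GC within 3 sigma of the target fraction
  cfg_gc <- sim_config(seed = 3, n_exons = 30, gc_fraction = 0.5,
                       exon_length_range = c(100L, 110L),
                       intron_length_range = c(200L, 300L))
  big <- simulate_gene(cfg_gc)
  N <- nchar(big$gene_sequence)
  gc_obs <- circaid:::gc_fraction(big$gene_sequence)
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / N))
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(exon_length_range = c(10, 5)), "degenerate")
  expect_error(sim_config(gc_fraction = 1.5), "0,1")
  expect_error(sim_config(intron_length_range = c(2, 3)), "intron")
})

test_that("configurations round-trip through their YAML schema", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "n_exons: 6", "read_error_rate: 0.002"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$n_exons, 6L)
  expect_equal(cfg$read_error_rate, 0.002)
  expect_equal(cfg$read_length, sim_config()$read_length)
  writeLines(c("seed: 1", "bogus_key: 3"), path)
  expect_error(read_sim_config(path), "bogus_key")
})

test_that("explicit circle structure is honoured and lengths conserve", {
  cfg <- sim_config(seed = 4)
  m <- simulate_gene(cfg)
  # mirrors a 2-exon inventory row with a truncated acceptor
  sim <- simulate_circrna(m, cfg, exons = c(6, 5), donor_trunc = 0,
                          acceptor_trunc = 12, homology_k = 0)
  expect_equal(sim$circ$segments$exon_index, c(5L, 6L))
  expect_equal(sim$circ$bsj$donor_exon_index, 6L)
  expect_equal(sim$circ$bsj$acceptor_exon_index, 5L)
  expect_true(sim$circ$bsj$acceptor_truncated)
  expect_false(sim$circ$bsj$donor_truncated)
  e5 <- nchar(circaid:::exon_seq(sim$model, 5))
  e6 <- nchar(circaid:::exon_seq(sim$model, 6))
  expect_equal(sim$circ$length, e5 - 12L + e6)

  # no truncation, no homology: length is the sum of full exon lengths
  sim0 <- simulate_circrna(m, cfg, exons = c(2, 3, 4), donor_trunc = 0,
                           acceptor_trunc = 0, homology_k = 0)
  expect_equal(sim0$circ$length,
               sum(vapply(2:4, function(i)
                 nchar(circaid:::exon_seq(sim0$model, i)), integer(1))))
  expect_error(simulate_circrna(m, cfg, exons = c(2, 3),
                                donor_trunc = 10000),
               "truncation")
})

test_that("planted junction homology is recovered exactly by the annotator", {
  for (k in c(0L, 3L, 5L, 8L)) {
    cfg <- sim_config(seed = 10 + k)
    m <- simulate_gene(cfg)
    sim <- simulate_circrna(m, cfg, homology_k = k)
    amb <- compute_overlap_ambiguity(sim$circ$bsj, sim$model)
    expect_equal(amb$k, k)
    expect_equal(amb$n_equivalent_placements, k + 1L)
  }
})

test_that("rolling-circle reads rotate the circle and flag junction spanning", {
  cfg <- sim_config(seed = 6, read_error_rate = 0)
  m <- simulate_gene(cfg)
  sim <- simulate_circrna(m, cfg)
  L <- sim$circ$length
  cfg_rot <- sim_config(seed = 6, read_error_rate = 0, read_length = L)
  reads <- simulate_reads(sim$circ, 10, cfg_rot)
  rotations <- vapply(0:(L - 1L), function(r)
    circaid:::rotate_str(sim$circ$sequence, r), character(1))
  for (r in reads) expect_true(r %in% rotations)
  # a read that stops short of the wrap point must not claim the junction
  starts <- as.integer(sub(".*start=(\\d+).*", "\\1", names(reads)))
  spans <- as.integer(sub(".*spans_bsj=(\\d)", "\\1", names(reads)))
  expect_identical(spans, as.integer(starts + L > L & starts > 0))
})

test_that("substitution errors occur at the configured binomial rate", {
  cfg <- sim_config(seed = 8, read_error_rate = 0.01, read_length = 500L)
  m <- simulate_gene(cfg)
  sim <- simulate_circrna(m, cfg)
  reads <- simulate_reads(sim$circ, 200, cfg)
  starts <- as.integer(sub(".*start=(\\d+).*", "\\1", names(reads)))
  mm <- 0L
  for (i in seq_along(reads)) {
    truth <- circaid:::circ_substr(sim$circ$sequence, starts[i], 500L)
    mm <- mm + circaid:::hamming(reads[[i]], truth)
  }
  N <- 200L * 500L
  expect_lt(abs(mm / N - 0.01), 3 * sqrt(0.01 * 0.99 / N))
})
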