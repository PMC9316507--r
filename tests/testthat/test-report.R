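test_that("the packaged inventory fixture is internally consistent", {
  t1 <- table1_fixture()
  expect_equal(nrow(t1), 9L)
  expect_equal(t1$accession, sprintf("ON0810%d", 37:45))
  expect_equal(as.integer(t1$exon_count),
               lengths(strsplit(t1$exons, ",")))
  t2 <- table2_fixture()
  expect_equal(nrow(t2), 18L)
  expect_true(all(t2$prediction_score <= 100))
})

test_that("catalog summaries match a brute-force tally", {
  t1 <- table1_fixture()
  s <- summarize_catalog(t1)
  oracle <- table_oracle_exon_counts(t1$exons)
  expect_equal(s$exon_counts[names(oracle)],
               stats::setNames(as.integer(oracle), names(oracle)))

  one <- data.frame(exons = "Exon 1, Exon 2", length = 100L)
  s1 <- summarize_catalog(one)
  expect_equal(unname(s1$exon_counts[c("1", "2")]), c(1L, 1L))
  expect_error(summarize_catalog(data.frame()), "empty")

  # simulated catalogs agree with the same tally
  set.seed(70)
  fake <- data.frame(
    exons = replicate(50, paste0("Exon ",
                                 sort(sample(1:10, sample(2:6, 1))),
                                 collapse = ", ")),
    length = sample(200:600, 50, replace = TRUE))
  sf <- summarize_catalog(fake)
  of <- table_oracle_exon_counts(fake$exons)
  expect_equal(sf$exon_counts[names(of)],
               stats::setNames(as.integer(of), names(of)))
  expect_equal(sf$min_length, min(fake$length))
  expect_equal(sf$max_length, max(fake$length))
})

test_that("per-miRNA circle counts match a brute-force tally", {
  counts <- summarize_mirna_table(table2_fixture())
  expect_equal(unname(counts["miR-494-3p"]), 7L)
  expect_equal(unname(counts["miR-6754-3p"]), 6L)
  expect_equal(length(summarize_mirna_table(
    data.frame(circ_id = character(0), mirna_id = character(0)))), 0L)
  set.seed(71)
  fake <- data.frame(circ_id = sample(paste0("c", 1:9), 40, replace = TRUE),
                     mirna_id = sample(paste0("m", 1:5), 40, replace = TRUE))
  counts2 <- summarize_mirna_table(fake)
  oracle <- vapply(split(fake$circ_id, fake$mirna_id),
                   function(x) length(unique(x)), integer(1))
  expect_equal(counts2[names(oracle)][order(names(oracle))],
               oracle[order(names(oracle))])
})

test_that("catalogs round-trip through TSV", {
  cfg <- sim_config(seed = 72, read_error_rate = 0)
  m <- simulate_gene(cfg)
  sim <- simulate_circrna(m, cfg)
  read <- circaid:::circ_substr(sim$circ$sequence, 40L, 700L)
  cc <- confirm_and_reconstruct(
    annotate_read(read, sim$model, read_id = "r1"), sim$model)
  dd <- dedupe_and_catalog(list(cc))
  path <- tempfile(fileext = ".tsv")
  write_catalog(dd$catalog, path)
  back <- read_catalog(path)
  expect_equal(back$circ_id, dd$catalog$circ_id)
  expect_equal(back$exons, dd$catalog$exons)
  expect_equal(back$length, dd$catalog$length)
  expect_equal(back$sequence, dd$catalog$sequence)
})

test_that("the pipeline recovers planted circles end to end, deterministically", {
  out1 <- tempfile()
  config <- list(
    simulate = list(seed = 7L, n_circles = 5L, n_reads_per_circle = 4L,
                    read_error_rate = 0),
    primers = list(exon = 4L),
    out_dir = out1)
  res <- suppressMessages(run_pipeline(config))
  expect_equal(res$status, 0L)
  expect_equal(nrow(res$catalog), 5L)
  truth_lens <- vapply(res$truths, `[[`, integer(1), "length")
  expect_setequal(res$catalog$length, truth_lens)
  expect_true(file.exists(file.path(out1, "catalog.tsv")))
  expect_true(file.exists(file.path(out1, "features.json")))
  expect_true(file.exists(file.path(out1, "primers.tsv")))

  out2 <- tempfile()
  config$out_dir <- out2
  res2 <- suppressMessages(run_pipeline(config))
  expect_identical(readLines(file.path(out1, "catalog.tsv")),
                   readLines(file.path(out2, "catalog.tsv")))

  # reads with no junction coverage leave an empty catalog and rejections
  cfg <- sim_config(seed = 73)
  g <- simulate_gene(cfg)
  bed <- tempfile(fileext = ".bed")
  fa <- tempfile(fileext = ".fa")
  rfa <- tempfile(fileext = ".fa")
  write_fasta(stats::setNames(g$gene_sequence, g$gene_id), fa)
  writeLines(sprintf("%s\t%d\t%d\texon%d", g$gene_id,
                     g$exons$genomic_start, g$exons$genomic_end,
                     g$exons$index), bed)
  write_fasta(c(r1 = substr(circaid:::exon_seq(g, 2), 1, 80),
                r2 = substr(circaid:::exon_seq(g, 3), 1, 80)), rfa)
  res3 <- suppressMessages(run_pipeline(list(
    inputs = list(bed = bed, fasta = fa, reads = rfa))))
  expect_equal(res3$status, 1L)
  expect_equal(nrow(res3$catalog), 0L)
  expect_equal(length(res3$rejections), 2L)

  expect_error(suppressMessages(run_pipeline(list(
    inputs = list(bed = bed, fasta = fa)))), "inputs\\$reads")
})
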