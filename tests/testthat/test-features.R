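test_that("translation follows the standard code and rejects broken ORFs", {
  expect_equal(translate_orf("ATGTAA"), "M")
  expect_equal(translate_orf("ATGGTGCTGGAC"), "MVLD")
  expect_error(translate_orf("ATGTA"), "multiple of 3")
  expect_error(translate_orf("ATGTAAGGG"), "internal stop")
  # cross-check against an independent translation of a 63-codon ORF
  set.seed(41)
  nt <- paste0("ATG", filler_codons(62, seed = 41))
  ours <- translate_orf(nt)
  oracle <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  expect_equal(ours, oracle)
  expect_equal(nchar(ours), 63L)
})

test_that("a sequence without ATG has no ORFs", {
  circ <- toy_circle(paste(rep("GCC", 40), collapse = ""))
  expect_equal(nrow(find_orfs(circ, "circular", min_aa = 5)), 0L)
  expect_equal(nrow(find_orfs(circ, "linearized_bsj", min_aa = 5)), 0L)
})

test_that("a junction-crossing ORF needs the circular scan", {
  # 60-aa ORF: ATG + 59 codons + TAA, placed so it straddles position 0
  body <- filler_codons(59, seed = 7)
  orf <- paste0("ATG", body, "TAA")            # 183 nt
  pad <- filler_codons(30, seed = 8)           # 90 nt of ORF-free filler
  # rotate left by 60 so the ORF start lands 60 nt before the junction
  lin <- paste0(orf, pad)
  circ <- toy_circle(circaid:::rotate_str(lin, 60L))
  hits <- find_orfs(circ, "circular", min_aa = 51)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, nchar(lin) - 60L)
  expect_true(hits$crosses_bsj)
  expect_equal(hits$length_aa, 60L)
  expect_true(hits$stop_found)
  # both fragments of the cut string are shorter than 51 aa
  expect_equal(nrow(find_orfs(circ, "linearized_bsj", min_aa = 51)), 0L)
})

test_that("circular ORFs contain every linearized-mode ORF", {
  contains <- function(lin_row, circ_rows, L) {
    any(vapply(seq_len(nrow(circ_rows)), function(i) {
      off <- (lin_row$start - circ_rows$start[i]) %% L
      off %% 3L == 0L &&
        off + 3L * lin_row$length_aa <= 3L * circ_rows$length_aa[i]
    }, logical(1)))
  }
  n_checked <- 0L
  for (s in 1:120) {
    set.seed(600 + s)
    L <- 3L * sample(60:140, 1L)
    circ <- toy_circle(random_seq(L))
    crc <- find_orfs(circ, "circular", min_aa = 15)
    for (mode in c("linearized_bsj", "linearized_adjacent")) {
      lin <- find_orfs(circ, mode, min_aa = 15)
      for (i in seq_len(nrow(lin))) {
        n_checked <- n_checked + 1L
        expect_true(contains(lin[i, ], crc, L))
      }
    }
  }
  expect_gt(n_checked, 50L)
})

test_that("peptide motif scanning matches naive substring search", {
  pep <- paste0("MA", "VLDVGSGTG", "KKK", "VIGIE", "STOP")
  hits <- scan_protein_motifs(pep)
  expect_equal(hits$position[hits$motif_name == "motif_I"], 3L)
  expect_equal(hits$position[hits$motif_name == "post_I"], 15L)
  expect_equal(nrow(scan_protein_motifs(pep, character(0))), 0L)
  expect_error(scan_protein_motifs(pep, c(bad = "")), "empty")
  set.seed(42)
  for (i in 1:20) {
    p <- paste(sample(LETTERS[1:20], 200, replace = TRUE), collapse = "")
    mot <- substr(p, 37, 41)
    naive <- which(vapply(1:(nchar(p) - 4L), function(j)
      substr(p, j, j + 4L) == mot, logical(1)))
    got <- scan_protein_motifs(p, c(m = mot))
    expect_equal(got$position, naive)
  }
})

test_that("seed sites reconstruct the miRNA seed by reverse complement", {
  mir <- c("miR-494-3p" = "UGAAACAUACACGGGAAACCUC")
  target <- paste0(filler_codons(20, seed = 9), "ATGTTTCA",
                   filler_codons(20, seed = 10))
  circ <- toy_circle(target)
  hits <- scan_mirna_sites(circ, mir)
  eight <- hits[hits$site_type == "8mer", ]
  expect_equal(nrow(eight), 1L)
  expect_equal(eight$motif, "AUGUUUCA")
  # reverse complement of the motif (minus the A1) is the seed 2-8
  seed_back <- revcomp(substr(chartr("U", "T", eight$motif), 1, 7))
  expect_equal(seed_back, chartr("U", "T", substr(mir[[1]], 2, 8)))

  # no complementarity: no sites
  none <- scan_mirna_sites(toy_circle(strrep("A", 60)),
                           c(m = "AAAAAAAAAAAAAAAAAAAAAA"))
  expect_equal(nrow(none), 0L)
  expect_error(scan_mirna_sites(circ, c(a = "UGAAACAUAC", a = "UGAAACAUAC")),
               "duplicate")
})

test_that("seed sites spanning the junction are found only by the circular scan", {
  mir <- c(m = "UGAAACAUACACGGGAAACCUC")
  base <- paste0(filler_codons(25, seed = 11), "ATGTTTCA",
                 filler_codons(25, seed = 12))
  # rotate so the 8mer straddles position 0
  site_at <- 76L  # 0-based start of ATGTTTCA in base
  circ <- toy_circle(circaid:::rotate_str(base, site_at + 4L))
  hits <- scan_mirna_sites(circ, mir)
  eight <- hits[hits$site_type == "8mer", ]
  expect_equal(nrow(eight), 1L)
  expect_true(eight$crosses_bsj)
  # a plain linear scan of the cut string cannot see it
  expect_false(grepl("ATGTTTCA", circ$sequence, fixed = TRUE))
})

test_that("DRACH consensus accepts the printed contexts and rejects poly-U", {
  t4 <- table4_fixture()
  for (ctx in unique(t4$context_9mer)) {
    expect_true(circaid:::drach_match(ctx))
  }
  expect_false(circaid:::drach_match("UUUUAUUUU"))  # central A, G absent
  polyU <- toy_circle(strrep("T", 45))
  expect_equal(nrow(scan_m6a(polyU)), 0L)
  # planted context is reported with its RNA 9-mer
  s <- paste0(filler_codons(10, seed = 13), "GAGGACATG",
              filler_codons(10, seed = 14))
  hits <- scan_m6a(toy_circle(s))
  expect_true("GAGGACAUG" %in% hits$context_9mer)
})

test_that("IUPAC motif counts are exact, circular, and shuffle-calibrated", {
  L <- 180L
  circ <- toy_circle(random_seq(L, seed = 15))
  tab <- data.frame(rbp = "any", pattern = "NNNN")
  expect_equal(scan_rbp_motifs(circ, tab)$count, L)

  # plant 14 copies of a 6-mer in a motif-free background
  bg <- gsub("T", "C", random_seq(300, seed = 16))  # no T: TTATTT absent
  pieces <- substring(bg, seq(1, 281, 20), seq(20, 300, 20))
  planted <- paste0(paste0(pieces[1:14], "TTATTT", collapse = ""),
                    pieces[15])
  hits <- scan_rbp_motifs(toy_circle(planted),
                          data.frame(rbp = "x", pattern = "UUAUUU"))
  expect_equal(hits$count, 14L)

  # absent pattern: count 0 and empirical p ~ 1
  set.seed(17)
  none <- scan_rbp_motifs(circ, data.frame(rbp = "no", pattern = "AAAAAAAAAA"),
                          n_shuffle = 30L)
  expect_equal(none$count, 0L)
  expect_equal(none$p_empirical, 1)
  expect_error(scan_rbp_motifs(circ, data.frame(rbp = "bad", pattern = "AXC")),
               "non-nucleotide")

  # dinucleotide shuffle preserves the dinucleotide composition
  set.seed(18)
  chars <- strsplit(random_seq(200), "")[[1]]
  shuf <- circaid:::dinucleotide_shuffle(chars)
  tally <- function(x) {
    t <- table(x)
    stats::setNames(as.integer(t), names(t))[sort(names(t))]
  }
  expect_equal(tally(paste0(shuf[-200], shuf[-1])),
               tally(paste0(chars[-200], chars[-1])))
  expect_equal(tally(shuf), tally(chars))
})
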