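# circaid

Full-length circular RNA (circRNA) annotation from junction-spanning
reads, divergent primer design, and circular feature scanning — in R.

## The problem

circRNAs form by back-splicing: a downstream splice donor joins an
upstream splice acceptor, producing a covalently closed transcript. The
only sequence evidence that separates a circRNA from its host gene's
linear transcripts is the back-splice junction (BSJ), where the 3' end
of the genomically downstream (donor) exon meets the 5' end of the
upstream (acceptor) exon. Full-length circRNA discovery therefore works
by amplifying circular templates with outward-facing (divergent) primer
pairs — which can only converge on a circle — sequencing the amplicons,
and annotating each read against the gene's exon model, accepting a
circle only if the read covers the BSJ.

Real junctions complicate this in two ways that `circaid` treats as
first-class:

- **Truncated exons.** One or both junction-facing exon ends may be
  shortened, creating non-canonical splice boundaries (no intronic
  `GT`/`AG`). The annotator reports retained-length offsets on both
  exons and classifies the splice sites.
- **Junction-overlap ambiguity.** The truncated ends may share an
  identical run of bases (3–8 nt in published inventories), so the
  junction can be placed at `k + 1` equivalent positions yielding the
  same circle. The package reports one deterministic canonical
  placement (ambiguous bases on the donor side) together with `k` and
  the run itself, since the bases cannot be attributed to either exon.

For whom: anyone validating or characterising full-length circRNAs of a
known gene — typically from divergent-PCR amplicon (Sanger) reads — and
anyone needing a seeded, ground-truthed simulator to test such
pipelines.

## What's inside

- `load_gene_model()` / `write_gene_model()` — BED + FASTA in, validated
  exon model (0-based half-open, transcript-oriented) out.
- `sim_config()`, `simulate_gene()`, `simulate_circrna()`,
  `simulate_reads()` — seeded synthetic loci, circles with planted
  truncations and junction homology, rolling-circle reads with
  substitution errors; every planted fact is recorded as ground truth.
- `annotate_read()`, `confirm_and_reconstruct()`, `dedupe_and_catalog()`
  — period collapse, seed-and-extend exon matching, one-backward-step
  chaining, canonical junction placement, junction-evidence
  confirmation, model-based reconstruction, rotation-invariant
  cataloguing.
- `compute_overlap_ambiguity()` — the ambiguity length `k`, the
  identical run, and the `k + 1` equivalent placements.
- `design_divergent_pair()`, `design_second_round()`,
  `predict_amplicon()`, `tm_and_gc()` — divergent and nested/semi-nested
  pairs under length/GC/Tm constraints (nearest-neighbour Tm), with
  perfect-match in-silico PCR on circular or linear templates.
- `find_orfs()`, `translate_orf()`, `scan_protein_motifs()`,
  `scan_mirna_sites()`, `scan_m6a()`, `scan_rbp_motifs()` — circular ORF
  finding (including both linearized cut modes), methyltransferase
  motif scanning, TargetScan-style seed sites, DRACH m6A consensus,
  IUPAC RBP motif counts with dinucleotide-shuffle p-values.
- `run_pipeline()` and a thin CLI (`inst/scripts/circaid`) with
  subcommands `simulate`, `design-primers`, `annotate`, `features`,
  `report`, `pipeline`.

## Worked example

```r
library(circaid)

cfg <- sim_config(seed = 7)
gene <- simulate_gene(cfg)
sim  <- simulate_circrna(gene, cfg)   # circle + ground truth + locus
sim$circ
#> circ_rna simcirc_seed7: 428 nt, 5 segment(s): Exon 2 *, Exon 4, Exon 7, Exon 9, Exon 10 *
#> BSJ: exon 10 (end offset 57, truncated) -> exon 2 (start offset 29, truncated)
#>   splice sites: non_canonical; overlap ambiguity k=5 (GUGCG)

reads <- simulate_reads(sim$circ, 3, cfg)      # 700 nt rolling-circle reads
res   <- annotate_read(reads[[1]], sim$model, read_id = names(reads)[1])
circ  <- confirm_and_reconstruct(res, sim$model)
identical(circ$sequence, sim$truth$sequence)
#> [1] TRUE

compute_overlap_ambiguity(circ$bsj, sim$model)$n_equivalent_placements
#> [1] 6
```

The circle is reported in canonical rotation (starting at the
acceptor's first retained base); `Exon 10 *` marks the truncated donor
whose retained length is 57 nt, and the 5 nt run `GUGCG` flanks both
genomic sides of the junction, so six junction placements produce this
same circle. The reconstruction equals the planted truth because the
read covered the junction and the circle is rebuilt from the model, not
the read.

Summarising a catalog (here, the packaged nine-circle inventory
fixture):

```r
s <- summarize_catalog(table1_fixture())
str(s[c("n_circrnas", "most_frequent_exon", "min_length", "max_length")])
#> List of 4
#>  $ n_circrnas        : int 9
#>  $ most_frequent_exon: int 6
#>  $ min_length        : int 204
#>  $ max_length        : int 551
```

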