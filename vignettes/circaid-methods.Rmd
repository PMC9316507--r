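---
title: "Annotating full-length circRNAs from junction-spanning reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating full-length circRNAs from junction-spanning reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaid)
```

## The problem

Circular RNAs (circRNAs) arise when a downstream splice donor is joined
back to an upstream splice acceptor. The only sequence feature that
distinguishes a circRNA from the linear transcripts of the same gene is
the back-splice junction (BSJ): the point where the 3' end of the
genomically downstream (donor) exon meets the 5' end of the upstream
(acceptor) exon. A practical discovery workflow therefore (i) amplifies
circular templates selectively with outward-facing ("divergent") primer
pairs, which can only converge on a circle, (ii) sequences the amplicons
end to end, and (iii) annotates each read against the host gene's exon
model, accepting a circRNA only when the read demonstrably covers the
BSJ.

`circaid` implements the dry-lab half of this workflow as reusable,
tested components: gene-model I/O, a seeded simulator that serves as
ground truth, the junction annotator, divergent primer design with
in-silico PCR, and circular feature scanners (ORFs, miRNA seed sites,
m6A consensus, RNA-binding-protein motifs).

## Coordinate and sequence conventions

All coordinates are 0-based half-open internally; exon indices are
1-based, matching the way exons are named in gene annotations. Minus
strand input is reverse-complemented once at load; everything
downstream is transcript-oriented and strand-free. Sequences are stored
as uppercase DNA (RNA input is converted U→T); motif output is rendered
back as RNA. Circles are kept in a canonical rotation that starts at
the acceptor's first retained base, which turns rotation-invariant
circle identity into plain string equality.

## The junction annotator

Annotation of one read proceeds in five stages.

1. **Period collapse.** Amplicon reads from rolling-circle reverse
   transcription may traverse the circle several times. The read's
   period is detected by self-overlap (anchor re-occurrence, then
   verification of the full overlap at ≤ 5% mismatches) and the read is
   collapsed to a single period. Because a full period is a rotation of
   the circle, the junction call is rotation-invariant; when a junction
   happens to fall within one anchor length of the period's ends, the
   period is deterministically rotated through a dyadic schedule (1/2,
   1/4, 3/4, 1/8, ... of the period, finest spacing p/32) until every
   junction sits clear of the read ends — the coarse-to-fine order
   resolves the common case in one or two tries, and the finest spacing
   is below the smallest viable placement window any circle from the
   generator's exon-size range can present.
2. **Seed-and-extend matching.** Exact k-mers of `min_anchor` nt
   (default 18) seed gap-free diagonal matches between read and exon
   sequences, extended across single-base mismatches while the match's
   mismatch fraction stays below `max_mismatch_rate` (default 2%). A
   mismatch is only bridged when at least 4 exactly matching bases
   follow it; without this guard the extension drifts across the
   junction on chance matches. Both orientations are scanned and
   flagged.
3. **Chaining.** A dynamic programme selects the chain of matches that
   maximises covered read bases subject to: consecutive segments
   near-adjacent on the read (gap ≤ `gap_tol`, overlap ≤
   `overlap_tol`), and exon indices non-decreasing except for at most
   one backward step — the BSJ candidate. Ties prefer fewer mismatches,
   then fewer segments. Chains covering less than `min_cover_frac`
   (default 90%) of the read are rejected as unannotatable.
4. **Junction placement.** The donor and acceptor matches usually claim
   a few of the same read bases — precisely the junction-overlap
   ambiguity — or, with sequencing errors, leave a small gap. Every
   candidate placement in that window is scored by its mismatches
   against the model on both sides; the best placement wins, with ties
   resolved donor-ward. This makes the reported junction the canonical
   form: ambiguous bases sit at the donor 3' end, and the ambiguity
   length *k* plus the identical run are reported alongside, since the
   run cannot be attributed to either exon on sequence evidence.
5. **Confirmation and reconstruction.** A circRNA is accepted only when
   the chain covers the BSJ with at least `min_flank` nt (default 10)
   of aligned sequence on each side — reads without junction evidence
   are rejected with a reason. The reference circle is reconstructed
   from the *model*, not the read, so sequencing errors never leak into
   the catalog. Identical circles from different reads are merged by
   canonical-rotation string equality.

### Junction-overlap ambiguity

When the retained donor suffix is identical to the genomic bases just
upstream of the retained acceptor start (and/or symmetrically on the
other side), the junction can be slid across k positions without
changing the circular sequence. `compute_overlap_ambiguity()` counts
the identity run, bounded by placements that keep both junction ends
inside their exons — so `k + 1` always equals the number of equivalent
placements, a property the test suite checks against brute-force
enumeration of all placements realising the same cyclic word.

### Parameter defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_anchor` | 18 | nt | long enough that random seeds in a ~3 kb locus are essentially impossible |
| `max_mismatch_rate` | 0.02 | fraction | an order of magnitude above Sanger-like error rates |
| `gap_tol` | 12 | nt | clustered substitutions leave unaligned patches of 5–10 nt; 12 bridges them yet stays well below `min_anchor`, so no junction can be fabricated from a gap |
| `overlap_tol` | 12 | nt | accommodates junction ambiguity (≤ 8 nt observed) plus edge noise |
| `min_cover_frac` | 0.9 | fraction | full-length amplicon reads should align almost entirely |
| `min_flank` | 10 | nt | minimum credible junction evidence per side |

All are exposed via `annot_params()`.

## The simulator as ground truth

`simulate_gene()` builds a single-gene locus with canonical `GT...AG`
introns and non-genic flanks; `simulate_circrna()` picks 2–6 exons,
truncates the two junction-facing ends with probability 0.8 each
(truncation length 1–30 nt), and plants junction homology of 3–8 nt in
two thirds of circles; `simulate_reads()` emits rolling-circle reads
(default 700 nt) with i.i.d. substitutions (default 0.1%). The same
seed always yields byte-identical output.

Defaults are chosen to emulate the conditions under which full-length
circRNA discovery by divergent PCR and Sanger sequencing operates: exon
lengths 80–110 nt make 2–6-exon circles span roughly 100–660 nt,
bracketing the 204–551 nt range of published full-length inventories,
and guaranteeing that a 700 nt read traverses any circle completely.
Truncation and homology frequencies mirror the published inventory (15
of 18 junction ends truncated; 6 of 9 circles with a 3–8 nt
junction-overlap run).

Homology planting edits the *gene* sequence — the bases upstream of the
acceptor's retained start are made identical to the retained donor
suffix — because the ambiguity is a genomic property that the annotator
must face on the same locus. The planted run is placed entirely within
the exons (the acceptor is truncated at least k nt when homology is
planted, matching the observation that such runs lie inside exonic
sequence), and the two bases that would extend the run are forced to
mismatch, so the planted k is exact and the recorded truth offsets are
already in canonical (donor-ward) form.

What the simulator does *not* emulate: indels and quality-correlated
errors of real chromatograms (substitution-only by design —
base-called amplicon reads are indel-poor), chimeric PCR artefacts,
genomic repeats shared between exons, and expression-level variation.
Passing tests therefore demonstrate algorithmic correctness under
clean, known truth, not performance on arbitrary real data.

## Divergent primers and in-silico PCR

`design_divergent_pair()` places a reverse primer wholly before a
forward primer on one exon, both facing outward, so the pair cannot
converge on the linear gene. Candidates must satisfy length 18–25 nt,
GC 40–60%, and Tm 57–63 °C (nearest-neighbour model, unified
dinucleotide parameters, entropy salt correction at 50 mM Na+ and
400 nM primer; a Wallace-rule estimate is available as a flag), must
occur exactly once in the gene on either strand, and the pair with the
best Tm balance wins. The second round is `nested` (both primers
strictly interior to the first-round product) or `semi_nested` (exactly
one primer reused). `predict_amplicon()` performs perfect-match
in-silico PCR on the doubled circle and reports the shortest
single-period product; on a linear template a divergent pair yields
nothing, which is the specificity property the tests assert across 100
seeded loci. Mismatch-tolerant binding and dimer/hairpin screening are
out of scope.

## Circular feature scanning

*ORFs.* Linear ORF tools force a cut; the package reproduces both cut
choices (`linearized_bsj` at the junction, `linearized_adjacent` at the
neighbouring splice site) and contrasts them with a genuinely circular
scan of the doubled sequence, where starts are reported in `[0, L)`,
translation runs across the junction, and ORFs that meet no stop within
one extra full period are capped at L/3 codons with `stop_found =
FALSE`. ORFs start at ATG and must encode at least 51 amino acids
("more than 50", stop excluded); within a frame, the first ATG after
the previous stop opens the reported ORF. The circular scan provably
dominates both linearizations — every linearized ORF is contained in a
circular one — and a junction-crossing ORF is found only by the
circular scan; both properties are exercised in the tests.

*miRNA seed sites.* Canonical seed classes on the target strand: 8mer
(reverse complement of miRNA positions 2–8 followed by A opposite
position 1), 7mer-m8, 7mer-A1. Each seed anchor is reported once with
its strongest class; sites spanning the junction are flagged. Scores of
external prediction databases are intentionally not reproduced — only
the motif arithmetic.

*m6A.* A DRACH consensus scan (D∈{A,G,U}, R∈{A,G}, H∈{A,C,U}) stands in
for learned m6A models, whose parameters are not reproducible from
printed output; the scanner checks the consensus membership of printed
site contexts and reports 9-mer RNA contexts circularly.

*RBP motifs.* IUPAC patterns are counted circularly (via
`Biostrings::matchPattern`), with an optional empirical p-value against
dinucleotide-preserving shuffles (Altschul–Erickson Eulerian-walk
shuffle); weighted-rank scores of external tools are out of scope.

Because the canonical rotation carries the ambiguous junction bases
exactly once, circular scanners never double-count them.

## Numerical and degenerate-input choices

Single-exon circles are supported (donor equals acceptor; the junction
offsets delimit one segment). Circles shorter than one codon are
rejected by the ORF finder; primers require exons of at least twice the
minimum primer length, and infeasible design constraints fail with the
violated constraint named. Catalog deduplication uses a
minimal-rotation key on top of the canonical rotation as a guard.
Reads shorter than `min_anchor` are rejected outright. All random
draws flow from a single integer seed per configuration; the RNG state
of the caller is restored after every simulation call.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on simulated
loci: 200 error-free round trips, 1000 junction-spanning reads at 0.5%
substitution noise, 500 (tests) / 200 (script) ambiguity-oracle
comparisons, 500 random circles for the ORF dominance law, and 100
seeded genes for primer specificity. These sizes keep the whole suite
in the low minutes on a single core while leaving the stochastic
acceptance margins far from their thresholds.

## Known limitations

- Exonic circles only: intron-retaining circRNAs are not modelled, and
  the annotator will reject reads whose circles include intronic
  sequence.
- Substitution-only alignment: indel-containing reads break the
  diagonal matching assumption and are typically rejected rather than
  rescued.
- Perfect-match in-silico PCR: primer binding with mismatches (and
  hence cross-amplification risk) is not modelled.
- Single-gene scope: the gene model holds one locus; multi-gene or
  genome-wide discovery is out of scope.
- The feature scanners are motif-level re-implementations; they do not
  reproduce the numerical scores of external prediction services.
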