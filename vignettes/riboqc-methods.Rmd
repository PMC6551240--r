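---
title: "riboqc: methods and design notes"
output: html_document
vignette: >
  %\VignetteIndexEntry{riboqc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design decisions behind
`riboqc`, in the spirit of a methods section: what each quantity means, which
choices were genuinely open and how they were resolved, and what the built-in
simulator does and does not emulate.

## The data model

Ribosome profiling reads are ~26–32 nt fragments of mRNA protected by a
translating ribosome. The ribosome's P-site — the codon being decoded — sits a
fixed, length-dependent distance downstream of the fragment's 5' end, so the
first analysis step is to shift every read 5' end by a per-length **P-site
offset**. All downstream metrics are computed on these adjusted positions.

`riboqc` represents each alignment as one row of an attribute table:
chromosome, genomic range, strand, sample, experiment type, read length, gene,
feature, P-site position, `start_dist` (transcript 5' end to P-site, spliced
coordinates), `end_dist` (P-site to the first nucleotide of the stop codon),
GC fraction, MAPQ and reading frame. Every tool downstream is a tally or
ratio over this table, which is why the table supports filtering and grouping
by any attribute.

Coordinate conventions: internally everything is 0-based half-open; 1-based
BAM/GFF inputs are converted exactly once at the parsing boundary. Transcript
coordinates are spliced (introns removed), position 0 being the first
transcribed nucleotide. `genomic_to_transcript()` and
`transcript_to_genomic()` are mutually inverse on exonic positions, which the
test suite verifies against a base-by-base walking oracle on random
multi-exon transcripts of both strands.

## Choices the annotation forces

**Major isoform.** Frames and distances need one transcript per gene. The rule
is: the coding transcript with the longest CDS; ties broken by longest spliced
length, then by lexicographically smallest transcript id. This is
deterministic, independent of record order in the annotation file, and matches
the common "representative isoform" convention. It is a tool decision — no
widely agreed standard exists.

**Feature priority.** A position usually overlaps nested records (gene → mRNA
→ exon → CDS). The most specific label wins: CDS > five_prime_UTR >
three_prime_UTR > exon > mRNA/transcript > gene. Non-coding RNA classes
(rRNA, tRNA, sn/sno/miRNA) outrank protein-coding labels at the same position
because contamination must stay visible in QC. Reads are assigned only to
same-strand features; opposite-strand overlap yields `Other`, since
footprints are strand-specific.

**Stop-codon convention.** GFF3 CDS records include the stop codon; GTF CDS
records exclude it and may carry separate `stop_codon` rows, which are merged
into the CDS span when present. In both dialects `cds_stop_t` is the first
nucleotide of the stop codon, so `end_dist = 0` means "P-site on the stop
codon" regardless of input dialect. The test suite renders one simulated locus
set in both dialects and requires identical parsed structures.

**Frame anchor.** The reading frame is anchored at the **translation start
codon** of the major isoform: `frame = (tpos − cds_start) mod 3`. An
alternative anchor at the transcript 5' end (`frame_anchor = "tss"`) is
available because the two anchors differ by `cds_start mod 3` and some
workflows quote the transcription-start-anchored register; the start codon is
the default because triplet periodicity is a property of translation.
Reads whose P-site falls outside the major isoform's spliced transcript
(introns, intergenic, non-coding genes) get frame `none` and absent
distances.

## P-site offset inference

For each read length, `start_anchored_density()` tallies **unadjusted 5'
ends** relative to the start codons of all major isoforms (window default
[−40, +20] nt — wide enough to contain the initiating footprint for all
lengths in use, narrow enough to stay start-specific). The offset is the
distance from the largest in-frame upstream peak to the start site.

Two details deserve explanation:

* **"In frame"** is interpreted via the trinucleotide register: footprint 5'
  ends of one length recur every 3 nt in a single register (shifted from the
  codon register by the offset itself). Candidates are therefore the upstream
  positions in the register carrying the most upstream density; within that
  register the tallest peak wins, ties resolving to the smaller offset. A
  literal "positions ≡ 0 mod 3" candidate set would make odd offsets (11, 13
  — both common in real data) unrecoverable by construction.
* **Candidates are bounded by the read length** (`offset ≤ length`), since the
  P-site must lie inside the read. This also guarantees the offset-table
  invariant `0 ≤ offset ≤ length`.

Lengths with fewer than `min_reads = 50` reads in the window, or with an
empty upstream density, fall back to the canonical eukaryotic offset of 12 nt
and are flagged (`fallback_used`) in the diagnostics. A fixed user-supplied
offset table can bypass inference entirely.

## QC metrics

* **Periodicity**: fractions of CDS-mapped P-sites in frames 0/1/2; f0 is the
  headline metric. Frame fractions sum to 1 by construction.
* **Complexity / duplication**: the fraction of distinct alignment tuples
  (chromosome, strand, start, length) among all alignments, and its
  complement. These names are used loosely in the field; this definition was
  chosen because it is computable from a BAM alone and proxies library
  diversity. Note that biological pileups (e.g. initiation peaks) inflate
  duplication beyond the PCR duplication rate — visible in the simulator,
  where measured duplication exceeds the duplication knob on footprint
  libraries but matches it on uniformly placed RNA-seq reads.
* **RPKM**: `count × 10⁹ / (total mapped reads × gene length)` with gene
  length the major isoform's spliced length and a read counted for the gene
  its P-site was assigned to (RNA-seq reads use offset 0, i.e. their 5' end).
  RPKM is invariant under whole-sample duplication, which is tested.
* **Translational efficiency**: `(RPKM_ribo + pc) / (RPKM_rna + pc)` with
  pseudocount 0 by default; genes with zero RNA-seq signal are returned as
  undefined rather than infinite. The ratio-of-RPKM form is the minimal
  standard definition; no attempt is made at statistical testing of
  differential translation, which belongs to count-model machinery outside
  this package's scope.
* **Metagene profiles** aggregate P-sites across all major isoforms relative
  to start or stop. Optional subsampling is uniform without replacement under
  a caller-fixed seed, so profiles are bit-for-bit reproducible and a
  subsample the size of the table is exactly the identity.

## Anomaly detection

Four independent strategies over the per-sample summary metrics:

1. **Expert thresholds** — defaults: in-frame fraction ≥ 0.50, CDS ≥ 50%,
   rRNA ≤ 20%, tRNA ≤ 10%. These are deliberately permissive tool defaults
   (clearly below what a good library achieves), configurable per metric with
   `min`/`max` direction semantics.
2. **Tukey's fence across the user's samples** — flag outside
   [Q1 − 1.5·IQR, Q3 + 1.5·IQR]. Quartiles use linear interpolation (R's
   default type 7), the fence multiplier is 1.5, and values exactly on a
   fence are *not* flagged; all three choices are conventions fixed for
   determinism and verified against a brute-force oracle. Requires ≥ 4
   samples, otherwise skipped with a warning.
3. **Percent error against controls** — `|observed − control| / |control|`
   with a 25% threshold, strictly exceeded; multiple controls are summarised
   by their mean; metrics with control mean 0 are skipped with a warning.
4. **Reference fences** — strategy 2's fences computed from a reference
   metric table (a TSV of summary rows from known good samples) instead of
   the user's own samples. The package ships no curated reference data;
   `reference_metrics_fixture()` builds a synthetic good-quality reference by
   running the full pipeline on simulated libraries, and any user TSV with
   the summary schema can be supplied instead.

## The simulator: what it does and does not emulate

`sim_spec()` defaults describe a good-quality eukaryotic footprinting library
and are the study conditions under which the package's recovery properties
are tested: 20 genes (ATG…TAA CDS of 100–200 codons, 60–120 nt UTRs, ~30%
multi-exon), read lengths 27/28/29 at probabilities 0.25/0.5/0.25 with true
offsets 11/12/13 nt, in-frame fraction 0.7 (remainder split evenly over
frames 1 and 2), 10% start-codon pileup, 5% rRNA and 2% tRNA contamination,
10% duplication, 85% uniquely mapped (MAPQ 50 vs 1), 3000 reads per sample.
Reads are written as aligned, coordinate-sorted, indexed BAM — the platform
starts at aligned reads, so no fastq/mapping simulation is attempted.
Multi-mapping is emulated purely through MAPQ values.

The simulator deliberately omits: sequencing errors and base qualities, UTR
and stop-codon ribosome occupancy structure beyond the start pileup, codon-
level dwell-time variation, splice-junction-spanning contamination, and
paired-end layouts. Passing recovery tests therefore demonstrates the
*correctness of the estimators on data satisfying their assumptions*, not
robustness to every artifact of real libraries.

## Numerical and degenerate-input behavior

* Empty BAM: empty table with a warning, not an error; empty annotation file:
  an error. Chromosome names in the annotation must be a subset of the FASTA's.
* Offset inference ties: equal register mass → the register holding the
  tallest single peak, then the peak nearest the start; equal peak heights →
  the smaller offset.
* Percentages are exact rational tallies (sums verified to 1e−9 before any
  rounding); no smoothing is applied anywhere.
* All stochastic steps (subsampling, simulation) run under locally scoped
  seeds (`withr::with_seed`), never mutating the caller's RNG state.

## Problem sizes in the test suite

The suite exercises studies of 1.2k–6k reads over 8–20 genes for estimator
recovery (binomial 3σ tolerances) and one 50k-read three-sample study for the
byte-identical reproducibility check — sizes chosen so the full suite runs in
about a minute while keeping every per-length bin far above the inference
support threshold. Recovery assertions use the generator's own parameters;
none of the tolerances were tuned to observed outcomes.

## Known limitations

* One offset per read length per sample; no per-gene or A/E-site offsets.
* No soft-clip-aware micro-adjustment of the 5' end; the retention rule keeps
  primary, mapped, non-supplementary alignments only; no UMI handling.
* Differential translation testing (fold-change significance) is out of
  scope; the package stops at RPKM, fold-change inputs and TE.
* The genome sequence is validated but not held per-base in memory beyond
  what Bioconductor's FASTA readers do; extremely large genomes are untested
  territory for the simulator (not for the QC path, which is interval-based).
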