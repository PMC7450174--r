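---
title: "Methods: isoform-level alternative splicing analysis with isoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform-level alternative splicing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoscope)
```

# Overview

`isoscope` re-implements, as one tested toolchain, the isoform-level
analyses that follow reference-guided transcript assembly in a
jasmonate-response RNA-seq study design: filtering of candidate
transcript models, classification of alternative-splicing (AS) events
between isoforms, prediction of nonsense-mediated decay (NMD) targets,
detection of AS-coupled miRNA target sites, projection of protein
domains between isoforms, validation of AS isoforms from
junction-spanning peptides, and a differential isoform-usage statistic.
Read mapping and transcript assembly are upstream of the package: its
inputs are gene models (GTF/GFF3), a genome (FASTA), pooled
splice-junction counts (BED6), per-base coverage (bedGraph), an
isoform abundance table (TSV), mature miRNA sequences (FASTA) and a
peptide-confidence table (TSV).

All internal coordinates are 0-based and half-open on an explicit
strand; GTF/GFF3 input and output convert from and to the 1-based
inclusive file convention. Minus-strand transcripts store exons in
genomic order and derive transcript (5'→3') order from the strand, so
there is a single source of truth for coordinates.

# Transcript-set filtering

Three filters act on a candidate transcript set, mirroring common
assembly post-processing:

* **Junction support** (`junction_support_filter`): a transcript is
  kept only if every one of its introns is supported by at least 3
  reads in the pooled junction table. Single-exon transcripts pass
  vacuously; a missing junction record counts as zero support and is
  reported. The filter is applied to the pooled table rather than per
  library: per-library semantics cannot be reconstructed from a merged
  junction file, and pooling is the permissive reading.
* **Intron-retention coverage** (`ir_coverage_filter`): over the
  retained intron of an IR event, the covered fraction is the fraction
  of bases with depth ≥ 1 ("covered" is deliberately the minimal
  definition) and the mean depth is taken over the whole region. The
  tiers are read as half-open bands: mean depth ≥ 4 at 100% coverage,
  ≥ 5 at [90%, 100%), ≥ 6 at [80%, 90%), and rejection below 80%.
  Interpolation between the three stated points was rejected as
  under-determined.
* **Abundance floor** (`abundance_floor_filter`): a transcript is kept
  if its maximum abundance over all samples is at least 5 (FPKM-like
  units). The maximum is used because the floor is conceptually applied
  at merge time, where anything expressed somewhere survives.

All three are monotone (more reads or deeper coverage can only help),
and their composition is an intersection of survivors, so filter order is
irrelevant. Intron length bounds (minimum 20 nt, maximum 8,000 nt) are
configuration values checked at parse time; violations are flags on the
model, not errors, keeping parsing separate from filtering policy.

# AS event classification

Events are defined pairwise between two isoforms of one gene and then
deduplicated by `(type, region)` across all pairs
(`classify_pair`, `classify_gene`). A full splicing-graph code scheme
was considered and rejected: only the event-type labels are consumed
downstream, and the pairwise definition is independently testable
against a brute-force per-base oracle.

The genome is segmented at all exon boundaries of the two isoforms;
maximal runs where exactly one isoform is exonic are the elementary
differences. Runs not separated by a *shared splice site* (a position
that is an intron start in both isoforms, or an intron end in both)
belong to one event. Each event is then typed from the membership of
its flanking bases, strand-aware (donor/acceptor and first/last follow
transcript orientation, never genomic left/right):

| flanks (both isoforms) | type | alternative region |
|---|---|---|
| exonic / exonic | IR | the retained intron |
| intronic / intronic | ES | the skipped exon |
| intronic / exonic | AltA on `+`, AltD on `-` | span between the two sites |
| exonic / intronic | AltD on `+`, AltA on `-` | span between the two sites |
| reaches the 5' terminus | AltFirst | the non-shared terminal spans |
| reaches the 3' terminus | AltLast | the non-shared terminal spans |

Anything that fits no single template — multi-run internal events,
mixed ownership, events touching both termini — is labeled `Complex`
and never force-fit. Terminal-exon variants are kept distinct from
AltA/AltD; analyses that lump terminal events into acceptor/donor
categories will count relative proportions differently, and the mapping
is one relabeling away. Mutually-exclusive-exon detection is out of
scope (its pairwise signature here is `Complex`).

# ORF prediction and NMD rules

`find_orf` scans the three forward frames of the mature transcript for
complete `ATG…stop` spans, keeping one candidate per (frame, stop): the
span from the 5'-most ATG after the previous stop. The longest
candidate of at least `min_len_aa` residues (default 100, the common
ORF-prediction convention) is returned. The prediction is `ambiguous`
when two candidates tie, or when the runner-up reaches
`ambiguity_ratio` times the top length; the exclusion of transcripts
with no or ambiguous ORF predictions mirrors standard practice. There
is no quantitative published definition of "multiple ORF predictions",
so the tie/ratio rule is this package's, surfaced in configuration with
a default of exact ties only. Homology evidence integration and
reverse-strand scanning are deliberately absent: transcripts are
already stranded, and domain/BLAST support is an input elsewhere, not
here.

`nmd_call` applies two rules, both strict inequalities, measured 5'→3'
in transcript coordinates from the first base of the stop codon:

* rule (a): 3'UTR length > 350 nt;
* rule (b): distance from the stop codon to the last exon–exon
  junction > 55 nt (negative when the stop lies in the last exon;
  undefined for single-exon transcripts, which can only trigger
  rule (a)).

Measuring from the first base of the stop codon matches the standard
"50–55 nt" exon-junction-complex convention.

# Domain projection

`project_domains` maps each primary-isoform domain codon through the
genome into a variant isoform. A codon survives *in frame* when its
three bases are exonic in the variant, consecutive in variant
transcript order, inside the variant CDS, and aligned to the variant
codon grid. Domains with all codons in frame are `retained`; with at
least half, `truncated`; below half (the boundary is configurable),
`lost` — frame-shifted domains lose every codon and are always `lost`.
`novel_isoform_screen` flags a variant when it retains at least one
domain and its ordered `(name, status)` arrangement differs from the
primary's: the pattern of a repressor-like isoform that keeps a
dimerization domain but loses its DNA-binding region.

# miRNA target sites and AS coupling

Published plant target-prediction servers do not print their scoring
internals, so `scan_targets` defines a transparent stand-in with the
same decision structure: slide the reversed miRNA along the transcript;
score each duplex position 0 for a Watson–Crick pair, 0.5 for a G:U
wobble, 1 for a mismatch (gaps disallowed); double penalties in the
seed (miRNA positions 2–13); report sites with total expectation at or
below 5. All constants live in `mirna_config`. Overlapping hits of one
miRNA keep the lowest penalty, ties resolved 5'-most.

`coupled_as_mirna` calls a (gene, miRNA) pair *AS-coupled* when an
equivalent site — same miRNA, overlapping genomic projection — is
present in at least one isoform, absent in at least one, and the
projection intersects an event's alternative region. Equivalence by
genomic projection, not transcript offsets, because isoforms shift
transcript coordinates. Overlap (rather than containment) with the
alternative region is used; a site gained at a region boundary is still
a splicing-dependent site. Genes with two distinct miRNAs on one
transcript get a `multi_site` flag.

# Junction-spanning peptide validation

Three criteria form a pure filter chain (`validate_isoforms`): keep
peptides with confidence ≥ 0.95 (the boundary passes); map by exact
substring against the predicted proteome and discard peptides hitting
two or more genes (I/L equivalence is off by default — exact matching
is the strictest reading); and accept a peptide as evidence for an
(event, isoform) pair only when its mapped interval covers a boundary
of the event's alternative region with at least one complete residue on
each side. The original screen involved a manual validation step; the
explicit overhang rule replaces it and is reported as such. The
boundary position inside an isoform is defined as the number of that
isoform's transcript bases 5' of the genomic boundary, which addresses
both the exon–exon junction of the isoform that splices a region out
and the exon–intron boundary of the isoform that retains it.

# Differential isoform usage

The upstream study used an assembly-suite differential test whose
internal statistic is not restated in its methods; this package defines
a documented, testable replacement with the same decision structure.
Per sample, isoform proportions are abundances over their gene total,
with all-zero samples excluded and flagged rather than renormalized.
The per-gene statistic is the square root of the Jensen–Shannon
divergence (base-2) between the two conditions' mean proportion
vectors — means of per-replicate proportions, so replicate variance
enters the null. The null distribution permutes replicate labels:
exhaustively over all distinct non-identity assignments when there are
at most `n_perm` of them, otherwise sampling `n_perm` without
replacement, and `p = (1 + #{null ≥ observed}) / (1 + #permutations)`.
q-values are Benjamini–Hochberg across genes.

With 3v3 replicates there are 19 non-identity assignments, so the
formula's floor is 1/20; moreover the statistic is symmetric under
swapping the two groups, so the observed value's mirror assignment
always ties it and the smallest p that can occur is 2/20 = 0.1. The
test is exact at multiples of 0.1 and reports `min_attainable_p`
alongside q so this resolution limit is never silent. No individual
gene can reach p < 0.1 from a 3v3 contrast; claims at stricter levels
need more replicates or pooled contrasts.

`expression_ratio_matrix` exports treated/control mean-abundance ratios
(log2 column included) for heatmap-style reporting, with an optional
pseudo-abundance (default 0) added to both means.

# The synthetic study generator

`simulate_study` generates the full input suite with planted ground
truth, emulating the study layout: 3 genotypes (wild type and two
mutants) × 2 tissues × control/treatment × 3 replicates. Each locus
lives on its own contig and is built in "logical" coordinates with the
transcript 5' end on the left; minus-strand loci are produced by
reflecting the finished layout and reverse-complementing the contig, so
the planting code is strand-free while consumers see genuine
minus-strand geometry.

Every planted event type occupies its own slot in the gene (alternative
first exon and skippable exon in the 5'UTR, donor shift on a 5'UTR
intron, retained intron inside the CDS, acceptor shift and alternative
last exon in the 3'UTR), and any two slots are separated by at least
one splice site shared by every isoform. Isoforms form a chain —
isoform *k*+1 carries the first *k* events — which makes the set of
pairwise differences across all isoform pairs exactly the planted
events, so classifier recovery can be asserted as set equality.

The coding design pins the remaining truth:

* 5'UTR sequence is generated ATG-free, and every 5'UTR piece starts
  with `C` and ends with `CC`, so no concatenation of pieces across any
  isoform's junctions can create a start codon;
* the CDS is long (≈ 900 nt before the retained-intron slot) so that no
  spurious ORF can outgrow the planted one by chance;
* retained introns are 160–180 nt: long enough that a premature stop
  inside them leaves a 3'UTR over 350 nt (a planted NMD positive),
  short enough to host no competing ORF, and they carry an engineered
  in-frame stop plus a lysine placed so that a tryptic peptide spans
  the exon/retained-intron boundary with ≥ 4 residues on each side;
* primary isoforms keep their stop within 55 nt of the last junction
  and a 3'UTR under 350 nt, so only intron-retaining isoforms are NMD
  positives;
* planted miRNA sites are exact reverse complements of random 21-nt
  miRNAs written either into a retained intron (alternative-region
  sites, present only in retaining isoforms) or into the shared
  terminal 3'UTR (fully shared sites); unplanted miRNAs are decoys;
* the peptide table mixes engineered junction peptides, non-junction
  decoys sampled away from every event boundary, and ambiguous peptides
  copied in-frame into a second gene's first coding exon between
  engineered K/G flanks; a configurable fraction of confidences falls
  below 0.95.

Noise models are the package's own choice — the study reports none:
replicate abundances are log-normal around condition means (σ = 0.25),
pooled junction supports are Poisson with mean depth × summed
proportion of supporting isoforms, and coverage is Poisson around the
isoform-mixture depth. Differential loci shift a proportion mass of
`delta` (default 0.3) from the primary to the second isoform under
treatment. Default depth is 20, roughly the regime where a real
junction filter at 3 reads starts to bite minor isoforms.

What the generator does *not* emulate — and therefore what passing
tests do not show about real data: alignment and assembly artifacts
(soft-clipping, misassembled boundaries, fragmented transcripts),
shared exons between neighboring genes, sequence-composition biases,
homologous gene families (peptide ambiguity is planted, not emergent),
imperfect miRNA sites with bulges, spectrum-level peptide error, and
library-size or batch effects. Tests on this generator establish
algorithmic correctness against a known truth, not robustness to those
artifacts.

Determinism: every generator draws from its own seeded stream without
touching the caller's RNG state; identical seeds give byte-identical
outputs.

# Problem sizes and verification

The test suite verifies the classifier against an independent per-base
brute-force oracle on 1,000 randomized two-isoform loci (≤ 6 exons),
recovers 100% of planted events and NMD flags on a 500-locus study
covering all six event types, round-trips planted miRNA sites and
junction peptides on the same study, and checks the permutation test's
calibration on 500 null loci. The worked analysis under `analysis/`
uses a 120-locus study; `scripts/acceptance.R` re-derives its summary
quantities on 200 loci. These sizes were chosen so each property is
measured with comfortable Monte-Carlo margins while the whole suite
stays quick to run.

# Known limitations

* `Complex` events are detected but not subtyped; mutually exclusive
  exons land there by design.
* The 3v3 permutation floor means the differential test cannot reach
  p < 0.1 on a single within-condition contrast (see above).
* ORF prediction ignores homology evidence and non-ATG starts, and
  requires a complete stop codon inside the transcript.
* Peptide mapping is exact-substring; modified residues or I/L
  ambiguity need the configurable equivalence switched on.
* The IR coverage filter evaluates IR regions against a single pooled
  coverage track, matching the pooled junction filter.
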