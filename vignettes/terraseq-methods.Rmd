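---
title: "terraseq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{terraseq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

Telomeric repeat-containing RNA (TERRA) is a long noncoding RNA
transcribed from subtelomeric promoters into the telomeric UUAGGG
repeat. terraseq implements the full desk-side analysis stack for TERRA:
repeat-tract detection in assemblies and long reads, transcription-region
annotation, region-based quantification, cross-sample normalization and
poly(A) partition analysis, together with a seeded simulator that plants
every quantity the other modules estimate.

TERRA transcription regions come in three classes. Type I regions sit at
chromosome ends and carry at least one of the three subtelomeric tandem
repeat element families of 61, 29 and 37 bp at their promoter; Type II
regions sit at chromosome ends but lack all three; Type III regions arise
from interstitial telomeric sequences (ITS), telomere-like tracts away
from chromosome ends. A region runs from its transcription start site
(TSS) to the distal edge of its telomeric tract and is partitioned into a
subtelomeric interval (unique sequence) and the telomeric tract itself.

# Repeat-tract detection

Tracts are called by exact-hexamer chaining: all exact occurrences of the
repeat unit (default `TTAGGG`; its reverse complement for the opposite
orientation) are collected, reduced to a non-overlapping set
left-to-right, and consecutive occurrences at most `maxGap` bp apart are
chained. A chain is reported when its span reaches `minTract` bp and its
purity — the fraction of the span covered by exact copies,
$6 n_\mathrm{units} / \mathrm{span}$ — reaches `minPurity`. Boundaries
are trimmed to the outermost exact match, so a pure planted tract is
recovered at base precision. `N` bases never match and count against
purity. Degenerate variant repeats (TGAGGG, TCAGGG, ...) are not matched
unless supplied via `motifSet`: genome scans target canonical repeats.

Parameter defaults, with rationale:

* **Genome scans**: `minTract = 200` (the conventional floor for calling
  an ITS), `maxGap = 24` (four motif units; bridges short interruptions
  without fusing unrelated runs), `minPurity = 0.8`. These are
  calibration choices, exposed in the configuration; at full assembly
  scale the ITS count is sensitive to `maxGap`/`minPurity` and a
  sensitivity sweep is recommended when comparing against published
  counts.
* **Read measurement** (`measureReadTract`): `minTract = 24`,
  `maxGap = 48`, `minPurity = 0.5`. At a total read error of ~8%
  (substitution + indel, the realistic direct-RNA regime) the probability
  that a hexamer window survives error-free is about $0.92^6 \approx
  0.61$, so the exact-match purity of an all-telomeric read concentrates
  around 0.60-0.70 (10th percentile ≈ 0.57). A floor of 0.5 keeps those
  chains while remaining unreachable by chance hits: two isolated random
  hexamers within one `maxGap` are needed to reach purity 0.5 at the
  24 bp minimum span, an event with negligible probability in
  non-telomeric sequence. With this setting the simulator's 8%-error
  reads yield a mean absolute tract-length error of ~2% of the planted
  length; error-free reads are recovered exactly because planted tract
  lengths are whole motif units.

Terminal/interstitial classification: on each sequence the tract nearest
coordinate 1 is `terminal_p` if it starts within `endWindow` (default
100 kb, the span of chromosome-end TERRA territory) of the start, the
tract nearest the other end `terminal_q` symmetrically; everything else
is interstitial. Distance ties go to the longer tract.

# Promoter elements

The 61/29/37 bp element families have no universal printed consensus;
real analyses should supply per-genome consensuses as FASTA
(`readElementConsensuses`). The package ships fixed *synthetic* stand-in
consensuses (`elementConsensuses`, also in
`inst/extdata/synthetic_element_consensuses.fa`) that make the simulator
and tests self-contained; they share no sequence with the real families
and are free of telomeric hexamers.

Array detection slides the consensus over both strands allowing
substitutions and single-base indels (edit distance at most
$\lfloor (1-\texttt{minIdentity}) L \rfloor$), resolves overlapping hits
best-identity-first, and chains hits whose start-to-start spacing is at
most 1.5 element lengths. Arrays need `minCopies` (default 2) copies —
the minimum that distinguishes a tandem array from a lone hit; the
threshold is exposed because scoring promoter content at single-copy
resolution is equally defensible. `minIdentity` defaults to 0.8 since
subtelomeric elements diverge between arms. Raising `minIdentity` can in
principle split an array whose interior copy drops below threshold into
two arrays; under edge-degraded arrays (the common real pattern) the
array count is monotone in the threshold, and the tests exercise exactly
that regime.

The promoter signature of a region scores, over the 3 kb window upstream
of the TSS (oriented with transcription), which element families overlap
by at least 1 bp. Any non-empty signature supports Type I.

# Region calling

Published TERRA region sets were assigned by expert inspection of three
evidence tracks; terraseq makes that rule algorithmic. For each
classified tract the `endWindow` on the transcription-upstream side is
searched for:

1. a contiguous run of log2 capture/control enrichment bins at or above
   `enrThreshold` (default 1, i.e. 2-fold — the paper-style heatmaps use
   log2 enrichment but print no cutoff, so this default is a design
   choice) that reaches the tract (within one bin);
2. long-read 5' ends (after unique-read filtering) on the region strand;
3. CAGE tag clusters (single-linkage within 50 bp, modal peak) on the
   region strand.

At least `minEvidence` (default 2 of 3) classes must be present,
mirroring the triple-evidence spirit while staying automatic; arms that
fail are reported as TERRA-free. The TSS is placed with precedence CAGE
> long-read 5' ends > enrichment-run boundary. "Nearest CAGE peak
upstream of the run boundary" is implemented as nearest peak to the
boundary with ties preferring the upstream side, because the run boundary
is only bin-resolution (30 bp) and a genuine TSS peak can fall one bin
inside the run. A second, telomere-distal enriched run with its own CAGE
or 5'-end support yields a second region (`tss_rank = "distal"`),
capturing arms with two TSSs. Candidate regions under 200 bp are
discarded as noise and regions are clipped to sequence bounds.

Strand convention: a q-arm region lies on the strand where TTAGGG reads
toward increasing coordinates, a p-arm region on the opposite strand;
ITS regions take the G-rich tract orientation, and their search window
is placed on the 5' flank that orientation implies.

Coverage enrichment is computed per 30 bp bin as
$\log_2((c + p)/(k + p))$ with pseudocount $p = 1$ by default (the
upstream tools' internal stabilizer is undocumented, so the value is a
configuration choice).

# Quantification

Counting semantics follow region-extraction practice: a read pair is one
fragment (union of mate reference spans; orientation taken from the
first-in-pair mate), a fragment overlapping a feature by at least 1 bp
counts, and a fragment overlapping several features counts once per
feature (nonunique-all). Three modes:

* `arm_specific` — MAPQ ≥ 30 (paired) or MAPQ = 255 (the single-end
  unique-mapping convention of the common spliced aligner); only
  subtelomeric sub-intervals are counted, because only uniquely mappable
  subtelomeric sequence identifies the arm.
* `total` — primary alignments, MAPQ ≥ 1, duplicates removed; both
  sub-intervals are counted. Duplicate removal is flag-based when
  duplicate flags are present and positional (identical
  seq/start/end/strand records collapse) otherwise; both are exposed.
* `capture` — MAPQ ≥ 30 over whole regions (fragments counted, the
  natural unit once pairs are fetched together).

Total TERRA per sample sums Type I and Type II features with
telomere-proximal TSSs (both sub-features), excluding Type III. CPM uses
the whole-library mapped-fragment total, not the TERRA subtotal. The
poly(A) analysis computes each region's share of its fraction's total
TERRA reads (Types I-III) and reports
$\log_2(\mathrm{frac}^+ / \mathrm{frac}^-)$, flagging regions with a
zero in either fraction rather than emitting infinities.

# Normalization

The merged gene + TERRA table is filtered at mean CPM ≥ 1 in at least
one sample group (aggregator and group count configurable; TERRA
features are always retained — they are the analyte). Smooth quantile
normalization then interpolates, at every rank $u$, between the global
quantile reference $\bar Q_u$ and the group reference $\bar Q_{g,u}$
with weight $w_u$, the running median (window `windowFrac` = 0.05 of the
ranks, endpoints copying the nearest computed value) of
$1 - SSB_u/SST_u$ clamped to $[0,1]$ and set to 1 where $SST_u = 0$ —
which also covers single-sample groups. With one group this reduces
exactly to classical quantile normalization (verified against
limma's implementation); ranks are preserved within samples, ties
receive the mean of their tied normalized values, and the output is
invariant to sample order and group relabeling. Normalization operates
on the count scale; log transforms are left to the caller.

# The simulator and what passing means

`simConfig()` defaults define the study conditions used throughout the
tests and the acceptance script: a six-arm mini-genome with arms of
300-500 kb — three Type I regions of differing promoter composition
(one lacking the 29 bp element), one Type II region, and two expressed
ITS (Type III) regions whose promoters carry only the 37 bp element, the
composition typically observed at interstitial TERRA promoters.
Telomere tracts are 1.5-2.5 kb, transcribed subtelomeric intervals
4-6 kb, expression 120-300 expected fragments per region, CAGE at 50
tags per TSS with 5 bp jitter, and long reads at 120 per sample with
per-read tract lengths of 0.1-1.5 kb. These sizes keep the full
annotation cycle within seconds while leaving every boundary thousands
of bins away from trivial edge cases. All tract lengths are whole motif
units so planted lengths coincide with exact-motif tract boundaries.

Background sequence is i.i.d. uniform ACGT with every chance telomeric
hexamer outside planted tracts scrubbed away, so planted truth is the
only telomeric signal — slightly stronger than rejection near tracts
only, and what makes exact-recovery assertions meaningful. Short-read
samples draw Poisson fragment counts per region plus uniform background;
SAM records are emitted straight from generative coordinates with
SAM-conformant FLAG/MAPQ fields (no aligner), including configurable
low-MAPQ and flagged-duplicate records; long-read SAM records carry
full-span match CIGARs with the read stored in FASTA. Long reads are a
subtelomeric prefix plus a planted tract corrupted by independent
per-base substitution/insertion/deletion.

What the simulator does *not* emulate: mappability structure (every
subtelomere is unique by construction, so MAPQ filters behave ideally),
sequence-composition bias, splicing, degenerate repeat variants inside
real telomere tracts, and Nanopore signal-level error structure
(homopolymer-biased errors). Passing the planted-truth tests therefore
demonstrates algorithmic correctness under the stated error model, not
performance on real subtelomeres, where paralogy between arms is the
dominant difficulty.

# Numerical and interface choices

Coordinates are 1-based closed internally (the native Bioconductor
IRanges/GRanges convention); BED output is 0-based half-open and GTF
1-based inclusive, with round-trip import/export tested. Writers emit
records in deterministic order so outputs are diffable. CAGE clustering
breaks modal ties toward the most 5' position relative to transcription;
terminal-classification ties go to the longer tract; all generators are
pure functions of (configuration, seed).

The acceptance script (`scripts/acceptance.R`) re-simulates the default
study conditions from a supplied seed and recomputes: region recovery
(count, types, maximum TSS error, tract-side partition mismatches),
long-read tract-length recovery at 8% and 0% error (500 reads),
counting versus a brute-force quadratic overlap oracle over 20 random
configurations, the single-group quantile-normalization reduction and
rank preservation, the closed-form poly(A) arithmetic, and the
total-TERRA definition on a hand-built matrix.

# Known limitations

* Full-assembly ITS counts depend on the chaining calibration
  (`maxGap`, `minPurity`); comparisons against published counts should
  report a sensitivity sweep.
* The distal-TSS search reports at most one distal region per arm.
* Antisense TERRA units are not annotated; regions are called only in
  the orientation reading into the telomeric tract.
* Counting merges all surviving records of one read id into a single
  fragment span; chimeric alignments of one read across regions are not
  counted separately.
* The identity-threshold monotonicity of element-array counts can break
  when an interior array copy sits exactly at threshold (array
  splitting), as noted above.
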