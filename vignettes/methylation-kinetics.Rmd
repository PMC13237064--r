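---
title: "Methods: measuring de novo methylation kinetics from single-cell bisulfite data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring de novo methylation kinetics from single-cell bisulfite data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

In the male germline, DNA methylation is erased in primordial germ
cells and re-established in prospermatogonia. In primates this
establishment is slow — months rather than days — and cells taken from
one testis sit at visibly different points along the way. scBS-seq
gives, per cell, a table of cytosine calls (methylated / unmethylated
counts per position). `scmethkin` turns a cohort of such tables into:

1. a QC'd cell roster,
2. an ordering of cells by global CpG methylation ("G-groups"),
3. per-region acquisition kinetics (fast / intermediate / slow),
4. context-resolved profiles and non-CpG motif usage,
5. expression correlates of gene-body methylation speed.

The G-group ordering is the load-bearing assumption: because global
methylation only rises during establishment, binning cells by their
global level is a monotone proxy for developmental progression. The
package never infers per-cell pseudotime; it only uses the ordered
bins.

# Per-cell measures

**Strand merging.** The two cytosines of a CpG dyad report the same
methylation state, so CG calls are merged onto the + strand C of the
dyad, summing counts over whichever strands were observed. Dyads
covered on one strand keep that strand's counts — discarding them would
throw away most of the data at ~1-call depth. CH calls are kept
per strand (CH sites are not palindromic).

**Global level.** The mean over covered dyads of the per-dyad rate
`n_meth / (n_meth + n_unmeth)` — a *site* mean, not a pooled-count
mean, so a few deep sites cannot dominate a shallow cell. The lambda
spike-in contig is excluded everywhere.

**Conversion rate.** The spike-in is fully unmethylated, so its pooled
unmethylated fraction across all contexts estimates bisulfite
conversion. Conversion is reported per cell but is not an exclusion
criterion by default (a floor can be enabled); reported methylation
levels are raw, not conversion-corrected.

**Coverage rate.** Covered CpG dyads over reference dyads (spike-in
excluded). Dyads, not individual CpG cytosines, are counted; this is
configurable in the sense that the caller controls the denominator via
`genome_cpg_count`.

**Somatic contamination.** Maternally methylated imprinted DMRs are
~50% methylated in somatic cells and unmethylated in male germ cells.
A cell is flagged when the mean across sufficiently covered DMRs
(default ≥ 5 dyads each) of per-DMR mean methylation reaches 0.25 —
halfway between the germline expectation (~0, plus conversion noise)
and the somatic expectation (~0.5), with margin on both sides at low
depth. No numeric threshold is standard in the field; 0.25 is this
package's choice. A cell with no covered DMR is *indeterminate* (NA
with a warning), never silently passed.

**Exclusion.** A cell is excluded iff coverage < 1% of reference dyads
or the somatic flag is set. Low mapping rate acts only through its
coverage consequence, which is how sub-percent mapping manifests.
Exclusion is a pure function of the QC table: idempotent,
order-independent, every reason recorded.

# Groups, tiles, and the kinetic score

**Binning.** Preset schemes: marmoset (0–10, …, 50–60, 60–80%),
human (0–20, then decadal to 80%), and a five-bin cynomolgus scheme
whose bounds are data-driven and *non-contiguous*; a level falling in
a gap is an error rather than a silent nearest-bin assignment. Bins
are half-open `[lo, hi)` with the top bin closed — the printed bin
labels ("0–10%", "10–20%") do not state inclusivity, so one convention
had to be picked; half-open with closed top is the standard
histogram convention.

**Tile means.** The genome is cut into fixed tiles (500 kbp by
default; the toy analyses in this package use 100 kbp so a megabase
genome still yields tens of tiles). Per tile × group, the mean is
taken over all covered dyad–cell observations pooled across the
group's cells; an equal-cell-weight mode exists. Tile–group
combinations with fewer than `min_sites` observations (default 50) are
undefined.

**Score.** With early pair (G1, G3) and late pair (G5, G7):

S = (m(G3) − m(G1)) − (m(G7) − m(G5)).

A region that does most of its gaining early scores positive (fast);
one that gains late scores negative (slow). S is a pure difference of
differences — invariant to adding a constant to all four means — and is
defined only where all four group means are defined. Scoring pairs are
species presets ((G2−G1) − (G5−G3) for the five-bin cynomolgus
scheme).

**Classification.** No numeric fast/slow cutoff exists in the
literature, so the default rule is ascending tertiles of S among
scored tiles: slow, intermediate, fast. The split depends only on
ranks, so any strictly monotone transform of S yields identical
classes. Remainder tiles (when n mod 3 ≠ 0) go to the lower classes
first; the synthetic planter uses the same size rule, which is what
makes planted labels exactly recoverable when every tile is scored. A
threshold rule (`|S| > t`) is available.

**Enrichment.** Per annotation category, a chi-squared test on the
2 × k contingency of (bp overlapping, bp not overlapping) × class over
classified tiles, df = k − 1. bp overlap rather than element counts:
it is insensitive to how fragmented an annotation is. The enrichment
ratio is the class overlap fraction over the all-classified overlap
fraction. If any expected cell drops below 5 the p-value switches to a
Monte Carlo estimate and the output records it.

**Gene bodies.** The same score over gene-body intervals
(min_sites 20 — gene bodies are much smaller than tiles), tertile
classes among scored genes, and a promoter accessibility score: total
ATAC-peak bp overlapping the promoter, weighted by the peak signal
column when present (absent peaks give 0).

# Contexts, masking, tertiles, motifs

**Context profiles.** Mean over dyad observations inside each
category footprint, per group; a dyad under overlapping annotations
counts in each — categories are questions, not a partition. A
`genome_wide` meta-category is always included.

**Active-region masking.** Active elements (promoters, CpG islands,
ATAC peaks) stay unmethylated through establishment and drag the
genome-wide mean down. The mask around each element is the element
unioned with ±2 kb around its *midpoint* (the midpoint reading of
"± 2 kb from the center"); the masked mean is recomputed over dyads
outside the mask and the delta reported per group. Promoters can
optionally be pre-filtered to exclude low-CpG promoters
(observed/expected CpG < 0.4 within the promoter; the 0.4 cutoff is
this package's choice of a conventional CGI-style threshold).

**Expression tertiles.** Genes ranked by mean log-normalized
expression (`log1p(count / library × 10⁴)`) across included cells,
split into high/mid/low tertiles (sizes differ by ≤ 1, ties broken by
gene id). Per group and tertile pair, a two-sided Wilcoxon rank-sum
test on gene-body methylation; BH adjustment across all reported
tests. Normalization always uses the full per-cell library, computed
before any gene selection.

**Non-CpG motifs.** Per group, the methylated-call fraction among CG
and among CH calls (CHG/CHH pooled into CH to match the dinucleotide
framing; the finer split is retained in the output), and the motif
distribution of methylated calls — CHN over the twelve CAN/CCN/CTN
trinucleotides, CGN over CGA/CGC/CGG/CGT. Call-pooled by default
(each sequenced call counts once); a site-binarized mode exists, and
at ~1-call depth the two coincide. At realistic conversion rates a
substantial share of "methylated" CH calls are conversion artifacts,
which are uniform over motifs and therefore dilute motif preferences;
motif-recovery tests run at conversion = 1 for exactly this reason.

# The synthetic cohort generator

The generator is first-class, tested code: every downstream stage is
validated by recovering what it plants.

**Genome.** 1–2 chromosomes of 1–2 Mb (plus a 48.5-kb spike-in
contig), built so that every CpG dyad is explicitly planted: background
density 0.02 per bp, 0.12 inside CpG islands and imprinted DMRs
(DMRs are CpG-dense so single cells cover enough sites to be
flagged). Kinetic classes are planted on 100-kbp tiles in the same
ascending-split sizes the classifier uses. Genes (default 20 per
2 Mb, 10–30 kb, all + strand, 1-kb promoters, 3–8 exons) are placed
into tiles with weights fast:intermediate:slow = 3:2:1 — that bias *is*
the planted genic-faster-than-intergenic signal. Promoter ATAC peaks
encode planted accessibility by width (600/400/200 bp for
fast/intermediate/slow genes). LINE/LTR intervals and three imprinted
DMRs (MEST, RB1, PLAGL1) are placed without overlap; impossible
placements raise a capacity error rather than degrading silently.

**Kinetics.** Each class follows a piecewise-linear gain curve
`min(ceiling, r_early·min(τ, ½) + r_late·max(τ − ½, 0))` along a
latent uniform progression τ ∈ [0,1]; defaults: fast (1.5, 0.2,
ceiling 0.85), intermediate (0.9, 0.6, 0.75), slow (0.4, 1.0, 0.65).
This realizes gradual, region-wise acquisition with fast regions
finishing higher — not a switch-like pattern. Active regions stay at
`active_region_level` (default 0); imprinted DMRs at 0 in germ cells.
Somatic cells (default 1% of the cohort, matching roughly one
contaminating cell per hundred) carry 0.5 at imprinted DMRs and a
uniform 0.75 elsewhere.

**Observation model.** A cell observes each CpG dyad with probability
`coverage_fraction` (default 0.2, in the ballpark of the 10–35%
genome coverage of real single cells); covered dyads are seen on +, −
or both strands. Depth defaults to 1 call per covered strand
(single-molecule scBS-seq; `1 + Poisson(depth − 1)` when depth > 1).
Conversion failure is one-sided: an unmethylated cytosine reads
methylated with probability 1 − c (default c = 0.993, inside the
reported 99.2–99.4% range); over-conversion of 5mC is not modeled,
matching how conversion is estimated from unmethylated spike-in only.
The spike-in contributes `lambda_calls` truly unmethylated calls per
cell. CH sites are observed at a separate, lower fraction (default
0.05) purely to keep cohort tables at desk scale — CH sites outnumber
CpGs ~20-fold and carry ~1% signal.

**CH model.** True CH methylation rises linearly from 0.05% to 0.45%
with τ; at default conversion the *observed* CH fraction spans
~0.75–1.15%, reproducing the reported raw range — i.e., at realistic
conversion roughly half of observed CH methylation is artifact, which
is a property of the data type, not a bug. Methylated CH calls are
distributed so their motif distribution equals `ch_motif_weights`
(CAC 0.30, CAG 0.25, the rest uniform — the DNMT3A/DNMT3B preference).

**Expression.** Gene counts are negative binomial with planted tiers
by kinetic class (fast→high μ=50, intermediate→mid μ=10, slow→low
μ=2), plus 60 background genes (log-normal means) that stabilize
library sizes and the control-gene draws of the mitotic score, ten
cell-cycle genes and a DNMT1-like maintenance marker expressed only in
the mitotic fraction (default 12% of germ cells). Methylation is not
diluted at division (maintenance assumed); a switch disables
maintenance, halving methylation in mitotic cells, for contrast
experiments.

**What the generator does not emulate.** Read-level artifacts (PCR
bias, chimeras, duplicates), non-uniform coverage along the genome
(real coverage tracks mappability and GC), strand-biased conversion,
sequence evolution of repeats, negative strands for genes, copy
number, and any coupling between expression and coverage. Passing
recovery tests therefore demonstrates the *estimators and decision
rules* are correct under the stated statistical model — not that the
pipeline is robust to every artifact of real libraries.

# Numerical choices and degenerate inputs

- Interval tables are 0-based half-open (BED convention); cytosine
  tables carry 1-based per-strand positions (report convention);
  conversion happens only at the I/O boundary and where sites meet
  intervals.
- Undefined quantities are explicit errors (no covered dyads, zero
  lambda coverage, mask covering everything) or explicit NAs with a
  recorded reason (tile–group below `min_sites`, indeterminate somatic
  status) — never silent zeros.
- Ties in tertile splits are broken by stable id order; tertile
  remainders go to the earlier bins; both rules are shared between the
  planter and the classifiers.
- Problem sizes in the test suite — 0.3–2 Mb genomes, 10–103 cells,
  100-kbp tiles — were chosen so the full suite exercises every stage
  end to end on a desktop in about a minute and a half while keeping
  every recovery margin (binomial 3·SD bounds, ±0.02–0.03 closed-form
  tolerances) comfortably powered.

# Known limitations

- The G-group ordering compresses real time: groups are unevenly
  populated and group boundaries are arbitrary percentages. The
  kinetic score is a contrast between bins, not a rate in 1/months.
- At depth ~1 per site, per-dyad rates are almost always 0 or 1;
  everything informative happens at the aggregation level, and
  site-level and call-level definitions coincide. Deeper data would
  make the site-mean vs pooled-mean distinction matter more.
- Raw methylation levels include the conversion-failure floor
  (~0.7%); CpG conclusions are insensitive to it, but CH fractions and
  CGN/CHN motif shares are materially shaped by it.
- The chi-squared enrichment treats bp as independent observations;
  with megabase footprints the p-values are astronomically small and
  should be read as rankings, with the enrichment ratio carrying the
  effect size.
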