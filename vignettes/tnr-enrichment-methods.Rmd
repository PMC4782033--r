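---
title: "Methods: stratified epigenetic enrichment around tri-nucleotide repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified epigenetic enrichment around tri-nucleotide repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnrenrich)
```

# The problem

A small set of tandem tri-nucleotide repeats (TNRs) in the human genome
can expand across generations and cause disease; thousands of
comparable repeats never do. `tnrenrich` tests whether the epigenetic
context of the disease-associated repeats (the *foreground*) differs
from that of ordinary repeats (the *background*), in healthy cell
types, using interval-called epigenetic maps: broad histone ChIP-seq
peaks, methylated-CpG site lists, and narrow chromatin-accessibility
peaks, one map per (assay, cell type).

The central design commitment is stratification: a CAG repeat in a
coding exon must be compared with other exonic CAG repeats, not with
the genome at large, because both unit sequence and genic region
independently shape chromatin state. All three statistics in the
package condition on strata built from the canonical repeat-unit class
and the genic labels exon / intron / 5′UTR / 3′UTR.

# Repeat-unit classes

A period-3 tract can be read in three phases on either strand, so each
repeat unit belongs to an equivalence class of six triplets under
cyclic rotation and reverse complement. Homopolymer triplets (AAA,
CCC, GGG, TTT) describe mononucleotide runs and are excluded, leaving
60 triplets in exactly 10 classes of 6 — a fact the test suite asserts
by full enumeration. Classes are keyed by their lexicographically
smallest member; the four classes that cover every cataloged disease
locus are reported under their conventional labels CAG, GCG, GAA and
GAC. This canonicalization is what makes strata well-defined: a tract
written CTG on the plus strand is a CAG-class repeat.

# The catalog and the background

The packaged catalog records 32 disease-associated loci on hg19 at
base-pair resolution. The source table gives 1-based start positions
and repeat-unit counts; on load these become 0-based half-open
intervals with `end = start + 3 * unit_count`, the convention used
everywhere internally (BED files round-trip unchanged). Genic-region
flags are part of the curated record; several loci carry more than one
label (e.g. the AR repeat is both exonic and 3′UTR), and labels are an
unordered set — no primary/secondary distinction is modelled, since no
reproducible rule for one is available.

The background is *all* TNRs, built either by scanning genome sequence
for maximal perfect tracts (`scan_sequence()`) or by importing
external repeat calls from BED (`import_background()`). The scanner
deliberately models only perfect tracts: interrupted-repeat scoring
belongs to specialised tools whose BED output the import path accepts
unchanged. Two numerical choices make the scanner exact rather than
heuristic: a tract is anchored at its leftmost full unit, and trailing
partial units are excluded, so `end − start = 3 × unit_count` is an
invariant and maximality (no extension by a full unit on either side)
is testable. The default threshold is 6 repeat units, the conventional
floor for genome-wide triplet-repeat surveys; a `"zipseq"` preset
lowers it to 3 units to mirror the sensitivity of experimentally
determined CAG-repeat databases. Foreground loci are *not* removed
from the background by default — the background is defined as all
repeats, undistinguished — and a flag (`exclude_da_from_bg`) exists
for the alternative.

# Genic annotation

Gene models come from BED12 (via `rtracklayer`) or a tabular dialect.
"Exon" means *coding* exon (overlap with exon blocks intersected with
the CDS); exonic sequence outside the CDS is labelled 5′UTR or 3′UTR
on the strand-appropriate side; introns are the gaps between exon
blocks. This matters: a purely structural exon definition would make
every UTR repeat exonic and collapse the strata the analysis depends
on. Labels accumulate over all overlapping transcripts (union over
transcripts); non-coding transcripts, which have no CDS, contribute
intron labels only — their exonic sequence is left unlabelled rather
than invented. The per-base brute-force oracle in the test suite pins
this partition down, including the strand flip that swaps the UTR
labels.

Two background matchers are provided and used deliberately:

* *single-axis strata* (`stratify()`: one unit class and/or one
  region) for the grouped test, whose report is organised by stratum;
* *identical matching* (`matched_background()`: same unit class and
  exactly the same label set) for both per-locus tests — the pooled
  rates and distance densities of M2 and M3 are only meaningful
  against repeats whose full annotation matches the query locus.

# Matching rules

Each assay category has its own rule for "the repeat carries the
mark":

* **Broad histone peaks** — the repeat's start point or end point (its
  last base) lies inside a peak. The rule is applied literally, so a
  peak strictly inside a long repeat does not match; since this edge
  case is plausibly an artifact of how such overlaps are computed in
  practice, a `strict_intersection` flag provides plain overlap, off
  by default.
* **Methylated CpGs** — an endpoint within `dnam_window = 200` bp of a
  site, distance counted as bases between point and site. The wider
  criterion compensates for CpG sites being orders of magnitude
  shorter than histone peaks.
* **Narrow accessibility peaks** — any overlap with the tract.

For M2 a `uniform_window` switch applies the within-200-bp rule to all
categories instead; the default keeps the per-category rules, which
are defined once and used by both M1 and M2.

# The three statistics

**M1 (grouped, per cell type).** For one stratum, one assay and one
cell type, the 2×2 table (foreground/background × match/no-match) is
tested with the two-sided Fisher exact test under the
point-probability rule — the sum of hypergeometric probabilities of
all tables with the observed margins no more probable than the
observed table. The implementation delegates to `stats::fisher.test`;
the test suite and acceptance script verify it against exhaustive
enumeration on random small tables. Direction (over/under) is read
from the observed proportions, separately from the p-value. Zero
margins carry no evidence: p = 1, flagged degenerate. P-values are
deliberately left uncorrected; the summary statistic is the percentage
of cell types at p ≤ 0.05 by direction, which is read as a trend
across maps rather than a single test. Mark-group unions ("Any
active", "Any repressive") are per-cell-type interval unions of the
group's maps, scored the same way.

**M2 (per locus, pooled over cell types).** For locus and assay, `k`
of `n` cell types match; the null is Binomial(n, p̂) with p̂ the pooled
match fraction over (matched background repeat, cell type) pairs. The
reported tail is upper (P(X ≥ k)) when k/n exceeds p̂, lower
otherwise; ties go to the lower tail. Bonferroni correction is applied
across all tests in the invocation — conservative by intent, because
the method's independence assumptions (across cell types, and between
cell identity and epigenetic state) are knowingly optimistic. A pooled
rate of exactly 0 or 1 with a contrary observation is reported as
p = 0 with a degeneracy flag rather than silently.

**M3 (per locus, distance).** Distances are center-to-center
(`floor((start+end)/2)` on both sides; full-peak midpoint, since
summit information is not assumed available), transformed as
`x = log10(d + 1)` so d = 0 maps to 0. The background density is a
Gaussian KDE with Silverman bandwidth `h = 1.06 · sd(x) · n^(−1/5)`,
floored at `h_floor = 1e-3` (log10 scale) so constant distances do not
produce a zero bandwidth. The statistic is the exact left-tail area of
the KDE, `p_left = mean(Φ((x_obs − x_i)/h))` — no numerical
integration is involved, and the test suite confirms agreement with
quadrature to 1e-6 and convergence to the empirical CDF (± half the
ties) as h → 0. Only the left tail is ever scored: the method is a
one-sided test for *proximity* enrichment. Profiles need at least two
defined background distances; an absent distance (no mark on the
chromosome) yields no result rather than an arbitrary value.

# The synthetic generator

`generate_scenario()` builds the entire study from a seed: genome,
gene model, planted repeats, per-cell-type maps, and a ground-truth
manifest. Design choices that make ground truth *exact* rather than
probabilistic:

* Repeats sit one per 13 kb slot, so intervals placed for one repeat
  can never match, or become the nearest mark of, another.
* The random genome is scrubbed of accidental tracts at the scenario's
  scanner threshold, and each planted tract's flanking bases are set
  to break period-3 continuation, so the scanner recovers planted loci
  exactly — count, coordinates and class.
* Once the per-(assay, cell type) Bernoulli match draw is made,
  interval placement satisfies the category's matching rule by
  construction (broad peaks cover the start point; CpGs sit within the
  window; narrow peaks intersect the tract), and non-matching repeats
  receive one distal mark at a recorded center distance (1.5–5 kb,
  log-uniform), multiplied by `proximity_shift` for foreground loci
  and floored at 350 bp so a distal mark can never satisfy any
  matching rule.
* One transcript is built around each repeat so that its genic label
  is exactly the intended one.

The null-calibration condition was fixed once at match probability 0.5
for both groups with 12 foreground and 500 background repeats — the
same group sizes as the power scenario — and the tests assert the
grouped test's rejection rate falls within three binomial standard
errors of 0.05 over 2,000 simulated cell types. Because Fisher's test
is discrete, the true rate sits slightly below 0.05; that mild
conservatism is inherent to the statistic, not a defect of the
implementation.

What the generator does *not* emulate: realistic genome composition,
spatially correlated chromatin states, interrupted repeats,
length-matched backgrounds, or cell-type-specific effect structure.
Passing the synthetic suite therefore demonstrates that the statistics
are implemented correctly and respond to planted effects at the stated
sizes — not that real epigenomes satisfy the tests' independence
assumptions.

# Problem sizes and determinism

The simulations used by the tests and the acceptance script are sized
for a laptop-class single core: 2,000 cell types for null calibration,
20 for power (match probability 0.9 vs 0.1), 300 background repeats
for the proximity scenario with shift 0.3 and 50 held-out background
controls. All randomness flows from explicit seeds through R's default
generator; scenario generation restores the caller's RNG state, and
identical configurations produce byte-identical output files.

# Known limitations

* The scanner does not model interrupted tracts; use the BED import
  for sensitive external callers.
* Non-coding transcripts leave their exonic sequence unlabelled.
* M2's independence assumptions make its DNA-methylation calls the
  least trustworthy of the three methods (methylation is strongly
  cell-type specific); read M2 alongside M1/M3, not alone.
* Group sizes in small strata (down to a single locus) leave the
  grouped test without power; the package warns rather than refusing.
* No liftover: catalog coordinates are hg19, and inputs must share a
  build.
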