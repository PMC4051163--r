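---
title: "Methods: co-expression networks, expression and motif Z-scores, and miRNA target rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression networks, expression and motif Z-scores, and miRNA target rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txmine)
```

txmine mines functional signal out of bulk transcriptome compendia of the
kind assembled for crop species: replicated microarray intensity tables and
RNA-seq read counts spanning tissues, developmental stages and stress
treatments. This vignette is the package's own account of the statistics it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## Replicate summaries and read-count transforms

Per probe and condition the package reports the arithmetic mean
$\bar{x}$, the sample standard deviation with divisor $n-1$, and the
standard error $\mathrm{stdev}/\sqrt{n}$. A condition measured once gets
stdev = stderr = 0 by convention: with a single replicate there is no
dispersion estimate, and the divisor-$(n-1)$ definition is the only one
under which the reported standard error is meaningful.

Read counts are normalized as
$\mathrm{RPKM} = 10^9 \, C / (N L)$ (reads in gene $C$, library size $N$,
gene length $L$ in bp), and per-position display counts as
$n = \log_2(N+1)$. Alignment, adapter trimming and quality control are out
of scope: the package ingests already-counted reads.

## ZFE: Z-score for expression

Raw intensities from different experiments are not comparable; ZFE puts
every probe on a common standardized scale. A probe is **eligible** when
(i) at least one condition mean exceeds the experiment's Average Signal
$A$ (the scanner software's per-experiment signal average, supplied as an
input scalar) and (ii) max(mean)/min(mean) $\ge 2$. Ineligible probes get
ZFE = 0 everywhere — probes that never rise above the array's average
signal, or never change two-fold, carry mostly background noise.

Two formulas cover the two experiment designs:

* **Profile experiments** (multi-tissue / time-course):
  $\mathrm{ZFE}_c = (\bar{x}_c - \bar{\bar{x}})/\mathrm{sd}(\bar{x})$,
  where the mean $\bar{\bar{x}}$ and standard deviation (divisor $n-1$)
  are taken *across the condition means* of that probe. The denominator is
  the across-condition spread, not a replicate stdev: the intent is to
  standardize the shape of the profile, and the eligibility filter's
  two-fold clause guarantees the spread is non-zero. Eligible rows are
  exactly mean-zero, and ZFE is invariant under global intensity
  rescaling.
* **Treatment/control experiments**:
  $\mathrm{ZFE} = \log_2(\bar{x}_T/\bar{x}_C)$ against an explicitly
  supplied treatment-to-control pairing (time-matched pairings are a
  special case of the same map). A zero control mean for an eligible probe
  is floored at 1.0 and recorded; GCOS-scaled intensities that close to
  zero are noise, and the floor keeps the log defined.

The max/min ratio uses the same floor of 1.0 in its denominator, for the
same reason.

## Mutual-rank co-expression networks

For genes $X$ and $Y$, all pairwise Pearson correlations are computed over
the pooled samples; each gene's partners are sorted by PCC from large to
small; $a$ is the position of $Y$ in $X$'s list and $b$ the converse; and

$$\mathrm{MR} = \sqrt{ab}.$$

MR is the geometric mean of the two reciprocal list positions — the form
under which mutual rank was introduced for plant co-expression databases —
and the package implements exactly that, with ties in PCC broken
lexicographically by gene id so ranks are deterministic. MR is symmetric,
always $\ge 1$, and equals 1 iff the two genes are each other's top
partner. Genes with zero variance across samples have no defined
correlation; they are excluded from ranking and reported in a skip log.
Probe-to-gene collapsing, where needed, keeps the probe with the highest
across-sample variance.

The genome-scale network keeps edges with MR $\le 30$ (the threshold used
for published plant co-expression networks); isolated nodes are retained,
and the exchange-file summary line reports the average degree
$2|E|/|V|$.

The three-level ego network around a chosen gene follows the display
rules: level 1 = the 10 smallest-MR partners of the center; level 2 = per
level-1 gene, its 5 smallest-MR partners (excluding the center); level 3 =
from each level-2 gene's own top-10 list, only edges landing on genes
already displayed in levels 1–2 — other genes are unlikely to be closely
related to the center and are dropped. All lists are MR-ascending with
lexicographic tie-break, so the view is fully deterministic. Per-probe
correlate lists use the display convention PCC > 0.7 (positive) and
PCC < −0.65 (negative), truncated at 60 per list.

## ZFM: length-stratified motif enrichment

Promoter cis-element enrichment cannot be tested against a naive
background: motif counts scale with promoter length, and gene sets are
biased in promoter length. The ZFM null preserves length composition.
Promoters are stratified into `<500`, `500–1000`, `1000–2000`, `2000–3000`
and `>=3000` bp bins — the open-ended last bin is added so the strata
partition all lengths. For a foreground of $m$ promoters, `k_sets`
(default 1000) surrogate sets are drawn from the genome-wide promoter set,
each taking from every bin, *without replacement and independently across
sets*, exactly the foreground's count in that bin ("same proportions" is
implemented as exact per-bin counts: deterministic stratification, no
multinomial noise). Then, per motif,

$$\mathrm{ZFM} = \frac{N - \overline{N}_{\mathrm{sur}}}{\mathrm{sd}(N_{\mathrm{sur}})},
\qquad P = 1 - \Phi(\mathrm{ZFM}),$$

computed **only when** $N > \overline{N}_{\mathrm{sur}}$; depleted motifs
are reported with `enriched = FALSE` and $P = 1$ rather than as negative-Z
significance. A zero surrogate deviation with $N$ above the mean is a
degenerate null and is flagged as such with $P = 0$; a foreground equal to
the whole genome set makes every surrogate identical and flags nothing.
The default reporting cutoff is $P < 0.1$, with $P < 0.05$ as the display
preset.

Counting totals all (possibly overlapping) occurrences, not the number of
promoters containing the motif. Scanning is forward-strand by default
(plain PLACE-style scans); both-strand scanning is an explicit flag that
reports reverse-complement-pattern matches on forward coordinates, under
which counts are invariant to reverse-complementing every promoter. A
sequence `N` is matched by nothing except the pattern letter `N`. Fixing
`seed` fixes every surrogate draw bit-exactly. For repeated foregrounds
against one genome set, `promoter_motif_count_matrix()` precomputes the
per-promoter counts the resampling sums over.

## miRNA target rules

Plant miRNAs direct cleavage through near-perfect complementarity, so
rule-based scoring over ungapped windows is appropriate. Each transcript
window of miRNA length is paired antiparallel (miRNA position $i$ against
window position $L+1-i$) and each position classified Watson–Crick, G:U
wobble, or mismatch. Four criteria gate a site:

(a) total mismatch score $\le 4$ and first-half score $\le 2.5$, with G:U
counting 0.5; (b) longest consecutive mismatch run $\le 2$ overall and
$\le 1$ within positions 2–12; (c) positions 11 and 12 perfectly paired
(the cleavage-site pairing requirement); (d) the site duplex retains at
least 75% of the perfect-duplex hybridization energy,
$\mathrm{MFE}_{\mathrm{site}}/\mathrm{MFE}_{\mathrm{perfect}} \ge 0.75$.

Open aspects were resolved as follows, each exposed as a parameter where
reasonable:

* *First half* is miRNA positions 1–10 from the 5′ end — the conserved-
  pairing half in plant miRNA:target literature.
* *G:U weighting* applies uniformly to the total and first-half budgets
  (the psRNATarget convention); `gu_weight_total = 1` restricts the
  half-weight to the first-half clause only.
* *Runs*: a wobble is a paired position, so it terminates a mismatch run
  (MM,GU,MM is two runs of length 1, not one of length 2) — wobble pairs
  stack and prevent a single large internal loop.
* *Positions 11–12* count from the miRNA 5′ end; duplexes shorter than 12
  nt satisfy the clause vacuously.
* *Criterion (d)* is a retained-stability ratio. Reading the threshold as
  "site energy below 75% of the perfect energy" would pass arbitrarily
  weak sites, inverting the filter's purpose.

Energies come from a self-contained nearest-neighbor stack model: a
Turner-style $\Delta G^\circ_{37}$ table for the ten unique Watson–Crick
stacks (completed by strand symmetry), a compact two-level
parameterization for wobble-containing stacks (−1.2 kcal/mol with one
wobble, −0.5 with two), a +1.0 kcal/mol destabilization per contiguous
internal mismatch run, and a cap at 0. Criterion (d) consumes only the
*ratio* of two such sums over the same miRNA, so it is insensitive to the
absolute parameter scale; the model deliberately omits dangling ends,
terminal-AU and initiation terms, which cancel in the ratio to first
order. Adding a mismatch to a duplex can only remove stacks and add a
penalty, so the ratio is monotone in defects.

## Pattern and tissue-specific search

A qualitative query (high = +1, even = 0, low = −1 per condition; at least
two conditions, not all equal) is correlated against each eligible probe's
ZFE over exactly the query's conditions — absent conditions are ignored,
not imputed, mirroring the per-experiment restriction of the interactive
tool. Probes with $r \ge 0.7$ are returned in descending order; results
are invariant under positive affine transforms of the query encoding.
Tissue/time-specific search returns eligible probes with ZFE at or above a
user threshold in one condition. Raising either threshold can only shrink
the result set.

## Synthetic data: what it emulates, and what it does not

The generators produce every input type the toolkit consumes, seeded and
bit-reproducible, with the caller's RNG state untouched:

* **Expression**: log-normal intensities centered on `intensity_scale`
  (default 500, matching TGT-500 array scaling) with between-gene spread
  0.5 and replicate noise `noise_sigma` (default 0.2, a typical
  within-condition CV for scaled arrays); co-expression modules enter as
  shared per-condition latent factors, pattern probes as an additive
  log-scale term, treatment effects as a multiplicative fold change
  (default 4×). The default Average Signal A is 100 so that
  moderately expressed simulated probes pass eligibility.
* **Promoters**: i.i.d. base composition with deterministic
  largest-remainder stratification over the five length bins and uniform
  lengths within bins; motif instances are concrete realizations of the
  IUPAC pattern planted uniformly without overlap, at a per-promoter or
  per-bp rate.
* **Duplexes**: transcripts embedding exact-complement sites perturbed by
  stated defects, with a truth table of the intended per-criterion
  verdicts.

These fixtures emulate the *statistical regimes* of compendium data —
planted correlation structure, planted enrichment over a matched null,
controlled complementarity defects — not its biology: no probe
cross-hybridization, no batch or platform effects, no promoter sequence
composition beyond i.i.d. bases, no transcript secondary structure.
Passing tests therefore demonstrate that the statistics behave as designed
under their own model assumptions, not that those assumptions hold for any
particular real compendium.

## Test problem sizes and numerical choices

The suite exercises the oracle-equivalence properties on 50 random
matrices of up to 25 genes, calibrates the ZFM null on a 300-promoter
genome set with 30-promoter foregrounds over 200 replicates at
`k_sets = 200`, checks planted-motif power at a 3× rate on a
2000-promoter genome, enumerates all 16384 target windows of a 7-nt toy
miRNA against an independent rule oracle, and recovers 30 planted
pattern probes among 970 nulls over 16 conditions — sizes chosen so each
property is measured with comfortable Monte-Carlo margin while the whole
suite stays desk-scale. Deterministic tie-breaks (lexicographic ids
everywhere a sort could tie), the intensity floor of 1.0, the capped
energy sum, and the explicit degenerate-null flag are the numerical guard
rails; every stochastic test fixes its seed.

## Known limitations

* The energy model is a ranking device for criterion (d), not a
  thermodynamics engine; absolute kcal/mol values should not be quoted.
* MR ranking is quadratic in gene count and intended for the desk-scale
  and compendium-subset analyses the package targets.
* ZFM's normal-tail P-value inherits the usual discreteness of count
  resampling: for rare motifs the achievable P-values are coarse, which
  is why the null-calibration check works with a band rather than a point.
* The eligibility filter ties ZFE to the supplied Average Signal A;
  re-deriving A from raw array files is out of scope.
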