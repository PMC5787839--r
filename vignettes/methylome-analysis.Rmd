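---
title: "Models and design choices in bsmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in bsmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bsmeth implements a complete whole-genome bisulfite (WGBS) methylome
analysis for plant genomes — context classification, nonconversion-corrected
methylation levels, windowed Fisher-exact DMR calling, gene/TE differential
methylation, metagene and quintile profiling, and methylation–expression
integration — together with a simulator that generates the data the
pipeline consumes, with full ground truth. This vignette explains the
underlying models, the tunable parameters, and the design decisions taken
where the methodology was genuinely open.

## The measurement model

Bisulfite treatment converts unmethylated cytosines to uracil (read as T)
while methylated cytosines are protected. At a cytosine covered by
`m` methylated and `u` unmethylated read calls the methylation level is
`ML = m / (m + u)`. Conversion is imperfect: an unmethylated cytosine
escapes conversion with probability `r` (the *nonconversion rate*, of the
order of 0.001 in practice), so a read reports methylated with probability
`ML + (1 - ML) r = ML (1 - r) + r`. Inverting this expectation gives the
corrected level `(ML - r) / (1 - r)`, which we clamp to [0, 1]: at truly
unmethylated sites sampling noise routinely drives the corrected value
slightly negative, and methylation levels are probabilities.

`r` is estimated from an unmethylated spike-in chromosome (lambda phage
DNA added before bisulfite treatment) as the pooled methylated-read
fraction over all spike-in cytosines. The estimator needs at least 10^4
pooled reads by default; below that the function aborts and asks for an
explicit `r` override rather than returning a noisy calibration.

### Contexts

Plant methylation is context-specific: CG, CHG and CHH (H = A, T or C),
determined by the two bases immediately downstream of the cytosine *on its
own strand*. Both strands are classified (a G on the plus strand is a
cytosine on the minus strand); sites whose two downstream bases run off
the chromosome end, or whose trinucleotide contains N, are excluded rather
than guessed. Strands are reported separately throughout; pooling
symmetric CpG dyads is available as an explicit, optional operation
(`merge_symmetric_cpg()`), never applied silently.

### Calling methylated sites

The headline summary "percent methylation" (the fraction of C sites that
are methylated, per context) needs a binary per-site call, and no standard
operational definition exists at the level of a count table. We call a
covered site methylated when its methylated count is inconsistent with
nonconversion alone: a one-sided binomial test of `m` against
`Binomial(m + u, r)`, Benjamini–Hochberg adjusted across all covered
sites, called at q < 0.05. This is the familiar binomial-against-error
strategy used by single-base methylome studies; it is a documented
stand-in, and the FDR threshold is a parameter.

Coverage matters: sites with fewer than `min_coverage = 4` reads are
flagged uncovered and excluded from levels, windows and calls. With ~10x
mean coverage this keeps the large majority of sites while suppressing
high-variance singletons. The threshold is configurable.

## Windows and DMRs

Methylation landscapes are summarized in 3000-bp windows stepped by
600 bp; differential testing uses 1000-bp windows stepped by 100 bp. In
both cases the window level is the *count-pooled* level
`sum(m) / sum(m + u)` over covered sites — never the mean of per-site
levels, which would weight a 4-read site equally with a 40-read site.

Window geometry: windows start at 1, 1 + step, …, and all fully fitting
windows are emitted. A truncated terminal window is added only when the
chromosome extends beyond the last full window's end by at least half a
window (short leftovers are high-variance slivers and are dropped); a
chromosome shorter than one window yields a single truncated window when
at least half a window long. Note that when the step is smaller than half
the window — as in both standard geometries here — full windows already
reach within one step of the chromosome end, so the trailing rule only
comes into play for non-overlapping geometries and short chromosomes.

DMR calling between two conditions proceeds per context:

1. Replicates are pooled by count summation per condition. Fisher's exact
   test operates on one 2x2 table per window (methylated/unmethylated by
   condition); a replicate-aware dispersion model (beta-binomial) is out
   of scope, and pooling is the behaviour of the classic two-sample
   sliding-window callers this stage reconstructs.
2. A window is tested only if both conditions have at least
   `min_sites = 5` covered cytosines of the context in it.
3. Two-sided Fisher exact p-values are computed by hypergeometric
   enumeration (all tables no more probable than the observed one, with a
   1e-7 relative slack against floating-point ties), then BH-adjusted per
   context across all tested windows genome-wide — contexts differ
   greatly in site density and effect scale, so a shared adjustment would
   let CG windows dominate the CHH threshold.
4. Significant windows (q < 0.05 *and* absolute pooled level difference
   >= `min_delta = 0.1`) of the same context and direction are merged when
   overlapping or book-ended, and the merged DMR's levels are recomputed
   from the site counts on the merged span. The `min_delta` filter exists
   because Fisher significance at high counts flags biologically trivial
   differences; 0.1 is a default, not a constant.

Genes are annotated against DMRs by three regions: promoter (2 kb upstream
of the transcript start, strand-aware), gene body (transcript span) and
TTR (2 kb downstream of the transcript end). The TTR extent is not a
standardized quantity; we chose 2 kb for symmetry with the promoter. A
gene may be both hyper- and hypomethylated via different regions or
contexts and is then counted in both categories, matching region-separate
accounting. For transposable elements the test is per TE (per context and
a combined all-context variant), with two criteria: FDR-adjusted p < 0.05
and methylation fold change > 2, where the fold change is
`(ML_case + 0.01) / (ML_control + 0.01)` or its inverse, whichever is
>= 1. We read the significance criterion as FDR-adjusted because the
adjustment step immediately precedes it in the source protocol; a raw-p
mode is available (`use_fdr = FALSE`). The 0.01 pseudocount keeps folds
finite at zero methylation.

## Profiles and quintiles

Every base of the genome belongs to exactly one compartment under the
precedence TE > gene sub-feature (5'UTR, CDS, 3'UTR, intron) >
promoter/downstream flank > intergenic. Metagene profiles rescale each
gene to a fixed axis — 20 promoter bins, 5 x 5'UTR, 20 body, 5 x 3'UTR,
20 downstream, with 2-kb flanks — and pool counts per bin across genes;
minus-strand genes are flipped so the axis runs 5' to 3'. Fixed bin counts
(rather than per-bp profiles) give a deterministic axis onto which
variable-length features pool exactly; genes shorter than the bin count
are assigned proportionally, so bin assignment is always a partition and
count totals are conserved. TE profiles use a single 20-bin body.

Quintile stratifications share one primitive: a special class is extracted
first (nonexpressed genes at FPKM < 0.1; "unmethylated" genes whose region
has fewer than 5 covered cytosines or no FDR-called mC), the remainder is
rank-ordered ascending and split into five groups whose sizes differ by at
most one, larger groups at the low end, ties broken by stable item-id
order. Genes whose region has no covered cytosine at all are excluded and
tallied, not silently binned. Expression is summarized as
log10(FPKM + 0.01) for boxplots — standard dynamic-range handling.

Boxplot statistics use quartiles by linear interpolation of order
statistics at (n+1)p (quantile type 6) with whiskers at the most extreme
points within 1.5 interquartile ranges of the quartiles. Group-wise
expression comparisons use the two-sided Wilcoxon rank-sum test: exact by
full enumeration when both samples are tie-free and the smaller has at
most 8 observations, otherwise the normal approximation with tie and
continuity corrections. Expression change in the integration table is
log2((FPKM_case + 0.01) / (FPKM_control + 0.01)); DE labels are inputs
(from an upstream DE caller or the simulator truth) — no DE caller is
implemented here.

## The simulator

The generator emulates the study design the pipeline targets: ~10x mean
per-cytosine coverage (Poisson per site, which exercises the coverage
filter in a way uniform coverage would not), nonconversion rate 0.0012
(conversion 99.88%), two biological replicates per condition, a
lambda-sized (48,502 bp) unmethylated spike-in on a dedicated chromosome
named `lambda`, a TE-rich genome with classed TEs, and genes with
UTR/CDS/intron structure.

True per-site methylation is drawn per compartment and context from a
*zero-inflated Beta*: a site is methylated with probability `p_meth`, and
methylated sites draw their level from Beta(mean, concentration). Plant
per-site methylation is strongly bimodal, and the headline
percentage-of-methylation statistic is the fraction of methylated sites —
only an explicit methylated-site fraction makes that a configurable truth
a test can recover. The default compartment parameters encode the
canonical plant patterns: TEs hypermethylated in all contexts, a 5'UTR
dip, CHH highest in promoters among gene-proximal compartments, and
genome-wide context levels landing near 54% / 38% / 8.5% (CG/CHG/CHH) at
the default TE fraction. A concentration of `Inf` gives a point mass,
useful for flat-truth tests.

DMRs are planted by shifting the true level of the chosen context by
±effect inside sampled intervals, clamped to [0, 1]. Clamping means a
planted effect is only fully realized where the baseline leaves headroom —
one cannot hypermethylate an already-methylated region by 0.4 — so the
benchmark configurations host DMRs in an intergenic compartment set to a
moderate unimodal level (p_meth 1, mean 0.35, concentration 20). When the
host compartment is intergenic the simulator reserves the host intervals
during genome packing (with a 2-kb margin from genes and TEs), which
guarantees capacity and keeps each planted DMR inside a single
compartment; other host compartments are sampled from the realized
compartment partition. Noise then follows the measurement model exactly:
coverage ~ Poisson(mean), methylated count ~ Binomial(coverage,
ML (1 - r) + r). Over-conversion error (a methylated C read as
unmethylated) is fixed at zero, matching the one-parameter correction the
pipeline applies.

Expression is log-normal with a configurable nonexpressed fraction and DE
fraction (fold changes uniform on a configured range, up/down balanced).
An optional coupling biases genes under planted promoter hyper-DMRs toward
repression (and hypo toward induction), providing a planted
methylation–expression association for the integration stage to recover.

Everything is deterministic: each stochastic stage derives its own seed
from the configuration seed (and condition/replicate indices), so a fixed
configuration yields byte-identical files, including across partial reruns.

### What the simulator does not emulate

Read-level artefacts are out of scope by construction: mapping bias,
M-bias along reads, PCR duplicates, CHH asymmetry from strand-specific
library chemistry, sequence evolution of TE families, and spatial
autocorrelation of methylation beyond the compartment structure. Passing
tests therefore demonstrate that the statistical machinery is correct
under the stated sampling model — not that any upstream aligner or caller
is artefact-free on real reads. Alignment itself (and RNA-seq
quantification / DE calling) is deliberately outside the package: counts
and FPKM tables are inputs.

## Problem sizes and numerical choices

The packaged tests run the DMR benchmark on a 1-Mb genome with 50 planted
CG DMRs (1–2 kb, delta ML 0.4, 10x coverage, two pooled replicates), a
matched null of the same size, an effect-size sweep (0.1/0.2/0.4) on
600 kb, and context-level recovery on 300 kb; these sizes give tight
Monte-Carlo bands (binomial 3-sigma for sampled fractions) while keeping
the whole suite to a few minutes on one CPU. Fisher p-values are compared
to an independent enumeration oracle to 1e-12 over tables with N <= 60;
beyond that, floating-point summation order is the accuracy limit, which
the 1e-7 relative tie slack absorbs. The BH step is `stats::p.adjust`;
the Wilcoxon step is `stats::wilcox.test`; both are cross-checked in the
test suite against independently coded references (step-up formula;
full enumeration).

## Known limitations

* Fisher on pooled counts ignores between-replicate biological variance;
  with many replicates a beta-binomial model would be preferable.
* The per-site mC call, the window significance/merge criteria and the
  TTR span are documented reconstructions where the field has no single
  convention; all are parameters.
* The window-level correction applies `(ML - r)/(1 - r)` to the pooled
  ratio; whether summaries should use corrected or raw levels is
  configurable (`correct =` flag), defaulting to corrected.
* The simulator's truth is piecewise-independent across sites given the
  compartment; real methylomes are autocorrelated, so window-level power
  estimates here are mildly optimistic.
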