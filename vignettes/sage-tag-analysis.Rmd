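---
title: "Comparing two SAGE tag libraries: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two SAGE tag libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagetags)
```

## The measurement model

Serial Analysis of Gene Expression (SAGE) measures transcript abundance by
counting short cDNA-derived sequence tags. In the LongSAGE variant each tag
is 21 bp: the CATG recognition site of the anchoring enzyme (NlaIII)
followed by 17 informative bases released by the tagging enzyme (MmeI),
which cuts at a fixed distance downstream of its site. Two tags are ligated
tail-to-tail into a *ditag*, ditags are concatenated into long inserts
(*concatemers*), and each sequenced clone yields a run of ditag cores
separated by CATG anchors. Counting canonical tags across clones gives a
digital expression profile per library; comparing two libraries tag by tag
gives a differential expression screen.

This package implements the full computational arm of such a comparison:

1. **Extraction** — concatemer FASTA to ditag cores to canonical tags to a
   two-library count table (`extract_tag_table()`).
2. **Differential representation** — the Audic–Claverie exact test plus a
   library-size corrected ratio statistic with a banded report
   (`sage_test()`).
3. **qPCR validation** — efficiency-corrected relative quantification with
   a permutation significance test (`expression_ratio()`).
4. **Simulation** — seeded generators for every input with known ground
   truth (`simulate_truth()`, `sample_libraries()`,
   `libraries_to_concatemers()`, `simulate_qpcr()`).

## Tag canonicalization

A 21-bp tag can be recorded three ways: as read (`CATG` prefix), as the
opposite-strand read (`CATG` suffix; the reverse complement restores the
canonical form), or as the in-place complementary strand (`GTAC` prefix, a
convention seen in tag primer listings; the positionwise complement
restores it). `canonical_tag()` maps all three onto the CATG-prefixed form
and is idempotent, so the same physical tag can never be counted twice
under different orientations. Strings that fit none of the three patterns
are rejected rather than guessed at.

## Extraction rules

`split_concatemer()` takes every maximal segment strictly between
consecutive CATG anchors as a candidate ditag core. The accepted length
window defaults to 32–38 bp: MmeI cuts 19–21 bases from its site, so each
tag contributes 17 ± 2 informative bases. Segments outside the window, or
containing N, are logged with a reason (`short_core`, `long_core`,
`contains_n`) rather than silently dropped; sequences with no anchor log
`no_anchor`. Partial segments before the first and after the last anchor
are cloning junctions, not ditags, and are ignored. A core of length
34–38 always yields two 17-base tags from its opposite ends
(`ditag_to_tags()`); any overlap or gap in the middle caused by cut-site
variability is ignored, which keeps extraction deterministic and exactly
invertible for simulation.

Duplicate-ditag removal (`deduplicate_ditags()`) treats cores equal up to
reverse complement as the same ligation product, because a clone insert is
read in arbitrary orientation. It defaults **off**: published tag totals
are typically raw counts, and removing PCR duplicates is a separate
analytic decision exposed as a flag.

## The Audic–Claverie test

For a tag seen $x$ times in library A (total $N_A$) and $y$ times in
library B (total $N_B$), the probability of $y$ given $x$ under equal
expression is

$$
p(y \mid x) \;=\;
\left(\frac{N_B}{N_A}\right)^{y}
\frac{(x+y)!}{x!\,y!\,\bigl(1 + N_B/N_A\bigr)^{x+y+1}} .
$$

Over $k = 0, 1, 2, \dots$ these probabilities sum to exactly one (they are
a negative binomial with size $x+1$ and success probability
$N_A/(N_A+N_B)$), which licenses complement evaluation of tails. The
implementation works in log space via `lgamma()` so that counts in the
hundreds lose no precision; the left tail $P(K \le y)$ is accumulated with
log-sum-exp, while the right tail $P(K \ge y)$ is summed directly upward
from $y$ (the term ratio $(x+k+1)/(k+1) \cdot N_B/(N_A+N_B)$ eventually
drops below one) so that small right tails retain full *relative*
accuracy instead of the absolute-only accuracy a complement would give.

The two-sided p-value doubles the smaller tail and caps at one — the usual
convention for exact two-library count tests. The doubling rule is a
design choice: with discrete counts any two-sided construction is somewhat
conservative, and this one is the simplest and the most widely used. A
consequence worth knowing: under a null simulation the fraction of tags
with $p \le \alpha$ sits *below* $\alpha$, so the type-I property is
checked as a one-sided bound ($\le \alpha$ plus binomial slack), not a
two-sided band.

Multiple-testing correction defaults to **none**. Shallow libraries (a
few thousand tags) rarely survive FDR control, and the uncorrected
per-tag test is how such screens are conventionally reported — the
Benjamini–Hochberg option is available behind the `correction` argument,
and `threshold_sensitivity()` reports how the significant-tag count moves
with $\alpha$ when the original threshold of a published count is
unknown.

## The Dif ratio and its banded report

The second statistic is a library-size corrected representation ratio:
$\mathrm{Dif} = (n_A / n_B)\, C$ with $C = \mathrm{round}(T_B/T_A, 2)$.
Rounding $C$ to two decimals before use reproduces the convention of
reported tables (totals 1894 and 2670 give $C = 1.41$, not 1.4098…), at
the cost of exact reciprocity under library swap — the product of the two
directions differs from 1 by the rounding of $C$, which the tests account
for. A tag absent from B gives $+\infty$, absent from A gives 0; both are
maximal evidence and always fall outside the significance band.

Values in $[0.6, 1.6]$ are treated as consistent with equal
representation; anything outside the band is flagged. The banded report
(`binned_report()`) assigns each tag's Dif, rounded to **one decimal**, to
the ranges 2.7–3.7, 1.7–2.6, 0.6–1.6 and 0.3–0.5. Rounding to one decimal
closes the apparent gaps between printed range edges (1.6 → 1.7,
2.6 → 2.7); an explicit `out_of_table` bin catches everything else, so
percentages always total 100. Two weightings are provided because
published "relative content" percentages are ambiguous: `by_tag_count`
(default) weights each tag by its library-A count — the reading most
consistent with "content of the library" — while `by_unique_tag` counts
each tag once.

## qPCR validation arm

Quantification follows the efficiency-corrected relative model. Per-well
amplification efficiency is estimated from the raw fluorescence curve in
the window-of-linearity style: subtract a baseline (mean of the first 3
cycles), find the contiguous window (default 4 points) of log signal with
the best linear fit, and take $E = 10^{\text{slope}}$, clamped to
$(1, 2]$. The estimate is scale-invariant and deterministic; flat or
non-amplifying curves raise an error instead of returning a number.

The normalized quantity for one well pair is
$Q = E_t^{-\mathrm{Ct}_t} / E_r^{-\mathrm{Ct}_r}$ — transcripts of the
target per transcript of the reference gene at the detection threshold.
Target and reference wells are paired strictly by (group, replicate);
unpaired designs are rejected rather than silently averaged, because
averaging across a broken pairing biases the ratio. The between-group
ratio is $R = \bar Q_A / \bar Q_B$ with a first-order propagated standard
error.

Significance uses a group-label permutation test on $|\log R|$: all
$\binom{n_A+n_B}{n_A}$ label assignments are enumerated when there are at
most 10,000, otherwise `n_perm` assignments are sampled under the
mandatory seed with the $(k+1)/(n+1)$ small-sample correction. A
label-permutation test is the natural nonparametric stand-in for
randomization-based qPCR ratio tests whose exact resampling schemes are
not published; it is exact under exchangeability and reproducible by
construction.

## The synthetic-data generator

The generator is the package's ground-truth instrument, and its defaults
describe the study design it emulates: two libraries of 1894 and 2670
total tags (250 clones of ~8 ditags each), drawn multinomially from a
shared transcript-abundance distribution, with a small planted
differentially expressed fraction (2% by default, fold changes 5 and 1/5
planted symmetrically — both directions of enrichment occur in real
two-species comparisons). Abundances are log-normal
(`abundance_log_sd = 2`): SAGE libraries are classically dominated by a
few very abundant transcripts with a long singleton tail, and a heavy
right-skew reproduces the empirical pattern that a shallow library
contains mostly unique tags. Every generator requires an explicit seed;
there is no implicit randomness anywhere.

Concatemer realization is the exact inverse of extraction: the tag
multiset is shuffled, consecutive tags pair into 34-bp cores (second tag
reverse-complemented), and `tags_per_clone` cores are joined per clone
with CATG separators and anchors at both ends. Two constructive details
keep the round-trip *exact*: catalog 17-mers are rejected if they would
put a CATG inside the 21-bp tag, or if they end in `CA` or `CAT` — the
only endings that can spell CATG across a ditag junction — so no pairing
of catalog tags can ever create a spurious anchor. For arbitrary
user-supplied tables, which may contain such tags, junction clashes are
instead repaired by deterministically swapping partners (with a bounded
reshuffle fallback), preserving the tag multiset. An odd library
total is padded by duplicating one random tag, and the pad is reported.

What the generator deliberately does **not** model: sequencing errors in
tags, cloning and PCR bias, linker contamination, and duplicate-ditag
artifacts. Tests passing on synthetic data therefore demonstrate
correctness of the pipeline's accounting and statistics under clean
multinomial sampling — not robustness to the artifacts of a wet-lab
library, which would need the optional noise hooks and a dedicated
robustness study.

## Numerical and testing choices

* Exactness standard: the log-space Audic–Claverie evaluation is held to
  12 significant digits against big-rational brute force over the grid
  $x, y \le 30$ at totals (1894, 2670), and to the negative-binomial
  identity across other total pairs.
* Tail tolerance: left tails to $10^{-12}$ absolute; right tails to full
  relative accuracy by direct summation (cutoff: terms below
  $10^{-17}$ of the accumulated sum).
* Problem sizes in the test-suite simulations — 200 null draws for the
  type-I check, 60 truth draws for the power check, 50 libraries for the
  round-trip check, 15 replicated experiments per planted qPCR ratio —
  were chosen to make the Monte-Carlo error comfortably smaller than the
  property margins being asserted while keeping the default suite quick.
* Ties in the window-of-linearity search resolve to the earliest window;
  with noiseless exponentials all candidate windows agree to rounding.

## Known limitations

* The Audic–Claverie test assumes independent sampling of tags; tag
  multisets with PCR duplication violate this unless ditag deduplication
  is enabled.
* The Dif band (0.6–1.6) is a reporting convention, not a calibrated
  significance region; the claimed correspondence between that band and a
  specific significance level is not derivable from the test and is not
  modeled.
* One library per condition means biological replication is absent by
  design; the qPCR arm with per-individual replicates is the intended
  validation path.
* The efficiency estimator assumes a visible exponential phase; very
  early-plateau curves will be rejected.
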