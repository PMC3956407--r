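# sagetags

Tools for comparing the transcriptomes of two samples measured with
Serial Analysis of Gene Expression (SAGE). The package covers the whole
computational arm of a two-library SAGE study: extracting canonical
21-bp tags from sequenced concatemer clones, counting tags per library,
detecting differentially represented tags, and validating selected genes
by efficiency-corrected qPCR — together with fully seeded synthetic-data
generators so every stage can be exercised against known ground truth.
It is aimed at analysts working with shallow tag-count libraries (a few
thousand tags per condition), where exact count statistics matter and
multiple-testing correction is rarely affordable.

## The statistics at the core

**Audic–Claverie exact test.** For a tag seen `x` times in library A
(total `N_A`) and `y` times in library B (total `N_B`), the probability
of `y` given `x` under equal expression is

```
p(y | x) = (N_B/N_A)^y * (x+y)! / ( x! * y! * (1 + N_B/N_A)^(x+y+1) )
```

evaluated in log space. Tail sums over `k = 0..y` (which total exactly 1
over all `k`) give left/right tail probabilities; the two-sided p-value
doubles the smaller tail and caps at 1.

**Dif ratio.** A library-size corrected representation ratio
`Dif = (n_A/n_B) * C` with `C = round(T_B/T_A, 2)` (totals 1894 and 2670
give `C = 1.41`). Values outside the band `[0.6, 1.6]` are flagged, and a
banded report assigns each tag's Dif (rounded to one decimal) to the
ranges 2.7–3.7, 1.7–2.6, 0.6–1.6, 0.3–0.5 plus an explicit out-of-table
bin.

**qPCR relative quantification.** Per-well efficiency from the
window-of-linearity of the raw fluorescence curve (`E = 10^slope`,
clamped to `(1, 2]`), normalized quantities
`Q = E_t^-Ct_t / E_r^-Ct_r` against a reference gene, group ratio
`R = Q_A/Q_B`, and a group-label permutation test on `|log R|`
(exhaustive up to 10,000 assignments, otherwise seeded sampling).

See the vignette `vignettes/sage-tag-analysis.Rmd` for the model
assumptions, parameter defaults and design rationale.

## Worked example

Simulate a paired pair of libraries with 2% planted differential
expression, fit the two-library test, and validate one gene by simulated
qPCR:

```r
library(sagetags)

cfg   <- sim_config(n_transcripts = 500, de_fraction = 0.02, seed = 20)
truth <- simulate_truth(cfg)
tab   <- sample_libraries(truth)
fit   <- sage_test(tab)
summary(fit)
#> Two-library SAGE differential representation test
#>   libraries: library_A (N = 1894), library_B (N = 2670)
#>   correction coefficient C = 1.41; Dif band [0.6, 1.6]
#>   unique tags: 323
#>   significant by test (alpha = 0.05, correction = none): 9
#>   outside Dif band: 201
#>
#> Dif binned report (by_tag_count)
#>          range percent
#> 1      2.7-3.7     3.0
#> 2      1.7-2.6     7.4
#> 3      0.6-1.6    80.8
#> 4      0.3-0.5     3.0
#> 5 out_of_table     5.8
#> Total significant: 19.2%

sim <- simulate_qpcr(c(ependymin_like = 2.5), e = 2, replicates = 5,
                     noise_sd_ct = 0.2, seed = 21)
expression_ratio(sim$wells, "ependymin_like", seed = 22)
#> qPCR relative expression: ependymin_like
#>   Q_A = 0.04702, Q_B = 0.01394 (n = 5, 5)
#>   R = Q_A/Q_B = 3.373 +/- 0.43, permutation p = 0.007937 (exhaustive)
```

Reading the output: of 4,564 sampled tags (1,894 + 2,670), 323 are
unique; 9 tags pass the exact test at alpha 0.05; the Dif report shows
80.8% of library-A tag mass inside the equal-representation band. Note
how many more tags fall *outside* the band (201) than pass the exact
test (9): at counts of 1–3 the Dif ratio is far noisier than the test,
which is why both statistics are reported. The qPCR arm recovers the
planted 2.5-fold enrichment (R = 3.37 ± 0.43, within sampling noise of
truth) with the smallest p the 5+5 exhaustive permutation design can
produce (2/252).

The command-line front end exposes the same stages as subcommands
(`simulate`, `extract`, `detest`, `report`, `qpcr`, `pipeline`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","sagetags.R",package="sagetags"))')" \
  simulate --seed 7 --out-dir sim/
```

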