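---
title: "TMM normalization: model, estimator and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TMM normalization: model, estimator and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmmnorm)
```

## The sampling model and what normalization must fix

A sequencing library is a multinomial sample of size $N_k$ from the RNA
population of sample $k$: gene $g$ occupies a fraction
$\mu_{gk}/S_k$ of that population, where $\mu_{gk}$ is its expression
(transcript count, with gene length absorbed) and
$S_k = \sum_g \mu_{gk}$ is the sample's total RNA output. Hence
$E[Y_{gk}] = N_k\,\mu_{gk}/S_k$. $N_k$ is known; $S_k$ is not, and it is
the quantity that differs between samples with different RNA repertoires.
Dividing counts by $N_k$ alone therefore leaves every gene's normalized
abundance multiplied by the unknown $1/S_k$, which shows up as a global
offset of the pairwise log-ratios $M_g$ — composition bias. Only the
ratio $f_k = S_k/S_r$ between two samples is identifiable, and it is all
that count-based tests need, because it converts the observed library
size into an effective one.

## The estimator

For a sample $k$ and reference $r$, `compute_ma()` evaluates, for genes
with nonzero counts in both libraries,

$$M_g = \log_2\frac{Y_{gk}/N_k}{Y_{gr}/N_r},\quad
  A_g = \tfrac12\log_2\Bigl(\tfrac{Y_{gk}}{N_k}\tfrac{Y_{gr}}{N_r}\Bigr),\quad
  \widehat{\mathrm{var}}(M_g)=\tfrac{N_k-Y_{gk}}{N_kY_{gk}}
        +\tfrac{N_r-Y_{gr}}{N_rY_{gr}},$$

the variance being the delta-method approximation for a log relative risk
of two binomial proportions. Under the assumption that most genes are not
differentially expressed, every null gene's $M_g$ is centred on
$-\log_2(S_k/S_r)$, so a robust location estimate of the $M$ distribution
estimates the factor. `doubly_trim()` removes the tails — 30% from each
end of the $M$ distribution and 5% from each end of the $A$ distribution,
over the same candidate pool, keeping the intersection $G^*$ — and
`tmm_pair()` averages the survivors with precision weights:

$$\log_2\hat f_k=\frac{\sum_{g\in G^*}M_g/\widehat{\mathrm{var}}(M_g)}
                      {\sum_{g\in G^*}1/\widehat{\mathrm{var}}(M_g)}.$$

`factor` $=2^{\log_2\hat f_k}$ multiplies library $k$'s size
(`effective_size` in a multi-library `tmm()` fit);
`production_ratio` $=1/\mathit{factor}$ estimates $S_k/S_r$. A factor of
0.68, say, means sample $k$ produces roughly $1/0.68 \approx 1.5$ times
the RNA of the reference and its effective size must shrink accordingly.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `m_trim` | 0.30 | fraction removed from *each* tail of $M$ (dimensionless) |
| `a_trim` | 0.05 | fraction removed from *each* tail of $A$ |
| `a_min`  | none | hard lower bound on $A$ before trimming, for data whose low-abundance log-ratios are unstable |
| `weighted` | `TRUE` | precision weights vs. plain trimmed mean |
| `reference` | first library | or `"auto"`: the library whose median $A$ against the first is closest to zero |

The 30%/5% defaults assume differential expression affects well under
30% of genes in any one direction; raise `m_trim` only with evidence of
heavier asymmetric DE, at a cost in variance (fewer genes averaged).

### Numerical choices

* $M$ is computed as `log2(Y_k/N_k) - log2(Y_r/N_r)`, a difference of
  logs, so swapping sample and reference negates every $M_g$ *bitwise*
  and the estimator is exactly antisymmetric.
* Trim ranks use mid-ranks (ties share their average rank), so a group of
  genes with identical $M$ survives or falls together. A stable
  first-come tie order was considered and rejected: when a tied group
  straddles a trim boundary it splits differently under library swap,
  breaking antisymmetry by visible amounts on tied count data.
  Mid-ranks also coincide with the rule used by the reference
  implementation in the wild, which the test suite uses as an independent
  cross-check.
* With $n$ candidates, each trim keeps ranks
  $\lfloor n\,\mathrm{frac}\rfloor + 1$ through
  $n - \lfloor n\,\mathrm{frac}\rfloor$; the double trim is the
  intersection of the two keep-sets computed over the same pool, not a
  sequential re-ranking.
* Genes with $Y=0$ in either library are removed before trimming ($M$
  undefined). A gene holding an entire library in both samples has zero
  approximate variance and is excluded with a warning (only possible in
  pathological near-single-gene libraries). Self-comparison yields factor
  1 exactly; an empty $G^*$ raises an error suggesting smaller trims.
* Scale invariance: multiplying *every* count by $c$ leaves the factor
  unchanged (weights scale uniformly by $1/c$). Rescaling a single
  library leaves $M$, $A$ and the trim unchanged but shifts the
  *weighted* mean, because the variance is a sum of per-library terms;
  only the unweighted estimator is invariant to one-sided rescaling.
  This is a property of the delta-method weights, not an implementation
  artifact.

## The tests

For two single libraries, `two_library_test()` applies the conditional
exact binomial test: given $t = y_1+y_2$, under the null
$y_1 \sim \mathrm{Bin}(t,\ \tilde N_1/(\tilde N_1+\tilde N_2))$ with
$\tilde N$ the effective sizes — for a pair, the square-root split
$\tilde N_k = N_k\sqrt f$, $\tilde N_r = N_r/\sqrt f$, which preserves
the product of the sizes while scaling their ratio by $f$. The two-sided
p-value sums all outcome probabilities not exceeding the observed one
(minimum-likelihood convention, with $1+10^{-7}$ relative slack for
floating-point ties); totals above $10^4$ use an exact two-tail-boundary
evaluation (binary search on the unimodal pmf) instead of full
summation. P-values are exact and never continuity-corrected; displayed
log-fold-changes add half a count only when a zero is involved.

With replicated groups, counts are modelled as
$Y_{gk}\sim\mathrm{Poisson}(\lambda_{g,z(k)}\tilde N_k)$, the
normalization entering through the offset $\tilde N_k = N_k f_k$.
`poisson_lr_test()` uses the closed-form MLEs (group sums over group
effective-size sums) and refers
$2\sum_k Y_{gk}\ln(\hat\lambda_{z(k)}/\hat\lambda_0)$ to $\chi^2_1$;
`poisson_exact_test()` exploits that group totals are Poisson and applies
the conditional binomial test to within-group pooled counts. The two
agree in ranking almost perfectly on informative genes; the exact test is
conservative at small totals because of discreteness. FDR control is
Benjamini–Hochberg (`bh_adjust()`), the field default; the choice of
step-up procedure is a package decision, not dictated by the model.

## What the simulator emulates — and what it does not

`simulate_experiment()` reproduces the composition-bias mechanism
exactly as the sampling model states it: base expression per gene is
drawn from a configurable source, condition-unique genes get expression 0
in the other condition, DE genes are multiplied by `fold_change` in the
favoured condition, truth totals $S_z$ are summed, and every library is
an independent Poisson draw with mean $\mu_{gz}/S_z\cdot N_k$. The truth
object records $S_z$, per-gene labels, and the realized DE fractions
(counts are floored, so configured and realized fractions can differ at
small gene numbers).

The default expression source is a heavy-tailed parametric stand-in —
$\lceil e^{N(4,\,2)}\rceil$ on the natural-log scale, median ≈ 55 with a
long right tail — chosen to mimic the skewed count distributions of real
libraries while keeping the package free of external data; log-sd 2 is
the spread, and log-mean 4 a typical magnitude, of log-count
distributions in bulk transcriptome data. An empirical source
(`build_source(counts)`) resamples any user-supplied library instead.

Not emulated: biological overdispersion (all replication is Poisson,
i.e. technical), gene-length or GC sampling bias, and any mapping
artifacts. Passing tests therefore demonstrate correctness of the
estimator and tests *under the stated sampling model*, not robustness to
overdispersed biological replicates — the exact and LR tests here are
anti-conservative on such data, and a dispersion-aware model should be
used instead.

### Problem sizes used in the checks

The packaged checks run at desk scale, with sizes chosen to make each
property legible: oracle comparisons use matrices of 50–500 genes;
recovery and robustness checks use 5,000–10,000 genes. Depth matters
scientifically, not just computationally: the twice-the-RNA scenario is
run at $10^6$ reads (mean counts of hundreds, since half the genes are
absent in one condition), while the robustness-to-asymmetric-DE check
runs 10,000 genes at $10^7$ reads — the depth regime of the tissue
datasets this literature analyzed, giving mean counts in the hundreds.
This matters because the 30% trim can only excise a 25% one-directional
DE block if the 1-log2 DE offset stands clear of the Poisson noise of
$M$ (sd $\approx \sqrt{2/Y}/\ln 2$); at mean counts of ~15 the ranks mix
and the factor estimate degrades to ~7% error. That depth dependence is
a genuine limitation of the robustness claim, stated here rather than
hidden.

## Known limitations

* Factors are pairwise against one reference; no recentring (e.g. to
  geometric mean 1) is applied, so factors from different references are
  not directly comparable.
* The delta-method weights assume binomial sampling within a library;
  with overdispersion they overweight high-count genes.
* The exact binomial p-value convention (minimum-likelihood) is one of
  several two-sided conventions; ranking is barely affected but exact
  p-values near discontinuities can differ across conventions.
* `reference = "auto"` is a deterministic heuristic (median-$A$ proximity
  to the first library), not an optimality criterion.
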