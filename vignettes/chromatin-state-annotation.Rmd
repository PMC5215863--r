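---
title: "Chromatin-state annotation with overdispersed count HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin-state annotation with overdispersed count HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countseg)
```

## The model

Chromatin assays (ChIP-seq of histone modifications, DNA accessibility)
produce read counts along the genome. countseg partitions the genome into
fixed-width bins (200 bp by default), counts fragment midpoints per bin and
per assay ("track"), and models the resulting multivariate count sequence
with a hidden Markov model. Each hidden state represents a recurrent
combination of signal levels — a chromatin state such as promoter, enhancer
or repressed region. Conditional on the state, tracks are independent, so
the state emission factorizes into per-track distributions.

Raw Poisson emissions underestimate the variance of sequencing counts. The
package therefore supports two overdispersed emission families, both
derivable as Poisson mixtures:

* **Negative binomial** (Poisson–Gamma): mean $\mu$, dispersion $r$,
  variance $\mu + \mu^2/r$. The Poisson limit is recovered as
  $r \to \infty$.
* **Poisson-lognormal**: a Poisson whose rate is lognormal with log-mean
  $\mu_{\log}$ and log-sd $\sigma$. Its pmf has no closed form and is
  evaluated by numerical quadrature (below). It has heavier tails than the
  negative binomial at equal variance, which suits the extreme coverage
  spikes of real chromatin data.

Variance is modelled separately for every state and track. Parameters are
fitted by Baum–Welch (EM): the E-step computes posterior state
probabilities with a log-space forward–backward recursion; the M-step
updates initial and transition probabilities in closed form and refits each
state-track emission by bounded numerical maximum likelihood. Because an
emission pmf depends on a bin only through its count, the weighted
objective is first collapsed onto the set of *unique* counts
($f_c = \sum_{t: o_t = c} \Pr(s_t = i \mid O)$), which reduces each M-step
evaluation from the number of bins to the number of distinct counts without
changing the objective. When several cell types with different sequencing
depths are fitted jointly, grouping keys are (count, cell type) pairs.

## Library-size correction

Sequencing depth varies between libraries. For track $d$ in cell type $l$
with library size $r_{d,l}$ (total read count), `compute_size_factors()`
uses the total-count method:

$$s_{d,l} = \frac{1}{r_{d,l}} \cdot \frac{\sum_{k} r_{d,k}}{|\mathcal L|}$$

This is the multiplier that scales library $l$ *to* the track's average
depth, so $s_{d,l}\,r_{d,l}$ is constant across cell types. Inside the
likelihood the emission mean of a state must instead be scaled *to* each
library's depth, i.e. multiplied by the depth-relative factor
$1/s_{d,l}$ (`emission_factors()`). With this convention a fitted $\mu$ is
expressed in reads per bin at the average library size, and a model fitted
on one cell type agrees with a joint fit that includes a deeper duplicate
of the same cell type — the invariance the correction exists to provide.
The distinction between the two directions matters: applying the
total-count factor directly to the emission mean would scale deeper
libraries *down* and shallower ones *up*, and no single $\mu$ could fit
both.

## Initialization

EM converges to a local optimum, so initialization matters. The package
uses the thresholding/k-means scheme standard for chromatin count data:

1. Per track, an enrichment threshold $n_d$ — the smallest integer
   $n > 0$ with $\Pr(X > n) < 10^{-4}$ for Poisson $X$ with the track's
   mean — separates signal from background counts.
2. Counts below their track's threshold are set to 0 in a working copy.
3. Bins that are all-zero after thresholding form a *background cluster*.
4. k-means with $K-1$ centers runs on $\log(\text{count} + 1)$ of the
   remaining bins (pseudocount 1; 10 seeded restarts).
5. Emission parameters are estimated per cluster and track by method of
   moments from the raw counts (negative binomial $r$ clamped to
   $[10^{-2}, 10^4]$; poilog $\sigma$ to $[0.05, 5]$).
6. Initial and transition probabilities start uniform.

Clustering runs on raw (unscaled) thresholded counts pooled across cell
types; size factors enter only through the likelihood. Note the practical
consequence of thresholding: a state whose mean lies *below* the
genome-wide Poisson threshold of every track is absorbed into the
background cluster and can only be separated later by EM itself. Real
chromatin tracks are sparse (background means well below one read per
bin), which is the regime the scheme is designed for.

## Numerical choices

* **Poisson-lognormal quadrature.** In $m = \log\lambda$ the log-integrand
  $x m - e^m - (m - \mu)^2 / 2\sigma^2 + \text{const}$ is strictly concave,
  so its mode is found by Newton iteration and the integration support
  (where the integrand exceeds mode $\times e^{-45}$) is bracketed by
  bisection. Fixed 60-node Gauss–Legendre quadrature on that interval is
  deterministic and accurate to below $10^{-8}$ absolute pmf error for
  $x \le 100$, $\sigma \le 4$ (verified against adaptive quadrature in the
  tests).
* **Emission optimization** runs in $(\log\mu, \log r)$ /
  $(\mu_{\log}, \log\sigma)$ to enforce positivity, with L-BFGS-B, box
  bounds, and a fixed pattern of three perturbed restarts. For the
  negative binomial with a common size factor the weighted MLE of $\mu$ is
  the weighted sample mean for *every* $r$ (stationarity of the
  likelihood), so $\mu$ is profiled out exactly and only $r$ is optimized.
* **Degenerate emissions.** If all posterior weight sits on zero counts,
  the mean is clamped to $10^{-3}$ reads/bin rather than 0, keeping the
  log-pmf finite. All pmf evaluations inside EM are floored at
  $10^{-300}$ so isolated outlier bins cannot produce $-\infty$
  log-likelihoods.
* **Recursions** run in log space (not with scaling factors): with
  probability floors in place the correctness argument is simpler, and the
  cost is identical. The forward–backward and Viterbi cores are compiled
  (Rcpp).
* **Convergence**: relative log-likelihood improvement below $10^{-6}$ or
  500 iterations, both configurable.
* **Decoding.** Per-bin posterior argmax is the default (it matches the
  per-bin granularity of the benchmarks); exact Viterbi is available.
  Ties break toward the lower state index in both.
* **$\sigma$ floor.** On Poisson-distributed data the poilog MLE drives
  $\sigma \to 0$, where the quadrature degenerates; the optimizer bounds
  $\sigma \ge 0.05$, which biases the implied mean by under
  $e^{0.00125} - 1 \approx 0.13\%$ — negligible against sampling noise.

## Benchmarking statistics

A segmentation is evaluated against reference regions (e.g. transcription
start sites or high-occupancy-of-target regions) by turning it into a
binary classifier: per state, precision is the fraction of its segments
(or 200 bp bins) overlapping the reference; states are sorted by
decreasing precision; cumulative recall and FDR are traced as states are
added in that order; and the state rank, used as a per-bin score, yields
an AUC with midrank tie handling (equal, by construction, to
$P(\text{score}_{pos} > \text{score}_{neg}) + \tfrac12 P(\text{tie})$).
Overlap means $\ge 1$ bp intersection (configurable); reference regions
are merged before recall counting so overlapping references are not
double-counted. Recall denominators are reference units (regions at
segment level, true bins at bin level) — the natural reading of
"recall"; the predicted-segment denominator appears only in the FDR.

Enrichment statistics follow the nucleotide-density convention: a TF with
$TF^{nt}$ peak nucleotides, $TF_s^{nt}$ of them in state $s$ covering
$s^{nt}$ of a genome of length $l$, has enrichment
$(TF_s^{nt}/TF^{nt})/(s^{nt}/l)$, normalized per TF to sum to 1 over
states. Co-binding of two TFs within a state is a Jaccard index over peaks
restricted to the state; the package counts *sites* by default (a
co-occurrence is a reciprocal $\ge 1$ bp peak overlap, and the
co-occurrence count is the average of the two directional hit counts so
the rate is symmetric), with a nucleotide intersection-over-union mode
behind a flag. GWAS trait enrichment tests each trait with at least 20
catalog SNPs against the rest of the catalog with a one-sided Fisher's
exact test (SNPs are 1 bp points), adjusted by Benjamini–Yekutieli across
all (trait, cell type) tests; coverage-controlled recall subsamples whole
segments uniformly without replacement until a fixed genomic coverage is
reached (overshoot allowed on the last draw), repeated 100 times for
empirical 95% intervals. Being an exact test on discrete tables, the
Fisher p-value is *conservative* (super-uniform) for traits with few
SNPs; null p-values approach uniformity only as catalogs grow, which the
calibration tests exercise at both regimes.

## What the synthetic generator does and does not emulate

`example_model()` + `simulate_hmm_counts()` generate data exactly from the
fitted model class: a background state with low mean everywhere plus
signal states each enriched in its own track, diagonal-dominant
background-returning transitions, and per-cell-type depth multipliers.
`plant_reference_regions()` and `plant_snps()` place benchmark regions and
GWAS catalogs with known in-state precision and density ratios. Default
conditions used across tests and the acceptance script: 200 bp bins,
$K = 3$, $D = 2$, self-transitions 0.95, background mean 0.5 reads/bin,
signal mean 20 reads/bin, NB dispersion 5 — sparse, strongly enriched
tracks of the kind the initialization scheme expects; recovery runs use
50 000 bins (a 10 Mb chromosome), chosen large enough that sampling error
sits well below the tested tolerances.

Passing these tests shows the estimator is correct *under its own
assumptions*. Real data violate them in ways the generator does not
emulate: mappability and copy-number artifacts, spatially varying
background, correlated tracks within a state, fragment-length structure,
and chromatin states that are mixtures rather than homogeneous emitters.
Benchmarks on synthetic data therefore validate the machinery, not the
biology; state labels (promoter, enhancer, ...) remain the user's
interpretive call.

## Worked example

```{r example, eval = FALSE}
library(countseg)

genome <- binned_genome(data.frame(chrom = "chrS", length = 2e6),
                        bin_width = 200)
truth <- example_model(K = 3, D = 2, family = "negbinom")
sim <- simulate_hmm_counts(truth, genome, seed = 1)

init <- initialize_hmm(sim$counts[[1]], K = 3, family = "negbinom", seed = 1)
fit <- baum_welch(init, sim$counts[[1]])
glance(fit)
tidy(fit)

path <- posterior_decode(forward_backward(fit, sim$counts[[1]]))
annotation <- path_to_segments(path, genome)
summarize_states(annotation, genome, counts = sim$counts[[1]])

refs <- plant_reference_regions(path_to_segments(sim$truth$paths[[1]], genome),
                                genome, "S3", precision_in_state = 1,
                                n = 200, seed = 2)
auc_score(annotation, refs, genome)
autoplot(cumulative_recall_fdr(annotation, refs, genome, level = "bin"))
```

## Known limitations

* $K$ is user-chosen; no statistical selection criterion is provided.
* Zero-inflated or mixture emissions are not implemented.
* The fragment-shift estimator is the plain strand cross-correlation of
  5'-end coverage at 1 bp resolution; no smoothing or artifact masking.
* Fitting is single-threaded; the count-grouping trick, the profiled NB
  M-step and the compiled recursions are the speed levers instead.
* Whether published chromatin-state maps of this model family used
  Viterbi or posterior decoding is not documented; both are provided, and
  the two agree on all but ambiguous bins for well-separated states.
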