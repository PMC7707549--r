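---
title: "Model and methods behind noveltytagm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind noveltytagm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noveltytagm)
```

## The problem

Spatial proteomics experiments (LOPIT, hyperLOPIT, LOPIT-DC, organellar
maps) quantify each protein across L sub-cellular fractions, giving a
profile $\mathbf{x}_i = (x_{1i}, \dots, x_{Li})$ for each of N proteins.
Proteins that reside in the same sub-cellular niche share a characteristic
profile. A curated marker list annotates a subset of proteins with one of K
known niches; the task is to assign the remaining proteins — while
acknowledging three realities of such data: many proteins are dispersed and
fit no niche; annotation is incomplete, so genuinely novel sub-cellular
phenotypes may hide in the unlabelled set; and any assignment should come
with calibrated uncertainty, not a hard label.

## The model

Each protein carries a component label $z_i \in \{1,\dots,K_{max}\}$ and an
outlier indicator $\phi_i$:

$$\mathbf{x}_i \mid z_i = k, \phi_i \;\sim\;
  \mathcal{N}(\boldsymbol\mu_k, \Sigma_k)^{\phi_i}\,
  \mathcal{T}(\kappa, \mathbf{M}, V)^{1-\phi_i},$$

a Gaussian for niche-resident proteins and a single heavy-tailed
multivariate Student-t for dispersed ones, with
$p(\phi_i = 0) = \varepsilon$ inferred from the data. The outlier
parameters are fixed empirically: $\kappa = 4$, $\mathbf{M}$ the global
mean profile, and $V$ half the global covariance (labelled and unlabelled
proteins together, unbiased $N-1$ estimator). "Half the global variance" is
read as the full $L \times L$ covariance matrix — the t density is
multivariate and a full scale matrix is the natural choice — with
`outlier_scale = "diagonal"` available for ill-conditioned data.

Novelty detection comes from *overfitting* the mixture: on top of the K
marker-anchored components, $K_{novelty}$ additional components (default
10) with identical, exchangeable priors are provided. With a modest
Dirichlet concentration on the mixture weights, components not supported by
the data remain empty, so the occupied count — monitored as the convergence
diagnostic — estimates how many phenotypes the data actually support.
Mixture weights follow a symmetric Dirichlet(α) with α = 1 by default;
larger values inhibit emptying and are discouraged in the documentation.

Component means and covariances carry a conjugate Normal-Inverse-Wishart
(NIW) prior and are never sampled: the collapsed Gibbs sampler works with
per-component sufficient statistics (count, sum, scatter) and evaluates
posterior-predictive densities, which are multivariate t with
$\nu_n - L + 1$ degrees of freedom under the standard conjugate updates.

### Prior defaults and why

The exact priors used in the original analyses are not part of the main
published text, so the package adopts weakly informative, scale-matched
empirical-Bayes conventions, all overridable through `model_spec()` or a
YAML configuration:

* `mu0` — global empirical mean; centres every component on the data.
* `lambda0 = 0.01` — weak confidence in `mu0`, letting component locations
  follow their members.
* `nu0 = L + 2` — the weakest proper choice with a finite prior covariance.
* `S0 = cov(X) / K_{max}^{2/L}` — divides the total data scatter by the
  volume share a single component is expected to occupy.
* `eps ~ Beta(2, 10)` — mild preference for a small outlier fraction.

Novelty components share the known components' NIW prior: exchangeability
is what justifies both the overfitted-mixture emptying argument and the
label-invariant summaries below.

### Sampling scheme

One sweep visits proteins in ascending index order (a fixed scan order
keeps runs reproducible). For an unlabelled protein the pair
$(z_i, \phi_i)$ is drawn jointly from a single categorical over the
$K_{max}$ Gaussian slots plus one aggregated outlier slot:

* slot $k$: $(n_{-i,k} + \alpha)\,(1-\varepsilon)\,p_k(\mathbf{x}_i)$, with
  $p_k$ the collapsed predictive and $n_{-i,k}$ the count of other proteins
  with $z = k$;
* outlier: $\varepsilon\, g(\mathbf{x}_i)\sum_k (n_{-i,k} + \alpha)$, after
  which a latent component label is drawn from the conditional prior
  weights, keeping the component-indexed outlier terms of the likelihood
  well defined and the PSM coherent.

Marker proteins keep $z$ fixed but have $\phi$ resampled against their own
component (`fix_marker_phi = TRUE` disables this); markers can genuinely be
dispersed relative to their class. The sweep ends with the conjugate
update $\varepsilon \sim \mathrm{Beta}(u + \#\{\phi=0\},\, v +
\#\{\phi=1\})$. All densities are evaluated in log space with log-sum-exp
normalisation; scale matrices that fail a Cholesky factorisation receive a
diagonal jitter of $10^{-8}\,\mathrm{tr}(S)/L$ before a second attempt.

The inner loop is compiled (RcppArmadillo) with cached per-component
Cholesky factors invalidated only when a component's membership changes.
Correctness of the whole collapsed scheme is established distributionally:
on problems small enough to enumerate every $(z, \phi)$ configuration with
closed-form NIW marginal likelihoods, the sampler's assignment frequencies
match the exact posterior within Monte-Carlo error (see the test suite and
`scripts/acceptance.R`).

## Posterior summaries

All summaries pool chains after burn-in; every reported quantity is
invariant to component relabelling, so label switching across chains is
harmless.

* **Posterior similarity matrix (PSM).** Entry $(i,j)$ is the fraction of
  retained draws in which unlabelled proteins $i$ and $j$ share a
  component. Draws where a protein is an outlier contribute through its
  latent label by default (`psm_exclude_outliers` flips this). Marker
  proteins are excluded: their assignment is fixed, so their co-clustering
  is degenerate.
* **maxPEAR clustering.** The PSM is summarised into one partition by
  maximising the posterior expected adjusted Rand index, computable in
  closed form from the PSM for any candidate partition. The candidate set
  is every cut of an average-linkage dendrogram on $1 - \mathrm{PSM}$
  (optionally also the sampled partitions); on every instance small enough
  to check, the selected partition attains the exhaustive set-partition
  optimum. A PSM with no off-diagonal mass returns singletons with a
  warning.
* **Discovery probability.** For unlabelled protein $i$,
  $1 - \tfrac1T\sum_t \sum_{k \le K} P(z_i^{(t)} = k \mid \cdot)$, using
  the retained (Rao-Blackwellised) conditional allocation probabilities.
  It is high both for members of coherent new phenotypes and for outliers —
  which is why the PSM heatmap filters on the outlier probability as well.
* **Outlier probability.** The posterior frequency of $\phi_i = 0$.
* **Putative phenotypes.** maxPEAR clusters whose mean discovery
  probability exceeds 0.5 (predominantly novel) and that contain at least
  one protein with discovery probability above 0.95, reported in
  decreasing size order.

## The synthetic-data generator

`simulate_spatial_proteome()` draws data from exactly the structure the
model assumes: spherical Gaussian niches (anisotropic diagonal covariances
optional), a $t_4$ outlier component centred on the layout, hidden
phenotypes that receive no markers, and curated markers drawn from inlier
proteins of visible niches only. Separation deserves a note: it is
specified as the ratio of inter-mean distance to the within-component RMS
radius $\sigma\sqrt{L}$. A per-dimension reading ($5\sigma$ mean distance
regardless of L) makes high-dimensional niches overlap their own radius,
at which point the empirically-scaled Student-t honestly absorbs whole
clusters — a regime the generator's defaults deliberately avoid, because
its purpose is to emulate resolvable niche structure. Profiles are not
forced onto the simplex; `simplex = TRUE` applies a row-wise softmax to
mimic sum-normalised LOPIT exports.

What the generator does *not* emulate: instrument-level effects (TMT ratio
compression, missing values), correlated replicate structure, or niches
with non-elliptical shapes. Passing recovery tests on these fixtures
therefore demonstrates correctness of the inference machinery under the
model's own assumptions, not robustness to real-data misspecification.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale configurations
chosen to make the statistical checks sharp: enumeration problems with four
unlabelled univariate proteins and $10^5$ thinned draws; emptying and
masking designs with 200 proteins in 7–10 fractions at separation 5;
phenotype-count designs with 180 proteins and two planted niches across
five seeds. Default fitting parameters for real data are larger
(`chains = 4`, `n_iter = 10000`, `burn = 2000`, `thin = 4`) and are
deliberately configuration, not constants — the published analyses this
model family targets run tens of thousands of iterations.

Degenerate inputs are handled explicitly: an all-labelled dataset with
`k_novelty = 0` warns that nothing remains to infer; `eps = 0` removes the
outlier slot exactly; empty novelty components use the bare prior
predictive with weight α; ties between components with identical
statistics are exact by construction.

## Known limitations

* The single-site sampler can mix slowly between modes that split one
  cluster across several novelty components; running several chains and
  monitoring the occupied-component scale reduction (threshold 1.1 in
  `diagnose()`) is the intended guard. No split-merge or tempering moves
  are provided, by design.
* In geometries where niche spread approaches niche separation, the
  empirically-fixed outlier component competes with genuine niches and the
  posterior legitimately shifts mass to $\phi = 0$; this is model
  behaviour, not a sampling failure, and shows up as a high posterior
  outlier rate.
* Missing values are rejected, not imputed; replicate concatenation is
  left to the user.
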