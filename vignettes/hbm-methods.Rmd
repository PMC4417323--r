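---
title: "Spike-and-slab models for GWAS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-and-slab models for GWAS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbmgwas)
```

## The model

A quantitative phenotype on $n$ individuals is modelled jointly on all $N$
SNPs:

$$ y = X\beta + Wb + \varepsilon, \qquad \varepsilon \sim N(0, \sigma_e^2 I), $$

where $X$ holds fixed effects (intercept, externally supplied principal
components, ...), and $W$ is the column-standardized genotype matrix: allele
counts $x_{ij} \in \{0,1,2\}$ transformed as
$w_{ij} = (x_{ij} - 2p_i)/\sqrt{2p_i(1-p_i)}$ with $p_i$ the empirical
reference-allele frequency. Each SNP effect follows a mixture of a point
mass at zero and a normal "slab",

$$ b_j \mid I_j \sim (1 - I_j)\,\delta_0 + I_j\, N(0, \sigma_b^2),
   \qquad I_j \sim \text{Bernoulli}(p), $$

so the latent indicators perform variable selection while every SNP stays
in the model. The mixed linear model used by GCTA-style heritability
analysis is the special case $p = 1$. The proportion of phenotypic
variance explained is

$$ \mathrm{PVE} = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_e^2},
   \qquad \sigma_g^2 = \sigma_b^2 \times \#\{j : I_j = 1\}, $$

i.e. the genetic variance counts the slab SNPs only. Priors are
conjugate and deliberately diffuse: $p \sim \mathrm{Beta}(1,1)$,
$\sigma_b^2, \sigma_e^2 \sim \mathrm{IG}(0.001, 0.001)$, and independent
$N(0, \sigma_a^2)$ on each fixed effect with $\sigma_a = 10^5$ interpreted
as a prior *standard deviation* (the diffuse intent is unambiguous even
though a variance reading would also be diffuse).

## The sampler

`run_gibbs()` is a component-wise Gibbs sampler. Per sweep, for each SNP in
turn, the indicator is drawn with the effect integrated out: with
$z_j = w_j^\top r_{-j}/\sigma_e^2$ and
$d_j = w_j^\top w_j/\sigma_e^2 + 1/\sigma_b^2$, the posterior log-odds of
inclusion are

$$ \log\frac{p}{1-p} - \tfrac12 \log(\sigma_b^2 d_j) + \frac{z_j^2}{2 d_j}, $$

then $b_j \mid I_j = 1 \sim N(z_j/d_j,\, 1/d_j)$ and $b_j = 0$ otherwise.
The residual $r = y - X\beta - Wb$ is maintained incrementally, so a sweep
costs $O(nN)$ regardless of how many SNPs are active — this is what makes
the sampler practical when $p$ is small and $N$ is large. The fixed
effects, the two variances and $p$ then follow from their standard
conjugate full conditionals (normal, inverse-gamma, inverse-gamma, Beta).

Two variants are exposed because each is the natural object for a
different check, not because routine use needs them:

* **Spike width.** `hbm_priors(spike_sd = 0.01)` replaces the point mass
  by a narrow $N(0, \sigma^2)$ spike, under which the mixture is a pair of
  normals. The two parameterizations agree on posterior inclusion
  probabilities to within 0.05 on our fixtures; the exact point mass is
  the default because excluded effects are then exactly zero.
* **Block refresh.** `chain_config(block_refresh = TRUE)` re-draws all
  active effects jointly after the scan. The joint draw uses a Cholesky
  factor of the $k \times k$ precision when $k \le n$ and the
  Sherman–Morrison–Woodbury route (rank $n$) when the active set exceeds
  the sample size, following the constant-cost Gaussian sampling scheme
  of Bhattacharya, Chakraborty and Mallick (2016, *Biometrika*). The two
  routes agree on posterior moments to $10^{-8}$.

Chain defaults are 5,000 burn-in sweeps and 2,000 retained draws. All
density ratios are computed in log space; Cholesky factorizations retry
once with a $10^{-8}$ jitter; inverse-gamma draws are clamped to
$[10^{-12}, 10^{12}]$ because the IG(0.001, 0.001) prior occasionally
produces astronomically large draws when the active set is momentarily
empty (in that state the slab variance is drawn from its prior, which is
the documented fallback).

Initialization: $I = 0$, $b = 0$, $\beta$ at its least-squares value,
$\sigma_e^2 = \mathrm{Var}(y)/2$, $\sigma_b^2 = 0.1$, and $p = 0.01$
rather than the prior mean 0.5 — starting at GWAS-realistic sparsity
avoids a long early phase in which thousands of SNPs are activated and
then slowly pruned; the chain is ergodic either way. The scan order is
sequential by default (reproducibility); a per-sweep random permutation is
available (`scan_order = "random"`) and targets the same posterior.

Selection uses posterior inclusion probabilities (the per-SNP mean of the
retained indicator draws) with a default threshold of 0.5 — the median
probability model. The threshold is configurable, and the reported
posterior mean of $p$ times $N$ is the natural cross-check on the size of
the selected set.

## The REML baseline

`fit_mlm_reml()` maximizes the restricted likelihood of
$y \sim N(X\beta,\, A\sigma_g^2 + I\sigma_e^2)$, with $A = WW^\top/N$ the
genomic relationship matrix. The GRM is eigendecomposed once and all
iterations work in the rotated basis where the covariance is diagonal, so
each iteration is $O(n)$ after the one-off $O(n^3)$ decomposition. The
first step is an EM update; later steps take the average-information
direction with an EM fallback whenever an AI step would leave the
parameter space or reduce the restricted likelihood, and variances are
clamped at a small positive boundary. Standard errors come from the
inverse AI matrix; the PVE standard error by the delta method. This is a
self-contained re-implementation of the standard AI-REML scheme — the
contract is agreement with the restricted-likelihood optimum (verified
against a dense grid search), not numerical identity with any particular
external program. Per-SNP BLUP effects are backsolved as
$\hat b = (\sigma_g^2/N)\, W^\top V^{-1}(y - X\hat\beta)$, which makes the
MLM's effect-dilution explicit: its per-SNP variance is $\sigma_g^2/N$
however sparse the true architecture is.

## The simulator

`simulate_gwas()` emulates the benchmark designs with known truth:

* Genotypes: per SNP a minor-allele frequency is drawn from U(0.05, 0.5)
  and counts are i.i.d. Binomial(2, MAF) — Hardy–Weinberg equilibrium and
  linkage equilibrium. An optional autoregressive LD-block mode
  (`ld_rho`) couples adjacent SNPs for robustness probes.
* Effects: exactly `round(mixture_p * n_snps)` SNPs (not Bernoulli
  thinning, so truth counts are reproducible) receive $N(0, \sigma_b^2)$
  slab effects; the rest are zero (**Case 1**) or $N(0, 0.01^2)$ noisy
  effects (**Case 2**, the misspecification stress test).
* Noise: $\sigma_e^2$ is calibrated from the *empirical* variance of the
  realized slab-only genetic values,
  $\sigma_e^2 = \widehat{\mathrm{Var}}(W_{\mathrm{slab}} b_{\mathrm{slab}})
  (1-\mathrm{PVE})/\mathrm{PVE}$, so the realized slab PVE equals the
  target exactly in-sample. Using the slab-only values matches the PVE
  definition above; in Case 2 the small noisy effects are *additional*
  variance that a correctly specified analysis should attribute to the
  residual, which is precisely what the MLM cannot do — its PVE estimate
  absorbs the noise effects into $\sigma_g^2$ and lands above the truth.

What the simulator does **not** reproduce about real genotype panels:
linkage disequilibrium (except the stylized AR mode), population
structure and relatedness, allele-frequency/effect-size coupling, and
case–control ascertainment. Passing tests therefore demonstrate
correctness of the estimation machinery under the model's own
assumptions, not robustness to those real-data features.

## Study sizes used in the test suite

The original benchmarks used $N = 10^4$–$10^5$ SNPs on restricted-access
cohort genotypes with multi-hour, large-memory runs. The packaged studies
are desk-scale replications chosen so each chain runs in seconds:

* Parameter recovery (Case 1): $N = 2{,}000$, $n = 500$, $p = 0.01$,
  $\sigma_b^2 = 0.1$, PVE 0.5; chains of 2,000 burn-in + 1,000 kept;
  10 seeds.
* Misspecification contrast (Case 2): $N = 5{,}000$, $n = 1{,}000$,
  $p = 0.003$. Of the two Case 2 designs, this is the one where the
  expected MLM upward bias (noise-to-slab variance ratio $1/3$, about
  $+0.07$ PVE) is resolvable above REML sampling noise at desk scale; at
  $p = 0.01$ the stated spike and slab widths put the bias at $+0.024$,
  below the noise floor of any run we can afford, so a paired comparison
  there would measure noise.
* Detection operating point: $N = 5{,}000$, $n = 1{,}000$, $p = 0.003$,
  5 seeds. At these sizes an average slab effect carries a marginal
  $z \approx 3.6$, so roughly half of the *random* slab effects (the
  smaller half) sit below the evidence level that prior odds of
  $\sim 1/300$ require for PIP $\ge 0.5$ — the measured true-positive
  rate of $\approx 0.56$ at a false-positive rate below $10^{-3}$ is the
  information-theoretic operating point of these study conditions, not a
  sampler limitation (doubling the chain length does not change it).
* The exact-enumeration oracle (all $2^N$ indicator configurations,
  $N \le 9$, hyperparameters held fixed on both sides) and the REML
  grid-search oracle run at $n = 40$–$50$.

The posterior-concentration check compares $n = 250$ against
$n = 1{,}000$ on robust (IQR) spreads: the raw posterior s.d. of
$\sigma_b^2$ is dominated by the rare prior draws taken when the active
set is momentarily empty, and the spread of $p$ at these sizes is driven
by how many signals are detected at all, so only $\sigma_b^2$ and PVE
spreads are asserted to shrink.

## Known limitations

* Independence of indicators ignores LD; in dense LD the PIP mass of a
  causal signal is shared across its proxies.
* The collapsed component-wise update costs a full $O(nN)$ sweep even at
  high sparsity; for $N \gg 10^5$ a screened or blocked scan would be
  needed.
* The PVE convention counts slab SNPs only; under architectures with many
  tiny true effects the "true" PVE is itself a modelling choice, and the
  Case 2 analyses quantify exactly this ambiguity.
* Monomorphic SNPs must be removed before standardization
  (`filter_snps()`); missing genotypes are mean-imputed (standard GWAS
  practice — the QC pipeline filters heavily before this matters).
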