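---
title: "QSPR modeling of binary mixtures with mixqspr: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QSPR modeling of binary mixtures with mixqspr: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixqspr)
```

# The modeling problem

Deep eutectic solvents (DESs) are binary mixtures of a hydrogen-bond
acceptor (HBA, typically a quaternary ammonium halide salt) and a
hydrogen-bond donor (HBD) at a fixed molar ratio. Their bulk properties —
here, surface tension $\sigma$ in mN/m — depend on both components, on the
molar ratio, and on temperature. `mixqspr` implements a complete
quantitative structure–property relationship (QSPR) workflow for such
mixtures: descriptor construction, leakage-free data splitting,
forward-selection linear modeling, a validation battery, and consensus
prediction. It also ships a frozen, published six-variable model
(`predict_sigma_m12()`) as a ready-to-use predictor.

# Weighted-mixture descriptors

Per-component molecular descriptors $D_1, D_2$ (Dragon-style 0D–2D values,
supplied as a table — the package does not compute them) are combined with
the molar fractions $x_1 + x_2 = 1$ into weighted-mixture (WM) descriptors:

$$D_{pmix} = x_1 D_1 + x_2 D_2, \qquad D_{nmix} = |x_1 D_1 - x_2 D_2|.$$

`build_features()` with `method = 1` emits only the $D_{pmix}$ columns;
`method = 2` emits both. Three auxiliary candidate variables are always
appended: the measurement temperature (K) and two binary indicators for a
chloride or bromide anion on the salt HBA — the cation carries the
molecular descriptors, the anion enters only through the flags.

Candidate columns then pass `filter_features()`: variance below 0.001
drops a column; scanning pairs in input order, $|r| > 0.95$ drops the
*later* column. Both cutoffs are strict inequalities, and the
keep-the-earlier rule makes the filter deterministic and idempotent. The
filter is applied to the training rows only and the surviving column list
is reused for test/external rows, so no information leaks from evaluation
sets into column selection.

# Deterministic mixtures-out and compounds-out splitting

Random record-wise splits leak information for mixture data: the same DES
measured at several temperatures would straddle the partition. Two schemes
avoid this, both driven by a `(seed, interval)` pair:

* **MO (mixtures-out)** — unique mixtures (component pair + reduced molar
  ratio; temperature does not enter the identity) are sorted by occurrence
  count, descending, with lexicographic tie-break. Stepping through that
  list from position `seed` with stride `interval` selects the test
  mixtures; all their records move to the test set together.
* **CO (compounds-out)** — the same stepping rule runs independently over
  the occurrence-sorted HBA list and HBD list; every record containing a
  selected chemical (in its role) is a test record, so selected chemicals
  never appear in training.

`enumerate_valid_splits()` scans all `seed ≤ 6, interval ≤ 6` pairs and
retains splits with `|train| > |test|` and `|test| ≥ 0.15·|train|`,
collapsing duplicate partitions. The stepping interpretation of
"seed/interval grouping" is the simplest deterministic reading; the design
keeps `mo_split()`/`co_split()` as the single point where an alternative
(e.g. block-grouping) could be swapped in if transcribed measured data
ever showed the step rule does not reproduce published set sizes.
Degenerate selections raise errors rather than silently producing empty
sets; the enumerator simply skips them.

Molar ratios are canonicalized by continued-fraction rationalization of
$x_1$ at tolerance $10^{-6}$ (so $x_1 = 0.333333$ is the ratio 1:2); if no
small-denominator fraction fits, $x_1$ rounded to four decimals identifies
the mixture. Mixture identity deliberately includes the ratio: the same
pair at 1:2 and 1:3 are different solvents with different properties.

# Forward selection under an error-reduction policy

Models are ordinary least squares fits (`fit_ols()`, QR-based, with exact
per-coefficient standard errors). Descriptors enter by greedy sequential
forward selection (`sfs_select()`): at each step the candidate maximizing
the scoring criterion — training $R^2$, negative MAE, negative mean
Poisson deviance, or mean out-of-fold $R^2$ over a seeded 5-/10-fold
assignment — is provisionally added. The addition is kept only if it
reduces the leave-one-out mean absolute error by at least 5%:
$\mathrm{MAE}_{LOO}^{new} \le 0.95\,\mathrm{MAE}_{LOO}^{old}$, comparing
against the immediately preceding model. Selection stops at the first
rejection. This policy fixes the model size objectively, so models built
under different scorings and splits are comparable on a neutral footing.
Score ties break toward the lowest column index; with a fixed column
order the whole path is deterministic.

$\mathrm{MAE}_{LOO}$ inside the policy uses the exact hat-matrix identity
for OLS deleted residuals, $e_{(i)} = e_i/(1 - h_i)$, which equals the
literal $n$-refit loop to machine precision (this equivalence is one of
the package's core oracle tests). The Poisson-deviance scoring requires
positive responses; predictions are clipped at $10^{-6}$ as a numerical
safety net only, since surface tensions are positive.

# Validation battery

For a model and split, `validation_report()` assembles:

* $Q^2_{LOO} = 1 - \mathrm{PRESS}/\sum(y-\bar y)^2$ and
  $\mathrm{MAE}_{LOO}$ via the hat identity;
* **leave-chemical-out** statistics: every unique chemical (either role)
  is removed with all its records, coefficients are refit with the same
  feature subset, the removed records predicted, and all held-out
  predictions pooled. A record contributes once per chemical it contains;
  the total sum of squares is taken about the pooled observed mean.
  Refitting coefficients only (not re-running selection) keeps the
  statistic a property of the model under evaluation; a chemical whose
  removal leaves too few records is skipped and reported;
* external $R^2_{Pred} = 1 - \sum(y-\hat y)^2/\sum(y-\bar y_{tr})^2$ with
  the training mean as reference, MAE and %AARD (plus per-record %RD);
* scaled $r_m^2$ metrics: both vectors min–max scaled to $[0,1]$, then
  $r_m^2 = r^2(1 - \sqrt{r^2 - r_0^2})$ with $r_0^2$ from the
  through-origin regression, in both directions, with
  $\Delta r_m^2 = |r_m^2 - r_m'^2|$; square-root arguments are clamped at
  zero against underflow;
* Y-randomization (`y_randomization()`): 1000 seeded response
  permutations refit with the same features;
  $cR_p^2 = R\sqrt{R^2 - \overline{R_r^2}}$, clamped at zero;
* leverage applicability domain (`williams()`): $h_i = x_i'(X'X)^{-1}x_i$
  with intercept augmentation, warning leverage $h^* = 3(p+1)/N_{tr}$,
  standardized residuals as raw residuals over the training residual SD
  (plain residuals, not LOO-deleted — the conventional Williams-plot
  choice), $\pm 3$ response-outlier bounds; external rows are evaluated
  with the training $(X'X)^{-1}$.

$Q^2_{LCO} \le Q^2_{LOO}$ is *not* guaranteed and not asserted; what
matters diagnostically is their difference, which flags models biased
toward particular components.

# Campaigns, ranking and consensus

`run_campaign()` reproduces the full workflow: an optional one-off CO
carve-out of an external validation set (default seed 3, interval 4)
happens first; then every admissible split × descriptor method × scoring
produces one model with its full report; cell failures are recorded and
the campaign continues. `rank_models()` scores each cell by the mean of
$Q^2_{LOO}$, $Q^2_{LCO}$ and test-set $R^2_{Pred}$ (ties by test MAE);
`top_unique_models()` retains the best 15 distinct (partition, feature
set) pairs; `final_score()` averages the four predictivity statistics
(adding external $R^2_{Pred}$) to pick the overall winner.

Consensus prediction (`consensus_predict()`) combines two or more fitted
models: CM0 is the plain mean, CM1 the mean over *qualified* models, CM2
an inverse-error weighted mean, CM3 the per-record best model. A model
qualifies for a record when the record lies inside the model's leverage
domain ($h \le h^*$); per-record errors are the model's mean absolute
training residual over the $k = 10$ nearest training records, by
Euclidean distance in the model's standardized feature space. The
qualification and weighting rules are this package's own concrete choices
for the published strategy names (which defer to a closed-source tool);
the strategy layer is deliberately small so alternative rules can be
substituted without API change. Records with no qualified model fall back
to CM0 and are flagged.

Non-linear baselines (`tune_and_fit()`: kNN, random forest, SVM,
multilayer perceptron, gradient boosting) are tuned by a small grid search
scored by mean 5-fold CV $R^2$ with a fold assignment shared across
methods, then refit on the full training set — a fair non-linear yardstick
for a fixed descriptor subset.

# The synthetic-data generator

`generate_synthetic()` emulates the *statistical* structure the pipeline
assumes, with known ground truth — not DES hydrogen-bonding physics. The
defaults are the package's study conditions:

* 15 HBAs and 25 HBDs, each with 30 iid standard-normal descriptors. The
  library size matters: with too few components, pmix columns of distinct
  descriptors become strongly correlated through component reuse, and
  identification of the true feature set is no longer well-posed. Forty
  components is a realistic diversity for a ~60-mixture study.
* 60 unique mixtures at ratios from {1:1, 1:2, 1:3, 1:4, 2:1}, measured
  over 278.15–358.15 K in 20 K steps — 300 records.
* response $\sigma = 90 + \sum_j \beta_j D^{(j)}_{pmix} - 0.104\,T +
  \varepsilon$, $\varepsilon \sim N(0, 1\ \mathrm{mN/m})$, with five
  informative descriptors, $\beta = (4, -3, 3.5, -2.5, 2)$ — surface
  tensions around 55 mN/m, decreasing with temperature at a realistic
  rate.
* nuisance structure: three constant descriptors and three exact
  duplicates of informative ones, which the variance and correlation
  filters must remove; halide flags assigned per HBA (chloride with
  probability 0.7) and carrying no true signal.

Everything is reproducible bit-for-bit from the config seed. What passing
tests on these data do **not** show: robustness to non-Gaussian noise,
temperature-dependent coefficients, descriptor measurement error, or the
strong family structure of real DES datasets — they certify the machinery,
not chemistry.

# Numerical choices and edge cases

* Constant response: $R^2$ is reported as 0 by convention; rank-deficient
  designs raise an error naming the dependent columns.
* An empty forward-selection first step returns the intercept-only model
  with a warning flag rather than failing.
* Occurrence-sort ties break lexicographically (C collation) so splits
  are platform-independent.
* Cross-validated scorings draw their fold assignment from an explicit
  seed through an RNG-state-preserving wrapper; library calls never
  perturb the caller's RNG stream.
* The frozen published model stores coefficients at printed precision
  exactly; its standard errors are metadata and are not propagated into
  prediction intervals.

# Problem sizes used by the test-suite and acceptance script

The shipped checks run at deliberately small scale: 50 random systems of
15–24 records for the LOO oracle; 50 generator replicates at the default
300-record conditions for recovery (the observed exact-recovery rate is
reported as a percentage, with pooled 2-standard-error coefficient
coverage over the ~300 recovered coefficients — per-coefficient 2-SE
intervals have ~95% nominal coverage, so a joint all-coefficients check
per replicate would be expected to fail in about a quarter of replicates
even for a perfectly calibrated fit); a 200-record dataset for the split
invariants; and a 3×2×2-cell campaign for end-to-end recovery. These
sizes were chosen so the whole battery stays interactive while every
statistical claim retains enough replicates to be meaningful.

# Known limitations

* Descriptor values must be precomputed externally; only their
  combination into WM space is handled here.
* Ternary mixtures are out of scope; the data model is strictly binary.
* The consensus qualification/weighting internals are principled
  stand-ins, not a port of the original consensus tool.
* Leave-chemical-out refits coefficients under a frozen feature subset; a
  variant that re-runs selection per removal would measure the
  *procedure* rather than the model and is not implemented.
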