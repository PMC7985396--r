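---
title: "Assessing scale-freeness of biochemical reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing scale-freeness of biochemical reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfnet)
```

# The question

A genome or metagenome, once its enzymes are resolved to the reactions they
catalyze, defines a system of biochemical reactions. Whether the networks
induced by such systems are "scale-free" — whether their degree
distributions follow a discrete power law $f(x) = x^{-\alpha}$, typically
with $2 < \alpha < 3$ — is a long-debated question, complicated by two
facts: a reaction system admits many different graph projections, and
eyeballing a straight line on a log-log plot is not a statistical test.
`sfnet` implements the full assessment pipeline: eight network projections
per dataset, rigorous discrete power-law fitting with goodness-of-fit and
likelihood-ratio model comparison on every projection, a classification
ladder over the eight verdicts, and experiments asking whether
individual-level (genome) and ecosystem-level (metagenome) systems are
distinguishable from their degree-distribution statistics alone.

# Network projections

Each dataset is a set of reactions, each reaction a substrate set and a
product set of compound identifiers (stoichiometry is dropped; the
projections depend only on participation). Four construction rules are
applied to the whole dataset:

* **bi_full** — bipartite: compound connected to reaction if it
  participates on either side;
* **uni_compounds** — compounds connected if they co-occur in a reaction
  (either side);
* **uni_reactions** — reactions connected if they share a compound;
* **uni_subs_not_connected** — compounds connected only when they occur on
  *opposite* sides of a reaction.

Each rule is taken as the entire graph and as its largest connected
component (LCC), giving eight projections. All graphs are simple: parallel
edges collapse, and no rule creates self-loops (a compound on both sides of
one reaction contributes no self-edge; a reaction never neighbors itself).
The bipartite degree sequence pools compound and reaction nodes into one
distribution, so every projection yields exactly one degree distribution.
Reactions are treated as unordered substrate/product bipartitions:
physiological direction and reversibility are not tracked, and the stored
orientation only matters to `uni_subs_not_connected`, which is symmetric in
the two sides anyway. No currency-metabolite filtering is applied — hub
compounds are part of the measured structure. LCC ties (two equally large
components) are broken toward the component containing the
lexicographically smallest node id, for determinism.

# Fitting the discrete power law

The tail model on $\{x_{min}, x_{min}+1, \dots\}$ is
$p(x) = x^{-\alpha} / \zeta(\alpha, x_{min})$ with the Hurwitz zeta
normalizer, evaluated by explicit summation plus an Euler–Maclaurin
closure (`hurwitz_zeta()`, accurate to ~1e-12).

Two estimators of $\alpha$ are provided by `mle_alpha()`. The closed-form
half-shift estimator
$\hat\alpha = 1 + n\,[\sum_i \ln(x_i/(x_{min}-\tfrac12))]^{-1}$ with
standard error $\sigma = (\hat\alpha-1)/\sqrt{n_{tail}}$ is the standard
continuous approximation and the package default for that function, for
comparability with the literature. It is, however, substantially biased at
very small cutoffs: on zeta-distributed data with $x_{min}=1$ it converges
to 2.02 when the truth is 2.5 (a fact easily verified by computing the
expectation of $\ln x$ under the zeta model). The *pipeline* therefore
uses the exact discrete MLE — direct numerical maximization of the zeta
likelihood (`method = "exact"`, `powerlaw_fit_at()`, `select_xmin()`) —
which is unbiased at every cutoff. The exact MLE is also what makes the
nested-model inequality $\mathcal{L}_{\text{plwc}} \ge \mathcal{L}_{PL}$
hold, since only a maximized power-law likelihood can be dominated
consistently.

The reported $\sigma$ keeps the leading-term formula
$(\hat\alpha-1)/\sqrt{n_{tail}}$. At small cutoffs this understates the
exact MLE's sampling SD by a model-dependent constant factor (about 1.2 at
$\alpha = 3.5$, $x_{min} = 1$, measured by simulation), because the
discrete Fisher information differs from the continuous one; the omitted
higher-order correction is positive. Users doing tight coverage analysis
at very small cutoffs should treat $3\sigma$ as somewhat narrower than
three true standard errors.

**Cutoff selection.** Candidates for $x_{min}$ are the distinct observed
positive degrees excluding the largest (so at least two distinct values
remain in the tail). At each candidate the exact MLE is fit and the
Kolmogorov–Smirnov distance
$D = \max_{x \ge x_{min}} |S(x) - P(x)|$
between the empirical and model tail CDFs is evaluated at the observed
support points; the candidate minimizing $D$ wins, ties going to the
smaller cutoff (equal distance, more data). Degenerate sequences (fewer
than two distinct positive values) raise a classed condition and are
treated downstream as failing every criterion.

**Goodness of fit.** The semi-parametric bootstrap builds `n_boot`
synthetic datasets of the empirical size: each observation comes from the
fitted power law above the cutoff with probability $n_{tail}/n$, otherwise
uniformly from the empirical observations below it. Each synthetic set is
refit end to end — including cutoff re-selection — and the p-value is the
fraction of synthetic KS distances at least as large as the empirical one;
$p < 0.1$ rules the power law out. The study default is 1000 synthetic
sets; the package's own experiments use 200 (calibration) down to 30
(feature extraction), sizes chosen to keep full runs in minutes. Under a
true power law ($n = 2000$, 200 replicates, `n_boot = 200`) the p-values
are uniform to a KS test and the rejection rate sits at the nominal 10%
within Monte-Carlo error.

A practical caveat the calibration work exposed: with a *free* cutoff the
test has little power against smooth non-power-law data at these sample
sizes — on Poisson-like or geometric degrees the KS scan retreats into a
small upper micro-tail that a steep power law fits genuinely well, and the
p-value is honestly large. Rejection is reliable when the cutoff is known
and fixed; `gof_pvalue(..., refit = "fixed")` paired with
`powerlaw_fit_at()` mirrors that protocol, and the power experiments below
use it.

# Alternative distributions and likelihood ratios

Four competing tail models are fitted on the same tail
$\{x \ge x_{min}\}$, all as discrete distributions normalized by numerical
summation (explicit terms to $\max(x_{max}, x_{min}+50)$, integral plus
half-term closure beyond):

| family | unnormalized $f(x)$ | parameters |
|---|---|---|
| exponential | $e^{-\lambda x}$ | $\lambda$ |
| lognormal | $x^{-1} e^{-(\ln x - \mu)^2/2s^2}$ | $\mu, s$ |
| stretched exponential | $x^{\beta-1} e^{-\lambda x^\beta}$ | $\lambda, \beta$ |
| power law with cutoff | $x^{-\alpha} e^{-\lambda x}$ | $\alpha, \lambda$ |

Fits use bounded quasi-Newton (`L-BFGS-B`) from three spread starting
points; a family that fails to converge is flagged and reported
inconclusive rather than aborting the projection. The log-likelihood ratio
$\mathcal{R} = \mathcal{L}_{PL} - \mathcal{L}_{Alt}$ is computed as a sum
of per-observation differences. For the three non-nested families the
significance of its sign comes from the normalized ratio
$\mathcal{R}/(\sigma_R \sqrt{n_{tail}})$ against a standard normal
(two-sided), with $\sigma_R^2$ the empirical variance of the
per-observation differences; for the nested cutoff family, $2|\mathcal{R}|$
is referred to a one-degree chi-squared. A verdict is only issued at
$p < 0.01$: `alt_favored` when $\mathcal{R} < 0$, `pl_favored` when
$\mathcal{R} > 0$, otherwise `inconclusive`.

Measured operating characteristics at the generating cutoff
($n = 10^4$, 50 replicates): geometric tails ($\lambda = 0.1$) yield
`alt_favored` for the exponential family in essentially every replicate,
while true power-law tails almost never produce a false `alt_favored`
(the boundary mixture makes the nested test conservative). Run *after* free
cutoff selection, the same comparisons lose most of their power for the
truncation reason above — which is why comparisons in the assessment
pipeline share the power-law fit's selected cutoff, exactly as the
headline analysis does, and why conclusions from them are about the
selected tail, not the full distribution.

# The classification ladder

Each dataset's eight assessments are reduced to four per-graph flags —
goodness-of-fit $p \ge 0.1$, $n_{tail} \ge 50$, $2 < \hat\alpha < 3$, and
"no alternative favored" — and the dataset is classified:

* **Super-Weak** — ≥ 50% of graphs favor no alternative (independent of
  the nested tiers below);
* **Weakest** — ≥ 50% of graphs have $p \ge 0.1$;
* **Weak** — ≥ 50% of graphs have $p \ge 0.1$ and $n_{tail} \ge 50$;
* **Strong** — Weak plus Super-Weak, with the per-graph requirement
  extended by $2 < \hat\alpha < 3$;
* **Strongest** — the Strong per-graph requirement for ≥ 90% of graphs and
  no alternative favored for ≥ 95%.

With exactly eight graphs the thresholds are integer counts applied as
$\ge$: 4 of 8, 8 of 8, and 8 of 8 (7/8 is 87.5%, below both tightened
thresholds). All eight projections are always counted, including LCC
duplicates of connected datasets; degenerate projections fail every
criterion, which is the conservative choice.

# Distinguishing individuals from ecosystems

Every projection contributes one feature vector: $\hat\alpha$, the four
signed likelihood-ratio encodings (`dexp`, `dln`, `dplwc`, `dstrexp` — the
normalized ratio when a verdict was reached, 0 when inconclusive, missing
when the family's fit failed), mean degree, $n$, $n_{tail}$, $n_{edges}$,
the goodness-of-fit $p$, and $x_{min}$. Missing values are median-imputed
with medians learned on the training split only.

**Balanced logistic.** For a single predictor, each of 100 repeats draws a
balanced training set — total size 80% of the minority level's projection
count, half per level (with 785 × 8 ecosystem projections that is exactly
5024) — fits a two-class logistic model (a two-class multinomial model is
the same model), and scores per-class accuracy on the held-out rows; mean
accuracies are reported.

**Random forest.** 100 trees, 3 features per split, in three scenarios:
all 11 predictors; without the three direct size measures ($n$, $n_{tail}$,
$n_{edges}$); and the size-blind forest per projection kind. The half/half
train–test split is *grouped by dataset* and stratified by level: the
eight rows of one dataset always land in the same half. A row-level split
was tried and rejected — with exchangeable levels it produced test
accuracies well above chance purely by memorizing dataset signatures
shared between halves, which is leakage, not discrimination. Out-of-bag error is
reported from the training half but remains optimistically biased under
clustering (a tree's out-of-bag rows have in-bag siblings); grouped test
accuracy is the honest figure. Accuracy error bands in the package's
experiments use the number of distinct test *datasets* per class as the
binomial $n$, since projections of one dataset are strongly correlated.

# The synthetic generator

Real inputs at study scale are thousands of annotated genomes and
metagenomes resolved through enzyme and reaction databases; the package
instead generates reaction datasets with the statistical structure the
analysis assumes. Reactions are built sequentially; each compound slot is
filled by a previously seen compound with weight equal to its current
participation count, or by a brand-new compound with weight
`reuse_strength` — a Chinese-restaurant scheme, i.e. the canonical
rich-get-richer mechanism, producing a few hub compounds and many rare
ones. Defaults are genome-scale: 600 reactions, 1–3 compounds per side,
`reuse_strength = 400` (chosen so compound richness roughly tracks
reaction count, as in real metabolic annotations). A `"uniform"` mode
draws compounds from a fixed pool and yields near-homogeneous
participation — the negative control. Two-level ensembles plant level
differences explicitly: a `"size"` effect (ecosystem datasets carry
`size_ratio` ≈ 2.5–3× more reactions), a `"mean_degree"` effect
(ecosystem arity 2–4 vs 1–3), or none (exchangeable levels); per-dataset
reaction counts are jittered by a uniform factor in [0.65, 1.45] so levels
overlap rather than separating trivially. The generator makes no claim of
thermodynamic or stoichiometric realism, and passing tests on it show the
*pipeline* behaves correctly — not that real metabolisms are or are not
scale-free.

# Problem sizes and numerical choices

The package's own experiments are sized to run in minutes on one core:
estimator recovery uses $n = 10^4$ with 100 replicates per condition; GOF
calibration 200 replicates at $n = 2000$ with 200 bootstrap sets;
model-comparison power 50 replicates at $n = 10^4$; discrimination
experiments 20–60 datasets per level at 80–120 reactions each with 30–60
bootstrap sets for feature extraction. Numerical details worth knowing:
the zeta sampler inverts a cumulative table of 8192 support points and
falls back to bisection on the survival function beyond it; alternative-
family normalizers work in log space with a max-shift to avoid overflow;
the exponent search runs over $(1, 50]$; and all randomness flows from
explicit seeds through `withr::with_seed`, so every reported number is
bit-reproducible.

# Limitations

Degree distributions are a coarse summary; none of this measures pathway
structure, stoichiometry, or dynamics. The goodness-of-fit test is weak
against smooth alternatives once the cutoff floats (see above), so
"cannot reject" at a deep cutoff is weak evidence. The reported $\sigma$
is the leading-term formula and is slightly anti-conservative at
$x_{min} \le 2$. The synthetic generator is a statistical stand-in: its
preferential-reuse mechanism is one plausible route to heavy tails, not a
model of metabolism, and conclusions about real genomes require real
annotations fed through `read_reaction_table()`/`resolve_ec_list()`.
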