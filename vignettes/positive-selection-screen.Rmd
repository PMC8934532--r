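---
title: "Methods: a branch-site codon screen for lineage-specific positive selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a branch-site codon screen for lineage-specific positive selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model, the numerical choices, and
the scope of the synthetic-data generators behind `omegascreen`.  It is a
methods document: everything stated here is either a definition or a design
decision; quantitative claims about behaviour are made (and checked) by the
test suite and by `scripts/acceptance.R`, not here.

## The model

### Codon substitution process

Sequences are modelled at the codon level over the 61 sense codons of the
standard genetic code (stop codons are excluded from the state space; the
alignment constructor rejects them).  The instantaneous rate from codon $i$
to codon $j \ne i$ follows the Goldman–Yang structure:

$$
q_{ij} =
\begin{cases}
0 & \text{more than one nucleotide differs} \\
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\omega \kappa \pi_j & \text{nonsynonymous transition,}
\end{cases}
$$

where $\kappa$ is the transition/transversion rate ratio, $\omega$ the
nonsynonymous/synonymous rate ratio, and $\pi$ the stationary codon
distribution.  Diagonal entries make rows sum to zero.  The chain is
reversible ($\pi_i q_{ij} = \pi_j q_{ji}$), which the implementation
exploits: $B = \Pi^{1/2} Q \Pi^{-1/2}$ is symmetric, so transition
probabilities $P(t) = e^{Qt}$ come from one symmetric eigendecomposition
per distinct $\omega$, reused across all branch lengths.

Codon frequencies use the F3x4 parameterisation: position-specific
nucleotide frequencies are estimated from the alignment (with a +1
pseudocount per base to avoid zero frequencies), multiplied per codon, and
renormalised over sense codons.

### Site classes and the branch model

Following the standard site-class construction, each codon site belongs to
one of three classes with proportions $p_0, p_1, p_2$ ($p_2 = 1 - p_0 -
p_1$):

* class 0: purifying, $0 \le \omega_0 < 1$;
* class 1: neutral, $\omega_1 = 1$;
* class 2: potentially selected, $\omega_2 \ge 1$.

Three nested models are provided.  `M1` has classes 0 and 1 only.  `M2`
adds class 2 on every branch.  `M2_branch` — the workhorse — gives class-2
sites $\omega_2$ only on the designated *foreground* branch; on background
branches class-2 sites evolve neutrally ($\omega = 1$).  The foreground
branch is marked in Newick input with the conventional `#1` tag on a tip or
internal node label, or programmatically with `set_foreground()`.

The per-site likelihood is the mixture
$\ell_s = \sum_c p_c \, \ell_{s,c}$, where each $\ell_{s,c}$ is a
Felsenstein pruning likelihood with that class's transition matrices;
sites are independent, so the alignment log-likelihood is
$\sum_s \log \ell_s$ over compressed site patterns.  Gaps and ambiguous
codons are treated as missing data (marginalised), so an all-missing column
contributes exactly zero.

### The branch likelihood-ratio test

The hypothesis test for positive selection on the foreground branch
compares:

* null: `M2_branch` with $\omega_2$ fixed at 1 (at the boundary, the
  foreground model coincides with the background model on every branch);
* alternative: `M2_branch` with $\omega_2$ free in $[1, 999]$.

The statistic is $2(\ln L_1 - \ln L_0)$, clamped at zero, referred to the
upper tail of $\chi^2_1$.  Because the null places $\omega_2$ on the
boundary of the alternative's parameter space, the plain $\chi^2_1$
reference is conservative-to-liberal depending on the data-generating
regime; the conventional 50:50 mixture of a point mass at zero and
$\chi^2_1$ is available via `null_dist = "mixture"` and halves positive
p-values.  The default follows common practice for this test family:
$\chi^2_1$ with $\alpha = 0.001$ (so the critical value is the familiar
10.828).

A test result is *accepted* as a positive-selection call when all of:
p-value $< \alpha$, $\hat\omega_2 \ge 1$, and fitted tree length $\le 10$
substitutions per codon — very long trees almost always indicate alignment
error rather than biology, so they are excluded rather than celebrated.

`include_m1 = FALSE` by default: the two-class M1 fit is a useful
convergence diagnostic but is never the test null here, and fitting it
roughly doubles the cost of a screen; it can be switched on per call.

## Numerical design

**Likelihood engine.**  Pruning is implemented in C++ with per-pattern
column rescaling (maximum-renormalisation with a log-scale accumulator), so
alignments of hundreds of codons on realistic trees do not underflow.  The
engine also returns an analytic gradient with respect to every branch
length, computed in a single extra pre-order pass.

**Branch-length parameterisation.**  The mixture's mean substitution rate
depends on the class proportions and $\omega$ values, which would couple
every branch-length coordinate to every mixture parameter.  The optimizer
therefore works in *unscaled* time $s = t/\rho$ against raw (unit-scaled
per class, unmixed) rate matrices; reported branch lengths are $t = s
\rho_e$, where $\rho_e$ is the mean rate of the mixture active on edge $e$
(foreground and background mixtures differ under `M2_branch`).  The
likelihood is invariant under this reparameterisation, and it makes the
class-proportion gradients analytic.

**Optimization.**  Bounded quasi-Newton (L-BFGS-B) over $(\log\kappa,\,
p_0,\, p_1/(1-p_0),\, \omega_0,\, \log\omega_2,\, s_1 \ldots s_E)$ with
box constraints ($\kappa \in [0.05, 50]$, $\omega_0 \in [10^{-4},
0.9999]$, $\omega_2 \in [1, 999]$, $s \in [10^{-8}, 30]$).  Branch-length
and class-proportion gradients are analytic; the three remaining scalars
use central finite differences.  Convergence is declared when the
log-likelihood improves by less than `lnL_tol = 1e-8` between iterations
(mapped to the corresponding `factr`).  Multi-start (default 3 starts,
jittered from the seeded generator) guards against local optima; the
batch screen defaults to 1 start per orthogroup for throughput, and the
null fit in the LRT is warm-started from the alternative fit, which in
practice removes the main source of spurious negative statistics.  Ties
between starts are broken toward the lower $\hat\omega_2$.  Reported
$\hat\omega_2$ is clipped to $[1, 999]$; estimates pinned at 999 should be
read as "very large", not as point estimates.

**Exact small-sample statistics.**  The downstream 2x2 tests use the
two-sided Fisher exact test in its point-probability form (sum of all
table probabilities not exceeding the observed one, within a $10^{-7}$
relative slack).  Multiple testing uses Benjamini–Hochberg.  Group mean
comparisons use the pooled-variance two-sample t-test.  These wrap the
standard `stats` implementations; the test suite validates them against an
independent hypergeometric enumeration and the $\chi^2_1$/erfc identity so
the check does not rest on a single code path.

**Discrete Kolmogorov–Smirnov test.**  Genomic clustering compares the
cumulative distribution of selected genes over megabase windows against
the background gene distribution with $D = \max_w |F_{\mathrm{sel}}(w) -
F_{\mathrm{bg}}(w)|$.  Window counts are small and heavily tied, so the
asymptotic KS distribution is anti-conservative; the p-value is therefore
Monte Carlo: selected genes are re-drawn multinomially from the background
window distribution and the estimator is $(\#\{D^\ast \ge D\} + 1)/(n +
1)$, which is never zero and is itself super-uniform.  The asymptotic
formula remains available, flagged as approximate.

**Alignment QC.**  Edge trimming keeps the alignment between the first and
last run of three consecutive fully conserved columns, a deterministic
proxy for "well-aligned core".  Region masking flags, per sequence, short
windows in which one taxon accumulates unique differences (a run of
`unique_run_min` or more columns where it disagrees with an otherwise
conserved column), which captures the common exon-boundary
misannotation artifact.  No external aligner is invoked;
`conservation_score()` provides the column-consistency score used as the
QC gate.  Alignments shorter than 100 codons after QC are excluded — short
alignments have too little information for a stable three-class fit.

## Synthetic data: what the generators cover

`simulate_codon_alignment()` draws each site's class from $(p_0, p_1,
p_2)$, the root codon from $\pi$, and evolves states down the tree with the
class- and branch-appropriate transition matrices — the exact generative
counterpart of the fitted model, including the per-edge mixture rate
scaling.  Its default $\pi$ is the self-consistent F3x4 fixed point, so
that the simulator's stationary distribution and the estimator's frequency
model coincide.  The true per-site class is returned for oracle checks.
No indels are simulated: the screen operates post-alignment, and the
masking rules are exercised on hand-built fixtures instead.

`simulate_orthogroup_batch()` produces null and selected alignments with a
truth table; `simulate_landscape()` places gene spans on scaffolds with
optional planted clusters; `simulate_expression()` builds log-normal
expression matrices with optional near-duplicate tissue pairs (calibrated
to $r > 0.95$) and an optional additive focal-tissue shift applied before
normalization.  The default tree fixture is an 8-leaf unrooted topology
with one designated foreground terminal branch.

What passing tests on these generators demonstrate: correctness of the
likelihood (against brute-force enumeration), calibration and power of the
LRT *under the model*, and calibration/sensitivity of the downstream
statistics under their own null.  What they do not demonstrate: robustness
to model violation (indels, alignment error beyond the masked artifacts,
selection regimes outside the three-class family), nor anything about any
particular empirical data set.

## Limitations

* The $\chi^2_1$ reference for a boundary null is an approximation; in
  simulations with little information about $\omega_2$ the statistic can
  exceed its nominal distribution (a tiny $\hat p_2$ class absorbing a
  large $\hat\omega_2$).  The `mixture` option is more conservative;
  neither is exact at finite samples.
* F3x4 frequencies are estimated once from the alignment, not jointly
  maximised.
* The paralog-pruning and QC rules are deterministic heuristics chosen for
  auditability, not optimality.
* Branch lengths are estimated per orthogroup under the codon model;
  there is no across-orthogroup shrinkage.
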