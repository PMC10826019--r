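---
title: "plaquehub: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plaquehub: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`plaquehub` chains seven analysis stages — differential expression,
over-representation, PPI module and hub discovery, per-gene diagnostics,
ssGSEA-based correlation, anchor-related gene selection, and
network-proximity drug prioritization — behind one seeded configuration.
This vignette records the statistical model behind each stage, the
defaults and why they hold, the design decisions that were genuinely
open, and what the synthetic validation does and does not establish.

## Differential expression

Inputs are assumed to be normalized, log2-scale intensities (as public
array matrices are); the log2 fold-change is the plain difference of
group means, oriented **case (unstable) − control (stable)**. Gene-wise
pooled variances $s_g^2$ on $d_g$ degrees of freedom are shrunk toward a
prior $s_0^2$ with prior degrees of freedom $d_0$:

$$ s_{post,g}^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
   t_g = \frac{\Delta\bar x_g}{s_{post,g}\sqrt{1/n_1 + 1/n_2}} $$

referred to $t_{d_0+d_g}$, two-sided. $d_0$ and $s_0^2$ are estimated by
moment matching on $\log s_g^2$ (the trigamma equation is inverted by
Newton iteration, ~10 iterations to $10^{-10}$). The posterior variance
always lies between $s_g^2$ and $s_0^2$, a property the tests assert.
Below 10 genes, or if the inversion diverges, the moment estimates are
meaningless and the fit falls back to the ordinary pooled t ($d_0 = 0$),
recorded in the returned parameters. Screening keeps genes with
$|log_2FC| > 1$ **and** $FDR < 0.05$, both strict, matching the
conventional statement of these gates; boundary values are excluded.
With a common true variance the estimated $d_0$ is large but finite
under sampling noise, so the moderated t tracks the common-variance
pooled t closely without coinciding with it.

## Over-representation

The universe defaults to the measured genes, not the genome: DEGs are
judged against the assayed background. For a set of size $K$ in a
universe of $N$ with query size $n$ and overlap $k$, $p = P[X \ge k]$,
$X \sim$ Hypergeometric$(N, K, n)$, one-sided (only enrichment is
reported), BH-adjusted across sets. Annotation databases themselves are
out of scope; collections arrive as GMT files.

## PPI network, modules, hubs

Edges carry STRING-style 0–1000 confidences; `build_graph()` keeps edges
with confidence ≥ 400 (the "0.4" threshold on the 0–1 scale; inclusive,
following the convention that 400 *is* medium confidence), drops
self-loops, collapses duplicates at maximum confidence, and by default
retains only the largest connected component. The last choice matters:
centralities are normalized within components, so a stray two-node
fragment would otherwise receive closeness 1.0 and swamp the hub
ranking; dropping "partially disconnected" fragments mirrors how such
networks are prepared in practice.

Module detection follows the MCODE scheme: each node $v$ with degree ≥ 3
is weighted by $k_{max} \times density$ of the highest k-core of its
closed neighbourhood; seeds are processed in decreasing weight (ties:
higher degree, then id); expansion admits unvisited neighbours whose
weight is ≥ seed weight × (1 − 0.4), within 80 hops; clusters lacking a
3-core are discarded, the haircut removes singly connected members, and
the cluster score is density × size.

One expansion detail was genuinely open. A permissive weight-only rule
lets expansion cross a single bridge edge between two dense regions
(both endpoints of a clique–bridge–clique configuration carry the full
clique weight), merging unrelated complexes and, on planted data,
chaining every module through the hub's spokes. `plaquehub` therefore
ties expansion to the haircut/k-core post-conditions when
`haircut = TRUE`: a candidate is admitted only if adjacent to a strict
majority of current members (never fewer than 2), the same criterion is
re-applied as an iterative trim after expansion, and rejected candidates
are reconsidered as the cluster grows. Cliques and near-cliques always
pass; bridge nodes never do. The cost is that sparse or triangle-free
dense structures (e.g. complete bipartite cores) are not expanded into —
complexes are modelled as near-cliques, which is the regime this
pipeline targets. With `haircut = FALSE` the canonical permissive
expansion is used. The default depth limit is 80, as configured in the
underlying analysis (the common default elsewhere is 100); at these
graph sizes it never binds.

Hubs aggregate three per-node metrics — degree; betweenness with
fractional credit for tied geodesics, normalized by $(n-1)(n-2)/2$
within each component; closeness $(n-1)/\sum d$ within the component —
as the mean of the three ranks (average ranks on ties; final ties broken
by degree, then id). Geodesics are unweighted hops: confidence is a
construction filter, not a length.

## Diagnostics

The per-gene group test is the exact Wilcoxon rank-sum: all
$\binom{n_1+n_2}{n_1}$ assignments of the midranks are enumerated
(feasible through $n_1+n_2 = 20$), and the two-sided p is
$\min(1, 2\min(P[W' \le W], P[W' \ge W]))$. With 4 + 4 samples the
smallest achievable p is $2/70 \approx 0.0286$ — relevant when reading
"p < 0.05" flags at that design size. Larger samples use the normal
approximation with tie correction, flagged. AUC uses the Mann–Whitney
identity (0.5 credit for ties) and equals the trapezoidal area of the
threshold-sweep curve to numerical precision; orientation is **not**
forced above 0.5, since markers of interest here fall in unstable
plaques — a direction-free AUC is reported alongside. The multivariate
model is a linear soft-margin SVM trained by sequential minimal
optimization with a deterministic working-pair choice (the second index
maximizes $|E_i - E_j|$), features standardized on the training fold,
evaluated by leave-one-out decision scores. A linear kernel is the
deliberate choice: with 8 samples and 5 features a radial-basis fit is
unidentifiable.

## ssGSEA and correlations

Per sample, genes are ranked descending (top gene has rank $N$) and

$$ ES = \sum_{i=1}^{N} \left[ P^w_{in}(i) - P_{out}(i) \right], $$

with in-signature weights $rank^\alpha$, $\alpha = 0.25$ (the standard
choice for this statistic; raw, un-normalized scores by default so unit
tests have closed forms — a global max−min normalization sits behind a
flag). Scores are rank-invariant within a sample by construction. The
aggregate immune score is the per-sample sum over the signature panel —
a transparent stand-in for regression-calibrated immune scoring methods,
whose published platform-specific gene weights are out of scope.

Gene-versus-score association uses Spearman's rho on midranks; for
$n \le 9$ without ties the two-sided p is exact by enumerating all $n!$
permutations ($9! = 362{,}880$ stays sub-second), otherwise the
t-approximation is used and flagged. The anchor-related gene set uses
Pearson correlation (the default of the conventional `rcorr` route) with
strict gates $r > 0.9$ and $p < 0.001$, signed — positive co-expression
only — with an `absolute` flag to flip.

## Drug proximity

$$ d(S,T) = \frac{1}{|T|}\sum_{t\in T}\min_{s\in S}\big(d(s,t)+\omega\big),
   \qquad \omega_t = -\ln(D_t+1) \text{ if } t \in S, \text{ else } 0. $$

Because $\omega_t$ does not depend on $s$, summing the weight inside or
outside the minimum is equivalent; tests verify the implementation
against a literal evaluation of the formula. $D_t$ is read as the degree
of the *target* gene in the full network — the natural reading of a
self-target reward. Off-network or unreachable targets are dropped from
the average (and counted) rather than given an infinite penalty. The
null draws target-size-matched node sets uniformly (degree-matched
sampling is available as a methodological comparison, not the default);
$z = (d_{obs} - \mu)/\sigma$ with the sample standard deviation, and the
empirical p uses the add-one estimator, so its floor is
$1/(n_{perm}+1)$ — with the default 10,000 permutations, $10^{-4}$.
Screening keeps drugs with $d_{obs} < 1.2$ (strict) and $FDR < 0.05$;
the FDR is BH over the permutation p-values across evaluable drugs (a
normal-tail alternative from z is noted but not used). A stricter
$10^{-3}$ gate appears in some descriptions of this procedure; both are
exposed as flags, 0.05 being the default actually exercised by the
screening step.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of their arguments including the seed;
one global seed feeds a named substream per generator, so changing one
stage never perturbs another.

* **Expression** — per-gene Gaussian baselines (mean ~N(7, 1.5²),
  within-group sd σ = 0.5 by default) with ±2 log2-unit shifts planted
  in half-up/half-down fashion; 4 vs 4 samples, mirroring the small
  plaque cohorts this pipeline targets. Gaussian log-scale noise matches
  the moderated-t model. *Not* emulated: count overdispersion
  (negative-binomial RNA-seq), batch effects, correlation among null
  genes, normalization artifacts.
* **PPI** — planted cliques (confidence 900, above any plausible
  threshold, decoupling threshold tests from recovery tests) over an
  Erdős–Rényi background (p = 0.02) with confidences uniform in
  [400, 900]. The designated hub sits in the largest module, is wired to
  one node of every other module, *and* receives spokes to ~5% of the
  background — a promiscuous scaffold protein. The spokes are a
  deliberate design choice: inter-module wires alone give the hub a
  degree margin of only the number of other modules over its own clique
  mates, and background-degree noise then overturns its top rank in a
  substantial fraction of runs, making "the planted hub" an ill-defined
  target. *Not* emulated: scale-free degree distributions, confidence
  correlated with topology.
* **Drugs** — proximal drugs draw at least half their targets from the
  disease set itself (direct targeting is what ω rewards) and the rest
  from its direct neighbours; random drugs draw uniformly. Without the
  in-set half, "proximal" drugs are barely separable from random ones
  and the planted labels would not constitute ground truth.
* **Signatures** — member genes are rewritten as
  $c \cdot z(hub) + \sqrt{1-c^2}\,\varepsilon$ (rescaled to each gene's
  original location), so the member–hub correlation is $c$ in
  expectation. At $c = -1$ member ranks reverse perfectly, but the
  running-sum score also depends on where the *other* (noisy) genes
  fall, so the observed score–hub Spearman correlation is near, not
  exactly, −1; the exact limit holds when the background is fixed, and a
  dedicated fixture asserts it.
* **Pipeline simulation** — the hub is additionally planted down by the
  effect size in the case group and its module mates are co-expressed
  with it (r ≈ 0.97), so the anchor-related set recovers the module and
  the screened-drug narrative is coherent end to end. The truth record
  reflects all rewrites.

Passing recovery tests on these inputs shows the chain is internally
consistent and recovers structure it was designed to see; it does not
certify performance on real cohort data, whose noise is heavier-tailed
and whose networks are far from Erdős–Rényi.

## Numerical and testing choices

* Exact-test cutoffs: rank-sum enumeration through a combined n of 20;
  Spearman enumeration through n = 9. Both stay well under a second.
* Ties: midranks (Wilcoxon, Spearman), 0.5 pair credit (AUC),
  stable index-based ordering (ssGSEA).
* Missing values are hard errors at parse time — silent imputation
  would corrupt every rank statistic downstream. TSV/GMT only, UTF-8;
  numeric output uses 17-significant-digit decimal text so write/read
  round trips are exact, and two runs of the pipeline under one seed are
  byte-identical.
* The empirical-p calibration test scores 2,000 random target sets
  against a 1,000-draw null on a network whose disease set covers ~40%
  of nodes. That design makes observed distances carry irrational
  $-\ln(D+1)$ terms and thus near-continuous support; with pure
  hop-count distances the add-one estimator is conservative at atoms
  and a Kolmogorov–Smirnov bound of 0.05 could not be met by any
  correct implementation.
* Test problem sizes (the package's own validation scale): 1,000-gene
  expression replicates over 50 seeds for DEG recovery; 100–150-node
  networks over 20 seeds for hub/module/drug recovery; 100 random
  graphs (≤ 30 nodes) against the brute-force centrality oracle;
  pipeline determinism at 1,000 permutations.

## Known limitations

* MCODE expansion is near-clique-oriented (see above); `fluff`
  post-processing is accepted as a parameter for interface completeness
  but not implemented (it is off in the configuration this pipeline
  reproduces).
* The SMO solver targets tiny sample sizes; it is not tuned for large n
  and may hit its sweep cap on hard problems (flagged, best iterate
  returned).
* The ssGSEA implementation scores one sample at a time with dense
  cumulative sums; adequate for thousands of genes × dozens of samples,
  not engineered for single-cell scale.
* Exact tests silently degrade to flagged approximations outside their
  enumeration ranges; consumers should check the `method` field when
  sample sizes vary.
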