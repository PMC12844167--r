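---
title: "Modelling host-microbiota co-metabolism with cometnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling host-microbiota co-metabolism with cometnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gut bacteria live on what reaches the intestinal lumen, and a large share of
that supply is actively secreted or transported there by the host. A host
genotype that weakens the synthesis or transport of a metabolite can
therefore starve (or advantage) specific bacterial taxa. `cometnet` models
this interface with constraint-based metabolic models: a tissue-contextualized
host genome-scale metabolic model (GEM) is coupled to individual bacterial
GEMs through a shared luminal compartment, and the effect of withdrawing
single host-supplied metabolites on each bacterium's growth is quantified by
uniform flux sampling and a differential screen.

This vignette explains the model, the algorithmic choices, and what the
synthetic test bed does and does not demonstrate.

## Constraint-based core

A model is a stoichiometric matrix $S$ (metabolites x reactions), flux
bounds $l \le v \le u$, gene-protein-reaction (GPR) rules, subsystem labels
and a biomass objective. All analyses operate on the steady-state polytope

$$P = \{\, v : S v = 0,\; l \le v \le u \,\}.$$

FBA maximizes the biomass flux over $P$; FVA reports each reaction's
feasible flux interval; single-reaction deletion re-optimizes after pinning
one flux to zero, calling a reaction essential when the optimum falls below
1% of wild type (`essentiality_tolerance = 0.01`, the conventional cutoff).
The linear programs are solved by a bounded-variable two-phase primal
simplex implemented in compiled code (`src/lp.cpp`): the package targets
desk-scale models (tens to a few hundred reactions) where a dense simplex
with periodic refactorization is simple, fast and exactly reproducible.
Tolerances: steady-state residual 1e-6, bound violation 1e-9, pivot
tolerance 1e-9. Bounds beyond 1e6 are treated as effectively unbounded;
flux sampling refuses models with bounds at or above 1e5, since uniform
sampling on unbounded rays is undefined.

## Expression contextualization

A tissue model is built from a generic model and a bulk TPM table in four
steps:

1. **Aggregation** — the arithmetic mean TPM per gene across samples
   (`aggregate_expression()`).
2. **Active-gene filter** — genes with mean TPM strictly greater than 1
   (`filter_active_genes()`), the threshold conventional for tissue-specific
   GEM construction.
3. **Core extraction** — `extract_context_model()` removes reactions whose
   GPR evaluates to FALSE under the active set (GPR-less and protected
   reactions always stay), then restores removed reactions greedily in
   decreasing expression-score order until the objective can carry flux.
   This is a deliberately simple, transparent stand-in for MILP-based
   extraction methods: it preserves their qualitative contract
   (expression-weighted core, feasible output) at toy scale, and its
   restoration set is reported via `attr(x, "restored_reactions")`.
4. **E-flux bounds** — `apply_eflux()` scores each reaction through its GPR
   (AND = min, OR = max; unmeasured genes drop out of OR and poison AND,
   so absent annotations never spuriously pin a reaction to zero), scales
   scores to $[0,1]$ by the 95th percentile (clipped; an `"absolute"`
   max-scaling is available) and tightens bounds to
   $[\max(l, -B\hat s),\ \min(u, B\hat s)]$, where $B$ is the model's bound
   magnitude. Bounds are never widened, so the flux space only contracts.

`compare_models()` reports structural reductions, GPR coverage, the paired
span contraction (Wilcoxon signed-rank by default; the unpaired rank-sum
variant is provided because both appear in common practice for this
comparison) and the essential-set difference. Pruning a redundant route can
make the surviving route essential, so the contextualized model may have
*more* essential reactions than the generic one — the direction the package
asserts in its tests.

## Joint-model assembly

`merge_models()` builds the multi-species model. Each member is id-prefixed
with its tag, its boundary exchanges on the extracellular compartment `[e]`
are removed, and `create_interspace()` adds, for each of the $n$
extracellular metabolites, a lumen twin `met_u` and one reversible transport
`met[e] <-> met[u]` with coefficients $-1/+1$ — stacked over members the new
columns form the block $[-I_n; I_n]$. Lumen metabolites with the same base
id are unified across members, making the lumen the sole shared interface.

The host is special-cased: its original boundary exchanges are relocated
behind a body-fluid compartment `[b]` (`met[e] <-> met[b] ->` outside), so
host nutrition arrives via the bloodstream while secretion to the microbiota
flows through the lumen; no microbial reaction touches `[b]`.

**Lumen boundary.** Each lumen metabolite gets one exchange reaction with
efflux open and influx closed — the host is the sole supplier. This is the
package's own choice where a diet term is not specified; the `diet` argument
opens influx per metabolite. The synthetic community deliberately feeds the
microbes' carbon source (glucose) through the diet rather than the host, so
the energy supply is not itself a co-metabolite and restriction scenarios
probe only the planted dependencies.

**Futile cycles.** Merged reversible transports can form secrete-and-reuptake
loops carrying arbitrary circular flux. `remove_futile_cycles()` closes all
boundary exchanges, runs FVA on the interspace transports, and for each
lumen metabolite still able to carry flux restricts the host transport to
secretion-only and microbial transports to uptake-only; any restriction that
shifts a member's biomass optimum by more than 1e-6 is reverted. This is the
minimal directional restriction that preserves optima.

**Co-metabolites.** A lumen metabolite is a co-metabolite when the host
transport can carry secretion flux and at least one microbial transport can
carry uptake flux, certified by FVA on the joint model; the remaining lumen
content is classified host-derived or microbe-derived, giving the lumen
composition report.

The default analysis mode is host-single-strain: one pairwise joint model
per microbe. This isolates host-driven effects from inter-microbial
competition and cross-feeding; an all-member merge is possible with the same
function but is not what the screening pipeline runs.

## Flux sampling

`achr_sample()` implements artificial-centering hit-and-run. Warm-up points
are the FVA-style vertices (each reaction maximized and minimized; random
dense objectives fill any surplus), capped at `min(2 n_reactions, 2000)`.
The chain repeatedly draws a direction through the running center and a
random warm-up point, computes the feasible chord from the bounds (the
direction stays in the null space of $S$ automatically, as a difference of
feasible points), steps uniformly on the chord, and updates the running
center incrementally over all visited states. The warm-up phase acts as
burn-in; no additional states are discarded, and the retained sample records
its full configuration. Every `thinning`-th state is kept. With R's RNG
driving the chain, a fixed seed reproduces samples bit for bit.

Defaults follow standard sampling practice for metabolic models: 10,000
retained points with thinning 100. The screening pipeline and the test suite
run a scaled-down desk configuration (2,000 points, thinning 10) so a full
community analysis completes in seconds per member on one CPU; the sampler's
statistical contracts (uniform moments on analytic box polytopes, FVA-box
containment, autocorrelation decay with thinning) are asserted at both
scales.

## Differential screen

For each co-metabolite and member, the member's uptake transports are pinned
to zero (`lb = ub = 0` — a binary loss-of-supply scenario, not a
concentration gradient), the polytope is resampled, and each reaction is
tested:

* two-sample Kolmogorov-Smirnov on the flux distributions (asymptotic p),
  Benjamini-Hochberg corrected across reactions; a reaction absent from one
  model is compared against constant zero;
* the normalized flux change
  $FC = (S_R - S_U)/|S_R + S_U|$ of the mean fluxes, screened at
  $|FC| \ge 0.82$ — the value at which a same-sign 10:1 mean-flux ratio
  lands ($9/11 \approx 0.818$); if both means are zero $FC = 0$, and a
  vanishing denominator with unequal means yields a flagged sentinel
  ($\pm 10^{12}$) rather than an overflow;
* a percentile bootstrap 95% CI of the mean per-point flux difference
  (paired by sample index); zero must fall outside it.

A reaction is significant only when all three filters pass — they are
applied as an order-independent conjunction.

**Biomass classes.** Restricting a co-metabolite classifies the member as
`blocked` (restricted biomass mean below 1e-9), `reduced`, or `unchanged`.
`reduced` requires the same three-filter conjunction on the biomass reaction
in the decrease direction, not the KS test alone: with Monte-Carlo samples a
bare KS test rejects at its nominal rate even for identical distributions,
which would randomly promote unaffected metabolites; the FC gate pins
`reduced` to order-of-magnitude effects, which is also what the screening
threshold means everywhere else in the pipeline. Key co-metabolites are
those with at least one non-`unchanged` member.

**Enrichment.** Significant member reactions are mapped to subsystems and
tested hypergeometrically: for a subsystem holding $K$ of the member's $N$
reactions, with $n$ significant reactions of which $k$ in the subsystem,
both $P(X = k)$ and the upper tail $P(X \ge k)$ are reported (log-space via
the standard distribution functions), BH-corrected across subsystems. The
default flag uses the tail — the standard over-representation reading — with
the literal point-mass criterion available as `mode = "point"`, since the
point form is how the test is sometimes stated; both columns are always
emitted. The background $N$ is the member's full reaction count including
transport and interspace reactions, configurable via `background`.

## The synthetic test bed

`generate_community_fixture()` builds the standard study conditions: a
secreting host (nutrient uptake, a GPR-covered central chain, biosynthesis +
secretion + exchange for a 12-metabolite panel), five microbes, three
planted key co-metabolites and two decoys. Microbes carry:

* **hard auxotrophies** — the metabolite enters biomass with no internal
  synthesis route, so restriction blocks growth;
* **partial dependencies** — a low-capacity internal bypass (0.05 flux
  units against a demand of 0.5 per unit biomass) makes restriction reduce
  growth about 40-fold, far beyond the 10-fold FC gate;
* **decoys** — taken up and degraded to a secreted waste product without
  touching biomass, so restriction leaves growth unchanged.

The first hard auxotrophy is wired through a three-step activation chain
labelled with its own subsystem, planting a downstream enrichment signal.
Expression tables draw gene means log-normally above (active) or below
(inactive) the TPM = 1 line with multiplicative per-sample noise; activity is
Bernoulli per gene, so the realized active fraction fluctuates binomially
around its target. Every generator verifies its planted classes by direct
FBA at generation time and is a deterministic function of (seed,
parameters).

What passing on this test bed shows: the assembly, sampling and screening
machinery recover planted ground truth of exactly the kinds the method
claims to detect, under controlled conditions. What it does not show:
behaviour on genome-scale reconstructions (thousands of reactions, loops,
degeneracy at much larger scale), real expression data (no batch structure,
no isoform ambiguity), or biological realism of toy stoichiometry. Published
quantities that depend on specific external reconstructions and cohorts are
correspondingly out of the package's testable scope.

## Numerical and design notes

* The simplex uses Dantzig pricing with a Bland fallback after half the
  iteration budget, eliminating cycling on degenerate toy polytopes.
* Degenerate ACHR chords (fixed subspaces) are re-drawn, counted and
  reported; a fully pinned polytope returns its unique point replicated.
* `flux_change` ties ($S_R = S_U$) return exactly 0, never 0/0.
* Bootstrap CIs inside `differential_analysis()` share one resampling-weight
  matrix across reactions (a single matrix product), which is why the
  differential stage costs milliseconds, and are seeded per scenario.
* Pipeline stage seeds derive from the global seed by a stable string hash
  of the stage/scenario name, so any stage is independently reproducible.
* Re-running a stage with an identical configuration reproduces artifacts
  byte for byte; every artifact carries a JSON sidecar with the config, the
  derived seed and input hashes.

## Known limitations

* The greedy core extraction is not an optimal (MILP) context extraction;
  it can restore more reactions than strictly necessary.
* The futile-cycle rule restricts transport directionality globally per
  metabolite; thermodynamically infeasible internal loops within a member
  are out of scope (no loopless FBA).
* The enrichment background treats all member reactions equally;
  transport-heavy models dilute pathway signal unless `background` is
  narrowed.
* Single-chain sampling: convergence is monitored by the split-half
  diagnostic in `validate_sample()`, not by multi-chain statistics.
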