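---
title: "Methods: from inhibition maps to dynamic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from inhibition maps to dynamic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timdyn)
```

This vignette records the modelling assumptions, conventions and numerical
choices behind `timdyn`, at the level of detail a maintainer or reviewer
needs to judge what the package's outputs do and do not mean.

## State space and conventions

A panel of `n` inhibitable targets (kinases) is an ordered character vector;
`n ≤ 16` is enforced because every layer of the package enumerates the
`2^(n+1)` joint states explicitly. Conventions, fixed once and used
everywhere:

* **Subset index**: an inhibition combination is an `n`-bit integer with
  target 1 in the most significant bit, so `{K1, K3}` on a three-target
  panel is `101₂ = 5`.
* **Dynamic state**: `n + 1` bits; the target bits shifted left by one, the
  tumor phenotype (1 = proliferating) in the least significant bit.
* **Grid layout**: printed tables split the panel into column targets (the
  first `⌈n/2⌉` names) and row targets (the rest), both axes ordered by the
  reflected-binary Gray sequence, so adjacent rows/columns differ by a
  single inhibition. The flat JSON form is layout-free.

## Binarization

`binarize(x, alpha)` marks a combination blocking when its sensitivity is
`≥ alpha`. The boundary is deliberately inclusive: the embedded six-kinase
screen has a cell exactly at a printed threshold (0.55), and only the
inclusive convention reproduces the screen's printed thresholded maps. The
threshold itself is a pharmacological choice — 0.5 corresponds to "halves
tumor viability at an approved dose"; lower values admit weaker
inhibitions.

## Series-parallel structure inference

A directional pathway is a series chain of blocks, each block a set of
parallel lines of targets; the tumor survives while some block retains a
fully uninhibited line. The blocking combinations of such a circuit form
exactly the monotone closure of a union of one-per-line transversal
products, so inference runs:

1. minimal blocking sets of the (monotone, validated) TIM;
2. two targets share a **line** iff they never co-occur in a minimal set
   and exchanging one for the other maps the antichain onto itself;
3. minimal sets touching the same set of lines form a **block**, whose
   family must be the complete one-per-line product;
4. the candidate's cut function is verified against the TIM on all `2^n`
   subsets before it is returned.

Failure at any step returns an empty candidate list with the uncovered
minimal sets attached — monotone but non-series-parallel maps exist (the
smallest is 2-of-3 majority) and are reported rather than approximated.

Two genuine representation ambiguities are resolved canonically:

* a block consisting of one serial line has the same cut function as that
  many singleton blocks in series; the canonical form always splits, which
  also matches how single-kinase chains are conventionally drawn;
* targets in no minimal blocking set are **off-circuit**: they exist in the
  state space but sit on no survival line. They are wired to a line-end
  target of the terminal block by default. The choice is arbitrary by
  construction — an off-circuit target feeds nothing, so no steady-state
  quantity computed here depends on it.

## Boolean networks and intervention

`build_bn()` applies the update rules: a mutated / latently activated
target rises to 1 within one step; any other target ORs its immediate
upstream activators (its line predecessor, or every line-end of the
previous block for a line head); the tumor bit follows the OR of the
terminal block's line-ends *evaluated at the current step* (delayed
convention). The delayed convention is forced by the worked example's
printed transition `0010 → 1101`; the instantaneous alternative contradicts
it. Only OR activation is generated by inference (the common case in
curated pathway databases); AND-gated inputs would require a richer pathway
description than a TIM can identify.

Drugs act by masking: sustained inhibition of a set `I` maps each freshly
computed successor through `f_c` (targets in `I` forced to 0, tumor bit
untouched), i.e. the matrix form `P·T_c`. One printed aside in the source
material ("1001 will transition to 1010" under sustained inhibition of the
upstream pair) is inconsistent with that formulation — mask-after-update
gives `0010` — and is treated as a misprint of `0010`; the matrix semantics
is used throughout.

Because pathway networks are feed-forward (the only feedback is a mutated
target's self-activation), every sustained mask drives them to a fixed
point. `bn_to_tim()` nevertheless handles general attractors: a cycle
mixing tumor phenotypes scores 0 (tumor not eradicated) and is recorded in
a diagnostic attribute. This branch is reachable only for hand-built
networks, e.g. a tumor flip-flop.

## Markov layer

Two treatment semantics are implemented: **reset** (each row is replaced by
the row of its masked image) and **redirect** (`P·T_c`, transition mass
aggregated onto masked images). Their stationary distributions agree after
aggregating each preimage class onto its fixed state; the package verifies
this equivalence property on hundreds of random ergodic chains at `1e-10`.
Evaluation uses the redirect form, which keeps the masked subspace
explicit.

**Perturbation.** Ergodicity is obtained by independent per-bit flips with
probability `p` applied *after* the masked transition, on *all* `n + 1`
bits including the tumor bit. The source material does not print this
convention; it was fixed by matching the worked example's perturbed
steady-state table, which the all-bits/after-transition kernel reproduces
to `≤ 1e-5` while every alternative (targets-only flips, flips before
masking) misses by `~1e-3`. The targets-only kernel remains available
(`perturb(..., bits = "targets")`).

**Stationary distributions** are direct linear solves (`πP = π`, `Σπ = 1`,
one equation replaced by the normaliser). Reducible chains are analysed
along the trajectory from a declared start state; the package refuses to
summarise a chain from which several closed classes are reachable. For
`p = 0` profiles the start state defaults to all-ones — every target and
the tumor active — which is the evaluation convention under which the
trivial pair construction (`trivial_chain_from_ptim()`) realises its PTIM
*exactly*. This point is sharper than it looks: the trivial chain's pair
classes are all closed under any mask, so its perturbed stationary
distribution at small `p > 0` converges to a *mixture* over pair classes,
not to the intended entry. Exactness holds for the unperturbed chain
started at all-ones, and that is what the package asserts.

**Resting-pair construction** (`algorithm1_chain()`; the single-backbone,
"cancer stem cell" perspective). The PTIM is thresholded, a backbone BN is
built, and the resting pair `(s, s+1)` of each effective combination `c` —
the tumor-free state the sustained mask drives the all-active state into,
plus its tumorous partner — is made stochastic: mass `1 − p_c` to the
partner, `p_c` to the backbone successor of `s` with the tumor bit forced
off, which the mask collapses back onto `s`. Combinations sharing a pair
(the deeper mask owns it) are resolved by a leak transition from the
tumor-free row to a state re-activating one target of the difference; the
leak weight is a one-dimensional golden-section search against the
perturbed steady state (tolerance `1e-6`, endpoints checked explicitly so a
binary PTIM stays deterministic). The backbone orientation is chosen among
the enumerable orientations (capped at 120) to minimise the number of
shared pairs. The result is verified against the input PTIM at `p = 0.001`
within `ε = 0.02`; failure is an error naming the worst combination, not a
silent approximation.

## Context-sensitive PBN layer

`sensitivity_levels()` clusters the PTIM values into plateaus of spread
`≤ ε` (greedy over sorted unique values; default `ε = 0.05`, matching
screen noise), discards the plateau at or below `ε` as noise, and defines
level values `v_k` (plateau maxima), thresholds `v_k − ε`, and selection
weights `v_1, v_2 − v_1, …`. Explicit thresholds/weights are accepted
instead (the six-kinase example uses 0.3/0.55/0.8 with weights
0.5/0.25/0.25, equal-increment thresholds being another reasonable rule); a
weight deficit `1 − v_m` is assigned to the last network when
normalisation is requested.

One Boolean network is built per level TIM. When a level TIM is
series-parallel this goes through structure inference; when it is monotone
but not series-parallel (the toy example's middle level is 2-of-3
majority), `monotone_bn()` realises it directly — every target latently
activated, tumor updated by the monotone survival function — which
reproduces any monotone TIM's masked attractors exactly. The collapsed
chain on (network, state) pairs resamples the governing network from the
selection weights with probability `q` per step (possibly re-selecting the
same network — this makes the stationary network marginal exactly the
weights), then steps, masks and perturbs. As `p, q → 0` every profile entry
converges to the weight-mixture of level TIM entries, which is why the
reconstruction errors depend only on levels and weights and not on the
(unidentifiable) wiring of the per-level networks.

## Regimens

A periodic regimen is evaluated on the period-product chain: stationary
distribution at one phase boundary, propagated around the cycle, sensitivity
= phase-averaged tumor-free mass. The phase average is the physically
sensible time average; period-1 regimens reduce exactly to the model's
profile entry, and the value is invariant under cyclic rotation of the
period. Alternating-regimen outputs beyond the sustained cases should be
read as demonstrations: they depend on per-level network wiring that the
input PTIM does not identify.

## Experiment design

The orientation-discovery simulator mirrors the closed-form bounds' two
phases. Phase 1 resolves the serial order of `L` blocks by random-pivot
queries (inhibit one block, read which blocks go dark downstream), a
quicksort-type recursion whose exact expectation `(2m − 1)/3` and worst
case `m − 1` match the bound's terms; the package checks the recursion
against an exhaustive enumeration of pivot sequences for `m ≤ 5`. Phase 2
resolves within-line order: a line of length `b ≥ 3` needs `b − 2` position
queries, the first free with probability 1/3 (information carried over from
phase 1), batched across up to `a_i − 1` lines per experiment. The 1/3
carry-over is a reconstruction: it reproduces the per-line expectation
`(2b − 4)/3` and worst case `b − 2` exactly for `b = 3`, the only line
length exercised by the 13-target example; expected values for `b ≥ 4` are
not treated as ground truth (the printed general form of the expected bound
is typographically corrupted at that term, and the reduced form implemented
here is the one actually evaluated in the source material).

## Synthetic data

`random_pathway()` samples block/line/length shapes uniformly from given
ranges (defaults: 1–3 blocks, 1–3 lines, lengths 1–3, panel capped at 10)
with the first block's line heads as latent activations — the minimal
driver set. `random_ptim()` plants a known mixture: nested level TIMs
obtained by repeatedly adding a parallel line to a random block (blocking
strictly harder each level), combined with chosen cumulative levels plus
bounded uniform noise. These generators emulate the *structure* of screen
data — plateaued sensitivities, monotone blocking, small panels — but not
its failure modes: real screens have non-monotone noise, estimation error
concentrated near thresholds, and off-target drug effects. A passing test
suite therefore certifies the algebra and the reconstructions, not
robustness to violated monotonicity.

## Problem sizes and costs

All computations are dense linear algebra on `2^(n+1)`-state spaces: the
toy examples use `n = 3` (16 states), the drug-screen example `n = 6` (128
states, collapsed chain 384, 64 stationary solves ≈ 2 s), property tests
use random panels up to `n = 8` and 200 random chains with `n ≤ 4`, and the
simulation example uses 10,000 runs (≈ 1 s). The full test suite runs in
well under a minute on one core.

## Known limitations

* Tumor-suppressor targets (inhibition *causing* proliferation) are not
  modelled; the framework assumes oncogene-type targets throughout.
* `infer_structures()` returns the canonical candidate only; enumerating
  all block-mergings of the serial-line ambiguity would multiply output
  without changing any steady-state quantity.
* PTIM estimation from raw drug-screen viability data is out of scope; the
  map is this package's input, not its product.
* Non-series-parallel monotone TIMs get a dynamic realisation
  (`monotone_bn()`) but no pathway interpretation, and instantaneously
  random (non-context-sensitive) PBNs are not implemented.
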