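---
title: "Probing-directed RNA folding with per-nucleotide soft constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing-directed RNA folding with per-nucleotide soft constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapefold)
```

## The model

A secondary structure $S$ on an RNA $a_1 \dots a_n$ is a set of
Watson–Crick or GU pairs with no pseudoknots, no base triples, and at
least $\theta = 3$ unpaired bases in every hairpin loop. Chemical probing
(SHAPE, in-line) yields per-nucleotide reactivities that, after
normalization, we read as probabilities $q_i \in [0,1]$ that nucleotide
$i$ is unpaired.

Each structure has a binary pairing indicator $x_i(S) \in \{0, 1\}$
($1$ = unpaired; the same orientation as $q$), and its disagreement with
the data is the unnormalized L1 distance

$$d(S, q) = \sum_{i=1}^{n} |x_i(S) - q_i| \in [0, n].$$

Soft constraints tilt the Boltzmann ensemble by this distance. Every
position contributes a weight $\omega(i, x) = e^{-\beta |x - q_i| / RT}$,
paired or unpaired as the structure dictates, so the weighted partition
function is

$$Z' = \sum_S e^{-E(S)/RT} \, e^{-\beta\, d(S,q)/RT},$$

with $E$ the Turner nearest-neighbor free energy and $\beta \ge 0$
(kcal/mol) the data-strength parameter. No structure is forbidden; the
data only reweight. At $\beta = 0$, or when every $q_i = 0.5$ (up to a
global constant factor $e^{-\beta n/2RT}$), the classic unweighted
ensemble is recovered.

The engine computes $Z'$ by a weighted McCaskill recursion over interval
tables $Z$, $Z^B$ (closed by a pair), $Z^M$, $Z^{M1}$ (multiloop parts
with $\ge 1$ / exactly $1$ component), seeded with $Z(i, i-1) = 1$; each
position contributes exactly one weight factor in every term, which is
what makes the per-structure factorization above exact (it is asserted
directly in the tests). A mirrored outside pass yields the weighted pair
probabilities $p'_{ij}$, and the min-sum transform of the same recursion
(sums for products, minima for sums, $\beta|x - q_i|$ for the weights)
gives the weighted MFE structure minimizing $E(S) + \beta\, d(S,q)$.

## Self-consistency diagnostics

* **Expected distance** $ED = \sum_i [u_i(1 - q_i) + (1 - u_i) q_i]$,
  where $u_i$ is the ensemble unpaired probability — the quadratic-time
  form of the ensemble average of $d(S,q)$. Weighting always decreases it
  ($ED' < ED$ whenever the ensemble spans more than one distance value),
  and $ED(\beta)$ is strictly decreasing in $\beta$; as
  $\beta \to \infty$ it approaches $\min_S d(S, q)$.
* **Critical distance** $d^* = (RT/\beta)\ln(Z/Z')$. From the definitions,
  $P'(S)/P(S) = e^{-\beta d(S,q)/RT} Z/Z'$, so $P'(S) > P(S)$ exactly when
  $d(S,q) < d^*$: the ensemble moves probability toward structures that
  agree with the data better than this threshold. As $\beta \to 0^+$,
  $d^* \to ED$ (unweighted); the implementation returns that limit at
  $\beta = 0$ rather than $0/0$.
* **Pointwise entropy** $H_i$ (nats): Shannon entropy of position $i$'s
  pairing-outcome distribution — all possible partners plus "unpaired"
  ("full"), or the paired/unpaired dichotomy only ("binary", the signal a
  probing experiment can see).
* **Morgan–Higgs diversity** $D = 2\sum_{i<j} p_{ij}(1 - p_{ij})$: the
  expected base-pair symmetric-difference distance between two independent
  draws from the ensemble.

All four are validated against exhaustive enumeration
(`bruteForceEnsemble()`) on sequences short enough to enumerate.

## Reactivity normalization

SHAPE reactivities are mapped by a continuous piecewise-linear function
through configurable breakpoints; the defaults are

| raw interval | target interval |
|---|---|
| [0, 0.25] | [0, 0.35] |
| [0.25, 0.3] | [0.35, 0.55] |
| [0.3, 0.7] | [0.55, 0.85] |
| [0.7, 2.2] | [0.85, 1.0] |

anchored at the published moderate (0.3) and high (0.7) reactivity
thresholds; values above 2.2 clamp to 1, negative values to 0 (slightly
negative background-subtracted SHAPE carries the same "paired" signal as
0), and very low reactivities deliberately do not map near 0 so the data
cannot over-claim pairing. These breakpoint values are defaults of this
package, exposed in `defaultNormalizationConfig()` as the single source of
truth, not canonical constants. In-line probing, whose signal is more
diffuse, is normalized by clipping at the 2.5th/97.5th percentile outliers
(mapped to 0 and 1) and interpolating linearly in between; a degenerate
all-equal profile returns $q = 0.5$ everywhere with a warning. Both maps
are monotone with range $[0,1]$. Missing values (absent or `-999` in the
reactivity file) are filled with $q = 0.5$, which makes the paired and
unpaired weights at that position identical — genuinely "no information".

## Tunable parameters

* `beta` (kcal/mol, default 1.0): strength of the data term. In practice
  it should be calibrated per dataset against a reference structure;
  `betaGridSearch()` scans a grid (default 0–3 by 0.1) maximizing
  sensitivity + PPV (objective configurable to product or min — the
  choice is exposed because published practice only states that both
  quantities were optimized). Ties break toward smaller `beta`; an
  undefined PPV (no predicted pairs) counts as 0.
* `theta` (default 3): minimum hairpin loop size.
* Energy parameters: the bundled `turner-min` set — published 37 °C
  Watson–Crick stack values, representative GU and loop-initiation values,
  affine multiloops $a + bk + cu$ with $(3.4, 0.4, 0.0)$ kcal/mol,
  asymmetry penalty $\min(3.0, 0.6|n_1 - n_2|)$, internal/bulge loops
  capped at total size 30, Jacobson–Stockmayer extrapolation
  $E(\max) + 1.75\,RT\ln(u/\max)$ beyond the tables. Deliberately absent,
  mirroring the scope of a standalone per-nucleotide engine: dangles,
  coaxial stacking, tetraloop bonuses, 1×1/2×2 special tables. The set's
  revision provenance is therefore mixed and documented in the parameter
  file itself; all correctness guarantees are parameter-set independent.
* Deigan comparison mode: pseudo-energy $m\ln(s+1) + b$ with defaults
  $m = 2.6$, $b = -0.8$ kcal/mol, applied on *raw* reactivities inside
  stack contexts only — operationally, all four positions of every
  stacked-pair term, so interior helix positions are counted twice and
  isolated pairs receive no term; missing reactivities contribute 0.

## Numerical choices

* **Overflow safety.** The DP runs in linear space with a per-position
  rescaling factor derived from the plain MFE (the classic partition
  function scaling trick), engaged for sequences over 60 nt; this keeps
  the tables in double range for thousands of nucleotides at 37 °C.
  Probabilities are scale-invariant, and reported $\log Z$ values have the
  rescaling removed exactly. Loop weights use log-cumulative sums, whose
  rounding is orders of magnitude below the 1e-9 tolerance the tests
  demand.
* **Traceback determinism.** At ties the unpaired extension is preferred,
  then pair candidates in increasing position order — fixed and
  documented so identical inputs give identical outputs.
* **Reduction exactness.** At $\beta = 0$ all weights are exactly 1.0 and
  the weighted code path reproduces the plain fold bitwise. The
  all-missing case multiplies every weight by the same constant
  $e^{-\beta/2RT}$; that is a global factor mathematically but not in
  floating point, so the tests assert the structure identically and the
  probabilities at 1e-12.
* **Base case.** Short intervals are handled by seeding $Z(i, i-1) = 1$
  and letting the unpaired-extension rule build the pure
  $\prod \omega(k, 1)$ products; this seeding is validated against the
  enumeration oracle rather than asserted from any external statement.
* **Degenerate inputs.** $0/0$ accuracy ratios (empty prediction or empty
  reference) are reported as `NA`, never 0 or 1; $0 \ln 0 = 0$ in
  entropies; `criticalDistance()` at $\beta = 0$ requires the caller to
  supply the documented limit.

## The synthetic-data generator

`makeFixtures()` emulates a probing experiment on a known structure: a
random sequence (length 8–16, the range where the enumeration oracle is
exhaustive), a reference structure drawn uniformly from the complete
structure space, and reactivity profiles $q = x \pm \text{Unif}(0,
\text{noise})$ clipped to $[0,1]$, with default noise 0.2 — a moderate
perturbation that leaves the signal clearly informative, as probing data
on structured RNAs typically are. Zero-noise profiles replace the drawn
structure by the minimum-energy structure sharing its pairing indicator,
because a binary profile determines a structure only up to its indicator
and the large-$\beta$ weighted MFE provably converges to the
minimum-energy structure among the distance minimizers. Malformed files
are also emitted for negative I/O tests.

What the generator does *not* emulate: position-dependent probe
chemistry, correlated noise along helices, tertiary-contact protections,
missing-data clustering at primer sites, and the crystal-vs-solution
discrepancies that real benchmarks show (the package's
`discrepancyPositions()` exists to quantify those on real data). A green
test suite therefore establishes the mathematics of the engine — oracle
equivalence, self-consistency theorems, format round-trips — not
prediction accuracy on laboratory data, which additionally depends on the
energy model's completeness (see above) and data quality.

## Known limitations

* No pseudoknots, no suboptimal/stochastic sampling, no pair-specific
  (mutate-and-map style) weights — the weight of a paired position is the
  same whichever partner it takes.
* The energy model omits dangles and coaxial stacking, so absolute free
  energies and MFE structures will differ from RNAstructure/ViennaRNA on
  real RNAs; comparisons across modes inside this package remain
  internally consistent.
* `enumerateStructures()` is exponential and refuses sequences beyond 20
  nt by default; it is a validation oracle, not a prediction tool.
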