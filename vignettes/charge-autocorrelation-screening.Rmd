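---
title: "Screening by sign-split autocorrelation of partial charges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening by sign-split autocorrelation of partial charges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChargeScreen)
```

## The model

A molecule is treated as a set of point charges: atom $i$ has 3D position
$(x_i, y_i, z_i)$ (Å) and a pre-assigned partial charge $q_i$ (elementary
charge units).  How the charges were assigned (MMFF94x, Gasteiger, ...) is
outside the package's scope — they are input data — but query and database
must be prepared with the same charge model, since the descriptor compares
charge products quantitatively.

The spatial autocorrelation of the charges collects, for every unordered
atom pair $i < j$, the product $q_i q_j$ at lag $k$ equal to the
inter-atomic distance $d_{ij}$:

$$\mathrm{AC}(m, k) \;=\; \sum_{i=1}^{A-1} \sum_{j=i+1}^{A} q_i q_j\,
\delta_{k\,d_{ij}}.$$

Each pair enters once, and the $k = 0$ (self) term is ignored.  Because
the products carry signs, binning them together would cancel positive
against negative contributions that happen to fall at the same distance;
the terms are therefore *sign-split* first: products $q_i q_j \ge 0$ form
the positive part, products $< 0$ the negative part ($\mathrm{AC}^+$,
$\mathrm{AC}^-$).

Each part is then discretized by **linear binning** on the grid
$0, dx, 2dx, \dots$: a pair at distance $d$ between grid points $x$ and
$z = x + dx$ contributes $c_x = q_{ij}(z - d)/dx$ at $x$ and
$c_z = q_{ij}(d - x)/dx$ at $z$.  Linear binning conserves total mass
exactly and, unlike a histogram, varies continuously as $d$ crosses a bin
boundary.  The result is the descriptor pair
$\mathrm{LBAC}^\pm$ — two vectors whose entries depend only on distances
and charge products, hence invariant under translation and rotation (and,
unavoidably, under reflection and global charge-sign flip; see
*Limitations*).

Two descriptors are compared by **cross-correlation at lag zero**:

$$\mathrm{CC}(m, n) \;=\; \sum_{k=0}^{p} \mathrm{LBAC}^+_m[k]\,
\mathrm{LBAC}^+_n[k] \;+\; \sum_{k=0}^{q} \mathrm{LBAC}^-_m[k]\,
\mathrm{LBAC}^-_n[k],$$

with $p$ and $q$ the shorter of the two positive / negative lengths
(vector length is set by a molecule's largest inter-atomic distance, so
lengths differ between molecules).  No lag scan is performed: the
encoding is already alignment-free, so the meaningful comparison is at
lag zero only.  Continuous Tanimoto and Tversky ratios are derived from
the three dot products $AB$, $AA$, $BB$:
$T = AB/(AA + BB - AB)$ and
$T_{\alpha\beta} = AB/(AB + \alpha(AA - AB) + \beta(BB - AB))$ with
$(\alpha,\beta) = (1,0)$ weighting the query ("ref") and $(0,1)$ the
database molecule.  These continuous generalizations are this package's
documented choice of formula; they are clamped to 0 when $AB < 0$ so the
ratio scores stay in $[0, 1]$, while CC passes the raw (possibly
negative) value through because it is used for ranking, not as a metric.

## Parameters that matter

* **`dx` (grid step, Å; default 0.005).**  Balances approximation error
  against vector length.  Steps in $[0.001, 0.009]$ behave comparably;
  the package warns outside this range and errors only for
  $dx \le 0$.  A fine step preserves the near-exact distance matches
  that make two related structures score highly; a coarse step (e.g.
  0.5 Å) blurs peaks together and degrades ranking, which the
  acceptance checks demonstrate on synthetic sets.
* **Scorer (default CC).**  Raw cross-correlation ranks best in
  practice; Tanimoto/Tversky are provided for workflows that need
  bounded scores or asymmetric (substructure-flavoured) weighting.
* **Conformer filtering (default on).**  Conformers share a molecule
  name; after scoring, only the best-scoring record per name is kept,
  then ranks are assigned.  Ties keep first-seen input order, so runs
  are reproducible; ranking is dense (1..N).

## Numerical choices

* Grid anchored at distance 0; bin $t$ represents distance $t\,dx$, so
  two molecules' vectors are comparable index-by-index as the truncated
  CC sum assumes.
* Products exactly zero (one charge is zero) are assigned to the
  positive part, matching the $\ge 0$ split rule.
* Coincident atoms ($d_{ij} = 0$) are dropped with a warning — they
  carry no shape information and would otherwise put mass at lag zero.
* Bin accumulation order is fixed, so encoding is bit-reproducible on a
  platform; mirror images and charge-flipped copies encode
  *bit-identically* (negation and squaring are exact in IEEE
  arithmetic), while rotations agree to ~1e-9 per bin (round-off in the
  distance computation only).
* All-zero-charge molecules encode to an all-zero positive vector — not
  an error; they simply score 0 against everything.
* Single-atom molecules yield empty vectors; empty-vs-anything CC is 0.

## ROC and AUC

Screens are evaluated against active/decoy labels (actives are marked by
a molecule-name prefix, by convention `active`).  The ROC curve is built
by descending score with tied scores collapsed into a single step
(diagonal segment), so the trapezoidal area equals the Mann–Whitney
estimator $P(\mathrm{score}_a > \mathrm{score}_d) + \tfrac12 P(=)$.  The
tests pin this equivalence against an exhaustive pair-counting oracle.
AUC 0.5 is random ranking, 1.0 perfect separation.  Summaries over many
queries report mean, median and quartiles (linear-interpolation, type-7
order statistics).  AUC is computed after conformer filtering, matching
the pipeline order in which filtering precedes evaluation.

## What the synthetic generator emulates — and what it does not

`makeScreeningSet()` emulates a screening benchmark at desk scale:

* the **query** is a random point-charge molecule (default 20 atoms
  uniform in a 10 Å box, charges $\mathcal{N}(0, 0.2^2)$ e — the typical
  magnitude of force-field partial charges);
* **actives** (default 20) are rigid-transformed copies of the query
  with Gaussian jitter on coordinates (sd 0.005 Å) and charges (sd
  0.01 e), named `active_*`: "same compound, slightly different
  conformer/charges";
* **decoys** (default 700) are independent random molecules with the
  same atom count and charge spread, named `decoy_*`: physically
  matched, geometrically unrelated.

The coordinate-jitter default equals one grid step at the default `dx`.
This is deliberate: the perturbation of an inter-atomic distance is then
about $0.005\sqrt{2} \approx 0.007$ Å, within the two-bin support of
linear binning, so a jittered active keeps most of its peak overlap with
the query and scores above the decoy background across seeds.  Larger
jitter (several grid steps) decorrelates the spiky fine-grid vectors
rapidly — an instructive reminder that the method assumes query and
database conformers/charges are prepared identically.

What the toy sets do **not** model: chemistry (bonds, characteristic
bond-length peaks, valence), conformational flexibility beyond isotropic
jitter, and decoys that are topologically similar to actives.  Passing
the synthetic recovery checks therefore demonstrates the correctness of
the encoding/scoring machinery and the qualitative parameter behaviour,
not the absolute screening power obtainable on curated benchmarks with
real charge models.

Problem sizes used in the automated checks — 720-molecule default sets,
ten 170-molecule sets for the grid-step comparison, a 10,000-molecule
streaming equivalence file, 200 null-calibration simulations — were
chosen as the smallest sets on which the statistics above are stable.

## Limitations

By construction the descriptor cannot distinguish a molecule $m$ from
its mirror image $n$, from its charge-flipped copy $m'$, or from $n'$:
reflections preserve all distances, and flipping every charge sign
preserves all products, so
$\mathrm{CC}(m,m) = \mathrm{CC}(m,m') = \mathrm{CC}(m,n) =
\mathrm{CC}(m,n')$ holds exactly (it is asserted bit-exactly in the
tests).  Enantioselective targets therefore need a complementary
descriptor.  The method also inherits whatever systematic errors the
charge model carries, and comparing files charged by different models is
unsupported.

## Design choices that were genuinely open

* **Tanimoto/Tversky formulas** are not uniquely fixed by the scoring
  menu; the standard continuous forms over the three CC dot products
  were adopted, with `Tversky_ref` placing $\alpha$ on the query.
* **Tie handling** in ranking (stable, first-seen wins) and in ROC
  construction (single diagonal step) were chosen for reproducibility
  and for exact agreement with the pair-counting AUC estimator.
* **Vector storage** keeps trailing bins up to the largest distance's
  upper neighbour; since CC truncates to the shorter operand, padding
  conventions cannot affect scores.
* **Streaming mode** trades ranking and conformer filtering for
  constant memory, mirroring the split between the ranking screen and
  large-database scoring; equality of the scores themselves is pinned
  by a 10,000-molecule test.

## A minimal session

```{r example, eval = FALSE}
set <- makeScreeningSet(seed = 1)
records <- labelActives(screen(set$query, set$database))
head(records, 3)
auc(rocCurve(records))
```
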