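---
title: "Curating multi-source aqueous solubility data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating multi-source aqueous solubility data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solcure)
```

## The model

Public aqueous solubility collections report LogS — log10 of solubility in
mol/L — for overlapping sets of molecules, with repeated and conflicting
measurements. `solcure` treats each record as a noisy observation of a
molecule's solubility and attaches a *quality weight* to every record and
every dataset. The workflow rests on three operations:

* **Identity.** Two records of the same molecule are *identical* when
  their LogS values differ by at most the identity tolerance
  (default 0.01). Molecule identity itself is string equality of
  standardized canonical SMILES; tautomers, which SMILES cannot
  distinguish, remain distinct records until value-based merging decides.
* **Merging.** A molecule's weighted values `(v_k, w_k)` are merged by
  greedy *partial clustering*: repeatedly find the closest pair; if its
  gap is strictly below `d`, replace it by the weight-weighted mean with
  summed weight, else stop. On the real line the closest pair is adjacent
  in sorted order and a merged centroid stays between its neighbours, so
  the greedy loop operates on a sorted vector. Total weight and the global
  weighted mean are invariant under any merge sequence. The guarantee at
  termination is that the *final* closest pair is at least `d` apart;
  because centroids move, intermediate gaps larger than `d` can shrink,
  and no stronger claim is made.
* **Weighting.** Within a dataset, a molecule's record weights are
  rescaled to total 1.0 (each distinct value weighted by its frequency of
  occurrence). Across datasets, a record enters curation with weight
  `record weight × dataset quality weight`, and after clustering each
  molecule's total is capped at a threshold by proportional rescaling.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `identical_tol` | 0.01 | LogS | identity tolerance for redundancy and within-dataset merging |
| `merge_gap_d` | 0.5 | LogS | partial-clustering merge gap; the published recommendation |
| `temp_center ± temp_halfwidth` | 25 ± 5 | °C | accepted experiment window |
| `ph_center ± ph_halfwidth` | 7 ± 1 | — | accepted pH window |
| `element_blacklist` | 44 symbols | — | heavy metals/metalloids excluded from drug-design scope |
| `weight_cap_threshold` | 1.0 | — | per-molecule curated weight ceiling |
| `env_policy` | `remove` | — | off-window records: remove, or keep flagged |

The default cap of 1.0 keeps curated weights on the same scale as the
per-molecule total of 1.0 established by normalization; molecules attested
by several datasets accumulate more raw weight and are clipped back to the
cap, while singly-attested molecules keep totals below it — which is
exactly the intended relative devaluation.

## The curation schedule

Datasets belong to quality groups (`high`, `low`, `kinetic`) and carry an
assigned weight in [0, 1] (`solubility_sources()` ships the published
reference assignment). A target may be curated with: itself, always;
same-group datasets of equal-or-higher weight; and, when the target is
low-quality, any high-quality dataset. Kinetic data has no thermodynamic
partners. These rules reproduce the published seven-dataset schedule
table, which the acceptance suite checks cell by cell.

Two readings of the workflow were genuinely open and are settled here:

* *Tie-breaking* when two pairs share the minimal gap: the pair with the
  smaller lower value merges first. Ties are decided on exact floating
  point equality — values that print identically but differ in the last
  bit are not ties.
* *"Truncate the maximum total weights"* is implemented as a per-molecule
  proportional rescale to the cap rather than a hard cut of individual
  records, since the records of a molecule are subsequently described as
  normalized.
* The target's own records are also multiplied by the target's dataset
  weight, so all pooled weights share one scale; downstream training only
  consumes relative weights.

## Numerical choices and degenerate inputs

* The weighted RMSE divides by `n`, not by the weight sum, exactly as the
  metric is defined for weighted test sets; a normalized variant exists
  behind `normalize = TRUE` and is never the default.
* Spearman's coefficient uses the closed form `1 − 6 Σ d² / (n(n²−1))`
  when ranks are unique and falls back to the Pearson correlation of
  average ranks under ties (the standard extension).
* Identity uses an inclusive boundary (`≤ tol`), merging a strict one
  (`< d`): "identical within 0.01" naturally includes the boundary, while
  the merge rule is stated as "less than d".
* Correlation of a constant vector raises an error rather than returning
  `NA`; empty clustering input, molecules with zero total weight, and
  duplicate dataset ids are errors.
* Splits use floor allocation with the remainder to train; empty
  nonzero-ratio bins are then topped up one record from train, so
  `n = 5` at `[0.8, 0.1, 0.1]` yields (3, 1, 1). Scaffold splitting
  assigns whole Bemis–Murcko scaffold groups, largest first (ties broken
  by a seeded shuffle), to the first unfilled bin in train → val → test
  order; acyclic molecules form one "no-ring" group; a scaffold larger
  than the train quota is placed in train with a warning.

## The chemistry layer

No R-native cheminformatics toolkit is assumed: standardization
(parse → sanitize → largest-fragment → charge-neutralize → canonical),
atom enumeration, SF5/SF6 substructure detection, Murcko scaffolds and SDF
reading are delegated to RDKit through a batched `python` subprocess with
a per-session cache. Whether desalting and neutralization are enabled is a
documented convention of this package (mirroring the MolVS default flow),
not a fact about the original protocol. One consequence is deliberate: the
element and SF-group filters examine *every* fragment of the input
structure, so a blacklisted counter-ion (e.g. `[Li+].[Cl-]`) triggers the
filter even though the standardizer would keep only the largest fragment.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` describes a world of `n_molecules` pool molecules with
true LogS drawn from N(−3, 1.5) — a typical drug-like solubility range;
neither the workflow nor its evaluation depends on this choice. Each
dataset covers a pool molecule with probability `p_overlap` and records
either the exact true value or truth plus N(0, `noise_sd`). Exactness is
driven by a per-molecule *measurement difficulty* latent `u ~ U(0,1)`
shared across datasets: a record is exact iff `u < p_same_value` of its
dataset. The shared latent means easy molecules agree everywhere, so two
datasets with equal `p_same_value = p` show an exact-agreement fraction of
`p` — not `p²` as independent coins would give — matching how agreement
fractions are reported between real collections. Closed-form expected
redundancy matrices follow from the min/difference/complement
decomposition of the latent plus Gaussian overlap terms, and the
acceptance suite checks measured matrices against them at three standard
errors. Contamination (off-window temperatures, heavy-metal molecules) is
injected at per-dataset rates.

The generator's default world — three datasets with weights 1.0/0.85/0.4,
roughly half-pool coverage, 20–40 % exact agreement, noise SD 0.3–0.8 LogS
and a few percent contamination — was chosen once as a plausible miniature
of real multi-source collections and is not tuned to any test outcome.

The generator does **not** emulate: assay-specific or systematic
(non-Gaussian) error structure, kinetic-vs-thermodynamic offsets,
tautomer-induced value splits, unit-conversion mistakes, or correlated
coverage (real datasets share ancestry; here membership is independent).
A green end-to-end test therefore establishes that the machinery is
correct under the stated statistical model, not that the default weights
are optimal for any real collection.

## Known limitations

* The dataset quality weights are inputs, not estimates; searching for a
  better assignment is explicitly out of scope.
* Redundancy matrices are membership-based (a record counts once per cell
  no matter how many matches exist), so they are not symmetric and rows
  need not sum to anything in particular.
* The SDF reader takes the first matching LogS-named property and ignores
  unit conversion; tables are assumed to be in LogS already.
* Exact replication of the originally published record counts would
  require the original deposited files, which are not bundled; the
  pipeline is validated on synthetic collections with planted truth
  instead.
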