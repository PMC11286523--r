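---
title: "Methods: NOT-gate target and iCAR partner discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NOT-gate target and iCAR partner discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notgate)
```

## The model

A NOT-gate CAR T-cell kills a cell only when the activating (principal)
antigen is bound AND the inhibitory (iCAR) antigen is not. Safety therefore
reduces to a set statement over healthy tissues: writing $T_{on}(p)$ for the
set of healthy tissues in which principal $p$ is expressed, an iCAR partner
$q$ protects all of them iff

$$T_{on}(p) \subseteq T_{on}(q) \quad \text{and} \quad q \notin \text{tumour surface}.$$

`notgate` operationalises this with seven eligibility rules over three
tables (tumour surfaceome, healthy-tissue proteome matrix, gene × cell-line
dependency screen):

* **Principal** (rules 1–4): membrane-annotated, has a defined extracellular
  domain (ECD), median tumour surface expression $> 3.5$ AU on the 0–5 AU
  scale, ECD $> 175$ aa, aggregated Chronos score $\le -0.25$, and no
  detection in any tissue flagged as T-cell lineage.
* **iCAR** (rules 5–6): absent from the tumour surfaceome (or recorded there
  at exactly 0 — the two cases are logged distinctly), with a catalogued
  ECD ($> 0$ aa, plus any user minimum).
* **Pairing** (rule 7): coverage of $T_{on}(p)$ as above, evaluated as
  presence/absence per tissue. We deliberately do **not** require
  quantitative correlation of expression levels: the safety argument only
  needs the iCAR to be *detectable* wherever the principal is, and protein
  intensities from different platforms are not comparable on a common scale.

Candidates are ranked by a vector score. With $e$ and $s$ the min–max
normalisations (over the candidate set) of median surface expression and of
$-\text{Chronos}$ respectively,

$$\mathrm{score} = \sqrt{e^2 + s^2} \in [0, \sqrt 2].$$

The exact published formula behind this style of ranking is not available,
so the package makes its own choice and isolates it in one function
(`vector_score()`): the Euclidean norm is symmetric in its two components,
matches the name "vector score", and — the property we actually rely on —
preserves Pareto order: a candidate at least as expressed and at least as
essential as another, strictly better in one, never ranks below it. A
rank-sum alternative can be swapped in without touching the rest of the
pipeline. Whether normalisation should run over all filtered candidates or
only the post-essentiality subset is equally unspecified upstream; the
package normalises over whatever candidate set it is handed, which makes the
choice explicit in the caller's code.

## Tunable parameters

All thresholds live in one `filter_config()` object:

| parameter | unit | default | why |
|---|---|---|---|
| `min_expression` | AU (0–5) | 3.5 | published working point; strict `>` ("above 3.5") |
| `min_ecd` | amino acids | 175 | scFv accessibility; strict `>` ("greater than 175") |
| `max_chronos` | Chronos units | −0.25 | essentiality cut; inclusive `<=` ("−0.25 or below"); `Inf` disables |
| `tissue_on_threshold` | intensity | 0 | any detection counts as "expressed"; exposed because proteomic noise floors differ per platform |
| `exclude_t_cell_expressed` | flag | `TRUE` | rule 4, against tissues *flagged* `t_cell` rather than a hard-coded name list (tissue naming varies between proteome releases) |
| `require_dependency_entry` | flag | `TRUE` | genes absent from the dependency table cannot be called essential; toggleable because dependency screens have false negatives |
| `use_in_vivo` | flag | `FALSE` | optional in-vivo CRISPR intersection; in-vivo surface-protein screens are small, so this is opt-in |
| `min_icar_ecd` | amino acids | 0 | extra iCAR ECD floor, e.g. to exclude small-ECD/multi-pass proteins from a partner list; no published numeric cut exists, so it is user-supplied |

The Chronos boundary deserves a note: the source material states the cut
both as strictly below and as "−0.25 or below". The package adopts the
inclusive form — a gene at exactly −0.25 passes — and tests pin this
down (`test-acceptance.R`, criterion 6). The difference matters only at the
exact boundary value.

## Missing values are not zeros

Three places where "unknown" and "absent" must not be conflated, each
resolved conservatively with respect to patient safety:

* A missing healthy-tissue measurement is kept as `NA` by the reader, never
  imputed to 0.
* A tissue with a missing value for the *principal* is excluded from
  $T_{on}(p)$ (unknown is not ON) and flagged in the log — it silently
  neither demands nor receives protection, which is the one unavoidable
  asymmetry of incomplete data.
* A missing value for an *iCAR candidate* in a required tissue counts as NOT
  covered: an unprotected tissue must never be assumed protected.

A principal whose $T_{on}$ is empty is fully tumour-specific and needs no
iCAR; every candidate is then vacuously feasible and the engine raises a
prominent warning instead of a quiet all-pass.

## Aggregating the dependency screen

Upstream usage is "one Chronos score per gene" without a stated collapse
over cell lines. `aggregate_chronos()` takes the median across the
configured disease cell lines (mean switchable), skipping missing per-line
scores and reporting how many lines contributed (`n_lines`). The median is
permutation-invariant and robust to a single outlier line; a gene with no
usable score is excluded and listed, not silently given `NA`.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` produces all four inputs with machine-readable planted
truth, deterministically per seed (byte-identical files on rerun, and the
caller's RNG stream is restored). Defaults state a desk-scale world chosen
once: 120 surfaceome proteins, 400 proteome proteins, 20 tissues (2 T-cell
lineage, 4 essential-cell-type), 3 planted principals with disjoint
ON-tissue sets, 4 feasible and 6 partial partners each, ON level 2.0 with
half-normal noise (sd 0.3), 12 disease + 3 other cell lines — a shadow of
the real inputs' shape (thousands of surface proteins, ~17k proteome
entries, tens of tissues) at roughly 40× reduction.

Qualitative shapes mirrored: background surface expression is a truncated
normal on the AU scale; background tissue intensities are zero-inflated
log-normal, so "not expressed" is a common, realistic state (in the real
iCAR space the large majority of proteome proteins are absent from the
tumour surface); background Chronos is centred near 0.

Exactness of recovery is engineered, not hoped for: background surface
expression is capped at 3.4 AU (below the 3.5 threshold), planted Chronos
draws are clamped below −0.3, and every non-partner proteome row is zeroed
across the union of planted ON sets. Consequently a green
planted-recovery test establishes that the pipeline implements the rules
and the coverage logic *exactly* on inputs where the answer is provable —
it does **not** establish robustness to threshold-straddling noise,
batch effects, inter-platform scale differences, or annotation errors,
none of which the generator attempts to model. Threshold sensitivity can be
probed by raising `noise_sd`, at the price of losing guaranteed recovery.

## Numerical and determinism choices

* Threshold comparisons are exactly as stated above (two strict, one
  inclusive); no epsilons are added.
* Ranking ties are broken by more negative Chronos, then by gene symbol in
  C-locale (radix) order, so output files are identical across platforms
  and locale settings.
* Combination counting is plain multiplication in doubles — exact for any
  realistic candidate-set sizes (up to $2^{53}$ pairs).
* All tables are written by `data.table::fwrite` with shortest round-trip
  float formatting; fixture values are rounded to 6 decimals at generation
  time so written fixtures re-read bit-for-bit.
* Degenerate inputs: an empty surfaceome filters to an empty candidate set
  (not an error); ranking a single candidate sets both normalised
  components to 0.5 (a constant component carries no information); an empty
  disease-line set is an argument error.

## Known limitations

* The published dataset-dependent headline counts (candidate-space sizes,
  the 45-essential set, the 26→13 partner narrowing for the transferrin
  receptor, per-target combination counts) require the authors' deposited
  data files and the binarisation threshold used there; they are not
  reproducible from this repository and are not claimed by any test. The
  pipeline accepts those files through the dialect-configurable readers
  with default thresholds matching the published filter panel.
* One published headline is internally inconsistent: 716 principal × 1348
  iCAR candidates is stated to give 968,032 theoretical combinations, but
  the product is 965,168. `count_combinations()` is exact by invariant, so
  the corresponding acceptance test is left failing on purpose, with the
  companion test asserting the true product.
* Gene symbols are the join key, upper-cased, with no alias resolution;
  cross-dataset symbol drift must be fixed upstream.
* The multi-iCAR greedy set cover (`icar_set_cover()`) is an extension
  beyond single-partner NOT-gating and is labelled as such; greedy cover is
  not guaranteed minimal.
* Rule 7 ignores expression *levels* by design; a partner detectable at
  trace level in a required tissue counts as covering it. Raise
  `tissue_on_threshold` to demand more than trace detection on both sides
  of the gate.
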