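---
title: "Two-stage recommendation of reaction conditions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage recommendation of reaction conditions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Given an organic reaction written as reactant and product structures, which
reagents (bases, acids, metals, coupling agents, ...) and solvents should be
used, and at what temperature? Reaction databases record, for each reaction,
one or a few *condition records*: a set of up to three reagents, a set of up
to two solvents, a temperature, and the yield obtained. The search space of
condition combinations is combinatorially large while the recorded evidence
per reaction is tiny, which makes direct classification over full condition
tuples hopeless. `rxncond` follows the two-stage architecture of modern
recommender systems:

1. **Candidate generation** — a multi-label network looks at the reaction
   and assigns every reagent and every solvent label an independent
   probability of being relevant.
2. **Ranking** — thresholded candidates are expanded combinatorially into
   *reaction contexts* (a reagent subset of size 1–3 crossed with a solvent
   subset of size 1–2), and a listwise ranking network scores each context
   by yield-derived relevance and predicts its temperature.

## Reaction representation

Both networks consume a **reaction difference fingerprint**: the Morgan
circular count fingerprint (radius 2, folded to 4096 counts) of the product
set, concatenated with the element-wise difference between the reactant-set
and product-set fingerprints, 8192 dimensions in total. Count (not binary)
fingerprints are summed over each molecule set, so the vector is linear in
the set and the signed difference half carries stoichiometry as well as the
transformation itself.

The fingerprint is computed by the package on molecular graphs obtained
from OpenBabel (via ChemmineOB): canonical SMILES are parsed to a V2000 MOL
block, and atom environments of radius 0–2 are hashed with a deterministic
integer fold. Initial atom invariants are (atomic number, degree, bond-order
sum); formal charge is not part of the invariant, which merges a handful of
charged/neutral atom environments but has no practical effect on
discriminating whole molecules in our use. An environment is only emitted
while its covered bond set still grows, so a lone atom (methane, water, a
bare metal) occupies exactly one position. Identical canonical SMILES give
bit-identical vectors across processes; fingerprints are memoised keyed by
canonical SMILES, radius and width.

## Preprocessing

`read_reaction_table()` and friends implement the standard cleaning ladder
for reaction-condition tables:

1. rows whose reaction SMILES does not parse are dropped (and counted);
2. rows without a solvent or without a yield are dropped;
3. rows with more than two solvents or three reagents are dropped;
4. a chemical appearing as both reagent and solvent is reassigned entirely
   to the role in which it occurs more often dataset-wide (ties go to
   reagent — a deterministic choice, logged);
5. records containing any label rarer than `min_label_freq = 10` are
   removed, iterating with recounted frequencies to a fixed point, because
   one removal pass can drag other labels below the threshold;
6. labels are resolved to canonical SMILES — directly when the label parses
   as SMILES, otherwise through a shipped offline name-to-SMILES table
   (`inst/extdata/name_to_smiles.tsv`); hydrate names map to the anhydrous
   form, so "sodium carbonate monohydrate" and "sodium carbonate" are one
   label. Names absent from the table stay as verbatim text labels. The
   offline table replaces live name-resolution services so that builds and
   tests are hermetic;
7. rows with identical canonical reaction SMILES merge into one entry
   carrying several condition records;
8. the train/validation/test split (8:1:1) is drawn over those merged
   entries, so a reaction never leaks across subsets.

Yields are stored as fractions; values in (1, 100] are interpreted as
percentages and divided by 100 (logged). An agents segment in
`reactants>agents>products` SMILES, and a `catalysts` column if present,
are folded into the reagent labels before role counting.

## Candidate generation

The network maps the 8192-dim fingerprint through a shared hidden layer
(default 1024 ReLU units, dropout 0.3) and one task-specific hidden layer
per task onto two sigmoid output vectors, one per vocabulary. The
multi-label target of a reaction is the union of labels over all its
records. Per-label losses use the **focal loss**

$$\mathrm{FL}(p, y) = \begin{cases}-(1-p)^{\gamma}\log p & y = 1\\
-p^{\gamma}\log(1-p) & y = 0\end{cases}$$

which reduces to binary cross-entropy at $\gamma = 0$ and down-weights easy
examples for $\gamma > 0$ — the right behaviour under the heavy label
imbalance of reaction data, where a few workhorse reagents dominate.
$\gamma = 2$ is the default for both tasks (the common focal-loss choice;
per-task values are configurable). Probabilities are clamped to
$[10^{-7}, 1-10^{-7}]$ before logs.

The two task losses are combined with learned homoscedastic uncertainty
weights

$$\mathcal{L} = \frac{\mathcal{L}_r}{2\sigma_r} +
\frac{\mathcal{L}_s}{2\sigma_s} + \log \sigma_r\sigma_s,$$

with $\sigma_r, \sigma_s > 0$ enforced by optimizing their logarithms,
initialized at 1 and trained jointly with the weights by Adam. We implement
the $1/(2\sigma)$ weighting exactly as written above; the
homoscedastic-uncertainty literature more commonly uses $1/(2\sigma^2)$,
which is available as `loss_variant = "sigma2"`.

**Thresholding.** Labels with probability at or above a cutoff become
candidates. The cutoff is chosen on validation data as the grid value
maximizing the mean of the reagent and solvent example-based F1 scores
(ties go to the smallest value, favouring recall); 0.3 is the canonical
choice for real data. The comparison is inclusive ($\ge$), which differs
from a strict reading only on measure-zero ties. If a task retains no label
at the cutoff, the single argmax label is used and the fallback is flagged,
so the enumeration below is never empty.

**Enumeration.** With $N_r$ reagent and $N_s$ solvent candidates, all
non-empty reagent subsets of size $\le 3$ are crossed with all non-empty
solvent subsets of size $\le 2$:

$$\left(\sum_{i=1}^{3}\binom{N_r}{i}\right)\times
\left(\sum_{i=1}^{2}\binom{N_s}{i}\right)$$

contexts, in a fixed order (subset size, then candidate rank) so downstream
ranking is reproducible. A configurable cap (default 10,000) guards against
degenerate thresholds.

## Hard negative sampling

Ranking needs unfavourable contexts, but literature-derived databases
rarely record failures. We therefore mine **hard negatives**: labels the
trained candidate model scores strictly above 0.1 yet that never occur in
the reaction's records — plausible-looking wrong answers. Positives and
hard negatives are pooled and enumerated as above into one training list
per reaction. A context whose reagent set and solvent set both exactly
equal a recorded condition receives that record's relevance
$s = 2\cdot\mathrm{yield} + 2 \in [2, 4]$ (yield as a fraction) and its
temperature; every other context receives $s = 0$ and no temperature
target.

Three deliberate choices, where the rule could be read more than one way:

- **Exact-set positivity.** A context assembled purely from positive labels
  but not equal to any recorded set scores 0. The alternative (any context
  free of negative labels counts as positive) blurs the target; exact
  matching mirrors how the recommendations are later evaluated.
- **Cap.** Hard negatives are capped at the top-5 per task by probability,
  bounding the combinatorial blow-up of list lengths.
- **One pass.** Negatives are mined once with the final candidate model,
  not per epoch.

## Listwise ranking and temperature

Each context row is the reaction fingerprint concatenated with multi-hot
reagent and solvent vectors (multi-hot, because contexts hold up to three
reagents and two solvents). Fingerprint and condition branches pass through
separate dense layers, concatenate into a trunk, and end in two scalar
heads: a relevance score and a temperature.

Training is listwise in the ListNet sense. For a list of $n$ scores the
**top-one probability** is the softmax
$P_s(i) = e^{s_i}/\sum_j e^{s_j}$ (computed with max-subtraction; shift
invariant). The ranking loss is the Kullback–Leibler divergence
$\mathrm{KL}(P_{\mathrm{target}} \| P_{\mathrm{pred}})$ between the
distributions induced by the target relevances and the predicted scores —
the direction matching ListNet's softmax cross-entropy up to a constant
(the reverse direction is a config switch). A one-context list carries no
ranking signal and contributes only temperature loss.

Temperature targets are standardized by the training mean and SD and
trained with MSE on exactly the rows that carry a recorded temperature;
records lacking a temperature stay in the label targets but are masked out
of the temperature loss. The two losses are combined with the same learned
homoscedastic scheme as in stage one. At inference the raw score head
orders contexts (stable sort; ties keep enumeration order) and the
temperature head is de-normalized to Celsius and clamped to the training
range widened by 50 °C as a sanity bound.

Relevance uses yield as a *fraction*, so recorded contexts score in
$[2, 4]$ against 0 for negatives; treating printed percents as-is would
saturate the softmax (gaps of $e^{100}$), which is why percents are
converted upstream.

## Evaluation protocols

- **Example-based multi-label metrics** over predicted vs. true label sets:
  Hamming loss $\frac{1}{N}\sum_i |Z_i \Delta Y_i|/q$, and per-instance
  precision $|Y\cap Z|/|Z|$, recall $|Y\cap Z|/|Y|$, F1
  $2|Y\cap Z|/(|Y|+|Z|)$, averaged over instances. An empty prediction
  contributes precision (and F1) 0 rather than dropping the instance. The
  identity $F1 = 2PR/(P+R)$ holds per instance but *not* for the averaged
  aggregates, and is not used.
- **Top-k exact match**: a reaction is a hit at $k$ if any recorded
  (reagent set, solvent set) pair equals any top-$k$ recommended pair — set
  equality on both roles, temperature excluded. Partial overlap does not
  count.
- **Multi-record table**: reactions bucketed by record count (1–5); for
  each bucket the fraction with at least $j$ records inside the top-20.
- **Temperature**: MAE, fractions within ±10/±20 °C, and constant
  mean/median baselines.
- **Embeddings**: activations of the shared or task-specific hidden layers,
  exported as a matrix for external projection (t-SNE or similar is out of
  scope).

## The synthetic world

Real training tables of this kind are proprietary, so the package ships a
generator whose output has the statistical structure the method relies on,
letting every stage be trained and tested hermetically:

- **Templates with learnable signal.** Each template is a functional-group
  transform (aldehyde reduction, esterification, amide coupling, ...)
  applied to scaffolds decorated with random alkyl/ether substituents, so
  reactions of one template share a strong fingerprint signature while
  remaining distinct molecules.
- **Condition structure.** Each template carries 4–6 compatible conditions
  built as variations around a core reagent and core solvent, with latent
  mean yields in [0, 1]; the unique best condition has the highest latent
  yield by construction. Records are drawn with probability
  $\propto e^{\mathrm{yield}/0.2}$, mimicking the literature's bias toward
  high-yielding conditions while keeping every condition represented.
- **Imbalance.** Label choices follow Zipf-like weights, so the top decile
  of reagent labels covers well over half of all occurrences — the regime
  the focal loss is for.
- **Noise and multiplicity.** Recorded yields are latent yields plus
  clamped Gaussian noise (SD 0.05 by default); temperatures are
  condition-level means (spread across templates over −10…130 °C) plus
  noise (SD 5 °C); 8.8% of reactions carry 2–5 records, matching the
  sparse multi-condition structure of real tables.
- **Leakage guard.** The latent truth (full compatibility tables with
  latent yields) is returned separately and never written into the dataset
  files consumed by training; a test enforces this.

What the generator does **not** emulate: chemical feasibility beyond the
template structure, correlated noise, systematic reporting bias by journal
or year, name-string noise (labels are emitted as SMILES), and the sheer
vocabulary scale of real databases (~1300 reagents). Passing benchmarks on
this world therefore demonstrates that the machinery learns the structure
it assumes — not that the particular accuracy figures transfer to any real
corpus.

## The recovery benchmark

`recovery_benchmark()` is the package's standing end-to-end check: a world
of 40 reagents, 15 solvents and 8 templates; 4000 reactions with yield
noise SD 0.05 and multi-condition fraction 0.088; both stages trained on
the 8:1:1 split. It reports held-out example-based F1 per task at the
optimized threshold, top-k exact-match rates, the mean per-reaction
Spearman correlation between predicted context scores and latent yields
(computed over each test reaction's full compatibility table, pooled as a
mean over reactions — the quantity that matters is the ordering *within* a
reaction's candidate list), and temperature MAE against the constant
mean/median baselines.

The benchmark's model configuration is sized for the 55-label world: a
512-count fingerprint fold (1024-dim reaction fingerprint), a 256-unit
shared layer, 25 candidate epochs and 12 ranking epochs. These are the
package's defaults for this world size and complete in a few minutes on a
single CPU; the full-scale defaults (4096-bit fold, 1024-unit layer) are
what one would use on a database-scale corpus.

## Numerical choices and degenerate inputs

- Probability clamps at $10^{-7}$ before logs; softmax with
  max-subtraction; $\sigma$ parameters as logarithms.
- All sorting uses radix order on fixed label strings — locale-independent.
- Candidate fallback: an empty thresholded task yields its argmax label,
  flagged.
- Threshold ties resolve to the smaller cutoff; score ties keep enumeration
  order (stable sort).
- Temperature predictions clamp to the training range ±50 °C.
- Seeds: a single global seed fans out to per-stage seeds through a fixed
  affine derivation, so stages are independently reproducible; training is
  deterministic given seed and BLAS build, not bit-portable across
  hardware.
- Empty inputs (no training entries, empty lists, empty score vectors)
  raise errors rather than returning silent defaults.

## Known limitations

- Records with no reagent at all can be stored but never matched by the
  enumeration (which builds non-empty reagent subsets); real tables where
  solvent-only conditions matter would need an explicit empty-reagent
  context.
- The candidate network treats labels independently; co-occurrence
  constraints (a reagent that only works in one solvent) are left entirely
  to the ranking stage.
- Relevance is yield-derived only; cost- or separation-based relevance
  definitions would slot into `relevance_score()` but are not implemented.
- The offline name table covers common laboratory chemicals; exotic names
  without SMILES stay verbatim labels, which fragments their statistics.
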