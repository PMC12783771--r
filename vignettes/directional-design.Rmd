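---
title: "Directional multi-objective sequence design: methods and design choices"
author: "seqDirector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional multi-objective sequence design: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqDirector)
```

## The problem

Allosteric transcription factor (aTF) biosensors couple ligand binding to
reporter gene expression: a metal-responsive regulator such as a lead sensor
distorts its operator on binding Pb(2+) and switches on a fluorescent
reporter. Natural aTFs rarely meet diagnostic requirements out of the box —
the canonical failure mode is a sensor that responds to the target analyte
(lead) only at high concentrations while responding strongly to a common
interferent (zinc). Improving one property by directed evolution routinely
degrades the other, so the engineering problem is inherently
multi-objective: raise the lead response while suppressing the zinc
response, simultaneously.

`seqDirector` implements a machine-learning-guided directed-evolution
workflow for this problem built around three ideas:

1. **Screen-derived objective metrics.** Each mutant is screened under
   three conditions (no ligand, low lead, high zinc). Fold change
   (FC = induced / uninduced signal) and dynamic range (DR = induced
   signal - leak) are normalized to a same-batch wildtype, giving the
   objective vector `f(X) = [f_Zn(X), f_Pb(X)]`.
2. **Directional paired training data.** Instead of regressing sequence on
   activity, every *pair* of measured variants becomes a training example
   labeled per objective with a direction token, `<inc>` or `<dec>`,
   recording which way the metric moved from the first sequence to the
   second. From M variants, up to choose(M, 2) pairs per orientation can
   be formed — substantial augmentation exactly when data are scarce.
3. **Conditional sequence-to-sequence generation.** A model
   `P(X2 | d, X1)` is trained to reproduce the target sequence of each
   pair given the direction tokens and the source sequence. At design
   time, prompting with `<dec> <inc>` (zinc down, lead up) and sampling
   from validated seed sequences proposes new variants biased toward the
   desired trade-off, in a single generation step.

## Metrics and the noise threshold

FC is mean induced signal over mean no-ligand signal; a non-positive leak
makes FC undefined and the record is flagged rather than silently zeroed.
DR may be negative; negative *normalized* DR is clamped to zero only when
values are prepared as model-training labels (the `clampNegativeDr` flag),
never in reporting. Normalization always pairs a mutant with the wildtype
measured in the same batch, absorbing day-to-day assay drift; whether to
use a batch-matched or campaign-global wildtype was genuinely open, and the
batch-matched choice is the one that makes replicate screens on different
days comparable at all.

Pairs are informative only when the measured change exceeds experimental
noise. The per-objective threshold tau defaults to **2 x the pooled
replicate SD of the wildtype metric across batches**: within each batch a
per-replicate wildtype metric value is formed (replicate signal against the
batch-mean leak, normalized by the batch wildtype value), its variance
taken, and variances pooled. A 2-SD rule is conservative and reproducible
from any screen table; it is configurable per objective (`objectiveSpec()`).

## The labeling rule

For a pair (X1, X2) and objective k with delta = f_k(X2) - f_k(X1):

- `<inc>` when delta > tau_k,
- `<dec>` when delta < -tau_k,
- otherwise the pair is **excluded**.

A two-way rule that assigns `<dec>` to every delta <= tau would mislabel
small positive changes as decreases, contradicting the requirement that
sub-noise pairs be excluded; the symmetric three-way rule above is the only
self-consistent reading, and it is what `assignDirection()` implements. Two
further policies were open:

- **Retention**: a pair is kept only when *every* objective clears its
  threshold ("all"). Every emitted token must be evidence-backed; emitting
  a confident label for one objective alongside a guessed label for
  another would corrupt the training signal.
- **Orientation**: both orientations of each unordered pair are used by
  default, with every token flipped in the reversed copy. The model then
  sees each comparison as both an improvement recipe and a degradation
  recipe, which is the stated benefit of directional labels over
  preference-only schemes. Single orientation is available for ablation.

Duplicate sequences are collapsed to their mean metrics before pairing, so
no zero-edit pair can arise. Categories (2^j label tuples; four for two
objectives) are balanced by seeded downsampling to the smallest non-empty
category — empty categories are reported, never fabricated.

## The conditional model

The model factorizes autoregressively,

```
P(X2 | d, X1) = prod_t P(X2_t | d, X1, X2_<t),
```

and training maximizes the conditional log-likelihood (token-level
cross-entropy) with AdamW (decoupled weight decay; defaults lr 1e-4,
weight decay 1e-4). The vocabulary is the residue alphabet plus the two
direction tokens and four control tokens (pad, start, end, unknown).

The built-in backbone is deliberately small: a **position-aligned
conditional decoder**. At step t it conditions on the direction-token
embeddings, the source residue aligned at position t, a positional
embedding, and the embedding of the previously emitted token, through one
ReLU hidden layer onto a softmax over the vocabulary. Two properties
motivated this architecture over a deeper attention stack:

- In the substitution-only regime source and target have equal length and
  differ at point positions, so the diagonal alignment is not an
  approximation — it is the true correspondence. Attention layers would
  have to learn what is here hard-wired.
- It trains from scratch on one CPU in seconds-to-minutes at test scale,
  which keeps the whole loop verifiable end to end. The method's substance
  is the data construction and the conditioning, not backbone scale.

The output layer is initialized to zero, so an untrained model emits
exactly the uniform distribution — a convenient analytic anchor for tests.
A pretrained-backbone adapter path is exposed through configuration
(`backbone = "pretrained-adapter"`, with low-rank adapter settings rank 16,
scaling 32, dropout 0.05 passed through); the tiny backbone ignores the
adapter settings with a notice, since it is fully trained. Nothing in the
package requires a pretrained model.

Training details that were open and are fixed here: teacher forcing during
training; a 10% validation split **by unordered-pair identity**, so both
orientations of a pair land on the same side (otherwise the validation set
leaks through mirrored copies); greedy decoding for monitoring; sampling
reserved for design. The BLEU-style corpus validity score (modified n-gram
precision up to 4-grams with brevity penalty, residues as tokens,
exponential smoothing of zero higher-order counts, zero unigram overlap
scoring 0) is monitoring-only and gates nothing; epochs, batch size and
the optional patience-based stop are declared in `trainConfig()` and
recorded in every checkpoint sidecar. All randomness flows from one
recorded seed; identical data + config + seed reproduce identical loss
curves, and checkpoints reload bit-stably.

## Design step

Seeds are all measured sequences strictly better than wildtype in every
prompted direction (for the selective prompt: higher lead response and
lower zinc response), ordered by descending lead metric; if none qualify
the wildtype is used with a warning (or a hard failure on request). Each
seed yields 20 candidates by top-k sampling (k = 10), in exactly one
generation pass. Decodes that change length or emit non-residue tokens are
dropped and counted, never aligned — in a substitution-only regime they
are invalid by construction. The filter then removes wildtype-identical
candidates, candidates above the mutation-order cap (default 6), and
previously screened ids, deduplicates globally, and truncates to plate
capacity (default 382 = a 384-well plate minus control wells). Capacity
ranking uses **sampling frequency** — how often the model independently
proposed the same candidate, a proxy for its confidence — with first-seen
order as the tie-break; the published campaign does not state how its
libraries were cut down from raw generations, so the package declares this
rule explicitly. Per-objective seed metrics (normalized FC vs normalized
DR) are round-configurable, mirroring campaigns that train on mixed
metrics, and an `intersectLibraries()` utility supports screening only
candidates proposed under two different training metrics.

## The synthetic landscape

`LandscapeSpec` defines a ground-truth genotype-to-response map:
per-mutation effects act **additively on log-signal** per condition
(fold change therefore composes multiplicatively, matching how FC behaves
in real screens and keeping the ground truth analytically checkable),
optional pairwise epistasis terms act on log-signal, and each simulated
replicate is noiseless signal x lognormal(0, sigma_m) + N(0, sigma_a),
floored at zero, in biological triplicate by default.

Two presets are provided, both 8-letter alphabet, length 20, sized so the
tiny backbone trains in well under a minute per model on one CPU:

- **`toyGrammarLandscape()`** — the conditioning testbed. The lead
  objective is controlled entirely by position 6 through a strictly
  monotone effect ladder over the alphabet, the zinc objective by position
  13. The "grammar" a conditional model must learn is exact and known:
  under `<dec> <inc>`, move position 6 up its ladder, position 13 down,
  copy everything else. It is noise-free so the pairing rule at tau = 0 is
  also exact. Tests train on exhaustive pairs among 52 genotypes and
  decode greedily from 12 held-out genotypes chosen to be improvable in
  the prompted direction (a seed already at the top of the lead ladder has
  no consistent decode, just as a best-in-class mutant is not a useful
  seed).
- **`toyCampaignLandscape()`** — the campaign testbed. The wildtype
  encodes the starting phenotype of a lead sensor that needs fixing: lead
  FC 1.2 (barely responsive at low lead) and zinc FC 8 (strongly
  zinc-activated), so "lead up / zinc down" is the nontrivial direction.
  Of 140 possible substitutions, 6 are selective (lead +0.95, zinc -0.95
  in log-signal), 30 knock out both responses, 20 raise both, 84 are
  neutral; the layout is a fixed internal constant. Noise sigma_m = 0.1
  and sigma_a = 1 (1% of leak) put the default 2-SD tau around 0.3 on the
  normalized-FC scale, large enough to exclude most null pairs while
  keeping true selective effects (|delta| ~ 1.5) clearly above threshold.
  The default landscape is purely additive; `withEpistasis = TRUE` adds
  two pairwise terms for exercising the epistasis machinery.

What the simulator emulates: batch-scale plate screens with replicate
noise, a wildtype reference in every batch, additive-plus-epistatic
genotype effects, and the three-condition design. What it does not:
biophysical realism (metal coordination, allostery, dose-response
surfaces), sequence-context effects beyond pairwise epistasis, and
real-assay artifacts such as plate-position effects. Passing tests
demonstrate that the workflow's statistics and learning machinery behave
correctly on a landscape of known structure — not that any particular
wet-lab campaign will succeed.

## Campaign loop and problem sizes

`runCampaign()` chains the stages per round (screen, metrics, tau
estimation, pairing, balancing, training, seed selection, generation,
filtering) and evaluates each proposed library against ground truth,
reporting the selective fraction alongside a random baseline matched for
mutation-order distribution and a one-sided binomial test of the >= 3x
enrichment claim. Stage failures abort with stage-tagged diagnostics.

Test-scale sizes, chosen so a full three-round campaign runs in under two
minutes on one CPU: initial screen of all 140 single mutants plus 60
random doubles; round libraries of 60; at most 12 seeds per round; pair
categories capped at 400 before balancing; training with the toy preset
(`toyTrainConfig()`: lr 5e-3, 40 epochs, batch 256, hidden width 96 —
the larger learning rate reflects that the tiny backbone is trained from
scratch rather than fine-tuned). The published campaign's library schedule
(382, 200, 108) is available by passing `roundSizes = c(382, 200, 108)`.

## Numerical choices and degenerate inputs

- Positions are 1-based throughout, matching mutation notation (D64K is
  residue 64); canonical mutant ids sort substitutions by position, so
  deduplication across rounds has one canonical form. Wildtype sentinels:
  `""` and `"WT"`.
- Probability underflow is guarded by flooring probabilities at 1e-300
  inside log; per-step distributions are exact softmaxes (sum to 1 within
  1e-6, asserted in tests).
- Greedy decoding breaks ties by lowest token id (deterministic).
- Fewer than two distinct records yield an empty paired dataset with a
  warning; an empty filtered library is allowed and flagged; an all-seed
  fallback to wildtype is warned about.
- NaN/Inf training loss aborts immediately with the epoch and batch size
  in the message.
- `sample()`-style seeding never touches the caller's RNG state: every
  seeded operation saves and restores `.Random.seed`.

## Known limitations

- The tiny backbone's diagonal alignment cannot represent insertions or
  deletions; the whole package is substitution-only by design.
- Directional labels are binary per objective; continuous or ranked
  labels are out of scope.
- The pretrained-backbone path is a configuration surface, not a bundled
  model; users supply their own adapter.
- Balancing discards data from over-represented categories rather than
  reweighting; with strongly skewed screens this can leave few pairs.
- The enrichment statistics compare against a random baseline matched on
  mutation order only; matching on position usage would be stricter.
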