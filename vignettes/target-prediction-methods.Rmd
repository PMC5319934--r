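---
title: "Multi-fingerprint nearest-neighbor target prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-fingerprint nearest-neighbor target prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, the numerical
choices, and what the bundled synthetic worlds do and do not demonstrate.

## The prediction model

The working hypothesis is the similarity principle of ligand-based
virtual screening: structurally similar molecules tend to share targets.
`ppb` operationalizes it as nearest-neighbor search against a reference
database of target-annotated actives, with three refinements that address
the principle's known failure modes:

1. **Several notions of similarity at once.** A single fingerprint sees a
   single aspect of structure. Six base encodings are searched
   independently — shape (APfp, 21-D atom-pair counts over topological
   distances 1–21, longer paths clamped into the last bin so the total
   pair count is conserved), pharmacophore layout (Xfp, 55-D: five
   category channels — all pairs, acceptor–acceptor, donor–donor,
   acceptor–donor, aromatic–aromatic — each over 11 distance bins),
   global composition (MQN, the 42 molecular quantum numbers), SMILES
   text statistics (SMIfp, counts of a fixed 34-symbol alphabet), hashed
   substructure paths (Sfp, 1024 bits, Daylight-type, fragments up to 7
   atoms), and circular atom environments (ECfp4, bond diameter 4, folded
   to 1024 bits). Scale-sensitive schemes (APfp, Xfp, MQN, SMIfp) favor
   global resemblance; the two hashed bit-schemes favor exact
   substructure overlap. Their disagreements are informative, which is
   why the consensus vote (below) is the primary ranking key.

2. **Commensurate fusion.** Four fused schemes (Ffp1 = Xfp+SMIfp+Sfp,
   Ffp2 = Xfp+MQN+SMIfp, Ffp3 = Ffp1+ECfp4, Ffp4 = all five) combine base
   distances after mode-matching: each scheme's distances are scaled by
   `mode(Xfp) / mode(scheme)`, where the mode is the most frequent
   city-block distance among random compound pairs. Without this step the
   1024-bit schemes (typical distances of tens) would be drowned out by
   Xfp (typical distances around a hundred). By linearity of the
   city-block distance, weighting distances and scaling the concatenated
   vectors are the same operation; the package mandates the
   distance-weighting view and tests the equivalence to 1e-9 relative.

3. **Calibrated significance.** A raw distance is meaningless across
   targets (group sizes and chemotype diversity differ wildly), so each
   (target, scheme) pair carries its own null: the distribution of
   distances between the group's members and random background molecules.
   City-block distances on count vectors are discrete and overdispersed,
   which motivates a negative binomial fit; the p-value of an observed
   nearest-member distance d is the null CDF P(D ≤ round(d)) — the
   probability that a random molecule gets at least that close. The
   p-value is only ever used the way it is defined: within its own
   (target, scheme) pair, entering the ranking through per-target sums
   and the 0.01 high-confidence threshold, never as a cross-target score.

A query is processed as: standardize → six base fingerprints → rank the
whole database in each of the ten spaces → collect the first `n_targets`
distinct targets per space (a target's hit distance is automatically the
minimum over its members, since the scan is in ascending order) → merge
by consensus. The consensus sorts by (votes desc, p-value sum asc, best
p asc, target id asc) — a deliberate total order, so reports are
byte-reproducible. The *combined* view keeps targets voted by at least
two schemes; it trades a little recall for precision and is the
recommended list for prospective use.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| potency cutoff | 10 µM | activity records (IC50/EC50/GI50/Ki/KD/Potency) at or below this enter the database; values converted from pM–M |
| inhibition cutoff | > 50 % | percent-inhibition records must exceed this (strict) |
| `min_size` | 10 | smallest retained target group; below this a NB null and a nearest-member distance are too noisy to mean much |
| `n_targets` | 20 | targets collected per fingerprint space |
| `min_votes` | 1 | consensus filter; the combined view always applies ≥ 2 |
| `scaling_pairs` | 1e5 | random pairs for mode calibration; modes stabilize far below this at desk scale |
| `calib_n_max` | 1e6 | cap on member × background pairs per null fit |
| high-confidence flag | p ≤ 0.01 | marks hits unlikely under the null |

Unit handling is strict by design: potency values in units that cannot be
converted to micromolar drop the record with a warning, because silently
keeping them would corrupt the 10 µM threshold. Activity qualifiers
(">", "<") are not modeled; the loader treats the numeric value as-is.

## Standardization and perception

Structures are processed as non-stereo SMILES: stereo descriptors are
stripped before canonicalization (the fingerprints are 2-D topological,
so stereochemistry carries no signal here and its removal makes
deduplication stricter). Protonation at pH 7.4 is applied by OpenBabel's
rule-based transform table — carboxylic, sulfonic and phosphonic acids
and tetrazoles deprotonated; aliphatic amines, amidines and guanidines
protonated — chosen over a commercial pKa engine so that results are
reproducible with open tools. Canonicalization is idempotent, and
hydrogen-bond perception uses a documented rule (acceptors: N/O without
positive charge; donors: N/O bearing hydrogen) shared by Xfp and the MQN
polarity counts. Aromaticity is read from the canonical SMILES itself
(lowercase atoms), cross-checked atom-by-atom against the structure
table. MQN ring counts use a smallest-set-of-smallest-rings computed by
shortest-cycle-per-edge candidates with a greedy GF(2) independence pass.

## Numerical choices

* **NB fitting**: maximum likelihood over (log size, logit prob),
  initialized at the method-of-moments estimate, BFGS with relative
  tolerance 1e-8 on the objective. Underdispersed samples (variance ≤
  mean), for which the NB MLE diverges, fall back to a Poisson fit and
  are flagged; constant samples are recorded as failed entries and
  excluded from p-value ranking (hits still carry distances). Fused and
  scaled distances are rounded to the nearest integer before fitting to
  preserve discreteness.
* **Mode estimation**: unit-width integer bins on raw distances; ties
  break toward the smaller distance. A zero mode (structurally uniform
  molecule sample) aborts calibration with a degenerate-calibration
  error instead of producing infinite scale factors.
* **Tie-breaking**: equal distances rank by lexicographic compound id;
  equal consensus keys by target id. Determinism across platforms was
  preferred over any pretense that ties carry information.
* **Identifiability caveat**: the NB size parameter is weakly identified
  when the null mass concentrates near zero (success probability near
  0.9); its MLE then carries a sampling SD of several percent even at
  1e5 observations. This is a property of the likelihood, not of the
  optimizer — MASS::fitdistr returns the same estimates — and is why
  p-values, which are insensitive to this direction of the likelihood,
  are the quantity the ranking actually consumes.

## The synthetic worlds

`generate_fixture()` builds no-download test data: each target is one of
24 hand-validated drug-like scaffolds (anilides, diaryl ureas, fused
heteroaromatics, ...) decorated combinatorially at up to three ring
positions with 12 small substituents; group members receive log-uniform
potencies in [1 nM, 10 µM] (a fraction of deliberately failing rows —
20–100 µM potencies, ≤ 50 % inhibitions — exercises the retention
filter); background molecules are decorations of scaffolds assigned to
no target. Held-out queries are single-substituent mutations of group
members, which makes the intended ground truth — the query's nearest
structural family is its own group — true by construction. The generator
verifies that property by brute force (ECfp4 city-block nearest neighbor
over all actives) before returning and deterministically regenerates
from the next derived seed on the rare failure, so a returned world is
always self-consistent.

What the worlds emulate: the database-building rules, group structure,
multi-space search, calibration and consensus machinery at full
fidelity. What they do not emulate: the chemotype diversity, activity
noise, and target-family correlations of real bioactivity databases, nor
property-matched decoys. Green tests on these worlds therefore validate
the *machinery* — filters, distances, fits, ranking, determinism — not
prospective accuracy on real pharmacology, for which the reference
database must be built from real activity data via
`load_activity_table()`.

Problem sizes were chosen to keep a complete build-and-benchmark cycle
in tens of seconds: 5 targets × 12 actives, 60 background molecules,
2e4-pair scaling and null samples. Modes and NB parameters are stable at
these sizes for the bundled chemistry; production use on real data
should raise `scaling_pairs` and `calib_n_max` toward their defaults.

## Design decisions on open points

* Xfp's exact 55-D layout is underdetermined by its dimension alone; the
  package fixes 5 channels × 11 bins with the toolkit-standard
  acceptor/donor definitions and treats that layout as normative.
* The SMIfp alphabet is fixed to 34 symbols covering the drug-like
  SMILES vocabulary, with Cl/Br consumed as two-character tokens first.
* Whether values or distances are scaled in fusion is irrelevant for the
  city-block metric; the distance-weighting view is implemented and the
  concatenation equivalence is enforced by test.
* A hit without a calibrated null contributes p = 1.0 to consensus sums,
  ranking it below otherwise-equal calibrated hits rather than above.
* The p-value sum runs over voting schemes only; a scheme that did not
  retrieve the target has no defined p-value for it.
* `benchmark_run` removes each held-out drug from the database at query
  time without re-filtering group sizes or re-fitting nulls: a
  single-compound perturbation of a ≥ 10-member group moves the null far
  less than its fitting noise.

## Known limitations

* Predictions are only as good as the reference database; targets absent
  from it are invisible, and the consensus can only vote among annotated
  pharmacology.
* 2-D topological fingerprints cannot separate stereoisomers, by
  construction.
* The NB null assumes background molecules are exchangeable with future
  queries; a query far outside the background's property range gets
  optimistic p-values.
* OpenBabel's pH model is rule-based; unusual ionizable groups outside
  its transform table stay neutral.
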