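---
title: "Ontograms from cranial sutures: models, scoring and validation"
author: "ontogram package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontograms from cranial sutures: models, scoring and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontogram)
```

## The problem

Skeletal maturity in archosaurs (and, by extension, in fossil dinosaurs) is
often judged from cranial sutures: the fibrous articulations of the skull
roof, face and palate, and the cartilaginous synchondroses of the skull
base, are open early in life and — in many vertebrates — progressively
narrow, close and finally obliterate. Whether that progression is reliable
enough to stage isolated specimens is an empirical question, and the two
living ends of the archosaur bracket answer it differently: an emu-like
(avian) series closes and obliterates nearly all of its sutures, whereas a
crocodylian series keeps almost all sutures open and even widens them with
age, obliterating only a midline pair during embryonic development.

This package implements the quantitative machinery used to characterize
such series:

1. **Ontograms** — single-species trees built by maximum parsimony from
   ontogenetic characters.
2. **Closure scoring** — numeric averages of sutural closure and
   interdigitation per specimen, ontogenetic category and anatomical group,
   with size–closure trend fits.
3. **Histomorphometry** — an average sutural width statistic from stained
   sections.
4. **Reliability** — repeatability of the coding itself.
5. **Simulation** — a generator of ontogenetic series with known ground
   truth, so every stage of the pipeline can be validated end to end.

## The ontogram model

Specimens are coded for two aspects of each suture or synchondrosis:

* *closure*, four ordered conditions scored 0–3: open, partially closed,
  closed (conjoined but with a visible suture line), completely obliterated
  (no trace of the line);
* *interdigitation*, three conditions scored 0–2: straight, slightly, very
  interdigitated.

A suture showing different conditions in different regions is coded
*polymorphic*: the cell holds the full set of observed states. A
hypothetical embryo in which every character is at its immature state
(all zeros) is appended as the outgroup; it polarizes every character so
that depth from the root tracks maturity.

Characters are equally weighted and unordered, and trees are scored by
Fitch parsimony. Two semantics for polymorphic cells are provided:

* `uncertainty` (default): the state set enters the Fitch downpass as a
  set, giving the conservative lower bound on steps;
* `polymorphism`: each polymorphic cell is additionally charged
  `|states| - 1` steps, so within-specimen variation itself counts as
  change.

The published analyses we model do not state which setting their parsimony
program used, so the default is the lower bound and the flag lets users
match the alternative; published tree lengths should accordingly be read
as bounds rather than exact targets.

### Search

`heuristic_search()` repeats, for each of `n_addition_replicates` random
addition sequences, stepwise insertion of taxa at their best position
followed by tree-bisection-reconnection (TBR) branch swapping. The
hypothetical embryo is always inserted last: the ingroup structure forms
first and the root then attaches at its single most parsimonious position,
rather than an early random placement committing the search to one
orientation of the maturity axis. Swapping
accepts strictly shorter trees (first improvement, scanning the
neighborhood lazily); at each local optimum, equal-length neighbors are
pooled with the optimum, deduplicated by a canonical split signature, and
truncated at `maxtrees` with a flag while the search for shorter trees
continues. Replicate `r` draws its randomness from a stream derived from
`(seed, r)`, so results are identical under any execution order.

### Consensus, support and the obliteration sequence

All output trees are rooted on the hypothetical embryo. The strict
consensus keeps clades present in every most parsimonious tree (MPT); the
majority-rule consensus keeps clades in more than the cutoff fraction
(default 50%) and labels them with percent occurrence. Bootstrap support
resamples characters with replacement, runs a one-replicate search per
resample, and reports the percentage of replicate trees containing each
reference clade.

Tree quality is summarized by the ensemble indices: consistency
`CI = m/L`, homoplasy `HI = 1 - CI` and retention `RI = (g - L)/(g - m)`,
where `m` and `g` are the summed per-character minimum and maximum
(star-tree) step bounds, plus the variants excluding parsimony-
uninformative characters (those with `m = g`). One numerical subtlety: with
set-valued cells the attainable minimum for a character is the smallest
number of states that intersect every scored cell, minus one — a state
observed only inside polymorphic cells need not force a step. Using the
naive count of all observed states can exceed the realized tree length and
break the `CI <= 1` guarantee, so the attainable bound is what
`character_step_bounds()` computes.

ACCTRAN reconstruction assigns single states to internal nodes of each
binary MPT by unit-cost dynamic programming; among equally parsimonious
assignments, changes are placed as close to the root as possible (ties at
a node prefer changing immediately, and prefer the more mature state).
Reconstruction is done per MPT, never on consensus trees, which may
contain polytomies.

The *obliteration sequence* asks, for each closure character, whether the
specimens scoring exactly `{3}` form a clade — the same clade — on every
MPT. Characters passing that filter are ordered by clade size (largest
first, i.e. obliterations acquired nearest the root first, mirroring the
backbone of a pectinate ontogram); the rest are flagged inconsistent. A
polymorphic `{2,3}` never counts as obliterated: complete obliteration is
categorical.

`ontogram_linearity()` quantifies how well the ontogram follows ontogeny:
the Spearman correlation between each specimen's root-to-tip depth on the
majority-rule consensus and its ontogenetic rank (age when known,
otherwise ordered category). +1 is a perfectly ontogeny-ordered pectinate
tree; a negative value means the tree runs against ontogeny, the signature
of widening sutures.

```{r, eval = FALSE}
sim <- sim_ontogeny_study(n_specimens = 20, seed = 1)
fit <- ontogram(sim$matrix, sim$records,
                config = search_config(n_addition_replicates = 10, seed = 1))
summary(fit)
plot(fit)
```

## Closure scoring

A cell's *score* is the arithmetic mean of its states (`{0,1}` scores 0.5),
so closure averages lie in [0, 3] and interdigitation averages in [0, 2].
Missing cells are excluded from denominators, never imputed. Category
averages pool all cell scores of the category's specimens (grand mean of
cells) by default; the specimen-mean alternative is exposed
(`method = "specimen_mean"`) because printed summaries do not always say
which was used, and with near-complete matrices the two agree closely.

`suture_trend()` fits the closure average against a skull-size proxy by
least squares and reports the Pearson correlation; the `log` model uses
the natural logarithm of size (the correlation is base-invariant, so the
choice of base is immaterial). `obliteration_fraction()` reports the
fraction of distinct sutures — closure characters grouped by suture, so a
suture scored in several views counts once — whose every scored view-cell
is exactly `{3}`.

Staging schemes map a length variable to ordered categories with
lower-bound-inclusive intervals. The crocodylian scheme uses total length
with bounds at 122, 201 and 271 cm. The emu scheme stages on skull length;
because observed category ranges overlap (age, where known, took priority
over size in the source series), the default bounds (97, 143, 152 mm) are
the least-mature skull length observed per category, and staged categories
should be treated as approximate near the boundaries. Conversion from
skull length to total length is deliberately not built in; supply your own
mapping if your metadata need it.

## Histomorphometry

The width statistic is the ratio of the unossified sutural area (µm²) on a
stained section to the length of the central suture trace (µm): for a
rectangular band this is exactly the band width, and in general it is the
mean gap width along the trace. Widths are reported at full precision and
rounded half-up, and printed-table comparisons use a ±1 µm tolerance
because published tables mix rounding conventions. Normalization divides
by skull length converted to µm; units are explicit at this boundary
(section skull lengths in cm, specimen-table skull lengths in mm) to
prevent silent ten-fold errors.

`polygon_measures()` computes the shoelace area of the section outline and
the Euclidean length of the trace polyline, refusing self-intersecting
outlines. `sim_suture_section()` builds validation geometry: a sinusoidal
trace of given amplitude and wavelength surrounded by a band of constant
perpendicular width. Where the half-width exceeds the local radius of
curvature (tight interdigitation crests) the raw offset curve folds over
itself; those local loops are trimmed, which mirrors the converging bone
fronts of a real tight crest and reduces the measured area slightly below
`width x length` — the validation tolerance of 5% absorbs this, and the
estimator is exact for straight bands.

## Reliability

Two codings of the same grid are compared three ways: Cohen's kappa on the
categorical cell labels (a cell's category is its canonical state-set
string, so `{0,1}` vs `{1}` is a disagreement — partial credit is left to
the correlation), the raw disagreement count, and the Pearson correlation
of the paired numeric cell scores. The kappa Z statistic uses the
classical null-variance standard error. Published kappa values for this
kind of coding cannot be recomputed without the second (unpublished)
coding, so they serve as context rather than targets; the simulator's
coder-noise model (`sim_coder_noise()`, adjacent-state errors at rate `q`)
provides calibrated inputs instead.

## The synthetic generator

`sim_ontogeny_study()` emulates the two empirical regimes. Ages are
uniform over `age_range`; sizes follow a saturating growth curve
(von Bertalanffy form, defaults 55 to 160 mm at rate 0.15/yr with 3 mm
noise — an emu-like series) with Gaussian noise kept monotone-in-mean;
each suture contributes one closure and one interdigitation character
with its own onset and transition duration. The latent maturity of
character `k` in a specimen of age `a` is
`u = clamp((a - onset)/duration, 0, 1)`.

* *closing* mode: closure state `round(3u)` — sutures pass through
  partially closed and closed before obliterating, so mid-trajectory
  specimens show intermediate states (rounding, not flooring, is what
  makes states 1–2 prevalent mid-series);
* *widening* mode: closure state `2 - round(2u)` — sutures start closed
  and open up, never reaching 3; complete obliteration is reserved for
  `n_embryonic_obliterations` designated midline characters fixed at `{3}`
  in every specimen, reproducing the crocodylian pattern in which an
  embryo has already obliterated the pair and nothing else ever does.

Interdigitation scores `round(2u)` in both modes. With probability `p`
(default 0.1) a cell becomes a polymorphic adjacent pair. Defaults
(24 specimens, 20 sutures in four anatomical groups) mirror the scale of
the emu study series, including its character arithmetic: a few sutures
are scored for closure in a second anatomical view (`n_multiview`,
defaults 2 closing / 6 widening), so the matrix carries slightly more
closure than interdigitation characters, as such matrices do. Onsets span
the first 60% of the age range so that most transitions complete within
the sampled lifespan, matching the near-complete endpoint averages of the
series the two regimes emulate.

One property of the widening regime deserves emphasis. Its closure
characters (descending toward the all-zero outgroup state) and
interdigitation characters (ascending away from it) pull the ontogram's
orientation in opposite directions, and for clean monotone trajectories
the globally most parsimonious trees can be *orientation-degenerate*:
equally short trees exist with the maturity axis running either way, the
closure majority deciding only caterpillar-shaped candidates. Across
simulated replicates the inverted (old-near-root) orientation is the more
frequent outcome but not a guaranteed one, so single widening-regime
ontograms should be read together with the size-closure trend fit (whose
negative sign is recovered essentially always) rather than alone.

What the generator does *not* emulate: intraspecific variation beyond
coder-style noise, wild/domestic or dietary covariates, view-specific
scores for multi-view sutures, and character correlation beyond the shared
age axis. Passing recovery tests therefore demonstrates that the pipeline
recovers known signal of realistic size and noise — not that real series
are this clean.

## Numerical and design choices

* Both `(...)` and `{...}` NEXUS groups are read as state sets; the bracket
  style is retained as an annotation so a stricter treatment could
  distinguish them. Taxon ids match specimen tables after collapsing
  whitespace, underscores and case.
* Characters are 0-indexed internally and 1-indexed in user-facing output,
  following NEXUS convention.
* Tie-breaks: stepwise addition resolves equal-cost insertions uniformly
  at random from the replicate's stream; ACCTRAN ties prefer the change on
  the current (more rootward) edge and then the larger state; pool order
  is canonicalized by split signature so output is seed-stable.
* Degenerate inputs are errors, not guesses: fewer than 4 taxa for search,
  polytomies in scoring/reconstruction, all-missing columns (bounds (0,0)
  with a warning), zero-variance trend variables, missing lengths for
  staging (category `unknown` with a warning).
* Problem sizes used in the shipped tests and acceptance script — 6–7-taxon
  exhaustive oracles (105/945 topologies), 14–21-specimen searches, 20-seed
  sign-recovery at 20 specimens x 40 characters, a few hundred bootstrap or
  permutation replicates — were chosen as the smallest sizes at which each
  property is sharply decided.

## Known limitations

* The heuristic search is exact only in the oracle-verified small regime;
  like any hill climber it can miss global optima on large, conflict-rich
  matrices with few addition replicates.
* Bootstrap retains a single tree per replicate (as the modeled protocol
  did); clades tied at a replicate's optimum are therefore sampled, not
  averaged.
* The obliteration sequence requires exact cross-MPT clade identity; under
  heavy polymorphism noise many characters are (correctly) flagged
  inconsistent rather than forced into a rank.
* Printed MPT *counts* from plateau-rich searches depend on the original
  program's swapping and cap behavior and are not reproduction targets;
  lengths and index values are.
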