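---
title: "Modelling the emergence of an action repository during speech acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the emergence of an action repository during speech acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phonmap)
```

## The scientific question

Place of articulation — whether a consonant is formed at the lips, the
alveolar ridge or the velum — is coded in the acoustic signal only
indirectly, through short bursts and formant transitions, and is therefore
hard to learn from listening alone. Tactile and proprioceptive feedback
from one's own articulation codes it directly: during /b/ the lips touch,
during /d/ the tongue tip does. `phonmap` implements a connectionist model
of early speech acquisition in which this asymmetry can be studied: two
growing self-organizing maps (GSOMs) — a semantic map over word meanings
(S-MAP) and a phonetic map over sensory syllable representations (P-MAP) —
are coupled by a Hebbian association and trained on a synthetic model
language in three modalities (auditory only, somatosensory only, or both).
The quantity of interest is how well phonetic features become topographic
structure on the P-MAP, measured by counting *feature regions*.

## The synthetic model language

The generator emulates the statistical structure of a 70-word monosyllabic
lexicon: every vowel of /i e a o u/ as a V word, every consonant of
/b d g p t k m n l/ crossed with every vowel (45 CV words), and the onset
clusters /bl gl pl kl/ crossed with every vowel (20 CCV words). Each word
receives three realizations differing only in seeded jitter — ±10 %
relative timing and ±0.05 absolute articulatory-target jitter — for 210
stimulus items, with a 10 ms frame hop throughout.

**Semantic vectors.** Published corpora of hand-coded child-directed
semantics are not available as data, so word meanings are generated
hierarchically: words are grouped into categories (default 14 categories of
about 5 words) sharing 2 category features each, and the rest of a
361-feature global inventory is distributed as idiosyncratic features
(4–5 per word). Every vector is unique, has at least 3 active features, and
the category-to-form pairing is a seeded random bijection, making meaning
arbitrary with respect to phonetic form. The inventory size, category
geometry and jitter magnitudes are configuration keys
(`corpus_config()`).

**Motor plans and trajectories.** Each word is planned as timed actions on
four articulator tiers (lip aperture, tongue tip, tongue dorsum, jaw
height) expressed as normalized distances in [0, 1], 0 meaning contact.
Plosives and nasals contribute a contact action (target 0) on the tier
matching their place, supported by a jaw action; laterals a tongue-tip
contact; vowels set targets on all four tiers (values adapted from standard
articulatory descriptions, e.g. /a/ has a low jaw and far dorsum, /o u/
small lip aperture). Trajectories interpolate between neutral values and
action targets with 60 ms cosine ramps — smooth enough that a consonant
ramps directly into the following vowel (coarticulation), and overlapping
contradictory targets on one tier are rejected. The somatosensory
representation is the exact complement, activation = 1 − distance, so
contact produces maximal activation on exactly one tier: place of
articulation is linearly recoverable from this representation by design,
which is the hypothesized basis of the somatosensory advantage. Vocal-tract
geometry beyond these four tiers (e.g. separate upper/lower lip points) is
deliberately collapsed.

**Auditory synthesis.** The 24-band bark spectrogram is synthesized
directly in the bark domain from the plan's phonetic score, without a
waveform: vowels contribute Gaussian band bumps at F1/F2/F3 (reference
formant values from standard phonetics tables, seeded ±5 % jitter), with
40 ms initial transitions from a place-dependent F2 locus (labial 900 Hz,
alveolar 1800 Hz, velar 2100 Hz) and a rising F1; voiceless plosive
closures are silent and release into a 20 ms burst with a place-dependent
spectral centroid (labial diffuse-low, alveolar high, velar compact-mid)
plus aspiration; voiced closures carry a low voice bar; nasals a low
murmur; laterals vowel-like formants with attenuated mid bands. Per-frame
multiplicative band jitter (log-sd 0.1) makes the auditory place cues
noisy and brief relative to the vowel, which is what makes place genuinely
harder to learn from audition than from touch. Frequencies map to bands
via Traunmüller's bark approximation. A `bark_filterbank()` front end
(STFT via `signal::specgram`, critical-band integration, log compression)
accepts external waveforms, but the default pipeline never needs audio.

**Vectorization.** GSOM input must be fixed-length, and syllable durations
vary, so each modality is time-normalized to 30 frames by linear
interpolation and flattened (auditory 720, somatosensory 120 dimensions).
In combined mode each block is scaled so both have unit expected squared
norm over the corpus — neither modality dominates by dimensionality alone.
The normalization length and weighting are open modelling choices exposed
in the configuration.

## The growing map engine

Maps live on an integer 2-D lattice with 4-neighbourhood topology and
start as a seeded 2×2 lattice around the data mean. A presentation finds
the best-matching unit (BMU, Euclidean; ties to the lowest node id), moves
the BMU and lattice neighbours within the radius toward the input with a
Gaussian profile `h(d) = exp(−d²/r²)`, and accumulates the BMU's
quantization distance as error. Nodes whose accumulated error exceeds the
growth threshold grow: boundary nodes spawn nodes into all free
4-neighbour positions (weights linearly extrapolated past the parent from
the opposite neighbour, or nudged deterministically toward the map mean
when there is none — the kernel is RNG-free so runs are reproducible from
the R-side seed alone) and reset their error; interior nodes keep half
their error and push the rest onto their neighbours, migrating growth
pressure to the boundary. Node count never decreases and the lattice stays
connected; both are property-tested.

The growth thresholds are expressed directly in accumulated-distance units
(defaults: 45 for the S-MAP, 18 for the P-MAP). A spread-factor
parameterization scaled by input dimensionality was considered and
rejected: with unit-normalized inputs in 720–840 dimensions it produces
thresholds three orders of magnitude above per-step errors and freezes
growth. The defaults were chosen so that, on the default corpus, nodes
holding items of different words (typical distance ≈ 1) split within about
a cycle while nodes holding only one word's realizations (distance ≈ 0.26)
split slowly — reproducing strong but not total item separation
(≈ 200 of 210 items on own nodes after 50 cycles).

## Training regimen

`run_training()` executes cycle 0 (one high-learning-rate pass per item,
learning rate 0.5, radius 2, association rate 0.3) to establish the maps
and an initial interconnection, then 50 cycles. Per cycle every item is
presented 7 times in seeded shuffled order (1470 base steps); the map
learning rate decays linearly 0.35 → 0.05 and the neighbourhood radius
3 → 1 across cycles. Association updates use a bounded Hebbian rule with
competitive decay: the co-active winners' link moves toward 1 by
`lr (1 − w)` (default `lr` 0.15) while the rest of the winner's row and
column decays by `(1 − lr/2)`; weights therefore stay in [0, 1] and
repeated conflicting pairings converge to equal intermediate strengths.

Two checking processes keep the maps functional. After every step, items
sharing their P-MAP winner with items of a different word are re-presented
(2 extra presentations each). From cycle 11 — the transition from babbling
to imitation — an end-of-cycle interconnection check verifies every word's
produce→perceive round trip and re-presents failing words' items at a
tripled association rate, together with any items conflicting on the
produced node. Corrective work is capped at 20 % of a cycle's base steps
so the step budget stays interpretable; all corrective actions are logged.
The exact corrective budgets are modelling choices with no external
reference; the cap and repetition counts are configuration keys.

**Perception.** An external speaker provides no somatosensory signal, so
perception always enters through the auditory channel. For combined-mode
models the percept's P-MAP winner is found on the *auditory sub-distance*
of the node weights. An alternative that imputes the somatosensory block
with the corpus mean and matches on the full distance is available
(`perception = "impute"`); it was not kept as the default because the
imputed block contributes word-dependent distance offsets that cap
round-trip accuracy near 50 % on the default corpus, whereas the
sub-distance route converges to a correct round trip. Somatosensory-only
models, which exist for map-ordering analysis, perceive their own
somatosensory vector (self-perception).

**Production** reads the trained association in the other direction and
returns the stored exemplar nearest to the winning P-MAP node's weights —
the exemplar registry stands in for a motor-plan state map, which this
model does not decode from weights.

## Evaluation

Per cycle the package records: unclear nodes (≥ 2 items of ≥ 2 words),
clear non-separated nodes (≥ 2 items, one word), occupied nodes, intra- vs
inter-word BMU lattice distance, round-trip accuracy, and feature-region
counts for syllable structure, place, manner, voicing, vowel height and
backness. For region counting, occupied nodes take the majority label of
their items (ties to the lowest item id), unoccupied nodes the label of
the nearest occupied node (ties to the lowest node id), and regions are
4-connected components of equal label over the completed lattice — the
completed-map convention matches the way such maps are usually displayed
with region boundaries drawn across the whole lattice. V words carry
`"none"` for consonantal features and form their own regions; CCV onsets
are labeled `plosive-lateral` for manner and by their initial consonant
for place and voicing.

Modality contrasts use a two-sided Wilcoxon rank-sum test. For combined
sample sizes up to 20 the p-value is computed by full enumeration of the
rank-sum permutation distribution, which is exact under ties; larger
samples fall back to the normal approximation with tie correction
(`stats::wilcox.test`).

## What the synthetic corpus does and does not show

The generator preserves the representational geometry that the maps learn
from: realizations of one word cluster tightly (mean vector distance
≈ 0.26) relative to different words (≈ 0.96); place is explicit in the
somatosensory code and noisy/brief in the auditory code; manner is clearly
coded auditorily (silence + burst vs murmur vs lateral formants) and
almost invisible somatosensorially (all closures feel alike). On these
conditions, ten-seed experiments reproduce the qualitative findings:
place-of-articulation region counts are significantly lower under combined
training from cycle 10 on, manner shows no significant difference, unclear
nodes nearly vanish by cycle 50, and round trips become accurate.

What passing these tests does *not* show: natural speech has vastly more
acoustic variability (speaker state, prosody, coarticulatory context) than
the parametric synthesizer, the semantic generator is a stand-in for
hand-coded semantics, and absolute region counts depend on map size and
growth parameters. The simulations support the mechanism — somatosensory
input accelerates learning of place — not quantitative predictions about
real acoustic corpora.

## Numerical choices and degenerate inputs

* Ties everywhere resolve to the lowest id (BMU search, association
  argmax, majority labels, nearest-occupied completion), making runs
  deterministic under a seed.
* Map and association objects wrap compiled state with reference
  semantics; `clone_map()`/`map_state()` take snapshots, and plain-text
  archives (`export_model()`) round-trip full model state.
* Degenerate inputs are validated: empty signals, zero-dimensional maps,
  empty assignments, inconsistent cluster inventories and semantic
  inventories too small for unique ≥ 3-feature vectors all raise errors.
* `cycles = 0` performs only the establishing cycle and records its
  metrics row.

## Problem sizes

The default experiment — 3 modalities × 10 seeds × 50 cycles on 210
items — was chosen to match the study design while remaining a
single-CPU job: one combined-mode run takes roughly half a minute with the
compiled kernel, and the full experiment runs in the test suite.

## Known limitations

* Monosyllables only; no prosody, no voicing continua, no multisyllabic
  words.
* The phonemic state map (an explicit phonological layer above the P-MAP)
  is out of scope; phonological structure exists here only implicitly in
  the map ordering and the S↔P association.
* The articulatory front end is parametric, not a vocal-tract synthesis;
  `bark_filterbank()` exists for external audio but the shipped
  experiments never use waveforms.
* S-MAP→P-MAP activation is strict winner-take-all; graded spreading
  activation is not implemented.
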