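---
title: "Profile-HMM read extraction: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-HMM read extraction: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmdemux)
```

## The problem

Raw reads from multiplexed sequencing libraries are composites: sample
barcodes, spacers, adapters and unique molecular identifiers (UMIs) surround
the biological insert, and every one of these blocks is subject to
sequencing errors. `hmmdemux` treats the read layout — the *read
architecture* — as a generative model: the user declares the ordered blocks,
the package compiles them into a single global profile hidden Markov model
(HMM), and every read is scored, labeled per nucleotide, demultiplexed and
trimmed against that model.

## The model

### Architecture grammar

An architecture is an ordered list of blocks, each declared as
`<kind>:<body>`:

| kind | meaning | example |
|------|---------|---------|
| `B`  | mutually exclusive sample barcodes (equal length, no `N`) | `B:GTA,AAC` |
| `F`  | fingerprint / UMI; the run of `N`s fixes its length | `F:NNNN` |
| `S`  | fixed spacer | `S:GGGG` |
| `P`  | partial adapter, may be truncated or absent | `P:AGGGAGG...` |
| `R`  | the mappable insert, always declared `R:N` | `R:N` |

Exactly one `R` block is required. `N` is only meaningful in `F` and `R`
blocks; allowing it in spacers or barcodes would make the emission
semantics ambiguous, so it is rejected there. Lower-case input is
upper-cased. Architecture *files* hold one architecture per line
(`<name> <blocks...>`, `#` comments allowed); the file format is this
package's own, since only the feature itself is standard.

### Compilation to a profile HMM

Each block becomes a profile-HMM segment between a silent entry and a
silent exit state, and segments are concatenated in declared order with one
global silent start and end:

* **Fixed blocks** (spacer, barcode alternative, adapter) are linear chains
  of match states. A match state for base $X$ emits $X$ with probability
  $1-3e$ and each other base with $e$, where $e$ is the `base_error` of the
  `error_model()`. With `indel_open` $>0$ each chain also carries insert
  states (background emissions, self-transition `indel_extend`) and delete
  states, so the model tolerates indels in fixed blocks — this is what lets
  a read with a deleted UMI base still align, and then fail the fingerprint
  *length* check rather than disappear into a garbage alignment.
* **Fingerprints** are chains of match states emitting the background
  frequencies (every UMI is equally plausible).
* **Barcode segments** hold one chain per declared alternative, all sharing
  the entry/exit silent states, plus one *background chain* of the same
  length emitting background frequencies. The background chain captures
  reads whose barcode is too ambiguous to assign; if it wins, the read is
  rejected rather than guessed.
* **The read block** is a single match column emitting background
  frequencies with a self-looping insert state, giving the insert length a
  geometric prior with mean `expected_read_length` (default 1000 — nearly
  flat over realistic read lengths; the threshold calibration is rank-based,
  so this prior shifts all scores but not the accept/reject ordering).
* **Partial adapters** may be entered at any column, exited after any
  column, or skipped entirely (entry skip probability 0.1, per-column exit
  hazard 0.1). This models 5' adapters truncated at the read start and 3'
  adapters truncated at the read end.

All dynamic programming is in log space with log-sum-exp; $-\infty$
represents impossible events. Within a read position, silent states are
resolved in a topological sweep (the builder guarantees that silent-target
transitions always point forward in the state numbering).

### Scoring

Every read $x$ gets:

* $P(x|M)$ — total forward probability under the architecture model;
* $P(x|R)$ — zero-order background probability $\prod_i f_{x_i}$;
* $V$ — the posterior mass of the winning barcode chain, computed from the
  forward value at the barcode segment's entry silent state, the entry
  transition, the first emission and the backward value, summed over all
  read positions (1 if no barcodes are declared). The masses over all
  chains, including the background chain, sum to 1;
* the extraction error probability
  $P_{err} = 1 - \frac{P(x|M)\, V}{P(x|M) + P(x|R)}$ and its phred scale
  $q = -10\log_{10} P_{err}$, capped at 60 (the cap mirrors mapping-quality
  conventions and handles $P_{err}$ underflowing to 0).

`N` in a read is emitted by every emitting state with the background
frequency of the state's most likely base, and scores as the maximum base
frequency under the background model, keeping ambiguous bases close to
score-neutral between the two hypotheses.

### Decoding and extraction

Per-position posterior label probabilities (summed over each segment's
states, with the background barcode chain as its own pseudo-label) feed an
optimal-accuracy decoder: a dynamic program over (position, segment) that
maximizes the summed posterior of the chosen labels under the constraint
that segments appear in declared order, each as one contiguous (possibly
empty) block. Skipping a mandatory (non-partial) segment costs a large
fixed penalty (1000) instead of being forbidden outright — a soft version
of a gap penalty, so mandatory blocks are only empty when the posterior
leaves them essentially no mass. Score ties are broken towards the
earliest possible segment transition, which makes decoding deterministic.

The positions labeled `R` become the extracted read, fingerprint-labeled
positions concatenate into the UMI (also encoded base-4 as an integer,
`A,C,G,T` $\to$ `0..3`, big-endian). A read is rejected, with the reason
recorded, when its $q$ is below the threshold, when the background chain
wins the barcode, when the decoded UMI length differs from the declared
total, when the UMI contains `N`, or when no position is labeled as the
read. The barcode identity is taken from the $V$-argmax, not re-derived
from the labeling; the labeling is used for trimming only.

## Threshold calibration

A fixed $q$ cutoff cannot fit all architectures: with many fixed bases the
model and background score distributions separate cleanly, with a bare
short barcode they overlap. `calibrate_threshold()` therefore emits reads
from the model itself and from the background model (length-matched), scores
both sets, and picks the cutoff maximizing sensitivity plus specificity over
all midpoints of the pooled scores. Defaults: 10,000 reads per class
(stabilizes the cutoff across seeds), seed 42, read-segment length matched
to the data (the pipeline uses the median input length minus the
architecture's fixed length). The emission samples the model as-is —
including its error rates and the background barcode chain — so the
calibrated operating point already reflects how tolerant the model is.

## Post-extraction filters

* **Contaminants**: each extracted read is searched semi-globally against
  every reference sequence on both strands with the Myers bit-vector
  recurrence over 64-bit words (block-extended for reads longer than 64 nt);
  a read is removed when its best hit is within `max_edits`
  (default 3) and the hit is attributed to the single best reference.
  The user-facing criterion is *at most* `max_edits` errors.
* **Low complexity**: a simplified DUST statistic over the first 64 nt:
  $100 \sum_t \binom{c_t}{2} / (w-3)$ with $c_t$ the overlapping 3-mer
  counts and $w$ the window length; flagged above 100 (a 64-nt homopolymer
  scores 3100, uniform random sequence around 3, so the margin is wide).
  The exact historical DUST variant is unpublished; this normalization and
  threshold are declared here and configurable.

## The simulator and what passing tests mean

`simulate_dataset()` renders architecture-conforming reads (uniform barcode
choice, random UMIs, random 30-nt insert bodies by default) with per-base
substitutions at a chosen rate (indels optional and off by default),
plus uniform i.i.d. decoy reads of matching lengths, and records exact
ground truth per read. The benchmark conditions follow the simulation
design the method was validated on: 90%/10% architecture/decoy mixtures,
barcode sets with maximal dissimilarity (e.g. eight 6-nt barcodes at
pairwise Hamming distance $\ge 3$), error rates in the 0–10% range. The
test suite runs this at 9,000 + 1,000 reads, where auto-thresholded
demultiplexing achieves precision $\ge 0.99$ with recall $\ge 0.90$ at 1%
error, and recall $\ge 0.99$ with zero misassignments at 0% error.

The simulator does **not** emulate position-dependent instrument error
profiles, quality-string information (qualities are constant `I`), GC bias,
or chimeric reads. Passing benchmarks therefore demonstrate the method's
behavior under idealized i.i.d. substitution noise, not instrument-specific
artifacts.

## Numerical and design choices

* `error_model()` defaults: `base_error = 0.05`, `indel_open = 0.01`,
  `indel_extend = 0.3`. These are scoring tolerances, not instrument
  estimates: they keep the model permissive across the 1–10% error range
  the benchmarks cover, and they are configurable.
* Background frequencies default to uniform; the pipeline estimates them
  from the first 100,000 input reads.
* Barcode chain priors are uniform over the alternatives plus the
  background chain. Argmax ties resolve to the lowest chain index; a tie
  involving the background chain resolves to background (conservative:
  prefer rejecting over guessing).
* The forward/backward identity is enforced at run time to $10^{-9}$ in
  log space; the test suite checks both dynamic programs against exhaustive
  path enumeration on models small enough to enumerate.
* Paired-end handling: the architecture applies to read 1; read 2 follows
  read 1's accept/reject decision and barcode. With a second architecture
  declared, decisions are joint — log-odds add, barcode confidences
  multiply. (How the original tool shares evidence across mates is not
  documented; this is this package's declared contract.)
* Problem sizes in the shipped tests (9,000+1,000-read benchmarks, 10,000
  calibration emissions, 20 detection trials, 500 edit-distance
  comparisons) were chosen so the full suite completes in minutes on one
  CPU while keeping the binomial noise on the measured rates well inside
  the asserted bounds.

## Known limitations

* No training of HMM parameters from data (no Baum–Welch); the error model
  is declared, not estimated.
* Quality strings are carried through but not used in scoring.
* Only `N` is supported beyond `A,C,G,T`; other IUPAC ambiguity codes are
  rejected.
* Partial adapters are only modeled at their declared positions; an
  adapter appearing unexpectedly mid-read is not trimmed.
* The multi-barcode-segment case multiplies per-segment confidences; with
  a single barcode segment (the common case) this reduces to the standard
  definition.

## A worked example

```{r example}
arch <- parse_architecture(c("B:GTA,AAC", "R:N"), name = "mini")
hmm <- assemble_global_hmm(arch)
sc <- score_read(hmm, "GTAACGTACGTACGT")
sc
post <- posterior_labels(sc$matrices, hmm)
labels <- optimal_accuracy_decode(post, arch)
extract_read(list(id = "r1", seq = "GTAACGTACGTACGT",
                  qual = strrep("I", 15)),
             labels, arch, sc, threshold = 0)
```
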