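---
title: "Mapping protein interaction domains from Y2H fragment libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protein interaction domains from Y2H fragment libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The experiment being modelled

A protein–protein interaction detected in a yeast two-hybrid (Y2H) assay
tells you *that* two proteins touch, not *where*. Fragment-library domain
mapping localises the contact: the prey ORF (carried on a circular
activation-domain plasmid) is randomly sheared, the fragments are re-cloned
*en masse* behind the activation-domain fusion tag, and the library is mated
against the bait under auxotrophic reporter selection. Only clones whose
insert (i) sits in the prey's native reading frame, (ii) is translated
without a premature stop, and (iii) carries the complete bait-binding motif
can activate the reporter and grow. Sequencing the surviving inserts and
stacking their mapped intervals produces a coverage profile whose *plateau*
— the stretch covered by essentially every selected fragment — is the core
binding motif, at amino-acid resolution.

`fragmap` implements both halves of this design:

* a **simulator** of the wet side (shearing, random-orientation cloning,
  reporter selection, paired-end sequencing), so every downstream stage can
  be tested against known truth without any sequencing data; and
* the **analysis pipeline** (circular-plasmid read mapping, duplicate
  removal, reading-frame assignment, stratified coverage, plateau calling,
  transactivation-motif auditing) that would equally be applied to real
  FASTQ or SAM input.

## Coordinate conventions

Nucleotide coordinates are 0-based half-open and circular: any position is
normalised mod plasmid length, and substring extraction works on the doubled
sequence so the origin needs no special casing. All user-facing residue
intervals are 1-based inclusive, reported in the conventional
"aa $a$ to $b$ ($w$ aa)" phrasing with $w = b - a + 1$. A residue counts as
covered by a fragment only when its *complete codon* lies inside the
fragment — partial codons encode nothing.

## The six reading-frame classes

A sheared fragment can be cloned at any of three codon offsets on either
strand, giving six frame classes, labelled `+1,+2,+3` (sense) and
`-1,-2,-3` (antisense). The labels are bookkeeping; the class that places
the insert in the prey's native frame is `+2` by default (configurable via
`frame_label_map()`). The frame of a mapped fragment pair is decided from
its leftmost base, `(start - cds_start) mod 3`, plus the strand — the same
pure function the simulator uses at cloning time, because that base is what
recombination fuses to the adaptor. In an unselected library the six
classes are uniform (each $\approx 16.67\%$); under reporter selection the
coding class dominates almost completely.

The construct logic also fixes the adaptor frame: the 5' adaptor is chosen
so that translation reads through it as the linker peptide `HSFPTRRSSDL`,
with a terminal `CT` overhang that pairs with the first insert base to give
leucine (`CTN` is fully degenerate), so no junction can create a stop codon.
`fusion_construct_spec()` validates exactly this invariant.

## The selection model

`binding_model()` encodes which fragments survive:

* **binding** — coding frame, translation from the junction reaches the last
  residue of the true interval without a stop (an N-terminal fusion
  tolerates stops *after* the motif), the residue span covers the whole true
  interval, and no overlap with a `forbidden_interval` (a negative element
  that abolishes binding, producing a sharp coverage edge);
* **self_activation** — coding frame and in-frame coverage of a
  transactivating (TAD) interval, with probability `tad_rate`;
* **background** — any fragment, with probability `background_rate`
  (empty-vector colonies).

`coverage_stringency` (default 0) is the probability that a *partial*
coverer of the true interval is still selected, modelling leaky
triple-dropout selection; the default models stringent quadruple-dropout
media, which is what produces clean plateau geometry. All stochastic rules
draw one pre-generated uniform per fragment, so raising a rate with the same
seed can only add fragments (useful for monotonicity testing).

## Reads, mapping, stratification

Each selected fragment yields one 2×150 nt read pair from opposite ends of
its cloned strand (constant Q37 qualities; substitution-only error model —
indels are deliberately out of scope since the internal mapper is ungapped).
The mapper is exact-seed (k-mer, default $k = 15$) plus full-length
mismatch verification on both strands of the doubled circular reference;
ambiguous best hits are dropped rather than placed randomly, and proper
pairs require opposite strands with an insert inside
`[read_len, mean_len + 6·sd_len]`. External aligners are supported through
a minimal text SAM import/export (1-based POS, `NM` tag; secondary and
supplementary records skipped).

Coverage is stratified the standard way: **All** (every mapped fragment,
singleton read spans included in nucleotide space), **UniquePE** (proper
pairs deduplicated on the exact (start, end, strand) key — one
representative per identical coordinate pair, singletons discarded), and
**InFrame** (UniquePE fragments in the coding class overlapping the CDS).
These are nested, and their tracks are pointwise ordered. Tracks are
written as run-length-merged bedGraph (text, IGV-loadable); residue-space
tracks use a `<plasmid>_aa` pseudo-chromosome with one "base" per residue.
bigWig is intentionally not produced: it is a binary container with no
analytic content beyond the bedGraph.

## Plateau calling and its statistics

With full-coverage selection every surviving in-frame fragment covers the
whole motif, so the residue-space InFrame depth is exactly the number of
(unique) selected fragments across the motif and decays on the flanks. The
caller takes the longest maximal run of residues with depth
$\ge \tau \cdot \max(\text{depth})$ (ties: higher mean depth, then
leftmost).

The default $\tau = 0.99$ comes from the flank geometry. For a motif of
$w$ residues and fragments of length $L$ nt, the admissible in-frame
junction placements number about $N = (L - 3w)/3$, and the first flanking
residue is covered by a fraction $(N-1)/N$ of selected fragments — a drop
of $1/N$ per residue ($\approx 2\%$ for $w = 71$, $L = 350$). So
$\tau = 0.99$ sits between the plateau and its first flank *in expectation*
whenever $N < 100$, while tolerating minor mapping loss that an exact-max
threshold would not. The margin must also beat counting noise: the flank
depth fluctuates with standard deviation $\sqrt{d/N}$ at plateau depth
$d$, so the $0.01\,d$ margin is reliable only when
$0.01\,d \gg \sqrt{d/N}$, i.e. $d$ of a few thousand. This is why the
packaged scenarios shear $10^6$ fragments (the transformant scale a
saturating screen aims for): roughly $N/(2 \cdot \text{plasmid length})$
of the library survives selection, giving plateau depths near 2,000 where
the edge estimate is stable; at a few hundred survivors the called edge
wobbles by ±1 residue.

Disjoint runs above `secondary_floor` (default 0.5·max, minimum 10
residues) are reported as secondary calls; runs merely contiguous with the
primary (its shoulders) are not. `flank_asymmetry()` measures, from each
plateau edge, the distance to half-maximal depth; a short 3' slope with a
long 5' slope is the signature of a downstream negative element. Slopes
that hit the ORF boundary are reported boundary-censored.

## Scenario design

Five packaged scenarios (`make_scenario()`) reproduce canonical mapping
outcomes on synthetic sequence. Real interactor sequences are not bundled;
a random stop-free ORF of the documented length carries the published motif
coordinates as simulation truth. Choices worth recording:

* **Plasmid size 9 kb, ORF placed at nt 3000.** Typical AD-fusion plasmid
  scale; coordinates arbitrary but fixed.
* **Library size $10^6$** for the selection scenarios (see above);
  $5 \times 10^4$ for the pre-selection control, where only frame
  *fractions* matter and no saturation is needed.
* **`craf_mek1` uses the 200-bp shear fraction.** With a hard forbidden
  element abutting the motif's 3' end, every selected fragment's 3' end is
  pinned within one codon, so its 5' extent is (end − length): with 350-bp
  fragments (~117 aa capacity) every survivor would overshoot a 66-aa
  motif by ~50 aa on the 5' side and the called plateau would inflate
  leftwards at any depth. Resolution of both edges against a wall requires
  fragment capacity comparable to the motif width — hence the 200-bp
  fraction (~66 aa). The same geometry predicts the empirical observation
  that longer fragments inflate the 5' side of wall-bounded motifs.
* **`mdm2_p53` seeds the activator nonamer `EVYQVTVYQ` at aa 274–282**
  with `tad_rate = 0.16`. The rate is calibrated so the acidic
  false-positive peak sits between the secondary floor (0.5) and the
  primary threshold (0.99) relative to the specific N-terminal plateau
  *across* plasmid seeds — the plateau depth itself varies ~1.4× between
  seeds because the number of stop-free backbone junctions upstream of a
  5'-proximal motif is a small random integer.
* **Deterministic seeding.** One master seed per run; child streams per
  stage (reference 0, shear 1, selection 2, reads 3) derived
  arithmetically, so identical config + seed gives byte-identical
  artifacts, while any stage can be rerun in isolation.

```{r scenario-example}
library(fragmap)
sc <- make_scenario("craf_kras", seed = 7)
report <- run_scenario(sc, outdir = "kras_run")
report$call     # aa 58 to 128 (71 aa)
```

## The TAD scanner is an approximation

Nine-residue transactivation motifs of acidic/hydrophobic/aromatic
character can activate the reporter without any bait interaction. The
scanner tests every 9-residue window against a position-class pattern whose
shipped default accepts classic acidic activator nonamers (it matches
`EVYQVTVYQ`) and rejects basic or featureless runs. It *approximates* the
behaviour of published 9aaTAD predictors; it does not replicate any
external tool, whose exact rules and stringency tiers are not public.
Consequently hits are advisory annotations — a call overlapping a hit is
flagged `possible_self_activation`, never suppressed, because coverage
alone cannot adjudicate binding versus self-activation.

## What the simulator does and does not emulate

Emulated: uniform shear positions on a circular template, truncated-normal
size-selected fragment lengths, random cloning orientation (six frame
classes), junction-dependent stop readthrough, full-coverage reporter
selection with configurable leakiness, negative binding elements,
TAD-driven self-activation, content-independent background, per-base
substitution sequencing error, PCR duplicates as identical-coordinate
fragments (removed again by dedup).

Not emulated: indels and quality-score decay, chimeric fragments, cloning
bias and GC effects, growth-rate competition between clones (an optional
geometric copy-count skew exists but defaults off, since dedup removes it),
mating efficiency, reporter chemistry differences between Gal4- and
LexA-based systems (represented simply as independent seeds), and real
vector sequence. Passing tests therefore demonstrate correctness of the
*pipeline logic* under a clean generative model, not robustness to every
artefact of real libraries — for real data, the SAM/FASTQ import path plus
the stratified tracks are the intended entry point.

## Numerical and degenerate-input choices

* Ambiguous reads (tied best score at distinct locations) are unmapped.
* Same-strand or out-of-bounds pairs count as two singletons; singletons
  contribute to All-mode nucleotide coverage only.
* The dedup key is exact (start, end, strand); dedup is idempotent.
* An all-zero coverage track, an empty selection, and an empty frame
  distribution are explicit errors, not silent empties.
* A fragment arc that wraps onto both ends of the CDS (possible only when
  fragment length approaches the backbone gap) is rejected as
  non-contiguous rather than misreported as one interval.
* Insert bounds default to `[read_len, mean_len + 6·sd_len]` — permissive,
  but excluding chimeric arcs on the circle.

## Problem sizes used by the test suite

Unit tests run on toy plasmids (0.9–4.5 kb, 100–500-aa ORFs, libraries of
300–60,000 fragments). The end-to-end acceptance tests run each packaged
scenario once at its default $10^6$-fragment scale (a few thousand
selected fragments, seconds to map) plus 200 small noise-free selections
for the caller/oracle equivalence and an 800-pair mapping-accuracy
fixture. The whole suite completes in a few minutes on one CPU.
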