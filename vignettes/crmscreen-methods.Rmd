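---
title: "Methods: muscle CRM prediction and reporter-screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle CRM prediction and reporter-screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmscreen)
```

`crmscreen` implements the analysis chain of a skeletal-muscle enhancer
screen: candidate cis-regulatory modules (CRMs) are predicted as clusters of
muscle-regulator binding sites, validated by dual-luciferase reporter assays
across fibroblasts, myoblasts and differentiated myotubes, and the validated
set is characterised against the non-responders by composition,
conservation, binding-depth and enrichment statistics. This vignette
documents the models, the parameters that matter, the synthetic-data
generator the tests rely on, and the numerical choices made where the design
was genuinely open.

## Coordinates and formats

All internal coordinates are 0-based half-open, the BED convention; a single
convention end to end removes the classic off-by-one drift. Published
coordinate tables are 1-based inclusive and are converted on input with
`table_to_bed()` (`start - 1, end`). FASTA is read through Biostrings;
BED, bedGraph and JASPAR flat files are parsed in-package because the
analysis needs per-record rejection semantics (a malformed BED record is
dropped with a warning, not a hard failure) and bedGraph tracks expanded to
per-base vectors. bigWig/bigBed and lift-over are out of scope: conservation
tracks enter as bedGraph, pre-mapped to the working assembly.

## Motif model and scanning

A position frequency matrix (counts $c_{bj}$, background $q_b$, total
pseudocount $p$ distributed as $p \cdot q_b$) gives log-odds weights

$$ w_{bj} = \log_2 \frac{(c_{bj} + p\,q_b) / (N_j + p)}{q_b}. $$

The pseudocount default is 0.8, common JASPAR practice; the background
defaults to uniform. A window's relative score is
$(s - s_\min)/(s_\max - s_\min)$ with the attainable bounds computed
column-wise, so the best word scores exactly 1 — this is the scale on which
the conventional "80% threshold" of motif-cluster scanners is defined, and
0.8 is the scanning default throughout. Both strands are scanned (the minus
strand via the reverse-complemented weight matrix), and `N` bases contribute
the background-expected column weight $\sum_b q_b w_{bj}$, which is the
score's expectation under no information.

Overlapping hits of the *same* motif are resolved greedily by descending
score (ties: leftmost start, then plus strand — determinism matters for
reproducible site lists); hits of different motifs may overlap, since
composite elements are real. Matrix-to-matrix similarity is the mean
per-column score $2 - \sum_b |f_a(b) - f_b(b)|$ over the best ungapped
offset alignment covering at least half the shorter motif, in both
orientations by default (`both_strands = FALSE` restricts to the given
strand; note a poly-A and a poly-T point-mass matrix are identical under
reverse complement, so orientation changes this score qualitatively). The
original published matrix-alignment algorithm is not reimplemented, so its
printed values are not comparable targets.

## CRM prediction

Search regions follow the oPOSSUM construction: ±10 kb around each TSS,
minus protein-coding exon intervals, minus ±50 bp around each alternative
TSS. Candidate scoring tiles regions with 200-bp windows at a 50-bp step.
The window size matches the scale of experimentally assayed inserts
(predicted cores of a few hundred bp); hits are credited to every window
they intersect so no site is lost at a boundary.

Two scorers represent the family of published cluster methods:

- a logistic discriminator over per-motif features (best relative score and
  hit count per window), fitted by Newton/IRLS with an L2 ridge penalty
  (default $10^{-3}$) on the non-intercept coefficients — the penalty
  guarantees a finite deterministic fit even when training classes are
  separable, which window data frequently are;
- an additive cluster score: the maximum total relative score over a
  non-overlapping subset of the window's hits (solved exactly by weighted
  interval scheduling) minus an optional gap penalty times the uncovered
  window fraction. The exact optimum, rather than a greedy approximation,
  makes the score monotone under added hits, a property the tests verify.

Hidden-Markov-model cluster scoring is intentionally out of scope; no
per-program claims are made. Windows at or above the probability cutoff are
merged when touching; merged predictions composed entirely of SP1 sites
(equivalently, with zero non-SP1 hits) are removed, since GC-box-only
clusters are ubiquitous and not muscle-informative. A conservation filter
optionally keeps predictions whose maximum per-base score reaches 0.7.
Recovery of planted CRMs is evaluated at region level — candidate regions
scored by their best window — because window-level truth labels are noisy
at CRM boundaries by construction of the tiling.

## Reporter-assay analysis

The QC rule: a well whose firefly reading is below 1000 relative light
units (LRU) is a failed transfection; if firefly passes but renilla does
not, renilla is floored to 1000 before the ratio is taken. The threshold is
inclusive (≥), fixing the boundary so the flooring rule is continuous at
exactly 1000. Flooring bounds every reported ratio by firefly/1000,
suppressing the spurious large ratios that small denominators produce.
Technical replicates are averaged; a lone passing replicate is used alone
and flagged; a clone with no passing replicate is excluded for that cell
type.

Ratios are normalized per phase × cell-type batch with a generalized-log
transform $h(x) = \operatorname{asinh}((x - a)/b)$, the standard
variance-stabilising family for additive-multiplicative error. $(a, b)$ are
fitted by maximum likelihood with per-clone means profiled out (the
transformation Jacobian included), so only within-clone spread informs the
calibration; for purely multiplicative noise the fit approaches a log
transform. Because a free scale $b$ shifts each batch's location by
$-\log b$, batches are then aligned by subtracting the batch median — the
robust-calibration step of variance-stabilising normalization, valid
because most inserts in a screen are inactive. Screens where responders
approach half the library would bias this anchor; the packaged pipeline
keeps non-responders at 3:1.

Myotube selectivity is tested per clone with a moderated statistic
$d = (\bar{x}_{MT} - \bar{x}_{other}) / (s + s_0)$ computed on
replicate-level normalized values, where $s$ is the pooled within-clone
standard error and $s_0$ the median of per-clone $s$ values (the fudge
factor that keeps low-variance clones from dominating). Replicate-level
values are used because averaging first would leave one value per cell type
and no estimable spread. The false discovery rate is estimated by
permutation of one global column labeling (cell type × replicate) shared by
all clones — the unpaired two-class design. A shared labeling is essential:
permuting within clones independently has only ${6 \choose 2} = 15$
distinct splits per clone, so the estimated FDR can never fall below ~1/15
and the procedure would be unable to call anything at 0.05. For each
candidate cutoff the FDR estimate is the median permutation exceedance
count over the observed count; the most permissive cutoff at or below the
target (default 0.05) is used, one-sided in the myotube direction. The
default 1000 permutations are reduced to 200 in simulation loops, which is
ample for an FDR granularity of 0.05 at screen sizes.

Phase 1 advances plasmids with a raw-ratio fold ≥ 2 in myotubes over both
other cell types (inclusive boundary; computed on raw mean ratios — the
fold rule predates normalization in the lab workflow), or a positive
moderated call, plus designated control rows. Phase 2 retests advanced
plasmids in myoblasts and myotubes only, from independent plasmid
preparations. Positives from both phases are pooled per insert, and the
consensus rule requires at least two positive clones making up at least
half the available clones — single-clone support is never sufficient.

## Property analyses

Composition profiles count mononucleotides, overlapping dinucleotides (on
the given strand only; reverse-complement symmetrisation is available but
off by default, as strand-specific skews are themselves of interest),
GC content, and the skews $(G-C)/(G+C)$ and $(A-T)/(A+T)$. N bases are
removed before counting. Set comparisons use two-sided Wilcoxon rank-sum
tests on per-region values.

Conservation summaries report the per-region mean and maximum score, a
conserved flag (at least one run of ≥ 20 consecutive bases each ≥ 0.7) and
the conserved make-up (fraction of bases strictly above 0.7). The two
thresholds deliberately differ in strictness (≥ vs >) because the two
published definitions differ; both are implemented exactly as stated.
Set-level make-up pools summed conserved lengths over summed region
lengths rather than averaging per-region fractions, matching the stated
table construction. TSS distance is 0 inside a region, else the gap to the
nearest region base; CpG association flags any island intersecting the
region ± 1 kb, with a half-open flank (an island starting exactly at the
flank end does not count).

TFBS phylogenetic depth compares, per transcription factor, the mean
conservation score at retained site positions with the mean at positions
covered by no site at all, within each region set. The fold threshold 2 is
inclusive; the selected TF list is determined on the responding sets and
then applied to all sets, and per-TF folds are compared between sets by
two-sample t-tests. Folds are computed only when the non-site mean is
positive — phyloP scores can be negative and a ratio of signed means is
not interpretable — otherwise the TF is skipped with a warning.

Enrichment statistics: the Fisher exact engine computes hypergeometric
tails directly (`greater` is $P(X \ge a)$; `two_sided` sums outcome
probabilities not exceeding the observed, with the standard relative
tolerance guard). Enrichment tests are one-sided (greater); this choice
reproduces published over-representation scores exactly from their printed
count tables, as the acceptance tests assert. Peak-overlap contingency
emits all four standard comparisons with the one-sided p in the direction
of greater responder/myotube overlap alongside the opposite side and the
two-sided value, since published tables do not always state sidedness. The
overlap threshold is 1 bp, exposed as a parameter. The oPOSSUM-style
Z-score uses nucleotide-level rates, $z = (x - np)/\sqrt{np(1-p)}$ with $n$
the foreground nucleotide total and $p$ the background site rate; published
Z values are not comparable targets because the underlying nucleotide
totals are not published. ROC curves use midrank (tie-corrected) AUC, equal
to the normalized Mann–Whitney statistic.

## Synthetic data: what it emulates, what it does not

The generator plants everything the analysis later estimates, under one
seed with byte-identical reruns:

- **Genomes** are i.i.d. background at GC 0.41 (human-like) with planted
  200-bp CRMs whose local GC is raised by 0.03 — emulating the observed
  responder/non-responder contrast of 0.54 vs 0.51 — each carrying four
  non-overlapping sites sampled from consensus-derived muscle-motif models
  (MEF2-, SRF-, Myf-, TEAD-, SP1-like; synthetic constructions, not curated
  database matrices) with relative score ≥ 0.85, random strand.
- **Conservation tracks**: Beta(1,9) background (mean 0.1, clipped to
  [0,1]) for the phastCons-like track and Normal(0.1, 0.1) for the
  phyloP-like track; planted CRMs are lifted by 0.5 and planted site
  positions are lifted to twice the CRM-flank mean, so the depth analysis
  has a known target fold of 2. Zero elevation leaves the track
  statistically flat.
- **Plate data**: renilla is lognormal around 2×10⁴ LRU with coefficient
  of variation 0.3 (multiplicative error is the standard luciferase noise
  model; the source protocol states none); firefly is renilla × baseline 2
  × effect × lognormal noise, where effect is 15 in myotubes for planted
  positives (the strongest published control construct) and 1 otherwise;
  5% of wells fail transfection (both channels below 1000 LRU); the two
  phases draw independently, emulating independent plasmid preparations.
- **Peaks** overlap each region with probability 0.58 (responders) vs 0.16
  (non-responders), the published myotube MyoD rates, extending beyond the
  region by random 20–200 bp flanks.

Not emulated: phylogenetic alignment structure (conservation is noise plus
offsets, not an evolutionary model), chromatin context, plate-position
effects, primer/cloning artifacts, and correlated motif co-occurrence.
Passing tests therefore demonstrate that the statistical machinery recovers
planted structure at realistic noise levels and sample sizes — not that the
biological effect sizes themselves are correct for any particular genome.

## Problem sizes and numerical choices

Simulation-based tests use 10–50 kb genomes with 3–10 planted CRMs, screens
of 8–32 inserts with 2–4 clones each, 100 seeded null runs and 40 seeded
power runs at 200 permutations — sizes chosen so the full suite exercises
every stage in a few minutes on one CPU while leaving comfortable
statistical margins. Fixed seeds make every simulated assertion
deterministic. Degenerate inputs are handled explicitly: a flat PWM gives
every window relative score 1; a constant normalization batch returns a
constant; an all-identical differential input gives $d = 0$ exactly; empty
hit margins give Fisher p = 1; Newton/IRLS caps at 100 iterations with a
step tolerance of $10^{-10}$.

## Limitations

The two prediction scorers stand in for a family of published programs;
no per-program result is reproduced. The consensus-positive and QC rules
are faithful to their stated definitions but inherit their arbitrariness
(inclusive boundaries chosen where the statements were silent). The
moderated-statistic FDR is a screen-scale estimate: with very few clones
its granularity is coarse, and the batch median alignment assumes inactive
inserts dominate. Real phastCons/phyloP tracks, JASPAR matrices and ChIP
peaks are deliberately not shipped; analyses over real data require the
user's own local copies in the supported plain-text formats.
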