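---
title: "Annotating and classifying CNL N-terminal (ECC) domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and classifying CNL N-terminal (ECC) domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecckit)
library(dplyr)
```

## The biological problem

Plant CC-type NLR immune receptors (CNLs) carry an N-terminal
coiled-coil (CC) domain that, for many receptors, suffices to trigger
hypersensitive cell death when expressed alone. ecckit works on the
*extended* CC fragment — the ECC — defined as the entire N-terminus up
to (but not including) the Walker-A P-loop of the NB–ARC domain. The
package annotates the sequence features that organize this region,
classifies receptors into architecture groups, summarizes replicated
yeast two-hybrid (Y2H) interaction screens among ECCs, constructs the
chimera/deletion/point-mutant panels used to dissect the region, and
maps a single locus controlling ECC-induced necrosis in an F2
population.

## The annotation model

An ECC annotation is a composition of feature finders, each of which is
deliberately simple and fully specified:

* **Hydropathy** — Kyte–Doolittle values averaged over a sliding window
  of three residues; only fully interior windows are reported, so the
  profile is two residues shorter than the sequence. The window-3 choice
  matches how hydrophobicity profiles of CC domains are usually drawn;
  the edge policy (drop incomplete windows) is ours.
* **Helix blocks** — per-residue Chou–Fasman helix propensities smoothed
  with a centered 7-residue window (edge windows shrink); maximal runs
  above `theta_helix = 1.03` of at least 6 residues become blocks. This
  internal heuristic stands in for a consensus of secondary-structure
  predictors; a user-supplied per-residue track always overrides it.
  Blocks are labelled H1a/H1b/H2a/H2b in order; when only three blocks
  are found the first is taken as a merged H1, reflecting that the
  H1a/H1b separation is often not resolved.
* **Heptad register** — within each helix, the frame (of seven) that
  maximizes L/I/V at the `a`/`d` interface positions, ties to the
  smaller offset. This operationalizes the defining heptad repeat of CC
  domains without an external coiled-coil predictor.
* **Motifs** — EDVID (exact five-residue match by default; mismatches
  opt-in because only Groups C/D conserve it sharply), the 10-residue
  polar stretch immediately upstream of EDVID (Group D evidence; at
  least `theta_polar = 8` of 10 in S/T/N/Q/D/E/K/R/H/Y), the
  pre-P-loop consensus `[VI] G x8 [LI] x3 L` (leftmost match; the VG
  position anchors downstream coordinates), and a configurable Walker-A
  P-loop `G x4 G K [ST]` searched after the pre-P-loop. The P-loop
  pattern is our operational choice: the ECC boundary needs *some*
  P-loop definition, and canonical Walker A is the standard one.
* **Charged motif** — the 9-residue window at −11..−3 relative to the V
  of VG, both ends inclusive. "Charged" counts D/E (acidic) and K/R
  (basic); histidine is excluded because its protonation state is
  ambiguous and the mutational series of interest targets E↔K. The
  window always exists upstream of a located VG, so the *motif* is only
  called when at least half the window is charged
  (`theta_charged = 0.5`); this makes deletion clones re-annotate as
  charged-absent rather than reporting an uncharged window.
* **CC-END and CCVX** — CC-END is the last heptad a/d hydrophobic of the
  last (H2b) helix; CCVX is the variable segment between CC-END and the
  charged motif. Canonical CCVX lengths are 16–18 residues; other
  lengths are flagged `non-canonical`, not rejected.

Coordinates are 1-based inclusive with the initiator Met at position 1,
so residue labels like "Gly-2", "C21" or "G158" map directly onto
positions. Missing features are recorded as absent, never fabricated,
and every annotation asserts the ordering invariant
helices ≺ CC-END ≺ CCVX ≺ charged ≺ VG ≺ P-loop.

```{r annotate-demo}
panel <- gen_ecc_panel(panel_spec(), seed = 1)
ann <- annotate_panel(panel$panel)
classified <- classify_panel(ann)
count(classified, group)
tidy(ann$annotation[[30]])
```

## Group classification

Groups A–E describe N-terminal architectures: A is the CC_R (RPW8-like)
class of helper CNLs; B has its own helix arrangement with N-terminal
acylation motifs (Gly-2/Gly-3 myristoylation, Cys-4/Ser-4
palmitoylation) and no EDVID; C and D share the four-helix topology with
EDVID in H2a, with D additionally carrying the 10-polar stretch; E
lacks a clearly defined CC domain. The classifier is a transparent
cascade: no helix → E; match to a CC_R consensus profile (percent
identity ≥ `theta_rpw8 = 60`) → A; EDVID + polar stretch → D;
EDVID → C; otherwise B. Acylation and β-flank evidence are recorded but
not required — strand prediction is delegated to optional user tracks.

Because no machine-readable CC_R consensus is published, the package
ships a synthetic 30-residue signature (`rpw8_signature()`), which is
also what the panel generator plants in Group A fixtures; substitute a
consensus built from real CC_R sequences for real data. The threshold of
60% identity was chosen by margin: on synthetic panels the signature
scores 100% in Group A and at most ~40% elsewhere, so the rule is far
from both failure modes.

For clustering, sequences are encoded as structure words: per-residue
triples of hydropathy class (H/P by Kyte–Doolittle sign), heptad letter
and helix class, taken as contiguous k-tuples (k = 3). The distance is
one minus a weighted Jaccard similarity of word multisets, with words
containing an a/d interface symbol up-weighted (`w_ad = 2`). The
published clustering method is described only as "structural words
weighting and variability analysis"; our concrete scheme is therefore a
declared interpretation — it is a true metric, it is testable, and its
weights are configurable, but reproducing the published cladogram
exactly is not promised. Trees are built by classical neighbor joining
(negative branch estimates clamped to zero and flagged) and compared by
Robinson–Foulds distance.

## The interactome module

Matings are scored in four replicates per bait/prey orientation on
media lacking His and adenine. The positivity rule is not part of the
published design, so the package makes it explicit: an unordered pair
becomes an edge when at least `min_support = 3` of its (up to 8)
orientation-replicates are positive — tolerant to single-replicate
dropout while still demanding reproduction. Network summaries count
homomeric and heteromeric edges and the nodes involved; the
degree–phenotype Pearson correlation counts a self-association as one
interaction; the group-pair Fisher test compares edge frequencies
between dyad classes (e.g. CC_R–canonical vs canonical–canonical);
"higher-affinity partner" means a heteromeric edge whose replicate
support strictly exceeds the clone's self-edge support — replicate
support is our proxy for the qualitative affinity statements, and it is
flagged as such in the documentation.

## QTL mapping

The mapping module is a deliberately transparent single-marker scan
rather than Composite Interval Mapping, whose cofactor selection is
tool-specific: at each marker the (numeric) ordinal phenotype is
regressed on an additive code plus a dominance indicator,
complete-case, and `LOD = (n/2) log10(RSS0/RSS1)`. The genome-wide
threshold is the Churchill–Doerge empirical `1 − alpha` quantile of the
maximum LOD over phenotype permutations (the study design used 1,000
permutations at `alpha = 0.05`). Support intervals take the contiguous
region within a 1.5-LOD drop of the peak, widened to the first flanking
marker below the drop on each side; the published interval rule is not
stated, so 1.5-LOD is our declared convention. A Kruskal–Wallis scan is
available as a rank-based robustness check, and a Pearson chi-square
goodness-of-fit test covers segregation ratios such as the 14:16
observation against 1:1.

```{r qtl-demo}
pop <- gen_f2_population(qtl_model(), seed = 2)
fit <- scan_qtl(pop, n_perm = 200, seed = 3)
glance(fit)
fit$peaks
```

## What the synthetic generator emulates

`gen_ecc_panel()` assembles sequences from the group architectures:
group-specific N-terminal caps, helix blocks with L/I/V planted at
heptad a/d positions, P/G-rich turns, a CCVX linker drawn from
16–18 residues, a charged 9-mer at −11..−3 of a planted VG pre-P-loop,
and a Walker-A terminus. Defaults reproduce the study conditions: 56
sequences in the published group sizes (6 A, 8 C, 14 D, the rest B and
E). The construction is designed so that at zero noise every planted
motif is provably the unique (or leftmost) match its scanner looks
for: helix fillers exclude G — so the only `[VI]G` dipeptide is the
planted VG — and R — so no 7-window of fillers dips below the helix
threshold; D occurs only in the charged motif and EDVID, which makes an
accidental EDVID impossible; and the charged 9-mer is a fixed multiset
(one E, four D, two K, two R, shuffled) flanked by P/G so its smoothed
helix-propensity bump can never reach the 6-residue minimum block
length. Substitution noise (`epsilon`) is applied outside protected
anchors by default, so feature coordinates stay exact while
classification accuracy degrades with noise, which is the property the
tests assert.

What the generator does **not** emulate: real CNL sequence diversity
(indels, divergent helix spacings, paralog structure), alignment
uncertainty, Y2H auto-activation artifacts beyond a flat false-positive
rate, and genotyping error or segregation distortion in the F2. Passing
tests therefore demonstrate that the *method* recovers what it is
defined to find under its own assumptions — not that those assumptions
hold for any particular genome.

`gen_y2h_screen()` draws latent true edges per group pair (defaults:
8% heteromeric dyad probability regardless of group, 9% self — the
observed regime where interaction frequency does not follow sequence
relatedness), then scores 4 replicates per orientation with
false-negative rate 0.1 and false-positive rate 0.01.
`gen_f2_population()` simulates gametes as Markov chains under the
Haldane map function on 5 chromosomes × 10 markers at 10 cM, with a
single QTL (default chromosome 3, 40 cM) of additive effect
`a ≈ 0.873` and dominance `d = a/2` against unit residual variance —
incomplete dominance explaining ~30% of phenotypic variance, n = 75.
The continuous phenotype is discretized to the 1–5 ordinal scale at its
empirical quintiles; quintiles of the *realized* distribution (rather
than of the genetic values alone) keep the discretization well defined
under the null, where the genetic contribution is constant.

## Numerical choices and degenerate inputs

* Heptad frame ties break to the smaller offset; a helix with no L/I/V
  still receives a register (frame 0).
* Markers with fewer than two observed genotype classes, or a constant
  phenotype, get LOD 0 with a `monomorphic` flag; perfect fits are
  capped at `lod_max = 50` with a `perfect_fit` flag instead of
  returning infinity.
* Weighted-Jaccard distance between two empty word profiles is defined
  as 1; NJ negative branch lengths are clamped at 0 and counted in the
  tree's `clamped_branches` attribute.
* The Fisher odds ratio reported is the sample cross-product ratio (so
  equal densities give exactly 1); the p value comes from the exact
  conditional test.
* Permutations, screens, panels and populations all take explicit
  seeds and restore the caller's RNG state; nothing seeds from the
  clock.

## Problem sizes used in the checks

The packaged tests run the feature-recovery property on 240 noise-free
fixtures across 20 seeds, the classification floor on panels covering
all five groups, NJ topology recovery on random 5–12 leaf additive
matrices, Y2H calibration on 20 screens of 30 clones, and the QTL
operating characteristics on 200 null populations and 50 populations
with the planted effect, each against a 200-permutation threshold.
These sizes give Monte-Carlo error small enough for the stated bounds
(binomial CI of the 5% genome-wide size; ≥80% detection; ≥90% interval
coverage) while keeping the whole suite to a couple of minutes.

## Known limitations

* The helix heuristic is propensity-based; on real sequences a
  predictor-consensus track should be supplied (`track` argument).
* The structure-word scheme and the CC_R signature are declared
  stand-ins where the published method is under-specified; both are
  configurable and clearly flagged in output metadata.
* Group C vs D separation rests on the polar stretch alone; receptors
  whose Group D membership derives from NB–ARC phylogeny rather than
  the stretch would need external evidence.
* The QTL scan is single-marker: no interval imputation, no cofactors,
  complete-case handling of missing genotypes. This trades power for
  clarity and is recorded in the scan output.
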