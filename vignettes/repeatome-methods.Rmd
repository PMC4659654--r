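---
title: "Methods: graph-based repeatome characterization from low-pass reads"
author: "repeatome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-based repeatome characterization from low-pass reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Most of a typical plant genome is repetitive DNA — LTR retrotransposons,
DNA transposons, and tandemly arranged satellite families — and differences
in genome size between related species are driven largely by the
differential amplification and removal of these repeats. Assembling dozens
of multi-gigabase genomes to study this is neither feasible nor necessary:
at low sequencing coverage (0.01–0.5x), only sequences present in many
genomic copies find similar partner reads, so an all-to-all comparison of
raw reads already exposes the repeat fraction.

`repeatome` implements this low-pass strategy as a reusable toolkit:

1. **Similarity graph.** Every read pair whose best ungapped local alignment
   reaches ≥ 90% identity over ≥ 55 bp contributes an edge; connected
   components of this graph are *read clusters* and proxy repeat families.
   The number of reads in a cluster is proportional to the genomic abundance
   of the corresponding repeat.
2. **Quantification.** A cluster's per-species read count divided by the
   species' total analysed reads is its genome proportion; multiplied by the
   monoploid genome size (1Cx) it becomes an absolute amount in Mbp/1Cx.
   All abundance arithmetic uses 1Cx so that a tetraploid (where
   1Cx = 1C / 2) is comparable to diploids.
3. **Conservation (Hs/Ho).** For reads pooled per repeat group across
   species, each read's intra-specific hit frequency Hs (distinct
   same-species partners over same-species group size, self excluded) is
   compared with its inter-specific frequency Ho. Because both counts are
   normalized by group sizes, the ratio is independent of copy-number
   differences between species: conserved repeats give Hs/Ho ≈ 1 (0 on the
   log10 scale), species-private variants give ratios ≫ 1.
4. **Solo-LTR estimation (Rsf).** Ectopic recombination between the two
   LTRs of a retrotransposon excises the internal region and leaves a solo
   LTR. Junction models (a 30 nt LTR_3'end tag and a 30 nt 5'UTR tag flanking
   the validated LTR/internal boundary) are read off cluster contigs, and
   reads are counted as LU (tag pair adjacent: an intact element) or Lx
   (LTR_3'end followed by non-5'UTR sequence: an insertion site). A
   full-length element contributes one LU junction (5' LTR) and one Lx
   junction (3' LTR); a solo-LTR contributes one Lx junction. Hence
   `Rsf = (Lx − LU)/LU` estimates the solo:full ratio, with 0 meaning all
   elements are intact.
5. **Genome-size statistics.** Per repeat class, Mbp/1Cx is regressed on
   1Cx (ordinary least squares, R² and F-test p), and the *average
   contribution to pairwise genome-size differences* is the unweighted mean
   over species pairs of `100 × ΔA/ΔG`, each pair oriented by the larger
   genome so that negative values mean "larger in the smaller genome".
   Contributions are additive across classes and scale invariant.

## The similarity criterion and its oracle

Read comparison is ungapped: a candidate alignment is a diagonal (a fixed
offset between two reads, in either orientation), and a hit is the longest
contiguous segment on any diagonal with identity ≥ 90% and length ≥ 55
columns (identity = matches / columns; `N` never matches). The bundled
simulator evolves sequences by substitutions only, so best local alignments
are genuinely gap-free and this criterion is exact rather than an
approximation.

Candidate diagonals are found with exact-match k-mer seeds and then scored
exactly with an integer prefix-sum scan. The seed length default is 8
because it is the largest seed that *guarantees* finding every qualifying
segment on 100 nt reads: a segment of length L ≥ 55 at ≥ 90% identity
carries at most `floor(L/10)` mismatches, and its longest exact run has at
least `ceil((L − m)/(m + 1))` bases, which is minimized at 8 (e.g. L = 60,
m = 6). Under this bound the seeded search is provably hit-set-identical to
`all_pairs_hits()`, an independently coded exhaustive enumeration over all
pairs and all diagonals, and the test suite asserts exact equality of the
two hit sets on simulated read sets.

## The simulator and what it does (not) emulate

`sim_family()` + `make_ancestral_library()` + `build_species_genome()`
generate multi-species genomes with exact ground truth:

* **LTR elements** are `LTR + internal + LTR` with identical LTRs starting
  `TG` and ending `CA`, and a primer-binding-site motif (reverse complement
  of a tRNA 3' end, default the initiator-Met dodecamer) 3 bp into the
  internal region. A copy becomes a solo-LTR with probability
  `solo_fraction` (clean intra-element recombination: one LTR retained,
  no target-site artifacts).
* **Satellites** are tandem arrays of a mutated monomer, grouped into
  `ceiling(copies / monomers_per_array)` arrays.
* **Divergence** has two knobs: `divergence` mutates every copy
  independently; `lineage_divergence` applies one shared set of
  substitutions per species *before* per-copy divergence. The second knob is
  what creates species-private sequence variants — with per-copy divergence
  alone, intra- and inter-specific identities coincide and no Hs/Ho
  separation can exist.
* Background is i.i.d. sequence at 40% GC; insertions are uniform in the
  background, so every element has unique flanking sequence. Truth tables
  record exact insertion coordinates and every LTR junction position.

Evolution is substitution-only (no indels, no nesting), reads are uniform
(no GC or fragmentation bias of library preparation), and insertion times
are not modelled. Consequently, passing tests demonstrate the estimators'
correctness under clean sampling statistics; they do not certify robustness
to indel-rich histories or biased library chemistry, both of which affect
real data (satellite quantification in particular).

## Contigs, masking, and junction detection

Cluster contigs are built by greedy overlap-layout-consensus: the read with
most hits seeds the layout, reads are placed breadth-first at the offset and
strand implied by their best hit to an already placed read, and the
consensus is the per-column majority. Each read's *core* is its longest
segment agreeing with the consensus at ≥ 90%; the remainder is masked. Two
numerical details matter:

* A maximal 90%-identity interval extended into random flanking sequence
  keeps absorbing chance matches, so cores systematically overrun true
  junctions by several bases. Cores are therefore trimmed until both ends
  open with 4 consecutive exact matches, which pins the masking onset to the
  boundary within a base or two.
* The layout of an LTR element is inherently ambiguous: the two identical
  LTRs either collapse onto one contig locus or unroll into two, and the
  contig orientation relative to the element is arbitrary. Junction
  detection therefore scans both contig orientations, and the
  masked-fraction threshold (`high = 0.25`) reflects the worst layout, where
  the flank-read mass at one LTR-end locus is about a quarter of the local
  depth ((N_full + N_solo)/(2N_full + N_solo) split over two loci);
  background columns stay near zero, so the threshold separates cleanly.

A candidate boundary is the modal masking-onset column of a hot region; it
is validated only if the consensus shows the `CA` LTR terminus directly
upstream (allowing a ±2 column shift: onsets scatter under sequencing
errors) and a PBS motif (≥ 10 of 12 positions) within 30 bp downstream.
Both 30 nt tags are then read off the consensus. False candidates — e.g. the
LTR-end boundary that an unrolled layout places in front of the *second* LTR
copy rather than the 5'UTR — fail the PBS check and are reported with their
rejection reason.

## Junction read counting

A read is classified at a boundary placement β when its LTR_3'end-tag hit
(≥ 90% over ≥ 27 bp) leaves at least 30 bp of read downstream of the tag:
it is LU if the 5'UTR tag matches directly adjacent, Lx if the downstream
region shows no similarity to the 5'UTR tag. Requiring the same 30 bp
window for both categories makes the two junction types equally detectable
per read — with asymmetric windows (UTR-tag hits allowed down to 27 bp of
remaining read) the expected ratio E[Lx]/E[LU] would be deflated by a
factor 44/47, i.e. Rsf would be biased by about −0.2 at a solo:full ratio
of 2. Under the symmetric rule E[Lx]/E[LU] = (N_full + N_solo)/N_full holds
and measured deviations across solo:full ∈ {0, 0.5, 1, 2} are below 0.08.

## Validation scenarios and problem sizes

The bundled scenarios are the package's study conditions; they are fixed
once and shared by the test suite and `scripts/acceptance.R`:

* `scenario_comparative_panel()` — three 10 Mbp species at 0.05x coverage
  (5,000 reads each) with a high-copy Ogre-like LTR family, a conserved
  Angela-like family, a shared satellite, a lineage-divergent
  (species-private) satellite, and a sister-species satellite. Sized so
  that each family is sampled by hundreds of reads while the pooled
  all-to-all comparison stays within ~10^5 hits.
* `scenario_sololtr(ratio)` — one LTR family with ~2,000 full-length
  copies (2.5 kb element, 300 bp LTRs) plus solos at the requested ratio,
  read sampling at 0.2x. Copy number is chosen to yield ~200 LU reads per
  run so that a single Rsf estimate has a sampling error near 0.15.
* `scenario_replicates()` — six satellite families at 0.2–0.3% of a 10 Mbp
  genome next to three mobile-element families at 2–4%. With two
  independent 0.05x read samplings, satellite clusters (~10–15 reads each)
  show visibly larger Poisson fold-variation than mobile-element clusters
  (~100–200 reads), and summing read counts per class suppresses both —
  the sampling-statistics component of the replicate-variation effect.
  Library-preparation bias, the other component in real experiments, is
  deliberately not modelled.
* `scenario_contribution_panel(f)` — an eight-species abundance table in
  which one class explains a known fraction `f` of all pairwise
  genome-size differences, used to validate the contribution statistic to
  within 2 percentage points.

Divergence defaults (2% per copy, 1–8% per lineage, 0.5–1% sequencing
error) represent young, recently amplified repeat families, which are the
ones low-pass clustering resolves best.

## Degenerate inputs and tie-breaking

Empty read sets yield empty hit tables; reads without hits are reported as
singletons, never silently dropped; clusters are numbered by decreasing
size with ties broken by the smallest member read id; consensus ties pick
the alphabetically first base; species with fewer than two reads in a
cluster get `NA` similarity rather than an error; `Rsf` with `LU = 0` is
flagged undefined and printed as a dash. All simulation and sampling
functions are deterministic given their seed.

## Known limitations

* The ungapped similarity model is exact for the simulator but
  approximates real indel-containing alignments.
* Nested and tandem element insertions, which bias junction counts in real
  genomes, are not generated.
* Cluster annotation uses nucleotide-level matching to a reference library
  (or simulator truth); protein-domain-based classification of LTR lineages
  is out of scope.
* Scalability targets low-pass designs (up to ~10^6 reads per run), not
  full-coverage datasets.
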