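---
title: "Screening amplicon datasets for one diatom family: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening amplicon datasets for one diatom family: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Environmental SSU rDNA metabarcoding surveys sequence short hypervariable
regions (V4, ~390 bp; V9, ~130 bp) from bulk plankton and sediment DNA/cDNA.
Recovering the reads of **one target family** — here the ancient, species-poor
diatom family Leptocylindraceae (*Leptocylindrus*, *Tenuicylindrus*) — from
such datasets is harder than it sounds: the family's known species differ
substantially from each other at the marker, the family sits at a basal
position among diatoms, and at the permissive identity cut-offs needed to
catch divergent family material, many reads of *other* diatom lineages are
captured too. `taxascreen` implements a complete, reference-guided screen
with explicit false-positive control, plus the downstream biogeographic and
statistical analyses, and a synthetic-data generator that makes the whole
funnel testable offline against a known ground truth.

## The screening funnel

Given environmental reads, an annotated reference panel (family species,
other diatoms, and two distant bolidophyte outgroups), and a sample metadata
table, `run_screen()` executes:

1. **Initial assignment** (`assign_reads`): every read is scored against
   every reference by the identity of the optimal *global* alignment. The
   read receives the full taxonomy of its best hit, or, when several hits tie
   (identities equal after rounding to 4 decimals), the last common ancestor
   (LCA) of the tied references. Reads assigned within Bacillariophyta form
   the initial dataset.
2. **Capture clustering at 0.90** (`greedy_capture`): each read joins the
   reference of maximal identity provided it reaches 0.90; clusters keyed by
   non-family references are eliminated. The 0.90 threshold is permissive by
   design — the family's internal divergence at the marker approaches 7%, so a
   stricter cut-off would lose genuine family material, while 0.90 inevitably
   admits some non-family diatoms. Those are dealt with downstream.
3. **Chimera screen** (`chimera_screen`): a read is flagged when the
   length-weighted combination of its best 5' segment identity and best 3'
   segment identity against two *different* references exceeds its best
   full-length identity by at least 0.02, over breakpoints scanned at every
   10% of read length. Segment identities are read off the per-position match
   profile of the global alignments rather than re-aligned, trading a little
   sensitivity for a single pass over the references. With closely related
   parents (a few percent divergence) the attainable gain is small, so the
   screen is precise but deliberately conservative; such chimeras cluster
   with their parents and do not distort species-level results. A sequence
   observed identically at least `protect_multiplicity` times (default 3) is
   never flagged: replication is evidence of a biological template, and
   without this rescue a *genuinely divergent* lineage bracketed by the
   reference panel reliably looks chimeric — a known failure mode of
   reference-based chimera detection that would silently delete exactly the
   novel material the screen exists to find.
4. **OTU formation at 0.97** (`recluster_otus`): within each family capture
   cluster, greedy incremental clustering processes reads longest-first (ties
   by id), each read joining the best existing OTU seed at ≥ 0.97 or founding
   a new OTU. The seed read is the OTU representative.
5. **Rare-OTU removal** (`remove_rare_otus`): OTUs with fewer than 3 reads
   (singletons and doubletons) are removed as probable sequencing errors.
6. **Phylogenetic validation** (`template_align`, `nj_tree`, `root_tree`,
   `family_clade`, `assign_species_by_clade`): one representative per OTU is
   threaded into the master reference alignment, a neighbor-joining tree is
   built from Jukes–Cantor distances, rooted on the bolidophytes, internal
   edges shorter than half a substitution's worth of distance are collapsed
   into polytomies (species calls should not hinge on noise-resolved
   splits), and the smallest clade containing all family references is
   extracted. An OTU inside that clade is assigned to species S when its
   smallest enclosing clade containing any reference contains only
   references of S; a label backed by several references additionally
   delimits its clade by those references' own MRCA, so material attaching
   outside it (sister to the whole species group) is not absorbed. An OTU
   inside the family clade but not resolvable to one species is
   *family-unplaced* (a candidate new taxon); outside the clade it is a
   putative false positive, confirmed by a nearest-reference identity check
   and removed.

   Topology alone cannot separate a divergent novel lineage from
   error-derived material in ambiguous positions, so `run_screen` adds a
   divergence gate (`min_novel_divergence`, default 0.06): a
   *family-unplaced* verdict stands only for OTUs at least 6% diverged from
   their nearest reference — between the sequencing-error scale (about 4% at
   1% error) and the family's interspecies distances — while less divergent
   topologically-ambiguous OTUs take their nearest reference's species.
   Species whose references are practically indistinguishable at the marker
   (*L. danicus* / *L. hargravesii*) are merged into one label via
   `species_merge`, as such surveys report them.
7. **Tables**: per-sample species counts, proportions of each sample's total
   reads, per-site mean relative frequencies (surface cDNA samples by
   default, averaged over size fractions), and presence/absence.

The stage-by-stage read and OTU counts form the funnel report — the
pipeline's canonical summary, mirroring the count tables such screens
publish.

## Alignment and identity

All decisions rest on one primitive: global pairwise alignment
(Needleman–Wunsch with affine gaps, Gotoh's three-state recursion) under
match +5, mismatch −4, gap open −10, gap extend −1 (a gap of length $k$ costs
$-10 - k$). Traceback ties resolve deterministically: diagonal, then up, then
left. **Identity** is matches divided by alignment columns *after stripping
the terminal-gap run at each end*, so a short tag inside a longer reference
is not penalised for length; the alternative convention of greedy clustering
tools (matches over the shorter sequence length) is available via
`denom = "shorter"`. `N` matches nothing, including itself.

Two exact shortcuts keep the batch operations fast without changing any
result:

* for equal-length pairs at Hamming distance $h \le (5 - 2(-10-1))/9 = 3$,
  no gapped alignment can outscore the diagonal, so identity is exactly
  $(L-h)/L$;
* for equal-length pairs in general, the diagonal score bounds the optimum
  from below, which confines every optimal path to a band of half-width
  $\lfloor (9h - 20)/7 \rfloor + 1$ around the diagonal; the banded DP is
  therefore *provably identical* to the full DP, at a fraction of the cost.

Both are verified in the test suite against an exhaustive enumeration of
alignment paths (short pairs) and an independent aligner
(`Biostrings::pairwiseAlignment`, longer pairs).

## Statistics

* **Differential tag counts** (`ac_pmf`, `ac_test`): the exact conditional
  distribution of a tag's count $y$ in a library of $N_2$ reads given $x$
  counts in a library of $N_1$ reads,
  $p(y \mid x) = (N_2/N_1)^y \, (x+y)! \, / \, (x! \, y! \, (1+N_2/N_1)^{x+y+1})$,
  computed in log space (it is the negative binomial with size $x+1$ and
  probability $N_1/(N_1+N_2)$, which the tests exploit as an independent
  check). The expected range is the equal-tail interval at $\alpha = 0.05$;
  the two-sided p-value doubles the smaller tail, capped at 1. The cited
  statistic is one-sided; the equal-tail two-sided form matches the use of
  "expected ranges" and is symmetric under swapping the libraries. No
  multiple-testing correction is applied by default (none was applied in the
  screen this reproduces); `p.adjust` can be applied to the output.
* **Rarefaction** (`rarefaction`): the hypergeometric closed form
  $E[S(n)] = \sum_i (1 - \binom{N-N_i}{n}/\binom{N}{n})$, delegated to
  `vegan::rarefy` and cross-checked against Monte-Carlo subsampling.
* **OTU sharing** (`venn_sharing`, `pairwise_sharing`): exclusive region
  counts for 2–4 sites; more sites fall back to the pairwise matrix.
* **Furthest-neighbor OTUs** (`furthest_neighbor_cluster`): distances
  $1 - \text{identity}$ rounded to 1/1000, complete-linkage agglomeration
  (`hclust`), partitions nested across cut-offs.
* **Phylogenetic signal** (`random_tree_g1`): the $g_1$ skewness
  (standardised third central moment) of the parsimony tree-length
  distribution over uniform random labelled topologies
  (`ape::rtopology`; Fitch lengths via `phangorn::fitch`). Left skew
  indicates tree-like structure; critical values for 4-state data are the
  caller's to supply.

## The synthetic-data generator

`simulate_study()` emulates the structure of a six-site European coastal
survey at desk scale:

* **Reference panel** (`make_reference_panel`): one ancestor sequence;
  family species mutated at mutually disjoint positions so pairwise
  divergences are exact by construction (identities 0.93–0.99); with ≥ 5
  species, the fifth is built as a close sister (~1.5% divergence) of the
  first, mirroring the *L. danicus* / *L. hargravesii* pair; outgroup diatoms
  at 0.80–0.90 to the family; two bolidophyte-like far outgroups below 0.80,
  built as a cherry so rooting is well-defined. The panel carries no indels,
  so it doubles as its own master alignment (query indels still exercise the
  template threading).
* **Communities**: a dominant species and log-spread minor species; fixed
  absences (the fourth species missing from the two Mediterranean-style
  sites, the fifth from the Black-Sea-style site), emulating widespread but
  not ubiquitous species; a **novel clade** — the close pair's common stem
  mutated by 29 substitutions + 7 indels (V4) or the length-scaled 8 + 2
  (V9), landing just above the 0.90 capture boundary and resolving below the
  pair's cherry — planted at one site only, providing a rare-taxon detection
  case with the geometry of a divergent sister lineage.
* **Reads**: per-base substitution errors (default 1%); 1% two-parent
  chimeras joined at a uniform breakpoint; 5% off-target reads drawn from
  the outgroup diatoms *and* the far outgroups, so both the taxon filter and
  the capture stage see true negatives; optionally one planted singleton and
  one doubleton error-variant OTU per present species and sample, giving the
  rare-OTU filter known true positives. Platform-specific error profiles
  (454 homopolymers, quality decay) and PCR bias are *not* modelled.
* **Ground truth**: every read's origin (species, chimera with parents, or
  off-target source), the true species × sample presence matrix, and the
  true OTU grouping.

Everything is a pure function of (config, design, seed); generation twice
with one seed is byte-identical.

What passing tests on these data do and do not show: they demonstrate that
the funnel's logic — capture, refinement, rare-read removal, clade-based
validation — recovers a known community exactly under a realistic error
model, and that the novel-clade machinery isolates divergent material. They
do not demonstrate robustness to platform-specific artefacts, intragenomic
rDNA variation, or alignment ambiguity in real hypervariable regions, none
of which the generator emulates.

## Problem sizes and numerical choices

The survey-scale simulation used by the acceptance checks runs the V9-length
region (130 bp) at 10⁴ reads per site across 6 sites with 1% error — the
shorter of the two real amplicons, matched by a length-scaled novel clade
(8 substitutions + 2 indels from the species-pair stem, i.e. ~0.91 identity
to its nearest reference — the same just-above-capture margin as 29 + 7 on
390 bp), with the *L. danicus*/*L. hargravesii* pair reported as one merged
label. At this amplicon length, 1% error genuinely fragments OTUs (each
read is within 3 substitutions of an OTU seed or founds its own), which is
why such surveys report hundreds of V9 OTUs for a handful of species; the
rare-OTU filter and the validation stage absorb the fragmentation. Tie detection rounds identities to 4 decimals (equal-scoring
alignments must compare equal); the consensus confidence threshold is
inclusive (≥ 0.80); ties in the database-mining doubt check resolve to
discard (conservative); the mining retention floor for a query is computed
over *all* family references, not only those among the returned hits (the
alternative reading is possible; this one is stable and reproducible).
Negative neighbor-joining branch lengths are clamped to zero with the
deficit shifted to the adjacent edges, preserving path lengths. Identity
denominators, scoring, thresholds and breakpoints are all exposed as
arguments with the defaults above.

## Known limitations

* Tree inference is neighbor joining over Jukes–Cantor distances, not
  maximum likelihood: the validation rules consume only clade membership,
  for which NJ on desk-scale panels is adequate, but deep-branch support
  should not be over-interpreted. Bootstrap support (`bootstrap_support`)
  uses column-resampling NJ replicates.
* Species whose references are indistinguishable at a region must be merged
  upstream (`species_merge`) — the package reports, it does not adjudicate.
* The chimera screen is reference-based only and conservative for
  closely-related parents (see above).
* Greedy capture enforces no alignment-coverage constraints; with the
  terminal-gap-trimmed identity, a long perfect overlap could in principle
  capture a partial read. Amplicon datasets of near-constant length make
  this a non-issue, but data with wildly varying read lengths should use
  `denom = "shorter"`.
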