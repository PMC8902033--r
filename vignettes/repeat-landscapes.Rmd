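---
title: "Characterizing repeat landscapes and assembly collapse with repeatscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing repeat landscapes and assembly collapse with repeatscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatscape)
```

## The problem

In repeat-rich plant genomes, tandem satellites, rDNA arrays, telomeric
repeats and LTR retrotransposons make up a third to four fifths of the
DNA. Because assemblers struggle to resolve long arrays of near-identical
units, tandem repeats are systematically *collapsed* in draft assemblies:
the assembly contains far fewer copies than the genome. repeatscape
implements a survey workflow that (i) discovers repeat families directly
from a low-pass read sample, without an assembly, and (ii) quantifies
collapse by comparing two independent copy-number estimates for each
family — one from the assembly, one from raw reads.

## The copy-number model

The central statistic, for a repeat represented by a contig of length
$L_c$, is

$$\widehat{C} \;=\; \frac{\text{total aligned length}}{L_c},$$

where the total aligned length sums aligned bases over all local
alignment hits passing *strict* identity > 0.7 and coverage > 0.7
filters.

* **Assembly route** (`assembly_copy_number()`): the contig is aligned to
  every assembly sequence; each passing hit contributes its aligned query
  length. Coverage is per hit (aligned query length over contig length).
* **Read route** (`read_copy_number()`): every read of a sample
  subsampled to exactly 1× genome coverage (`reads_for_1x()` gives the
  count) is aligned to the contig. At 1× the expected read depth over
  every genomic copy of the contig is 1, so the summed aligned bases
  estimate the family's genomic extent and $\widehat{C}$ its copy
  number — with no assembly in the loop.

The read/assembly ratio (`fold_change()`, reported to one decimal) is
the collapse signal: ≈ 1 for faithfully assembled families and ≫ 1 when
copies are missing from the assembly.

### Read-level coverage, and why it is not per-hit

For reads longer than a tandem monomer, a read almost never aligns to
the monomer contig in one piece: a 150-bp read wrapping a 140-bp monomer
boundary splits into two diagonal pieces, each below a 70% per-hit
coverage bound. A per-hit rule would discard ~44% of genuine satellite
reads and ruin the estimator's consistency. The read route therefore
applies identity per hit but coverage per *read* — the union of a read's
identity-passing aligned intervals must exceed 70% of its length — the
same convention as BLAST's query-coverage-per-subject.

### Overlap handling (`merge_overlaps`)

By default, overlapping hits each count in full — a literal transcription
of the total-aligned-length formula. Two situations make the literal sum
a biased estimator, and both are handled by the interval-union semantics
behind `merge_overlaps = TRUE`:

* a query spanning several monomers of a tandem array produces
  period-shifted, mutually overlapping hits (a two-monomer query roughly
  doubles the assembly-side sum);
* reads lying inside one of a retroelement's two identical terminal
  repeats align at both terminal-repeat positions and are counted twice
  (≈ +7% for a 5-kb element with 300-bp termini), and on highly periodic
  contigs (telomere motif) every read hits dozens of diagonals.

Under union semantics each identity-passing hit is additionally extended
to its full diagonal span *within the contig* before the union, so the
mismatch columns that the run scoring trims at hit ends are counted as
alignment columns; the extension can never cross contig bounds, so reads
only partially overlapping an array are not inflated. Parameter-recovery
checks and the acceptance script use union semantics; every estimate
records which was used.

## The alignment engine

Because the simulators mutate by substitution only, true homologies are
gapless and lie on single diagonals. A hit is the maximum-scoring run
(match +1, mismatch −2; first-encountered maximum on ties) on a
diagonal; at most one hit per (strand, diagonal) can pass a >50%
coverage filter, so one best run per diagonal is lossless. Candidate
diagonals come from exact shared 12-mers. Correctness is *defined* by
equivalence with an all-diagonals scan, and the test suite checks the
filtered hit sets against an independent R implementation of that
exhaustive oracle on 200 randomized planted-copy instances (0.6–9.5 kb;
planted divergence ≤ 0.15 so every true hit contains an exact seed). The
−2 mismatch penalty makes a run's score positive only above 2/3
identity, comfortably below the 0.7 filter, while trimming chance
micro-matches; per-hit length floors (30 bp for contig-vs-assembly,
20 bp — just above the seed — for read mapping) suppress the remainder.
A 40% diverged query yields no passing hits; note that a 25% diverged
copy still passes, as ~75% identity sits above the 70% filter.

## Read clustering

An edge joins two reads when some ungapped alignment in either
orientation reaches identity ≥ 0.8 over ≥ 0.55 of the shorter read;
repeat clusters are connected components with ≥ 10 members, and a
cluster's genome proportion is its share of all sampled reads. Two
points deserve note:

* The identity and length-fraction are *separate* knobs. A single
  shared-k-mer-fraction threshold cannot express "high identity over a
  length fraction": at the default 5% per-copy divergence two
  same-family reads share only ~20% of 15-mers despite ~90% pairwise
  identity, while two exactly identical reads overlapping by a mere
  30 bp share the same fraction. The alignment edge rule separates the
  two axes; the exploratory shared-k-mer kernel is still available as
  `read_similarity()`.
* Candidate pairs are restricted to pairs sharing at least one exact
  canonical k-mer (k = 11) via an inverted index. This prefilter is
  lossless — any pair with positive similarity shares a k-mer — so the
  restriction is a pure acceleration, and clustering is deterministic
  and seed-free.

The identity floor of 0.8 tolerates the default 5% planted divergence
doubled across two copies (expected pairwise identity ~0.90); the 0.55
length fraction keeps short incidental genomic overlaps between
single-copy reads from percolating into spurious clusters at survey
sampling depths.

## Representative contigs

Each cluster is assembled greedily: the seed is the member with the
highest degree in the similarity graph; the contig extends at both ends
through overlapping members (≥ 40 bp at ≥ 0.8 identity) and is polished
by per-column plurality vote (alphabetical tie-break). Repeat structure
makes three safeguards necessary, all deterministic:

* **Fork-aware extension.** At the outer edge of a terminal repeat the
  candidate overhangs split between per-copy genomic flanks (mutually
  different) and the body context carried over from the element's twin
  terminal repeat. An end is closed when no candidate agrees with more
  than 60% of the others over the adjacent 20 bp, so contigs stop at
  element boundaries instead of assembling chimeras.
* **End completion.** Reads from the second terminal repeat are absorbed
  as "interior" by the first copy of the repeat inside the growing
  contig; a completion pass re-uses all members (capped at +400 bp per
  end) so truncated termini are finished.
* **Support trimming and containment.** Polish trims contig ends whose
  column support falls below max(2, 10% of the median support) —
  private flank sequence of a single genomic copy; candidates whose
  polished sequence is ≥ 75% contained in a longer candidate are
  dropped. The survivor with the highest mean read depth (ties: longer,
  then lexicographic id) is returned. Without containment, a
  terminal-repeat-only fragment — twice the depth of the element body,
  since elements carry two termini — would win the depth rule.

## Annotation

Classification precedence is telomeric (≥ 10 consecutive exact
`TTTAGGG` units, either strand) > reference-library match > tandem
periodicity (`Simple/Sat`) > terminal-repeat structure (`LTR_like`) >
`Unknown`. Periodicity must outrank terminal repeats because a tandem
array trivially matches its own ends. Periodicity is the smallest
self-alignment offset $p \le L/2$ agreeing at ≥ 0.8 identity over the
whole shifted overlap. The terminal-repeat detector reports the
*score-maximal* (match +1 / mismatch −2) qualifying prefix–suffix match
of ≥ 100 bp at ≥ 0.8 identity: a longest-qualifying rule would drift
~25% past the true boundary, because appending random flank to an exact
300-bp terminal repeat keeps mean identity above 0.8 out to ~375 bp,
whereas the score maximum sits exactly at the planted length. Library
entries whose id contains `rdna` or `telo` map to their own labels; a
small synthetic fixture library ships in `inst/extdata/`.

## Distribution classes

Hits are binned into fixed windows (default 10 kb; 2 kb on the ~2-Mb
test genomes — the window should be small relative to `span_fraction`
times the genome). A repeat is **non-dispersed** when ≥ 50% of its
aligned bases lie in the greedy, descending-signal set of windows
jointly covering ≤ 1% of the genome (both comparisons inclusive);
**terminal enrichment** asks whether ≥ 50% of aligned bases fall within
50 kb of a chromosome end (computed from the hits, not the window
grid); **colocalization** is the Jaccard index of two repeats' enriched
window sets. The 50%-in-1% rule is this package's quantitative stand-in
for what is usually an eyeball call on alignment dot-plots; both
parameters are exposed and recorded. It entails a design constraint:
a family can only be called non-dispersed if its loci are small relative
to the genome, so the bundled distribution test genome plants tandem
loci below 1% of the genome each.

## Comparative typing

Read-based abundance replaces cytological signal: a family is present
in an accession when its 1× read estimate reaches 10 copies (inclusive;
detectability by hybridization implies many copies). Patterns across an
outgroup + reference + ≥ 2 ingroup accessions are typed with precedence
type1 (present everywhere) > type2 (all ingroup, not outgroup) > type3
(a proper nonempty ingroup subset, outgroup free) > type4 (absent
everywhere except possibly the reference) > other, a total and
deterministic function of the presence row.

## The synthetic-genome module

`build_genome()` plants families of four kinds — tandem satellite
(140-bp monomer default), rDNA-like array (3-kb unit), telomeric array
(`TTTAGGG`), dispersed LTR-like element (5 kb with 300-bp identical
termini) — into i.i.d. random background (GC 0.44, a typical grass
value), recording every copy in a BED-compatible 0-based half-open
ground-truth table. Divergence is substitution-only (expected per-base
rate per copy), so planted copy lengths are exact and the copy-number
oracle is unambiguous; dispersed copies are placed without overlap by
rejection sampling, on either strand with probability 1/2; tandem
copies are head-to-tail on the forward strand. Intra-family divergence
defaults to 5% — a modelling choice in the range typical of active
repeat families, exposed as a parameter — except telomeric arrays,
which default to 0 because telomerase synthesizes essentially identical
units (and mutated units would, correctly, stop looking like telomere
motif runs). `collapse_assembly()` keeps the first ⌈copies/factor⌉
copies of each tandem locus and splices out the rest, remapping all
coordinates; factor 1 is the identity.

What the generator does **not** model: indels (so real-data alignments
would be gapped, and the ungapped engine is a simulator-matched choice,
not a general-purpose aligner), nested or fragmented element
insertions, segmental duplication, sequencing-quality structure, or any
actual crop sequence content. Passing parameter-recovery tests
therefore demonstrates the statistical machinery, not robustness to
every artifact of real survey data.

## Problem sizes and determinism

The standard study conditions (`example_genome_spec()`) are a 2-Mb
genome (4 × 500 kb): satellite ×1000 (7% of the genome), rDNA ×50
(7.5%), telomeric arrays (1.1%), dispersed element ×100 (25%) — about
41% repetitive, surveyed at 1× (13,333 reads of 150 bp, substitution
error 0.001 emulating quality-filtered short reads) with 5,000-read
samples for clustering. Recovery is checked over 10 replicate genomes
(5 in the acceptance script), fold change over 5; these sizes keep a
full run in minutes on one CPU while leaving per-seed Poisson noise
(~3% for the satellite) well inside the tolerances being asserted.
Every stochastic step takes an explicit seed; clustering and assembly
are seed-free and deterministic; `run_pipeline()` reruns are
byte-identical (manifest md5).

## Limitations

* The ungapped alignment model is exact for the simulator but
  approximate for real reads with indels; the engine is factored so a
  gapped aligner can replace it behind the same hit schema.
* Copy numbers are expressed in units of the query contig: a
  two-monomer satellite contig halves the count and (unmerged) doubles
  the assembly-side sum. Comparisons are meaningful per contig, as in
  any total-aligned-length survey.
* The dispersed/non-dispersed rule depends on window size and genome
  size; defaults target multi-hundred-kb to multi-Mb toy genomes and
  should be re-scaled for real chromosomes.
* Representative-contig assembly resolves the classic LTR boundary
  ambiguity heuristically; on adversarial inputs a rotated (circularly
  permuted) element consensus can still emerge, which annotation
  usually, but not provably, still recognizes via its duplicated ends.
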