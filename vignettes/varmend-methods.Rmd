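---
title: "Methods: tiered prioritization, trio inheritance filtering, and star-allele calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered prioritization, trio inheritance filtering, and star-allele calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varmend)
library(dplyr)
```

varmend interprets jointly called variant data for Mendelian disease risk
and drug response. This vignette is the package's own account of the four
models it implements — the two-track tiering scheme, the trio inheritance
HMM, the candidate-discovery modes, and the star-allele caller — together
with the assumptions, tunable parameters, numerical choices, and known
limitations of each.

## Data model and missing-data semantics

All functions speak tibbles. A VCF becomes a long "calls" table (one row per
biallelic variant × sample) with integer allele codes, where multiallelic
records are split per alternate allele (`0` reference, `1` the record's own
alternate, `2` any other alternate of the original record — a marker that
preserves the per-sample allele multiset across the split). Genotypes are
classified `CALLED`, `NO_CALL`, or `LOW_CONFIDENCE`; the thresholds (depth
< 10 or genotype quality < 20 by default) are configuration, since callers
differ in what "confidently genotyped" means, and a low-confidence genotype
is never treated as called by trio logic or haplotype construction.

Absence is not zero, anywhere. A variant missing from a frequency survey has
an unknown frequency; a missing conservation score is no evidence of
conservation; a missing pathogenicity prediction casts no vote. The only
asymmetry is deliberate: a variant absent from *every* survey is treated as
rare, because "never observed" is the strongest rarity statement a survey
can make.

Coordinates are 1-based inclusive in VCF space and 0-based half-open in all
internal interval arithmetic (BED convention), converted only at the I/O
boundary. Variant keys are normalized — shared suffix then prefix trimmed,
position advanced per leading base removed — so that annotation, catalog,
and star-allele lookups are exact string matches on
`chrom:pos:ref:alt`.

## Two-track, four-tier prioritization

Variants are prioritized separately along two tracks, and the union of tiers
1–3 of both tracks is the review set.

**Reported track** (variants present in a disease-mutation catalog): tier 1,
loss of function — splice-dinucleotide, nonsense, nonstop, frameshift, and
large (≥ 50 bp by default) coding indels; tier 2, rare variants regardless
of functional class; tier 3, missense and non-frameshift indels regardless
of frequency; tier 4, the remainder. Frequency filters are deliberately not
applied to tiers 1 and 3: well-known pathogenic alleles can be common, and
filtering them out would defeat the catalog's purpose.

**Novel track** (absent from the catalog): only rare variants in
monogenic-disease genes are eligible at all; within those, tier 1 is loss of
function, tier 2 is missense with conservation consensus (GERP++ > 2 *and*
rescaled PhyloP > 0.95, both strict as printed, both required, absence
failing) or any non-frameshift indel, tier 3 is missense with a
pathogenicity consensus of at least three of four algorithm calls (SIFT
"Damaging"; LRT "Deleterious"; PolyPhen2 "Probably/Possibly damaging";
MutationTaster "Disease causing (automatic)"), and tier 4 the remainder.

Open design points we settled: tiers are evaluated in numeric order with
first match winning (the only reading consistent with a tier 4 defined as
"not meeting criteria for tiers 1–3"); rarity means at or below the 1%
threshold in **every** survey with data, since a single common-population
observation refutes rarity, and an all-absent profile is rare; the novel
track requires monogenic-gene membership while the reported track trusts
catalog membership alone; the large-indel size is not defined by any
published criterion we implement, so it is a visible parameter
(`threshold_large`, default 50 bp). The rescaled PhyloP column is treated as
an opaque score compared against 0.95. Every assignment carries a
machine-readable rationale string for audit.

Downstream, the local-cohort filter removes retained variants whose
frequency in the local sequencing environment is ≥ 25% (platform-specific
artifacts and population structure inflate local frequency long before
public surveys catch up); absent local frequency retains the variant. The
gene-set restriction accepts any user list and drops Y-chromosome genes for
female samples.

## The trio inheritance HMM

Each site where father, mother, and child are all confidently called (SNVs
only by default — indel inheritance-error rates are too caller-dependent; a
switch exists) is encoded as one of three symbols with precedence
MIA > ALLHET > CONSISTENT:

* **MIA** — no assignment of one allele from each parent reproduces the
  child genotype (Mendelian inheritance abnormality);
* **ALLHET** — all three members heterozygous, the signature of reference
  compression (a collapsed repeat makes every sample look heterozygous);
  the configuration is Mendelian-consistent, which is exactly why it needs
  its own symbol;
* **CONSISTENT** — everything else.

Three hidden states — `GOOD`, `COMPRESSION`, `MIA_RICH` — generate these
symbols. The published description names the states but not the observation
model or any probabilities, so the emission table, expected tract lengths,
and stationary weights here are package defaults, chosen once on these
grounds and exposed in `hmm_params()`:

| state | CONSISTENT | MIA | ALLHET | tract length |
|---|---|---|---|---|
| GOOD | 0.989 | 0.001 | 0.010 | 10 Mb |
| COMPRESSION | 0.40 | 0.10 | 0.50 | 100 kb |
| MIA_RICH | 0.55 | 0.40 | 0.05 | 100 kb |

The MIA rate in good data sits at the scale of sequencing error (true de
novo events are orders of magnitude rarer per site); compression tracts are
dominated by universal heterozygosity; artifact tracts are short relative
to the genome (stationary weights 0.98/0.01/0.01).

Transitions are distance-scaled: over a gap of $d$ bp the probability of
staying in state $s$ is $e^{-d/L_s}$, and the leave probability is split
between the other two states in proportion to their stationary weights. A
zero gap gives the identity matrix; as $d \to \infty$ rows forget the
current state. This is what makes the same parameters usable on sparse
capture data and dense WGS: the model pays per base pair, not per marker.

Decoding is exact Viterbi in log space (ties broken toward `GOOD`, then the
lower state index, keeping the filter conservative); posterior
probabilities from forward–backward are available on request
(`posterior = TRUE`). The path is collapsed into maximal segments with
boundaries at midpoints between adjacent observed sites; chromosome ends
extend only to the first/last observation, because the model has no
information beyond them. Segment labels are written back into the VCF
FILTER field as *soft* labels — records are annotated, never dropped. The Y
chromosome never contributes observations; X contributes only for female
children, and an unknown child sex is handled like male (the conservative
choice, since hemizygous male X calls follow no diploid transmission
model).

## Trio candidate modes

Five discovery modes run downstream of the HMM; modes 1–4 only report sites
in decoded good-data segments (sites on contigs without observations count
as good — the filter removes positively identified artifact, it does not
demand coverage):

1. **De novo** — both parents confidently homozygous-reference, child
   confidently heterozygous. Strict mode (default) rejects any parental
   low-confidence call; a lenient flag tolerates them.
2. **Compound heterozygous** — per gene, all unordered pairs of
   child-heterozygous variants with at least one rare member. Phase is
   inferred from transmission alone: an alternate allele is *transmissible
   from* a parent only if some one-allele-from-each-parent assignment gives
   the child its genotype with that parent donating the alternate. Pairs
   forced onto opposite parents are `TRANS_CONFIRMED`; pairs forced onto the
   same single parent are provably cis and excluded; everything else
   (including de novo members) is reported `PHASE_UNKNOWN` rather than
   dropped, with the status flag left to downstream triage.
3. **Rare homozygous** — child confidently hom-alt, variant rare, both
   parents carriers (a hom-alt child with a non-carrier parent is an MIA,
   handled by the other channels).
4. **Hemizygous** — child apparently hom-alt with exactly one carrier
   parent *and* an overlapping deletion interval (from `<DEL>` records or a
   BED). The deletion list is not lineage-resolved, so any overlap
   qualifies and calls are flagged putative; without deletion support the
   site stays in the MIA channel. These are loss-of-function candidates.
5. **Dominant with reduced penetrance** — rare child-carried variants in a
   curated inherited-disease gene set. No segregation requirement and no
   region restriction: penetrance is assumed reduced, so an unaffected
   carrier parent is expected, and the mode screens a gene list rather than
   genome-wide inheritance patterns.

## Star-allele diplotypes and drug-response annotation

Pharmacogene haplotypes are assigned without molecular phase. For each gene,
the definition table (long TSV: `gene allele chrom pos ref alt`, reference
allele `*1` implicit) fixes a universe of defining positions. Construction
proceeds in three steps: (1) the *skeleton* pair carries the shared
nucleotide at every confidently homozygous position, leaves heterozygous
positions open, and marks uncovered/uncalled/low-confidence positions
unknown on both haplotypes; (2) heterozygous positions are expanded into all
complementary assignments — exactly $\max(1, 2^{h-1})$ unordered pairs for
$h$ heterozygous positions, the first being pinned to one haplotype to kill
mirror duplicates, with a refusal above $h = 12$ (such calls belong to a
human curator, and the cap keeps the tool's predictions high-confidence);
(3) a perfect-match search compares each haplotype against the definitions:
fully known haplotypes must match exactly, haplotypes with unknowns yield
the *set* of alleles identical at all known positions — tag variants are
not disambiguated. One candidate pair is `RESOLVED`; several are
`AMBIGUOUS` and all are reported; none is `UNASSIGNED`, with the raw
haplotype pairs returned instead.

A subtlety worth stating: ambiguity is not only caused by missing data. A
fully called genotype heterozygous at several defining positions can have
more than one recombination that perfect-matches a defined pair; the caller
then reports all of them, by design. Unique resolution is guaranteed only
when the definitions are structurally identifiable — for example when
alleles own pairwise disjoint defining-position sets, the construction
`make_star_fixture(disjoint = TRUE)` uses for its uniqueness checks.

Copy-number alleles (e.g. whole-gene duplications) are out of scope and a
declared limitation. Single-variant drug-response annotation is a keyed
join against a knowledge-base table filtered by an ordered evidence scale
(1A strongest … 4 weakest); only alternate-allele carriers are annotated,
and unknown level strings are skipped with a warning.

## Synthetic data: what it emulates, what it does not

`simulate_trio()` generates the study conditions the package is validated
under: two autosomes of planted state segments (by default 400-site
good-data stretches around one 80-site compression and one 80-site MIA-rich
tract, mean marker spacing 3 kb), per-site trio genotypes drawn so each
site's symbol follows its segment's emission row (the same defaults the
decoder uses), planted candidate events of all five modes in good-data
segment interiors, de-novo-patterned artifact sites inside the MIA-rich
tract, a survey-frequency table (planted events rare at 0.1%, background
common at 5–50% or absent at rate 5%), a 100-kb gene tiling, and deletion
intervals under hemizygous events. Events are planted at least five sites
from any planted state change because segment boundaries are only estimable
to within about one marker spacing; the truth manifest plus these margins
fully determine the expected candidate output. Background good-region MIAs
deliberately avoid the de novo and hemizygosity genotype patterns so the
manifest stays sufficient. Every generator is a pure function of its seed,
with separated streams per generator so adding one never perturbs another.

What the simulation does **not** model: linkage disequilibrium, read-level
error processes, indel-specific error modes, population structure in the
frequency assignments, or sex chromosomes in the trio (the toy gene model
carries an X, the trio plan does not). Passing tests therefore demonstrate
algorithmic correctness against the stated model — exact Viterbi, exact
tier logic, exhaustive-match star calling — not calibration of the default
HMM parameters on real sequencing artifacts, which users should revisit per
platform.

Problem sizes used by the validation suite and `scripts/acceptance.R`:
Viterbi-versus-enumeration on 200 instances of up to 8 sites (3^8 paths);
segment recovery over 100 simulated trios of 570 sites (tracts of 60 sites,
well above the 50-site design floor); tiering against an independently
coded decision table on 10,000 randomized annotated variants plus an
exhaustive 1,152-combination predicate grid; candidate recall over three
full simulations; 500 random star fixtures for the truth-in-set guarantee.
These finish in a couple of minutes on one CPU while exercising every
branch the models have.

## Numerical and degenerate-input choices

Log-space dynamic programming throughout; emission and stationary
probabilities are validated to lie strictly in (0,1) so logs are finite.
Viterbi ties resolve toward `GOOD` (first-maximum). Empty chromosomes
decode to empty segment lists; an empty VCF prioritizes to an empty table
with exit status 0; empty interval sets yield empty reports. `ref == alt`
is rejected as a non-variant. Row-stochasticity of every transition matrix
holds to 1e-12 and is asserted in tests. The gene-level effect class is the
most severe across transcripts under a fixed total severity order, making
it invariant to transcript ordering.

## Known limitations

Effect classification needs a sequence-backed gene model (provided for the
toy genome; the file-driven `run_prioritize()` entry point tiers on catalog
membership and frequency alone when no model is supplied). True left
alignment against a reference genome is out of scope — normalization trims
representations, which is exact for the fixtures and typical caller output
but will not reconcile representations that differ by placement within a
homopolymer. Quartet-style full inheritance-state phasing, recombination
mapping, cohort burden statistics, and CYP2D6 structural genotyping are out
of scope.
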