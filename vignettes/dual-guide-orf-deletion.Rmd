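---
title: "Designing dual-gRNA whole-ORF deletions with dgRNAdesign"
author: "dgRNAdesign authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing dual-gRNA whole-ORF deletions with dgRNAdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(dgRNAdesign))
```

# The problem

RNAi knockdown leaves residual protein, and point-mutant CRISPR alleles can
be bypassed by reinitiation or alternative splicing. A more decisive
reagent is a *pair* of SpCas9 guides that excises the entire open-reading
frame: one guide cutting in the first coding exon near the start codon, a
second cutting in the exon containing the stop codon. Re-ligation of the
flanks removes essentially all coding sequence, and the short junction
product gives a clean, size-diagnostic PCR readout. Building such pairs at
library scale (a hundred genes or more) raises design constraints that a
per-gene web-tool session does not capture well:

* **Isoform structure.** Genes with alternative splice forms have several
  annotated start and stop codons; deleting "the" ORF means anchoring at
  the most 5' start codon and the most 3' stop codon over *all* isoforms.
* **Nested and overlapping genes.** In compact genomes, other genes'
  coding sequence frequently sits inside introns of the target (or
  overlaps its exons). Cut sites must not disrupt a neighbour's CDS, which
  can force the first guide several exons downstream.
* **Strain backgrounds.** The reagents are used in cell lines and fly
  stocks whose genomes differ from the reference by hundreds of thousands
  of SNPs and indels. A guide that spans a background variant may simply
  not cut in that background; since a single construct must serve many
  backgrounds, a candidate overlapping a variant in *any* catalogued
  background is rejected outright.
* **Specificity.** Mismatches in the 12-nt PAM-proximal *seed* are the
  main determinant of (non-)cutting at off-target sites; the screen must
  enumerate candidate off-targets exactly, with no heuristic misses.

`dgRNAdesign` implements this whole procedure as a reproducible pipeline:
annotation-aware region selection, PAM scanning, three-way screening
(variants, off-targets, efficiency), pair ranking with alternates, cloning
oligo emission, and in-silico diagnostic PCR - plus a deterministic
synthetic-fixture generator that makes the entire pipeline testable
without any external downloads.

# The procedure and its assumptions

## Target regions

For a gene model (one or more CDS chains), the two anchors are the most 5'
start-codon base and the most 3' stop-codon base over all chains. The
START window begins at the start-codon anchor and extends ~100 bp (default
`windowLength = 100`) into the ORF; the STOP window ends at the stop-codon
anchor and extends ~100 bp back toward the ORF interior. Both are clipped
to their exon, and exons shorter than `minWindow = 30` bp are skipped as
offering too few PAM opportunities.

The published descriptions of this style of design say only that regions
lie "around" the codons; anchoring the windows *at* the codons and
extending them into the ORF is this package's documented choice. It
maximises the deleted coding fraction while keeping both cuts inside
coding sequence, and it makes window placement a deterministic function of
the annotation.

When a default window overlaps any CDS base of a *different* gene, the
window slides 1 bp at a time toward the ORF interior, moving exon by exon
along the same transcript until a clean placement exists; the result is
flagged `shifted` with an audit note. Sliding never moves outside the gene
or upstream of the anchor: for a gene whose first exons are buried under
nested ORFs this reproduces the observed practice of designing the first
guide on a much later exon. Only foreign *CDS* blocks a window - UTR or
intronic overlap is permitted, since the criterion is that neighbouring
coding sequence must not be disrupted. If no exon admits a clean window of
at least `minWindow` bp, the gene fails with `NoCleanRegion` naming the
blocking genes.

## Guide discovery

Within each region every 20-nt protospacer adjacent to an NGG PAM is
enumerated on both strands. The protospacer must lie fully inside the
region; the PAM may overhang the region edge by up to `pamSlack = 3` bp.
Candidates containing N are discarded (unresolved sequence cannot be
matched against backgrounds), and candidates crossing exon-intron
boundaries are *retained*, because Cas9 cuts genomic DNA, not mRNA.

The blunt cut is modelled between protospacer positions 17 and 18, i.e.
3 bp 5' of the PAM. Internally each guide stores `cut_after`, the 1-based
coordinate of the last reference base 5' of the cleaved bond; all deletion
arithmetic follows from the two `cut_after` values.

Cloning follows the single-tube vector-amplification scheme: the forward
oligo is `G` + N19 + the 20-nt scaffold arm `GTTTTAGAGCTAGAAATAGC` (40 nt
in all), the reverse oligo is the invariant `GAAGTATTGAGGAAAACATA`. N19 is
the protospacer minus its 5'-most base; the expression vector supplies the
leading G. Scanning and off-target matching use the full 20-mer; the
emitted spacer is G+N19. This reconciles 20-nt genomic matching with
19-base target bookkeeping, and the audit function accepts both 19- and
20-nt query sequences via the same G+N19 equivalence.

## Screening

Each candidate passes through three screens, always all three (failures
are recorded, not short-circuited, so audits are complete):

1. **Background variants.** A candidate fails if any SNP or indel from any
   labelled background set overlaps its protospacer-plus-PAM footprint
   (23 bp). Overlap - not allele sequence - is the criterion: VCF records
   are reference-stranded, and any variant under the footprint may abolish
   or degrade cutting in that background. Insertions occupy their single
   anchor base for overlap purposes, a deliberately conservative rule: an
   insertion anywhere under the protospacer breaks the match regardless of
   the inserted length.
2. **Off-targets.** An off-target is any site on either strand of any
   chromosome with an admitted PAM (NGG or NAG; the N is a wildcard and
   PAM bases never count as mismatches) whose 20-nt alignment to the
   candidate has at most `maxMMSeed = 0` mismatches in the 12-nt seed and
   at most `maxMMTotal = 3` mismatches overall. Zero predicted off-targets
   is required for a PASS. The original procedure delegated this call to a
   web tool whose exact stringency settings are not recoverable; the
   seed-exact/<=3-mismatch default encodes the stated 12-bp-core logic in
   an explicit, testable form, and all four knobs are configurable. The
   audit function reports counts under a small stringency grid rather than
   asserting any single historical setting.
3. **Efficiency.** Candidates are scored with an additive position-weight
   model rescaled to [0, 10] (sum of per-position base weights, affinely
   mapped using the table's own attainable extremes; a degenerate
   all-equal table maps everything to 5). The shipped default table
   encodes three broad rules of thumb - G favoured and T strongly
   disfavoured immediately 5' of the PAM, a mild penalty for T runs in the
   PAM-proximal half, a small G/C bonus in the seed - and is deliberately
   a placeholder: the prediction tool used in the original workflow is
   external and its formula unpublished, so the scorer is pluggable (any
   complete 4 x 20 matrix). By default `efficiencyFloor = 0`: efficiency
   *ranks* candidates, it does not reject them, mirroring how predicted
   scores were used to choose among already-clean guides.

## Pair design

PASS candidates in each region are ranked by efficiency (descending), then
by fewer variants within 10 bp of the site (a robustness tie-break against
imperfect background catalogues), then by cut coordinate. Pairs are
enumerated over the PASS x PASS grid subject to a minimum cut separation
(`minSeparation = 200` bp - below the smallest deletions such reagent sets
report, which start around 400 bp, while excluding degenerate
overlapping-window pairs). The chosen pair maximises summed efficiency
(ties: START cut, then STOP cut, ascending), and up to `nAlternates = 5`
runner-up pairs are kept: bench reality is that some pairs fail in cells,
and the alternates list supports that retry loop without re-running the
design. "Optimal" is thus a documented, reproducible surrogate for what
was originally an empirical choice among synthesised pairs.

The repair model is perfect blunt re-ligation: the deletion allele is the
reference with `(cut1, cut2]` excised. Real junctions carry small indels,
but for the package's purposes - deletion size bookkeeping and diagnostic
amplicon arithmetic - the blunt model is exactly the arithmetic used to
interpret diagnostic gels, and junction microindels of a few bases do not
change a gel-resolved band call.

## Diagnostic PCR

Primer pairs are mapped by exact match only (both strands, every
chromosome); a primer must map uniquely to be predictive, and orientation
is normalised so predictions are invariant to which primer is labelled
"forward". Product sizes span the 5' end of the forward primer to the 5'
end of the reverse primer inclusive - the standard gel convention - so
that when both primers survive, `wt_size - del_size` equals the deletion
size exactly. Failure modes are reported as statuses
(`AmbiguousPrimer`, `PrimerLost`, `Divergent`, `NoProduct`) rather than
exceptions, so whole primer panels can be audited in one pass.

Products are called detectable up to `maxAmplifiable = 5000` bp, with a
warn tier to 10 kb. When both alleles amplify and the deletion product is
shorter, predictions carry a bias note: in a mixed template the short
junction product tends to outcompete the long wild-type product, so the
frequent absence of a wild-type band from edited samples is expected
behaviour, flagged rather than treated as an inconsistency. Nested designs
(an outer pair re-amplified with an inner pair, used to detect rare
deletion alleles in mosaic material) are checked for strict containment of
the inner amplicon within the outer on both alleles, reporting all four
sizes.

Exact-match mapping is a deliberate simplification: these diagnostics are
presence/size calls on gels, and melting-temperature or
mismatch-tolerance modelling would add parameters without adding anything
the package's outputs test.

# The synthetic fixture generator

`makeBundle(seed, difficulty, ...)` builds, deterministically from a seed,
a complete miniature study: a random genome (default GC 0.43, fly-like),
planted gene models with explicit start/stop codons and GT..AG splice
dinucleotides, two labelled background variant sets (emulating a cell-line
and an injection-stock background - two labels, because the any-background
rejection rule only bites with more than one), and a difficulty-specific
hazard:

* `CLEAN` - no hazards; background variants are kept clear of the target
  regions.
* `NESTED_ORF` - a foreign CDS annotation overlapping the host's first
  coding exon and first intron, forcing the START window onto a later
  exon (the nested-gene topology that occurs in compact genomes).
* `MULTI_ISOFORM` - up to four CDS chains with distinct start/stop codons.
* `SNP_DENSE` - variant density 0.004/bp, the genome-wide rate implied by
  roughly 600,000 SNPs over a ~140 Mb genome, applied around the gene.
* `OFFTARGET_TRAP` - seed-exact near-duplicates of real candidates planted
  in intergenic space (0-2 mismatches, all outside the seed; NGG or NAG).
* `SINGLE_EXON` - a one-exon gene whose CDS may be shorter than the
  minimum cut separation, so the correct outcome may be `NoViablePair`.

At generation time the bundle's ground truth (regions, the optimal pair or
the expected failure, planted primer pairs with their two product sizes)
is computed by *naive* oracles: loop-and-regex implementations of the same
documented rules, independent of the GRanges/Biostrings pipeline -
brute-force window scans over a foreign-CDS mask, substring PAM scans, and
an all-positions mismatch count over raw character vectors
(`bruteForceOfftargets`). The test suite then demands that the real
pipeline reproduce the oracle's answer exactly, across all difficulties.

What the generator does *not* emulate: real exon length and GC
heterogeneity, repeat families (off-target structure in real genomes is
dominated by repeats; here it is dominated by planted traps), linked
variants/haplotypes, structural variation, and annotation errors. Passing
tests therefore demonstrate algorithmic correctness under the documented
rules, not robustness to annotation noise - the tool takes the annotation
as given, including which exon is "first" in each release.

# Numerical and degenerate-input choices

* Coordinates are 1-based closed (the Bioconductor convention) everywhere
  internally; GFF3 and VCF are converted on read, and every report emits
  both 1-based closed and 0-based half-open coordinates. One convention
  internally means no off-by-one drift between modules.
* `cut_after` (last base 5' of the break) makes deletion size a plain
  difference of two integers; the two guides' cuts are ordered before any
  arithmetic, so minus-strand genes need no special cases downstream.
* Ties are broken deterministically at every stage (anchor-exon choice:
  longest then leftmost containing segment; candidate order: cut then
  strand; pair order: efficiency sum, then START cut, then STOP cut).
  Efficiency comparisons are made on values rounded to 9 decimals, so
  summation-order floating-point noise can never flip a tie-break.
  Identical inputs and configuration give byte-identical reports, which
  the acceptance suite verifies by checksum.
* Empty results are values, not errors: a region with no PAM yields an
  empty candidate set, a primer may map nowhere, and per-gene design
  failures (`NoCleanRegion`, `NoViablePair` with the failing stage) are
  classed conditions that batch runs record per gene without aborting.
* The efficiency rescale degenerates gracefully: a constant weight table
  maps all guides to the midpoint 5 rather than dividing by zero.

# Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` size their simulations to run
comfortably on a single CPU: 10 kb fixture genomes for the 1000-bundle
(tests) and 300-bundle (script) design-recovery sweeps, 50 kb genomes for
the off-target oracle comparisons, 20 guides x 23 footprint positions x 3
variant types for the exhaustive variant-flip check, and 200-500 random
templates for amplicon conservation. These sizes are the package's own
choice of desk-scale study conditions; the generator accepts genomes up to
200 kb.

# Limitations

* The efficiency scorer is a ranking heuristic, not a trained activity
  model; treat its absolute values as ordinal.
* Off-target enumeration is mismatch-only (no DNA/RNA bulges) and PAMs are
  restricted to NGG/NAG, per the SpCas9 seed model it implements.
* The blunt-join repair model ignores junction indels; predicted deletion
  band sizes are exact only up to those few bases.
* Primer mapping is exact-match; primers with SNPs under them in a given
  background are outside the model (run the audit against that
  background's VCF instead).
* One gene is designed at a time; double knockouts are two independent
  designs, and single-construct multi-gene optimisation is out of scope.
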