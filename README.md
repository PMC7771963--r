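# dgRNAdesign

Design of **dual-gRNA whole-ORF deletions** for SpCas9: pick one guide in
the first coding exon and one in the stop-codon exon so that the two blunt
cuts excise the complete open-reading frame, screen every candidate
against multiple background genomes' variants and against predicted
off-targets, emit the cloning oligos, and predict the deletion-diagnostic
PCR bands.

The package is written for people building *libraries* of knockout
reagents (one construct per gene, across tens to hundreds of genes) in
compact genomes such as *Drosophila*, where three things bite at scale:
genes have isoforms with different start/stop codons; other genes' coding
sequence sits inside the target's introns; and the fly stocks and cell
lines actually used differ from the reference genome by >10⁵ SNPs/indels,
so a guide designed on the reference may not match any real template.

## The core procedure

For a gene *g* with CDS chains *T₁…Tₙ*:

1. **Anchors.** `start = most 5' start-codon base over all Tᵢ`,
   `stop = most 3' stop-codon base over all Tᵢ`.
2. **Regions.** A ~100 bp START window anchored at `start` extending into
   the ORF, and a ~100 bp STOP window ending at `stop` extending back
   toward the interior, each clipped to its exon. Windows overlapping a
   *different* gene's CDS slide interior-ward, exon by exon, until clean
   (regions are then flagged `shifted`).
3. **Candidates.** All 20-nt protospacers with an NGG PAM, both strands.
   The blunt cut sits between protospacer positions 17|18 (3 bp 5' of the
   PAM): `cut = pamStart − 4` (+ strand) or `pamEnd + 3` (− strand).
4. **Screen.** PASS iff (i) no SNP/indel from *any* labelled background
   VCF overlaps the 23 bp protospacer+PAM footprint, (ii) zero predicted
   off-targets — any NGG/NAG site with ≤ 0 mismatches in the 12-nt
   PAM-proximal seed and ≤ 3 mismatches overall, enumerated exactly — and
   (iii) the position-weight efficiency score (0–10, pluggable table)
   reaches the floor (default 0: efficiency ranks, it does not reject).
5. **Pair.** Over PASS×PASS with cut separation ≥ 200 bp, maximise summed
   efficiency (deterministic tie-breaks); keep 5 runner-up pairs for the
   bench retry loop. Deletion size `= cut₂ − cut₁` under the blunt
   re-ligation model.
6. **Oligos.** Forward `G + N19 + GTTTTAGAGCTAGAAATAGC` (40 nt; N19 = the
   19 PAM-proximal protospacer bases, the vector supplies the leading G);
   reverse `GAAGTATTGAGGAAAACATA` (invariant).
7. **Diagnostics.** Exact-match primer mapping; product size = 5' end of
   forward to 5' end of reverse, inclusive, on the reference and on the
   deletion allele, so `wt − del = deletion size`. Nested (outer/inner)
   plans are checked for strict containment on both alleles, and a
   small-product amplification-bias note explains missing wild-type bands.

Inputs are standard formats: FASTA (assembly), GFF3 (gene/mRNA/CDS),
VCF v4.x (one file per background, labelled), TSV (guide and primer
tables for auditing).

## Worked example

The package ships a deterministic fixture generator, so a complete run
needs no external data. `NESTED_ORF` plants a foreign ORF over the host's
first coding exon — the situation that forces the first guide downstream:

```r
library(dgRNAdesign)

b <- makeBundle(42, "NESTED_ORF", genomeLength = 15000)   # synthetic study
files <- writeBundle(b, "demo")                           # FASTA/GFF3/VCF/TSV

res <- designGenes(files[["genome"]], files[["gff"]],
    c(S2Rplus = unname(files[["vcf_S2Rplus"]]),
      attP40  = unname(files[["vcf_attP40"]])),
    genes = "gene01")
res$designs$gene01
#> DeletionDesign for 'gene01' on chrF
#>   guide 1 (START): ATCAAACTAATAAAGGAGAC | cut after 8596
#>   guide 2 (STOP):  CATGGTTTGGCCGCGATCAG | cut after 8880
#>   deletion: 8597-8880 (1-based excised bases), 284 bp; 5 alternate pairs
```

The guide-1 region was pushed off exon 1 by the nested ORF — visible in
the audit table, which reports both coordinate conventions:

```r
regionsTable(b@genes$gene01, b@genome, b@genes)
#>   gene_id  role chrom start1 end1 start0 end0 anchor shifted
#> 1  gene01 START  chrF   8589 8672   8588 8672   8014    TRUE
#> 2  gene01  STOP  chrF   8814 8913   8813 8913   8913   FALSE
```

Cloning oligos for both guides follow the G(N19)+scaffold scheme:

```r
res$designs$gene01@oligos$forward
#> [1] "GTCAAACTAATAAAGGAGACGTTTTAGAGCTAGAAATAGC"
#> [2] "GATGGTTTGGCCGCGATCAGGTTTTAGAGCTAGAAATAGC"
```

And the planted nested-PCR primers give the expected band shift — a
284 bp difference between wild-type and deletion products, with the
small-product bias flagged:

```r
predictAmplicons(readPrimerTable(files[["primers"]]), files[["genome"]],
                 res$designs$gene01)
#>           name  tier status wt_size del_size
#> 1 gene01_inner INNER     OK     595      311
#> 2 gene01_outer OUTER     OK     976      692
```

Here 595 − 311 = 976 − 692 = 284 bp, the designed deletion size; in a
mixed template the 311 bp junction band is expected to dominate the
595 bp wild-type band.

A thin command-line front-end with `design`, `audit`, `amplicon` and
`fixtures` subcommands is installed at
`system.file("scripts", "dgrna.R", package = "dgRNAdesign")`.

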