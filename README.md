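# tagdge — digital gene expression tag-seq analysis

`tagdge` is an R package for analysing SAGE-style digital gene expression
(DGE-tag / Tag-seq) libraries, in which each transcript molecule is
represented by a single restriction-anchored 21 bp tag: NlaIII recognises a
CATG site and MmeI cuts 17 bp downstream of it, so a tag is `CATG` plus the
next 17 transcript bases, and gene expression is inferred from tag copy
numbers.  The package targets the classic two-species, three-stage,
two-replicate gland transcriptome design (e.g. honeybee hypopharyngeal
glands across newly-emerged, nurse and forager workers), but every stage is
generic.

It implements the complete pipeline:

1. **Reference tag databases** — enumerate every possible CATG + 17 nt
   21-mer from transcript FASTA (sense strand) and genome FASTA (both
   strands), with exact and single-mismatch lookup (mismatches restricted
   to the 17 nt suffix; the enzymatically defined anchor must match).
2. **Tag QC** — filter raw reads/tags into *clean tags*: drop adaptor-only
   and empty records, low-quality records (any N, or any base below a
   Phred floor), non-21 bp tags, and tags with library copy number < 2;
   abundance-bin profiles and nested-subsampling saturation curves.
3. **Mapping and quantification** — map clean tags to the transcript
   database with genome fallback; only *unambiguous* tags (all hits in one
   gene) count toward gene expression, normalised to
   TPM = count / clean tags × 10⁶.
4. **Differential expression** — an empirical noise-distribution
   probability statistic.  For a contrast with condition means x̄₁, x̄₂ per
   gene:

       M = log2(x̄₁ / x̄₂)        D = |x̄₁ − x̄₂|

   A null ("noise") distribution pools (|M*|, |D*|) from every
   within-condition replicate-vs-replicate comparison across all genes, and

       P₁(g) = #{ noise pairs with |M*| < |M_g| and |D*| < |D_g| } / #noise

   Genes with P₁ ≥ 0.8 (odds P₁/P₀ of 4:1) and |M| ≥ 1 are called
   differentially expressed.
5. **Enrichment** — hypergeometric upper-tail test of DEG sets against any
   gene→term annotation table (GO, KEGG, …), Benjamini–Hochberg adjusted.
6. **Comparative clustering** — genes × stages matrices of
   log2(TPM_species1 / TPM_species2) over replicate means (zero means
   replaced by 0.01), with average-linkage hierarchical clustering and
   Newick export.
7. **A ground-truthed simulator** — reference transcriptome/genome,
   12-library factorial design, log-normal abundances, planted stage and
   species effects, replicate dispersion, per-base sequencing error,
   divergence between species, and contaminant tags at Hamming distance
   ≥ 2 from every reference tag.  Every read carries its source in the
   emitted truth tables, so the whole pipeline is testable offline.

## Worked example

```r
library(tagdge)

cfg <- sim_config(n_genes = 500, depth = 30000, seed = 7)
ref <- simulate_reference(cfg, out_dir = "demo")
sim <- simulate_libraries(cfg, ref, out_dir = "demo")

design <- sim$design
design$path <- design$fastq
pc <- pipeline_config(transcript_fasta = ref$paths[["transcripts_sp1"]],
                      genome_fasta = ref$paths[["genome"]],
                      design = design,
                      annotation = simulate_annotation(cfg, sim$truth),
                      out_dir = "demo/out", seed = 7)
res <- run_pipeline(pc)

print(res$expr)
#> Tag expression matrix: 500 genes x 12 libraries
#>   mean unambiguous mapping: 95.60% of clean tags

print(res$fits_stage[[1]])
#> Noise-distribution DE fit: sp1: newly_emerged vs nurse
#>   500 genes, 1000 noise pairs; thresholds P1 >= 0.8, |M| >= 1
#>   significant: 30 (20 up in sp1_newly_emerged_1+sp1_newly_emerged_2,
#>                    10 up in sp1_nurse_1+sp1_nurse_2)

head(res$enrichment[, c("term_id", "N", "n", "M", "m", "P", "Q")], 3)
#>    term_id   N  n  M  m            P            Q
#> 1 TERM:M03 331 48 39 26 2.889088e-16 9.533991e-15
#> 2 TERM:M02 331 48 40 26 7.657563e-16 1.263498e-14
#> 3 TERM:M01 331 48 40 24 2.751253e-13 3.026378e-12
```

Reading the output: 95.6% of clean tags map unambiguously to a single
gene (the simulation's species 1 is its own reference, so only sequencing
errors and shared tags are lost).  In the newly-emerged vs nurse contrast,
30 genes pass the P₁ ≥ 0.8 and |log2 ratio| ≥ 1 rule — 20 higher in
newly-emerged workers, 10 higher in nurses — and the planted
"stage-regulated module" marker terms dominate the enrichment table, with
26 of the 39 genes of `TERM:M03` among the 48 annotated DEGs
(P ≈ 3 × 10⁻¹⁶).

`run_pipeline()` also writes per-stage TSVs (QC, mapping summary shaped
like the classic per-library accounting table, expression matrix, one DE
table per contrast, DEG overlap counts, enrichment, ratio matrix,
dendrogram) plus a run log under `out_dir`.  A thin command-line wrapper
with per-stage subcommands (`simulate`, `build-db`, `qc`, `map`, `de`,
`enrich`, `cluster`, `run-all`) is installed at
`inst/scripts/tagdge.R`.

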