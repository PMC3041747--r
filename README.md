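# spliceGC

Tools for asking whether **GC content around exon–intron junctions tracks
splice-site usage through the stability of local pre-mRNA secondary
structure** — and for testing that question end-to-end on synthetic
genomes with planted, recoverable effects.

The package is aimed at computational biologists studying alternative
splicing who want a self-contained, fully testable reimplementation of
this style of genomic survey: splice-site categorization from transcript
models, fixed-width junction windows, minimum-free-energy (MFE) folding,
decoy-site controls, composition-preserving permutation nulls, and the
associated statistics.

## What it computes

For each splice site (donor = 5'ss, GT consensus; acceptor = 3'ss, AG
consensus) the package extracts the sense-strand window of length
2·flank + 1 (141 nt by default) centered on the junction and computes

* **GC metrics** — GC number/fraction overall and per exonic/intronic
  half, positional GC profiles aligned on the junction, and
  junction-proximal GC normalized by the wider exonic region;
* **structural stability** — the MFE over pseudoknot-free secondary
  structures under a simplified nearest-neighbor energy model
  (Watson–Crick + GU pairs, stacking enthalpies/entropies, loop
  penalties, affine multiloops) with temperature control (37 °C default;
  25/24 °C presets), validated against an exhaustive enumeration oracle;
* **category comparisons** — alternative vs constitutive vs skipped
  (cassette) vs first-exon sites by Wilcoxon rank tests (exact
  enumeration at small n), GC–MFE linear regression, GC-matched bin
  tests, and distance-controlled pairing within 3000 nt;
* **controls** — decoy splice sites (nearest GT/AG scoring above
  background 150–300 nt into the flanking intron, under a position
  log-odds scorer trained on real sites) and mono-/dinucleotide-preserving
  shuffles (Altschul–Erickson Euler-path) for the nucleotide-order effect;
* **tissue specificity** — the Δ ≥ 10 %, p < 0.3 any-tissue rule, with an
  explicit `unclassified` class for the rule's stated gap.

## Worked example

```r
library(spliceGC)

## a synthetic genome with planted category effects
syn   <- generate_genome_annotation(synthetic_config(seed = 7, n_genes = 20))
sites <- classify_splice_sites(syn$models)
table(sites$category)
#>       alternative      constitutive first_alternative first_constitutive
#>                80                40                 6                 17
#>           skipped
#>                40

## junction windows + folding
w <- extract_windows(syn$genome, sites, flank = 70)
w$mfe <- fold_mfe_many(w$sequence, make_model(37))

## cohort route: planted GC means 0.52 / 0.48 / 0.47 recovered
co <- generate_windows_cohort(synthetic_config(seed = 5), n_per_category = 400)
co$mfe <- fold_mfe_many(co$sequence, make_model(37))
aggregate(cbind(gc_fraction, mfe) ~ category, co, mean)
#>       category gc_fraction       mfe
#> 1  alternative   0.5173227 -36.57672
#> 2 constitutive   0.4779255 -33.27055
#> 3      skipped   0.4653723 -32.79942

alt  <- subset(co, category == "alternative")
cons <- subset(co, category == "constitutive")
rank_sum_test(alt$mfe, cons$mfe, alternative = "less")$p_value
#> [1] 8.619375e-16

## GC alone explains the stability gap: matched bins are non-significant
two <- subset(co, category %in% c("alternative", "constitutive"))
gm  <- gc_matched_compare(two$mfe, two$category, two$gc_number)
mean(gm$p_value[gm$tested] > 0.05)
#> [1] 0.875

## GC vs stability coupling on random 141-mers
set.seed(3)
s   <- vapply(runif(500, .3, .7), function(p) paste(
        sample(c("G","C","A","T"), 141, TRUE, c(p/2,p/2,(1-p)/2,(1-p)/2)),
        collapse = ""), character(1))
cor(vapply(s, gc_count, integer(1)), fold_mfe_many(s, make_model(37)))
#> [1] -0.8864332
```

Reading of those numbers: alternative-site windows carry ~4 GC
percentage points more than constitutive ones and fold ~3 kcal/mol more
stably; once windows are matched on GC number the stability difference
vanishes in ~90 % of bins; and GC count alone explains ~79 % of MFE
variance on random sequence. The full pipeline
(`run_full_analysis(run_config())`) chains every stage — classification,
windows, folding, category tests, regressions, matched bins, distance
pairs, first-exon and exon-length contrasts, tissue rule, decoys,
order-effect shuffles — into a reproducible, seeded report bundle
(`report_summary()` prints it; `write_report_tables()` emits TSVs). A
thin CLI wraps the same stages:

```sh
Rscript inst/cli/splicegc simulate --out sim --seed 3 --genes 10
Rscript inst/cli/splicegc classify --gtf sim/annotation.gtf --out sim/sites.tsv
Rscript inst/cli/splicegc run-all  --out report --seed 3
```

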