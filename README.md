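# gwaspathnet

Case–control allelic association and network-based pathway ranking for
targeted SNP panels, built for studies of inflammatory bowel disease (IBD)
and its clinical subphenotypes, but applicable to any case–control panel.

Population-specific GWAS panels (here: an IBD risk panel contrasting
Crohn's disease, ulcerative colitis and their Montreal-classification
subphenotypes against healthy controls) yield a handful of significant SNPs
per phenotype. Those SNPs only become interpretable once their carrier genes
are placed in their functional context: the protein-association networks
they participate in and the signaling pathways those networks implicate.
`gwaspathnet` implements that whole chain as composable, tested R
functions, together with synthetic-data generators so every stage can be
exercised offline with known ground truth.

## What it computes

**Association stage.** For each SNP, the 2×2 allele-count table
(a, b; c, d) of minor/major allele copies in affected vs unaffected samples
gives the 1-df basic allelic test

> χ² = N (ad − bc)² / ((a+b)(c+d)(a+c)(b+d)),  N = a+b+c+d,

its asymptotic p-value, and the allele-1 odds ratio OR = ad / bc with the
log-scale 95% CI exp(ln OR ± 1.96 √(1/a+1/b+1/c+1/d)). Quality control
filters SNPs on missing rate, minor allele frequency and the
Hardy–Weinberg exact test (controls only), with conventional GWAS defaults
(≤ 5% missing, MAF ≥ 1%, HWE p ≥ 1e-6).

**Network stage.** Risk genes are mapped to proteins and expanded through a
confidence-thresholded interaction table (combined score ≥ 0.400) into an
association network with at most 20 first-shell and 10 second-shell
interactors, ranked by summed edge confidence. Each protein is scored by

> combined = 0.2 · degree + 0.3 · harmonic closeness + 0.5 · betweenness

on min–max rescaled centralities; pathways are ranked by the mean combined
score of their contributing proteins. Clustering is by the Markov Cluster
Algorithm (inflation 3) on the protein network and by Girvan–Newman
edge-betweenness communities on pathway networks.

**Pathway stage.** Gene-set over-representation is scored by the
hypergeometric upper tail with BH-adjusted p-values; the top-10 enriched
sets become seed pathways that are connected into a complementary pathway
network through a Jaccard-overlap scaffold. Phenotype SNP/pathway sets are
compared by Venn regions, the two analysis routes are merged into a
consensus, and disease–disease networks link phenotypes by the Jaccard
index of their pathway profiles.

A transcription of the study's per-phenotype SNP association table ships
with the package (`read_table2()`), including the documented normalization
of four truncated rsIDs.

## Worked example

Simulate a cohort whose control allele frequencies and odds ratios mirror
the packaged IBD panel (573 cases / 445 controls), run QC and association,
then compare subphenotype SNP sets:

```r
library(gwaspathnet)
spec <- table2_sim_spec("IBD", missing_rate = 0.01)
gm   <- simulate_genotypes(573, 445, spec, seed = 2026, case_label = "IBD")
qc   <- qc_filter(gm, "HC")
res  <- run_association(gm, "IBD", "HC", alpha = 0.05, snps = qc$kept)
print(res, digits = 3)
#> Allelic association: IBD vs HC (alpha = 0.05)
#> 10 significant SNP(s)
#>        snp_id ...    f_a    f_u  chi2 df        p     p_bh   or_ ci_low ci_high
#> 1   rs4986790 ... 0.0229 0.0666 23.53  1 1.23e-06 1.60e-05 0.329  0.206   0.526
#> 2  rs17309827 ... 0.2967 0.3959 21.68  1 3.22e-06 2.09e-05 0.644  0.534   0.775
#> 3  rs10761659 ... 0.4032 0.5023 19.68  1 9.13e-06 3.96e-05 0.669  0.560   0.800
#> ...
```

Ten of the thirteen simulated signals are recovered at α = 0.05; the
estimated odds ratios sit close to their simulation targets (e.g.
rs10761659: 0.669 vs target 0.7212, CI 0.56–0.80). The same run on the
published table's subphenotype SNP lists reproduces the reported overlap:

```r
venn_regions(table2_snp_sets(c("B1", "B2")))$`B1+B2`
#> [1] "rs17309827" "rs10761659" "rs17234657"
```

The full flow — association, both pathway routes, comparisons and the
disease–disease network — runs from one config via `run_pipeline()`
(`inst/scripts/run_pipeline.R` wraps it for shell use) and writes a JSON
manifest with an MD5 hash per output file; re-runs with the same config and
seed are byte-identical.

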