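# oglyco

Downstream analysis of differential O-glycoproteomics experiments in R:
from glycopeptide-spectrum matches to a site catalog, protein-region and
glycan-patch maps, isoform-specific regulation calls across a
GalNAc-transferase knockout panel, and MS1-based glycosylation
site-occupancy estimates.

## The problem

Mucin-type O-glycosylation is initiated by a family of 20 polypeptide
GalNAc-transferases (GalNAc-Ts) with overlapping but distinct substrate
specificities. Mapping which enzyme controls which serine/threonine site —
and how fully each site is actually occupied — requires stitching together
several quantitative analyses that are usually run as one-off scripts:

1. **Site catalog** — aggregate ETD glycopeptide-spectrum matches (PSMs)
   into non-redundant protein-coordinate O-glycosites. A site is
   *unambiguous* when its ptmRS-style localization probability exceeds 95%;
   glycans that cannot be placed are kept as *ambiguous* sites spanning the
   peptide's S/T/Y range. Reporter quantification uses the HCD spectrum of
   the same precursor as the best-scoring ETD PSM per glycopeptide.
2. **Region mapping** — assign each site to one of five protein regions
   (annotated domain; stem, i.e. within 50 aa of the transmembrane span of a
   type-I/II membrane protein; functional region; terminus, within 10 aa of
   the mature N- or C-terminus; linker between domains < 100 aa apart), with
   per-domain-type glycosylation rates and within-domain positional bins.
3. **Glycan patches** — mucin-like regions detected as maximal clusters with
   ≥ 5 sites inside a 25-aa window.
4. **Differential calls** — per knockout: total-intensity normalization,
   removal of sites on abundance-changed proteins, fold change as the ratio
   of replicate medians (KO/WT), two-sided equal-variance t-tests on log2
   intensities, Benjamini–Hochberg FDR; *down* means FC < 0.5 and adjusted
   p < 0.05. A site regulated in exactly one knockout is *isoform-specific*.
5. **Occupancy** — from MS1 peak areas of glycoforms and the
   non-glycosylated peptide, after acceptance filtering
   (|ppm| < 1.5, idotp > 0.85, RT within 5 min, id score ≥ 200):

   occupancy = Σ area(glycoforms) / (Σ area(glycoforms) + area(non-glyco)),

   with a `High` flag when the non-glycosylated form is never detected, and
   xTn percentages giving each glycoform's share of the glycosylated signal.

A synthetic-data generator (`sim_config()`, `simulate_dataset()`) produces
proteomes, feature architectures, PSM tables with TMT channel intensities,
and MS1 peak tables from known ground truth, so every stage is testable
without any deposited raw data.

## Worked example

```r
library(oglyco)

cfg <- sim_config(seed = 7, n_proteins = 15, n_sites = 80,
                  conditions = c("WT", "T2", "T3"), n_regions = 20)
d <- simulate_dataset(cfg, dir = "simrun")

catal <- build_catalog(d$psms, d$proteome)
print(catal)
#> O-glycosite catalog: 89 sites (79 unambiguous, 10 ambiguous) on 15 proteins
#>   unambiguous fraction: 88.8%

pc <- pipeline_config("simrun/proteome.fasta", "simrun/features.tsv",
                      "simrun/psms.tsv",
                      protein_tsv = "simrun/protein_table.tsv",
                      peak_tsv = "simrun/peaks.tsv", out_dir = "simrun/out")
res <- run_pipeline(pc)
res$summary
#>                    metric value
#> 1             total_sites  89.0
#> 2       unambiguous_sites  79.0
#> 3           glycoproteins  15.0
#> 4              pct_domain  24.7
#> ...
#> 11            patch_count   3.0
#> 12         max_patch_size   9.0
#> 13         sites_down_any   8.0
#> 14 isoform_specific_sites   8.0
#> 15      occupancy_regions  20.0
#> 16     occupancy_pct_high  60.0
```

The catalog recovers the planted ground-truth sites; three of the planted
site clusters qualify as glycan patches (largest: 9 sites); the eight sites
targeted in the simulated knockouts are all called down and
isoform-specific; and 60% of the 20 simulated peptide regions are estimated
as highly occupied, matching the configured occupancy mixture. Stage tables
(`site_catalog.tsv`, `patches.tsv`, `regulation.tsv`, `occupancy.tsv`), a
summary and a JSON run manifest are written to `simrun/out/`.

A thin command-line wrapper with `simulate` / `catalog` / `regions` /
`patches` / `occupancy` / `run` subcommands is installed at
`system.file("cli", "oglyco.R", package = "oglyco")`.

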