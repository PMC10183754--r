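# specklesplice

Quantification toolkit for cell-type-resolved studies of the Na-K-2Cl
cotransporter **NKCC1** (*Slc12a2*) and the neuronal marker **KCC2** in
brain tissue. It is written for groups who quantify ultrasensitive
fluorescent in situ hybridization (RNAscope) images, splice-variant
evidence in RNA-seq alignments, and single-cell UMI matrices, and who want
each step reproducible and testable against exact synthetic ground truth.

The package covers three procedures:

1. **Per-cell RNAscope speckle counting.** Nuclei are segmented from the
   DAPI channel and expanded radially by 10 px (1.6 µm at 0.16 µm/px) to
   approximate the cytoplasm. mRNA speckles are 8-connected suprathreshold
   components, filtered by a minimum area of 8 px, with the intensity
   threshold calibrated on negative-control images so background stays at
   or below 0.1 speckles/cell (one speckle per 10 cells). Speckles are
   assigned to the cell containing their centroid. Cells with ≥10 KCC2
   speckles are neurons, cells with 0 are non-neuronal, 1–9 are
   unclassified; NKCC1 counts are binned (0 / 1–4 / 5–10 / 11–15 / ≥16).
2. **Exon-21 splice-junction quantification.** NKCC1a includes the 48-nt
   cassette exon-21, NKCC1b skips it. N gaps in spliced alignments (or
   rows of a STAR-style junction table) are matched exactly against the
   skip and include junction templates of an exon model, and variant
   fractions are reported as
   `frac_a = n_include / (n_include + n_skip)` with integer percentages
   reconciled to sum to 100.
3. **ln(TPM+1) harmonization.** Per-cell UMI counts are normalized as
   `ln(gene_umi / total_umi × 10⁶ + 1)`, detection rules are applied per
   dataset (inclusive threshold on the ln(TPM+1) scale, or
   any-transcript), and expression is aggregated by annotated cell type.

A synthetic-scene generator (`generate_fish_scene()`,
`generate_junction_reads()`, `generate_umi_matrix()`) produces images,
alignments and count matrices with exportable ground truth, so the whole
pipeline is verifiable without any external download.

## Worked example

Quantify the pooled neuron junction tallies (44 exon-skipping reads, 14
exon-including reads) end to end through synthetic alignments:

```r
library(specklesplice)

model <- exon_model("chr18",
                    rbind(c(100, 200), c(300, 348), c(400, 500)),
                    focal_exon = 2, expected_focal_length = 48)
sam <- tempfile(fileext = ".sam")
generate_junction_reads(list(list(model$templates$skip, 44),
                             list(model$templates$include_5p, 14)),
                        sam, emit = "sam")
jx <- classify_junctions(extract_junctions(sam), model)
compute_variant_fractions(jx)
#>   sample_id n_skip n_include    frac_a    frac_b percent_a percent_b
#> 1    pooled     44        14 0.2413793 0.7586207        24        76
```

76% of the junction reads skip exon-21 (NKCC1b) and 24% include it
(NKCC1a): in this pool the skipping variant dominates.

Run the full image pipeline on a synthetic 100-cell scene of KCC2-rich
neurons and KCC2-negative glia:

```r
scene <- generate_fish_scene(scene_spec(seed = 42))
res <- run_rnascope_pipeline(scene)
res$calibration
#> calibration: threshold 255.3, 0.090 speckles/cell over 100 cells (target 0.1)
res$summary[, c("group", "n", "frac_nkcc1_pos", "frac_very_high", "mean_nkcc1")]
#>          group  n frac_nkcc1_pos frac_very_high mean_nkcc1
#> 1       neuron 50           0.98              0       3.56
#> 2 non_neuronal 50           1.00              0       8.24
```

The calibration found the smallest intensity threshold keeping the
negative-control rate at or below one speckle per 10 cells; at that
threshold 98% of neurons show at least one NKCC1 speckle and non-neuronal
cells average ~8 speckles, matching the generating rates (4 and 8
speckles/cell). Comparing against the scene's ground truth:

```r
map <- match_cells_to_truth(res$masks[[1]], scene)
mean(as.character(res$cells$cell_class[map]) ==
     scene$ground_truth$cells$true_class)
#> [1] 1
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/specklesplice.R` (subcommands `simulate`, `segment`,
`spots`, `splice`, `scrna`, `run`).

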