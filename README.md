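# f2impute

Pedigree-based genotype imputation accuracy in F2 crosses of divergent
breeds.

## What this is for

F2 resource populations — two divergent purebred founder lines (e.g. 4
Duroc boars x 15 Pietrain sows), their F1, and a large F2 mapping
generation — carry rich phenotype archives, but typing every F2 animal on
a high-density (HD, 60K-class) SNP array is costly. Because founders are
few and only two meioses separate F0 from F2, genotypes of F2 animals
typed on a cheap low-density tagSNP panel (LowD, 9K-class) can be imputed
to HD from linkage information alone. `f2impute` is a simulation and
evaluation toolkit for that design, aimed at quantitative geneticists
planning re-genotyping of existing resource populations. It provides:

- **Gene-dropping simulation** of the three-generation population:
  mosaic-model founder breed haplotypes with high within-breed LD and
  breed-divergent allele frequencies; Poisson crossover counts (mean =
  chromosome length in Morgans, 1 Mb = 1 cM by default) with uniform
  crossover positions, matching Haldane's map function
  θ = ½(1 − e^(−2d)).
- **Marker QC**: unmapped markers, Mendelian-inconsistency masking,
  animal/marker missingness (10%), MAF (0.01).
- **TagSNP selection** by LD-threshold greedy cover (every marker in
  r² ≥ r²_t with a tag) or by evenly spaced segment centers.
- **Imputation** via grandparental-origin hidden Markov models on
  litter-based family units (4 F0, 2 F1, ≤ 10 F2): transmission-based F0
  phasing, a 4-state forward–backward chain per F1 and per F2 with
  independent Haldane transitions per gamete (Rcpp core, exact against an
  exhaustive-path oracle).
- **Accuracy statistics**: allelic-dosage accuracy
  IA = 1 − mean|g − ĝ|/2, per-SNP R² (squared Pearson correlation),
  haplotyping (switch) accuracy, uncertain-phase fractions, covariate
  stratification, and the HD-vs-LowD genotyping cost ratio.

## Worked example

Simulate the 64.2 Mb / 1,405-marker chromosome analog at full pedigree
scale, type the F2 on a ~0.30 Mb evenly spaced panel (the 9K-chip
density) with F0 and F1 at HD, impute, and score:

```r
library(f2impute)
map <- even_map(1405, 64.2)          # 60K-density chromosome analog
ped <- build_pedigree()              # 4/15 F0, 56 F1, 932 F2
pop <- simulate_study_population(map, breed_model(), ped, seed = 1)
qc  <- qc_filter(pop$drop$geno, qc_config(), ped = ped, map = map)
tags <- select_tagsnp_even(qc$map, 214)   # ~0.30 Mb panel (9K analog)
print(tags)
#> tag_set: 214 markers, method 'even' (parameter 214), mean spacing 0.300 Mb

truth <- pop$drop$geno[, qc$map$snp]
obs <- apply_genotyping_scenario(truth, ped,
                                 scenario_spec("HD", "HD", "LowD"), tags)
imp <- run_imputation(obs, ped, qc$map)

f2 <- generation_ids(ped, "F2")
non_tag <- !(qc$map$snp %in% tags$snp)
mask <- matrix(rep(non_tag, each = length(f2)), nrow = length(f2))
imputation_accuracy(truth[f2, ], imp$dosage, mask)
#> IA  = 0.9990 over 1110012 imputed genotypes
r2_per_snp(truth[f2, ], imp$dosage, mask)$summary
#> R2  = 0.9975 (mean over 1191 markers)
```

An IA of 0.999 means the imputed expected dosage of a typical untyped F2
genotype is within about 0.002 dosage units of truth; under this design
a 9K panel on the progeny recovers essentially the full 60K content.
Dropping the F1 to the low-density panel (`scenario_spec("HD", "LowD",
"LowD")`) costs roughly 0.17 in IA — the F1 phase, not the F2 panel, is
the binding constraint. `run_scenario_grid()` automates this comparison
over tag densities, scenarios and replicate seeds and returns a tidy
results table; `summarize_grid()` aggregates it.

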