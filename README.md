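# qclms

Quantitative cross-linking/mass spectrometry (QCLMS) comparison of protein
conformations, and cross-link-driven Bayesian integrative modeling of
domain architecture — in R.

## The problem

A bifunctional cross-linker such as BS3 (11.4 Å spacer, amine-reactive
toward K/S/T/Y and protein N termini) covalently tethers residue pairs that
are close in solution: a lysine–lysine link implies a Cα–Cα distance below
about 27.4 Å (spacer + both side chains + 2 Å displacement allowance per
residue). Cross-linking two conformers of the same protein with light (BS3)
and heavy (BS3-d4) reagents, mixing the digests, and comparing MS1 elution
peak areas asks a sharper question: *which residue–residue proximities are
preserved, gained, lost, or changed in yield between conformers?* The
motivating system is complement component C3 and its activated derivatives
C3b and C3(H2O), whose TED domain migrates along the length of the molecule
upon activation.

`qclms` implements the complete downstream analysis:

- **Quantitation comparison** (`quantify_crosslinks()`,
  `classify_crosslinks()`, `merge_three_way()`): condition-oriented log2
  peptide ratios, per-sample median normalization, the median-of-peptides
  residue-pair fold change, label-swap replica validation, the robust
  percentile outlier test ("Significance A",
  `p = erfc(z/√2)/2` on one-sided percentile spreads), classification into
  unique/enriched/mutual categories, and the three-way Venn merge of two
  comparisons sharing a reference condition.
- **Structure assessment** (`read_structure()`, `assess_links()`):
  Cα–Cα distances in PDB/mmCIF structures, nearest-resolved-residue
  substitution, violation calls against `max_link_distance()`, and PyMOL
  visualization scripts.
- **Integrative modeling** (`build_representation()`,
  `replica_exchange_sample()`, `cluster_solutions()`): rigid-body +
  flexible-string bead representation, a Bayesian score with per-class
  cross-link uncertainties ψ (likelihood term
  `ψ + (1−2ψ)·f(d)` with a logistic forward model `f`), excluded-volume /
  connectivity / disulfide priors, replica-exchange Metropolis Monte
  Carlo, k-means ensemble clustering, precision/accuracy metrics,
  restraint-satisfaction maps and per-domain localization densities
  (CCP4/MRC output).
- **Synthetic data** (`make_toy_protein()`, `simulate_crosslinks()`,
  `simulate_quant()`): fully seeded ground-truthed toy proteins in
  multiple conformational states, distance-limited link detection with a
  noise rate, and label-swap quantitation tables — so the whole pipeline
  is testable end to end offline.

Results are tibbles (with `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures), so everything composes with the pipe.

## Worked example

The synthetic benchmark tables emulate the two pairwise comparisons of the
complement study (C3 vs C3(H2O) and C3b vs C3(H2O)); running the pipeline
recovers the planted bookkeeping from the simulated peak areas:

```r
library(qclms)

b <- simulate_benchmark_quant(seed = 1)
cmp1 <- b$cmp1$quant |>
  quantify_crosslinks(b$cmp1$design, b$conditions1) |>
  classify_crosslinks()
glance(cmp1)
#>   condition1 condition2 n_quantified alpha n_unique_1 n_enriched_1 n_mutual
#> 1 C3         C3H2O                94  0.05         10            1       57
#> # n_enriched_2: 4, n_unique_2: 22

cmp2 <- b$cmp2$quant |>
  quantify_crosslinks(b$cmp2$design, b$conditions2) |>
  classify_crosslinks()
merged <- merge_three_way(cmp1, cmp2)
glance(merged)
#>   condition_a condition_ref condition_b n_total n_all_three n_ref_only
#> 1 C3          C3H2O         C3b             101          48          9
```

94 links quantified in the first comparison (10 unique to C3, 1 C3-enriched,
57 mutual, 4 C3(H2O)-enriched, 22 unique to C3(H2O)); 101 links in the
three-way union, 48 present in all three conformers, 9 exclusive to
C3(H2O). The links present in the reference condition become the modeling
restraint set (85 links, classed by cross-experiment consistency):

```r
restraints <- modeling_restraint_set(merged, "ref")
dplyr::count(restraints, class)
#>   class          n
#> 1 consistent    84
#> 2 single         1
```

Modeling the hydrolysed-like state of the synthetic complement-like
benchmark from its 85 simulated cross-links (desk profile: 8 replicas,
20,000 models, ~2 minutes):

```r
bs  <- synthetic_benchmark_system("C3H2O", seed = 1)
cfg <- sampler_config(n_replicas = 8, n_models = 20000, n_best = 200,
                      init_radius = 80, seed = 11)
ens <- replica_exchange_sample(bs$rep, bs$restraints, scoring_params(), cfg)
cl  <- cluster_solutions(select_best(ens, 200), k = 2)
cl
#> <xl_clusters> k = 2; sizes: 110, 90; restraint satisfaction: 97.6 %, 100 %
#> (best: cluster 2)
precision_accuracy(cl, reference = bs$reference)
#> precision: 1.1 A; accuracy: 9.9 A
satisfaction_report(cl)$fraction_satisfied
#> [1] 1
```

The best cluster satisfies all 85 restraints at the 35 Å criterion and
reproduces the planted domain architecture to ~10 Å Cα RMSD after
superposition on the fixed core — the same order as the accuracy reported
for the real complement models. Localization densities for any domain are
written as standard volumetric maps:

```r
dens <- localization_density(cl, "TED", voxel = 5)
write_density_mrc(dens, "ted_density.mrc")
```

See `vignette("qclms-methods")` for the full account of the model, its
assumptions, parameter choices and limitations.

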