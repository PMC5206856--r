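# httscan

Mutational stability landscapes and mutant design for the huntingtin
N-terminal helix.

## What this is for

The 17-residue N-terminal segment of huntingtin exon 1
(`MATLEKLMKAFESLKSF`) is an alpha-helix implicated in the aggregation
cascade of Huntington's disease through two proposed routes:
self-association of the helix into oligomer-seeding bundles, and
hydrophobic cross-talk with the adjacent polyglutamine tract. `httscan`
is an R package for the corresponding computational design exercise,
aimed at structural bioinformaticians who want a self-contained,
reproducible desk-scale pipeline rather than an MD cluster workload:

1. build an idealized helical model of the peptide from sequence alone;
2. score stability with a decomposed energy
   `E = E_solv + E_LJ + E_Coul` (SASA-weighted implicit solvation,
   Lennard-Jones and Coulomb terms with 1-2/1-3 exclusions and a 10 A
   cutoff) and relax structures by steepest descent;
3. scan all 17 x 19 single-point mutations into a dE landscape
   (`dE = E - E0`; negative = stabilizing);
4. estimate n-point mutants additively, `dE~ = sum_i dE(m_i, p_i)`, and
   enumerate the top-k combinations exactly;
5. score sequences with compositional features (net charge,
   Kyte-Doolittle hydrophobicity, Chou-Fasman propensities, a composite
   aggregation score);
6. filter ranked combinations by three criteria: stability rank,
   hydrophobic-to-charged replacement, and disruption of the
   intermolecular lysine contact at positions 6/15;
7. analyze coordinate trajectories with optimally superposed RMSD and
   per-atom RMSF, including a seeded synthetic-trajectory generator.

The package also embeds the printed reference tables for the 20
top-ranked 3-point mutants and can invert their additive structure by
least squares, recovering the nine underlying single-point values from
the printed 3-point sums.

## Worked example

```r
library(httscan)

native <- build_ideal_helix(htt_nterm_sequence())
native
#> <peptide> MATLEKLMKAFESLKSF
#>   17 residues, 136 heavy atoms, 137 bonds

cfg <- energy_config()          # cutoff 10 A, probe 1.4 A, SASA solvation
relaxed <- minimize(native, cfg, max_steps = 200)
total_energy(relaxed, cfg)
#> LJ       96.470  Coulomb     -176.440  Solvation     11.554  Total      -68.416 kcal/mol

# full single-point landscape: 17 positions x 20 residues, ~30 s
landscape <- scan_single_point(native, cfg, max_steps = 200)
dim(landscape$values)
#> [1] 17 20

# additive top-k enumeration over the landscape
enumerate_top_k(landscape, n = 3, k = 3)
#>   rank     mutations delta_e_estimate
#> 1    1 L4P K9F A10D        -333.8876
#> 2    2  T3D L4P K9F        -330.5573
#> 3    3 L4P K9P A10D        -324.2632
```

Energies are on the package's own versioned united-atom parameter scale
(`httscan-ua-1`): signs, orderings and differences are meaningful;
absolute values are not comparable to explicit-solvent force fields,
so the package's own top-ranked combinations differ from the printed
reference list, which was produced with a different energy model.

Working with the printed reference tables instead:

```r
fit <- fit_single_point()        # 20 printed 3-point sums -> 9 single-point values
fit$design_rank
#> [1] 9
max(abs(fit$residuals))
#> [1] 0.04517544

# leave-one-out prediction of the selected triple mutant
fit16 <- fit_single_point(exclude_ids = "M16")
fit16$predict("L4K E12K K15E")
#> [1] -627.4722        # printed value: -627.5

# the three-criteria filter
report <- select_candidates(table1())
report$id[report$passes_all]
#>  [1] "M1"  "M2"  "M4"  "M5"  "M6"  "M11" "M14" "M15" "M16" "M18" "M20"

net_charge(mutant_sequence("L4K E12K K15E"))
#> [1] 2                # matches the printed charge column
```

The leave-one-out prediction reproduces the printed sum to 0.03 energy
units; the triple mutant L4K E12K K15E passes all three selection
criteria (it replaces an aliphatic leucine with a lysine and substitutes
the contact lysine at position 15).

## The analysis workflow

Numbered driver scripts under `analysis/` run the full pipeline and
write their tables under `results/`:

| script | what it does |
| --- | --- |
| `01_build_native.R` | native helix model, relaxation, energy breakdown |
| `02_landscape_scan.R` | 323-mutant scan, landscape CSV, classification |
| `03_rank_combinations.R` | top-20 2-point and 3-point additive rankings |
| `04_sequence_features.R` | feature table for native + 20 printed mutants |
| `05_candidate_selection.R` | three-criteria reports (printed list + own landscape) |
| `06_table_fit.R` | least-squares recovery, leave-one-out, additivity identities |
| `07_trajectories.R` | synthetic trajectories, RMSD/RMSF for native and triple mutant |

Run them in order from the repository root, e.g.
`Rscript analysis/02_landscape_scan.R`.

## The methods vignette

`vignettes/htt-mutant-design.Rmd` documents the model and its
assumptions: the parameter table and its charge conventions, the
geometry of the helix builder, the minimization protocol, why SASA is
evaluated in a canonical molecular frame, the additivity error of
multi-point estimates, the aliphatic default of the hydrophobic
criterion, the identifiability structure of the least-squares fit, and
what the synthetic-trajectory generator does and does not emulate.
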