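# ythbind

Quantitative analysis of how YTH reader domains recognise
N6-methyladenosine (m⁶A) in single-stranded RNA. The package implements
the four measurement chains used to characterise such an interaction by
solution NMR and calorimetry, together with a synthetic-data generator so
that every stage can be exercised and validated without any experimental
download:

1. **Chemical-shift-perturbation (CSP) mapping.** HSQC titration peak
   lists (Sparky or TSV) are tracked point-to-point by nearest-neighbour
   chaining; per-residue perturbations between the free and the bound
   state are combined as

   Δδ = √( δ_HN² + (δ_N / 6.51)² )

   with the ¹⁵N dimension down-weighted by 6.51. Peaks broadened beyond
   detection in intermediate exchange cannot be followed and are assigned
   a capped perturbation of 0.3 ppm; prolines and residues unassigned in
   either state are reported as a status, not a number.

2. **Modified scaffold-independent analysis (SIA).** Each position of an
   RNA hexamer is probed with the four nucleotide substitutions; for every
   oligo the per-residue perturbations are summed, sums are normalised to
   the largest within the position, and the winning nucleotide is fixed
   into the scaffold before the next position is assayed (assay order
   4, 3, 2, 6, 1 — position 5 is never assayed). The result is an IUPAC
   consensus such as `NGANNN`.

3. **One-site ITC analysis.** Per-injection heats of a Wiseman titration
   are forward-modelled from the cumulative heat content

   Q = (N·M·ΔH·V₀/2)·[1 + X/(N·M) + 1/(N·K·M) − √((1 + X/(N·M) + 1/(N·K·M))² − 4X/(N·M))]

   with perfusion-cell dilution of both concentrations and the
   displaced-volume correction, and fitted by χ²-minimised least squares
   for K, ΔH and N; Kd = 1/K, ΔG = −RT ln K = ΔH − TΔS. `fold_change()`
   expresses the affinity gain conferred by methylation as the ratio of
   dissociation constants with propagated uncertainty.

4. **Ensemble statistics.** Multi-model PDB bundles (protein chain plus
   RNA chain including the m⁶A heteroresidue) are superposed onto an
   iteratively refined mean structure (Kabsch least squares), RMSD to the
   mean is reported per atom class, CYANA `.upl` / NMR-STAR distance
   restraints are classified by residue separation |i−j| (intraresidual,
   sequential, medium, long, intermolecular, hydrogen bond), and
   protein–RNA hydrogen bonds / hydrophobic contacts are detected
   geometrically.

Intended users: structural biologists and method developers analysing
protein–RNA binding by NMR titration, ITC or NMR ensembles, and anyone
needing a reproducible reference implementation of these standard
calculations.

## Worked example

Simulate the two study titrations (45 × 6 µl injections; 125 µM RNA into
10 µM protein for the methylated complex, 410 µM into 14 µM for the
unmethylated one), fit the one-site model and compare the affinities:

```r
library(ythbind)

s_me <- injection_schedule(45, 6e-6, 1.4e-3, cell_conc = 10e-6,
                           syringe_conc = 125e-6)
fit_me <- fit_one_site(simulate_itc(kd = 0.1e-6, dH = -10, n_sites = 1,
                                    schedule = s_me))
fit_me
#> One-site ITC fit
#>   Kd  = 1e-07 M  (K = 1e+07 1/M, c = 100)
#>   dH  = -10 kcal/mol   N = 1 sites
#>   dG  = -9.39 kcal/mol   dS = -2.082 cal/mol/K  (T = 293.15 K)
#>   chi2 = 1.26e-26 ucal^2 over 45 injections

s_un <- injection_schedule(45, 6e-6, 1.4e-3, cell_conc = 14e-6,
                           syringe_conc = 410e-6)
fit_un <- fit_one_site(simulate_itc(kd = 5e-6, dH = -5, n_sites = 1,
                                    schedule = s_un))
fold_change(fit_un, fit_me)
#> Affinity fold-change: 50 (Kd 5e-06 M -> 1e-07 M)
```

The fitted dissociation constants (0.1 µM methylated, 5 µM unmethylated)
recover the planted values exactly at zero noise, and the fold-change of
50 is the affinity gain conferred by the N6-methyl group. The c-value
(N·K·[cell]) of 100 indicates a well-determined sigmoid.

A sequence-preference run on synthetic substitution panels with a 3×
preference for G at position 2 and A at position 3, under 20%
multiplicative CSP noise:

```r
prof <- list(`2` = c(A = 1, C = 1, G = 3, U = 1),
             `3` = c(A = 3, C = 1, G = 1, U = 1))
sim <- simulate_sia_panels(prof, order = c(4, 3, 2, 6, 1),
                           noise_frac = 0.2, seed = 7)
run_sia(sim$panels)
#> Scaffold-independent analysis
#>   assay order: 4, 3, 2, 6, 1
#> Position 4 scores: A=0.98 C=0.98 G=1.00 U=0.99 -> winner N
#> Position 3 scores: A=1.00 C=0.32 G=0.28 U=0.30 -> winner A
#> Position 2 scores: A=0.38 C=0.33 G=1.00 U=0.36 -> winner G
#> Position 6 scores: A=0.99 C=0.97 G=0.97 U=1.00 -> winner N
#> Position 1 scores: A=0.89 C=0.92 G=1.00 U=1.00 -> winner N
#>   consensus: 5'-NGANNN-3'
```

Positions with near-tied normalised scores are called `N`; only the
planted preferences are picked up, giving the `NGANNN` consensus.

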