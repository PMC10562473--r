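# phosphosep

Multisite phosphorylation as a switch for the phase separation of
intrinsically disordered proteins (IDPs), analysed from sequence.

Cyclin-dependent kinases phosphorylate many substrates on several
serines/threonines at once, and each phosphate adds two negative charges.
For a disordered protein whose condensation is driven by charge patterning
and weak mean-field attractions, that rewrite of the charge sequence can
either promote or abolish liquid–liquid phase separation depending on *how
many* sites are occupied — a buffered, switch-like control. `phosphosep`
provides the pieces needed to study this mechanism computationally, for
people working at the interface of cell-cycle signalling, IDP polymer
physics and phosphoproteomics:

* **Charge sequences** (`assign_charges`, `apply_phosphomimetic`,
  `enumerate_phospho_patterns`): fixed-charge models (D/E −1, R/K +1,
  phospho-S/T −2, mimics −1), phosphosite-combination enumeration, and
  CDK-consensus (S/T-P) site detection.
* **SCDM maps** (`compute_scdm`, `scdm_composite`, `sequence_scd`):
  sequence charge decoration matrices, SCDM(i,j) =
  (1/(j−i)) Σ<sub>i≤n<m≤j</sub> q<sub>m</sub>q<sub>n</sub>√(m−n), negative =
  attractive.
* **Phase diagrams** (`free_energy_model`, `critical_point`, `spinodal`,
  `binodal`, `phospho_scan`): mean-field free energy
  f = (φ/N)ln φ + counterion and solvent entropy − (ε/T\*)φ² + RPA
  electrostatic correlation built on the sequence structure factor
  S(k) = (1/N) Σ q<sub>m</sub>q<sub>n</sub> e^(−k²|m−n|/6), in reduced
  temperature T\*; exhaustive 2<sup>n</sup> phosphosite scans of critical
  points.
* **IDR selection** (`read_plddt_cif`, `select_idr_plddt`,
  `select_idr_iupred`): AlphaFold-pLDDT (<50) or IUPred (>0.5) based
  selection of the analysis region, with the longest-ordered-run
  truncation rule.
* **Coarse-grained simulator** (`simulate_chain`, `radius_of_gyration`,
  `fit_scaling_exponent`, `theta_temperature`, `fit_binodal`): one bead per
  residue, harmonic bonds (1000 kJ/mol/nm², 0.38 nm), screened Coulomb
  (Debye 1 nm), hydrophobicity-scaled LJ pair terms, BAOAB Langevin at
  10 fs / 25 ps⁻¹; θ-temperature from R<sub>ij</sub> = 0.55|i−j|^ν and
  coexistence fits ρ<sub>H</sub>−ρ<sub>L</sub> = A(T<sub>c</sub>−T)^0.325.
* **FRAP kinetics** (`normalize_trace`, `fit_recovery`, `t_half`,
  `total_recovery`): y = c − a·e^(−kt) recovery fits with both half-time
  conventions exposed.
* **Enrichment statistics** (`pooled_odds_ratio`, `expected_observed_idr`,
  `classify_dynamic_sites`, `classify_motifs`, ...): compositional-bias
  corrected enrichment of phosphorylation in disordered regions, dynamic
  site calling, kinase-motif classification, imputation.
* **Synthetic data** (`synth_proteome`, `synth_polyampholyte`,
  `synth_frap`, `synth_physics_curves`, `ki67_consensus_repeat`): seeded
  generators with planted ground truth, so the entire pipeline runs and is
  tested without any downloads.

## Worked example: a phosphosite-combination scan

The package ships a synthetic 122-residue consensus-repeat-like IDP with
eleven proline-directed phosphosites and net charge +7e:

```r
library(phosphosep)

kc <- ki67_consensus_repeat()
sites <- candidate_proline_directed_sites(kc)
length(sites)
#> [1] 11

cs <- assign_charges(kc, "scdm")
net_charge(cs)
#> [1] 7

cp0 <- critical_point(free_energy_model(cs$charges, eps_fh = 2.5))
cp0$Tc; cp0$phic
#> [1] 2.940184
#> [1] 0.1838707
```

Scanning all 2048 phosphorylation patterns (a couple of minutes on one
core) shows the switch: partial phosphorylation moves the chain toward
charge neutrality and *raises* the critical temperature, while eight or
more sites overshoot to a strongly negative chain and *suppress* phase
separation below the unmodified level:

```r
scan <- phospho_scan(kc, eps_fh = 2.5)
aggregate(Tc ~ n_phospho, scan, range)
#>    n_phospho     Tc.min    Tc.max
#> 1          0   2.940184  2.940184
#> 2          1   3.182464  3.191627
#> 5          4   3.937184  4.005279
#> 9          8   2.851004  2.889361
#> 12        11   2.473042  2.473042
```

Every 11-site pattern sits below the unmodified critical temperature
(2.47 vs 2.94), every 1–6-site stoichiometry contains enhancers (up to
4.01 at four sites), and the crossover to uniform suppression happens at
eight sites. The same sequences can be compared by SCDM
(`scdm_composite(compute_scdm(nonP), compute_scdm(P))`) or simulated
directly (`simulate_chain(kc, 300, pattern = ...)`).

A FRAP trace fitted with the recovery model reports both half-time
conventions:

```r
fit <- fit_recovery(synth_frap(a = 0.6, k = 0.1, c = 1))
c(fit$k, fit$t_half_paper, fit$total_recovery)
#> [1]  0.10000 14.42695  1.00000
```

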