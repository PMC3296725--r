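# crypticfold

Reconciling the two free energies of protein unfolding — and predicting
what hides between them.

For a two-state protein the free energy of unfolding from an equilibrium
denaturation melt (ΔG_U) and the free energy of exchange from
native-state hydrogen/deuterium exchange (ΔG_HX, the mean of the four
largest residue-specific values) should agree.  In practice they rarely
do.  `crypticfold` works through the four recognised sources of the
discrepancy, in order:

1. **Intrinsic rates and exchange energetics.**  For every backbone
   amide the intrinsic (random-coil) rate is the three-channel sum

   k_rc = k_a·R_a·10^(−pD) + k_b·R_b·10^(pD−pK_D) + k_w·R_w

   with log-additive side-chain factors for the residue owning the NH
   and its left neighbour (cystine and cis/trans-proline variants are
   taken from the 3D structure), each channel Arrhenius-scaled from
   293 K with activation energies of 14/17/19 kcal/mol.  Under EX2
   conditions a measured k_ex gives the protection factor
   P = k_rc/k_ex and ΔG_HX = RT ln P.
2. **Cis–trans proline isomerization.**  Exchange reports only the
   first step of N ⇌ U(native isomer) ⇌ U(isomer mixture); the slow
   second step stabilises U by RT·Σ ln(1+K_i) per proline, where K_i is
   the unfolded-state equilibrium constant towards the non-native
   conformer (from tabulated cis fractions of Xaa–Pro model peptides).
   Subtracting it gives ΔG_HX\*.  Proline conformations are called from
   the structure: trans iff Cα(Xaa)–Cα(Pro) > Cα(Xaa)–Cδ(Pro).
3. **Melting-curve baselines.**  The two-state signal model
   S(C) = [S_n(C) + S_u(C)·e^(−(ΔG_U−mC)/RT)] / [1 + e^(−(ΔG_U−mC)/RT)]
   is fitted with linear, exponential or polynomial pre-/post-transition
   baselines (multi-start Levenberg–Marquardt); a non-linear baseline
   fit yields the corrected ΔG_U\* with C_m = ΔG_U/m.
4. **Cryptic intermediates / metastable states.**  Hydrogen-bonded
   amides (N···O ≤ 3.28 Å, both heavy-atom angles in 90–180°) in
   regular secondary structure (H-bond stretches plus ±30° torsion
   windows) are clustered by a binary contact-order matrix over
   backbone-nitrogen distances at 7 Å.  Two or more clusters are
   candidate cryptic unfolding intermediates, each with a free-energy
   coverage [min, max] of its residues' ΔG_HX (clusters with matching
   coverage form cooperative units).  A single cluster triggers the
   metastable-state search instead: all residues with
   ΔG_HX > ΔG_X = ΔG_U\* + (ΔG_HX − ΔG_HX\*) are clustered the same way.

Everything needed to exercise the pipeline is generated in code: ideal
helices and antiparallel sheets at exact torsions, two-island geometries
with planted cluster truth, melting curves with known parameters, and
synthetic reconstructions of published benchmark geometries (disulfide
networks, Xaa–Pro fragments, residue-group islands).

## Worked example

```r
library(crypticfold)
# A protein with two compact folded modules, 20 A apart, and
# residue-specific exchange free energies measured for both
fx <- build_two_island(separation = 20, residues_per_island = 8, seed = 2)
s  <- parse_pdb(fx$pdb_text)
hb <- detect_backbone_hbonds(s)
ss <- assign_secondary_structure(s, hb)
dg <- dg_map_from_table(s, fx$dg_table)

ledger <- energy_ledger(dg_u = 4.2, dg_hx = 6.6,
                        dg_u_star = 4.2, dg_hx_star = 6.3)
print(ledger)
pred <- predict_intermediates(s, ss, hb, dg, ledger)
print(pred)
```

```
energy_ledger (kcal/mol): dG_U 4.20 | dG_U* 4.20 | dG_HX 6.60 | dG_HX* 6.30 | dG_X 4.50
  dG_HX* vs dG_U : discrepant (tolerance 0.40)
  dG_HX* vs dG_U*: discrepant
intermediate_prediction: mode = cryptic_intermediates 
  cluster 1 (4 residues), coverage 4.26-5.89 kcal/mol
  cluster 2 (4 residues), coverage 1.77-2.64 kcal/mol
```

The 2.4 kcal/mol gap between ΔG_HX* and ΔG_U is too large for proline
isomerization alone (the 0.3 kcal/mol correction is already applied) and
the two spatially separated clusters — recovered exactly as planted —
are the structural reading: two weakly stabilised unfolding units whose
residues' exchange energies span distinct ranges, i.e. candidate cryptic
intermediates that a melting curve alone would miss.  Had the modules
been within 7 Å the single merged cluster would instead route the
analysis to the metastable-state search above ΔG_X = 4.5 kcal/mol.

A full run from files (structure, exchange table, optional melt) is one
call — `run_pipeline(run_config(...))` — or, from a shell, the thin CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","crypticfold.R",package="crypticfold"))')" \
    run-all --pdb protein.pdb --exchange exchange.tsv --dgu 4.2 \
    --ph 7.0 --temp 298 --out results/
```

It writes `rates.tsv`, `report.json` and one PDB file per cluster.

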