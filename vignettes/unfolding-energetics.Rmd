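---
title: "Unfolding energetics, exchange energetics, and the search for cryptic intermediates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unfolding energetics, exchange energetics, and the search for cryptic intermediates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypticfold)
```

## The problem

Two routes lead to a protein's stability.  A denaturation melt followed
by a two-state fit gives the free energy of unfolding, ΔG_U.
Native-state hydrogen/deuterium exchange, read residue by residue under
EX2 conditions, gives free energies of exchange whose four largest
values average to the global ΔG_HX.  For a clean two-state protein
measured under matched conditions the two numbers should coincide; the
recurring observation is that they do not.  The discrepancy carries
information, and this package decomposes it into its four recognised
sources: the cis–trans isomerization of Xaa–Pro bonds in the unfolded
state, inadequate treatment of melting-curve baselines, cryptic
unfolding intermediates (which depress ΔG_U), and higher-energy
metastable denatured states (which inflate ΔG_HX).

The pipeline takes a 3D structure, the scalars ΔG_U and ΔG_U\*, and
residue-specific exchange data (rates k_ex or free energies directly),
and walks the four stages in order, stopping as soon as the ledger
balances.

## Stage 1: intrinsic rates

Exchange from the open state proceeds through acid-, base- and
water-catalysed channels.  For the amide NH of residue *i*:

$$k_{rc} = k_a R_a\,10^{-pD} + k_b R_b\,10^{pD - pK_D} + k_w R_w$$

where each $R$ is the product of two log-additive side-chain factors —
one for residue *i* itself and one for its left neighbour *i−1* — and
pD is the pH-meter reading plus 0.4 in D₂O.  Each channel is scaled
from the 293 K reference to the experiment temperature by an Arrhenius
factor with activation energies of 14 (acid), 17 (base) and 19 (water)
kcal/mol; the gas constant is 1.9872×10⁻³ kcal mol⁻¹ K⁻¹ throughout,
rates are min⁻¹.

The reference constants and the per-residue factors are bundled as an
editable YAML file (`inst/extdata/intrinsic_rate_factors.yaml`,
poly-alanine basis, D₂O, 293 K) rather than hard-coded: the scheme is a
convention, and users who prefer another calibration — or who work in
H₂O, for which the bundled file is not valid — point the pipeline at a
replacement file of the same layout.  Three simplifications are
deliberate and documented here: the water channel shares the base
factors (the standard convention); pK_D is held at its 293 K value at
all temperatures; and ionic strength is recorded in every report but
applies no correction, because the bundled convention defines none.
Asp/Glu are treated as ionized and His as neutral — the factors are not
re-titrated against the run pD.

Structure awareness enters through two variant rows: cysteines whose
sulphur atoms sit within 2.3 Å of a partner (detected by greedy
nearest-pair matching, cutoff inclusive) use the cystine factors, and a
proline's contribution to its right-hand neighbour depends on whether
its imide bond is cis or trans.  That call is purely geometric: trans
iff Cα(Xaa)–Cα(Pro) exceeds Cα(Xaa)–Cδ(Pro).  The first residue of a
chain carries a free amine rather than an amide, so it contributes no
rate of its own; residue 2 and the chain's last residue receive the
N- and C-terminal correction factors.

With measured EX2 rates in hand, each residue gets a protection factor
$P = k_{rc}/k_{ex}$ and $\Delta G_{HX} = RT\,\ln P$; the global value
is the mean of the four largest (with fewer than four residues the mean
of all, under protest).

## Stage 2: the proline correction

Unfolding with prolines is effectively three-state,
$N \rightleftharpoons U_{native\ isomer} \rightleftharpoons U_{mixture}$:
isomerization is slow on the exchange timescale, so H/D exchange senses
only the first step while a melt senses both.  The unfolded-state
isomer equilibrium stabilises U by $RT\ln(1+K)$ per proline, so

$$\Delta G_{HX}^{*} = \Delta G_{HX} - RT \sum_i \ln(1 + K_i),
\qquad K_i = \begin{cases} f_i/(1-f_i) & \text{native trans}\\
(1-f_i)/f_i & \text{native cis}\end{cases}$$

with $f_i$ the unfolded-state cis fraction for the preceding residue
type.  The correction is always a decrease, small for native-trans
prolines (~0.05–0.1 kcal/mol each at typical $f$) and large for
native-cis ones (1–1.5 kcal/mol), which is exactly the asymmetry seen
in published ledgers.  This subtractive form is the only one that
reproduces both the small group-wise corrections of proteins whose
discrepancy vanishes after the correction and the worked
metastable-threshold value used in stage 4.

The cis fractions live in `inst/extdata/proline_cis_fractions.tsv`,
chosen once to span the 6–38 % range reported for Xaa–Pro model
peptides: aromatic Xaa high (Trp 0.37, Tyr 0.24 — the one value
directly attested for model compounds — Phe 0.33), β-branched and
other aliphatics low (Ile/Leu/Val/Cys 0.10, Thr 0.08), glycine at the
bottom (0.06), everything else intermediate.  A user-supplied table
(e.g. protein-derived constants) replaces the file wholesale.  The
correction temperature defaults to the exchange experiment's; reported
ledger values are conventionally read at 0.1 kcal/mol resolution while
full precision is kept internally.

If $|\Delta G_{HX}^{*} - \Delta G_U| \le$ 0.4 kcal/mol (the default
tolerance, inclusive, reflecting the typical total contribution of
trans prolines) the discrepancy is accounted for and the pipeline
stops.

## Stage 3: baselines

The melt is fitted to

$$S(C) = \frac{S_n(C) + S_u(C)\,e^{-(\Delta G_U - mC)/RT}}
              {1 + e^{-(\Delta G_U - mC)/RT}}$$

with each limb's baseline independently linear
($Y + m_{side} C$), exponential ($I_c + I_0 e^{-C/s}$, $s>0$) or
polynomial (degree 2 by default; degrees above 3 are rejected because a
high-order baseline can absorb the transition itself).  The exponential
form encodes a folded-state signal that relaxes to an asymptote before
the transition; its amplitude is tied to the zero-denaturant signal,
$I_0 = S_n(0) - I_c$, an assumption we flag because the functional form
is pluggable.  Whether the decay scale $s$ is fitted or fixed is a free
choice; it is fitted here.

Fitting is multi-start Levenberg–Marquardt: 20 candidate midpoints on a
grid across the observed concentration range, $m$ seeded from the
transition's maximum slope via $dS/dC|_{C_m} = (S_u-S_n)m/4RT$,
baseline starts from the curve's extremes, best residual wins, fixed
order so the result is deterministic.  $m$ is bounded positive (an
unfolding transition), $s$ bounded away from zero, and
$C_m = \Delta G_U/m$ by construction.  A curve that a straight line
explains as well as the two-state model is rejected as having no
resolvable transition, as are fits whose midpoint falls far outside the
observed range.  An optional `weights` argument (inverse variances)
makes the fit efficient when the noise is heteroscedastic — e.g.
optical signals with constant *relative* error; synthetic-recovery
checks in the test suite use exactly that noise model, per-point
Gaussian noise with σ equal to 1 % of the noiseless signal.  When either
baseline is non-linear the fitted ΔG_U is reported as the
baseline-corrected ΔG_U\*.

## Stage 4: contact-order clustering

Candidate amides are those that (i) donate a backbone hydrogen bond,
(ii) sit in regular secondary structure, and (iii) carry a measured
ΔG_HX.  Hydrogen bonds use heavy-atom criteria only — N···O ≤ 3.28 Å
with both the acceptor angle N—O=C and the donor angle O—N—Cα inside
[90°, 180°], all bounds inclusive — because deposited structures
usually lack hydrogens; explicit H atoms are ignored, prolines never
donate, peptide-bonded pairs are excluded (the amide N is covalently
attached to the preceding carbonyl carbon), and when several acceptors
qualify the shortest N···O wins (one H per amide).  Regular secondary
structure demands both a hydrogen-bond pattern — a stretch of at least
two consecutive i→i+4 (α) or i→i+3 (3₁₀) bonds, or a ladder of at
least two registered sheet rungs (antiparallel: N_i→O_j with N_j→O_i,
progressing i+2/j−2; parallel: N_i→O_{j−1} with N_{j+1}→O_i,
progressing i+2/j+2) — and torsions inside the class window, centre
±30° around (−57, −47), (−60, −30), (−139, 135) and (−119, −113)
respectively.  "At least two" is the smallest defensible reading of a
"stretch" and is exposed as a parameter.  H-bonded NHs in loops or at
the surface are excluded from candidacy because they exchange through
local fluctuations, not through the unfolding events of interest.

The contact-order matrix over the candidates is binary: 1 when the two
backbone nitrogens (explicitly N, not Cα) are within 7 Å, inclusive.
Clusters are the connected components; residues with no partner are
reported as unclustered singletons, not as intermediates, because a
group is defined by having at least one in-group contact.  Output order
is descending size with ties broken by smallest author residue number —
author numbering with chain id is the universal residue key throughout,
since that is how published residue lists are written.  Each cluster
carries its free-energy coverage (the [min, max] of members' ΔG_HX) and
clusters whose coverage endpoints both agree within the global 0.4
kcal/mol tolerance are flagged as cooperative units; the endpoint rule
is our operationalisation of "same coverage", and the tolerance is
configurable.

Two or more clusters ⇒ candidate cryptic intermediates.  Exactly one ⇒
the metastable search: all residues (not only candidates) with
$\Delta G_{HX} > \Delta G_X$, strictly, where
$\Delta G_X = \Delta G_U^{*} + (\Delta G_{HX} - \Delta G_{HX}^{*})$,
are selected and subdivided by the same contact machinery.  Per-cluster
coordinate subsets are written as standard PDB text.

## Parsing and structural conventions

Parsing is delegated to `bio3d::read.pdb`: ATOM records only, waters
and HETATMs dropped, alternate locations other than ' '/'A' removed,
and only the first MODEL of an NMR ensemble — published per-protein
geometry tables report single values, and whether they derive from the
first model or an ensemble average is not stated, so first-model is the
assumption.  Side-chain acceptors are not considered (the stage-4
question concerns backbone NHs); there is no hydrogen placement and no
full secondary-structure method beyond the printed criteria.

## The synthetic-data generators

Every test input is built in code.  Backbone builders place N/CA/C/O
atoms by internal coordinates (N–Cα 1.458, Cα–C 1.525, C–N 1.329,
C–O 1.231 Å, ω = 180°) at exact torsions, so an ideal helix at
(−57, −47) provably carries its i→i+4 ladder within the 3.28 Å
criterion, and a two-strand antiparallel sheet is assembled by a
deterministic rigid-placement optimisation that realises the rung
network at ~2.9 Å.  Two-island fixtures plant cluster truth (compact
modules at a requested separation, free energies drawn from distinct
ranges under a fixed seed); melting-curve fixtures evaluate the signal
model and add seeded noise.  All builders are byte-reproducible given
their arguments.

For published point measurements on proteins whose deposited
coordinates are not bundled with the package, the fixtures module
builds *synthetic reconstructions*: minimal geometries in which the
published quantities (S–S separations, Cα–Cα/Cα–Cδ distances,
residue-group islands) are planted exactly, with the real sequences
supplying residue identities.  Tests on these fixtures verify that the
measurement, classification and clustering machinery reproduces the
published calls end-to-end from coordinates realising those values;
they do not re-derive the values from the deposited crystallographic or
NMR coordinates, and they say nothing about parsing those particular
entries.  Likewise the generators emulate clean backbone geometry and
EX2 statistics only: no side chains beyond Cβ-free poly-alanine, no
missing atoms or altloc pathology, no EX1 mixing — so passing tests
demonstrate correctness of the algorithms under stated assumptions, not
robustness to every pathology of real depositions.

Problem sizes used by the shipped suite were chosen to keep the whole
run in well under a minute of CPU while still exercising every path:
structures of 10–60 residues, 100-seed clustering-oracle sweeps at ≤ 40
residues, and 50-seed melt-recovery sweeps at 40 points per curve.

## Numerical choices and degenerate inputs

All geometric cutoffs are inclusive (≤ 2.3 Å, ≤ 3.28 Å, ≤ 7 Å, angle
bounds, the 0.4 kcal/mol tolerance — the last with a 10⁻⁹ slack so the
boundary survives decimal-to-binary representation).  Distances agree
with brute-force recomputation from raw coordinates to 10⁻⁹ Å.
Cysteines lacking an SG atom are excluded from disulfide search with a
warning; an N-terminal proline cannot be classified and is skipped with
a warning; a proline missing its Cδ is an error naming the residue.
Exchange tables must carry exactly one of k_ex or dG_hx; non-positive
rates are rejected.  Ties in the cis/trans distance rule (equal
distances) read as cis by the strict `d_caca > d_cacd` trans test, a
measure-zero case in practice.

## Known limitations

No EX1 kinetics, no k_op/k_cl estimation, no side-chain exchange, no
denaturant dependence of residue-level ΔG_HX, no thermal-melt
(ΔH/ΔCp) fitting, no three-state melt models, and no automatic
baseline-kind selection (the user chooses; AIC is reported for
information).  The free-energy-landscape and kinetic interpretation of
predicted clusters is outside the package's claims: a cluster is a
structural hypothesis to be tested by denaturant-dependent exchange or
NMR/MS, not a demonstrated intermediate.
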