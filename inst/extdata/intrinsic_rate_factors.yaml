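# Intrinsic (random-coil) amide exchange reference rates and side-chain
# neighbour factors, poly-DL-alanine basis, D2O solvent, 293 K.
# Bundled from the standard model-compound convention for backbone amide
# H/D exchange; all factors are log10 units.  For each amide NH the acid,
# base and water channels are
#   k = ka * 10^(a_self(i) + a_prev(i-1)) * 10^(-pD)
#     + kb * 10^(b_self(i) + b_prev(i-1)) * 10^(pD - pKD)
#     + kw * 10^(w_self(i) + w_prev(i-1))
# where "self" is the residue owning the NH and "prev" its left
# neighbour.  Water-channel factors follow the base-channel factors by
# convention.  NTERM adds to the *_prev sum of the second residue (free
# N-terminal amine); CTERM adds to the *_self sum of the last residue
# (ionized carboxylate).  Users may supply a replacement file with the
# same layout (e.g. for H2O-solvent reference rates).
version: "1.0"
solvent: D2O
temperature_ref: 293
log_ka: 1.62        # per-molar per-minute, acid channel
log_kb: 10.05       # per-molar per-minute, base channel
log_kw: -1.5        # per-minute, water channel
pKD: 15.05          # molar ionization constant of D2O at 293 K
activation_energies:   # kcal/mol
  acid: 14
  base: 17
  water: 19
factors:
  #        acid_self acid_prev base_self base_prev
  ALA:     [ 0.00,  0.00,  0.00,  0.00]
  ARG:     [-0.59, -0.32,  0.08,  0.22]
  ASN:     [-0.58, -0.13,  0.49,  0.32]
  ASP:     [-0.90, -0.12,  0.69,  0.60]   # ionized carboxylate
  CYS:     [-0.54, -0.46,  0.62,  0.55]   # free thiol
  CYS2:    [-0.74, -0.58,  0.55,  0.46]   # cystine (disulfide-bonded)
  GLN:     [-0.47, -0.27,  0.06,  0.20]
  GLU:     [-0.90, -0.31, -0.51, -0.15]   # ionized carboxylate
  GLY:     [-0.22,  0.22,  0.27,  0.17]
  HIS:     [ 0.00,  0.00, -0.10,  0.14]   # neutral imidazole
  ILE:     [-0.91, -0.59, -0.73, -0.23]
  LEU:     [-0.57, -0.13, -0.58, -0.21]
  LYS:     [-0.56, -0.29, -0.04,  0.12]
  MET:     [-0.64, -0.28, -0.01,  0.11]
  PHE:     [-0.52, -0.43, -0.24,  0.06]
  PRO:     [ 0.00, -0.19,  0.00, -0.24]   # trans imide bond
  PRO_CIS: [ 0.00, -0.85,  0.00,  0.60]   # cis imide bond
  SER:     [-0.44, -0.39,  0.37,  0.30]
  THR:     [-0.79, -0.47, -0.07,  0.20]
  TRP:     [-0.40, -0.44, -0.41, -0.11]
  TYR:     [-0.41, -0.37, -0.27,  0.05]
  VAL:     [-0.74, -0.30, -0.70, -0.14]
  NTERM:   [ 0.00, -1.32,  0.00,  1.62]   # free N-terminal amine (prev slot)
  CTERM:   [ 0.96,  0.00, -1.80,  0.00]   # C-terminal carboxylate (self slot)
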