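# Synthetic input generators.  Everything the test-suite and the examples
# consume can be built here from code: ideal secondary-structure
# coordinates (poly-alanine backbones with exact torsions), two-island
# geometries with planted cluster truth, melting curves with known
# parameters, and small synthetic benchmark geometries that reproduce
# published point measurements (cystine S-S distances, Xaa-Pro distances,
# contact-island memberships) for proteins whose deposited coordinates are
# not bundled.  All builders are deterministic given their arguments and a
# seed.

# run expr with a temporarily-seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Build an n-residue poly-alanine backbone (N, CA, C, O) with the given
# per-residue torsions; returns an atom data frame.  phi/psi may be
# scalars or length-n vectors; omega is fixed at 180.
build_backbone <- function(n, phi, psi, chain = "A", resno = seq_len(n),
                           resid = "ALA") {
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  resid <- rep_len(resid, n)
  b <- cf_constants$bond
  a <- cf_constants$angle
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b["n_ca"], 0, 0)
  ang <- a["n_ca_c"] * pi / 180
  C[1, ] <- CA[1, ] + b["ca_c"] * c(-cos(ang), sin(ang), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         b["c_n"], a["ca_c_n"], psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          b["n_ca"], a["c_n_ca"], 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         b["ca_c"], a["n_ca_c"], phi[i])
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         b["c_o"], a["ca_c_o"], psi[i] + 180)
  }
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(chain = chain, resno = resno[i], insert = "",
               resid = resid[i], elety = c("N", "CA", "C", "O"),
               x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
               y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
               z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
               stringsAsFactors = FALSE)
  }))
  atoms
}

atoms_to_pdb_text <- function(atoms) {
  paste(c(format_pdb_atoms(atoms), "END"), collapse = "\n")
}

rigid_transform <- function(m, rot = c(0, 0, 0), trans = c(0, 0, 0)) {
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  t(Rz %*% Ry %*% Rx %*% t(m)) + matrix(trans, nrow(m), 3, byrow = TRUE)
}

#' Ideal alpha-helix fixture
#'
#' Poly-alanine backbone with exact (phi, psi) torsions; the default
#' (-57, -47) produces the canonical i -> i+4 hydrogen-bond ladder with
#' every N...O within the 3.28 A criterion.
#'
#' @param n_residues Number of residues (at least 6).
#' @param phi,psi Backbone torsions in degrees.
#' @return PDB-format text.
#' @export
build_ideal_helix <- function(n_residues, phi = -57, psi = -47) {
  if (n_residues < 6) stop("an ideal helix fixture needs at least 6 residues")
  atoms_to_pdb_text(build_backbone(n_residues, phi, psi))
}

#' Extended-chain fixture
#'
#' Fully extended poly-alanine (phi = psi = 180) with no backbone
#' hydrogen bonds.
#'
#' @param n_residues Number of residues.
#' @return PDB-format text.
#' @export
build_extended_chain <- function(n_residues) {
  atoms_to_pdb_text(build_backbone(n_residues, 180, 180))
}

#' Ideal two-strand antiparallel sheet fixture
#'
#' Two poly-alanine strands at sheet torsions (-139, 135), rigidly placed
#' (by deterministic numerical optimisation) so that the antiparallel
#' rung pattern N_i -> O_j / N_j -> O_i forms between registered partner
#' residues.  With the default strand length 6 the rungs are
#' (2,15), (4,13), (6,11) in residue numbering 1..6 / 11..16.
#'
#' @param n_per_strand Residues per strand (even, at least 4).
#' @return PDB-format text.
#' @export
build_ideal_hairpin <- function(n_per_strand = 6) {
  if (n_per_strand < 4 || n_per_strand %% 2 != 0) {
    stop("n_per_strand must be an even number >= 4")
  }
  n <- n_per_strand
  s1 <- build_backbone(n, -139, 135, resno = seq_len(n))
  s2 <- build_backbone(n, -139, 135, resno = seq(n + 5, n + 4 + n))
  xyz1 <- as.matrix(s1[, c("x", "y", "z")])
  xyz2 <- as.matrix(s2[, c("x", "y", "z")])
  # target rungs (i in strand 1, j in strand 2 residue numbering)
  ii <- seq(2, n, by = 2)
  jj <- (2 * n + 6) - ii - 1   # e.g. n=6: i=2,4,6 -> j=15,13,11
  idx <- function(atoms, resno, elety) {
    which(atoms$resno == resno & atoms$elety == elety)
  }
  obj <- function(p) {
    m2 <- rigid_transform(xyz2, rot = p[1:3], trans = p[4:6])
    err <- 0
    for (k in seq_along(ii)) {
      i <- ii[k]; j <- jj[k]
      dno1 <- vdist(xyz1[idx(s1, i, "N"), ], m2[idx(s2, j, "O"), ])
      dno2 <- vdist(m2[idx(s2, j, "N"), ], xyz1[idx(s1, i, "O"), ])
      err <- err + (dno1 - 2.9)^2 + (dno2 - 2.9)^2
    }
    # keep CA atoms from clashing
    ca1 <- xyz1[s1$elety == "CA", , drop = FALSE]
    ca2 <- m2[s2$elety == "CA", , drop = FALSE]
    dmin <- min(as.matrix(stats::dist(rbind(ca1, ca2)))[
      seq_len(nrow(ca1)), nrow(ca1) + seq_len(nrow(ca2))])
    err + max(0, 3.8 - dmin)^2 * 10
  }
  # antiparallel start: flip strand 2 end-over-end and offset sideways
  p0 <- c(pi, 0, 0, mean(xyz1[, 1]) - mean(xyz2[, 1]), 4.8, 0)
  fit <- stats::optim(p0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  m2 <- rigid_transform(xyz2, rot = fit$par[1:3], trans = fit$par[4:6])
  s2$x <- m2[, 1]; s2$y <- m2[, 2]; s2$z <- m2[, 3]
  atoms_to_pdb_text(rbind(s1, s2))
}

#' Two-island fixture with planted cluster truth
#'
#' Two compact helical islands whose centroids are separated by a
#' requested distance, plus a residue free-energy table drawn from two
#' distinct ranges.  The ground truth (island membership) is returned so
#' cluster-recovery can be asserted.
#'
#' @param separation Centroid separation in Angstrom.
#' @param residues_per_island Number of residues per island.
#' @param seed RNG seed for the free-energy draws.
#' @param dg_ranges List of two length-2 numeric ranges (kcal/mol).
#' @return List: `pdb_text`, `dg_table` (data frame residue, dg_hx),
#'   `truth` (data frame residue, island).
#' @export
build_two_island <- function(separation, residues_per_island = 8, seed = 1,
                             dg_ranges = list(c(4, 6), c(1.5, 3))) {
  if (separation <= 0) stop("separation must be positive")
  n <- residues_per_island
  i1 <- build_backbone(n, -57, -47, resno = seq_len(n))
  i2 <- build_backbone(n, -57, -47, resno = seq(n + 11, n + 10 + n))
  shift <- function(atoms, by) {
    atoms$x <- atoms$x + by[1]; atoms$y <- atoms$y + by[2]
    atoms$z <- atoms$z + by[3]; atoms
  }
  c1 <- colMeans(i1[, c("x", "y", "z")])
  c2 <- colMeans(i2[, c("x", "y", "z")])
  i2 <- shift(i2, c1 - c2 + c(separation, 0, 0))
  dg <- with_seed(seed, c(
    stats::runif(n, dg_ranges[[1]][1], dg_ranges[[1]][2]),
    stats::runif(n, dg_ranges[[2]][1], dg_ranges[[2]][2])
  ))
  resno <- c(seq_len(n), seq(n + 11, n + 10 + n))
  list(
    pdb_text = atoms_to_pdb_text(rbind(i1, i2)),
    dg_table = data.frame(residue = resno, dg_hx = dg),
    truth = data.frame(residue = resno,
                       island = rep(1:2, each = n))
  )
}

#' Synthetic melting curve with known parameters
#'
#' Evaluates the two-state signal model on an even concentration grid and
#' adds seeded Gaussian noise.
#'
#' @param dg_u,m Thermodynamic parameters (kcal/mol, kcal/mol/M).
#' @param pre,post Baseline models from [make_baseline()].
#' @param noise_sd Noise standard deviation in signal units; either a
#'   scalar or a vector recycled over the concentration grid (e.g.
#'   proportional noise, 1% of the noiseless signal).
#' @param seed RNG seed.
#' @param n_points Number of concentrations.
#' @param c_max Maximum denaturant molarity (default 2.5 * Cm).
#' @param temperature Kelvin.
#' @return A `melting_curve` data frame (concentration, signal).
#' @export
build_melting_curve <- function(dg_u, m, pre, post, noise_sd = 0, seed = 1,
                                n_points = 40, c_max = NULL,
                                temperature = 288) {
  if (is.null(c_max)) c_max <- 2.5 * dg_u / m
  conc <- seq(0, c_max, length.out = n_points)
  sig <- two_state_signal(conc, dg_u, m, pre, post, temperature)
  if (any(noise_sd > 0)) {
    sig <- sig + with_seed(seed, stats::rnorm(n_points, 0,
                                              rep_len(noise_sd, n_points)))
  }
  curve <- data.frame(concentration = conc, signal = sig)
  class(curve) <- c("melting_curve", "data.frame")
  curve
}

#' Synthetic cystine/cysteine benchmark geometry
#'
#' Builds a minimal structure (N, CA, SG atoms per cysteine) in which the
#' listed residue pairs have exactly the requested S-S distances and all
#' other inter-pair sulphur distances are large.  This is a synthetic
#' stand-in used to exercise disulfide detection against published point
#' measurements when the deposited coordinates of a protein are not
#' available locally.
#'
#' @param pairs Data frame with columns resno_a, resno_b, distance.
#' @param free Optional data frame with columns resno_a, resno_b, distance
#'   for free-cysteine pairs placed beyond the cutoff.
#' @return PDB-format text.
#' @export
build_cystine_benchmark <- function(pairs, free = NULL) {
  blocks <- list()
  origin_x <- 0
  add_pair <- function(ra, rb, d, x0) {
    mk <- function(resno, sgx, sgy) {
      data.frame(chain = "A", resno = resno, insert = "", resid = "CYS",
                 elety = c("N", "CA", "SG"),
                 x = c(x0 + sgx, x0 + sgx + 1.45, x0 + sgx),
                 y = c(sgy + 2.4, sgy + 2.4, sgy),
                 z = c(0, 0, 0), stringsAsFactors = FALSE)
    }
    rbind(mk(ra, 0, 0), mk(rb, 0, -d))
  }
  all <- rbind(pairs, free)
  for (r in seq_len(nrow(all))) {
    blocks[[r]] <- add_pair(all$resno_a[r], all$resno_b[r], all$distance[r],
                            origin_x)
    origin_x <- origin_x + 40
  }
  atoms <- do.call(rbind, blocks)
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  atoms_to_pdb_text(atoms)
}

#' Synthetic Xaa-Pro benchmark geometry
#'
#' Builds isolated Xaa-Pro fragments in which the CA(Xaa)-CA(Pro) and
#' CA(Xaa)-CD(Pro) distances equal the requested values exactly, so that
#' cis/trans classification can be exercised against published
#' measurements.  Synthetic stand-in; not deposited coordinates.
#'
#' @param table Data frame with columns resno (proline author number),
#'   d_caca, d_cacd, and optionally left_resid (3-letter code of the
#'   preceding residue, default "ALA").
#' @return PDB-format text.
#' @export
build_proline_benchmark <- function(table) {
  if (is.null(table$left_resid)) table$left_resid <- "ALA"
  r_cacd <- 2.4  # CA(Pro)-CD(Pro) separation used for the construction
  blocks <- list()
  z0 <- 0
  for (r in seq_len(nrow(table))) {
    d1 <- table$d_caca[r]; d2 <- table$d_cacd[r]
    # left CA at origin, Pro CA on x-axis, Pro CD in the xy-plane
    x <- (d1^2 + d2^2 - r_cacd^2) / (2 * d1)
    y2 <- d2^2 - x^2
    if (y2 < 0) stop("requested distances are not geometrically realisable")
    # one chain per fragment so that consecutive prolines never collide
    ch <- LETTERS[(r - 1) %% 26 + 1]
    left <- data.frame(chain = ch, resno = table$resno[r] - 1, insert = "",
                       resid = table$left_resid[r], elety = c("N", "CA"),
                       x = c(-1.2, 0), y = c(0.8, 0), z = z0,
                       stringsAsFactors = FALSE)
    pro <- data.frame(chain = ch, resno = table$resno[r], insert = "",
                      resid = "PRO", elety = c("N", "CA", "CD"),
                      x = c(d1 - 1.0, d1, x),
                      y = c(1.0, 0, sqrt(y2)), z = z0,
                      stringsAsFactors = FALSE)
    blocks[[r]] <- rbind(left, pro)
    z0 <- z0 + 25
  }
  atoms_to_pdb_text(do.call(rbind, blocks))
}

#' Synthetic contact-island benchmark geometry
#'
#' Places backbone nitrogen "beads" (with CA companions) for named
#' residues so that consecutive members of each group are within the
#' contact cutoff (path-connected) while distinct groups are far apart.
#' Used as a synthetic stand-in for cluster-membership benchmarks on
#' proteins whose deposited coordinates are not available locally.
#'
#' @param groups List of integer vectors of author residue numbers.
#' @param resids Optional list (parallel to `groups`) of 3-letter residue
#'   codes; default poly-alanine.
#' @param spacing Distance between consecutive members of a group (A).
#' @param gap Distance between group baselines (A); must exceed the
#'   contact cutoff.
#' @return PDB-format text.
#' @export
build_contact_islands <- function(groups, resids = NULL, spacing = 5,
                                  gap = 30) {
  blocks <- list()
  for (g in seq_along(groups)) {
    resno <- groups[[g]]
    rid <- if (is.null(resids)) rep("ALA", length(resno)) else resids[[g]]
    for (k in seq_along(resno)) {
      blocks[[length(blocks) + 1]] <- data.frame(
        chain = "A", resno = resno[k], insert = "", resid = rid[k],
        elety = c("N", "CA"),
        x = c(spacing * (k - 1), spacing * (k - 1) + 1.0),
        y = c(gap * (g - 1), gap * (g - 1) + 1.0),
        z = 0, stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, blocks)
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  atoms_to_pdb_text(atoms)
}

#' Synthetic multi-sheet benchmark with a planted candidate count
#'
#' Assembles several ideal two-strand antiparallel sheets, spatially
#' separated, inside one chain.  By construction each sheet contributes a
#' known set of hydrogen-bonded donors in regular secondary structure
#' (for strand length 6: four qualified donors per sheet), so the
#' candidate-selection count of the whole fixture is known exactly.
#'
#' @param n_sheets Number of two-strand sheets.
#' @param n_per_strand Residues per strand (default 6).
#' @return List: `pdb_text`, `expected_donors` (author residue numbers
#'   whose NH is a qualified candidate), `n_residues`.
#' @export
build_sheet_battery <- function(n_sheets, n_per_strand = 6) {
  one <- build_ideal_hairpin(n_per_strand)
  s0 <- parse_pdb(one)$atoms
  span <- max(s0$resno)
  blocks <- list()
  expected <- integer()
  for (k in seq_len(n_sheets)) {
    b <- s0
    b$resno <- b$resno + (k - 1) * (span + 4)
    b$z <- b$z + (k - 1) * 40
    blocks[[k]] <- b
    # interior rung donors of each sheet (see build_ideal_hairpin): rung
    # donors are 2,4,...,n and the partner strand's mirror; strand-end
    # residues lose a torsion across the chain gap and drop out
    n <- n_per_strand
    ii <- seq(2, n, by = 2)
    jj <- (2 * n + 6) - ii - 1
    donors <- sort(c(ii, jj))
    donors <- donors[donors > 1 & donors < 2 * n + 4 &
                       donors != n & donors != n + 5]
    expected <- c(expected, donors + (k - 1) * (span + 4))
  }
  atoms <- do.call(rbind, blocks)
  list(pdb_text = atoms_to_pdb_text(atoms),
       expected_donors = sort(expected),
       n_residues = n_sheets * 2 * n_per_strand)
}
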