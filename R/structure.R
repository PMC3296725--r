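# Structural model: PDB parsing and all geometry used by the pipeline
# (disulfides, proline isomer state, backbone hydrogen bonds, secondary
# structure, backbone-nitrogen distances).  Parsing is delegated to
# bio3d::read.pdb; this file owns the residue bookkeeping and the printed
# geometric criteria.

#' Parse PDB-format text into a protein structure
#'
#' Reads standard PDB ATOM records (wwPDB v3.3 columns) into a
#' `protein_structure` object.  HETATM records and waters are ignored;
#' alternate locations other than `' '`/`'A'` are dropped; for multi-model
#' (NMR) files only the first MODEL is used.
#'
#' @param pdb_text Character scalar (possibly multi-line) or character
#'   vector of lines containing PDB-format text.
#' @param id Optional identifier stored on the object.
#' @return An object of class `protein_structure` with elements `atoms`
#'   (data frame: chain, resno, insert, resid, elety, x, y, z), `residues`
#'   (one row per residue, in file order, with a unique `key`), and `id`.
#' @seealso [read_structure()] to read from a file path.
#' @export
parse_pdb <- function(pdb_text, id = "structure") {
  lines <- unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n"))
  if (!any(grepl("^ATOM", lines))) {
    stop("no ATOM records found: cannot build a structure from this text")
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  read_structure(tf, id = id)
}

#' Read a protein structure from a PDB file
#'
#' @param path Path to a PDB-format file.
#' @inheritParams parse_pdb
#' @return A `protein_structure`; see [parse_pdb()].
#' @export
read_structure <- function(path, id = basename(path)) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                          verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "DOD", "WAT")), , drop = FALSE]
  if (nrow(at) == 0) stop("structure is empty after removing HETATM/waters")
  bad <- !is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)
  if (any(bad)) {
    stop("malformed coordinate field for atom serial ",
         paste(at$eleno[bad], collapse = ", "))
  }
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = at$elety,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  key <- res_key(atoms$chain, atoms$resno, atoms$insert)
  # drop duplicate atom names within a residue (first wins; can arise from
  # unusual altloc schemes)
  atoms <- atoms[!duplicated(paste(key, atoms$elety)), , drop = FALSE]
  key <- res_key(atoms$chain, atoms$resno, atoms$insert)
  first <- !duplicated(key)
  residues <- data.frame(
    key = key[first],
    chain = atoms$chain[first], resno = atoms$resno[first],
    insert = atoms$insert[first], resid = atoms$resid[first],
    stringsAsFactors = FALSE
  )
  residues$seqpos <- seq_len(nrow(residues))
  if (anyDuplicated(residues$key)) {
    stop("residue identifiers (chain, number, insertion code) are not unique")
  }
  if (!any(atoms$elety == "N")) {
    stop("no backbone nitrogen atoms found; not a protein structure")
  }
  s <- structure(list(atoms = atoms, residues = residues, id = id),
                 class = "protein_structure")
  s
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure '", x$id, "': ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " atoms, chains: ",
      paste(unique(x$residues$chain), collapse = " "), "\n", sep = "")
  invisible(x)
}

# canonical residue key "chain:resno:insert"
res_key <- function(chain, resno, insert = "") {
  insert[is.na(insert)] <- ""
  paste(chain, resno, insert, sep = ":")
}

# one-letter code + author number, the labelling used in result tables
# (e.g. "C3" for Cys3)
residue_label <- function(s, keys) {
  i <- match(keys, s$residues$key)
  paste0(bio3d::aa321(s$residues$resid[i]), s$residues$resno[i])
}

# resolve residue selectors (key strings or author residue numbers) to keys
resolve_keys <- function(s, residues) {
  if (is.numeric(residues)) {
    i <- match(residues, s$residues$resno)
    if (anyNA(i)) {
      stop("unknown residue number(s): ",
           paste(residues[is.na(i)], collapse = ", "))
    }
    return(s$residues$key[i])
  }
  miss <- setdiff(residues, s$residues$key)
  if (length(miss)) stop("unknown residue key(s): ", paste(miss, collapse = ", "))
  residues
}

# coordinates of one named atom of one residue (numeric(3), or NULL)
atom_xyz <- function(s, key, elety) {
  a <- s$atoms
  i <- which(res_key(a$chain, a$resno, a$insert) == key & a$elety == elety)
  if (length(i) == 0) return(NULL)
  c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
}

# coordinate matrix for a given atom name across a set of residue keys
# (rows in the order of `keys`; NA rows where the atom is absent)
atom_matrix <- function(s, keys, elety) {
  a <- s$atoms[s$atoms$elety == elety, , drop = FALSE]
  akey <- res_key(a$chain, a$resno, a$insert)
  i <- match(keys, akey)
  m <- cbind(a$x[i], a$y[i], a$z[i])
  rownames(m) <- keys
  m
}

#' Detect disulfide bridges
#'
#' Pairs cysteine residues whose sulphur (SG) atoms lie within the cutoff
#' distance, using greedy nearest-pair matching, and reports all remaining
#' cysteines as free with their nearest SG-SG distance.
#'
#' @param s A `protein_structure`.
#' @param cutoff Maximum S-S distance of a cystine bridge in Angstrom
#'   (inclusive; default 2.3).
#' @return An object of class `disulfide_assignment`: list with `pairs`
#'   (data frame: key_a, key_b, label_a, label_b, distance), `free`
#'   (data frame: key, label, nearest_sg), and `unresolvable` (keys of
#'   cysteines lacking an SG atom).
#' @export
detect_disulfides <- function(s, cutoff = cf_constants$disulfide_cutoff) {
  cys <- s$residues$key[s$residues$resid == "CYS"]
  sg <- atom_matrix(s, cys, "SG")
  bad <- cys[apply(sg, 1, function(r) any(is.na(r)))]
  if (length(bad)) {
    warning("cysteine(s) lacking an SG atom excluded from disulfide search: ",
            paste(residue_label(s, bad), collapse = ", "))
  }
  cys <- setdiff(cys, bad)
  sg <- sg[cys, , drop = FALSE]
  n <- length(cys)
  pairs <- data.frame(key_a = character(), key_b = character(),
                      label_a = character(), label_b = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  nearest <- rep(NA_real_, n)
  if (n >= 2) {
    d <- as.matrix(stats::dist(sg))
    diag(d) <- Inf
    nearest <- apply(d, 1, min)
    unpaired <- rep(TRUE, n)
    repeat {
      dd <- d
      dd[!unpaired, ] <- Inf
      dd[, !unpaired] <- Inf
      m <- min(dd)
      if (!is.finite(m) || m > cutoff) break
      ij <- which(dd == m, arr.ind = TRUE)[1, ]
      i <- min(ij); j <- max(ij)
      pairs <- rbind(pairs, data.frame(
        key_a = cys[i], key_b = cys[j],
        label_a = residue_label(s, cys[i]), label_b = residue_label(s, cys[j]),
        distance = m, stringsAsFactors = FALSE
      ))
      unpaired[c(i, j)] <- FALSE
    }
    free_idx <- which(unpaired)
  } else {
    free_idx <- seq_len(n)
  }
  free <- data.frame(key = cys[free_idx],
                     label = if (length(free_idx)) residue_label(s, cys[free_idx]) else character(),
                     nearest_sg = nearest[free_idx],
                     stringsAsFactors = FALSE)
  structure(list(pairs = pairs, free = free, unresolvable = bad,
                 cutoff = cutoff),
            class = "disulfide_assignment")
}

#' @export
print.disulfide_assignment <- function(x, ...) {
  cat("disulfide_assignment: ", nrow(x$pairs), " cystine pair(s), ",
      nrow(x$free), " free cysteine(s)\n", sep = "")
  if (nrow(x$pairs)) {
    cat(sprintf("  %s-%s  %.3f A\n", x$pairs$label_a, x$pairs$label_b,
                x$pairs$distance), sep = "")
  }
  if (nrow(x$free)) {
    cat(sprintf("  free: %s (nearest SG %.3f A)\n", x$free$label,
                x$free$nearest_sg), sep = "")
  }
  invisible(x)
}

# keys of cysteines participating in a disulfide pair
cystine_keys <- function(disulfides) {
  if (is.null(disulfides)) return(character())
  c(disulfides$pairs$key_a, disulfides$pairs$key_b)
}

#' Classify Xaa-Pro peptide bonds as cis or trans
#'
#' For every proline the distances from the preceding residue's C-alpha to
#' the proline's C-alpha (`d_caca`) and C-delta (`d_cacd`) are measured;
#' the bond is trans when `d_caca > d_cacd` and cis otherwise.  A proline
#' with no preceding residue in its chain is skipped with a warning.
#'
#' @param s A `protein_structure`.
#' @return Data frame (one row per classified proline): key, label, chain,
#'   resno, left_key, left_resid, d_caca, d_cacd, conformation
#'   ("cis"/"trans").
#' @export
classify_prolines <- function(s) {
  rs <- s$residues
  out <- list()
  for (i in which(rs$resid == "PRO")) {
    if (i == 1 || rs$chain[i - 1] != rs$chain[i]) {
      warning("N-terminal proline ", residue_label(s, rs$key[i]),
              " has no preceding residue; skipped")
      next
    }
    ca_pro <- atom_xyz(s, rs$key[i], "CA")
    cd_pro <- atom_xyz(s, rs$key[i], "CD")
    ca_left <- atom_xyz(s, rs$key[i - 1], "CA")
    if (is.null(cd_pro)) {
      stop("proline ", residue_label(s, rs$key[i]), " is missing its CD atom")
    }
    if (is.null(ca_pro) || is.null(ca_left)) {
      stop("missing CA atom around proline ", residue_label(s, rs$key[i]))
    }
    d1 <- vdist(ca_left, ca_pro)
    d2 <- vdist(ca_left, cd_pro)
    out[[length(out) + 1]] <- data.frame(
      key = rs$key[i], label = residue_label(s, rs$key[i]),
      chain = rs$chain[i], resno = rs$resno[i],
      left_key = rs$key[i - 1], left_resid = rs$resid[i - 1],
      d_caca = d1, d_cacd = d2,
      conformation = if (d1 > d2) "trans" else "cis",
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(key = character(), label = character(),
                      chain = character(), resno = integer(),
                      left_key = character(), left_resid = character(),
                      d_caca = numeric(), d_cacd = numeric(),
                      conformation = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Detect backbone hydrogen bonds
#'
#' Heavy-atom criteria: donor-N to acceptor-O distance at most `cutoff`
#' (default 3.28 A) and both the acceptor angle N-O=C and the donor angle
#' O-N-CA within \[90, 180\] degrees (all bounds inclusive).  Prolines and
#' residues lacking backbone atoms are never donors; peptide-bonded pairs
#' (the donor N covalently attached to the acceptor carbonyl C) are
#' excluded.  When several acceptors
#' qualify for one donor, the shortest N...O is kept.
#'
#' @param s A `protein_structure`.
#' @param cutoff Maximum N...O distance (A).
#' @param angle_range Inclusive angle window in degrees for both angles.
#' @return Data frame: donor, acceptor (residue keys), donor_seqpos,
#'   acceptor_seqpos, distance, acceptor_angle, donor_angle.
#' @export
detect_backbone_hbonds <- function(s, cutoff = cf_constants$hbond_cutoff,
                                   angle_range = c(90, 180)) {
  rs <- s$residues
  n_m <- atom_matrix(s, rs$key, "N")
  ca_m <- atom_matrix(s, rs$key, "CA")
  c_m <- atom_matrix(s, rs$key, "C")
  o_m <- atom_matrix(s, rs$key, "O")
  don <- which(rs$resid != "PRO" &
                 stats::complete.cases(n_m) & stats::complete.cases(ca_m))
  acc <- which(stats::complete.cases(c_m) & stats::complete.cases(o_m))
  out <- list()
  for (i in don) {
    best <- NULL
    for (j in acc) {
      if (i == j) next
      # the donor N is covalently bonded to the preceding carbonyl C; a
      # peptide-bonded pair is not a hydrogen bond
      if (vdist(n_m[i, ], c_m[j, ]) <= 2.0) next
      d <- vdist(n_m[i, ], o_m[j, ])
      if (d > cutoff) next
      a_acc <- vec_angle(n_m[i, ], o_m[j, ], c_m[j, ])
      if (a_acc < angle_range[1] || a_acc > angle_range[2]) next
      a_don <- vec_angle(o_m[j, ], n_m[i, ], ca_m[i, ])
      if (a_don < angle_range[1] || a_don > angle_range[2]) next
      if (is.null(best) || d < best$distance) {
        best <- data.frame(donor = rs$key[i], acceptor = rs$key[j],
                           donor_seqpos = i, acceptor_seqpos = j,
                           distance = d, acceptor_angle = a_acc,
                           donor_angle = a_don, stringsAsFactors = FALSE)
      }
    }
    if (!is.null(best)) out[[length(out) + 1]] <- best
  }
  if (length(out) == 0) {
    return(data.frame(donor = character(), acceptor = character(),
                      donor_seqpos = integer(), acceptor_seqpos = integer(),
                      distance = numeric(), acceptor_angle = numeric(),
                      donor_angle = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Backbone phi/psi torsion angles
#'
#' Torsions are only defined across intact peptide bonds (C-N distance at
#' most 2.5 A between file-consecutive residues of the same chain);
#' residues at chain termini or breaks get NA.
#'
#' @param s A `protein_structure`.
#' @return Data frame: key, seqpos, phi, psi (degrees).
#' @export
backbone_torsions <- function(s) {
  rs <- s$residues
  n <- nrow(rs)
  n_m <- atom_matrix(s, rs$key, "N")
  ca_m <- atom_matrix(s, rs$key, "CA")
  c_m <- atom_matrix(s, rs$key, "C")
  bonded <- rep(FALSE, n)  # bonded[i]: peptide bond between i-1 and i
  for (i in 2:max(2, n)) {
    if (i > n) break
    if (rs$chain[i] != rs$chain[i - 1]) next
    if (any(is.na(c_m[i - 1, ])) || any(is.na(n_m[i, ]))) next
    bonded[i] <- vdist(c_m[i - 1, ], n_m[i, ]) <= 2.5
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ok_self <- !any(is.na(n_m[i, ])) && !any(is.na(ca_m[i, ])) &&
      !any(is.na(c_m[i, ]))
    if (!ok_self) next
    if (i > 1 && bonded[i]) {
      phi[i] <- vec_dihedral(c_m[i - 1, ], n_m[i, ], ca_m[i, ], c_m[i, ])
    }
    if (i < n && bonded[i + 1]) {
      psi[i] <- vec_dihedral(n_m[i, ], ca_m[i, ], c_m[i, ], n_m[i + 1, ])
    }
  }
  data.frame(key = rs$key, seqpos = rs$seqpos, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

# the four torsion windows (centre +/- 30 degrees)
ss_torsion_windows <- list(
  alpha_helix       = c(phi = -57, psi = -47),
  three_ten_helix   = c(phi = -60, psi = -30),
  parallel_beta     = c(phi = -119, psi = -113),
  antiparallel_beta = c(phi = -139, psi = 135)
)

in_window <- function(phi, psi, centre, half_width = 30) {
  !is.na(phi) && !is.na(psi) &&
    phi >= centre["phi"] - half_width && phi <= centre["phi"] + half_width &&
    psi >= centre["psi"] - half_width && psi <= centre["psi"] + half_width
}

#' Assign regular secondary structure
#'
#' A residue is labelled helical when it lies inside a run of at least
#' `min_run` consecutive i -> i+4 (alpha) or i -> i+3 (3-10) backbone
#' hydrogen bonds and its (phi, psi) fall inside the class torsion window
#' (centre +/- 30 degrees).  Sheet residues must belong to a ladder of at
#' least `min_run` registered inter-strand rungs: antiparallel rungs pair
#' N_i -> O_j with N_j -> O_i (rung progression i+2, j-2), parallel rungs
#' pair N_i -> O_(j-1) with N_(j+1) -> O_i (progression i+2, j+2).  All
#' other residues are labelled "none".
#'
#' @param s A `protein_structure`.
#' @param hbonds Data frame from [detect_backbone_hbonds()].
#' @param min_run Minimum number of consecutive class H-bonds ("a
#'   stretch"); default 2.
#' @return Object of class `ss_assignment`: data frame key, seqpos, phi,
#'   psi, label with label in alpha_helix, three_ten_helix, parallel_beta,
#'   antiparallel_beta, none.
#' @export
assign_secondary_structure <- function(s, hbonds, min_run = 2) {
  tor <- backbone_torsions(s)
  n <- nrow(tor)
  label <- rep("none", n)
  has_bond <- function(i, j) {
    any(hbonds$donor_seqpos == i & hbonds$acceptor_seqpos == j)
  }

  mark <- function(cand, class) {
    w <- ss_torsion_windows[[class]]
    for (i in cand) {
      if (label[i] == "none" && in_window(tor$phi[i], tor$psi[i], w)) {
        label[i] <<- class
      }
    }
  }

  # helices: runs of consecutive i -> i+4 (or i+3) bonds; a run covering
  # turns a..b spans residues a..b+step
  for (step in c(4, 3)) {
    class <- if (step == 4) "alpha_helix" else "three_ten_helix"
    starts <- sort(unique(hbonds$acceptor_seqpos[
      hbonds$donor_seqpos - hbonds$acceptor_seqpos == step]))
    if (length(starts) == 0) next
    runs <- split(starts, cumsum(c(1, diff(starts) != 1)))
    for (r in runs) {
      if (length(r) < min_run) next
      mark(seq(min(r), max(r) + step), class)
    }
  }

  # sheet ladders
  rungs_anti <- rungs_par <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (abs(j - i) < 3) next
      if (has_bond(i, j) && has_bond(j, i)) {
        rungs_anti <- rbind(rungs_anti, c(i, j))
      }
      if (j - 1 >= 1 && j + 1 <= n && has_bond(i, j - 1) && has_bond(j + 1, i)) {
        rungs_par <- rbind(rungs_par, c(i, j))
      }
    }
  }
  ladderize <- function(rungs, dj, class) {
    if (is.null(rungs)) return(invisible())
    rungs <- rungs[order(rungs[, 1]), , drop = FALSE]
    used <- rep(FALSE, nrow(rungs))
    for (k in seq_len(nrow(rungs))) {
      if (used[k]) next
      chain <- k
      repeat {
        last <- chain[length(chain)]
        nxt <- which(rungs[, 1] == rungs[last, 1] + 2 &
                       rungs[, 2] == rungs[last, 2] + dj & !used)
        if (length(nxt) == 0) break
        used[nxt[1]] <- TRUE
        chain <- c(chain, nxt[1])
      }
      used[chain] <- TRUE
      if (length(chain) < min_run) next
      ii <- range(rungs[chain, 1])
      jj <- range(rungs[chain, 2])
      mark(c(seq(ii[1], ii[2]), seq(jj[1], jj[2])), class)
    }
  }
  ladderize(rungs_anti, -2, "antiparallel_beta")
  ladderize(rungs_par, +2, "parallel_beta")

  tor$label <- label
  class(tor) <- c("ss_assignment", "data.frame")
  tor
}

#' Distance between backbone nitrogen atoms of two residues
#'
#' @param s A `protein_structure`.
#' @param res_a,res_b Residue keys or author residue numbers.
#' @return Euclidean distance in Angstrom.
#' @export
backbone_N_distance <- function(s, res_a, res_b) {
  ka <- resolve_keys(s, res_a)
  kb <- resolve_keys(s, res_b)
  na_ <- atom_xyz(s, ka, "N")
  nb_ <- atom_xyz(s, kb, "N")
  if (is.null(na_) || is.null(nb_)) {
    stop("missing backbone N atom for ",
         paste(c(ka, kb)[c(is.null(na_), is.null(nb_))], collapse = ", "))
  }
  vdist(na_, nb_)
}

# wwPDB-column ATOM record formatter shared by the fixture builders and the
# per-cluster subset writer
format_pdb_atoms <- function(atoms) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          seq_len(nrow(atoms)),
          ifelse(nchar(atoms$elety) < 4, paste0(" ", atoms$elety), atoms$elety),
          " ", atoms$resid, atoms$chain, atoms$resno,
          ifelse(atoms$insert == "", " ", atoms$insert),
          atoms$x, atoms$y, atoms$z, 1.00, 0.00)
}

#' Write a subset of residues as PDB text
#'
#' Used to emit per-cluster coordinate files.
#'
#' @param s A `protein_structure`.
#' @param residues Residue keys or author numbers to keep.
#' @param file Optional path; when NULL the text is returned invisibly.
#' @return The PDB text, invisibly.
#' @export
write_structure_subset <- function(s, residues, file = NULL) {
  keys <- resolve_keys(s, residues)
  sel <- res_key(s$atoms$chain, s$atoms$resno, s$atoms$insert) %in% keys
  txt <- c(format_pdb_atoms(s$atoms[sel, , drop = FALSE]), "END")
  if (!is.null(file)) writeLines(txt, file)
  invisible(paste(txt, collapse = "\n"))
}
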