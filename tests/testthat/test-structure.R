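# Structural model: parsing, disulfides, prolines, hydrogen bonds,
# secondary structure and backbone distances.

test_that("PDB parsing round-trips the fixture builders and rejects junk", {
  s <- parse_pdb(build_ideal_helix(10))
  expect_s3_class(s, "protein_structure")
  expect_equal(nrow(s$residues), 10)
  expect_true(all(table(res_key_of <- paste(s$atoms$chain, s$atoms$resno)) == 4))
  expect_error(parse_pdb("REMARK nothing here\nEND"), "ATOM")
  # residue keys unique, every atom finite
  expect_false(anyDuplicated(s$residues$key) > 0)
  expect_true(all(is.finite(c(s$atoms$x, s$atoms$y, s$atoms$z))))
})

test_that("disulfide detection pairs greedily with an inclusive 2.3 A cutoff", {
  # boundary: exactly 2.30 A is a cystine
  txt <- build_cystine_benchmark(
    data.frame(resno_a = 1, resno_b = 2, distance = 2.30))
  d <- detect_disulfides(parse_pdb(txt))
  expect_equal(nrow(d$pairs), 1)
  expect_equal(d$pairs$distance, 2.30, tolerance = 1e-3)
  # beyond the cutoff: both free, with the nearest-SG distance reported
  txt2 <- build_cystine_benchmark(
    NULL, free = data.frame(resno_a = 1, resno_b = 2, distance = 2.31))
  d2 <- detect_disulfides(parse_pdb(txt2))
  expect_equal(nrow(d2$pairs), 0)
  expect_equal(nrow(d2$free), 2)
  expect_equal(d2$free$nearest_sg, c(2.31, 2.31), tolerance = 1e-3)
})

test_that("disulfide pairing is involutive: no cysteine in two pairs", {
  txt <- build_cystine_benchmark(
    data.frame(resno_a = c(3, 14, 42, 54), resno_b = c(21, 38, 53, 59),
               distance = c(2.018, 2.013, 2.023, 2.022)))
  d <- detect_disulfides(parse_pdb(txt))
  members <- c(d$pairs$key_a, d$pairs$key_b)
  expect_equal(anyDuplicated(members), 0)
  expect_equal(sort(key_resno(members)), c(3, 14, 21, 38, 42, 53, 54, 59))
})

test_that("proline classification is exhaustive and follows the distance rule", {
  tab <- data.frame(resno = c(10, 30, 50),
                    d_caca = c(3.81, 3.04, 3.80),
                    d_cacd = c(2.88, 3.88, 2.76))
  p <- classify_prolines(parse_pdb(build_proline_benchmark(tab)))
  expect_equal(nrow(p), 3)  # every proline with complete atoms classified
  expect_equal(p$conformation, c("trans", "cis", "trans"))
  expect_equal(p$conformation, ifelse(p$d_caca > p$d_cacd, "trans", "cis"))
  expect_equal(p$d_caca, tab$d_caca, tolerance = 1e-2)
  expect_equal(p$d_cacd, tab$d_cacd, tolerance = 1e-2)
})

test_that("an N-terminal proline is skipped with a warning", {
  atoms <- data.frame(chain = "A", resno = c(1, 1, 1), resid = "PRO",
                      elety = c("N", "CA", "CD"),
                      x = c(0, 1.4, 2.0), y = c(0, 0, 1), z = 0)
  s <- parse_pdb(hand_pdb(atoms))
  expect_warning(p <- classify_prolines(s), "preceding")
  expect_equal(nrow(p), 0)
})

test_that("the ideal helix carries the full i -> i+4 hydrogen-bond ladder", {
  s <- parse_pdb(build_ideal_helix(12))
  hb <- detect_backbone_hbonds(s)
  # every turn donor i (5..12) bonds exactly its i-4 carbonyl
  turn <- hb[hb$donor_seqpos >= 5, ]
  expect_equal(sort(turn$donor_seqpos), 5:12)
  expect_equal(turn$acceptor_seqpos[order(turn$donor_seqpos)], 1:8)
  expect_true(all(hb$distance <= 3.28))
  expect_true(all(hb$acceptor_angle >= 90 & hb$acceptor_angle <= 180))
  expect_true(all(hb$donor_angle >= 90 & hb$donor_angle <= 180))
  # verify one bond by direct geometry
  n5 <- crypticfold:::atom_xyz(s, "A:5:", "N")
  o1 <- crypticfold:::atom_xyz(s, "A:1:", "O")
  expect_equal(hb$distance[hb$donor == "A:5:" & hb$acceptor == "A:1:"],
               sqrt(sum((n5 - o1)^2)), tolerance = 1e-9)
})

test_that("an extended chain has no backbone hydrogen bonds", {
  hb <- detect_backbone_hbonds(parse_pdb(build_extended_chain(10)))
  expect_equal(nrow(hb), 0)
})

test_that("hydrogen-bond angle and distance windows are enforced at the boundary", {
  # donor residue 1 (N, CA), acceptor residue 5 (C, O); N...O = 3.2 A but
  # acceptor angle N-O=C of 85 degrees -> rejected.  The carbonyl C sits
  # at 1.23 A from O making the requested angle with the O->N direction.
  place_c <- function(theta_deg) {
    th <- theta_deg * pi / 180
    c(3.2 - 1.23 * cos(th), 1.23 * sin(th))
  }
  bad_c <- place_c(85)
  atoms <- data.frame(
    chain = "A", resno = c(1, 1, 5, 5), resid = c("ALA", "ALA", "ALA", "ALA"),
    elety = c("N", "CA", "C", "O"),
    x = c(0, -0.5, bad_c[1], 3.2), y = c(0, 1.37, bad_c[2], 0), z = 0)
  expect_equal(nrow(detect_backbone_hbonds(parse_pdb(hand_pdb(atoms)))), 0)
  # same geometry with the acceptor angle at 120 degrees -> accepted
  ok_c <- place_c(120)
  atoms$x[3] <- ok_c[1]; atoms$y[3] <- ok_c[2]
  hb <- detect_backbone_hbonds(parse_pdb(hand_pdb(atoms)))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 3.2, tolerance = 1e-3)
})

test_that("helix and hairpin fixtures are labelled by class and torsion window", {
  s <- parse_pdb(build_ideal_helix(12))
  ss <- assign_secondary_structure(s, detect_backbone_hbonds(s))
  expect_equal(ss$label[2:11], rep("alpha_helix", 10))
  expect_equal(ss$label[c(1, 12)], c("none", "none"))  # torsions undefined
  expect_equal(ss$phi[2:11], rep(-57, 10), tolerance = 0.2)
  expect_equal(ss$psi[2:11], rep(-47, 10), tolerance = 0.2)

  sh <- parse_pdb(build_ideal_hairpin(6))
  ssh <- assign_secondary_structure(sh, detect_backbone_hbonds(sh))
  lab <- setNames(ssh$label, key_resno(ssh$key))
  expect_true(all(lab[c("2", "3", "4", "13", "14", "15")] == "antiparallel_beta"))
  expect_false(any(ssh$label == "alpha_helix"))
})

test_that("an isolated hydrogen bond does not create a helix label", {
  # a 3-10-like i -> i+3 geometry exists at the helix N-terminus (donor 4)
  # but a single bond is not a stretch
  s <- parse_pdb(build_ideal_helix(12))
  ss <- assign_secondary_structure(s, detect_backbone_hbonds(s))
  expect_false(any(ss$label == "three_ten_helix"))
})

test_that("secondary-structure labels are invariant to rigid motion", {
  s <- parse_pdb(build_ideal_helix(10))
  lab0 <- assign_secondary_structure(s, detect_backbone_hbonds(s))$label
  s2 <- s
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  th <- c(0.4, -1.1, 2.2)
  rot <- crypticfold:::rigid_transform(xyz, rot = th, trans = c(12, -5, 40))
  s2$atoms$x <- rot[, 1]; s2$atoms$y <- rot[, 2]; s2$atoms$z <- rot[, 3]
  lab1 <- assign_secondary_structure(s2, detect_backbone_hbonds(s2))$label
  expect_identical(lab0, lab1)
})

test_that("backbone N distances agree with hand computation", {
  atoms <- data.frame(chain = "A", resno = c(1, 1, 2, 2), resid = "GLY",
                      elety = c("N", "CA", "N", "CA"),
                      x = c(0, 1, 3, 4), y = c(0, 0, 4, 4), z = 0)
  s <- parse_pdb(hand_pdb(atoms))
  expect_equal(backbone_N_distance(s, 1, 2), 5.0)
  expect_equal(backbone_N_distance(s, 1, 1), 0)
  # arbitrary pair on the helix fixture equals the raw-coordinate oracle
  h <- parse_pdb(build_ideal_helix(8))
  n2 <- crypticfold:::atom_xyz(h, "A:2:", "N")
  n7 <- crypticfold:::atom_xyz(h, "A:7:", "N")
  expect_equal(backbone_N_distance(h, 2, 7), sqrt(sum((n2 - n7)^2)),
               tolerance = 1e-9)
})

test_that("structure subsets are written as parseable PDB text", {
  s <- parse_pdb(build_ideal_helix(8))
  txt <- write_structure_subset(s, c(2, 3, 4))
  s2 <- parse_pdb(txt)
  expect_equal(s2$residues$resno, 2:4)
  expect_equal(nrow(s2$atoms), 12)
})
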