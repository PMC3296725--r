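# Intrinsic exchange rates: reference-table arithmetic, temperature
# scaling and profile bookkeeping.

cond7 <- exchange_conditions(7.0, 298)

test_that("pD correction applies only in D2O", {
  expect_equal(exchange_conditions(7.0, solvent = "D2O")$pD, 7.4)
  expect_equal(exchange_conditions(7.0, solvent = "H2O")$pD, 7.0)
  expect_error(exchange_conditions(7, temperature = -1), "positive")
})

test_that("base catalysis dominates above the rate minimum", {
  k_lo <- krc_at_reference("ALA", "ALA", exchange_conditions(4.6))
  k_hi <- krc_at_reference("ALA", "ALA", exchange_conditions(8.6))
  expect_gt(as.numeric(k_hi), as.numeric(k_lo))
})

test_that("rates match an independent evaluation of the bundled table", {
  # spreadsheet-style oracle: read the YAML directly and evaluate the
  # three-channel sum by hand for several contexts
  y <- yaml::read_yaml(system.file("extdata", "intrinsic_rate_factors.yaml",
                                   package = "crypticfold"))
  tab <- load_rate_table()
  for (ctx in list(c("ALA", "GLY"), c("LYS", "TRP"), c("CYS2", "VAL"),
                   c("PRO_CIS", "SER"))) {
    left <- ctx[1]; right <- ctx[2]
    pD <- 7.4; Tt <- 298
    fl <- y$factors[[left]]; fr <- y$factors[[right]]
    arr <- function(E) exp(-(E / 1.9872e-3) * (1 / Tt - 1 / 293))
    manual <-
      10^(y$log_ka + fr[[1]] + fl[[2]] - pD) * arr(14) +
      10^(y$log_kb + fr[[3]] + fl[[4]] + pD - y$pKD) * arr(17) +
      10^(y$log_kw + fr[[3]] + fl[[4]]) * arr(19)
    got <- krc_at_reference(left, right, cond7, tab)
    expect_equal(as.numeric(got), manual, tolerance = 1e-12,
                 label = paste(left, right))
    expect_equal(sum(attr(got, "channels")), as.numeric(got))
  }
})

test_that("temperature scaling is the per-channel Arrhenius form", {
  expect_equal(temperature_scale(5, 17, 293), 5)  # identity at the reference
  expect_gt(temperature_scale(1, 14, 310), 1)     # faster when warmer
  fac <- temperature_scale(1, 17, 298)
  expect_equal(fac, exp(-(17 / 1.9872e-3) * (1 / 298 - 1 / 293)),
               tolerance = 1e-12)
})

test_that("k_rc(pD) is convex with a single interior minimum", {
  pd <- seq(2, 12, by = 0.25)
  k <- vapply(pd, function(p) {
    as.numeric(krc_at_reference("ALA", "LEU",
                                exchange_conditions(p - 0.4, 298)))
  }, 1.0)
  expect_true(all(k > 0 & is.finite(k)))
  d2 <- diff(diff(k))
  expect_true(all(d2 > -1e-12))           # convex
  expect_equal(sum(diff(sign(diff(k))) != 0), 1)  # one minimum
})

test_that("rates stay positive and finite across pD and temperature", {
  for (pd in c(2, 7, 12)) {
    for (Tt in c(273, 298, 373)) {
      k <- krc_at_reference("ARG", "ASN",
                            exchange_conditions(pd - 0.4, Tt))
      expect_true(is.finite(k) && k > 0)
    }
  }
})

test_that("prolines have no exchangeable amide", {
  expect_warning(k <- krc_at_reference("ALA", "PRO", cond7), "proline")
  expect_true(is.na(k))
})

test_that("unknown residue codes are reported by name", {
  expect_error(krc_at_reference("XYZ", "ALA", cond7), "XYZ")
})

test_that("profile bookkeeping skips prolines and the N-terminal amine", {
  seq60 <- ctx3_sequence
  prof <- krc_profile_sequence(seq60, cond7)
  # 60 residues - 5 prolines - 1 N-terminal free amine
  expect_equal(nrow(prof), 54)
  expect_false(any(prof$resid == "PRO"))
  expect_false(1 %in% prof$resno)
  expect_true(all(prof$k_rc > 0))
})

test_that("structure-aware and sequence-only profiles agree without cysteines", {
  s <- parse_pdb(build_ideal_helix(8))
  p_struct <- krc_profile(s, cond7,
                          disulfides = detect_disulfides(s),
                          prolines = classify_prolines(s))
  p_seq <- krc_profile_sequence(paste(rep("A", 8), collapse = ""), cond7)
  expect_equal(p_struct$k_rc, p_seq$k_rc, tolerance = 1e-12)
})

test_that("a cis-proline assignment changes only its right neighbour's rate", {
  tab <- data.frame(resno = 5, d_caca = 3.8, d_cacd = 2.8)
  atoms <- crypticfold:::build_backbone(8, -57, -47)
  atoms$resid[atoms$resno == 5] <- "PRO"
  s <- parse_pdb(crypticfold:::atoms_to_pdb_text(atoms))
  trans_prof <- krc_profile(s, cond7)
  cis <- data.frame(key = "A:5:", conformation = "cis")
  cis_prof <- krc_profile(s, cond7, prolines = cis)
  changed <- trans_prof$resno[abs(trans_prof$k_rc - cis_prof$k_rc) > 1e-12]
  expect_equal(changed, 6)
})

test_that("a cystine assignment changes only local rates", {
  # 8-residue poly-Ala with a CYS at position 4: compare free vs cystine
  atoms <- crypticfold:::build_backbone(8, -57, -47)
  atoms$resid[atoms$resno == 4] <- "CYS"
  s <- parse_pdb(crypticfold:::atoms_to_pdb_text(atoms))
  free <- krc_profile(s, cond7)
  paired <- structure(list(pairs = data.frame(key_a = "A:4:", key_b = "A:99:"),
                           free = data.frame(), unresolvable = character()),
                      class = "disulfide_assignment")
  bonded <- krc_profile(s, cond7, disulfides = paired)
  changed <- free$resno[abs(free$k_rc - bonded$k_rc) > 1e-12]
  expect_setequal(changed, c(4, 5))  # own NH and the right neighbour's
})
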