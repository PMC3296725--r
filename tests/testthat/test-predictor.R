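# Stage IV: candidate selection, contact-order matrix, clustering,
# coverage, cooperative units and the metastable search.

test_that("candidate selection requires donor + regular label + dG value", {
  s <- parse_pdb(build_ideal_helix(12))
  hb <- detect_backbone_hbonds(s)
  ss <- assign_secondary_structure(s, hb)
  dg_all <- setNames(rep(5, 12), s$residues$key)
  sel <- select_candidate_residues(s, ss, hb, dg_all)
  donors <- unique(hb$donor)
  regular <- ss$key[ss$label != "none"]
  expect_setequal(sel, intersect(donors, regular))
  # a residue with dG but label "none" is excluded
  expect_false("A:1:" %in% sel)
  # dropping a residue's dG drops it from the selection
  sel2 <- select_candidate_residues(s, ss, hb, dg_all[names(dg_all) != "A:6:"])
  expect_setequal(setdiff(sel, sel2), "A:6:")
  expect_error(select_candidate_residues(s, ss, hb,
                                         c("A:1:" = 3)), "check")
})

test_that("the contact-order matrix is binary, symmetric and inclusive at 7 A", {
  atoms <- data.frame(chain = "A", resno = rep(1:3, each = 2), resid = "ALA",
                      elety = rep(c("N", "CA"), 3),
                      x = c(0, 1, 6.9, 7.9, 14.0, 15.0),
                      y = 0, z = 0)
  s <- parse_pdb(hand_pdb(atoms))
  cm <- contact_order_matrix(s, 1:3)
  expect_equal(diag(cm$matrix), c(0L, 0L, 0L), ignore_attr = TRUE)
  expect_identical(cm$matrix, t(cm$matrix))
  expect_equal(cm$matrix[1, 2], 1L)  # 6.9 A -> contact
  expect_equal(cm$matrix[2, 3], 0L)  # 7.1 A -> no contact
  expect_equal(unname(cm$distances[2, 3]), 7.1, tolerance = 1e-6)
})

test_that("distance exactly 7.0 A counts as a contact", {
  atoms <- data.frame(chain = "A", resno = rep(1:2, each = 2), resid = "ALA",
                      elety = rep(c("N", "CA"), 2),
                      x = c(0, 1, 7.0, 8.0), y = 0, z = 0)
  cm <- contact_order_matrix(parse_pdb(hand_pdb(atoms)), 1:2)
  expect_equal(cm$matrix[1, 2], 1L)
})

test_that("clustering is transitive and matches the brute-force oracle", {
  # A-B and B-C contacts merge into one cluster
  atoms <- data.frame(chain = "A", resno = rep(1:3, each = 2), resid = "ALA",
                      elety = rep(c("N", "CA"), 3),
                      x = c(0, 1, 5, 6, 10, 11), y = 0, z = 0)
  s <- parse_pdb(hand_pdb(atoms))
  cl <- cluster_contacts(contact_order_matrix(s, 1:3))
  expect_equal(length(cl$clusters), 1)
  expect_setequal(key_resno(cl$clusters[[1]]), 1:3)
  # random geometries across seeds
  for (seed in 1:20) {
    n <- 5 + (seed %% 26)
    s <- parse_pdb(random_bead_pdb(n, seed))
    cm <- contact_order_matrix(s, seq_len(n))
    cl <- cluster_contacts(cm)
    memb <- bf_components(cm$matrix)
    oracle <- split(cm$residues, memb)
    oracle_cl <- Filter(function(g) length(g) >= 2, oracle)
    expect_equal(length(cl$clusters), length(oracle_cl))
    got <- lapply(cl$clusters, sort)
    want <- lapply(oracle_cl, sort)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
    # singletons + clusters partition the input
    expect_setequal(c(unlist(cl$clusters), cl$singletons), cm$residues)
  }
})

test_that("cluster output is ordered and independent of input order", {
  s <- parse_pdb(random_bead_pdb(20, 99))
  keys <- s$residues$key
  cl1 <- cluster_contacts(contact_order_matrix(s, keys))
  set.seed(1)
  cl2 <- cluster_contacts(contact_order_matrix(s, sample(keys)))
  norm <- function(cl) lapply(cl$clusters, function(g) sort(key_resno(g)))
  expect_identical(norm(cl1), norm(cl2))
  sizes <- vapply(cl1$clusters, length, 1L)
  expect_true(all(diff(sizes) <= 0))  # descending size
})

test_that("cluster invariants hold: intra-connectivity, inter-separation", {
  s <- parse_pdb(random_bead_pdb(30, 7))
  cm <- contact_order_matrix(s, 1:30)
  cl <- cluster_contacts(cm)
  for (g in cl$clusters) {
    sub <- cm$matrix[g, g, drop = FALSE]
    expect_true(all(rowSums(sub) >= 1))  # every member touches the group
  }
  if (length(cl$clusters) >= 2) {
    for (i in seq_len(length(cl$clusters) - 1)) {
      for (j in seq(i + 1, length(cl$clusters))) {
        expect_gt(min(cm$distances[cl$clusters[[i]], cl$clusters[[j]]]), 7)
      }
    }
  }
})

test_that("raising the cutoff never increases the cluster count", {
  for (seed in c(2, 5, 13)) {
    s <- parse_pdb(random_bead_pdb(25, seed))
    counts <- vapply(c(4, 6, 8, 10, 14), function(cut) {
      length(cluster_contacts(contact_order_matrix(s, 1:25, cut))$clusters) +
        length(cluster_contacts(contact_order_matrix(s, 1:25, cut))$singletons)
    }, 1L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("coverage reports the min/max span and demands complete data", {
  dg <- c(a = 3.0, b = 4.2, c = 5.6)
  expect_equal(unname(coverage(c("a", "b", "c"), dg)), c(3.0, 5.6))
  expect_equal(unname(coverage("b", dg)), c(4.2, 4.2))
  expect_error(coverage(c("a", "zz"), dg), "zz")
  set.seed(4)
  v <- setNames(stats::runif(9, 0, 10), letters[1:9])
  expect_equal(unname(coverage(letters[1:9], v)),
               c(min(v), max(v)), tolerance = 1e-12)
})

test_that("cooperative units require both endpoints to agree within tolerance", {
  covs <- list(c(2.0, 5.0), c(2.1, 5.0), c(6.0, 9.0))
  cu <- cooperative_units(covs)
  expect_equal(nrow(cu), 1)
  expect_equal(c(cu$a, cu$b), c(1, 2))
  expect_equal(nrow(cooperative_units(list(c(1, 2), c(1, 2)))), 1)  # identical
  expect_equal(nrow(cooperative_units(list(c(1, 2)))), 0)
})

test_that("the metastable search uses a strict threshold", {
  atoms <- data.frame(chain = "A", resno = rep(1:3, each = 2), resid = "ALA",
                      elety = rep(c("N", "CA"), 3),
                      x = c(0, 1, 5, 6, 10, 11), y = 0, z = 0)
  s <- parse_pdb(hand_pdb(atoms))
  dg <- setNames(c(2.0, 3.0, 2.6), s$residues$key)
  ms <- metastable_search(s, dg, dg_x = 2.4)
  expect_equal(ms$mode, "metastable_state")
  expect_setequal(key_resno(ms$selected), c(2, 3))
  # boundary: dG_HX exactly equal to dG_X is excluded
  dg2 <- setNames(c(2.4, 2.4, 2.4), s$residues$key)
  ms2 <- metastable_search(s, dg2, dg_x = 2.4)
  expect_equal(length(ms2$selected), 0)
  expect_match(ms2$note, "no metastable residues")
})

test_that("a planted contiguous patch is recovered as one metastable cluster", {
  # seven spatially contiguous residues above threshold, mirroring a
  # three-finger toxin's strands 3-5 patch
  resno <- c(26, 27, 28, 29, 38, 53, 55)
  s <- parse_pdb(build_contact_islands(list(resno, c(2, 10, 70)), spacing = 5))
  dg <- setNames(rep(NA_real_, nrow(s$residues)), s$residues$key)
  dg[match(resno, key_resno(names(dg)))] <- c(3.0, 3.2, 2.9, 3.5, 2.6, 2.8, 3.9)
  dg[is.na(dg)] <- 1.0
  ms <- metastable_search(s, dg, dg_x = 2.4)
  expect_equal(length(ms$clusters), 1)
  expect_setequal(key_resno(ms$clusters[[1]]), resno)
})

test_that("prediction switches modes on the cluster count", {
  tw <- build_two_island(20, 8, seed = 2)
  s <- parse_pdb(tw$pdb_text)
  hb <- detect_backbone_hbonds(s)
  ss <- assign_secondary_structure(s, hb)
  dg <- dg_map_from_table(s, tw$dg_table)
  led <- energy_ledger(4.2, 6.6, dg_u_star = 4.2, dg_hx_star = 6.3)
  p <- predict_intermediates(s, ss, hb, dg, led)
  expect_equal(p$mode, "cryptic_intermediates")
  expect_equal(length(p$clusters), 2)
  # each recovered cluster sits inside one planted island
  island_of <- setNames(tw$truth$island, tw$truth$residue)
  for (g in p$clusters) {
    expect_equal(length(unique(island_of[as.character(key_resno(g))])), 1)
  }
  expect_gt(p$coverages[[1]][2], p$coverages[[2]][2])  # distinct dG ranges
  # near islands merge into one candidate cluster -> metastable mode
  tw2 <- build_two_island(5, 8, seed = 2)
  s2 <- parse_pdb(tw2$pdb_text)
  hb2 <- detect_backbone_hbonds(s2)
  ss2 <- assign_secondary_structure(s2, hb2)
  dg2 <- dg_map_from_table(s2, tw2$dg_table)
  p2 <- predict_intermediates(s2, ss2, hb2, dg2,
                              energy_ledger(2.3, 3.9, dg_u_star = 2.3,
                                            dg_hx_star = 3.8))
  expect_equal(p2$mode, "metastable_state")
  expect_equal(p2$dg_x, 2.4)
})

test_that("per-cluster PDB files are written and parse back", {
  tw <- build_two_island(20, 6, seed = 3)
  s <- parse_pdb(tw$pdb_text)
  hb <- detect_backbone_hbonds(s)
  ss <- assign_secondary_structure(s, hb)
  dg <- dg_map_from_table(s, tw$dg_table)
  out <- tempfile("clusters")
  p <- predict_intermediates(s, ss, hb, dg,
                             energy_ledger(4, 6, dg_u_star = 4,
                                           dg_hx_star = 5.8),
                             out_dir = out)
  files <- list.files(out, pattern = "^cluster_..\\.pdb$", full.names = TRUE)
  expect_equal(length(files), length(p$clusters))
  s1 <- read_structure(files[1])
  expect_setequal(s1$residues$resno, key_resno(p$clusters[[1]]))
})
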