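# Independent oracles and shared synthetic inputs for the test suite.

# Brute-force connected components by transitive closure of the boolean
# adjacency matrix (independent of the igraph-backed implementation).
bf_components <- function(adj) {
  n <- nrow(adj)
  reach <- (adj > 0) | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  memb <- integer(n)
  grp <- 0L
  for (i in seq_len(n)) {
    if (memb[i] == 0L) {
      grp <- grp + 1L
      memb[reach[i, ]] <- grp
    }
  }
  memb
}

# residue numbers of a vector of "chain:resno:insert" keys
key_resno <- function(keys) as.integer(sub("^[^:]*:(-?[0-9]+):.*$", "\\1", keys))

# random bead geometry on a grid: n residues (N + CA atoms), returns the
# PDB text; used for clustering-oracle equivalence
random_bead_pdb <- function(n, seed, box = 25) {
  set.seed(seed)
  xyz <- matrix(stats::runif(3 * n, 0, box), ncol = 3)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(chain = "A", resno = i, insert = "", resid = "ALA",
               elety = c("N", "CA"),
               x = c(xyz[i, 1], xyz[i, 1] + 1), y = xyz[i, 2], z = xyz[i, 3],
               stringsAsFactors = FALSE)
  }))
  paste(c(crypticfold:::format_pdb_atoms(atoms), "END"), collapse = "\n")
}

# minimal hand-built PDB text from an atom table (independent of the
# package's fixture builders for boundary-geometry tests)
hand_pdb <- function(atoms) {
  paste(c(sprintf(
    "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(nrow(atoms)), atoms$elety, atoms$resid, atoms$chain,
    atoms$resno, atoms$x, atoms$y, atoms$z), "END"), collapse = "\n")
}

# cardiotoxin III (60 aa) and cobrotoxin sequence contexts used by the
# proline-correction checks (public sequence knowledge)
ctx3_sequence <- "LKCNKLVPLFYKTCPAGKNLCYKMFMVATPKVPVKRGCIDVCPKSSLLVKYVCCNTDRCN"

# printed free-energy table used for tolerance-verdict assertions
# (columns: protein, dg_hx, dg_hx_star, dg_u, group)
published_ledgers <- data.frame(
  protein = c("OMTKY3", "Barnase", "CI2", "434cro", "RNaseT1",
              "HEWL", "RNaseH", "Barstar", "HPr", "SrcSH3", "CBTX",
              "T4Lysozyme", "ApoCytb562", "CTXIII", "PPL", "CytC"),
  dg_hx = c(8.2, 10.1, 7.6, 4.0, 10.7,
            12.4, 10.9, 6.2, 5.8, 6.2, 3.9, 17.7, 5.5, 6.6, 7.0, 13.0),
  dg_hx_star = c(7.2, 9.9, 7.1, 3.9, 8.2,
                 12.2, 9.3, 6.0, 5.7, 6.1, 3.8, 17.5, 5.3, 6.3, 7.0, 12.7),
  dg_u = c(7.2, 9.8, 7.0, 3.7, 7.9,
           11.7, 9.9, 5.0, 4.7, 4.7, 2.3, 16.0, 3.3, 4.2, 4.9, 10.0),
  group = rep(c("I", "II"), c(5, 11)),
  stringsAsFactors = FALSE
)
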