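# Stage IV: candidate amide selection, the 7 Angstrom backbone-nitrogen
# contact-order matrix, connected-component clustering into candidate
# cryptic intermediates with free-energy coverage and cooperative units,
# and the metastable-state search above the dG_X threshold.

#' Map a residue exchange table onto a structure
#'
#' Converts a table with author residue numbers (optional chain) and a
#' `dg_hx` column into a named vector keyed by structure residue keys.
#'
#' @param s A `protein_structure`.
#' @param table Data frame with columns residue, optional chain, dg_hx.
#' @return Named numeric vector (names = residue keys).
#' @export
dg_map_from_table <- function(s, table) {
  rs <- s$residues
  if (!is.null(table$chain)) {
    i <- match(paste(table$chain, table$residue),
               paste(rs$chain, rs$resno))
  } else {
    i <- match(table$residue, rs$resno)
  }
  if (anyNA(i)) {
    stop("exchange-table residue(s) absent from structure: ",
         paste(table$residue[is.na(i)], collapse = ", "))
  }
  stats::setNames(table$dg_hx, rs$key[i])
}

#' Select candidate amides for intermediate prediction
#'
#' Keeps residues whose backbone NH donates a hydrogen bond, whose
#' secondary-structure label is a regular class (not "none"), and for
#' which a residue-specific dG_HX is available.  Hydrogen-bonded NHs in
#' loops or at the surface are excluded: they exchange through local
#' structural fluctuations rather than through the unfolding events of
#' interest.
#'
#' @param s A `protein_structure`.
#' @param ss [assign_secondary_structure()] result.
#' @param hbonds [detect_backbone_hbonds()] result.
#' @param dg_map Named dG_HX vector from [dg_map_from_table()].
#' @return Character vector of residue keys.
#' @export
select_candidate_residues <- function(s, ss, hbonds, dg_map) {
  donors <- unique(hbonds$donor)
  regular <- ss$key[ss$label != "none"]
  sel <- intersect(intersect(donors, regular), names(dg_map))
  if (length(sel) == 0) {
    stop("no hydrogen-bonded amides in regular secondary structure carry a ",
         "dG_HX value; check the structure, exchange table and conditions")
  }
  sel[order(match(sel, s$residues$key))]
}

#' Backbone-nitrogen contact order matrix
#'
#' Binary symmetric matrix over the given residues: entry (i, j) is 1
#' exactly when the distance between the two backbone nitrogen atoms is
#' within the cutoff (inclusive) and i != j.
#'
#' @param s A `protein_structure`.
#' @param residues Residue keys or author numbers.
#' @param cutoff Angstrom (default 7.0).
#' @return Object of class `contact_matrix`: list with `residues`,
#'   `matrix` (0/1), `distances`, `cutoff`.
#' @export
contact_order_matrix <- function(s, residues,
                                 cutoff = cf_constants$contact_cutoff) {
  keys <- resolve_keys(s, residues)
  nm <- atom_matrix(s, keys, "N")
  if (any(is.na(nm))) {
    stop("missing backbone N atom for: ",
         paste(keys[apply(nm, 1, anyNA)], collapse = ", "))
  }
  d <- as.matrix(stats::dist(nm))
  m <- (d <= cutoff) * 1L
  diag(m) <- 0L
  dimnames(m) <- dimnames(d) <- list(keys, keys)
  structure(list(residues = keys, matrix = m, distances = d, cutoff = cutoff),
            class = "contact_matrix")
}

#' Cluster the contact-order matrix
#'
#' Groups residues so that every member of a group is within the cutoff
#' of at least one other member (connected components of the contact
#' graph) and members of different groups are all beyond the cutoff.
#' Residues with no contact partner are reported separately as
#' singletons, not as clusters.  Clusters are ordered by descending size,
#' ties by smallest author residue number.
#'
#' @param cm A `contact_matrix`.
#' @return List: `clusters` (list of character key vectors), `singletons`
#'   (character keys).
#' @export
cluster_contacts <- function(cm) {
  keys <- cm$residues
  g <- igraph::graph_from_adjacency_matrix(cm$matrix, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(keys, comp$membership)
  singles <- unlist(groups[vapply(groups, length, 1L) == 1], use.names = FALSE)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  resno_of <- function(k) as.integer(sub("^[^:]*:([-0-9]+):.*$", "\\1", k))
  ord <- order(-vapply(groups, length, 1L),
               vapply(groups, function(g) min(resno_of(g)), 1L))
  list(clusters = unname(lapply(groups[ord], unname)),
       singletons = if (is.null(singles)) character() else singles)
}

#' Free-energy coverage of a cluster
#'
#' @param members Residue keys of one cluster.
#' @param dg_map Named dG_HX vector.
#' @return c(min, max) in kcal/mol.
#' @export
coverage <- function(members, dg_map) {
  miss <- setdiff(members, names(dg_map))
  if (length(miss)) {
    stop("cluster member(s) without dG_HX: ", paste(miss, collapse = ", "))
  }
  v <- dg_map[members]
  c(min = min(v), max = max(v))
}

#' Cooperative units among clusters
#'
#' Clusters with the same free-energy coverage unfold together; "same" is
#' operationalized as both interval endpoints agreeing within the
#' tolerance.
#'
#' @param coverages List of c(min, max) vectors (one per cluster).
#' @param tolerance kcal/mol (default 0.4).
#' @return Data frame of cluster index pairs (a, b); zero rows when none.
#' @export
cooperative_units <- function(coverages, tolerance = cf_constants$tolerance) {
  out <- data.frame(a = integer(), b = integer())
  n <- length(coverages)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (abs(coverages[[i]][1] - coverages[[j]][1]) <= tolerance &&
          abs(coverages[[i]][2] - coverages[[j]][2]) <= tolerance) {
        out <- rbind(out, data.frame(a = i, b = j))
      }
    }
  }
  out
}

#' Metastable-state search
#'
#' Selects all residues with dG_HX strictly above the threshold dG_X and
#' subdivides them with the contact-order matrix; each subgroup is a
#' candidate higher-energy metastable denatured state.
#'
#' @param s A `protein_structure`.
#' @param dg_map Named dG_HX vector.
#' @param dg_x Threshold in kcal/mol (from [dg_x()]).
#' @param cutoff Contact cutoff in Angstrom.
#' @param tolerance Coverage tolerance for cooperative units.
#' @return `intermediate_prediction` with mode "metastable_state"; when
#'   no residue exceeds the threshold, `clusters` is empty and `note`
#'   says so.
#' @export
metastable_search <- function(s, dg_map, dg_x,
                              cutoff = cf_constants$contact_cutoff,
                              tolerance = cf_constants$tolerance) {
  sel <- names(dg_map)[dg_map > dg_x]
  if (length(sel) == 0) {
    return(structure(list(
      mode = "metastable_state", clusters = list(), coverages = list(),
      cooperative = data.frame(a = integer(), b = integer()),
      singletons = character(), selected = character(), dg_x = dg_x,
      cutoff = cutoff,
      note = "no metastable residues above threshold"
    ), class = "intermediate_prediction"))
  }
  cl <- cluster_contacts(contact_order_matrix(s, sel, cutoff))
  covs <- lapply(cl$clusters, coverage, dg_map = dg_map)
  structure(list(
    mode = "metastable_state", clusters = cl$clusters, coverages = covs,
    cooperative = cooperative_units(covs, tolerance),
    singletons = cl$singletons, selected = sel, dg_x = dg_x,
    cutoff = cutoff, note = NULL
  ), class = "intermediate_prediction")
}

#' Predict cryptic intermediates or metastable states
#'
#' Runs the candidate selection and contact-order clustering.  Two or
#' more clusters are reported as candidate cryptic intermediates with
#' free-energy coverages and cooperative units; a single cluster triggers
#' the metastable-state search over all residues with
#' dG_HX > dG_X from the ledger.
#'
#' @param s A `protein_structure`.
#' @param ss [assign_secondary_structure()] result.
#' @param hbonds [detect_backbone_hbonds()] result.
#' @param dg_map Named dG_HX vector.
#' @param ledger An [energy_ledger()] (supplies dG_X).
#' @param cutoff Contact cutoff (A).
#' @param tolerance Coverage tolerance (kcal/mol).
#' @param out_dir Optional directory: per-cluster PDB subset files are
#'   written there as cluster_01.pdb, ...
#' @return Object of class `intermediate_prediction`: mode
#'   ("cryptic_intermediates" or "metastable_state"), clusters,
#'   coverages, cooperative pairs, singletons, selected residues, dg_x.
#' @export
predict_intermediates <- function(s, ss, hbonds, dg_map, ledger,
                                  cutoff = cf_constants$contact_cutoff,
                                  tolerance = cf_constants$tolerance,
                                  out_dir = NULL) {
  sel <- select_candidate_residues(s, ss, hbonds, dg_map)
  cl <- cluster_contacts(contact_order_matrix(s, sel, cutoff))
  if (length(cl$clusters) >= 2) {
    covs <- lapply(cl$clusters, coverage, dg_map = dg_map)
    pred <- structure(list(
      mode = "cryptic_intermediates", clusters = cl$clusters,
      coverages = covs, cooperative = cooperative_units(covs, tolerance),
      singletons = cl$singletons, selected = sel, dg_x = ledger$dg_x,
      cutoff = cutoff, note = NULL
    ), class = "intermediate_prediction")
  } else {
    pred <- metastable_search(s, dg_map, ledger$dg_x, cutoff, tolerance)
    pred$candidate_clusters <- cl$clusters
    pred$singleton_candidates <- cl$singletons
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(pred$clusters)) {
      write_structure_subset(s, pred$clusters[[k]],
                             file.path(out_dir, sprintf("cluster_%02d.pdb", k)))
    }
  }
  pred
}

#' @export
print.intermediate_prediction <- function(x, ...) {
  cat("intermediate_prediction: mode =", x$mode, "\n")
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  for (k in seq_along(x$clusters)) {
    cov <- x$coverages[[k]]
    cat(sprintf("  cluster %d (%d residues), coverage %.2f-%.2f kcal/mol\n",
                k, length(x$clusters[[k]]), cov[1], cov[2]))
  }
  if (length(x$singletons)) {
    cat("  unclustered singletons:", length(x$singletons), "\n")
  }
  if (nrow(x$cooperative)) {
    cat("  cooperative unit pairs:",
        paste(sprintf("(%d,%d)", x$cooperative$a, x$cooperative$b),
              collapse = " "), "\n")
  }
  invisible(x)
}
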