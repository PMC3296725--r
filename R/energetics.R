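# EX2 exchange energetics: residue-specific free energies of exchange and
# protection factors, the global free energy of exchange, the cis-trans
# proline-isomerization correction, the metastable threshold free energy,
# and tolerance comparisons.

GAS_R <- 1.9872e-3  # kcal mol^-1 K^-1

#' Residue-specific free energy of exchange under EX2 conditions
#'
#' dG_HX = -RT ln(k_ex / k_rc) = RT ln(P) with protection factor
#' P = k_rc / k_ex.
#'
#' @param k_ex Observed exchange rate constant (min^-1).
#' @param k_rc Intrinsic (random-coil) rate constant (min^-1).
#' @param temperature Kelvin.
#' @return Free energy in kcal/mol, with attribute `protection_factor`.
#' @export
dg_hx <- function(k_ex, k_rc, temperature) {
  if (any(k_ex <= 0) || any(k_rc <= 0)) {
    stop("rate constants must be positive")
  }
  dg <- -GAS_R * temperature * log(k_ex / k_rc)
  attr(dg, "protection_factor") <- k_rc / k_ex
  dg
}

#' Protection factor
#'
#' @inheritParams dg_hx
#' @return P = k_rc / k_ex (dimensionless).
#' @export
protection_factor <- function(k_ex, k_rc) {
  if (any(k_ex <= 0) || any(k_rc < 0)) stop("rate constants must be positive")
  k_rc / k_ex
}

#' Global free energy of exchange
#'
#' The protein-level dG_HX is the arithmetic mean of the four largest
#' residue-specific values; with fewer than four values, the mean of all
#' of them is returned with a warning.
#'
#' @param values Numeric vector of residue-specific dG_HX (kcal/mol).
#' @return kcal/mol.
#' @export
global_dg_hx <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no residue-specific dG_HX values supplied")
  if (length(values) < 4) {
    warning("fewer than four residue-specific dG_HX values; averaging all ",
            length(values))
    return(mean(values))
  }
  mean(sort(values, decreasing = TRUE)[1:4])
}

#' Load unfolded-state proline cis fractions
#'
#' Reads the bundled (or a user-supplied) table of unfolded-state cis
#' fractions f_cis of Xaa-Pro imide bonds, keyed by the preceding residue
#' Xaa (CYS2 = cystine variant).
#'
#' @param path Optional replacement file (tab-separated, columns resid,
#'   f_cis), e.g. protein-derived values.
#' @return Named numeric vector of cis fractions in (0, 1).
#' @export
load_cis_fractions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "proline_cis_fractions.tsv",
                        package = "crypticfold", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  f <- stats::setNames(tab$f_cis, tab$resid)
  if (any(f <= 0 | f >= 1)) stop("cis fractions must lie strictly in (0, 1)")
  f
}

#' Correct the global dG_HX for cis-trans proline isomerization
#'
#' H/D exchange reports only the equilibrium between the native state and
#' the unfolded state in the native proline conformation; the subsequent
#' slow isomerization to the unfolded-state cis/trans mixture stabilizes
#' the unfolded ensemble by RT ln(1 + K) per proline, where K is the
#' unfolded-state equilibrium constant towards the non-native conformer
#' (native trans: K = f_cis / (1 - f_cis); native cis:
#' K = (1 - f_cis) / f_cis).  The corrected value is
#' dG_HX* = dG_HX - RT * sum(ln(1 + K_i)) and is never larger than
#' dG_HX.
#'
#' @param dg_hx Global free energy of exchange (kcal/mol).
#' @param prolines Data frame with columns `conformation` ("cis"/"trans")
#'   and `left_resid` (3-letter code of the preceding residue; "CYS2"
#'   for cystine), as produced by [classify_prolines()] (optionally with
#'   cystine recoding).
#' @param cis_fractions Named vector from [load_cis_fractions()].
#' @param temperature Kelvin.
#' @return dG_HX* in kcal/mol, with attribute `correction` (the
#'   subtracted term) and `per_proline` (its per-proline breakdown).
#' @export
proline_correction <- function(dg_hx, prolines,
                               cis_fractions = load_cis_fractions(),
                               temperature = 298.15) {
  if (is.null(prolines) || nrow(prolines) == 0) {
    out <- dg_hx
    attr(out, "correction") <- 0
    attr(out, "per_proline") <- numeric()
    return(out)
  }
  miss <- setdiff(prolines$left_resid, names(cis_fractions))
  if (length(miss)) {
    stop("no cis fraction for preceding residue(s): ",
         paste(unique(miss), collapse = ", "))
  }
  f <- cis_fractions[prolines$left_resid]
  K <- ifelse(prolines$conformation == "trans", f / (1 - f), (1 - f) / f)
  per <- GAS_R * temperature * log1p(K)
  out <- dg_hx - sum(per)
  attr(out, "correction") <- sum(per)
  attr(out, "per_proline") <- unname(per)
  out
}

#' Threshold free energy for the metastable-state search
#'
#' dG_X = dG_U* + (dG_HX - dG_HX*): the unfolding free energy corrected
#' for both baseline treatment (via dG_U*) and cis-trans proline
#' isomerization (via the dG_HX - dG_HX* term).  Residues with
#' dG_HX above this threshold are metastable-state candidates.
#'
#' @param dg_u_star Baseline-corrected unfolding free energy (kcal/mol).
#' @param dg_hx Global free energy of exchange (kcal/mol).
#' @param dg_hx_star Proline-corrected free energy of exchange (kcal/mol).
#' @return dG_X in kcal/mol.
#' @export
dg_x <- function(dg_u_star, dg_hx, dg_hx_star) {
  stopifnot(is.finite(dg_u_star), is.finite(dg_hx), is.finite(dg_hx_star))
  dg_u_star + (dg_hx - dg_hx_star)
}

#' Compare two free energies at a tolerance
#'
#' @param a,b kcal/mol.
#' @param tolerance Inclusive tolerance (default 0.4 kcal/mol, the
#'   typical contribution of trans prolines).
#' @return "consistent" if |a - b| <= tolerance else "discrepant".
#' @export
compare_energies <- function(a, b, tolerance = cf_constants$tolerance) {
  # small slack so the inclusive boundary survives binary representation
  # of decimal inputs (|5.0 - 5.4| must equal 0.4)
  ifelse(abs(a - b) <= tolerance + 1e-9, "consistent", "discrepant")
}

#' Assemble the free-energy ledger of a protein
#'
#' Collects the five scalar free energies, derives dG_X and the
#' tolerance verdicts used to route the pipeline.
#'
#' @param dg_u Unfolding free energy from a linear-baseline melt fit.
#' @param dg_u_star Unfolding free energy after baseline treatment
#'   (defaults to dg_u).
#' @param dg_hx Global free energy of exchange.
#' @param dg_hx_star Proline-corrected dg_hx (defaults to dg_hx).
#' @param tolerance Comparison tolerance in kcal/mol.
#' @return Object of class `energy_ledger`.
#' @export
energy_ledger <- function(dg_u, dg_hx, dg_u_star = dg_u,
                          dg_hx_star = dg_hx,
                          tolerance = cf_constants$tolerance) {
  if (dg_hx_star > dg_hx + 1e-9) {
    stop("dg_hx_star cannot exceed dg_hx: the isomerization correction is ",
         "a non-negative decrease")
  }
  structure(list(
    dg_u = dg_u, dg_u_star = dg_u_star,
    dg_hx = dg_hx, dg_hx_star = dg_hx_star,
    dg_x = dg_x(dg_u_star, dg_hx, dg_hx_star),
    tolerance = tolerance,
    verdicts = c(
      hx_star_vs_u = compare_energies(dg_hx_star, dg_u, tolerance),
      hx_star_vs_u_star = compare_energies(dg_hx_star, dg_u_star, tolerance)
    )
  ), class = "energy_ledger")
}

#' @export
print.energy_ledger <- function(x, ...) {
  cat(sprintf(paste0("energy_ledger (kcal/mol): dG_U %.2f | dG_U* %.2f | ",
                     "dG_HX %.2f | dG_HX* %.2f | dG_X %.2f\n"),
              x$dg_u, x$dg_u_star, x$dg_hx, x$dg_hx_star, x$dg_x))
  cat(sprintf("  dG_HX* vs dG_U : %s (tolerance %.2f)\n",
              x$verdicts[["hx_star_vs_u"]], x$tolerance))
  cat(sprintf("  dG_HX* vs dG_U*: %s\n", x$verdicts[["hx_star_vs_u_star"]]))
  invisible(x)
}

#' Read a residue exchange table
#'
#' Tab-separated with a header; columns: `residue` (author number),
#' optional `chain`, and exactly one of `k_ex` (min^-1) or `dg_hx`
#' (kcal/mol).
#'
#' @param path File path.
#' @return Data frame with the validated columns.
#' @export
read_exchange_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!"residue" %in% names(tab)) stop("exchange table needs a 'residue' column")
  has_kex <- "k_ex" %in% names(tab)
  has_dg <- "dg_hx" %in% names(tab)
  if (has_kex == has_dg) {
    stop("exchange table must have exactly one of 'k_ex' or 'dg_hx'")
  }
  if (has_kex && any(tab$k_ex <= 0)) stop("k_ex values must be positive")
  tab
}
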