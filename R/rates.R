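# Intrinsic (random-coil) exchange rates for backbone amide protons from
# sequence context and solution conditions.  The reference-rate scheme
# sums acid-, base- and water-catalysed channels, each modulated by
# log-additive side-chain factors of the residue owning the NH and its
# left neighbour, evaluated at 293 K and then Arrhenius-scaled per
# channel to the experiment temperature.

#' Solution conditions for an exchange experiment
#'
#' @param pH_read pH-meter reading.
#' @param temperature Absolute temperature in K.
#' @param ionic_strength Molar ionic strength (recorded; the bundled
#'   reference table applies no explicit ionic-strength correction and
#'   this is flagged in reports).
#' @param solvent "D2O" (default) or "H2O".  In D2O the reading is
#'   corrected for the deuterium isotope effect: pD = pH_read + 0.4.
#' @return Object of class `exchange_conditions`.
#' @export
exchange_conditions <- function(pH_read, temperature = 293,
                                ionic_strength = 0.1, solvent = c("D2O", "H2O")) {
  solvent <- match.arg(solvent)
  if (temperature <= 0) stop("temperature must be positive (Kelvin)")
  structure(list(
    pH_read = pH_read,
    pD = if (solvent == "D2O") pH_read + 0.4 else pH_read,
    temperature = temperature,
    ionic_strength = ionic_strength,
    solvent = solvent
  ), class = "exchange_conditions")
}

#' @export
print.exchange_conditions <- function(x, ...) {
  cat(sprintf("exchange_conditions: pH read %.2f (pD %.2f), %g K, I = %g M, %s\n",
              x$pH_read, x$pD, x$temperature, x$ionic_strength, x$solvent))
  invisible(x)
}

#' Load a reference rate table
#'
#' Reads the bundled (or a user-supplied) YAML file of reference rate
#' constants, side-chain neighbour factors and activation energies.  The
#' bundled table is the D2O poly-alanine-basis convention at 293 K; users
#' working in H2O must supply their own table of the same layout.
#'
#' @param path Path to a YAML file; default the bundled table.
#' @return Object of class `rate_table`: list with `constants` (log_ka,
#'   log_kb, log_kw, pKD, activation energies, reference temperature) and
#'   `factors` (matrix, rows = residue codes incl. CYS2/PRO/PRO_CIS and
#'   the NTERM/CTERM corrections, columns acid_self, acid_prev,
#'   base_self, base_prev).
#' @export
load_rate_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "intrinsic_rate_factors.yaml",
                        package = "crypticfold", mustWork = TRUE)
  }
  y <- yaml::read_yaml(path)
  fac <- do.call(rbind, y$factors)
  colnames(fac) <- c("acid_self", "acid_prev", "base_self", "base_prev")
  std <- setdiff(rownames(fac), c("NTERM", "CTERM"))
  need <- c("ALA", "ARG", "ASN", "ASP", "CYS", "CYS2", "GLN", "GLU", "GLY",
            "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "PRO_CIS",
            "SER", "THR", "TRP", "TYR", "VAL")
  miss <- setdiff(need, std)
  if (length(miss)) stop("rate table is missing factors for: ",
                         paste(miss, collapse = ", "))
  structure(list(
    constants = list(
      log_ka = y$log_ka, log_kb = y$log_kb, log_kw = y$log_kw,
      pKD = y$pKD,
      E = c(acid = y$activation_energies$acid,
            base = y$activation_energies$base,
            water = y$activation_energies$water),
      T_ref = y$temperature_ref, solvent = y$solvent, version = y$version
    ),
    factors = fac
  ), class = "rate_table")
}

rate_factor <- function(table, resid, column) {
  if (!resid %in% rownames(table$factors)) {
    stop("unknown residue code in rate table lookup: ", resid)
  }
  table$factors[resid, column]
}

#' Arrhenius temperature scaling of a rate constant
#'
#' k(T) = k(293) * exp(-(E/R) * (1/T - 1/293)), applied per catalysis
#' channel with that channel's activation energy.
#'
#' @param k_293 Rate constant at the 293 K reference (min^-1).
#' @param E Activation energy in kcal/mol (acid 14, base 17, water 19).
#' @param temperature Target temperature in K.
#' @return Scaled rate constant (min^-1).
#' @export
temperature_scale <- function(k_293, E, temperature) {
  if (temperature <= 0) stop("temperature must be positive (Kelvin)")
  k_293 * exp(-(E / cf_constants$R) * (1 / temperature - 1 / cf_constants$T_ref))
}

# channel terms at the experiment temperature for one NH; left/right are
# residue codes as in the factors table; nterm/cterm add the terminal
# corrections
krc_terms <- function(left, right, conditions, table,
                      nterm = FALSE, cterm = FALSE) {
  if (right %in% c("PRO", "PRO_CIS")) {
    warning("proline has no exchangeable backbone NH; returning NA")
    return(c(acid = NA_real_, base = NA_real_, water = NA_real_))
  }
  la <- rate_factor(table, right, "acid_self") + rate_factor(table, left, "acid_prev")
  lb <- rate_factor(table, right, "base_self") + rate_factor(table, left, "base_prev")
  if (nterm) {
    la <- la + rate_factor(table, "NTERM", "acid_prev")
    lb <- lb + rate_factor(table, "NTERM", "base_prev")
  }
  if (cterm) {
    la <- la + rate_factor(table, "CTERM", "acid_self")
    lb <- lb + rate_factor(table, "CTERM", "base_self")
  }
  cst <- table$constants
  pD <- conditions$pD
  k293 <- c(
    acid = 10^(cst$log_ka + la - pD),
    base = 10^(cst$log_kb + lb + pD - cst$pKD),
    water = 10^(cst$log_kw + lb)   # water channel shares the base factors
  )
  c(acid = unname(temperature_scale(k293[["acid"]], cst$E[["acid"]],
                                    conditions$temperature)),
    base = unname(temperature_scale(k293[["base"]], cst$E[["base"]],
                                    conditions$temperature)),
    water = unname(temperature_scale(k293[["water"]], cst$E[["water"]],
                                     conditions$temperature)))
}

#' Intrinsic exchange rate for one amide in a given neighbour context
#'
#' @param left,right Residue codes (3-letter, plus the variants CYS2,
#'   PRO, PRO_CIS) of the residues to the left and right of the amide
#'   proton; `right` is the residue owning the NH.
#' @param conditions An [exchange_conditions()] object.
#' @param table A [load_rate_table()] object.
#' @param nterm,cterm Apply the terminal corrections.
#' @return k_rc in min^-1, with attribute `channels` giving the acid,
#'   base and water contributions.  NA (with a warning) when `right` is a
#'   proline, which has no exchangeable NH.
#' @export
krc_at_reference <- function(left, right, conditions,
                             table = load_rate_table(),
                             nterm = FALSE, cterm = FALSE) {
  ch <- krc_terms(left, right, conditions, table, nterm, cterm)
  k <- sum(ch)
  names(k) <- NULL
  attr(k, "channels") <- unname(ch)
  names(attr(k, "channels")) <- c("acid", "base", "water")
  k
}

# map a residue of a structure to its rate-table code, honouring cystine
# and cis-proline assignments
residue_rate_code <- function(resid, key, cystines, cis_keys) {
  if (resid == "CYS" && key %in% cystines) return("CYS2")
  if (resid == "PRO" && key %in% cis_keys) return("PRO_CIS")
  if (!resid %in% c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                    "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                    "THR", "TRP", "TYR", "VAL")) {
    stop("unknown residue code: ", resid)
  }
  resid
}

#' Intrinsic exchange rate profile of a structure
#'
#' One result per exchangeable backbone NH: every residue except prolines
#' and each chain's first residue (whose free amine exchanges too fast to
#' carry an amide NH).  Disulfide-bonded cysteines use the cystine
#' factors, and prolines contribute cis- or trans-specific left-neighbour
#' factors according to the structural assignment.
#'
#' @param s A `protein_structure`.
#' @param conditions An [exchange_conditions()] object.
#' @param disulfides Optional [detect_disulfides()] result.
#' @param prolines Optional [classify_prolines()] result.
#' @param table A [load_rate_table()] object.
#' @return Data frame: key, label, chain, resno, resid, left_code,
#'   right_code, nterm, cterm, k_rc, acid, base, water.
#' @export
krc_profile <- function(s, conditions, disulfides = NULL, prolines = NULL,
                        table = load_rate_table()) {
  rs <- s$residues
  cyss <- cystine_keys(disulfides)
  cis_keys <- if (!is.null(prolines)) {
    prolines$key[prolines$conformation == "cis"]
  } else character()
  out <- list()
  for (i in seq_len(nrow(rs))) {
    first_in_chain <- i == 1 || rs$chain[i] != rs$chain[i - 1]
    if (first_in_chain || rs$resid[i] == "PRO") next
    last_in_chain <- i == nrow(rs) || rs$chain[i + 1] != rs$chain[i]
    right <- residue_rate_code(rs$resid[i], rs$key[i], cyss, cis_keys)
    left <- residue_rate_code(rs$resid[i - 1], rs$key[i - 1], cyss, cis_keys)
    second_in_chain <- i == 2 || (i > 2 && rs$chain[i - 2] != rs$chain[i])
    ch <- krc_terms(left, right, conditions, table,
                    nterm = second_in_chain, cterm = last_in_chain)
    out[[length(out) + 1]] <- data.frame(
      key = rs$key[i], label = residue_label(s, rs$key[i]),
      chain = rs$chain[i], resno = rs$resno[i], resid = rs$resid[i],
      left_code = left, right_code = right,
      nterm = second_in_chain, cterm = last_in_chain,
      k_rc = sum(ch), acid = ch[[1]], base = ch[[2]], water = ch[[3]],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intrinsic rate profile from a plain sequence
#'
#' Sequence-only variant of [krc_profile()] (no structure, so no cystine
#' or cis-proline adjustments).
#'
#' @param sequence One-letter amino-acid string.
#' @inheritParams krc_profile
#' @return Data frame as in [krc_profile()], keyed by position.
#' @export
krc_profile_sequence <- function(sequence, conditions,
                                 table = load_rate_table()) {
  aa1 <- strsplit(toupper(sequence), "")[[1]]
  aa3 <- bio3d::aa123(aa1)
  if (any(is.na(aa3))) {
    stop("unknown one-letter code(s): ",
         paste(unique(aa1[is.na(aa3)]), collapse = ", "))
  }
  n <- length(aa3)
  out <- list()
  for (i in 2:n) {
    if (aa3[i] == "PRO") next
    ch <- krc_terms(aa3[i - 1], aa3[i], conditions, table,
                    nterm = i == 2, cterm = i == n)
    out[[length(out) + 1]] <- data.frame(
      key = paste0(aa1[i], i), label = paste0(aa1[i], i),
      chain = "A", resno = i, resid = aa3[i],
      left_code = aa3[i - 1], right_code = aa3[i],
      nterm = i == 2, cterm = i == n,
      k_rc = sum(ch), acid = ch[[1]], base = ch[[2]], water = ch[[3]],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
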