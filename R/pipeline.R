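# Four-stage orchestration: rates/energetics -> proline correction ->
# melting-curve treatment -> intermediate prediction, with provenance
# echoing and machine-readable reports.

#' Assemble a pipeline run configuration
#'
#' @param pdb Path to a PDB file, or PDB-format text.
#' @param exchange Optional path to a residue exchange table
#'   ([read_exchange_table()] format).
#' @param melt Optional path to a melting curve ([read_melting_curve()]).
#' @param dg_u Unfolding free energy from the melt analysis (kcal/mol).
#' @param dg_u_star Optional baseline-corrected unfolding free energy; if
#'   absent it is taken from the melt fit (stage 3) or defaults to dg_u.
#' @param pH,temperature,ionic_strength,solvent Solution conditions.
#' @param tolerance Free-energy comparison tolerance (kcal/mol).
#' @param disulfide_cutoff,hbond_cutoff,contact_cutoff Geometry cutoffs (A).
#' @param kpro Optional path overriding the bundled cis-fraction table.
#' @param rate_table Optional path overriding the bundled reference rates.
#' @param pre,post Baseline kinds for the melt fit.
#' @param out Optional output directory for tables and reports.
#' @return Object of class `run_config`.
#' @export
run_config <- function(pdb, exchange = NULL, melt = NULL,
                       dg_u = NA_real_, dg_u_star = NA_real_,
                       pH = 7.0, temperature = 298, ionic_strength = 0.1,
                       solvent = "D2O",
                       tolerance = cf_constants$tolerance,
                       disulfide_cutoff = cf_constants$disulfide_cutoff,
                       hbond_cutoff = cf_constants$hbond_cutoff,
                       contact_cutoff = cf_constants$contact_cutoff,
                       kpro = NULL, rate_table = NULL,
                       pre = "linear", post = "linear", out = NULL) {
  stopifnot(disulfide_cutoff > 0, hbond_cutoff > 0, contact_cutoff > 0)
  structure(list(
    pdb = pdb, exchange = exchange, melt = melt,
    dg_u = dg_u, dg_u_star = dg_u_star,
    conditions = exchange_conditions(pH, temperature, ionic_strength, solvent),
    tolerance = tolerance,
    disulfide_cutoff = disulfide_cutoff, hbond_cutoff = hbond_cutoff,
    contact_cutoff = contact_cutoff,
    kpro = kpro, rate_table = rate_table,
    pre = pre, post = post, out = out
  ), class = "run_config")
}

load_config_structure <- function(config) {
  if (length(config$pdb) == 1 && !grepl("\n", config$pdb) &&
      file.exists(config$pdb)) {
    read_structure(config$pdb)
  } else {
    parse_pdb(config$pdb)
  }
}

#' Stage 1: intrinsic rates and exchange energetics
#'
#' Parses the structure, detects disulfides and proline conformations,
#' computes the intrinsic-rate profile, and (when an exchange table is
#' supplied) the per-residue protection factors, dG_HX values and the
#' global dG_HX.
#'
#' @param config A [run_config()].
#' @return List (class `stage1_result`): structure, disulfides, prolines,
#'   rates (data frame, with p and dg_hx columns when measured rates were
#'   given), dg_hx_global (NA without an exchange table), dg_map,
#'   conditions.
#' @export
run_stage1 <- function(config) {
  s <- load_config_structure(config)
  message("stage 1: structure '", s$id, "' with ", nrow(s$residues),
          " residues")
  disulf <- detect_disulfides(s, config$disulfide_cutoff)
  pro <- classify_prolines(s)
  table <- if (is.null(config$rate_table)) load_rate_table() else
    load_rate_table(config$rate_table)
  rates <- krc_profile(s, config$conditions, disulf, pro, table)
  rates$p <- NA_real_
  rates$dg_hx <- NA_real_
  dg_map <- NULL
  dg_global <- NA_real_
  if (!is.null(config$exchange)) {
    ex <- read_exchange_table(config$exchange)
    i <- match(ex$residue, rates$resno)
    if ("k_ex" %in% names(ex)) {
      ok <- !is.na(i)
      temperature <- config$conditions$temperature
      rates$p[i[ok]] <- protection_factor(ex$k_ex[ok], rates$k_rc[i[ok]])
      rates$dg_hx[i[ok]] <- as.numeric(
        dg_hx(ex$k_ex[ok], rates$k_rc[i[ok]], temperature))
    } else {
      rates$dg_hx[i[!is.na(i)]] <- ex$dg_hx[!is.na(i)]
    }
    have <- !is.na(rates$dg_hx)
    dg_map <- stats::setNames(rates$dg_hx[have], rates$key[have])
    dg_global <- global_dg_hx(rates$dg_hx)
    message(sprintf("stage 1: global dG_HX (mean of four largest) = %.2f kcal/mol",
                    dg_global))
  } else {
    message("stage 1: no exchange table supplied; rates-only output")
  }
  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(rates, file.path(config$out, "rates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  structure(list(structure = s, disulfides = disulf, prolines = pro,
                 rates = rates, dg_hx_global = dg_global, dg_map = dg_map,
                 conditions = config$conditions),
            class = "stage1_result")
}

#' Stage 2: cis-trans proline isomerization correction
#'
#' Applies the unfolded-state proline correction to the global dG_HX and
#' compares dG_HX* with dG_U at the configured tolerance.
#'
#' @param config A [run_config()].
#' @param stage1 A [run_stage1()] result.
#' @param dg_hx Override for the global dG_HX (defaults to the stage-1
#'   value).
#' @return List (class `stage2_result`): dg_hx, dg_hx_star, correction,
#'   verdict, prolines.
#' @export
run_stage2 <- function(config, stage1, dg_hx = stage1$dg_hx_global) {
  if (!is.finite(dg_hx)) {
    stop("stage 2 needs a global dG_HX (supply an exchange table or dg_hx)")
  }
  pro <- stage1$prolines
  if (nrow(pro)) {
    # cystine left neighbours use the cystine cis fraction
    cyss <- cystine_keys(stage1$disulfides)
    pro$left_resid[pro$left_resid == "CYS" & pro$left_key %in% cyss] <- "CYS2"
  }
  fcis <- if (is.null(config$kpro)) load_cis_fractions() else
    load_cis_fractions(config$kpro)
  star <- proline_correction(dg_hx, pro, fcis,
                             config$conditions$temperature)
  verdict <- compare_energies(as.numeric(star), config$dg_u, config$tolerance)
  message(sprintf("stage 2: dG_HX* = %.2f vs dG_U = %.2f -> %s",
                  as.numeric(star), config$dg_u, verdict))
  if (verdict == "consistent") {
    message("stage 2: discrepancy accounted by proline isomerisation; ",
            "no further search needed")
  }
  structure(list(dg_hx = dg_hx, dg_hx_star = as.numeric(star),
                 correction = attr(star, "correction"),
                 per_proline = attr(star, "per_proline"),
                 verdict = verdict, prolines = pro),
            class = "stage2_result")
}

#' Stage 3: melting-curve baseline treatment
#'
#' Fits the melting curve with the configured baseline kinds when one is
#' supplied; otherwise passes through the user-provided dG_U*.
#'
#' @param config A [run_config()].
#' @return List (class `stage3_result`): dg_u_star, fit (NULL for
#'   pass-through), source ("fit" or "input").
#' @export
run_stage3 <- function(config) {
  if (!is.null(config$melt)) {
    curve <- read_melting_curve(config$melt)
    fit <- fit_melting(curve, config$pre, config$post,
                       temperature = config$conditions$temperature)
    dgs <- if (!is.na(fit$dg_u_star)) fit$dg_u_star else fit$dg_u
    message(sprintf("stage 3: fitted dG_U* = %.2f kcal/mol (m = %.2f, C_m = %.2f M)",
                    dgs, fit$m, fit$cm))
    structure(list(dg_u_star = dgs, fit = fit, source = "fit"),
              class = "stage3_result")
  } else {
    dgs <- if (is.finite(config$dg_u_star)) config$dg_u_star else config$dg_u
    message(sprintf("stage 3: no melting curve; using dG_U* = %.2f", dgs))
    structure(list(dg_u_star = dgs, fit = NULL, source = "input"),
              class = "stage3_result")
  }
}

#' Stage 4: intermediate / metastable-state prediction
#'
#' @param config A [run_config()].
#' @param stage1 A [run_stage1()] result (structure + dG map).
#' @param ledger An [energy_ledger()].
#' @return An `intermediate_prediction`; when `config$out` is set, a
#'   JSON report and per-cluster PDB files are written there.
#' @export
run_stage4 <- function(config, stage1, ledger) {
  s <- stage1$structure
  if (is.null(stage1$dg_map)) stop("stage 4 needs residue-specific dG_HX")
  hb <- detect_backbone_hbonds(s, config$hbond_cutoff)
  ss <- assign_secondary_structure(s, hb)
  pred <- predict_intermediates(s, ss, hb, stage1$dg_map, ledger,
                                cutoff = config$contact_cutoff,
                                tolerance = config$tolerance,
                                out_dir = config$out)
  message("stage 4: mode = ", pred$mode, " with ", length(pred$clusters),
          " cluster(s); dG_X threshold ", sprintf("%.2f", ledger$dg_x),
          " kcal/mol")
  if (!is.null(config$out)) {
    write_prediction_report(pred, ledger, config,
                            file.path(config$out, "report.json"))
  }
  pred
}

#' Write the machine-readable prediction report
#'
#' @param pred An `intermediate_prediction`.
#' @param ledger An `energy_ledger`.
#' @param config The `run_config` (echoed for provenance).
#' @param path Output JSON path.
#' @return The report list, invisibly.
#' @export
write_prediction_report <- function(pred, ledger, config, path) {
  rep <- list(
    mode = pred$mode,
    dg_x = ledger$dg_x,
    ledger = list(dg_u = ledger$dg_u, dg_u_star = ledger$dg_u_star,
                  dg_hx = ledger$dg_hx, dg_hx_star = ledger$dg_hx_star,
                  tolerance = ledger$tolerance,
                  verdicts = as.list(ledger$verdicts)),
    clusters = lapply(seq_along(pred$clusters), function(k) {
      list(members = pred$clusters[[k]],
           coverage = as.list(pred$coverages[[k]]))
    }),
    cooperative_pairs = pred$cooperative,
    singletons = pred$singletons,
    settings = list(
      contact_cutoff = config$contact_cutoff,
      hbond_cutoff = config$hbond_cutoff,
      disulfide_cutoff = config$disulfide_cutoff,
      tolerance = config$tolerance,
      conditions = unclass(config$conditions),
      ionic_strength_note = "recorded only; no explicit correction applied"
    )
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}

#' Run the full four-stage pipeline
#'
#' @param config A [run_config()].
#' @param stop_when_consistent Stop after stage 2 when dG_HX* and dG_U
#'   agree within tolerance (the pipeline's default routing).
#' @return List with elements stage1, stage2, stage3, ledger and (unless
#'   stopped early) prediction.
#' @export
run_pipeline <- function(config, stop_when_consistent = TRUE) {
  s1 <- run_stage1(config)
  s2 <- run_stage2(config, s1)
  if (stop_when_consistent && s2$verdict == "consistent") {
    return(list(stage1 = s1, stage2 = s2, stage3 = NULL,
                ledger = energy_ledger(config$dg_u, s2$dg_hx,
                                       dg_hx_star = s2$dg_hx_star,
                                       tolerance = config$tolerance),
                prediction = NULL))
  }
  s3 <- run_stage3(config)
  ledger <- energy_ledger(config$dg_u, s2$dg_hx, dg_u_star = s3$dg_u_star,
                          dg_hx_star = s2$dg_hx_star,
                          tolerance = config$tolerance)
  pred <- run_stage4(config, s1, ledger)
  list(stage1 = s1, stage2 = s2, stage3 = s3, ledger = ledger,
       prediction = pred)
}
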