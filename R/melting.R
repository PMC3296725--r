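# Two-state equilibrium denaturation analysis: the Santoro-Bolen signal
# model with pluggable pre-/post-transition baselines (linear,
# exponential or polynomial) fitted by multi-start Levenberg-Marquardt
# nonlinear least squares.

#' Construct a baseline model
#'
#' Three baseline families for the folded (pre) and unfolded (post)
#' signal limbs:
#' * linear: `Y + slope * C`
#' * exponential: `Ic + I0 * exp(-C / s)` - a signal that relaxes to the
#'   asymptote `Ic` with concentration scale `s` (M), amplitude
#'   `I0 = S(0) - Ic`
#' * polynomial: `sum(coef[k] * C^(k-1))`, default degree 2 (degree > 3
#'   is rejected to avoid absorbing the transition)
#'
#' @param kind "linear", "exponential" or "polynomial".
#' @param parameters Numeric vector: linear (intercept, slope);
#'   exponential (Ic, I0, s with s > 0); polynomial (degree+1
#'   coefficients, constant first).
#' @return Object of class `baseline_model`.
#' @export
make_baseline <- function(kind = c("linear", "exponential", "polynomial"),
                          parameters) {
  kind <- match.arg(kind)
  n <- length(parameters)
  if (kind == "linear" && n != 2) stop("linear baseline needs 2 parameters")
  if (kind == "exponential") {
    if (n != 3) stop("exponential baseline needs 3 parameters (Ic, I0, s)")
    if (parameters[3] <= 0) stop("exponential decay scale s must be positive")
  }
  if (kind == "polynomial" && (n < 2 || n > 4)) {
    stop("polynomial baseline supports degree 1 to 3")
  }
  structure(list(kind = kind, parameters = unname(parameters)),
            class = "baseline_model")
}

#' Evaluate a baseline model
#'
#' @param baseline A `baseline_model`.
#' @param concentration Denaturant molarity (vectorized).
#' @return Signal values.
#' @export
eval_baseline <- function(baseline, concentration) {
  p <- baseline$parameters
  switch(baseline$kind,
    linear = p[1] + p[2] * concentration,
    exponential = p[1] + p[2] * exp(-concentration / p[3]),
    polynomial = {
      out <- rep(0, length(concentration))
      for (k in seq_along(p)) out <- out + p[k] * concentration^(k - 1)
      out
    }
  )
}

#' Two-state denaturation signal
#'
#' S(C) = \[S_n(C) + S_u(C) exp(-(dG_U - m C)/RT)\] /
#' \[1 + exp(-(dG_U - m C)/RT)\], the two-state model with
#' concentration-dependent folded and unfolded baselines.
#'
#' @param concentration Denaturant molarity (vectorized).
#' @param dg_u Free energy of unfolding at zero denaturant (kcal/mol).
#' @param m Denaturant dependence of dG (kcal/mol/M).
#' @param pre,post Baseline models for the folded and unfolded limbs.
#' @param temperature Kelvin.
#' @return Signal values.
#' @export
two_state_signal <- function(concentration, dg_u, m, pre, post,
                             temperature = 288) {
  K <- exp(-(dg_u - m * concentration) / (GAS_R * temperature))
  (eval_baseline(pre, concentration) + eval_baseline(post, concentration) * K) /
    (1 + K)
}

baseline_par_names <- function(kind, side, degree = 2) {
  switch(kind,
    linear = paste0(c("Y_", "m_"), side),
    exponential = paste0(c("Ic_", "I0_", "s_"), side),
    polynomial = paste0("a", 0:degree, "_", side)
  )
}

#' Describe the composite two-state model equation
#'
#' Returns the structured description (parameter names, count, bounds) of
#' the two-state equation assembled from the chosen baseline kinds, as
#' used for fit reporting.
#'
#' @param pre_kind,post_kind Baseline kinds ("linear", "exponential",
#'   "polynomial").
#' @param degree Polynomial degree (default 2).
#' @return List: `pre_kind`, `post_kind`, `parameters` (character),
#'   `n_parameters`, `lower` (named lower bounds).
#' @export
build_model_equation <- function(pre_kind, post_kind, degree = 2) {
  kinds <- c("linear", "exponential", "polynomial")
  if (!pre_kind %in% kinds) stop("unknown baseline kind: ", pre_kind)
  if (!post_kind %in% kinds) stop("unknown baseline kind: ", post_kind)
  if (degree > 3) stop("polynomial baseline degree above 3 is not supported")
  pars <- c(baseline_par_names(pre_kind, "n", degree),
            baseline_par_names(post_kind, "u", degree),
            "dG_U", "m")
  lower <- stats::setNames(rep(-Inf, length(pars)), pars)
  lower[grep("^s_", pars)] <- 1e-3   # exponential decay scale must be positive
  lower["m"] <- 1e-3                 # unfolding transitions have m > 0
  list(pre_kind = pre_kind, post_kind = post_kind, parameters = pars,
       n_parameters = length(pars), lower = lower)
}

n_baseline_pars <- function(kind, degree = 2) {
  switch(kind, linear = 2, exponential = 3, polynomial = degree + 1)
}

# crude baseline starting values from the curve extremes
baseline_start <- function(kind, conc, sig, side, degree = 2, cm_guess) {
  k <- max(3, min(5, floor(length(conc) / 4)))
  idx <- if (side == "n") seq_len(k) else seq(length(conc) - k + 1, length(conc))
  fitlm <- stats::lm(sig[idx] ~ conc[idx])
  switch(kind,
    linear = unname(stats::coef(fitlm)),
    exponential = {
      ic <- sig[idx][which.max(abs(conc[idx] - conc[ifelse(side == "n", 1,
                                                           length(conc))]))]
      c(ic, sig[ifelse(side == "n", 1, length(conc))] - ic,
        max(0.2, 0.3 * cm_guess))
    },
    polynomial = c(unname(stats::coef(fitlm)), rep(0, degree - 1))
  )
}

#' Fit a melting curve to the two-state model
#'
#' Multi-start Levenberg-Marquardt least squares over all baseline and
#' thermodynamic parameters.  Midpoints C_m are seeded on a grid across
#' the observed concentration range; dG_U is initialized as
#' m_guess * C_m with m_guess from the transition's maximum slope; the
#' best residual over all starts wins (fixed ordering, deterministic).
#' When either baseline is nonlinear the fitted dG_U is the
#' baseline-corrected estimate (reported as `dg_u_star`).
#'
#' @param curve Data frame (concentration, signal), e.g. from
#'   [build_melting_curve()] or [read_melting_curve()].
#' @param pre_kind,post_kind Baseline kinds.
#' @param temperature Kelvin (required; thermodynamic scale of the fit).
#' @param degree Polynomial baseline degree.
#' @param n_starts Number of C_m grid starts (default 20).
#' @param weights Optional per-point weights (inverse variances) for
#'   heteroscedastic signals, e.g. `1/signal^2` when the optical noise is
#'   proportional to the signal; default unweighted.
#' @return Object of class `two_state_fit`: dg_u, m, cm (= dg_u/m),
#'   dg_u_star, pre, post (fitted `baseline_model`s), rss, converged,
#'   n_points, aic, model (from [build_model_equation()]), parameters
#'   (named vector), temperature.
#' @export
fit_melting <- function(curve, pre_kind = "linear", post_kind = "linear",
                        temperature = 288, degree = 2, n_starts = 20,
                        weights = NULL) {
  conc <- curve$concentration
  sig <- curve$signal
  sw <- if (is.null(weights)) rep(1, length(conc)) else sqrt(weights)
  if (length(conc) < 8) {
    warning("melting curve must be adequately defined with sufficient data ",
            "points (fewer than 8 supplied)")
  }
  if (any(conc < 0)) stop("denaturant concentrations must be non-negative")
  model <- build_model_equation(pre_kind, post_kind, degree)
  npre <- n_baseline_pars(pre_kind, degree)
  npost <- n_baseline_pars(post_kind, degree)

  unpack <- function(p) {
    list(pre = make_baseline(pre_kind, p[seq_len(npre)]),
         post = make_baseline(post_kind, p[npre + seq_len(npost)]),
         dg = p[npre + npost + 1], m = p[npre + npost + 2])
  }
  resid_fun <- function(p) {
    u <- unpack(p)
    sw * (two_state_signal(conc, u$dg, u$m, u$pre, u$post, temperature) - sig)
  }

  # transition slope -> m scale: dS/dC at Cm is (Su-Sn) m / (4RT)
  ds <- diff(sig) / diff(conc)
  amp <- abs(sig[length(sig)] - sig[1])
  m_guess <- max(0.5, 4 * GAS_R * temperature * max(abs(ds)) /
                   max(amp, .Machine$double.eps))
  cm_grid <- seq(stats::quantile(conc, 0.15), stats::quantile(conc, 0.85),
                 length.out = n_starts)
  lower <- rep(-Inf, model$n_parameters)
  lower[match(names(model$lower)[is.finite(model$lower)],
              model$parameters)] <- model$lower[is.finite(model$lower)]

  best <- NULL
  for (cm0 in cm_grid) {
    p0 <- c(baseline_start(pre_kind, conc, sig, "n", degree, cm0),
            baseline_start(post_kind, conc, sig, "u", degree, cm0),
            m_guess * cm0, m_guess)
    p0 <- pmax(p0, lower + ifelse(is.finite(lower), 1e-3, 0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun, lower = lower,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("two-state fit failed to converge from any start; check that the ",
         "curve shows a transition")
  }
  p <- best$fit$par
  u <- unpack(p)
  n <- length(conc)
  cm <- u$dg / u$m
  # degenerate curve guard: a curve without a transition is explained by a
  # straight line as well as by the two-state model
  rss_line <- sum(stats::resid(stats::lm(sig ~ conc))^2)
  if (!is.finite(cm) || cm <= 0 || cm > max(conc) * 2 ||
      rss_line < 1.5 * best$rss + 1e-12) {
    stop("no resolvable unfolding transition in the melting curve")
  }
  nonlinear <- pre_kind != "linear" || post_kind != "linear"
  structure(list(
    dg_u = u$dg, m = u$m, cm = cm,
    dg_u_star = if (nonlinear) u$dg else NA_real_,
    pre = u$pre, post = u$post,
    rss = best$rss, converged = best$fit$info %in% 1:4,
    n_points = n,
    aic = n * log(best$rss / n) + 2 * model$n_parameters,
    model = model,
    parameters = stats::setNames(p, model$parameters),
    temperature = temperature
  ), class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("two_state_fit (%s/%s baselines): dG_U = %.3f kcal/mol, m = %.3f kcal/mol/M, C_m = %.3f M\n",
              x$model$pre_kind, x$model$post_kind, x$dg_u, x$m, x$cm))
  cat(sprintf("  RSS %.3g over %d points; converged: %s\n",
              x$rss, x$n_points, x$converged))
  if (!is.na(x$dg_u_star)) {
    cat(sprintf("  nonlinear baseline(s): dG_U reported as dG_U* = %.3f\n",
                x$dg_u_star))
  }
  invisible(x)
}

#' Read a melting curve from a two-column file
#'
#' Tab-separated concentration (M) and signal; '#' comments allowed.
#'
#' @param path File path.
#' @return A `melting_curve` data frame.
#' @export
read_melting_curve <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", header = FALSE,
                           stringsAsFactors = FALSE)
  if (is.character(tab[1, 1]) && is.na(suppressWarnings(as.numeric(tab[1, 1])))) {
    tab <- tab[-1, , drop = FALSE]  # tolerate a header line
  }
  curve <- data.frame(concentration = as.numeric(tab[[1]]),
                      signal = as.numeric(tab[[2]]))
  if (anyNA(curve)) stop("non-numeric entries in melting-curve file")
  class(curve) <- c("melting_curve", "data.frame")
  curve
}
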