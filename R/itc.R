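# Gas constant in cal mol-1 K-1 (thermodynamics reported in kcal / cal units)
.R_cal <- 1.98720

#' ITC injection schedule
#'
#' Describes a perfusion-cell titration: the macromolecule sits in the cell
#' at `cell_conc`, the titrant is delivered from the syringe at
#' `syringe_conc` in `n_injections` injections of `injection_volume`.
#'
#' @param n_injections number of injections.
#' @param injection_volume per-injection volume (litres); scalar or vector.
#' @param cell_volume active cell volume V0 (litres); default 1.4 ml,
#'   typical of a VP-ITC cell.
#' @param cell_conc macromolecule concentration in the cell (molar).
#' @param syringe_conc titrant concentration in the syringe (molar).
#' @param temperature kelvin.
#' @return object of class `injection_schedule`.
#' @export
injection_schedule <- function(n_injections = 45L,
                               injection_volume = 6e-6,
                               cell_volume = 1.4e-3,
                               cell_conc,
                               syringe_conc,
                               temperature = 293.15) {
  dv <- rep_len(injection_volume, n_injections)
  stopifnot(n_injections >= 1, all(dv > 0), cell_volume > 0,
            cell_conc > 0, syringe_conc > 0, temperature > 0)
  if (sum(dv) >= cell_volume)
    stop("cumulative injected volume must stay below the cell volume")
  structure(list(n_injections = as.integer(n_injections),
                 injection_volume = dv, cell_volume = cell_volume,
                 cell_conc = cell_conc, syringe_conc = syringe_conc,
                 temperature = temperature),
            class = "injection_schedule")
}

# Dilution-corrected total concentrations in the cell after each injection
# (perfusion-cell convention: displaced liquid carries cell contents out).
schedule_concentrations <- function(schedule) {
  v <- cumsum(schedule$injection_volume)
  V0 <- schedule$cell_volume
  d <- 1 + v / (2 * V0)
  list(v = v,
       Mt = schedule$cell_conc * (1 - v / (2 * V0)) / d,
       Xt = schedule$syringe_conc * (v / V0) / d)
}

#' One-site (Wiseman) forward model of injection heats
#'
#' Computes the per-injection heats of a single-site binding titration.
#' After injection i the cumulative heat content of the cell is
#' \deqn{Q_i = \frac{N M_i \Delta H V_0}{2}\left[1 + \frac{X_i}{N M_i} +
#'   \frac{1}{N K M_i} - \sqrt{\left(1 + \frac{X_i}{N M_i} +
#'   \frac{1}{N K M_i}\right)^2 - \frac{4 X_i}{N M_i}}\right],}
#' with dilution-corrected total concentrations \eqn{M_i} (macromolecule)
#' and \eqn{X_i} (titrant); the observed heat of injection i is
#' \eqn{\Delta Q_i = Q_i - Q_{i-1} + (dV_i/V_0)(Q_i + Q_{i-1})/2}, the last
#' term accounting for heat carried out with the displaced volume.
#'
#' @param K association constant (M^-1).
#' @param dH binding enthalpy (kcal/mol).
#' @param n_sites stoichiometry N (sites per macromolecule).
#' @param schedule an [injection_schedule()].
#' @return numeric vector of per-injection heats in microcalories.
#' @export
one_site_heats <- function(K, dH, n_sites, schedule) {
  stopifnot(inherits(schedule, "injection_schedule"))
  if (!is.finite(K) || K <= 0) stop("association constant K must be > 0")
  if (n_sites <= 0) stop("stoichiometry must be > 0")
  cc <- schedule_concentrations(schedule)
  if (any(cc$Mt <= 0) || any(cc$Xt < 0)) stop("negative concentrations")
  dH_cal <- dH * 1000
  V0 <- schedule$cell_volume
  b <- 1 + cc$Xt / (n_sites * cc$Mt) + 1 / (n_sites * K * cc$Mt)
  disc <- pmax(b^2 - 4 * cc$Xt / (n_sites * cc$Mt), 0)
  Q <- n_sites * cc$Mt * dH_cal * V0 / 2 * (b - sqrt(disc))
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev + (schedule$injection_volume / V0) * (Q + Qprev) / 2
  dQ * 1e6
}

#' Bundle measured injection heats with their schedule
#'
#' @param schedule an [injection_schedule()].
#' @param heats per-injection heats (microcalories), one per injection.
#' @param dilution_heats optional per-injection heats of dilution from a
#'   control titration, subtracted before fitting.
#' @return object of class `itc_experiment`.
#' @export
itc_experiment <- function(schedule, heats, dilution_heats = NULL) {
  stopifnot(inherits(schedule, "injection_schedule"),
            length(heats) == schedule$n_injections)
  if (!is.null(dilution_heats))
    stopifnot(length(dilution_heats) == schedule$n_injections)
  structure(list(schedule = schedule, heats = heats,
                 dilution_heats = dilution_heats),
            class = "itc_experiment")
}

#' Molar ratio (titrant over macromolecule) after each injection
#' @param x an `itc_experiment` or `injection_schedule`.
#' @return numeric vector of ratios.
#' @export
molar_ratio <- function(x) {
  s <- if (inherits(x, "itc_experiment")) x$schedule else x
  cc <- schedule_concentrations(s)
  cc$Xt / cc$Mt
}

#' @export
print.itc_experiment <- function(x, ...) {
  s <- x$schedule
  cat("ITC experiment:", s$n_injections, "injections of",
      format(s$injection_volume[1] * 1e6), "ul;",
      format(s$syringe_conc * 1e6), "uM titrant into",
      format(s$cell_conc * 1e6), "uM cell at",
      format(s$temperature - 273.15), "C\n")
  invisible(x)
}

# Initial estimates from the shape of the isotherm: dH from the
# early-injection plateau, N from the half-height molar ratio, K from the
# width of the transition (sharper sigmoid <-> larger c = N K Mt0).
itc_init <- function(exp, heats, idx) {
  s <- exp$schedule
  ratio <- molar_ratio(exp)[idx]
  h <- heats
  per_mol <- h * 1e-6 / (s$injection_volume[idx] * s$syringe_conc) # cal/mol
  dH0 <- stats::median(per_mol[seq_len(min(3, length(per_mol)))]) / 1000
  if (!is.finite(dH0) || dH0 == 0) dH0 <- -10
  half <- which(abs(per_mol) <= abs(per_mol[1]) / 2)
  N0 <- if (length(half)) ratio[half[1]] else 1
  if (!is.finite(N0) || N0 <= 0) N0 <- 1
  lo <- which(abs(per_mol) <= 0.75 * abs(per_mol[1]))
  hi <- which(abs(per_mol) <= 0.25 * abs(per_mol[1]))
  width <- if (length(lo) && length(hi)) max(ratio[hi[1]] - ratio[lo[1]], 0.05)
           else 0.5
  c0 <- min(max(4 / width, 1), 1e4)
  K0 <- c0 / (N0 * s$cell_conc)
  list(K = K0, dH = dH0, N = N0)
}

#' Fit the one-site binding model to an ITC experiment
#'
#' Least-squares (chi-squared) fit of the Wiseman one-site model
#' ([one_site_heats()]) to measured per-injection heats, estimating the
#' association constant K, binding enthalpy and stoichiometry. The entropy
#' follows from \eqn{\Delta G = -RT \ln K = \Delta H - T \Delta S}.
#' Starting values are derived from the isotherm shape unless supplied.
#'
#' @param exp an [itc_experiment()].
#' @param init optional starting values `list(K =, dH =, N =)`.
#' @param exclude_first drop the first injection (common practice for real
#'   thermograms where the first injection is unreliable).
#' @return object of class `itc_fit` with components `K` (M^-1), `Kd` (M),
#'   `dH` (kcal/mol), `n_sites`, `dG` (kcal/mol), `dS` (cal/mol/K), `chi2`,
#'   standard errors, the c-value and the fitted heats.
#' @export
fit_one_site <- function(exp, init = NULL, exclude_first = FALSE) {
  stopifnot(inherits(exp, "itc_experiment"))
  heats <- exp$heats
  if (!is.null(exp$dilution_heats)) heats <- heats - exp$dilution_heats
  idx <- seq_along(heats)
  if (exclude_first) idx <- idx[-1]
  if (length(idx) < 6L)
    stop("fit_one_site: need at least 6 informative injections")
  if (is.null(init)) init <- itc_init(exp, heats[idx], idx)
  s <- exp$schedule
  df <- data.frame(y = heats[idx])
  fit <- minpack.lm::nlsLM(
    y ~ one_site_heats(exp(logK), dH, N, s)[idx],
    data = df,
    start = list(logK = log(init$K), dH = init$dH, N = init$N),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  est <- stats::coef(fit)
  K <- exp(est[["logK"]])
  dH <- est[["dH"]]
  N <- est[["N"]]
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    c(logK = NA_real_, dH = NA_real_, N = NA_real_))
  Tk <- s$temperature
  dG_cal <- -.R_cal * Tk * log(K)
  dS <- (dH * 1000 - dG_cal) / Tk
  cval <- N * K * s$cell_conc
  if (cval < 1 || cval > 1000)
    warning(sprintf(
      "c-value %.3g outside the well-determined range [1, 1000]; %s",
      cval, "parameter uncertainties may be large"))
  fitted <- one_site_heats(K, dH, N, s)[idx]
  res <- heats[idx] - fitted
  structure(list(K = K, Kd = 1 / K, dH = dH, n_sites = N,
                 dG = dG_cal / 1000, dS = dS,
                 temperature = Tk, chi2 = sum(res^2),
                 se = c(Kd = (1 / K) * se[["logK"]], dH = se[["dH"]],
                        N = se[["N"]], logK = se[["logK"]]),
                 c_value = cval, injections = idx,
                 fitted_heats = fitted, residuals = res,
                 experiment = exp, converged = TRUE),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, digits = 4, ...) {
  cat("One-site ITC fit\n")
  cat(sprintf("  Kd  = %s M  (K = %s 1/M, c = %.3g)\n",
              format(signif(x$Kd, digits)), format(signif(x$K, digits)),
              x$c_value))
  cat(sprintf("  dH  = %s kcal/mol   N = %s sites\n",
              format(signif(x$dH, digits)), format(signif(x$n_sites, digits))))
  cat(sprintf("  dG  = %s kcal/mol   dS = %s cal/mol/K  (T = %.2f K)\n",
              format(signif(x$dG, digits)), format(signif(x$dS, digits)),
              x$temperature))
  cat(sprintf("  chi2 = %s ucal^2 over %d injections\n",
              format(signif(x$chi2, digits)), length(x$injections)))
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  tab <- data.frame(
    estimate = c(object$Kd, object$dH, object$n_sites, object$dG, object$dS),
    se = c(object$se[["Kd"]], object$se[["dH"]], object$se[["N"]], NA, NA),
    row.names = c("Kd (M)", "dH (kcal/mol)", "N (sites)",
                  "dG (kcal/mol)", "dS (cal/mol/K)"))
  structure(list(coefficients = tab, chi2 = object$chi2,
                 c_value = object$c_value, fit = object),
            class = "summary.itc_fit")
}

#' @export
print.summary.itc_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameter table:\n")
  print(format(x$coefficients, digits = 4))
  invisible(x)
}

#' @export
coef.itc_fit <- function(object, ...) {
  c(K = object$K, dH = object$dH, N = object$n_sites)
}

#' @export
residuals.itc_fit <- function(object, ...) object$residuals

#' Predicted injection heats from a fitted one-site model
#' @param object an `itc_fit`.
#' @param schedule optional alternative [injection_schedule()]; defaults to
#'   the fitted experiment's schedule.
#' @param ... unused.
#' @return per-injection heats (microcalories).
#' @export
predict.itc_fit <- function(object, schedule = NULL, ...) {
  if (is.null(schedule)) schedule <- object$experiment$schedule
  one_site_heats(object$K, object$dH, object$n_sites, schedule)
}

#' Simulate replicate experiments from a fitted one-site model
#' @param object an `itc_fit`.
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param noise_sd Gaussian noise per injection (microcalories); defaults
#'   to the residual standard deviation of the fit.
#' @param ... unused.
#' @return list of [itc_experiment()] objects.
#' @export
simulate.itc_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = NULL, ...) {
  if (is.null(noise_sd)) noise_sd <- stats::sd(object$residuals)
  s <- object$experiment$schedule
  with_seed(seed, lapply(seq_len(nsim), function(i)
    itc_experiment(s, one_site_heats(object$K, object$dH, object$n_sites, s) +
                     stats::rnorm(s$n_injections, 0, noise_sd))))
}

#' Plot a one-site fit as a Wiseman isotherm
#'
#' Normalised heats (kcal per mole of injectant) against the molar ratio,
#' with the fitted curve overlaid.
#'
#' @param x an `itc_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.itc_fit <- function(x, ...) {
  s <- x$experiment$schedule
  ratio <- molar_ratio(x$experiment)[x$injections]
  per_mol <- function(h) h * 1e-6 /
    (s$injection_volume[x$injections] * s$syringe_conc) / 1000
  obs <- x$experiment$heats[x$injections]
  if (!is.null(x$experiment$dilution_heats))
    obs <- obs - x$experiment$dilution_heats[x$injections]
  graphics::plot(ratio, per_mol(obs), xlab = "molar ratio [titrant]/[cell]",
                 ylab = "kcal per mole of injectant", pch = 16, ...)
  graphics::lines(ratio, per_mol(x$fitted_heats), col = "red")
  invisible(x)
}

#' Affinity fold-change between two binding fits
#'
#' Ratio of the weaker to the tighter dissociation constant, e.g. to express
#' the affinity gain conferred by N6-methylation of the bound RNA. Relative
#' uncertainties of the two Kd values are propagated in quadrature.
#'
#' @param fit_weak `itc_fit` (or bare Kd in molar) of the weaker binder.
#' @param fit_tight `itc_fit` (or bare Kd in molar) of the tighter binder.
#' @return object of class `fold_change` with elements `ratio`, `se`,
#'   `kd_weak`, `kd_tight`.
#' @export
fold_change <- function(fit_weak, fit_tight) {
  grab <- function(f) {
    if (inherits(f, "itc_fit")) c(f$Kd, f$se[["Kd"]])
    else c(as.numeric(f), 0)
  }
  w <- grab(fit_weak); t <- grab(fit_tight)
  if (!is.finite(w[1]) || !is.finite(t[1]) || w[1] <= 0 || t[1] <= 0)
    stop("fold_change: dissociation constants must be positive")
  ratio <- w[1] / t[1]
  rel <- sqrt((w[2] / w[1])^2 + (t[2] / t[1])^2)
  structure(list(ratio = ratio, se = ratio * rel,
                 kd_weak = w[1], kd_tight = t[1]),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("Affinity fold-change: %.3g (Kd %.3g M -> %.3g M)\n",
              x$ratio, x$kd_weak, x$kd_tight))
  if (is.finite(x$se) && x$se > 0)
    cat(sprintf("  propagated se: %.2g\n", x$se))
  invisible(x)
}
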