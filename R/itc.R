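## One-site isothermal titration calorimetry: forward simulation under the
## overfilled-cell displacement model used by MicroCal-style instruments,
## and nonlinear least-squares recovery of (n, Kd, dH) from per-injection
## heats, plus derived thermodynamics.

#' Titration protocol (instrument geometry)
#'
#' Defaults reproduce the study geometry: 680 µM ligand titrated from the
#' syringe into 350 µl of 68 µM macromolecule as 38 x 1 µl injections at
#' 25 °C.
#'
#' @param cell_volume active cell volume, µl.
#' @param cell_conc macromolecule concentration in the cell, µM.
#' @param syringe_conc ligand concentration in the syringe, µM.
#' @param injection_volumes per-injection volumes, µl (>= 2 injections).
#' @param temperature experiment temperature, K.
#' @return Object of class `titration_protocol`.
#' @export
titration_protocol <- function(cell_volume = 350, cell_conc = 68,
                               syringe_conc = 680,
                               injection_volumes = rep(1, 38),
                               temperature = 298.15) {
  check_scalar(cell_volume, "cell_volume")
  check_scalar(cell_conc, "cell_conc")
  check_scalar(syringe_conc, "syringe_conc")
  check_scalar(temperature, "temperature")
  if (length(injection_volumes) < 2L || any(injection_volumes <= 0))
    stop_invalid("need >= 2 injections, all volumes > 0")
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes = as.numeric(injection_volumes),
                 temperature = temperature),
            class = "titration_protocol")
}

#' One-site binding parameters
#'
#' @param n_sites binding stoichiometry (sites per macromolecule, > 0).
#' @param kd dissociation constant, M (> 0).
#' @param dh binding enthalpy, kcal per mol of ligand bound (non-zero for
#'   an identifiable fit).
#' @return Object of class `one_site_params`.
#' @export
one_site_params <- function(n_sites, kd, dh) {
  check_scalar(n_sites, "n_sites")
  check_scalar(kd, "kd")
  if (!is.numeric(dh) || length(dh) != 1L || !is.finite(dh))
    stop_invalid("dh must be a finite numeric scalar")
  structure(list(n_sites = n_sites, kd = kd, dh = dh),
            class = "one_site_params")
}

#' @export
print.one_site_params <- function(x, ...) {
  cat(sprintf("One-site parameters: n = %.3f, Kd = %.3g M (%.2f µM), dH = %.2f kcal/mol\n",
              x$n_sites, x$kd, x$kd * 1e6, x$dh))
  invisible(x)
}

## per-injection model heats (kcal) under the displacement dilution model:
## after cumulative injected volume dVtot, the effective cell concentrations
## are  Mt = M0 (1 - dVtot/2V0)/(1 + dVtot/2V0),  Xt = X0 (dVtot/V0)/(1 +
## dVtot/2V0); the total heat content of the cell is
##   Q = n Mt dH V0 / 2 * [1 + X/(nM) + Kd/(nM) - sqrt((1+X/(nM)+Kd/(nM))^2
##        - 4X/(nM))]
## and the i-th injection heat is dQ_i = Q_i - Q_{i-1} + (dV_i/V0)(Q_i +
## Q_{i-1})/2, correcting for the liquid displaced from the overfilled cell.
itc_model_heats <- function(n, kd, dh, protocol) {
  V0 <- protocol$cell_volume * 1e-6          # L
  dV <- protocol$injection_volumes * 1e-6    # L
  M0 <- protocol$cell_conc * 1e-6            # M
  X0 <- protocol$syringe_conc * 1e-6         # M
  cum <- cumsum(dV)
  Mt <- M0 * (1 - cum / (2 * V0)) / (1 + cum / (2 * V0))
  Xt <- X0 * (cum / V0) / (1 + cum / (2 * V0))
  r <- Xt / (n * Mt)
  k <- kd / (n * Mt)
  Q <- n * Mt * dh * V0 / 2 *
    (1 + r + k - sqrt(pmax((1 + r + k)^2 - 4 * r, 0)))
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev + (dV / V0) * (Q + Qprev) / 2
  list(dq = dQ, molar_ratio = Xt / Mt,
       moles_injected = X0 * dV)
}

#' Simulate a one-site ITC titration
#'
#' Generates per-injection heats for a given geometry and thermodynamic
#' truth under the overfilled-cell displacement model (see the package
#' vignette for the formulas). With `noise_sd = 0` the output is
#' deterministic.
#'
#' @param protocol a [titration_protocol()].
#' @param truth a [one_site_params()].
#' @param noise_sd Gaussian noise on the raw injection heats, µcal.
#' @param seed optional integer seed for the noise.
#' @return Data frame of class `itc_heats`: `injection`, `volume_ul`,
#'   `molar_ratio` (cumulative ligand/macromolecule), `raw_q_ucal` and
#'   `q_per_mol` (kcal per mol of injectant).
#' @examples
#' heats <- simulate_titration(titration_protocol(),
#'                             one_site_params(1, 1.7e-6, -6.2))
#' head(heats)
#' @export
simulate_titration <- function(protocol, truth, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(protocol, "titration_protocol"),
            inherits(truth, "one_site_params"))
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  m <- itc_model_heats(truth$n_sites, truth$kd, truth$dh, protocol)
  raw_ucal <- m$dq * 1e9                    # kcal -> µcal
  if (noise_sd > 0)
    raw_ucal <- with_seed_or_current(seed,
      raw_ucal + rnorm(length(raw_ucal), sd = noise_sd))
  out <- data.frame(injection = seq_along(raw_ucal),
                    volume_ul = protocol$injection_volumes,
                    molar_ratio = m$molar_ratio,
                    raw_q_ucal = raw_ucal,
                    q_per_mol = raw_ucal * 1e-9 / m$moles_injected)
  class(out) <- c("itc_heats", "data.frame")
  out
}

#' Wiseman c-value of a protocol/parameter combination
#'
#' `c = n * [macromolecule] / Kd`; isotherms with c between roughly 1 and
#' 1000 are reliably fittable.
#'
#' @param protocol a [titration_protocol()].
#' @param params a [one_site_params()].
#' @return The dimensionless c-value.
#' @export
wiseman_c <- function(protocol, params) {
  params$n_sites * protocol$cell_conc * 1e-6 / params$kd
}

#' Fit the one-site binding model to injection heats
#'
#' Levenberg-Marquardt least squares on the per-mol injection heats, with
#' parameters (n, log Kd, dH); log Kd keeps the dissociation constant
#' positive and well conditioned.
#'
#' @param heats an `itc_heats` data frame (from [simulate_titration()] or
#'   [read_itc_csv()]).
#' @param protocol the [titration_protocol()] that produced the heats.
#' @param init optional [one_site_params()] starting values; a heuristic
#'   start is derived from the isotherm when absent.
#' @param discard_first drop the first injection before fitting (a common
#'   instrument practice); default keeps it.
#' @return Object of class `one_site_fit`: `params` (a
#'   [one_site_params()]), `se` (asymptotic standard errors for n_sites,
#'   kd, dh), `covariance` (on the internal n/logKd/dH scale), `c_value`,
#'   `flat_warning`, `converged`, `residual_sd`.
#' @examples
#' heats <- simulate_titration(titration_protocol(),
#'                             one_site_params(1, 1.7e-6, -6.2))
#' fit_one_site(heats, titration_protocol())
#' @export
fit_one_site <- function(heats, protocol, init = NULL,
                         discard_first = FALSE) {
  stopifnot(inherits(heats, "data.frame"),
            inherits(protocol, "titration_protocol"))
  keep <- seq_len(nrow(heats))
  if (discard_first) keep <- keep[-1L]
  if (length(keep) < 3L)
    stop_invalid("need >= 3 informative injections")
  q_obs <- heats$q_per_mol[keep]
  if (is.null(init)) {
    dh0 <- q_obs[1L]
    if (dh0 == 0) dh0 <- max(abs(q_obs)) * sign(sum(q_obs) + 1e-30)
    half <- which(abs(q_obs) <= abs(dh0) / 2)
    n0 <- if (length(half)) heats$molar_ratio[keep][half[1L]] else 1
    n0 <- max(n0, 0.1)
    init <- one_site_params(n0, protocol$cell_conc * 1e-6 / 10, dh0)
  }
  model_fun <- function(n, lkd, dh) {
    m <- itc_model_heats(n, exp(lkd), dh, protocol)
    (m$dq / m$moles_injected)[keep]
  }
  fit <- minpack.lm::nlsLM(
    q_obs ~ model_fun(n, lkd, dh),
    start = list(n = init$n_sites, lkd = log(init$kd), dh = init$dh),
    lower = c(1e-3, log(1e-15), -1e4),
    upper = c(1e3, log(1), 1e4),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  est <- coef(fit)
  cv <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  kd_hat <- exp(est[["lkd"]])
  se <- sqrt(pmax(diag(cv), 0))
  params <- one_site_params(est[["n"]], kd_hat, est[["dh"]])
  c_value <- wiseman_c(protocol, params)
  structure(list(params = params,
                 se = c(n_sites = unname(se[1L]),
                        kd = kd_hat * unname(se[2L]),
                        dh = unname(se[3L])),
                 covariance = cv,
                 c_value = c_value,
                 flat_warning = c_value < 0.1 || c_value > 1e4,
                 converged = fit$convInfo$isConv,
                 residual_sd = sd(stats::residuals(fit))),
            class = "one_site_fit")
}

#' @export
print.one_site_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("One-site fit: n = %.3f (±%.3g), Kd = %.3g M (±%.2g), dH = %.3f kcal/mol (±%.2g)\n",
              p$n_sites, x$se[["n_sites"]], p$kd, x$se[["kd"]],
              p$dh, x$se[["dh"]]))
  cat(sprintf("  Wiseman c = %.3g%s\n", x$c_value,
              if (x$flat_warning) "  [warning: isotherm too flat/steep for a reliable fit]" else ""))
  invisible(x)
}

#' Derived binding thermodynamics
#'
#' \eqn{\Delta G = RT \ln(K_d / c^\circ)} with \eqn{c^\circ = 1} M, and
#' \eqn{\Delta S = (\Delta H - \Delta G)/T}.
#'
#' @param params a [one_site_params()].
#' @param t temperature, K.
#' @return Object of class `thermo_derived`: `dg` (kcal/mol), `ds`
#'   (cal/(mol K)), `temperature` (K).
#' @examples
#' derived_thermo(one_site_params(1, 1.7e-6, -6.2))
#' @export
derived_thermo <- function(params, t = 298.15) {
  stopifnot(inherits(params, "one_site_params"))
  check_scalar(t, "t")
  dg <- .R_KCAL * t * log(params$kd)
  ds <- (params$dh - dg) / t * 1000
  structure(list(dg = dg, ds = ds, temperature = t),
            class = "thermo_derived")
}

#' @export
print.thermo_derived <- function(x, ...) {
  cat(sprintf("dG = %.2f kcal/mol, dS = %.2f cal/(mol K) at %.2f K\n",
              x$dg, x$ds, x$temperature))
  invisible(x)
}

#' Write injection heats as CSV
#' @param heats an `itc_heats` data frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_itc_csv <- function(heats, file) {
  write.csv(as.data.frame(heats), file, row.names = FALSE)
  invisible(file)
}

#' Read injection heats from CSV
#' @param file CSV with columns `injection`, `volume_ul`, `molar_ratio`,
#'   `raw_q_ucal`, `q_per_mol`.
#' @return An `itc_heats` data frame.
#' @export
read_itc_csv <- function(file) {
  out <- read.csv(file)
  need <- c("injection", "volume_ul", "molar_ratio", "raw_q_ucal",
            "q_per_mol")
  if (!all(need %in% names(out)))
    stop_invalid("missing columns: ", paste(setdiff(need, names(out)),
                                            collapse = ", "))
  class(out) <- c("itc_heats", "data.frame")
  out
}
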