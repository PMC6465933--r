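## Random-chain scaling laws: closed-form reference dimensions for an
## unfolded polypeptide of N residues, used as the "theoretical" column
## against measured SAXS/QELS values.

#' Polymer scaling models for unfolded protein chains
#'
#' Returns one of the two built-in parameterizations of the power law
#' \eqn{R_g = R_0 N^\nu}: the excluded-volume statistics of chemically
#' denatured proteins (\eqn{R_0 = 1.98} Å, \eqn{\nu = 0.602}) or of
#' intrinsically disordered proteins under native conditions
#' (\eqn{R_0 = 2.54} Å, \eqn{\nu = 0.522}).
#'
#' @param name `"idp"` or `"denatured"`.
#' @return An object of class `scaling_model` with fields `name`, `r0`
#'   (Å) and `nu` (dimensionless).
#' @examples
#' scaling_model("idp")
#' @export
scaling_model <- function(name = c("idp", "denatured")) {
  name <- match.arg(name)
  pars <- switch(name,
                 idp       = list(r0 = 2.54, nu = 0.522),
                 denatured = list(r0 = 1.98, nu = 0.602))
  structure(list(name = name, r0 = pars$r0, nu = pars$nu),
            class = "scaling_model")
}

#' @export
print.scaling_model <- function(x, ...) {
  cat(sprintf("Random-chain scaling model '%s': Rg = %.2f * N^%.3f (Å)\n",
              x$name, x$r0, x$nu))
  invisible(x)
}

as_scaling_model <- function(model) {
  if (inherits(model, "scaling_model")) {
    if (model$r0 <= 0 || model$nu <= 0.3 || model$nu >= 1.0)
      stop_invalid("scaling model out of range: need r0 > 0, 0.3 < nu < 1.0")
    return(model)
  }
  if (is.character(model) && length(model) == 1L) return(scaling_model(model))
  stop_invalid("'model' must be a scaling_model or one of \"idp\", \"denatured\"")
}

check_n_residues <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) ||
      n < 1 || n != round(n))
    stop_invalid("n_residues must be a positive integer (got ",
                 deparse(substitute(n)), " = ", format(n), ")")
  as.numeric(n)
}

#' Predicted radius of gyration of a random chain
#'
#' Evaluates \eqn{R_g = R_0 N^\nu} for a chain of `n` residues under the
#' chosen scaling model. All internal lengths are in Å; use
#' [angstrom_to_nm()] for report-style nm values.
#'
#' @param n number of residues (positive integer).
#' @param model a [scaling_model()] object or its name (default `"idp"`).
#' @return Predicted Rg in Å.
#' @examples
#' predict_rg(348, "idp")        # ~53.9 A, i.e. 5.39 nm
#' predict_rg(348, "denatured")
#' @export
predict_rg <- function(n, model = "idp") {
  n <- check_n_residues(n)
  model <- as_scaling_model(model)
  model$r0 * n^model$nu
}

#' Predicted root-mean-square end-to-end distance of a random chain
#'
#' Evaluates \eqn{\sqrt{\langle L^2\rangle} = \sqrt{L_0 N}} with
#' \eqn{L_0 = 81.8} Å. Used as the theoretical proxy for the maximum
#' dimension (Dmax) of an unfolded chain.
#'
#' @param n number of residues (positive integer).
#' @return RMS end-to-end distance in Å.
#' @examples
#' predict_end_to_end(348)   # ~168.7 A = 16.9 nm
#' predict_end_to_end(1383)  # > 300 A: a full-length chain can span > 30 nm
#' @export
predict_end_to_end <- function(n) {
  n <- check_n_residues(n)
  sqrt(81.8 * n)
}

#' Combined theoretical size prediction
#'
#' @param n number of residues.
#' @param model scaling model for the Rg law (see [scaling_model()]).
#' @param note free-text provenance of the residue count.
#' @return Object of class `theory_prediction` with `rg` and
#'   `end_to_end` (both Å), `model_used` and `n_residues`.
#' @export
predict_chain_dimensions <- function(n, model = "idp", note = "") {
  model <- as_scaling_model(model)
  out <- list(rg = predict_rg(n, model),
              end_to_end = predict_end_to_end(n),
              model_used = model$name,
              n_residues = as.integer(n),
              note = note)
  structure(out, class = "theory_prediction")
}

#' @export
print.theory_prediction <- function(x, ...) {
  cat(sprintf("Theoretical chain dimensions (N = %d, model '%s'):\n",
              x$n_residues, x$model_used))
  cat(sprintf("  Rg          = %6.1f Å = %.2f nm\n",
              x$rg, angstrom_to_nm(x$rg)))
  cat(sprintf("  sqrt(<L^2>) = %6.1f Å = %.1f nm\n",
              x$end_to_end, angstrom_to_nm(x$end_to_end)))
  invisible(x)
}

#' Compactness ratio Rg/Rh
#'
#' The ratio of radius of gyration to hydrodynamic radius reports on chain
#' compaction: a uniform sphere gives \eqn{\sqrt{3/5} \approx 0.775}, while
#' expanded coils exceed 1. Both arguments must share units.
#'
#' @param rg radius of gyration.
#' @param rh hydrodynamic radius (> 0).
#' @return Dimensionless ratio rg/rh.
#' @examples
#' compactness_ratio(sqrt(3 / 5) * 30, 30)  # sphere: 0.7746
#' compactness_ratio(5.68, 4.79)            # extended IDP: > 1
#' @export
compactness_ratio <- function(rg, rh) {
  check_scalar(rg, "rg")
  if (!is.numeric(rh) || length(rh) != 1L || !is.finite(rh) || rh <= 0)
    stop_invalid("rh must be > 0")
  rg / rh
}

#' Convert Å to nm
#' @param x length in Å.
#' @return Length in nm.
#' @export
angstrom_to_nm <- function(x) x / 10
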