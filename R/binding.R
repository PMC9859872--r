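#' Antibody binding parameters
#'
#' Kinetic constants of the detection antibody together with the molar mass
#' of the analyte, used to convert mass concentrations (ug/l) into molar
#' concentrations and to evaluate the competitive-inhibition isotherm.
#'
#' The defaults are the kinetics of an anti-amitriptyline antibody
#' (ka = 2.4e4 / M / s, kd = 1.3e-3 / s) and the molar mass of amitriptyline
#' (277.4 g/mol). The equilibrium dissociation constant is always `kd / ka`.
#'
#' @param ka association rate constant, 1/(M s); must be > 0.
#' @param kd dissociation rate constant, 1/s; must be > 0.
#' @param analyte_molar_mass molar mass of the analyte, g/mol; must be > 0.
#'
#' @return An object of class `binding_params` with fields `ka`, `kd`,
#'   `Kd` (= kd/ka, molar) and `analyte_molar_mass`.
#' @examples
#' bp <- binding_params()
#' bp$Kd                      # ~5.42e-8 M
#' free_fraction(0, bp)       # 1: no inhibition without analyte
#' @export
binding_params <- function(ka = 2.4e4, kd = 1.3e-3, analyte_molar_mass = 277.4) {
  if (!is.numeric(ka) || length(ka) != 1L || !is.finite(ka) || ka <= 0)
    stop("'ka' must be a single positive number")
  if (!is.numeric(kd) || length(kd) != 1L || !is.finite(kd) || kd <= 0)
    stop("'kd' must be a single positive number")
  if (!is.numeric(analyte_molar_mass) || length(analyte_molar_mass) != 1L ||
      !is.finite(analyte_molar_mass) || analyte_molar_mass <= 0)
    stop("'analyte_molar_mass' must be a single positive number")
  structure(
    list(ka = ka, kd = kd, Kd = kd / ka, analyte_molar_mass = analyte_molar_mass),
    class = "binding_params"
  )
}

#' @export
print.binding_params <- function(x, ...) {
  cat("Antibody binding parameters\n")
  cat(sprintf("  ka = %.3g 1/(M s), kd = %.3g 1/s, Kd = %.4g M\n", x$ka, x$kd, x$Kd))
  cat(sprintf("  analyte molar mass = %.1f g/mol (Kd = %.2f ug/l)\n",
              x$analyte_molar_mass, x$Kd * x$analyte_molar_mass * 1e6))
  invisible(x)
}

#' Free fraction of detection antibody in a competitive assay
#'
#' Fraction of detection-antibody binding sites not blocked by free analyte
#' at equilibrium, using the analyte-excess isotherm `Kd / (Kd + C)` with
#' `C` the molar analyte concentration. Only this free fraction can still
#' bind the immobilized antigen on the test line, so the test-line signal
#' of a binding-inhibition assay is proportional to it.
#'
#' @param concentration analyte mass concentration(s), ug/l; must be >= 0.
#' @param params a [binding_params()] object.
#'
#' @return Numeric vector of fractions in `[0, 1]`, monotone non-increasing
#'   in `concentration`.
#' @examples
#' bp <- binding_params()
#' free_fraction(c(0, 15, 1000), bp)
#' @export
free_fraction <- function(concentration, params = binding_params()) {
  stopifnot(inherits(params, "binding_params"))
  if (!is.numeric(concentration) || any(!is.finite(concentration)))
    stop("'concentration' must be finite numeric")
  if (any(concentration < 0))
    stop("'concentration' must be >= 0 (ug/l)")
  c_molar <- concentration * 1e-6 / params$analyte_molar_mass  # ug/l -> g/l -> mol/l
  params$Kd / (params$Kd + c_molar)
}
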