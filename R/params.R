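#' Electron-transfer model parameters
#'
#' Bundles every physical parameter of the Marcus-Kakitani-Mataga rate model
#' for one donor--acceptor system: the frequency prefactor and distance gate of
#' the adiabatic/nonadiabatic sigmoid, the dielectric constants and effective
#' spherical radii entering the solvent reorganization energy, the
#' donor--acceptor dielectric constant of the ion-pair Coulomb term, the donor
#' ionization potential and acceptor (excited isoalloxazine) electron
#' affinity, and the temperature.
#'
#' The defaults are illustrative placeholder values for a generic ultrafast
#' flavoprotein donor; they are not fitted to any particular protein. The
#' default critical distance `r0_nm = 1.0` places sub-nanometre donors near
#' the adiabatic plateau of the gate, the regime in which logarithmic rates
#' show a parabolic dependence on distance.
#'
#' @param nu0_per_ps Frequency prefactor \eqn{\nu_0} (ps^-1), > 0.
#' @param beta_per_nm Distance decay coefficient \eqn{\beta} (nm^-1), > 0.
#' @param r0_nm Critical adiabatic/nonadiabatic distance \eqn{R_0} (nm), > 0.
#' @param eps_da Static dielectric constant between donor and acceptor
#'   (dimensionless), >= 1.
#' @param eps_static Bulk static dielectric constant \eqn{\epsilon_0}
#'   (dimensionless).
#' @param eps_optical Optical dielectric constant \eqn{\epsilon_\infty}
#'   (dimensionless), must be < `eps_static`.
#' @param a_donor_nm,a_acceptor_nm Effective spherical radii of donor and
#'   acceptor (nm), > 0.
#' @param temperature_k Temperature (K), > 0.
#' @param e_ip_ev Donor ionization potential (eV).
#' @param e_ea_ev Acceptor electron affinity (eV); shifts with the monitored
#'   emission wavelength through the flavin environment.
#' @return An object of class `et_params`: a validated named list with the
#'   fields above.
#' @examples
#' p <- et_params()
#' reorganization_energy(0.72, p)
#' @seealso [read_et_params()], [et_rate()], [free_energy_gap()]
#' @export
et_params <- function(nu0_per_ps = 1000,
                      beta_per_nm = 14,
                      r0_nm = 1.0,
                      eps_da = 2,
                      eps_static = 5,
                      eps_optical = 2,
                      a_donor_nm = 0.25,
                      a_acceptor_nm = 0.25,
                      temperature_k = 298,
                      e_ip_ev = 7.2,
                      e_ea_ev = 6.0) {
  p <- list(
    nu0_per_ps = nu0_per_ps, beta_per_nm = beta_per_nm, r0_nm = r0_nm,
    eps_da = eps_da, eps_static = eps_static, eps_optical = eps_optical,
    a_donor_nm = a_donor_nm, a_acceptor_nm = a_acceptor_nm,
    temperature_k = temperature_k, e_ip_ev = e_ip_ev, e_ea_ev = e_ea_ev
  )
  validate_et_params(p)
  structure(p, class = "et_params")
}

validate_et_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("nu0_per_ps", "beta_per_nm", "r0_nm", "eps_da", "eps_static",
              "eps_optical", "a_donor_nm", "a_acceptor_nm", "temperature_k",
              "e_ip_ev", "e_ea_ev")) {
    if (is.null(p[[f]]) || !num1(p[[f]])) {
      abort(paste0("`", f, "` must be a single finite number."))
    }
  }
  pos <- c("nu0_per_ps", "beta_per_nm", "r0_nm", "a_donor_nm",
           "a_acceptor_nm", "temperature_k")
  for (f in pos) {
    if (p[[f]] <= 0) abort(paste0("`", f, "` must be > 0."))
  }
  if (p$eps_da < 1) abort("`eps_da` must be >= 1.")
  if (p$eps_optical >= p$eps_static) {
    abort("`eps_optical` must be smaller than `eps_static`.")
  }
  invisible(p)
}

#' @export
print.et_params <- function(x, ...) {
  cat("<et_params>\n")
  cat(sprintf("  gate:  nu0 = %g ps^-1, beta = %g nm^-1, R0 = %g nm\n",
              x$nu0_per_ps, x$beta_per_nm, x$r0_nm))
  cat(sprintf("  dielectrics: eps_DA = %g, eps_static = %g, eps_optical = %g\n",
              x$eps_da, x$eps_static, x$eps_optical))
  cat(sprintf("  radii: a_D = %g nm, a_A = %g nm;  T = %g K\n",
              x$a_donor_nm, x$a_acceptor_nm, x$temperature_k))
  cat(sprintf("  electronic gap: E_IP = %g eV, E_EA = %g eV\n",
              x$e_ip_ev, x$e_ea_ev))
  invisible(x)
}

#' Read and write model parameters as JSON
#'
#' The configuration file is a flat JSON object whose keys carry explicit
#' units (`nu0_per_ps`, `beta_per_nm`, `r0_nm`, `eps_da`, `eps_static`,
#' `eps_optical`, `a_donor_nm`, `a_acceptor_nm`, `temperature_k`, `e_ip_ev`,
#' `e_ea_ev`). Unknown keys are rejected so a typo cannot silently fall back
#' to a default.
#'
#' @param path File path of the JSON configuration.
#' @param params An [et_params()] object (for writing).
#' @return `read_et_params()` returns an [et_params()] object;
#'   `write_et_params()` returns `path` invisibly.
#' @export
read_et_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(et_params))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("Unknown parameter key(s) in config: ",
                 paste(extra, collapse = ", ")))
  }
  do.call(et_params, raw)
}

#' @rdname read_et_params
#' @export
write_et_params <- function(params, path) {
  stopifnot(inherits(params, "et_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
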