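# Physical constants, eV / nm / ps unit system. Conversions happen only at
# I/O boundaries; everything internal is eV, nm, ps, ps^-1.

#' Physical constants used throughout the package
#'
#' Returns the constants of the eV/nm/ps unit system used by all rate and
#' energy functions: the Coulomb constant \eqn{e^2/(4\pi\epsilon_0)} in
#' eV nm, the Boltzmann constant in eV/K, and the default temperature in K.
#'
#' @return A named list with elements `coulomb_ev_nm` (1.439964 eV nm),
#'   `k_boltzmann_ev_per_k` (8.617333e-5 eV/K) and `temperature_k` (298 K).
#' @examples
#' et_constants()$coulomb_ev_nm
#' @export
et_constants <- function() {
  list(
    coulomb_ev_nm = 1.439964,
    k_boltzmann_ev_per_k = 8.617333e-5,
    temperature_k = 298
  )
}

.C_E <- 1.439964      # e^2/(4 pi eps_vac), eV nm
.K_B <- 8.617333e-5   # eV / K
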