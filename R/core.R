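# Marcus-Kakitani-Mataga rate model: the rate for one snapshot is
#   k = nu0 / (1 + exp[beta (Rc - R0)]) * exp[-(dG0 + lambda)^2 / (4 lambda kB T)]
# with the solvent reorganization energy lambda from the two-sphere
# dielectric continuum expression and dG0 decomposed into the electronic gap,
# the donor-cation/acceptor-anion Coulomb attraction and the point-charge
# electrostatics of the protein environment.

kbt_ev <- function(params) .K_B * params$temperature_k

#' Solvent reorganization energy of the two-sphere continuum model
#'
#' \deqn{\lambda(R_c) = C_e \left(\frac{1}{2a_D} + \frac{1}{2a_A} -
#'   \frac{1}{R_c}\right)\left(\frac{1}{\epsilon_\infty} -
#'   \frac{1}{\epsilon_0}\right)}
#' with \eqn{C_e} the Coulomb constant in eV nm. \eqn{\lambda} increases
#' monotonically with the donor--acceptor distance and vanishes when the
#' Pekar factor is zero.
#'
#' @param rc Donor--acceptor distance(s) in nm, > 0.
#' @param params An [et_params()] object.
#' @return Reorganization energy in eV (vectorized over `rc`).
#' @examples
#' reorganization_energy(0.72, et_params())
#' @export
reorganization_energy <- function(rc, params) {
  stopifnot(inherits(params, "et_params"))
  if (any(!is.finite(rc)) || any(rc <= 0)) {
    abort("`rc` must be finite and > 0 (nm).")
  }
  pekar <- 1 / params$eps_optical - 1 / params$eps_static
  .C_E * (1 / (2 * params$a_donor_nm) + 1 / (2 * params$a_acceptor_nm) -
            1 / rc) * pekar
}

#' Distance at which the reorganization energy takes a given value
#'
#' Inverts the two-sphere continuum expression; handy for constructing
#' synthetic datasets with a prescribed \eqn{\lambda}.
#'
#' @param lambda_ev Target reorganization energy (eV), > 0.
#' @param params An [et_params()] object.
#' @return Distance in nm. Errors if no positive distance attains the target.
#' @export
rc_for_lambda <- function(lambda_ev, params) {
  stopifnot(inherits(params, "et_params"))
  pekar <- 1 / params$eps_optical - 1 / params$eps_static
  s <- 1 / (2 * params$a_donor_nm) + 1 / (2 * params$a_acceptor_nm)
  inv_rc <- s - lambda_ev / (.C_E * pekar)
  if (any(inv_rc <= 0)) {
    abort("Requested `lambda_ev` is not attainable at any finite distance.")
  }
  1 / inv_rc
}

#' Coulomb attraction energy of the photo-generated ion pair
#'
#' Magnitude \eqn{C_e / (\epsilon_0^{DA} R_c)} of the electrostatic
#' attraction between the donor cation and the acceptor anion. It enters the
#' free-energy gap with a negative sign (ion-pair stabilization); see
#' [free_energy_gap()].
#'
#' @inheritParams reorganization_energy
#' @param eps_da Static dielectric constant between donor and acceptor, >= 1.
#' @return Energy magnitude in eV (vectorized over `rc`).
#' @export
coulomb_pair_energy <- function(rc, eps_da) {
  if (any(!is.finite(rc)) || any(rc <= 0)) {
    abort("`rc` must be finite and > 0 (nm).")
  }
  if (any(eps_da < 1)) abort("`eps_da` must be >= 1.")
  .C_E / (eps_da * rc)
}

#' Electrostatic energy between the ion pair and protein charges
#'
#' Sums, over every charged site \eqn{j} with charge \eqn{q_j} (in units of
#' the elementary charge), the interaction with the acceptor anion (charge
#' \eqn{-1}) and the donor cation (charge \eqn{+1}):
#' \deqn{E_{net} = \sum_j C_e q_j \left[\frac{-1}{\epsilon |r_j - r_A|} +
#'   \frac{+1}{\epsilon |r_j - r_D|}\right].}
#'
#' @param charges A data frame with columns `x`, `y`, `z` (nm) and `charge`
#'   (elementary charges); an optional `label` column is ignored. Zero rows
#'   give zero energy.
#' @param donor_center,acceptor_center Numeric length-3 positions (nm).
#' @param eps_net Dielectric constant screening the ion-pair/protein-charge
#'   interaction, >= 1.
#' @return Energy in eV.
#' @export
net_electrostatic_energy <- function(charges, donor_center, acceptor_center,
                                     eps_net) {
  stopifnot(length(donor_center) == 3, length(acceptor_center) == 3)
  if (eps_net < 1) abort("`eps_net` must be >= 1.")
  if (is.null(charges) || nrow(charges) == 0) return(0)
  req <- c("x", "y", "z", "charge")
  if (!all(req %in% names(charges))) {
    abort("`charges` needs columns x, y, z, charge.")
  }
  pos <- as.matrix(charges[, c("x", "y", "z")])
  d_a <- sqrt(rowSums(sweep(pos, 2, acceptor_center)^2))
  d_d <- sqrt(rowSums(sweep(pos, 2, donor_center)^2))
  if (any(d_a == 0) || any(d_d == 0)) {
    abort("A charge site coincides with the donor or acceptor center.")
  }
  sum(.C_E * charges$charge * (-1 / (eps_net * d_a) + 1 / (eps_net * d_d)))
}

#' Standard free-energy gap of the electron-transfer reaction
#'
#' For the reaction donor + excited acceptor -> donor cation + acceptor
#' anion, the gap between photo-products and reactants is
#' \deqn{\Delta G^0 = (E_{IP} - E_{EA}) - \frac{C_e}{\epsilon_0^{DA} R_c} +
#'   E_{net},}
#' the electronic gap stabilized by the ion-pair Coulomb attraction and
#' shifted by the protein point-charge term. Favourable transfer has
#' \eqn{\Delta G^0 < 0}; the empirical laws are plotted against
#' \eqn{-\Delta G^0}.
#'
#' @inheritParams reorganization_energy
#' @param charges Optional data frame of protein charges as in
#'   [net_electrostatic_energy()]; `NULL` means no environment charges.
#' @param donor_center,acceptor_center Optional length-3 positions (nm);
#'   required only when `charges` is non-empty.
#' @return \eqn{\Delta G^0} in eV.
#' @examples
#' free_energy_gap(0.72, et_params())
#' @export
free_energy_gap <- function(rc, params, charges = NULL,
                            donor_center = NULL, acceptor_center = NULL) {
  stopifnot(inherits(params, "et_params"))
  e_net <- 0
  if (!is.null(charges) && nrow(charges) > 0) {
    if (is.null(donor_center) || is.null(acceptor_center)) {
      abort("Donor and acceptor centers are required with explicit charges.")
    }
    e_net <- net_electrostatic_energy(charges, donor_center, acceptor_center,
                                      eps_net = params$eps_da)
  }
  (params$e_ip_ev - params$e_ea_ev) -
    coulomb_pair_energy(rc, params$eps_da) + e_net
}

#' Marcus-Kakitani-Mataga electron-transfer rate
#'
#' \deqn{k = \frac{\nu_0}{1 + \exp[\beta (R_c - R_0)]}
#'   \exp\left[-\frac{(\Delta G^0 + \lambda)^2}{4 \lambda k_B T}\right]}
#' in ps^-1. The sigmoidal prefactor gates between the adiabatic plateau
#' (\eqn{R_c \ll R_0}, rate \eqn{\approx \nu_0} times the Franck--Condon
#' factor) and the nonadiabatic exponential distance decay
#' (\eqn{R_c \gg R_0}, the classical Dutton regime with slope
#' \eqn{-\beta} in \eqn{\ln k} vs \eqn{R_c}).
#'
#' @inheritParams reorganization_energy
#' @param dg0 Standard free-energy gap(s) \eqn{\Delta G^0} (eV).
#' @param lam Reorganization energy(ies) \eqn{\lambda} (eV), > 0.
#' @return Rate in ps^-1 (`et_rate`) or its natural logarithm (`ln_et_rate`);
#'   vectorized over `rc`, `dg0`, `lam`.
#' @examples
#' p <- et_params()
#' et_rate(0.72, dg0 = -1.1, lam = reorganization_energy(0.72, p), params = p)
#' @export
et_rate <- function(rc, dg0, lam, params) {
  exp(ln_et_rate(rc, dg0, lam, params))
}

#' @rdname et_rate
#' @details `ln_et_rate()` evaluates the logarithm directly (via `log1p`) so
#'   deep-inverted-region rates underflow gracefully. For fixed `rc` it is an
#'   exact downward parabola in \eqn{-\Delta G^0} with vertex at
#'   \eqn{-\Delta G^0 = \lambda} and curvature \eqn{-1/(4\lambda k_B T)}.
#' @export
ln_et_rate <- function(rc, dg0, lam, params) {
  stopifnot(inherits(params, "et_params"))
  if (any(!is.finite(lam)) || any(lam <= 0)) {
    abort("`lam` must be finite and > 0 (eV).")
  }
  if (any(!is.finite(rc)) || any(rc <= 0)) {
    abort("`rc` must be finite and > 0 (nm).")
  }
  log(params$nu0_per_ps) -
    log1p(exp(params$beta_per_nm * (rc - params$r0_nm))) -
    (dg0 + lam)^2 / (4 * lam * kbt_ev(params))
}

#' Evaluate the rate model along a snapshot series
#'
#' Takes a per-snapshot table (one row per molecular-dynamics time point)
#' carrying at least `rc_nm` and `neg_sfeg_ev`, fills `lambda_ev` from the
#' continuum expression where absent, and computes `ln_rate`
#' (\eqn{\ln k}, k in ps^-1) for every row. A supplied `lambda_ev` column is
#' respected, so externally computed reorganization energies pass through
#' untouched. Row order and count are preserved.
#'
#' @param snapshots A data frame with columns `rc_nm`, `neg_sfeg_ev` and
#'   optionally `lambda_ev`; extra columns are kept.
#' @param params An [et_params()] object.
#' @return A tibble: the input with `lambda_ev` and `ln_rate` populated.
#' @examples
#' snaps <- tibble::tibble(time_ps = 0:2, rc_nm = c(0.7, 0.72, 0.74),
#'                         neg_sfeg_ev = c(1.1, 1.12, 1.09))
#' trajectory_rates(snaps, et_params())
#' @export
trajectory_rates <- function(snapshots, params) {
  stopifnot(inherits(params, "et_params"))
  snapshots <- as_tibble(snapshots)
  for (col in c("rc_nm", "neg_sfeg_ev")) {
    if (!col %in% names(snapshots)) {
      abort(paste0("`snapshots` is missing required column `", col, "`."))
    }
  }
  bad <- which(!is.finite(snapshots$rc_nm) | snapshots$rc_nm <= 0 |
                 !is.finite(snapshots$neg_sfeg_ev))
  if (length(bad) > 0) {
    abort(paste0("Invalid snapshot at row ", bad[1],
                 ": rc_nm must be > 0 and neg_sfeg_ev finite."))
  }
  if (!"lambda_ev" %in% names(snapshots) ||
      all(is.na(snapshots$lambda_ev))) {
    snapshots$lambda_ev <- reorganization_energy(snapshots$rc_nm, params)
  }
  if (any(!is.finite(snapshots$lambda_ev) | snapshots$lambda_ev <= 0)) {
    i <- which(!is.finite(snapshots$lambda_ev) | snapshots$lambda_ev <= 0)[1]
    abort(paste0("Non-positive reorganization energy at row ", i,
                 "; check radii and dielectric constants."))
  }
  snapshots$ln_rate <- ln_et_rate(snapshots$rc_nm, -snapshots$neg_sfeg_ev,
                                  snapshots$lambda_ev, params)
  snapshots
}
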