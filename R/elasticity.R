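#' Bending or torsional rigidity from a persistence length
#'
#' In the worm-like chain picture the persistence length is the rigidity in
#' thermal units: `lp = B / (kB T)`, so `B = lp * kB * T` (J nm).
#'
#' @param persistence_nm Persistence length, nm (> 0).
#' @param temperature_K Absolute temperature, K (>= 0).
#' @return Rigidity in J nm.
#' @export
#' @examples
#' rigidity_from_persistence(50, 300)  # 2.07e-19 J nm (bending, B-DNA)
#' rigidity_from_persistence(95, 300)  # 3.933e-19 J nm (torsion)
rigidity_from_persistence <- function(persistence_nm, temperature_K) {
  check_scalar_number(persistence_nm, "persistence_nm", positive = TRUE)
  check_scalar_number(temperature_K, "temperature_K", nonnegative = TRUE)
  persistence_nm * BOLTZMANN_J_PER_K * temperature_K
}

#' Landau coefficients from the elastic rigidities
#'
#' The quadratic Landau expansion of the free-energy density in the
#' two-component order parameter carries two coefficients tied to the
#' elastic rod constants: `k1 = 4 B` (bending) and `k1 + k2 = 4 C`
#' (torsion), hence `k2 = 4 C - 4 B`.
#'
#' @param B Bending rigidity (> 0), any consistent unit.
#' @param C Torsional rigidity (> 0), same unit as `B`.
#' @return A list with components `k1` and `k2`.
#' @export
#' @examples
#' landau_coefficients(2.07e-19, 3.933e-19)
landau_coefficients <- function(B, C) {
  check_scalar_number(B, "B", positive = TRUE)
  check_scalar_number(C, "C", positive = TRUE)
  list(k1 = 4 * B, k2 = 4 * C - 4 * B)
}

#' Helix rotation per base pair
#'
#' The equilibrium rotation angle between consecutive base pairs,
#' `omega0 = 2 pi / n_i` rad/bp (about 0.6 rad/bp for B-DNA with 10.5
#' bp/turn).
#'
#' @param bp_per_turn Base pairs per helical turn (> 0).
#' @return Rotation in radians per base pair.
#' @export
#' @examples
#' helix_rotation_per_bp(10.5)
helix_rotation_per_bp <- function(bp_per_turn) {
  check_scalar_number(bp_per_turn, "bp_per_turn", positive = TRUE)
  2 * pi / bp_per_turn
}

#' Elastic constants of B-DNA in SI and reduced units
#'
#' Collects everything the energy functionals need: persistence lengths,
#' temperature, SI rigidities `B_si = lp kB T` and `C_si = lt kB T` (J nm),
#' the reduced rigidities `B_red = B_si / (kB T)` and `C_red = C_si / (kB T)`
#' (numerically the persistence lengths; energies then come out in kB T per
#' unit arc length), and the Landau coefficients `k1 = 4 B`, `k2 = 4 C - 4 B`
#' in both unit systems.
#'
#' @param lp_nm Bending persistence length, nm (default 50, B-DNA).
#' @param lt_nm Torsional persistence length, nm (default 95).
#' @param temperature_K Absolute temperature, K (default 300).
#'
#' @return An object of class `elastic_constants`.
#' @export
#' @examples
#' ec <- elastic_constants()
#' ec$B_si  # 2.07e-19 J nm
#' ec$B_red # 50
elastic_constants <- function(lp_nm = 50, lt_nm = 95, temperature_K = 300) {
  check_scalar_number(lp_nm, "lp_nm", positive = TRUE)
  check_scalar_number(lt_nm, "lt_nm", positive = TRUE)
  check_scalar_number(temperature_K, "temperature_K", positive = TRUE)
  kB <- BOLTZMANN_J_PER_K
  B_si <- rigidity_from_persistence(lp_nm, temperature_K)
  C_si <- rigidity_from_persistence(lt_nm, temperature_K)
  k_si <- landau_coefficients(B_si, C_si)
  k_red <- landau_coefficients(lp_nm, lt_nm)
  structure(
    list(
      lp_nm = lp_nm,
      lt_nm = lt_nm,
      temperature_K = temperature_K,
      kB = kB,
      B_si = B_si,
      C_si = C_si,
      B_red = B_si / (kB * temperature_K),
      C_red = C_si / (kB * temperature_K),
      k1_si = k_si$k1,
      k2_si = k_si$k2,
      k1_red = k_red$k1,
      k2_red = k_red$k2
    ),
    class = "elastic_constants"
  )
}

#' @export
print.elastic_constants <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<elastic_constants> T = %g K\n",
      "  lp = %g nm -> B = %.4g J nm (B_red = %g)\n",
      "  lt = %g nm -> C = %.4g J nm (C_red = %g)\n"
    ),
    x$temperature_K, x$lp_nm, x$B_si, x$B_red, x$lt_nm, x$C_si, x$C_red
  ))
  invisible(x)
}

#' @method tidy elastic_constants
#' @export
tidy.elastic_constants <- function(x, ...) {
  tibble::tibble(
    lp_nm = x$lp_nm, lt_nm = x$lt_nm, temperature_K = x$temperature_K,
    kB = x$kB, B_si = x$B_si, C_si = x$C_si,
    B_red = x$B_red, C_red = x$C_red,
    k1_si = x$k1_si, k2_si = x$k2_si,
    k1_red = x$k1_red, k2_red = x$k2_red
  )
}

#' Convert a reduced energy to joules
#'
#' Reduced energies are in units of kB T; multiply by `kB * T` to return
#' to SI.
#'
#' @param energy_red Energy in kB T units.
#' @param constants An [elastic_constants()] object supplying kB and T.
#' @return Energy in joules.
#' @export
#' @examples
#' energy_to_si(1071, elastic_constants())
energy_to_si <- function(energy_red, constants = elastic_constants()) {
  stopifnot(inherits(constants, "elastic_constants"))
  energy_red * constants$kB * constants$temperature_K
}
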