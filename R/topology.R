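#' Geometry of a wrapped DNA segment
#'
#' Bundles the base-pair count and the standard B-DNA / nucleosome core
#' particle (NCP) geometry. The superhelix radius is derived as
#' `(ncp_diameter - dna_diameter) / 2`, i.e. the distance from the NCP
#' geometric centre to the DNA helix axis (4.5 nm for the defaults).
#'
#' @param n_bp Number of base pairs (> 0).
#' @param bp_per_turn Base pairs per double-helix turn; 10.5 for B-DNA.
#' @param rise_per_bp Axial rise per base pair, nm.
#' @param dna_diameter Diameter of the double helix, nm.
#' @param ncp_diameter Diameter of the nucleosome core particle, nm.
#' @param superhelix_pitch Pitch of the superhelical wrap, nm.
#'
#' @return An object of class `dna_geometry`: a list with the fields above
#'   plus `superhelix_radius` (nm) and `contour_length` (nm).
#' @export
#' @examples
#' geom <- dna_geometry(147)
#' geom$superhelix_radius # 4.5 nm
#' linking_number(geom)   # 14
dna_geometry <- function(n_bp,
                         bp_per_turn = 10.5,
                         rise_per_bp = 0.34,
                         dna_diameter = 2,
                         ncp_diameter = 11,
                         superhelix_pitch = 2.8) {
  check_scalar_number(n_bp, "n_bp", positive = TRUE)
  if (n_bp < 1) stop_invalid("`n_bp` must be at least 1")
  check_scalar_number(bp_per_turn, "bp_per_turn", positive = TRUE)
  check_scalar_number(rise_per_bp, "rise_per_bp", positive = TRUE)
  check_scalar_number(dna_diameter, "dna_diameter", positive = TRUE)
  check_scalar_number(ncp_diameter, "ncp_diameter", positive = TRUE)
  check_scalar_number(superhelix_pitch, "superhelix_pitch", positive = TRUE)
  if (ncp_diameter <= dna_diameter) {
    stop_invalid("`ncp_diameter` must exceed `dna_diameter`")
  }
  structure(
    list(
      n_bp = n_bp,
      bp_per_turn = bp_per_turn,
      rise_per_bp = rise_per_bp,
      dna_diameter = dna_diameter,
      ncp_diameter = ncp_diameter,
      superhelix_pitch = superhelix_pitch,
      superhelix_radius = (ncp_diameter - dna_diameter) / 2,
      contour_length = n_bp * rise_per_bp
    ),
    class = "dna_geometry"
  )
}

#' @export
print.dna_geometry <- function(x, ...) {
  cat(sprintf(
    "<dna_geometry> %g bp, %g bp/turn, superhelix radius %g nm\n",
    x$n_bp, x$bp_per_turn, x$superhelix_radius
  ))
  invisible(x)
}

#' Linking number of closed circular DNA
#'
#' For relaxed closed circular DNA the linking number is the number of
#' double-helix turns, `Lk = N / n_i`, with `N` base pairs and `n_i` base
#' pairs per turn. The value is kept exact (no rounding); use
#' [lk_integer()] when an integer linking number is required.
#'
#' @param x A [dna_geometry()] object, or a numeric base-pair count.
#' @param bp_per_turn Base pairs per helical turn; ignored when `x` is a
#'   `dna_geometry` (its own value is used).
#'
#' @return The linking number as a real number.
#' @export
#' @examples
#' linking_number(147)        # 14
#' linking_number(63)         # 6
#' linking_number(dna_geometry(168))
linking_number <- function(x, bp_per_turn = 10.5) {
  if (inherits(x, "dna_geometry")) {
    return(x$n_bp / x$bp_per_turn)
  }
  check_scalar_number(x, "n_bp", positive = TRUE)
  check_scalar_number(bp_per_turn, "bp_per_turn", positive = TRUE)
  x / bp_per_turn
}

#' Round a linking number to an exact integer
#'
#' Closed circular DNA has an integer linking number; the ratio
#' `n_bp / bp_per_turn` is only integral for commensurate lengths. This
#' accessor rounds to the nearest integer and errors when the residual
#' exceeds `tol`.
#'
#' @param lk Real linking number.
#' @param tol Maximum allowed distance from the nearest integer.
#' @return An integer-valued number.
#' @export
#' @examples
#' lk_integer(linking_number(147)) # 14
lk_integer <- function(lk, tol = 1e-9) {
  check_scalar_number(lk, "lk")
  rounded <- round(lk)
  if (abs(lk - rounded) > tol) {
    stop_invalid("linking number %.12g is not integral (residual %.3g > tol %.3g)",
                 lk, abs(lk - rounded), tol)
  }
  rounded
}

#' Writhe of a superhelical wrap
#'
#' Converts a number of superhelical turns and a handedness into a signed
#' writhe. Left-handed wrapping (the nucleosomal case) is negative: 1.75
#' left-handed turns give Wr = -1.75.
#'
#' @param turns Number of superhelical turns (>= 0).
#' @param handedness `"left"` or `"right"`.
#' @return Signed writhe.
#' @export
#' @examples
#' writhe_from_wrap(1.75, "left") # -1.75
writhe_from_wrap <- function(turns, handedness = c("left", "right")) {
  check_scalar_number(turns, "turns", nonnegative = TRUE)
  handedness <- match.arg(handedness)
  if (handedness == "left") -turns else turns
}

#' Twist from White's formula
#'
#' White's formula for closed circular DNA is `Lk = Wr + Tw`; given the
#' linking number and writhe the twist is `Tw = Lk - Wr`.
#'
#' @param lk Linking number.
#' @param wr Writhe.
#' @return The twist.
#' @export
#' @examples
#' twist_from_white(14, -1.75) # 15.75
twist_from_white <- function(lk, wr) {
  check_scalar_number(lk, "lk")
  check_scalar_number(wr, "wr")
  lk - wr
}

#' Average bending angle per superhelical pitch
#'
#' Taking one pitch of the wrapped DNA as the unit of arc length, the
#' average bending angle over that unit is `|Wr| * 360 / Tw` degrees. The
#' magnitude of the writhe is used: the bend angle is a geometric opening
#' angle and carries no handedness sign.
#'
#' @param wr_magnitude Absolute writhe (> 0).
#' @param tw Twist (> 0).
#' @return Bending angle in degrees.
#' @export
#' @examples
#' bend_angle_per_pitch(1.75, 15.75) # 40 degrees
bend_angle_per_pitch <- function(wr_magnitude, tw) {
  check_scalar_number(wr_magnitude, "wr_magnitude", positive = TRUE)
  check_scalar_number(tw, "tw", positive = TRUE)
  wr_magnitude * 360 / tw
}

#' Topological state of closed circular DNA
#'
#' Validates and stores the (Lk, Wr, Tw) triple together with the bending
#' angle. White's formula `Lk = Wr + Tw` is enforced to within 1e-12 on
#' construction.
#'
#' @param lk Linking number.
#' @param wr Writhe (negative for a left-handed wrap).
#' @param tw Twist; defaults to `lk - wr`.
#' @param bend_angle_deg Bending angle per unit arc length, degrees, in
#'   (0, 360]. Defaults to `bend_angle_per_pitch(abs(wr), tw)` when `wr`
#'   is non-zero and `tw` positive.
#'
#' @return An object of class `topology_state`.
#' @export
#' @examples
#' topology_state(lk = 14, wr = -1.75)
topology_state <- function(lk, wr, tw = lk - wr, bend_angle_deg = NULL) {
  check_scalar_number(lk, "lk")
  check_scalar_number(wr, "wr")
  check_scalar_number(tw, "tw")
  if (abs(lk - (wr + tw)) >= 1e-12) {
    stop_invalid("White's formula violated: |Lk - (Wr + Tw)| = %.3g >= 1e-12",
                 abs(lk - (wr + tw)))
  }
  if (is.null(bend_angle_deg)) {
    if (wr == 0 || tw <= 0) {
      stop_invalid("`bend_angle_deg` must be supplied when wr == 0 or tw <= 0")
    }
    bend_angle_deg <- bend_angle_per_pitch(abs(wr), tw)
  }
  check_scalar_number(bend_angle_deg, "bend_angle_deg")
  if (bend_angle_deg <= 0 || bend_angle_deg > 360) {
    stop_invalid("`bend_angle_deg` must lie in (0, 360], got %g", bend_angle_deg)
  }
  structure(
    list(lk = lk, wr = wr, tw = tw, bend_angle_deg = bend_angle_deg),
    class = "topology_state"
  )
}

#' @export
print.topology_state <- function(x, ...) {
  cat(sprintf("<topology_state> Lk = %g, Wr = %g, Tw = %g, bend = %g deg\n",
              x$lk, x$wr, x$tw, x$bend_angle_deg))
  invisible(x)
}

#' @method tidy topology_state
#' @export
tidy.topology_state <- function(x, ...) {
  tibble::tibble(
    lk = x$lk, wr = x$wr, tw = x$tw, bend_angle_deg = x$bend_angle_deg
  )
}

#' Factorizations of a Hopf charge
#'
#' A torus-knot (Hopfion) configuration with Hopf charge `W` has integer
#' toroidal and poloidal winding numbers with `P * Q = W`. This enumerates
#' every ordered pair of positive integers whose product is `w`, sorted by
#' `p`; the number of rows equals the divisor count of `w`.
#'
#' @param w Positive integer Hopf charge (= linking number).
#' @return A tibble with integer columns `p` and `q`.
#' @export
#' @examples
#' hopf_factorizations(14) # (1,14), (2,7), (7,2), (14,1)
hopf_factorizations <- function(w) {
  check_scalar_number(w, "w", positive = TRUE)
  if (abs(w - round(w)) > 1e-9 || w < 1) {
    stop_invalid("`w` must be a positive integer, got %g", w)
  }
  w <- as.integer(round(w))
  p <- seq_len(w)
  p <- p[w %% p == 0L]
  tibble::tibble(p = p, q = w %/% p)
}
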