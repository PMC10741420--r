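#' Define a wrapped-DNA scenario
#'
#' A scenario bundles the geometric inputs of one modelled nucleosome
#' case: DNA length, wrap turns and handedness, the mapped bending angle
#' `R` and the coordinate rates. [run_scenario()] turns it into a full
#' topology + energy report. The canonical cases ship as presets, see
#' [preset_scenario()].
#'
#' @param name Identifier.
#' @param n_bp Number of base pairs.
#' @param wrap_turns Superhelical wrap turns (>= 0).
#' @param handedness `"left"` (nucleosomal) or `"right"`.
#' @param r_deg Bending angle R, degrees, open interval (0, 90).
#' @param m,n Coordinate rates (default 1).
#' @param bp_per_turn Base pairs per helical turn (default 10.5).
#' @param description Free-text note.
#' @return An object of class `scenario`.
#' @export
#' @examples
#' scenario("custom", n_bp = 147, wrap_turns = 1.75, r_deg = 20)
scenario <- function(name, n_bp, wrap_turns, handedness = c("left", "right"),
                     r_deg, m = 1, n = 1, bp_per_turn = 10.5,
                     description = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  handedness <- match.arg(handedness)
  geometry <- dna_geometry(n_bp, bp_per_turn = bp_per_turn)
  check_scalar_number(wrap_turns, "wrap_turns", nonnegative = TRUE)
  check_r_deg(r_deg)
  lk <- linking_number(geometry)
  wr <- writhe_from_wrap(wrap_turns, handedness)
  tw <- twist_from_white(lk, wr)
  # constructing the state validates White's formula for the preset
  topo <- topology_state(lk, wr, tw)
  structure(
    list(
      name = name, geometry = geometry, wrap_turns = wrap_turns,
      handedness = handedness, r_deg = r_deg, m = m, n = n,
      topology = topo, description = description
    ),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %g bp, %g %s-handed turns, R = %g deg\n",
              x$name, x$geometry$n_bp, x$wrap_turns, x$handedness, x$r_deg))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  invisible(x)
}

scenario_registry <- function() {
  canonical <- list(
    nucleosome147 = scenario(
      "nucleosome147", 147, 1.75, "left", r_deg = 20,
      description = "Canonical nucleosome core particle: 147 bp, 1.75 left-handed turns, Lk = 14."
    ),
    short63 = scenario(
      "short63", 63, 0.75, "left", r_deg = 20,
      description = "Sub-nucleosomal 63 bp wrap (0.75 turns), Lk = 6."
    ),
    long168 = scenario(
      "long168", 168, 2, "left", r_deg = 20,
      description = "Extended 168 bp wrap (2 turns), Lk = 16."
    ),
    long189 = scenario(
      "long189", 189, 2.25, "left", r_deg = 20,
      description = "Over-long 189 bp wrap (2.25 turns), Lk = 18."
    )
  )
  variants <- lapply(c(5, 12, 18, 22, 30), function(r) {
    scenario(
      sprintf("nucleosome147_r%d", r), 147, 1.75, "left", r_deg = r,
      description = sprintf("147 bp nucleosome with the mapped bending angle varied to R = %d deg.", r)
    )
  })
  names(variants) <- vapply(variants, `[[`, "", "name")
  c(canonical, variants)
}

#' List the preset scenarios
#'
#' @return A tibble with one row per preset (`name`, `n_bp`, `wrap_turns`,
#'   `handedness`, `r_deg`, `lk`, `description`).
#' @export
#' @examples
#' list_scenarios()
list_scenarios <- function() {
  reg <- scenario_registry()
  dplyr::bind_rows(lapply(reg, function(sc) {
    tibble::tibble(
      name = sc$name, n_bp = sc$geometry$n_bp, wrap_turns = sc$wrap_turns,
      handedness = sc$handedness, r_deg = sc$r_deg,
      lk = sc$topology$lk, description = sc$description
    )
  }))
}

#' Fetch a preset scenario by name
#'
#' @param name Preset identifier, e.g. `"nucleosome147"`.
#' @return A [scenario()] object.
#' @export
#' @examples
#' preset_scenario("nucleosome147")
preset_scenario <- function(name) {
  reg <- scenario_registry()
  if (!name %in% names(reg)) {
    stop_invalid("unknown preset '%s'; available: %s",
                 name, paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}

#' Run a scenario end to end
#'
#' Computes the topology summary, the continuous free-energy profile over
#' the toroidal winding and the integer-factorization minimum for one
#' scenario. The computation is fully deterministic: identical inputs
#' yield identical reports.
#'
#' @param sc A [scenario()] or a preset name.
#' @param constants An [elastic_constants()] object.
#' @param p_step Profile grid spacing (default 0.1).
#' @return An object of class `scenario_report`: a list with `scenario`,
#'   `topology` (one-row tibble), `profile` ([energy_profile()]) and
#'   `integer_min` ([integer_minimum()]).
#' @export
#' @examples
#' rep <- run_scenario("nucleosome147")
#' rep$topology
#' glance(rep$profile)
run_scenario <- function(sc, constants = elastic_constants(), p_step = 0.1) {
  if (is.character(sc)) sc <- preset_scenario(sc)
  stopifnot(inherits(sc, "scenario"))
  topo <- sc$topology
  topo_row <- tibble::tibble(
    name = sc$name,
    n_bp = sc$geometry$n_bp,
    lk = topo$lk,
    wr = topo$wr,
    tw = topo$tw,
    bend_angle_deg = topo$bend_angle_deg,
    superhelix_radius_nm = sc$geometry$superhelix_radius
  )
  w <- lk_integer(topo$lk)
  prof <- energy_profile(w, sc$r_deg, sc$m, sc$n, constants, p_step = p_step)
  imin <- integer_minimum(w, sc$r_deg, sc$m, sc$n, constants)
  structure(
    list(scenario = sc, topology = topo_row, profile = prof,
         integer_min = imin),
    class = "scenario_report"
  )
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> %s\n", x$scenario$name))
  cat(sprintf("  Lk = %g, Wr = %g, Tw = %g, bend = %g deg\n",
              x$topology$lk, x$topology$wr, x$topology$tw,
              x$topology$bend_angle_deg))
  cat(sprintf("  grid minimum %.6g kBT/unit at P = %g; integer best P = %d\n",
              x$profile$f_min_grid, x$profile$p_min_grid,
              x$integer_min$p_best))
  invisible(x)
}

#' Write an energy profile as CSV
#'
#' Writes the `P` grid and free-energy values as an RFC-4180 style CSV
#' (header row `P,F_kBT_per_unit_length`, `.` decimal separator, 12
#' significant digits). Refuses to write an empty profile.
#'
#' @param profile An [energy_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_profile_csv(energy_profile(14, 20), f)
#' head(read.csv(f))
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "energy_profile"))
  grid <- profile$grid
  if (is.null(grid) || nrow(grid) == 0) {
    stop_invalid("refusing to write an empty profile")
  }
  lines <- c(
    "P,F_kBT_per_unit_length",
    sprintf("%s,%s", signif12(grid$p), signif12(grid$f))
  )
  writeLines(lines, path)
  invisible(path)
}

signif12 <- function(x) {
  formatC(x, digits = 12, format = "g")
}

#' JSON summary of a scenario report or profile
#'
#' Serialises the scalar summary (topology numbers, grid and refined
#' minima, parameters) as pretty JSON, the sidecar format of the
#' command-line interface.
#'
#' @param x An `energy_profile`, `integer_minimum` or `scenario_report`.
#' @return A JSON string (class `json`).
#' @export
report_json <- function(x) {
  payload <- if (inherits(x, "energy_profile")) {
    c(list(p_min = x$p_min, f_min = x$f_min,
           p_min_grid = x$p_min_grid, f_min_grid = x$f_min_grid),
      list(params = x$params))
  } else if (inherits(x, "integer_minimum")) {
    list(p_best = x$p_best, f_best = x$f_best, params = x$params,
         candidates = as.data.frame(x$candidates))
  } else if (inherits(x, "scenario_report")) {
    list(
      scenario = x$scenario$name,
      topology = as.list(x$topology),
      profile = list(p_min = x$profile$p_min, f_min = x$profile$f_min,
                     p_min_grid = x$profile$p_min_grid,
                     f_min_grid = x$profile$f_min_grid),
      integer_min = list(p_best = x$integer_min$p_best,
                         f_best = x$integer_min$f_best)
    )
  } else {
    stop_invalid("no JSON report for class <%s>", paste(class(x), collapse = "/"))
  }
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
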