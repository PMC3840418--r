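# Unit-checked conversions between areal CaCO3 mass fluxes (e.g. g cm^-2 d^-1)
# and vertical reef-framework rates (mm y^-1). A year is fixed at 365 days.

.MASS_G  <- c(g = 1, kg = 1000)      # grams per unit
.AREA_CM2 <- c(cm2 = 1, m2 = 1e4)    # cm^2 per unit
.TIME_D  <- c(d = 1, y = 365)        # days per unit

.match_unit <- function(unit, table, what) {
  unit <- gsub("²", "2", tolower(trimws(unit)))
  if (!unit %in% names(table)) {
    stop("unknown_unit: unrecognised ", what, " unit '", unit,
         "' (expected one of: ", paste(names(table), collapse = ", "), ")",
         call. = FALSE)
  }
  unit
}

#' Areal calcium-carbonate mass rate
#'
#' Constructs a mass flux per unit area per unit time with explicit units.
#' Negative values denote dissolution (mass loss), positive values accretion.
#'
#' @param value Numeric flux value (finite). May be a vector.
#' @param mass_unit One of `"g"`, `"kg"`.
#' @param area_unit One of `"cm2"`, `"m2"` (superscript-2 glyphs accepted).
#' @param time_unit One of `"d"`, `"y"` (1 y = 365 d).
#' @param units Alternatively, a single slash-separated string such as
#'   `"g/cm2/d"` or `"kg/m2/y"`; overrides the three unit arguments.
#' @return An object of class `areal_mass_rate`.
#' @examples
#' areal_mass_rate(-4.2e-5, "g", "cm2", "d")
#' areal_mass_rate(15.3, units = "kg/m2/y")
#' @export
areal_mass_rate <- function(value, mass_unit = "g", area_unit = "cm2",
                            time_unit = "d", units = NULL) {
  if (!is.null(units)) {
    u <- parse_rate_units(units)
    mass_unit <- u$mass_unit; area_unit <- u$area_unit; time_unit <- u$time_unit
  }
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop("invalid_value: rate value must be finite numeric", call. = FALSE)
  }
  structure(
    list(value = as.numeric(value),
         mass_unit = .match_unit(mass_unit, .MASS_G, "mass"),
         area_unit = .match_unit(area_unit, .AREA_CM2, "area"),
         time_unit = .match_unit(time_unit, .TIME_D, "time")),
    class = "areal_mass_rate"
  )
}

#' Parse a slash-separated unit triple
#'
#' @param units A string like `"g/cm2/d"`: mass, area, time separated by `/`.
#' @return A list with `mass_unit`, `area_unit`, `time_unit` tokens.
#' @export
parse_rate_units <- function(units) {
  stopifnot(is.character(units), length(units) == 1L)
  parts <- strsplit(units, "/", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    stop("unknown_unit: unit string must be 'mass/area/time', got '", units, "'",
         call. = FALSE)
  }
  list(mass_unit = .match_unit(parts[1], .MASS_G, "mass"),
       area_unit = .match_unit(parts[2], .AREA_CM2, "area"),
       time_unit = .match_unit(parts[3], .TIME_D, "time"))
}

#' @export
print.areal_mass_rate <- function(x, ...) {
  cat(format(x$value), " ", x$mass_unit, " ", x$area_unit, "^-1 ",
      x$time_unit, "^-1\n", sep = "")
  invisible(x)
}

#' Convert an areal mass rate to different units
#'
#' Exact conversion between any two unit triples drawn from \{g, kg\} x
#' \{cm2, m2\} x \{d, y\}, with 1 y = 365 d.
#'
#' @param rate An [areal_mass_rate()] object.
#' @param mass_unit,area_unit,time_unit Target units.
#' @param units Optional target triple as a string, e.g. `"kg/m2/y"`.
#' @return An `areal_mass_rate` in the target units, numerically equal.
#' @examples
#' r <- areal_mass_rate(4.2e-5, "g", "cm2", "d")
#' convert_areal_mass_rate(r, units = "g/m2/d")   # 0.42
#' @export
convert_areal_mass_rate <- function(rate, mass_unit = "kg", area_unit = "m2",
                                    time_unit = "y", units = NULL) {
  stopifnot(inherits(rate, "areal_mass_rate"))
  if (!is.null(units)) {
    u <- parse_rate_units(units)
    mass_unit <- u$mass_unit; area_unit <- u$area_unit; time_unit <- u$time_unit
  }
  mt <- .match_unit(mass_unit, .MASS_G, "mass")
  at <- .match_unit(area_unit, .AREA_CM2, "area")
  tt <- .match_unit(time_unit, .TIME_D, "time")
  # via base units g cm^-2 d^-1
  base <- rate$value * .MASS_G[[rate$mass_unit]] /
    (.AREA_CM2[[rate$area_unit]] * .TIME_D[[rate$time_unit]])
  areal_mass_rate(base * .AREA_CM2[[at]] * .TIME_D[[tt]] / .MASS_G[[mt]],
                  mt, at, tt)
}

#' Reef-framework properties for mass-thickness conversion
#'
#' @param mineral_density Bulk density of the carbonate mineral in g cm^-3
#'   (default 2.9, aragonite crystal density).
#' @param framework_porosity Void fraction of the consolidated reef framework,
#'   in `[0, 1)` (default 0.5).
#' @return An object of class `framework_properties`.
#' @export
framework_properties <- function(mineral_density = 2.9,
                                 framework_porosity = 0.5) {
  if (!is.numeric(mineral_density) || length(mineral_density) != 1L ||
      !is.finite(mineral_density) || mineral_density <= 0) {
    stop("invalid_density: mineral_density must be a single positive number",
         call. = FALSE)
  }
  if (!is.numeric(framework_porosity) || length(framework_porosity) != 1L ||
      !is.finite(framework_porosity) ||
      framework_porosity < 0 || framework_porosity >= 1) {
    stop("invalid_porosity: framework_porosity must lie in [0, 1)",
         call. = FALSE)
  }
  structure(list(mineral_density = mineral_density,
                 framework_porosity = framework_porosity),
            class = "framework_properties")
}

#' Convert an areal mass flux to a vertical framework rate
#'
#' A flux of r kg CaCO3 m^-2 y^-1 deposited into (or dissolved out of) a
#' framework of solid fraction (1 - porosity) and mineral density rho
#' corresponds to a vertical rate of r / (rho * (1 - porosity)) mm y^-1
#' (rho in g cm^-3). The sign is preserved: dissolution (negative flux)
#' gives a negative vertical rate.
#'
#' @param rate An [areal_mass_rate()], or a plain number interpreted as
#'   kg m^-2 y^-1.
#' @param props A [framework_properties()] object.
#' @return Vertical rate in mm y^-1.
#' @examples
#' mass_rate_to_vertical_rate(15.3, framework_properties())  # ~10.55 mm/y
#' @export
mass_rate_to_vertical_rate <- function(rate, props = framework_properties()) {
  stopifnot(inherits(props, "framework_properties"))
  if (is.numeric(rate)) rate <- areal_mass_rate(rate, units = "kg/m2/y")
  r <- convert_areal_mass_rate(rate, units = "kg/m2/y")$value
  # kg m^-2 y^-1 over kg m^-3 of framework, times 1000 mm/m:
  # simplifies to r / (rho_g_cm3 * (1 - phi)) in mm/y
  r / (props$mineral_density * (1 - props$framework_porosity))
}

#' Convert a vertical framework rate to an areal mass flux
#'
#' Exact inverse of [mass_rate_to_vertical_rate()].
#'
#' @param vertical_rate Vertical rate in mm y^-1.
#' @param props A [framework_properties()] object.
#' @param units Target unit triple for the result (default `"kg/m2/y"`).
#' @return An [areal_mass_rate()].
#' @export
vertical_rate_to_mass_rate <- function(vertical_rate,
                                       props = framework_properties(),
                                       units = "kg/m2/y") {
  stopifnot(inherits(props, "framework_properties"),
            is.numeric(vertical_rate), all(is.finite(vertical_rate)))
  r <- vertical_rate * props$mineral_density * (1 - props$framework_porosity)
  convert_areal_mass_rate(areal_mass_rate(r, units = "kg/m2/y"), units = units)
}
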