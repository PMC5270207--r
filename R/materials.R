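#' Acoustic and thermal properties of a propagation medium
#'
#' A material record carries every physical constant the acoustic and thermal
#' models need for one medium.  All fields are SI except `attenuation`, which
#' is kept in the customary dB cm^-1 MHz^-1 of equipment data sheets and
#' converted to nepers at the point of use (see
#' [db_per_cm_to_neper_per_m()]).
#'
#' Solids additionally carry a shear (transverse) wave speed, which must be
#' below the longitudinal speed; fluids have none.  The `assumed` field lists
#' the names of constants that are not measured values for this medium but
#' package defaults (e.g. the water constants and the bone shear speed), so
#' that provenance survives serialisation.
#'
#' @param name Short label for the medium.
#' @param density Mass density, kg m^-3. Strictly positive.
#' @param sound_speed Longitudinal sound speed, m s^-1. Strictly positive.
#' @param attenuation Attenuation coefficient, dB cm^-1 MHz^-1 (amplitude
#'   dB). Non-negative.
#' @param specific_heat Specific heat capacity, J kg^-1 K^-1. Strictly
#'   positive.
#' @param thermal_conductivity Thermal conductivity, W m^-1 K^-1.
#'   Non-negative (zero disables conduction, useful for adiabatic checks).
#' @param shear_speed Shear wave speed, m s^-1, or `NULL` for fluids. If
#'   present it must be strictly less than `sound_speed`.
#' @param assumed Character vector naming fields whose values are package
#'   assumptions rather than measured constants.
#'
#' @return An object of class `dia_material`.
#' @seealso [builtin_material()] for the three media used in the phantom
#'   study, [acoustic_impedance()], [thermal_diffusivity()].
#' @export
#' @examples
#' gel <- material("gel", density = 1030, sound_speed = 1520,
#'                 attenuation = 0.4, specific_heat = 3900,
#'                 thermal_conductivity = 0.55)
#' acoustic_impedance(gel)
material <- function(name, density, sound_speed, attenuation, specific_heat,
                     thermal_conductivity, shear_speed = NULL,
                     assumed = character()) {
  m <- structure(
    list(
      name = as.character(name)[1],
      density = as.numeric(density)[1],
      sound_speed = as.numeric(sound_speed)[1],
      attenuation = as.numeric(attenuation)[1],
      specific_heat = as.numeric(specific_heat)[1],
      thermal_conductivity = as.numeric(thermal_conductivity)[1],
      shear_speed = if (is.null(shear_speed)) NULL else as.numeric(shear_speed)[1],
      assumed = as.character(assumed)
    ),
    class = "dia_material"
  )
  validate_material(m)
}

validate_material <- function(m) {
  chk <- function(v, what, min_ok) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("material '%s': %s must be a finite number", m$name, what))
    }
    if (!min_ok(v)) {
      abort(sprintf("material '%s': %s out of range (got %g)", m$name, what, v))
    }
  }
  chk(m$density, "density", function(v) v > 0)
  chk(m$sound_speed, "sound_speed", function(v) v > 0)
  chk(m$attenuation, "attenuation", function(v) v >= 0)
  chk(m$specific_heat, "specific_heat", function(v) v > 0)
  chk(m$thermal_conductivity, "thermal_conductivity", function(v) v >= 0)
  if (!is.null(m$shear_speed)) {
    chk(m$shear_speed, "shear_speed", function(v) v > 0)
    if (m$shear_speed >= m$sound_speed) {
      abort(sprintf(
        "material '%s': shear_speed (%g) must be below sound_speed (%g)",
        m$name, m$shear_speed, m$sound_speed
      ))
    }
  }
  z <- m$density * m$sound_speed
  if (!is.finite(z) || z <= 0) {
    abort(sprintf("material '%s': acoustic impedance is not positive", m$name))
  }
  m
}

#' Built-in phantom and coupling media
#'
#' Returns the material constants of the three media in the layered
#' calorimeter: the agar-based soft-tissue phantom, the 1 mm synthetic
#' cortical bone disc, and the 36 degC water bath that couples and backs the
#' phantom.
#'
#' Tissue and bone constants are the characterised values for these phantom
#' materials.  Two documented overrides apply:
#' \itemize{
#'   \item the bone density is recorded as 1700.59 kg m^-3 -- the
#'     characterisation sheet's unit (g cm^-3) is physically impossible for
#'     synthetic cortical bone and is read as kg m^-3;
#'   \item the bone shear speed is not characterised; the default 1462 m s^-1
#'     (half the longitudinal speed, typical of cortical-bone mimics) is
#'     flagged in `assumed` and only matters for the trapped-energy
#'     calculation.
#' }
#' Water constants are literature values near 36 degC and are flagged as
#' assumed; they can be overridden by constructing a [material()] directly.
#'
#' @param name One of `"tissue_phantom"`, `"bone_phantom"`, `"water"`.
#' @return A [material()] record.
#' @export
#' @examples
#' builtin_material("tissue_phantom")
#' thermal_diffusivity(builtin_material("tissue_phantom")) # ~1.45e-7 m^2/s
builtin_material <- function(name) {
  switch(name,
    tissue_phantom = material(
      "tissue_phantom",
      density = 1050, sound_speed = 1540, attenuation = 0.5,
      specific_heat = 3800, thermal_conductivity = 0.58
    ),
    bone_phantom = material(
      "bone_phantom",
      density = 1700.59, sound_speed = 2924.31, attenuation = 6.15,
      specific_heat = 1256.34, thermal_conductivity = 0.47,
      shear_speed = 1462,
      assumed = c("shear_speed", "density_unit_read_as_kg_m3")
    ),
    water = material(
      "water",
      density = 994, sound_speed = 1523, attenuation = 0.0022,
      specific_heat = 4178, thermal_conductivity = 0.62,
      assumed = c("density", "sound_speed", "attenuation",
                  "specific_heat", "thermal_conductivity")
    ),
    abort(sprintf(
      "unknown material '%s'; available: tissue_phantom, bone_phantom, water",
      name
    ))
  )
}

#' Thermal diffusivity of a material
#'
#' `k / (rho * c_p)` in m^2 s^-1.  For the tissue phantom this reproduces the
#' characterised 0.15e-6 m^2 s^-1 after rounding to two significant figures,
#' a useful self-consistency check on the constants.
#'
#' @param m A [material()].
#' @return Thermal diffusivity, m^2 s^-1.
#' @export
thermal_diffusivity <- function(m) {
  stopifnot(inherits(m, "dia_material"))
  m$thermal_conductivity / (m$density * m$specific_heat)
}

#' Characteristic acoustic impedance of a material
#'
#' The rho*c product, in Rayl (kg m^-2 s^-1).  Impedance mismatch across an
#' interface governs how much energy is reflected there.
#'
#' @param m A [material()].
#' @return Acoustic impedance, Rayl.
#' @export
acoustic_impedance <- function(m) {
  stopifnot(inherits(m, "dia_material"))
  m$density * m$sound_speed
}

#' @export
print.dia_material <- function(x, ...) {
  cat(sprintf("<material: %s>\n", x$name))
  cat(sprintf("  density              %g kg/m^3\n", x$density))
  cat(sprintf("  sound speed          %g m/s\n", x$sound_speed))
  if (!is.null(x$shear_speed)) {
    cat(sprintf("  shear speed          %g m/s\n", x$shear_speed))
  }
  cat(sprintf("  attenuation          %g dB/cm/MHz\n", x$attenuation))
  cat(sprintf("  specific heat        %g J/kg/K\n", x$specific_heat))
  cat(sprintf("  thermal conductivity %g W/m/K\n", x$thermal_conductivity))
  if (length(x$assumed)) {
    cat("  assumed:", paste(x$assumed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.dia_material <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    density = x$density,
    sound_speed = x$sound_speed,
    shear_speed = if (is.null(x$shear_speed)) NA_real_ else x$shear_speed,
    attenuation = x$attenuation,
    specific_heat = x$specific_heat,
    thermal_conductivity = x$thermal_conductivity
  )
}

#' Define one layer of a stack
#'
#' @param material A [material()].
#' @param thickness Layer thickness, m. Strictly positive.
#' @return A layer record for [layer_stack()].
#' @export
layer <- function(material, thickness) {
  stopifnot(inherits(material, "dia_material"))
  thickness <- as.numeric(thickness)[1]
  if (!is.finite(thickness) || thickness <= 0) {
    abort("layer thickness must be a positive length in metres")
  }
  list(material = material, thickness = thickness)
}

#' Ordered one-dimensional stack of media
#'
#' Describes the axial geometry the transducer radiates into: finite layers
#' in beam order, then a semi-infinite backing medium (the water bath in both
#' study arms).  Interface depths are the cumulative layer thicknesses, with
#' z = 0 at the transducer face.
#'
#' @param ... [layer()] records, proximal to distal.
#' @param backing The semi-infinite [material()] behind the last layer.
#' @param label Optional label for reports.
#' @return An object of class `dia_stack`.
#' @seealso [phantom_stack()] for the two canonical study stacks.
#' @export
layer_stack <- function(..., backing, label = NULL) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) && is.null(layers[[1]]$material)) {
    layers <- layers[[1]]
  }
  if (!length(layers)) abort("a layer stack needs at least one layer")
  ok <- vapply(layers, function(l) {
    is.list(l) && inherits(l$material, "dia_material") &&
      is.numeric(l$thickness) && l$thickness > 0
  }, logical(1))
  if (!all(ok)) abort("layers must be built with layer(material, thickness)")
  stopifnot(inherits(backing, "dia_material"))
  depths <- cumsum(vapply(layers, `[[`, numeric(1), "thickness"))
  if (any(diff(c(0, depths)) <= 0)) abort("interface depths must increase")
  structure(
    list(layers = layers, backing = backing,
         label = label %||% "stack"),
    class = "dia_stack"
  )
}

#' The two canonical calorimeter stacks
#'
#' The phantom consists of two soft-tissue layers (10 mm and 20 mm) backed by
#' the water bath; the second study arm inserts a 1 mm bone layer between the
#' distal tissue face and the water.  The two tissue layers are the same
#' material, so their 10 mm interface is acoustically matched; reflections
#' arise only at tissue/bone, bone/water and tissue/water boundaries.
#'
#' @param bone If `TRUE`, include the 1 mm bone layer after the 30 mm of
#'   tissue.
#' @param tissue,bone_material,backing Override the built-in media.
#' @param bone_thickness Bone layer thickness, m.
#' @return A [layer_stack()] labelled `"with_bone"` or `"without_bone"`.
#' @export
#' @examples
#' phantom_stack()            # tissue 10 mm + 20 mm, water backing
#' phantom_stack(bone = TRUE) # ... + bone 1 mm
phantom_stack <- function(bone = FALSE,
                          tissue = builtin_material("tissue_phantom"),
                          bone_material = builtin_material("bone_phantom"),
                          backing = builtin_material("water"),
                          bone_thickness = 1e-3) {
  layers <- list(layer(tissue, 10e-3), layer(tissue, 20e-3))
  if (bone) layers <- c(layers, list(layer(bone_material, bone_thickness)))
  layer_stack(layers, backing = backing,
              label = if (bone) "with_bone" else "without_bone")
}

#' @export
print.dia_stack <- function(x, ...) {
  cat(sprintf("<layer stack: %s>\n", x$label))
  z0 <- 0
  for (l in x$layers) {
    cat(sprintf("  %7.1f-%7.1f mm  %s\n", z0 * 1e3, (z0 + l$thickness) * 1e3,
                l$material$name))
    z0 <- z0 + l$thickness
  }
  cat(sprintf("  %7.1f+        mm  %s (backing)\n", z0 * 1e3, x$backing$name))
  invisible(x)
}

#' Total thickness of the finite layers of a stack
#' @param stack A [layer_stack()].
#' @return Depth of the last interface, m.
#' @export
stack_depth <- function(stack) {
  stopifnot(inherits(stack, "dia_stack"))
  sum(vapply(stack$layers, `[[`, numeric(1), "thickness"))
}

#' Interface depths of a stack
#' @param stack A [layer_stack()].
#' @return Depths of all interfaces (including the final layer/backing
#'   interface), m.
#' @export
interface_depths <- function(stack) {
  stopifnot(inherits(stack, "dia_stack"))
  cumsum(vapply(stack$layers, `[[`, numeric(1), "thickness"))
}

stack_has_solid <- function(stack) {
  any(vapply(stack$layers, function(l) !is.null(l$material$shear_speed),
             logical(1)))
}

#' Transducer calibration record
#'
#' Holds the calibrated source parameters of the therapy unit: total acoustic
#' power, effective radiating area (ERA), beam non-uniformity ratio (BNR),
#' frequency, duty cycle and irradiation time.  The defaults are the
#' calibration used throughout the package: 4.18 W over 3.36 cm^2 at 1 MHz,
#' continuous mode, 120 s, giving an effective intensity of 1.24 W cm^-2.
#'
#' BNR is recorded but does not shape the modelled beam (a uniform top-hat
#' column of area ERA is used); `face_temperature_coupling` records that
#' transducer self-heating is excluded from the thermal model.
#'
#' @param frequency Operating frequency, Hz.
#' @param acoustic_power Total emitted acoustic power, W.
#' @param era Effective radiating area, m^2.
#' @param bnr Beam non-uniformity ratio (dimensionless).
#' @param duty_cycle Fraction of time emitting; 1 = continuous.
#' @param duration Irradiation time, s.
#' @param face_temperature_coupling Logical; kept `FALSE` (self-heating of
#'   the transducer face is not modelled).
#' @return An object of class `dia_transducer`.
#' @export
#' @examples
#' tx <- transducer_spec()
#' effective_intensity(tx$acoustic_power, tx$era) / 1e4  # W/cm^2
transducer_spec <- function(frequency = 1e6, acoustic_power = 4.18,
                            era = 3.36e-4, bnr = 3.91, duty_cycle = 1,
                            duration = 120,
                            face_temperature_coupling = FALSE) {
  if (!is.finite(era) || era <= 0) abort("era must be positive (m^2)")
  if (!is.finite(acoustic_power) || acoustic_power < 0) {
    abort("acoustic_power must be non-negative (W)")
  }
  if (!is.finite(duty_cycle) || duty_cycle <= 0 || duty_cycle > 1) {
    abort("duty_cycle must lie in (0, 1]")
  }
  if (!is.finite(frequency) || frequency <= 0) abort("frequency must be positive")
  if (!is.finite(duration) || duration < 0) abort("duration must be non-negative")
  structure(
    list(frequency = frequency, acoustic_power = acoustic_power, era = era,
         bnr = bnr, duty_cycle = duty_cycle, duration = duration,
         face_temperature_coupling = isTRUE(face_temperature_coupling)),
    class = "dia_transducer"
  )
}

#' @export
print.dia_transducer <- function(x, ...) {
  cat("<transducer>\n")
  cat(sprintf("  frequency  %g MHz\n", x$frequency / 1e6))
  cat(sprintf("  power      %g W over ERA %g cm^2 (BNR %g)\n",
              x$acoustic_power, x$era * 1e4, x$bnr))
  cat(sprintf("  intensity  %.3g W/cm^2 effective\n",
              effective_intensity(x$acoustic_power, x$era) / 1e4))
  cat(sprintf("  mode       duty %g, duration %g s\n", x$duty_cycle, x$duration))
  invisible(x)
}

#' Radius of the modelled beam column
#'
#' The beam is modelled as a uniform top-hat column with the transducer's
#' effective radiating area, so its radius is `sqrt(ERA / pi)` (about
#' 10.34 mm for the default calibration).
#'
#' @param tx A [transducer_spec()].
#' @return Beam radius, m.
#' @export
beam_radius <- function(tx) {
  stopifnot(inherits(tx, "dia_transducer"))
  sqrt(tx$era / pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
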