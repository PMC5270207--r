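# Oblique-incidence fluid/solid reflectance with mode conversion, and the
# "trapped energy" fraction: how much of the source energy ends up shuttling
# between the bone surface and the transducer face instead of entering the
# bone on first arrival.

#' Plane-wave reflectance of a fluid/solid interface
#'
#' Classical solution for a plane wave in a lossless fluid striking a solid
#' half-space: Snell's law gives the refracted longitudinal and shear
#' angles, the angle-dependent impedances are `Z_i = rho c_i / cos(theta_i)`,
#' and the solid presents the combined normal impedance
#' `Z_tot = Z_L cos^2(2 theta_s) + Z_S sin^2(2 theta_s)`.  The energy
#' reflectance is `|(Z_tot - Z_f)/(Z_tot + Z_f)|^2`; the transmitted energy
#' is partitioned between the longitudinal and shear branches in proportion
#' to their contributions to `Z_tot`.  Beyond a branch's critical angle that
#' branch becomes evanescent and carries no energy.
#'
#' At normal incidence the shear branch vanishes and the result reduces to
#' [normal_energy_reflectance()].
#'
#' @param angle Incidence angle(s) in the fluid, degrees from the interface
#'   normal; `|angle| < 90` (the result is even in the angle).
#' @param fluid The incident-side [material()] (treated as lossless here).
#' @param solid The solid [material()]; must have a `shear_speed`.
#' @return A tibble with columns `angle`, `energy_reflectance`,
#'   `energy_transmittance_long`, `energy_transmittance_shear`.  Below all
#'   critical angles the three fractions sum to 1.
#' @export
#' @examples
#' fluid_solid_reflectance(0, builtin_material("tissue_phantom"),
#'                         builtin_material("bone_phantom"))
fluid_solid_reflectance <- function(angle,
                                    fluid = builtin_material("tissue_phantom"),
                                    solid = builtin_material("bone_phantom")) {
  stopifnot(inherits(fluid, "dia_material"), inherits(solid, "dia_material"))
  if (is.null(solid$shear_speed)) {
    abort(sprintf("material '%s' has no shear_speed; a solid is required",
                  solid$name))
  }
  if (any(!is.finite(angle)) || any(abs(angle) >= 90)) {
    abort("incidence angle must lie in (-90, 90) degrees")
  }
  th <- angle * pi / 180
  cf <- fluid$sound_speed
  cl <- solid$sound_speed
  cs <- solid$shear_speed

  one <- function(th1) {
    s1 <- sin(th1)
    # complex cosines: evanescent branches get imaginary cos -> Re(Z) = 0
    cos_c <- function(sin_t) sqrt(as.complex(1 - sin_t^2))
    sl <- s1 * cl / cf
    ss <- s1 * cs / cf
    zf <- fluid$density * cf / cos(th1)
    zl <- solid$density * cl / cos_c(sl)
    zs <- solid$density * cs / cos_c(ss)
    th_s <- asin(as.complex(ss))
    c2 <- cos(2 * th_s)^2
    s2 <- sin(2 * th_s)^2
    ztot <- zl * c2 + zs * s2
    refl <- (ztot - zf) / (ztot + zf)
    rE <- Mod(refl)^2
    # transmitted energy split by the real (propagating) parts of the
    # branch impedances' contributions
    wl <- Re(zl * c2)
    ws <- Re(zs * s2)
    wt <- wl + ws
    if (wt <= 0) {
      c(rE, 0, 0)
    } else {
      tE <- 1 - rE
      c(rE, tE * wl / wt, tE * ws / wt)
    }
  }
  m <- vapply(th, one, numeric(3))
  tibble::tibble(
    angle = angle,
    energy_reflectance = pmin(pmax(m[1, ], 0), 1),
    energy_transmittance_long = pmin(pmax(m[2, ], 0), 1),
    energy_transmittance_shear = pmin(pmax(m[3, ], 0), 1)
  )
}

#' Coherent normal-incidence reflectance of a solid plate
#'
#' Transfer-matrix (Airy summation) reflectance of a lossy plate between two
#' fluids at normal incidence, retaining phase: thickness resonances of the
#' plate modulate the reflectance, unlike the half-space model.  Provided as
#' the alternative bone model for the trapped-energy calculation; the
#' half-space model is the default (see [trapped_fraction()]).
#'
#' @param plate The plate [material()].
#' @param front,back Fluids on the incident and far side.
#' @param thickness Plate thickness, m.
#' @param frequency Frequency, Hz.
#' @return Energy reflectance in `[0, 1]`.
#' @export
plate_reflectance <- function(plate, front = builtin_material("tissue_phantom"),
                              back = builtin_material("water"),
                              thickness = 1e-3, frequency = 1e6) {
  z1 <- acoustic_impedance(front)
  z2 <- acoustic_impedance(plate)
  z3 <- acoustic_impedance(back)
  r1 <- (z2 - z1) / (z2 + z1)
  r2 <- (z3 - z2) / (z3 + z2)
  k <- 2 * pi * frequency / plate$sound_speed
  alpha <- material_alpha_np(plate, frequency)
  phase <- exp(2i * k * thickness - 2 * alpha * thickness)
  r <- (r1 + r2 * phase) / (1 + r1 * r2 * phase)
  Mod(r)^2
}

#' Fraction of source energy trapped between transducer and bone
#'
#' Operationalises the reverberation bookkeeping for a stack containing a
#' bone layer: the fraction of the emitted energy that is reflected back
#' toward the (perfectly reflecting) transducer face on first arrival at the
#' bone, rather than transmitted into the bone.  At incidence angle `theta`
#' this is the fluid/solid energy reflectance of the tissue/bone interface
#' (longitudinal and shear transmission branches included) multiplied, by
#' default, by the one-way tissue-path intensity attenuation at that
#' obliquity (`path = depth / cos(theta)`).
#'
#' The bone is treated as a half-space for the reflectance
#' (`bone_model = "half_space"`); `bone_model = "plate"` instead uses the
#' coherent 1 mm plate reflectance, available at normal incidence only.
#' An alternative multi-bounce definition (steady-state fraction of emitted
#' energy circulating in the tissue column, face reflectance applied each
#' round trip) is available via `definition = "multibounce"`.
#'
#' @param angle Incidence angle(s), degrees; `0 <= angle < 90`.
#' @param stack A [layer_stack()] containing a bone (solid) layer.
#' @param tx A [transducer_spec()].
#' @param include_path_attenuation Multiply by the one-way tissue path
#'   attenuation (default `TRUE`).
#' @param face_reflectance Transducer-face energy reflectance, used by the
#'   multibounce definition; default 1.
#' @param bone_model `"half_space"` (default) or `"plate"`.
#' @param definition `"first_arrival"` (default) or `"multibounce"`.
#' @return Trapped fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' trapped_fraction(0) # ~0.18 with the default constants
trapped_fraction <- function(angle, stack = phantom_stack(bone = TRUE),
                             tx = transducer_spec(),
                             include_path_attenuation = TRUE,
                             face_reflectance = 1,
                             bone_model = c("half_space", "plate"),
                             definition = c("first_arrival", "multibounce")) {
  bone_model <- match.arg(bone_model)
  definition <- match.arg(definition)
  stopifnot(inherits(stack, "dia_stack"))
  solid_idx <- which(vapply(stack$layers,
                            function(l) !is.null(l$material$shear_speed),
                            logical(1)))
  if (!length(solid_idx)) {
    abort("stack has no bone (solid) layer; trapped energy is undefined")
  }
  solid_idx <- solid_idx[1]
  bone <- stack$layers[[solid_idx]]$material
  tissue <- stack$layers[[1]]$material
  depth <- sum(vapply(stack$layers[seq_len(solid_idx - 1)], `[[`, numeric(1),
                      "thickness"))

  refl <- if (bone_model == "half_space") {
    fluid_solid_reflectance(angle, tissue, bone)$energy_reflectance
  } else {
    if (any(angle != 0)) {
      abort("bone_model = 'plate' is available at normal incidence only")
    }
    rep(plate_reflectance(bone, front = tissue, back = stack$backing,
                          thickness = stack$layers[[solid_idx]]$thickness,
                          frequency = tx$frequency), length(angle))
  }
  mu <- 2 * material_alpha_np(tissue, tx$frequency) # intensity Np/m
  a_path <- if (include_path_attenuation) {
    exp(-mu * depth / cos(angle * pi / 180))
  } else {
    rep(1, length(angle))
  }
  first <- a_path * refl
  if (definition == "first_arrival") {
    pmin(pmax(first, 0), 1)
  } else {
    # energy still circulating after each face/bone round trip: geometric
    # residence sum normalised by the emitted energy
    loop <- face_reflectance * refl * a_path^2
    pmin(pmax(first / (1 - loop), 0), 1)
  }
}

#' Sweep the trapped-energy fraction over incidence angles
#'
#' @param angles Incidence angles, degrees; default 0 to 15 in 0.5 deg steps
#'   (the obliquity range relevant to a hand-held treatment head).
#' @inheritParams trapped_fraction
#' @param ... Passed on to [trapped_fraction()].
#' @return A tibble of class `dia_sweep` with columns `angle` (deg) and
#'   `fraction`, plus attributes `min` and `max` over the sweep.
#' @export
#' @examples
#' sw <- trapped_sweep()
#' range(sw$fraction)
trapped_sweep <- function(angles = seq(0, 15, by = 0.5),
                          stack = phantom_stack(bone = TRUE),
                          tx = transducer_spec(), ...) {
  if (!length(angles)) abort("angle sweep must be non-empty")
  fr <- trapped_fraction(angles, stack = stack, tx = tx, ...)
  out <- tibble::tibble(angle = angles, fraction = fr)
  structure(out, min = min(fr), max = max(fr),
            class = c("dia_sweep", class(out)))
}

#' Write a trapped-energy sweep as delimited text
#'
#' Two-column tab-separated table (`angle_deg`, `fraction`) with a one-line
#' comment header; byte-stable for fixed inputs.
#'
#' @param sweep A [trapped_sweep()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "dia_sweep"))
  lines <- c(
    "# diatherm trapped-energy sweep",
    "angle_deg\tfraction",
    sprintf("%.12g\t%.12g", sweep$angle, sweep$fraction)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.dia_sweep <- function(x, ...) {
  cat(sprintf("<trapped-energy sweep: %d angles, %.1f-%.1f deg>\n",
              nrow(x), min(x$angle), max(x$angle)))
  cat(sprintf("  trapped fraction %.1f%% to %.1f%%\n",
              100 * attr(x, "min"), 100 * attr(x, "max")))
  NextMethod()
}
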