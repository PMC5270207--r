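# Human-editable YAML configuration for materials, stacks and runs.  Numeric
# values are serialised as full-precision strings so a write/read round trip
# reproduces every constant bit-exactly.

material_fields <- c("density", "sound_speed", "attenuation", "specific_heat",
                     "thermal_conductivity", "shear_speed", "assumed")

material_to_list <- function(m) {
  out <- list(
    density = sprintf("%.17g", m$density),
    sound_speed = sprintf("%.17g", m$sound_speed),
    attenuation = sprintf("%.17g", m$attenuation),
    specific_heat = sprintf("%.17g", m$specific_heat),
    thermal_conductivity = sprintf("%.17g", m$thermal_conductivity)
  )
  if (!is.null(m$shear_speed)) out$shear_speed <- sprintf("%.17g", m$shear_speed)
  if (length(m$assumed)) out$assumed <- as.list(m$assumed)
  out
}

material_from_list <- function(name, lst) {
  unknown <- setdiff(names(lst), material_fields)
  if (length(unknown)) {
    abort(sprintf("material '%s': unknown config keys: %s", name,
                  paste(unknown, collapse = ", ")))
  }
  required <- setdiff(material_fields, c("shear_speed", "assumed"))
  missing <- setdiff(required, names(lst))
  if (length(missing)) {
    abort(sprintf("material '%s': missing config keys: %s", name,
                  paste(missing, collapse = ", ")))
  }
  material(
    name,
    density = as.numeric(lst$density),
    sound_speed = as.numeric(lst$sound_speed),
    attenuation = as.numeric(lst$attenuation),
    specific_heat = as.numeric(lst$specific_heat),
    thermal_conductivity = as.numeric(lst$thermal_conductivity),
    shear_speed = if (is.null(lst$shear_speed)) NULL
                  else as.numeric(lst$shear_speed),
    assumed = unlist(lst$assumed) %||% character()
  )
}

#' Write materials (and optionally a stack) to a YAML config
#'
#' The schema has two top-level keys: `materials`, a named map of material
#' records (SI units; attenuation in dB cm^-1 MHz^-1), and an optional
#' `stack` with a `backing` material name and a list of
#' `{material, thickness_m}` layers.  Unknown keys are rejected on read.
#' Numbers round-trip bit-exactly.
#'
#' @param path Output file path.
#' @param materials A named list of [material()] records, or a single
#'   material.
#' @param stack Optional [layer_stack()] whose media are all in `materials`.
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_materials_config(f, list(tissue = builtin_material("tissue_phantom")))
#' read_materials_config(f)$materials$tissue
write_materials_config <- function(path, materials, stack = NULL) {
  if (inherits(materials, "dia_material")) {
    materials <- setNames(list(materials), materials$name)
  }
  if (is.null(names(materials)) || any(names(materials) == "")) {
    abort("materials must be a named list")
  }
  cfg <- list(materials = lapply(materials, material_to_list))
  if (!is.null(stack)) {
    stopifnot(inherits(stack, "dia_stack"))
    key_of <- function(m) {
      hit <- which(vapply(materials, function(x) identical(x$name, m$name),
                          logical(1)))
      if (!length(hit)) {
        abort(sprintf("stack material '%s' is not in the materials list",
                      m$name))
      }
      names(materials)[hit[1]]
    }
    cfg$stack <- list(
      label = stack$label,
      backing = key_of(stack$backing),
      layers = lapply(stack$layers, function(l) {
        list(material = key_of(l$material),
             thickness_m = sprintf("%.17g", l$thickness))
      })
    )
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a materials/stack YAML config
#'
#' @param path File path written by [write_materials_config()] (or edited by
#'   hand following the same schema).
#' @return A list with `materials` (named list of [material()] records) and,
#'   if present, `stack` (a [layer_stack()]).
#' @export
read_materials_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("materials", "stack"))
  if (length(unknown)) {
    abort(sprintf("unknown top-level config keys: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$materials)) abort("config has no 'materials' section")
  mats <- lapply(names(cfg$materials), function(nm) {
    material_from_list(nm, cfg$materials[[nm]])
  })
  names(mats) <- names(cfg$materials)
  out <- list(materials = mats)
  if (!is.null(cfg$stack)) {
    s <- cfg$stack
    unknown <- setdiff(names(s), c("label", "backing", "layers"))
    if (length(unknown)) {
      abort(sprintf("unknown stack config keys: %s",
                    paste(unknown, collapse = ", ")))
    }
    get_mat <- function(nm) {
      if (is.null(mats[[nm]])) {
        abort(sprintf("stack refers to unknown material '%s'", nm))
      }
      mats[[nm]]
    }
    layers <- lapply(s$layers, function(l) {
      layer(get_mat(l$material), as.numeric(l$thickness_m))
    })
    out$stack <- layer_stack(layers, backing = get_mat(s$backing),
                             label = s$label %||% "stack")
  }
  out
}

run_config_fields <- c("arm", "duration_s", "dr_m", "dz_m", "solid_dz_m",
                       "radius_m", "margin_m", "bath_c", "seed",
                       "face_reflectance", "sweep_angles_deg")

#' Default configuration of a full study run
#'
#' Flat key-value record driving [run_study()]: which arms to simulate, the
#' grid spec, irradiation time, bath temperature, face reflectance, the
#' trapped-energy sweep angles and the measurement seed.
#'
#' @param ... Overrides of the default fields.
#' @return A named list of class `dia_run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    arm = c("without_bone", "with_bone"),
    duration_s = 120, dr_m = 0.5e-3, dz_m = 0.5e-3, solid_dz_m = 1e-4,
    radius_m = 32.5e-3, margin_m = 10e-3, bath_c = 36, seed = 0L,
    face_reflectance = 1, sweep_angles_deg = seq(0, 15, by = 0.5)
  )
  over <- list(...)
  unknown <- setdiff(names(over), run_config_fields)
  if (length(unknown)) {
    abort(sprintf("unknown run-config fields: %s",
                  paste(unknown, collapse = ", ")))
  }
  structure(modifyList(cfg, over), class = "dia_run_config")
}

#' Write a run config to YAML
#' @param cfg A [run_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "dia_run_config"))
  lst <- lapply(unclass(cfg), function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else v
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a run config from YAML
#' @param path File path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  unknown <- setdiff(names(lst), run_config_fields)
  if (length(unknown)) {
    abort(sprintf("unknown run-config fields: %s",
                  paste(unknown, collapse = ", ")))
  }
  numf <- setdiff(run_config_fields, "arm")
  for (f in intersect(numf, names(lst))) {
    lst[[f]] <- as.numeric(unlist(lst[[f]]))
  }
  if (!is.null(lst$seed)) lst$seed <- as.integer(lst$seed)
  do.call(run_config, lst)
}
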