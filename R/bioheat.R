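# Axisymmetric explicit finite-volume solver for the perfusion-free Pennes
# bioheat equation, rho c dT/dt = div(k grad T) + q, on a cell-centred
# (r, z) grid aligned with the layer interfaces.

#' Canonical thermocouple positions
#'
#' Six probes: TP1-TP3 at the 10 mm interface and TP4-TP6 at the 30 mm
#' interface, each row 10 mm apart laterally with the centre probe (TP2,
#' TP5) on the beam axis.  In the axisymmetric model the off-axis pairs map
#' to the same radius.
#'
#' @return A tibble with columns `probe`, `r` (m), `z` (m).
#' @export
default_probes <- function() {
  tibble::tibble(
    probe = paste0("TP", 1:6),
    r = c(10, 0, 10, 10, 0, 10) * 1e-3,
    z = c(10, 10, 10, 30, 30, 30) * 1e-3
  )
}

# Build the cell-centred axisymmetric grid for a stack: z faces follow the
# layer boundaries exactly (so every cell lies in one medium), with local
# axial refinement inside solid (bone) layers; the water backing margin and
# the radial extent close the domain.
build_grid <- function(stack, dr = 0.5e-3, dz = 0.5e-3, solid_dz = 1e-4,
                       radius = 32.5e-3, margin = 10e-3) {
  stopifnot(inherits(stack, "dia_stack"))
  if (dr <= 0 || dz <= 0 || solid_dz <= 0) abort("dr, dz must be positive")
  if (margin < 0) abort("backing margin must be non-negative")
  segs <- c(
    lapply(stack$layers, function(l) {
      step <- if (is.null(l$material$shear_speed)) dz else solid_dz
      list(material = l$material, thickness = l$thickness, step = step)
    }),
    if (margin > 0) list(list(material = stack$backing, thickness = margin,
                              step = dz))
  )
  zf <- 0
  mat_id <- integer(0)
  mats <- list()
  for (s in segs) {
    n <- max(1L, round(s$thickness / s$step))
    zf <- c(zf, zf[length(zf)] + s$thickness * seq_len(n) / n)
    key <- s$material$name
    if (is.null(mats[[key]])) mats[[key]] <- s$material
    mat_id <- c(mat_id, rep(match(key, names(mats)), n))
  }
  nr <- max(2L, round(radius / dr))
  rf <- radius * (0:nr) / nr
  structure(
    list(
      rf = rf, rc = (rf[-1] + rf[-length(rf)]) / 2, dr = radius / nr, nr = nr,
      zf = zf, zc = (zf[-1] + zf[-length(zf)]) / 2,
      dzv = diff(zf), nz = length(zf) - 1L,
      mat_id = mat_id, materials = mats,
      radius = radius, depth = max(zf), stack_label = stack$label
    ),
    class = "dia_grid"
  )
}

# Face conductances (W/K), heat capacity and source for a grid.  Material
# properties vary with z only; axial faces between unlike media use the
# series (harmonic-mean) conductance of the two half-cells.
build_thermal <- function(grid, stack, tx, face_reflectance = 1) {
  k_z <- vapply(grid$materials, `[[`, numeric(1),
                "thermal_conductivity")[grid$mat_id]
  rhoc_z <- vapply(grid$materials,
                   function(m) m$density * m$specific_heat,
                   numeric(1))[grid$mat_id]
  nr <- grid$nr
  nz <- grid$nz
  rf <- grid$rf
  ring <- pi * (rf[-1]^2 - rf[-(nr + 1)]^2)      # annular area per r-cell
  V <- outer(ring, grid$dzv)                      # cell volumes
  invC <- 1 / (V * matrix(rhoc_z, nr, nz, byrow = TRUE))

  # radial faces: (nr+1) x nz; axis face 0, outer face to bath at half-cell
  Gr <- matrix(0, nr + 1, nz)
  for (j in seq_len(nz)) {
    h <- grid$dzv[j]
    Gr[2:nr, j] <- k_z[j] * 2 * pi * rf[2:nr] * h / grid$dr
    Gr[nr + 1, j] <- k_z[j] * 2 * pi * rf[nr + 1] * h / (grid$dr / 2)
  }
  # axial faces: nr x (nz+1); transducer face insulated, distal face to bath
  Gz <- matrix(0, nr, nz + 1)
  if (nz > 1) {
    hres <- grid$dzv / (2 * k_z)                  # half-cell thermal resistance
    gz_int <- 1 / (hres[-nz] + hres[-1])          # per unit area
    for (jj in seq_len(nz - 1)) Gz[, jj + 1] <- ring * gz_int[jj]
  }
  Gz[, nz + 1] <- ring * k_z[nz] / (grid$dzv[nz] / 2)

  # cell-averaged heat deposition (W): exact slab integral of the intensity
  # times the absorption, weighted by the annular overlap with the beam
  fl <- layered_flux(stack, tx, face_reflectance)
  depth <- stack_depth(stack)
  edges <- c(0, interface_depths(stack))
  mats <- lapply(stack$layers, `[[`, "material")
  alpha <- vapply(mats, function(m) material_alpha_np(m, tx$frequency),
                  numeric(1))
  alpha_b <- material_alpha_np(stack$backing, tx$frequency)
  z1 <- grid$zf[-(nz + 1)]
  z2 <- grid$zf[-1]
  zmid <- (z1 + z2) / 2
  idx <- findInterval(zmid, edges, rightmost.closed = FALSE)
  a_here <- ifelse(zmid >= depth, alpha_b,
                   alpha[pmin(pmax(idx, 1L), length(alpha))])
  imean <- slab_mean_intensity(fl, z1, pmin(z2, grid$depth), depth)
  q_z <- 2 * a_here * imean                       # W/m^3 per z-slab in beam
  rb <- beam_radius(tx)
  rin <- rf[-(nr + 1)]
  rout <- rf[-1]
  frac <- pmin(pmax((rb^2 - rin^2) / (rout^2 - rin^2), 0), 1) # beam overlap
  heatW <- outer(frac * ring, grid$dzv) * matrix(q_z, nr, nz, byrow = TRUE)

  list(Gr = Gr, Gz = Gz, invC = invC, heatW = heatW, V = V,
       rhoc_z = rhoc_z, k_z = k_z)
}

#' Assemble a bioheat solver state
#'
#' Builds the grid, acoustic source and face conductances for a stack and
#' transducer, ready for time stepping with [bioheat_step()] or
#' [simulate_heating()].
#'
#' @param stack A [layer_stack()].
#' @param tx A [transducer_spec()].
#' @param dr,dz Radial and axial cell size, m (defaults 0.5 mm).
#' @param solid_dz Axial cell size inside solid (bone) layers, m (default
#'   0.1 mm, resolving the 1 mm bone disc with 10 cells).
#' @param radius Domain radius, m; default 32.5 mm, the internal radius of
#'   the PVC calorimeter ring.
#' @param margin Water backing margin beyond the last interface, m.
#' @param bath Bath temperature, degC, imposed on the outer radius and
#'   distal boundaries (Dirichlet); the transducer face is zero-flux.
#' @param initial Initial temperature, degC.
#' @param face_reflectance Transducer-face energy reflectance for the
#'   acoustic reverberation model.
#' @return An object of class `dia_state`: grid, temperature matrix `T`
#'   (nr x nz, degC), time, and precomputed operator pieces.
#' @export
bioheat_setup <- function(stack, tx = transducer_spec(), dr = 0.5e-3,
                          dz = 0.5e-3, solid_dz = 1e-4, radius = 32.5e-3,
                          margin = 10e-3, bath = 36, initial = 36,
                          face_reflectance = 1) {
  grid <- build_grid(stack, dr = dr, dz = dz, solid_dz = solid_dz,
                     radius = radius, margin = margin)
  th <- build_thermal(grid, stack, tx, face_reflectance)
  structure(
    list(grid = grid, T = matrix(initial, grid$nr, grid$nz), time = 0,
         bath = bath, initial = initial, th = th, stack = stack, tx = tx),
    class = "dia_state"
  )
}

#' Largest stable explicit time step
#'
#' Explicit forward-Euler stability bound computed from the assembled
#' operator: `dt_max = safety / max_i(sum_faces(G) / (rho c V))_i`, with a
#' 0.9 safety factor by default.  On a uniform single-medium grid this
#' reduces to the familiar `0.9 min(dr,dz)^2 / (4 alpha)` bound up to the
#' cylindrical-geometry factors.
#'
#' @param state A [bioheat_setup()] state.
#' @param safety Safety factor in (0, 1].
#' @return Time step, s (may be `Inf` when conduction is disabled).
#' @export
stability_dt <- function(state, safety = 0.9) {
  th <- state$th
  nr <- state$grid$nr
  gsum <- th$Gr[-(nr + 1), , drop = FALSE] + th$Gr[-1, , drop = FALSE] +
    th$Gz[, -(state$grid$nz + 1), drop = FALSE] + th$Gz[, -1, drop = FALSE]
  s <- max(gsum * th$invC)
  if (s <= 0) Inf else safety / s
}

#' Advance the bioheat state by one explicit step
#'
#' Pure-R reference implementation of the finite-volume update; the
#' multi-step kernel used by [simulate_heating()] performs the identical
#' arithmetic in compiled code.  Refuses a time step above the stability
#' bound.
#'
#' @param state A [bioheat_setup()] state.
#' @param dt Time step, s.
#' @return The updated state.
#' @export
bioheat_step <- function(state, dt) {
  stopifnot(inherits(state, "dia_state"))
  bound <- stability_dt(state, safety = 1)
  if (dt > bound * (1 + 1e-12)) {
    abort(sprintf(
      "dt = %g s exceeds the explicit stability bound %g s; reduce dt",
      dt, bound
    ))
  }
  Tm <- state$T
  th <- state$th
  nr <- state$grid$nr
  nz <- state$grid$nz
  bath <- state$bath
  up <- cbind(matrix(NA_real_, nr, 1), Tm[, -nz, drop = FALSE])
  dn <- cbind(Tm[, -1, drop = FALSE], matrix(bath, nr, 1))
  inn <- rbind(matrix(NA_real_, 1, nz), Tm[-nr, , drop = FALSE])
  out <- rbind(Tm[-1, , drop = FALSE], matrix(bath, 1, nz))
  gz_up <- th$Gz[, -(nz + 1), drop = FALSE]
  gz_dn <- th$Gz[, -1, drop = FALSE]
  gr_in <- th$Gr[-(nr + 1), , drop = FALSE]
  gr_out <- th$Gr[-1, , drop = FALSE]
  flux <- gz_up * ifelse(gz_up > 0, up - Tm, 0) +
    gz_dn * (dn - Tm) +
    gr_in * ifelse(gr_in > 0, inn - Tm, 0) +
    gr_out * (out - Tm)
  state$T <- Tm + dt * th$invC * (flux + th$heatW)
  state$time <- state$time + dt
  state
}

# Interpolation weights for a probe at (r, z): bilinear in cell centres, with
# two refinements.  (1) A probe lying exactly on an interior z face between
# unlike media uses the conduction-weighted face temperature
# (k/h)-weighted mean of the two adjacent cells, the consistent estimate of
# the interface temperature where the gradient is discontinuous.  (2) Radii
# inside the first cell centre take the axis cell value (even symmetry).
probe_weights <- function(grid, r, z, k_z) {
  if (r < 0 || r > grid$radius || z < 0 || z > grid$depth) {
    abort(sprintf("probe at (r = %g, z = %g) lies outside the grid", r, z))
  }
  # radial weights
  rc <- grid$rc
  if (r <= rc[1]) {
    ri <- 1L; rw <- 1
  } else if (r >= rc[grid$nr]) {
    ri <- grid$nr; rw <- 1
  } else {
    i <- findInterval(r, rc)
    w <- (r - rc[i]) / (rc[i + 1] - rc[i])
    ri <- c(i, i + 1L); rw <- c(1 - w, w)
  }
  # axial weights
  zf_int <- grid$zf[c(-1, -(grid$nz + 1))]
  on_face <- which(abs(zf_int - z) < 1e-9)
  if (length(on_face)) {
    j <- on_face[1]                       # face between z-cells j and j+1
    c_lo <- k_z[j] / (grid$dzv[j] / 2)
    c_hi <- k_z[j + 1] / (grid$dzv[j + 1] / 2)
    if (c_lo + c_hi == 0) {
      zi <- c(j, j + 1L); zw <- c(0.5, 0.5)
    } else {
      zi <- c(j, j + 1L); zw <- c(c_lo, c_hi) / (c_lo + c_hi)
    }
  } else {
    zc <- grid$zc
    if (z <= zc[1]) {
      zi <- 1L; zw <- 1
    } else if (z >= zc[grid$nz]) {
      zi <- grid$nz; zw <- 1
    } else {
      j <- findInterval(z, zc)
      w <- (z - zc[j]) / (zc[j + 1] - zc[j])
      zi <- c(j, j + 1L); zw <- c(1 - w, w)
    }
  }
  idx <- as.vector(outer(ri, (zi - 1L) * grid$nr, `+`))
  w <- as.vector(outer(rw, zw))
  keep <- w > 0
  list(idx = idx[keep], w = w[keep])
}

#' Read probe temperatures from a state
#'
#' @param state A [bioheat_setup()] state (or the `field` of a simulation).
#' @param probes Tibble with columns `probe`, `r`, `z` (m).
#' @return A tibble `probe`, `temp_c`.
#' @export
probe_temperatures <- function(state, probes = default_probes()) {
  stopifnot(inherits(state, "dia_state"))
  k_z <- state$th$k_z
  temp <- vapply(seq_len(nrow(probes)), function(p) {
    w <- probe_weights(state$grid, probes$r[p], probes$z[p], k_z)
    sum(w$w * state$T[w$idx])
  }, numeric(1))
  tibble::tibble(probe = probes$probe, temp_c = temp)
}

#' Simulate interface heating of a layered phantom
#'
#' Builds the acoustic intensity and heat-source fields once (stationary
#' transducer, continuous mode), then advances the perfusion-free bioheat
#' equation with the explicit finite-volume kernel to `duration`, recording
#' each probe at `sample_every` intervals.  The time step is auto-computed
#' from the stability bound and rounded down so the sampling cadence is an
#' integer number of steps.
#'
#' @inheritParams bioheat_setup
#' @param probes Probe positions, see [default_probes()].
#' @param duration Irradiation time, s; defaults to the transducer record's
#'   duration (120 s).
#' @param dt Time step, s; `NULL` (default) auto-computes from
#'   [stability_dt()].
#' @param sample_every Probe sampling cadence, s.
#' @return An object of class `dia_sim`: `field` (the final `dia_state`),
#'   `series` (tibble `time_s`, `probe`, `temp_c`), `dt`, `n_steps`, and the
#'   run configuration.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_heating(phantom_stack(), duration = 10)
#' probe_endpoints(sim)
#' }
simulate_heating <- function(stack = phantom_stack(), tx = transducer_spec(),
                             probes = default_probes(), duration = tx$duration,
                             dr = 0.5e-3, dz = 0.5e-3, solid_dz = 1e-4,
                             radius = 32.5e-3, margin = 10e-3, bath = 36,
                             initial = 36, dt = NULL, sample_every = 1,
                             face_reflectance = 1) {
  if (duration < 0) abort("duration must be non-negative")
  state <- bioheat_setup(stack, tx, dr = dr, dz = dz, solid_dz = solid_dz,
                         radius = radius, margin = margin, bath = bath,
                         initial = initial, face_reflectance = face_reflectance)
  k_z <- state$th$k_z
  pw <- lapply(seq_len(nrow(probes)), function(p) {
    probe_weights(state$grid, probes$r[p], probes$z[p], k_z)
  })

  if (duration == 0) {
    series <- tibble::tibble(
      time_s = 0,
      probe = probes$probe,
      temp_c = vapply(pw, function(w) sum(w$w * state$T[w$idx]), numeric(1))
    )
    return(structure(
      list(field = state, series = series, dt = NA_real_, n_steps = 0L,
           probes = probes, duration = 0, sample_every = sample_every),
      class = "dia_sim"
    ))
  }

  bound <- stability_dt(state)
  if (is.null(dt)) {
    dt <- min(bound, sample_every)
  } else if (dt > bound / 0.9 * (1 + 1e-12)) {
    abort(sprintf("dt = %g s exceeds the stability bound %g s", dt, bound / 0.9))
  }
  stride <- max(1L, as.integer(ceiling(sample_every / dt - 1e-9)))
  dt <- sample_every / stride
  n_steps <- as.integer(round(duration / dt))

  res <- bioheat_run(
    state$T, state$th$heatW, state$th$invC, state$th$Gr, state$th$Gz,
    state$bath, dt, n_steps, stride,
    probe_i = as.integer(unlist(lapply(pw, `[[`, "idx")) - 1L),
    probe_w = as.numeric(unlist(lapply(pw, `[[`, "w"))),
    probe_off = c(0L, cumsum(vapply(pw, function(w) length(w$idx), integer(1))))
  )
  state$T <- res$T
  state$time <- n_steps * dt
  colnames(res$series) <- probes$probe
  series <- tibble::as_tibble(res$series)
  series$time_s <- res$times
  series <- tidyr::pivot_longer(series, -"time_s", names_to = "probe",
                                values_to = "temp_c")
  structure(
    list(field = state, series = series[order(series$probe, series$time_s), ],
         dt = dt, n_steps = n_steps, probes = probes, duration = duration,
         sample_every = sample_every),
    class = "dia_sim"
  )
}

#' Endpoint temperature of each probe
#'
#' The maximum over the recorded series; with the source on throughout the
#' run and monotone heating this equals the final reading.
#'
#' @param sim A [simulate_heating()] result.
#' @return A tibble `probe`, `temp_c`.
#' @export
probe_endpoints <- function(sim) {
  stopifnot(inherits(sim, "dia_sim"))
  dplyr::summarise(dplyr::group_by(sim$series, .data$probe),
                   temp_c = max(.data$temp_c), .groups = "drop")
}

#' Total enthalpy gain of the domain since the start of the run
#'
#' `sum(rho c V (T - initial))` over all cells, J.  Bounded above by
#' `duty_cycle * acoustic_power * time` (energy conservation: the bath
#' boundaries only remove heat).
#'
#' @param state A `dia_state` (e.g. `sim$field`).
#' @return Enthalpy gain, J.
#' @export
enthalpy_gain <- function(state) {
  stopifnot(inherits(state, "dia_state"))
  rhoc <- matrix(state$th$rhoc_z, state$grid$nr, state$grid$nz, byrow = TRUE)
  sum(rhoc * state$th$V * (state$T - state$initial))
}

#' @export
print.dia_sim <- function(x, ...) {
  cat(sprintf("<bioheat simulation: %s, %g s, dt = %.4g s, %d steps>\n",
              x$field$grid$stack_label, x$duration, x$dt, x$n_steps))
  print(probe_endpoints(x))
  invisible(x)
}

#' @export
tidy.dia_sim <- function(x, ...) x$series

#' @export
glance.dia_sim <- function(x, ...) {
  ep <- probe_endpoints(x)
  tibble::tibble(
    stack = x$field$grid$stack_label,
    duration_s = x$duration, dt_s = x$dt, n_steps = x$n_steps,
    nr = x$field$grid$nr, nz = x$field$grid$nz,
    max_temp_c = max(x$field$T), max_probe_c = max(ep$temp_c),
    enthalpy_gain_j = enthalpy_gain(x$field)
  )
}

#' @export
tidy.dia_state <- function(x, ...) {
  tibble::tibble(
    r = rep(x$grid$rc, times = x$grid$nz),
    z = rep(x$grid$zc, each = x$grid$nr),
    temp_c = as.vector(x$T)
  )
}

#' Interpolate a temperature field at arbitrary points
#'
#' Bilinear interpolation of the cell-centred field (with the same
#' interface-aware axial rule as the probes); used e.g. to compare fields
#' computed on different grids.
#'
#' @param state A `dia_state`.
#' @param r,z Coordinates, m (recycled to equal length).
#' @return Temperatures, degC.
#' @export
field_at <- function(state, r, z) {
  stopifnot(inherits(state, "dia_state"))
  n <- max(length(r), length(z))
  r <- rep_len(r, n)
  z <- rep_len(z, n)
  vapply(seq_len(n), function(i) {
    w <- probe_weights(state$grid, r[i], z[i], state$th$k_z)
    sum(w$w * state$T[w$idx])
  }, numeric(1))
}

#' Export a temperature map as delimited text
#'
#' Tab-separated `(r_m, z_m, temp_c)` grid with a comment header recording
#' the stack, grid spec, time and time step.  Byte-stable for fixed inputs;
#' [read_map()] round-trips the numeric values to full precision.
#'
#' @param sim A [simulate_heating()] result (or a `dia_state`).
#' @param path Output file path.
#' @param dt Time step to record when exporting a bare state.
#' @return `path`, invisibly.
#' @export
export_map <- function(sim, path, dt = NULL) {
  state <- if (inherits(sim, "dia_sim")) sim$field else sim
  stopifnot(inherits(state, "dia_state"))
  dt <- dt %||% if (inherits(sim, "dia_sim")) sim$dt else NA_real_
  g <- state$grid
  df <- tidy.dia_state(state)
  lines <- c(
    "# diatherm temperature map",
    sprintf("# stack: %s", g$stack_label),
    sprintf("# nr: %d", g$nr),
    sprintf("# nz: %d", g$nz),
    sprintf("# dr_m: %.12g", g$dr),
    sprintf("# dt_s: %.12g", if (is.null(dt) || is.na(dt)) NA else dt),
    sprintf("# time_s: %.12g", state$time),
    "r_m\tz_m\ttemp_c",
    sprintf("%.17g\t%.17g\t%.17g", df$r, df$z, df$temp_c)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a temperature map written by [export_map()]
#'
#' @param path File path.
#' @return A tibble `r`, `z`, `temp_c` with the header metadata in attribute
#'   `meta` (named character vector).
#' @export
read_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  meta <- sub("^# *", "", hdr[-1])
  meta <- strsplit(meta, ": ", fixed = TRUE)
  meta <- setNames(
    vapply(meta, function(x) paste(x[-1], collapse = ": "), character(1)),
    vapply(meta, `[[`, character(1), 1)
  )
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.delim(con, sep = "\t", header = TRUE)
  out <- tibble::tibble(r = df$r_m, z = df$z_m, temp_c = df$temp_c)
  attr(out, "meta") <- meta
  out
}
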