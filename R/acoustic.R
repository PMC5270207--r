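# Normal-incidence layered intensity model: forward/backward energy fluxes
# per layer with incoherent (energy) summation of all interface-reflected
# passes, transducer face treated as a reflector of given reflectance.

#' Effective source intensity
#'
#' Spatial-average intensity over the effective radiating area:
#' `power / era`.  With the default calibration (4.18 W, 3.36 cm^2) this is
#' 1.24 W cm^-2 (12 400 W m^-2 to three significant figures).
#'
#' @param power Total acoustic power, W (non-negative).
#' @param era Effective radiating area, m^2 (strictly positive).
#' @return Intensity, W m^-2.
#' @export
#' @examples
#' effective_intensity(4.18, 3.36e-4) / 1e4 # 1.24 W/cm^2
effective_intensity <- function(power, era) {
  if (any(!is.finite(era)) || any(era <= 0)) abort("era must be positive (m^2)")
  if (any(!is.finite(power)) || any(power < 0)) {
    abort("power must be non-negative (W)")
  }
  power / era
}

#' Convert an attenuation coefficient from dB/cm to Np/m
#'
#' Equipment data sheets quote amplitude attenuation in dB cm^-1 (per MHz);
#' the propagation model works in amplitude nepers per metre:
#' `alpha_np = alpha_db * 100 * ln(10) / 20`.
#'
#' @param alpha_db_cm Amplitude attenuation, dB cm^-1 (non-negative; already
#'   multiplied by frequency in MHz if quoted per MHz).
#' @return Amplitude attenuation, Np m^-1.
#' @export
#' @examples
#' db_per_cm_to_neper_per_m(0.5)  # 5.7565 Np/m at 1 MHz for tissue phantom
db_per_cm_to_neper_per_m <- function(alpha_db_cm) {
  if (any(!is.finite(alpha_db_cm)) || any(alpha_db_cm < 0)) {
    abort("attenuation must be non-negative")
  }
  alpha_db_cm * 100 * log(10) / 20
}

# Amplitude attenuation of a material at a given frequency, Np/m.
# Attenuation is treated as linear in frequency.
material_alpha_np <- function(m, frequency) {
  db_per_cm_to_neper_per_m(m$attenuation * frequency / 1e6)
}

#' Energy reflectance of a normal-incidence interface
#'
#' For plane waves at normal incidence between media of characteristic
#' impedances `z1` and `z2`, the fraction of incident energy reflected is
#' `((z2 - z1) / (z2 + z1))^2`; the remainder is transmitted.
#'
#' @param z1,z2 Acoustic impedances, Rayl (strictly positive; `z2 = Inf`
#'   gives the rigid-wall limit 1).
#' @return Energy reflectance in `[0, 1]`.
#' @export
#' @examples
#' z_t <- acoustic_impedance(builtin_material("tissue_phantom"))
#' z_b <- acoustic_impedance(builtin_material("bone_phantom"))
#' normal_energy_reflectance(z_t, z_b) # ~0.259
normal_energy_reflectance <- function(z1, z2) {
  if (any(!is.finite(z1)) || any(z1 <= 0) || any(z2 <= 0) || any(is.na(z2))) {
    abort("impedances must be positive")
  }
  ifelse(is.infinite(z2), 1, ((z2 - z1) / (z2 + z1))^2)
}

# Solve the incoherent two-flux balance of a stack: unknowns are the forward
# flux entering the top of each finite layer (F_1..F_L), the backward flux at
# the bottom of each finite layer (B_1..B_L), and the forward flux entering
# the backing (F_{L+1}).  a_j = exp(-mu_j d_j) is the one-way intensity
# attenuation of layer j; R_i the energy reflectance of interface i; the
# transducer face reflects a fraction `face_reflectance` of the returning
# energy back into layer 1.  The closed-form solve() solution equals the sum
# of the geometric multiple-reflection series.
layered_flux <- function(stack, tx, face_reflectance = 1) {
  stopifnot(inherits(stack, "dia_stack"), inherits(tx, "dia_transducer"))
  if (face_reflectance < 0 || face_reflectance > 1) {
    abort("face_reflectance must lie in [0, 1]")
  }
  i0 <- effective_intensity(tx$acoustic_power, tx$era) * tx$duty_cycle
  L <- length(stack$layers)
  mats <- lapply(stack$layers, `[[`, "material")
  d <- vapply(stack$layers, `[[`, numeric(1), "thickness")
  mu <- vapply(mats, function(m) 2 * material_alpha_np(m, tx$frequency),
               numeric(1))
  a <- exp(-mu * d)
  z <- vapply(mats, acoustic_impedance, numeric(1))
  zb <- acoustic_impedance(stack$backing)
  zn <- c(z, zb)
  R <- normal_energy_reflectance(zn[seq_len(L)], zn[seq_len(L) + 1])
  Tr <- 1 - R

  # unknown order: F_1..F_L, F_backing, B_1..B_L
  n <- 2L * L + 1L
  A <- matrix(0, n, n)
  b <- numeric(n)
  iF <- seq_len(L + 1L)
  iB <- L + 1L + seq_len(L)
  # source + face reflection: F_1 - Rf * a_1 * B_1 = I0
  A[1, iF[1]] <- 1
  A[1, iB[1]] <- -face_reflectance * a[1]
  b[1] <- i0
  row <- 1L
  for (i in seq_len(L)) {
    below_B <- if (i < L) iB[i + 1L] else NA_integer_ # backing carries no B
    a_below <- if (i < L) a[i + 1L] else NA_real_
    # F_{i+1} = T_i a_i F_i + R_i a_{i+1} B_{i+1}
    row <- row + 1L
    A[row, iF[i + 1L]] <- 1
    A[row, iF[i]] <- -Tr[i] * a[i]
    if (i < L) A[row, below_B] <- -R[i] * a_below
    # B_i = R_i a_i F_i + T_i a_{i+1} B_{i+1}
    row <- row + 1L
    A[row, iB[i]] <- 1
    A[row, iF[i]] <- -R[i] * a[i]
    if (i < L) A[row, below_B] <- -Tr[i] * a_below
  }
  x <- solve(A, b)
  list(
    forward = x[iF][seq_len(L)],
    backward = x[iB],
    forward_backing = x[iF][L + 1L],
    mu = mu, d = d, a = a, z_top = c(0, cumsum(d))[seq_len(L)],
    reflectance = R, i0 = i0,
    mu_backing = 2 * material_alpha_np(stack$backing, tx$frequency),
    face_reflectance = face_reflectance
  )
}

#' Per-layer energy fluxes of the multiple-reflection model
#'
#' Exposes the solved forward and backward energy fluxes at the top and
#' bottom of each layer, useful for inspecting how much energy reverberates
#' between an interface and the transducer face.
#'
#' @param stack A [layer_stack()].
#' @param tx A [transducer_spec()].
#' @param face_reflectance Energy reflectance of the transducer face for
#'   returning waves, in `[0, 1]`; default 1 (perfect reflector).
#' @return A tibble with one row per finite layer plus the backing:
#'   `layer`, `material`, `z_top` (m), `forward_top`, `backward_bottom`
#'   (W m^-2; the backing has no backward flux).
#' @export
layer_fluxes <- function(stack, tx = transducer_spec(), face_reflectance = 1) {
  fl <- layered_flux(stack, tx, face_reflectance)
  L <- length(stack$layers)
  tibble::tibble(
    layer = c(seq_len(L), NA_integer_),
    material = c(vapply(stack$layers, function(l) l$material$name, character(1)),
                 stack$backing$name),
    z_top = c(fl$z_top, stack_depth(stack)),
    forward_top = c(fl$forward, fl$forward_backing),
    backward_bottom = c(fl$backward, 0)
  )
}

# Axial intensity (W/m^2) at depths z (m) on the beam axis; z may extend into
# the backing.  Point values (not cell averages).
axial_intensity_values <- function(fl, z, depth) {
  L <- length(fl$d)
  out <- numeric(length(z))
  z_edges <- c(fl$z_top, depth)
  for (j in seq_len(L)) {
    in_layer <- z >= z_edges[j] & z < z_edges[j + 1]
    if (j == L) in_layer <- in_layer | z == depth & FALSE
    zeta <- z[in_layer] - z_edges[j]
    out[in_layer] <- fl$forward[j] * exp(-fl$mu[j] * zeta) +
      fl$backward[j] * exp(-fl$mu[j] * (fl$d[j] - zeta))
  }
  in_back <- z >= depth
  out[in_back] <- fl$forward_backing * exp(-fl$mu_backing * (z[in_back] - depth))
  out
}

#' Steady acoustic intensity field in a layer stack
#'
#' Computes the time-averaged intensity on an axisymmetric (r, z) grid from
#' the normal-incidence multiple-reflection energy model: within the top-hat
#' beam column (radius `sqrt(ERA/pi)`) the axial intensity is the incoherent
#' sum of the forward-attenuated wave and all interface-reflected passes,
#' with the transducer face re-reflecting returning energy; outside the
#' column the intensity is zero.  With a single matched semi-infinite medium
#' the field reduces to the plain attenuation law `I0 * 10^(-alpha_dB z/10)`.
#'
#' @param stack A [layer_stack()].
#' @param tx A [transducer_spec()].
#' @param r,z Numeric vectors of radial and axial node coordinates, m.  `z`
#'   must reach at least the stack depth (the field must cover the stack plus
#'   any backing margin you need).
#' @param face_reflectance Energy reflectance of the transducer face, `[0, 1]`.
#' @return A tibble of class `dia_intensity` with columns `r`, `z`,
#'   `intensity` (W m^-2), one row per node, and attributes `beam_radius`,
#'   `stack_label`, `frequency`.
#' @export
#' @examples
#' tx <- transducer_spec()
#' f <- intensity_field(phantom_stack(), tx, r = 0, z = c(0, 0.01, 0.03))
#' f$intensity / 1e4 # W/cm^2: 1.24 at the face, ~1.10 at 10 mm
intensity_field <- function(stack, tx = transducer_spec(), r, z,
                            face_reflectance = 1) {
  stopifnot(inherits(stack, "dia_stack"))
  depth <- stack_depth(stack)
  if (max(z) < depth) {
    abort(sprintf(
      "grid is shallower than the stack: max(z) = %g m < stack depth %g m",
      max(z), depth
    ))
  }
  if (any(z < 0) || any(r < 0)) abort("r and z must be non-negative")
  fl <- layered_flux(stack, tx, face_reflectance)
  iz <- axial_intensity_values(fl, z, depth)
  rb <- beam_radius(tx)
  grid <- tidyr::expand_grid(r = r, z = z)
  grid$intensity <- ifelse(grid$r <= rb, iz[match(grid$z, z)], 0)
  structure(
    tibble::as_tibble(grid),
    beam_radius = rb,
    stack_label = stack$label,
    frequency = tx$frequency,
    class = c("dia_intensity", class(grid))
  )
}

#' Volumetric heat-source density from an intensity field
#'
#' Plane-wave absorption converts intensity to heat at rate
#' `q = 2 * alpha_Np * I` (W m^-3), with the amplitude attenuation of the
#' local medium evaluated at the transducer frequency.
#'
#' @param field A [intensity_field()] result.
#' @param stack The [layer_stack()] the field was computed for (supplies the
#'   medium at each depth).
#' @param tx The [transducer_spec()] (supplies the frequency).
#' @return The field tibble with an added `q` column (W m^-3), class
#'   `dia_heat_source`.
#' @export
heat_source <- function(field, stack, tx = transducer_spec()) {
  stopifnot(inherits(field, "dia_intensity"), inherits(stack, "dia_stack"))
  depth <- stack_depth(stack)
  edges <- c(0, interface_depths(stack))
  mats <- lapply(stack$layers, `[[`, "material")
  alpha <- vapply(mats, function(m) material_alpha_np(m, tx$frequency),
                  numeric(1))
  alpha_b <- material_alpha_np(stack$backing, tx$frequency)
  idx <- findInterval(field$z, edges, rightmost.closed = FALSE)
  a_here <- ifelse(field$z >= depth, alpha_b,
                   alpha[pmin(pmax(idx, 1L), length(alpha))])
  out <- field
  out$q <- 2 * a_here * out$intensity
  class(out) <- c("dia_heat_source", setdiff(class(field), "dia_intensity"))
  out
}

# Cell-averaged intensity over axial slabs [z1, z2] (both inside one layer or
# the backing), used by the thermal solver so deposited power is exact per
# cell.  Returns W/m^2 averaged over the slab.
slab_mean_intensity <- function(fl, z1, z2, depth) {
  mean_one <- function(zlo, zhi) {
    if (zhi <= depth) {
      j <- findInterval(zlo, c(fl$z_top, depth), rightmost.closed = TRUE)
      j <- min(max(j, 1L), length(fl$d))
      mu <- fl$mu[j]
      zeta1 <- zlo - fl$z_top[j]
      zeta2 <- zhi - fl$z_top[j]
      dz <- zeta2 - zeta1
      if (mu == 0) {
        fl$forward[j] + fl$backward[j]
      } else {
        fwd <- fl$forward[j] * (exp(-mu * zeta1) - exp(-mu * zeta2)) / (mu * dz)
        bwd <- fl$backward[j] *
          (exp(-mu * (fl$d[j] - zeta2)) - exp(-mu * (fl$d[j] - zeta1))) / (mu * dz)
        fwd + bwd
      }
    } else {
      mu <- fl$mu_backing
      zeta1 <- zlo - depth
      zeta2 <- zhi - depth
      if (mu == 0) {
        fl$forward_backing
      } else {
        fl$forward_backing * (exp(-mu * zeta1) - exp(-mu * zeta2)) /
          (mu * (zeta2 - zeta1))
      }
    }
  }
  mapply(mean_one, z1, z2)
}
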