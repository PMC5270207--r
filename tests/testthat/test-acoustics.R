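test_that("effective intensity is power over ERA", {
  expect_equal(signif(effective_intensity(4.18, 3.36e-4) / 1e4, 3), 1.24)
  expect_equal(effective_intensity(0, 3.36e-4), 0)
  expect_equal(effective_intensity(1, 1e-4) / 1e4, 1) # 1 W over 1 cm^2
  expect_error(effective_intensity(1, 0), "era")
  expect_error(effective_intensity(-1, 1e-4), "power")
})

test_that("dB/cm converts to amplitude Np/m by ln(10)/20 per cm", {
  expect_equal(db_per_cm_to_neper_per_m(0.5), 0.5 * 100 * log(10) / 20)
  expect_equal(db_per_cm_to_neper_per_m(0.5), 5.7565, tolerance = 1e-4)
  expect_equal(db_per_cm_to_neper_per_m(0), 0)
  expect_equal(db_per_cm_to_neper_per_m(6.15), 70.80, tolerance = 1e-4)
  expect_error(db_per_cm_to_neper_per_m(-1), "non-negative")
})

test_that("acoustic impedance is the rho*c product", {
  expect_equal(acoustic_impedance(builtin_material("tissue_phantom")),
               1050 * 1540)
  expect_equal(acoustic_impedance(builtin_material("bone_phantom")),
               1700.59 * 2924.31)
  expect_equal(acoustic_impedance(material("unit", 1, 1, 0, 1, 1)), 1)
})

test_that("normal-incidence energy reflectance follows the impedance mismatch", {
  z_t <- 1050 * 1540
  z_b <- 1700.59 * 2924.31
  expect_equal(normal_energy_reflectance(z_t, z_t), 0)
  expect_equal(normal_energy_reflectance(z_t, z_b),
               ((z_b - z_t) / (z_b + z_t))^2)
  expect_equal(normal_energy_reflectance(z_t, z_b), 0.2594, tolerance = 5e-4)
  expect_equal(normal_energy_reflectance(z_t, Inf), 1) # rigid wall
  # reflectance + transmittance = 1 across random impedance pairs
  withr::with_seed(7, {
    z1 <- exp(runif(50, 10, 17))
    z2 <- exp(runif(50, 10, 17))
    r <- normal_energy_reflectance(z1, z2)
    expect_true(all(abs(r + (1 - r) - 1) < 1e-12))
    expect_true(all(r >= 0 & r <= 1))
  })
  expect_error(normal_energy_reflectance(0, 1), "positive")
})

test_that("axial intensity reduces to the attenuation law without contrasts", {
  tissue <- builtin_material("tissue_phantom")
  # matched backing: single semi-infinite medium, no reflections anywhere
  s <- layer_stack(layer(tissue, 30e-3), backing = tissue, label = "matched")
  tx <- transducer_spec()
  z <- seq(0, 0.04, by = 1e-3)
  f <- intensity_field(s, tx, r = 0, z = z)
  i0 <- effective_intensity(tx$acoustic_power, tx$era)
  expect_equal(f$intensity, i0 * 10^(-0.5 * z * 100 / 10), tolerance = 1e-12)
  expect_true(all(diff(f$intensity) < 0)) # strictly decreasing for alpha > 0

  # zero attenuation, no contrast: uniform column at I0
  lossless <- material("lossless", 1050, 1540, 0, 3800, 0.58)
  s2 <- layer_stack(layer(lossless, 30e-3), backing = lossless)
  f2 <- intensity_field(s2, tx, r = 0, z = z)
  expect_equal(f2$intensity, rep(i0, length(z)))
})

test_that("the default no-bone stack is nearly matched at 10 mm", {
  f <- intensity_field(phantom_stack(), transducer_spec(), r = 0,
                       z = c(0.01, 0.03))
  # tissue/tissue interface is matched; only the faint tissue/water echo adds
  expect_equal(f$intensity[f$z == 0.01] / 1e4, 1.24 * 10^(-0.05),
               tolerance = 5e-3)
})

test_that("beam is a top-hat column of radius sqrt(ERA/pi)", {
  tx <- transducer_spec()
  rb <- beam_radius(tx)
  f <- intensity_field(phantom_stack(), tx,
                       r = c(0, rb * 0.99, rb * 1.01, 0.03), z = c(0, 0.03))
  inside <- f$r <= rb
  expect_true(all(f$intensity[inside] > 0))
  expect_true(all(f$intensity[!inside] == 0))
  # on-axis surface intensity carries at least the source intensity
  expect_gte(f$intensity[f$r == 0 & f$z == 0],
             effective_intensity(tx$acoustic_power, tx$era))
})

test_that("reflected energy raises the intensity above the bone", {
  tx <- transducer_spec()
  zq <- 0.0299
  with_bone <- intensity_field(phantom_stack(bone = TRUE), tx, r = 0,
                               z = c(zq, 0.031))
  matched <- effective_intensity(tx$acoustic_power, tx$era) *
    10^(-0.5 * zq * 100 / 10)
  expect_gt(with_bone$intensity[with_bone$z == zq], matched)
})

test_that("grid shallower than the stack is refused", {
  expect_error(
    intensity_field(phantom_stack(bone = TRUE), transducer_spec(),
                    r = 0, z = c(0, 0.02)),
    "shallower"
  )
})

test_that("closed-form flux solution equals explicit pass summation", {
  k <- oracle_bone_stack_constants()
  oracle <- flux_pass_sum(k$i0, k$mu, k$d, k$refl, k$face_r, n_pass = 1000)
  got <- layer_fluxes(phantom_stack(bone = TRUE), transducer_spec())
  expect_equal(got$forward_top[1:3], oracle$forward, tolerance = 1e-10)
  expect_equal(got$backward_bottom[1:3], oracle$backward, tolerance = 1e-10)
  expect_equal(got$forward_top[4], oracle$forward_backing, tolerance = 1e-10)
})

test_that("the reflection series is converged by 50 passes", {
  k <- oracle_bone_stack_constants()
  q50 <- column_absorbed(flux_pass_sum(k$i0, k$mu, k$d, k$refl, 1, 50),
                         k$mu, k$d)
  q1000 <- column_absorbed(flux_pass_sum(k$i0, k$mu, k$d, k$refl, 1, 1000),
                           k$mu, k$d)
  expect_lt(abs(q50 - q1000) / q1000, 1e-6)
})

test_that("heat source is 2 alpha I in the local medium", {
  tx <- transducer_spec()
  stack <- phantom_stack(bone = TRUE)
  f <- intensity_field(stack, tx, r = 0, z = c(0, 0.005, 0.0305, 0.035))
  q <- heat_source(f, stack, tx)
  a_t <- db_per_cm_to_neper_per_m(0.5)
  a_b <- db_per_cm_to_neper_per_m(6.15)
  a_w <- db_per_cm_to_neper_per_m(0.0022)
  expect_equal(q$q[1], 2 * a_t * f$intensity[1])
  expect_equal(q$q[3], 2 * a_b * f$intensity[3]) # inside the bone disc
  expect_equal(q$q[4], 2 * a_w * f$intensity[4]) # water: q ~ 0
  expect_lt(q$q[4] / q$q[1], 1e-2)

  # without reflecting interfaces the face value is the closed form 2 alpha I0
  tissue <- builtin_material("tissue_phantom")
  matched <- layer_stack(layer(tissue, 30e-3), backing = tissue)
  qm <- heat_source(intensity_field(matched, tx, r = 0, z = c(0, 0.03)),
                    matched, tx)
  expect_equal(qm$q[1], 2 * a_t * 12400, tolerance = 0.005)
  expect_equal(qm$q[1], 1.428e5, tolerance = 0.005)
})

test_that("energy is conserved at every interface of the flux solution", {
  # absorbed + transmitted + re-emitted toward the face accounts for I0
  k <- oracle_bone_stack_constants()
  fl <- flux_pass_sum(k$i0, k$mu, k$d, k$refl, 1, 2000)
  absorbed <- column_absorbed(fl, k$mu, k$d)
  transmitted <- fl$forward_backing
  expect_equal(absorbed + transmitted, k$i0, tolerance = 1e-9)
})
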