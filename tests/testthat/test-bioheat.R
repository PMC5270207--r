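# Small grids keep the solver unit tests fast; the full-resolution runs live
# in the acceptance suite.
small_args <- list(dr = 2e-3, dz = 2e-3, solid_dz = 2.5e-4, radius = 20e-3,
                   margin = 6e-3)

test_that("uniform bath with no source is a discrete equilibrium", {
  lossless <- material("quiet", 1050, 1540, 0, 3800, 0.58)
  s <- layer_stack(layer(lossless, 30e-3), backing = lossless)
  st <- do.call(bioheat_setup, c(list(s, transducer_spec(acoustic_power = 0)),
                                small_args))
  st1 <- bioheat_step(st, stability_dt(st))
  expect_equal(st1$T, st$T) # stays 36 degC everywhere
  sim <- do.call(simulate_heating,
                 c(list(s, transducer_spec(acoustic_power = 0), duration = 5),
                   small_args))
  expect_true(all(abs(sim$series$temp_c - 36) < 1e-12))
})

test_that("adiabatic heating follows dT = q dt / (rho c)", {
  insulated <- material("adiabatic", 1050, 1540, 0.5, 3800, 0)
  s <- layer_stack(layer(insulated, 30e-3), backing = insulated)
  st <- bioheat_setup(s, transducer_spec(), dr = 1e-3, dz = 1e-3,
                      radius = 12e-3, margin = 2e-3)
  expect_equal(stability_dt(st), Inf) # no conduction, no stability limit
  st1 <- bioheat_step(st, 1)
  # first on-axis cell: q = 2 alpha I0 (up to the slab average), rho c known
  dT <- st1$T[1, 1] - 36
  q0 <- 2 * db_per_cm_to_neper_per_m(0.5) * effective_intensity(4.18, 3.36e-4)
  expect_equal(dT, q0 / (1050 * 3800), tolerance = 0.01)
  expect_equal(dT, 0.0358, tolerance = 0.01)
  # outside the beam column nothing heats
  expect_equal(st1$T[st$grid$nr, 1], 36)
})

test_that("a hot interior spike relaxes monotonically (maximum principle)", {
  tissue <- builtin_material("tissue_phantom")
  s <- layer_stack(layer(tissue, 30e-3), backing = tissue)
  st <- do.call(bioheat_setup, c(list(s, transducer_spec(acoustic_power = 0)),
                                small_args))
  st$T[3, 5] <- 50
  dt <- stability_dt(st)
  peak <- max(st$T)
  for (i in 1:25) {
    st <- bioheat_step(st, dt)
    expect_lt(max(st$T), peak)
    expect_gte(min(st$T), 36 - 1e-12) # never undershoots the bath
    peak <- max(st$T)
  }
})

test_that("time steps above the stability bound are refused with the bound", {
  st <- do.call(bioheat_setup, c(list(phantom_stack(), transducer_spec()),
                                small_args))
  bound <- stability_dt(st, safety = 1)
  expect_error(bioheat_step(st, bound * 1.2), "stability bound")
  expect_s3_class(bioheat_step(st, bound * 0.9), "dia_state")
})

test_that("the compiled kernel reproduces the reference R stepper", {
  st <- do.call(bioheat_setup, c(list(phantom_stack(bone = TRUE),
                                      transducer_spec()), small_args))
  dt <- stability_dt(st)
  r_state <- st
  for (i in 1:7) r_state <- bioheat_step(r_state, dt)
  res <- diatherm:::bioheat_run(
    st$T, st$th$heatW, st$th$invC, st$th$Gr, st$th$Gz, st$bath, dt,
    n_steps = 7L, sample_stride = 0L,
    probe_i = integer(0), probe_w = numeric(0), probe_off = 0L
  )
  expect_equal(res$T, r_state$T, tolerance = 1e-13)
})

test_that("zero duration reads the initial bath temperature everywhere", {
  sim <- do.call(simulate_heating, c(list(phantom_stack(), duration = 0),
                                     small_args))
  expect_equal(unique(sim$series$temp_c), 36)
  expect_equal(nrow(sim$series), 6)
})

test_that("probes outside the grid are refused", {
  expect_error(
    do.call(simulate_heating,
            c(list(phantom_stack(),
                   probes = tibble::tibble(probe = "bad", r = 0, z = 1)),
              small_args)),
    "outside the grid"
  )
})

test_that("on-axis probes heat monotonically while the source is on", {
  sim <- do.call(simulate_heating, c(list(phantom_stack(bone = TRUE),
                                          duration = 20), small_args))
  for (p in c("TP2", "TP5")) {
    series <- sim$series$temp_c[sim$series$probe == p]
    expect_true(all(diff(series) > -1e-12))
  }
  # endpoint = maximum over the series under monotone heating
  ep <- probe_endpoints(sim)
  final <- dplyr::filter(sim$series, time_s == max(time_s))
  expect_equal(ep$temp_c[order(ep$probe)], final$temp_c[order(final$probe)])
})

test_that("mirrored probes read identical temperatures", {
  probes <- tibble::tibble(
    probe = c("L", "C", "R"),
    r = c(10e-3, 0, 10e-3),
    z = c(10e-3, 10e-3, 10e-3)
  )
  sim <- do.call(simulate_heating, c(list(phantom_stack(), probes = probes,
                                          duration = 10), small_args))
  ep <- probe_endpoints(sim)
  expect_equal(ep$temp_c[ep$probe == "L"], ep$temp_c[ep$probe == "R"])
})

test_that("enthalpy gain never exceeds the emitted acoustic energy", {
  tx <- transducer_spec()
  sim <- do.call(simulate_heating, c(list(phantom_stack(bone = TRUE), tx,
                                          duration = 30), small_args))
  expect_lt(enthalpy_gain(sim$field),
            tx$duty_cycle * tx$acoustic_power * 30)
  expect_gt(enthalpy_gain(sim$field), 0)
})

test_that("exported maps are byte-stable and round-trip numerically", {
  sim <- do.call(simulate_heating, c(list(phantom_stack(), duration = 5),
                                     small_args))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  export_map(sim, f1)
  export_map(sim, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_map(f1)
  expect_equal(back$temp_c, tidy(sim$field)$temp_c, tolerance = 1e-12)
  expect_equal(back$r, tidy(sim$field)$r, tolerance = 1e-12)
  meta <- attr(back, "meta")
  expect_equal(meta[["stack"]], "without_bone")
  expect_equal(as.numeric(meta[["dt_s"]]), sim$dt)
  expect_true(all(c("nr", "nz", "dr_m", "time_s") %in% names(meta)))
})

test_that("probe series export is wide, deterministic delimited text", {
  sim <- do.call(simulate_heating, c(list(phantom_stack(), duration = 3),
                                     small_args))
  f <- withr::local_tempfile()
  write_probe_series(sim, f)
  got <- utils::read.delim(f, comment.char = "#")
  expect_equal(names(got), c("time_s", paste0("TP", 1:6)))
  expect_equal(nrow(got), 4) # t = 0..3 s at 1 s cadence
  expect_equal(got$TP2[1], 36)
})
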