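# Independent oracles used across the suite.  These are deliberately written
# from first principles (and kept dumb) so they do not share code with the
# package implementations they check.

# Explicit pass-by-pass summation of the multiple-reflection series for a
# stack of finite layers over a semi-infinite backing, normal incidence,
# incoherent energy bookkeeping.  Each sweep of the fixed-point loop
# propagates the wave field through one more reflection pass, so `n_pass`
# sweeps equal summing the first `n_pass` reflected passes.
flux_pass_sum <- function(i0, mu, d, refl, face_r, n_pass) {
  a <- exp(-mu * d)
  L <- length(d)
  tr <- 1 - refl
  fwd <- numeric(L + 1)
  bwd <- numeric(L)
  for (pass in seq_len(n_pass)) {
    fwd_new <- fwd
    bwd_new <- bwd
    fwd_new[1] <- i0 + face_r * a[1] * bwd[1]
    for (i in seq_len(L)) {
      below <- if (i < L) a[i + 1] * bwd[i + 1] else 0
      fwd_new[i + 1] <- tr[i] * a[i] * fwd[i] + refl[i] * below
      bwd_new[i] <- refl[i] * a[i] * fwd[i] + tr[i] * below
    }
    fwd <- fwd_new
    bwd <- bwd_new
  }
  list(forward = fwd[seq_len(L)], backward = bwd,
       forward_backing = fwd[L + 1])
}

# Column-integrated absorbed power per unit area implied by a pass-sum flux
# solution (layers only): absorbed = sum_j (in - out) over both directions.
column_absorbed <- function(fl, mu, d) {
  a <- exp(-mu * d)
  sum(fl$forward * (1 - a) + fl$backward * (1 - a))
}

# Two-sided Mann-Whitney p by complete enumeration of group assignments,
# midranks for ties, extremity measured about the null mean of U.
mw_enumeration_p <- function(x, y) {
  pool <- c(x, y)
  n_x <- length(x)
  u_of <- function(xx, yy) {
    r <- rank(c(xx, yy))
    sum(r[seq_along(xx)]) - length(xx) * (length(xx) + 1) / 2
  }
  u0 <- u_of(x, y)
  mid <- n_x * length(y) / 2
  cmb <- utils::combn(length(pool), n_x)
  us <- apply(cmb, 2, function(ix) u_of(pool[ix], pool[-ix]))
  mean(abs(us - mid) >= abs(u0 - mid) - 1e-9)
}

# The default-stack constants, derived in the test rather than taken from
# the package, for use by the flux oracle.
oracle_bone_stack_constants <- function(face_r = 1) {
  np <- function(db_cm) db_cm * 100 * log(10) / 20
  z_t <- 1050 * 1540
  z_b <- 1700.59 * 2924.31
  z_w <- 994 * 1523
  r_of <- function(z1, z2) ((z2 - z1) / (z2 + z1))^2
  list(
    i0 = 4.18 / 3.36e-4,
    mu = 2 * np(c(0.5, 0.5, 6.15)),
    d = c(10e-3, 20e-3, 1e-3),
    refl = c(0, r_of(z_t, z_b), r_of(z_b, z_w)),
    face_r = face_r
  )
}
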