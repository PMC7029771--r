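test_that("eigen rates satisfy their defining identities", {
  tr <- std_tracer()

  # I = 0: discriminant collapses, KF/KS are just the two relaxation rates
  er0 <- eigen_rates(tr, compound_spec(1e6, 1e-2), I = 0)
  expect_equal(er0$KA, 2.56e6 * 12.5e-9 + 1.67e-3)
  expect_equal(er0$KB, 1e-2)
  expect_equal(er0$KF, max(er0$KA, er0$KB))
  expect_equal(er0$KS, min(er0$KA, er0$KB), tolerance = 1e-12)

  # hand-derived quadratic roots for the reference competition condition
  er <- eigen_rates(tr, compound_spec(1e6, 1e-2), I = 250e-9)
  expect_equal(er$KF, 0.291079, tolerance = 1e-5)
  expect_equal(er$KS, 0.00259105, tolerance = 1e-5)
  expect_equal(er$KF * er$KS, 7.542e-4, tolerance = 1e-6)

  # algebraic invariants over random parameter sets
  set.seed(11)
  for (i in 1:50) {
    cp <- compound_spec(10^runif(1, 4, 9), 10^runif(1, -5, -1))
    I <- 10^runif(1, -10, -5)
    e <- eigen_rates(tr, cp, I)
    expect_gte(e$KF, e$KS)
    expect_equal(e$KF + e$KS, e$KA + e$KB, tolerance = 1e-12)
    expect_equal(e$KF * e$KS,
                 tr$k1 * tr$L * cp$k4 + tr$k2 * cp$k3 * I + tr$k2 * cp$k4,
                 tolerance = 1e-12)
  }

  expect_error(eigen_rates(tr, compound_spec(1e6, 1e-2), I = -1), "I")
  expect_error(tracer_spec(12.5e-9, -1, 1e-3), "k1")
})

test_that("competition trace reduces to mono-exponential association at I = 0", {
  tr <- std_tracer()
  t <- seq(0, 400, 10)
  y <- specific_binding_trace(t, tr, compound_spec(1e6, 1e-2), I = 0)
  expect_equal(y, mono_association_trace(t, tr$L, tr$k1, tr$k2), tolerance = 1e-12)
  expect_equal(y[1], 0)
})

test_that("competition trace matches ODE oracle and its equilibrium limit", {
  tr <- std_tracer()
  cp <- compound_spec(1e6, 1e-2)
  t <- seq(10, 400, 10)
  closed <- specific_binding_trace(t, tr, cp, I = 250e-9)
  ode <- mechanism_ode_trace(t, tr, cp, I = 250e-9)
  expect_lt(max(rel_dev(closed, ode)), 1e-6)

  # t -> Inf limit equals the competitive isotherm
  er <- eigen_rates(tr, cp, 250e-9)
  y_inf <- specific_binding_trace(50 / er$KS, tr, cp, 250e-9)
  occ <- equilibrium_competition_occupancy(tr, cp$KD2, 250e-9)
  expect_equal(y_inf, occ, tolerance = 1e-4)

  # property: closed form vs ODE across random parameter sets
  set.seed(23)
  for (i in 1:20) {
    cp2 <- compound_spec(10^runif(1, 4, 9), 10^runif(1, -5, -1))
    I <- 10^runif(1, -10, -5)
    a <- specific_binding_trace(t, tr, cp2, I)
    b <- mechanism_ode_trace(t, tr, cp2, I)
    expect_lt(max(abs(a - b)) / max(abs(b)), 1e-5)
  }
})

test_that("normalised model is the vehicle-relative inversion of the raw model", {
  tr <- std_tracer()
  cp <- compound_spec(1e6, 1e-2)
  t <- seq(0, 400, 10)
  yhat <- normalized_compound_binding_trace(t, tr, cp, I = 250e-9)
  expect_identical(yhat[1], 0)  # defined piecewise at the origin
  expect_true(all(yhat >= 0 & yhat <= 100))

  raw <- specific_binding_trace(t[-1], tr, cp, I = 250e-9)
  veh <- specific_binding_trace(t[-1], tr, cp, I = 0)
  expect_equal(yhat[-1], 100 * (1 - raw / veh), tolerance = 1e-9)

  # no compound, no compound binding
  expect_equal(normalized_compound_binding_trace(t, tr, cp, I = 0),
               rep(0, length(t)))
})

test_that("percent-equilibrium formula behaves and reproduces the 26% -> 97% case", {
  expect_equal(percent_equilibrium(0, 1e6, 12.5e-9, 1e-3), 0)
  p <- percent_equilibrium(c(10, 100, 1000), 1e6, 12.5e-9, 1e-3)
  expect_true(all(diff(p) > 0))

  # observed rate solved from 26% at 400 s, evaluated at 4,680 s
  kobs <- -log(1 - 0.26) / 400
  expect_equal(percent_equilibrium(4680, kon = kobs, L = 1, koff = 1e-300),
               97.0487, tolerance = 1e-4)

  # reference tracer is essentially equilibrated within 400 s
  expect_gt(percent_equilibrium(400, 2.56e6, 12.5e-9, 1.67e-3), 99.999)

  # at I = 0 the formula is exactly 100 * B(t)/B(Inf) of the association model
  t <- seq(10, 400, 10)
  b <- mono_association_trace(t, 12.5e-9, 2.56e6, 1.67e-3)
  b_inf <- 12.5e-9 / (12.5e-9 + 1.67e-3 / 2.56e6)
  expect_equal(percent_equilibrium(t, 2.56e6, 12.5e-9, 1.67e-3),
               100 * b / b_inf, tolerance = 1e-12)

  expect_error(percent_equilibrium(-1, 1e6, 1e-9, 1e-3))
})

test_that("association and chase traces obey their closed-form identities", {
  t <- seq(0, 2400, 10)
  # half-life identity and half-saturation
  kobs <- 1e6 * 12.5e-9 + 1e-3
  plateau <- 12.5e-9 / (12.5e-9 + 1e-3 / 1e6)
  expect_equal(mono_association_trace(log(2) / kobs, 12.5e-9, 1e6, 1e-3),
               plateau / 2, tolerance = 1e-12)
  KD <- 1e-3 / 1e6
  expect_equal(mono_association_trace(1e9, KD, 1e6, 1e-3), 0.5, tolerance = 1e-6)

  y <- association_then_dissociation_trace(t, 1200, 12.5e-9, 1e6, 1e-3)
  # continuity at the chase point and strict decay after it
  expect_equal(y[t == 1200],
               mono_association_trace(1200, 12.5e-9, 1e6, 1e-3))
  post <- y[t > 1200]
  expect_true(all(diff(post) < 0))
  # koff = 0: flat after chase
  yf <- association_then_dissociation_trace(t, 1200, 12.5e-9, 1e6, 1e-300)
  expect_equal(diff(yf[t >= 1200]), rep(0, sum(t > 1200)), tolerance = 1e-9)
  # dissociation slope on log scale is independent of L
  y10 <- association_then_dissociation_trace(t, 1200, 125e-9, 1e6, 1e-3)
  s1 <- diff(log(y[t > 1200]))
  s10 <- diff(log(y10[t > 1200]))
  expect_equal(s1, s10, tolerance = 1e-9)
  expect_error(association_then_dissociation_trace(t, -5, 12.5e-9, 1e6, 1e-3),
               "t_chase")
})

test_that("signal drift is a multiplicative mono-exponential decay", {
  t <- seq(0, 400, 10)
  s <- rep(100, length(t))
  expect_identical(apply_signal_drift(s, t, drift_params(0)), s)
  d <- apply_signal_drift(s, t, drift_params(0.0028))
  expect_equal(d[t == 400], 100 * exp(-1.12), tolerance = 1e-12)
  expect_equal(100 * exp(-1.12), 32.62, tolerance = 1e-3)
  expect_error(apply_signal_drift(s[-1], t, drift_params(0.001)), "length")
})

test_that("equilibrium competition occupancy follows the competitive isotherm", {
  tr <- tracer_spec(L = 1e-9, k1 = 1e6, k2 = 1e-3)  # KD1 = 1 nM = L
  expect_equal(equilibrium_competition_occupancy(tr, 1e-9, 0), 0.5)
  occ <- vapply(10^seq(-10, -5), function(I)
    equilibrium_competition_occupancy(tr, 1e-9, I), numeric(1))
  expect_true(all(diff(occ) < 0))
  expect_lt(equilibrium_competition_occupancy(tr, 1e-9, 1), 1e-6)
  # Cheng-Prusoff point: I = KD2 (1 + L/KD1) halves the I = 0 occupancy
  tr2 <- std_tracer()
  KD2 <- 1e-8
  I50 <- KD2 * (1 + tr2$L / tr2$KD1)
  expect_equal(equilibrium_competition_occupancy(tr2, KD2, I50),
               equilibrium_competition_occupancy(tr2, KD2, 0) / 2,
               tolerance = 1e-12)
})

test_that("ODE mechanisms: irreversible absorbs, induced fit nests the 1:1 model", {
  tr <- std_tracer()
  t <- seq(10, 400, 10)

  irr <- compound_spec(1e6, 0, mechanism = "irreversible")
  y_end <- mechanism_ode_trace(c(1e6), tr, irr, I = 250e-9)
  expect_lt(y_end, 1e-4)  # absorbing state: tracer fully displaced eventually

  indu0 <- compound_spec(1e6, 1e-2, mechanism = "induced-fit",
                         k_iso_fwd = 0, k_iso_rev = 0)
  rev <- compound_spec(1e6, 1e-2)
  expect_equal(mechanism_ode_trace(t, tr, indu0, 250e-9),
               mechanism_ode_trace(t, tr, rev, 250e-9), tolerance = 1e-8)

  # genuine induced fit deepens apparent inhibition at long times
  indu <- compound_spec(1e6, 1e-2, mechanism = "induced-fit",
                        k_iso_fwd = 1e-2, k_iso_rev = 1e-3)
  expect_lt(mechanism_ode_trace(3600, tr, indu, 250e-9),
            mechanism_ode_trace(3600, tr, rev, 250e-9))
})

test_that("degenerate KF ~ KS inputs produce finite output near the exact limit", {
  tr <- std_tracer()
  KA <- tr$k1 * tr$L + tr$k2
  t <- seq(0, 400, 10)

  # I = 0 with k4 = KA: both relaxation rates coincide exactly
  cp <- compound_spec(1e6, KA)
  y <- specific_binding_trace(t, tr, cp, I = 0)
  expect_true(all(is.finite(y)))
  expect_equal(y, mono_association_trace(t, tr$L, tr$k1, tr$k2), tolerance = 1e-6)

  # vanishing I with KB = KA drives |KF - KS|/KF below 1e-10: the
  # epsilon-perturbed branch must stay finite and match the I -> 0 limit
  I_tiny <- 1e-30
  cp2 <- compound_spec(1e6, KA - 1e6 * I_tiny)
  er <- eigen_rates(tr, cp2, I_tiny)
  expect_lt(er$Diff / er$KF, 1e-10)
  y2 <- specific_binding_trace(t, tr, cp2, I_tiny)
  expect_true(all(is.finite(y2)))
  expect_equal(y2, mono_association_trace(t, tr$L, tr$k1, tr$k2), tolerance = 1e-6)
})
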