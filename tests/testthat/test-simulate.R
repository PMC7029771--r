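test_that("time grid matches the design", {
  expect_equal(build_time_grid(assay_design(400, 10)), seq(10, 400, 10))
  expect_length(build_time_grid(assay_design(400, 1)), 400)
  expect_length(build_time_grid(assay_design(3600, 10)), 360)
  expect_equal(build_time_grid(assay_design(400, 10, include_t0 = TRUE))[1], 0)
  expect_error(assay_design(5, 10), "interval")
  expect_error(assay_design(400, 10, dose_series = c(2.5e-9)), "vehicle")
})

test_that("zero-noise simulation is exactly the deterministic model", {
  tr <- std_tracer()
  cp <- compound_spec(1e6, 1e-2)
  ts <- simulate_kpca(std_design(), tr, cp, noise_model(0))
  t <- build_time_grid(std_design())
  for (dose in c(2.5e-9, 250e-9)) {
    id <- ts$data$trace_id[ts$data$dose_M == dose & ts$data$role == "dose"][1]
    got <- ts$data$signal[ts$data$trace_id == id]
    expect_equal(got, specific_binding_trace(t, tr, cp, dose), tolerance = 1e-15)
  }
})

test_that("simulation is bitwise reproducible under a fixed seed", {
  tr <- std_tracer(); cp <- compound_spec(1e6, 1e-2)
  a <- simulate_kpca(std_design(), tr, cp, noise_model(0.01), seed = 123)
  b <- simulate_kpca(std_design(), tr, cp, noise_model(0.01), seed = 123)
  expect_identical(a$data, b$data)
  c <- simulate_kpca(std_design(), tr, cp, noise_model(0.01), seed = 124)
  expect_false(identical(a$data$signal, c$data$signal))
  # counter-derived sub-seeds are stable regardless of how many are drawn
  expect_identical(derive_seed(99, 7), derive_seed(99, 7))
  expect_false(derive_seed(99, 7) == derive_seed(99, 8))
  expect_true(derive_seed(2^30, 2^20) < 2^31)
})

test_that("perturbed generation equals unperturbed generation with scaled truth", {
  tr <- std_tracer(); cp <- compound_spec(1e6, 1e-2)
  pert <- perturbation_spec("compound_conc_all_wells", factor = 1.4)
  ts_p <- simulate_kpca(std_design(), tr, cp, noise_model(0), perturbation = pert)
  dsn_scaled <- assay_design(400, 10, dose_series = c(0, 1.4 * c(2.5e-9, 25e-9, 250e-9, 2500e-9)))
  ts_s <- simulate_kpca(dsn_scaled, tr, cp, noise_model(0))
  expect_equal(ts_p$data$signal[ts_p$data$role == "dose"],
               ts_s$data$signal[ts_s$data$role == "dose"], tolerance = 1e-15)
  # nominal metadata still carries the unperturbed doses
  expect_equal(ts_p$metadata$doses_nominal, c(2.5e-9, 25e-9, 250e-9, 2500e-9))
  # single-well kind perturbs exactly one dose
  pert1 <- perturbation_spec("compound_conc_single_well", factor = 2)
  ts_1 <- simulate_kpca(std_design(), tr, cp, noise_model(0), perturbation = pert1)
  expect_equal(sum(ts_1$metadata$doses_true != ts_1$metadata$doses_nominal), 1)
})

test_that("normalisation maps controls to 0/100, matches the closed form, cancels drift", {
  tr <- std_tracer(); cp <- compound_spec(1e6, 1e-2)
  ts <- simulate_kpca(std_design(), tr, cp, noise_model(0))
  tsn <- normalize_traces(ts)
  t <- build_time_grid(std_design())
  for (dose in c(25e-9, 2500e-9)) {
    id <- tsn$data$trace_id[tsn$data$dose_M == dose][1]
    expect_equal(tsn$data$signal[tsn$data$trace_id == id],
                 normalized_compound_binding_trace(t, tr, cp, dose),
                 tolerance = 1e-9)
  }
  # vehicle maps to 0% compound binding, background to 100%
  veh <- ts$data$signal[ts$data$trace_id == "vehicle_01"]
  bg <- ts$data$signal[ts$data$trace_id == "background_01"]
  expect_equal(100 * (1 - (veh - bg) / (veh - bg)), rep(0, length(t)))

  # common multiplicative drift cancels in the ratio
  tsd <- drift_trace_set(ts, 0.0028)
  tsdn <- normalize_traces(tsd)
  expect_equal(tsdn$data$signal, tsn$data$signal, tolerance = 1e-9)

  # re-normalising is refused, not silently applied
  expect_error(normalize_traces(tsn), "already normalised")
})

test_that("Monte Carlo means converge to the noiseless trace", {
  tr <- std_tracer(); cp <- compound_spec(1e6, 1e-2)
  dsn <- assay_design(100, 25)  # 4 time points keeps this cheap
  noiseless <- simulate_kpca(dsn, tr, cp, noise_model(0))
  truth <- noiseless$data$signal[noiseless$data$trace_id == "dose_03"]
  n <- 400; sdf <- 0.05
  sims <- vapply(seq_len(n), function(r) {
    ts <- simulate_kpca(dsn, tr, cp, noise_model(sdf), seed = derive_seed(5, r))
    ts$data$signal[ts$data$trace_id == "dose_03"]
  }, numeric(4))
  win <- tr$L / (tr$L + tr$KD1)
  tol <- 3 * (sdf * win) / sqrt(n)
  expect_true(all(abs(rowMeans(sims) - truth) < tol))
})

test_that("ePCA endpoint matches the kinetic model and the equilibrium isotherm", {
  tr <- std_tracer(); cp <- compound_spec(1e6, 1e-2)
  doses <- c(0, 10^seq(-11, -6, 1))
  dr_inf <- simulate_epca(tr, cp, 1e9, doses, noise_model(0))
  occ0 <- equilibrium_competition_occupancy(tr, cp$KD2, 0)
  expected <- vapply(doses, function(I)
    100 * equilibrium_competition_occupancy(tr, cp$KD2, I) / occ0, numeric(1))
  expect_equal(dr_inf$response_pct, expected, tolerance = 1e-6)
  expect_equal(dr_inf$response_pct[doses == 0], 100, tolerance = 1e-9)
})

test_that("tracer plates reproduce association and chase models", {
  dsn <- assay_design(400, 10)
  Ls <- c(5e-9, 12.5e-9, 50e-9)
  tsa <- simulate_tracer_plate("association", 1e6, 1e-3, Ls, design = dsn,
                               noise = noise_model(0))
  t <- build_time_grid(dsn)
  expect_equal(tsa$data$signal[tsa$data$trace_id == "L_02"],
               mono_association_trace(t, 12.5e-9, 1e6, 1e-3), tolerance = 1e-15)

  # fast-dissociating tracer: post-chase signal collapses within ~40 s
  tsc <- simulate_tracer_plate("association_then_dissociation", 1e6, 0.1, Ls,
                               t_chase = 200, design = dsn, noise = noise_model(0))
  y <- tsc$data$signal[tsc$data$trace_id == "L_03"]
  expect_lt(y[t == 240] / max(y), 0.02)

  # slow-dissociating tracer barely decays after the chase
  tss <- simulate_tracer_plate("association_then_dissociation", 1e6, 1e-5, Ls,
                               t_chase = 200, design = dsn, noise = noise_model(0))
  ys <- tss$data$signal[tss$data$trace_id == "L_03"]
  expect_gt(ys[t == 400] / ys[t == 200], 0.99)

  expect_error(simulate_tracer_plate("association_then_dissociation", 1e6, 1e-3,
                                     Ls, t_chase = 500, design = dsn),
               "t_chase")
})
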