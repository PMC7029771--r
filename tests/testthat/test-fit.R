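test_that("noiseless kPCA round trips recover the generating rates", {
  tr <- std_tracer(); cp <- compound_spec(1e6, 1e-2)
  ts <- simulate_kpca(std_design(), tr, cp, noise_model(0))

  f_raw <- fit_kpca_global(ts)
  expect_true(f_raw$converged)
  expect_lt(rel_dev(f_raw$estimates["k3"], 1e6), 1e-3)
  expect_lt(rel_dev(f_raw$estimates["k4"], 1e-2), 1e-3)
  expect_lt(abs(f_raw$estimates["y0"]), 1e-9)
  expect_lt(rel_dev(f_raw$estimates["Bmax"], 1), 1e-6)

  f_norm <- fit_kpca_normalized(normalize_traces(ts))
  expect_lt(rel_dev(f_norm$estimates["k3"], 1e6), 1e-3)
  expect_lt(rel_dev(f_norm$estimates["k4"], 1e-2), 1e-3)
  # raw and normalised fits agree on the same noiseless data
  expect_lt(rel_dev(f_norm$estimates["k3"], f_raw$estimates["k3"]), 1e-6)
  expect_lt(rel_dev(f_norm$estimates["k4"], f_raw$estimates["k4"]), 1e-6)
})

test_that("fits are deterministic and never worse than their start points", {
  tr <- std_tracer(); cp <- compound_spec(1e6, 1e-2)
  ts <- simulate_kpca(std_design(), tr, cp, noise_model(0.01), seed = 31)
  f1 <- fit_kpca_global(ts)
  f2 <- fit_kpca_global(ts)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$sse, f2$sse)

  # objective non-increase: reported SSE <= SSE at every multi-start origin,
  # recomputed independently with lm() solving the amplitude parameters
  d <- ts$data[ts$data$role %in% c("dose", "vehicle") & ts$data$time_s > 0, ]
  d <- d[order(d$trace_id, d$time_s), ]
  d$dose_M[is.na(d$dose_M)] <- 0
  for (l3 in c(3, 6.5, 10)) {
    for (l4 in c(-7, -3, 1)) {
      f <- unlist(lapply(split(d, d$trace_id), function(g)
        specific_binding_trace(g$time_s, tr, compound_spec(10^l3, 10^l4),
                               g$dose_M[1])), use.names = FALSE)
      sse0 <- sum(stats::resid(stats::lm(d$signal ~ f))^2)
      expect_lte(f1$sse, sse0 + 1e-12)
    }
  }
})

test_that("slow dissociators: on-rate precise, off-rate flagged ill-determined", {
  tr <- std_tracer(); cp <- compound_spec(1e6, 1e-5)
  ts <- simulate_kpca(std_design(), tr, cp, noise_model(0))
  f <- fit_kpca_global(ts)
  expect_lt(rel_dev(f$estimates["k3"], 1e6), 0.01)
  expect_true(f$ill_determined[["k4"]])

  # independent profile scan: the objective is flat in k4 below 1e-4
  d <- ts$data[ts$data$role %in% c("dose", "vehicle") & ts$data$time_s > 0, ]
  d$dose_M[is.na(d$dose_M)] <- 0
  sse_at <- function(k4) {
    sum(unlist(lapply(split(d, d$trace_id), function(g) {
      (g$signal - specific_binding_trace(g$time_s, tr, compound_spec(1e6, k4),
                                         g$dose_M[1]))^2
    })))
  }
  scale <- sum(d$signal^2)
  profile <- vapply(c(1e-8, 1e-7, 1e-6, 1e-5, 5e-5), sse_at, numeric(1))
  expect_lt(max(profile) / scale, 1e-4)
})

test_that("drift fit recovers KDrift and nests the plain model", {
  tr <- std_tracer(); cp <- compound_spec(1e6, 1e-2)
  ts0 <- simulate_kpca(std_design(), tr, cp, noise_model(0))
  tsd <- drift_trace_set(ts0, 0.0028)

  f <- fit_kpca_drift(tsd)
  expect_lt(rel_dev(f$estimates["k3"], 1e6), 1e-3)
  expect_lt(rel_dev(f$estimates["k4"], 1e-2), 1e-3)
  expect_lt(rel_dev(f$estimates["KDrift"], 0.0028), 1e-3)

  # KDrift = 0 data: drift estimate collapses, rates match the plain fit
  f0 <- fit_kpca_drift(ts0)
  expect_lt(f0$estimates[["KDrift"]], 1e-6)
  fg <- fit_kpca_global(ts0)
  expect_lt(rel_dev(f0$estimates["k3"], fg$estimates["k3"]), 1e-4)

  # normalising drifted data removes the drift without a drift parameter
  fn <- fit_kpca_normalized(normalize_traces(tsd))
  expect_lt(rel_dev(fn$estimates["k3"], 1e6), 1e-3)
  expect_lt(rel_dev(fn$estimates["k4"], 1e-2), 1e-3)
})

test_that("tracer characterisation fits round trip in both designs", {
  Ls <- c(5e-9, 12.5e-9, 50e-9)
  dsn <- assay_design(1200, 10)
  tsa <- simulate_tracer_plate("association", 1e6, 1e-3, Ls, design = dsn,
                               noise = noise_model(0))
  fa <- fit_association_global(tsa)
  expect_lt(rel_dev(fa$estimates["kon"], 1e6), 1e-3)
  expect_lt(rel_dev(fa$estimates["koff"], 1e-3), 1e-3)

  tsc <- simulate_tracer_plate("association_then_dissociation", 1e6, 1e-3, Ls,
                               t_chase = 600, design = dsn, noise = noise_model(0))
  fc <- fit_assoc_then_dissoc_global(tsc)
  expect_lt(rel_dev(fc$estimates["kon"], 1e6), 1e-3)
  expect_lt(rel_dev(fc$estimates["koff"], 1e-3), 1e-3)

  # fast-dissociating tracer with fast sampling: chase design still works
  dsn1 <- assay_design(120, 1)
  tsf <- simulate_tracer_plate("association_then_dissociation", 1e7, 0.5, Ls,
                               t_chase = 60, design = dsn1, noise = noise_model(0.01),
                               seed = 17)
  ff <- fit_assoc_then_dissoc_global(tsf)
  expect_lt(rel_dev(ff$estimates["koff"], 0.5), 0.2)

  # slow koff in a short window: post-chase decay (~0.2%) is near the noise,
  # so the koff CI is wide; extending the window restores the information
  tss <- simulate_tracer_plate("association_then_dissociation", 1e6, 1e-5, Ls,
                               t_chase = 200, design = assay_design(400, 10),
                               noise = noise_model(0.01), seed = 19)
  fs <- fit_assoc_then_dissoc_global(tss)
  koff_row <- fs$parameters[fs$parameters$parameter == "koff", ]
  expect_gt(koff_row$ci_hi / koff_row$ci_lo, 5)
  tsl <- simulate_tracer_plate("association_then_dissociation", 1e6, 1e-5, Ls,
                               t_chase = 2000, design = assay_design(20000, 100),
                               noise = noise_model(0.01), seed = 19)
  fl <- fit_assoc_then_dissoc_global(tsl)
  koff_long <- fl$parameters[fl$parameters$parameter == "koff", ]
  expect_lt(koff_long$se, koff_row$se / 4)
  expect_lt(rel_dev(fl$estimates["koff"], 1e-5), 0.5)
})

test_that("dose-response fit composes with Cheng-Prusoff to return KD", {
  tr <- std_tracer(); cp <- compound_spec(1e6, 1e-2)  # KD2 = 10 nM
  dr <- simulate_epca(tr, cp, 1e9, c(0, 10^seq(-12, -5, 0.5)), noise_model(0))
  f <- fit_dose_response(dr)
  ic50_expected <- cp$KD2 * (1 + tr$L / tr$KD1)
  expect_lt(rel_dev(f$estimates["IC50"], ic50_expected), 1e-6)
  expect_lt(rel_dev(cheng_prusoff(unname(f$estimates["IC50"]), tr$L, tr$KD1),
                    cp$KD2), 1e-6)
  expect_false(f$poor_fit)

  # Cheng-Prusoff arithmetic
  expect_equal(cheng_prusoff(1e-8, 0, 1e-9), 1e-8)
  expect_equal(1 + 12.5e-9 / std_tracer()$KD1, 20.16, tolerance = 1e-3)

  # flat curve carries no IC50 information
  flat <- data.frame(dose_M = c(0, 10^seq(-12, -6, 1)),
                     response_pct = rep(100, 8))
  class(flat) <- c("dose_response", "data.frame")
  expect_error(fit_dose_response(flat), class = "kinbind_nonconvergence")
})

test_that("degenerate fitting inputs raise informative errors", {
  tr <- std_tracer(); cp <- compound_spec(1e6, 1e-2)
  ts <- simulate_kpca(assay_design(400, 10, dose_series = c(0, 250e-9)),
                      tr, cp, noise_model(0))
  expect_error(fit_kpca_global(ts), "nonzero dose")
  tsn <- normalize_traces(simulate_kpca(std_design(), tr, cp, noise_model(0)))
  tsn$data <- tsn$data[tsn$data$dose_M == 0, ]
  expect_error(fit_kpca_normalized(tsn), "nonzero")
  expect_error(fit_kpca_normalized(simulate_kpca(std_design(), tr, cp, noise_model(0))),
               "normalised")
})
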