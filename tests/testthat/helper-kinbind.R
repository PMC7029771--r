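# shared fixtures: everything is generated in code at test time

std_tracer <- function() tracer_spec(L = 12.5e-9, k1 = 2.56e6, k2 = 1.67e-3)

std_design <- function(...) assay_design(...)

# apply a common multiplicative drift to every well of a raw trace set
# (signals are specific, background-subtracted in these fixtures: y0 = 0)
drift_trace_set <- function(ts, KDrift) {
  stopifnot(ts$state == "raw")
  ts$data$signal <- ts$data$signal * exp(-KDrift * ts$data$time_s)
  ts
}

# small Monte Carlo run: simulate + fit n replicates of one compound
mc_fits <- function(compound, design = std_design(), tracer = std_tracer(),
                    noise = noise_model(), n = 20, seed = 7,
                    fitter = fit_kpca_global) {
  lapply(seq_len(n), function(r) {
    ts <- simulate_kpca(design, tracer, compound, noise,
                        seed = derive_seed(seed, r))
    tryCatch(fitter(ts, tracer = tracer), error = function(e) e)
  })
}

rel_dev <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)
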