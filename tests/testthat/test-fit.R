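# Nonlinear fitting of the recoil model and exponential-order selection.

test_that("noiseless traces are recovered to solver tolerance", {
  truth <- relaxation_params(2.0, 6.5, 0.7, 18)
  tr <- generate_trace(truth, frame_interval = 0.09, duration = 120,
                       noise_sd = 0, seed = 1)
  fit <- fit_relaxation(tr)
  expect_true(fit$converged)
  cf <- coef(fit)
  for (nm in names(cf))
    expect_equal(cf[[nm]], truth[[nm]], tolerance = 1e-3)
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("noisy traces recover the slow mode within calibrated tolerances", {
  # tolerances frozen after a 200-seed calibration at sd 0.15 um:
  # X_s within 5% and tau_s within 15% relative (observed q90 ~0.7% / 2%)
  truth <- relaxation_params(2.0, 6.5, 0.7, 18)
  for (s in c(11, 12, 13, 14, 15)) {
    tr <- generate_trace(truth, noise_sd = 0.15, duration = 60, seed = s)
    cf <- coef(fit_relaxation(tr))
    expect_lt(abs(cf[["X_s"]] - 6.5) / 6.5, 0.05)
    expect_lt(abs(cf[["tau_s"]] - 18) / 18, 0.15)
  }
})

test_that("fitting is deterministic given the trace", {
  tr <- generate_trace(paper_range_params(), noise_sd = 0.15, seed = 3)
  expect_identical(coef(fit_relaxation(tr)), coef(fit_relaxation(tr)))
})

test_that("mechanics -> synthesis -> fit round trip closes", {
  mech <- mechanical_params(sigma = 10, k = 1, kf = 10, ks = 1,
                            eta_f = 6.5, eta_s = 20)
  truth <- relaxation_from_mechanics(mech)
  tr <- generate_trace(truth, duration = 120, noise_sd = 0, seed = 1)
  cf <- coef(fit_relaxation(tr))
  for (nm in names(cf))
    expect_equal(cf[[nm]], truth[[nm]], tolerance = 1e-3)
})

test_that("order-2 fit on single-exponential truth does not beat order 1", {
  single <- relaxation_params(1e-9, 6.5, 1e-9, 18)  # effectively one mode
  tr <- generate_trace(single, noise_sd = 0.05, duration = 90, seed = 5)
  f1 <- fit_relaxation(tr, model_order = 1)
  f2 <- fit_relaxation(tr, model_order = 2)
  # nested models: order 2 can only match the noise floor, not undercut it
  expect_gte(f2$residual_rms, 0.9 * f1$residual_rms)
})

test_that("order selection prefers two modes only when two are present", {
  dbl <- generate_trace(paper_range_params(), noise_sd = 0.05, seed = 2)
  expect_identical(compare_exponential_orders(dbl)$preferred, 2L)
  sng <- generate_trace(relaxation_params(1e-9, 6.5, 1e-9, 18),
                        noise_sd = 0.05, duration = 90, seed = 6)
  expect_identical(compare_exponential_orders(sng)$preferred, 1L)
  # coincident timescales: the orders are indistinguishable
  degen <- generate_trace(relaxation_params(3, 3, 10, 10.0001),
                          noise_sd = 0.05, duration = 90, seed = 7)
  expect_identical(compare_exponential_orders(degen)$preferred, 1L)
  # on the noiseless degenerate trace the fitted timescales coincide and the
  # order-2 fit is flagged as effectively single-exponential
  degen0 <- generate_trace(relaxation_params(3, 3, 10, 10.0001),
                           noise_sd = 0, duration = 90, seed = 1)
  expect_true("effectively_single" %in% fit_relaxation(degen0)$flags)
})

test_that("degenerate and invalid traces are rejected or flagged", {
  expect_error(fit_relaxation(displacement_trace(1:4 / 10, rep(1, 4))),
               ">= 5 points")
  expect_error(fit_relaxation(displacement_trace(1:6 / 10, rep(2, 6))),
               "all equal")
  down <- displacement_trace(seq(0, 5, by = 0.5), seq(5, 0, by = -0.5) +
                               c(0, 1e-3, 0, 1e-3, 0, 1e-3, 0, 1e-3, 0, 1e-3, 0))
  fit <- fit_relaxation(down)
  expect_true("degenerate" %in% fit$flags)
})

test_that("identifiability holds for well-separated modes under noise", {
  # spec-level guard: tau_s/tau_f >= 10, both X >= 0.5 um, 100 replicates,
  # median relative bias of X_f + X_s below 5%
  truth <- paper_range_params()
  total <- truth$X_f + truth$X_s
  est <- vapply(1:100, function(s) {
    tr <- generate_trace(truth, noise_sd = 0.15, duration = 60, seed = 200 + s)
    sum(coef(fit_relaxation(tr))[c("X_f", "X_s")])
  }, numeric(1))
  expect_lt(median(abs(est - total) / total), 0.05)
})

test_that("fit methods expose the usual modelling interface", {
  tr <- generate_trace(paper_range_params(), noise_sd = 0.1, seed = 9)
  fit <- fit_relaxation(tr)
  expect_named(coef(fit), c("X_f", "X_s", "tau_f", "tau_s"))
  expect_length(residuals(fit), length(tr))
  expect_equal(fitted(fit) + residuals(fit), tr$displacements)
  expect_equal(predict(fit), fitted(fit))
  s <- summary(fit)
  expect_true(all(is.finite(s$coefficients[, "Std. Error"])))
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$displacements, sims[[2]]$displacements))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("trace CSV round trip preserves data and metadata", {
  tr <- generate_trace(paper_range_params(), noise_sd = 0.1, seed = 10,
                       orientation = "PD", genotype = "wt",
                       specimen_id = "w01")
  path <- tempfile(fileext = ".csv")
  write_displacement_trace(tr, path)
  back <- read_displacement_trace(path)
  expect_equal(back$times, tr$times)
  expect_equal(back$displacements, tr$displacements, tolerance = 1e-9)
  expect_equal(back$delta_t, 0.65)
  expect_equal(back$orientation, "PD")
  expect_equal(back$genotype, "wt")
  bad <- tempfile(fileext = ".csv")
  writeLines(c("time_s,foo", "0,1"), bad)
  expect_error(read_displacement_trace(bad), "displacement_um")
})

test_that("fit results serialize to JSON", {
  tr <- generate_trace(paper_range_params(), noise_sd = 0.1, seed = 11)
  fit <- fit_relaxation(tr)
  path <- tempfile(fileext = ".json")
  write_fit_result(fit, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$params$X_f, coef(fit)[["X_f"]], tolerance = 1e-9)
  expect_equal(obj$model_order, 2)
  expect_true(obj$converged)
})
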