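test_that("linear trapezoid reproduces hand-computed areas", {
  p <- simple_profile(c(0, 1, 2), c(10, 5, 0))
  expect_equal(compute_auc_0t(p, "linear"), 10)   # 7.5 + 2.5
  const <- simple_profile(c(0, 8), c(3, 3))
  expect_equal(compute_auc_0t(const, "linear"), 24)  # c * T
  expect_error(compute_auc_0t(simple_profile(2, 5)), "2 points")
  expect_warning(auc0 <- compute_auc_0t(simple_profile(c(0, 1), c(0, 0))),
                 "all-zero")
  expect_equal(auc0, 0)
})

test_that("dense trapezoid matches the closed-form mono-exponential AUC", {
  p <- mono_exp_profile(c0 = 100, k = 0.5, times = seq(0, 15, by = 0.01))
  analytic <- 100 / 0.5 * (1 - exp(-0.5 * 15))
  expect_equal(compute_auc_0t(p, "linear"), analytic,
               tolerance = 0.01)
  # log-down trapezoid is exact on exponential decline even at coarse steps
  coarse <- mono_exp_profile(times = seq(0, 15, by = 1))
  expect_equal(compute_auc_0t(coarse, "linlog"),
               100 / 0.5 * (1 - exp(-0.5 * 15)), tolerance = 1e-12)
})

test_that("AUC is additive over contiguous intervals and stable under exact interpolation", {
  times <- c(0, 0.5, 1.3, 2, 4, 9)
  conc <- c(80, 60, 35, 25, 9, 1)
  p <- simple_profile(times, conc)
  p_lo <- simple_profile(times[1:4], conc[1:4])
  p_hi <- simple_profile(times[4:6], conc[4:6])
  expect_equal(compute_auc_0t(p), compute_auc_0t(p_lo) + compute_auc_0t(p_hi))
  # inserting a point that lies exactly on a linear segment changes nothing
  mid_t <- 3; mid_c <- approx(times, conc, xout = mid_t)$y
  p_ins <- simple_profile(sort(c(times, mid_t)),
                          append(conc, mid_c, after = 4))
  expect_equal(compute_auc_0t(p_ins), compute_auc_0t(p))
})

test_that("terminal slope is exact on log-linear data and scale invariant", {
  p <- simple_profile(c(4, 6, 8), 100 * exp(-0.5 * c(4, 6, 8)))
  fit <- fit_lambda_z(p)
  expect_equal(fit$lambda_z, 0.5)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$half_life, log(2) / 0.5)

  p7 <- simple_profile(c(4, 6, 8), 7 * 100 * exp(-0.5 * c(4, 6, 8)))
  expect_equal(fit_lambda_z(p7)$lambda_z, 0.5)

  rising <- simple_profile(c(4, 6, 8), c(1, 2, 3))
  expect_equal(fit_lambda_z(rising)$flag, "no terminal decline")
  expect_true(is.na(fit_lambda_z(rising)$lambda_z))
  expect_error(fit_lambda_z(simple_profile(c(1, 2), c(5, 2))), ">= 3")
})

test_that("terminal window extends back to the peak but never across it", {
  # absorption peak at t = 2, clean 0.2/h decline afterwards
  t <- c(0.5, 1, 2, 4, 8, 12, 16)
  conc <- c(30, 60, 100, 100 * exp(-0.2 * (c(4, 8, 12, 16) - 2)))
  fit <- fit_lambda_z(simple_profile(t, conc))
  expect_equal(fit$lambda_z, 0.2, tolerance = 1e-10)
  expect_equal(fit$n_points, 4)  # all post-peak points, peak excluded
  expect_equal(fit$r_squared, 1)
})

test_that("AUC extrapolation and CL/Vd follow their defining identities", {
  expect_equal(compute_auc_inf(10, 0, 0.5)$auc_0inf, 10)
  ext <- compute_auc_inf(10, 1, 0.5)
  expect_equal(ext$auc_0inf, 12)
  expect_equal(ext$pct_extrapolated, 100 * 2 / 12)
  noslope <- compute_auc_inf(10, 1, NA_real_)
  expect_equal(noslope$auc_0inf, 10)
  expect_match(noslope$flag, "no lambda_z")

  cv <- compute_cl_vd(dose = 1, auc_0inf = 1e6, lambda_z = 0.5)
  expect_equal(cv$cl, 1)            # 1 mg/kg over 1e6 h.ng/mL
  expect_equal(compute_cl_vd(2, 1e6, 0.5)$cl, 2)  # linear in dose
  expect_equal(cv$vd * 0.5, cv$cl)  # Vd.lambda_z = CL
})

test_that("NCA on mono-exponential data recovers the generating constants", {
  p <- mono_exp_profile(c0 = 2500, k = 0.3, times = seq(0, 15, by = 0.05),
                        dose = 5)
  res <- run_nca(p)
  expect_equal(res$lambda_z, 0.3, tolerance = 1e-6)
  expect_equal(res$auc_0inf, 2500 / 0.3, tolerance = 0.005)
  # CL = dose/AUCinf, Vd = CL/k = V_central for one compartment
  expect_equal(res$cl, 5e6 / (2500 / 0.3), tolerance = 0.005)
  expect_equal(res$vd, 5e6 / 2500, tolerance = 0.005)
})

test_that("CL and Vd are invariant to consistent unit rescaling", {
  t <- seq(0, 15, by = 0.1)
  p_ng <- simple_profile(t, 2500 * exp(-0.3 * t), dose = 5)
  r1 <- run_nca(p_ng)
  # concentrations in ug/mL with dose interpreted in g/kg: both scale 1e-3
  p_ug <- simple_profile(t, 2.5 * exp(-0.3 * t), dose = 0.005)
  r2 <- run_nca(p_ug)
  expect_equal(r1$cl, r2$cl)
  expect_equal(r1$vd, r2$vd)
})

test_that("single-time-point ratio behaves across edge cases", {
  expect_equal(timepoint_ratio(30.7, 10), 3.07)
  expect_equal(timepoint_ratio(5, 5), 1)
  expect_equal(timepoint_ratio(0, 10), 0)
  expect_warning(r <- timepoint_ratio(3, 0), "undefined")
  expect_true(is.na(r))
})

test_that("composite profiles carry the sparse-sampling AUC standard error", {
  times <- c(1, 2, 4, 8)
  set.seed(42)
  profiles <- lapply(1:4, function(i) {
    pk_profile(paste0("m", i), "WT", "plasma", times,
               100 * exp(-0.3 * times) * exp(rnorm(4, 0, 0.1)))
  })
  comp <- composite_profile(profiles)
  mat <- do.call(rbind, lapply(profiles, `[[`, "concentrations"))
  expect_equal(comp$concentrations, colMeans(mat))
  res <- run_nca(comp)
  # Bailer: Var(AUC) = sum w_i^2 s_i^2 / n_i with trapezoid weights
  w <- c(0.5, 1.5, 3, 2)
  expect_equal(res$auc_se,
               sqrt(sum(w^2 * apply(mat, 2, sd)^2 / 4)))
  expect_error(composite_profile(list(profiles[[1]],
                                      simple_profile(1:2, 1:2, "brain"))),
               "one group and one matrix")
})

test_that("below-quantification concentrations are dropped with a logged count", {
  p <- simple_profile(c(1, 2, 4, 8, 15), c(100, 40, 12, 3, 0.05))
  expect_message(res <- run_nca(p, loq = 0.5), "1 observation")
  expect_equal(res$auc_0t, compute_auc_0t(simple_profile(c(1, 2, 4, 8),
                                                         c(100, 40, 12, 3))))
})
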