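test_that("analytic cumulants match quadrature oracle for varied substrates", {
  set.seed(31)
  subs <- list(
    single_tensor_substrate(c(2, 0.5, 0.5)),
    single_tensor_substrate(c(1.2, 0.9, 0.2), random_rotation()),
    voxel_substrate(list(
      diffusion_compartment(eigenvalues = c(1, 1, 1), fraction = 0.5),
      diffusion_compartment(eigenvalues = c(2, 2, 2), fraction = 0.5))),
    voxel_substrate(list(
      diffusion_compartment(eigenvalues = c(2, 0.5, 0.5), fraction = 0.5),
      diffusion_compartment(eigenvalues = c(2, 0.5, 0.5),
                            rotation = random_rotation(), fraction = 0.3),
      diffusion_compartment(eigenvalues = c(3, 3, 3), fraction = 0.2)))
  )
  for (sub in subs) {
    ana <- substrate_cumulants(sub)
    num <- oracle_cumulants(sub)
    expect_equal(ana$d, num$d, tolerance = 1e-3)
    expect_equal(ana$k_lte, num$k_lte, tolerance = 1e-3)
    expect_equal(ana$k_ste, num$k_ste, tolerance = 1e-3)
  }
})

test_that("closed-form cumulants reproduce hand-derived single-tensor values", {
  cum <- substrate_cumulants(single_tensor_substrate(c(2, 0.5, 0.5)))
  expect_equal(cum$d, 1)
  expect_equal(cum$k_lte, 3 * (4 * 1.5^2 / 45), tolerance = 1e-12) # 0.6
  expect_equal(cum$k_ste, 0)
})

test_that("joint powder fit recovers cumulants in the small-b regime", {
  sub <- single_tensor_substrate(c(2, 0.5, 0.5))
  sch <- small_b_ufa_scheme(0.2)
  fit <- fit_powder_kurtosis_joint(
    powder_average(generate_signal(sub, sch), sch))
  expect_lt(abs(fit$d - 1.0), 0.02)
  expect_lt(abs(fit$k_lte - 0.6), 0.02)
  expect_lt(abs(fit$k_ste), 0.02)

  iso <- single_tensor_substrate(c(1, 1, 1))
  fi <- fit_powder_kurtosis_joint(
    powder_average(generate_signal(iso, sch), sch))
  expect_equal(fi$k_lte, 0, tolerance = 1e-6)
  expect_equal(fi$k_ste, 0, tolerance = 1e-6)
  expect_equal(fi$ufa, 0, tolerance = 1e-6)

  ## two isotropic compartments: k_lte = k_ste > 0, no microscopic anisotropy
  mix <- voxel_substrate(list(
    diffusion_compartment(eigenvalues = c(1, 1, 1), fraction = 0.5),
    diffusion_compartment(eigenvalues = c(2, 2, 2), fraction = 0.5)))
  fm <- fit_powder_kurtosis_joint(
    powder_average(generate_signal(mix, sch), sch))
  expect_gt(fm$k_lte, 0)
  expect_equal(fm$k_lte, fm$k_ste, tolerance = 1e-6)
  expect_equal(fm$ufa, 0, tolerance = 1e-6)
})

test_that("fitted cumulants converge to the analytic limit as b_max shrinks", {
  sub <- single_tensor_substrate(c(2, 0.5, 0.5))
  errs <- vapply(c(2.0, 1.0, 0.5), function(bm) {
    sch <- small_b_ufa_scheme(bm)
    fit <- fit_powder_kurtosis_joint(
      powder_average(generate_signal(sub, sch), sch))
    abs(fit$k_lte - 0.6) + abs(fit$d - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("ufa closed form matches its oracles and clamps", {
  expect_equal(ufa_from_cumulants(1, 0.6, 0), sqrt(0.5), tolerance = 1e-5)
  expect_equal(ufa_from_cumulants(0.8, 0.3, 0.3), 0)
  expect_equal(ufa_from_cumulants(0.8, 0.2, 0.3), 0)
  ## stick limit: K difference 2.4 gives exactly 1 for any d
  expect_equal(ufa_from_cumulants(0.7, 2.4, 0), 1)
  expect_equal(ufa_from_cumulants(2, 2.4, 0), 1)
  expect_error(ufa_from_cumulants(0, 0.5, 0), "positive")
  ## bounded for extreme but finite inputs
  expect_true(ufa_from_cumulants(1, 50, 0) <= 1)
})

test_that("single-tensor equivalence: fitted uFA equals FA (sampled)", {
  set.seed(33)
  sch <- small_b_ufa_scheme(0.2)
  for (i in 1:20) {
    ev <- stats::runif(3, 0.2, 2.5)
    sub <- single_tensor_substrate(ev, random_rotation())
    fit <- fit_powder_kurtosis_joint(
      powder_average(generate_signal(sub, sch), sch))
    expect_lt(abs(fit$ufa - oracle_fa(ev)), 0.01)
  }
})

test_that("orientation dispersion leaves uFA unchanged while FA collapses", {
  mk <- function(orients) {
    voxel_substrate(lapply(orients, function(ax)
      diffusion_compartment(axisymmetric_tensor(2, 0.5, ax),
                            fraction = 1 / length(orients))))
  }
  coherent <- mk(list(c(1, 0, 0)))
  crossing <- mk(list(c(1, 0, 0), c(0, 1, 0)))
  dispersed <- mk(lapply(seq_len(30), function(i)
    fibonacci_directions(30)[i, ]))
  sch_u <- small_b_ufa_scheme(0.2)
  sch_d <- small_b_dti_scheme(0.2)
  res <- lapply(list(coherent, crossing, dispersed), function(sub) {
    uf <- fit_powder_kurtosis_joint(
      powder_average(generate_signal(sub, sch_u), sch_u))$ufa
    fa <- fit_dti_wlls(generate_signal(sub, sch_d), sch_d, max_b = 0.3)$fa
    c(ufa = uf, fa = fa)
  })
  ufas <- vapply(res, `[[`, numeric(1), "ufa")
  fas <- vapply(res, `[[`, numeric(1), "fa")
  expect_true(all(abs(ufas - sqrt(0.5)) < 0.02))
  expect_lt(abs(fas[1] - sqrt(0.5)), 0.02)
  expect_lt(abs(fas[2] - 0.408), 0.02)
  expect_true(all(diff(fas) < 0))       # strictly decreasing with dispersion
})

test_that("fit preconditions are enforced", {
  sub <- single_tensor_substrate(c(1, 1, 1))
  ## only 3 shells
  sch3 <- acquisition_scheme(c(0.1, 1, 2), c("STE", "STE", "LTE"),
                             rbind(0, 0, c(1, 0, 0)))
  expect_error(fit_powder_kurtosis_joint(
    powder_average(generate_signal(sub, sch3), sch3)), "underdetermined")
  ## one STE b-value only
  sch1 <- acquisition_scheme(c(0, 1, 1, 2), c("LTE", "STE", "LTE", "LTE"),
                             rbind(0, 0, c(1, 0, 0), c(0, 1, 0)))
  expect_error(fit_powder_kurtosis_joint(
    powder_average(generate_signal(sub, sch1), sch1)), "STE b-values")
  ## non-positive powder signal flags the voxel invalid
  sch <- small_b_ufa_scheme(0.5)
  pa <- powder_average(generate_signal(sub, sch), sch)
  pa$mean_signal[2] <- 0
  expect_false(fit_powder_kurtosis_joint(pa)$valid)
})
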