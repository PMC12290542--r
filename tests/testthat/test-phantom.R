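test_that("micro-tensor inversion reproduces target MD and uFA exactly", {
  for (ufa in c(0, 0.3, 0.51, 0.707, 0.9)) {
    mt <- micro_tensor_for(0.8, ufa)
    sub <- single_tensor_substrate(c(mt$axial, mt$radial, mt$radial))
    truth <- substrate_truth(sub)
    expect_equal(truth$md, 0.8, tolerance = 1e-10)
    expect_equal(truth$ufa, ufa, tolerance = 1e-10)
  }
  ## closed-form round trip: MD 1, uFA sqrt(0.5) is the diag(2, .5, .5) tensor
  mt <- micro_tensor_for(1, sqrt(0.5))
  expect_equal(mt$axial, 2, tolerance = 1e-10)
  expect_equal(mt$radial, 0.5, tolerance = 1e-10)
  ## any uFA < 1 is reachable with a prolate tensor; radial stays positive
  expect_gt(micro_tensor_for(0.5, 0.99)$radial, 0)
})

test_that("phantom ground truth honours the orientation rules", {
  base <- list(region_md = c(SB = 1, CA1 = 1, `CA2/3` = 1, `CA4/DG` = 1),
               region_ufa = c(SB = sqrt(0.5), CA1 = sqrt(0.5),
                              `CA2/3` = sqrt(0.5), `CA4/DG` = sqrt(0.5)),
               affected_side = "none")
  mk <- function(rule) do.call(phantom_spec, c(base, orientation_rule = rule))

  ph_cross <- build_hippocampus_phantom(mk("crossing-90"))
  vox <- ph_cross$region_voxels[["left/CA4/DG"]]
  expect_equal(ph_cross$truth$fa[vox][1], 0.408, tolerance = 1e-3)
  expect_equal(ph_cross$truth$ufa[vox][1], sqrt(0.5), tolerance = 1e-9)

  ph_coh <- build_hippocampus_phantom(mk("coherent"))
  expect_equal(ph_coh$truth$fa[vox][1], sqrt(0.5), tolerance = 1e-9)
  expect_equal(ph_coh$truth$ufa[vox][1], sqrt(0.5), tolerance = 1e-9)

  ph_disp <- build_hippocampus_phantom(mk("dispersed"))
  expect_lt(ph_disp$truth$fa[vox][1], 0.15)
  expect_equal(ph_disp$truth$ufa[vox][1], sqrt(0.5), tolerance = 1e-9)

  ## isotropic recipe: both anisotropies vanish
  iso <- do.call(phantom_spec, c(list(
    region_md = base$region_md,
    region_ufa = c(SB = 0, CA1 = 0, `CA2/3` = 0, `CA4/DG` = 0),
    affected_side = "none")))
  ph_iso <- build_hippocampus_phantom(iso)
  expect_equal(ph_iso$truth$fa[vox][1], 0, tolerance = 1e-12)
  expect_equal(ph_iso$truth$ufa[vox][1], 0, tolerance = 1e-12)
})

test_that("phantom truth agrees with the numerical cumulant oracle", {
  ph <- build_hippocampus_phantom(phantom_spec())
  for (key in c("left/CA4/DG", "right/SB")) {
    sub <- ph$substrates[[key]]
    num <- oracle_cumulants(sub)
    truth <- substrate_truth(sub)
    expect_equal(truth$d, num$d, tolerance = 2e-3)
    expect_equal(truth$k_lte, num$k_lte, tolerance = 2e-3)
    expect_equal(ufa_from_cumulants(num$d, num$k_lte, num$k_ste),
                 truth$ufa, tolerance = 1e-3)
  }
})

test_that("pathology lowers affected-side ground-truth uFA by the target", {
  spec <- phantom_spec(affected_side = "left", ufa_reduction = 0.05)
  ph <- build_hippocampus_phantom(spec)
  l <- ph$truth$ufa[ph$region_voxels[["left/CA4/DG"]][1]]
  r <- ph$truth$ufa[ph$region_voxels[["right/CA4/DG"]][1]]
  expect_equal(r - l, 0.05, tolerance = 1e-6)
  ## unaffected regions stay symmetric
  expect_equal(ph$truth$ufa[ph$region_voxels[["left/CA1"]][1]],
               ph$truth$ufa[ph$region_voxels[["right/CA1"]][1]])
  ## pathology also raises MD (radial diffusivity increase)
  expect_gt(ph$truth$md[ph$region_voxels[["left/CA4/DG"]][1]],
            ph$truth$md[ph$region_voxels[["right/CA4/DG"]][1]])
  expect_error(build_hippocampus_phantom(
    phantom_spec(ufa_reduction = 0.9)), "too large")
})

test_that("simulated datasets are deterministic and respect the SNR contract", {
  ph <- build_hippocampus_phantom(phantom_spec())
  d1 <- simulate_subject_dataset(ph, snr = 40, seed = 5)
  d2 <- simulate_subject_dataset(ph, snr = 40, seed = 5)
  expect_identical(d1$dwi_ufa$data, d2$dwi_ufa$data)
  d3 <- simulate_subject_dataset(ph, snr = 40, seed = 6)
  expect_false(identical(d1$dwi_ufa$data, d3$dwi_ufa$data))
  ## noise-free run reproduces the deterministic forward signal
  dnf <- simulate_subject_dataset(ph, snr = Inf, seed = 1)
  vox <- ph$region_voxels[["left/SB"]][1]
  sig <- generate_signal(ph$substrates[["left/SB"]], dnf$dwi_ufa$scheme)
  grid <- dim(dnf$dwi_ufa$data)
  flat <- matrix(dnf$dwi_ufa$data, ncol = grid[4])
  expect_equal(flat[vox, ], sig, tolerance = 1e-12)
  expect_error(simulate_subject_dataset(ph, snr = -1), "positive")
})

test_that("noise-free pipeline recovers the phantom maps in the small-b regime", {
  ph <- build_hippocampus_phantom(phantom_spec(affected_side = "none"))
  ds <- simulate_subject_dataset(ph, small_b_dti_scheme(0.2),
                                 small_b_ufa_scheme(0.2), snr = Inf)
  maps <- compute_maps(ds$dwi_dti, ds$dwi_ufa, ds$mask, max_b = 0.3)
  fit_tab <- subject_region_table(maps, ph$labels_left, ph$labels_right, "s")
  true_tab <- subject_region_table(ph$truth, ph$labels_left,
                                   ph$labels_right, "s")
  m <- dplyr::inner_join(fit_tab, true_tab,
                         by = c("region", "hemisphere", "metric"),
                         suffix = c("_fit", "_true"))
  mu <- m[m$metric == "ufa", ]
  expect_lt(max(abs(mu$value_fit - mu$value_true)), 0.02)
  ## all-zero mask: empty maps, no error
  empty <- compute_maps(ds$dwi_dti, ds$dwi_ufa,
                        array(FALSE, dim(ds$mask)), max_b = 0.3)
  expect_equal(sum(empty$mask), 0)
})

test_that("recovery error decreases with SNR; truncation bias stays small", {
  ph <- build_hippocampus_phantom(phantom_spec(affected_side = "none"))
  true_tab <- subject_region_table(ph$truth, ph$labels_left,
                                   ph$labels_right, "s")
  tu <- true_tab[true_tab$metric == "ufa", c("region", "hemisphere", "value")]
  bias_at <- function(snr, n_subj = 4) {
    est <- purrr::map_dfr(seq_len(n_subj), function(i) {
      ds <- simulate_subject_dataset(ph, dti_scheme(), ufa_scheme(),
                                     snr = snr, seed = 100 * i)
      maps <- compute_maps(ds$dwi_dti, ds$dwi_ufa, ds$mask)
      tab <- subject_region_table(maps, ph$labels_left, ph$labels_right,
                                  paste0("s", i))
      tab[tab$metric == "ufa", c("region", "hemisphere", "value")]
    })
    est <- dplyr::summarise(dplyr::group_by(est, .data$region,
                                            .data$hemisphere),
                            value = mean(.data$value), .groups = "drop")
    m <- dplyr::inner_join(est, tu, by = c("region", "hemisphere"),
                           suffix = c("_fit", "_true"))
    mean(abs(m$value_fit - m$value_true))
  }
  b50 <- bias_at(50)
  b100 <- bias_at(100)
  binf <- bias_at(Inf, n_subj = 1)
  ## quadratic-truncation bias of the compact scheme, noise-free
  expect_lt(binf, 0.03)
  ## Rician noise only adds bias on top of it
  expect_lt(binf, b100 + 1e-3)
  expect_lt(b100, b50 + 1e-3)
})

test_that("phantom cohort tables feed the asymmetry analysis end to end", {
  coh <- simulate_phantom_cohort(n_subjects = 5, snr = 50, seed = 11)
  expect_equal(length(unique(coh$subject_id)), 5)
  uni <- coh[coh$region == "CA4/DG" & coh$metric == "ufa", ]
  w <- tidyr::pivot_wider(uni[, c("subject_id", "hemisphere", "value")],
                          names_from = "hemisphere", values_from = "value")
  ## the affected (left) side reads lower on average; per-subject noise can
  ## cross occasionally at this SNR and region size
  expect_lt(mean(w$left), mean(w$right) - 0.02)
  expect_gte(sum(w$left < w$right), 4)
})
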