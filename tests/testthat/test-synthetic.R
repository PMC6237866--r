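test_that("the plasma model rises linearly to its peak and decays tri-exponentially", {
  # degenerate: zero amplitudes give the zero curve
  z <- aif_params(1, c(0, 0, 0), c(1, 2, 3))
  expect_equal(simulate_aif(z, c(0.5, 1, 5))$activity, c(0, 0, 0))

  # single-exponential e-folding: one decay time after the peak, value = A1/e
  p <- aif_params(1, c(10, 0, 0), c(0.5, 5, 50))
  v <- aif_value(p, 1 + 1 / 0.5)
  expect_equal(v, 10 / exp(1), tolerance = 1e-9)

  # the arterial sampling grid has 25 samples over 10 s .. 60 min
  times <- arterial_sample_times()
  expect_length(times, 25)
  expect_equal(range(times), c(1 / 6, 60))
  expect_length(simulate_aif(default_aif_params(), times)$activity, 25)

  expect_error(simulate_aif(default_aif_params(), c(2, 1)), "increasing")
})

test_that("the parent-fraction model is 1 at t = 0, monotone, and ~50% at 60 min", {
  h <- default_hill_params()
  expect_equal(parent_fraction(h, 0), 1)
  tgrid <- seq(0, 90, by = 0.5)
  f <- parent_fraction(h, tgrid)
  expect_true(all(diff(f) <= 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(parent_fraction(h, 60), 0.50, tolerance = 0.02)
  # no metabolism limit
  h0 <- hill_params(0, 1, 5)
  expect_equal(parent_fraction(h0, c(0, 10, 60)), c(1, 1, 1))
  expect_error(parent_fraction(h, -1), ">= 0")
})

test_that("tissue simulation is zero without input and linear in K1", {
  s <- fx_schedule()
  p <- tcm_params(0.1, 0.05, 0.03, 0.02)
  zero <- simulate_2tcm(p, function(t) rep(0, length(t)), s)
  expect_equal(zero$activity, rep(0, 38))

  one <- simulate_2tcm(tcm_params(0.1, 0.05, 0.03, 0.02), fx_input(), s)
  two <- simulate_2tcm(tcm_params(0.2, 0.05, 0.03, 0.02), fx_input(), s)
  expect_equal(two$activity, 2 * one$activity, tolerance = 1e-6)

  expect_error(simulate_2tcm(p, tac(c(0.5, 30), c(1, 1)), s), "cover")
})

test_that("the ODE path matches the closed-form 1TCM solution and an independent 2TCM convolution", {
  aif <- fx_aif()
  # 1TCM: piecewise-analytic convolution as the oracle, on the solver grid
  sol <- solve_2tcm_grid(tcm_params(0.1, 0.05), aif, t_end = 60, step = 1 / 60)
  truth <- oracle_1tcm_closed_form(0.1, 0.05, aif, sol$times)
  expect_lt(max(abs(sol$tissue - truth)), 1e-6)

  # full 2TCM: eigen-decomposed recursive convolution as the oracle
  s <- fx_schedule()
  p <- tcm_params(0.3, 0.1, 0.15, 0.1)
  ours <- simulate_2tcm(p, fx_input(), s, step = 1 / 60)
  orac <- oracle_2tcm_conv(p, fx_input(), s, step = 1 / 60)
  expect_equal(ours$activity, orac$activity, tolerance = 1e-3)
})

test_that("ground-truth identities hold on the parameter tables", {
  # DVR = Vt / Vt_ref and BP_ND = DVR - 1, to machine precision
  vt_ref <- tcm_vt(tcm_params(0.3, 0.1))
  for (b in c(0.45, 0.9, 1.5)) {
    p <- petkin:::bpnd_to_tcm(b)
    expect_equal(tcm_vt(p) / vt_ref - 1, b, tolerance = 1e-12)
  }
})

test_that("TAC noise is seed-deterministic with the stated variance model", {
  s <- fx_schedule()
  clean <- fx_ref_tac()
  expect_identical(add_tac_noise(clean, s, 0, seed = 1), clean)
  n1 <- add_tac_noise(clean, s, 0.05, seed = 42)
  n2 <- add_tac_noise(clean, s, 0.05, seed = 42)
  expect_identical(n1$activity, n2$activity)
  expect_false(identical(n1$activity,
                         add_tac_noise(clean, s, 0.05, seed = 43)$activity))

  # Monte-Carlo check: empirical SD at the last frame within 15% of nominal
  nf <- 0.05
  last <- vapply(1:1000, function(i)
    add_tac_noise(clean, s, nf, seed = i)$activity[38], numeric(1))
  nominal <- nf * clean$activity[38]
  expect_lt(abs(sd(last) - nominal) / nominal, 0.15)
})

test_that("noiseless phantom voxels carry exactly their region's curve", {
  atlas <- fx_atlas()
  ph <- fx_phantom()
  s <- fx_schedule()
  bp <- fx_truth_bpnd()
  for (r in c("thalamus_p", "cerebellum", "amygdala_l")) {
    curve <- simulate_2tcm(petkin:::bpnd_to_tcm(bp[[r]]), fx_input(), s)
    idx <- which(atlas_mask(atlas, r))
    flat <- matrix(ph$voxels, prod(dim(atlas$labels)), 38)
    expect_equal(flat[idx[1], ], curve$activity, tolerance = 1e-12)
    expect_equal(flat[idx[length(idx)], ], curve$activity, tolerance = 1e-12)
  }
  # background stays zero
  expect_equal(sum(ph$voxels[atlas$labels == 0]), 0)
  expect_error(build_phantom(atlas, list(cerebellum = tcm_params(0.3, 0.1)),
                             fx_input(), s), "missing tcm parameters")
})

test_that("phantom noise differs across seeds but regional means agree", {
  atlas <- fx_atlas()
  s <- fx_schedule()
  pars <- petkin:::regional_tcm_params(fx_truth_bpnd())
  p1 <- build_phantom(atlas, pars, fx_input(), s, noise_fraction = 0.05, seed = 1)
  p2 <- build_phantom(atlas, pars, fx_input(), s, noise_fraction = 0.05, seed = 2)
  expect_false(identical(p1$voxels, p2$voxels))
  idx <- which(atlas_mask(atlas, "thalamus_p"))
  f1 <- matrix(p1$voxels, prod(dim(atlas$labels)), 38)
  f2 <- matrix(p2$voxels, prod(dim(atlas$labels)), 38)
  m1 <- mean(f1[idx, 38]); m2 <- mean(f2[idx, 38])
  # means agree within Monte-Carlo error (~4 SE)
  se <- 0.05 * mean(f1[idx, 38]) / sqrt(length(idx))
  expect_lt(abs(m1 - m2), 4 * sqrt(2) * se)
})

test_that("generated cohorts honour group sizes and target association strengths", {
  cohort <- generate_cohort(cohort_spec(seed = 21), make_images = FALSE)
  expect_equal(nrow(cohort$subjects), 21)
  expect_equal(as.vector(table(cohort$subjects$sex)), c(10, 11))
  expect_equal(sum(cohort$subjects$arterial_sampled), 4)
  expect_true(all(cohort$subjects$sex[cohort$subjects$arterial_sampled] == "M"))

  # a strong link reproduces its target R^2 on a large check cohort
  spec <- cohort_spec(n_female = 100, n_male = 100, seed = 5,
                      trait_links = list(list(trait = "tci_cooperativeness",
                                              region = "thalamus",
                                              direction = "negative",
                                              target_r2 = 0.8, sex = "all")))
  big <- generate_cohort(spec, make_images = FALSE)
  th <- rowMeans(big$truth$bpnd[, thalamus_subregions()])
  r2 <- cor(th, big$subjects$tci_cooperativeness)^2
  band <- r2_band(0.8, 200)
  expect_gt(r2, band[1])
  expect_lt(r2, band[2])
  expect_lt(cor(th, big$subjects$tci_cooperativeness), 0)  # direction

  # an unlinked trait is null: |r| small on 200 subjects
  r_null <- cor(th, big$subjects$tci_harm_avoidance)
  expect_lt(abs(r_null), 2.58 / sqrt(200))  # 99% normal bound

  # determinism and invalid configs
  again <- generate_cohort(spec, make_images = FALSE)
  expect_identical(big$subjects, again$subjects)
  expect_error(cohort_spec(trait_links = list(list(trait = "baq_total",
                                                   region = "thalamus",
                                                   direction = "positive",
                                                   target_r2 = 1, sex = "F"))),
               "target_r2")
})
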