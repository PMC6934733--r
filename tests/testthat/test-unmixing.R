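# unmixing: signature estimation, mixing matrix, per-pixel solve, CB
# baseline, FRET maps.

test_that("estimate_af_signature normalizes medians and is scale invariant", {
  ctl <- const_acq(30, 20, 50)
  sig <- estimate_af_signature(ctl, full_mask(8, 8))
  expect_equal(sig$coefficients, c(0.3, 0.2, 0.5))

  ctl7 <- const_acq(30 * 7, 20 * 7, 50 * 7)
  expect_equal(estimate_af_signature(ctl7, full_mask(8, 8))$coefficients,
               sig$coefficients)

  expect_error(estimate_af_signature(ctl, label_mask(matrix(0L, 8, 8))),
               "50")
  expect_error(estimate_af_signature(const_acq(0, 20, 50),
                                     full_mask(8, 8)), "<= 0")
})

test_that("estimate_af_signature recovers a Poisson-noised AF field to 0.01", {
  af_true <- spectral_signature("autofluorescence", c(0.25, 0.25, 0.5))
  sigs <- default_sigs(); sigs$autofluo <- af_true
  cfg <- simulation_config(height = 100, width = 100, n_cells = 5,
                           signatures = sigs, af_mean = 200,
                           photon_budget = 1, seed = 31L)
  truth <- generate_tissue(cfg)
  ctl <- render_acquisition(truth, cfg, specimen = "sensor_free")
  sig <- estimate_af_signature(ctl, full_mask(100, 100))
  expect_lt(max(abs(sig$coefficients - c(0.25, 0.25, 0.5))), 0.01)
})

test_that("sensor signature estimation handles the no-AF and scaled cases", {
  afs <- default_sigs()$autofluo
  don <- const_acq(80, 20, 0)
  acc <- const_acq(4, 76, 0)
  est <- estimate_sensor_signatures(don, acc, afs, full_mask(8, 8))
  expect_equal(est$donor$coefficients, c(0.8, 0.2, 0))
  expect_equal(est$acceptor$coefficients, c(0.05, 0.95, 0))

  don2 <- const_acq(160, 40, 0)    # doubled exposure, same spectrum
  est2 <- estimate_sensor_signatures(don2, acc, afs, full_mask(8, 8))
  expect_equal(est2$donor$coefficients, est$donor$coefficients)
})

test_that("sensor signatures are recovered from synthetic references", {
  # bleed-free acceptor truth: recoverable within +/-0.02 under noise + AF
  sigs <- default_sigs()
  sigs$acceptor <- spectral_signature("acceptor_fluor", c(0.05, 0.95, 0))
  cfg <- simulation_config(height = 80, width = 80, n_cells = 30,
                           signatures = sigs, af_mean = 300,
                           direct_excitation = 1, seed = 33L)
  truth <- generate_tissue(cfg)
  acc <- render_acquisition(truth, cfg, specimen = "acceptor_only")
  don <- render_acquisition(truth, cfg, specimen = "donor_only", seed = 77L)
  est <- estimate_sensor_signatures(don, acc, sigs$autofluo,
                                    full_mask(80, 80))
  expect_lt(max(abs(est$acceptor$coefficients - c(0.05, 0.95, 0))), 0.02)
  expect_lt(max(abs(est$donor$coefficients - c(0.80, 0.20, 0))), 0.02)

  # with 600 nm bleed-through the decomposition has an exact gauge freedom;
  # the estimator must return the zero-bleed gauge representative
  # sig' = (sig - sig[3]/af[3] * af) renormalized  [closed-form oracle]
  sigs2 <- default_sigs()           # acceptor (0.05, 0.90, 0.05)
  cfg2 <- simulation_config(height = 80, width = 80, n_cells = 30,
                            signatures = sigs2, af_mean = 300,
                            direct_excitation = 1, seed = 34L)
  truth2 <- generate_tissue(cfg2)
  acc2 <- render_acquisition(truth2, cfg2, specimen = "acceptor_only")
  est2 <- estimate_sensor_signatures(don, acc2, sigs2$autofluo,
                                     full_mask(80, 80))
  s <- c(0.05, 0.90, 0.05); af <- c(0.3, 0.2, 0.5)
  gauge <- s - s[3] / af[3] * af
  gauge <- gauge / sum(gauge)
  expect_lt(max(abs(est2$acceptor$coefficients - gauge)), 0.02)
})

test_that("build_mixing_matrix conditions and rejects degeneracy", {
  e <- function(i) { v <- c(0, 0, 0); v[i] <- 1; v }
  M <- build_mixing_matrix(spectral_signature("donor_fluor", e(1)),
                           spectral_signature("acceptor_fluor", e(2)),
                           spectral_signature("autofluorescence", e(3)))
  expect_equal(unname(M$matrix), diag(3))
  expect_equal(M$condition_number, 1)

  same <- c(0.5, 0.3, 0.2)
  expect_error(build_mixing_matrix(
    spectral_signature("donor_fluor", same),
    spectral_signature("acceptor_fluor", same),
    spectral_signature("autofluorescence", e(3))), "ill-conditioned")

  # condition number agrees with the independent SVD-based oracle kappa()
  M2 <- default_M()
  expect_equal(M2$condition_number, kappa(M2$matrix, exact = TRUE),
               tolerance = 1e-12)
})

test_that("unmix_image inverts the forward model exactly (both policies)", {
  M <- default_M()
  # identity mixing: abundances pass through
  Mi <- build_mixing_matrix(
    spectral_signature("donor_fluor", c(1, 0, 0)),
    spectral_signature("acceptor_fluor", c(0, 1, 0)),
    spectral_signature("autofluorescence", c(0, 0, 1)))
  acq <- const_acq(10, 20, 5)
  um <- unmix_image(acq, Mi)
  expect_true(all(um$donor_abundance == 10))
  expect_true(all(um$acceptor_abundance == 20))
  expect_true(all(um$autofluo_abundance == 5))
  expect_true(all(um$residual_norm == 0))

  # noiseless forward-model inversion to 1e-9 on random non-negative pixels
  set.seed(12)
  d <- matrix(runif(100, 0, 50), 10, 10)
  a <- matrix(runif(100, 0, 50), 10, 10)
  af <- matrix(runif(100, 0, 200), 10, 10)
  acq2 <- acq_from_abundances(d, a, af, M)
  for (policy in c("nnls", "clamp")) {
    um2 <- unmix_image(acq2, M, policy)
    expect_lt(max(abs(um2$donor_abundance - d)), 1e-9)
    expect_lt(max(abs(um2$acceptor_abundance - a)), 1e-9)
    expect_lt(max(abs(um2$autofluo_abundance - af)), 1e-9)
    expect_lt(max(um2$residual_norm), 1e-9)
  }

  # pure-species completeness: a pure-AF pixel yields zero sensor abundance
  pure <- acq_from_abundances(matrix(0, 4, 4), matrix(0, 4, 4),
                              matrix(120, 4, 4), M)
  ump <- unmix_image(pure, M, "nnls")
  expect_lt(max(ump$donor_abundance), 1e-9)
  expect_lt(max(ump$acceptor_abundance), 1e-9)
})

test_that("unconstrained branch matches an independent per-pixel solver", {
  M <- default_M()
  A <- t(M$matrix)
  set.seed(3)
  n <- 400
  X <- matrix(runif(3 * n, 0, 100), 3, n)
  Y <- A %*% X
  acq <- acq_from_abundances(matrix(X[1, ], 20, 20), matrix(X[2, ], 20, 20),
                             matrix(X[3, ], 20, 20), M)
  um <- unmix_image(acq, M, "clamp")
  # oracle: one qr.solve per pixel, coded independently of the package path
  oracle <- vapply(seq_len(n), function(j) qr.solve(A, Y[, j]), numeric(3))
  expect_lt(max(abs(rbind(as.vector(um$donor_abundance),
                          as.vector(um$acceptor_abundance),
                          as.vector(um$autofluo_abundance)) - oracle)), 1e-9)
})

test_that("nnls policy attains the constrained optimum (optim oracle)", {
  M <- default_M()
  A <- t(M$matrix)
  set.seed(8)
  n <- 60
  # noisy pixels, some with negative unconstrained solutions
  Y <- matrix(rnorm(3 * n, mean = 20, sd = 15), 3, n)
  Y[Y < 0] <- 0
  acq <- acq_from_abundances(matrix(0, 6, 10), matrix(0, 6, 10),
                             matrix(0, 6, 10), M)
  acq$donor$pixels <- matrix(Y[1, ], 6, 10)
  acq$acceptor$pixels <- matrix(Y[2, ], 6, 10)
  acq$autofluo$pixels <- matrix(Y[3, ], 6, 10)
  um <- unmix_image(acq, M, "nnls")
  X <- rbind(as.vector(um$donor_abundance), as.vector(um$acceptor_abundance),
             as.vector(um$autofluo_abundance))
  expect_true(all(X >= 0))
  obj <- function(x, y) sum((A %*% x - y)^2)
  for (j in seq_len(n)) {
    oracle <- stats::optim(c(1, 1, 1), obj, y = Y[, j], method = "L-BFGS-B",
                           lower = 0)$value
    expect_lte(obj(X[, j], Y[, j]), oracle + 1e-6)
  }
  # residual_norm is consistent with the returned abundances
  expect_equal(as.vector(um$residual_norm),
               sqrt(colSums((A %*% X - Y)^2)), tolerance = 1e-10)
})

test_that("constant background subtraction behaves and retains AF structure", {
  expect_true(all(constant_background_subtract(const_acq(10, 10, 10),
                                               c(10, 10, 10))$donor$pixels == 0))
  acq <- const_acq(7, 8, 9)
  same <- constant_background_subtract(acq, c(0, 0, 0))
  expect_equal(same$donor$pixels, acq$donor$pixels)
  expect_true(same$background_corrected)
  expect_error(constant_background_subtract(acq, c(-1, 0, 0)), ">= 0")

  # heterogeneous AF + uniform sensor: CB leaves the AF pattern in the
  # sensor channels, LU removes it
  cfg <- simulation_config(height = 64, width = 64, n_cells = 10,
                           expression_sdlog = 0,
                           conc = list(dist = "fixed", value = 5),
                           af_granule_density = 0, seed = 21L)
  truth <- generate_tissue(cfg)
  acq <- render_acquisition(truth, cfg)
  bg <- mean(truth$af_field) * c(0.3, 0.2, 0.5)
  cb <- constant_background_subtract(acq, bg)
  lu <- unmix_image(acq, default_M())
  af <- as.vector(truth$af_field)
  expect_gt(cor(as.vector(cb$donor$pixels), af), 0.5)
  expect_lt(abs(cor(as.vector(lu$donor_abundance), af)), 0.1)
})

test_that("compute_fret_map ratios, guards and ordering are correct", {
  Mi <- build_mixing_matrix(
    spectral_signature("donor_fluor", c(1, 0, 0)),
    spectral_signature("acceptor_fluor", c(0, 1, 0)),
    spectral_signature("autofluorescence", c(0, 0, 1)))
  um <- unmix_image(const_acq(10, 5, 0), Mi)
  fm <- compute_fret_map(um, min_intensity = 1)
  expect_true(all(fm$valid))
  expect_true(all(fm$ratio == 0.5))

  um0 <- unmix_image(const_acq(0, 5, 0), Mi)
  fm0 <- compute_fret_map(um0, min_intensity = 1)
  expect_false(any(fm0$valid))            # donor = 0 guard
  expect_error(compute_fret_map(um, min_intensity = 0), "> 0")
  expect_error(compute_fret_map(const_acq(1, 1, 1), 1), "unmixed")

  # two populations, bound fractions 0.2 vs 0.8: binding reduces the ratio
  spec <- sensor_spec()
  c_low <- 0.2 / 0.8 * spec$kd; c_high <- 0.8 / 0.2 * spec$kd
  mk <- function(cv) simulation_config(height = 40, width = 80, n_cells = 16,
                                       conc = list(dist = "fixed", value = cv),
                                       seed = 55L)
  ratio_of <- function(cv) {
    cfg <- mk(cv)
    fm <- compute_fret_map(unmix_image(render_acquisition(
      generate_tissue(cfg), cfg), default_M()), 10)
    mean(fm$ratio[fm$valid])
  }
  expect_lt(ratio_of(c_high), ratio_of(c_low))
})

test_that("FRET ratio is invariant to per-pixel intensity scaling", {
  M <- default_M()
  set.seed(9)
  for (i in 1:20) {
    x <- runif(3, 5, 80)
    k <- runif(1, 0.1, 10)
    base <- acq_from_abundances(matrix(x[1], 1, 1), matrix(x[2], 1, 1),
                                matrix(x[3], 1, 1), M)
    scaled <- acquisition_set(
      channel_image(base$donor$pixels * k, "donor"),
      channel_image(base$acceptor$pixels * k, "acceptor"),
      channel_image(base$autofluo$pixels * k, "autofluo"))
    r1 <- compute_fret_map(unmix_image(base, M), 1e-6)$ratio[1, 1]
    r2 <- compute_fret_map(unmix_image(scaled, M), 1e-6)$ratio[1, 1]
    expect_equal(r2, r1, tolerance = 1e-9)
  }
})

test_that("residual is positive in expectation under Poisson noise", {
  # low counts so some pixels have negative unconstrained solutions (the
  # exactly determined 3x3 solve has zero residual unless NNLS activates)
  cfg <- tiny_config(photon_budget = 30, af_mean = 20,
                     af_granule_density = 0)
  truth <- generate_tissue(cfg)
  noisy <- render_acquisition(truth, cfg, noise = TRUE)
  um <- unmix_image(noisy, default_M(), "nnls")
  expect_gt(mean(um$residual_norm), 0)
})
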