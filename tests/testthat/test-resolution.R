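test_that("analytic resolution of an invertible square system is the identity", {
  withr::with_seed(41, G <- matrix(rnorm(49), 7, 7) + 3 * diag(7))
  g <- gain_matrix(G)
  k <- mne_kernel(g, lambda2 = 0)
  R <- analytic_resolution(k, g)
  expect_equal(R$values, diag(7), tolerance = 1e-9)
})

test_that("resolution columns are kernel responses to unit sources", {
  g <- gain_matrix(fix_std$gain$values[, 1:40])
  k <- mne_kernel(g, diag(nrow(g$values)) * mean(g$values^2), 0.5)
  R <- analytic_resolution(k, g)
  for (j in c(1, 17, 40)) {
    e_j <- rep(0, 40); e_j[j] <- 1
    expect_equal(R$values[, j],
                 as.vector(apply_kernel(k, g$values %*% e_j)),
                 tolerance = 1e-13)
  }
  expect_error(analytic_resolution(k, fix_std$gain),
               class = "sourcefidelity_invalid_argument")
})

test_that("patch activation has the documented shape and mass", {
  pc <- fix_std$parc
  n <- fix_std$space$n_sources
  X <- patch_activation(pc, 3, n, amplitude = 1e-8, duration = 0.1,
                        sampling_rate = 1000)
  expect_equal(ncol(X), 100) # 100 ms at 1000 Hz
  expect_equal(colSums(X), rep(length(pc$patches[[3]]) * 1e-8, 100))
  expect_true(all(X[setdiff(1:n, pc$patches[[3]]), ] == 0))
  expect_error(patch_activation(pc, pc$n_patches + 1, n),
               class = "sourcefidelity_invalid_argument")
})

test_that("snr_alpha recovers trivial and hand-computed scalings", {
  # one patch, one modality, signal rms equal to noise rms -> alpha = target
  g <- gain_matrix(matrix(c(1, -1), 2, 1))
  patterns <- matrix(2, 1, 1) # signal = (2, -2), rms = 2
  noise <- matrix(c(2, 2, -2, -2), 2) # rms = 2
  expect_equal(snr_alpha(g, patterns, noise, 3)$alpha, 3, tolerance = 1e-12)
  # doubling the noise doubles alpha
  expect_equal(snr_alpha(g, patterns, 2 * noise, 3)$alpha, 6, tolerance = 1e-12)
  # three modalities with per-modality ratios 1, 2, 4 and target 1
  g3 <- gain_matrix(rbind(1, 2, 4), modality = c("eeg", "grad", "mag"))
  patterns3 <- matrix(1, 1, 1)
  noise3 <- matrix(c(1, 1, 1), 3, 4) # each modality noise rms 1
  spec <- snr_alpha(g3, patterns3, noise3, 1)
  expect_equal(spec$alpha, 1 / mean(c(1, 2, 4)), tolerance = 1e-12)
  # degenerate noise
  expect_error(snr_alpha(g, patterns, noise * 0, 1),
               class = "sourcefidelity_invalid_argument")
  # infinite target omits the noise
  expect_true(snr_alpha(g, patterns, NULL, Inf)$noise_omitted)
})

test_that("infinite-SNR empirical resolution equals the patch-reduced analytic matrix", {
  fx <- fix_std
  er <- empirical_resolution("MNE", fx$space, fx$parc, fx$gain, fx$epochs,
                             snr = Inf, seed = 5)
  k <- mne_kernel(fx$gain, lambda2 = 0)
  pr <- patch_reduce(analytic_resolution(k, fx$gain), fx$parc)
  expect_lt(norm(er$values - pr, "F") / norm(pr, "F"), 1e-10)
})

test_that("empirical resolution entries match a brute-force loop oracle", {
  fx <- make_fixture(n_sources = 80, n_patches = 10, n_sensors = 16, seed = 44,
                     n_epochs = 12, epoch_duration = 0.15)
  er <- empirical_resolution("MNE", fx$space, fx$parc, fx$gain, fx$epochs,
                             snr = Inf, amplitude = 1e-8, duration = 0.02,
                             n_evoked = 4, seed = 6)
  # independently coded loops over dipoles and time at infinite SNR
  k <- mne_kernel(fx$gain, lambda2 = 0)
  n_t <- 20
  for (j in c(1, 5, 10)) {
    X <- matrix(0, fx$space$n_sources, n_t)
    for (kk in fx$parc$patches[[j]]) X[kk, ] <- 1e-8
    Xhat <- k$K %*% (fx$gain$values %*% X)
    for (i in c(2, 7)) {
      acc <- 0
      for (kk in fx$parc$patches[[i]]) for (t in 1:n_t) acc <- acc + abs(Xhat[kk, t])
      oracle <- acc / (n_t * length(fx$parc$patches[[i]]))
      expect_equal(er$values[i, j], oracle, tolerance = 1e-12)
    }
  }
})

test_that("zero-SNR columns carry no signal", {
  fx <- make_fixture(n_sources = 80, n_patches = 10, n_sensors = 16, seed = 44,
                     n_epochs = 12, epoch_duration = 0.15)
  er <- empirical_resolution("MNE", fx$space, fx$parc, fx$gain, fx$epochs,
                             snr = 0, duration = 0.02, n_evoked = 4, seed = 6)
  expect_equal(er$alpha, 0)
  expect_equal(er$lambda2, 1e6)
  expect_true(all(is.finite(er$values)))
})

test_that("linear estimators superpose across patch activations", {
  fx <- fix_std
  k <- linear_kernel("sLORETA", fx$gain, fix_cov, 1 / 9)
  S <- fx$gain$values %*% patch_activation(fx$parc, 2, fx$space$n_sources)[, 1] +
    fx$gain$values %*% patch_activation(fx$parc, 9, fx$space$n_sources)[, 1]
  x12 <- apply_kernel(k, S)
  x1 <- apply_kernel(k, fx$gain$values %*%
                       patch_activation(fx$parc, 2, fx$space$n_sources)[, 1])
  x2 <- apply_kernel(k, fx$gain$values %*%
                       patch_activation(fx$parc, 9, fx$space$n_sources)[, 1])
  expect_equal(x12, x1 + x2, tolerance = 1e-10)
})

test_that("patch_reduce of the identity on singleton patches is the identity", {
  ss <- build_sphere_source_space(12, seed = 3)
  pc <- parcellate(ss, 12, seed = 3)
  R <- structure(list(values = diag(12), method = "MNE", lambda2 = 0),
                 class = "resolution_matrix")
  expect_equal(patch_reduce(R, pc, amplitude = 1), diag(12), ignore_attr = TRUE)
  # linear in the activation amplitude
  expect_equal(patch_reduce(R, pc, amplitude = 2.5), 2.5 * diag(12),
               ignore_attr = TRUE)
})

test_that("resolution matrix text round trip preserves values and metadata", {
  fx <- make_fixture(n_sources = 80, n_patches = 10, n_sensors = 16, seed = 44,
                     n_epochs = 12, epoch_duration = 0.15)
  er <- empirical_resolution("sLORETA", fx$space, fx$parc, fx$gain, fx$epochs,
                             snr = 1, duration = 0.02, n_evoked = 4, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_resolution(er, path)
  back <- read_resolution(path)
  expect_identical(back$values, er$values)
  expect_identical(back$method, "sLORETA")
  expect_equal(back$snr, 1)
})
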