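test_that("peak error handles trivial geometries and all-zero estimates", {
  ss <- build_sphere_source_space(50, seed = 51)
  pc <- parcellate(ss, 5, seed = 51)
  patch <- pc$patches[[1]]
  ctr <- patch_center(patch, ss)
  x <- rep(0, 50); x[ctr] <- 1
  expect_equal(peak_error(x, ss, patch), 0)
  expect_true(is.na(peak_error(rep(0, 50), ss, patch)))
  expect_error(peak_error(rep(1, 10), ss, patch),
               class = "sourcefidelity_invalid_argument")
})

test_that("peak error equals a direct distance for a two-dipole miss", {
  ss <- build_sphere_source_space(10, bumpiness = 0, seed = 1, jitter = 0)
  ss$positions[1, ] <- c(0, 0, 0.08)
  ss$positions[2, ] <- c(0.03, 0, 0.08) # 3 cm apart
  ss$surface_positions[1, ] <- ss$surface_positions[1, ] # patch {1} centers on 1
  x <- rep(0, 10); x[2] <- 5 # peak at the wrong dipole
  expect_equal(peak_error(x, ss, 1L), 0.03, tolerance = 1e-12)
})

test_that("peak error matches a brute-force scan oracle on random estimates", {
  ss <- build_sphere_source_space(50, seed = 52)
  pc <- parcellate(ss, 5, seed = 52)
  withr::with_seed(53, {
    for (rep in 1:5) {
      x <- rnorm(50)
      patch <- pc$patches[[sample(5, 1)]]
      # oracle: explicit scan
      best <- 1; for (k in 2:50) if (abs(x[k]) > abs(x[best])) best <- k
      ctr <- patch_center(patch, ss)
      oracle <- sqrt(sum((ss$positions[ctr, ] - ss$positions[best, ])^2))
      expect_equal(peak_error(x, ss, patch), oracle)
    }
  })
})

test_that("spatial dispersion has its closed-form values", {
  ss <- build_sphere_source_space(10, seed = 54)
  x <- rep(0, 10); x[4] <- 2
  expect_equal(spatial_dispersion(x, ss), 0) # single-dipole estimate
  # two equal amplitudes distance d apart -> d/2
  x2 <- rep(0, 10); x2[c(2, 7)] <- 3
  d <- sqrt(sum((ss$positions[2, ] - ss$positions[7, ])^2))
  expect_equal(spatial_dispersion(x2, ss), d / 2, tolerance = 1e-12)
  expect_true(is.na(spatial_dispersion(rep(0, 10), ss)))
})

test_that("spatial dispersion matches a direct-sum oracle", {
  ss <- build_sphere_source_space(40, seed = 55)
  withr::with_seed(56, x <- rnorm(40)^2)
  j <- which.max(abs(x))
  acc <- 0
  for (k in 1:40) {
    acc <- acc + sqrt(sum((ss$positions[j, ] - ss$positions[k, ])^2)) * abs(x[k])
  }
  expect_equal(spatial_dispersion(x, ss), acc / sum(abs(x)), tolerance = 1e-12)
})

test_that("center-of-gravity error behaves on closed-form cases", {
  ss <- build_sphere_source_space(10, seed = 57)
  x <- rep(0, 10); x[3] <- 1
  expect_equal(cog_error(x, ss, ss$positions[3, ]), 0)
  x2 <- rep(0, 10); x2[c(1, 5)] <- 1
  mid <- (ss$positions[1, ] + ss$positions[5, ]) / 2
  expect_equal(cog_error(x2, ss, ss$positions[1, ]),
               sqrt(sum((ss$positions[1, ] - mid)^2)), tolerance = 1e-12)
  withr::with_seed(58, x3 <- abs(rnorm(10)))
  cg <- colSums(ss$positions * x3) / sum(x3)
  expect_equal(cog_error(x3, ss, ss$positions[2, ]),
               sqrt(sum((ss$positions[2, ] - cg)^2)), tolerance = 1e-12)
})

test_that("column normalization scales maxima to one and flags zero columns", {
  expect_equal(normalize_columns(diag(3)), diag(3), ignore_attr = TRUE)
  m <- matrix(c(1, 2, 4, 0, 0, 0), 3, 2)
  nm <- normalize_columns(m)
  expect_equal(max(nm[, 1]), 1)
  expect_equal(nm[, 1], c(0.25, 0.5, 1))
  expect_identical(attr(nm, "zero_columns"), 2L)
})

test_that("classification counts match hand values and a cell-by-cell oracle", {
  n <- 4
  cc <- classification_counts(diag(n), 0.5)
  expect_equal(unlist(cc[, c("tp", "fp", "tn", "fn")]),
               c(tp = n, fp = 0, tn = n^2 - n, fn = 0))
  cc1 <- classification_counts(matrix(1, n, n), 0.5)
  expect_equal(cc1$fp, n^2 - n)
  expect_equal(cc1$tp, n)
  # random 20 x 20 vs exhaustive loop
  withr::with_seed(59, m <- matrix(runif(400), 20))
  m <- normalize_columns(m)
  for (thr in c(0.2, 0.5, 0.9)) {
    tp <- fp <- tn <- fn <- 0
    for (i in 1:20) for (j in 1:20) {
      active <- m[i, j] > thr
      if (i == j) { if (active) tp <- tp + 1 else fn <- fn + 1 }
      else { if (active) fp <- fp + 1 else tn <- tn + 1 }
    }
    got <- classification_counts(m, thr)
    expect_equal(unlist(got[, c("tp", "fp", "tn", "fn")]),
                 c(tp = tp, fp = fp, tn = tn, fn = fn))
  }
  # totals are structural
  got <- classification_counts(m, 0.3)
  expect_equal(got$tp + got$fn, 20)
  expect_equal(got$fp + got$tn, 20^2 - 20)
})

test_that("ROC of the identity is exactly one and of uniform noise about half", {
  expect_equal(roc_prc(diag(30))$auroc, 1)
  expect_equal(roc_prc(diag(30))$auprc, 1)
  withr::with_seed(60, {
    aucs <- replicate(10, roc_prc(matrix(runif(50 * 50), 50))$auroc)
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
})

test_that("threshold sweep matches a hand-enumerated 3x3 table", {
  m <- matrix(c(1.0, 0.4, 0.1,
                0.6, 1.0, 0.3,
                0.2, 0.0, 1.0), 3, 3, byrow = TRUE)
  thresholds <- c(0.75, 0.5, 0.25)
  rp <- roc_prc(m, thresholds)
  # exhaustive oracle: loop every cell at every threshold
  for (ti in seq_along(thresholds)) {
    tp <- fp <- tn <- fn <- 0
    for (i in 1:3) for (j in 1:3) {
      active <- m[i, j] > thresholds[ti]
      if (i == j) { if (active) tp <- tp + 1 else fn <- fn + 1 }
      else { if (active) fp <- fp + 1 else tn <- tn + 1 }
    }
    expect_equal(rp$curve$tp[ti], tp)
    expect_equal(rp$curve$fp[ti], fp)
    expect_equal(rp$curve$tpr[ti], tp / 3)
    expect_equal(rp$curve$fpr[ti], fp / 6)
  }
  # areas from the oracle points (plus ROC endpoints), trapezoid
  fpr <- rp$curve$fpr; tpr <- rp$curve$tpr; ppv <- rp$curve$ppv
  ox <- c(0, fpr, 1); oy <- c(0, tpr, 1)
  o <- order(ox, oy)
  xs <- ox[o]; ys <- oy[o]
  auroc_oracle <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  expect_equal(rp$auroc, auroc_oracle)
  o2 <- order(tpr, ppv)
  auprc_oracle <- sum(diff(tpr[o2]) * (ppv[o2][-1] + ppv[o2][-3]) / 2)
  expect_equal(rp$auprc, auprc_oracle)
})

test_that("undefined PPV at high thresholds uses the horizontal asymptote", {
  m <- diag(c(1, 1, 1)) * 0.5 # max normalizes to 1 after normalize_columns
  m <- normalize_columns(m)
  rp <- roc_prc(m, thresholds = c(1, 0.9, 0.5, 0))
  # at T = 1 there are no positives; PPV must copy the T = 0.9 value (1)
  expect_equal(rp$curve$ppv[rp$curve$threshold == 1], 1)
})

test_that("fidelity metrics tibble summarizes an empirical run per patch", {
  fx <- make_fixture(n_sources = 80, n_patches = 10, n_sensors = 16, seed = 44,
                     n_epochs = 12, epoch_duration = 0.15)
  er <- empirical_resolution("MNE", fx$space, fx$parc, fx$gain, fx$epochs,
                             snr = 3, duration = 0.02, n_evoked = 4, seed = 8)
  fm <- fidelity_metrics(er, fx$space, fx$parc)
  expect_s3_class(fm, "tbl_df")
  expect_equal(nrow(fm), 10)
  expect_true(all(fm$pe >= 0 & fm$sd >= 0))
  expect_equal(fm$size, lengths(fx$parc$patches))
  expect_equal(attr(fm, "zero_frac"), 0)
})
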