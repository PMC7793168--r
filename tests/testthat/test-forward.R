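test_that("dipole field vanishes for moment parallel to displacement", {
  src <- c(0, 0, 0); sen <- c(0.1, 0, 0)
  B <- dipole_field(src, c(2, 0, 0), sen) # moment parallel to d
  expect_equal(B, c(0, 0, 0))
})

test_that("dipole field falls off as inverse distance squared", {
  src <- c(0, 0, 0); m <- c(0, 1e-8, 0)
  B1 <- dipole_field(src, m, c(0.1, 0, 0))
  B2 <- dipole_field(src, m, c(0.2, 0, 0))
  expect_equal(sqrt(sum(B1^2)) / sqrt(sum(B2^2)), 4, tolerance = 1e-12)
})

test_that("dipole field matches a numerical Biot-Savart short-element oracle", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      src <- rnorm(3, sd = 0.02)
      m <- rnorm(3, sd = 1e-8)
      sen <- src + rnorm(3, sd = 0.1) + c(0.15, 0, 0)
      # current element of length L along m-hat with I*L = |m|, integrated
      mhat <- m / sqrt(sum(m^2))
      L <- 1e-6
      nseg <- 200
      s <- (seq_len(nseg) - 0.5) / nseg - 0.5
      B <- c(0, 0, 0)
      for (t in s) {
        p <- src + t * L * mhat
        r <- sen - p
        B <- B + 1e-7 * (sqrt(sum(m^2)) / L) *
          (L / nseg) * c(mhat[2] * r[3] - mhat[3] * r[2],
                         mhat[3] * r[1] - mhat[1] * r[3],
                         mhat[1] * r[2] - mhat[2] * r[1]) / sum(r^2)^1.5
      }
      expect_equal(dipole_field(src, m, sen), B, tolerance = 1e-6)
    }
  })
  expect_error(dipole_field(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)),
               class = "sourcefidelity_singular")
})

test_that("gain rows equal direct field evaluations and columns are independent", {
  ss <- build_sphere_source_space(5, bumpiness = 0.1, seed = 4)
  sa <- sensor_array(rbind(c(0.12, 0, 0), c(0, 0.13, 0.01)),
                     rbind(c(1, 0, 0), c(0, 1, 0)), "mag")
  g <- build_gain(ss, sa)
  expect_equal(dim(g$values), c(2L, 5L))
  for (s in 1:2) {
    for (k in 1:5) {
      B <- dipole_field(ss$positions[k, ], ss$orientations[k, ],
                        sa$positions[s, ])
      expect_equal(g$values[s, k], sum(B * sa$orientations[s, ]),
                   tolerance = 1e-12)
    }
  }
  # permuting sources permutes columns identically
  perm <- c(3, 1, 5, 2, 4)
  ss2 <- ss
  ss2$positions <- ss$positions[perm, ]
  ss2$orientations <- ss$orientations[perm, ]
  ss2$surface_positions <- ss$surface_positions[perm, ]
  g2 <- build_gain(ss2, sa)
  expect_equal(g2$values, g$values[, perm], tolerance = 0)
})

test_that("gain is linear in the dipole moment", {
  # doubling the moment doubles the signal: columns scale with amplitude
  g <- fix_std$gain
  X1 <- patch_activation(fix_std$parc, 1, fix_std$space$n_sources,
                         amplitude = 1e-8, duration = 0.002)
  X2 <- patch_activation(fix_std$parc, 1, fix_std$space$n_sources,
                         amplitude = 2e-8, duration = 0.002)
  expect_equal(g$values %*% X2, 2 * (g$values %*% X1), tolerance = 1e-12)
})

test_that("radial dipole in a spherical radial-sensor array is near-silent", {
  sa <- sphere_sensor_array(64, radius = 0.12, seed = 1, jitter = 0)
  p <- c(0.05, 0, 0)
  row_energy <- function(moment) {
    sum(vapply(seq_len(sa$n_sensors), function(s) {
      sum(dipole_field(p, moment, sa$positions[s, ]) * sa$orientations[s, ])^2
    }, numeric(1)))
  }
  e_rad <- row_energy(c(1e-8, 0, 0)) # radial moment
  e_tan <- row_energy(c(0, 1e-8, 0)) # tangential moment
  expect_lt(e_rad, 1e-20 * e_tan)
})

test_that("gradiometer and EEG rows behave sensibly", {
  ss <- build_sphere_source_space(20, bumpiness = 0.1, seed = 6)
  sa <- sphere_sensor_array(12, modality = c(rep("mag", 4), rep("grad", 4),
                                             rep("eeg", 4)), seed = 6)
  g <- build_gain(ss, sa)
  expect_true(all(is.finite(g$values)))
  sets <- modality_sets(g)
  expect_named(sets, c("eeg", "grad", "mag"))
  expect_length(sets$grad, 4)
})

test_that("gain text round trip is bit-exact and errors are classed", {
  g <- gain_matrix(matrix(c(pi, exp(1), sqrt(2), -1 / 3, 2e-13, 7), 3, 2),
                   modality = c("mag", "mag", "grad"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gain(g, path)
  back <- read_gain(path)
  expect_identical(back$values, g$values)
  expect_identical(back$modality, g$modality)
  # documented layout: one row per sensor, tab-delimited %.17g
  lines <- readLines(path)
  expect_length(lines, 3)
  expect_identical(lines[1], paste(sprintf("%.17g", g$values[1, ]),
                                   collapse = "\t"))
  expect_error(read_gain(path, n_sources = 5),
               class = "sourcefidelity_format")
  writeLines(c("1\t2", "3"), path)
  expect_error(read_gain(path), class = "sourcefidelity_format")
})

test_that("sensors inside the source surface are rejected", {
  ss <- build_sphere_source_space(10, radius = 0.08, seed = 1)
  sa <- sphere_sensor_array(8, radius = 0.05, seed = 1)
  expect_error(build_gain(ss, sa), class = "sourcefidelity_invalid_argument")
})
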