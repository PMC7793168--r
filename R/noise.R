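#' Structured sensor-noise model
#'
#' Noise = spatially mixed AR(1) latent factors plus a white sensor floor:
#' at each time step the latent factors follow a unit-marginal-variance AR(1)
#' process, are mixed into sensor space by `spatial_mixing`, and independent
#' Gaussian sensor noise of variance `sensor_floor` is added. The implied
#' stationary covariance is `M M' + sensor_floor * I`, which must be
#' positive definite. This two-knob model emulates resting-state recordings
#' whose sensor covariance is dominated by spatially structured background
#' brain activity.
#'
#' @param spatial_mixing `n_sensors x n_factors` mixing matrix.
#' @param ar_coefficient AR(1) coefficient in `[0, 1)`.
#' @param sensor_floor White sensor-noise variance (>= 0).
#' @param sampling_rate Sampling rate in Hz.
#' @return A `noise_model`.
#' @export
noise_model <- function(spatial_mixing, ar_coefficient = 0.95,
                        sensor_floor = 0, sampling_rate = 1000) {
  M <- as.matrix(spatial_mixing)
  ar_coefficient <- check_scalar(ar_coefficient, "ar_coefficient", min = 0)
  if (ar_coefficient >= 1) stop_invalid("`ar_coefficient` must be in [0, 1)")
  sensor_floor <- check_scalar(sensor_floor, "sensor_floor", min = 0)
  C <- tcrossprod(M) + diag(sensor_floor, nrow(M))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop_invalid("implied noise covariance is not positive definite")
  structure(list(spatial_mixing = M, ar_coefficient = ar_coefficient,
                 sensor_floor = sensor_floor, sampling_rate = sampling_rate,
                 n_sensors = nrow(M)),
            class = "noise_model")
}

#' Brain-like noise model derived from a gain matrix
#'
#' Builds the spatial mixing from randomly selected gain columns, so the
#' noise has the spatial signature of background source activity seen
#' through the forward model, plus a white floor set as a fraction of the
#' mixed power.
#'
#' @param gain A `gain_matrix`.
#' @param n_factors Number of background source factors.
#' @param amplitude Dipole moment of each background factor, A m.
#' @param floor_frac White-floor variance as a fraction of mean mixed power.
#' @param ar_coefficient AR(1) coefficient of the factors.
#' @param sampling_rate Hz.
#' @param seed Seed for the factor-column draw.
#' @return A `noise_model`.
#' @export
brain_noise_model <- function(gain, n_factors = 20L, amplitude = 1e-8,
                              floor_frac = 0.1, ar_coefficient = 0.95,
                              sampling_rate = 1000, seed = 1L) {
  n_factors <- check_count(n_factors, "n_factors")
  idx <- with_seed(derive_seed(seed, 5L),
                   sample.int(ncol(gain$values), n_factors))
  M <- gain$values[, idx, drop = FALSE] * amplitude
  floor_var <- floor_frac * mean(rowSums(M^2))
  noise_model(M, ar_coefficient, floor_var, sampling_rate)
}

# Stationary covariance implied by the model.
model_covariance <- function(model) {
  tcrossprod(model$spatial_mixing) + diag(model$sensor_floor, model$n_sensors)
}

#' Simulate resting-state epochs
#'
#' @param model A `noise_model`.
#' @param n_epochs Number of epochs.
#' @param duration Epoch duration in seconds.
#' @param seed Integer seed; epochs are mutually independent and the whole
#'   set is deterministic per seed.
#' @return An `epoch_set` with `epochs` (`n_epochs x n_sensors x n_times`
#'   array), `epoch_duration`, `sampling_rate`.
#' @export
simulate_epochs <- function(model, n_epochs = 135L, duration = 0.5, seed = 1L) {
  if (!inherits(model, "noise_model")) stop_invalid("not a noise_model")
  n_epochs <- check_count(n_epochs, "n_epochs")
  n_times <- as.integer(round(duration * model$sampling_rate))
  if (n_times < 1L) stop_invalid("duration too short for the sampling rate")
  n_sensors <- model$n_sensors
  n_factors <- ncol(model$spatial_mixing)
  a <- model$ar_coefficient
  out <- array(0, dim = c(n_epochs, n_sensors, n_times))
  with_seed(derive_seed(seed, 7L), {
    for (e in seq_len(n_epochs)) {
      x <- matrix(0, n_sensors, n_times)
      if (n_factors > 0L) {
        Z <- matrix(stats::rnorm(n_factors * n_times), n_factors, n_times)
        if (a > 0) {
          s <- sqrt(1 - a^2)
          for (t in 2:n_times) Z[, t] <- a * Z[, t - 1] + s * Z[, t]
        }
        x <- model$spatial_mixing %*% Z
      }
      if (model$sensor_floor > 0) {
        x <- x + matrix(stats::rnorm(n_sensors * n_times,
                                     sd = sqrt(model$sensor_floor)),
                        n_sensors, n_times)
      }
      out[e, , ] <- x
    }
  })
  structure(list(epochs = out, epoch_duration = duration,
                 sampling_rate = model$sampling_rate,
                 n_epochs = n_epochs, n_sensors = n_sensors, n_times = n_times),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d sensors x %d samples (%.3g s @ %g Hz)\n",
              x$n_epochs, x$n_sensors, x$n_times, x$epoch_duration,
              x$sampling_rate))
  invisible(x)
}

subset_epochs <- function(set, idx) {
  structure(list(epochs = set$epochs[idx, , , drop = FALSE],
                 epoch_duration = set$epoch_duration,
                 sampling_rate = set$sampling_rate,
                 n_epochs = length(idx), n_sensors = set$n_sensors,
                 n_times = set$n_times),
            class = "epoch_set")
}

#' Split epochs into an evoked-averaging pool and a covariance pool
#'
#' A seeded random draw without replacement of `n_evoked` epochs forms the
#' evoked pool; the remainder is reserved for noise-covariance estimation
#' (defaults mirror a 135 = 49 + 86 split).
#'
#' @param set An `epoch_set`.
#' @param n_evoked Number of epochs for the evoked pool (< n_epochs).
#' @param seed Integer seed.
#' @return List with elements `evoked` and `covariance`, both `epoch_set`s.
#' @export
split_epochs <- function(set, n_evoked = 49L, seed = 1L) {
  if (!inherits(set, "epoch_set")) stop_invalid("not an epoch_set")
  n_evoked <- check_count(n_evoked, "n_evoked")
  if (n_evoked >= set$n_epochs) {
    stop_invalid("`n_evoked` (%d) must be smaller than the number of epochs (%d)",
                 n_evoked, set$n_epochs)
  }
  idx <- with_seed(derive_seed(seed, 13L), sample.int(set$n_epochs, n_evoked))
  list(evoked = subset_epochs(set, sort(idx)),
       covariance = subset_epochs(set, setdiff(seq_len(set$n_epochs), idx)))
}

#' Evoked-average noise matrix
#'
#' Draws a seeded random contiguous window of `n_times` samples from each
#' epoch in the pool and averages the windows, emulating the residual noise
#' in an evoked response averaged over `n_epochs` trials (variance shrinks
#' as ~1/n_epochs).
#'
#' @param pool An `epoch_set` (the evoked pool).
#' @param n_times Window length in samples (<= epoch length).
#' @param seed Integer seed for the window draws.
#' @return `n_sensors x n_times` noise matrix.
#' @export
evoked_noise <- function(pool, n_times = 100L, seed = 1L) {
  if (!inherits(pool, "epoch_set")) stop_invalid("not an epoch_set")
  n_times <- check_count(n_times, "n_times")
  if (n_times > pool$n_times) {
    stop_invalid("window of %d samples exceeds epoch length %d", n_times, pool$n_times)
  }
  acc <- matrix(0, pool$n_sensors, n_times)
  with_seed(derive_seed(seed, 17L), {
    for (e in seq_len(pool$n_epochs)) {
      start <- sample.int(pool$n_times - n_times + 1L, 1L)
      acc <- acc + matrix(pool$epochs[e, , start:(start + n_times - 1L)],
                          pool$n_sensors, n_times)
    }
  })
  acc / pool$n_epochs
}

#' Estimate the noise covariance from an epoch pool
#'
#' Sample covariance pooled over epochs and time with the per-epoch,
#' per-sensor mean removed, plus diagonal loading (`loading` times the mean
#' diagonal) to guarantee positive definiteness.
#'
#' @param pool An `epoch_set` with at least 2 epochs.
#' @param loading Diagonal loading fraction (>= 0).
#' @return A `noise_covariance` with fields `C`, `n_epochs_used`, `loading`.
#' @export
estimate_covariance <- function(pool, loading = 0.05) {
  if (!inherits(pool, "epoch_set")) stop_invalid("not an epoch_set")
  if (pool$n_epochs < 2L) stop_invalid("need at least 2 epochs to estimate covariance")
  loading <- check_scalar(loading, "loading", min = 0)
  demeaned <- lapply(seq_len(pool$n_epochs), function(e) {
    x <- matrix(pool$epochs[e, , ], pool$n_sensors, pool$n_times)
    x - rowMeans(x)
  })
  X <- do.call(cbind, demeaned) # n_sensors x (n_epochs * n_times)
  C <- tcrossprod(X) / (ncol(X) - 1)
  C <- (C + t(C)) / 2
  C <- C + diag(loading * mean(diag(C)), nrow(C))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop_invalid("estimated covariance is not positive definite (increase `loading`)")
  }
  structure(list(C = C, n_epochs_used = pool$n_epochs, loading = loading),
            class = "noise_covariance")
}

#' @export
print.noise_covariance <- function(x, ...) {
  cat(sprintf("<noise_covariance> %d x %d from %d epochs, loading %.3g\n",
              nrow(x$C), ncol(x$C), x$n_epochs_used, x$loading))
  invisible(x)
}

#' Rescale a noise covariance to the gain-matrix power scale
#'
#' Scales `C` so that `tr(C) = tr(G G')`, putting unit-amplitude source
#' signal power and noise power on a common scale. The Tikhonov coupling
#' `lambda^2 = SNR^-2` is only meaningful on such a common scale: gain
#' entries carry field units per unit dipole moment while recorded noise
#' carries field units, so their raw traces differ by many orders of
#' magnitude.
#'
#' @param gain A `gain_matrix`.
#' @param cov A `noise_covariance`.
#' @return A `noise_covariance` with rescaled `C`.
#' @export
balance_covariance <- function(gain, cov) {
  s <- sum(gain$values^2) / sum(diag(cov$C))
  out <- cov
  out$C <- cov$C * s
  out$scale <- s
  out
}
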