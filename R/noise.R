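#' Construct a noise profile
#'
#' Bundles the baseline noise SD and the spatial resolution used by the
#' segmentation rules. Usually produced by [characterize_noise()]; construct
#' directly when the noise level is known (e.g. for simulated data).
#'
#' @param noise_sd_bp Baseline Gaussian noise SD (bp), >= 0.
#' @param resolution_bp Spatial resolution (bp): the smallest reliably
#'   detectable length change. Defaults to the 200 bp floor.
#' @param n_baselines Number of baseline traces the profile was derived from.
#' @return A one-row tibble of class `noise_profile`.
#' @export
noise_profile <- function(noise_sd_bp,
                          resolution_bp = .fs_const$resolution_floor,
                          n_baselines = 0L) {
  if (noise_sd_bp < 0) abort("noise_sd_bp must be >= 0")
  if (resolution_bp < noise_sd_bp) {
    abort("resolution_bp must be at least the noise SD")
  }
  structure(
    tibble(noise_sd_bp = noise_sd_bp, resolution_bp = resolution_bp,
           n_baselines = as.integer(n_baselines)),
    class = c("noise_profile", "tbl_df", "tbl", "data.frame")
  )
}

#' Characterize baseline noise and derive the spatial resolution
#'
#' For each baseline trace the histogram of positions is fitted with a
#' Gaussian; the noise SD of the profile is the largest fitted SD. The
#' spatial resolution is 200 bp when every fitted SD is below 200 bp
#' (the assay's floor); otherwise the largest SD is rounded up to the next
#' 100 bp.
#'
#' @param baselines A single baseline tibble (`time_s`, `position_bp`), a
#'   list of them, or one tibble with a `trace_id` column. Each baseline must
#'   cover at least 60 s.
#' @return A [noise_profile()] tibble with `noise_sd_bp`, `resolution_bp`,
#'   `n_baselines`.
#' @examples
#' bl <- simulate_baseline(150, 500, seed = 1)
#' characterize_noise(bl)
#' @export
characterize_noise <- function(baselines) {
  if (is.data.frame(baselines)) {
    baselines <- if ("trace_id" %in% names(baselines)) {
      split(baselines, baselines$trace_id)
    } else list(baselines)
  }
  if (length(baselines) == 0) abort("need at least one baseline trace")
  sds <- map_dbl(baselines, function(b) {
    stopifnot(is.data.frame(b), "position_bp" %in% names(b))
    if (max(b$time_s) - min(b$time_s) < 60) {
      abort("each baseline must cover at least 60 s")
    }
    .gaussian_sd_of_histogram(b$position_bp)
  })
  max_sd <- max(sds)
  resolution <- if (max_sd < .fs_const$resolution_floor) {
    .fs_const$resolution_floor
  } else {
    ceiling(max_sd / 100) * 100
  }
  noise_profile(max_sd, resolution, length(baselines))
}

# Gaussian SD from a least-squares fit to the position histogram; falls back
# to the sample SD when the histogram fit is degenerate.
.gaussian_sd_of_histogram <- function(y) {
  s <- sd(y)
  if (!is.finite(s) || s == 0) return(0)
  h <- graphics::hist(y, breaks = "FD", plot = FALSE)
  df <- tibble(x = h$mids, cnt = h$counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(cnt ~ A * exp(-(x - mu)^2 / (2 * sig^2)), data = df,
                      start = list(A = max(df$cnt), mu = mean(y), sig = s),
                      lower = c(A = 0, mu = -Inf, sig = 1e-9)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(s)
  abs(coef(fit)[["sig"]])
}

#' Low-pass smooth a trace with an FFT filter
#'
#' Zeroes every Fourier component above the cutoff frequency and inverts the
#' transform. Used for display and QC only: rates are always estimated on the
#' unsmoothed trace.
#'
#' @param trace Tibble with `time_s` and one or both of `position_bp`,
#'   `position_nm`.
#' @param cutoff_hz Cutoff frequency; must be below the Nyquist frequency.
#' @return The trace with position columns replaced by their smoothed
#'   versions.
#' @export
smooth_fft <- function(trace, cutoff_hz) {
  stopifnot(is.data.frame(trace), "time_s" %in% names(trace))
  n <- nrow(trace)
  if (n < 2) return(trace)
  fs <- 1 / (trace$time_s[2] - trace$time_s[1])
  nyquist <- fs / 2
  if (cutoff_hz >= nyquist) {
    abort(sprintf("cutoff_hz must be below the Nyquist frequency (%g Hz)",
                  nyquist))
  }
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * fs / n
  keep <- freq <= cutoff_hz
  for (col in intersect(c("position_bp", "position_nm"), names(trace))) {
    spec <- fft(trace[[col]])
    spec[!keep] <- 0
    trace[[col]] <- Re(fft(spec, inverse = TRUE)) / n
  }
  trace
}
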