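#' Behavioral generator parameters
#'
#' Parameters of the synthetic response model: a three-component mixture
#' (target / swap / guess) with shared von Mises precision on the
#' doubled-angle circle, plus two systematic biases applied on
#' target-component trials — an attractive pull toward the previous trial's
#' target and a repulsive push away from the same-trial nontarget, each a
#' derivative-of-Gaussian (DoG) of the signed inducer-minus-target distance.
#'
#' Defaults emulate the study conditions this package targets: blocks of a
#' 400-trial orientation recall session with mean absolute error near 12 deg,
#' a swap rate of 0.033, and degree-scale biases peaking at intermediate
#' angular distances.
#'
#' @param kappa von Mises concentration on the doubled-angle circle
#'   (unitless, >= 0). Ignored when `noiseless = TRUE`.
#' @param p_target,p_guess,p_swap Mixture probabilities; must sum to 1.
#' @param attract_amp,attract_width Peak amplitude (deg) and peak location
#'   (deg) of the attractive between-trial DoG bias.
#' @param repulse_amp,repulse_width Same for the repulsive within-trial bias
#'   (amplitude is the peak magnitude; the bias is applied with negative
#'   sign, i.e. away from the same-trial nontarget).
#' @param noiseless If `TRUE`, the von Mises noise is suppressed entirely
#'   (the kappa -> infinity limit), leaving only the deterministic biases.
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(kappa = 8,
                            p_target = 0.92,
                            p_guess = 0.047,
                            p_swap = 0.033,
                            attract_amp = 1.5,
                            attract_width = 25,
                            repulse_amp = 1,
                            repulse_width = 20,
                            noiseless = FALSE) {
  p <- c(p_target, p_guess, p_swap)
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9) {
    abort("mixture probabilities must lie in [0,1] and sum to 1 (within 1e-9).")
  }
  if (attract_width <= 0 || repulse_width <= 0) abort("DoG widths must be > 0.")
  if (!noiseless && (!is.finite(kappa) || kappa < 0)) {
    abort("`kappa` must be finite and >= 0 (or set `noiseless = TRUE`).")
  }
  structure(
    list(kappa = kappa, p_target = p_target, p_guess = p_guess,
         p_swap = p_swap, attract_amp = attract_amp,
         attract_width = attract_width, repulse_amp = repulse_amp,
         repulse_width = repulse_width, noiseless = noiseless),
    class = "behavior_params"
  )
}

#' Neural generator parameters
#'
#' Parameters of the synthetic epoch model. Each trial's epoch is an
#' orientation-tuned pattern — a fixed pair of orthonormal channel vectors
#' weighted by cos/sin of the doubled encoded orientation — modulated by a
#' piecewise-linear stimulus-locked envelope, plus an optional sign-reversed
#' lingering trace of the previous trial's target and i.i.d. Gaussian sensor
#' noise. The encoded orientation may be shifted away from an inducer
#' (`repulse_shift`) when the absolute inducer distance falls inside
#' `shift_range`, emulating a repulsive encoding bias.
#'
#' @param n_channels Number of sensors (>= 8).
#' @param sfreq Sampling rate, Hz.
#' @param t_start,t_end Epoch bounds in seconds relative to stimulus onset.
#' @param signal_onset,signal_peak,signal_offset Envelope knots, seconds;
#'   must satisfy `t_start < onset < peak < offset <= t_end`.
#' @param snr Pattern amplitude over noise SD (unitless, >= 0).
#' @param repulse_shift Encoding shift magnitude in degrees, applied away
#'   from the inducer.
#' @param shift_range Two-element range `[lo, hi]` (degrees) of absolute
#'   inducer distance for which the shift applies, `0 <= lo < hi <= 90`.
#' @param linger_amp Signed amplitude of the previous-target pattern;
#'   negative values inject a sign-reversed lingering trace.
#' @param noise_sd Gaussian sensor noise SD (unitless).
#' @param seed Integer seed; fixes channel patterns, positions and noise.
#' @return A list of class `neural_params`.
#' @export
neural_params <- function(n_channels = 32,
                          sfreq = 100,
                          t_start = -0.2,
                          t_end = 0.8,
                          signal_onset = 0.1,
                          signal_peak = 0.35,
                          signal_offset = 0.75,
                          snr = 1,
                          repulse_shift = 0,
                          shift_range = c(10, 50),
                          linger_amp = 0,
                          noise_sd = 1,
                          seed = 1) {
  if (n_channels < 8) abort("`n_channels` must be >= 8.")
  if (!(t_start < signal_onset && signal_onset < signal_peak &&
        signal_peak < signal_offset && signal_offset <= t_end)) {
    abort("envelope must satisfy t_start < onset < peak < offset <= t_end.")
  }
  if (snr < 0) abort("`snr` must be >= 0.")
  if (length(shift_range) != 2 || shift_range[1] < 0 ||
      shift_range[1] >= shift_range[2] || shift_range[2] > 90) {
    abort("`shift_range` must be [lo, hi] with 0 <= lo < hi <= 90.")
  }
  structure(
    list(n_channels = as.integer(n_channels), sfreq = sfreq,
         t_start = t_start, t_end = t_end, signal_onset = signal_onset,
         signal_peak = signal_peak, signal_offset = signal_offset,
         snr = snr, repulse_shift = repulse_shift,
         shift_range = shift_range, linger_amp = linger_amp,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "neural_params"
  )
}
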