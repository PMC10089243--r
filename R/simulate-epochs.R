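#' Simulate orientation-tuned multichannel epochs
#'
#' Builds an epoched recording for one stimulus event per trial. Each
#' trial's epoch is
#' `snr * (cos(2 theta_enc) u + sin(2 theta_enc) v) h(t)
#'  + linger_amp * (cos(2 theta_prev) u + sin(2 theta_prev) v) h(t)
#'  + noise`,
#' where `u`, `v` are fixed orthonormal channel vectors, `h(t)` a
#' piecewise-linear rise/fall envelope over
#' (`signal_onset`, `signal_peak`, `signal_offset`), `theta_prev` the
#' previous trial's target (term absent on first-of-block trials) and
#' `theta_enc` the presented orientation, optionally shifted *away* from an
#' inducer orientation: `theta_enc = theta - repulse_shift * sign(delta)`
#' with `delta = circular_error(inducer, theta)`, applied when
#' `abs(delta)` lies within `shift_range`. Noise is i.i.d. Gaussian per
#' sample. Trials on which the chosen grating was not presented yield
#' noise-only epochs.
#'
#' The inducer defaults to the same-trial other grating for
#' `which_event = "grating2"` and to the previous trial's target for
#' `"grating1"`.
#'
#' @param trials A trial table (see [simulate_trials()]).
#' @param params A [neural_params()] object; its `seed` fixes patterns,
#'   positions and noise.
#' @param which_event Which stimulus presentation to epoch around.
#' @param inducer Optional numeric vector of inducer orientations per trial,
#'   overriding the default choice; `NA` disables the shift for a trial.
#' @return An `ori_epochs` object; `info` records the generation
#'   parameters, the event, and per-trial encoded orientations
#'   (`theta_enc`, `NA` for noise-only trials).
#' @export
simulate_epochs <- function(trials, params = neural_params(),
                            which_event = c("grating2", "grating1"),
                            inducer = NULL) {
  stopifnot(inherits(params, "neural_params"))
  which_event <- match.arg(which_event)
  n <- nrow(trials)
  theta <- if (which_event == "grating2") trials$ori2 else trials$ori1
  if (is.null(inducer)) {
    inducer <- if (which_event == "grating2") trials$ori1 else trials$prev_target_ori
  }
  stopifnot(length(inducer) == n)

  delta <- circular_error(inducer, theta)
  shift <- rep(0, n)
  in_range <- !is.na(delta) & abs(delta) >= params$shift_range[1] &
    abs(delta) <= params$shift_range[2] & delta != 0
  shift[in_range] <- -params$repulse_shift * sign(delta[in_range])
  theta_enc <- wrap_ori(theta + shift)

  times <- seq(params$t_start, params$t_end, by = 1 / params$sfreq)
  n_t <- length(times)
  n_ch <- params$n_channels
  env <- envelope_pwl(times, params$signal_onset, params$signal_peak,
                      params$signal_offset)

  withr::with_seed(params$seed, {
    u <- rnorm(n_ch)
    v <- rnorm(n_ch)
    u <- u / sqrt(sum(u^2))
    v <- v - sum(u * v) * u
    v <- v / sqrt(sum(v^2))

    # trial x channel pattern amplitudes
    a_cos <- ifelse(is.na(theta_enc), 0, params$snr * cos(2 * theta_enc * pi / 180))
    a_sin <- ifelse(is.na(theta_enc), 0, params$snr * sin(2 * theta_enc * pi / 180))
    thp <- trials$prev_target_ori
    l_cos <- ifelse(is.na(thp), 0, params$linger_amp * cos(2 * thp * pi / 180))
    l_sin <- ifelse(is.na(thp), 0, params$linger_amp * sin(2 * thp * pi / 180))
    pat <- (a_cos + l_cos) %o% u + (a_sin + l_sin) %o% v  # trials x channels

    data <- array(rnorm(n * n_ch * n_t, sd = params$noise_sd),
                  dim = c(n, n_ch, n_t))
    for (j in seq_len(n_t)) {
      if (env[j] != 0) data[, , j] <- data[, , j] + pat * env[j]
    }
    as_ori_epochs(
      data, times, params$sfreq,
      channel_names = sprintf("CH%03d", seq_len(n_ch)),
      channel_types = rep("generic", n_ch),
      channel_positions = fibonacci_hemisphere(n_ch),
      trial_ids = trials$trial,
      info = list(params = unclass(params), which_event = which_event,
                  theta_enc = theta_enc)
    )
  })
}

# piecewise-linear envelope: 0 before onset, 1 at peak, 0 after offset
envelope_pwl <- function(t, onset, peak, offset) {
  h <- numeric(length(t))
  rise <- t >= onset & t <= peak
  fall <- t > peak & t <= offset
  h[rise] <- (t[rise] - onset) / (peak - onset)
  h[fall] <- (offset - t[fall]) / (offset - peak)
  h
}

# deterministic quasi-uniform sensor layout on the upper unit hemisphere;
# nearby indices are not necessarily nearby in space, which makes the layout
# a fair test surface for position-based neighborhoods
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                  # heights in (0, 1): upper hemisphere
  r <- sqrt(1 - z^2)
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}
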