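#' Three-component von Mises mixture model of continuous-report errors
#'
#' Fits, by expectation-maximization, the classical continuous-report
#' mixture: responses center on the target with probability `p_target`,
#' on the same-trial nontarget ("swap errors") with `p_swap`, or are
#' uniform guesses with `p_guess`. Target- and swap-centered components
#' share one von Mises concentration `kappa` on the doubled-angle circle.
#' The swap component is dropped for trials with no nontarget (its
#' responsibility is zero there); probabilities remain a single shared set.
#'
#' @param data A data frame with one row per trial.
#' @param error_target Column of signed errors to the target, degrees in
#'   (-90, 90].
#' @param error_nontarget Column of signed errors to the nontarget, or
#'   `NULL` when no trial has one; `NA` entries mark trials without a
#'   nontarget.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @return An object of class `mixture_fit` with elements `kappa`,
#'   `p` (named probabilities), `weights` (tibble of per-trial posterior
#'   responsibilities: `w_target`, `w_swap`, `w_guess`), `loglik`,
#'   `loglik_trace`, `converged`, `n_iter`, `n_trials`. `tidy()` returns
#'   the parameter estimates, `glance()` the fit summary.
#' @examples
#' trials <- simulate_trials(400, seed = 3) |> simulate_responses(seed = 3)
#' fit <- trials |>
#'   dplyr::mutate(e_t = circular_error(response, target_ori),
#'                 e_nt = circular_error(response, nontarget_ori)) |>
#'   fit_mixture(e_t, e_nt)
#' tidy(fit)
#' @export
fit_mixture <- function(data, error_target, error_nontarget = NULL,
                        max_iter = 500, tol = 1e-8) {
  e_t <- eval_tidy(enquo(error_target), data)
  e_nt <- eval_tidy(enquo(error_nontarget), data)
  n <- length(e_t)
  if (n < 3) abort("too few trials to fit a mixture.")
  if (anyNA(e_t)) abort("`error_target` must be defined for every trial.")
  if (is.null(e_nt)) e_nt <- rep(NA_real_, n)
  has_nt <- !is.na(e_nt)

  # degrees on (-90, 90] -> doubled-angle radians on (-pi, pi]
  x_t <- e_t * pi / 90
  x_s <- ifelse(has_nt, e_nt * pi / 90, 0)

  # method-of-moments initialization for kappa from the circular variance
  # of target errors; mixing weights start at a generic (0.8, 0.1, 0.1)
  rbar0 <- min(sqrt(mean(cos(x_t))^2 + mean(sin(x_t))^2), 0.95)
  # kappa floor: below ~0.5 a von Mises is near-uniform and the mixture is
  # unidentifiable against the guess component; the floor restores it
  kappa_min <- 0.5
  kappa <- max(a1inv(rbar0), kappa_min)
  p <- c(target = 0.8, swap = if (any(has_nt)) 0.1 else 0, guess = NA)
  p["guess"] <- 1 - p["target"] - p["swap"]

  log_dvm <- function(x, k) k * (cos(x) - 1) - log(2 * pi) -
    log(besselI(k, 0, expon.scaled = TRUE))
  log_unif <- -log(2 * pi)

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  w <- NULL
  for (it in seq_len(max_iter)) {
    lt <- log(p["target"]) + log_dvm(x_t, kappa)
    lg <- log(p["guess"]) + log_unif
    ls <- ifelse(has_nt, log(p["swap"] + 1e-300) + log_dvm(x_s, kappa), -Inf)
    # trials without a nontarget renormalize over the available components
    lnorm <- ifelse(has_nt, 0, log(p["target"] + p["guess"] + 1e-300))
    mx <- pmax(lt, lg, ifelse(is.finite(ls), ls, -Inf))
    den <- exp(lt - mx) + exp(lg - mx) + ifelse(is.finite(ls), exp(ls - mx), 0)
    ll <- sum(mx + log(den) - lnorm)
    trace <- c(trace, ll)
    w <- cbind(
      w_target = exp(lt - mx) / den,
      w_swap = ifelse(is.finite(ls), exp(ls - mx) / den, 0),
      w_guess = exp(lg - mx) / den
    )
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step
    p <- c(target = mean(w[, "w_target"]), swap = mean(w[, "w_swap"]),
           guess = mean(w[, "w_guess"]))
    denom <- sum(w[, "w_target"]) + sum(w[, "w_swap"])
    if (denom > 0) {
      rbar <- (sum(w[, "w_target"] * cos(x_t)) +
                 sum(w[, "w_swap"] * cos(x_s) * has_nt)) / denom
      kappa <- min(max(a1inv(max(rbar, 0)), kappa_min), 1e3)
    }
  }
  structure(
    list(kappa = kappa,
         p = c(p_target = unname(p["target"]), p_swap = unname(p["swap"]),
               p_guess = unname(p["guess"])),
         weights = as_tibble(w), loglik = trace[length(trace)],
         loglik_trace = trace, converged = converged,
         n_iter = length(trace), n_trials = n),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> kappa = %.3f, p_target = %.3f, p_swap = %.3f, p_guess = %.3f\n",
    x$kappa, x$p["p_target"], x$p["p_swap"], x$p["p_guess"]))
  cat(sprintf("  loglik = %.3f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @rdname fit_mixture
#' @param x A `mixture_fit` object.
#' @param ... Unused.
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(term = c("kappa", "p_target", "p_swap", "p_guess"),
         estimate = c(x$kappa, unname(x$p)))
}

#' @rdname fit_mixture
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
         n_trials = x$n_trials)
}
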