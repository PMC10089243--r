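#' Configuration for a simulated end-to-end run
#'
#' Collects every tunable of the simulate -> behavior -> decode -> neural
#' bias -> stats workflow into one serializable list. A run is reproducible
#' from the config alone; [run_pipeline()] stamps every output with a hash
#' of the config that produced it.
#'
#' @param seed Master seed for the run.
#' @param n_trials,block_size,condition_mix Trial-table layout (see
#'   [simulate_trials()]).
#' @param behavior A [behavior_params()] object.
#' @param neural A [neural_params()] object.
#' @param which_event Which grating presentation to decode.
#' @param window_len,n_folds,var_kept,n_classes Decoding parameters.
#' @param inducer,delta_range Neural-bias trial selection (see
#'   [select_inducer_trials()]).
#' @param analysis_window Time window (s) for scalar summaries.
#' @param n_iter Permutation iterations for the sign-flip null.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       n_trials = 400, block_size = 50,
                       condition_mix = c(0.25, 0.25, 0.25, 0.25),
                       behavior = behavior_params(),
                       neural = neural_params(seed = seed),
                       which_event = "grating2",
                       window_len = 5, n_folds = 10, var_kept = 0.90,
                       n_classes = 10,
                       inducer = "same_trial_other_grating",
                       delta_range = NULL,
                       analysis_window = c(0.25, 0.6),
                       n_iter = 10000) {
  structure(
    list(seed = seed, n_trials = n_trials, block_size = block_size,
         condition_mix = condition_mix, behavior = behavior,
         neural = neural, which_event = which_event,
         window_len = window_len, n_folds = n_folds, var_kept = var_kept,
         n_classes = n_classes, inducer = inducer,
         delta_range = delta_range, analysis_window = analysis_window,
         n_iter = n_iter),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `behavior` and `neural`
#' sub-maps are passed to [behavior_params()] / [neural_params()].
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the `yaml` package is required to read YAML configs.")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$behavior)) raw$behavior <- do.call(behavior_params, raw$behavior)
  if (!is.null(raw$neural)) raw$neural <- do.call(neural_params, raw$neural)
  do.call(run_config, raw)
}

config_hash <- function(config) {
  if (requireNamespace("digest", quietly = TRUE)) {
    digest::digest(unclass(config), algo = "crc32")
  } else {
    # order-sensitive 32-bit FNV-1a over the deparsed config
    s <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
    h <- 2166136261
    for (b in s) h <- ((bitwXor(h, b)) * 16777619) %% 2^32
    sprintf("%08x", h)
  }
}

#' Run the full simulated-experiment workflow
#'
#' Executes simulate -> behavioral analysis -> decode -> neural bias ->
#' sign-flip inference for one synthetic subject and writes versioned
#' outputs (trial table, bias curve, mixture fit, cosine evidence summary,
#' asymmetry time course, stats report, log) into `dir`. Idempotent: the
#' same config yields byte-identical numeric outputs.
#'
#' @param config A [run_config()] object.
#' @param dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results: `trials`,
#'   `curve`, `mixture`, `evidence`, `cosine`, `asym`, `null`, and the
#'   output `dir`.
#' @export
run_pipeline <- function(config = run_config(), dir = tempfile("run_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(line, "\n", file = log_path, sep = "", append = TRUE)
    if (!quiet) message(line)
  }
  stage <- "simulate"
  result <- tryCatch({
    logf("config hash %s; stage: simulate", hash)
    trials <- simulate_trials(config$n_trials, config$block_size,
                              config$condition_mix, seed = config$seed)
    trials <- simulate_responses(trials, config$behavior, seed = config$seed)
    utils::write.csv(cbind(trials, config_hash = hash),
                     file.path(dir, "trials.csv"), row.names = FALSE)

    stage <- "behavior"
    logf("stage: behavior")
    beh <- dplyr::filter(trials, !is.na(.data$prev_target_ori))
    beh <- dplyr::mutate(
      beh,
      err = circular_error(.data$response, .data$target_ori),
      d_btw = circular_error(.data$prev_target_ori, .data$target_ori))
    curve <- bias_curve(beh, .data$err, .data$d_btw)
    utils::write.csv(cbind(as.data.frame(curve), config_hash = hash),
                     file.path(dir, "bias_curve.csv"), row.names = FALSE)
    mix <- fit_mixture(
      dplyr::mutate(trials,
                    e_t = circular_error(.data$response, .data$target_ori),
                    e_nt = circular_error(.data$response, .data$nontarget_ori)),
      .data$e_t, .data$e_nt)

    stage <- "decode"
    logf("stage: decode (%d trials)", nrow(trials))
    epochs <- simulate_epochs(trials, config$neural,
                              which_event = config$which_event)
    present <- if (config$which_event == "grating2") trials$ori2 else trials$ori1
    shown <- !is.na(present)
    if (sum(shown) < config$n_classes * config$n_folds) {
      abort(sprintf(
        "decode stage needs >= %d presented trials for %d-class, %d-fold stratified CV; got %d.",
        config$n_classes * config$n_folds, config$n_classes,
        config$n_folds, sum(shown)))
    }
    sub <- as_ori_epochs(epochs$data[shown, , , drop = FALSE], epochs$times,
                         epochs$sfreq, epochs$channel_names,
                         epochs$channel_types, epochs$channel_positions,
                         epochs$trial_ids[shown])
    feats <- build_features(sub, window_len = config$window_len)
    ev <- decode_cv(feats, present[shown],
                    class_bins(config$n_classes),
                    n_folds = config$n_folds, var_kept = config$var_kept,
                    seed = config$seed)
    cs <- cosine_evidence(align_evidence(ev, present[shown]))
    utils::write.csv(
      cbind(tidy(cs), config_hash = hash),
      file.path(dir, "cosine_evidence.csv"), row.names = FALSE)

    stage <- "neural_bias"
    logf("stage: neural bias (inducer: %s)", config$inducer)
    sel <- select_inducer_trials(trials[shown, , drop = FALSE],
                                 inducer = config$inducer,
                                 delta_range = config$delta_range)
    rel <- align_evidence(ev, present[shown])
    asym <- asymmetry_score(rel, sel, window = config$analysis_window)
    utils::write.csv(cbind(tidy(asym), config_hash = hash),
                     file.path(dir, "asymmetry.csv"), row.names = FALSE)

    stage <- "stats"
    logf("stage: stats (%d sign-flip iterations)", config$n_iter)
    null <- signflip_null(list(asym$trial_scores), neural_bias_stat,
                          n_iter = config$n_iter, seed = config$seed)
    report <- list(
      config_hash = hash, seed = config$seed,
      behavioral = list(summed_bias = summed_bias(curve),
                        mixture = as.list(tidy(mix)$estimate) |>
                          stats::setNames(tidy(mix)$term)),
      neural = list(window_mean = asym$window_mean,
                    n_cw = asym$n_cw, n_ccw = asym$n_ccw),
      stats = list(observed = null$observed, z = null$z, p_z = null$p_z,
                   p_perm = null$p_perm, n_iter = null$n_iter)
    )
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    logf("done")
    list(trials = trials, curve = curve, mixture = mix, evidence = ev,
         cosine = cs, asym = asym, null = null, dir = dir)
  }, error = function(e) {
    logf("FAILED at stage %s: %s", stage, conditionMessage(e))
    abort(sprintf("pipeline failed at stage `%s`: %s", stage,
                  conditionMessage(e)))
  })
  invisible(result)
}
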