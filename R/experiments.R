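# Deterministic derived seed for a (generator seed, hidden count) cell.
cell_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 9176 + 1) %% 2147483629)
}

# From a generated trial: representative two-cycle segment, normalized
# targets, harmonic spec (amplitudes in degrees) and a ready training
# pattern. `variant`/`amplitude_scale` control the oscillator inputs.
trial_to_pattern <- function(trial, variant = "AM", amplitude_scale = 1) {
  segment <- select_representative_cycles(trial)
  norm <- normalize_targets(segment)
  spec <- extract_harmonics(segment)
  inputs <- build_sine_inputs(spec, variant, segment$time,
                              amplitude_scale = amplitude_scale)
  list(inputs = inputs, targets = norm$signals, Tc = segment$Tc,
       spec = spec, segment = segment, norm = norm,
       velocity_kmh = trial$velocity_kmh)
}

#' Configuration for the single-pattern proof-of-concept experiment
#'
#' Trains networks to map the three-harmonic oscillator set extracted from
#' one walking trial (3 km/h) onto its six normalized elevation angles, for
#' each input variant: `SEA` (extracted fundamental), `SEB` (+0.25 Hz) and
#' `SEC` (-0.25 Hz). Defaults are desk-scale: 10 restarts instead of the
#' full-scale 100.
#'
#' @param velocity_kmh walking speed of the learned trial.
#' @param n_hidden hidden units.
#' @param n_iterations,n_restarts training budget per variant and seed.
#' @param variants non-empty subset of `c("SEA", "SEB", "SEC")`.
#' @param seeds generator seeds, one synthetic "subject" each.
#' @param duration_s,sample_rate_hz,noise_sd,cycle_jitter passed to the gait
#'   generator (noiseless, jitter-free by default so variant ordering is not
#'   masked by measurement noise).
#' @return List of class `experiment1_config`.
#' @export
experiment1_config <- function(velocity_kmh = 3, n_hidden = 30,
                               n_iterations = 10000, n_restarts = 10,
                               variants = c("SEA", "SEB", "SEC"),
                               seeds = 1:3,
                               duration_s = 20, sample_rate_hz = 100,
                               noise_sd = 0, cycle_jitter = 0) {
  variants <- match.arg(variants, several.ok = TRUE)
  if (length(variants) == 0) stop("variants must be non-empty")
  structure(as.list(environment()), class = "experiment1_config")
}

#' Run the proof-of-concept experiment
#'
#' For every generator seed and input variant: generate the trial, extract
#' the representative two-cycle segment and its harmonic spec, build the
#' variant's oscillator inputs, train with restarts and record the best mean
#' similarity index. A failing variant is reported as `NA` without aborting
#' the others.
#'
#' @param config an [experiment1_config()].
#' @param keep_models keep the best trained model per cell.
#' @return Object of class `experiment1_result`: `results` (data.frame with
#'   seed, variant, mean_si, E, recoveries), `models`, `config`.
#' @export
run_experiment1 <- function(config = experiment1_config(),
                            keep_models = TRUE) {
  stopifnot(inherits(config, "experiment1_config"))
  rows <- list(); models <- list()
  for (s in config$seeds) {
    gcfg <- gait_config(velocity_kmh = config$velocity_kmh,
                        duration_s = config$duration_s,
                        sample_rate_hz = config$sample_rate_hz,
                        noise_sd = config$noise_sd,
                        cycle_jitter = config$cycle_jitter, seed = s)
    trial <- generate_trial(gcfg)
    for (v in config$variants) {
      key <- paste0("seed", s, "_", v)
      res <- tryCatch({
        pat <- trial_to_pattern(trial, variant = v)
        tcfg <- training_config(n_iterations = config$n_iterations,
                                n_restarts = config$n_restarts,
                                seed = cell_seed(s, match(v, c("SEA", "SEB", "SEC"))))
        model <- drnn_train_restarts(list(pat[c("inputs", "targets", "Tc")]),
                                     config$n_hidden, tcfg)
        if (keep_models) models[[key]] <- model
        data.frame(seed = s, variant = v, mean_si = model$mean_si,
                   E = model$E_best, recoveries = model$recoveries)
      }, error = function(e)
        data.frame(seed = s, variant = v, mean_si = NA_real_, E = NA_real_,
                   recoveries = NA_integer_,
                   stringsAsFactors = FALSE))
      rows[[key]] <- res
    }
  }
  structure(list(results = do.call(rbind, c(rows, make.row.names = FALSE)),
                 models = models, config = config),
            class = "experiment1_result")
}

#' Configuration for multi-velocity learning and prediction
#'
#' One network per hidden-unit count is trained simultaneously on the five
#' learned walking velocities (amplitude- and frequency-modulated oscillator
#' inputs) and then asked to predict the four unlearned intermediate
#' velocities. Defaults are desk-scale (5 restarts x 5,000 iterations versus
#' the full-scale 100 x 50,000).
#'
#' @param learn_velocities,predict_velocities km/h; must be disjoint.
#' @param hidden_sweep hidden-unit counts to evaluate.
#' @param n_iterations,n_restarts training budget per cell.
#' @param seeds generator seeds (synthetic "subjects").
#' @param duration_s,sample_rate_hz,noise_sd,cycle_jitter gait generator
#'   settings (defaults mirror the generator's own defaults).
#' @return List of class `experiment2_config`.
#' @export
experiment2_config <- function(learn_velocities = c(1.5, 2.5, 3.5, 4.5, 5.5),
                               predict_velocities = c(2, 3, 4, 5),
                               hidden_sweep = c(1, 4, 20, 80),
                               n_iterations = 5000, n_restarts = 5,
                               seeds = 1,
                               duration_s = 20, sample_rate_hz = 100,
                               noise_sd = 0.3, cycle_jitter = 0.02) {
  if (length(intersect(learn_velocities, predict_velocities)) > 0)
    stop("predict velocities must be disjoint from learned velocities")
  if (length(learn_velocities) == 0 || length(hidden_sweep) == 0)
    stop("learn_velocities and hidden_sweep must be non-empty")
  structure(as.list(environment()), class = "experiment2_config")
}

# Build learned and prediction patterns for one generator seed. The common
# amplitude scale (mean a1 over the learned velocities maps to 1) keeps the
# oscillator inputs in the sigmoid's useful range while preserving the
# velocity modulation of the amplitudes.
experiment2_patterns <- function(config, seed) {
  gcfg <- gait_config(duration_s = config$duration_s,
                      sample_rate_hz = config$sample_rate_hz,
                      noise_sd = config$noise_sd,
                      cycle_jitter = config$cycle_jitter, seed = seed)
  learn_trials <- generate_dataset(config$learn_velocities, gcfg)
  specs <- lapply(learn_trials, function(tr)
    extract_harmonics(select_representative_cycles(tr)))
  amp_scale <- 1 / mean(vapply(specs, `[[`, numeric(1), "a1"))
  learn <- lapply(learn_trials, trial_to_pattern, variant = "AM",
                  amplitude_scale = amp_scale)
  predict <- NULL
  if (length(config$predict_velocities) > 0) {
    predict_trials <- generate_dataset(config$predict_velocities, gcfg)
    predict <- lapply(predict_trials, trial_to_pattern, variant = "AM",
                      amplitude_scale = amp_scale)
  }
  list(learn = learn, predict = predict, amp_scale = amp_scale)
}

#' Run the multi-velocity experiment
#'
#' For each generator seed and hidden-unit count: multi-pattern training on
#' the learned velocities with restarts, best network selected by mean
#' similarity index; prediction similarity at the unlearned velocities
#' (inputs built from harmonics extracted from trials at those velocities);
#' weight-sign and time-constant summaries of the best network. Failing
#' sweep cells are logged as `NA` and the sweep continues.
#'
#' @param config an [experiment2_config()].
#' @param keep_models keep the best model per cell.
#' @return Object of class `experiment2_result`: `results` (data.frame with
#'   seed, n_hidden, learn_si, predict_si, pct_neg_weights, median_T, E),
#'   `per_velocity` (per learned/predicted velocity SI), `models`, `config`.
#' @export
run_experiment2 <- function(config = experiment2_config(),
                            keep_models = FALSE) {
  stopifnot(inherits(config, "experiment2_config"))
  rows <- list(); vel_rows <- list(); models <- list()
  for (s in config$seeds) {
    pats <- experiment2_patterns(config, s)
    learn_pats <- lapply(pats$learn, `[`, c("inputs", "targets", "Tc"))
    pred_pats <- lapply(pats$predict %||% list(), `[`,
                        c("inputs", "targets", "Tc"))
    for (h in config$hidden_sweep) {
      key <- paste0("seed", s, "_h", h)
      res <- tryCatch({
        tcfg <- training_config(n_iterations = config$n_iterations,
                                n_restarts = config$n_restarts,
                                seed = cell_seed(s, h))
        model <- drnn_train_restarts(learn_pats, h, tcfg)
        pred_si <- if (length(pred_pats) > 0)
          mean_pattern_si(model, pred_pats) else NA_real_
        wsd <- weight_sign_distribution(model)
        tcs <- time_constant_stats(model)
        if (keep_models) models[[key]] <- model
        for (i in seq_along(learn_pats)) {
          vkey <- paste0(key, "_L", i)
          vel_rows[[vkey]] <- data.frame(
            seed = s, n_hidden = h, phase = "learning",
            velocity_kmh = config$learn_velocities[i],
            si = mean_pattern_si(model, learn_pats[i]))
        }
        for (i in seq_along(pred_pats)) {
          vkey <- paste0(key, "_P", i)
          vel_rows[[vkey]] <- data.frame(
            seed = s, n_hidden = h, phase = "prediction",
            velocity_kmh = config$predict_velocities[i],
            si = mean_pattern_si(model, pred_pats[i]))
        }
        data.frame(seed = s, n_hidden = h, learn_si = model$mean_si,
                   predict_si = pred_si, pct_neg_weights = wsd$pct_neg,
                   median_T = tcs$median, E = model$E_best)
      }, error = function(e)
        data.frame(seed = s, n_hidden = h, learn_si = NA_real_,
                   predict_si = NA_real_, pct_neg_weights = NA_real_,
                   median_T = NA_real_, E = NA_real_))
      rows[[key]] <- res
    }
  }
  structure(
    list(results = do.call(rbind, c(rows, make.row.names = FALSE)),
         per_velocity = if (length(vel_rows) > 0)
           do.call(rbind, c(vel_rows, make.row.names = FALSE)) else NULL,
         models = models, config = config),
    class = "experiment2_result")
}

#' Render a plain-markdown summary of experiment results
#'
#' @param results an `experiment1_result` or `experiment2_result`.
#' @param path optional file to write to.
#' @return Character vector of markdown lines, invisibly when written.
#' @export
make_report <- function(results, path = NULL) {
  if (is.null(results$results) || nrow(results$results) == 0)
    stop("empty results: nothing to report")
  df <- results$results
  fmt_table <- function(d) {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(x) sprintf("%.4g", x))
    header <- paste("|", paste(names(d), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(d)), collapse = " | "), "|")
    body <- apply(d, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
    c(header, sep, body)
  }
  lines <- character()
  if (inherits(results, "experiment1_result")) {
    lines <- c("# Proof of concept: oscillator variants", "",
               sprintf("Velocity %g km/h, %d hidden units, %d iterations x %d restarts.",
                       results$config$velocity_kmh, results$config$n_hidden,
                       results$config$n_iterations, results$config$n_restarts),
               "", fmt_table(df))
  } else if (inherits(results, "experiment2_result")) {
    lines <- c("# Multi-velocity learning and prediction", "",
               sprintf("Learned velocities: %s km/h; predicted: %s km/h; %d iterations x %d restarts.",
                       paste(results$config$learn_velocities, collapse = ", "),
                       paste(results$config$predict_velocities, collapse = ", "),
                       results$config$n_iterations, results$config$n_restarts),
               "", "## Similarity and structure by hidden-unit count", "",
               fmt_table(df))
    if (!is.null(results$per_velocity))
      lines <- c(lines, "", "## Per-velocity similarity", "",
                 fmt_table(results$per_velocity))
  } else {
    lines <- c("# Results", "", fmt_table(df))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
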