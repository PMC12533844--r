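#' Simulate a stimulus-response experiment
#'
#' Generates \code{n_fish * n_trials} synthetic acquisitions with a stimulus
#' event at \code{onset_s}. In a known fraction \code{p_respond} of trials
#' (drawn per trial) the elicited archetype (AsLB for acoustic, VsLB for
#' visual) is injected at the stimulus onset plus its archetype latency;
#' every trial also carries sparse spontaneous scoot/turn traffic away from
#' the stimulus window. The ground-truth response flag of each trial is
#' returned, so pipeline response rates can be checked against a known p.
#'
#' @param config a [synthetic_config()].
#' @param n_fish number of fish.
#' @param n_trials trials (replicate acquisitions) per fish; default 6.
#' @param stimulus "acoustic" or "visual".
#' @param onset_s stimulus onset; default 5.
#' @param p_respond probability a trial contains the elicited bout.
#' @param seed RNG seed.
#' @return list of trials, each with \code{fish_id}, \code{trial_id},
#'   \code{track}, \code{labels}, \code{event}, \code{responded_truth}.
#' @export
simulate_experiment <- function(config, n_fish, n_trials = 6,
                                stimulus = "acoustic", onset_s = 5,
                                p_respond = 0.8, seed = 1) {
  set.seed(seed)
  target <- if (stimulus == "acoustic") "AsLB" else "VsLB"
  arch <- archetype_params(target, fps = config$fps)
  n_tot <- n_fish * n_trials
  # exactly round(p * n) trials respond, so the injected fraction is known
  responders <- seq_len(n_tot) %in% sample.int(n_tot, round(p_respond * n_tot))
  trials <- list()
  for (f in seq_len(n_fish)) for (tr in seq_len(n_trials)) {
    responds <- responders[(f - 1L) * n_trials + tr]
    sched <- data.frame(start_s = c(1.2, 7.8), label = c("scoot", "turn"))
    if (responds) {
      lat <- stats::runif(1, arch$latency_range[1], arch$latency_range[2])
      sched <- rbind(sched, data.frame(start_s = onset_s + lat,
                                       label = target))
    }
    ev <- stimulus_event(stimulus, onset_s)
    g <- generate_track(sched, config,
                        seed = sample.int(.Machine$integer.max, 1),
                        events = list(ev))
    g$track$well_id <- sprintf("fish%02d_trial%d", f, tr)
    trials[[length(trials) + 1L]] <-
      list(fish_id = f, trial_id = tr, track = g$track, labels = g$labels,
           event = ev, responded_truth = responds)
  }
  trials
}

#' Per-frame behavior calls for one track
#'
#' Runs the inference half of the pipeline on a single acquisition: windows,
#' egocentric alignment, featurization with the classifier's frozen stats,
#' classification, and majority voting.
#'
#' @param track a [pose_track()].
#' @param classifier a \code{behavior_classifier}.
#' @param W window width; default the classifier's.
#' @return a \code{frame_labels} object.
#' @export
call_behaviors <- function(track, classifier, W = NULL) {
  if (is.null(W)) W <- classifier$W
  w <- egocentric_align(make_windows(track, W = W))
  pred <- predict(classifier, w)
  majority_vote(pred$labels, W = W, T_ = n_frames(track),
                classes = classifier$classes, starts = w$starts,
                fps = track$fps)
}

#' Run the pipeline end to end
#'
#' One-call orchestration of simulate -> featurize -> train -> predict ->
#' vote -> bouts -> assays on synthetic data, writing every stage product
#' plus a run manifest (config snapshot, package version, per-stage output
#' file hashes) into \code{out_dir}. Reruns with the same config and seed
#' reproduce identical outputs, hence identical hashes.
#'
#' @param out_dir output directory (created).
#' @param plate_format 24 or 96.
#' @param n_fish,n_trials experiment size; defaults 4 fish x 2 trials keep
#'   the default run light.
#' @param stimulus "acoustic" or "visual".
#' @param p_respond fraction of trials with an injected elicited bout.
#' @param n_per_class training examples per class; default 100.
#' @param seed master seed; stage seeds derive from it.
#' @param W window width; default 40.
#' @param ntree forest size; default 100.
#' @param stages subset of c("simulate", "train", "predict", "respond") to
#'   run; later stages require the products of earlier ones in memory, so
#'   this must be a prefix of the full list.
#' @param verbose log stage timings to stderr.
#' @return list with the manifest and in-memory stage products.
#' @export
run_pipeline <- function(out_dir, plate_format = 24, n_fish = 4,
                         n_trials = 2, stimulus = "acoustic",
                         p_respond = 0.75, n_per_class = 100, seed = 1,
                         W = 40, ntree = 100,
                         stages = c("simulate", "train", "predict",
                                    "respond"),
                         verbose = FALSE) {
  all_stages <- c("simulate", "train", "predict", "respond")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  idx <- sort(match(stages, all_stages))
  if (!identical(idx, seq_len(max(idx))))
    stop("dependency error: stage '",
         all_stages[setdiff(seq_len(max(idx)), idx)[1]],
         "' must run before '", all_stages[max(idx)], "'")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- synthetic_config(plate_format = plate_format)
  log_ <- function(...) if (verbose) message(sprintf(...))
  outputs <- character(0)
  res <- list()

  if ("simulate" %in% stages) {
    t0 <- Sys.time()
    res$dataset <- generate_labeled_dataset(cfg, n_per_class,
                                            seed = seed, W = W)
    res$trials <- simulate_experiment(cfg, n_fish, n_trials,
                                      stimulus = stimulus,
                                      p_respond = p_respond,
                                      seed = seed + 1L)
    lab_path <- file.path(out_dir, "training_labels.csv")
    utils::write.csv(data.frame(index = seq_along(res$dataset$labels),
                                label = res$dataset$labels),
                     lab_path, row.names = FALSE)
    outputs <- c(outputs, lab_path)
    log_("simulate: %d labeled windows, %d trials (%.1f s)",
         length(res$dataset$labels), length(res$trials),
         as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("train" %in% stages) {
    t0 <- Sys.time()
    feats <- featurize(res$dataset$windows)
    sp <- split_dataset(res$dataset$labels, 0.9, seed = seed + 2L)
    train_fm <- structure(list(vectors = feats$vectors[sp$train, ,
                                                       drop = FALSE],
                               norm_max = feats$norm_max,
                               norm_mean = feats$norm_mean,
                               window_starts = feats$window_starts[sp$train],
                               usable = feats$usable[sp$train], W = W,
                               plate_format = plate_format),
                          class = "feature_matrix")
    res$classifier <- train_classifier(train_fm,
                                       res$dataset$labels[sp$train],
                                       rf_seed = seed + 3L, ntree = ntree)
    test_fm <- feats
    test_fm$vectors <- feats$vectors[sp$test, , drop = FALSE]
    test_fm$usable <- feats$usable[sp$test]
    test_fm$window_starts <- feats$window_starts[sp$test]
    res$evaluation <- evaluate_classifier(res$classifier, test_fm,
                                          res$dataset$labels[sp$test])
    bundle_path <- file.path(out_dir, "classifier.rds")
    save_classifier(res$classifier, bundle_path)
    eval_path <- file.path(out_dir, "evaluation.json")
    jsonlite::write_json(list(macro_f1 = res$evaluation$macro_f1,
                              f1 = as.list(res$evaluation$f1),
                              confusion = res$evaluation$confusion),
                         eval_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    outputs <- c(outputs, bundle_path, eval_path)
    log_("train: macro-F1 %.3f (%.1f s)", res$evaluation$macro_f1,
         as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("predict" %in% stages) {
    t0 <- Sys.time()
    res$calls <- lapply(res$trials, function(tr)
      call_behaviors(tr$track, res$classifier, W = W))
    res$bouts <- lapply(res$calls, extract_bouts)
    calls_df <- do.call(rbind, lapply(seq_along(res$trials), function(i)
      data.frame(fish_id = res$trials[[i]]$fish_id,
                 trial_id = res$trials[[i]]$trial_id,
                 frame = seq_len(res$calls[[i]]$T) - 1L,
                 label = res$calls[[i]]$labels,
                 margin = res$calls[[i]]$margin)))
    calls_path <- file.path(out_dir, "calls.csv")
    utils::write.csv(calls_df, calls_path, row.names = FALSE)
    bouts_df <- do.call(rbind, lapply(seq_along(res$trials), function(i) {
      b <- res$bouts[[i]]
      if (!nrow(b)) return(NULL)
      kin <- kinematic_series(res$trials[[i]]$track)
      b <- annotate_bouts(b, kin)
      cbind(data.frame(fish_id = res$trials[[i]]$fish_id,
                       trial_id = res$trials[[i]]$trial_id), b)
    }))
    bouts_path <- file.path(out_dir, "bouts.csv")
    utils::write.csv(bouts_df, bouts_path, row.names = FALSE)
    outputs <- c(outputs, calls_path, bouts_path)
    log_("predict: %d trials called (%.1f s)", length(res$calls),
         as.numeric(Sys.time() - t0, units = "secs"))
  }

  if ("respond" %in% stages) {
    t0 <- Sys.time()
    trials_fl <- lapply(seq_along(res$trials), function(i)
      list(fish_id = res$trials[[i]]$fish_id,
           trial_id = res$trials[[i]]$trial_id,
           frame_labels = res$calls[[i]],
           event = res$trials[[i]]$event))
    res$assay <- response_assay(trials_fl, fps = cfg$fps)
    tab_path <- file.path(out_dir, "responses.csv")
    utils::write.csv(res$assay$table, tab_path, row.names = FALSE)
    rates_path <- file.path(out_dir, "rates.json")
    jsonlite::write_json(list(trial_rate = res$assay$trial_rate,
                              fish_rate = res$assay$fish_rate,
                              p_respond_truth = p_respond),
                         rates_path, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, tab_path, rates_path)
    log_("respond: trial rate %.3f, fish rate %.3f (%.1f s)",
         res$assay$trial_rate, res$assay$fish_rate,
         as.numeric(Sys.time() - t0, units = "secs"))
  }

  manifest <- list(
    config = list(plate_format = plate_format, n_fish = n_fish,
                  n_trials = n_trials, stimulus = stimulus,
                  p_respond = p_respond, n_per_class = n_per_class,
                  seed = seed, W = W, ntree = ntree, stages = stages),
    version = as.character(utils::packageVersion("fishbout")),
    outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
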