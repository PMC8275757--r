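# Pipeline driver: preprocess -> contrast/cluster -> PDI -> scores ->
# models -> prediction, with a provenance manifest.

#' Pipeline configuration
#'
#' Settings for [run_pipeline()]. All seeds are explicit; every output file
#' is stamped with the configuration hash.
#'
#' @param seed master seed; stage seeds default to offsets of it.
#' @param cohort a [cohort_config()] for simulate-first mode (its own seed
#'   wins if set); \code{NULL} uses \code{seed}.
#' @param input_dir directory of CSV inputs (ignored in simulate mode).
#' @param out_dir output directory (created if needed).
#' @param simulate generate a synthetic cohort instead of reading inputs.
#' @param bin_width_ms epoch bin width override (NULL = native grid).
#' @param window,baseline epoching windows, ms relative to stimulus onset.
#' @param threshold,n_iter,flip_mode,tail cluster-test settings.
#' @param window_mode \code{"data_driven"} (largest significant cluster;
#'   error if none), \code{"fixed_paper"} (3.4-5.6 s) or \code{"auto"}
#'   (data-driven with fixed fallback, logged).
#' @param engine regression engine, \code{"bayes"} or \code{"ols"}.
#' @param run_prediction run the leave-2-out analysis.
#' @param prediction_n_iter iterations of the accuracy permutation null
#'   (0 skips the null).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = NULL,
                            input_dir = NULL,
                            out_dir = tempfile("pupilcontrol_out_"),
                            simulate = TRUE,
                            bin_width_ms = NULL,
                            window = c(-500, 7000),
                            baseline = c(-500, 0),
                            threshold = 3,
                            n_iter = 1000,
                            flip_mode = "per_participant",
                            tail = "positive",
                            window_mode = "auto",
                            engine = "bayes",
                            run_prediction = TRUE,
                            prediction_n_iter = 1000) {
  if (!is_count(seed)) pc_stop_config("seed must be a single integer")
  if (!window_mode %in% c("data_driven", "fixed_paper", "auto"))
    pc_stop_config("unknown window_mode: ", window_mode)
  if (!simulate && is.null(input_dir))
    pc_stop_config("input_dir is required when simulate = FALSE")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

load_cohort_inputs <- function(input_dir) {
  f <- function(name) file.path(input_dir, name)
  runs <- read_pupil_multi(f("pupil_samples.csv"))
  events <- read_events_csv(f("events.csv"))
  ratings <- read_ratings_csv(f("ratings.csv"))
  choices <- read_choices_csv(f("choices.csv"))
  demo <- NULL
  if (file.exists(f("participants.csv"))) {
    demo <- utils::read.csv(f("participants.csv"), stringsAsFactors = FALSE)
    check_columns(demo, list(participant_id = "character", age = "numeric",
                             task_order = "character"), f("participants.csv"))
  }
  ids <- names(runs)
  participants <- lapply(ids, function(id) {
    i <- if (!is.null(demo)) match(id, demo$participant_id) else NA_integer_
    list(participant_id = id,
         run = runs[[id]],
         events = events[events$participant_id == id, , drop = FALSE],
         ratings = ratings[ratings$participant_id == id, , drop = FALSE],
         choices = choices[choices$participant_id == id, , drop = FALSE],
         age = if (!is.na(i)) demo$age[i] else NA_real_,
         task_order = if (!is.na(i)) demo$task_order[i] else NA_character_)
  })
  names(participants) <- ids
  participants
}

# multi-participant pupil sample file -> named list of runs
read_pupil_multi <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"lost" %in% names(df)) df$lost <- 0
  out <- lapply(split(df, df$participant_id), function(d) {
    dt <- diff(d$t_ms)
    pupil_run(ifelse(d$lost == 1, NA_real_, d$diameter), 1000 / dt[1],
              loss_flags = d$lost == 1, participant_id = d$participant_id[1])
  })
  out
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing, the Reappraise>View contrast and cluster test,
#' PDI extraction, behavioural scores, the success and HCS regressions, the
#' PDI-HCS rank correlation and (optionally) the leave-2-out prediction.
#' All numeric outputs are written under \code{config$out_dir} together
#' with a manifest carrying the configuration and its hash; the run is
#' byte-reproducible given the configuration.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a result bundle (list) with elements \code{cohort}
#'   (simulate mode), \code{epochs}, \code{contrast}, \code{cluster},
#'   \code{pdi}, \code{scores}, \code{success_model}, \code{hcs_model},
#'   \code{rank_correlation}, \code{prediction}, \code{log},
#'   \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  stage <- "input"
  res <- tryCatch({
    if (config$simulate) {
      ccfg <- config$cohort %||% cohort_config(seed = config$seed)
      cohort <- generate_cohort(ccfg)
      note("simulated cohort of ", nrow(cohort$truth),
           " participants (seed ", ccfg$seed, ")")
      participants <- cohort$participants
    } else {
      cohort <- NULL
      participants <- load_cohort_inputs(config$input_dir)
      note("loaded ", length(participants), " participants from ",
           config$input_dir)
    }

    stage <- "preprocess"
    epochs <- lapply(participants, function(p) {
      preprocess_run(p$run, p$events, config$window, config$baseline,
                     config$bin_width_ms)
    })
    note("preprocessed ", length(epochs), " runs")

    stage <- "cluster"
    contrast <- build_contrast(epochs)
    note("contrast over ", nrow(contrast), " participants x ",
         ncol(contrast), " bins")
    ct <- cluster_test(contrast, threshold = config$threshold,
                       n_iter = config$n_iter, flip_mode = config$flip_mode,
                       tail = config$tail, seed = config$seed + 1L)

    stage <- "pdi"
    pdi <- switch(config$window_mode,
      data_driven = compute_pdi(contrast, ct),
      fixed_paper = compute_pdi(contrast, NULL),
      auto = if (!is.null(ct$significant_window)) compute_pdi(contrast, ct)
             else {
               note("no significant cluster; falling back to the fixed 3.4-5.6 s window")
               compute_pdi(contrast, NULL)
             })

    stage <- "scores"
    scores <- if (!is.null(cohort)) build_score_table(cohort, pdi) else
      score_table_from_tables(participants, pdi)

    stage <- "models"
    success_model <- fit_success_model(scores, engine = config$engine)
    hcs_model <- fit_hcs_model(scores, engine = config$engine)
    rc <- rank_correlation(scores$PDI, scores$HCS)

    stage <- "prediction"
    prediction <- NULL
    if (config$run_prediction) {
      prediction <- if (config$prediction_n_iter > 0)
        accuracy_permutation_null(scores, config$prediction_n_iter,
                                  seed = config$seed + 2L)
      else loo2_accuracy(scores)
    }

    list(cohort = cohort, epochs = epochs, contrast = contrast, cluster = ct,
         pdi = pdi, scores = scores, success_model = success_model,
         hcs_model = hcs_model, rank_correlation = rc,
         prediction = prediction, log = log)
  }, pc_data_error = function(e) {
    pc_stop_data("pipeline stage '", stage, "': ", conditionMessage(e))
  })

  write_pipeline_outputs(res, config)
  invisible(res)
}

score_table_from_tables <- function(participants, pdi) {
  rows <- lapply(participants, function(p) {
    s <- reappraisal_success(p$ratings$view_rating, p$ratings$reappraise_rating,
                             p$ratings$valence)
    data.frame(participant_id = p$participant_id,
               RS = overall_success(s, p$ratings$valence),
               AffectiveDistance = affective_distance(p$ratings$view_rating),
               HCS = as.numeric(health_challenge_success(p$choices)),
               Age = p$age %||% NA_real_,
               TaskOrder = p$task_order %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$PDI <- pdi$pdi[match(out$participant_id, pdi$participant_id)]
  out <- out[, c("participant_id", "PDI", "RS", "AffectiveDistance",
                 "HCS", "Age", "TaskOrder")]
  class(out) <- c("score_table", "data.frame")
  out
}

regression_json <- function(fit) {
  list(model = fit$model, engine = fit$engine, n = fit$n,
       coefficients = fit$coefficients, sigma = fit$sigma,
       r_squared = fit$r_squared,
       bayes_factor = fit$bayes_factor %||% NULL)
}

write_pipeline_outputs <- function(res, config) {
  cfg_plain <- unclass(config)
  cfg_plain$cohort <- if (!is.null(config$cohort)) unclass(config$cohort)
  # hash captures the analysis settings, not where they ran
  hash <- pc_hash(cfg_plain[setdiff(names(cfg_plain),
                                    c("out_dir", "input_dir"))])
  f <- function(name) file.path(config$out_dir, name)

  pdi_out <- res$pdi
  pdi_out$config_hash <- hash
  utils::write.csv(pdi_out, f("pdi.csv"), row.names = FALSE)
  sc <- as.data.frame(res$scores); sc$config_hash <- hash
  utils::write.csv(sc, f("scores.csv"), row.names = FALSE)
  write_cluster_json(res$cluster, f("cluster.json"))
  models <- list(config_hash = hash,
                 success_model = regression_json(res$success_model),
                 hcs_model = regression_json(res$hcs_model),
                 rank_correlation = unclass(res$rank_correlation))
  jsonlite::write_json(models, f("models.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  if (!is.null(res$prediction)) {
    pr <- res$prediction
    out <- if (inherits(pr, "loo2_permutation"))
      list(accuracy = pr$observed$accuracy, n_splits = pr$observed$n_splits,
           tie_count = pr$observed$tie_count, p = pr$p, n_iter = pr$n_iter,
           seed = pr$seed, config_hash = hash)
    else list(accuracy = pr$accuracy, n_splits = pr$n_splits,
              tie_count = pr$tie_count, config_hash = hash)
    jsonlite::write_json(out, f("prediction.json"), auto_unbox = TRUE,
                         digits = NA)
    if (inherits(pr, "loo2_permutation"))
      utils::write.csv(data.frame(accuracy = pr$null_accuracies),
                       f("prediction_null.csv"), row.names = FALSE)
  }
  manifest <- list(config = cfg_plain, config_hash = hash,
                   files = list.files(config$out_dir), log = res$log)
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(hash)
}

#' Write a simulated cohort to CSV inputs
#'
#' Materialises a synthetic cohort in the four-file CSV layout that
#' [run_pipeline()] reads in non-simulate mode (\code{pupil_samples.csv},
#' \code{events.csv}, \code{ratings.csv}, \code{choices.csv}).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- do.call(rbind, lapply(cohort$participants, function(p)
    data.frame(participant_id = p$participant_id, t_ms = pupil_time(p$run),
               diameter = p$run$diameter, lost = as.integer(p$run$loss_flags))))
  utils::write.csv(samples, file.path(dir, "pupil_samples.csv"),
                   row.names = FALSE, na = "")
  bind <- function(field) do.call(rbind, lapply(cohort$participants, function(p)
    cbind(participant_id = p$participant_id, p[[field]])))
  write_events_csv(bind("events"), file.path(dir, "events.csv"))
  write_ratings_csv(bind("ratings"), file.path(dir, "ratings.csv"))
  ch <- bind("choices")
  write_choices_csv(ch, file.path(dir, "choices.csv"))
  utils::write.csv(data.frame(participant_id = cohort$truth$participant_id,
                              age = cohort$truth$age,
                              task_order = cohort$truth$task_order),
                   file.path(dir, "participants.csv"), row.names = FALSE)
  invisible(dir)
}
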