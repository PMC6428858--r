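# End-to-end orchestration: corpus -> cochleagrams -> feature pool ->
# scoring -> MIF selection -> evaluation, including the control variants.

#' Compute cochleagrams for every call in a corpus
#'
#' @param corpus A corpus tibble ([generate_corpus()] / [read_corpus()]).
#' @param params A [frontend_params()].
#' @param mode `"cochleagram"` or `"waveform"` (control).
#' @return Named list of `cochleagram`s (names = `call_id`).
#' @export
corpus_cochleagrams <- function(corpus, params = frontend_params(),
                                mode = "cochleagram") {
  sr <- attr(corpus, "sample_rate")
  if (is.null(sr)) sr <- corpus$sample_rate[1]
  out <- lapply(corpus$waveform, make_representation, sample_rate = sr,
                params = params, mode = mode)
  names(out) <- corpus$call_id
  out
}

#' Whole-call feature pool (grandmother-cell control)
#'
#' Each entire within-class cochleagram is one feature.
#'
#' @param cochleagrams Named list of within-class training `cochleagram`s.
#' @return Unscored feature tibble.
#' @export
whole_call_pool <- function(cochleagrams) {
  nms <- names(cochleagrams)
  rows <- lapply(seq_along(cochleagrams), function(i) {
    g <- cochleagrams[[i]]
    nch <- nrow(g$rates)
    tibble::tibble(
      feature_id = sprintf("whole%04d", i), source_call = nms[i],
      ch_lo = 1L, ch_hi = nch, t_on_ms = 0,
      length_ms = ncol(g$rates) / g$frame_rate * 1000,
      bandwidth_oct = if (nch == 1) 0 else
        log2(g$center_freqs[nch] / g$center_freqs[1]),
      patch = list(g$rates))
  })
  dplyr::bind_rows(rows)
}

#' Averaged-call feature (single-template control)
#'
#' Aligns every within-class training cochleagram to the longest one at its
#' best NCC lag and averages, yielding a single average-call template.
#'
#' @param cochleagrams Named list of within-class training `cochleagram`s.
#' @return Unscored feature tibble with one row.
#' @export
average_call_pool <- function(cochleagrams) {
  lens <- vapply(cochleagrams, function(g) ncol(g$rates), integer(1))
  ref <- cochleagrams[[which.max(lens)]]
  acc <- ref$rates
  cnt <- matrix(1, nrow(acc), ncol(acc))
  for (i in seq_along(cochleagrams)) {
    if (i == which.max(lens)) next
    g <- cochleagrams[[i]]
    L <- ncol(g$rates)
    if (stats::var(as.numeric(g$rates)) == 0) next
    tr <- ncc_trace_cpp(g$rates, ref$rates)
    lag <- which.max(tr) - 1L
    idx <- (lag + 1):(lag + L)
    acc[, idx] <- acc[, idx] + g$rates
    cnt[, idx] <- cnt[, idx] + 1
  }
  avg <- acc / cnt
  nch <- nrow(avg)
  tibble::tibble(
    feature_id = "average_call", source_call = names(cochleagrams)[1],
    ch_lo = 1L, ch_hi = nch, t_on_ms = 0,
    length_ms = ncol(avg) / ref$frame_rate * 1000,
    bandwidth_oct = if (nch == 1) 0 else
      log2(ref$center_freqs[nch] / ref$center_freqs[1]),
    patch = list(avg))
}

default_quotas <- function(n_features) {
  list(list(n = round(n_features / 3), max_bandwidth_oct = 1,
            max_length_ms = 100))
}

#' Train a MIF set on a corpus
#'
#' Runs the full training path for one binary task: front-end, random feature
#' pool (or a control pool), template-match responses, threshold/merit/weight
#' scoring, and greedy selection (or the no-greedy control).
#'
#' @param corpus Corpus tibble; only the `train` split is used.
#' @param task A [task_spec()].
#' @param frontend A [frontend_params()].
#' @param n_features Size of the initial random pool (default 6000, of which
#'   one third is reserved for small features by the default quota).
#' @param quotas See [sample_random_features()]; `NULL` for the default
#'   (a third of the pool constrained to < 1 octave and < 100 ms); pass
#'   `list()` for no quota.
#' @param constraints Size constraints applied to the whole pool
#'   (size-constrained variants).
#' @param variant One of `"default"`, `"waveform"`, `"no_greedy"`,
#'   `"whole_call"`, `"average_call"`.
#' @param n_top Number of features kept by the `no_greedy` variant (default:
#'   size of a greedy run on the same pool).
#' @param total_target,min_added Greedy stopping parameters (bits).
#' @param seed Integer seed (feature sampling).
#' @param cochleagrams Optional precomputed training cochleagrams (named by
#'   `call_id`, matching the variant's front-end mode).
#' @return A `mif_set`; the scored pool and detections are attached as
#'   attributes `"scored_pool"` and `"detections"`.
#' @export
train_mifs <- function(corpus, task, frontend = frontend_params(),
                       n_features = 6000, quotas = NULL,
                       constraints = list(),
                       variant = c("default", "waveform", "no_greedy",
                                   "whole_call", "average_call"),
                       n_top = NULL, total_target = 0.999, min_added = 0.001,
                       seed = 1, cochleagrams = NULL) {
  variant <- match.arg(variant)
  train <- corpus[corpus$split == "train", ]
  if (nrow(train) == 0) stop("corpus has no training split", call. = FALSE)
  mode <- if (variant == "waveform") "waveform" else "cochleagram"
  if (is.null(cochleagrams)) {
    cochleagrams <- corpus_cochleagrams(train, frontend, mode)
  } else {
    cochleagrams <- cochleagrams[train$call_id]
  }
  labels <- train[[task$by]]
  memb <- task_membership(task, labels)
  within_ids <- train$call_id[memb$keep][memb$within]
  pool <- switch(variant,
    whole_call = whole_call_pool(cochleagrams[within_ids]),
    average_call = average_call_pool(cochleagrams[within_ids]),
    {
      if (is.null(quotas)) quotas <- default_quotas(n_features)
      if (mode == "waveform") {
        quotas <- lapply(quotas, function(q)
          q[setdiff(names(q), c("min_bandwidth_oct", "max_bandwidth_oct"))])
        constraints <- constraints[setdiff(names(constraints),
                                           c("min_bandwidth_oct",
                                             "max_bandwidth_oct"))]
      }
      sample_random_features(cochleagrams[within_ids], n_features,
                             constraints = constraints, quotas = quotas,
                             seed = seed)
    })
  scored <- score_features(pool, cochleagrams, labels, task)
  mifs <- if (variant == "no_greedy") {
    if (is.null(n_top)) {
      g <- greedy_select(scored$features, scored$detections, total_target,
                         min_added, task = task, frontend = frontend)
      n_top <- nrow(g$features)
    }
    select_top_merit(scored$features, scored$detections, n_top, task = task,
                     frontend = frontend)
  } else {
    greedy_select(scored$features, scored$detections, total_target,
                  min_added, task = task, frontend = frontend)
  }
  attr(mifs, "scored_pool") <- scored$features
  attr(mifs, "detections") <- scored$detections
  attr(mifs, "variant") <- variant
  mifs
}

#' Pipeline configuration
#'
#' @param tasks Character vector of within-class labels (one binary task
#'   each), or a list of [task_spec()]s.
#' @param specs Call-type specs for synthesis ([default_call_specs()]);
#'   ignored when `manifest` is given.
#' @param manifest Optional path to a corpus manifest CSV (measured calls).
#' @param n_per_class,n_callers,noise_snr_db,sample_rate Synthesis settings.
#' @param frontend A [frontend_params()].
#' @param n_features,quotas,constraints,variant,total_target,min_added See
#'   [train_mifs()].
#' @param seed Master seed; every randomized stage derives its own substream.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tasks, specs = default_call_specs(),
                            manifest = NULL, n_per_class = 100,
                            n_callers = 8, noise_snr_db = 10,
                            sample_rate = 48000,
                            frontend = frontend_params(),
                            n_features = 6000, quotas = NULL,
                            constraints = list(), variant = "default",
                            total_target = 0.999, min_added = 0.001,
                            seed = 1) {
  structure(list(tasks = tasks, specs = specs, manifest = manifest,
                 n_per_class = n_per_class, n_callers = n_callers,
                 noise_snr_db = noise_snr_db, sample_rate = sample_rate,
                 frontend = frontend, n_features = n_features,
                 quotas = quotas, constraints = constraints,
                 variant = variant, total_target = total_target,
                 min_added = min_added, seed = seed),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Synthesizes (or loads) a corpus, trains one MIF set per task on the train
#' split, evaluates each on the held-out test split, and (optionally) writes
#' the artifacts: MIF-set containers, per-feature CSV, ROC/DET CSVs, and a
#' run log.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `corpus`, per-task `mif_sets`, `evaluations`, and
#'   `report` (one row per task: n MIFs, total information, AUC, hit rate at
#'   5% false alarms).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_lines <- c(sprintf("mifcat pipeline; variant=%s; master seed=%d",
                         config$variant, config$seed))
  stage <- function(msg) {
    log_lines <<- c(log_lines,
                    sprintf("[%6.1fs] %s",
                            as.numeric(difftime(Sys.time(), t0, "secs")),
                            msg))
  }
  corpus <- if (!is.null(config$manifest)) {
    read_corpus(config$manifest)
  } else {
    if (is.null(config$specs)) stop("no corpus manifest and no synthesis spec",
                                    call. = FALSE)
    generate_corpus(config$specs, config$n_per_class, config$n_callers,
                    seed = substream_seed(config$seed, "corpus"),
                    sample_rate = config$sample_rate,
                    noise_snr_db = config$noise_snr_db)
  }
  stage(sprintf("corpus ready: %d calls", nrow(corpus)))
  mode <- if (config$variant == "waveform") "waveform" else "cochleagram"
  cg_train <- corpus_cochleagrams(corpus[corpus$split == "train", ],
                                  config$frontend, mode)
  cg_test <- corpus_cochleagrams(corpus[corpus$split == "test", ],
                                 config$frontend, mode)
  stage("cochleagrams computed")
  tasks <- config$tasks
  if (is.character(tasks)) tasks <- lapply(tasks, task_spec)
  mif_sets <- list()
  evaluations <- list()
  rows <- list()
  for (tk in tasks) {
    nm <- tk$within_class
    mifs <- tryCatch(
      train_mifs(corpus, tk, config$frontend, config$n_features,
                 config$quotas, config$constraints, config$variant,
                 total_target = config$total_target,
                 min_added = config$min_added,
                 seed = substream_seed(config$seed, paste0("features_", nm)),
                 cochleagrams = cg_train),
      error = function(e) stop(sprintf("stage train[%s]: %s", nm,
                                       conditionMessage(e)), call. = FALSE))
    stage(sprintf("task %s: %d MIFs, total %.3f bits (stop: %s)", nm,
                  nrow(mifs$features), mifs$total_information,
                  mifs$stop_reason))
    test <- corpus[corpus$split == "test", ]
    ev <- evaluate_mifs(mifs, cg_test, test[[tk$by]])
    stage(sprintf("task %s: test AUC %.3f", nm, ev$auc))
    mif_sets[[nm]] <- mifs
    evaluations[[nm]] <- ev
    rows[[nm]] <- tibble::tibble(
      task = nm, variant = config$variant,
      n_features_pool = config$n_features,
      n_mifs = nrow(mifs$features),
      total_information = mifs$total_information,
      stop_reason = mifs$stop_reason, auc = ev$auc,
      hit_at_fa05 = hit_rate_at_fa(ev$roc, 0.05))
  }
  report <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(mif_sets)) {
      save_mif_set(mif_sets[[nm]], file.path(out_dir,
                                             paste0("mifs_", nm, ".json")))
      write.csv(tidy(mif_sets[[nm]]),
                file.path(out_dir, paste0("features_", nm, ".csv")),
                row.names = FALSE)
      write.csv(evaluations[[nm]]$roc,
                file.path(out_dir, paste0("roc_", nm, ".csv")),
                row.names = FALSE)
      write.csv(evaluations[[nm]]$det,
                file.path(out_dir, paste0("det_", nm, ".csv")),
                row.names = FALSE)
    }
    write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  list(corpus = corpus, mif_sets = mif_sets, evaluations = evaluations,
       report = report, log = log_lines)
}
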