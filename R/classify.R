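# Detection of MIFs in novel stimuli, weighted-evidence classification,
# ROC/DET evaluation, and model-variant comparison.

#' Detect MIFs in a stimulus representation
#'
#' In `"call"` mode each MIF yields one detected/not-detected flag: it is
#' detected if the maximum of its NCC function over the call exceeds its
#' optimal threshold. In `"stream"` mode every threshold crossing is returned
#' as a detection event, at 2 ms resolution (a refractory period between
#' events of the same MIF).
#'
#' @param mif_set A `mif_set`.
#' @param rep A `cochleagram` (same front-end as training).
#' @param mode `"call"` or `"stream"`.
#' @param refractory_ms Minimum separation of events per MIF (stream mode).
#' @return Call mode: tibble `feature_id`, `max_ncc`, `detected`, `weight`.
#'   Stream mode: tibble of events `feature_id`, `time_ms`, `ncc`, `weight`
#'   (empty if no crossings).
#' @export
detect_mifs <- function(mif_set, rep, mode = c("call", "stream"),
                        refractory_ms = 2) {
  mode <- match.arg(mode)
  feats <- mif_set$features
  if (mode == "call") {
    resp <- vapply(seq_len(nrow(feats)), function(i)
      feature_response(feats[i, ], rep, short = "floor")$max_ncc, numeric(1))
    return(tibble::tibble(feature_id = feats$feature_id, max_ncc = resp,
                          detected = resp >= feats$threshold,
                          weight = feats$weight))
  }
  ev <- lapply(seq_len(nrow(feats)), function(i) {
    patch <- feats$patch[[i]]
    if (ncol(rep$rates) < ncol(patch)) return(NULL)
    band <- rep$rates[feats$ch_lo[i]:feats$ch_hi[i], , drop = FALSE]
    tr <- ncc_trace_cpp(patch, band)
    hit <- which(tr >= feats$threshold[i])
    if (length(hit) == 0) return(NULL)
    t_ms <- (hit - 1) / rep$frame_rate * 1000
    keep <- enforce_refractory(t_ms, refractory_ms)
    tibble::tibble(feature_id = feats$feature_id[i], time_ms = t_ms[keep],
                   ncc = tr[hit[keep]], weight = feats$weight[i])
  })
  out <- dplyr::bind_rows(ev)
  if (nrow(out) == 0) {
    out <- tibble::tibble(feature_id = character(), time_ms = numeric(),
                          ncc = numeric(), weight = numeric())
  }
  out
}

enforce_refractory <- function(times, refractory_ms) {
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory_ms) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  keep
}

#' Evidence score of a call for one MIF set
#'
#' The weighted detection sum, normalized by the sum of absolute weights of
#' the set, so that scores lie in \[-1, 1\] (1 when every MIF is detected and
#' all weights are positive; 0 when nothing is detected).
#'
#' @param mif_set A `mif_set`.
#' @param rep A `cochleagram`, or a precomputed [detect_mifs()] call-mode
#'   tibble.
#' @return Scalar evidence score.
#' @export
call_score <- function(mif_set, rep) {
  det <- if (inherits(rep, "cochleagram")) detect_mifs(mif_set, rep, "call")
  else rep
  w <- mif_set$features$weight
  sum(w[det$detected]) / sum(abs(w))
}

#' Time-binned evidence traces for a stimulus stream
#'
#' Detection events of each category's MIF set are weighted by their
#' log-likelihood ratios and summed in fixed time bins (default 50 ms),
#' normalized per category by the sum of absolute weights of its set.
#'
#' @param mif_sets Named list of `mif_set`s (one per category).
#' @param rep A `cochleagram` of the stimulus stream.
#' @param bin_ms Bin width in ms.
#' @param refractory_ms Passed to [detect_mifs()].
#' @return A `mif_evidence` tibble: `bin_start_ms`, `category`, `evidence`,
#'   with the detection events in attribute `"events"`.
#' @export
evidence_trace <- function(mif_sets, rep, bin_ms = 50, refractory_ms = 2) {
  stopifnot(length(mif_sets) >= 1, !is.null(names(mif_sets)))
  dur_ms <- ncol(rep$rates) / rep$frame_rate * 1000
  breaks <- seq(0, dur_ms + bin_ms, by = bin_ms)
  all_ev <- list()
  rows <- list()
  for (nm in names(mif_sets)) {
    ms <- mif_sets[[nm]]
    ev <- detect_mifs(ms, rep, "stream", refractory_ms)
    ev$category <- nm
    all_ev[[nm]] <- ev
    norm <- sum(abs(ms$features$weight))
    bin <- findInterval(ev$time_ms, breaks)
    e <- vapply(seq_len(length(breaks) - 1), function(b)
      sum(ev$weight[bin == b]) / norm, numeric(1))
    rows[[nm]] <- tibble::tibble(bin_start_ms = breaks[-length(breaks)],
                                 category = nm, evidence = e)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "events") <- dplyr::bind_rows(all_ev)
  class(out) <- c("mif_evidence", class(out))
  out
}

#' Plot evidence traces
#' @param object A `mif_evidence` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mif_evidence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_start_ms, .data$evidence,
                                       color = .data$category)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (ms)", y = "evidence") +
    ggplot2::theme_minimal()
}

#' ROC curve from evidence scores
#'
#' Sweeps an overall evidence threshold over all unique scores (plus
#' sentinels) and computes hit and false-alarm rates; the AUC is the
#' trapezoidal area.
#'
#' @param scores_within,scores_outside Numeric evidence scores.
#' @return A `mif_roc` tibble (`threshold`, `fa_rate`, `hit_rate`) with
#'   attribute `auc`.
#' @export
roc_curve <- function(scores_within, scores_outside) {
  stopifnot(length(scores_within) >= 1, length(scores_outside) >= 1)
  th <- c(Inf, sort(unique(c(scores_within, scores_outside)),
                    decreasing = TRUE), -Inf)
  hit <- vapply(th, function(t) mean(scores_within >= t), numeric(1))
  fa <- vapply(th, function(t) mean(scores_outside >= t), numeric(1))
  auc <- sum(diff(fa) * (head(hit, -1) + tail(hit, -1)) / 2)
  out <- tibble::tibble(threshold = th, fa_rate = fa, hit_rate = hit)
  attr(out, "auc") <- auc
  class(out) <- c("mif_roc", class(out))
  out
}

#' Detection-error-tradeoff points
#'
#' @inheritParams roc_curve
#' @return Tibble `threshold`, `fa_rate`, `miss_rate`.
#' @export
det_curve <- function(scores_within, scores_outside) {
  r <- roc_curve(scores_within, scores_outside)
  tibble::tibble(threshold = r$threshold, fa_rate = r$fa_rate,
                 miss_rate = 1 - r$hit_rate)
}

#' Area under a ROC curve
#' @param roc A `mif_roc`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' Hit rate at a low-false-alarm operating point
#'
#' The hit rate at the operating point with the largest false-alarm rate not
#' exceeding `fa_max`.
#'
#' @param roc A `mif_roc`.
#' @param fa_max Maximum admissible false-alarm rate.
#' @return Hit rate in \[0, 1\].
#' @export
hit_rate_at_fa <- function(roc, fa_max = 0.05) {
  ok <- roc$fa_rate <= fa_max
  if (!any(ok)) return(0)
  max(roc$hit_rate[ok])
}

#' Plot a ROC curve
#' @param object A `mif_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mif_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fa_rate, .data$hit_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-alarm rate", y = "hit rate",
                  subtitle = sprintf("AUC = %.3f", roc_auc(object))) +
    ggplot2::theme_minimal()
}

#' Score a set of calls with a MIF set
#'
#' @param mif_set A `mif_set`.
#' @param cochleagrams Named list of `cochleagram`s.
#' @return Tibble `call_id`, `score`.
#' @export
score_calls <- function(mif_set, cochleagrams) {
  responses <- compute_responses(mif_set$features, cochleagrams,
                                 short = "floor")
  det <- sweep(responses, 1, mif_set$features$threshold, `>=`)
  w <- mif_set$features$weight
  tibble::tibble(call_id = colnames(responses),
                 score = as.numeric(crossprod(det, w)) / sum(abs(w)))
}

#' Evaluate a MIF set on a labeled call set
#'
#' Scores every call, then builds ROC and DET curves under the task's class
#' membership.
#'
#' @param mif_set A `mif_set`.
#' @param cochleagrams Named list of `cochleagram`s.
#' @param labels Class labels aligned with `cochleagrams`.
#' @param task Task defining within/outside membership; defaults to the task
#'   the MIF set was trained on.
#' @return A `mif_eval` list: `scores` tibble (with `within` flag), `roc`,
#'   `det`, `auc`.
#' @export
evaluate_mifs <- function(mif_set, cochleagrams, labels,
                          task = mif_set$task) {
  stopifnot(inherits(task, "task_spec"))
  memb <- task_membership(task, labels)
  sc <- score_calls(mif_set, cochleagrams[memb$keep])
  sc$within <- memb$within
  roc <- roc_curve(sc$score[sc$within], sc$score[!sc$within])
  structure(list(scores = sc, roc = roc,
                 det = tibble::tibble(threshold = roc$threshold,
                                      fa_rate = roc$fa_rate,
                                      miss_rate = 1 - roc$hit_rate),
                 auc = roc_auc(roc), task = task),
            class = "mif_eval")
}

#' @export
print.mif_eval <- function(x, ...) {
  cat(sprintf("<mif_eval> %d within / %d outside calls; AUC %.3f\n",
              sum(x$scores$within), sum(!x$scores$within), x$auc))
  invisible(x)
}

#' @export
glance.mif_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc,
                 hit_at_fa05 = hit_rate_at_fa(x$roc, 0.05),
                 n_within = sum(x$scores$within),
                 n_outside = sum(!x$scores$within))
}

#' Evaluate a MIF set under a different task
#'
#' Standard evaluation with mismatched task labels: MIFs trained to
#' discriminate one category are scored under another task's class
#' membership. Used as a chance-level control (task-specificity of MIFs).
#'
#' @param mif_set A `mif_set` trained on task A.
#' @param cochleagrams Named list of `cochleagram`s.
#' @param labels Class labels aligned with `cochleagrams`.
#' @param task_b The evaluation [task_spec()].
#' @return A `mif_eval`.
#' @export
cross_task_evaluation <- function(mif_set, cochleagrams, labels, task_b) {
  evaluate_mifs(mif_set, cochleagrams, labels, task = task_b)
}

#' Compare model variants by their added-information sequences
#'
#' Two-sided rank-sum (Wilcoxon) tests between every pair of variants'
#' cumulative added-information sequences, Bonferroni-corrected for the
#' number of pairs.
#'
#' @param sequences Named list (>= 2) of numeric vectors, each of length
#'   >= 2: the per-step added (or cumulative) information of one variant.
#' @return Tibble `variant_a`, `variant_b`, `statistic`, `p_value`,
#'   `p_adjusted`.
#' @export
compare_variants <- function(sequences) {
  stopifnot(length(sequences) >= 2, !is.null(names(sequences)))
  if (any(vapply(sequences, length, integer(1)) < 2)) {
    stop("each sequence needs length >= 2", call. = FALSE)
  }
  nms <- names(sequences)
  pairs <- utils::combn(nms, 2)
  res <- apply(pairs, 2, function(p) {
    wt <- suppressWarnings(wilcox.test(sequences[[p[1]]], sequences[[p[2]]],
                                       alternative = "two.sided",
                                       exact = FALSE))
    c(statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  out <- tibble::tibble(variant_a = pairs[1, ], variant_b = pairs[2, ],
                        statistic = res["statistic", ],
                        p_value = res["p_value", ])
  out$p_adjusted <- pmin(1, out$p_value * ncol(pairs))
  out
}
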