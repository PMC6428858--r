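# Random fragment features: sampling, template-match responses, mutual
# information threshold optimization, log-likelihood weights, complexity.

#' Task specification for a binary categorization
#'
#' The method is a series of binary classifications: one within-class
#' category versus everything else. The class prior used during threshold
#' search and the prior used for reporting merit/added information are both
#' configurable; by convention the search prior is 0.10 and the reporting
#' prior is the balanced 0.5, under which 1 bit corresponds to perfect
#' classification.
#'
#' @param within_class Label of the within-class category.
#' @param by Column of the corpus holding the labels (`"call_type"` or
#'   `"caller"`).
#' @param outside_classes Optional character vector restricting the
#'   outside-class; default: every other label.
#' @param prior_threshold Class prior p(C) used during threshold search.
#' @param prior_report Class prior used when reporting merit and added
#'   information.
#' @return A `task_spec` list.
#' @export
task_spec <- function(within_class, by = "call_type", outside_classes = NULL,
                      prior_threshold = 0.10, prior_report = 0.5) {
  stopifnot(prior_threshold > 0, prior_threshold < 1,
            prior_report > 0, prior_report < 1)
  structure(list(within_class = within_class, by = by,
                 outside_classes = outside_classes,
                 prior_threshold = prior_threshold,
                 prior_report = prior_report),
            class = "task_spec")
}

# labels -> logical within-class indicator, honoring outside_classes
task_membership <- function(task, labels) {
  within <- labels == task$within_class
  keep <- if (is.null(task$outside_classes)) rep(TRUE, length(labels)) else
    within | labels %in% task$outside_classes
  list(within = within[keep], keep = keep)
}

#' Sample random rectangular features from cochleagrams
#'
#' Each feature is a rectangle fully inside one source cochleagram: a random
#' channel span (bandwidth) and time window. Quotas reserve part of the pool
#' for constrained sizes (e.g. small features: bandwidth < 1 octave and
#' duration < 100 ms), mirroring the sampling scheme in which 2000 of 6000
#' features were restricted to be small.
#'
#' @param cochleagrams List of `cochleagram` objects (within-class training
#'   calls); names (or list index) identify the source call.
#' @param n_total Total number of features.
#' @param constraints List with elements `min_length_ms`, `max_length_ms`,
#'   `min_bandwidth_oct`, `max_bandwidth_oct` applied to all non-quota draws.
#' @param quotas List of quota lists, each with `n` plus constraint fields as
#'   above; e.g. `list(list(n = 2000, max_bandwidth_oct = 1,
#'   max_length_ms = 100))`.
#' @param seed Integer seed.
#' @return Tibble of unscored features: `feature_id`, `source_call`,
#'   `ch_lo`, `ch_hi`, `t_on_ms`, `length_ms`, `bandwidth_oct`, and a
#'   `patch` list-column of channel x frame matrices.
#' @export
sample_random_features <- function(cochleagrams, n_total,
                                   constraints = list(), quotas = NULL,
                                   seed = 1) {
  stopifnot(length(cochleagrams) >= 1, n_total >= 1)
  src_names <- names(cochleagrams)
  if (is.null(src_names)) src_names <- as.character(seq_along(cochleagrams))
  base <- list(min_length_ms = 10, max_length_ms = Inf,
               min_bandwidth_oct = 0, max_bandwidth_oct = Inf)
  cons <- utils::modifyList(base, constraints)
  plan <- list()
  n_quota <- 0
  for (q in quotas) {
    qq <- utils::modifyList(cons, q[setdiff(names(q), "n")])
    plan[[length(plan) + 1]] <- list(n = q$n, cons = qq)
    n_quota <- n_quota + q$n
  }
  if (n_quota > n_total) stop("quotas exceed n_total", call. = FALSE)
  plan[[length(plan) + 1]] <- list(n = n_total - n_quota, cons = cons)
  cg1 <- cochleagrams[[1]]
  cfs <- cg1$center_freqs
  nch <- nrow(cg1$rates)
  frame_rate <- cg1$frame_rate
  with_local_seed(seed, {
    rows <- vector("list", n_total)
    k <- 0
    for (p in plan) {
      if (p$n == 0) next
      for (i in seq_len(p$n)) {
        k <- k + 1
        rows[[k]] <- sample_one_feature(cochleagrams, src_names, cfs, nch,
                                        frame_rate, p$cons)
      }
    }
    out <- dplyr::bind_rows(rows)
    out$feature_id <- sprintf("f%05d", seq_len(nrow(out)))
    dplyr::relocate(out, "feature_id")
  })
}

sample_one_feature <- function(cochleagrams, src_names, cfs, nch, frame_rate,
                               cons) {
  # feasible channel spans for the bandwidth constraint (waveform mode: 1 ch)
  if (nch == 1) {
    spans <- 1L
  } else {
    bw_of_span <- vapply(seq_len(nch), function(s)
      if (s == 1) 0 else log2(cfs[s] / cfs[1]), numeric(1))
    # upper bounds are strict ("less than 1 octave"), lower bounds inclusive
    spans <- which(bw_of_span >= cons$min_bandwidth_oct &
                     bw_of_span < cons$max_bandwidth_oct)
    spans <- spans[spans >= 2 | cons$min_bandwidth_oct == 0]
    if (length(spans) == 0)
      stop("bandwidth constraint infeasible for this filterbank",
           call. = FALSE)
  }
  min_fr <- max(2L, ceiling(cons$min_length_ms * frame_rate / 1000))
  # sources long enough for the minimum length
  ok <- which(vapply(cochleagrams, function(g) ncol(g$rates) >= min_fr,
                     logical(1)))
  if (length(ok) == 0)
    stop(sprintf(
      "length constraint infeasible: no source cochleagram has >= %g ms",
      cons$min_length_ms), call. = FALSE)
  si <- ok[sample.int(length(ok), 1)]
  g <- cochleagrams[[si]]
  tfr <- ncol(g$rates)
  lim <- cons$max_length_ms * frame_rate / 1000
  max_fr <- min(tfr, if (is.finite(lim)) ceiling(lim) - 1 else tfr)
  len <- sample.int(max_fr - min_fr + 1L, 1) + min_fr - 1L
  t0 <- sample.int(tfr - len + 1L, 1)
  span <- spans[sample.int(length(spans), 1)]
  ch_lo <- sample.int(nch - span + 1L, 1)
  ch_hi <- ch_lo + span - 1L
  patch <- g$rates[ch_lo:ch_hi, t0:(t0 + len - 1L), drop = FALSE]
  tibble::tibble(
    source_call = src_names[si],
    ch_lo = ch_lo, ch_hi = ch_hi,
    t_on_ms = (t0 - 1) / frame_rate * 1000,
    length_ms = len / frame_rate * 1000,
    bandwidth_oct = if (nch == 1) 0 else log2(cfs[ch_hi] / cfs[ch_lo]),
    patch = list(patch)
  )
}

#' Template-match response of a feature to a representation
#'
#' The response is the maximum over time lags of the normalized
#' cross-correlation (NCC) between the feature patch and the same-channel
#' band of the representation: at each lag both are mean-subtracted and
#' divided by their standard deviations before the inner product, so the
#' response lies in \[-1, 1\] and equals +1 for a perfect match. Features are
#' matched only within the channel (frequency) span they cover, but at any
#' time.
#'
#' @param feature One row of a feature tibble (data frame or list with
#'   `patch`, `ch_lo`, `ch_hi`).
#' @param rep A `cochleagram`.
#' @param short How to treat a representation shorter in time than the
#'   feature: `"error"` (default, per the operation contract) or `"floor"`
#'   (return response -1: the feature cannot be detected).
#' @return List with `max_ncc` and `best_lag_ms` (`NA` when floored).
#' @export
feature_response <- function(feature, rep, short = c("error", "floor")) {
  short <- match.arg(short)
  patch <- if (is.data.frame(feature)) feature$patch[[1]] else feature$patch
  ch_lo <- feature$ch_lo[[1]]; ch_hi <- feature$ch_hi[[1]]
  if (ch_hi > nrow(rep$rates))
    stop("feature channel span not present in representation", call. = FALSE)
  band <- rep$rates[ch_lo:ch_hi, , drop = FALSE]
  res <- ncc_max_many_cpp(patch, list(band), short == "floor", -1)
  list(max_ncc = res$max[1],
       best_lag_ms = if (is.na(res$lag[1])) NA_real_ else
         res$lag[1] / rep$frame_rate * 1000)
}

#' Responses of many features to many representations
#'
#' @param features Feature tibble ([sample_random_features()]).
#' @param cochleagrams Named list of `cochleagram`s.
#' @param short See [feature_response()]; the scoring pipeline floors
#'   responses of features longer than a call at -1.
#' @return features x calls numeric matrix of max-NCC responses, with
#'   dimnames.
#' @export
compute_responses <- function(features, cochleagrams, short = "floor") {
  allow_short <- identical(short, "floor")
  nms <- names(cochleagrams)
  if (is.null(nms)) nms <- as.character(seq_along(cochleagrams))
  out <- matrix(NA_real_, nrow(features), length(cochleagrams),
                dimnames = list(features$feature_id, nms))
  for (i in seq_len(nrow(features))) {
    ch_lo <- features$ch_lo[i]; ch_hi <- features$ch_hi[i]
    bands <- lapply(cochleagrams, function(g)
      g$rates[ch_lo:ch_hi, , drop = FALSE])
    out[i, ] <- ncc_max_many_cpp(features$patch[[i]], bands,
                                 allow_short, -1)$max
  }
  out
}

#' Plug-in mutual information between a binary detection and the class
#'
#' Estimates I(f; C) in bits from hit/false-alarm counts under a supplied
#' class prior p(C): the conditional detection probabilities are estimated
#' from the counts, the class marginal is fixed at the prior.
#'
#' @param n11 Detections among within-class calls (hits).
#' @param n01 Detections among outside-class calls (false alarms).
#' @param n_within,n_outside Class sizes (> 0).
#' @param prior Class prior p(C = 1) in (0, 1).
#' @return Mutual information in bits (vectorized over `n11`/`n01`).
#' @export
mutual_information <- function(n11, n01, n_within, n_outside, prior = 0.5) {
  if (n_within <= 0 || n_outside <= 0) stop("zero-size class", call. = FALSE)
  stopifnot(prior > 0, prior < 1, all(n11 >= 0), all(n11 <= n_within),
            all(n01 >= 0), all(n01 <= n_outside))
  p1 <- n11 / n_within   # p(f=1 | C=1)
  p0 <- n01 / n_outside  # p(f=1 | C=0)
  pf1 <- prior * p1 + (1 - prior) * p0
  term <- function(pj, pf, pc) {
    out <- numeric(length(pj))
    nz <- pj > 0
    out[nz] <- pj[nz] * log2(pj[nz] / (pf[nz] * pc))
    out
  }
  term(prior * p1, pf1, prior) +
    term(prior * (1 - p1), 1 - pf1, prior) +
    term((1 - prior) * p0, pf1, 1 - prior) +
    term((1 - prior) * (1 - p0), 1 - pf1, 1 - prior)
}

#' Optimal detection threshold and merit of a feature
#'
#' Sweeps candidate thresholds (midpoints between consecutive sorted unique
#' pooled responses, plus a sentinel above the maximum) and returns the
#' threshold maximizing mutual information at the search prior; the merit is
#' the mutual information at that threshold evaluated at the reporting prior.
#' Ties are broken toward the lowest qualifying threshold. A feature whose
#' responses are all identical is degenerate: merit 0, threshold above all
#' responses.
#'
#' @param responses_within,responses_outside Numeric response vectors.
#' @param task A [task_spec()] (supplies both priors).
#' @return List with `threshold`, `merit` (bits, reporting prior),
#'   `merit_search` (bits, search prior), `degenerate`.
#' @export
optimize_threshold <- function(responses_within, responses_outside,
                               task = task_spec("within")) {
  stopifnot(length(responses_within) >= 1, length(responses_outside) >= 1)
  pooled <- sort(unique(c(responses_within, responses_outside)))
  if (length(pooled) == 1) {
    return(list(threshold = pooled + 1, merit = 0, merit_search = 0,
                degenerate = TRUE))
  }
  grid <- c(pooled[-length(pooled)] + diff(pooled) / 2,
            pooled[length(pooled)] + 1)
  nw <- length(responses_within); no <- length(responses_outside)
  n11 <- vapply(grid, function(th) sum(responses_within >= th), numeric(1))
  n01 <- vapply(grid, function(th) sum(responses_outside >= th), numeric(1))
  mi_search <- mutual_information(n11, n01, nw, no, task$prior_threshold)
  best <- which(mi_search >= max(mi_search) - 1e-15)
  # lowest qualifying threshold among ties
  best <- best[which.min(grid[best])]
  list(threshold = grid[best],
       merit = mutual_information(n11[best], n01[best], nw, no,
                                  task$prior_report),
       merit_search = mi_search[best],
       degenerate = FALSE)
}

#' Log-likelihood weight of a feature
#'
#' The evidence a detection contributes: log2 of the ratio of detection
#' probabilities in the two classes, with add-half (Jeffreys) smoothing on
#' all four contingency cells so the weight is finite even with zero false
#' alarms. Features informative by their absence have negative weight.
#'
#' @inheritParams mutual_information
#' @return Weight in bits (possibly negative).
#' @export
log_likelihood_weight <- function(n11, n01, n_within, n_outside) {
  log2(((n11 + 0.5) / (n_within + 1)) / ((n01 + 0.5) / (n_outside + 1)))
}

#' Feature complexity: reduced kurtosis
#'
#' Excess kurtosis (kurtosis - 3) of the pooled activity values in a feature
#' patch. Uniform-activity (including empty) regions give ~Gaussian pooled
#' activity and a value near 0; whole calls, with many silent and few
#' high-activity bins, give large positive values. A zero-variance patch is
#' defined to have complexity 0.
#'
#' @param patch Numeric matrix (or a one-row feature data frame).
#' @return Reduced kurtosis (dimensionless).
#' @export
feature_complexity <- function(patch) {
  if (is.data.frame(patch)) patch <- patch$patch[[1]]
  x <- as.numeric(patch)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0) return(0)
  mean((x - m)^4) / v^2 - 3
}

#' Score a feature pool on a training set
#'
#' Computes responses of every feature to every training call, optimizes each
#' feature's detection threshold, and attaches merit, log-likelihood weight
#' and complexity. Returns the scored features plus the detection matrix used
#' by the greedy search.
#'
#' @param features Feature tibble.
#' @param cochleagrams Named list of training `cochleagram`s (both classes).
#' @param labels Character vector of class labels aligned with
#'   `cochleagrams`.
#' @param task A [task_spec()].
#' @param responses Optional precomputed response matrix
#'   ([compute_responses()]).
#' @return List with `features` (scored tibble: adds `threshold`, `merit`,
#'   `weight`, `complexity`, `degenerate`) and `detections` (a
#'   `mif_detections` object: responses, binary detections, labels).
#' @export
score_features <- function(features, cochleagrams, labels, task,
                           responses = NULL) {
  memb <- task_membership(task, labels)
  if (is.null(responses)) {
    responses <- compute_responses(features, cochleagrams[memb$keep])
  } else {
    responses <- responses[, memb$keep, drop = FALSE]
  }
  within <- memb$within
  nw <- sum(within); no <- sum(!within)
  if (nw == 0 || no == 0) stop("zero-size class", call. = FALSE)
  n <- nrow(features)
  threshold <- merit <- weight <- complexity <- numeric(n)
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    opt <- optimize_threshold(responses[i, within], responses[i, !within],
                              task)
    threshold[i] <- opt$threshold
    merit[i] <- opt$merit
    degenerate[i] <- opt$degenerate
    det <- responses[i, ] >= opt$threshold
    weight[i] <- log_likelihood_weight(sum(det[within]), sum(det[!within]),
                                       nw, no)
    complexity[i] <- feature_complexity(features$patch[[i]])
  }
  scored <- dplyr::mutate(features, threshold = threshold, merit = merit,
                          weight = weight, complexity = complexity,
                          degenerate = degenerate)
  detections <- new_mif_detections(responses, threshold, within,
                                   scored$feature_id)
  list(features = scored, detections = detections)
}

new_mif_detections <- function(responses, thresholds, within, feature_ids) {
  detections <- sweep(responses, 1, thresholds, `>=`)
  structure(list(responses = responses, detections = detections,
                 within = within, feature_ids = feature_ids),
            class = "mif_detections")
}

#' @export
print.mif_detections <- function(x, ...) {
  cat(sprintf("<mif_detections> %d features x %d calls (%d within-class)\n",
              nrow(x$responses), ncol(x$responses), sum(x$within)))
  invisible(x)
}

#' Per-feature summary table
#'
#' @param x Scored feature tibble (from [score_features()]`$features`).
#' @param ... Unused.
#' @return Tibble without the patch list-column, mirroring the per-feature
#'   report (merit, weight, threshold, bandwidth, length, complexity).
#' @export
feature_table <- function(x, ...) {
  dplyr::select(x, -"patch")
}
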