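# Greedy selection of the most informative features (MIFs).

# I(C; f_a, f_b) in bits from binary detection vectors, class prior supplied.
joint_class_information <- function(da, db, within, prior) {
  nw <- sum(within); no <- sum(!within)
  mi <- 0
  for (a in c(FALSE, TRUE)) for (b in c(FALSE, TRUE)) {
    cell <- (da == a) & (db == b)
    p_w <- sum(cell & within) / nw
    p_o <- sum(cell & !within) / no
    p_marg <- prior * p_w + (1 - prior) * p_o
    if (p_w > 0) {
      pj <- prior * p_w
      mi <- mi + pj * log2(pj / (p_marg * prior))
    }
    if (p_o > 0) {
      pj <- (1 - prior) * p_o
      mi <- mi + pj * log2(pj / (p_marg * (1 - prior)))
    }
  }
  mi
}

single_class_information <- function(d, within, prior) {
  mutual_information(sum(d & within), sum(d & !within),
                     sum(within), sum(!within), prior)
}

#' Pairwise added information of a candidate feature
#'
#' The information a candidate adds to an already-chosen set, operationalized
#' conservatively as the minimum over chosen features s of
#' I(C; f_s, f_cand) - I(C; f_s), computed from the joint binary detection
#' tables. A candidate whose detections duplicate a chosen feature adds 0;
#' for an empty chosen set the added information is the candidate's own
#' single-feature information.
#'
#' @param candidate Feature id (or row index into the detection matrix).
#' @param chosen Character/integer vector of already-chosen features (possibly
#'   empty).
#' @param detections A `mif_detections` object.
#' @param prior Class prior for the information computation (reporting
#'   prior).
#' @return Added information in bits (>= 0).
#' @export
pairwise_added_information <- function(candidate, chosen, detections,
                                       prior = 0.5) {
  D <- detections$detections
  within <- detections$within
  dc <- D[candidate, ]
  if (length(chosen) == 0) {
    return(single_class_information(dc, within, prior))
  }
  inc <- vapply(chosen, function(s) {
    joint_class_information(D[s, ], dc, within, prior) -
      single_class_information(D[s, ], within, prior)
  }, numeric(1))
  max(0, min(inc))
}

new_mif_set <- function(features, added_information, stop_reason, task,
                        prior, frontend = NULL) {
  features$added_information <- added_information
  features <- dplyr::relocate(features, "added_information",
                              .after = "feature_id")
  structure(list(features = features,
                 total_information = sum(added_information),
                 stop_reason = stop_reason, task = task, prior = prior,
                 frontend = frontend),
            class = "mif_set")
}

#' @export
print.mif_set <- function(x, ...) {
  cat(sprintf(
    "<mif_set> %d MIFs, total information %.3f bits (stop: %s); task: %s\n",
    nrow(x$features), x$total_information, x$stop_reason,
    if (inherits(x$task, "task_spec")) x$task$within_class else "?"))
  invisible(x)
}

#' Greedy selection of most informative features
#'
#' Starts from the feature of maximal merit and iteratively adds the feature
#' maximizing pairwise added information with respect to the chosen set,
#' until the cumulative total reaches `total_target` bits or the best
#' candidate adds less than `min_added` bits, whichever comes first.
#' Deterministic: ties are broken toward the lower feature index.
#'
#' @param scored Scored feature tibble (from [score_features()]).
#' @param detections Matching `mif_detections`.
#' @param total_target Stop when cumulative information reaches this (bits).
#' @param min_added Stop when the best candidate adds less than this (bits).
#' @param max_mifs Optional hard cap on set size.
#' @param task,frontend Carried into the returned object for provenance.
#' @return A `mif_set`: ordered features with per-step `added_information`,
#'   `total_information`, `stop_reason`.
#' @export
greedy_select <- function(scored, detections, total_target = 0.999,
                          min_added = 0.001, max_mifs = Inf, task = NULL,
                          frontend = NULL) {
  if (nrow(scored) == 0) stop("empty feature pool", call. = FALSE)
  prior <- if (!is.null(task)) task$prior_report else 0.5
  h_class <- -prior * log2(prior) - (1 - prior) * log2(1 - prior)
  ids <- scored$feature_id
  # first MIF: maximal merit (ties -> lower index)
  first <- which.max(scored$merit)
  chosen <- ids[first]
  added <- single_class_information(detections$detections[chosen, ],
                                    detections$within, prior)
  total <- added
  stop_reason <- NULL
  repeat {
    if (total >= total_target) { stop_reason <- "total_target"; break }
    if (length(chosen) >= min(nrow(scored), max_mifs)) {
      stop_reason <- if (length(chosen) >= nrow(scored)) "pool_exhausted"
      else "max_mifs"
      break
    }
    remaining <- setdiff(ids, chosen)
    gains <- vapply(remaining, function(cand)
      pairwise_added_information(cand, chosen, detections, prior),
      numeric(1))
    best <- which.max(gains) # which.max takes the first (lowest index) tie
    if (gains[best] < min_added) { stop_reason <- "min_added"; break }
    chosen <- c(chosen, remaining[best])
    # the pairwise-min increment can overestimate the joint gain; cap the
    # recorded step so the cumulative total stays within H(C)
    gain <- min(gains[best], h_class - total)
    added <- c(added, gain)
    total <- total + gain
  }
  sel <- scored[match(chosen, scored$feature_id), ]
  new_mif_set(sel, added, stop_reason, task, prior, frontend)
}

#' Top-merit feature selection (no-greedy control)
#'
#' Takes the `n` features of highest merit without redundancy elimination;
#' the added-information sequence is recomputed in merit order for reporting,
#' so that cumulative-information curves are comparable with the greedy
#' search.
#'
#' @param scored Scored feature tibble.
#' @param detections Matching `mif_detections`.
#' @param n Number of features (1 <= n <= pool size).
#' @inheritParams greedy_select
#' @return A `mif_set` with stop reason `"top_merit"`.
#' @export
select_top_merit <- function(scored, detections, n, task = NULL,
                             frontend = NULL) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (n > nrow(scored)) stop("n exceeds pool size", call. = FALSE)
  prior <- if (!is.null(task)) task$prior_report else 0.5
  h_class <- -prior * log2(prior) - (1 - prior) * log2(1 - prior)
  ord <- order(-scored$merit, seq_len(nrow(scored)))[seq_len(n)]
  ids <- scored$feature_id[ord]
  added <- numeric(n)
  total <- 0
  for (i in seq_len(n)) {
    g <- pairwise_added_information(ids[i], ids[seq_len(i - 1)],
                                    detections, prior)
    added[i] <- min(g, h_class - total)
    total <- total + added[i]
  }
  new_mif_set(scored[ord, ], added, "top_merit", task, prior, frontend)
}

#' Iterative re-selection excluding prior MIFs (resampling control)
#'
#' Re-runs the greedy search on the pool with all previously selected MIFs
#' removed, to verify that the initial random pool contains redundant
#' MIF-like features (successive disjoint sets should classify comparably).
#'
#' @param scored Scored feature tibble (the full pool).
#' @param prior_mif_sets List of `mif_set`s whose features are excluded.
#' @param detections Matching `mif_detections` for the full pool.
#' @inheritParams greedy_select
#' @return A `mif_set` disjoint from all prior sets.
#' @export
resample_excluding <- function(scored, prior_mif_sets, detections,
                               total_target = 0.999, min_added = 0.001,
                               task = NULL, frontend = NULL) {
  used <- unlist(lapply(prior_mif_sets, function(m) m$features$feature_id))
  keep <- !(scored$feature_id %in% used)
  if (!any(keep)) stop("feature pool exhausted by prior MIF sets",
                       call. = FALSE)
  sub <- scored[keep, ]
  subdet <- structure(list(
    responses = detections$responses[sub$feature_id, , drop = FALSE],
    detections = detections$detections[sub$feature_id, , drop = FALSE],
    within = detections$within,
    feature_ids = sub$feature_id), class = "mif_detections")
  greedy_select(sub, subdet, total_target, min_added, task = task,
                frontend = frontend)
}

#' Tidy a MIF set
#'
#' @param x A `mif_set`.
#' @param ... Unused.
#' @return Tibble: one row per selected feature in selection order, with
#'   `mif_rank`, `added_information`, `merit`, `weight`, `threshold`, size
#'   and complexity columns (the per-feature report).
#' @export
tidy.mif_set <- function(x, ...) {
  out <- dplyr::select(x$features, -"patch")
  dplyr::mutate(out, mif_rank = dplyr::row_number(), .before = 1)
}

#' One-row summary of a MIF set
#'
#' @param x A `mif_set`.
#' @param ... Unused.
#' @return Tibble with `n_mifs`, `total_information`, `stop_reason`,
#'   `within_class`, mean length and bandwidth.
#' @export
glance.mif_set <- function(x, ...) {
  tibble::tibble(
    n_mifs = nrow(x$features),
    total_information = x$total_information,
    stop_reason = x$stop_reason,
    within_class = if (inherits(x$task, "task_spec")) x$task$within_class
    else NA_character_,
    mean_length_ms = mean(x$features$length_ms),
    mean_bandwidth_oct = mean(x$features$bandwidth_oct)
  )
}
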