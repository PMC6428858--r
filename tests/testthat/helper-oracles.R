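# Independent oracles used to check the implementation paths.

# Plug-in mutual information of a binary detection and the class, from the
# 2x2 contingency counts under a fixed class prior. Written directly from the
# definition I = sum p(f,c) log2 [ p(f,c) / (p(f) p(c)) ].
oracle_mi <- function(n11, n01, nw, no, prior) {
  p_f_c1 <- c(1 - n11 / nw, n11 / nw) # f = 0, 1 | C = 1
  p_f_c0 <- c(1 - n01 / no, n01 / no) # f = 0, 1 | C = 0
  mi <- 0
  for (f in 1:2) {
    pf <- prior * p_f_c1[f] + (1 - prior) * p_f_c0[f]
    for (ci in 1:2) {
      pc <- if (ci == 2) prior else 1 - prior
      pj <- pc * (if (ci == 2) p_f_c1[f] else p_f_c0[f])
      if (pj > 0) mi <- mi + pj * log2(pj / (pf * pc))
    }
  }
  mi
}

# I(C; f_a, f_b): joint over the 4 detection states, prior-weighted.
oracle_joint_mi <- function(da, db, within, prior) {
  mi <- 0
  for (a in c(FALSE, TRUE)) for (b in c(FALSE, TRUE)) {
    pw <- mean(da[within] == a & db[within] == b)
    po <- mean(da[!within] == a & db[!within] == b)
    pf <- prior * pw + (1 - prior) * po
    for (ci in 1:2) {
      pc <- if (ci == 2) prior else 1 - prior
      pj <- pc * (if (ci == 2) pw else po)
      if (pj > 0) mi <- mi + pj * log2(pj / (pf * pc))
    }
  }
  mi
}

# Naive per-lag NCC loop: z-normalize feature and patch at each lag with
# population standard deviations, average the product.
oracle_ncc_trace <- function(feat, band) {
  L <- ncol(feat)
  n <- length(feat)
  znorm <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) return(NULL)
    (x - mean(x)) / s
  }
  fz <- znorm(as.numeric(feat))
  vapply(seq_len(ncol(band) - L + 1), function(lag) {
    p <- as.numeric(band[, lag:(lag + L - 1), drop = FALSE])
    pz <- znorm(p)
    if (is.null(pz)) return(0)
    mean(fz * pz)
  }, numeric(1))
}

# AUC by exhaustive pair counting, ties scored 1/2.
oracle_auc <- function(scores_within, scores_outside) {
  s <- 0
  for (w in scores_within) for (o in scores_outside) {
    s <- s + (w > o) + 0.5 * (w == o)
  }
  s / (length(scores_within) * length(scores_outside))
}

# Exhaustive step-wise greedy: first pick = max merit, then argmax over the
# min-over-chosen pairwise information increment, recomputed from scratch
# with the oracle formulas at every step.
oracle_greedy <- function(merits, D, within, prior, total_target = 0.999,
                          min_added = 0.001) {
  h_class <- -prior * log2(prior) - (1 - prior) * log2(1 - prior)
  n <- nrow(D)
  chosen <- which.max(merits)
  total <- oracle_mi(sum(D[chosen, ] & within), sum(D[chosen, ] & !within),
                     sum(within), sum(!within), prior)
  while (total < total_target && length(chosen) < n) {
    gains <- rep(NA_real_, n)
    for (cand in setdiff(seq_len(n), chosen)) {
      inc <- vapply(chosen, function(s)
        oracle_joint_mi(D[s, ], D[cand, ], within, prior) -
          oracle_mi(sum(D[s, ] & within), sum(D[s, ] & !within),
                    sum(within), sum(!within), prior), numeric(1))
      gains[cand] <- max(0, min(inc))
    }
    best <- which.max(gains)
    if (gains[best] < min_added) break
    chosen <- c(chosen, best)
    total <- total + min(gains[best], h_class - total)
  }
  chosen
}

# wrap a rates matrix as a cochleagram
rates_map <- function(rates, frame_rate = 1000) {
  mifcat:::new_cochleagram(rates, seq_len(nrow(rates)) * 100, frame_rate,
                           "cochleagram")
}

# a one-row feature tibble from a patch
patch_feature <- function(patch, ch_lo = 1, id = "f1", threshold = 0.5,
                          weight = 1) {
  tibble::tibble(feature_id = id, source_call = "src",
                 ch_lo = as.integer(ch_lo),
                 ch_hi = as.integer(ch_lo + nrow(patch) - 1),
                 t_on_ms = 0, length_ms = ncol(patch),
                 bandwidth_oct = 0.5, patch = list(patch),
                 threshold = threshold, merit = NA_real_, weight = weight,
                 complexity = NA_real_, degenerate = FALSE)
}

# a mif_set built directly from feature rows (for unit tests)
toy_mif_set <- function(features, task = task_spec("twitter_like")) {
  mifcat:::new_mif_set(features, rep(0, nrow(features)), "manual", task, 0.5,
                       frontend_params())
}

# random detection structures for property tests
random_detections <- function(n_features, n_calls, seed) {
  set.seed(seed)
  within <- rep(c(TRUE, FALSE), length.out = n_calls)
  resp <- matrix(runif(n_features * n_calls), n_features, n_calls,
                 dimnames = list(sprintf("f%03d", seq_len(n_features)),
                                 sprintf("c%03d", seq_len(n_calls))))
  th <- runif(n_features, 0.3, 0.7)
  mifcat:::new_mif_detections(resp, th, within, rownames(resp))
}
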