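# scored feature tibble + detections from an explicit detection matrix
scored_from_detections <- function(det, prior = 0.5) {
  ids <- det$feature_ids
  merits <- vapply(ids, function(id)
    oracle_mi(sum(det$detections[id, ] & det$within),
              sum(det$detections[id, ] & !det$within),
              sum(det$within), sum(!det$within), prior), numeric(1))
  tibble::tibble(feature_id = ids, source_call = "src", ch_lo = 1L,
                 ch_hi = 2L, t_on_ms = 0, length_ms = 10, bandwidth_oct = 0.2,
                 patch = replicate(length(ids), matrix(rnorm(8), 2),
                                   simplify = FALSE),
                 threshold = 0.5, merit = merits, weight = 1,
                 complexity = 0, degenerate = FALSE)
}

test_that("pairwise added information is the conservative min-increment", {
  det <- random_detections(6, 40, seed = 21)
  sc <- scored_from_detections(det)
  # duplicate detections add nothing
  det2 <- det
  det2$detections <- rbind(det$detections, dup = det$detections[1, ])
  det2$responses <- rbind(det$responses, dup = det$responses[1, ])
  det2$feature_ids <- c(det$feature_ids, "dup")
  expect_equal(pairwise_added_information("dup", det$feature_ids[1], det2),
               0)
  # empty chosen set: the candidate's own information
  expect_equal(pairwise_added_information("f001", character(0), det),
               oracle_mi(sum(det$detections[1, ] & det$within),
                         sum(det$detections[1, ] & !det$within),
                         sum(det$within), sum(!det$within), 0.5),
               tolerance = 1e-12)
  # ceiling: a perfect chosen feature leaves nothing to add
  perf <- det
  perf$detections[2, ] <- perf$within
  expect_equal(pairwise_added_information("f001", "f002", perf), 0,
               tolerance = 1e-12)
  # brute-force oracle over all chosen features
  chosen <- c("f002", "f004", "f005")
  inc <- vapply(chosen, function(s)
    oracle_joint_mi(det$detections[s, ], det$detections["f003", ],
                    det$within, 0.5) -
      oracle_mi(sum(det$detections[s, ] & det$within),
                sum(det$detections[s, ] & !det$within),
                sum(det$within), sum(!det$within), 0.5), numeric(1))
  expect_equal(pairwise_added_information("f003", chosen, det),
               max(0, min(inc)), tolerance = 1e-12)
})

test_that("greedy selection matches step-wise exhaustive search on toy pools", {
  for (seed in 31:35) {
    det <- random_detections(8, 40, seed = seed)
    sc <- scored_from_detections(det)
    got <- greedy_select(sc, det)
    want <- oracle_greedy(sc$merit, det$detections, det$within, 0.5)
    expect_identical(got$features$feature_id, det$feature_ids[want])
    # cumulative curve: non-decreasing, bounded by H(C) = 1
    expect_true(all(got$features$added_information >= -1e-12))
    expect_lte(got$total_information, 1 + 1e-12)
    expect_equal(got$features$added_information[1], max(sc$merit),
                 tolerance = 1e-12)
  }
})

test_that("greedy stopping rules fire for perfect and redundant pools", {
  within <- rep(c(TRUE, FALSE), each = 20)
  perfect <- matrix(rep(within, each = 3), 3, 40,
                    dimnames = list(c("a", "b", "c"), NULL))
  det <- mifcat:::new_mif_detections(perfect * 1, rep(0.5, 3), within,
                                     c("a", "b", "c"))
  m <- greedy_select(scored_from_detections(det), det)
  expect_equal(nrow(m$features), 1)
  expect_equal(m$stop_reason, "total_target")
  # duplicates of one imperfect feature: redundancy stops the search
  imp <- within; imp[1:5] <- FALSE
  dup <- matrix(rep(imp, each = 4), 4, 40,
                dimnames = list(letters[1:4], NULL))
  det2 <- mifcat:::new_mif_detections(dup * 1, rep(0.5, 4), within,
                                      letters[1:4])
  m2 <- greedy_select(scored_from_detections(det2), det2)
  expect_equal(nrow(m2$features), 1)
  expect_equal(m2$stop_reason, "min_added")
  expect_error(greedy_select(scored_from_detections(det2)[0, ], det2),
               "empty")
})

test_that("top-merit control loses to greedy on redundant pools", {
  det <- random_detections(8, 50, seed = 44)
  sc <- scored_from_detections(det)
  expect_identical(select_top_merit(sc, det, 1)$features$feature_id,
                   greedy_select(sc, det)$features$feature_id[1])
  expect_equal(nrow(select_top_merit(sc, det, 8)$features), 8)
  expect_error(select_top_merit(sc, det, 0), "positive")
  expect_error(select_top_merit(sc, det, 9), "pool")
  # engineered redundancy: many copies of the best feature plus one
  # complementary feature; greedy finds the pair, top-merit keeps copies
  within <- rep(c(TRUE, FALSE), each = 25)
  best <- within; best[1:10] <- FALSE         # hits 15/25
  compl <- !within; compl <- within & !best   # hits the remaining 10
  D <- rbind(b1 = best, b2 = best, b3 = best, c1 = compl)
  det3 <- mifcat:::new_mif_detections(D * 1, rep(0.5, 4), within,
                                      rownames(D))
  sc3 <- scored_from_detections(det3)
  g <- greedy_select(sc3, det3)
  t3 <- select_top_merit(sc3, det3, 2)
  expect_gt(sum(g$features$added_information[1:2]),
            sum(t3$features$added_information) + 1e-9)
})

test_that("resampling control yields disjoint sets and errors on exhaustion", {
  within <- rep(c(TRUE, FALSE), each = 20)
  perfect <- matrix(rep(within, each = 2), 2, 40,
                    dimnames = list(c("a", "b"), NULL))
  det <- mifcat:::new_mif_detections(perfect * 1, rep(0.5, 2), within,
                                     c("a", "b"))
  sc <- scored_from_detections(det)
  first <- greedy_select(sc, det)
  second <- resample_excluding(sc, list(first), det)
  expect_identical(sort(c(first$features$feature_id,
                          second$features$feature_id)), c("a", "b"))
  expect_error(resample_excluding(sc, list(first, second), det), "exhausted")
})
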