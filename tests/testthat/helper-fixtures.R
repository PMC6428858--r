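# Shared fixtures, built once per test run on first use.

.fixture_env <- new.env(parent = emptyenv())

memoize <- function(key, builder) {
  if (!exists(key, .fixture_env)) assign(key, builder(), .fixture_env)
  get(key, .fixture_env)
}

# small front-end for module-level tests
tiny_frontend <- function() {
  frontend_params(n_channels = 32, cf_min = 1000, cf_max = 12000,
                  frame_rate = 250)
}

# a small trained fixture: corpus, cochleagrams, MIF sets for both tasks
tiny_run <- function() {
  memoize("tiny_run", function() {
    fp <- tiny_frontend()
    corpus <- generate_corpus(n_per_class = 30, n_callers = 4, seed = 42)
    cg_train <- corpus_cochleagrams(corpus[corpus$split == "train", ], fp)
    cg_test <- corpus_cochleagrams(corpus[corpus$split == "test", ], fp)
    mifs <- lapply(c(twitter_like = "twitter_like",
                     trill_like = "trill_like"), function(cls)
      train_mifs(corpus, task_spec(cls), fp, n_features = 150,
                 seed = substream_seed(42, paste0("features_", cls)),
                 cochleagrams = cg_train))
    list(fp = fp, corpus = corpus, cg_train = cg_train, cg_test = cg_test,
         mifs = mifs)
  })
}

# deterministic random half-split indicator
with_seed_split <- function(n, seed) {
  set.seed(seed)
  sample(rep(c(TRUE, FALSE), length.out = n))
}

# The scaled-down end-to-end study: two structured call categories plus the
# distractor class, 8 synthetic callers, 100 train + 100 test calls per
# class, 500-feature initial pools, fixed seed. Shared by the end-to-end
# acceptance properties (classification, size-constrained variants,
# cross-task controls).
acceptance_run <- function() {
  memoize("acceptance_run", function() {
    seed <- 101
    fp <- frontend_params(n_channels = 48, cf_min = 500, cf_max = 14000,
                          frame_rate = 500)
    corpus <- generate_corpus(n_per_class = 200, n_callers = 8,
                              seed = substream_seed(seed, "corpus"))
    cg_train <- corpus_cochleagrams(corpus[corpus$split == "train", ], fp)
    cg_test <- corpus_cochleagrams(corpus[corpus$split == "test", ], fp)
    test <- corpus[corpus$split == "test", ]
    out <- list(seed = seed, fp = fp, corpus = corpus, cg_test = cg_test,
                test_labels = test$call_type)
    for (cls in c("twitter_like", "trill_like")) {
      tk <- task_spec(cls)
      fseed <- substream_seed(seed, paste0("features_", cls))
      m <- train_mifs(corpus, tk, fp, n_features = 500, seed = fseed,
                      cochleagrams = cg_train)
      m_small <- train_mifs(corpus, tk, fp, n_features = 500,
                            quotas = list(),
                            constraints = list(max_length_ms = 100,
                                               max_bandwidth_oct = 1),
                            seed = fseed, cochleagrams = cg_train)
      m_whole <- train_mifs(corpus, tk, fp, variant = "whole_call",
                            cochleagrams = cg_train)
      out[[cls]] <- list(
        mifs = m,
        eval = evaluate_mifs(m, cg_test, test$call_type),
        eval_small = evaluate_mifs(m_small, cg_test, test$call_type),
        eval_whole = evaluate_mifs(m_whole, cg_test, test$call_type))
    }
    out
  })
}
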