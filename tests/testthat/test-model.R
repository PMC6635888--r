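test_that("association updates are bounded Hebbian with competitive decay", {
  model <- make_fixture("hand-built-model", seed = 2)
  A0 <- association_matrix(model)
  associate_step(model, 1, 1, lr = 0)
  expect_equal(association_matrix(model), A0)  # lr = 0 is a no-op

  # repeated co-activation drives one link monotonically toward 1
  w_prev <- association_matrix(model)[2, 2]
  for (i in 1:60) {
    associate_step(model, 2, 2, lr = 0.2)
    w <- association_matrix(model)[2, 2]
    expect_gte(w, w_prev - 1e-12)
    w_prev <- w
  }
  expect_gt(w_prev, 0.99)
  expect_true(all(association_matrix(model) >= 0 &
                    association_matrix(model) <= 1))
})

test_that("equally frequent conflicting pairs converge to equal weights", {
  model <- make_fixture("hand-built-model", seed = 2)
  for (i in 1:300) {
    associate_step(model, 1, 3, lr = 0.1)
    associate_step(model, 1, 4, lr = 0.1)
  }
  A <- association_matrix(model)
  expect_lt(abs(A[1, 3] - A[1, 4]), 0.05)
  expect_gt(A[1, 3], 0.2)
})

test_that("the association matrix tracks map growth", {
  model <- speech_model(tiny_corpus(), "a+s")
  phonmap:::sync_assoc(model)
  expect_equal(dim(association_matrix(model)), c(4L, 4L))
  phonmap:::gsom_set_errors_(model$p_map$ptr, rep(100, 4))
  maybe_grow(model$p_map, 1)
  phonmap:::sync_assoc(model)
  A <- association_matrix(model)
  expect_equal(nrow(A), 4L)
  expect_equal(ncol(A), map_size(model$p_map))
  expect_true(all(A[, 5:ncol(A)] == 0))  # new columns start at zero
})

test_that("a hand-built model has a perfect round trip", {
  model <- make_fixture("hand-built-model", seed = 1)
  # one-hot association: produce returns the designated node per word
  for (w in model$word_ids) {
    pr <- produce(model, w)
    expect_equal(model$item_word[pr$exemplar], match(w, model$word_ids))
    expect_equal(perceive(model, model$corpus$items[[pr$exemplar]]), w)
  }
  rt <- round_trip_accuracy(model)
  expect_equal(rt$perception, 1)
  expect_equal(rt$production, 1)
})

test_that("untrained associations raise errors", {
  model <- speech_model(tiny_corpus(), "a+s")
  expect_error(produce(model, model$word_ids[1]), "no learned form")
  expect_error(perceive(model, tiny_corpus()$items[[1]]), "unknown form")
  expect_error(produce(model, 999), "unregistered")
})

test_that("random one-hot associations perceive at chance level", {
  corpus <- tiny_corpus()
  n_words <- nrow(corpus$lexicon$words)
  accs <- vapply(1:60, function(s) {
    set.seed(s + 100)
    model <- make_fixture("hand-built-model", seed = 1)
    A <- association_matrix(model)
    A[] <- 0
    for (j in seq_len(ncol(A))) A[sample(nrow(A), 1), j] <- 1
    phonmap:::assoc_set_matrix_(model$assoc, A)
    round_trip_accuracy(model)$perception
  }, 0)
  chance <- 1 / length(make_fixture("hand-built-model", 1)$word_ids)
  expect_lt(abs(mean(accs) - chance), 0.12)
})

test_that("model archives round-trip through plain-text export", {
  rr <- tiny_run()
  dir <- withr::local_tempdir()
  export_model(rr$model, dir)
  back <- import_model(dir)
  expect_equal(map_state(back$p_map)$weights,
               map_state(rr$model$p_map)$weights, tolerance = 1e-6)
  expect_equal(association_matrix(back), association_matrix(rr$model),
               tolerance = 1e-6)
  expect_equal(round_trip_accuracy(back), round_trip_accuracy(rr$model))
})
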