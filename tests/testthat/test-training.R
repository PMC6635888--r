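test_that("a cycle presents every item `presentations` times", {
  corpus <- build_corpus(corpus_config(vowels = "a", consonants = "b",
                                       clusters = character(0),
                                       semantic_features = 20,
                                       realizations_per_word = 1))
  cfg <- training_config(mode = "a", cycles = 2, babbling_cycles = 1,
                         presentations = 1, seed = 3)
  set.seed(3)
  model <- speech_model(corpus, "a")
  log <- run_cycle(model, corpus, 1, cfg)
  expect_equal(log$base_steps, 2L)  # 2 items x 1 presentation
})

test_that("a default cycle on the full corpus takes 1470 base steps", {
  corpus <- default_corpus()
  cfg <- training_config(mode = "a+s", seed = 1)
  set.seed(1)
  model <- speech_model(corpus, "a+s")
  log <- run_cycle(model, corpus, 1, cfg)
  expect_equal(log$base_steps, 210L * 7L)
  expect_lte(log$extra_steps, floor(0.2 * 1470))  # corrective budget cap
})

test_that("training is reproducible from (config, corpus, seed)", {
  cfg <- training_config(mode = "a+s", cycles = 4, babbling_cycles = 2,
                         seed = 21)
  r1 <- run_training(cfg, tiny_corpus())
  r2 <- run_training(cfg, tiny_corpus())
  expect_identical(map_state(r1$model$p_map), map_state(r2$model$p_map))
  expect_identical(association_matrix(r1$model),
                   association_matrix(r2$model))
  expect_identical(r1$metrics, r2$metrics)
  r3 <- run_training(cfg, tiny_corpus(), seed = 22)
  expect_false(identical(r1$metrics, r3$metrics))
})

test_that("metrics are recorded for cycle 0 and every training cycle", {
  rr <- tiny_run()  # 8 cycles
  expect_equal(rr$metrics$cycle, 0:8)
  expect_equal(nrow(rr$log), 9)
  cfg0 <- training_config(mode = "a", cycles = 0, babbling_cycles = 0,
                          seed = 2)
  rr0 <- run_training(cfg0, tiny_corpus())
  expect_equal(rr0$metrics$cycle, 0L)  # only the establishment cycle
})

test_that("interconnection checks stay silent during babbling", {
  rr <- tiny_run()  # babbling_cycles = 3
  expect_true(all(rr$log$ic_events[rr$log$cycle <= 3] == 0))
  unc <- rr$metrics$n_unclear
  expect_lte(unc[length(unc)], unc[2])  # unclear nodes do not end higher
})

test_that("the per-step GSOM check fires exactly on shared-word collisions", {
  model <- make_fixture("hand-built-model", seed = 1)
  # private node: no corrective action
  expect_null(gsom_check(model, 1))
  # force two items of different words onto one node
  model$last_bmu[2] <- model$last_bmu[4]
  chk <- gsom_check(model, 4)
  expect_equal(chk$conflicts, 2L)
  expect_equal(sort(unique(chk$presentations)), c(2L, 4L))
  expect_length(chk$presentations, 2 * 2)  # default two repetitions
})

test_that("the interconnection check re-trains exactly the broken words", {
  model <- make_fixture("hand-built-model", seed = 1)
  cfg <- training_config(mode = "a+s", cycles = 2, babbling_cycles = 1)
  expect_equal(interconnection_check(model, model$corpus, cfg),
               integer(0))  # perfect model: no action
  # break word 2: erase its association row
  A <- association_matrix(model)
  wrow <- find_bmu(model$s_map, model$sem[2, ])
  A[wrow, ] <- 0
  phonmap:::assoc_set_matrix_(model$assoc, A)
  fixed <- interconnection_check(model, model$corpus, cfg)
  expect_equal(fixed, model$word_ids[2])
  # the corrective pass restored a nonzero association for that word
  expect_gt(sum(association_matrix(model)[wrow, ]), 0)
})

test_that("an experiment aligns seeds across modes", {
  cfg <- training_config(cycles = 3, babbling_cycles = 1, runs = 2,
                         seed = 5)
  ex <- run_experiment(cfg, tiny_corpus(), modes = c("a", "a+s"))
  expect_named(ex, c("a", "a+s"))
  expect_length(ex$a, 2)
  expect_length(ex$`a+s`, 2)
  expect_equal(vapply(ex$a, `[[`, 0L, "seed"),
               vapply(ex$`a+s`, `[[`, 0L, "seed"))
  td <- tidy_metrics(ex)
  expect_setequal(unique(td$mode), c("a", "a+s"))
  expect_equal(nrow(td[td$metric == "n_unclear" & td$mode == "a", ]),
               2 * 4)  # 2 runs x (3 cycles + cycle 0)
})
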