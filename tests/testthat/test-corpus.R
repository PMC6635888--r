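test_that("corpus size follows |lexicon| x realizations and is deterministic", {
  tiny <- tiny_corpus()
  expect_equal(length(tiny$items), 18)  # 6 words x 3
  one <- build_corpus(corpus_config(vowels = c("i", "a"),
                                    consonants = c("b", "d"),
                                    clusters = character(0),
                                    semantic_features = 31,
                                    realizations_per_word = 1))
  expect_equal(length(one$items), 6)
  c1 <- build_corpus(phonmap:::tiny_config(5))
  c2 <- build_corpus(phonmap:::tiny_config(5))
  expect_identical(lapply(c1$items, `[[`, "auditory"),
                   lapply(c2$items, `[[`, "auditory"))
  expect_identical(c1$scaling, c2$scaling)
})

test_that("all representations stay in [0,1] and somato complements distance", {
  for (it in tiny_corpus()$items) {
    expect_true(all(it$auditory >= 0 & it$auditory <= 1))
    expect_true(all(it$somato >= 0 & it$somato <= 1))
    expect_equal(unclass(it$somato), 1 - unclass(it$trajectories),
                 ignore_attr = TRUE)
  }
})

test_that("training vectors have the stated block layout and balance", {
  tiny <- tiny_corpus()
  it <- tiny$items[[1]]
  expect_length(vectorize(it, "a"), 24 * 30)
  expect_length(vectorize(it, "s"), 4 * 30)
  v <- vectorize(it, "a+s", scaling = tiny$scaling)
  expect_length(v, 840)
  expect_equal(table(attr(v, "modality_mask"))[["a"]], 720)
  # corpus-average squared block norms agree within 10 %
  X <- corpus_vectors(tiny, "a+s")
  mask <- attr(X, "modality_mask")
  na <- mean(rowSums(X[, mask == "a"]^2))
  ns <- mean(rowSums(X[, mask == "s"]^2))
  expect_lt(abs(na - ns) / max(na, ns), 0.10)
  expect_error(vectorize(list(auditory = NULL, somato = NULL), "a"),
               "empty")
})

test_that("realizations of a word lie closer than items of different words", {
  for (mode in c("a", "s", "a+s")) {
    X <- corpus_vectors(default_corpus(), mode)
    wid <- attr(X, "word_id")
    d <- as.matrix(dist(X))
    same <- outer(wid, wid, "==") & upper.tri(d)
    diff <- (!outer(wid, wid, "==")) & upper.tri(d)
    expect_lt(mean(d[same]), mean(d[diff]))
  }
})

test_that("place of articulation is recoverable from the somatosensory rep alone", {
  # during the initial closure, the contact tier dominates the activation:
  # a fixed linear readout gated to the closure interval recovers place for
  # every plosive/nasal item
  corpus <- default_corpus()
  lex <- corpus$lexicon
  tier_of_place <- c(labial = 1L, alveolar = 2L, velar = 3L)
  checked <- 0L
  for (it in corpus$items) {
    segs <- lex$segments[[match(it$word_id, lex$words$word_id)]]
    cons <- segs[segs$kind == "consonant" &
                   segs$manner %in% c("plosive", "nasal"), , drop = FALSE]
    if (nrow(cons) == 0) next
    ev <- it$plan$score[it$plan$score$role %in% c("closure", "murmur"), ][1, ]
    times <- (seq_len(ncol(it$somato)) - 1) * 10
    frames <- which(times >= ev$on & times < (ev$on + ev$off) / 2)
    peak <- apply(unclass(it$somato)[1:3, frames, drop = FALSE], 1, max)
    expect_equal(unname(which.max(peak)), tier_of_place[[cons$place[1]]])
    checked <- checked + 1L
  }
  expect_equal(checked, (45 + 20 - 5) * 3)  # all but the /l/-initial CV
})

test_that("corpus export writes consistent plain-text tables", {
  dir <- withr::local_tempdir()
  export_corpus(tiny_corpus(), dir)
  meta <- read.table(file.path(dir, "items.tsv"), header = TRUE)
  expect_equal(nrow(meta), 18)
  arrays <- read.table(file.path(dir, "arrays.tsv"), header = TRUE,
                       sep = "\t")
  it0 <- arrays[arrays$item == 0 & arrays$kind == "auditory", ]
  expect_equal(max(it0$row), 24)
  expect_equal(max(it0$frame), meta$frames[1])
})
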