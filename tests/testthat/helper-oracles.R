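# Shared fixtures (built once per session) and independent oracles used to
# cross-check the compiled implementations.

.fixture_env <- new.env()

tiny_corpus <- function() {
  if (is.null(.fixture_env$tiny))
    .fixture_env$tiny <- make_fixture("tiny-corpus", seed = 7L)
  .fixture_env$tiny
}

default_corpus <- function() {
  if (is.null(.fixture_env$full))
    .fixture_env$full <- build_corpus(corpus_config(seed = 1L))
  .fixture_env$full
}

# brute-force nearest-neighbour scan (oracle for find_bmu)
brute_bmu <- function(weights, x) {
  d2 <- rowSums((weights - matrix(x, nrow(weights), length(x),
                                  byrow = TRUE))^2)
  which(d2 == min(d2))[1]
}

# direct per-node tally (oracle for classify_nodes)
tally_classify <- function(node_of_item, word_of_item) {
  unc <- 0L; cns <- 0L; occ <- 0L
  for (k in unique(node_of_item)) {
    at <- which(node_of_item == k)
    occ <- occ + 1L
    if (length(at) >= 2) {
      if (length(unique(word_of_item[at])) >= 2) unc <- unc + 1L
      else cns <- cns + 1L
    }
  }
  c(unc, cns, occ)
}

# recursive flood fill over a labeled lattice (oracle for
# count_feature_regions)
flood_fill_regions <- function(labeling) {
  key <- paste(labeling$x, labeling$y)
  idx <- setNames(seq_len(nrow(labeling)), key)
  seen <- rep(FALSE, nrow(labeling))
  n_regions <- 0L
  for (start in seq_len(nrow(labeling))) {
    if (seen[start]) next
    n_regions <- n_regions + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        j <- idx[paste(labeling$x[i] + d[1], labeling$y[i] + d[2])]
        if (!is.na(j) && !seen[j] &&
            labeling$label[j] == labeling$label[i]) {
          seen[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  n_regions
}

# nearest-occupied + majority labeling oracle (for label_lattice)
naive_label <- function(pos, node_of_item, item_labels) {
  n <- nrow(pos)
  lab <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    at <- which(node_of_item == k)
    if (length(at) == 0) next
    tab <- table(factor(item_labels[at], levels = unique(item_labels[at])))
    lab[k] <- names(tab)[which.max(tab)]
  }
  occ <- which(!is.na(lab))
  for (k in seq_len(n)) {
    if (!is.na(lab[k])) next
    d2 <- (pos[occ, 1] - pos[k, 1])^2 + (pos[occ, 2] - pos[k, 2])^2
    lab[k] <- lab[occ[which.min(d2)]]
  }
  lab
}

# a short trained run on the tiny corpus, reused by model-level tests
tiny_run <- function() {
  if (is.null(.fixture_env$tiny_run)) {
    cfg <- training_config(mode = "a+s", cycles = 8, babbling_cycles = 3,
                           seed = 11)
    .fixture_env$tiny_run <- run_training(cfg, tiny_corpus())
  }
  .fixture_env$tiny_run
}
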