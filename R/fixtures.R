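#' Deterministic small test instances
#'
#' Registered fixtures:
#' * `"tiny-corpus"`: 2 vowels x 2 consonants, no clusters — 6 words
#'   (2 V + 4 CV), 18 items, 31 semantic features.
#' * `"hand-built-model"`: a two-word model whose maps and one-hot
#'   association are constructed directly, so its round trip is perfect by
#'   construction.
#' * `"toy-lattice-labelings"`: small labeled lattices with known
#'   feature-region counts.
#'
#' @param name fixture name.
#' @param seed seed.
#' @return the fixture object.
#' @export
make_fixture <- function(name, seed = 1L) {
  switch(name,
    "tiny-corpus" = build_corpus(tiny_config(seed)),
    "hand-built-model" = hand_built_model(seed),
    "toy-lattice-labelings" = toy_labelings(),
    stop("unknown fixture name: ", name))
}

tiny_config <- function(seed = 1L)
  corpus_config(vowels = c("i", "a"), consonants = c("b", "d"),
                clusters = character(0), semantic_features = 31,
                seed = seed)

# Two-word model with item vectors as P-MAP nodes, word semantic vectors as
# S-MAP nodes, and a one-hot association; round_trip_accuracy == 1 by
# construction.
hand_built_model <- function(seed = 1L) {
  corpus <- build_corpus(
    corpus_config(vowels = c("i", "a"), consonants = character(0),
                  clusters = character(0), semantic_features = 12,
                  seed = seed))
  model <- speech_model(corpus, "a+s")
  n_items <- nrow(model$X)
  # P-MAP: one node per item, laid out on one row
  model$p_map <- map_from_state(list(
    positions = cbind(seq_len(n_items) - 1L, 0L),
    weights = model$X))
  # S-MAP: one node per word on one row
  model$s_map <- map_from_state(list(
    positions = cbind(seq_len(nrow(model$sem)) - 1L, 0L),
    weights = model$sem))
  A <- matrix(0, nrow(model$sem), n_items)
  for (i in seq_len(n_items)) A[model$item_word[i], i] <- 1
  assoc_set_matrix_(model$assoc, A)
  model$last_bmu <- gsom_bmu_batch_(model$p_map$ptr, model$X)
  model
}

toy_labelings <- function() {
  grid <- expand.grid(x = 0:2, y = 0:2)
  mk <- function(label) data.frame(node_id = 1:9, x = grid$x, y = grid$y,
                                   label = label, occupied = TRUE)
  list(
    uniform = list(labeling = mk("p"), regions = 1L),
    half_split = list(labeling = mk(ifelse(grid$x <= 1, "p", "q")),
                      regions = 2L),
    checkerboard = list(labeling = mk(ifelse((grid$x + grid$y) %% 2 == 0,
                                             "p", "q")),
                        regions = 9L),
    three_stripes = list(labeling = mk(c("p", "q", "p")[grid$x + 1]),
                         regions = 3L))
}
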