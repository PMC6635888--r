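#' Two-map speech model (S-MAP + P-MAP + association)
#'
#' Binds a semantic growing map over the lexicon's feature vectors and a
#' phonetic growing map over the corpus item vectors with a bidirectional
#' associative interconnection whose link weights live in `[0, 1]`. The
#' association matrix is resized (new rows/columns start at 0) whenever
#' either map grows. Models are environments (reference semantics): the
#' training drivers update them in place.
#'
#' @param corpus a [build_corpus()] result.
#' @param mode training modality, `"a"`, `"s"` or `"a+s"`.
#' @param noise_sd initial map weight noise (around the data means).
#' @param perception for combined-mode models: `"auditory"` matches
#'   percepts on the auditory sub-distance of the P-MAP weights (an
#'   external speaker provides no somatosensory signal); `"impute"`
#'   instead fills the somatosensory block of the query with the corpus
#'   mean and matches on the full distance.
#' @return an object of class `speech_model`.
#' @export
speech_model <- function(corpus, mode, noise_sd = 0.02,
                         perception = c("auditory", "impute")) {
  mode <- norm_mode(mode)
  perception <- match.arg(perception)
  X <- corpus_vectors(corpus, mode)
  sem <- corpus$lexicon$semantic
  storage.mode(sem) <- "double"
  m <- new.env(parent = emptyenv())
  m$mode <- mode
  m$corpus <- corpus
  m$X <- X
  m$sem <- sem
  m$item_word <- match(attr(X, "word_id"), corpus$lexicon$words$word_id)
  m$word_ids <- corpus$lexicon$words$word_id
  m$s_map <- init_map(ncol(sem), colMeans(sem), noise_sd)
  m$p_map <- init_map(ncol(X), colMeans(X), noise_sd)
  m$assoc <- assoc_create_(4L, 4L)
  m$last_bmu <- rep(0L, nrow(X))
  m$perception <- perception
  qc <- perception_columns(X, mode, perception)
  m$qcols <- qc
  m$query <- perception_query_matrix(X, mode, perception, qc)
  class(m) <- "speech_model"
  m
}

# Perception always enters through the auditory channel. In combined mode
# the default matches on the auditory sub-distance of the P-MAP weights;
# the "impute" alternative fills the somatosensory block with the corpus
# mean and matches on the full distance. In somatosensory-only mode the
# item's own somatosensory vector is the query (self-perception).
perception_columns <- function(X, mode, perception) {
  if (mode == "a+s" && perception == "auditory")
    which(attr(X, "modality_mask") == "a")
  else seq_len(ncol(X))
}

perception_query_matrix <- function(X, mode, perception, qcols) {
  if (mode != "a+s") return(X)
  if (perception == "auditory") return(X[, qcols, drop = FALSE])
  Q <- X
  s_cols <- which(attr(X, "modality_mask") == "s")
  Q[, s_cols] <- matrix(colMeans(X[, s_cols, drop = FALSE]),
                        nrow(X), length(s_cols), byrow = TRUE)
  Q
}

# P-MAP winners of the model's perception queries (or a compatible matrix)
perceive_bmus <- function(model, Q = model$query)
  gsom_bmu_batch_sub_(model$p_map$ptr, Q, model$qcols)

# query row for a single auditory representation
auditory_query <- function(model, auditory_rep) {
  corpus <- model$corpus
  nf <- corpus$config$norm_frames
  item <- list(auditory = auditory_rep, somato = NULL)
  a <- item_block(item, "a", nf) * corpus$scaling[["a"]]
  if (model$mode == "a") return(a)
  if (model$mode == "s")
    stop("a somatosensory-only model cannot perceive a bare auditory ",
         "representation; pass a stimulus_item")
  if (model$perception == "auditory") return(a)
  mask <- attr(model$X, "modality_mask")
  q <- numeric(ncol(model$X))
  q[mask == "a"] <- a
  s_cols <- which(mask == "s")
  q[s_cols] <- colMeans(model$X[, s_cols, drop = FALSE])
  q
}

#' @export
print.speech_model <- function(x, ...) {
  cat("Speech model (mode ", x$mode, "): S-MAP ", map_size(x$s_map),
      " nodes, P-MAP ", map_size(x$p_map), " nodes, ",
      length(x$word_ids), " words, ", nrow(x$X), " items\n", sep = "")
  invisible(x)
}

#' Association matrix of a model
#' @param model a [speech_model()].
#' @return S-nodes x P-nodes matrix of link weights in `[0, 1]`.
#' @export
association_matrix <- function(model) assoc_matrix_(model$assoc)

#' One Hebbian association step
#'
#' Strengthens the link between the co-active S-MAP and P-MAP winners by
#' `lr * (1 - w)` and decays every other link in the winner's row and
#' column by `(1 - lr * decay_ratio)`; weights remain in `[0, 1]`.
#'
#' @param model a [speech_model()].
#' @param s_bmu,p_bmu winning node ids.
#' @param lr association learning rate.
#' @param decay_ratio competitive decay relative to `lr`.
#' @return the model, invisibly.
#' @export
associate_step <- function(model, s_bmu, p_bmu, lr, decay_ratio = 0.5) {
  sync_assoc(model)
  assoc_update_(model$assoc, as.integer(s_bmu), as.integer(p_bmu),
                lr, decay_ratio)
  invisible(model)
}

sync_assoc <- function(model) {
  assoc_resize_(model$assoc, map_size(model$s_map), map_size(model$p_map))
  invisible(model)
}

word_index <- function(model, word_id) {
  i <- match(word_id, model$word_ids)
  if (is.na(i)) stop("unregistered word_id: ", word_id)
  i
}

#' Produce a word
#'
#' Semantic route: the word's semantic vector activates its S-MAP winner;
#' the learned association projects it to the most strongly linked P-MAP
#' node (ties toward the lowest node id); the stored exemplar whose training
#' vector is nearest to that node's weights stands in for the motor-plan
#' state readout.
#'
#' @param model a trained [speech_model()].
#' @param word_id the word to produce.
#' @return list with `p_node`, `s_node`, `exemplar` (item index) and `item`
#'   (the `stimulus_item`, including its motor plan and representations).
#' @export
produce <- function(model, word_id) {
  wi <- word_index(model, word_id)
  s_bmu <- find_bmu(model$s_map, model$sem[wi, ])
  sync_assoc(model)
  row <- assoc_row_(model$assoc, s_bmu)
  if (all(row == 0)) stop("no learned form for word ", word_id)
  p_node <- which.max(row)
  w <- map_weights(model$p_map)[p_node, ]
  d2 <- colSums((t(model$X) - w)^2)
  ex <- which.min(d2)
  list(p_node = p_node, s_node = s_bmu, exemplar = ex,
       item = model$corpus$items[[ex]])
}

#' Perceive an auditory form
#'
#' Auditory route: the representation is vectorized under the model's mode
#' (somatosensory block imputed with the corpus mean in combined mode), the
#' P-MAP winner is found, and the association column projects it back to an
#' S-MAP node whose registered word is returned.
#'
#' @param model a trained [speech_model()].
#' @param rep an `auditory_rep`, or a `stimulus_item` (whose auditory
#'   representation is used; in somatosensory-only mode, its somatosensory
#'   representation).
#' @return the perceived `word_id`.
#' @export
perceive <- function(model, rep) {
  q <- if (inherits(rep, "stimulus_item")) {
    v <- vectorize(rep, model$mode, model$corpus$config$norm_frames,
                   model$corpus$scaling)
    if (model$mode == "a+s" && model$perception == "impute") {
      s_cols <- which(attr(model$X, "modality_mask") == "s")
      v[s_cols] <- colMeans(model$X[, s_cols, drop = FALSE])
    }
    v[if (model$mode == "a+s" && model$perception == "auditory")
        model$qcols else TRUE]
  } else auditory_query(model, rep)
  p_bmu <- gsom_bmu_batch_sub_(model$p_map$ptr, matrix(q, nrow = 1),
                               model$qcols)[1]
  sync_assoc(model)
  col <- assoc_col_(model$assoc, p_bmu)
  if (all(col == 0)) stop("unknown form: no association for P-MAP node ",
                          p_bmu)
  s_node <- which.max(col)
  node2word <- snode_words(model)
  wid <- node2word[as.character(s_node)]
  if (is.na(wid)) {
    # no word currently maps to this S node; fall back to the nearest word
    ws <- map_weights(model$s_map)[s_node, ]
    wid <- model$word_ids[which.min(colSums((t(model$sem) - ws)^2))]
  }
  unname(wid)
}

# word registered at each S-MAP node (lowest word_id claims a shared node)
snode_words <- function(model, word_bmus = NULL) {
  bmus <- word_bmus %||% gsom_bmu_batch_(model$s_map$ptr, model$sem)
  keep <- !duplicated(bmus)
  setNames(model$word_ids[keep], bmus[keep])
}

#' Round-trip performance of a trained model
#'
#' Perception accuracy: fraction of corpus items whose auditory (or, in
#' somatosensory-only mode, somatosensory) form is perceived as the item's
#' own word. Production success: fraction of words whose produced P-MAP
#' node is occupied exclusively by that word's items.
#'
#' @param model a trained [speech_model()].
#' @param corpus the training corpus (defaults to the model's).
#' @param assignment,A,p_bmus optional precomputed pieces (item
#'   assignment, association matrix, perception winners), reused by the
#'   per-cycle evaluation.
#' @return list with `perception`, `production`.
#' @export
round_trip_accuracy <- function(model, corpus = model$corpus,
                                assignment = NULL, A = NULL,
                                p_bmus = NULL) {
  sync_assoc(model)
  st <- model_readout(model, assignment, A, p_bmus)
  list(perception = mean(st$ok_item),
       production = mean(st$ok_word))
}

# shared batch computation behind round trips and the interconnection
# check: perception verdict per item, production verdict per word
model_readout <- function(model, assignment = NULL, A = NULL,
                          p_bmus = NULL) {
  if (is.null(A)) A <- association_matrix(model)
  words <- model$word_ids
  word_bmus <- gsom_bmu_batch_(model$s_map$ptr, model$sem)
  node2word <- snode_words(model, word_bmus)
  ids <- if (is.null(assignment)) gsom_bmu_batch_(model$p_map$ptr, model$X)
         else if (inherits(assignment, "item_assignment"))
           assignment$item_node else assignment
  if (is.null(p_bmus)) p_bmus <- perceive_bmus(model)

  cols <- A[, p_bmus, drop = FALSE]  # s-nodes x items
  s_pred <- max.col(t(cols), ties.method = "first")
  wid_pred <- node2word[as.character(s_pred)]
  ok_item <- colSums(cols) > 0 & !is.na(wid_pred) &
    wid_pred == words[model$item_word]

  rows <- A[word_bmus, , drop = FALSE]  # words x p-nodes
  p_pred <- max.col(rows, ties.method = "first")
  nz_row <- rowSums(rows) > 0
  ok_word <- vapply(seq_along(words), function(w) {
    if (!nz_row[w]) return(FALSE)
    at <- which(ids == p_pred[w])
    length(at) > 0 && all(model$item_word[at] == w)
  }, TRUE)
  list(ok_item = unname(ok_item), ok_word = ok_word, ids = ids,
       p_bmus = p_bmus, p_pred = p_pred, nz_row = nz_row,
       word_bmus = word_bmus)
}

#' Export a model as plain-text archives
#'
#' Writes per-map state tables (positions, errors, weights), the
#' association matrix and a YAML metadata file into `dir`.
#'
#' @param model a [speech_model()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump_map <- function(map, stem) {
    st <- map_state(map)
    write.table(data.frame(x = st$positions[, 1], y = st$positions[, 2],
                           error = st$errors),
                file.path(dir, paste0(stem, "_nodes.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(st$weights, file.path(dir, paste0(stem, "_weights.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  dump_map(model$s_map, "smap")
  dump_map(model$p_map, "pmap")
  sync_assoc(model)
  write.table(association_matrix(model), file.path(dir, "assoc.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  yaml::write_yaml(list(mode = model$mode,
                        corpus_config = unclass(model$corpus$config)),
                   file.path(dir, "model.yaml"))
  invisible(dir)
}

#' Rebuild a model from an [export_model()] archive
#'
#' The corpus is regenerated from the archived configuration (the corpus is
#' deterministic under its seed), then the archived map and association
#' states are restored.
#'
#' @param dir archive directory.
#' @return a `speech_model`.
#' @export
import_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  cfg <- do.call(corpus_config, meta$corpus_config)
  corpus <- build_corpus(cfg)
  model <- speech_model(corpus, meta$mode)
  load_map <- function(stem) {
    nodes <- read.table(file.path(dir, paste0(stem, "_nodes.tsv")),
                        header = TRUE, sep = "\t")
    w <- as.matrix(read.table(file.path(dir, paste0(stem, "_weights.tsv")),
                              sep = "\t"))
    map_from_state(list(positions = cbind(nodes$x, nodes$y), weights = w,
                        errors = nodes$error))
  }
  model$s_map <- load_map("smap")
  model$p_map <- load_map("pmap")
  A <- as.matrix(read.table(file.path(dir, "assoc.tsv"), sep = "\t"))
  assoc_set_matrix_(model$assoc, unname(A))
  model$last_bmu <- gsom_bmu_batch_(model$p_map$ptr, model$X)
  model
}
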