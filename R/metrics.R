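#' Classify P-MAP nodes by the items they represent
#'
#' Following the map-quality measures of the training regimen: an *unclear*
#' node hosts at least two items of at least two different words (a source
#' of perception/production confusion); a *clear non-separated* node hosts
#' at least two items that all belong to the same word (the inverse of
#' overlearning); an *occupied* node hosts at least one item.
#'
#' @param assignment an [assign_items()] result (or a plain vector of
#'   per-item node ids).
#' @param word_of_item integer/character word of each item.
#' @return list with `n_unclear`, `n_clear_nonseparated`, `n_occupied`.
#' @export
classify_nodes <- function(assignment, word_of_item) {
  ids <- if (inherits(assignment, "item_assignment")) assignment$item_node
         else assignment
  by_node <- split(word_of_item, ids)
  n_items <- lengths(by_node)
  n_words <- vapply(by_node, function(w) length(unique(w)), 0L)
  list(n_unclear = sum(n_items >= 2 & n_words >= 2),
       n_clear_nonseparated = sum(n_items >= 2 & n_words == 1),
       n_occupied = length(by_node))
}

# per-word value of a phonetic feature; V words carry "none" for the
# consonantal features, CCV onsets (always plosive + lateral) are labeled
# "plosive-lateral" for manner and by their first consonant for place and
# voicing
word_feature <- function(lexicon, feature) {
  vapply(seq_len(nrow(lexicon$words)), function(i) {
    segs <- lexicon$segments[[i]]
    cons <- segs[segs$kind == "consonant", , drop = FALSE]
    vow <- segs[segs$kind == "vowel", , drop = FALSE][1, ]
    switch(feature,
           structure = lexicon$words$structure[i],
           place = if (nrow(cons) == 0) "none" else cons$place[1],
           manner = if (nrow(cons) == 0) "none"
                    else if (nrow(cons) >= 2) "plosive-lateral"
                    else cons$manner[1],
           voicing = if (nrow(cons) == 0) "none"
                     else if (cons$voiced[1]) "voiced" else "voiceless",
           vowel_height = vow$vowel_height,
           vowel_backness = vow$vowel_backness,
           stop("unknown feature: ", feature))
  }, "")
}

#' Label every lattice node with a phonetic feature value
#'
#' Occupied nodes take the majority label of their items (ties toward the
#' item with the lowest id); unoccupied nodes take the label of the nearest
#' occupied node in lattice distance (ties toward the lowest node id), so
#' the labeling partitions the complete map into feature regions.
#'
#' @param map the P-MAP (`gsom`).
#' @param assignment an [assign_items()] result for the corpus vectors.
#' @param feature one of `"structure"`, `"place"`, `"manner"`,
#'   `"voicing"`, `"vowel_height"`, `"vowel_backness"`.
#' @param corpus the corpus (supplies item words and the lexicon), or a
#'   per-item label vector via `item_labels`.
#' @param item_labels optional explicit per-item labels.
#' @return a `feature_labeling`: data.frame `node_id`, `x`, `y`, `label`,
#'   `occupied`.
#' @export
label_lattice <- function(map, assignment, feature = "place",
                          corpus = NULL, item_labels = NULL) {
  ids <- if (inherits(assignment, "item_assignment")) assignment$item_node
         else assignment
  if (length(ids) == 0) stop("empty assignment")
  if (is.null(item_labels)) {
    if (is.null(corpus)) stop("need corpus or item_labels")
    wf <- word_feature(corpus$lexicon, feature)
    word_of_item <- match(vapply(corpus$items, `[[`, 0L, "word_id"),
                          corpus$lexicon$words$word_id)
    item_labels <- wf[word_of_item]
  }
  pos <- map_positions(map)
  n <- map_size(map)
  label <- rep(NA_character_, n)
  for (k in unique(ids)) {
    at <- which(ids == k)  # ascending item ids: first max is lowest-id tie
    tab <- table(factor(item_labels[at], levels = unique(item_labels[at])))
    label[k] <- names(tab)[which.max(tab)]
  }
  occupied <- which(!is.na(label))
  if (length(occupied) == 0) stop("empty assignment")
  for (k in seq_len(n)) {
    if (!is.na(label[k])) next
    d2 <- (pos[occupied, 1] - pos[k, 1])^2 + (pos[occupied, 2] - pos[k, 2])^2
    label[k] <- label[occupied[which.min(d2)]]  # lowest node id on ties
  }
  structure(data.frame(node_id = seq_len(n), x = pos[, 1], y = pos[, 2],
                       label = label,
                       occupied = seq_len(n) %in% occupied,
                       stringsAsFactors = FALSE),
            feature = feature, class = c("feature_labeling", "data.frame"))
}

#' Count feature regions of a labeled lattice
#'
#' A feature region is a maximal 4-connected component of lattice nodes
#' sharing one feature value; fewer regions indicate better topographic
#' ordering of that feature.
#'
#' @param labeling a [label_lattice()] result (or any data.frame with
#'   `x`, `y`, `label`).
#' @return integer region count. `region_membership()` returns the region
#'   id of every node instead.
#' @export
count_feature_regions <- function(labeling) {
  if (nrow(labeling) == 0) return(0L)
  max(region_membership(labeling))
}

#' @rdname count_feature_regions
#' @export
region_membership <- function(labeling) {
  n <- nrow(labeling)
  key <- paste(labeling$x, labeling$y, sep = ",")
  idx <- setNames(seq_len(n), key)
  edges <- integer(0)
  for (d in list(c(1, 0), c(0, 1))) {
    nb <- idx[paste(labeling$x + d[1], labeling$y + d[2], sep = ",")]
    ok <- which(!is.na(nb) & labeling$label == labeling$label[nb])
    edges <- c(edges, rbind(ok, nb[ok]))
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Intra- versus inter-word clustering on the P-MAP plane
#'
#' Mean Euclidean lattice distance between the best-matching nodes of items
#' of the same word (`intra`) and of different words (`inter`). A trained
#' map groups the realizations of a word together, so `intra < inter`.
#'
#' @param map the P-MAP.
#' @param assignment an [assign_items()] result.
#' @param word_of_item word of each item.
#' @return list with `intra`, `inter`.
#' @export
word_clustering_score <- function(map, assignment, word_of_item) {
  ids <- if (inherits(assignment, "item_assignment")) assignment$item_node
         else assignment
  pos <- map_positions(map)
  p <- pos[ids, , drop = FALSE]
  d <- as.matrix(dist(p))
  same <- outer(word_of_item, word_of_item, "==")
  ut <- upper.tri(d)
  list(intra = mean(d[ut & same]), inter = mean(d[ut & !same]))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact for combined sample sizes up to 20 via full enumeration of the
#' rank-sum permutation distribution (ties handled exactly); larger samples
#' use the normal approximation with tie correction.
#'
#' @param sample_a,sample_b numeric samples.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("both samples must be nonempty")
  m <- length(sample_a); n <- length(sample_b); N <- m + n
  if (N <= 20) {
    r <- rank(c(sample_a, sample_b))
    w_obs <- sum(r[seq_len(m)])
    sets <- combn(N, m)
    w_all <- colSums(matrix(r[sets], nrow = m))
    mu <- m * (N + 1) / 2
    mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    suppressWarnings(wilcox.test(sample_a, sample_b, exact = FALSE,
                                 correct = TRUE)$p.value)
  }
}

#' Compare a metric across training modes
#'
#' Summarizes aligned run collections as per-cycle mean and standard
#' deviation per mode, with the two-sided rank-sum p-value across runs —
#' the layout used to compare feature-region counts between auditory-only
#' and auditory-plus-somatosensory training.
#'
#' @param results_a,results_b lists of `run_result`s (same run count).
#' @param metric a metrics column name, e.g. `"regions_place"`.
#' @param cycles cycle(s) at which to compare.
#' @return data.frame: `cycle`, `mean_a`, `sd_a`, `mean_b`, `sd_b`, `p`.
#' @export
compare_modes <- function(results_a, results_b, metric, cycles) {
  if (length(results_a) != length(results_b))
    stop("unequal run counts")
  pull <- function(results, cy) vapply(results, function(r) {
    i <- match(cy, r$metrics$cycle)
    if (is.na(i)) stop("cycle ", cy, " not recorded")
    as.numeric(r$metrics[[metric]][i])
  }, 0)
  out <- lapply(cycles, function(cy) {
    a <- pull(results_a, cy); b <- pull(results_b, cy)
    data.frame(cycle = cy, mean_a = mean(a), sd_a = sd(a),
               mean_b = mean(b), sd_b = sd(b),
               p = wilcoxon_rank_sum(a, b))
  })
  do.call(rbind, out)
}

#' Evaluate a model against its corpus
#'
#' Computes the per-cycle metrics record: node classification counts,
#' feature-region counts for every phonetic feature, clustering score and
#' round-trip accuracy.
#'
#' @param model a [speech_model()].
#' @param corpus the training corpus.
#' @return one-row data.frame.
#' @export
evaluate_model <- function(model, corpus = model$corpus) {
  assignment <- assign_items(model$p_map, model$X)
  cls <- classify_nodes(assignment, model$item_word)
  feats <- c("structure", "place", "manner", "voicing",
             "vowel_height", "vowel_backness")
  regions <- vapply(feats, function(f)
    count_feature_regions(label_lattice(model$p_map, assignment, f,
                                        corpus)), 0L)
  names(regions) <- paste0("regions_", feats)
  clu <- word_clustering_score(model$p_map, assignment, model$item_word)
  rt <- round_trip_accuracy(model, corpus, assignment = assignment)
  data.frame(n_unclear = cls$n_unclear,
             n_clear_nonseparated = cls$n_clear_nonseparated,
             n_occupied = cls$n_occupied,
             n_nodes = map_size(model$p_map),
             as.list(regions),
             intra = clu$intra, inter = clu$inter,
             rt_perception = rt$perception, rt_production = rt$production)
}
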