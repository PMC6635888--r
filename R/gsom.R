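#' Initialize a growing self-organizing map
#'
#' Creates the initial 2 x 2 lattice at positions (0,0), (0,1), (1,0),
#' (1,1), with weights drawn as small seeded noise around a supplied center
#' (typically the corpus mean). The map object wraps compiled state and has
#' reference semantics; see [clone_map()].
#'
#' @param input_dim dimensionality of the input vectors (>= 1).
#' @param center numeric vector of length `input_dim` (default zeros).
#' @param noise_sd standard deviation of the initial weight noise.
#' @return an object of class `gsom`.
#' @export
init_map <- function(input_dim, center = NULL, noise_sd = 0.02) {
  if (input_dim < 1) stop("input_dim must be >= 1")
  if (is.null(center)) center <- numeric(input_dim)
  if (length(center) != input_dim) stop("center has wrong length")
  pos <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  w <- matrix(rep(center, each = 4), 4, input_dim) +
    matrix(rnorm(4 * input_dim, 0, noise_sd), 4, input_dim)
  new_gsom(gsom_create_(input_dim, pos, w, numeric(4)))
}

new_gsom <- function(ptr) structure(list(ptr = ptr), class = "gsom")

#' Reconstruct a map from an explicit state
#'
#' @param state a list with `positions` (n x 2 integer), `weights`
#'   (n x dim) and optionally `errors`.
#' @return a `gsom`.
#' @export
map_from_state <- function(state) {
  w <- as.matrix(state$weights)
  pos <- matrix(as.integer(as.matrix(state$positions)), ncol = 2)
  err <- state$errors %||% numeric(nrow(w))
  new_gsom(gsom_create_(ncol(w), pos, w, err))
}

#' Snapshot the full state of a map
#' @param map a `gsom`.
#' @return list with `positions`, `weights`, `errors`.
#' @export
map_state <- function(map)
  list(positions = gsom_positions_(map$ptr),
       weights = gsom_weights_(map$ptr),
       errors = gsom_errors_(map$ptr))

#' Deep-copy a map
#' @param map a `gsom`.
#' @return an independent `gsom` with identical state.
#' @export
clone_map <- function(map) new_gsom(gsom_clone_(map$ptr))

#' @rdname map_state
#' @export
map_size <- function(map) gsom_size_(map$ptr)

#' @rdname map_state
#' @export
map_dim <- function(map) gsom_dim_(map$ptr)

#' @rdname map_state
#' @export
map_positions <- function(map) gsom_positions_(map$ptr)

#' @rdname map_state
#' @export
map_weights <- function(map) gsom_weights_(map$ptr)

#' @rdname map_state
#' @export
map_errors <- function(map) gsom_errors_(map$ptr)

#' @export
print.gsom <- function(x, ...) {
  pos <- map_positions(x)
  cat("Growing self-organizing map:", map_size(x), "nodes, input dim",
      map_dim(x), "; lattice extent [",
      min(pos[, 1]), ",", max(pos[, 1]), "] x [",
      min(pos[, 2]), ",", max(pos[, 2]), "]\n")
  invisible(x)
}

#' Best-matching unit (winner-takes-all search)
#'
#' Returns the node with minimal Euclidean distance to `x`; exact ties are
#' broken toward the lowest node id.
#'
#' @param map a `gsom`.
#' @param x input vector of the map's dimensionality.
#' @return integer node id (1-based).
#' @export
find_bmu <- function(map, x) gsom_bmu_(map$ptr, as.numeric(x))

#' Adapt the map toward one input
#'
#' Moves the winner and its lattice neighbours within `radius` toward `x`
#' by `lr * h(d)` with a Gaussian lattice-distance profile `h`, and adds the
#' winner's Euclidean quantization distance to its accumulated error.
#' Modifies the map in place.
#'
#' @param map a `gsom`.
#' @param x input vector.
#' @param bmu the winner for `x` (see [find_bmu()]).
#' @param step_params list with `lr` and `radius`.
#' @return the map, invisibly.
#' @export
adapt <- function(map, x, bmu, step_params = list(lr = 0.1, radius = 1)) {
  gsom_adapt_(map$ptr, as.numeric(x), as.integer(bmu),
              step_params$lr, step_params$radius)
  invisible(map)
}

#' Error-driven growth with edge-only node insertion
#'
#' Every node whose accumulated error exceeds the threshold either spawns
#' new nodes into its free lattice-neighbour positions (if it lies on the
#' map boundary; weights are linearly extrapolated from the node and its
#' opposite neighbour) and resets its error, or — if interior — pushes half
#' of its error onto its lattice neighbours so that growth pressure
#' migrates to the boundary. Modifies the map in place.
#'
#' @param map a `gsom`.
#' @param growth_threshold accumulated-error threshold.
#' @return list with `map` and `new_nodes` (integer ids, possibly empty).
#' @export
maybe_grow <- function(map, growth_threshold) {
  ids <- gsom_grow_(map$ptr, growth_threshold)
  list(map = map, new_nodes = ids)
}

#' Map every item vector to its best-matching node
#'
#' @param map a `gsom`.
#' @param vectors items x dim matrix.
#' @return an `item_assignment`: list with `item_node` (per-item node id)
#'   and `node_items` (per-node list of item indices).
#' @export
assign_items <- function(map, vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) == 0) stop("vectors must be nonempty")
  ids <- gsom_bmu_batch_(map$ptr, vectors)
  node_items <- split(seq_len(nrow(vectors)), ids)
  structure(list(item_node = ids, node_items = node_items,
                 n_nodes = map_size(map)),
            class = "item_assignment")
}

#' Export a map as a TSV table
#'
#' One row per node: id, lattice coordinates, accumulated error, assigned
#' items and (optionally) a label.
#'
#' @param map a `gsom`.
#' @param path output path.
#' @param assignment optional [assign_items()] result.
#' @param labels optional per-node label vector.
#' @return the path, invisibly.
#' @export
export_map <- function(map, path, assignment = NULL, labels = NULL) {
  pos <- map_positions(map)
  df <- data.frame(node_id = seq_len(map_size(map)),
                   x = pos[, 1], y = pos[, 2],
                   error = map_errors(map))
  if (!is.null(assignment))
    df$items <- vapply(as.character(df$node_id), function(k)
      paste(assignment$node_items[[k]], collapse = ";"), "",
      USE.NAMES = FALSE)
  if (!is.null(labels)) df$label <- labels
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
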