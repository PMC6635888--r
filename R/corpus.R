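norm_mode <- function(mode) {
  m <- c(a = "a", auditory = "a", s = "s", somatosensory = "s",
         `a+s` = "a+s", combined = "a+s", `s+a` = "a+s")[[tolower(mode)]]
  if (is.null(m)) stop("mode must be one of auditory (a), somatosensory (s), ",
                       "auditory+somatosensory (a+s)")
  m
}

mode_blocks <- function(mode) switch(norm_mode(mode),
                                     "a" = "a", "s" = "s", "a+s" = c("a", "s"))

#' Build the synthetic stimulus corpus
#'
#' Generates the full stimulus set of the model language: for every word of
#' the lexicon, `realizations_per_word` jittered realizations, each carrying
#' a motor plan, articulator trajectories, a 24-band auditory representation
#' and a 4-tier somatosensory representation (default 70 x 3 = 210 items).
#' Per-modality vectorization scalings are computed over the corpus so that
#' auditory and somatosensory blocks contribute equal expected squared norm
#' in combined mode. Deterministic under the config seed.
#'
#' @param config a [corpus_config()].
#' @return a `speech_corpus`: list with `lexicon`, `items` (list of
#'   `stimulus_item`), `config`, and vectorization metadata.
#' @export
build_corpus <- function(config = corpus_config()) {
  lex <- build_lexicon(config)
  items <- list()
  for (i in seq_len(nrow(lex$words))) {
    wid <- lex$words$word_id[i]
    word <- get_word(lex, wid)
    for (r in seq_len(config$realizations_per_word) - 1L) {
      seed_item <- (config$seed * 7919L + wid * 31L + r * 7L) %%
        .Machine$integer.max
      item <- withr_seed(seed_item, {
        plan <- synthesize_motor_plan(word, config)
        traj <- render_trajectories(plan, config$frame_hop_ms)
        structure(list(word_id = wid, realization = r, plan = plan,
                       trajectories = traj,
                       somato = somatosensory_rep(traj),
                       auditory = synthesize_auditory(word, plan, config)),
                  class = "stimulus_item")
      })
      items[[length(items) + 1]] <- item
    }
  }
  corpus <- list(lexicon = lex, items = items, config = config)
  class(corpus) <- "speech_corpus"
  corpus$scaling <- corpus_block_scaling(corpus)
  corpus
}

# raw (unscaled) time-normalized block for one modality of one item
item_block <- function(item, block, norm_frames) {
  rep <- if (block == "a") item$auditory else item$somato
  t_old <- seq(0, 1, length.out = ncol(rep))
  t_new <- seq(0, 1, length.out = norm_frames)
  as.vector(apply(unclass(rep), 1, function(row)
    approx(t_old, row, t_new)$y))
}

# per-modality scale factors giving unit expected squared norm over the corpus
corpus_block_scaling <- function(corpus) {
  nf <- corpus$config$norm_frames
  vapply(c(a = "a", s = "s"), function(b) {
    msq <- mean(vapply(corpus$items,
                       function(it) sum(item_block(it, b, nf)^2), 0))
    if (msq == 0) 1 else 1 / sqrt(msq)
  }, 0)
}

#' Fixed-length training vector of a stimulus item
#'
#' Each included modality is time-normalized to `norm_frames` frames by
#' linear interpolation along the time axis, flattened, scaled by the
#' corpus-level per-modality factor (so both modalities contribute equal
#' expected squared norm when combined) and concatenated. The
#' `modality_mask` attribute marks which entries stem from which block.
#'
#' @param item a `stimulus_item`.
#' @param mode `"a"`, `"s"` or `"a+s"` (aliases `auditory`,
#'   `somatosensory`, `combined`).
#' @param norm_frames frames after time normalization.
#' @param scaling named scale factors `c(a =, s =)`; defaults to no scaling.
#' @return numeric vector (24 x frames, 4 x frames, or their concatenation)
#'   with a `modality_mask` attribute.
#' @export
vectorize <- function(item, mode, norm_frames = 30, scaling = c(a = 1, s = 1)) {
  blocks <- mode_blocks(mode)
  parts <- lapply(blocks, function(b) {
    rep <- if (b == "a") item$auditory else item$somato
    if (is.null(rep) || ncol(rep) == 0) stop("item with empty representation")
    item_block(item, b, norm_frames) * scaling[[b]]
  })
  v <- unlist(parts, use.names = FALSE)
  attr(v, "modality_mask") <- rep(blocks, vapply(parts, length, 0L))
  v
}

#' Training-vector matrix of a corpus
#'
#' @param corpus a [build_corpus()] result.
#' @param mode training modality (see [vectorize()]).
#' @return items x D matrix with attributes `modality_mask`, `scaling` and
#'   `word_id` (per row).
#' @export
corpus_vectors <- function(corpus, mode) {
  nf <- corpus$config$norm_frames
  vs <- lapply(corpus$items, vectorize, mode = mode, norm_frames = nf,
               scaling = corpus$scaling)
  X <- do.call(rbind, vs)
  attr(X, "modality_mask") <- attr(vs[[1]], "modality_mask")
  attr(X, "scaling") <- corpus$scaling
  attr(X, "word_id") <- vapply(corpus$items, `[[`, 0L, "word_id")
  X
}

#' @export
print.speech_corpus <- function(x, ...) {
  cat("Speech corpus:", length(x$items), "items =", nrow(x$lexicon$words),
      "words x", x$config$realizations_per_word, "realizations\n")
  invisible(x)
}

#' Export a corpus as plain-text tables
#'
#' Writes `lexicon.tsv` (via [export_lexicon()]), `items.tsv` (item
#' metadata) and `arrays.tsv` — a long table (`item`, `kind`, `row`,
#' `frame`, `value`) holding every auditory, somatosensory and trajectory
#' sample.
#'
#' @param corpus a [build_corpus()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  export_lexicon(corpus$lexicon, file.path(dir, "lexicon.tsv"))
  meta <- data.frame(
    item = seq_along(corpus$items) - 1L,
    word_id = vapply(corpus$items, `[[`, 0L, "word_id"),
    realization = vapply(corpus$items, `[[`, 0L, "realization"),
    frames = vapply(corpus$items, function(it) ncol(it$auditory), 0L))
  write.table(meta, file.path(dir, "items.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rows <- lapply(seq_along(corpus$items), function(i) {
    it <- corpus$items[[i]]
    long <- function(m, kind) data.frame(
      item = i - 1L, kind = kind,
      row = rep(seq_len(nrow(m)), ncol(m)),
      frame = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.vector(unclass(m)))
    rbind(long(it$auditory, "auditory"), long(it$somato, "somato"),
          long(it$trajectories, "trajectory"))
  })
  write.table(do.call(rbind, rows), file.path(dir, "arrays.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
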