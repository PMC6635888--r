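#' Segment inventory of the model language
#'
#' The model language is built from five vowels (/i e a o u/) and nine
#' consonants (/b d g p t k m n l/). Consonants carry place (labial,
#' alveolar, velar), manner (plosive, nasal, lateral) and voicing; vowels
#' carry height and backness. CCV onsets are restricted to the clusters
#' /bl gl pl kl/.
#'
#' @param symbols character vector of phone labels to look up (default: the
#'   full inventory).
#' @return a data.frame with one row per segment and columns `symbol`,
#'   `kind`, `place`, `manner`, `voiced`, `vowel_height`, `vowel_backness`.
#' @export
segment_inventory <- function(symbols = NULL) {
  inv <- data.frame(
    symbol = c("i", "e", "a", "o", "u",
               "b", "d", "g", "p", "t", "k", "m", "n", "l"),
    kind = c(rep("vowel", 5), rep("consonant", 9)),
    place = c(rep("none", 5),
              "labial", "alveolar", "velar",
              "labial", "alveolar", "velar",
              "labial", "alveolar", "alveolar"),
    manner = c(rep("none", 5),
               rep("plosive", 6), "nasal", "nasal", "lateral"),
    voiced = c(rep(TRUE, 5),
               TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    vowel_height = c("high", "mid", "low", "mid", "high", rep("none", 9)),
    vowel_backness = c("front", "front", "central", "back", "back",
                       rep("none", 9)),
    stringsAsFactors = FALSE
  )
  if (is.null(symbols)) return(inv)
  miss <- setdiff(symbols, inv$symbol)
  if (length(miss) > 0)
    stop("unknown segment symbol(s): ", paste(miss, collapse = ", "))
  inv[match(symbols, inv$symbol), , drop = FALSE]
}

#' Default corpus configuration
#'
#' Collects every knob of the synthetic model-language generator. The
#' defaults reproduce the study conditions: 70 monosyllabic words (5 V,
#' 45 CV, 20 CCV), three jittered realizations each (210 items), a global
#' inventory of 361 semantic features, 10 ms frame hop, 30-frame time
#' normalization, timing jitter of +/-10 % and articulatory target jitter of
#' +/-0.05.
#'
#' @param vowels,consonants,clusters segment inventory; clusters are
#'   two-phone onset strings.
#' @param semantic_features total number of distinct semantic features across
#'   the lexicon.
#' @param category_size target number of words per semantic category.
#' @param features_per_category shared features per semantic category.
#' @param realizations_per_word realizations generated per word.
#' @param frame_hop_ms sampling hop of all representations, in ms.
#' @param norm_frames fixed frame count after time normalization.
#' @param timing_jitter relative jitter applied to action on/offsets.
#' @param target_jitter absolute jitter applied to articulatory targets.
#' @param amp_jitter log-sd of multiplicative auditory band-amplitude jitter.
#' @param aud_gain global gain of the auditory synthesizer (0 silences it).
#' @param seed master seed for lexicon and corpus generation.
#' @return a list of class `corpus_config`.
#' @export
corpus_config <- function(vowels = c("i", "e", "a", "o", "u"),
                          consonants = c("b", "d", "g", "p", "t", "k",
                                         "m", "n", "l"),
                          clusters = c("bl", "gl", "pl", "kl"),
                          semantic_features = 361,
                          category_size = 5,
                          features_per_category = 2,
                          realizations_per_word = 3,
                          frame_hop_ms = 10,
                          norm_frames = 30,
                          timing_jitter = 0.10,
                          target_jitter = 0.05,
                          amp_jitter = 0.10,
                          aud_gain = 1,
                          seed = 1L) {
  cfg <- list(vowels = vowels, consonants = consonants, clusters = clusters,
              semantic_features = semantic_features,
              category_size = category_size,
              features_per_category = features_per_category,
              realizations_per_word = realizations_per_word,
              frame_hop_ms = frame_hop_ms, norm_frames = norm_frames,
              timing_jitter = timing_jitter, target_jitter = target_jitter,
              amp_jitter = amp_jitter, aud_gain = aud_gain,
              seed = as.integer(seed))
  class(cfg) <- "corpus_config"
  validate_corpus_config(cfg)
  cfg
}

validate_corpus_config <- function(cfg) {
  inv <- segment_inventory()
  bad <- setdiff(c(cfg$vowels, cfg$consonants), inv$symbol)
  if (length(bad) > 0)
    stop("configuration error: unknown segments ", paste(bad, collapse = ", "))
  if (any(inv$kind[match(cfg$vowels, inv$symbol)] != "vowel"))
    stop("configuration error: non-vowel in vowel inventory")
  if (any(inv$kind[match(cfg$consonants, inv$symbol)] != "consonant"))
    stop("configuration error: non-consonant in consonant inventory")
  for (cl in cfg$clusters) {
    ph <- strsplit(cl, "")[[1]]
    if (length(ph) != 2)
      stop("configuration error: cluster '", cl, "' is not two phones")
    if (!all(ph %in% cfg$consonants))
      stop("configuration error: cluster '", cl,
           "' uses consonants outside the inventory")
  }
  if (cfg$realizations_per_word < 1) stop("realizations_per_word must be >= 1")
  invisible(cfg)
}

#' Build the model-language lexicon
#'
#' Forms one word per syllable of the cross-product: every vowel as a V word,
#' every consonant x vowel as a CV word, and every onset cluster x vowel as a
#' CCV word (default 5 + 45 + 20 = 70 words). Each word receives a sparse
#' binary semantic vector from a seeded hierarchical category scheme: words
#' are grouped into semantic categories that share category features, and
#' every word adds idiosyncratic features of its own, so vectors are unique,
#' have at least three active features, and the global feature inventory has
#' exactly `semantic_features` members. The assignment of meanings
#' (categories) to phonetic forms is a seeded random bijection, so meaning is
#' arbitrary with respect to form.
#'
#' @param config a [corpus_config()].
#' @return a list of class `lexicon` with elements `words` (data.frame:
#'   `word_id`, `structure`, `phones`), `segments` (list of per-word segment
#'   data.frames), `semantic` (binary words x features matrix) and
#'   `feature_names`.
#' @export
build_lexicon <- function(config = corpus_config()) {
  validate_corpus_config(config)
  forms <- c(config$vowels,
             as.vector(t(outer(config$consonants, config$vowels, paste0))),
             if (length(config$clusters) > 0)
               as.vector(t(outer(config$clusters, config$vowels, paste0))))
  structure_of <- function(f) {
    n <- nchar(f)
    c("V", "CV", "CCV")[n]
  }
  words <- data.frame(word_id = seq_along(forms) - 1L,
                      structure = vapply(forms, structure_of, ""),
                      phones = forms, stringsAsFactors = FALSE,
                      row.names = NULL)
  segments <- lapply(forms, function(f)
    segment_inventory(strsplit(f, "")[[1]]))
  sem <- generate_semantics(length(forms), config)
  lex <- list(words = words, segments = segments,
              semantic = sem$matrix, feature_names = sem$feature_names,
              config = config)
  class(lex) <- "lexicon"
  lex
}

# Hierarchical semantic feature generator. Categories share
# `features_per_category` features; the remaining inventory is distributed
# round-robin as idiosyncratic features, guaranteeing uniqueness and >= 3
# active features per word. Category-to-form pairing is a seeded bijection.
generate_semantics <- function(n_words, config) {
  total <- config$semantic_features
  n_cat <- max(1L, round(n_words / config$category_size))
  fpc <- config$features_per_category
  n_cat_feats <- n_cat * fpc
  n_idio <- total - n_cat_feats
  if (n_idio < n_words)
    stop("configuration error: semantic_features too small for ", n_words,
         " unique words (need >= ", n_cat_feats + n_words, ")")
  base <- n_idio %/% n_words
  extra <- n_idio %% n_words
  if (base + fpc < 3)
    stop("configuration error: cannot give every word >= 3 active features")
  withr_seed(config$seed + 101L, {
    category <- sample(rep_len(seq_len(n_cat), n_words))  # random bijection
    idio_counts <- base + (seq_len(n_words) %in% sample(n_words, extra))
  })
  feature_names <- c(
    paste0("cat", rep(seq_len(n_cat), each = fpc), "_f", seq_len(fpc)),
    paste0("idio", seq_len(n_idio)))
  m <- matrix(0L, n_words, total, dimnames = list(NULL, feature_names))
  idio_next <- n_cat_feats + 1L
  for (w in seq_len(n_words)) {
    cf <- (category[w] - 1L) * fpc + seq_len(fpc)
    m[w, cf] <- 1L
    if (idio_counts[w] > 0) {
      idx <- idio_next + seq_len(idio_counts[w]) - 1L
      m[w, idx] <- 1L
      idio_next <- idio_next + idio_counts[w]
    }
  }
  list(matrix = m, feature_names = feature_names, category = category)
}

# run expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' @export
print.lexicon <- function(x, ...) {
  tab <- table(x$words$structure)
  cat("Model-language lexicon: ", nrow(x$words), " words (",
      paste(sprintf("%s %s", tab, names(tab)), collapse = ", "), "); ",
      ncol(x$semantic), " semantic features\n", sep = "")
  invisible(x)
}

#' Export a lexicon as a TSV table
#'
#' One row per word: `word_id`, `structure`, `phones`, and the active
#' semantic features joined by semicolons.
#'
#' @param lexicon a [build_lexicon()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_lexicon <- function(lexicon, path) {
  feats <- apply(lexicon$semantic, 1, function(r)
    paste(lexicon$feature_names[r > 0], collapse = ";"))
  df <- cbind(lexicon$words, semantic_features = feats)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
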