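#' @rdname render_trajectories
#' @format NULL
#' @export
articulator_tiers <- c("lip", "tip", "dorsum", "jaw")

# neutral normalized distances (0 = contact/high, 1 = far/low/open)
tier_neutral <- c(lip = 0.60, tip = 0.70, dorsum = 0.70, jaw = 0.50)

# vowel articulatory targets per tier
vowel_targets <- rbind(
  i = c(lip = 0.55, tip = 0.45, dorsum = 0.15, jaw = 0.25),
  e = c(lip = 0.60, tip = 0.55, dorsum = 0.30, jaw = 0.35),
  a = c(lip = 0.85, tip = 0.75, dorsum = 0.90, jaw = 0.80),
  o = c(lip = 0.25, tip = 0.80, dorsum = 0.40, jaw = 0.45),
  u = c(lip = 0.20, tip = 0.85, dorsum = 0.30, jaw = 0.35))

place_tier <- c(labial = "lip", alveolar = "tip", velar = "dorsum")

# segment durations in ms
seg_dur <- list(closure_voiced = 70, closure_voiceless = 90,
                burst = 20, aspiration = 20, voiced_vot = 15,
                nasal = 80, lateral = 70, vowel = 200,
                lead = 40, tail = 40, transition = 40)

get_word <- function(lexicon, word_id) {
  i <- match(word_id, lexicon$words$word_id)
  if (is.na(i)) stop("unknown word_id: ", word_id)
  list(word_id = word_id,
       structure = lexicon$words$structure[i],
       phones = lexicon$words$phones[i],
       segments = lexicon$segments[[i]],
       semantic = lexicon$semantic[i, ])
}

#' Synthesize a motor plan for a word
#'
#' Emits per-tier articulatory actions: consonant closures land as contact
#' actions (target 0) on the tier matched to their place of articulation
#' (lips for labial, tongue tip for alveolar, tongue dorsum for velar, with
#' a supporting jaw action), and the vowel sets targets on all four tiers.
#' Voiceless plosives get longer closures and a longer voice-onset interval
#' than voiced ones. Per-realization jitter perturbs action timing
#' (relative) and targets (absolute); with `jitter = FALSE` the canonical
#' plan is returned.
#'
#' @param word a word as returned by `get_word()` (internally) or an element
#'   context of a [build_lexicon()]; may also be given as
#'   `synthesize_motor_plan(lexicon, word_id = )`.
#' @param config a [corpus_config()] supplying jitter magnitudes.
#' @param seed integer seed making the realization deterministic.
#' @param jitter apply realization jitter?
#' @param word_id used when `word` is a lexicon.
#' @return an object of class `motor_plan`: list with `actions` (data.frame
#'   `tier`, `target`, `on`, `off` in ms), `total_duration`, and a phonetic
#'   `score` of acoustic events consumed by [synthesize_auditory()].
#' @export
synthesize_motor_plan <- function(word, config = corpus_config(),
                                  seed = NULL, jitter = TRUE,
                                  word_id = NULL) {
  if (inherits(word, "lexicon")) word <- get_word(word, word_id)
  segs <- word$segments
  if (!is.null(seed)) {
    return(withr_seed(seed,
      synthesize_motor_plan(word, config, seed = NULL, jitter = jitter)))
  }
  jit_t <- function(x) if (jitter) x * (1 + runif(1, -config$timing_jitter,
                                                  config$timing_jitter)) else x
  jit_v <- function(x) {
    if (!jitter) return(x)
    out <- x + runif(length(x), -config$target_jitter, config$target_jitter)
    out[out < 0] <- 0
    out[out > 1] <- 1
    out
  }

  actions <- list()
  score <- list()
  add_action <- function(tier, target, on, off)
    actions[[length(actions) + 1]] <<- data.frame(tier = tier,
                                                  target = target,
                                                  on = on, off = off)
  add_event <- function(phone, role, on, off, place = "none", voiced = TRUE)
    score[[length(score) + 1]] <<- data.frame(phone = phone, role = role,
                                              on = on, off = off,
                                              place = place, voiced = voiced)

  t <- seg_dur$lead
  prev_place <- "none"
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    if (s$kind == "consonant") {
      if (s$manner == "plosive") {
        cl <- jit_t(if (s$voiced) seg_dur$closure_voiced
                    else seg_dur$closure_voiceless)
        vot <- jit_t(if (s$voiced) seg_dur$voiced_vot
                     else seg_dur$burst + seg_dur$aspiration)
        tier <- place_tier[[s$place]]
        add_action(tier, jit_v(0), t, t + cl)
        add_action("jaw", jit_v(0.35), t, t + cl)
        add_event(s$symbol, "closure", t, t + cl, s$place, s$voiced)
        add_event(s$symbol, "burst", t + cl,
                  t + cl + min(vot, seg_dur$burst), s$place, s$voiced)
        if (!s$voiced)
          add_event(s$symbol, "aspiration", t + cl + seg_dur$burst,
                    t + cl + vot, s$place, s$voiced)
        t <- t + cl + vot
      } else if (s$manner == "nasal") {
        cl <- jit_t(seg_dur$nasal)
        tier <- place_tier[[s$place]]
        add_action(tier, jit_v(0), t, t + cl)
        add_action("jaw", jit_v(0.35), t, t + cl)
        add_event(s$symbol, "murmur", t, t + cl, s$place, TRUE)
        t <- t + cl
      } else {  # lateral
        cl <- jit_t(seg_dur$lateral)
        add_action("tip", jit_v(0), t, t + cl)
        add_event(s$symbol, "lateral", t, t + cl, s$place, TRUE)
        t <- t + cl
      }
      prev_place <- s$place
    } else {  # vowel
      vd <- jit_t(seg_dur$vowel)
      tg <- jit_v(vowel_targets[s$symbol, ])
      for (tier in articulator_tiers)
        add_action(tier, tg[[tier]], t, t + vd)
      add_event(s$symbol, "vowel", t, t + vd,
                place = prev_place, voiced = TRUE)
      t <- t + vd
    }
  }
  plan <- list(actions = do.call(rbind, actions),
               score = do.call(rbind, score),
               total_duration = t + seg_dur$tail,
               phones = word$phones)
  class(plan) <- "motor_plan"
  plan
}

#' @export
print.motor_plan <- function(x, ...) {
  cat("Motor plan", if (!is.null(x$phones)) paste0("/", x$phones, "/"),
      ":", nrow(x$actions), "actions over",
      round(x$total_duration), "ms\n")
  invisible(x)
}

#' Render articulator trajectories from a motor plan
#'
#' Each tier interpolates between its neutral value and the plan's action
#' targets with smooth cosine ramps, holding targets over their action
#' intervals, sampled every `frame_hop_ms`. Values are clipped to `[0, 1]`.
#' Overlapping actions with contradictory targets on one tier are an error.
#'
#' @param plan a [synthesize_motor_plan()] result.
#' @param frame_hop_ms sample hop in ms.
#' @param ramp_ms duration of the cosine transition into/out of an action.
#' @return a `trajectory_set`: 4 x T matrix of normalized distances with
#'   tier rownames and a `frame_hop_ms` attribute.
#' @export
render_trajectories <- function(plan, frame_hop_ms = 10, ramp_ms = 60) {
  n_frames <- max(1L, floor(plan$total_duration / frame_hop_ms))
  times <- (seq_len(n_frames) - 1) * frame_hop_ms
  out <- matrix(NA_real_, length(articulator_tiers), n_frames,
                dimnames = list(articulator_tiers, NULL))
  for (tier in articulator_tiers) {
    acts <- if (is.null(plan$actions)) NULL else
      plan$actions[plan$actions$tier == tier, , drop = FALSE]
    out[tier, ] <- render_tier(acts, tier_neutral[[tier]], times,
                               plan$total_duration, ramp_ms)
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  structure(out, frame_hop_ms = frame_hop_ms, class = "trajectory_set")
}

# piecewise cosine interpolation through hold intervals
render_tier <- function(acts, neutral, times, total, ramp) {
  if (is.null(acts) || nrow(acts) == 0) return(rep(neutral, length(times)))
  acts <- acts[order(acts$on), , drop = FALSE]
  # merge/validate overlaps
  i <- 1
  while (i < nrow(acts)) {
    if (acts$on[i + 1] < acts$off[i] - 1e-9) {
      if (abs(acts$target[i + 1] - acts$target[i]) > 1e-9)
        stop("overlapping contradictory actions on tier")
      acts$off[i] <- max(acts$off[i], acts$off[i + 1])
      acts <- acts[-(i + 1), , drop = FALSE]
    } else i <- i + 1
  }
  # knot sequence: (time, value) pairs; cosine interpolation between knots
  kt <- c(0, max(0, acts$on[1] - ramp))
  kv <- c(neutral, neutral)
  for (i in seq_len(nrow(acts))) {
    kt <- c(kt, acts$on[i], acts$off[i])
    kv <- c(kv, acts$target[i], acts$target[i])
  }
  kt <- c(kt, min(total, acts$off[nrow(acts)] + ramp), total)
  kv <- c(kv, neutral, neutral)
  keep <- !duplicated(kt)
  kt <- kt[keep]; kv <- kv[keep]
  o <- order(kt); kt <- kt[o]; kv <- kv[o]
  vapply(times, function(t) {
    j <- findInterval(t, kt)
    if (j >= length(kt)) return(kv[length(kv)])
    if (j < 1) return(kv[1])
    t0 <- kt[j]; t1 <- kt[j + 1]
    if (t1 <= t0) return(kv[j + 1])
    frac <- (1 - cos(pi * (t - t0) / (t1 - t0))) / 2
    kv[j] + (kv[j + 1] - kv[j]) * frac
  }, numeric(1))
}

#' Somatosensory neural representation of articulator trajectories
#'
#' Tactile/proprioceptive coding: activation is the complement of the
#' normalized articulator distance, so contact (distance 0) yields maximal
#' activation 1 and a far articulator yields activation 0.
#'
#' @param trajectories a [render_trajectories()] result (values in `[0, 1]`).
#' @return a `somato_rep`: 4 x T activation matrix, same frame hop.
#' @export
somatosensory_rep <- function(trajectories) {
  v <- unclass(trajectories)
  if (any(v < 0 | v > 1)) stop("trajectory distances must lie in [0, 1]")
  structure(1 - v,
            frame_hop_ms = attr(trajectories, "frame_hop_ms") %||% 10,
            class = "somato_rep")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
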