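#' Training configuration
#'
#' The cycle regimen follows the acquisition schedule: an establishing
#' cycle 0, babbling cycles 1..`babbling_cycles` (maps self-organize; only
#' the per-step GSOM check runs), then imitation cycles up to `cycles`
#' during which the end-of-cycle interconnection check verifies every
#' word's produce/perceive round trip and schedules corrective passes.
#' Within each cycle every item is presented `presentations` times (210 x 7
#' = 1470 base steps at defaults), each presentation adapting both maps and
#' adjusting the association once.
#'
#' Learning rate and neighbourhood radius decay linearly across cycles;
#' growth thresholds are in accumulated quantization-distance units.
#'
#' @param mode training modality: `"a"`, `"s"` or `"a+s"`.
#' @param cycles number of full training cycles after cycle 0.
#' @param babbling_cycles cycles before the interconnection check engages.
#' @param presentations presentations of each item per cycle.
#' @param runs runs (distinct seeds) per mode in [run_experiment()].
#' @param seed base seed.
#' @param lr_start,lr_end map learning-rate schedule endpoints.
#' @param radius_start,radius_end neighbourhood radius schedule endpoints.
#' @param gt_s,gt_p growth thresholds of the S-MAP and P-MAP.
#' @param assoc_lr,assoc_decay association learning rate and competitive
#'   decay ratio.
#' @param check_reps extra presentations scheduled per GSOM-check firing.
#' @param check_cap_frac cap on corrective steps per cycle, as a fraction
#'   of the base steps.
#' @param ic_lr_boost association learning-rate multiplier during
#'   interconnection corrective passes.
#' @param cycle0_lr,cycle0_radius,cycle0_assoc_lr cycle-0 parameters.
#' @param noise_sd initial map weight noise.
#' @return a list of class `training_config`.
#' @export
training_config <- function(mode = "a+s", cycles = 50L,
                            babbling_cycles = 10L, presentations = 7L,
                            runs = 10L, seed = 1L,
                            lr_start = 0.35, lr_end = 0.05,
                            radius_start = 3, radius_end = 1,
                            gt_s = 45, gt_p = 18,
                            assoc_lr = 0.15, assoc_decay = 0.5,
                            check_reps = 2L, check_cap_frac = 0.2,
                            ic_lr_boost = 3,
                            cycle0_lr = 0.5, cycle0_radius = 2,
                            cycle0_assoc_lr = 0.3, noise_sd = 0.02) {
  cfg <- list(mode = norm_mode(mode), cycles = as.integer(cycles),
              babbling_cycles = as.integer(babbling_cycles),
              presentations = as.integer(presentations),
              runs = as.integer(runs), seed = as.integer(seed),
              lr_start = lr_start, lr_end = lr_end,
              radius_start = radius_start, radius_end = radius_end,
              gt_s = gt_s, gt_p = gt_p,
              assoc_lr = assoc_lr, assoc_decay = assoc_decay,
              check_reps = as.integer(check_reps),
              check_cap_frac = check_cap_frac,
              ic_lr_boost = ic_lr_boost,
              cycle0_lr = cycle0_lr, cycle0_radius = cycle0_radius,
              cycle0_assoc_lr = cycle0_assoc_lr, noise_sd = noise_sd)
  if (cfg$presentations < 1) stop("presentations must be >= 1")
  if (cfg$cycles > 0 && cfg$babbling_cycles >= cfg$cycles)
    stop("babbling_cycles must be smaller than cycles")
  class(cfg) <- "training_config"
  cfg
}

# linear per-cycle schedules
cycle_schedule <- function(config, cycle) {
  frac <- if (config$cycles <= 1) 1 else (cycle - 1) / (config$cycles - 1)
  list(lr = config$lr_start + frac * (config$lr_end - config$lr_start),
       radius = config$radius_start +
         frac * (config$radius_end - config$radius_start))
}

#' Run one training cycle
#'
#' Presents every item `presentations` times in a seeded shuffled order.
#' Each presentation adapts the S-MAP on the word's semantic vector and the
#' P-MAP on the item's training vector, updates the association at the two
#' winners, applies error-driven growth, and runs the per-step GSOM check
#' (colliding items of different words are re-presented, bounded by the
#' per-cycle cap). From the first imitation cycle on, the end-of-cycle
#' interconnection check repairs failing words.
#'
#' @param model a [speech_model()] (modified in place).
#' @param corpus the training corpus.
#' @param cycle_index 1-based cycle number.
#' @param config a [training_config()].
#' @return list log: `base_steps`, `check_events`, `extra_steps`,
#'   `ic_words` (word ids re-trained by the interconnection check).
#' @export
run_cycle <- function(model, corpus, cycle_index, config) {
  n_items <- nrow(model$X)
  sched <- cycle_schedule(config, cycle_index)
  order <- sample(rep(seq_len(n_items), config$presentations))
  sync_assoc(model)
  res <- run_cycle_(model$s_map$ptr, model$p_map$ptr, model$assoc,
                    model$sem, model$X, model$item_word, order,
                    lr_s = sched$lr, lr_p = sched$lr,
                    radius_s = sched$radius, radius_p = sched$radius,
                    gt_s = config$gt_s, gt_p = config$gt_p,
                    assoc_lr = config$assoc_lr,
                    assoc_decay = config$assoc_decay,
                    do_check = TRUE, extra_reps = config$check_reps,
                    max_extra = floor(config$check_cap_frac * length(order)),
                    last_bmu = model$last_bmu)
  model$last_bmu <- res$last_bmu
  ic <- if (cycle_index > config$babbling_cycles)
    interconnection_check(model, corpus, config, sched) else integer(0)
  list(base_steps = res$base_steps, check_events = res$check_events,
       extra_steps = res$extra_steps, ic_words = ic)
}

#' Per-step GSOM check (single-item form)
#'
#' Inspects whether the item's current P-MAP winner also hosts items of a
#' different word (an unclear node) and, if so, returns the corrective
#' presentations that the training step schedules; `NULL` otherwise. The
#' in-cycle check executed by [run_cycle()] applies exactly this rule after
#' every presentation.
#'
#' @param model a [speech_model()].
#' @param item_index item just presented.
#' @param check_reps presentations scheduled per conflicting item.
#' @return `NULL`, or list with `node`, `conflicts` and `presentations`.
#' @export
gsom_check <- function(model, item_index, check_reps = 2L) {
  node <- find_bmu(model$p_map, model$X[item_index, ])
  here <- which(model$last_bmu == node)
  conflicts <- here[model$item_word[here] != model$item_word[item_index]]
  if (length(conflicts) == 0) return(NULL)
  sched <- c(conflicts, item_index)
  list(node = node, conflicts = conflicts,
       presentations = rep(sched, check_reps))
}

#' End-of-cycle interconnection check
#'
#' Verifies the produce -> perceive round trip for every word. Each failing
#' word receives one corrective interconnection pass (its items are
#' re-presented with an elevated association learning rate); if the failure
#' involves an unclear P-MAP node, the conflicting items join the pass so
#' the maps also receive extra adaptation. Total corrective steps are
#' bounded by `check_cap_frac` of the cycle's base steps.
#'
#' @param model a [speech_model()] (modified in place).
#' @param corpus the training corpus.
#' @param config a [training_config()].
#' @param sched current cycle's learning schedule (list `lr`, `radius`).
#' @return integer vector of re-trained word ids (empty if none).
#' @export
interconnection_check <- function(model, corpus, config,
                                  sched = list(lr = config$lr_end,
                                               radius = config$radius_end)) {
  sync_assoc(model)
  st <- model_readout(model)
  words <- model$word_ids
  failing <- integer(0)
  extra_items <- list()
  for (w in seq_along(words)) {
    items_w <- which(model$item_word == w)
    perc_ok <- all(st$ok_item[items_w])
    if (st$ok_word[w] && perc_ok) next
    failing <- c(failing, w)
    conf <- if (st$nz_row[w]) {
      at <- which(st$ids == st$p_pred[w])
      at[model$item_word[at] != w]
    } else integer(0)
    extra_items[[length(extra_items) + 1]] <- c(items_w, conf)
  }
  if (length(failing) == 0) return(integer(0))

  cap <- floor(config$check_cap_frac * nrow(model$X) * config$presentations)
  order <- unlist(extra_items, use.names = FALSE)
  if (length(order) > cap) order <- order[seq_len(cap)]
  if (length(order) > 0) {
    res <- run_cycle_(model$s_map$ptr, model$p_map$ptr, model$assoc,
                      model$sem, model$X, model$item_word,
                      as.integer(order),
                      lr_s = sched$lr, lr_p = sched$lr,
                      radius_s = sched$radius, radius_p = sched$radius,
                      gt_s = config$gt_s, gt_p = config$gt_p,
                      assoc_lr = min(1, config$assoc_lr * config$ic_lr_boost),
                      assoc_decay = config$assoc_decay,
                      do_check = FALSE, extra_reps = 0L, max_extra = 0L,
                      last_bmu = model$last_bmu)
    model$last_bmu <- res$last_bmu
  }
  words[failing]
}

#' Run a full training
#'
#' Cycle 0 establishes the maps (one high-learning-rate presentation pass
#' per item plus initial association adjustment), then `cycles` full cycles
#' run with checks. Metrics are recorded after every cycle, including
#' cycle 0. Deterministic under `(config, corpus config, seed)`.
#'
#' @param config a [training_config()].
#' @param corpus a [build_corpus()] result.
#' @param seed overrides `config$seed` when given.
#' @return a `run_result`: list with `model`, `metrics` (data.frame with
#'   one row per cycle), `log` (per-cycle step/check counts), `seed`,
#'   `mode`.
#' @export
run_training <- function(config, corpus, seed = config$seed) {
  set.seed(seed)
  model <- speech_model(corpus, config$mode, config$noise_sd)
  n_items <- nrow(model$X)
  sync_assoc(model)
  res0 <- run_cycle_(model$s_map$ptr, model$p_map$ptr, model$assoc,
                     model$sem, model$X, model$item_word,
                     sample(n_items),
                     lr_s = config$cycle0_lr, lr_p = config$cycle0_lr,
                     radius_s = config$cycle0_radius,
                     radius_p = config$cycle0_radius,
                     gt_s = config$gt_s, gt_p = config$gt_p,
                     assoc_lr = config$cycle0_assoc_lr,
                     assoc_decay = config$assoc_decay,
                     do_check = FALSE, extra_reps = 0L, max_extra = 0L,
                     last_bmu = model$last_bmu)
  model$last_bmu <- res0$last_bmu
  metrics <- list(cbind(cycle = 0L, evaluate_model(model, corpus)))
  log <- list(data.frame(cycle = 0L, base_steps = res0$base_steps,
                         check_events = 0L, extra_steps = 0L,
                         ic_events = 0L))
  for (cy in seq_len(config$cycles)) {
    cl <- run_cycle(model, corpus, cy, config)
    metrics[[length(metrics) + 1]] <- cbind(cycle = cy,
                                            evaluate_model(model, corpus))
    log[[length(log) + 1]] <- data.frame(cycle = cy,
                                         base_steps = cl$base_steps,
                                         check_events = cl$check_events,
                                         extra_steps = cl$extra_steps,
                                         ic_events = length(cl$ic_words))
  }
  structure(list(model = model, metrics = do.call(rbind, metrics),
                 log = do.call(rbind, log), seed = seed,
                 mode = config$mode),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  cat("Training run (mode ", x$mode, ", seed ", x$seed, "): ",
      nrow(x$metrics) - 1, " cycles; final unclear ", last$n_unclear,
      ", occupied ", last$n_occupied, ", place regions ",
      last$regions_place, "\n", sep = "")
  invisible(x)
}

#' Run the multi-mode, multi-seed experiment
#'
#' Trains `runs` models per mode on the SAME corpus with an identical seed
#' list across modes, so P-MAP differences between modes are attributable
#' to the modality alone.
#'
#' @param config a [training_config()] (its `mode` field is ignored).
#' @param corpus a [build_corpus()] result.
#' @param modes modalities to train.
#' @return an `experiment_result`: named list (per mode) of lists of
#'   `run_result`s.
#' @export
run_experiment <- function(config, corpus, modes = c("a", "s", "a+s")) {
  out <- lapply(modes, function(m) {
    cfg <- config
    cfg$mode <- norm_mode(m)
    lapply(seq_len(config$runs) - 1L,
           function(r) run_training(cfg, corpus, seed = config$seed + r))
  })
  names(out) <- vapply(modes, norm_mode, "")
  class(out) <- "experiment_result"
  out
}

#' Tidy per-cycle metrics of an experiment
#'
#' @param experiment an [run_experiment()] result (or a single
#'   `run_result`).
#' @return long data.frame: `mode`, `run`, `seed`, `cycle`, `metric`,
#'   `value`.
#' @export
tidy_metrics <- function(experiment) {
  runs <- if (inherits(experiment, "run_result")) {
    list(list(experiment))
  } else experiment
  rows <- list()
  for (mode in names(runs) %||% "1") {
    rr <- if (is.list(runs) && !is.null(names(runs))) runs[[mode]]
          else runs[[1]]
    for (r in seq_along(rr)) {
      m <- rr[[r]]$metrics
      long <- data.frame(
        mode = rr[[r]]$mode, run = r - 1L, seed = rr[[r]]$seed,
        cycle = rep(m$cycle, ncol(m) - 1),
        metric = rep(setdiff(names(m), "cycle"), each = nrow(m)),
        value = unlist(m[setdiff(names(m), "cycle")], use.names = FALSE))
      rows[[length(rows) + 1]] <- long
    }
  }
  do.call(rbind, rows)
}
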