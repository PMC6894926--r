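#' Scanning-session design configuration
#'
#' Defaults encode the event-related design the pipeline emulates: 12 runs of
#' 56 experimental trials (28 actions x 2 actor-exemplars per run) plus 18
#' null events and 7 catch trials per run; a trial is a 1 s image followed by
#' 3 s fixation, a null event 4 s of fixation; runs are acquired at TR 2.5 s
#' for 142 volumes with 15 s of fixation at the start and end.
#'
#' @param n_runs number of functional runs
#' @param n_actions number of action conditions
#' @param n_exemplars exemplars per action (2 actors x 2 scenes x 3 views)
#' @param trial_dur_s stimulus duration in seconds
#' @param fix_dur_s post-stimulus fixation in seconds
#' @param null_dur_s null-event duration in seconds
#' @param n_null_per_run null events per run
#' @param n_catch_per_run catch trials per run
#' @param tr_s repetition time in seconds
#' @param volumes_per_run volumes acquired per run
#' @param lead_in_s fixation before the first trial of a run
#' @return a `design_config` list
#' @export
design_config <- function(n_runs = 12, n_actions = 28, n_exemplars = 12,
                          trial_dur_s = 1, fix_dur_s = 3, null_dur_s = 4,
                          n_null_per_run = 18, n_catch_per_run = 7,
                          tr_s = 2.5, volumes_per_run = 142, lead_in_s = 15) {
  cfg <- list(n_runs = n_runs, n_actions = n_actions,
              n_exemplars = n_exemplars, trial_dur_s = trial_dur_s,
              fix_dur_s = fix_dur_s, null_dur_s = null_dur_s,
              n_null_per_run = n_null_per_run,
              n_catch_per_run = n_catch_per_run, tr_s = tr_s,
              volumes_per_run = volumes_per_run, lead_in_s = lead_in_s)
  counts <- cfg[c("n_runs", "n_actions", "n_exemplars", "n_null_per_run",
                  "n_catch_per_run", "volumes_per_run")]
  stop_if(any(unlist(counts) <= 0), "all design counts must be positive")
  stop_if(n_exemplars %% 2 != 0,
          "n_exemplars must be even (two actors per action)")
  structure(cfg, class = "design_config")
}

# Exemplar bookkeeping: exemplar ids 1..n split into two actor halves; within
# an actor, scenes alternate A/B. The quasi-balance constraint is that the
# two exemplars of an action shown in one run use different actors AND
# different scenes.
exemplar_actor <- function(ex, n_exemplars) ifelse(ex <= n_exemplars / 2, 1L, 2L)
exemplar_scene <- function(ex, n_exemplars) {
  within <- ((ex - 1) %% (n_exemplars / 2))
  ifelse(within %% 2 == 0, "A", "B")
}

#' Generate a pseudorandomized trial sequence
#'
#' Builds the full session as a tibble of runs. Per run: `n_actions * 2`
#' experimental trials (each action once per actor, with complementary
#' scenes), `n_null_per_run` null events interleaved at random, and
#' `n_catch_per_run` catch trials, each an immediate repetition of the
#' previous trial's action with a different exemplar. Constraints enforced:
#'
#' * no two consecutive experimental trials share an action (catch trials
#'   are the sanctioned exception);
#' * over each half of the session (runs 1..R/2 and R/2+1..R) every
#'   action x exemplar combination appears exactly once;
#' * catch-trial actions are sampled without replacement within each 4-run
#'   block, so all actions serve as a catch once per block and never twice
#'   within a run.
#'
#' Onsets are in seconds from run start, after `lead_in_s` of fixation.
#'
#' @param config a [design_config()]
#' @param seed RNG seed
#' @param max_tries retries for the no-repeat shuffle before giving up
#' @return tibble with columns `run`, `trial`, `onset`, `duration`,
#'   `trial_type` (`exp`/`null`/`catch`), `action`, `exemplar`, `actor`,
#'   `scene`
#' @export
generate_trial_sequence <- function(config = design_config(), seed = 1,
                                    max_tries = 200) {
  cfg <- config
  nA <- cfg$n_actions; nE <- cfg$n_exemplars
  stop_if(cfg$n_runs %% 2 != 0, "n_runs must be even (two session halves)")
  stop_if(nE != cfg$n_runs,
          "n_exemplars must equal n_runs (each half shows each action %s",
          "n_runs/2 times with two exemplars per run)")
  with_seed(seed, {
    run_plan <- plan_exemplars(nA, nE, cfg$n_runs)
    catch_plan <- plan_catches(nA, cfg$n_runs, cfg$n_catch_per_run)
    runs <- lapply(seq_len(cfg$n_runs), function(r) {
      build_run(r, run_plan[[r]], catch_plan[[r]], cfg, max_tries)
    })
    dplyr::bind_rows(runs)
  })
}

# Assign, per action, its exemplars to runs: each half of the session uses
# each exemplar once; within a run an action's two exemplars come from
# different actors and different scenes.
plan_exemplars <- function(n_actions, n_exemplars, n_runs) {
  half <- n_runs / 2
  per_half <- function() {
    # for one action: pair each actor-1 exemplar with an actor-2 exemplar of
    # the opposite scene, one pair per run of the half; a random bijection
    # per scene group guarantees each actor-2 exemplar is used exactly once
    a2 <- (n_exemplars / 2 + 1):n_exemplars
    lapply(seq_len(n_actions), function(a) {
      a1 <- sample(seq_len(n_exemplars / 2))                 # actor 1 ids
      s1 <- exemplar_scene(a1, n_exemplars)
      mates <- integer(length(a1))
      for (sc in c("A", "B")) {
        need <- which(s1 == sc)
        pool <- a2[exemplar_scene(a2, n_exemplars) != sc]
        stop_if(length(pool) < length(need),
                "cannot scene-balance %d exemplars", n_exemplars)
        mates[need] <- sample(pool)[seq_along(need)]
      }
      lapply(seq_along(a1), function(i) c(a1[i], mates[i]))
    })
  }
  halves <- list(per_half(), per_half())
  lapply(seq_len(n_runs), function(r) {
    h <- if (r <= half) 1 else 2
    rh <- if (r <= half) r else r - half
    # run r: for each action the rh-th exemplar pair of its half
    do.call(rbind, lapply(seq_len(n_actions), function(a) {
      ex <- halves[[h]][[a]][[rh]]
      data.frame(action = a, exemplar = ex)
    }))
  })
}

# Catch actions sampled without replacement within each 4-run block.
plan_catches <- function(n_actions, n_runs, n_catch) {
  out <- vector("list", n_runs)
  block_size <- 4
  r <- 1
  while (r <= n_runs) {
    block <- r:min(r + block_size - 1, n_runs)
    pool <- sample(seq_len(n_actions))
    for (b in block) {
      take <- utils::head(pool, n_catch)
      pool <- setdiff(pool, take)
      out[[b]] <- take
    }
    r <- r + block_size
  }
  out
}

# Order one run: shuffle experimental trials under the no-consecutive-action
# constraint, splice in catch trials after their triggers, interleave nulls.
build_run <- function(run, plan, catch_actions, cfg, max_tries) {
  trials <- plan[rep(seq_len(nrow(plan)), 1), ]
  # each action appears twice (two exemplar rows per action in `plan`)
  ok <- FALSE
  for (try in seq_len(max_tries)) {
    ord <- sample(nrow(trials))
    acts <- trials$action[ord]
    if (!any(acts[-1] == acts[-length(acts)])) { ok <- TRUE; break }
  }
  stop_if(!ok, paste0("run %d: could not order %d trials without action ",
                      "repeats after %d tries"), run, nrow(trials), max_tries)
  seq_exp <- trials[ord, ]
  seq_exp$trial_type <- "exp"

  # catch trials: each follows a randomly chosen experimental trial of its
  # action, using a different exemplar
  sample_one <- function(x) x[sample.int(length(x), 1)]
  rows <- split(seq_len(nrow(seq_exp)), seq_exp$action)
  catch_rows <- lapply(catch_actions, function(a) {
    trigger <- sample_one(rows[[as.character(a)]])
    used <- seq_exp$exemplar[seq_exp$action == a]
    avail <- setdiff(seq_len(cfg$n_exemplars), used)
    stop_if(length(avail) == 0,
            "no unused exemplar available for a catch trial of action %d", a)
    data.frame(after = trigger, action = a, exemplar = sample_one(avail))
  })
  catch_rows <- if (length(catch_rows)) do.call(rbind, catch_rows) else
    data.frame(after = integer(), action = integer(), exemplar = integer())
  catch_rows <- catch_rows[order(catch_rows$after), ]

  events <- vector("list", nrow(seq_exp))
  for (i in seq_len(nrow(seq_exp))) {
    events[[i]] <- seq_exp[i, c("action", "exemplar", "trial_type")]
    hit <- catch_rows$after == i
    if (any(hit)) {
      events[[i]] <- rbind(events[[i]], data.frame(
        action = catch_rows$action[hit], exemplar = catch_rows$exemplar[hit],
        trial_type = "catch"))
    }
  }
  ev <- do.call(rbind, events)

  # interleave null events at uniformly random slots (unconstrained spacing)
  n_ev <- nrow(ev)
  null_slots <- sort(sample(n_ev + cfg$n_null_per_run, cfg$n_null_per_run))
  full <- data.frame(action = NA_integer_, exemplar = NA_integer_,
                     trial_type = "null")[rep(1, n_ev + cfg$n_null_per_run), ]
  full[setdiff(seq_len(nrow(full)), null_slots), ] <- ev
  rownames(full) <- NULL

  dur <- ifelse(full$trial_type == "null", cfg$null_dur_s,
                cfg$trial_dur_s + cfg$fix_dur_s)
  onset <- cfg$lead_in_s + cumsum(c(0, utils::head(dur, -1)))
  stim_dur <- ifelse(full$trial_type == "null", cfg$null_dur_s, cfg$trial_dur_s)
  tibble(
    run = run, trial = seq_len(nrow(full)), onset = onset,
    duration = stim_dur, trial_type = full$trial_type,
    action = full$action, exemplar = full$exemplar,
    actor = ifelse(is.na(full$exemplar), NA_integer_,
                   exemplar_actor(full$exemplar, cfg$n_exemplars)),
    scene = ifelse(is.na(full$exemplar), NA_character_,
                   exemplar_scene(full$exemplar, cfg$n_exemplars))
  )
}

#' Write a trial sequence as BIDS-style events TSV (one file per run)
#'
#' @param events tibble from [generate_trial_sequence()]
#' @param dir output directory
#' @return paths of the written files, invisibly
#' @export
write_events_tsv <- function(events, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(split(events, events$run), function(ev) {
    p <- file.path(dir, sprintf("run-%02d_events.tsv", ev$run[1]))
    utils::write.table(
      ev[, c("onset", "duration", "trial_type", "action", "exemplar",
             "actor", "scene")],
      p, sep = "\t", quote = FALSE, row.names = FALSE, na = "n/a")
    p
  }, character(1))
  invisible(unname(paths))
}
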