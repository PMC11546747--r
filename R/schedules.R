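# Operant task structures: progressive-ratio requirement sequences, demand
# price schedules, PR session simulation, and go/no-go trial plans.

.TASK_NAMES <- c("food_FR", "food_PR", "food_demand",
                 "remi_FR", "remi_PR", "remi_demand",
                 "go_nogo_p1", "go_nogo_p2")

#' Progressive-ratio response requirement sequence
#'
#' Response requirements escalate near-logarithmically across PR trials. The
#' first 16 requirements are the task's printed values
#' (1, 2, 4, 6, 9, 12, 15, 20, 25, 32, 40, 50, 62, 77, 95, 118); all entries
#' follow the generating rule `round(5 * exp(0.2 * i)) - 5`, which reproduces
#' the printed list exactly and extends it beyond trial 16.
#'
#' @param n_trials number of requirements to return (>= 1).
#' @return integer vector of length `n_trials`.
#' @examples
#' prRequirementSequence(16)   # ends at 118
#' prRequirementSequence(8)    # ends at 20
#' @export
prRequirementSequence <- function(n_trials) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || is.na(n_trials) ||
      n_trials < 1) {
    stop("'n_trials' must be a single integer >= 1")
  }
  i <- seq_len(as.integer(n_trials))
  # round half away from zero (no half-cases arise for i <= 20, but be exact)
  as.integer(floor(5 * exp(0.2 * i) + 0.5) - 5)
}

#' Demand-task unit price schedule
#'
#' Descending within-session lever-press costs for the food demand task and
#' the (ascending) remifentanil demand price ladder.
#'
#' @param task_name "food_demand" or "remi_demand".
#' @return integer vector of lever presses required per reward.
#' @examples
#' demandPriceSchedule("food_demand")  # 180 90 45 15 5
#' @export
demandPriceSchedule <- function(task_name) {
  if (!is.character(task_name) || length(task_name) != 1L) {
    stop("'task_name' must be a single string")
  }
  switch(task_name,
    food_demand = c(180L, 90L, 45L, 15L, 5L),
    remi_demand = c(6L, 10L, 16L, 25L, 40L, 63L, 100L, 158L),
    stop(sprintf("unknown demand task '%s' (expected food_demand or remi_demand)",
                 task_name))
  )
}

#' Build a schedule specification
#'
#' Bundles the structural parameters of one operant task. Defaults encode the
#' tasks as run: PR sessions end at the first 10-min window without a reward;
#' demand sessions are divided into fixed-price bins (10 min each).
#'
#' @param task_name one of `food_FR`, `food_PR`, `food_demand`, `remi_FR`,
#'   `remi_PR`, `remi_demand`, `go_nogo_p1`, `go_nogo_p2`.
#' @param session_length session cap in seconds.
#' @param ratio_progression response requirement per trial (PR) or per price
#'   bin (demand).
#' @param bin_length demand-task bin length in seconds.
#' @param timeout post-reward timeout in seconds.
#' @param cue_duration cue presentation length in seconds.
#' @return list of class "ScheduleSpec".
#' @export
scheduleSpec <- function(task_name,
                         session_length = NULL,
                         ratio_progression = NULL,
                         bin_length = 600,
                         timeout = 2,
                         cue_duration = 2) {
  task_name <- match.arg(task_name, .TASK_NAMES)
  is_pr <- task_name %in% c("food_PR", "remi_PR")
  is_demand <- task_name %in% c("food_demand", "remi_demand")
  if (is.null(ratio_progression)) {
    ratio_progression <- if (is_pr) prRequirementSequence(40L)
      else if (is_demand) demandPriceSchedule(task_name)
      else if (task_name %in% c("food_FR", "remi_FR")) rep(5L, 1000L)
      else integer()
  }
  if (is.null(session_length)) {
    session_length <- if (is_demand) bin_length * length(ratio_progression)
      else if (is_pr) 7200 else 2700
  }
  if (length(ratio_progression) && any(ratio_progression <= 0)) {
    stop("ratio_progression entries must be strictly positive")
  }
  if (is_pr && is.unsorted(ratio_progression)) {
    stop("PR ratio progression must be non-decreasing")
  }
  if (task_name == "food_demand" && any(diff(ratio_progression) >= 0)) {
    stop("food demand progression must be strictly decreasing")
  }
  if (session_length <= 0) stop("session_length must be positive")
  structure(list(task_name = task_name,
                 session_length = session_length,
                 ratio_progression = as.integer(ratio_progression),
                 bin_length = bin_length,
                 timeout = timeout,
                 cue_duration = cue_duration),
            class = "ScheduleSpec")
}

#' @export
print.ScheduleSpec <- function(x, ...) {
  cat(sprintf("ScheduleSpec <%s>: session %.0f s, %d ratio steps\n",
              x$task_name, x$session_length, length(x$ratio_progression)))
  invisible(x)
}

newTrialEvents <- function(time_s, event, trial_index) {
  o <- order(time_s)
  df <- data.frame(time_s = as.numeric(time_s)[o],
                   event = as.character(event)[o],
                   trial_index = as.integer(trial_index)[o])
  new("TrialEvents", events = df)
}

#' Simulate a progressive-ratio session
#'
#' A simple stochastic agent presses the active lever as a homogeneous
#' Poisson process at `press_rate`; once the current response requirement
#' exceeds `persistence_limit` the agent stops pressing. The session ends at
#' the first 10-minute window (sliding, reset at each reward) in which no
#' reward is obtained, or at the session cap. This agent is simulation
#' scaffolding for exercising the downstream analyses, not a behavioral
#' model.
#'
#' @param agent_params list with `press_rate` (presses/s, >= 0) and
#'   `persistence_limit` (presses-per-reward tolerance; `Inf` never quits).
#' @param schedule a PR \code{\link{scheduleSpec}}.
#' @param seed integer seed; identical (params, seed) replays bit-identically.
#' @param no_reward_timeout window in seconds without reward that terminates
#'   the session (10 minutes).
#' @return a \linkS4class{TrialEvents} object.
#' @examples
#' ev <- simulatePRSession(list(press_rate = 1, persistence_limit = 60),
#'                         scheduleSpec("food_PR"), seed = 1)
#' nTrials(ev)
#' @export
simulatePRSession <- function(agent_params, schedule, seed,
                              no_reward_timeout = 600) {
  if (!inherits(schedule, "ScheduleSpec") ||
      !schedule$task_name %in% c("food_PR", "remi_PR")) {
    stop("'schedule' must be a PR ScheduleSpec")
  }
  press_rate <- agent_params$press_rate
  persistence <- if (is.null(agent_params$persistence_limit)) Inf
                 else agent_params$persistence_limit
  if (is.null(press_rate) || press_rate < 0) {
    stop("press_rate must be non-negative")
  }
  ratios <- schedule$ratio_progression
  reward_code <- if (schedule$task_name == "remi_PR") "infusion" else "reward"

  withSeed(seed, {
    time_s <- numeric(); event <- character(); trial <- integer()
    push <- function(t, e, tr) {
      time_s <<- c(time_s, t); event <<- c(event, e); trial <<- c(trial, tr)
    }
    t <- 0
    last_reward <- 0
    tr <- 0L
    repeat {
      tr <- tr + 1L
      req <- if (tr <= length(ratios)) ratios[tr] else {
        # extend by the generating rule past the stored progression
        as.integer(floor(5 * exp(0.2 * tr) + 0.5) - 5)
      }
      push(t, "trial_start", tr)
      push(t, "cue_on", tr)
      cue_off_t <- t + schedule$cue_duration
      quit_pressing <- press_rate == 0 || req > persistence
      presses <- 0L
      deadline <- last_reward + no_reward_timeout
      done <- FALSE
      while (!done) {
        if (quit_pressing) {
          t <- min(deadline, schedule$session_length)
          break
        }
        gap <- stats::rexp(1L, rate = press_rate)
        if (t + gap >= deadline || t + gap >= schedule$session_length) {
          t <- min(deadline, schedule$session_length)
          break
        }
        t <- t + gap
        presses <- presses + 1L
        push(t, "active_press", tr)
        if (presses >= req) {
          push(t, reward_code, tr)
          last_reward <- t
          done <- TRUE
        }
      }
      if (cue_off_t <= t) push(cue_off_t, "cue_off", tr)
      if (!done) {               # timed out: session over
        push(t, "trial_end", tr)
        break
      }
      t <- t + schedule$timeout  # post-reward timeout before next trial
      push(min(t, schedule$session_length), "trial_end", tr)
      if (t >= schedule$session_length) break
    }
    newTrialEvents(time_s, event, trial)
  })
}

#' Pseudorandomized go/no-go session plan
#'
#' Each session presents 64 trials, 32 go and 32 no-go, ordered
#' pseudorandomly in blocks of 10 to 11 trials with near-balanced
#' within-block class quotas. Go cues last 5 s; no-go cues last 5 s in
#' phase 1 and 10 s in phase 2. Mean intertrial interval is 40 s.
#'
#' @param phase 1 or 2.
#' @param seed integer seed for the block shuffling.
#' @return list of class "GoNogoPlan" with `trial_types` (length 64),
#'   `cue_duration_go`, `cue_duration_nogo`, `mean_iti`, `block_sizes`.
#' @examples
#' plan <- goNogoSessionPlan(phase = 1, seed = 42)
#' table(plan$trial_types)
#' @export
goNogoSessionPlan <- function(phase, seed) {
  if (!phase %in% c(1, 2)) stop("'phase' must be 1 or 2")
  withSeed(seed, {
    # 2 blocks of 10 and 4 blocks of 11 cover the 64 trials
    sizes <- sample(c(10L, 10L, 11L, 11L, 11L, 11L))
    # per-block go quotas: balanced in 10-blocks; 11-blocks alternate 6/5 so
    # totals come to exactly 32 per class
    go_quota <- integer(length(sizes))
    go_quota[sizes == 10L] <- 5L
    elevens <- which(sizes == 11L)
    go_quota[elevens] <- sample(c(6L, 6L, 5L, 5L))
    types <- unlist(lapply(seq_along(sizes), function(b) {
      sample(c(rep("go", go_quota[b]), rep("nogo", sizes[b] - go_quota[b])))
    }))
    structure(list(trial_types = types,
                   cue_duration_go = 5,
                   cue_duration_nogo = if (phase == 1) 5 else 10,
                   mean_iti = 40,
                   block_sizes = sizes,
                   phase = phase),
              class = "GoNogoPlan")
  })
}

#' @export
print.GoNogoPlan <- function(x, ...) {
  cat(sprintf("GoNogoPlan (phase %d): %d trials (%d go / %d nogo), no-go cue %g s\n",
              x$phase, length(x$trial_types), sum(x$trial_types == "go"),
              sum(x$trial_types == "nogo"), x$cue_duration_nogo))
  invisible(x)
}
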