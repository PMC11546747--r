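# Config-driven pipeline runner with provenance manifests. The config is a
# named list (or a JSON file): a master `seed`, an output directory `out`,
# and a `stages` list whose entries select and parameterize the stages.
# Stages run in canonical dependency order:
#   simulate -> photometry -> spikes -> tca -> demand -> bias
# Every run writes a manifest tying outputs to the config hash, per-stage
# seeds and input checksums; identical configs replay stochastic outputs
# bit-identically.

.STAGE_ORDER <- c("simulate", "photometry", "spikes", "tca", "demand", "bias")

#' Run a pipeline configuration
#'
#' @param config named list or path to a JSON config file. Recognized
#'   fields: `seed` (integer, required when any stochastic stage is
#'   enabled), `out` (output directory), `stages` (named list; see below).
#'   Stage parameters: `simulate` (agent `press_rate`, `persistence_limit`,
#'   `task`), `photometry` (generator spec overrides), `spikes` (`n_units`,
#'   `profile_mix`), `tca` (`candidates`, `runs_per_candidate`,
#'   `n_trials`), `demand` (`Q0_true`, `alpha_true`, `k_true`, `k_policy`),
#'   `bias` (uses spike-stage cluster assignments).
#' @return invisibly, the manifest list (also written to
#'   `<out>/manifest.json`).
#' @export
runPipelineConfig <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$stages) || !length(config$stages)) {
    stop("schema violation: field 'stages' is missing or empty")
  }
  unknown <- setdiff(names(config$stages), .STAGE_ORDER)
  if (length(unknown)) {
    stop(sprintf("schema violation: unknown stage name '%s'", unknown[1]))
  }
  if (is.null(config$seed)) {
    stop("schema violation: field 'seed' is required")
  }
  out_dir <- config$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  stages <- intersect(.STAGE_ORDER, names(config$stages))
  written <- character()
  state <- list()
  log <- function(fmt, ...) {
    if (isTRUE(config$verbose)) message(sprintf("[%s] %s",
                                                format(Sys.time(), "%H:%M:%S"),
                                                sprintf(fmt, ...)))
  }

  for (stage in stages) {
    prm <- config$stages[[stage]]
    if (isFALSE(prm)) next
    if (isTRUE(prm) || is.null(prm)) prm <- list()
    s_seed <- childSeed(seed, match(stage, .STAGE_ORDER))
    log("stage %s (seed %d)", stage, s_seed)
    if (stage == "simulate") {
      ev <- simulatePRSession(
        list(press_rate = prm$press_rate %||% 0.8,
             persistence_limit = prm$persistence_limit %||% 120),
        scheduleSpec(prm$task %||% "food_PR"), seed = s_seed)
      state$events <- ev
      f <- file.path(out_dir, "events.csv")
      writeTrialEvents(ev, f); written <- c(written, f)
    } else if (stage == "photometry") {
      if (is.null(state$events)) stop("photometry stage requires simulate")
      spec <- prm
      spec$seed <- s_seed
      spec$duration <- spec$duration %||%
        (max(eventTable(state$events)$time_s) + 10)
      rec <- genPhotometrySession(spec, events = state$events)
      f <- file.path(out_dir, "photometry.csv")
      writePhotometry(rec, f); written <- c(written, f)
      dff <- detrendIsosbestic(rec)
      cues <- eventTimes(state$events, "cue_on")
      ws <- windowSpec()
      cues <- cues[cues + ws$psth_span[1] >= 0 &
                     cues + ws$psth_span[2] <= spec$duration]
      if (length(cues)) {
        ps <- eventPSTH(dff, cues, samplingRate(rec), ws)
        mt <- list(cue = windowMetrics(ps, ws$cue),
                   reward = windowMetrics(ps, ws$reward))
        f <- file.path(out_dir, "photometry_metrics.json")
        jsonlite::write_json(mt, f, auto_unbox = TRUE, digits = NA)
        written <- c(written, f)
      }
    } else if (stage == "spikes") {
      if (is.null(state$events)) stop("spikes stage requires simulate")
      spec <- prm
      spec$seed <- s_seed
      spec$n_units <- spec$n_units %||% 60L
      sess <- genSpikeSession(spec, state$events)
      state$spikes <- sess
      f <- file.path(out_dir, "spikes.csv")
      writeSpikeSession(sess, f); written <- c(written, f)
      psths <- buildUnitPSTHs(sess, state$events)
      state$psths <- psths
      feats <- t(vapply(psths, extractEncodingFeatures, numeric(4)))
      cl <- clusterEncodingPatterns(feats, seed = s_seed)
      state$clusters <- cl
      f <- file.path(out_dir, "cluster_assignments.csv")
      utils::write.csv(data.frame(unit_id = names(psths),
                                  cluster = clusterAssignments(cl)),
                       f, row.names = FALSE, quote = FALSE)
      written <- c(written, f)
    } else if (stage == "tca") {
      if (is.null(state$psths)) stop("tca stage requires spikes")
      n_tr <- prm$n_trials %||% 8L
      tens <- truncateToFirstTrials(state$psths, n = n_tr)
      sel <- selectRank(tens,
                        candidates = prm$candidates %||% 1:6,
                        runs_per_candidate = prm$runs_per_candidate %||% 5L,
                        seed = s_seed)
      model <- cpALS(tens, r = max(sel$selected_r, 1L, na.rm = TRUE),
                     seed = s_seed)
      for (mode in c("W", "B", "A")) {
        f <- file.path(out_dir, sprintf("tca_factor_%s.csv", mode))
        utils::write.csv(as.data.frame(slot(model, mode)), f,
                         row.names = FALSE)
        written <- c(written, f)
      }
      f <- file.path(out_dir, "tca_selection.json")
      jsonlite::write_json(unclass(sel), f, auto_unbox = TRUE, digits = NA)
      written <- c(written, f)
    } else if (stage == "demand") {
      spec <- list(Q0_true = prm$Q0_true %||% 50,
                   alpha_true = prm$alpha_true %||% 0.002,
                   k_true = prm$k_true %||% 2,
                   noise_sd = prm$noise_sd %||% 0.05, seed = s_seed)
      obs <- genDemandObservations(spec)
      fit <- fitDemandCurve(obs, k_policy = prm$k_policy %||% "fixed",
                            k_fixed = prm$k_true %||% 2)
      f <- file.path(out_dir, "demand_fit.json")
      jsonlite::write_json(as.list(demandParameters(fit)), f,
                           auto_unbox = TRUE, digits = NA)
      written <- c(written, f)
    } else if (stage == "bias") {
      if (is.null(state$clusters)) stop("bias stage requires spikes")
      asg <- clusterAssignments(state$clusters)
      y <- as.integer(asg != "nonencoding")
      x <- withSeed(childSeed(s_seed, 99L),
                    stats::rbinom(length(y), 1L, 0.5))
      res <- tryCatch(fitBayesLogistic(y, x),
                      error = function(e) list(error = conditionMessage(e)))
      f <- file.path(out_dir, "bias_test.json")
      jsonlite::write_json(
        if (!is.null(res$error)) res else
          list(beta_mean = res$beta_mean, ci_low = res$beta_ci[1],
               ci_high = res$beta_ci[2], bf10 = res$bf10, bf01 = res$bf01,
               evidence_label = res$evidence_label),
        f, auto_unbox = TRUE, digits = NA)
      written <- c(written, f)
    }
  }

  manifest <- list(
    config_hash = fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE)),
    seed = seed,
    stage_seeds = stats::setNames(
      as.list(vapply(stages, function(s) childSeed(seed, match(s, .STAGE_ORDER)),
                     integer(1))), stages),
    outputs = lapply(written, function(f) {
      list(path = basename(f),
           checksum = fnv1a(readChar(f, file.info(f)$size, useBytes = TRUE)))
    }),
    software = as.character(utils::packageVersion("operantNeuro")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
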