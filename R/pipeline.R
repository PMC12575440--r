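# End-to-end pipeline: write a simulated dataset as delimited text, analyze it
# back into battery/session/week tables, and compare blocks. All file formats
# are plain CSV with unit-bearing column names; a JSON manifest records the
# seed, configuration and ground truth.

#' Run configuration
#'
#' Bundles everything that determines a pipeline run. Serializes round-trip
#' identical via JSON; the hash is embedded in every artifact the run writes
#' so outputs can be traced to their configuration.
#'
#' @param seed Integer master seed.
#' @param n Cohort size.
#' @param zone_basis Zone-scheme basis (see [zone_scheme()]).
#' @param index_reference `"pooled"` (maxima over both blocks and timepoints,
#'   default) or `"per_block"`.
#' @param effects An [effect_config()].
#' @param noise A [measurement_noise()].
#' @return A list of class `run_config` with a `hash` element.
#' @export
run_config <- function(seed = 1, n = 22,
                       zone_basis = "percent_po_40min",
                       index_reference = c("pooled", "per_block"),
                       effects = effect_config(),
                       noise = measurement_noise()) {
  cfg <- list(seed = as.integer(seed), n = as.integer(n),
              zone_basis = zone_basis,
              index_reference = match.arg(index_reference),
              effects = unclass(effects), noise = unclass(noise))
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "run_config")
}

series_to_rows <- function(series, participant_id, session_id) {
  tibble::tibble(
    participant_id = participant_id, session_id = session_id,
    sample_period_s = sample_period(series),
    t_s = series$t_s, segment = series$segment, power_w = series$power_w,
    hr_bpm = series$hr_bpm, vo2_ml_min = series$vo2_ml_min, rer = series$rer
  )
}

rows_to_series <- function(rows) {
  gas_series(t_s = rows$t_s, power_w = rows$power_w,
             vo2_ml_min = rows$vo2_ml_min, rer = rows$rer,
             hr_bpm = rows$hr_bpm, segment = rows$segment,
             sample_period = rows$sample_period_s[1])
}

profile_to_rows <- function(profile, participant_id, block, timepoint, kind) {
  tibble::tibble(
    participant_id = participant_id, block = block, timepoint = timepoint,
    kind = kind, step_index = profile$step_index, power_w = profile$power_w,
    duration_s = 330, lactate_mmol_l = profile$lactate_mmol_l,
    vo2_ml_min = profile$vo2_ml_min, rer = profile$rer,
    hr_bpm = profile$hr_bpm,
    terminated = isTRUE(attr(profile, "terminated"))
  )
}

rows_to_profile <- function(rows) {
  lactate_profile(rows$power_w, rows$lactate_mmol_l, rows$vo2_ml_min,
                  rows$rer, rows$hr_bpm,
                  participant_id = rows$participant_id[1],
                  terminated = isTRUE(rows$terminated[1]))
}

# Simple free-training log generator: weekly low/moderate-intensity volume by
# zone, in minutes, loosely shaped like a cyclist's preparatory period.
simulate_training_log <- function(cohort, seed, weeks = 2) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    withr::with_seed(substream_seed(seed, i, "log"), {
      zone_mean_min <- c(480, 350, 140, 145, 70) / 2 * weeks
      dplyr::bind_rows(lapply(1:5, function(z) {
        tibble::tibble(
          participant_id = cohort$participant_id[i],
          date = sprintf("week%d", seq_len(weeks)),
          activity = "endurance", zone = z, intensity_pct = NA_real_,
          duration_min = pmax(0, stats::rnorm(weeks, zone_mean_min[z] / weeks,
                                              zone_mean_min[z] / (3 * weeks)))
        )
      }), tibble::tibble(
        participant_id = cohort$participant_id[i],
        date = rep(sprintf("week%d", seq_len(weeks)), 2),
        activity = rep(c("strength", "core"), each = weeks),
        zone = NA_real_, intensity_pct = NA_real_,
        duration_min = pmax(0, stats::rnorm(2 * weeks, 25, 12))
      ))
    })
  })
  dplyr::bind_rows(rows)
}

#' Simulate a study and write it as a delimited-text dataset
#'
#' Writes `cohort.csv`, `step_tests.csv`, `repeated_steps.csv`, `trials.csv`
#' (sprint, incremental-test and 15-min-trial series), `sessions.csv`
#' (interval-session series with per-interval RPE in `session_rpe.csv`),
#' `training_log.csv` and `manifest.json` (seed, config hash, ground truth)
#' into `dir`. Deterministic given the config seed.
#'
#' @param dir Output directory; must be empty unless `force = TRUE`.
#' @param config A [run_config()].
#' @param include_sessions Write the (large) interval-session series; switch
#'   off for battery-only datasets.
#' @param sessions_per_block How many of each block's sessions to emit series
#'   for (gas exchange was measured in a subset of sessions; 2 matches that).
#' @return Invisibly, the manifest list.
#' @export
simulate_dataset <- function(dir, config = run_config(),
                             include_sessions = TRUE,
                             sessions_per_block = 2) {
  if (dir.exists(dir) && length(list.files(dir)) > 0) {
    rlang::abort(sprintf("directory '%s' is not empty (use force: delete it yourself)", dir),
                 class = "blocktrain_invalid_argument")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  effects <- effect_config(blocks = config$effects$blocks,
                           washout_mean = config$effects$washout_mean,
                           washout_sd = config$effects$washout_sd)
  noise <- do.call(measurement_noise, config$noise)

  cohort <- generate_cohort(config$n, seed)
  state <- cohort
  steps <- list(); reps <- list(); trials <- list(); sessions <- list()
  rpes <- list(); truth <- list()
  for (b in c("MIT", "HIT")) {
    eff <- apply_block_effects(state, effects, b, seed)
    truth[[b]] <- eff$truth
    for (i in seq_len(config$n)) {
      for (tp in c("pre", "post")) {
        phys <- if (tp == "pre") state[i, ] else eff$cohort[i, ]
        bseed <- substream_seed(seed, i, "session",
                                extra = 13 * match(b, c("MIT", "HIT")) +
                                  match(tp, c("pre", "post")))
        prof <- simulate_step_test(phys, noise = noise,
                                   seed = substream_seed(bseed, 1, "step_test"))
        steps[[length(steps) + 1L]] <-
          profile_to_rows(prof, phys$participant_id, b, tp, "fresh")
        rs <- simulate_repeated_steps(phys, prof, noise,
                                      substream_seed(bseed, 1, "repeated"))
        if (!is.null(rs)) {
          reps[[length(reps) + 1L]] <-
            profile_to_rows(rs, phys$participant_id, b, tp, "semifatigued")
        }
        id <- function(test) sprintf("%s_%s_%s", b, tp, test)
        trials[[length(trials) + 1L]] <- dplyr::bind_rows(
          series_to_rows(simulate_sprint(phys, noise,
                                         substream_seed(bseed, 1, "sprint")),
                         phys$participant_id, id("sprint")),
          series_to_rows(simulate_vo2max_test(phys, noise,
                                              substream_seed(bseed, 1, "vo2max_test")),
                         phys$participant_id, id("vo2max")),
          series_to_rows(simulate_trial_15min(phys, noise,
                                              substream_seed(bseed, 1, "trial")),
                         phys$participant_id, id("trial15"))
        )
      }
      if (include_sessions) {
        shapes <- block_sessions(b)
        for (s in seq_len(min(sessions_per_block, length(shapes)))) {
          sess <- simulate_session(state[i, ], shapes[s], noise,
                                   substream_seed(seed, i, "session",
                                                  extra = 100 + 10 * match(b, c("MIT", "HIT")) + s))
          sid <- sprintf("%s_session%d", b, s)
          sessions[[length(sessions) + 1L]] <-
            series_to_rows(sess$series, state$participant_id[i], sid)
          rpes[[length(rpes) + 1L]] <- tibble::tibble(
            participant_id = state$participant_id[i], session_id = sid,
            block = b, shape = shapes[s],
            interval = seq_along(sess$rpe), rpe = sess$rpe, srpe = sess$srpe
          )
        }
      }
    }
    if (b == "MIT") state <- apply_washout(eff$cohort, effects, seed)
  }

  w <- function(x, f) readr::write_csv(x, file.path(dir, f))
  w(cohort, "cohort.csv")
  w(dplyr::bind_rows(steps), "step_tests.csv")
  w(dplyr::bind_rows(reps), "repeated_steps.csv")
  w(dplyr::bind_rows(trials), "trials.csv")
  if (include_sessions) {
    w(dplyr::bind_rows(sessions), "sessions.csv")
    w(dplyr::bind_rows(rpes), "session_rpe.csv")
  }
  w(simulate_training_log(cohort, seed), "training_log.csv")
  manifest <- list(seed = seed, config_hash = config$hash,
                   n = config$n, config = unclass(config),
                   truth = dplyr::bind_rows(truth))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(manifest)
}

#' Analyze a dataset directory into battery, session and week tables
#'
#' Reads the delimited dataset written by [simulate_dataset()] (or hand-made
#' files in the same schema), runs the measurement chain per participant x
#' block x timepoint, summarizes interval sessions against each participant's
#' pre-block reference maxima, and aggregates the training log. Per-record
#' failures are caught, logged and excluded; the run continues.
#'
#' @param dir Dataset directory.
#' @param out Optional results directory to write `batteries.csv`,
#'   `session_summary.csv`, `week_summary.csv` into.
#' @return A list: `batteries`, `session_summary`, `week_summary`,
#'   `errors` (tibble of excluded records with reasons).
#' @export
analyze_dataset <- function(dir, out = NULL) {
  rd <- function(f, required = TRUE) {
    path <- file.path(dir, f)
    if (!file.exists(path)) {
      if (required) rlang::abort(sprintf("missing dataset file: %s", f),
                                 class = "blocktrain_schema_error")
      return(NULL)
    }
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  cohort <- rd("cohort.csv")
  steps <- rd("step_tests.csv")
  reps <- rd("repeated_steps.csv", required = FALSE)
  trials <- rd("trials.csv")
  need <- c("participant_id", "block", "timepoint", "power_w", "lactate_mmol_l")
  if (!all(need %in% names(steps))) {
    rlang::abort(paste("step_tests.csv lacks columns:",
                       paste(setdiff(need, names(steps)), collapse = ", ")),
                 class = "blocktrain_schema_error")
  }

  errors <- list()
  batteries <- list()
  combos <- unique(steps[c("participant_id", "block", "timepoint")])
  for (r in seq_len(nrow(combos))) {
    key <- combos[r, ]
    res <- tryCatch({
      prof_rows <- dplyr::semi_join(steps, key,
                                    by = c("participant_id", "block", "timepoint"))
      prof <- rows_to_profile(prof_rows[order(prof_rows$step_index), ])
      rep_rows <- if (!is.null(reps)) {
        dplyr::semi_join(reps, key, by = c("participant_id", "block", "timepoint"))
      } else NULL
      rep_prof <- if (!is.null(rep_rows) && nrow(rep_rows) >= 2)
        rows_to_profile(rep_rows) else NULL
      tr <- trials[trials$participant_id == key$participant_id, ]
      pick <- function(test) {
        sid <- sprintf("%s_%s_%s", key$block, key$timepoint, test)
        rows <- tr[tr$session_id == sid, ]
        if (nrow(rows) == 0L) {
          rlang::abort(sprintf("missing trial series %s", sid),
                       class = "blocktrain_schema_error")
        }
        rows_to_series(rows)
      }
      mass <- cohort$body_mass_kg[cohort$participant_id == key$participant_id]
      vtest <- pick("vo2max")
      b <- assemble_battery(prof, pick("sprint"), vtest, rep_prof,
                            pick("trial15"), body_mass = mass,
                            participant_id = key$participant_id,
                            block = key$block, timepoint = key$timepoint)
      b$hr_max_bpm <- max(vtest$hr_bpm, na.rm = TRUE)
      b
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- tibble::tibble(
        participant_id = key$participant_id, block = key$block,
        timepoint = key$timepoint, reason = conditionMessage(res))
    } else {
      batteries[[length(batteries) + 1L]] <- res
    }
  }
  batteries <- dplyr::bind_rows(batteries)

  session_summary <- NULL
  sess <- rd("sessions.csv", required = FALSE)
  if (!is.null(sess)) {
    rpe <- rd("session_rpe.csv", required = FALSE)
    refs <- batteries[batteries$timepoint == "pre", ]
    keys <- unique(sess[c("participant_id", "session_id")])
    rows <- list()
    for (r in seq_len(nrow(keys))) {
      k <- keys[r, ]
      blk <- sub("_session.*$", "", k$session_id)
      ref <- refs[refs$participant_id == k$participant_id & refs$block == blk, ]
      if (nrow(ref) == 0L) next
      srows <- dplyr::semi_join(sess, k, by = c("participant_id", "session_id"))
      rrow <- if (!is.null(rpe)) {
        dplyr::semi_join(rpe, k, by = c("participant_id", "session_id"))
      } else NULL
      s <- summarize_session(
        rows_to_series(srows),
        vo2max = ref$vo2max_ml_min_kg * ref$body_mass_kg,
        hr_max = ref$hr_max_bpm,
        po_vo2max_w = ref$po_vo2max_w_kg * ref$body_mass_kg,
        body_mass = ref$body_mass_kg,
        rpe = if (!is.null(rrow) && nrow(rrow)) rrow$rpe else NA_real_,
        srpe = if (!is.null(rrow) && nrow(rrow)) rrow$srpe[1] else NA_real_)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(participant_id = k$participant_id,
                       session_id = k$session_id, block = blk), s)
    }
    session_summary <- dplyr::bind_rows(rows)
  }

  week_summary <- NULL
  log <- rd("training_log.csv", required = FALSE)
  if (!is.null(log)) {
    week_summary <- dplyr::bind_rows(lapply(
      split(log, log$participant_id),
      function(pl) dplyr::bind_cols(
        tibble::tibble(participant_id = pl$participant_id[1]),
        summarize_week(pl))
    ))
  }

  errors <- if (length(errors)) dplyr::bind_rows(errors) else
    tibble::tibble(participant_id = character(), block = character(),
                   timepoint = character(), reason = character())
  if (nrow(errors) > 0) {
    rlang::warn(sprintf("%d record(s) excluded during analysis", nrow(errors)))
  }
  out_list <- list(batteries = batteries, session_summary = session_summary,
                   week_summary = week_summary, errors = errors)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(batteries, file.path(out, "batteries.csv"))
    if (!is.null(session_summary))
      readr::write_csv(session_summary, file.path(out, "session_summary.csv"))
    if (!is.null(week_summary))
      readr::write_csv(week_summary, file.path(out, "week_summary.csv"))
    readr::write_csv(errors, file.path(out, "errors.csv"))
  }
  out_list
}

#' Compare blocks over a battery table
#'
#' Adds the composite endurance index (normalization basis per the config's
#' reference-set choice), computes per-outcome change scores and the full
#' between-block comparison (within-block paired tests, baseline-adjusted
#' block-by-time contrast, effect sizes with magnitude labels).
#'
#' @param batteries Battery table from [analyze_dataset()] (both timepoints
#'   present for at least two participants).
#' @param index_reference `"pooled"` or `"per_block"` normalization reference.
#' @param outcomes Outcome columns to analyze; defaults to all battery
#'   outcomes plus the endurance index.
#' @return A list: `comparison` (one row per outcome), `changes` (per-rider
#'   change scores), `batteries` (with the index column added).
#' @export
compare_dataset <- function(batteries, index_reference = c("pooled", "per_block"),
                            outcomes = NULL) {
  index_reference <- match.arg(index_reference)
  if (!all(c("pre", "post") %in% batteries$timepoint)) {
    rlang::abort("both timepoints required", class = "blocktrain_invalid_argument")
  }
  if (!"block" %in% names(batteries)) {
    rlang::abort("missing block column", class = "blocktrain_schema_error")
  }
  if (index_reference == "pooled") {
    basis <- index_basis(batteries)
    batteries$endurance_index <- endurance_index(batteries, basis)
  } else {
    batteries <- dplyr::bind_rows(lapply(split(batteries, batteries$block),
      function(bb) {
        bb$endurance_index <- endurance_index(bb, index_basis(bb))
        bb
      }))
  }
  if (is.null(outcomes)) {
    outcomes <- c("po_4mmol_w_kg", "po_vo2max_w_kg", "po_15min_w_kg",
                  "po_10sec_w_kg", "vo2max_ml_min_kg", "frac_util_4mmol_pct",
                  "frac_util_15min_pct", "ge_fresh_3rd_pct", "ge_fresh_2nd_pct",
                  "ge_tired_3rd_pct", "ge_tired_2nd_pct", "endurance_index")
    outcomes <- intersect(outcomes, names(batteries))
  }
  long <- battery_long(batteries, outcomes)
  changes <- change_scores(long[long$timepoint == "pre", ],
                           long[long$timepoint == "post", ])
  comparison <- dplyr::bind_rows(lapply(outcomes, function(oc) {
    tryCatch(compare_blocks(changes, oc), error = function(e) NULL)
  }))
  list(comparison = comparison, changes = changes, batteries = batteries)
}

#' Format a block-comparison table at reporting precision
#'
#' Powers (W·kg^-1) to two decimals, percentages and index values to the
#' precision used in physiological-response tables.
#'
#' @param comparison The `comparison` tibble from [compare_dataset()].
#' @return A character-formatted tibble for printing.
#' @export
format_comparison <- function(comparison) {
  fmt <- function(x, d) {
    mapply(function(xi, di) formatC(xi, format = "f", digits = di), x, d,
           USE.NAMES = FALSE)
  }
  digits <- ifelse(grepl("w_kg$", comparison$outcome), 2,
                   ifelse(comparison$outcome == "endurance_index", 3, 1))
  tibble::tibble(
    outcome = comparison$outcome,
    delta_a = sprintf("%s (%s)", fmt(comparison$mean_delta_a, digits),
                      fmt(comparison$sd_delta_a, digits)),
    delta_b = sprintf("%s (%s)", fmt(comparison$mean_delta_b, digits),
                      fmt(comparison$sd_delta_b, digits)),
    pct_a = sprintf("%s (%s)", fmt(comparison$mean_pct_a, 1),
                    fmt(comparison$sd_pct_a, 1)),
    pct_b = sprintf("%s (%s)", fmt(comparison$mean_pct_b, 1),
                    fmt(comparison$sd_pct_b, 1)),
    p_block_time = fmt(comparison$p_block_time, 2),
    es = sprintf("%s (%s)", fmt(comparison$cohens_d, 2), comparison$es_label)
  )
}
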