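#' Run the full analysis pipeline on a simulated cohort
#'
#' Orchestrates simulate -> summarise -> acquisition -> parse -> terminal
#' rates -> growth deciles -> theory fits as one reproducible run. All
#' randomness flows from the single master seed; re-running with the same
#' configuration reproduces every numeric output byte for byte. Artifacts
#' written to `out_dir`: `acquisition.csv`, `parse.csv`,
#' `terminal_rates.csv`, `deciles.csv`, `growth_models.json`,
#' `scalar_fits.json`, `theory_fit.json` and `manifest.json` (package
#' version, seed, configuration and its checksum).
#'
#' @param config List with any of: `out_dir` (required), `seed` (default
#'   1), `protocols` (default [default_protocols()]), `n_per_group`
#'   (default 12), `n_sessions` (optional override), `behavior` (a
#'   `"behavior_params"`), `parse_c` (default 6), `final_sessions` (5 or
#'   10), `thresholds` (named nats vector for acquisition criteria).
#' @return Invisibly, a list with the in-memory results (`acquisition`,
#'   `parse`, `terminal`, `deciles`, `scalar_fits`, `theory_fit`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  cfg <- list(
    out_dir = config$out_dir,
    seed = config$seed %||% 1L,
    protocols = config$protocols %||% default_protocols(),
    n_per_group = config$n_per_group %||% 12L,
    n_sessions = config$n_sessions,
    behavior = config$behavior %||% behavior_params(),
    parse_c = config$parse_c %||% 6,
    final_sessions = config$final_sessions %||% 5,
    thresholds = config$thresholds %||%
      c(odds4 = odds_to_threshold(4), p05 = odds_to_threshold(19))
  )
  stopifnot(cfg$final_sessions %in% c(5, 10), all(cfg$thresholds > 0))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- generate_cohort(cfg$protocols, cfg$n_per_group, cfg$behavior,
                            seed = cfg$seed, n_sessions = cfg$n_sessions)

  acq <- cohort_acquisition(cohort, thresholds = cfg$thresholds)
  utils::write.csv(acq, file.path(cfg$out_dir, "acquisition.csv"),
                   row.names = FALSE)

  parse_rows <- list()
  for (s in cohort) {
    for (ctx in c("CS", "ITI")) {
      iv <- if (ctx == "CS") build_cs_intervals(s$stream, s$schedule)
            else build_pre_intervals(s$stream, s$trials)
      if (length(iv$intervals) < 2) next
      seg <- parse_intervals(iv, c = cfg$parse_c)$segments
      parse_rows[[length(parse_rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, context = ctx,
        segment_start_trial = iv$trial[seg$start],
        segment_end_trial = iv$trial[seg$end],
        rate_per_s = seg$rate)
    }
  }
  parse_df <- do.call(rbind, parse_rows)
  utils::write.csv(parse_df, file.path(cfg$out_dir, "parse.csv"),
                   row.names = FALSE)

  term <- do.call(rbind, lapply(cohort, function(s) {
    cbind(data.frame(subject_id = s$subject_id, group = s$group),
          terminal_rates(s$trials, s$protocol, cfg$final_sessions))
  }))
  utils::write.csv(term, file.path(cfg$out_dir, "terminal_rates.csv"),
                   row.names = FALSE)

  ok_cs <- is.finite(term$cs_rate) & term$cs_rate > 0
  fits <- list(
    single_free = unclass(fit_scalar_regression(
      log10(c(term$cs_reinf_rate[ok_cs], term$ctx_reinf_rate)),
      log10(c(term$cs_rate[ok_cs], term$iti_rate)), "free")),
    shifted_shared = unclass(fit_shifted_shared(
      log10(term$cs_reinf_rate[ok_cs]), log10(term$cs_rate[ok_cs]),
      log10(term$ctx_reinf_rate), log10(term$iti_rate)))
  )
  jsonlite::write_json(fits, file.path(cfg$out_dir, "scalar_fits.json"),
                       auto_unbox = TRUE, digits = NA)

  dec_rows <- list(); model_rows <- list()
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    rec <- growth_decile_record(s$trials, acq$odds4[i])
    if (is.null(rec)) next
    dec_rows[[length(dec_rows) + 1L]] <- data.frame(
      subject_id = s$subject_id, d = seq(0.1, 0.9, 0.1),
      trial = rec$trials_at_decile)
    gf <- fit_growth_models(rec$trials_at_decile)
    model_rows[[s$subject_id]] <- list(
      best = gf$best,
      bic = lapply(gf$fits, function(f) f$bic))
  }
  dec_df <- do.call(rbind, dec_rows)
  if (!is.null(dec_df)) {
    utils::write.csv(dec_df, file.path(cfg$out_dir, "deciles.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(model_rows, file.path(cfg$out_dir, "growth_models.json"),
                       auto_unbox = TRUE, digits = NA)

  med <- stats::aggregate(reinf_to_acq ~ group + iota, data = acq,
                          FUN = stats::median, na.rm = TRUE)
  med$reinf_to_acq <- pmax(med$reinf_to_acq, 1)
  usable <- med$iota > 1 & is.finite(med$reinf_to_acq)
  theory <- if (sum(usable) >= 3) {
    lr <- fit_learning_rate(med$reinf_to_acq[usable], med$iota[usable])
    list(slope = lr$s, slope_ci = lr$s_ci, x_intercept_iota = lr$x_intercept_iota,
         r_squared = lr$r_squared, group_medians = med)
  } else list(slope = NA, note = "fewer than 3 usable groups")
  jsonlite::write_json(theory, file.path(cfg$out_dir, "theory_fit.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  cfg_plain <- cfg[c("seed", "n_per_group", "parse_c", "final_sessions")]
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE)
  manifest <- list(
    package = "infoacq",
    version = as.character(utils::packageVersion("infoacq")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = cfg_plain,
    config_hash = sum(utf8ToInt(as.character(cfg_json))),
    n_subjects = length(cohort),
    artifacts = c("acquisition.csv", "parse.csv", "terminal_rates.csv",
                  "deciles.csv", "growth_models.json", "scalar_fits.json",
                  "theory_fit.json")
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(acquisition = acq, parse = parse_df, terminal = term,
                 deciles = dec_df, scalar_fits = fits, theory_fit = theory,
                 manifest = manifest))
}
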