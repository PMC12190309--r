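#' Validated run configuration for the end-to-end pipeline
#'
#' Collects every tunable of the pipeline with its default, validates types
#' and rejects unknown keys (top level and within each parameter block), so
#' a typo in a config cannot silently fall back to a default.
#'
#' @param mode `"synthetic"` (simulate a cohort) or `"files"` (read a
#'   manifest of recorded passes).
#' @param seed integer seed driving every random draw of the run.
#' @param out_dir output directory for reports (`NULL` = don't write).
#' @param cohorts for synthetic mode: list of [cohort_spec()]s or paths to
#'   cohort YAML files; `NULL` uses the shipped PD + HOA defaults.
#' @param manifest for files mode: path to a manifest CSV with columns
#'   `participant, group, speed_cond, pass, speed_mps` and either
#'   `angles_csv` (tidy per-pass signals: `time_s, hip_deg, knee_deg,
#'   shank_gyro_z`) or `pelvis_csv, thigh_csv, shank_csv` (raw IMU CSVs).
#' @param filter list: `cutoff_hz` (default 6), `order` (default 4).
#' @param fusion list: `gain` (default 0.02), `calibration_window_s`
#'   (default 0).
#' @param events list: `min_peak_rad_s` (default 0.5), `min_separation_s`
#'   (default 0.3), `convention`, `override` (optional CSV of manually
#'   adjusted IC indices: `participant, speed_cond, pass, ic_index`).
#' @param stats list: `alpha` (default 0.05), `n_perm` (default 1000),
#'   `exclude_metrics` (default MARP + DP).
#' @param emit_raw synthetic mode: emit raw IMU streams and recover angles
#'   through the orientation chain instead of using the generated angles.
#' @return a validated `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "files"), seed = 1,
                       out_dir = NULL, cohorts = NULL, manifest = NULL,
                       filter = list(), fusion = list(), events = list(),
                       stats = list(), emit_raw = FALSE) {
  mode <- match.arg(mode)
  merge_block <- function(user, defaults, block) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0) {
      abort(sprintf("unknown %s config key(s): %s", block,
                    paste(unknown, collapse = ", ")))
    }
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    mode = mode,
    seed = as.integer(seed),
    out_dir = out_dir,
    cohorts = cohorts,
    manifest = manifest,
    filter = merge_block(filter, list(cutoff_hz = 6, order = 4), "filter"),
    fusion = merge_block(fusion, list(gain = 0.02, calibration_window_s = 0),
                         "fusion"),
    events = merge_block(events, list(min_peak_rad_s = 0.5,
                                      min_separation_s = 0.3,
                                      convention = "positive_midswing",
                                      override = NULL), "events"),
    stats = merge_block(stats, list(alpha = 0.05, n_perm = 1000,
                                    exclude_metrics = c("marp_deg", "dp_deg")),
                        "stats"),
    emit_raw = isTRUE(emit_raw)
  )
  if (mode == "files" && is.null(cfg$manifest)) {
    abort("files mode requires a `manifest`")
  }
  if (cfg$filter$cutoff_hz <= 0 || cfg$filter$order < 1) {
    abort("filter cutoff must be positive and order at least 1")
  }
  if (cfg$stats$alpha <= 0 || cfg$stats$alpha >= 1) abort("`alpha` must be in (0,1)")
  structure(cfg, class = "run_config")
}

resolve_cohorts <- function(cohorts) {
  if (is.null(cohorts)) {
    return(list(default_cohort_spec("pd"), default_cohort_spec("hoa")))
  }
  if (inherits(cohorts, "cohort_spec")) return(list(cohorts))
  lapply(cohorts, function(cc) {
    if (inherits(cc, "cohort_spec")) cc else read_cohort_spec(cc)
  })
}

load_manifest_passes <- function(manifest, fusion) {
  man <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  need <- c("participant", "group", "speed_cond", "pass", "speed_mps")
  missing <- setdiff(need, names(man))
  if (length(missing) > 0) {
    abort(sprintf("manifest is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  base <- dirname(manifest)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  sigs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    if ("angles_csv" %in% names(man)) {
      sig <- readr::read_csv(resolve(man$angles_csv[i]), show_col_types = FALSE,
                             progress = FALSE)
      if (!all(c("time_s", "hip_deg", "knee_deg", "shank_gyro_z") %in% names(sig))) {
        abort(sprintf("pass file %s lacks the tidy signal columns", man$angles_csv[i]))
      }
    } else if (all(c("pelvis_csv", "thigh_csv", "shank_csv") %in% names(man))) {
      recs <- list(
        pelvis = read_imu_csv(resolve(man$pelvis_csv[i]), "pelvis"),
        thigh = read_imu_csv(resolve(man$thigh_csv[i]), "thigh_r"),
        shank = read_imu_csv(resolve(man$shank_csv[i]), "shank_r")
      )
      ors <- lapply(recs, complementary_fuse, gain = fusion$gain)
      ang <- compute_joint_angles(ors$pelvis, ors$thigh, ors$shank,
                                  calibration_window_s = fusion$calibration_window_s)
      ang$shank_gyro_z <- recs$shank$gz
      sig <- ang
    } else {
      abort("manifest must provide either `angles_csv` or raw IMU path columns")
    }
    sigs[[i]] <- tibble::as_tibble(sig)
  }
  fs <- vapply(sigs, function(s) check_uniform_time(s$time_s), numeric(1))
  tibble::tibble(
    participant = man$participant, group = man$group,
    speed_cond = man$speed_cond, pass = man$pass, fs = fs,
    signals = sigs, speed_mps = man$speed_mps
  )
}

#' Coordination analysis of a set of walking passes
#'
#' The per-pass chain: zero-phase low-pass filtering, initial-contact
#' detection on the shank angular-velocity channel (or supplied/overridden
#' events), Hilbert-phase CRP over the span between the first and last IC,
#' segmentation into 101-point cycles, and joint-excursion extraction.
#' Cycles are then pooled per participant and speed into CRP ensembles.
#'
#' @param passes tibble with columns `participant`, `group`, `speed_cond`,
#'   `pass`, `fs`, `signals` (list of per-sample tibbles `time_s, hip_deg,
#'   knee_deg, shank_gyro_z`) and optionally `speed_mps`; a
#'   [simulate_cohort()] result may be given directly.
#' @param config a [run_config()] (filter/event settings are honoured).
#' @param speeds optional tibble `participant, speed_cond, speed_mps` used
#'   when `passes` lacks a speed column (e.g. synthetic truth).
#' @param events_truth optional tibble `participant, speed_cond, pass,
#'   ic_index` of known events, bypassing detection.
#' @return a `cohort_analysis` list: `summaries` (one row per participant x
#'   speed: MARP, DP, excursions, walking speed, cycle count), `curves`
#'   (per-participant ensemble mean and SD CRP curves), `pass_log` (per-pass
#'   cycle counts).
#' @export
analyze_cohort <- function(passes, config = run_config(), speeds = NULL,
                           events_truth = NULL) {
  if (inherits(passes, "synthetic_cohort")) {
    speeds <- speeds %||%
      passes$participants[c("participant", "speed_cond", "speed_mps")]
    passes <- passes$passes
  }
  override <- NULL
  if (!is.null(config$events$override)) {
    override <- readr::read_csv(config$events$override, show_col_types = FALSE,
                                progress = FALSE)
  }
  pass_rows <- list()
  crp_store <- list()
  exc_store <- list()
  for (i in seq_len(nrow(passes))) {
    row <- passes[i, ]
    sig <- row$signals[[1]]
    fs <- row$fs
    sig_f <- lowpass_filter(sig, cutoff_hz = config$filter$cutoff_hz,
                            order = config$filter$order, fs = fs)
    key <- sprintf("%s|%s", row$participant, row$speed_cond)
    ic <- NULL
    if (!is.null(events_truth)) {
      ic <- events_truth$ic_index[
        events_truth$participant == row$participant &
          events_truth$speed_cond == row$speed_cond &
          events_truth$pass == row$pass]
    }
    if (!is.null(override)) {
      ic_over <- override$ic_index[
        override$participant == row$participant &
          override$speed_cond == row$speed_cond &
          override$pass == row$pass]
      if (length(ic_over) > 0) ic <- ic_over
    }
    if (is.null(ic) || length(ic) == 0) {
      ev <- detect_initial_contacts(
        sig_f$shank_gyro_z, fs,
        min_peak_rad_s = config$events$min_peak_rad_s,
        min_separation_s = config$events$min_separation_s,
        convention = config$events$convention)
      ic <- ev$ic_index
    }
    n_cycles_pass <- 0L
    if (length(ic) >= 2) {
      crp_cycles <- pass_crp_cycles(sig_f[c("time_s", "hip_deg", "knee_deg")],
                                    ic, fs = fs)
      ang_cycles <- segment_and_normalize(
        sig_f[c("time_s", "hip_deg", "knee_deg")], ic)
      n_cycles_pass <- length(unique(crp_cycles$cycle))
      if (n_cycles_pass > 0) {
        crp_store[[key]] <- c(crp_store[[key]], list(crp_cycle_matrix(crp_cycles)))
        exc_store[[key]] <- c(exc_store[[key]], list(cycle_info(ang_cycles)))
      }
    }
    pass_rows[[i]] <- tibble::tibble(
      participant = row$participant, group = row$group,
      speed_cond = row$speed_cond, pass = row$pass,
      n_ic = length(ic), n_cycles = n_cycles_pass
    )
  }
  pass_log <- dplyr::bind_rows(pass_rows)
  cells <- dplyr::distinct(passes, .data$participant, .data$group, .data$speed_cond)
  summaries <- list()
  curves <- list()
  for (j in seq_len(nrow(cells))) {
    key <- sprintf("%s|%s", cells$participant[j], cells$speed_cond[j])
    mats <- crp_store[[key]]
    if (is.null(mats)) next
    m <- do.call(rbind, mats)
    ens <- crp_ensemble(m, participant = cells$participant[j],
                        speed_cond = cells$speed_cond[j])
    exc <- joint_excursion(dplyr::bind_rows(exc_store[[key]]))
    hip_exc <- exc$mean_excursion_deg[exc$joint == "hip"]
    knee_exc <- exc$mean_excursion_deg[exc$joint == "knee"]
    summaries[[j]] <- dplyr::mutate(glance(ens),
                                    group = cells$group[j],
                                    hip_excursion_deg = hip_exc,
                                    knee_excursion_deg = knee_exc)
    curves[[j]] <- dplyr::mutate(tidy(ens), group = cells$group[j])
  }
  summaries <- dplyr::bind_rows(summaries)
  curves <- dplyr::bind_rows(curves)
  if (!is.null(speeds)) {
    summaries <- dplyr::left_join(summaries, speeds,
                                  by = c("participant", "speed_cond"))
    names(summaries)[names(summaries) == "speed_mps"] <- "walking_speed_mps"
  } else if ("speed_mps" %in% names(passes)) {
    sp <- dplyr::distinct(passes, .data$participant, .data$speed_cond,
                          .data$speed_mps)
    summaries <- dplyr::left_join(summaries, sp,
                                  by = c("participant", "speed_cond"))
    names(summaries)[names(summaries) == "speed_mps"] <- "walking_speed_mps"
  }
  cols <- c("participant", "group", "speed_cond", "marp_deg", "dp_deg",
            "hip_excursion_deg", "knee_excursion_deg", "walking_speed_mps",
            "n_cycles")
  summaries <- summaries[intersect(cols, names(summaries))]
  structure(list(summaries = summaries, curves = curves, pass_log = pass_log),
            class = "cohort_analysis")
}

#' Group-level statistics on a cohort analysis
#'
#' Applies the statistical battery to participant summaries and ensemble
#' curves: Tukey-fence outlier exclusion on the preferred-speed condition,
#' a two-way ANOVA of walking speed on group x condition with Bonferroni
#' post hocs, two-way ANCOVAs (walking-speed covariate) for MARP, DP and the
#' joint excursions, and per-speed permutation SPM comparisons of the
#' participant ensemble mean (coordination) and SD (variability) CRP curves
#' between groups.
#'
#' @param analysis a `cohort_analysis` from [analyze_cohort()].
#' @param alpha significance level.
#' @param n_perm SPM permutation count.
#' @param exclude_metrics metrics screened by [iqr_exclude()].
#' @return a `gait_stats` list: `exclusions`, `speed_anova`, `ancovas`
#'   (named list of `gait_anova`), `spm` (named list of `spm_result` per
#'   speed x curve type), `summaries` (retained participant summaries).
#' @export
gait_group_stats <- function(analysis, alpha = 0.05, n_perm = 1000,
                             exclude_metrics = c("marp_deg", "dp_deg")) {
  summ <- analysis$summaries
  scr <- iqr_exclude(summ, metrics = exclude_metrics)
  kept <- scr$retained
  curves <- dplyr::filter(analysis$curves,
                          !.data$participant %in% scr$excluded$participant)
  speed_anova <- two_way_anova(kept, "walking_speed_mps", alpha = alpha)
  responses <- c(marp = "marp_deg", dp = "dp_deg",
                 hip_excursion = "hip_excursion_deg",
                 knee_excursion = "knee_excursion_deg")
  ancovas <- lapply(responses, function(r) {
    two_way_ancova(kept, r, covariate = "walking_speed_mps", alpha = alpha)
  })
  groups <- sort(unique(kept$group))
  spm <- list()
  if (length(groups) == 2) {
    for (cond in unique(kept$speed_cond)) {
      for (what in c("crp_mean_deg", "crp_sd_deg")) {
        sub <- dplyr::filter(curves, .data$speed_cond == cond)
        mat <- function(g) {
          wide <- tidyr::pivot_wider(
            dplyr::filter(sub, .data$group == g)[c("participant", "pct", what)],
            names_from = "pct", values_from = dplyr::all_of(what))
          as.matrix(wide[-1])
        }
        ya <- mat(groups[1])
        yb <- mat(groups[2])
        if (nrow(ya) >= 2 && nrow(yb) >= 2 && !anyNA(ya) && !anyNA(yb)) {
          spm[[paste(cond, what, sep = ".")]] <-
            spm_ttest2(ya, yb, alpha = alpha, n_perm = n_perm)
        }
      }
    }
  }
  structure(list(exclusions = scr$excluded, speed_anova = speed_anova,
                 ancovas = ancovas, spm = spm, summaries = kept,
                 alpha = alpha),
            class = "gait_stats")
}

#' Run the full pipeline from a configuration
#'
#' Executes the whole chain -- synthetic cohort generation (or manifest
#' loading), filtering, event detection, CRP/MARP/DP, excursions and the
#' statistical battery -- and, when `out_dir` is set, writes the report
#' bundle: `summaries.csv`, `curves.csv`, `spm_traces.csv`,
#' `exclusions.csv`, `stats.json`, figures and `run_log.txt` with per-stage
#' counts. Re-running with the same config and seed reproduces every output
#' byte for byte.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `analysis` (`cohort_analysis`), `stats`
#'   (`gait_stats`) and, for synthetic runs, `cohort` (the ground truth).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  if (config$mode == "synthetic") {
    specs <- resolve_cohorts(config$cohorts)
    cohort <- simulate_cohort(specs, seed = config$seed,
                              emit_raw = config$emit_raw)
    if (config$emit_raw) {
      # recover the angles through the orientation chain instead of truth
      for (i in seq_len(nrow(cohort$passes))) {
        imu <- cohort$passes$imu[[i]]
        ors <- lapply(imu, complementary_fuse, gain = config$fusion$gain)
        ang <- compute_joint_angles(
          ors$pelvis, ors$thigh_r, ors$shank_r,
          calibration_window_s = config$fusion$calibration_window_s)
        ang$shank_gyro_z <- cohort$passes$signals[[i]]$shank_gyro_z
        cohort$passes$signals[[i]] <- ang
      }
    }
    analysis <- analyze_cohort(cohort, config = config)
    truth <- cohort
  } else {
    passes <- load_manifest_passes(config$manifest, config$fusion)
    analysis <- analyze_cohort(passes, config = config)
    truth <- NULL
  }
  stats <- gait_group_stats(analysis, alpha = config$stats$alpha,
                            n_perm = config$stats$n_perm,
                            exclude_metrics = config$stats$exclude_metrics)
  if (!is.null(config$out_dir)) {
    write_report_bundle(analysis, stats, config)
  }
  invisible(list(analysis = analysis, stats = stats, cohort = truth))
}

write_report_bundle <- function(analysis, stats, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  readr::write_csv(analysis$summaries, p("summaries.csv"), progress = FALSE)
  readr::write_csv(analysis$curves, p("curves.csv"), progress = FALSE)
  readr::write_csv(stats$exclusions, p("exclusions.csv"), progress = FALSE)
  traces <- purrr::imap_dfr(stats$spm, function(s, nm) {
    dplyr::mutate(tidy(s), comparison = nm)
  })
  readr::write_csv(traces, p("spm_traces.csv"), progress = FALSE)
  report <- list(
    speed_anova = list(table = stats$speed_anova$table,
                       posthoc = stats$speed_anova$posthoc),
    ancovas = lapply(stats$ancovas, function(a) {
      list(table = a$table, posthoc = a$posthoc)
    }),
    spm = lapply(stats$spm, function(s) as.list(glance(s))),
    excluded_participants = unique(stats$exclusions$participant),
    n_retained = length(unique(stats$summaries$participant))
  )
  jsonlite::write_json(report, p("stats.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  # figures mirroring the ensemble-curve and SPM-trace report layout
  fig1 <- plot_group_curves(analysis$curves)
  ggplot2::ggsave(p("ensemble_curves.pdf"), fig1, width = 9, height = 6)
  if (length(stats$spm) > 0) {
    fig2 <- plot_spm_panels(stats$spm)
    ggplot2::ggsave(p("spm_traces.pdf"), fig2, width = 9, height = 6)
  }
  log_lines <- c(
    sprintf("mode: %s  seed: %d", config$mode, config$seed),
    sprintf("passes analysed: %d", nrow(analysis$pass_log)),
    sprintf("total cycles retained: %d", sum(analysis$pass_log$n_cycles)),
    sprintf("participant x speed cells: %d", nrow(analysis$summaries)),
    sprintf("participants excluded by the 1.5 x IQR rule: %d",
            length(unique(stats$exclusions$participant))),
    "per-pass cycle counts:",
    utils::capture.output(print(as.data.frame(analysis$pass_log), row.names = FALSE))
  )
  writeLines(log_lines, p("run_log.txt"))
  invisible(config$out_dir)
}
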