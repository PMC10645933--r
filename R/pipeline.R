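#' Default end-to-end pipeline configuration
#'
#' Returns the demo configuration of [run_pipeline()]: a three-group cohort
#' (sham / low / high), short simulated trials for the three behavioral
#' paradigms, a small synthetic histology section per mouse, and the study's
#' statistical decision procedure. Every analysis threshold that the source
#' protocol leaves unstated (facing cone, arm-entry depth, segmentation
#' method, annulus bounds) is surfaced here so a run is fully auditable.
#'
#' Per-group parameters may be a single value (shared) or a named vector
#' (one entry per group). By default all groups share identical generator
#' parameters, i.e. a null-effect study.
#'
#' @param seed master seed; per-mouse seeds are derived from it.
#' @param n_per_group named vector of animals per group.
#' @return a nested list, also writable as YAML via [yaml::write_yaml()].
#' @export
default_pipeline_config <- function(seed = 1, n_per_group = c(sham = 4, low = 4, high = 4)) {
  list(
    seed = seed,
    groups = names(n_per_group),
    n_per_group = as.list(n_per_group),
    behavior = list(
      frame_rate_hz = 10,
      facing_max_deg = 45,
      entry_depth_frac = 0.5,
      nort = list(duration_s = 120, novelty_preference = 0.75),
      ymaze = list(duration_s = 120, alternation_bias = 0.7),
      mwm_probe = list(duration_s = 60, goal_bias = 0.6)
    ),
    histology = list(
      enabled = TRUE,
      image_shape = c(320, 320),
      plaque_count = 3,
      border_margin_um = 20,
      enrichment_factor = 1.8,
      noise_sd = 3,
      min_area_um2 = 20,
      threshold_method = "otsu",
      near_um = c(0, 12),
      far_um = c(18, 60)
    ),
    stats = list(alpha = 0.05, gate_alpha = 0.05, n_monte_carlo = 2000)
  )
}

# per-group parameter lookup: scalar = shared, named = per group
param_for <- function(x, group) {
  x <- unlist(x)
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  if (!group %in% names(x)) stopf("no value of a per-group parameter for group '%s'", group)
  unname(x[[group]])
}

#' Run the full simulate-measure-test pipeline
#'
#' Orchestrates one end-to-end blinded run: randomize a synthetic cohort into
#' groups behind a sealed codebook, simulate per-animal trials and sections
#' with the group's generator parameters, extract all behavioral and
#' histological metrics keyed by blinded codes only, and finally unblind and
#' apply the statistical decision procedure. Group identity never appears in
#' any intermediate file; it is joined to the metrics only at the report
#' stage.
#'
#' @param config a configuration list as from [default_pipeline_config()],
#'   or the path of a YAML file holding one.
#' @param out_dir output directory; created if missing. Writes
#'   `codebook/` (public and sealed JSON), `metrics.csv` (blinded),
#'   `plaques.csv` (blinded per-plaque table), `stat_reports.json`,
#'   `summary.csv`, `summary.md` and `manifest.json`.
#' @return invisibly, a list with the blinded `metrics` table, the unblinded
#'   `results` table, `reports` (list of stat reports) and `summary` data
#'   frame.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  groups <- unlist(config$groups)
  npg <- unlist(config$n_per_group)[groups]
  n_total <- sum(npg)

  ## cohort + blinded randomization -----------------------------------------
  cb <- stage("randomize", {
    mice <- data.frame(
      id = sprintf("mouse%02d", seq_len(n_total)),
      sex = rep_len(c("F", "M"), n_total)
    )
    randomize_groups(mice, groups, seed = config$seed,
                     group_sizes = setNames(as.integer(npg), groups))
  })
  write_codebook(cb, file.path(out_dir, "codebook"))
  # generator needs true groups; analysis below uses codes only
  truth <- merge(cb$public, cb$sealed, by = "code")

  ## simulate + measure (blinded codes) -------------------------------------
  fr <- config$behavior$frame_rate_hz
  arena_n <- arena_nort()
  arena_y <- arena_ymaze()
  arena_m <- arena_mwm()
  metrics <- list()
  plaque_rows <- list()
  add_metric <- function(code, metric, value) {
    metrics[[length(metrics) + 1L]] <<- data.frame(
      code = code, metric = metric, value = as.numeric(value)
    )
  }
  stage("simulate+behavior", for (i in seq_len(nrow(truth))) {
    code <- truth$code[i]
    g <- truth$group[i]
    seed_i <- (config$seed * 1000L + i) %% .Machine$integer.max

    sim <- simulate_trajectory(behavior_sim_params(
      "nort", duration_s = config$behavior$nort$duration_s, frame_rate_hz = fr,
      novelty_preference = param_for(config$behavior$nort$novelty_preference, g),
      seed = seed_i
    ), arena_n)
    di <- discrimination_index(exploration_times(
      sim$trajectory, arena_n, facing_max_deg = config$behavior$facing_max_deg
    ))
    if (!is.na(di)) add_metric(code, "discrimination_index", di)

    sim <- simulate_trajectory(behavior_sim_params(
      "ymaze", duration_s = config$behavior$ymaze$duration_s, frame_rate_hz = fr,
      alternation_bias = param_for(config$behavior$ymaze$alternation_bias, g),
      seed = seed_i + 1L
    ), arena_y)
    arms <- detect_arm_entries(sim$trajectory, arena_y,
                               entry_depth_frac = config$behavior$entry_depth_frac)
    alt <- spontaneous_alternation(arms, as_percent = TRUE)
    add_metric(code, "arm_entries", length(arms))
    if (!is.na(alt)) add_metric(code, "alternation_pct", alt)

    sim <- simulate_trajectory(behavior_sim_params(
      "mwm_probe", duration_s = config$behavior$mwm_probe$duration_s, frame_rate_hz = fr,
      goal_bias = param_for(config$behavior$mwm_probe$goal_bias, g),
      seed = seed_i + 2L
    ), arena_m)
    pm <- mwm_probe_metrics(sim$trajectory, arena_m)
    add_metric(code, "target_quadrant_time_s", pm$quadrant_time_s[pm$target_quadrant])
    add_metric(code, "mean_distance_to_platform_cm", pm$mean_distance_to_platform_cm)
  })

  if (isTRUE(config$histology$enabled)) stage("histology", {
    hc <- config$histology
    for (i in seq_len(nrow(truth))) {
      code <- truth$code[i]
      g <- truth$group[i]
      seed_i <- (config$seed * 1000L + 500L + i) %% .Machine$integer.max
      sim <- simulate_histology_image(histo_sim_params(
        image_shape = unlist(hc$image_shape),
        plaque_count = hc$plaque_count,
        border_margin_um = hc$border_margin_um,
        enrichment_factor = param_for(hc$enrichment_factor, g),
        noise_sd = hc$noise_sd, seed = seed_i
      ))
      region <- region_annotation("prefrontal_cortex", unlist(hc$image_shape))
      seg <- segment_plaques(sim$images$plaque, region,
                             min_area_um2 = hc$min_area_um2,
                             threshold_method = hc$threshold_method)
      add_metric(code, "plaque_load", plaque_load(seg$mask, region))
      mr <- microglia_response(sim$images$microglia, seg$plaques, region,
                               near_um = unlist(hc$near_um),
                               far_um = unlist(hc$far_um),
                               plaque_mask = seg$mask)
      if (!is.na(mr$summary$ratio_mean)) {
        add_metric(code, "microglia_ratio", mr$summary$ratio_mean)
      }
      if (nrow(seg$plaques)) {
        plaque_rows[[length(plaque_rows) + 1L]] <-
          cbind(code = code, seg$plaques)
      }
    }
  })

  metrics <- do.call(rbind, metrics)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  if (length(plaque_rows)) {
    write.csv(do.call(rbind, plaque_rows), file.path(out_dir, "plaques.csv"),
              row.names = FALSE)
  }

  ## unblind + statistics ----------------------------------------------------
  res <- stage("stats", {
    cb2 <- unblind(cb, who = "pipeline")
    results <- metrics
    results$group <- group_of(cb2, results$code)
    alpha <- config$stats$alpha
    nmc <- config$stats$n_monte_carlo
    reports <- list()
    for (m in unique(results$metric)) {
      sub <- results[results$metric == m, ]
      reports[[paste0(m, "_groups")]] <- tryCatch(
        compare_groups(sub, alpha = alpha, gate_alpha = config$stats$gate_alpha,
                       n_monte_carlo = nmc, seed = config$seed),
        error = function(e) list(test = "skipped", error = conditionMessage(e))
      )
    }
    one_sample_refs <- c(discrimination_index = 0, alternation_pct = 22,
                         microglia_ratio = 1)
    for (m in intersect(names(one_sample_refs), unique(results$metric))) {
      for (g in groups) {
        v <- results$value[results$metric == m & results$group == g]
        if (length(v) >= 2 && sd(v) > 0) {
          reports[[paste0(m, "_", g, "_vs_", one_sample_refs[[m]])]] <-
            one_sample_test(v, one_sample_refs[[m]], alpha = alpha)
        }
      }
    }
    list(results = results, reports = reports)
  })

  ## report ------------------------------------------------------------------
  summary_df <- do.call(rbind, lapply(names(res$reports), function(nm) {
    r <- res$reports[[nm]]
    if (identical(r$test, "skipped")) return(NULL)
    data.frame(comparison = nm, test = r$test,
               statistic = unname(r$statistic[1]),
               p_value = r$p_value, stars = r$stars)
  }))
  write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(res$reports, unclass),
                       file.path(out_dir, "stat_reports.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  md <- c("# Pipeline run summary", "",
          sprintf("- animals: %d (%s)", n_total,
                  paste(sprintf("%s n=%d", groups, npg), collapse = ", ")),
          sprintf("- master seed: %s", config$seed), "",
          "| comparison | test | statistic | p | |",
          "|---|---|---|---|---|",
          sprintf("| %s | %s | %.4g | %.4g | %s |", summary_df$comparison,
                  summary_df$test, summary_df$statistic, summary_df$p_value,
                  summary_df$stars))
  writeLines(md, file.path(out_dir, "summary.md"))

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(config = config,
                   config_md5 = unname(tools::md5sum(tf)),
                   n_metrics = nrow(metrics))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(metrics = metrics, results = res$results,
                 reports = res$reports, summary = summary_df))
}
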