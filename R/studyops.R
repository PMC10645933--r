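#' Sex-balanced blinded randomization
#'
#' Allocates mice to treatment groups with sex balance enforced before any
#' randomness: within each sex, the shuffled animals are dealt round-robin to
#' the groups (in a shuffled group order), so group sizes differ by at most
#' one per sex. Unequal total group sizes (e.g. 19/20/21) can be requested
#' explicitly via `group_sizes`, in which case the round-robin skips groups
#' that reached capacity.
#'
#' The result is a blinding [codebook]: a public id-to-code table and a
#' sealed code-to-group mapping that is inaccessible until [unblind()] is
#' called.
#'
#' @param mice data frame with columns `id` and `sex`.
#' @param group_names character vector of group labels (e.g. sham/low/high).
#' @param seed integer seed; the same seed reproduces the assignment exactly.
#' @param group_sizes optional named integer vector of exact group sizes
#'   (must sum to `nrow(mice)`).
#' @return a `codebook` object.
#' @export
randomize_groups <- function(mice, group_names = c("sham", "low", "high"),
                             seed = NULL, group_sizes = NULL) {
  if (!is.data.frame(mice) || !all(c("id", "sex") %in% names(mice)) || nrow(mice) == 0L) {
    stopf("`mice` must be a non-empty data frame with columns `id` and `sex`")
  }
  if (anyDuplicated(mice$id)) stopf("mouse ids must be unique")
  if (length(group_names) < 1L) stopf("need at least one group")
  if (!is.null(group_sizes)) {
    if (is.null(names(group_sizes)) || !setequal(names(group_sizes), group_names)) {
      stopf("`group_sizes` must be named by `group_names`")
    }
    if (sum(group_sizes) != nrow(mice)) {
      stopf("`group_sizes` must sum to the number of mice")
    }
  }
  with_seed(seed, {
    capacity <- if (is.null(group_sizes)) {
      setNames(rep(Inf, length(group_names)), group_names)
    } else {
      group_sizes[group_names]
    }
    assigned <- setNames(rep(0L, length(group_names)), group_names)
    rows <- list()
    for (sx in unique(mice$sex)) {
      ids <- mice$id[mice$sex == sx]
      ids <- ids[sample.int(length(ids))]
      order_g <- sample(group_names)
      gi <- 1L
      for (id in ids) {
        tries <- 0L
        while (assigned[order_g[gi]] >= capacity[order_g[gi]]) {
          gi <- gi %% length(order_g) + 1L
          tries <- tries + 1L
          if (tries > length(order_g)) stopf("group capacities exhausted")
        }
        g <- order_g[gi]
        assigned[g] <- assigned[g] + 1L
        rows[[length(rows) + 1L]] <- data.frame(mouse_id = id, sex = sx, group = g)
        gi <- gi %% length(order_g) + 1L
      }
    }
    assignment <- do.call(rbind, rows)
    codes <- sprintf("M%03d", sample.int(9 * nrow(assignment)))[seq_len(nrow(assignment))]
    assignment$code <- codes
    codebook(assignment)
  })
}

#' Blinding codebook
#'
#' Holds the mapping from animal ids to blinded codes (public) and from codes
#' to treatment groups (sealed). Group identities are inaccessible — any
#' lookup raises an error — until [unblind()] is called; every unblinding is
#' recorded in an audit log.
#'
#' @param assignment data frame with columns `mouse_id`, `sex`, `code`,
#'   `group`.
#' @return an object of class `codebook` with elements `public` (mouse_id,
#'   sex, code), a sealed mapping, `unblinded` flag and `audit` log.
#' @export
codebook <- function(assignment) {
  needed <- c("mouse_id", "sex", "code", "group")
  if (!all(needed %in% names(assignment))) {
    stopf("`assignment` must have columns: %s", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(assignment$code) || anyDuplicated(assignment$mouse_id)) {
    stopf("id-code mapping must be bijective")
  }
  structure(list(
    public = assignment[, c("mouse_id", "sex", "code")],
    sealed = assignment[, c("code", "group")],
    unblinded = FALSE,
    audit = data.frame(time = character(0), event = character(0))
  ), class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook: %d animals, %s>\n", nrow(x$public),
              if (x$unblinded) "UNBLINDED" else "blinded"))
  invisible(x)
}

#' @describeIn codebook Reveal the group mapping; returns a new codebook with
#'   the audit log extended.
#' @param cb a `codebook`.
#' @param who free-text identity of the person unblinding (audited).
#' @export
unblind <- function(cb, who = "analyst") {
  if (!inherits(cb, "codebook")) stopf("`cb` must be a codebook")
  cb$unblinded <- TRUE
  cb$audit <- rbind(cb$audit, data.frame(
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    event = paste("unblinded by", who)
  ))
  cb
}

#' @describeIn codebook Look up group labels for codes; errors while blinded.
#' @param codes blinded codes to resolve.
#' @export
group_of <- function(cb, codes) {
  if (!inherits(cb, "codebook")) stopf("`cb` must be a codebook")
  if (!isTRUE(cb$unblinded)) {
    stopf("codebook is sealed: call unblind() after data collection and processing are complete")
  }
  cb$sealed$group[match(codes, cb$sealed$code)]
}

#' Persist and restore a codebook as two JSON files
#'
#' The public table and the sealed mapping are written to separate files
#' (`codebook_public.json`, `codebook_sealed.json`) so that blinding survives
#' process restarts: analysis code can load only the public part.
#'
#' @param cb a [codebook].
#' @param dir directory for the two files.
#' @param sealed also load the sealed mapping (required for [unblind()] and
#'   [group_of()] later).
#' @return `write_codebook` returns `dir` invisibly; `read_codebook` returns
#'   a `codebook` (with an empty sealed part if `sealed = FALSE`).
#' @export
write_codebook <- function(cb, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(cb$public, file.path(dir, "codebook_public.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  jsonlite::write_json(list(sealed = cb$sealed, audit = cb$audit),
                       file.path(dir, "codebook_sealed.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(dir, sealed = FALSE) {
  public <- jsonlite::read_json(file.path(dir, "codebook_public.json"),
                                simplifyVector = TRUE)
  out <- structure(list(public = public,
                        sealed = data.frame(code = character(0), group = character(0)),
                        unblinded = FALSE,
                        audit = data.frame(time = character(0), event = character(0))),
                   class = "codebook")
  if (sealed) {
    s <- jsonlite::read_json(file.path(dir, "codebook_sealed.json"),
                             simplifyVector = TRUE)
    out$sealed <- s$sealed
    if (length(s$audit)) out$audit <- s$audit
  }
  out
}

#' Pulsed light dose specification and arithmetic
#'
#' `dose_spec()` describes a transcranial light dose: 810 nm light pulsed at
#' 100 Hz with a 20 percent duty cycle for 120-s sessions, three sessions per
#' week (the defaults). `dose_summary()` derives the average irradiance
#' (peak times duty cycle), the per-session fluence (average irradiance times
#' session duration) and the cumulative fluence over the treatment course.
#'
#' @param peak_irradiance_mw_cm2 peak irradiance (mW/cm^2), e.g. 600 for the
#'   high-power and 6 for the low-power condition.
#' @param wavelength_nm center wavelength (nm).
#' @param pulse_rate_hz pulse rate (Hz).
#' @param duty_cycle fraction of each pulse period the light is on, in (0, 1].
#' @param session_s session duration (s).
#' @param sessions_per_week sessions per week.
#' @param duration_weeks treatment duration (weeks); default 22 (about five
#'   months).
#' @return `dose_spec()`: a list of class `dose_spec`. `dose_summary()`: list
#'   with `average_irradiance_mw_cm2`, `per_session_fluence_j_cm2`,
#'   `cumulative_fluence_j_cm2`.
#' @export
dose_spec <- function(peak_irradiance_mw_cm2,
                      wavelength_nm = 810,
                      pulse_rate_hz = 100,
                      duty_cycle = 0.2,
                      session_s = 120,
                      sessions_per_week = 3,
                      duration_weeks = 22) {
  check_pos(peak_irradiance_mw_cm2, "peak_irradiance_mw_cm2")
  check_pos(wavelength_nm, "wavelength_nm")
  check_pos(pulse_rate_hz, "pulse_rate_hz")
  check_pos(session_s, "session_s")
  check_pos(sessions_per_week, "sessions_per_week")
  check_pos(duration_weeks, "duration_weeks")
  if (duty_cycle <= 0 || duty_cycle > 1) stopf("`duty_cycle` must be in (0, 1]")
  structure(list(
    peak_irradiance_mw_cm2 = peak_irradiance_mw_cm2,
    wavelength_nm = wavelength_nm, pulse_rate_hz = pulse_rate_hz,
    duty_cycle = duty_cycle, session_s = session_s,
    sessions_per_week = sessions_per_week, duration_weeks = duration_weeks
  ), class = "dose_spec")
}

#' @rdname dose_spec
#' @param spec a `dose_spec`.
#' @export
dose_summary <- function(spec) {
  if (!inherits(spec, "dose_spec")) stopf("`spec` must be a dose_spec")
  avg <- spec$peak_irradiance_mw_cm2 * spec$duty_cycle
  per_session <- avg * spec$session_s / 1000 # mW s / cm^2 -> J / cm^2
  list(
    average_irradiance_mw_cm2 = avg,
    per_session_fluence_j_cm2 = per_session,
    cumulative_fluence_j_cm2 = per_session * spec$sessions_per_week * spec$duration_weeks
  )
}

#' Fur attenuation of transcranial light
#'
#' From paired power-meter readings under the brain with the scalp shaved and
#' unshaved at matched source powers: per-pair transmission
#' `unshaved / shaved * 100` (percent), its mean and s.d. across powers, and
#' the attenuation `100 - mean transmission`.
#'
#' @param power_shaved,power_unshaved paired transmitted powers (mW) at the
#'   same source settings; `power_shaved` must be positive.
#' @return list with `transmission_pct` (per pair), `transmission_mean_pct`,
#'   `transmission_sd_pct`, `attenuation_pct`.
#' @export
fur_attenuation <- function(power_shaved, power_unshaved) {
  if (length(power_shaved) != length(power_unshaved) || length(power_shaved) == 0L) {
    stopf("shaved and unshaved measurements must be non-empty and paired")
  }
  if (any(power_shaved <= 0)) stopf("shaved transmitted power must be positive")
  tr <- power_unshaved / power_shaved * 100
  list(
    transmission_pct = tr,
    transmission_mean_pct = mean(tr),
    transmission_sd_pct = if (length(tr) > 1L) sd(tr) else NA_real_,
    attenuation_pct = 100 - mean(tr)
  )
}
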