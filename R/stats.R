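#' Significance stars
#'
#' Stars follow the study's convention: `*` for p < 0.05, `**` for p < 0.01,
#' `***` for p < 0.001, empty otherwise.
#'
#' @param p p-value(s).
#' @return character vector of stars.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

new_stat_report <- function(test, statistic, df, p_value, alpha = 0.05,
                            normality = NULL, notes = character(0), extras = list()) {
  structure(c(list(
    test = test, statistic = statistic, df = df, p_value = p_value,
    normality = normality, alpha = alpha,
    stars = significance_stars(p_value), notes = notes
  ), extras), class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  st <- paste(sprintf("%s = %.4g", names(x$statistic), x$statistic), collapse = ", ")
  dfs <- if (length(x$df)) paste0(" (df = ", paste(signif(unlist(x$df), 4), collapse = ", "), ")") else ""
  cat(sprintf("%s: %s%s, p = %.4g %s\n", x$test, st, dfs, x$p_value, x$stars))
  if (!is.null(x$normality)) {
    dec <- if (isTRUE(x$normality$normal)) "normal" else "non-normal"
    cat(sprintf("  normality gate: %s (min Lilliefors p = %.3g)\n",
                dec, x$normality$min_p))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

# cache of Monte-Carlo null distributions of the Lilliefors statistic,
# keyed by (n, n_monte_carlo, seed)
.lillie_cache <- new.env(parent = emptyenv())

lilliefors_statistic <- function(x) {
  n <- length(x)
  xs <- sort(x)
  z <- (xs - mean(xs)) / sd(xs)
  Fz <- pnorm(z)
  i <- seq_len(n)
  max(max(i / n - Fz), max(Fz - (i - 1) / n))
}

#' Lilliefors test of composite normality
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with mean and
#' s.d. estimated from the sample, with the p-value obtained from a seeded
#' Monte-Carlo null: normal samples of the same size, parameters re-estimated
#' per replicate. The add-one rule `p = (1 + #{D* >= D}) / (B + 1)` keeps p
#' strictly positive. Null distributions are cached per (n, B, seed), so
#' repeated gating at the same sample size costs one simulation.
#'
#' @param x numeric sample, n >= 4, non-constant.
#' @param n_monte_carlo number of null replicates B (default 10000).
#' @param seed integer seed for the null simulation (default 1).
#' @return a `stat_report` with the statistic `D` and the Monte-Carlo p.
#' @export
lilliefors_test <- function(x, n_monte_carlo = 10000, seed = 1) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) stopf("Lilliefors test needs n >= 4 (got %d)", n)
  if (sd(x) == 0) stopf("Lilliefors test is undefined for a constant sample")
  D <- lilliefors_statistic(x)
  key <- paste(n, n_monte_carlo, seed, sep = "_")
  if (is.null(.lillie_cache[[key]])) {
    .lillie_cache[[key]] <- with_seed(seed, {
      vapply(seq_len(n_monte_carlo),
             function(i) lilliefors_statistic(rnorm(n)), numeric(1))
    })
  }
  null_D <- .lillie_cache[[key]]
  p <- (1 + sum(null_D >= D)) / (n_monte_carlo + 1)
  new_stat_report("Lilliefors (Monte-Carlo)", c(D = D), list(n = n), p,
                  extras = list(n_monte_carlo = n_monte_carlo, seed = seed))
}

# Gate helper: per-group normality decisions at `gate_alpha`.
normality_gate <- function(groups, gate_alpha, n_monte_carlo, seed) {
  tests <- lapply(groups, lilliefors_test, n_monte_carlo = n_monte_carlo, seed = seed)
  ps <- vapply(tests, `[[`, numeric(1), "p_value")
  list(per_group = ps, min_p = min(ps), normal = all(ps >= gate_alpha),
       gate_alpha = gate_alpha)
}

#' Compare metric values across treatment groups
#'
#' The study's multi-group decision procedure: each group is screened for
#' normality with the Monte-Carlo [lilliefors_test()]; if every group passes
#' (p >= `gate_alpha`), a one-way ANOVA is run, otherwise the report falls
#' back to the Kruskal-Wallis rank-sum test and is flagged (the original
#' procedure only describes the normal branch).
#'
#' @param table data frame with at least columns `group` and `value`; use
#'   `metric`/`timepoint` to filter a long table with `metric` and
#'   `timepoint` columns.
#' @param metric optional metric name to filter on.
#' @param timepoint optional timepoint to filter on.
#' @param alpha significance level for stars (default 0.05).
#' @param gate_alpha normality-gate level (default 0.05).
#' @param n_monte_carlo,seed Monte-Carlo settings of the normality gate.
#' @return a `stat_report`: F and df for ANOVA, or chi-squared and df for
#'   the flagged Kruskal-Wallis fallback.
#' @export
compare_groups <- function(table, metric = NULL, timepoint = NULL, alpha = 0.05,
                           gate_alpha = 0.05, n_monte_carlo = 10000, seed = 1) {
  if (!is.null(metric)) table <- table[table$metric == metric, , drop = FALSE]
  if (!is.null(timepoint)) table <- table[table$timepoint == timepoint, , drop = FALSE]
  table <- table[is.finite(table$value), , drop = FALSE]
  groups <- split(table$value, factor(table$group))
  if (length(groups) < 2L) stopf("need at least 2 groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 3L)) {
    stopf("group '%s' has fewer than 3 values", names(groups)[which(sizes < 3L)[1]])
  }
  gate <- normality_gate(groups, gate_alpha, n_monte_carlo, seed)
  if (gate$normal) {
    fit <- aov(value ~ factor(group), data = table)
    tab <- summary(fit)[[1]]
    new_stat_report(
      "One-way ANOVA",
      c(F = tab[1, "F value"]),
      list(df1 = tab[1, "Df"], df2 = tab[2, "Df"]),
      tab[1, "Pr(>F)"], alpha = alpha, normality = gate
    )
  } else {
    kw <- kruskal.test(table$value, factor(table$group))
    new_stat_report(
      "Kruskal-Wallis (non-normal fallback)",
      c(chi_squared = unname(kw$statistic)),
      list(df = unname(kw$parameter)),
      kw$p.value, alpha = alpha, normality = gate,
      notes = "normality gate failed; rank-based fallback used"
    )
  }
}

#' Paired two-timepoint comparison
#'
#' The study's within-animal decision procedure: the paired differences are
#' screened with the Monte-Carlo [lilliefors_test()]; if normal, a paired
#' Student's t-test is run, otherwise Wilcoxon's signed-rank test (exact null
#' for n <= 25 without ties, normal approximation with continuity correction
#' above). The signed-rank report includes the (positive, negative) rank
#' sums. All-zero differences are degenerate and reported as p = 1.
#'
#' @param before,after equal-length paired vectors (e.g. baseline and
#'   endpoint values of the same animals).
#' @param alpha,gate_alpha,n_monte_carlo,seed as in [compare_groups()].
#' @return a `stat_report`.
#' @export
compare_paired <- function(before, after, alpha = 0.05, gate_alpha = 0.05,
                           n_monte_carlo = 10000, seed = 1) {
  if (length(before) != length(after)) stopf("`before` and `after` must be paired")
  ok <- is.finite(before) & is.finite(after)
  before <- before[ok]; after <- after[ok]
  d <- after - before
  n <- length(d)
  if (all(d == 0)) {
    return(new_stat_report("Wilcoxon signed rank", c(W = 0), list(n = n), 1,
                           alpha = alpha,
                           notes = "all paired differences are zero (degenerate)"))
  }
  gate <- if (sd(d) > 0 && n >= 4) {
    normality_gate(list(differences = d), gate_alpha, n_monte_carlo, seed)
  } else {
    list(per_group = NA_real_, min_p = NA_real_, normal = FALSE, gate_alpha = gate_alpha)
  }
  if (isTRUE(gate$normal)) {
    tt <- t.test(after, before, paired = TRUE)
    new_stat_report("Paired t-test", c(t = unname(tt$statistic)),
                    list(df = unname(tt$parameter)), tt$p.value,
                    alpha = alpha, normality = gate)
  } else {
    dz <- d[d != 0]
    r <- rank(abs(dz))
    w_pos <- sum(r[dz > 0])
    w_neg <- sum(r[dz < 0])
    exact <- length(dz) <= 25 && !any(duplicated(abs(dz)))
    wt <- suppressWarnings(
      wilcox.test(after, before, paired = TRUE, exact = exact, correct = TRUE)
    )
    new_stat_report("Wilcoxon signed rank", c(W = unname(wt$statistic)),
                    list(n = n), wt$p.value, alpha = alpha, normality = gate,
                    extras = list(rank_sums = c(positive = w_pos, negative = -w_neg),
                                  exact = exact))
  }
}

#' One-sample t-test against a theoretical mean
#'
#' Used for the study's chance-level references: discrimination index against
#' 0, spontaneous alternation percentage against 22 (the 2/9 chance level),
#' and the microglial annulus ratio against 1 (no peri-plaque enrichment).
#'
#' @param sample numeric vector, n >= 2, non-constant.
#' @param reference theoretical mean under the null.
#' @param alpha significance level for stars.
#' @return a `stat_report` with t, df = n - 1 and the two-sided p.
#' @export
one_sample_test <- function(sample, reference, alpha = 0.05) {
  sample <- sample[is.finite(sample)]
  if (length(sample) < 2L) stopf("one-sample test needs n >= 2")
  if (!is.finite(reference)) stopf("`reference` must be finite")
  if (sd(sample) == 0) stopf("one-sample t-test is undefined for a constant sample")
  tt <- t.test(sample, mu = reference)
  new_stat_report(sprintf("One-sample t-test vs %g", reference),
                  c(t = unname(tt$statistic)), list(df = unname(tt$parameter)),
                  tt$p.value, alpha = alpha,
                  extras = list(reference = reference, mean = mean(sample)))
}

# Greenhouse-Geisser epsilon from the pooled within-subject covariance.
gg_epsilon <- function(wide, between) {
  k <- ncol(wide)
  if (k < 2L) return(1)
  groups <- split(seq_len(nrow(wide)), between)
  S <- matrix(0, k, k)
  dfree <- 0
  for (g in groups) {
    if (length(g) < 2L) next
    S <- S + stats::cov(wide[g, , drop = FALSE]) * (length(g) - 1L)
    dfree <- dfree + length(g) - 1L
  }
  S <- S / dfree
  C <- stats::contr.poly(k) # k x (k-1), orthonormal contrasts
  M <- t(C) %*% S %*% C
  unname((sum(diag(M)))^2 / ((k - 1) * sum(M^2)))
}

#' Mixed-design two-factor report with sphericity correction
#'
#' Fits the study's repeated-measures design — one between-subject factor
#' (treatment group or age cohort) and one within-subject factor (training
#' day or pool quadrant) — by a univariate mixed-design ANOVA, and corrects
#' the within-subject degrees of freedom with the Greenhouse-Geisser epsilon
#' estimated from the pooled within-cell covariance (epsilon is exactly 1
#' for a 2-level within factor). Post-hoc multiple comparisons are delegated
#' to \pkg{emmeans}: Sidak-adjusted pairwise comparisons or Dunnett-style
#' comparisons against a reference level.
#'
#' @param table data frame with columns `subject`, `value`, plus the factors.
#' @param within_factor,between_factor column names of the within- and
#'   between-subject factors. The within-subject design must be complete
#'   (every subject measured at every level).
#' @param posthoc `"none"`, `"sidak"` (pairwise within-factor comparisons at
#'   each between level) or `"dunnett"` (within-factor levels against
#'   `ref_level`, at each between level).
#' @param ref_level reference level for Dunnett comparisons.
#' @param alpha significance level for stars.
#' @return list of class `two_factor_report`: `effects` data frame (one row
#'   per effect with uncorrected and Greenhouse-Geisser-corrected df and p),
#'   `epsilon`, and `posthoc` (emmeans contrast summary or `NULL`).
#' @export
two_factor_report <- function(table, within_factor, between_factor,
                              posthoc = c("none", "sidak", "dunnett"),
                              ref_level = NULL, alpha = 0.05) {
  posthoc <- match.arg(posthoc)
  dat <- table
  needed <- c("subject", "value", within_factor, between_factor)
  if (!all(needed %in% names(dat))) {
    stopf("`table` must have columns: %s", paste(needed, collapse = ", "))
  }
  dat$subject <- factor(dat$subject)
  dat$.w <- factor(dat[[within_factor]])
  dat$.b <- factor(dat[[between_factor]])
  counts <- base::table(dat$subject, dat$.w)
  if (any(counts != 1L)) {
    stopf("within-subject design must be complete: every subject needs exactly one value per %s level",
          within_factor)
  }
  wide <- tapply(dat$value, list(dat$subject, dat$.w), identity)
  subj_between <- tapply(as.character(dat$.b), dat$subject, function(x) x[1])
  eps <- gg_epsilon(wide, subj_between[rownames(wide)])

  # build the call with the data embedded so downstream re-evaluation
  # (emmeans re-fits with sum-to-zero contrasts) is self-contained
  fit <- do.call("aov", list(
    stats::as.formula("value ~ .b * .w + Error(subject / .w)"), data = dat
  ))
  s <- summary(fit)
  btab <- s[["Error: subject"]][[1]]
  wtab <- s[["Error: subject:.w"]][[1]]
  row_of <- function(tab, term) {
    i <- which(trimws(rownames(tab)) == term)
    tab[i, , drop = FALSE]
  }
  b <- row_of(btab, ".b"); b_res <- row_of(btab, "Residuals")
  w <- row_of(wtab, ".w"); i_ <- row_of(wtab, ".b:.w"); w_res <- row_of(wtab, "Residuals")
  mk <- function(name, r, res, correct) {
    df1 <- r[1, "Df"]; df2 <- res[1, "Df"]; Fv <- r[1, "F value"]
    e <- if (correct) eps else 1
    data.frame(effect = name, F = Fv,
               df1 = df1, df2 = df2,
               df1_gg = df1 * e, df2_gg = df2 * e,
               p_uncorrected = r[1, "Pr(>F)"],
               p = pf(Fv, df1 * e, df2 * e, lower.tail = FALSE))
  }
  effects <- rbind(
    mk(between_factor, b, b_res, correct = FALSE),
    mk(within_factor, w, w_res, correct = TRUE),
    mk(paste0(between_factor, ":", within_factor), i_, w_res, correct = TRUE)
  )
  effects$stars <- significance_stars(effects$p)

  ph <- NULL
  if (posthoc != "none") {
    em <- emmeans::emmeans(fit, stats::as.formula("~ .w | .b"), data = dat)
    ph <- if (posthoc == "sidak") {
      summary(emmeans::contrast(em, method = "pairwise", adjust = "sidak"))
    } else {
      if (is.null(ref_level)) ref_level <- levels(dat$.w)[1]
      summary(emmeans::contrast(em, method = "trt.vs.ctrl",
                                ref = which(levels(dat$.w) == ref_level),
                                adjust = "dunnettx"))
    }
  }
  structure(list(effects = effects, epsilon = eps, posthoc = ph, alpha = alpha,
                 within_factor = within_factor, between_factor = between_factor),
            class = "two_factor_report")
}

#' @export
print.two_factor_report <- function(x, ...) {
  cat(sprintf("Mixed-design ANOVA (%s between, %s within), Greenhouse-Geisser epsilon = %.3f\n",
              x$between_factor, x$within_factor, x$epsilon))
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %s: F(%.1f, %.1f) = %.2f, p = %.4g %s\n",
                e$effect[i], e$df1_gg[i], e$df2_gg[i], e$F[i], e$p[i], e$stars[i]))
  }
  invisible(x)
}

#' Serialize a stat report to JSON
#'
#' @param report a `stat_report` or `two_factor_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stat_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}
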