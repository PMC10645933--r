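# Reference implementations (nortest, closed-form sums of squares, base R
# tests with known identities) serve as independent oracles.

test_that("the Lilliefors statistic matches nortest exactly", {
  set.seed(42)
  for (i in 1:20) {
    x <- switch(1 + i %% 3,
                rnorm(10 + i), rexp(10 + i), runif(10 + i))
    expect_equal(unname(lilliefors_test(x, n_monte_carlo = 10)$statistic["D"]),
                 unname(nortest::lillie.test(x)$statistic))
  }
})

test_that("Monte-Carlo Lilliefors p agrees with nortest's approximation", {
  set.seed(7)
  x <- rnorm(30)
  p_mc <- lilliefors_test(x, n_monte_carlo = 4000, seed = 2)$p_value
  p_ref <- nortest::lillie.test(x)$p.value
  expect_lt(abs(p_mc - p_ref), 0.06)
  # strongly bimodal data must be rejected
  y <- c(rnorm(20, -4, 0.3), rnorm(20, 4, 0.3))
  expect_lt(lilliefors_test(y, n_monte_carlo = 2000)$p_value, 0.01)
  # p is always strictly positive and at most 1
  expect_gt(lilliefors_test(y, n_monte_carlo = 500)$p_value, 0)
  expect_lte(lilliefors_test(x, n_monte_carlo = 500)$p_value, 1)
})

test_that("Lilliefors input contract is enforced", {
  expect_error(lilliefors_test(c(1, 2, 3)), "n >= 4")
  expect_error(lilliefors_test(rep(5, 10)), "constant")
})

test_that("the Lilliefors gate holds its nominal type-I error", {
  set.seed(123)
  n_rep <- 2000
  rejections <- sum(vapply(seq_len(n_rep), function(i) {
    lilliefors_test(rnorm(12), n_monte_carlo = 800, seed = 5)$p_value < 0.05
  }, logical(1)))
  # binomial band around 0.05 at 2000 replicates (~ +-3 sd)
  expect_gt(rejections / n_rep, 0.035)
  expect_lt(rejections / n_rep, 0.065)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  tab <- data.frame(
    group = rep(c("a", "b", "c"), each = 4),
    value = c(5.1, 4.8, 5.5, 5.0, 6.2, 6.0, 6.6, 6.1, 4.1, 4.5, 4.0, 4.2)
  )
  rep_ <- compare_groups(tab, n_monte_carlo = 500)
  # literal between/within sums of squares
  gm <- mean(tab$value)
  means <- tapply(tab$value, tab$group, mean)
  ss_b <- sum(4 * (means - gm)^2)
  ss_w <- sum((tab$value - means[tab$group])^2)
  F_hand <- (ss_b / 2) / (ss_w / 9)
  expect_equal(rep_$test, "One-way ANOVA")
  expect_equal(unname(rep_$statistic["F"]), F_hand, tolerance = 1e-12)
  expect_equal(rep_$df, list(df1 = 2, df2 = 9))
  expect_equal(rep_$p_value, pf(F_hand, 2, 9, lower.tail = FALSE))
})

test_that("for two balanced groups the ANOVA F equals t squared", {
  set.seed(5)
  tab <- data.frame(group = rep(c("a", "b"), each = 10),
                    value = c(rnorm(10), rnorm(10, 0.8)))
  rep_ <- compare_groups(tab, n_monte_carlo = 500)
  tt <- t.test(value ~ group, data = tab, var.equal = TRUE)
  expect_equal(unname(rep_$statistic["F"]), unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(rep_$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("clearly separated groups are detected and non-normal data flagged", {
  set.seed(9)
  tab <- data.frame(group = rep(c("a", "b", "c"), each = 8),
                    value = c(rnorm(8, 0), rnorm(8, 10), rnorm(8, 20)))
  rep_ <- compare_groups(tab, n_monte_carlo = 500)
  expect_lt(rep_$p_value, 1e-6)
  expect_equal(rep_$stars, "***")
  # lognormal-ish heavy tails in one group trip the gate -> Kruskal-Wallis
  tab2 <- data.frame(group = rep(c("a", "b"), each = 30),
                     value = c(exp(rnorm(30, 0, 1.5)), rnorm(30, 2)))
  rep2 <- compare_groups(tab2, n_monte_carlo = 2000, seed = 3)
  expect_match(rep2$test, "Kruskal")
  expect_false(rep2$normality$normal)
  kw <- kruskal.test(tab2$value, factor(tab2$group))
  expect_equal(unname(rep2$statistic["chi_squared"]), unname(kw$statistic))
  expect_equal(rep2$p_value, kw$p.value)
})

test_that("compare_groups validates its input", {
  expect_error(compare_groups(data.frame(group = "a", value = 1)), "2 groups")
  expect_error(compare_groups(data.frame(group = c("a", "a", "a", "b", "b"),
                                         value = c(1, 2, 3, 4, 5))),
               "fewer than 3")
})

test_that("paired comparisons: degenerate, normal, and rank branches", {
  x <- c(1, 2, 3, 4, 5)
  d0 <- compare_paired(x, x)
  expect_equal(d0$p_value, 1)
  expect_match(d0$notes, "degenerate")
  # normal differences use the paired t-test
  set.seed(11)
  b <- rnorm(20); a <- b + rnorm(20, 0.5, 0.4)
  rep_ <- compare_paired(b, a, n_monte_carlo = 1000)
  if (rep_$normality$normal) {
    tt <- t.test(a, b, paired = TRUE)
    expect_equal(unname(rep_$statistic["t"]), unname(tt$statistic))
    expect_equal(rep_$p_value, tt$p.value)
  }
  # rank sums of the signed-rank branch add to n(n+1)/2 with opposite signs
  set.seed(13)
  b2 <- exp(rnorm(40)); a2 <- b2 * exp(rnorm(40, 0.3))
  rep2 <- compare_paired(b2, a2, n_monte_carlo = 2000, seed = 4)
  if (grepl("Wilcoxon", rep2$test)) {
    rs <- rep2$rank_sums
    n_nz <- sum(a2 != b2)
    expect_equal(unname(rs["positive"] - rs["negative"]), n_nz * (n_nz + 1) / 2)
    expect_gte(unname(rs["positive"]), 0)
    expect_lte(unname(rs["negative"]), 0)
  }
  expect_error(compare_paired(1:3, 1:4), "paired")
})

test_that("the paired procedure has power at a one-sd shift", {
  set.seed(17)
  hits <- sum(vapply(1:40, function(i) {
    b <- rnorm(60); a <- b + rnorm(60, 1, 1)
    compare_paired(b, a, n_monte_carlo = 400, seed = 6)$p_value < 0.05
  }, logical(1)))
  expect_gte(hits, 38) # ~100% power expected at n = 60, delta = 1 sd
})

test_that("one-sample t-test matches the closed form and its symmetries", {
  x <- c(21.2, 24.5, 19.8, 23.1, 22.4, 20.9)
  rep_ <- one_sample_test(x, 22)
  t_hand <- (mean(x) - 22) / (sd(x) / sqrt(6))
  expect_equal(unname(rep_$statistic["t"]), t_hand, tolerance = 1e-12)
  expect_equal(rep_$p_value, 2 * pt(-abs(t_hand), 5), tolerance = 1e-12)
  # testing against the sample's own mean gives t = 0, p = 1
  rep0 <- one_sample_test(x, mean(x))
  expect_equal(unname(rep0$statistic["t"]), 0)
  expect_equal(rep0$p_value, 1)
  expect_error(one_sample_test(rep(3, 5), 0), "constant")
  expect_error(one_sample_test(c(4), 0), "n >= 2")
})

test_that("stars follow the p-value thresholds", {
  expect_equal(significance_stars(c(0.2, 0.049, 0.009, 0.0009, NA)),
               c("", "*", "**", "***", ""))
})

test_that("Greenhouse-Geisser epsilon is 1 for two within levels", {
  set.seed(19)
  tab <- expand.grid(subject = paste0("s", 1:12), day = c("d1", "d2"))
  tab$group <- rep(rep(c("g1", "g2"), each = 6), 2)
  tab$value <- rnorm(nrow(tab))
  rep_ <- two_factor_report(tab, "day", "group")
  expect_equal(rep_$epsilon, 1)
  expect_equal(rep_$effects$p, rep_$effects$p_uncorrected, tolerance = 1e-12)
})

test_that("epsilon stays in its theoretical range and reacts to sphericity violations", {
  set.seed(23)
  k <- 4
  mk_tab <- function(value_fn) {
    subj <- paste0("s", 1:16)
    tab <- expand.grid(subject = subj, day = paste0("d", 1:k))
    tab$group <- rep(rep(c("g1", "g2"), each = 8), k)
    tab$value <- value_fn(tab)
    tab
  }
  # spherical: iid noise -> epsilon near 1
  t1 <- mk_tab(function(tab) rnorm(nrow(tab)))
  e1 <- two_factor_report(t1, "day", "group")$epsilon
  # strongly non-spherical: one dominant subject-by-day component
  t2 <- mk_tab(function(tab) {
    load <- as.integer(factor(tab$day))
    subj_slope <- rnorm(16)[as.integer(factor(tab$subject))]
    subj_slope * load * 3 + rnorm(nrow(tab), sd = 0.3)
  })
  e2 <- two_factor_report(t2, "day", "group")$epsilon
  for (e in c(e1, e2)) {
    expect_gte(e, 1 / (k - 1) - 1e-9)
    expect_lte(e, 1 + 1e-9)
  }
  expect_lt(e2, e1)
  expect_gt(e1, 0.7)
})

test_that("mixed-design ANOVA detects a built-in group-by-day interaction", {
  set.seed(29)
  subj <- paste0("s", 1:20)
  tab <- expand.grid(subject = subj, day = paste0("d", 1:3))
  tab$group <- rep(rep(c("treated", "control"), each = 10), 3)
  slope <- ifelse(tab$group == "treated", 2, 0)
  tab$value <- slope * as.integer(factor(tab$day)) + rnorm(nrow(tab), sd = 0.8)
  rep_ <- two_factor_report(tab, "day", "group", posthoc = "sidak")
  eff <- rep_$effects
  expect_lt(eff$p[eff$effect == "group:day"], 0.001)
  expect_lt(eff$p[eff$effect == "day"], 0.001)
  expect_s3_class(rep_$posthoc, "data.frame")
  # Sidak pairwise within 3 levels: 3 contrasts per group level
  expect_equal(nrow(rep_$posthoc), 6)
  # dunnett posthoc against day 1: 2 contrasts per group level
  repd <- two_factor_report(tab, "day", "group", posthoc = "dunnett",
                            ref_level = "d1")
  expect_equal(nrow(repd$posthoc), 4)
  expect_error(two_factor_report(tab[-1, ], "day", "group"), "complete")
})

test_that("the gated group comparison holds its nominal type-I error under the null", {
  set.seed(31)
  n_rep <- 400
  rejections <- sum(vapply(seq_len(n_rep), function(i) {
    tab <- data.frame(group = rep(c("a", "b", "c"), each = 10),
                      value = rnorm(30))
    compare_groups(tab, n_monte_carlo = 800, seed = 5)$p_value < 0.05
  }, logical(1)))
  # ~ +-3 sd binomial band around 0.05 at 400 replicates
  expect_gt(rejections / n_rep, 0.02)
  expect_lt(rejections / n_rep, 0.085)
})

test_that("stat reports serialize to valid JSON", {
  rep_ <- one_sample_test(c(1.2, 0.8, 1.1, 0.95), 1)
  path <- tempfile(fileext = ".json")
  write_stat_report(rep_, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$p_value, rep_$p_value)
  expect_equal(back$test, rep_$test)
})
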