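test_that("Tukey-fence exclusion matches hand computation and edge rules", {
  base <- tidyr::expand_grid(participant = sprintf("P%d", 1:5),
                             speed_cond = c("slow", "preferred", "fast"))
  base$group <- "PD"
  base$marp_deg <- rep(c(1, 2, 3, 4, 100), each = 3)
  base$dp_deg <- 5
  # hand: Q1 = 2, Q3 = 4 (type-7), IQR = 2, fences (-1, 7) -> only 100 out
  scr <- iqr_exclude(base, metrics = "marp_deg")
  expect_equal(unique(scr$excluded$participant), "P5")
  expect_equal(scr$excluded$fence_low[1], -1)
  expect_equal(scr$excluded$fence_high[1], 7)
  expect_false("P5" %in% scr$retained$participant)
  # removal applies to every speed condition
  expect_equal(nrow(scr$retained), 4 * 3)

  # all-equal values sit on the fence and are retained
  base$marp_deg <- 60
  scr2 <- iqr_exclude(base, metrics = "marp_deg")
  expect_equal(nrow(scr2$excluded), 0)
})

test_that("planted outliers in a synthetic cohort are exactly recovered", {
  set.seed(71)
  summ <- toy_summaries(n_per_group = 24)
  # bounded base values: the Tukey fences on a uniform sample cannot flag
  # anything, so exactly the planted extremes are excluded by construction
  summ$marp_deg <- runif(nrow(summ), 55, 65)
  summ$dp_deg <- runif(nrow(summ), 8, 12)
  planted <- c("P03", "P07", "P30", "P31", "P44")
  summ$marp_deg[summ$participant %in% planted[1:3] &
                  summ$speed_cond == "preferred"] <- 170
  summ$dp_deg[summ$participant %in% planted[4:5] &
                summ$speed_cond == "preferred"] <- 80
  scr <- iqr_exclude(summ)
  expect_setequal(unique(scr$excluded$participant), planted)
  expect_equal(dplyr::n_distinct(scr$retained$participant), 48 - 5)
})

test_that("two-way ANOVA F matches the brute-force oracle on a toy design", {
  set.seed(72)
  toy <- tidyr::expand_grid(group = c("A", "B"),
                            speed_cond = c("s", "p", "f"),
                            rep = 1:2)
  toy$y <- rnorm(12, 10, 2) + ifelse(toy$group == "A", 1, 0)
  fit <- two_way_anova(toy, "y")
  oracle <- oracle_f_tests(toy, "y", "group", "speed_cond")
  for (nm in names(oracle)) {
    expect_equal(fit$table$statistic[fit$table$term == nm], oracle[[nm]],
                 tolerance = 1e-10)
  }
})

test_that("ANOVA type-I error and power behave under simulation", {
  set.seed(73)
  null_p <- replicate(200, {
    d <- tidyr::expand_grid(group = c("A", "B"), speed_cond = c("s", "p", "f"),
                            rep = 1:8)
    d$y <- rnorm(nrow(d))
    two_way_anova(d, "y")$table$p_value[1]
  })
  # type-I rate near alpha (binomial 95% band for 200 replicates)
  expect_gt(mean(null_p < 0.05), 0.02)
  expect_lt(mean(null_p < 0.05), 0.09)

  set.seed(74)
  power <- mean(replicate(50, {
    d <- tidyr::expand_grid(group = c("A", "B"), speed_cond = c("s", "p", "f"),
                            rep = 1:20)
    d$y <- rnorm(nrow(d)) + ifelse(d$group == "A", 2, 0)  # 2 SD shift
    two_way_anova(d, "y")$table$p_value[1] < 0.05
  }))
  expect_gt(power, 0.95)
})

test_that("ANCOVA matches the oracle and respects the interaction gate", {
  set.seed(75)
  toy <- tidyr::expand_grid(group = c("A", "B"),
                            speed_cond = c("s", "p", "f"),
                            rep = 1:2)
  toy$speed <- rnorm(12, 1, 0.3)
  toy$y <- rnorm(12, 60, 5) + 3 * toy$speed
  fit <- two_way_ancova(toy, "y", covariate = "speed")
  oracle <- oracle_f_tests(toy, "y", "group", "speed_cond", covariate = "speed")
  for (nm in names(oracle)) {
    expect_equal(fit$table$statistic[fit$table$term == nm], oracle[[nm]],
                 tolerance = 1e-8)
  }
  # partial eta2 consistent with F and dfs: F = (eta2/(1-eta2)) * df2/df1
  tab <- fit$table
  expect_equal(tab$statistic,
               tab$partial_eta2 / (1 - tab$partial_eta2) * tab$df2 / tab$df1,
               tolerance = 1e-8)
})

test_that("a response that is exactly the covariate loads only the covariate", {
  set.seed(76)
  d <- tidyr::expand_grid(group = c("A", "B"), speed_cond = c("s", "p", "f"),
                          rep = 1:4)
  d$speed <- rnorm(nrow(d), 1, 0.3)
  d$y <- d$speed + rnorm(nrow(d), 0, 1e-3)
  fit <- two_way_ancova(d, "y", covariate = "speed")
  f_cov <- fit$table$statistic[fit$table$term == "speed"]
  f_others <- fit$table$statistic[fit$table$term != "speed"]
  expect_gt(f_cov / max(f_others), 1e3)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- toy_summaries()
  expect_error(two_way_anova(dplyr::filter(d, !(group == "PD" & speed_cond == "slow")),
                             "walking_speed_mps"), "PD x slow is empty")
  d2 <- d
  d2$walking_speed_mps <- ave(d2$walking_speed_mps,
                              interaction(d2$group, d2$speed_cond))
  d2$walking_speed_mps <- rep(1, nrow(d2))
  expect_error(two_way_ancova(d2, "marp_deg"), "zero within-cell variance")
})

test_that("pointwise SPM t equals the hand-computed two-sample t", {
  # per-subject constant waveforms: A = {0, 1}, B = {2, 3}
  ya <- rbind(rep(0, 101), rep(1, 101))
  yb <- rbind(rep(2, 101), rep(3, 101))
  expect_warning(res <- spm_ttest2(ya, yb, n_perm = 200, seed = 1),
                 "fewer than 3")
  sp2 <- (var(c(0, 1)) + var(c(2, 3))) / 2
  t_hand <- (0.5 - 2.5) / sqrt(sp2 * (1 / 2 + 1 / 2))
  expect_equal(res$t, rep(t_hand, 101), tolerance = 1e-12)
})

test_that("a planted mid-cycle effect is recovered as an overlapping cluster", {
  set.seed(77)
  n <- 12
  base <- function() t(replicate(n, 60 + rnorm(1, 0, 3) +
                                   2 * sin(2 * pi * (0:100) / 101 + runif(1)) +
                                   rnorm(101, 0, 0.5)))
  ya <- base()
  yb <- base()
  yb[, 41:61] <- yb[, 41:61] + 9  # 3 SD shift over nodes 40-60% of cycle
  res <- spm_ttest2(ya, yb, n_perm = 500, seed = 2)
  expect_gt(nrow(res$clusters), 0)
  hit <- any(res$clusters$start_pct <= 60 & res$clusters$end_pct >= 40)
  expect_true(hit)
})

test_that("the permutation threshold falls as alpha rises", {
  set.seed(78)
  ya <- matrix(rnorm(10 * 101), 10)
  yb <- matrix(rnorm(10 * 101), 10)
  ts <- sapply(c(0.01, 0.05, 0.2), function(a) {
    spm_ttest2(ya, yb, alpha = a, n_perm = 400, seed = 5)$t_star
  })
  expect_true(all(diff(ts) < 0))
})

test_that("null SPM keeps its family-wise error near alpha (smoke run)", {
  set.seed(79)
  fp <- replicate(60, {
    ya <- matrix(rnorm(8 * 101), 8)
    yb <- matrix(rnorm(8 * 101), 8)
    nrow(spm_ttest2(ya, yb, n_perm = 200)$clusters) > 0
  })
  expect_lt(mean(fp), 0.15)  # loose smoke bound; the calibrated run uses 500 reps
})
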