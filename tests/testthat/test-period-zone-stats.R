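# Period x zone summaries, the two-way (repeated measures) ANOVA, and
# hot-moment detection.

test_that("cell summaries compute n, mean, sd, sem and a type-7 p90", {
  df <- data.frame(period = "drought", zone = "slope", flux = c(1, 2, 3))
  s <- summarize_period_zone(df, "flux")
  expect_equal(s$n, 3)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$sem, 1 / sqrt(3))
  ten <- data.frame(period = "p", zone = "z", flux = 1:10)
  expect_equal(summarize_period_zone(ten, "flux")$p90, 9.1)
})

test_that("summaries are invariant to input row order and omit empty cells", {
  set.seed(3)
  df <- data.frame(period = sample(c("drought", "pre_drought"), 40, TRUE),
                   zone = sample(c("ridge", "valley"), 40, TRUE),
                   flux = rnorm(40))
  a <- summarize_period_zone(df, "flux")
  b <- summarize_period_zone(df[sample(nrow(df)), ], "flux")
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  df2 <- df[!(df$period == "drought" & df$zone == "ridge"), ]
  s2 <- summarize_period_zone(df2, "flux")
  expect_false(any(s2$period == "drought" & s2$zone == "ridge"))
})

test_that("synthetic fluxes at generator defaults reproduce the slope CO2 pre-drought mean", {
  ft <- generate_flux_table(catena_config(seed = 1), days_per_period = 38)
  s <- summarize_period_zone(ft[ft$gas == "CO2", ], "flux")
  cell <- s[s$period == "pre_drought" & s$zone == "slope", ]
  expect_lt(abs(cell$mean - 3.79), 2 * 2.92 / sqrt(cell$n))
})

test_that("single-level factors and empty design cells raise explicit errors", {
  df <- data.frame(period = "drought", zone = c("ridge", "valley"),
                   flux = rnorm(20), chamber_id = "c1")
  expect_error(anova_period_zone(df, "flux"), "single level")
  df2 <- expand.grid(period = c("a", "b"), zone = c("ridge", "valley"),
                     rep = 1:4, stringsAsFactors = FALSE)
  df2$flux <- rnorm(nrow(df2))
  df2 <- df2[!(df2$period == "b" & df2$zone == "valley"), ]
  expect_error(anova_period_zone(df2, "flux"), "period=b, zone=valley")
})

test_that("the log transform refuses sign-indefinite responses", {
  df <- expand.grid(period = c("a", "b"), zone = c("r", "v"), rep = 1:5,
                    stringsAsFactors = FALSE)
  df$flux <- rnorm(nrow(df))  # CH4-like, contains negatives
  expect_error(anova_period_zone(df, "flux", log_transform = TRUE),
               "positive")
})

test_that("strong period and zone effects are detected; shuffled labels lose them", {
  ft <- generate_flux_table(catena_config(seed = 17), days_per_period = 38)
  co2 <- ft[ft$gas == "CO2", ]
  a <- anova_period_zone(co2, "flux", repeated = TRUE,
                         log_transform = TRUE)
  p_period <- a$terms$p[a$terms$term == "period"]
  p_zone <- a$terms$p[a$terms$term == "zone"]
  expect_lt(p_period, 0.001)
  expect_lt(p_zone, 0.001)
  expect_true(all(a$tukey$p_adj >= 0 & a$tukey$p_adj <= 1))
  set.seed(99)
  co2$period <- sample(co2$period)
  a2 <- anova_period_zone(co2, "flux", repeated = TRUE,
                          log_transform = TRUE, tukey = FALSE)
  # shuffling breaks the within-chamber nesting, so the period term can
  # surface in more than one error stratum; none may stay significant
  p_shuf <- a2$terms$p[a2$terms$term == "period"]
  expect_gt(min(p_shuf, na.rm = TRUE), 0.001)
})

test_that("hot-moment thresholds match the per-period 90th percentile", {
  df <- data.frame(period = rep(c("a", "b"), each = 12),
                   flux = c(rep(2, 12), 1:12))
  hm <- hot_moments(df)
  expect_equal(hm$thresholds$threshold[hm$thresholds$period == "a"], 2)
  expect_equal(hm$thresholds$n_hot[hm$thresholds$period == "a"], 0)
  expect_equal(hm$thresholds$threshold[hm$thresholds$period == "b"],
               unname(quantile(1:12, 0.9, type = 7)))
  short <- data.frame(period = c(rep("a", 12), rep("b", 9)), flux = 1)
  expect_error(hot_moments(short), "fewer than 10")
})

test_that("the hot-moment mixture inflates the p90/p50 ratio", {
  cfg <- catena_config(seed = 23)
  fr_on <- default_flux_regimes()
  fr_off <- fr_on; fr_off$hot_weight <- 0
  q <- vapply(list(fr_on, fr_off), function(fr) {
    ft <- generate_flux_table(cfg, fr, days_per_period = 300, seed = 5)
    x <- ft$flux[ft$gas == "CH4" & ft$zone == "valley" &
                   ft$period == "pre_drought"]
    c(p90 = unname(quantile(x, 0.9, type = 7)),
      p50 = unname(quantile(x, 0.5, type = 7)))
  }, numeric(2))
  # paired on the same seed: the bulk draws coincide, only the
  # hot-moment replacements differ
  expect_gt(q["p90", 1] / max(q["p50", 1], 1),
            q["p90", 2] / max(q["p50", 2], 1))
})
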