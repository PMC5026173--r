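test_that("Bland-Altman bias and limits of agreement follow the convention", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  ba <- bland_altman(c(11, 9), c(10, 10))  # raw differences +1, -1
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)

  # translation equivariance on the raw scale
  a <- c(1, 3, 7, 2); b <- c(2, 2, 5, 1)
  expect_equal(bland_altman(a + 4.2, b)$bias, bland_altman(a, b)$bias + 4.2)

  # percent-of-mean scale
  bp <- bland_altman(c(110), c(90), scale = "percent_of_mean") |> try(silent = TRUE)
  expect_s3_class(bp, "try-error")  # a single pair is rejected
  bp2 <- bland_altman(c(110, 100), c(90, 100), scale = "percent_of_mean")
  expect_equal(bp2$differences, c(20, 0))

  expect_error(bland_altman(1, 2), "2 complete pairs")
})

test_that("two-sample t handles standard and degenerate inputs", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  shift <- two_sample_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shift$p_value, 0.01)

  expect_equal(two_sample_t(c(0, 1), c(0, 1))$t, 0)

  # zero variance in both groups
  expect_equal(two_sample_t(c(5, 5), c(5, 5))$p_value, 1)
  expect_equal(two_sample_t(c(5, 5), c(6, 6))$p_value, 0)

  # agrees with stats::t.test when non-degenerate
  a <- c(1.2, 0.8, 1.4, 0.9); b <- c(1.0, 1.5, 1.7)
  expect_equal(two_sample_t(a, b, "welch")$p_value,
               stats::t.test(a, b)$p.value)
  expect_equal(two_sample_t(a, b, "student")$p_value,
               stats::t.test(a, b, var.equal = TRUE)$p.value)
})

make_gs_data <- function(effect = 0, seed = 1, n_per_group = 3,
                         doses = c(10, 35, 85, 160, 260, 460, 860),
                         sd = 0.02) {
  set.seed(seed)
  out <- expand.grid(subject = seq_len(2 * n_per_group), dose = doses)
  out$group <- ifelse(out$subject <= n_per_group, "control", "OVA")
  out$gs <- 1 + stats::rnorm(nrow(out), 0, sd) -
    ifelse(out$group == "OVA", effect * out$dose / max(doses), 0)
  out
}

test_that("two-way ANOVA partitions sums of squares on balanced designs", {
  data <- make_gs_data(effect = 0.3, seed = 3)
  cmp <- compare_dose_response(data)
  expect_true(cmp$balanced)
  ss <- cmp$anova$sum_sq
  total <- sum((data$gs - mean(data$gs))^2)
  expect_equal(sum(ss), total, tolerance = 1e-10)
  expect_setequal(cmp$anova$term,
                  c("group", "dose_f", "group:dose_f", "Residuals"))
})

test_that("identical groups show no group effect", {
  data <- make_gs_data(effect = 0, seed = 5)
  cmp <- compare_dose_response(data)
  p_group <- cmp$anova$p[cmp$anova$term == "group"]
  expect_gt(p_group, 0.05)
  expect_false(any(cmp$contrasts$significant))
})

test_that("simulated phenotype contrast is detected at late doses", {
  doses <- c(10, 35, 85, 160, 260, 460, 860)
  rows <- list()
  for (g in c("control", "OVA")) for (s in 1:3) {
    sp <- if (g == "control") control_phantom_spec(seed = s)
          else ova_phantom_spec(seed = 10 + s)
    ser <- generate_challenge_series(sp, seed = 100 * s + (g == "OVA"))
    gs <- global_signal_curve(ser)
    d <- gs[gs$role == "dose", ]
    rows[[length(rows) + 1]] <- data.frame(subject = paste0(g, s), group = g,
                                           dose = d$cumulative_dose_ug, gs = d$gs)
  }
  cmp <- compare_dose_response(do.call(rbind, rows))
  expect_lt(cmp$anova$p[cmp$anova$term == "group"], 0.05)
  late <- cmp$contrasts[cmp$contrasts$dose >= 460, ]
  expect_true(all(late$significant))
})

test_that("Bonferroni adjustment multiplies by the number of dose levels", {
  data <- make_gs_data(effect = 0.15, seed = 7)
  cmp <- compare_dose_response(data)
  expect_equal(cmp$contrasts$p_adj,
               pmin(1, cmp$contrasts$p_raw * 7))
  expect_true(all(cmp$contrasts$p_adj >= cmp$contrasts$p_raw, na.rm = TRUE))

  # a raw p of 0.02 over 7 dose levels is no longer significant
  expect_equal(min(1, 0.02 * 7), 0.14)
  expect_false(0.02 * 7 < 0.05)
})

test_that("mismatched dose grids are rejected", {
  data <- make_gs_data(effect = 0, seed = 9)
  data <- data[!(data$group == "OVA" & data$dose == 860), ]
  expect_error(compare_dose_response(data), "mismatched dose grids")
})
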