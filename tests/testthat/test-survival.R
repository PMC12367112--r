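test_that("Kaplan-Meier estimator matches hand product-limit values", {
  # all censored: survival stays at 1
  km0 <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_equal(km_survival(km0, c(1, 5, 100)), c(1, 1, 1))

  # single subject dying at t = 5
  km1 <- km_curve(5, 1)
  expect_equal(km_survival(km1, c(4.99, 5, 6)), c(1, 0, 0))

  # n = 3: events at 1 and 2, censor at 1.5. After the censor only one
  # subject remains at risk at t = 2, so the product limit drops to 0.
  km3 <- km_curve(c(1, 1.5, 2), c(1, 0, 1))
  expect_equal(km_survival(km3, c(0, 1, 1.9, 2)), c(1, 2/3, 2/3, 0))

  # censoring after the second event leaves 2 at risk: S = 2/3 then 1/3
  km3b <- km_curve(c(1, 2.5, 2), c(1, 0, 1))
  expect_equal(km_survival(km3b, c(1, 2)), c(2/3, 1/3))

  expect_error(km_curve(numeric(0), numeric(0)), "at least one")
  expect_error(km_curve(c(1, -1), c(1, 1)), "> 0")
})

test_that("log-rank agrees with the hand O/E/V tabulation", {
  # symmetric groups: chi-squared exactly zero
  lr0 <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                      rep(c("A", "B"), each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)

  # 6-subject fixture vs hand tabulation
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 1, 1, 1, 0)
  grp <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(time, event, grp)
  or <- logrank_oracle(time, event, grp)
  expect_equal(lr$chisq, or$chisq, tolerance = 1e-10)
  expect_equal(lr$p_value, or$p, tolerance = 1e-10)

  # label swap leaves the statistic unchanged
  lr_sw <- logrank_test(time, event, rev(grp))
  expect_equal(lr_sw$chisq, lr$chisq, tolerance = 1e-12)

  expect_error(logrank_test(1:4, rep(0, 4), c(1, 1, 2, 2)), "events")
  expect_error(logrank_test(1:4, rep(1, 4), rep(1, 4)), "two")
})

test_that("min-p cutpoint equals the exhaustive-scan oracle", {
  # constructed fixture: subjects with values >= 6 all die first
  values <- 1:10
  time <- c(10, 11, 12, 13, 14, 1, 2, 3, 4, 5)
  event <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  cp <- optimal_cutpoint(time, event, values)
  expect_gt(cp$cutpoint, 5)
  expect_lt(cp$cutpoint, 6)
  or <- cutpoint_oracle(time, event, values)
  expect_equal(cp$cutpoint, or$cutpoint)
  expect_equal(cp$p_value, or$p, tolerance = 1e-9)

  # random datasets, n up to 100
  with_seed_local(23, {
    for (rep in 1:10) {
      n <- sample(20:100, 1)
      v <- round(runif(n), 2)
      d <- simulate_survival(v, survival_sim_config(beta = -2,
                                                    seed = rep))
      cp <- optimal_cutpoint(d$time, d$event, v)
      or <- cutpoint_oracle(d$time, d$event, v)
      expect_equal(cp$cutpoint, or$cutpoint)
      expect_equal(cp$p_value, or$p, tolerance = 1e-9)
    }
  })
})

test_that("minprop constrains candidates and order does not matter", {
  values <- 1:10
  time <- c(5, 6, 7, 8, 9, 1, 2, 3, 4, 10)
  event <- c(1, 0, 1, 0, 1, 1, 1, 1, 0, 0)
  cp50 <- optimal_cutpoint(time, event, values, minprop = 0.5)
  expect_equal(nrow(cp50$candidates), 1L)   # only the median split
  expect_equal(cp50$cutpoint, 5.5)
  expect_equal(cp50$n_low, 5L)

  perm <- with_seed_local(3, sample(10))
  cp_a <- optimal_cutpoint(time, event, values)
  cp_b <- optimal_cutpoint(time[perm], event[perm], values[perm])
  expect_equal(cp_a$cutpoint, cp_b$cutpoint)
  expect_equal(cp_a$p_value, cp_b$p_value)

  expect_error(optimal_cutpoint(time, event, rep(1, 10)), "distinct")
  expect_error(optimal_cutpoint(time[1:3], event[1:3], 1:3,
                                minprop = 0.5), "admissible")
})

test_that("corrected cutpoint p-value is conservative and bounded", {
  with_seed_local(29, {
    v <- runif(60)
    d <- simulate_survival(v, survival_sim_config(beta = -2, seed = 6))
    cp <- optimal_cutpoint(d$time, d$event, v, corrected = TRUE)
    expect_gte(cp$p_corrected, cp$p_value)
    expect_lte(cp$p_corrected, 1)
  })
})

test_that("naive min-p selection is anticonservative under the null", {
  rej <- vapply(1:200, function(r) {
    v <- with_seed_local(40000 + r, runif(50))
    d <- simulate_survival(v, survival_sim_config(beta = 0, seed = r))
    p <- tryCatch(optimal_cutpoint(d$time, d$event, v)$p_value,
                  error = function(e) NA_real_)
    !is.na(p) && p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.10)
})

test_that("Cox fit is scale-equivariant and flags problems", {
  with_seed_local(37, {
    z <- runif(120)
    d <- simulate_survival(z, survival_sim_config(beta = -2, seed = 12))
    d$z <- z
    d$z10 <- 10 * z
    f1 <- cox_fit(d, "z")
    f10 <- cox_fit(d, "z10")
    expect_equal(f10$table$beta, f1$table$beta / 10, tolerance = 1e-6)
    expect_equal(f10$table$hr^10, f1$table$hr, tolerance = 1e-4)
    expect_true(f1$converged)
    expect_true(f1$table$ci_low < f1$table$hr &
                  f1$table$hr < f1$table$ci_high)
    expect_gt(f1$table$hr, 0)

    # monotone-likelihood separation is flagged, not silently reported
    sep <- data.frame(time = c(1, 2, 3, 10, 11, 12),
                      event = c(1, 1, 1, 1, 1, 1),
                      x = c(1, 1, 1, 0, 0, 0))
    fs <- cox_fit(sep, "x")
    expect_true(fs$separation)
  })
  expect_error(cox_fit(data.frame(time = 1:3, event = 0, x = 1:3), "x"),
               "event")
})

test_that("Cox recovers null and two-fold hazards in simulation", {
  null_ok <- vapply(1:25, function(r) {
    z <- with_seed_local(50000 + r, runif(300))
    d <- simulate_survival(z, survival_sim_config(beta = 0, seed = r))
    d$z <- z
    f <- cox_fit(d, "z")
    abs(f$table$beta) < 0.5 && f$table$ci_low < 1 && 1 < f$table$ci_high
  }, TRUE)
  expect_gte(mean(null_ok), 0.9)

  hr_ok <- vapply(1:25, function(r) {
    x <- rep(c(0, 1), 150)
    d <- simulate_survival(x, survival_sim_config(beta = log(2),
                                                  seed = 100 + r))
    d$x <- x
    f <- cox_fit(d, "x")
    f$table$hr > 1.5 && f$table$hr < 2.7
  }, TRUE)
  expect_gte(mean(hr_ok), 0.9)
})

test_that("multivariable Cox adjusts for confounders jointly", {
  with_seed_local(41, {
    n <- 300
    z <- runif(n)
    age <- rnorm(n, 65, 10)
    d <- simulate_survival(z, survival_sim_config(beta = -2, seed = 15))
    d$z <- z; d$age <- age; d$sex <- rbinom(n, 1, 0.5)
    f <- cox_fit(d, c("z", "age", "sex"))
    expect_equal(nrow(f$table), 3L)
    expect_setequal(f$table$term, c("z", "age", "sex"))
    expect_lt(f$table$hr[f$table$term == "z"], 1)
  })
})

test_that("Spearman correlation uses average ranks and the t approximation", {
  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_cor(1:8, -(1:8))$rho, -1)
  expect_equal(spearman_cor(1:4, c(1, 3, 2, 4))$rho, 0.8)
  r <- spearman_cor(c(1, 2, 2, 3, 5), c(2, 1, 4, 4, 6))
  ref <- suppressWarnings(stats::cor.test(c(1, 2, 2, 3, 5),
                                          c(2, 1, 4, 4, 6),
                                          method = "spearman"))
  expect_equal(r$rho, unname(ref$estimate))
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})
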