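test_that("the design defaults give 28 per group and 84 in total", {
  n <- sample_size()
  expect_equal(n$n_per_group, 28L)
  expect_equal(n$n_total, 84L)
  expect_equal(n$n_unadjusted, 23)
  # without dropout inflation the analytic n rounds to 23 per group
  expect_equal(sample_size(dropout = 0)$n_per_group, 23L)
  # ceiling-after-inflation alternative
  expect_equal(sample_size(rounding = "ceiling")$n_per_group, 29L)
  expect_error(sample_size(delta = 0), "nonzero")
})

test_that("sample size scales as expected in delta, sd, power and dropout", {
  expect_true(sample_size(delta = 100)$n_per_group < sample_size(delta = 50)$n_per_group)
  # quartering before rounding: n(delta) ~ 1/delta^2
  n1 <- 2 * ((qnorm(0.975) + qnorm(0.8)) * 60 / 50)^2
  n2 <- 2 * ((qnorm(0.975) + qnorm(0.8)) * 60 / 100)^2
  expect_equal(n1 / n2, 4)
  expect_gte(sample_size(sd = 80)$n_per_group, sample_size(sd = 60)$n_per_group)
  expect_gte(sample_size(power = 0.9)$n_per_group, sample_size(power = 0.8)$n_per_group)
  expect_gte(sample_size(dropout = 0.3)$n_per_group, sample_size(dropout = 0.2)$n_per_group)
})

test_that("empirical power is calibrated at the null and saturates at separation", {
  expect_equal(empirical_power(23, delta = 0, reps = 4000, seed = 2), 0.05,
               tolerance = 0.25)
  expect_equal(empirical_power(23, delta = 50, sd = 0.1, reps = 500, seed = 2), 1)
  expect_error(empirical_power(1), ">= 2")
})

test_that("the vectorized t-test matches stats::t.test trial by trial", {
  n <- 12
  reps <- 50
  withr::with_seed(77, {
    x <- matrix(rnorm(reps * n, 50, 60), nrow = reps)
    y <- matrix(rnorm(reps * n, 0, 60), nrow = reps)
  })
  ref <- vapply(seq_len(reps), function(i) {
    stats::t.test(x[i, ], y[i, ], var.equal = TRUE)$p.value < 0.05
  }, logical(1))
  # same draws through the package's generator path
  got <- empirical_power(n, delta = 50, sd = 60, reps = reps, seed = 77)
  expect_equal(got, mean(ref))
})

test_that("Monte-Carlo power agrees with the closed-form t-test power", {
  analytic <- stats::power.t.test(n = 23, delta = 50, sd = 60,
                                  sig.level = 0.05)$power
  mc <- empirical_power(23, delta = 50, sd = 60, reps = 10000, seed = 3)
  expect_lt(abs(mc - analytic), 0.015)
})

test_that("nine patients in one stratum randomize exactly 3:3:3", {
  roster <- tibble::tibble(patient_id = letters[1:9], site = "S1",
                           fev1_pct_pred = 60, cat = 15)
  asg <- randomize(roster, seed = 1)
  expect_equal(as.vector(table(asg$arm)), rep(3L, 3))
  expect_identical(asg, randomize(roster, seed = 1))
  expect_false(identical(asg$arm, randomize(roster, seed = 2)$arm))
  expect_error(randomize(dplyr::select(roster, -cat)), "cat")
  expect_error(randomize(dplyr::mutate(roster, cat = NA)), "NA")
})

test_that("arm counts within every site-stratum cell differ by at most one", {
  roster <- make_roster(85, n_sites = 4, seed = 10)
  asg <- randomize(roster, seed = 20)
  counts <- asg |>
    dplyr::count(site, stratum, arm) |>
    tidyr::complete(tidyr::nesting(site, stratum),
                    arm = unique(asg$arm), fill = list(n = 0))
  spread <- counts |>
    dplyr::group_by(site, stratum) |>
    dplyr::summarise(d = max(n) - min(n), .groups = "drop")
  expect_true(all(spread$d <= 1))
  expect_equal(nrow(asg), 85L)
})

test_that("marginal arm frequencies approach 1:1:1 over repeated runs", {
  roster <- make_roster(85, seed = 30)
  tallies <- c(fixed = 0, `fixed-interactive` = 0, control = 0)
  for (s in 1:100) {
    asg <- randomize(roster, seed = s)
    tallies <- tallies + table(factor(asg$arm, levels = names(tallies)))
  }
  gof <- stats::chisq.test(tallies)
  expect_gt(gof$p.value, 0.01)
})

test_that("baseline ANOVA reproduces a hand-computed F", {
  d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
  fit <- baseline_anova(d, "y", "g")
  td <- tidy(fit)
  expect_equal(td$statistic, 13.5)
  expect_equal(td$df, 1)
  expect_equal(td$df_resid, 4)
  expect_equal(glance(fit)$n, 6L)
})

test_that("degenerate one-way layouts behave sensibly", {
  same <- data.frame(g = rep(c("a", "b", "c"), each = 4), y = rep(1:4, 3))
  fit <- baseline_anova(same, "y", "g")
  expect_equal(tidy(fit)$statistic, 0)
  expect_equal(tidy(fit)$p.value, 1)
  uneq <- withr::with_seed(4, data.frame(
    g = rep(c("a", "b"), each = 50),
    y = c(rnorm(50, 10, 1), rnorm(50, 10, 5))
  ))
  expect_lt(tidy(baseline_anova(uneq, "y", "g"))$statistic, 5)
  expect_error(baseline_anova(data.frame(g = "a", y = 1), "y", "g"), "two groups")
  two <- data.frame(g = c("a", "a", "b"), y = 1:3)
  expect_error(baseline_anova(two, "y", "g"), "two observations")
})

test_that("one-way ANOVA matches the sums-of-squares oracle to 1e-10", {
  withr::with_seed(55, {
    for (rep in 1:50) {
      k <- sample(2:5, 1)
      n <- sample(3:12, k, replace = TRUE)
      d <- data.frame(g = rep(letters[1:k], n),
                      y = rnorm(sum(n), mean = rep(runif(k, 0, 5), n)))
      got <- tidy(baseline_anova(d, "y", "g"))
      orc <- oracle_oneway_F(d$y, d$g)
      expect_equal(got$statistic, orc$F, tolerance = 1e-10)
      expect_equal(got$p.value, orc$p, tolerance = 1e-10)
      expect_equal(got$df, orc$df1)
      expect_equal(got$df_resid, orc$df2)
    }
  })
})

test_that("constant outcomes give a zero visit effect", {
  oc <- tidyr::expand_grid(patient_id = sprintf("p%02d", 1:12),
                           visit = c("V1", "V2", "V3")) |>
    dplyr::mutate(arm = rep(rep(c("a", "b", "c"), each = 3), 4)[1:36],
                  cat = 10)
  # add subject-level variation but no visit change
  oc$cat <- oc$cat + as.integer(factor(oc$patient_id))
  fit <- rm_anova(oc, "cat")
  td <- tidy(fit)
  # no within-subject change at all: the visit sum of squares vanishes
  expect_lt(td$sumsq[td$term == "visit"], 1e-20)
  expect_equal(unique(fit$changes$mean_change), 0)
})

test_that("rm_anova keeps complete cases only and needs 2 per arm", {
  oc <- sim_null_outcomes(n_per_arm = 5)
  oc$cat[1] <- NA # drops patient fixed-01 entirely
  withr::with_seed(1, fit <- rm_anova(oc, "cat"))
  expect_equal(fit$n_complete, 14L)
  one <- dplyr::filter(oc, arm != "control" | patient_id == "control-01")
  expect_error(rm_anova(one, "cat"), "complete cases per arm")
})

test_that("an injected V2 CAT drop yields an interaction beyond the permutation null", {
  withr::with_seed(202, {
    oc <- sim_null_outcomes(n_per_arm = 12)
    # intervention arms improve by 5 CAT points at V2 and V3
    hit <- oc$arm != "control" & oc$visit != "V1"
    oc$cat[hit] <- oc$cat[hit] - 5
    f_obs <- tidy(rm_anova(oc, "cat"))
    f_obs <- f_obs$statistic[f_obs$term == "arm:visit"]
    # permutation oracle: shuffle arm labels across patients
    ids <- unique(oc$patient_id)
    arm_of <- oc$arm[match(ids, oc$patient_id)]
    f_null <- replicate(200, {
      perm <- setNames(sample(arm_of), ids)
      oc2 <- dplyr::mutate(oc, arm = perm[patient_id])
      td <- tidy(rm_anova(oc2, "cat"))
      td$statistic[td$term == "arm:visit"]
    })
    expect_gt(f_obs, stats::quantile(f_null, 0.95))
  })
})
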