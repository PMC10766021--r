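test_that("Kaplan-Meier estimates match hand product-limit computations", {
  # all censored: constant 1
  km <- kaplan_meier(c(3, 7, 12), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  # times 1,2,3 all events: 2/3, 1/3, 0
  km2 <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km2$surv, c(1, 2 / 3, 1 / 3, 0))
  # one event at 5 among two patients, other censored at 10
  km3 <- kaplan_meier(c(5, 10), c(1, 0))
  expect_equal(km3$surv[km3$time == 5], 0.5)
  # non-increasing, starts at 1, order-invariant
  withr::with_seed(2, {
    t <- rexp(40, 0.05); e <- rbinom(40, 1, 0.7)
    a <- kaplan_meier(t, e)
    b <- kaplan_meier(rev(t), rev(e))
    expect_equal(a, b)
    expect_true(all(diff(a$surv) <= 0))
    expect_equal(a$surv[1], 1)
  })
})

test_that("log-rank test matches per-event-time O-E arithmetic", {
  # identical groups: statistic 0, p 1
  t <- c(2, 4, 6, 8); e <- c(1, 1, 0, 1)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  # no events at all: defined as statistic 0, p 1
  lr0 <- logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0), c(1, 1, 2, 2))
  expect_equal(lr0$p, 1)

  # fixed small table: independent per-event-time hypergeometric arithmetic
  time <- c(1, 3, 5, 7, 2, 4, 6, 8)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  grp <- rep(c(0, 1), each = 4)
  oe <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    d <- sum(event == 1 & time == tt)
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d1 <- sum(event == 1 & time == tt & grp == 1)
    oe <- oe + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  want_stat <- oe^2 / v
  got <- logrank_test(time, event, grp)
  expect_equal(got$statistic, want_stat, tolerance = 1e-10)
  expect_equal(got$p, pchisq(want_stat, 1, lower.tail = FALSE))
  # symmetry under group swap
  expect_equal(logrank_test(time, event, 1 - grp)$statistic, got$statistic)
})

test_that("log-rank type-I error is near nominal on null simulations", {
  reject <- vapply(1:400, function(s) {
    withr::with_seed(1000 + s, {
      t <- rexp(60, 0.02); e <- rbinom(60, 1, 0.8)
      g <- rep(c(0, 1), 30)
      logrank_test(t, e, g)$p < 0.05
    })
  }, logical(1))
  expect_lt(abs(mean(reject) - 0.05), 0.03)
})

test_that("concordance matches exhaustive pair enumeration", {
  # perfect anti-ordering of marker and all-event times
  t <- c(1, 2, 3, 4, 5); m <- c(5, 4, 3, 2, 1)
  expect_equal(concordance_index(t, rep(1, 5), m), 1)
  expect_equal(concordance_index(t, rep(1, 5), rep(0.3, 5)), 0.5)
  withr::with_seed(17, {
    for (rep in 1:30) {
      n <- sample(4:10, 1)
      t <- round(rexp(n, 0.1), 4)   # continuous, no ties
      e <- rbinom(n, 1, 0.7)
      m <- runif(n)
      want <- oracle_concordance(t, e, m)
      got <- concordance_index(t, e, m)
      if (is.na(want)) expect_true(is.na(got))
      else {
        expect_equal(got, want, tolerance = 1e-12)
        # complement property absent marker ties
        expect_equal(concordance_index(t, e, -m), 1 - want, tolerance = 1e-12)
      }
    }
  })
})

test_that("cutoff search minimizes log-rank p on a feasible decile grid", {
  withr::with_seed(23, {
    n <- 120
    marker <- c(runif(n / 2, 0, 0.3), runif(n / 2, 0.7, 1))
    high <- marker > 0.5
    t <- rexp(n, ifelse(high, 0.08, 0.02))
    e <- rep(1, n)
    sel <- find_optimal_cutoff(t, e, marker)
    expect_gt(sel$cutoff, 0.3)
    expect_lt(sel$cutoff, 0.7)
    # brute force over an explicit candidate grid
    cand <- c(0.1, 0.25, 0.5, 0.75, 0.9)
    sel2 <- find_optimal_cutoff(t, e, marker, candidates = cand)
    ps <- vapply(cand, function(ct) {
      grp <- marker > ct
      if (min(sum(grp), sum(!grp)) < ceiling(0.1 * n)) return(NA_real_)
      logrank_test(t, e, grp)$p
    }, numeric(1))
    expect_equal(sel2$cutoff, cand[which.min(ps)])
    # infeasible constraint errors
    expect_error(find_optimal_cutoff(t, e, marker, candidates = c(-1, 2)),
                 class = "ki67cl_error_no_feasible_cutoff")
  })
})

test_that("the combined-statistic arithmetic follows the protocol", {
  per <- data.frame(fold = 1:3, cutoff = c(0.3, 0.4, 0.5),
                    p = c(0.01, 0.02, 0.03), c_index = c(0.7, 0.7, 0.7))
  cv <- summarize_cv(per)
  expect_equal(cv$combined_p, 0.04)
  expect_equal(unname(cv$combined_c["mean"]), 0.7)
  expect_equal(unname(cv$combined_c["sd"]), 0)
  expect_equal(cv$chosen_cutoff, 0.4)
  # cap at 1
  per$p <- c(0.6, 0.9, 0.8)
  expect_equal(summarize_cv(per)$combined_p, 1)
  # never below the median fold p
  withr::with_seed(5, for (rep in 1:20) {
    per$p <- runif(3)
    cv <- summarize_cv(per)
    expect_gte(cv$combined_p, median(per$p))
    expect_lte(cv$combined_p, 1)
  })
})

test_that("cross-validation is seeded, event-stratified and evaluated held-out", {
  withr::with_seed(41, {
    scores <- runif(240)
    co <- simulate_cohort(scores, cohort_sim_config(
      n_patients = 240, hazard_ratio_high = 3, seed = 11))
    cv1 <- cross_validate_marker(co, k = 3, seed = 2)
    cv2 <- cross_validate_marker(co, k = 3, seed = 2)
    expect_identical(cv1, cv2)
    expect_equal(nrow(cv1$per_fold), 3L)
    expect_true(all(cv1$per_fold$p >= 0 & cv1$per_fold$p <= 1))
    # folds partition records and each contains events
    fold <- make_folds(co$event, k = 3, seed = 2)
    expect_equal(sort(unique(fold)), 1:3)
    expect_true(all(tapply(co$event, fold, sum) > 0))
  })
})

test_that("Cox fits match the closed-form one-event partial likelihood", {
  # records (1, event, x=1), (2, event, x=0), (3, censored, x=1):
  # d logPL/db = 0 at exp(b) = 1/sqrt(2)
  rec <- survival_table(data.frame(patient_id = c("a", "b", "c"),
                                   time = c(1, 2, 3), event = c(1, 1, 0),
                                   marker = 0, x = c(1, 0, 1)))
  fit <- cox_fit(rec, "x")
  expect_equal(fit$coef[fit$term == "x"], -log(2) / 2, tolerance = 1e-6)
  expect_equal(fit$hr, exp(fit$coef))
  expect_true(fit$lower <= fit$hr && fit$hr <= fit$upper)

  # constant covariate dropped with HR 1 by convention
  rec$const <- 5
  fit2 <- cox_fit(rec, c("x", "const"), model_type = "MULTIVARIATE")
  expect_equal(fit2$hr[fit2$term == "const"], 1)

  # parameter recovery on a simulated proportional-hazards cohort
  withr::with_seed(19, {
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.01 * 2^x)
    cens <- pmin(rexp(n, 0.004), 150)
    rec3 <- survival_table(data.frame(
      patient_id = as.character(1:n), time = pmin(t, cens),
      event = as.integer(t <= cens), marker = x, x = x))
    fit3 <- cox_fit(rec3, "x")
    expect_gt(fit3$hr, 1.8)
    expect_lt(fit3$hr, 2.2)
  })
  expect_error(cox_fit(survival_table(data.frame(
    patient_id = "a", time = 1, event = 0, marker = 0, x = 1)), "x"),
    class = "ki67cl_error_cox")
})

test_that("fixed-cutoff stratification reports groups, p and curves", {
  withr::with_seed(29, {
    scores <- runif(200)
    co <- simulate_cohort(scores, cohort_sim_config(
      n_patients = 200, hazard_ratio_high = 3, seed = 3))
    st <- stratify_at_cutoff(co, 0.5)
    expect_equal(levels(st$group), c("low", "high"))
    expect_true(st$logrank_p < 0.05)
    expect_true(all(diff(st$km_curves$low$surv) <= 0))
    expect_error(stratify_at_cutoff(co, 2), class = "ki67cl_error_stratification")
  })
})

test_that("survival tables validate and read from CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,time_months,event,marker,grade",
               "P1,12.5,1,0.4,2", "P2,60,0,0.2,1"), path)
  st <- read_survival(path)
  expect_s3_class(st, "survival_table")
  expect_equal(st$time, c(12.5, 60))
  expect_equal(st$grade, c(2, 1))
  writeLines(c("patient_id,time_months,event,marker", "P1,-3,1,0.4"), path)
  expect_error(read_survival(path), class = "ki67cl_error_survival_table")
  writeLines(c("patient_id,event,marker", "P1,1,0.4"), path)
  expect_error(read_survival(path), class = "ki67cl_error_missing_column")
})
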