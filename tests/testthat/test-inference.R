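test_that("Pearson chi-square matches the defining formula and handles degeneracy", {
  m <- rbind(c(5, 5), c(5, 5))
  expect_equal(pearson_chi_square(m)$statistic, chisq_oracle(m))
  expect_equal(pearson_chi_square(m)$statistic, 0)
  expect_equal(pearson_chi_square(m)$p_value, 1)
  # proportional rows give a zero statistic
  expect_equal(pearson_chi_square(rbind(c(10, 20), c(30, 60)))$statistic, 0)
  withr::with_seed(41, {
    for (i in 1:20) {
      m <- matrix(rpois(6, 12) + 1, nrow = 3)
      expect_equal(pearson_chi_square(m)$statistic, chisq_oracle(m))
      expect_equal(pearson_chi_square(m)$df, 2)
    }
  })
  expect_error(pearson_chi_square(rbind(c(0, 0), c(1, 2))), "degenerate")
  expect_error(pearson_chi_square(rbind(c(1.5, 2), c(1, 2))), "integer")
})

test_that("the published blood-by-breed contrast reproduces under the uncorrected test", {
  m <- rbind(finnhorse = c(16, 62), standardbred = c(15, 136))
  res <- pearson_chi_square(m)
  expect_equal(round(res$p_value, 2), 0.03)
})

test_that("two-sided Fisher p equals exhaustive enumeration on small tables", {
  expect_equal(fisher_exact(rbind(c(1, 1), c(1, 1))), 1)
  withr::with_seed(13, {
    for (i in 1:40) {
      repeat {
        m <- matrix(rpois(4, 2.5), nrow = 2)
        if (all(rowSums(m) > 0) && sum(m) <= 20 && sum(m) > 0) break
      }
      expect_equal(fisher_exact(m), fisher_oracle_2x2(m), tolerance = 1e-10)
    }
  })
  expect_error(fisher_exact(rbind(c(0, 0), c(3, 4))), "all-zero row")
})

test_that("the bar-lesion jointedness contrast is extreme under Fisher's exact test", {
  m <- rbind(unjointed = c(34, 17), jointed = c(24, 146))
  expect_lt(fisher_exact(m), 0.001)
  # Monte-Carlo branch on a large r x 2 table agrees with the exact p
  big <- rbind(c(40, 60), c(55, 45), c(30, 70))
  exact <- stats::fisher.test(big)$p.value
  mc <- fisher_exact(big, exact_limit = 50, b = 2e4)
  expect_lt(abs(mc - exact), 0.02)
  # Monte-Carlo draw does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(fisher_exact(big, exact_limit = 50, b = 1e3))
  expect_identical(rnorm(1), before)
})

test_that("the crude odds ratio matches the closed form and the logistic slope", {
  m <- rbind(c(30, 8), c(49, 49))
  res <- odds_ratio_2x2(m)
  expect_equal(res$or, 3.75)
  expect_false(res$corrected)
  # equivalence with a single-predictor logistic fit
  ex <- exams_from_2x2(m)
  fit <- fit_logistic(ex, "bit_type")
  slope_or <- fit$coef$or[fit$coef$term == "bit_type"]
  expect_equal(slope_or, res$or, tolerance = 1e-9)
  expect_equal(odds_ratio_2x2(rbind(c(1, 1), c(1, 1)))$or, 1)
  zero <- odds_ratio_2x2(rbind(c(5, 0), c(3, 4)))
  expect_true(zero$corrected)
  expect_true(all(is.finite(zero$ci)))
  withr::with_seed(19, {
    for (i in 1:10) {
      m <- matrix(rpois(4, 10) + 1, nrow = 2)
      wo <- odds_ratio_2x2(m)
      ex <- exams_from_2x2(m)
      fit <- fit_logistic(ex, "bit_type")
      r <- fit$coef[fit$coef$term == "bit_type", ]
      expect_equal(r$or, wo$or, tolerance = 1e-7)
      expect_equal(c(r$ci_lo, r$ci_hi), wo$ci, tolerance = 1e-4)
    }
  })
})

test_that("univariable screening has nominal type-I error and flags real effects", {
  withr::with_seed(29, {
    # independence: rejection rate near alpha = .05
    hits <- replicate(120, {
      ex <- make_exams(400)
      ex$bit_type <- sample(c("snaffle_trotting", "crescendo"), 400, TRUE)
      ex$merged <- sample(c("AB", "CD"), 400, TRUE)
      univariable_screen(ex, "bit_type")$p_value < 0.05
    })
    expect_lt(abs(mean(hits) - 0.05), 0.05)
  })
  # a strongly separated factor yields p near zero
  ex <- make_exams(200)
  ex$sex <- rep(c("mare", "gelding"), each = 100)
  ex$merged <- rep(c("CD", "AB"), c(100, 100))
  expect_lt(univariable_screen(ex, "sex")$p_value, 1e-10)
  # a single-level factor is skipped with a warning
  expect_warning(out <- univariable_screen(ex, c("sex", "breed")),
                 "single observed level")
  expect_equal(out$factor, "sex")
  # the generator's bit-type signal is detectable at study-like power
  flagged <- vapply(1:12, function(s) {
    co <- generate_cohort(generator_config(n_horses = 1000, seed = 100 + s),
                          simulate_lesions = FALSE)
    sc <- univariable_screen(co$exams, "bit_type")
    sc$p_value < 0.05
  }, logical(1))
  expect_gte(mean(flagged), 11 / 12)
})

test_that("logistic fits report Wald inference and a saturated fit reproduces cell logits", {
  m <- rbind(c(30, 8), c(49, 49))
  ex <- exams_from_2x2(m)
  fit <- fit_logistic(ex, "bit_type")
  expect_equal(fit$n, 136)
  expect_equal(fit$coef$estimate[1], log(49 / 49), tolerance = 1e-8)
  expect_equal(fit$coef$estimate[2], log(30 / 8) - log(49 / 49),
               tolerance = 1e-8)
  # CI bounds bracket the OR; factor-level joint test has 1 df here
  expect_true(all(fit$coef$ci_lo < fit$coef$or & fit$coef$or < fit$coef$ci_hi))
  expect_equal(fit$factor_tests$df, 1L)
  # LR statistic equals the deviance drop against intercept-only
  null_ll <- {
    p0 <- mean(ex$merged == "CD")
    sum(log(ifelse(ex$merged == "CD", p0, 1 - p0)))
  }
  expect_equal(fit$lr_chisq, 2 * (fit$loglik - null_ll), tolerance = 1e-6)
  # saturated three-level factor: fitted probabilities equal cell means
  ex3 <- make_exams(90)
  ex3$sex <- rep(c("gelding", "mare", "stallion"), each = 30)
  ex3$merged <- c(rep(c("CD", "AB"), c(10, 20)), rep(c("CD", "AB"), c(21, 9)),
                  rep(c("CD", "AB"), c(15, 15)))
  f3 <- fit_logistic(ex3, "sex")
  expect_equal(unique(round(stats::fitted(f3$model), 10)),
               round(c(10 / 30, 21 / 30, 15 / 30), 10))
})

test_that("degenerate outcomes and separated levels raise distinct conditions", {
  ex <- make_exams(20, merged = "CD")
  expect_error(fit_logistic(ex, "sex"), class = "bitlesion_separation_error")
  ex <- exams_from_2x2(rbind(c(10, 0), c(20, 20)))
  expect_error(fit_logistic(ex, "bit_type"),
               class = "bitlesion_separation_error")
})

test_that("the separation fix reassigns exactly the minimum-point record with an audit trail", {
  ex <- exams_from_2x2(rbind(c(14, 0), c(60, 60)),
                       levels = c("straight_plastic", "snaffle_trotting"))
  ex$total_points <- ifelse(ex$merged == "CD", 12L, 0L)
  ex$total_points[which(ex$bit_type == "straight_plastic")[5]] <- 3L
  fixed <- apply_separation_fix(ex, "bit_type", "straight_plastic")
  sel <- fixed$bit_type == "straight_plastic"
  expect_equal(sum(fixed$merged[sel] == "CD"), 13)
  audit <- attr(fixed, "separation_fix")[[1]]
  expect_equal(audit$total_points, 3L)
  expect_equal(audit$from, "CD"); expect_equal(audit$to, "AB")
  expect_equal(fixed$merged[fixed$horse_id == audit$horse_id], "AB")
  # the fixed cohort now fits where the unfixed one raised separation
  expect_error(fit_logistic(ex, "bit_type"), class = "bitlesion_separation_error")
  fit <- fit_logistic(fixed, "bit_type")
  expect_true(fit$model$converged)
  # a mixed level is a no-op with a warning
  expect_warning(same <- apply_separation_fix(fixed, "bit_type",
                                              "straight_plastic"),
                 "mixed outcomes")
  expect_equal(same$merged, fixed$merged)
})

test_that("stepwise building drops noise, retains signal and keeps forced breed", {
  withr::with_seed(57, {
    keep <- replicate(15, {
      co <- generate_cohort(generator_config(n_horses = 2000,
                                             seed = sample.int(1e6, 1)),
                            simulate_lesions = FALSE)
      ex <- co$exams
      ex$noise_factor <- sample(c("u", "v"), nrow(ex), TRUE)
      sw <- stepwise_build(ex, c("bit_type", "sex", "noise_factor"))
      c(bit = "bit_type" %in% sw$final_terms,
        sex = "sex" %in% sw$final_terms,
        noise = "noise_factor" %in% sw$final_terms,
        breed = "breed" %in% sw$final_terms)
    })
    expect_true(all(keep["breed", ]))
    expect_gte(mean(keep["bit", ] & keep["sex", ] & !keep["noise", ]), 0.9)
  })
  # all-null candidates leave only the forced term
  withr::with_seed(71, {
    ex <- make_exams(600)
    ex$breed <- sample(c("standardbred", "finnhorse"), 600, TRUE)
    ex$galloped <- sample(c(TRUE, FALSE), 600, TRUE)
    ex$start_type <- sample(c("auto", "volt"), 600, TRUE)
    ex$merged <- sample(c("AB", "CD"), 600, TRUE)
    sw <- stepwise_build(ex, c("galloped", "start_type"))
    expect_equal(sw$final_terms, "breed")
    expect_true(all(c("galloped", "start_type") %in% sw$removed))
    # forced breed survives a non-significant p, and the log says so
    p_breed <- sw$fit$factor_tests$p_value[sw$fit$factor_tests$term == "breed"]
    expect_gt(p_breed, 0.05)
    expect_true(any(sw$log$action == "retain-forced"))
    expect_true(any(grepl("random-intercept", sw$log$detail)))
  })
})

test_that("interaction scans are null-calibrated and detect an injected interaction", {
  withr::with_seed(83, {
    # type-I error of the LR interaction test near alpha
    p0 <- replicate(150, {
      ex <- make_exams(500)
      ex$sex <- sample(c("gelding", "mare"), 500, TRUE)
      ex$galloped <- sample(c(TRUE, FALSE), 500, TRUE)
      ex$merged <- ifelse(runif(500) < plogis(0.3 * (ex$sex == "mare")),
                          "CD", "AB")
      fit <- fit_logistic(ex, c("sex", "galloped"))
      interaction_scan(fit, list(c("sex", "galloped")))$p_value
    })
    expect_lt(abs(mean(p0 < 0.05) - 0.05), 0.06)
    # injected sex x galloped log-OR of 1.5 is detected at moderate n
    hits <- replicate(10, {
      n <- 2500
      ex <- make_exams(n)
      ex$sex <- sample(c("gelding", "mare"), n, TRUE)
      ex$galloped <- sample(c(TRUE, FALSE), n, TRUE)
      lp <- -0.5 + 0.4 * (ex$sex == "mare") + 0.2 * ex$galloped +
        1.5 * (ex$sex == "mare") * ex$galloped
      ex$merged <- ifelse(runif(n) < plogis(lp), "CD", "AB")
      fit <- fit_logistic(ex, c("sex", "galloped"))
      interaction_scan(fit, list(c("sex", "galloped")))$p_value < 0.05
    })
    expect_gte(mean(hits), 0.8)
  })
  # an interaction with an empty cell is inestimable and comes back NA
  ex <- make_exams(120)
  ex$sex <- rep(c("gelding", "gelding", "mare"), 40)
  ex$galloped <- ex$sex == "gelding" & rep(c(TRUE, FALSE, FALSE), 40)
  ex$merged <- rep(c("AB", "CD", "CD", "AB"), 30)
  fit <- fit_logistic(ex, c("sex", "galloped"))
  sc <- interaction_scan(fit, list(c("sex", "galloped"), c("sex", "breed")))
  expect_true(is.na(sc$p_value[1]))
  expect_match(sc$note[1], "inestimable")
  expect_match(sc$note[2], "not in model")
})
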