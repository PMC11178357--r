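test_that("weights make each individual count once", {
  ev <- tibble::tibble(
    individual_id = c("a", "a", "a", "b"),
    length_um = c(100, 100, 100, 200),
    buckled = c(0, 1, 0, 1)
  )
  w <- assign_weights(ev)
  expect_equal(w$weight, c(1 / 3, 1 / 3, 1 / 3, 1))
  expect_equal(nrow(w), 4) # no events dropped
  # invariant under row permutation
  w2 <- assign_weights(ev[c(4, 2, 1, 3), ])
  expect_equal(
    w2$weight[order(w2$length_um, w2$buckled)],
    w$weight[order(w$length_um, w$buckled)]
  )
})

test_that("weighted MLE agrees with the glm oracle", {
  ev <- gen_events(population_spec(), n_events = 300, seed = 11)
  fit <- fit_logistic_length(ev)
  # independent route: weighted binomial glm in (intercept, slope)
  # parametrization; Lc = -b0/b1, dLc = 1/b1
  g <- suppressWarnings(glm(
    buckled ~ length_um,
    family = quasibinomial(), data = ev, weights = ev$weight
  ))
  b <- coef(g)
  expect_equal(unname(fit$estimate["Lc_um"]), unname(-b[1] / b[2]),
    tolerance = 1e-5
  )
  expect_equal(unname(fit$estimate["dLc_um"]), unname(1 / b[2]),
    tolerance = 1e-5
  )
})

test_that("logistic regression recovers the generating parameters", {
  spec <- population_spec(truth = list(Lc_um = 161, dLc_um = 35))
  ev <- gen_events(spec, n_events = 388, seed = 2024)
  fit <- fit_logistic_length(ev)
  expect_false(fit$separation)
  expect_lt(
    abs(fit$estimate["Lc_um"] - 161), 1.96 * fit$se["Lc_um"]
  )
  # MLE property: fitted likelihood at least that of the truth
  ll_truth <- sum(ev$weight * stats::dbinom(
    ev$buckled, 1, plogis((ev$length_um - 161) / 35), log = TRUE
  ))
  expect_gte(fit$loglik, ll_truth)
})

test_that("deterministic outcomes raise the separation flag", {
  ev <- tibble::tibble(
    individual_id = sprintf("i%02d", 1:40),
    length_um = seq(50, 400, length.out = 40),
    buckled = as.integer(seq(50, 400, length.out = 40) > 200)
  )
  fit <- fit_logistic_length(ev)
  expect_true(fit$separation)
  expect_true(all(is.na(fit$se)))
  expect_true(fit$separation_interval[1] <= 200,
              fit$separation_interval[2] >= 200)
})

test_that("duplicating an individual's events leaves the MLE unchanged", {
  ev <- gen_events(population_spec(), n_events = 150, seed = 5)
  dup_id <- ev$individual_id[1]
  ev2 <- assign_weights(
    dplyr::bind_rows(ev, dplyr::filter(ev, individual_id == dup_id))
  )
  f1 <- fit_logistic_length(ev)
  f2 <- fit_logistic_length(ev2)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-6)
})

test_that("velocity model with constant speed reduces to the length model", {
  ev <- gen_events(population_spec(), n_events = 200, seed = 9)
  ev$speed_um_s <- 2
  fl <- fit_logistic_length(ev)
  expect_warning(fv <- fit_logistic_velocity(ev, B = 1.4e-16), "aliased")
  expect_equal(fv$loglik, fl$loglik, tolerance = 1e-6)
  # Lc(v0 = 2) of the velocity fit equals the length-model Lc
  Lc_v <- (fv$estimate["alpha"] * 2)^(-1 / 3)
  expect_equal(unname(Lc_v), unname(fl$estimate["Lc_um"]), tolerance = 1e-3)
})

test_that("velocity-coupled fit recovers the friction coefficient", {
  spec <- population_spec(
    truth = list(eta_nNs_um2 = 0.6, dLc_um = 35, B = 1.4e-16)
  )
  ev <- gen_events(spec, n_events = 388, model = "velocity_coupled",
                   seed = 77)
  fit <- fit_logistic_velocity(ev, B = 1.4e-16)
  expect_lt(
    abs(fit$estimate["eta_nNs_um2"] - 0.6), 1.96 * fit$se["eta_nNs_um2"]
  )
  # the fitted median line Lc(v0) decreases with speed
  v <- seq(1, 3, by = 0.5)
  Lcv <- (fit$estimate["alpha"] * v)^(-1 / 3)
  expect_true(all(diff(Lcv) < 0))
})

test_that("Wald intervals have close to nominal coverage", {
  hits <- 0
  n_rep <- 150
  for (i in seq_len(n_rep)) {
    ev <- gen_events(population_spec(), n_events = 388, seed = 40000 + i)
    fit <- fit_logistic_length(ev)
    ci <- fit$estimate["Lc_um"] + c(-1.96, 1.96) * fit$se["Lc_um"]
    hits <- hits + (ci[1] <= 161 && 161 <= ci[2])
  }
  expect_gte(hits / n_rep, 0.90)
  expect_lte(hits / n_rep, 0.99)
})

test_that("implied critical-length quantiles follow the logistic closed form", {
  spec <- population_spec(truth = list(Lc_um = 161, dLc_um = 35))
  fit <- fit_logistic_length(gen_events(spec, n_events = 388, seed = 2024))
  Lc <- unname(fit$estimate["Lc_um"])
  dLc <- unname(fit$estimate["dLc_um"])
  q <- logistic_quantiles(fit, c(0.25, 0.5, 0.75))
  expect_equal(unname(q["q0.5"]), Lc)
  expect_equal(unname(q["q0.75"]), Lc + dLc * log(3))
  expect_equal(unname(q["q0.25"] + q["q0.75"]) / 2, Lc)
  expect_error(logistic_quantiles(fit, 1.2), "strictly")
})

test_that("tidiers and the frequency plot work", {
  fit <- fit_logistic_length(
    gen_events(population_spec(), n_events = 120, seed = 3)
  )
  td <- tidy(fit)
  expect_equal(td$term, c("Lc_um", "dLc_um"))
  gl <- glance(fit)
  expect_equal(gl$n_events, 120)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
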