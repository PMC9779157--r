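test_that("the linear predictor assembles constant, attributes and context", {
  cs <- default_coefs()
  zero_ped <- data.frame(age = 0, gen = 0, edu = 0, time = 0, group = 0,
                         zone = 0, mode = 0)
  zero_ctx <- data.frame(rcs = 0, dfd = 0, rnc = 0)
  expect_equal(linear_predictor(zero_ped, zero_ctx, cs), -3.212)

  # two pedestrians differing only by gender differ by exactly the gender
  # coefficient
  ctx <- data.frame(rcs = 0.5, dfd = 0.5, rnc = 0.5)
  ped_m <- data.frame(age = 3, gen = 1, edu = 2, time = 2, group = 2,
                      zone = 2, mode = 4)
  ped_f <- within(ped_m, gen <- 0)
  expect_equal(linear_predictor(ped_m, ctx, cs) -
                 linear_predictor(ped_f, ctx, cs), 0.011)

  # doubling coefficients leaves the value at const when covariates are 0
  cs2 <- cs
  cs2$attr <- cs$attr * 2
  cs2$context <- cs$context * 2
  expect_equal(linear_predictor(zero_ped, zero_ctx, cs2), -3.212)

  # a required attribute missing from the record is an error
  expect_error(linear_predictor(data.frame(age = 1), ctx, cs), "gen")
})

test_that("the hazard is the natural-response-corrected probit probability", {
  expect_equal(hazard_prob(0, flat_coefs()), 0.5)

  # probit tail checked against a CDF oracle independent of pnorm
  expect_equal(hazard_prob(-3.212, flat_coefs()), cdf_oracle(-3.212),
               tolerance = 1e-9)

  # natural-response floor as lp -> -Inf
  cs <- flat_coefs(natural_rate = 0.1981)
  expect_equal(hazard_prob(-Inf, cs), 0.1981)
  expect_equal(hazard_prob(Inf, cs), 1)

  # strictly increasing in lp, range (C, 1)
  lp <- seq(-6, 6, by = 0.25)
  h <- hazard_prob(lp, cs)
  expect_true(all(diff(h) > 0))
  expect_true(all(h > 0.1981 & h < 1))

  # sigma rescales the latent noise
  cs2 <- flat_coefs()
  cs2$sigma <- 2
  expect_equal(hazard_prob(1, cs2), pnorm(0.5))
})

test_that("staged-response probabilities are a cumulative probit", {
  # published intercepts at zero predictor, against the CDF oracle
  pr <- stage_probabilities(0, c(-3.212, -3.185))
  expect_equal(rowSums(pr), 1)
  expect_equal(unname(pr[1, 1]), cdf_oracle(-3.212), tolerance = 1e-9)
  expect_equal(unname(pr[1, 1] + pr[1, 2]), cdf_oracle(-3.185),
               tolerance = 1e-9)

  # equal thresholds squeeze the middle category to zero
  pr2 <- stage_probabilities(0.3, c(-1, -1))
  expect_equal(unname(pr2[1, 2]), 0)

  # normalization and nonnegativity for random inputs
  set.seed(5)
  lp <- rnorm(50)
  pr3 <- stage_probabilities(lp, c(-0.7, 0.4))
  expect_equal(rowSums(pr3), rep(1, 50))
  expect_true(all(pr3 >= 0))

  expect_error(stage_probabilities(0, c(1, -1)), "ascending")
  expect_error(stage_probabilities(0, numeric(0)), "intercepts")
})

test_that("first-passage mass follows the sequential decision chain", {
  fp <- first_passage(c(0.5, 0.5))
  expect_equal(fp$prob, c(0.5, 0.25))
  expect_equal(fp$censor, 0.25)

  fp2 <- first_passage(c(0.1, 0.2, 0.3))
  expect_equal(fp2$prob[3], 0.9 * 0.8 * 0.3)
  expect_equal(fp2, enumerate_first_passage(c(0.1, 0.2, 0.3)))

  expect_equal(first_passage(c(0, 0, 0))$censor, 1)
  expect_error(first_passage(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("first-passage matches exhaustive enumeration and conserves mass on a grid", {
  grid <- seq(0, 1, by = 0.1)
  # constant hazard sequences across horizons 1..6, full grid
  for (T in 1:6) {
    for (p in grid) {
      h <- rep(p, T)
      fp <- first_passage(h)
      or <- enumerate_first_passage(h)
      expect_lt(max(abs(fp$prob - or$prob)), 1e-12)
      expect_lt(abs(fp$censor - or$censor), 1e-12)
      expect_lt(abs(sum(fp$prob) + fp$censor - 1), 1e-12)
    }
  }
  # mixed sequences drawn from the same grid
  set.seed(81)
  for (rep in 1:60) {
    T <- sample(2:6, 1)
    h <- sample(grid, T, replace = TRUE)
    fp <- first_passage(h)
    or <- enumerate_first_passage(h)
    expect_lt(max(abs(fp$prob - or$prob)), 1e-12)
    expect_lt(abs(sum(fp$prob) + fp$censor - 1), 1e-12)
  }
})

test_that("the panel log-likelihood is the log of the chain product", {
  # one pedestrian escaping at t = 1 with hazard 1/2
  one <- data.frame(id = 1, period = 1, age = 2, gen = 1, edu = 1, time = 1,
                    group = 1, zone = 1, mode = 1, rcs = 0.25, dfd = 0.25,
                    rnc = 0.25, response = 1, is_control = 0)
  expect_equal(decision_loglik(one, flat_coefs(0)), log(0.5))

  # arbitrary panels: exp(loglik) equals the brute-force product of the
  # per-period chain terms, person by person
  set.seed(21)
  pop <- sample_population(attribute_dist(30), seed = 22)
  dat <- simulate_survey(pop, default_coefs(), periods = 5, seed = 23)
  cs <- default_coefs()
  ll <- decision_loglik(dat, cs)
  brute <- 0
  for (i in unique(dat$id)) {
    di <- dat[dat$id == i, ]
    di <- di[order(di$period), ]
    h <- hazard_prob(linear_predictor(di[, c("age", "gen", "edu", "time",
                                             "group", "zone", "mode")],
                                      di[, c("rcs", "dfd", "rnc")], cs), cs)
    T <- nrow(di)
    if (di$response[T] == 1L) {
      brute <- brute + log(prod(1 - h[-T]) * h[T])
    } else {
      brute <- brute + log(prod(1 - h))  # censored survival mass
    }
  }
  expect_equal(ll, brute, tolerance = 1e-12)

  # dropping censored panels reproduces the escape-only likelihood
  esc_ids <- unique(dat$id[dat$response == 1L])
  ll_esc <- decision_loglik(dat[dat$id %in% esc_ids, ], cs)
  expect_equal(decision_loglik(dat, cs, censored = FALSE), ll_esc)
})

test_that("likelihood increases with the hazard at an observed escape", {
  one <- data.frame(id = 1, period = 1, age = 0, gen = 0, edu = 0, time = 0,
                    group = 0, zone = 0, mode = 0, rcs = 0, dfd = 0,
                    rnc = 0, response = 1, is_control = 0)
  lls <- vapply(c(-1, 0, 1), function(const)
    decision_loglik(one, flat_coefs(const)), numeric(1))
  expect_true(all(diff(lls) > 0))
})

test_that("invalid panels and zero-probability observations are diagnosed", {
  bad <- data.frame(id = 1, period = 1:2, age = 1, gen = 1, edu = 1,
                    time = 1, group = 1, zone = 1, mode = 1, rcs = 0.25,
                    dfd = 0.25, rnc = 0.25, response = c(1, 1),
                    is_control = 0)
  expect_error(decision_loglik(bad, flat_coefs()), "more than once")

  one <- bad[1, ]
  expect_warning(ll <- decision_loglik(one, flat_coefs(-Inf)),
                 "probability zero")
  expect_identical(c(ll), -Inf)
})

test_that("the natural-response estimate is the control proportion with binomial SE", {
  nr <- natural_response(2973, 589)
  expect_equal(round(100 * nr$rate, 2), 19.81)
  expect_equal(nr$se, sqrt(nr$rate * (1 - nr$rate) / 2973))
  expect_equal(round(nr$se, 3), 0.007)

  nr0 <- natural_response(100, 0)
  expect_equal(nr0$rate, 0)
  expect_equal(nr0$se, 0)
  expect_error(natural_response(0, 0), "positive")
  expect_error(natural_response(10, 11), "0..subjects")
})
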