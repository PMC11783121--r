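obs_with_residual <- function(model, r, time = 35, dose = 20,
                              activity = model$ref_as) {
  pred <- predict_concentration(model, dose = dose, activity = activity,
                                time = time)
  data.frame(time = time, concentration = pred * exp(r), dose = dose)
}

test_that("an observation equal to the population prediction gives eta_hat zero", {
  m <- default_model()
  ebe <- estimate_eta(m, obs_with_residual(m, 0))
  expect_equal(ebe$eta_hat, 0)
  expect_equal(ebe$css20_updated, predict_css(m))
  expect_true(ebe$informative)
})

test_that("single-sample shrinkage is omega^2 / (omega^2 + sigma^2)", {
  # omega = sigma: half the residual
  m_eq <- pk_model(omega = 0.2, sigma = 0.2)
  expect_equal(estimate_eta(m_eq, obs_with_residual(m_eq, 0.5))$eta_hat, 0.25)
  # omega 0.25, sigma 0.20, residual +0.30:
  # 0.0625 / 0.1025 * 0.30 = 0.1829268
  m <- example_model()
  ebe <- estimate_eta(m, obs_with_residual(m, 0.30))
  expect_equal(ebe$shrinkage, 0.0625 / 0.1025)
  expect_equal(ebe$eta_hat, 0.1829268, tolerance = 1e-6)
})

test_that("closed form matches numerical maximisation of the MAP objective", {
  set.seed(21)
  for (i in 1:100) {
    m <- pk_model(tvc20 = runif(1, 15, 45), theta_as = runif(1, 1, 2.5),
                  omega = runif(1, 0.1, 0.6), sigma = runif(1, 0.05, 0.4))
    act <- runif(1, 0, 1.5); t <- runif(1, 22, 90); r <- rnorm(1, 0, 0.6)
    obs <- obs_with_residual(m, r, time = t, activity = act)
    ebe <- estimate_eta(m, obs, activity = act)
    objective <- function(eta) {
      pred <- predict_concentration(m, dose = 20, activity = act, eta = eta,
                                    time = t)
      -(log(obs$concentration) - log(pred))^2 / (2 * m$sigma^2) -
        eta^2 / (2 * m$omega^2)
    }
    num <- optimize(objective, c(-4, 4), maximum = TRUE, tol = 1e-10)$maximum
    expect_equal(ebe$eta_hat, num, tolerance = 1e-6)
  }
})

test_that("shrinkage bounds hold: |eta_hat| <= |residual| and eta_hat -> 0 with omega", {
  set.seed(22)
  for (r in rnorm(20, 0, 0.8)) {
    m <- default_model()
    ebe <- estimate_eta(m, obs_with_residual(m, r))
    expect_lte(abs(ebe$eta_hat), abs(r) + 1e-12)
  }
  m_tiny <- pk_model(omega = 1e-6, sigma = 0.2)
  expect_lt(abs(estimate_eta(m_tiny, obs_with_residual(m_tiny, 1))$eta_hat),
            1e-9)
})

test_that("samples inside the first 21 days are advisory only, day 22 onward informative", {
  m <- default_model()
  expect_warning(ebe <- estimate_eta(m, obs_with_residual(m, 0.2, time = 14)),
                 "advisory")
  expect_false(ebe$informative)
  expect_true(estimate_eta(m, obs_with_residual(m, 0.2, time = 22))$informative)
  upd <- suppressWarnings(update_recommendation(
    estimate_eta(m, obs_with_residual(m, 0.2, time = 10))))
  expect_true(upd$advisory)
})

test_that("multiple informative samples sharpen the shrinkage; early ones are excluded", {
  m <- default_model()
  r <- c(0.2, 0.4)
  obs2 <- rbind(obs_with_residual(m, r[1], time = 28),
                obs_with_residual(m, r[2], time = 42))
  ebe2 <- estimate_eta(m, obs2)
  k <- 2
  expect_equal(ebe2$shrinkage, m$omega^2 / (m$omega^2 + m$sigma^2 / k))
  expect_equal(ebe2$eta_hat, ebe2$shrinkage * mean(r))
  # an added early sample changes nothing by default ...
  obs3 <- rbind(obs_with_residual(m, -1.5, time = 7), obs2)
  expect_equal(estimate_eta(m, obs3)$eta_hat, ebe2$eta_hat)
  expect_equal(estimate_eta(m, obs3)$n_used, 2L)
  # ... but is used on request
  ebe3 <- estimate_eta(m, obs3, include_uninformative = TRUE)
  expect_equal(ebe3$n_used, 3L)
  expect_equal(ebe3$eta_hat,
               m$omega^2 / (m$omega^2 + m$sigma^2 / 3) * mean(c(-1.5, r)))
})

test_that("a dropping dose-corrected concentration raises a non-adherence warning", {
  m <- default_model()
  obs <- rbind(obs_with_residual(m, 0.3, time = 28),
               obs_with_residual(m, -0.8, time = 42))
  expect_warning(estimate_eta(m, obs), "non-adherence")
})

test_that("updated recommendations follow the shrunken prediction", {
  m <- default_model()
  ebe0 <- estimate_eta(m, obs_with_residual(m, 0, activity = 1.0),
                       activity = 1.0)
  apriori <- recommend_dose(predict_css(m, activity = 1.0))
  expect_identical(as.character(update_recommendation(ebe0)$category),
                   as.character(apriori$category))
  # css20 17 nM with eta_hat -0.40 -> 11.396 nM -> 30 mg
  # (11.396 * 1.5 = 17.09 >= 16)
  ebe <- structure(list(eta_hat = -0.40, shrinkage = 0.6,
                        css20_updated = 17 * exp(-0.40), informative = TRUE,
                        n_used = 1L, n_obs = 1L, residuals = -0.66),
                   class = "ebe_result")
  upd <- update_recommendation(ebe)
  expect_equal(ebe$css20_updated, 11.39544, tolerance = 1e-5)
  expect_identical(as.character(upd$category), "D30")
})

test_that("eta recovery: regression slope matches the shrinkage and RMSE shrinks", {
  m <- default_model()
  set.seed(301)
  n <- 2000
  eta <- rnorm(n, 0, m$omega)
  css_true <- predict_css(m, eta = eta)
  obs35 <- css_true * accumulation_fraction(m, 35) * exp(rnorm(n, 0, m$sigma))
  eta_hat <- vapply(obs35, function(conc) {
    estimate_eta(m, data.frame(time = 35, concentration = conc,
                               dose = 20))$eta_hat
  }, numeric(1))
  shr <- m$omega^2 / (m$omega^2 + m$sigma^2)
  slope <- coef(lm(eta_hat ~ eta))[["eta"]]
  expect_equal(slope, shr, tolerance = 0.05 / shr)
  rmse <- function(x) sqrt(mean((x - css_true)^2))
  expect_lt(rmse(predict_css(m, eta = eta_hat)), rmse(predict_css(m, eta = 0)))
})

test_that("degenerate observations are rejected", {
  m <- default_model()
  expect_error(estimate_eta(m, data.frame(time = 35, concentration = 0,
                                          dose = 20)), "> 0")
  expect_error(estimate_eta(m, data.frame(time = 0, concentration = 10,
                                          dose = 20)), "time")
  expect_error(estimate_eta(m, data.frame(time = numeric(0),
                                          concentration = numeric(0),
                                          dose = numeric(0))), "at least one")
})
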