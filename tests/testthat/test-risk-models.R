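test_that("AUROC matches the exhaustive case-control pair count exactly", {
  for (seed in 1:10) {
    dat <- withr::with_seed(seed, {
      n <- sample(8:30, 1)
      list(
        s = sample(1:6, n, replace = TRUE), # plenty of ties
        y = c(TRUE, FALSE, runif(n - 2) < 0.4)[1:n]
      )
    })
    a <- auroc(dat$s, dat$y)
    cases <- dat$s[dat$y]
    ctrls <- dat$s[!dat$y]
    pairs <- outer(cases, ctrls, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(a, mean(pairs), tolerance = 1e-12)
  }
})

test_that("AUROC is 1 under perfect separation and 0.5 under independence", {
  expect_equal(auroc(c(4, 5, 6, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 1)
  aucs <- vapply(1:30, function(seed) {
    withr::with_seed(seed, auroc(rnorm(300), rep(c(TRUE, FALSE), 150)))
  }, numeric(1))
  se <- sqrt(1 / (4 * 150) + 1 / (4 * 150)) # conservative null SE
  expect_lt(abs(mean(aucs) - 0.5), 3 * se / sqrt(30))
  expect_error(auroc(1:5, rep(TRUE, 5)), class = "hipshape_error_single_class")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  withr::local_seed(4)
  s <- rnorm(100)
  y <- runif(100) < plogis(s)
  a <- auroc(s, y)
  expect_equal(auroc(exp(s), y), a)
  expect_equal(auroc(qlogis(plogis(s)), y), a, tolerance = 1e-12)
  expect_equal(auroc(rank(s), y), a)
})

test_that("DeLong variance agrees with a jackknife oracle and pROC", {
  withr::local_seed(9)
  s <- rnorm(60)
  y <- runif(60) < plogis(1.5 * s)
  ci <- auroc_ci(s, y)
  expect_equal(ci$method, "delong")

  # Jackknife oracle for the AUROC variance.
  n <- length(s)
  loo <- vapply(seq_len(n), function(i) auroc(s[-i], y[-i]), numeric(1))
  jk_var <- (n - 1) / n * sum((loo - mean(loo))^2)
  expect_lt(abs(ci$se^2 - jk_var) / jk_var, 0.10)

  # Cross-check against the reference DeLong implementation.
  pr <- pROC::ci.auc(pROC::roc(y, s, quiet = TRUE), method = "delong")
  expect_equal(ci$conf_low, as.numeric(pr[1]), tolerance = 1e-8)
  expect_equal(ci$conf_high, as.numeric(pr[3]), tolerance = 1e-8)
})

test_that("DeLong intervals achieve nominal coverage on binormal scores", {
  mu <- sqrt(2) * qnorm(0.8) # population AUROC 0.8
  covered <- vapply(1:1000, function(seed) {
    withr::with_seed(seed, {
      s <- c(rnorm(170, mean = mu), rnorm(230))
      y <- rep(c(TRUE, FALSE), c(170, 230))
      ci <- auroc_ci(s, y)
      ci$conf_low <= 0.8 && 0.8 <= ci$conf_high
    })
  }, logical(1))
  expect_gt(mean(covered), 0.93)
  expect_lt(mean(covered), 0.97)
})

test_that("degenerate-AUROC intervals stay within [0, 1]", {
  s <- c(101:180, 1:100)
  y <- rep(c(TRUE, FALSE), c(80, 100))
  ci <- auroc_ci(s, y)
  expect_equal(ci$auroc, 1)
  expect_equal(ci$conf_high, 1)
  expect_gte(ci$conf_low, 0)
})

test_that("logistic fit matches closed forms and an independent optimizer", {
  # Intercept-only, balanced outcome: logit(0.5) = 0.
  d0 <- tibble::tibble(z = rnorm(50), fracture = rep(c(TRUE, FALSE), 25))
  f0 <- fit_fracture_model(d0, "z", adjust = character())
  expect_lt(abs(tidy(f0)$estimate[1]), 0.5) # intercept near 0

  # 2x2 design: coefficient equals the closed-form log odds ratio.
  d2 <- tibble::tibble(
    x = rep(c(1, 1, 0, 0), c(30, 10, 20, 40)),
    fracture = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 20, 40))
  )
  f2 <- fit_fracture_model(d2, "x", adjust = character())
  expect_equal(
    tidy(f2)$estimate[tidy(f2)$term == "x"],
    log(30 * 40 / (10 * 20)),
    tolerance = 1e-8
  )

  # Independent oracle: BFGS on the raw log-likelihood.
  dat <- sim_risk_data(300, beta = c(0.9, rep(0, 9)), seed = 2)
  fit <- fit_fracture_model(dat, paste0("mode", 1:3), adjust = c("age", "bmi"))
  xd <- cbind(1, as.matrix(dat[c(paste0("mode", 1:3), "age", "bmi")]))
  yv <- dat$fracture
  nll <- function(b) {
    eta <- xd %*% b
    -sum(yv * eta - log1p(exp(eta)))
  }
  gr <- function(b) -as.vector(t(xd) %*% (yv - plogis(xd %*% b)))
  opt <- optim(rep(0, 6), nll, gr,
    method = "BFGS",
    control = list(maxit = 5000, reltol = 1e-16)
  )
  expect_equal(unname(coef(fit$fit)), opt$par, tolerance = 1e-6)
})

test_that("separation errors advise ridge, and ridge produces a finite fit", {
  d <- tibble::tibble(x = c(1:10), fracture = c(rep(FALSE, 5), rep(TRUE, 5)))
  expect_error(
    fit_fracture_model(d, "x", adjust = character()),
    class = "hipshape_error_separation"
  )
  fr <- fit_fracture_model(d, "x", adjust = character(), ridge = 1e-4)
  expect_true(all(is.finite(tidy(fr)$estimate)))
  expect_true(fr$converged)
})

test_that("singular and constant designs fail with the offending columns named", {
  d <- sim_risk_data(100, seed = 3)
  d$dup <- 2 * d$mode1
  err <- expect_error(
    fit_fracture_model(d, c("mode1", "dup"), adjust = character()),
    class = "hipshape_error_singular"
  )
  expect_match(conditionMessage(err), "dup")
  d$flat <- 1
  err2 <- expect_error(
    fit_fracture_model(d, "flat", adjust = character()),
    class = "hipshape_error_constant_predictor"
  )
  expect_match(conditionMessage(err2), "flat")
})

test_that("odds-ratio table applies the Wald formulas", {
  dat <- sim_risk_data(500, beta = c(log(2.48), rep(0, 9)), seed = 5)
  fit <- fit_fracture_model(dat, paste0("mode", 1:2), adjust = c("age", "bmi"))
  td <- tidy(fit)
  zc <- qnorm(0.975)
  expect_equal(td$odds.ratio, exp(td$estimate))
  expect_equal(td$conf.low, exp(td$estimate - zc * td$std.error))
  expect_equal(td$conf.high, exp(td$estimate + zc * td$std.error))
  expect_equal(td$p.value, 2 * pnorm(-abs(td$estimate / td$std.error)))
  # CIs contain their point estimates; ORs positive.
  expect_true(all(td$conf.low < td$odds.ratio & td$odds.ratio < td$conf.high))
  expect_true(all(td$odds.ratio > 0))
})

test_that("null-mode Wald tests have about 5% type-I error", {
  hits <- 0
  total <- 0
  for (seed in 1:200) {
    dat <- sim_risk_data(250, beta = rep(0, 10), seed = seed)
    fit <- fit_fracture_model(dat, paste0("mode", 1:10), adjust = character())
    td <- tidy(fit)
    pv <- td$p.value[grepl("^mode", td$term)]
    hits <- hits + sum(pv < 0.05)
    total <- total + length(pv)
  }
  frac <- hits / total
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / total) + 0.005)
})

test_that("McFadden pseudo-R2 has its limits and matches manual arithmetic", {
  dat <- sim_risk_data(200, seed = 6)
  null_glm <- glm(fracture ~ 1, data = dat, family = binomial())
  expect_equal(mcfadden_r2(null_glm, null_glm), 0, tolerance = 1e-12)

  # Hand-computed 5-observation example: saturated-by-group closed form.
  d5 <- tibble::tibble(
    x = c(0, 0, 1, 1, 1),
    fracture = c(FALSE, TRUE, FALSE, TRUE, TRUE)
  )
  f5 <- fit_fracture_model(d5, "x", adjust = character())
  ll_model <- 2 * log(0.5) + log(1 / 3) + 2 * log(2 / 3) # group rates 1/2, 2/3
  ll_null <- 3 * log(3 / 5) + 2 * log(2 / 5)
  expect_equal(mcfadden_r2(f5), 1 - ll_model / ll_null, tolerance = 1e-6)

  # Perfect (penalized) prediction approaches 1.
  dp <- tibble::tibble(x = rep(c(-2, 2), 20), fracture = rep(c(FALSE, TRUE), 20))
  fp <- fit_fracture_model(dp, "x", adjust = character(), ridge = 1e-6)
  ll_p <- fp$fit$loglik
  ll_0 <- 40 * log(0.5)
  expect_gt(1 - ll_p / ll_0, 0.95)
})

test_that("glance reports coherent discrimination summaries", {
  dat <- sim_risk_data(400, beta = c(log(2.5), rep(0, 9)), seed = 8)
  fit <- fit_fracture_model(dat, "mode1", adjust = c("age", "bmi"))
  g <- glance(fit)
  expect_true(g$conf_low <= g$auroc && g$auroc <= g$conf_high)
  expect_true(g$auroc > 0.5 && g$auroc <= 1)
  expect_true(g$pseudo_r2 >= 0 && g$pseudo_r2 < 1)
  expect_equal(g$n_cases + g$n_controls, 400)
  expect_equal(g$auroc, auroc(risk_scores(fit), dat$fracture))
})
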