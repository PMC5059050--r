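# random small survival dataset; continuous times avoid ties unless asked
rand_surv <- function(n = NULL, p = NULL, tie_days = FALSE) {
  if (is.null(n)) n <- sample(10:30, 1)
  if (is.null(p)) p <- sample(1:3, 1)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  t <- rexp(n, 0.08 * exp(drop(X %*% rep(0.4, p))))
  if (tie_days) t <- ceiling(t)
  list(time = pmax(t, 1e-3), event = runif(n) < 0.7, x = X)
}

test_that("mirror-symmetric groups give a hazard ratio of one", {
  t <- c(1, 2, 3, 5, 8, 13, 1, 2, 3, 5, 8, 13) + 0.5
  ev <- rep(c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE), 2)
  x <- rep(c(0, 1), each = 6)
  fit <- cox_fit(t, ev, x)
  expect_equal(unname(fit$coef), 0, tolerance = 1e-8)
  expect_equal(unname(fit$hr), 1, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("six-subject fit maximizes the enumerated partial likelihood", {
  t <- 1:6
  ev <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)
  x <- c(1, 0, 1, 1, 0, 0)
  fit <- cox_fit(t, ev, x)
  b_ref <- cox_oracle_1d(t, ev, x)
  expect_equal(unname(fit$coef), b_ref, tolerance = 1e-6)
  expect_lt(fit$grad_norm, 1e-9)
})

test_that("one-covariate fits agree with the grid-search oracle", {
  set.seed(51)
  for (i in 1:10) {
    d <- rand_surv(p = 1)
    if (sum(d$event) == 0) next
    fit <- cox_fit(d$time, d$event, d$x)
    expect_equal(unname(fit$coef), cox_oracle_1d(d$time, d$event, drop(d$x)),
                 tolerance = 1e-6)
  }
})

test_that("coefficients and standard errors match coxph to 1e-6", {
  skip_if_not_installed("survival")
  set.seed(52)
  for (i in 1:10) {
    d <- rand_surv(tie_days = i %% 2 == 0)
    if (sum(d$event) < 2) next
    for (ties in c("efron", "breslow")) {
      fit <- cox_fit(d$time, d$event, d$x, ties = ties)
      ref <- survival::coxph(
        survival::Surv(d$time, d$event) ~ d$x, ties = ties,
        control = survival::coxph.control(eps = 1e-12, toler.chol = 1e-13,
                                          iter.max = 50)
      )
      expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
      expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
      expect_equal(unname(fit$loglik[2]), ref$loglik[2], tolerance = 1e-8)
    }
  }
})

test_that("Efron and Breslow coincide exactly on tie-free data", {
  set.seed(53)
  for (i in 1:10) {
    d <- rand_surv()
    if (sum(d$event) == 0) next
    fe <- cox_fit(d$time, d$event, d$x, ties = "efron")
    fb <- cox_fit(d$time, d$event, d$x, ties = "breslow")
    expect_identical(fe$coef, fb$coef)
    expect_identical(fe$se, fb$se)
  }
})

test_that("gradient norm at the optimum is below tolerance", {
  set.seed(54)
  for (i in 1:10) {
    d <- rand_surv()
    if (sum(d$event) < 2) next
    fit <- cox_fit(d$time, d$event, d$x)
    if (fit$converged) expect_lt(fit$grad_norm, 1e-9)
  }
})

test_that("rank deficiency is reported with the collinear column names", {
  set.seed(55)
  X <- cbind(a = rnorm(20), b = rnorm(20))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(cox_fit(rexp(20) + 0.1, rep(TRUE, 20), X), "c")
  expect_error(cox_fit(c(1, 2), c(FALSE, FALSE), c(0, 1)), "no events")
})

test_that("Wald intervals bracket the hazard ratio", {
  set.seed(56)
  d <- rand_surv(n = 40, p = 2)
  fit <- cox_fit(d$time, d$event, d$x)
  expect_true(all(fit$ci_lower < fit$hr & fit$hr < fit$ci_upper))
  expect_true(all(fit$hr > 0))
  s <- summary(fit)
  expect_s3_class(s, "tbl_df")
  expect_equal(nrow(s), 2)
})
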