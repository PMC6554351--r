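test_that("the exact binomial test reproduces enumeration over all outcomes", {
  # closed-form worked examples at n = 12
  expect_equal(binomial_test(11, 12)$p_value, 26 / 4096, tolerance = 1e-12)
  expect_equal(binomial_test(6, 12)$p_value, 1)
  expect_equal(binomial_test(12, 12)$p_value, 2 / 4096, tolerance = 1e-12)
  expect_equal(round(binomial_test(11, 12)$p_value, 3), 0.006)

  # oracle: enumerate all 2^n outcomes, two-sided by point-probability rule
  enum_p <- function(k, n) {
    probs <- choose(n, 0:n) / 2^n
    sum(probs[probs <= probs[k + 1] + 1e-12])
  }
  for (n in c(5, 9, 12, 16)) {
    for (k in 0:n) {
      expect_equal(binomial_test(k, n)$p_value, enum_p(k, n),
                   tolerance = 1e-9)
    }
  }
  expect_equal(binomial_test(11, 12, sidedness = "greater")$p_value,
               13 / 4096, tolerance = 1e-12)
})

test_that("paired t and Cohen's d follow the paired-differences definitions", {
  d <- c(0.4, 0.1, 0.5, 0.3, 0.2)
  res <- paired_t(d)
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$effect_size, mean(d) / sd(d))
  expect_equal(res$p_value, t.test(d)$p.value)
  zero <- paired_t(rep(0, 4))
  expect_equal(zero$statistic, 0)
  expect_equal(zero$effect_size, 0)
  expect_error(paired_t(1), ">= 2")
  td <- tidy(res)
  expect_equal(td$effect.size, res$effect_size)
})

test_that("Fisher-z pooling has its fixed point, closed form, bounds and small-rho limit", {
  expect_equal(as.numeric(fisher_z_mean(c(0.5, 0.5))), 0.5)
  expect_equal(as.numeric(fisher_z_mean(c(0.8, 0.3))),
               tanh((atanh(0.8) + atanh(0.3)) / 2), tolerance = 1e-12)
  set.seed(2)
  rhos <- runif(50, -0.95, 0.95)
  expect_lt(abs(as.numeric(fisher_z_mean(rhos))), 1)
  small <- runif(20, -0.01, 0.01)
  expect_equal(as.numeric(fisher_z_mean(small)), mean(small),
               tolerance = 1e-5)
  with_bad <- fisher_z_mean(c(0.5, 0.5, NA, 1))
  expect_equal(as.numeric(with_bad), 0.5)
  expect_equal(attr(with_bad, "n_excluded"), 2)
})

test_that("correlation helpers return NA on constant input and average tied ranks", {
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_true(is.na(pearson_r(1:5, rep(2, 5))))
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(x, y), cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(pearson_r(1:10, (1:10) * 2 + 1), 1)
})

test_that("the Huber fit is exact on noiseless lines and equals OLS inside delta", {
  x <- seq(-3, 3, by = 0.25)
  fit <- huber_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(tidy(fit)$estimate, c(1, 2), tolerance = 1e-9)

  # residuals strictly inside delta * scale: identical to least squares
  set.seed(4)
  y <- 2 * x + 1 + 0.004 * sin(seq_along(x))
  h <- huber_fit(x, y)
  ls <- coef(lm(y ~ x))
  expect_equal(h$slope, unname(ls[2]), tolerance = 1e-8)
  expect_equal(h$intercept, unname(ls[1]), tolerance = 1e-8)

  # a gross outlier moves OLS but barely moves the Huber fit
  y2 <- 2 * x + 1 + rnorm(length(x), 0, 0.1)
  y2[5] <- y2[5] + 50
  hr <- huber_fit(x, y2)
  expect_equal(hr$slope, 2, tolerance = 0.15)
  expect_gt(abs(coef(lm(y2 ~ x))[2] - 2), abs(hr$slope - 2))
  expect_error(huber_fit(1, 2), ">= 2")
})

test_that("test reports serialize with the documented schema", {
  tests <- list(shift = paired_t(c(0.2, 0.4, 0.3)),
                count = binomial_test(11, 12))
  path <- withr::local_tempfile(fileext = ".json")
  write_test_report(tests, path, inputs_digest = "toy")
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$test_name, c("shift", "count"))
  expect_equal(back$p[2], 26 / 4096, tolerance = 1e-9)
  expect_true(all(c("statistic", "d", "n", "sidedness") %in% names(back)))
})
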