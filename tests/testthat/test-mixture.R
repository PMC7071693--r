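test_that("bicScore and nbPmf implement their contracts", {
  expect_equal(bicScore(-100, r = 4, T = 1000), 4 * log(1000) + 200)
  expect_error(bicScore(-1, 1, 0), "T")
  expect_equal(nbPmf(0:5, size = 2, prob = 0.5),
               dnbinom(0:5, size = 2, prob = 0.5))
  expect_equal(nbPmf(-1L, 2, 0.5), 0)          # negative counts have mass 0
  expect_error(nbPmf(1, 2, 0), "prob")
  expect_error(nbPmf(1, 2, 1.5), "prob")
})

test_that("densityBackground is an NB with mean mu and size a", {
  a <- 2; mu <- 7
  p <- densityBackground(0:2000, a, mu)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(sum(p * 0:2000), mu, tolerance = 1e-8)
  expect_equal(sum(p * (0:2000)^2) - mu^2, mu + mu^2 / a, tolerance = 1e-6)
})

test_that("densitySignal1S equals the brute-force convolution", {
  y <- 0:60
  d <- densitySignal1S(y, a = 2, mu = 4, b = 3, c = 0.2, k = 2)
  expect_equal(d, bruteSignal1S(y, 2, 4, 3, 0.2, 2), tolerance = 1e-13)
  expect_true(all(d[y < 2] == 0))              # mass zero below k
})

test_that("densitySignal2S mixes two shared-offset convolutions", {
  y <- 0:80
  d <- densitySignal2S(y, a = 2, mu = 3, b1 = 5, c1 = 0.2, b2 = 2, c2 = 0.5,
                       piS1 = 0.3, k = 1)
  expect_equal(d, bruteSignal2S(y, 2, 3, 5, 0.2, 2, 0.5, 0.3, 1),
               tolerance = 1e-13)
  expect_error(densitySignal2S(y, 2, 3, 5, 0.2, 2, 0.5, 1.2, 1), "piS1")
})

test_that("mixtureDensity is the stated convex combination", {
  y <- 0:50
  p1s <- list(b = 3, c = 0.2, k = 2L, piS = 0.2)
  m <- mixtureDensity(y, a = 2, mu = 4, params = p1s, mode = "1S")
  expect_equal(m, 0.8 * densityBackground(y, 2, 4) +
                  0.2 * densitySignal1S(y, 2, 4, 3, 0.2, 2))
})

test_that("the cached group densities match the direct formulas", {
  set.seed(3)
  mu <- sample(c(0.5, 1, 2, 5, 9), 200, replace = TRUE)
  Y <- rnbinom(200, size = 2, mu = mu) + sample(0:30, 200, replace = TRUE)
  cache <- meripmix:::.mixCache(Y, mu, a = 2)
  expect_equal(cache$p0, vapply(seq_along(Y), function(j)
    densityBackground(Y[j], 2, mu[j]), 0))
  s <- meripmix:::.signalDens(cache, b = 3, c = 0.1, k = 4)
  direct <- vapply(seq_along(Y), function(j)
    densitySignal1S(Y[j], 2, mu[j], 3, 0.1, 4), 0)
  expect_equal(s, direct, tolerance = 1e-12)
})

test_that("emFit1S recovers the generating parameters at moderate scale", {
  set.seed(11)
  T <- 8000
  mu <- rep(c(2, 5, 10), length.out = T)
  sim <- simulateCounts(mu, a = 2,
                        list(b = 4, c = 0.1, k = 3L, piS = 0.2), seed = 11)
  fit <- emFit1S(sim$Y, mu, a = 2, k = 3)
  expect_true(fit$converged)
  expect_true(all(diff(fit$llTrace) >= -1e-8))  # non-decreasing trace
  expect_lt(abs(fit$params$piS - 0.2), 0.05)
  expect_lt(abs(fit$params$b / fit$params$c - 40) / 40, 0.2)
  expect_equal(length(fit$gamma), T)
  expect_true(all(fit$gamma >= 0 & fit$gamma <= 1))
})

test_that("emFit1S warns when the signal component vanishes", {
  ## every count sits below the offset k, so the signal density is zero
  ## for every bin and the responsibilities collapse immediately
  Y <- rep(c(0L, 1L, 2L), 1000)
  expect_warning(fit <- emFit1S(Y, rep(2, 3000), a = 2, k = 10),
                 "vanished")
  expect_lt(fit$params$piS, 1e-3)
})

test_that("emFit2S orders components and can fall back to 1S", {
  set.seed(13)
  T <- 8000
  mu <- rep(c(2, 5, 10), length.out = T)
  sim <- simulateCounts(mu, a = 2,
                        list(b1 = 4, c1 = 0.05, b2 = 4, c2 = 0.4,
                             piS1 = 0.5, k = 2L, piS = 0.25),
                        seed = 13)
  fit <- emFit2S(sim$Y, mu, a = 2, k = 2)
  p <- fit$params
  expect_gte(p$b1 / p$c1, p$b2 / p$c2)          # decreasing means
  expect_true(p$piS1 >= 0 && p$piS1 <= 1)
  expect_true(all(diff(fit$llTrace) >= -1e-8))
})

test_that("optimizeK scans the grid and breaks ties to the smaller k", {
  set.seed(14)
  mu <- rep(c(2, 6), each = 1500)
  sim <- simulateCounts(mu, a = 2,
                        list(b = 5, c = 0.1, k = 4L, piS = 0.2), seed = 14)
  opt <- optimizeK(sim$Y, mu, a = 2, kGrid = 0:6, mode = "1S")
  expect_equal(opt$table$k, 0:6)
  expect_true(opt$k %in% 0:6)
  expect_equal(opt$table$bic,
               bicScore(opt$table$loglik, 4, length(sim$Y)))
  ## the returned k is the first index attaining the minimal BIC
  expect_equal(opt$k, opt$table$k[which.min(opt$table$bic)])
  expect_error(optimizeK(sim$Y, mu, 2, integer(), "1S"), "non-empty")
})

test_that("selectMode compares best-in-mode BICs with ties to 1S", {
  f1 <- list(table = data.frame(bic = c(10, 8)))
  f2 <- list(table = data.frame(bic = c(9, 7)))
  expect_identical(selectMode(f1, f2), "2S")
  f2$table$bic <- c(9, 8)
  expect_identical(selectMode(f1, f2), "1S")    # tie -> 1S
  expect_identical(selectMode(f1, NULL), "1S")
})

test_that("fitMixture degenerates gracefully on all-zero counts", {
  bg <- new("BackgroundFit", kind = "constant", coefficients = list(),
            a = 2, mu = rep(0.5, 50), regressionBic = NA_real_,
            groups = data.frame(), zeroMu = 0.5, model = NULL)
  fit <- fitMixture(bg = bg, Y = rep(0L, 50))
  expect_equal(signalProportion(fit), 0)
  expect_equal(fit@mode, "1S")
})
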