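## Gaussian-consistency constant for the MAD; (MAD_CONSTANT * MAD)^2 is the
## robust variance estimate used for the per-group NB moments.
MAD_CONSTANT <- 1.4826

#' Group IP bin counts by their input bin count
#'
#' Bins sharing the same input count are assumed to share one background
#' NB distribution. For each unique input count value the group's robust
#' moments are computed: the mean as the median of the IP counts, the
#' variance as the squared scaled MAD (constant 1.4826), and a per-group
#' NB size estimate `mu^2 / (var - mu)` where the variance exceeds the
#' mean (undefined otherwise). Input counts above the `tailQuantile`
#' quantile are pooled into the top group so that a sparse tail does not
#' produce singleton groups.
#'
#' @param Y Integer vector of IP bin counts.
#' @param X Integer vector of input bin counts (same length).
#' @param tailQuantile Pooling quantile for the input-count tail
#'   (default 0.999).
#' @return A `data.frame` with columns `x` (group input count), `n`,
#'   `mu`, `var`, `aGroup` (`NA` where undefined).
#' @export
groupByInput <- function(Y, X, tailQuantile = 0.999) {
  stopifnot(length(Y) == length(X), length(Y) >= 1)
  xcap <- as.numeric(stats::quantile(X, tailQuantile, type = 1))
  xg <- pmin(X, xcap)
  ux <- sort(unique(xg))
  n <- mu <- v <- numeric(length(ux))
  for (i in seq_along(ux)) {
    s <- Y[xg == ux[i]]
    n[i] <- length(s)
    mu[i] <- stats::median(s)
    v[i] <- (MAD_CONSTANT * stats::median(abs(s - mu[i])))^2
  }
  aGroup <- ifelse(v > mu & mu > 0, mu^2 / (v - mu), NA_real_)
  data.frame(x = ux, n = n, mu = mu, var = v, aGroup = aGroup)
}

#' Estimate the background NB size parameter
#'
#' The n-weighted mean of the per-group size estimates over the groups
#' where the estimate is defined (group variance greater than group mean).
#'
#' @param groups Group table from [groupByInput()].
#' @return Positive scalar, the pooled size estimate.
#' @export
estimateSizeA <- function(groups) {
  ok <- !is.na(groups$aGroup)
  if (!any(ok))
    stop("no input-count group has variance above its mean; ",
         "cannot estimate the NB size - provide more data or set a manually")
  sum(groups$n[ok] * groups$aGroup[ok]) / sum(groups$n[ok])
}

## groups usable for the log-log regression: positive input count, positive
## robust mean, and enough bins for a stable median
.usableGroups <- function(groups, minGroupN = 3L) {
  groups[groups$x >= 1 & groups$mu > 0 & groups$n >= minGroupN, , drop = FALSE]
}

## weighted Gaussian log-likelihood of log-scale residuals, weights = group
## sizes; shared by the RLM and GAM BICs so the comparison is like-for-like
.wGaussLoglik <- function(resid, w) {
  sigma2 <- sum(w * resid^2) / sum(w)
  sum(w * stats::dnorm(resid, 0, sqrt(sigma2), log = TRUE))
}

#' Robust log-log regression of background mean on input count
#'
#' Iteratively reweighted robust regression (M-estimation) of
#' `log(mu_i)` on `log(x_i)` with group sizes as observation weights.
#'
#' @param groups Group table from [groupByInput()].
#' @param T Total number of bins (enters the BIC penalty).
#' @param minGroupN Groups smaller than this are excluded from fitting.
#' @return List with `kind = "rlm"`, `beta0`, `beta1`, `bic`, `loglik`,
#'   and the fitted `model`.
#' @export
fitRlm <- function(groups, T, minGroupN = 3L) {
  g <- .usableGroups(groups, minGroupN)
  if (nrow(g) < 3)
    stop("need at least 3 usable input-count groups for the robust ",
         "linear fit (got ", nrow(g), ")")
  dat <- data.frame(ly = log(g$mu), lx = log(g$x), w = g$n)
  fit <- MASS::rlm(ly ~ lx, data = dat, weights = w, maxit = 100)
  ll <- .wGaussLoglik(dat$ly - stats::fitted(fit), dat$w)
  list(kind = "rlm",
       beta0 = unname(stats::coef(fit)[1]),
       beta1 = unname(stats::coef(fit)[2]),
       loglik = ll,
       bic = bicScore(ll, r = 3, T = T),   # beta0, beta1, scale
       model = fit)
}

#' Penalized-spline regression of background mean on input count
#'
#' A generalized additive model `log(mu_i) = beta0 + f(log(x_i))` with a
#' cubic regression spline of basis dimension 9 (plus intercept),
#' smoothness selected by REML, group sizes as weights. The BIC charges
#' the model's total effective degrees of freedom.
#'
#' @inheritParams fitRlm
#' @return List with `kind = "gam"`, `beta0`, `beta` (spline
#'   coefficients), `edf`, `bic`, `loglik`, and the fitted `model`.
#' @export
fitGam <- function(groups, T, minGroupN = 3L) {
  g <- .usableGroups(groups, minGroupN)
  if (nrow(g) < 10)
    stop("need at least 10 usable input-count groups for the spline fit ",
         "(got ", nrow(g), ")")
  dat <- data.frame(ly = log(g$mu), lx = log(g$x), w = g$n)
  fit <- mgcv::gam(ly ~ s(lx, bs = "cr", k = 10), data = dat,
                   weights = w, method = "REML")
  ll <- .wGaussLoglik(dat$ly - stats::fitted(fit), dat$w)
  edf <- sum(fit$edf) + 1  # spline edf + intercept
  cf <- stats::coef(fit)
  list(kind = "gam",
       beta0 = unname(cf[1]),
       beta = unname(cf[-1]),
       edf = edf,
       loglik = ll,
       bic = bicScore(ll, r = edf + 1, T = T),  # + scale
       model = fit)
}

#' Choose between the robust linear and the spline background regression
#'
#' The regression with the strictly lower BIC wins; ties go to the
#' simpler robust linear model.
#'
#' @param rlmFit,gamFit Fits from [fitRlm()] / [fitGam()]; either may be
#'   `NULL` when unavailable.
#' @return The selected fit (list).
#' @export
selectRegression <- function(rlmFit, gamFit = NULL) {
  if (is.null(gamFit)) return(rlmFit)
  if (is.null(rlmFit)) return(gamFit)
  if (gamFit$bic < rlmFit$bic) gamFit else rlmFit
}

#' Predict per-bin background means from a background regression
#'
#' For bins with input count `>= 1` the mean is the regression value at
#' `log(X_j)`, exponentiated. Bins with input count 0 cannot enter the
#' log-log regression and receive the empirical median IP count of the
#' zero-input group. All means are floored at `muFloor` to keep the NB
#' probability parameter away from its boundary.
#'
#' @param reg Selected regression fit (list from [selectRegression()]).
#' @param X Integer vector of input bin counts.
#' @param zeroMu Background mean for zero-input bins (typically the
#'   median IP count of that group).
#' @param muFloor Lower bound on every mean (default 0.1).
#' @return Numeric vector of background means, same length as `X`.
#' @export
predictMu <- function(reg, X, zeroMu, muFloor = 0.1) {
  mu <- numeric(length(X))
  pos <- X >= 1
  if (any(pos)) {
    lx <- log(X[pos])
    f <- switch(reg$kind,
      rlm = reg$beta0 + reg$beta1 * lx,
      gam = as.numeric(mgcv::predict.gam(reg$model,
                                         newdata = data.frame(lx = lx))),
      constant = rep(log(reg$mu0), sum(pos)),
      stop("unknown regression kind")
    )
    mu[pos] <- exp(f)
  }
  mu[!pos] <- zeroMu
  pmax(mu, muFloor)
}

#' Fit the full background component
#'
#' Runs the grouping, size estimation, both regressions (the spline fit
#' silently falls back to the robust linear fit when too few groups are
#' usable), BIC selection, and per-bin mean prediction.
#'
#' @param cm A [BinCounts-class] object, or `NULL` when `Y`/`X` are given.
#' @param Y,X Optional raw count vectors (alternative to `cm`).
#' @param minGroupN Minimum group size used in regression fitting.
#' @param muFloor Lower bound on background means.
#' @return A [BackgroundFit-class] object.
#' @export
fitBackground <- function(cm = NULL, Y = NULL, X = NULL,
                          minGroupN = 3L, muFloor = 0.1) {
  if (!is.null(cm)) {
    Y <- ipCounts(cm)
    X <- inputCounts(cm)
  }
  groups <- groupByInput(Y, X)
  a <- estimateSizeA(groups)
  zeroRow <- groups$mu[groups$x == 0]
  zeroMu <- if (length(zeroRow)) max(zeroRow, muFloor) else muFloor
  rlmFit <- tryCatch(fitRlm(groups, T = length(Y), minGroupN = minGroupN),
                     error = function(e) e)
  gamFit <- tryCatch(fitGam(groups, T = length(Y), minGroupN = minGroupN),
                     error = function(e) NULL)
  if (inherits(rlmFit, "error")) {
    if (is.null(gamFit)) {
      ## too little grouping structure for any regression: constant background
      warning("too few input-count groups for regression; ",
              "using a constant background mean")
      reg <- list(kind = "constant", mu0 = max(stats::median(Y), muFloor),
                  bic = NA_real_)
    } else {
      reg <- gamFit
    }
  } else {
    if (is.null(gamFit) && nrow(.usableGroups(groups, minGroupN)) >= 10)
      warning("spline background fit failed; falling back to robust linear")
    reg <- selectRegression(rlmFit, gamFit)
  }
  mu <- predictMu(reg, X, zeroMu = zeroMu, muFloor = muFloor)
  groups$fitted <- predictMu(reg, groups$x, zeroMu = zeroMu,
                             muFloor = muFloor)
  coefs <- switch(reg$kind,
    rlm = list(beta0 = reg$beta0, beta1 = reg$beta1),
    gam = list(beta0 = reg$beta0, beta = reg$beta),
    constant = list(mu0 = reg$mu0)
  )
  new("BackgroundFit",
      kind = reg$kind, coefficients = coefs, a = a, mu = mu,
      regressionBic = if (is.na(reg$bic)) NA_real_ else reg$bic,
      groups = groups, zeroMu = zeroMu, model = reg)
}
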