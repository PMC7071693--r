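#' Bayesian information criterion
#'
#' `r * ln(T) - 2 * loglik`.
#'
#' @param loglik Maximized log-likelihood.
#' @param r Number of parameters charged.
#' @param T Number of observations (bins).
#' @return BIC score (lower is better).
#' @export
bicScore <- function(loglik, r, T) {
  stopifnot(T >= 1)
  r * log(T) - 2 * loglik
}

## number of signal-side parameters charged in the mode-selection BIC;
## background parameters are common to both modes and excluded
R_1S <- 4L  # b, c, piS, k
R_2S <- 7L  # b1, c1, b2, c2, piS, piS1, k

#' Negative-binomial probability mass
#'
#' Parameterized by (size, prob) with mean `size * (1 - prob) / prob`;
#' returns 0 for negative counts.
#'
#' @param y Integer count vector.
#' @param size Positive size parameter.
#' @param prob Probability parameter in (0, 1].
#' @return Probability masses.
#' @export
nbPmf <- function(y, size, prob) {
  if (prob <= 0 || prob > 1) stop("prob must lie in (0, 1]")
  out <- numeric(length(y))
  ok <- y >= 0
  out[ok] <- stats::dnbinom(y[ok], size = size, prob = prob)
  out
}

#' Background component density
#'
#' `NB(a, a / (a + mu))`: mean `mu`, variance `mu + mu^2 / a`.
#'
#' @param y Integer count vector.
#' @param a Background NB size.
#' @param mu Background mean of the bin.
#' @return Probability masses.
#' @export
densityBackground <- function(y, a, mu) {
  stopifnot(a > 0, mu > 0)
  nbPmf(y, size = a, prob = a / (a + mu))
}

## convolution of a background pmf vector (over 0..n-1) with a signal pmf
## vector, then offset by k: out[y+1] = sum_s bgv[y-k-s+1] * sigv[s+1]
.convOffset <- function(bgv, sigv, k, ymax) {
  n <- length(bgv)
  conv <- stats::convolve(bgv, rev(sigv), type = "open")[seq_len(n)]
  conv[conv < 0] <- 0  # FFT round-off
  out <- numeric(ymax + 1L)
  if (k <= ymax)
    out[(k + 1L):(ymax + 1L)] <- conv[seq_len(ymax - k + 1L)]
  out
}

#' One-signal (1S) component density
#'
#' The signal-bin count is `Y = N + S + k` with `N ~ NB(a, a/(a+mu))`,
#' `S ~ NB(b, c/(c+1))` (mean `b/c`) and `k` the minimum signal count, so
#' the density is the exact finite convolution
#' `sum_s P(N = y - k - s) P(S = s)`, zero below `k`.
#'
#' @param y Integer count vector.
#' @param a,mu Background NB size and bin mean.
#' @param b,c Signal NB size and rate-like parameter (`prob = c/(c+1)`).
#' @param k Minimum signal count (non-negative integer).
#' @return Probability masses.
#' @export
densitySignal1S <- function(y, a, mu, b, c, k) {
  stopifnot(a > 0, mu > 0, b > 0, c > 0, k >= 0)
  ymax <- max(y, k)
  grid <- 0:(ymax - k + 0L)
  bgv <- densityBackground(grid, a, mu)
  sigv <- nbPmf(grid, size = b, prob = c / (c + 1))
  dens <- .convOffset(bgv, sigv, as.integer(k), as.integer(ymax))
  out <- numeric(length(y))
  ok <- y >= 0
  out[ok] <- dens[y[ok] + 1L]
  out
}

#' Two-signal (2S) component density
#'
#' A mixture of two 1S convolutions sharing the offset `k`:
#' `piS1 * conv(NB(b1, c1/(c1+1))) + (1 - piS1) * conv(NB(b2, c2/(c2+1)))`.
#'
#' @param y Integer count vector.
#' @param a,mu Background NB size and bin mean.
#' @param b1,c1,b2,c2 Signal NB parameters of the two components.
#' @param piS1 First-component weight in `[0, 1]`.
#' @param k Minimum signal count.
#' @return Probability masses.
#' @export
densitySignal2S <- function(y, a, mu, b1, c1, b2, c2, piS1, k) {
  stopifnot(piS1 >= 0, piS1 <= 1)
  piS1 * densitySignal1S(y, a, mu, b1, c1, k) +
    (1 - piS1) * densitySignal1S(y, a, mu, b2, c2, k)
}

#' Mixture density of an IP bin count
#'
#' `(1 - piS) * background + piS * signal`, the signal density per the
#' fitted mode.
#'
#' @param y Integer count vector.
#' @param a Background NB size.
#' @param mu Background mean of the bin.
#' @param params Signal parameter list (1S: `b`, `c`, `k`, `piS`;
#'   2S: `b1`, `c1`, `b2`, `c2`, `piS1`, `k`, `piS`).
#' @param mode `"1S"` or `"2S"`.
#' @return Probability masses.
#' @export
mixtureDensity <- function(y, a, mu, params, mode = c("1S", "2S")) {
  mode <- match.arg(mode)
  p0 <- densityBackground(y, a, mu)
  p1 <- if (mode == "1S") {
    densitySignal1S(y, a, mu, params$b, params$c, params$k)
  } else {
    densitySignal2S(y, a, mu, params$b1, params$c1, params$b2, params$c2,
                    params$piS1, params$k)
  }
  (1 - params$piS) * p0 + params$piS * p1
}

## ---- EM machinery ---------------------------------------------------------
## Bins sharing an input count share a background mean, so densities are
## cached per unique-mu group; results are independent of the caching.

.mixCache <- function(Y, mu, a) {
  muU <- unique(mu)
  gi <- match(mu, muU)
  ymax <- max(Y)
  grid <- 0:ymax
  n <- ymax + 1L
  bgmat <- vapply(muU, function(m) densityBackground(grid, a, m),
                  numeric(n))                       # n x G
  ## FFT of the zero-padded background pmfs, computed once: every signal
  ## density is a linear convolution against these columns
  m <- stats::nextn(2L * n - 1L, 2L)
  pad <- matrix(0, m, length(muU))
  pad[seq_len(n), ] <- bgmat
  list(Y = Y, mu = mu, a = a, gi = gi, muU = muU, ymax = ymax,
       n = n, m = m, bgfft = stats::mvfft(pad),
       p0 = bgmat[cbind(Y + 1L, gi)])
}

## per-bin signal density for one NB(b, c/(c+1)) component at offset k,
## for all background groups at once via the cached FFTs
.signalDens <- function(cache, b, c, k) {
  k <- as.integer(k)
  sigv <- numeric(cache$m)
  sigv[seq_len(cache$n)] <- nbPmf(0:cache$ymax, size = b, prob = c / (c + 1))
  sf <- stats::fft(sigv)
  conv <- Re(stats::mvfft(cache$bgfft * sf, inverse = TRUE)) / cache$m
  conv <- conv[seq_len(cache$n), , drop = FALSE]   # P(N + S = 0..ymax)
  conv[conv < 0] <- 0
  smat <- matrix(0, cache$n, ncol(conv))           # shift by the offset k
  if (k <= cache$ymax)
    smat[(k + 1L):cache$n, ] <- conv[seq_len(cache$n - k), , drop = FALSE]
  smat[cbind(cache$Y + 1L, cache$gi)]
}

## method-of-moments NB parameters for the signal component from the
## weighted excess counts W_j = Y_j - k - mu_j. Because a signal bin's
## excess is S_j + (N_j - mu_j), the weighted excess variance contains the
## background NB variance on top of Var(S); `bgVar` (the weighted mean of
## mu_j + mu_j^2 / a) is subtracted so the moments match the signal NB
## itself. The near-Poisson clamp b = 1e3 applies when the corrected
## variance does not exceed the mean.
.momentsNb <- function(W, w, bgVar = 0) {
  sw <- sum(w)
  if (sw <= 0) return(list(b = 1e3, c = 1e3, m1 = 0))
  m1 <- sum(w * W) / sw
  m2 <- sum(w * W^2) / sw
  s2 <- m2 - m1^2 - bgVar
  m1c <- max(m1, 1e-8)
  b <- if (s2 > m1 && m1 > 0) m1^2 / (s2 - m1) else 1e3
  list(b = b, c = b / m1c, m1 = m1)
}

## weighted mean background NB variance of the bins
.wBgVar <- function(mu, a, w) {
  sw <- sum(w)
  if (sw <= 0) return(0)
  sum(w * (mu + mu^2 / a)) / sw
}

.guardLog <- function(p) log(pmax(p, .Machine$double.xmin))

#' EM fit of the one-signal mixture at fixed k
#'
#' E-step: posterior signal responsibilities under the current
#' parameters. M-step: `piS` is the mean responsibility; the signal NB
#' `(b, c)` is refit by method of moments on the responsibility-weighted
#' excess counts `W_j = Y_j - k - mu_j`, with the background NB variance
#' subtracted from the weighted excess variance so the moments target the
#' signal distribution itself. An update that would decrease the
#' observed-data log-likelihood is rejected and the iteration stops
#' there, so the recorded trace is non-decreasing.
#'
#' @param Y IP bin counts.
#' @param mu Per-bin background means.
#' @param a Background NB size.
#' @param k Fixed minimum signal count.
#' @param piInit Initial signal proportion (default 0.1).
#' @param tol Log-likelihood convergence tolerance (default 1e-4).
#' @param maxIter Maximum EM iterations (default 200).
#' @param cache Optional density cache (internal reuse across k).
#' @return List: `params` (with `piS`), `loglik`, `nIter`, `llTrace`,
#'   `gamma` (final responsibilities), `converged`.
#' @export
emFit1S <- function(Y, mu, a, k, piInit = 0.1, tol = 1e-4, maxIter = 200,
                    cache = NULL) {
  T <- length(Y)
  if (is.null(cache)) cache <- .mixCache(Y, mu, a)
  p0 <- cache$p0
  ## initial (b, c) from the moments of the upper-tail bins
  hi <- Y >= stats::quantile(Y, 0.9, type = 1)
  whi <- rep(1, sum(hi))
  init <- .momentsNb(Y[hi] - k - mu[hi], whi, .wBgVar(mu[hi], a, whi))
  b <- init$b; c <- init$c; piS <- piInit
  p1 <- .signalDens(cache, b, c, k)
  mix <- (1 - piS) * p0 + piS * p1
  ll <- sum(.guardLog(mix))
  if (!is.finite(ll))
    stop("non-finite log-likelihood at EM initialization (k = ", k, ")")
  llTrace <- ll
  gamma <- piS * p1 / pmax(mix, .Machine$double.xmin)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    sumG <- sum(gamma)
    if (sumG < 1e-6 * T) {
      warning("signal component vanished during EM (k = ", k, ")")
      piS <- sumG / T
      break
    }
    W <- Y - k - mu
    mom <- .momentsNb(W, gamma, .wBgVar(mu, a, gamma))
    piNew <- sumG / T
    p1New <- .signalDens(cache, mom$b, mom$c, k)
    mixNew <- (1 - piNew) * p0 + piNew * p1New
    llNew <- sum(.guardLog(mixNew))
    if (!is.finite(llNew))
      stop("non-finite log-likelihood at EM iteration ", it,
           " (k = ", k, ", b = ", b, ", c = ", c, ", piS = ", piS, ")")
    if (llNew < ll - 1e-10) {   # moment update overshot: keep current fit
      converged <- TRUE
      break
    }
    b <- mom$b; c <- mom$c; piS <- piNew
    p1 <- p1New; mix <- mixNew
    gamma <- piS * p1 / pmax(mix, .Machine$double.xmin)
    llTrace <- c(llTrace, llNew)
    if (abs(llNew - ll) < tol) { ll <- llNew; converged <- TRUE; break }
    ll <- llNew
  }
  list(params = list(b = b, c = c, k = as.integer(k), piS = piS),
       loglik = ll, nIter = length(llTrace), llTrace = llTrace,
       gamma = gamma, converged = converged)
}

#' EM fit of the two-signal mixture at fixed k
#'
#' Three responsibilities per bin (background, signal 1, signal 2); the
#' two signal NBs share the offset `k` and are refit per component by
#' weighted method of moments. After convergence components are ordered
#' by decreasing mean (`b1/c1 >= b2/c2`). If the inner signal weight
#' collapses (`piS1` outside `[1e-4, 1 - 1e-4]`), the returned fit is the
#' 1S fit at the same k with `collapsed = TRUE`.
#'
#' @inheritParams emFit1S
#' @return List as for [emFit1S()] with 2S `params`, plus `collapsed`.
#' @export
emFit2S <- function(Y, mu, a, k, piInit = 0.1, tol = 1e-4, maxIter = 200,
                    cache = NULL) {
  T <- length(Y)
  if (is.null(cache)) cache <- .mixCache(Y, mu, a)
  p0 <- cache$p0
  hi <- Y >= stats::quantile(Y, 0.9, type = 1)
  Whi <- Y[hi] - k - mu[hi]
  muHi <- mu[hi]
  med <- stats::median(Whi)
  up <- Whi > med
  init1 <- .momentsNb(Whi[up], rep(1, sum(up)),
                      .wBgVar(muHi[up], a, rep(1, sum(up))))
  init2 <- .momentsNb(Whi[!up], rep(1, sum(!up)),
                      .wBgVar(muHi[!up], a, rep(1, sum(!up))))
  b1 <- init1$b; c1 <- init1$c; b2 <- init2$b; c2 <- init2$c
  piS <- piInit; piS1 <- 0.5
  fallback <- function() {
    out <- emFit1S(Y, mu, a, k, piInit = piInit, tol = tol,
                   maxIter = maxIter, cache = cache)
    warning("two-signal component collapsed; falling back to the ",
            "one-signal fit (k = ", k, ")")
    p <- out$params
    out$params <- list(b1 = p$b, c1 = p$c, b2 = p$b, c2 = p$c,
                       piS1 = 1, k = p$k, piS = p$piS)
    out$collapsed <- TRUE
    out
  }
  d1 <- .signalDens(cache, b1, c1, k)
  d2 <- .signalDens(cache, b2, c2, k)
  sig <- piS1 * d1 + (1 - piS1) * d2
  mix <- (1 - piS) * p0 + piS * sig
  ll <- sum(.guardLog(mix))
  if (!is.finite(ll))
    stop("non-finite log-likelihood at EM initialization (2S, k = ", k, ")")
  llTrace <- ll
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    denom <- pmax(mix, .Machine$double.xmin)
    r1 <- piS * piS1 * d1 / denom
    r2 <- piS * (1 - piS1) * d2 / denom
    s1 <- sum(r1); s2 <- sum(r2)
    if (s1 + s2 < 1e-6 * T) {
      warning("signal component vanished during EM (2S, k = ", k, ")")
      piS <- (s1 + s2) / T
      break
    }
    piS1New <- s1 / (s1 + s2)
    if (piS1New < 1e-4 || piS1New > 1 - 1e-4) return(fallback())
    W <- Y - k - mu
    mom1 <- .momentsNb(W, r1, .wBgVar(mu, a, r1))
    mom2 <- .momentsNb(W, r2, .wBgVar(mu, a, r2))
    piNew <- (s1 + s2) / T
    d1New <- .signalDens(cache, mom1$b, mom1$c, k)
    d2New <- .signalDens(cache, mom2$b, mom2$c, k)
    sigNew <- piS1New * d1New + (1 - piS1New) * d2New
    mixNew <- (1 - piNew) * p0 + piNew * sigNew
    llNew <- sum(.guardLog(mixNew))
    if (!is.finite(llNew))
      stop("non-finite log-likelihood at EM iteration ", it, " (2S, k = ",
           k, ")")
    if (llNew < ll - 1e-10) { converged <- TRUE; break }
    b1 <- mom1$b; c1 <- mom1$c; b2 <- mom2$b; c2 <- mom2$c
    piS <- piNew; piS1 <- piS1New
    d1 <- d1New; d2 <- d2New; sig <- sigNew; mix <- mixNew
    llTrace <- c(llTrace, llNew)
    if (abs(llNew - ll) < tol) { ll <- llNew; converged <- TRUE; break }
    ll <- llNew
  }
  ## order components by decreasing mean for identifiability
  if (b1 / c1 < b2 / c2) {
    tmp <- c(b1, c1); b1 <- b2; c1 <- c2; b2 <- tmp[1]; c2 <- tmp[2]
    piS1 <- 1 - piS1
  }
  denom <- pmax(mix, .Machine$double.xmin)
  list(params = list(b1 = b1, c1 = c1, b2 = b2, c2 = c2,
                     piS1 = piS1, k = as.integer(k), piS = piS),
       loglik = ll, nIter = length(llTrace), llTrace = llTrace,
       gamma = piS * sig / denom, converged = converged,
       collapsed = FALSE)
}

#' Optimize the minimum signal count k
#'
#' Runs the EM at every k on the grid and returns the fit whose BIC
#' (`r ln(T) - 2 loglik`, `r` counting the signal-side parameters
#' including k itself) is minimal; ties go to the smaller k.
#'
#' @param Y IP bin counts.
#' @param mu Per-bin background means.
#' @param a Background NB size.
#' @param kGrid Candidate k values (default `0:10`).
#' @param mode `"1S"` or `"2S"`.
#' @param ... Passed to [emFit1S()] / [emFit2S()].
#' @return List: `k` (best), `fit` (EM result at best k), `table`
#'   (`data.frame` of k, loglik, bic).
#' @export
optimizeK <- function(Y, mu, a, kGrid = 0:10, mode = c("1S", "2S"), ...) {
  mode <- match.arg(mode)
  if (length(kGrid) == 0) stop("kGrid must be non-empty")
  kGrid <- sort(unique(as.integer(kGrid)))
  cache <- .mixCache(Y, mu, a)
  r <- if (mode == "1S") R_1S else R_2S
  fits <- vector("list", length(kGrid))
  ll <- bic <- numeric(length(kGrid))
  for (i in seq_along(kGrid)) {
    fits[[i]] <- if (mode == "1S") {
      emFit1S(Y, mu, a, kGrid[i], cache = cache, ...)
    } else {
      emFit2S(Y, mu, a, kGrid[i], cache = cache, ...)
    }
    ll[i] <- fits[[i]]$loglik
    bic[i] <- bicScore(ll[i], r, length(Y))
  }
  best <- which(bic == min(bic))[1]  # ties -> smaller k (grid is sorted)
  list(k = kGrid[best], fit = fits[[best]],
       table = data.frame(k = kGrid, loglik = ll, bic = bic))
}

#' Select the signal mode by BIC
#'
#' @param fit1S,fit2S Per-mode results from [optimizeK()] (lists with a
#'   `table` whose minimum BIC is compared).
#' @return `"1S"` or `"2S"`; ties go to `"1S"`.
#' @export
selectMode <- function(fit1S, fit2S) {
  if (is.null(fit2S)) return("1S")
  bic1 <- min(fit1S$table$bic)
  bic2 <- min(fit2S$table$bic)
  if (bic2 < bic1) "2S" else "1S"
}

#' Fit the full mixture model
#'
#' Optimizes k per mode, fits both signal modes by EM, and selects the
#' mode with the lower BIC (ties to 1S). If every IP count is zero the
#' fit degenerates to pure background with zero signal proportion.
#'
#' @param cm A [BinCounts-class] object, or `NULL` when `Y` is given.
#' @param bg A [BackgroundFit-class] (from [fitBackground()]).
#' @param Y Optional raw IP counts (alternative to `cm`).
#' @param kGrid Candidate minimum signal counts (default `0:10`).
#' @param modes Modes to fit: `c("1S", "2S")` (default), `"1S"` or
#'   `"2S"`.
#' @param ... Passed to the EM fitters.
#' @return A [MixtureFit-class] object.
#' @export
fitMixture <- function(cm = NULL, bg, Y = NULL, kGrid = 0:10,
                       modes = c("1S", "2S"), ...) {
  if (!is.null(cm)) Y <- ipCounts(cm)
  mu <- bg@mu
  a <- bg@a
  stopifnot(length(Y) == length(mu))
  if (all(Y == 0)) {
    p0 <- stats::dnbinom(Y, size = a, mu = mu)
    return(new("MixtureFit", background = bg, mode = "1S",
               params = list(b = 1, c = 1, k = 0L, piS = 0),
               loglik = sum(log(p0)), bic1S = NA_real_, bic2S = NA_real_,
               optimK = 0L, r = R_1S, fits = list()))
  }
  opt1 <- if ("1S" %in% modes) optimizeK(Y, mu, a, kGrid, "1S", ...) else NULL
  opt2 <- if ("2S" %in% modes) optimizeK(Y, mu, a, kGrid, "2S", ...) else NULL
  if (is.null(opt1) && is.null(opt2)) stop("no mode requested")
  mode <- if (is.null(opt1)) "2S" else selectMode(opt1, opt2)
  sel <- if (mode == "1S") opt1 else opt2
  new("MixtureFit",
      background = bg, mode = mode, params = sel$fit$params,
      loglik = sel$fit$loglik,
      bic1S = if (is.null(opt1)) NA_real_ else min(opt1$table$bic),
      bic2S = if (is.null(opt2)) NA_real_ else min(opt2$table$bic),
      optimK = as.integer(sel$k),
      r = if (mode == "1S") R_1S else R_2S,
      fits = list(`1S` = opt1, `2S` = opt2))
}
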