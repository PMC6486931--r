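#' Contrast-enhancement regression curve
#'
#' Evaluates the six-parameter model of a DCE-MRI signal-time curve: an
#' asymmetric generalised logistic (wash-in) multiplied by an exponential term
#' (washout),
#' \deqn{C(t) = G \left(1 - \left[1 + (2^\alpha - 1)
#'   e^{(t - t_{1/2})/\tau}\right]^{-1/\alpha}\right) e^{\beta t^k}.}
#' `G` scales the curve, `alpha` controls asymmetry, `tau` the steepness and
#' `t_half` the time of half maximum of the sigmoid; `beta` (scale) and `k`
#' (exponent) shape the terminal slope: `beta < 0` yields washout, `beta = 0`
#' a persistent plateau at `G`.
#'
#' @param t numeric vector of times in seconds (from contrast arrival).
#' @param G,alpha,tau,t_half,beta,k model parameters; `tau > 0`, `alpha > 0`,
#'   `G >= 0` required.
#' @return Numeric vector `C(t)`.
#' @examples
#' enhancement_curve(5, G = 1, alpha = 1, tau = 1, t_half = 5)  # G/2
#' @export
enhancement_curve <- function(t, G, alpha, tau, t_half, beta = 0, k = 1) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (!is.finite(G) || G < 0) stop("G must be non-negative", call. = FALSE)
  if (any(!is.finite(t))) stop("times must be finite", call. = FALSE)
  inner <- 1 + (2^alpha - 1) * exp((t - t_half) / tau)
  sig <- 1 - inner^(-1 / alpha)
  sig * G * exp(beta * abs(t)^k)
}

# Analytic time derivative of enhancement_curve (used for MDER).
enhancement_curve_deriv <- function(t, G, alpha, tau, t_half, beta = 0, k = 1) {
  e <- exp((t - t_half) / tau)
  D <- 1 + (2^alpha - 1) * e
  S <- 1 - D^(-1 / alpha)
  Sp <- (1 / alpha) * D^(-1 / alpha - 1) * (2^alpha - 1) * e / tau
  E <- exp(beta * abs(t)^k)
  Ep <- E * beta * k * abs(t)^(k - 1) * sign(t)
  # limit at t = 0 for k < 1 is unbounded; curve is never evaluated there in fits
  Ep[t == 0 & k >= 1] <- if (k == 1) beta else 0
  G * (Sp * E + S * Ep)
}

#' Fit the kinetic model to a characteristic kinetic curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, three seeded starts to
#' escape local minima) of [enhancement_curve()] to observed intensities, plus
#' summaries of the fitted curve over a 7-minute window from the start of
#' contrast enhancement: area under the curve (`auc`), maximum enhancement
#' (`cmax`) and its time (`tmax`), earliest time to half maximum (`t_half_obs`)
#' and the maximum of the analytic derivative (`mder`).
#'
#' @param ckc a `ckc` object from [characteristic_kinetic_curve()], or a
#'   numeric vector of intensities (then `times` must be given).
#' @param times acquisition times in seconds from contrast arrival (ignored
#'   when `ckc` is a `ckc` object).
#' @param window_s summary window length in seconds (default 420, i.e. 7 min).
#' @param seed integer seed controlling the randomised extra starts.
#' @return A `kinetic_fit` list: `par` (named G, alpha, tau, t_half, beta, k),
#'   `rss`, `converged`, and `summaries` (auc, cmax, tmax, t_half_obs, mder).
#' @export
fit_kinetic <- function(ckc, times = NULL, window_s = 420, seed = 1L) {
  if (inherits(ckc, "ckc")) { y <- ckc$intensity; times <- ckc$times }
  else y <- as.numeric(ckc)
  if (is.null(times) || length(times) != length(y))
    stop("times must accompany intensities", call. = FALSE)
  if (length(y) < 6L) stop("need at least 6 points to fit 6 parameters", call. = FALSE)
  if (any(times <= 0)) stop("times must be positive (shifted from onset)", call. = FALSE)

  ymax <- max(y); tmax_obs <- times[which.max(y)]
  t_half_guess <- {
    above <- which(y >= ymax / 2)
    if (length(above)) times[above[1L]] else times[ceiling(length(times) / 2)]
  }
  lower <- c(G = 1e-8, alpha = 0.05, tau = 0.5, t_half = min(times) / 2,
             beta = -0.05, k = 0.2)
  upper <- c(G = max(ymax * 10, 1e-6), alpha = 20, tau = 1000,
             t_half = max(times) * 2, beta = 0.05, k = 3)
  starts <- list(c(G = max(ymax, 1e-6), alpha = 1, tau = diff(range(times)) / 10,
                   t_half = t_half_guess, beta = 0, k = 1))
  extra <- with_seed(seed, replicate(2, {
    s <- starts[[1L]]
    s[["alpha"]] <- runif(1, 0.5, 3)
    s[["tau"]] <- runif(1, 5, 80)
    s[["t_half"]] <- runif(1, min(times), max(times))
    s[["beta"]] <- runif(1, -0.002, 0)
    s
  }, simplify = FALSE))
  starts <- c(starts, extra)

  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ enhancement_curve(times, G, alpha, tau, t_half, beta, k),
        start = as.list(s0), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(par = setNames(rep(NA_real_, 6),
                                         c("G", "alpha", "tau", "t_half", "beta", "k")),
                          rss = NA_real_, converged = FALSE,
                          summaries = rep(NA_real_, 5)), class = "kinetic_fit"))
  }
  par <- coef(best$fit)[c("G", "alpha", "tau", "t_half", "beta", "k")]
  sm <- kinetic_summaries(par, window_s = window_s)
  structure(list(par = par, rss = best$rss, converged = TRUE, summaries = sm),
            class = "kinetic_fit")
}

#' Summaries of a fitted enhancement curve over the 7-minute window
#'
#' @param par named parameter vector (G, alpha, tau, t_half, beta, k).
#' @param window_s window length in seconds from the start of enhancement.
#' @return Named vector: `auc` (intensity x seconds), `cmax`, `tmax` (s),
#'   `t_half_obs` (earliest time the curve reaches half of `cmax`, s), `mder`
#'   (maximum analytic derivative, intensity/s).
#' @export
kinetic_summaries <- function(par, window_s = 420) {
  f <- function(t) enhancement_curve(t, par[["G"]], par[["alpha"]], par[["tau"]],
                                     par[["t_half"]], par[["beta"]], par[["k"]])
  fp <- function(t) enhancement_curve_deriv(t, par[["G"]], par[["alpha"]], par[["tau"]],
                                            par[["t_half"]], par[["beta"]], par[["k"]])
  grid <- seq(1e-6, window_s, length.out = 1681L)
  cv <- f(grid)
  auc <- sum((cv[-1] + cv[-length(cv)]) / 2 * diff(grid))
  i <- which.max(cv)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(f, c(lo, hi), maximum = TRUE)
  cmax <- opt$objective; tmax <- opt$maximum
  if (cv[length(cv)] >= max(cv) - 1e-12) { cmax <- cv[length(cv)]; tmax <- window_s }
  # earliest crossing of cmax/2
  half <- cmax / 2
  ix <- which(cv >= half)
  t_half_obs <- if (length(ix) == 0L) NA_real_ else {
    i1 <- ix[1L]
    if (i1 == 1L) grid[1L]
    else uniroot(function(t) f(t) - half, c(grid[i1 - 1L], grid[i1]))$root
  }
  dv <- fp(grid)
  j <- which.max(dv)
  lo <- grid[max(1L, j - 1L)]; hi <- grid[min(length(grid), j + 1L)]
  mder <- optimize(fp, c(lo, hi), maximum = TRUE)$objective
  c(auc = auc, cmax = cmax, tmax = tmax, t_half_obs = t_half_obs, mder = mder)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic fit (sigmoid x exponential)\n")
  print(round(x$par, 5))
  cat(sprintf("RSS %.4g; converged: %s\n", x$rss, x$converged))
  cat("Summaries (7-min window):\n"); print(round(x$summaries, 4))
  invisible(x)
}
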