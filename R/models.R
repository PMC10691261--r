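#' Dose-response model mean functions
#'
#' Evaluate the mean log2 expression of one of the supported dose-response
#' models at the given doses. Parameterisations:
#' \describe{
#'   \item{linear / poly2 / poly3}{`b0 + b1*d (+ b2*d^2 + b3*d^3)`}
#'   \item{power}{`g + b * d^delta`, exponent `delta > 1`}
#'   \item{hill}{`g + v * d^n / (k^n + d^n)`, half-max dose `k > 0`,
#'     Hill coefficient `n` in (0, 18]}
#' }
#' All means are on the log2 expression scale; doses in micromolar.
#'
#' @param kind One of `"null"`, `"linear"`, `"poly2"`, `"poly3"`, `"power"`,
#'   `"hill"`.
#' @param params Named list or vector of parameters for that model.
#' @param dose Numeric vector of doses.
#' @return Numeric vector of model means.
#' @export
dr_mean <- function(kind, params, dose) {
  p <- as.list(params)
  switch(kind,
    null   = rep(p$b0, length(dose)),
    linear = p$b0 + p$b1 * dose,
    poly2  = p$b0 + p$b1 * dose + p$b2 * dose^2,
    poly3  = p$b0 + p$b1 * dose + p$b2 * dose^2 + p$b3 * dose^3,
    power  = p$g + p$b * dose^p$delta,
    hill   = p$g + p$v * dose^p$n / (p$k^p$n + dose^p$n),
    abort(sprintf("unknown model kind '%s'", kind))
  )
}

MODEL_KINDS <- c("linear", "poly2", "poly3", "power", "hill")
# free mean parameters per model; +1 for sigma gives the AIC parameter count
MODEL_NPAR <- c(linear = 2, poly2 = 3, poly3 = 4, power = 3, hill = 4)

SIGMA_FLOOR <- 1e-3  # log2 units; guards zero-residual degenerate fits

ll_normal <- function(rss, n) {
  sigma2 <- max(rss / n, SIGMA_FLOOR^2)
  -n / 2 * (log(2 * pi * sigma2) + rss / (n * sigma2))
}

fit_stats <- function(rss, n, npar_mean) {
  # residual SD reported with the degrees-of-freedom correction so the 1-SD
  # benchmark response is not biased low in small designs; the likelihood and
  # AIC remain the usual MLE quantities
  sigma <- max(sqrt(rss / max(n - npar_mean, 1)), SIGMA_FLOOR)
  ll <- ll_normal(rss, n)
  k <- npar_mean + 1
  list(sigma = sigma, loglik = ll, aic = 2 * k - 2 * ll, npar = k)
}

fit_poly <- function(kind, dose, y) {
  deg <- c(linear = 1L, poly2 = 2L, poly3 = 3L)[[kind]]
  X <- outer(dose, 0:deg, `^`)
  f <- lm.fit(X, y)
  rss <- sum(f$residuals^2)
  params <- setNames(as.list(unname(f$coefficients)), paste0("b", 0:deg))
  params[vapply(params, is.na, logical(1))] <- 0
  s <- fit_stats(rss, length(y), deg + 1L)
  new_drfit(kind, params, s, converged = !any(is.na(f$coefficients)))
}

# profile RSS for power: given delta, (g, b) solve by linear least squares
power_rss <- function(delta, dose, y) {
  X <- cbind(1, dose^delta)
  f <- lm.fit(X, y)
  sum(f$residuals^2)
}

fit_power <- function(dose, y, delta_max = 8) {
  # deterministic multi-start over the restricted exponent range (delta > 1)
  starts <- c(1.2, 2, 3.5, 6)
  best <- NULL
  for (s in starts) {
    lo <- max(1 + 1e-6, s / 2); hi <- min(delta_max, s * 2)
    opt <- optimize(power_rss, interval = c(lo, hi), dose = dose, y = y, tol = 1e-10)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  # one global refinement pass over the full interval around the best start
  opt <- optimize(power_rss, interval = c(1 + 1e-6, delta_max), dose = dose, y = y, tol = 1e-10)
  if (opt$objective < best$objective) best <- opt
  delta <- best$minimum
  f <- lm.fit(cbind(1, dose^delta), y)
  co <- unname(f$coefficients)
  params <- list(g = co[1], b = co[2], delta = delta)
  s <- fit_stats(sum(f$residuals^2), length(y), 3L)
  new_drfit("power", params, s, converged = all(is.finite(co)))
}

# profile RSS for hill: given (log k, n), (g, v) solve by linear least squares
hill_rss <- function(theta, dose, y, n_max = 18) {
  k <- exp(theta[1]); n <- theta[2]
  if (!is.finite(k) || k <= 0 || n <= 0 || n > n_max) return(Inf)
  frac <- dose^n / (k^n + dose^n)
  if (any(!is.finite(frac))) return(Inf)
  f <- lm.fit(cbind(1, frac), y)
  sum(f$residuals^2)
}

fit_hill <- function(dose, y, n_max = 18) {
  dpos <- sort(unique(dose[dose > 0]))
  # fixed multi-start grid: k spanning the dose range on log scale x two slopes
  k_starts <- exp(seq(log(min(dpos)), log(max(dpos)), length.out = 4))
  starts <- expand.grid(logk = log(k_starts), n = c(1, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(
      optim(as.numeric(starts[i, ]), hill_rss, dose = dose, y = y, n_max = n_max,
            method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) &&
        (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) return(failed_fit("hill"))
  k <- exp(best$par[1]); n <- min(max(best$par[2], 1e-6), n_max)
  frac <- dose^n / (k^n + dose^n)
  f <- lm.fit(cbind(1, frac), y)
  co <- unname(f$coefficients)
  if (any(!is.finite(co))) return(failed_fit("hill"))
  params <- list(g = co[1], v = co[2], k = k, n = n)
  s <- fit_stats(sum(f$residuals^2), length(y), 4L)
  new_drfit("hill", params, s, converged = TRUE)
}

new_drfit <- function(kind, params, stats, converged) {
  structure(
    list(kind = kind, params = params, sigma = stats$sigma,
         loglik = stats$loglik, aic = stats$aic, npar = stats$npar,
         converged = converged),
    class = "drfit")
}

failed_fit <- function(kind) {
  structure(list(kind = kind, params = NULL, sigma = NA_real_,
                 loglik = -Inf, aic = Inf, npar = MODEL_NPAR[[kind]] + 1,
                 converged = FALSE),
            class = "drfit")
}

#' Fit a single dose-response model to log2 expression values
#'
#' Maximum-likelihood fit under i.i.d. normal residuals (least squares for the
#' mean; `sigma` is the MLE residual SD, floored at 1e-3 log2 units).
#' Polynomials are solved directly; power and Hill use a deterministic
#' multi-start profile over their nonlinear parameters with the linear
#' parameters solved exactly at each step, so the whole fit is reproducible
#' without randomness.
#'
#' @param kind One of `"linear"`, `"poly2"`, `"poly3"`, `"power"`, `"hill"`.
#' @param dose Numeric vector of doses (one per observation).
#' @param y Numeric vector of log2 expression values.
#' @return A `drfit` object: list with `kind`, `params`, `sigma`, `loglik`,
#'   `aic`, `npar`, `converged`.
#' @export
fit_model <- function(kind, dose, y) {
  stopifnot(length(dose) == length(y))
  if (anyNA(dose) || anyNA(y)) abort("dose and y must not contain NA")
  kind <- match.arg(kind, MODEL_KINDS)
  switch(kind,
    linear = , poly2 = , poly3 = fit_poly(kind, dose, y),
    power = fit_power(dose, y),
    hill = fit_hill(dose, y))
}

#' @export
print.drfit <- function(x, ...) {
  cat(sprintf("<drfit> %s model%s\n", x$kind,
              if (!x$converged) " (fit failed)" else ""))
  if (!is.null(x$params)) {
    cat("  params:", paste(names(x$params),
                           sprintf("%.4g", unlist(x$params)),
                           sep = "=", collapse = ", "), "\n")
    cat(sprintf("  sigma=%.4g  logLik=%.4g  AIC=%.4g\n", x$sigma, x$loglik, x$aic))
  }
  invisible(x)
}
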