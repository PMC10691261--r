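#' Select among nested polynomial fits by likelihood-ratio testing
#'
#' Forward chain: the quadratic replaces the line only if twice the
#' log-likelihood gain exceeds the chi-square critical value at the parameter
#' difference (alpha = 0.05 by default); the cubic is considered only once the
#' quadratic has been adopted, per the usual stepwise nested chain. Zero
#' likelihood gain keeps the simpler model.
#'
#' @param fit_linear,fit_poly2,fit_poly3 `drfit` objects on identical data.
#' @param alpha Test level per step.
#' @return The winning `drfit`.
#' @export
nested_poly_select <- function(fit_linear, fit_poly2, fit_poly3, alpha = 0.05) {
  step_up <- function(best, challenger) {
    if (!challenger$converged) return(best)
    if (!best$converged) return(challenger)
    ddf <- challenger$npar - best$npar
    stat <- 2 * (challenger$loglik - best$loglik)
    if (ddf > 0 && stat > qchisq(1 - alpha, ddf)) challenger else best
  }
  best <- step_up(fit_linear, fit_poly2)
  if (best$kind == "poly2") best <- step_up(best, fit_poly3)
  best
}

#' Select the best overall dose-response model
#'
#' Hill fits whose half-max estimate falls below a third of the lowest
#' (nonzero) tested dose are excluded. The nested-LRT winner among the
#' polynomials is then compared by AIC with the power and any surviving Hill
#' fit; ties are broken toward fewer parameters, then by the fixed order
#' linear < poly2 < poly3 < power < hill.
#'
#' @param fits Named list of `drfit` objects (names in
#'   `c("linear","poly2","poly3","power","hill")`).
#' @param lowest_dose Lowest nonzero dose tested.
#' @param alpha Level of the nested polynomial LRT.
#' @return The winning `drfit`, or `NULL` when every fit failed.
#' @export
select_best_model <- function(fits, lowest_dose, alpha = 0.05) {
  best_poly <- nested_poly_select(fits$linear, fits$poly2, fits$poly3, alpha)
  candidates <- list(best_poly, fits$power, fits$hill)
  keep <- vapply(candidates, function(f) {
    if (is.null(f) || !f$converged) return(FALSE)
    if (f$kind == "hill" && f$params$k < lowest_dose / 3) return(FALSE)
    TRUE
  }, logical(1))
  candidates <- candidates[keep]
  if (length(candidates) == 0) return(NULL)
  kind_rank <- setNames(seq_along(MODEL_KINDS), MODEL_KINDS)
  aics <- vapply(candidates, `[[`, numeric(1), "aic")
  npars <- vapply(candidates, `[[`, numeric(1), "npar")
  ranks <- vapply(candidates, function(f) kind_rank[[f$kind]], numeric(1))
  ord <- order(round(aics, 10), npars, ranks)
  candidates[[ord[1]]]
}

#' Benchmark dose of a fitted curve
#'
#' Smallest dose in `(0, 10 * max_dose]` at which the fitted mean departs from
#' the fitted control mean by `bmr_factor` residual SDs (absolute change, so
#' up- and down-regulation are treated symmetrically). Located by scanning a
#' fine log-spaced grid for the first crossing and refining with root finding
#' to a relative tolerance of 1e-8. Returns `NA` when the curve never reaches
#' the benchmark response.
#'
#' @param fit A converged `drfit`.
#' @param max_dose Highest tested dose.
#' @param bmr_factor Benchmark response in units of the residual SD.
#' @return Dose (micromolar) or `NA_real_`.
#' @export
compute_bmd <- function(fit, max_dose, bmr_factor = 1) {
  if (is.null(fit) || !fit$converged) return(NA_real_)
  bmr <- bmr_factor * fit$sigma
  mu0 <- dr_mean(fit$kind, fit$params, 0)
  f <- function(d) abs(dr_mean(fit$kind, fit$params, d) - mu0) - bmr
  grid <- exp(seq(log(max_dose * 1e-6), log(max_dose * 10), length.out = 600))
  vals <- f(grid)
  if (vals[1] >= 0) {
    root <- uniroot(f, c(0, grid[1]), tol = grid[1] * 1e-9)$root
    return(root)
  }
  cross <- which(vals[-1] >= 0 & vals[-length(vals)] < 0)
  if (length(cross) == 0) return(NA_real_)
  i <- cross[1]
  uniroot(f, c(grid[i], grid[i + 1]), tol = grid[i] * 1e-8)$root
}

# profile log-likelihood at a fixed BMD b: the model is reparameterized so the
# benchmark constraint mu(b) - mu(0) = sgn * bmr_factor * sigma holds exactly,
# and the remaining parameters (including sigma) are maximized out. Returns the
# profiled log-likelihood and the optimum, which callers pass back in as a warm
# start when marching b outward (an under-maximized profile would spuriously
# narrow the interval).
profile_ll <- function(fit, dose, y, b, sgn, bmr_factor = 1, warm = NULL) {
  n <- length(y)
  ll_of_rss <- function(rss, sigma) {
    sigma <- max(sigma, SIGMA_FLOOR)
    -n / 2 * log(2 * pi * sigma^2) - rss / (2 * sigma^2)
  }
  kind <- fit$kind
  if (kind %in% c("linear", "poly2", "poly3")) {
    deg <- c(linear = 1L, poly2 = 2L, poly3 = 3L)[[kind]]
    # beta1 eliminated by the constraint; remaining mean params stay linear
    obj <- function(log_sigma) {
      sigma <- exp(log_sigma)
      offset <- (sgn * bmr_factor * sigma / b) * dose
      X <- matrix(1, length(y), 1)
      if (deg >= 2) X <- cbind(X, dose^2 - b * dose)
      if (deg >= 3) X <- cbind(X, dose^3 - b^2 * dose)
      f <- lm.fit(X, y - offset)
      rss <- sum(f$residuals^2)
      -ll_of_rss(rss, sigma)
    }
    opt <- optimize(obj, interval = log(c(fit$sigma / 50, fit$sigma * 50)), tol = 1e-10)
    return(list(ll = -opt$objective, par = opt$minimum))
  }
  nm <- function(obj, starts) {
    best <- NULL
    for (st in starts) {
      opt <- tryCatch(
        optim(st, obj, method = "Nelder-Mead",
              control = list(maxit = 800, reltol = 1e-11)),
        error = function(e) NULL)
      if (is.null(opt)) next
      opt <- optim(opt$par, obj, method = "Nelder-Mead",
                   control = list(maxit = 800, reltol = 1e-11))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    best
  }
  if (kind == "power") {
    obj <- function(par) {
      delta <- 1 + exp(par[1]); sigma <- exp(par[2])
      if (!is.finite(delta) || delta > 18) return(1e10)
      offset <- (sgn * bmr_factor * sigma / b^delta) * dose^delta
      resid <- y - offset
      g <- mean(resid)
      rss <- sum((resid - g)^2)
      -ll_of_rss(rss, sigma)
    }
    starts <- list(c(log(max(fit$params$delta - 1, 1e-3)), log(fit$sigma)))
    if (!is.null(warm)) starts <- c(list(warm), starts)
    opt <- nm(obj, starts)
    return(list(ll = -opt$value, par = opt$par))
  }
  if (kind == "hill") {
    obj <- function(par) {
      k <- exp(par[1]); nn <- par[2]; sigma <- exp(par[3])
      if (!is.finite(k) || nn <= 0 || nn > 18) return(1e10)
      v <- sgn * bmr_factor * sigma * (k^nn + b^nn) / b^nn
      mu <- v * dose^nn / (k^nn + dose^nn)
      resid <- y - mu
      g <- mean(resid)
      rss <- sum((resid - g)^2)
      -ll_of_rss(rss, sigma)
    }
    starts <- list(
      c(log(fit$params$k), fit$params$n, log(fit$sigma)),
      # half-max near the candidate BMD: lets k travel with b when the
      # constraint forces the curve shape away from the unconstrained MLE
      c(log(b), fit$params$n, log(fit$sigma)))
    if (!is.null(warm)) starts <- c(list(warm), starts)
    opt <- nm(obj, starts)
    return(list(ll = -opt$value, par = opt$par))
  }
  abort(sprintf("no profile available for model '%s'", kind))
}

#' Profile-likelihood confidence bounds on the benchmark dose
#'
#' Reparameterizes the fitted model so the BMD is an explicit parameter and
#' profiles the log-likelihood over it; the lower and upper bounds are the
#' doses at which the profiled log-likelihood drops from its maximum by half
#' the `level` critical value — two one-sided bounds at `(1 + level)/2` (the
#' default `level = 0.90` gives two one-sided 95% bounds). The critical value
#' uses the exact normal-model calibration `n * log(1 + qf(level, 1, n-p)/(n-p))`,
#' which reduces to `qchisq(level, 1)` as n grows but keeps small designs from
#' under-covering. When the profile fails to bracket the drop within
#' `bmd / 1e4` (below) or `bmd * 1e4` (above), the bound is set to that search
#' limit and flagged.
#'
#' @param fit A converged `drfit`.
#' @param dose,y The data the model was fitted to.
#' @param bmd The point estimate from [compute_bmd()].
#' @param bmr_factor Benchmark response in residual-SD units.
#' @param level Two-sided profile level (default 0.90, i.e. one-sided 95%).
#' @return A list with `bmdl`, `bmdu`, and logical `bracketed`.
#' @export
profile_interval <- function(fit, dose, y, bmd, bmr_factor = 1, level = 0.90) {
  stopifnot(is.finite(bmd), bmd > 0)
  n <- length(y)
  df_resid <- n - (fit$npar - 1)
  crit <- if (df_resid > 0) n * log(1 + stats::qf(level, 1, df_resid) / df_resid)
          else qchisq(level, 1)
  mu0 <- dr_mean(fit$kind, fit$params, 0)
  sgn <- sign(dr_mean(fit$kind, fit$params, bmd) - mu0)
  if (sgn == 0) sgn <- 1
  ll_hat <- fit$loglik
  bound <- function(direction) {
    limit <- if (direction < 0) bmd / 1e4 else bmd * 1e4
    step <- if (direction < 0) 1 / 1.6 else 1.6
    warm <- NULL
    dev <- function(b) {
      prof <- profile_ll(fit, dose, y, b, sgn, bmr_factor, warm = warm)
      warm <<- prof$par
      2 * (ll_hat - prof$ll) - crit
    }
    b_in <- bmd
    f_in <- dev(b_in)
    # the profile maximum sits at the MLE, so dev(bmd) <= -crit + tol < 0
    b_out <- bmd * step
    repeat {
      f_out <- dev(b_out)
      if (is.finite(f_out) && f_out > 0) break
      if ((direction < 0 && b_out <= limit) || (direction > 0 && b_out >= limit)) {
        return(list(value = limit, bracketed = FALSE))
      }
      b_in <- b_out; f_in <- f_out
      b_out <- b_out * step
    }
    root <- uniroot(dev, lower = min(b_in, b_out), upper = max(b_in, b_out),
                    f.lower = if (direction < 0) f_out else f_in,
                    f.upper = if (direction < 0) f_in else f_out,
                    tol = bmd * 1e-6)$root
    list(value = root, bracketed = TRUE)
  }
  lo <- bound(-1)
  hi <- bound(1)
  list(bmdl = min(lo$value, bmd), bmdu = max(hi$value, bmd),
       bracketed = lo$bracketed && hi$bracketed)
}

#' Likelihood-ratio lack-of-fit test
#'
#' Compares the fitted mean curve against the saturated per-dose-group-means
#' model: the statistic is `n * log(RSS_model / RSS_saturated)` (twice the
#' log-likelihood gap with the residual SD profiled out in both models),
#' referred to chi-square with degrees of freedom equal to the number of dose
#' levels minus the model's mean parameters. A curve passing exactly through
#' every group mean gives p = 1. Returns `NA` when no degrees of freedom
#' remain.
#'
#' @param fit A converged `drfit`.
#' @param dose,y The fitted data (>= 2 replicates at >= 2 doses).
#' @return P-value in [0, 1], or `NA_real_`.
#' @export
lack_of_fit <- function(fit, dose, y) {
  n <- length(y)
  mu_hat <- dr_mean(fit$kind, fit$params, dose)
  rss_model <- sum((y - mu_hat)^2)
  group_mean <- stats::ave(y, dose)
  rss_sat <- sum((y - group_mean)^2)
  floor_rss <- n * SIGMA_FLOOR^2
  df <- length(unique(dose)) - (fit$npar - 1)
  if (df <= 0) return(NA_real_)
  stat <- n * log(max(rss_model, floor_rss) / max(rss_sat, floor_rss))
  stat <- max(stat, 0)
  pchisq(stat, df, lower.tail = FALSE)
}

QC_FLAGS <- c("pass", "bmd_above_max_dose", "poor_fit", "wide_ci", "no_bmd")

qc_flag_one <- function(bmd, bmdl, bmdu, fit_p, max_dose, max_ratio, fit_p_min) {
  if (is.na(bmd)) return("no_bmd")
  if (bmd > max_dose) return("bmd_above_max_dose")
  if (is.na(fit_p) || fit_p <= fit_p_min) return("poor_fit")
  if (is.finite(bmdl) && is.finite(bmdu) && bmdu / bmdl > max_ratio) return("wide_ci")
  "pass"
}

#' Apply quality-control rejection rules to BMD results
#'
#' Flags each gene, in order: `no_bmd` (no benchmark response reached),
#' `bmd_above_max_dose` (extrapolation beyond the tested range), `poor_fit`
#' (lack-of-fit p <= `fit_p_min`), `wide_ci` (BMDU/BMDL ratio above
#' `max_ratio`); `pass` otherwise.
#'
#' @param results Tibble with columns `bmd`, `bmdl`, `bmdu`, `fit_p`.
#' @param max_dose Highest tested dose.
#' @param max_ratio Maximum allowed BMDU/BMDL ratio (default 40).
#' @param fit_p_min Lack-of-fit rejection level (default 0.1).
#' @return `results` with a `flag` column (and `significant` pass indicator).
#' @export
qc_filter <- function(results, max_dose, max_ratio = 40, fit_p_min = 0.1) {
  results %>%
    mutate(flag = purrr::pmap_chr(
      list(bmd, bmdl, bmdu, fit_p),
      function(bmd, bmdl, bmdu, fit_p) {
        qc_flag_one(bmd, bmdl, bmdu, fit_p, max_dose, max_ratio, fit_p_min)
      }))
}

#' Fit the full model suite to one gene and derive its benchmark dose
#'
#' Runs the five-model fit (linear, quadratic, cubic, power, Hill), the nested
#' polynomial selection and the AIC comparison with the Hill exclusion rule,
#' then computes the BMD at a `bmr_factor`-SD benchmark response, the
#' profile-likelihood BMDL/BMDU, and the lack-of-fit p-value.
#'
#' @param dose Numeric dose vector (one entry per observation; must include 0).
#' @param y Log2 expression values.
#' @param bmr_factor Benchmark response in residual-SD units (default 1).
#' @param alpha Nested-LRT level.
#' @return A `bmd_fit` object; see [tidy.bmd_fit()] and [glance.bmd_fit()].
#' @export
fit_gene_bmd <- function(dose, y, bmr_factor = 1, alpha = 0.05) {
  stopifnot(length(dose) == length(y), any(dose == 0), any(dose > 0))
  fits <- lapply(setNames(MODEL_KINDS, MODEL_KINDS), function(kind) {
    tryCatch(fit_model(kind, dose, y), error = function(e) failed_fit(kind))
  })
  lowest <- min(dose[dose > 0])
  max_dose <- max(dose)
  best <- select_best_model(fits, lowest, alpha)
  if (is.null(best)) {
    return(structure(list(fits = fits, best = NULL, dose = dose, y = y,
                          bmd = NA_real_, bmdl = NA_real_, bmdu = NA_real_,
                          fit_p = NA_real_, bracketed = NA,
                          bmr_factor = bmr_factor, max_dose = max_dose),
                     class = "bmd_fit"))
  }
  bmd <- compute_bmd(best, max_dose, bmr_factor)
  if (is.finite(bmd)) {
    ci <- profile_interval(best, dose, y, bmd, bmr_factor)
    bmdl <- ci$bmdl; bmdu <- ci$bmdu; bracketed <- ci$bracketed
  } else {
    bmdl <- NA_real_; bmdu <- NA_real_; bracketed <- NA
  }
  fit_p <- lack_of_fit(best, dose, y)
  structure(list(fits = fits, best = best, dose = dose, y = y,
                 bmd = bmd, bmdl = bmdl, bmdu = bmdu, fit_p = fit_p,
                 bracketed = bracketed, bmr_factor = bmr_factor,
                 max_dose = max_dose),
            class = "bmd_fit")
}

#' @export
print.bmd_fit <- function(x, ...) {
  if (is.null(x$best)) {
    cat("<bmd_fit> all model fits failed\n")
    return(invisible(x))
  }
  cat(sprintf("<bmd_fit> best model: %s  BMD=%.4g [%.4g, %.4g]  fit p=%.3g\n",
              x$best$kind, x$bmd, x$bmdl, x$bmdu, x$fit_p))
  invisible(x)
}

pack_params <- function(params) {
  if (is.null(params)) return(NA_character_)
  paste(names(params), sprintf("%.6g", unlist(params)), sep = "=", collapse = ";")
}

#' Benchmark-dose modeling across the prefiltered genes of one chemical
#'
#' The per-chemical BMD stage: for each retained gene, fits the model suite on
#' the chemical's samples, selects the best model, computes BMD/BMDL/BMDU and
#' the lack-of-fit p, and applies the QC rejection rules against the highest
#' tested dose.
#'
#' @param expr Log2 expression tibble from [log2_matrix()].
#' @param design Dose design tibble.
#' @param chemical Chemical name.
#' @param genes Character vector of gene ids to model (typically the retained
#'   set from [anova_prefilter()]); defaults to all genes in `expr`.
#' @param bmr_factor Benchmark response in residual-SD units (default 1).
#' @param max_ratio QC limit on BMDU/BMDL (default 40).
#' @param fit_p_min QC lack-of-fit rejection level (default 0.1).
#' @param alpha Nested-LRT level.
#' @return A tibble with columns `gene_id`, `chemical`, `model`, `params`,
#'   `sigma`, `loglik`, `aic`, `fit_p`, `bmd`, `bmdl`, `bmdu`, `flag`.
#' @export
fit_bmd <- function(expr, design, chemical, genes = NULL, bmr_factor = 1,
                    max_ratio = 40, fit_p_min = 0.1, alpha = 0.05) {
  design <- validate_design(design)
  chem <- chemical
  des <- filter(design, chemical == chem)
  if (nrow(des) == 0) abort(sprintf("chemical '%s' not in design", chem))
  if (is.null(genes)) genes <- expr$gene_id
  missing <- setdiff(genes, expr$gene_id)
  if (length(missing) > 0) abort(sprintf("gene '%s' absent from expression matrix", missing[1]))
  m <- as.matrix(expr[match(genes, expr$gene_id), des$sample_id])
  dose <- des$dose
  max_dose <- max(dose)
  rows <- purrr::map(seq_along(genes), function(i) {
    gf <- fit_gene_bmd(dose, as.numeric(m[i, ]), bmr_factor, alpha)
    best <- gf$best
    tibble(
      gene_id = genes[i], chemical = chem,
      model = if (is.null(best)) NA_character_ else best$kind,
      params = if (is.null(best)) NA_character_ else pack_params(best$params),
      sigma = if (is.null(best)) NA_real_ else best$sigma,
      loglik = if (is.null(best)) NA_real_ else best$loglik,
      aic = if (is.null(best)) NA_real_ else best$aic,
      fit_p = gf$fit_p, bmd = gf$bmd, bmdl = gf$bmdl, bmdu = gf$bmdu)
  })
  qc_filter(list_rbind(rows), max_dose, max_ratio, fit_p_min)
}
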