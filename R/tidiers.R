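#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a single dose-response model fit
#'
#' @param x A `drfit` from [fit_model()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`.
#' @method tidy drfit
#' @export
tidy.drfit <- function(x, ...) {
  if (is.null(x$params)) return(tibble(term = character(0), estimate = double(0)))
  tibble(term = c(names(x$params), "sigma"),
         estimate = c(unlist(x$params, use.names = FALSE), x$sigma))
}

#' @rdname tidy.drfit
#' @method glance drfit
#' @export
glance.drfit <- function(x, ...) {
  tibble(model = x$kind, sigma = x$sigma, loglik = x$loglik, aic = x$aic,
         npar = x$npar, converged = x$converged)
}

#' Tidy a per-gene benchmark-dose fit
#'
#' `tidy()` returns the best model's parameters; `glance()` a one-row summary
#' with the selected model, BMD point estimate and profile bounds, and the
#' lack-of-fit p; `augment()` the data with fitted means and residuals.
#'
#' @param x A `bmd_fit` from [fit_gene_bmd()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bmd_fit
#' @export
tidy.bmd_fit <- function(x, ...) {
  if (is.null(x$best)) return(tibble(term = character(0), estimate = double(0)))
  tidy(x$best)
}

#' @rdname tidy.bmd_fit
#' @method glance bmd_fit
#' @export
glance.bmd_fit <- function(x, ...) {
  best <- x$best
  tibble(
    model = if (is.null(best)) NA_character_ else best$kind,
    sigma = if (is.null(best)) NA_real_ else best$sigma,
    loglik = if (is.null(best)) NA_real_ else best$loglik,
    aic = if (is.null(best)) NA_real_ else best$aic,
    fit_p = x$fit_p, bmd = x$bmd, bmdl = x$bmdl, bmdu = x$bmdu,
    bracketed = x$bracketed)
}

#' @rdname tidy.bmd_fit
#' @method augment bmd_fit
#' @export
augment.bmd_fit <- function(x, ...) {
  fitted <- if (is.null(x$best)) rep(NA_real_, length(x$y))
            else dr_mean(x$best$kind, x$best$params, x$dose)
  tibble(dose = x$dose, y = x$y, .fitted = fitted, .resid = x$y - fitted)
}
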