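#' Fit the inverse-divergence crossover model
#'
#' Fits \eqn{y = \log(a) + b x^{-c}} by bounded nonlinear least squares,
#' where y is the per-window crossover value and x the per-window
#' polymorphism weight. With b > 0 and c > 0 the curve decreases
#' monotonically in x, describing local suppression of crossover repair by
#' interhomolog divergence. Initialization is a deterministic multi-start
#' over a log-spaced grid (a in 0.1/1/10, b in 0.1/1/10/100, c in
#' 0.25/0.5/1/2); the best converged start by residual sum of squares wins.
#' Windows with zero polymorphism weight are excluded from the fit
#' (\eqn{x^{-c}} is undefined at 0) and their count is reported, as are
#' excluded partial windows.
#'
#' @param wt A \code{window_table}, or any data.frame with columns
#'   \code{polymorphism_weight} and \code{crossover_value} (plus optional
#'   \code{included}).
#' @param response Column to model: \code{"crossover_value"} (default) or
#'   \code{"crossover_percent"}.
#' @return An object of class \code{divergence_fit}: \code{a}, \code{b},
#'   \code{c}, \code{residual_ss}, \code{converged}, \code{n_windows},
#'   \code{n_zero_poly_excluded}, \code{c_identifiable} and the fitted
#'   \code{nls} object (\code{fit}, NULL for the degenerate flat case).
#' @export
fit_divergence_model <- function(wt, response = "crossover_value") {
  df <- as.data.frame(wt)
  if (!is.null(df$included)) df <- df[df$included, , drop = FALSE]
  if (!all(c("polymorphism_weight", response) %in% names(df)))
    stop("need columns polymorphism_weight and ", response, call. = FALSE)
  x <- df$polymorphism_weight
  y <- df[[response]]
  zero <- x <= 0
  n_zero <- sum(zero)
  x <- x[!zero]; y <- y[!zero]
  if (length(x) < 4L)
    stop("need >= 4 windows with positive polymorphism weight", call. = FALSE)

  if (sd(y) < 1e-12) {
    # flat response: b = 0, c unidentifiable
    return(structure(list(a = exp(mean(y)), b = 0, c = NA_real_,
                          residual_ss = sum((y - mean(y))^2),
                          converged = TRUE, n_windows = length(x),
                          n_zero_poly_excluded = n_zero,
                          c_identifiable = FALSE, fit = NULL),
                     class = "divergence_fit"))
  }

  dat <- data.frame(x = x, y = y)
  starts <- expand.grid(a = c(0.1, 1, 10), b = c(0.1, 1, 10, 100),
                        c = c(0.25, 0.5, 1, 2))
  best <- NULL
  diagnostics <- character()
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ log(a) + b * x^(-c), data = dat,
                        start = as.list(starts[k, ]),
                        lower = c(a = 1e-9, b = -Inf, c = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        diagnostics <<- c(diagnostics, conditionMessage(e))
        NULL
      })
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("divergence model fit failed from every start; messages: ",
         paste(unique(diagnostics), collapse = "; "), call. = FALSE)
  cf <- coef(best$fit)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
                 residual_ss = best$rss, converged = TRUE,
                 n_windows = length(x), n_zero_poly_excluded = n_zero,
                 c_identifiable = TRUE, fit = best$fit),
            class = "divergence_fit")
}

#' @export
print.divergence_fit <- function(x, ...) {
  cat(sprintf("divergence model y = log(a) + b*x^(-c):\n"))
  cat(sprintf("  a = %.6g, b = %.6g, c = %s\n", x$a, x$b,
              if (is.na(x$c)) "unidentifiable (flat response)"
              else sprintf("%.6g", x$c)))
  cat(sprintf("  residual SS = %.4g over %d windows (%d zero-polymorphism excluded)\n",
              x$residual_ss, x$n_windows, x$n_zero_poly_excluded))
  invisible(x)
}

#' Predicted crossover value under a divergence fit
#'
#' @param object A \code{divergence_fit}.
#' @param newdata Numeric vector of polymorphism weights (> 0).
#' @param ... Unused.
#' @return Predicted crossover values.
#' @export
predict.divergence_fit <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  if (any(x <= 0)) stop("model undefined at x <= 0", call. = FALSE)
  if (is.na(object$c)) return(rep(log(object$a), length(x)))
  log(object$a) + object$b * x^(-object$c)
}
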