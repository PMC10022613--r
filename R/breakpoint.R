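#' Two-segment (breakpoint) linear regression
#'
#' Fits `y = b0 + b1 x + b2 (x - psi)+` with an unknown breakpoint `psi`
#' by the iterative working-linear-model scheme: at the current guess the
#' model `y ~ x + (x - psi)+ + I(x > psi)` is fitted and the breakpoint is
#' updated by `psi <- psi - gamma / b2` (the first-order correction implied
#' by the shift coefficient `gamma`) until the shift term vanishes.  If the iteration diverges or leaves the data range, an
#' exhaustive SSE grid search over interior candidate breakpoints is used
#' instead.  A flat SSE profile together with an insignificant slope
#' change yields a "no breakpoint" result rather than an error.
#'
#' @param x,y Numeric vectors (n >= 8); `x` must span the breakpoint.
#' @param init Initial breakpoint; default the median of `x`.
#' @param max_iter Maximum iterations.
#' @param tol Convergence tolerance on the breakpoint update.
#' @param n_boot Bootstrap replicates for the breakpoint standard error
#'   (0 skips the bootstrap).
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `bpfit`: list with `breakpoint`, `se`
#'   (bootstrap), `slope_before`, `slope_after`, `intercept`,
#'   `no_breakpoint`, `converged`, `iterations`, `method`
#'   (`"iterative"` or `"grid"`), the final `lm` fit, and the data.
#' @examples
#' x <- seq(-6, -0.5, by = 0.1)
#' y <- ifelse(x > -3.62, 0.8, 0.8 + 0.3 * (x + 3.62))
#' fit_breakpoint(x, y)$breakpoint   # -3.62
#' @export
fit_breakpoint <- function(x, y, init = NULL, max_iter = 50L,
                           tol = 1e-8, n_boot = 0L, seed = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 8L) stop("need at least 8 points", call. = FALSE)
  rx <- range(x)

  # no detectable slope change at all?
  lm0 <- stats::lm(y ~ x)
  sse0 <- sum(stats::residuals(lm0)^2)
  tss <- sum((y - mean(y))^2)
  if (sse0 <= max(1e-10 * tss, 1e-20))
    return(bpfit_none(x, y, lm0, sse0))

  fit_at <- function(psi) {
    u <- pmax(x - psi, 0)
    stats::lm(y ~ x + u)
  }
  sse_at <- function(psi) sum(stats::residuals(fit_at(psi))^2)

  iterate <- function(psi) {
    for (it in seq_len(max_iter)) {
      u <- pmax(x - psi, 0)
      v <- as.numeric(x > psi)
      fm <- stats::lm(y ~ x + u + v)
      b2 <- stats::coef(fm)[["u"]]
      g <- stats::coef(fm)[["v"]]
      if (!is.finite(b2) || !is.finite(g) || abs(b2) < 1e-12)
        return(list(ok = FALSE))
      step <- -g / b2
      psi_new <- psi + step
      if (psi_new <= rx[1] || psi_new >= rx[2]) return(list(ok = FALSE))
      if (abs(step) < tol)
        return(list(ok = TRUE, psi = psi_new, iterations = it))
      psi <- psi_new
    }
    list(ok = FALSE)
  }

  grid_search <- function() {
    cand <- sort(unique(x))
    cand <- cand[cand > rx[1] & cand < rx[2]]
    cand <- cand[-c(1:2, (length(cand) - 1):length(cand))]
    sse <- vapply(cand, sse_at, 0)
    list(psi = cand[which.min(sse)], sse = sse, cand = cand)
  }

  it <- iterate(if (is.null(init)) stats::median(x) else init)
  method <- "iterative"
  if (!it$ok) {
    gs <- grid_search()
    # flat profile check: no candidate improves on the single line
    if (min(gs$sse) > 0.999 * sse0)
      return(bpfit_none(x, y, lm0, sse0))
    ref <- iterate(gs$psi)
    it <- if (ref$ok) ref else list(psi = gs$psi, iterations = NA_integer_)
    method <- if (ref$ok) "grid+iterative" else "grid"
  }
  psi_hat <- it$psi

  fm <- fit_at(psi_hat)
  sse1 <- sum(stats::residuals(fm)^2)
  # F test of the slope change (2 extra parameters: psi and the new slope);
  # an (almost) exact two-segment fit is evidence enough on its own
  if (sse1 > 1e-12 * sse0) {
    fstat <- ((sse0 - sse1) / 2) / (sse1 / (n - 4))
    pval <- stats::pf(fstat, 2, n - 4, lower.tail = FALSE)
    if (!is.finite(fstat) || pval > 0.05)
      return(bpfit_none(x, y, lm0, sse0))
  }

  se <- NA_real_
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    bp_b <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, replace = TRUE)
      fb <- tryCatch(fit_breakpoint(x[i], y[i], init = psi_hat,
                                    max_iter = max_iter, tol = tol),
                     error = function(e) NULL)
      if (is.null(fb) || fb$no_breakpoint) NA_real_ else fb$breakpoint
    }, 0)
    se <- stats::sd(bp_b, na.rm = TRUE)
  }

  cf <- stats::coef(fm)
  structure(list(breakpoint = psi_hat, se = se,
                 intercept = cf[[1]], slope_before = cf[["x"]],
                 slope_after = cf[["x"]] + cf[["u"]],
                 no_breakpoint = FALSE,
                 converged = !is.na(it$iterations),
                 iterations = it$iterations, method = method,
                 fit = fm, x = x, y = y),
            class = "bpfit")
}

bpfit_none <- function(x, y, lm0, sse0) {
  cf <- stats::coef(lm0)
  structure(list(breakpoint = NA_real_, se = NA_real_,
                 intercept = cf[[1]], slope_before = cf[[2]],
                 slope_after = cf[[2]], no_breakpoint = TRUE,
                 converged = TRUE, iterations = 0L, method = "none",
                 fit = lm0, x = x, y = y),
            class = "bpfit")
}

#' @export
print.bpfit <- function(x, ...) {
  if (x$no_breakpoint) {
    cat("Two-segment regression: no breakpoint detected (single line)\n")
    cat(sprintf("  slope %.4g, intercept %.4g\n",
                x$slope_before, x$intercept))
  } else {
    cat("Two-segment regression\n")
    cat(sprintf("  breakpoint: %.4f%s\n", x$breakpoint,
                if (is.finite(x$se)) sprintf(" (boot SE %.3g)", x$se) else ""))
    cat(sprintf("  slopes: %.4g before, %.4g after (%s)\n",
                x$slope_before, x$slope_after, x$method))
  }
  invisible(x)
}

#' @export
summary.bpfit <- function(object, ...) {
  print(object)
  cat("\nWorking linear model:\n")
  print(summary(object$fit)$coefficients)
  invisible(object)
}

#' @export
coef.bpfit <- function(object, ...) {
  c(intercept = object$intercept, slope_before = object$slope_before,
    slope_after = object$slope_after, breakpoint = object$breakpoint)
}

#' @export
predict.bpfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.list(newdata)) newdata$x else newdata
  if (object$no_breakpoint)
    return(object$intercept + object$slope_before * x)
  object$intercept + object$slope_before * x +
    (object$slope_after - object$slope_before) * pmax(x - object$breakpoint, 0)
}

#' @export
residuals.bpfit <- function(object, ...) object$y - predict(object)

#' @export
plot.bpfit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "x", ylab = "y", ...)
  o <- order(x$x)
  graphics::lines(x$x[o], predict(x)[o], col = 2, lwd = 2)
  if (!x$no_breakpoint) graphics::abline(v = x$breakpoint, lty = 3, col = 4)
  invisible(x)
}
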