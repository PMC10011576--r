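#' Build acidification dose-response points from rate measurements
#'
#' Converts per-replicate treatment rates at each acidification level into
#' percent changes relative to the mean of the control replicates, giving
#' one dose-response point per (level, replicate). Treatments at different
#' levels are independent vessels, so changes are computed against the
#' control mean rather than by replicate pairing.
#'
#' @param treatment_rates A data.frame with columns `delta_ph` (>= 0,
#'   control pH minus treatment pH), `replicate`, `rate`, and optionally
#'   `site_id`.
#' @param control_rates Numeric vector of control replicate rates (same
#'   units as the treatment rates); its mean must be nonzero.
#' @return A data.frame with columns `site_id`, `replicate`, `delta_ph`,
#'   `percent_change`.
#' @export
build_response_points <- function(treatment_rates, control_rates) {
  req <- c("delta_ph", "replicate", "rate")
  missing_cols <- setdiff(req, names(treatment_rates))
  if (length(missing_cols)) {
    stop("treatment_rates lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(treatment_rates$delta_ph < 0)) {
    stop("delta_ph must be >= 0 (control pH minus treatment pH)",
         call. = FALSE)
  }
  ctrl <- mean(control_rates)
  if (!is.finite(ctrl) || ctrl == 0) {
    stop("control mean rate is zero or non-finite: percent change undefined",
         call. = FALSE)
  }
  data.frame(
    site_id = treatment_rates$site_id %||% NA_character_,
    replicate = treatment_rates$replicate,
    delta_ph = treatment_rates$delta_ph,
    percent_change = percent_change(treatment_rates$rate, ctrl)
  )
}

#' Fit an acidification-response polynomial through the origin
#'
#' Least-squares fit of percent change on `(delta_ph, delta_ph^2, ...)` with
#' the intercept structurally constrained to zero: an unacidified sample
#' (delta_ph = 0) has zero percent change by construction, so the curve
#' passes through the origin exactly rather than estimating an intercept.
#' Significance is an F-test of the fitted polynomial against the all-zero
#' (no response) null.
#'
#' @param points A data.frame with columns `delta_ph` and `percent_change`
#'   (as from [build_response_points()]).
#' @param degree Polynomial degree, 1 to 3 (default 2).
#' @return An object of class `response_curve`: list with `degree`,
#'   `coefficients` (terms x^1..x^degree), `se` (their standard errors),
#'   `r_squared`, `p_value`, `domain` (`[0, max delta_ph]`), `n`.
#' @examples
#' pts <- data.frame(delta_ph = rep(c(0.1, 0.3, 0.6), each = 2))
#' pts$percent_change <- -40 * pts$delta_ph - 60 * pts$delta_ph^2
#' fit_response(pts)$coefficients  # c(-40, -60)
#' @export
fit_response <- function(points, degree = 2) {
  stopifnot(all(c("delta_ph", "percent_change") %in% names(points)))
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3", call. = FALSE)
  x <- points$delta_ph
  y <- points$percent_change
  if (any(!is.finite(y))) stop("percent_change must be finite", call. = FALSE)
  # the origin is an implicit (exact) level; nonzero levels must still span
  # the polynomial
  if (length(unique(x[x > 0])) < degree) {
    stop("need at least `degree` distinct nonzero delta_ph levels",
         call. = FALSE)
  }
  X <- outer(x, seq_len(degree), `^`)
  colnames(X) <- paste0("x", seq_len(degree))
  fit <- stats::lm(y ~ 0 + X)
  cf <- unname(stats::coef(fit))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum(y^2)  # null model is identically zero
  n <- length(y)
  if (tss == 0) {
    r2 <- NA_real_
    p <- 1
    se <- rep(0, degree)
  } else {
    r2 <- 1 - rss / tss
    df2 <- n - degree
    fstat <- ((tss - rss) / degree) / (rss / df2)
    p <- if (is.finite(fstat)) stats::pf(fstat, degree, df2,
                                         lower.tail = FALSE) else 0
    # direct normal-equations SEs: avoids summary.lm's perfect-fit warning
    # on zero-noise data, where se is legitimately 0
    sigma2 <- if (df2 > 0) rss / df2 else 0
    se <- sqrt(diag(chol2inv(chol(crossprod(X)))) * sigma2)
  }
  structure(
    list(degree = degree, coefficients = cf, se = unname(se),
         r_squared = r2, p_value = p, domain = c(0, max(x)), n = n),
    class = "response_curve"
  )
}

#' @export
print.response_curve <- function(x, ...) {
  terms <- paste(sprintf("%+.4g x^%d", x$coefficients, seq_len(x$degree)),
                 collapse = " ")
  cat(sprintf(
    "<response_curve> %%change = %s  (R2 = %.3f, P = %.3g, n = %d, domain [0, %.3g])\n",
    terms, x$r_squared, x$p_value, x$n, x$domain[2]))
  invisible(x)
}

#' Evaluate an acidification-response curve at a pH decrease
#'
#' Polynomial evaluation of a fitted [fit_response()] curve. Evaluation
#' beyond the fitted delta_ph range is allowed but warned about as
#' extrapolation. `evaluate_response(curve, 0)` is exactly zero by the
#' origin constraint.
#'
#' @param curve A `response_curve`.
#' @param delta_ph pH decrease(s) at which to evaluate.
#' @return Percent change(s).
#' @examples
#' pts <- data.frame(delta_ph = c(0.1, 0.3, 0.6))
#' pts$percent_change <- -40 * pts$delta_ph - 60 * pts$delta_ph^2
#' evaluate_response(fit_response(pts), 0.21)  # -11.046
#' @export
evaluate_response <- function(curve, delta_ph) {
  stopifnot(inherits(curve, "response_curve"))
  if (any(delta_ph < curve$domain[1] | delta_ph > curve$domain[2])) {
    warning("evaluating response curve outside its fitted domain [",
            curve$domain[1], ", ", signif(curve$domain[2], 3),
            "]: extrapolation", call. = FALSE)
  }
  vapply(delta_ph,
         function(d) sum(curve$coefficients * d^seq_len(curve$degree)),
         numeric(1))
}
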