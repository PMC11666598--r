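#' Natural cubic spline basis with quartile knots
#'
#' Builds the natural cubic spline basis used for the baseline-metric term
#' of the amplitude models: `df` basis columns, linear beyond the boundary
#' knots, interior knots at the quartiles (25th/50th/75th percentiles for
#' `df = 4`) and boundary knots at the observed min/max. Thin wrapper over
#' [splines::ns()] that also reports the knots, since the printed
#' coefficient bins are the knot intervals.
#'
#' @param x Numeric vector of baseline metric values (at least 10 distinct
#'   values).
#' @param df Degrees of freedom / number of basis columns (default 4).
#' @return List with `basis` (n x df matrix), `knots` (interior) and
#'   `boundary` (boundary knots).
#' @export
natural_spline_basis <- function(x, df = 4) {
  if (length(unique(x[!is.na(x)])) < 10) {
    stop("`x` must have at least 10 distinct values", call. = FALSE)
  }
  b <- splines::ns(x, df = df)
  list(basis = matrix(b, ncol = df,
                      dimnames = list(NULL, paste0("ns", seq_len(df)))),
       knots = as.numeric(attr(b, "knots")),
       boundary = as.numeric(attr(b, "Boundary.knots")))
}

#' Generalized linear model of participant amplitude on covariates
#'
#' Fits the Gaussian identity-link model
#' \deqn{amp = \beta_0 + \beta_1 age + \beta_2 ns(baseline, 4) + \beta_3 BMI
#'   + \varepsilon}
#' where `baseline` is the participant's mean raw metric value (natural
#' cubic spline with `df` basis terms, quartile knots) and age and BMI enter
#' linearly. Coefficients are reported with large-sample 95% confidence
#' intervals and p-values; the spline coefficient rows are labelled by their
#' knot intervals.
#'
#' @param amps Tibble with one row per participant: `participant_amp`,
#'   `age`, `bmi`, `baseline`.
#' @param metric Label for the baseline metric (used in row labels).
#' @param df Spline degrees of freedom (default 4).
#' @return Object of class `amplitude_glm`: list with `lm`, `knots`,
#'   `boundary`, `coef_table` (tibble of term, estimate, CI, p), `n`,
#'   `r_squared`, `metric`, `df`.
#' @export
fit_amplitude_glm <- function(amps, metric = c("rhr", "rmssd"), df = 4) {
  metric <- match.arg(metric)
  need <- c("participant_amp", "age", "bmi", "baseline")
  miss <- setdiff(need, names(amps))
  if (length(miss) > 0) {
    stop("`amps` must contain columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- tidyr::drop_na(amps, dplyr::all_of(need))
  nsb <- natural_spline_basis(d$baseline, df = df)
  fit <- stats::lm(
    participant_amp ~ age + splines::ns(baseline, df = df) + bmi, data = d)
  qr_rank <- fit$qr$rank
  if (qr_rank < length(stats::coef(fit))) {
    stop("design matrix is rank deficient; covariates are collinear",
         call. = FALSE)
  }

  unit <- if (metric == "rhr") "BPM" else "ms"
  edges <- c(nsb$boundary[1], nsb$knots, nsb$boundary[2])
  bin_labels <- c(
    sprintf("%s (< %.1f %s)", toupper(metric), edges[2], unit),
    vapply(seq_len(df - 2), function(i) {
      sprintf("%s (%.1f %s - %.1f %s)", toupper(metric),
              edges[i + 1], unit, edges[i + 2], unit)
    }, character(1)),
    sprintf("%s (> %.1f %s)", toupper(metric), edges[df], unit)
  )
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  term <- rownames(sm)
  pretty <- term
  pretty[term == "(Intercept)"] <- "Intercept"
  pretty[term == "age"] <- "Age"
  pretty[term == "bmi"] <- "BMI"
  spline_rows <- grepl("^splines::ns", term)
  pretty[spline_rows] <- bin_labels
  coef_table <- tibble::tibble(
    term = pretty,
    estimate = sm[, "Estimate"],
    ci_lower = ci[, 1],
    ci_upper = ci[, 2],
    p_value = sm[, "Pr(>|t|)"]
  )
  structure(list(
    lm = fit, knots = nsb$knots, boundary = nsb$boundary,
    coef_table = coef_table, n = nrow(d),
    r_squared = summary(fit)$r.squared, metric = metric, df = df
  ), class = "amplitude_glm")
}

#' @export
print.amplitude_glm <- function(x, ...) {
  cat(sprintf("<amplitude_glm> %s_amp ~ age + ns(baseline, %d) + bmi, n = %d, R^2 = %.3f\n",
              toupper(x$metric), x$df, x$n, x$r_squared))
  print(x$coef_table)
  invisible(x)
}

#' Partial dependence of a covariate-model term
#'
#' Isolated contribution of one model term over a grid of its input, other
#' terms held at reference values (their sample means), with a pointwise 95%
#' band from the coefficient covariance. The curve is centered so that it is
#' zero at the reference point.
#'
#' @param fit An [fit_amplitude_glm()] object.
#' @param term One of `"age"`, `"baseline"`, `"bmi"`.
#' @param n_grid Number of grid points (default 200).
#' @return Tibble `x`, `estimate`, `ci_lower`, `ci_upper`.
#' @export
partial_dependence_glm <- function(fit, term = c("age", "baseline", "bmi"),
                                   n_grid = 200) {
  stopifnot(inherits(fit, "amplitude_glm"))
  term <- match.arg(term)
  d <- fit$lm$model
  data0 <- data.frame(
    age = mean(d$age), bmi = mean(d$bmi),
    baseline = mean(fit$boundary)  # midpoint of baseline range as reference
  )
  xr <- switch(term,
               age = range(d$age),
               bmi = range(d$bmi),
               baseline = fit$boundary)
  grid <- seq(xr[1], xr[2], length.out = n_grid)
  newd <- data0[rep(1, n_grid), , drop = FALSE]
  newd[[term]] <- grid

  # model.frame() honours predvars, freezing the training spline knots
  mt <- stats::delete.response(stats::terms(fit$lm))
  X <- stats::model.matrix(mt, stats::model.frame(mt, newd))
  X0 <- stats::model.matrix(mt, stats::model.frame(mt, data0))
  D <- sweep(X, 2, as.numeric(X0))
  beta <- stats::coef(fit$lm)
  est <- as.numeric(D %*% beta)
  se <- sqrt(rowSums((D %*% stats::vcov(fit$lm)) * D))
  tibble::tibble(x = grid, estimate = est,
                 ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se)
}
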