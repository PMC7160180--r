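#' Weighted linear regression through the origin
#'
#' The standard model for phylogenetically independent contrasts: no
#' intercept, observation weights carrying reconstruction confidence. When
#' the predictors are the indicator columns of the three-level host-change
#' factor, each coefficient is the weighted mean of the contrasts in that
#' class, which is what makes per-class coefficients interpretable. Fitting
#' is delegated to [stats::lm()]; the closed-form normal equations
#' \eqn{\beta = (X^T W X)^{-1} X^T W y} are what the result must reproduce.
#'
#' @param data A data frame.
#' @param formula A formula without an intercept (one is removed if
#'   present, with a message), e.g. `value ~ class` or
#'   `value ~ host_age + early_adoption + host_diversity + volatility`.
#' @param weights Optional column name (string) holding observation weights
#'   in (0, 1]; NULL means unweighted.
#' @return An object of class `hostshift_wls` wrapping the `lm` fit, with
#'   [tidy()] and [glance()] methods.
#' @export
wls_origin <- function(data, formula, weights = NULL) {
  data <- as.data.frame(data)
  if (nrow(data) == 0) abort("Cannot fit a model to an empty design table.")
  tt <- stats::terms(formula)
  if (attr(tt, "intercept") == 1) {
    formula <- stats::update(formula, . ~ . + 0)
    inform("Intercept removed: contrast regressions pass through the origin.")
  }
  w <- NULL
  if (!is.null(weights)) {
    if (!weights %in% names(data)) abort(paste0("No weight column '", weights, "'."))
    w <- data[[weights]]
    if (any(w <= 0)) abort("Weights must be > 0.")
  }
  X <- stats::model.matrix(formula, data)
  if (nrow(X) < ncol(X)) abort("Fewer observations than model terms.")
  if (qr(X)$rank < ncol(X)) abort("Rank-deficient design matrix.")
  fit <- if (is.null(w)) {
    stats::lm(formula, data = data)
  } else {
    data$.w <- w
    stats::lm(formula, data = data, weights = .w)
  }
  structure(list(fit = fit, formula = formula, weights = weights,
                 n = nrow(data)),
            class = "hostshift_wls")
}

#' @export
print.hostshift_wls <- function(x, ...) {
  cat("Weighted through-origin linear model (n =", x$n, ")\n")
  print(tidy(x))
  invisible(x)
}

#' @method tidy hostshift_wls
#' @export
tidy.hostshift_wls <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  s <- summary(x$fit)$coefficients
  out <- tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
  # degenerate zero-variance fits: a zero coefficient is exactly null
  degen <- !is.finite(out$statistic) & abs(out$estimate) < 1e-12
  out$statistic[degen] <- 0
  out$p.value[degen] <- 1
  if (conf.int) {
    ci <- stats::confint(x$fit, level = conf.level)
    out$conf.low <- ci[, 1]
    out$conf.high <- ci[, 2]
  }
  out
}

#' @method glance hostshift_wls
#' @export
glance.hostshift_wls <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    df.residual = x$fit$df.residual,
    nobs = x$n
  )
}

#' Coefficient plot for a fitted contrast model
#'
#' Point estimates with 95 percent confidence intervals per model term.
#'
#' @param object A `hostshift_wls` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hostshift_wls
#' @export
autoplot.hostshift_wls <- function(object, ...) {
  td <- tidy(object, conf.int = TRUE)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "coefficient (focal - sister contrast units)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Fit the host-use-change contrast model
#'
#' Filters a contrast table to one response, drops `complex` nodes (the
#' factor has exactly three levels), and fits the weighted through-origin
#' regression of contrast values on the gain/loss/none indicators.
#'
#' @param contrasts A `hostshift_contrasts` tibble.
#' @param response One of `"waiting_time"`, `"exclusive"`, `"inclusive"`.
#' @param weighted Use the event confidence weights?
#' @return A `hostshift_wls` fit.
#' @export
fit_change_model <- function(contrasts, response, weighted = TRUE) {
  df <- contrasts[contrasts$response == response &
                    contrasts$class %in% c("gain", "loss", "none"), ]
  if (nrow(df) == 0) abort(paste0("No usable contrasts for response '",
                                  response, "'."))
  df$class <- factor(df$class, levels = c("gain", "loss", "none"))
  wls_origin(df, value ~ class + 0, weights = if (weighted) "weight" else NULL)
}

#' Fit the ecological-opportunity model
#'
#' Weighted through-origin regression of gain-event contrast values on the
#' four opportunity indices.
#'
#' @param design Output of [assemble_design()].
#' @param response Contrast response to model.
#' @param weighted Use the event confidence weights?
#' @return A `hostshift_wls` fit.
#' @export
fit_opportunity_model <- function(design, response, weighted = TRUE) {
  df <- design[design$response == response, ]
  if (nrow(df) < 4) abort("Too few gain events to fit the opportunity model.")
  wls_origin(df,
             value ~ host_age + early_adoption + host_diversity + volatility + 0,
             weights = if (weighted) "weight" else NULL)
}
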