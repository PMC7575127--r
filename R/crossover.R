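#' Diet effect from a 2x2 crossover
#'
#' The classical two-period crossover estimator on animal-phase means. With
#' \eqn{d_i = y_i(\mathrm{phase 1}) - y_i(\mathrm{phase 2})}, the diet
#' effect (treatment minus control) is
#' \eqn{(\bar d_{TC} - \bar d_{CT}) / 2}, where \eqn{\bar d_{TC}} averages
#' the animals that received the treatment diet first. Its standard error
#' comes from the pooled two-sample variance of \eqn{d/2}, with
#' \eqn{n - 2} degrees of freedom. On balanced data this coincides with the
#' OLS diet coefficient from a model with diet, phase and animal indicators,
#' and is invariant to per-animal and per-phase additive shifts.
#'
#' @param values Numeric response, one value per animal-phase, aligned with
#'   the rows of \code{layout}.
#' @param layout Data frame with columns \code{animal_id}, \code{phase},
#'   \code{diet} (e.g. the \code{layout} element of a
#'   \code{\link{trial_dataset}}, or a \code{\link{trial_budgets}} table).
#' @param treatment,control Diet labels orienting the contrast
#'   (default \code{"PL"} minus \code{"RG"}).
#' @return An object of class \code{"effect_estimate"}: \code{response}
#'   (label, NA unless set by the caller), \code{diet_effect}, \code{se},
#'   \code{df}, \code{t_stat}, \code{p_value}, and \code{lsmeans} (named
#'   per-diet means).
#' @export
diet_effect <- function(values, layout, treatment = "PL", control = "RG") {
  stopifnot(length(values) == nrow(layout))
  df0 <- data.frame(animal_id = as.character(layout$animal_id),
                    phase = layout$phase, diet = as.character(layout$diet),
                    y = as.numeric(values), stringsAsFactors = FALSE)
  if (anyNA(df0$y)) stop("response contains missing values")
  phases <- sort(unique(df0$phase))
  if (length(phases) != 2) stop("exactly two phases are required")
  wide <- merge(df0[df0$phase == phases[1], c("animal_id", "diet", "y")],
                df0[df0$phase == phases[2], c("animal_id", "y")],
                by = "animal_id", suffixes = c("_1", "_2"))
  if (nrow(wide) * 2 != nrow(df0))
    stop("every animal must have both phases")
  wide$d <- wide$y_1 - wide$y_2
  trt_first <- wide$diet == treatment
  if (!any(trt_first) || all(trt_first))
    stop("both diet sequences must be represented")
  d_tc <- wide$d[trt_first]
  d_ct <- wide$d[!trt_first]
  effect <- (mean(d_tc) - mean(d_ct)) / 2
  n1 <- length(d_tc); n2 <- length(d_ct)
  dof <- n1 + n2 - 2
  sp2 <- (sum((d_tc - mean(d_tc))^2) + sum((d_ct - mean(d_ct))^2)) / dof
  se <- sqrt(sp2 * (1 / n1 + 1 / n2)) / 2
  t_stat <- if (se > 0) effect / se else if (effect == 0) 0 else Inf
  p <- if (is.finite(t_stat)) 2 * stats::pt(-abs(t_stat), dof) else 0
  lsm <- tapply(df0$y, df0$diet, mean)
  structure(list(response = NA_character_, diet_effect = effect, se = se,
                 df = dof, t_stat = t_stat, p_value = p,
                 lsmeans = lsm[c(treatment, control)]),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Diet effect%s: %.4g (SE %.4g, t = %.3g on %d df, P = %.3g)\n",
              if (is.na(x$response)) "" else paste0(" [", x$response, "]"),
              x$diet_effect, x$se, x$t_stat, x$df, x$p_value))
  cat("  lsmeans:", paste(sprintf("%s = %.4g", names(x$lsmeans), x$lsmeans),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Ordinary least squares with BIC
#'
#' Closed-form least squares (QR) of \code{y} on the supplied predictor
#' columns plus an intercept. Reports the residual sum of squares, adjusted
#' R-squared, and the Gaussian-likelihood BIC
#' \code{n log(rss/n) + p log(n)} with \code{p} counting all estimated
#' coefficients including the intercept.
#'
#' @param design Data frame or matrix of predictors (no intercept column);
#'   may have zero columns for the intercept-only model.
#' @param y Numeric response.
#' @return An object of class \code{"regression_fit"}: \code{terms},
#'   \code{coefficients} (named, intercept first), \code{residuals},
#'   \code{fitted}, \code{rss}, \code{n}, \code{r2_adj}, \code{bic}.
#' @export
ols <- function(design, y) {
  design <- as.data.frame(design)
  n <- length(y)
  p <- ncol(design) + 1L
  if (n <= p - 1L) stop("need more observations than terms")
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  r2_adj <- if (n > p) 1 - (1 - r2) * (n - 1) / (n - p) else NA_real_
  bic <- n * log(rss / n) + p * log(n)
  structure(list(terms = colnames(design), coefficients = beta,
                 residuals = res, fitted = fitted, rss = rss, n = n,
                 r2_adj = r2_adj, bic = bic),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat("OLS fit:", if (length(x$terms)) paste(x$terms, collapse = " + ")
      else "(intercept only)", "\n")
  print(round(x$coefficients, 6))
  cat(sprintf("  n = %d, RSS = %.6g, adj. R^2 = %.3f, BIC = %.3f\n",
              x$n, x$rss, x$r2_adj, x$bic))
  invisible(x)
}

#' Select a regression model by BIC
#'
#' Fits each candidate term set by \code{\link{ols}} and returns the fit
#' with the lowest BIC; ties are broken by fewer terms, then by order of
#' appearance.
#'
#' @param candidates List of character vectors, each naming columns of
#'   \code{design}.
#' @param design Data frame holding every predictor any candidate uses.
#' @param y Numeric response.
#' @return The winning \code{\link{ols}} fit, with the candidate index in
#'   attribute \code{"selected"}.
#' @export
select_model <- function(candidates, design, y) {
  if (length(candidates) < 2) stop("at least two candidate models required")
  design <- as.data.frame(design)
  fits <- lapply(candidates, function(tt) {
    miss <- setdiff(tt, names(design))
    if (length(miss)) stop("unknown term(s): ", paste(miss, collapse = ", "))
    ols(design[, tt, drop = FALSE], y)
  })
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  sizes <- lengths(candidates)
  best <- order(bics, sizes, seq_along(fits))[1]
  out <- fits[[best]]
  attr(out, "selected") <- best
  out
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation with domain checks: at least three pairs and
#' nonzero variance in both variables.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input")
  stats::cor(x, y, method = "pearson")
}
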