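#' Binomial GLM for coiling success
#'
#' Maximum-likelihood logistic regression of coiling success on support
#' diameter and tendril length, fitted by iteratively reweighted least
#' squares (IRLS), with Wald standard errors, z and p values, and complete-
#' separation detection. Main effects only by default, matching the analysis
#' the model is meant to recover; an interaction term is available behind a
#' flag.
#'
#' @name stats_glm
#' @keywords internal
NULL

#' Fit the coiling-success logistic regression
#'
#' IRLS on `success ~ diameter + length` (optionally `+ diameter:length`).
#' Convergence is declared when the largest absolute coefficient change
#' drops below `tol`; complete or quasi-complete separation is detected
#' (diverging coefficients with fitted probabilities saturating at 0/1) and
#' reported via `separation = TRUE` and `converged = FALSE` instead of
#' fabricating finite estimates.
#'
#' @param data A `success_dataset` data.frame (`diameter_mm`, `length_mm`,
#'   `success`).
#' @param interaction Include the diameter x length interaction. Default
#'   FALSE.
#' @param tol Convergence tolerance on max absolute coefficient change.
#'   Default 1e-8.
#' @param max_iter Maximum IRLS iterations. Default 100.
#' @return An object of class `glm_fit`: `coefficients`, `se`, `z`,
#'   `p_value` (Wald), `converged`, `separation`, `n_iterations`,
#'   `log_likelihood`, `vcov`, and the model terms.
#' @export
fit_logistic <- function(data, interaction = FALSE, tol = 1e-8,
                         max_iter = 100L) {
  validate_success_dataset(data)
  if (nrow(data) < 3L) stop("need at least 3 rows", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, diameter = data$diameter_mm,
             length = data$length_mm)
  if (interaction) {
    X <- cbind(X, `diameter:length` = data$diameter_mm * data$length_mm)
  }
  y <- as.numeric(data$success)
  for (j in 2:ncol(X)) {
    if (stats::sd(X[, j]) == 0) {
      stop(sprintf("rank deficiency: predictor '%s' is constant",
                   colnames(X)[j]), call. = FALSE)
    }
  }
  if (qr(X)$rank < ncol(X)) {
    stop("rank deficiency: design matrix is singular", call. = FALSE)
  }

  beta <- numeric(ncol(X))
  ll <- logistic_loglik(beta, X, y)
  ll_trace <- ll
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    # saturating fits with diverging coefficients signal separation
    if (max(abs(beta)) > 1e4 || all(w < 1e-10)) {
      separation <- TRUE
      break
    }
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (any(!is.finite(beta_new))) {
      separation <- TRUE
      break
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    ll <- logistic_loglik(beta, X, y)
    ll_trace <- c(ll_trace, ll)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && !separation && max(abs(beta)) > 50) {
    # monotone likelihood without a finite maximizer
    separation <- TRUE
  }

  if (separation) {
    se <- rep(NA_real_, ncol(X))
    vc <- matrix(NA_real_, ncol(X), ncol(X))
  } else {
    mu <- stats::plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-10)
    info <- crossprod(X * sqrt(w))
    vc <- solve(info)
    se <- sqrt(diag(vc))
  }
  zval <- beta / se
  structure(
    list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
         se = stats::setNames(se, colnames(X)),
         z = stats::setNames(zval, colnames(X)),
         p_value = stats::setNames(2 * stats::pnorm(-abs(zval)), colnames(X)),
         converged = converged && !separation,
         separation = separation,
         n_iterations = iter,
         log_likelihood = ll,
         ll_trace = ll_trace,
         vcov = vc,
         interaction = interaction,
         n = nrow(data)),
    class = "glm_fit"
  )
}

logistic_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("Coiling-success logistic regression (n = %d)\n", x$n))
  if (x$separation) {
    cat("  WARNING: complete or quasi-complete separation detected;\n")
    cat("  maximum-likelihood estimates are not finite.\n")
    return(invisible(x))
  }
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$z,
                    p = x$p_value)
  print(round(tab, 4))
  cat(sprintf("  converged in %d IRLS iterations, logLik %.3f\n",
              x$n_iterations, x$log_likelihood))
  invisible(x)
}

#' Wald confidence intervals for a logistic fit
#'
#' @param fit A converged `glm_fit`.
#' @param level Confidence level. Default 0.95.
#' @return A matrix with `lower` and `upper` columns.
#' @export
wald_ci <- function(fit, level = 0.95) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = fit$coefficients - q * fit$se,
        upper = fit$coefficients + q * fit$se)
}

#' Predicted coiling-success probability
#'
#' @param fit A converged `glm_fit`.
#' @param diameter Support diameter in mm (vectorized).
#' @param length Tendril length in mm (vectorized).
#' @return Probability in \[0, 1\].
#' @export
predict_success <- function(fit, diameter, length) {
  if (!fit$converged) {
    stop("fit did not converge (separation?); no predictions", call. = FALSE)
  }
  b <- fit$coefficients
  eta <- b[1] + b[2] * diameter + b[3] * length
  if (isTRUE(fit$interaction)) eta <- eta + b[4] * diameter * length
  unname(stats::plogis(eta))
}

#' Write a logistic-fit report as JSON
#'
#' @param fit A `glm_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_glm_report <- function(fit, path) {
  out <- list(coefficients = as.list(fit$coefficients),
              se = as.list(fit$se), z = as.list(fit$z),
              p_value = as.list(fit$p_value),
              converged = fit$converged, separation = fit$separation,
              n_iterations = fit$n_iterations,
              log_likelihood = fit$log_likelihood, n = fit$n)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
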