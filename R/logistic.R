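## Logistic regression with separation-aware fitting and Wald tests.

#' Fit a logistic regression for enrichment testing
#'
#' Maximum-likelihood fit by iteratively reweighted least squares. When the
#' ML fit fails to converge or a coefficient diverges — the signature of
#' (quasi-)complete separation, common for rare alteration features — the
#' fit falls back to Firth's bias-reduced penalized likelihood, which always
#' yields finite coefficients, and sets `separation_flag`.
#'
#' @param y Binary response vector (0/1).
#' @param X Design matrix including an intercept column.
#' @param tol Convergence tolerance on the coefficient step (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return Object of class `metbc_logit` with `coefficients`, `vcov`,
#'   `converged`, `iterations`, `separation_flag`, `method`.
#' @export
fit_logistic <- function(y, X, tol = 1e-8, max_iter = 100) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))
  if (length(y) <= ncol(X))
    stop("need more observations than predictors")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }

  irls <- function(penalized) {
    beta <- numeric(ncol(X))
    info <- NULL
    for (it in seq_len(max_iter)) {
      eta <- pmin(pmax(drop(X %*% beta), -30), 30)
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      info <- crossprod(X, X * w)
      if (penalized) {
        # Firth adjustment: augment the score with h_i (1/2 - mu_i)
        XW <- X * sqrt(w)
        h <- rowSums((XW %*% solve(info)) * XW)
        g <- crossprod(X, y - mu + h * (0.5 - mu))
      } else {
        g <- crossprod(X, y - mu)
      }
      step <- solve(info, g)
      beta <- beta + drop(step)
      if (!penalized && max(abs(beta)) > 12)
        return(list(diverged = TRUE))
      if (max(abs(step)) < tol)
        return(list(beta = beta, vcov = solve(info), iterations = it,
                    converged = TRUE))
    }
    list(beta = beta, vcov = solve(info), iterations = max_iter,
         converged = FALSE)
  }

  fit <- irls(penalized = FALSE)
  separated <- isTRUE(fit$diverged) || !isTRUE(fit$converged)
  method <- "ml"
  if (separated) {
    fit <- irls(penalized = TRUE)
    method <- "firth"
  }
  names(fit$beta) <- colnames(X)
  dimnames(fit$vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = fit$beta, vcov = fit$vcov,
                 converged = fit$converged, iterations = fit$iterations,
                 separation_flag = separated, method = method),
            class = "metbc_logit")
}

#' @export
coef.metbc_logit <- function(object, ...) object$coefficients

#' @export
vcov.metbc_logit <- function(object, ...) object$vcov

#' @export
print.metbc_logit <- function(x, ...) {
  cat("logistic fit (", x$method, "), ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations",
      if (x$separation_flag) "; separation detected" else "", "\n", sep = "")
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = x$coefficients, se = se,
                   z = x$coefficients / se))
  invisible(x)
}

#' Wald test on one coefficient of a logistic fit
#'
#' @param fit A `metbc_logit`.
#' @param predictor Coefficient name (or index).
#' @return List with `z`, `p` (two-sided, standard normal) and, when the
#'   standard error is degenerate, `reason`.
#' @export
wald_test <- function(fit, predictor) {
  stopifnot(inherits(fit, "metbc_logit"))
  b <- fit$coefficients[predictor]
  se <- sqrt(diag(fit$vcov))[predictor]
  if (is.na(se) || se <= 0)
    return(list(z = NA_real_, p = NA_real_, reason = "zero or undefined SE"))
  z <- unname(b / se)
  list(z = z, p = 2 * pnorm(-abs(z)))
}
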