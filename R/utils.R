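# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so stochastic operations own their randomness without
#' perturbing the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed; stays well below 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

# Fast logistic fit of y ~ 1 + x returning coef, se, convergence.
# x: numeric matrix WITHOUT intercept column; y in {0,1}.
logistic_fit <- function(x, y) {
  X <- cbind(1, x)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())
  )
  p <- ncol(X)
  cf <- fit$coefficients
  # covariance from the final IRLS weights
  se <- rep(NA_real_, p)
  ok <- !is.na(cf)
  if (sum(ok) > 0) {
    W <- fit$weights
    XtWX <- crossprod(X[, ok, drop = FALSE] * W, X[, ok, drop = FALSE])
    V <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (!is.null(V)) se[ok] <- sqrt(diag(V))
  }
  list(
    coef = cf,
    se = se,
    converged = isTRUE(fit$converged) && !any(is.na(cf)),
    null_deviance = fit$null.deviance %||%
      null_binomial_deviance(y),
    deviance = fit$deviance,
    fitted = fit$fitted.values
  )
}

null_binomial_deviance <- function(y) {
  p <- mean(y)
  if (p <= 0 || p >= 1) return(0)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot-style check with a readable message
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
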