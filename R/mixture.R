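## Weighted maximum-likelihood fit of a single beta distribution.
## Moment-matched start, Nelder-Mead on log-parameters.
beta_wmle <- function(x, w = rep(1, length(x))) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  v <- sum(w * (x - m)^2) / sw
  v <- max(v, 1e-10)
  common <- max(m * (1 - m) / v - 1, 0.1)
  start <- log(pmax(c(m, 1 - m) * common, 1e-3))
  nll <- function(lp) {
    ab <- exp(lp)
    if (any(!is.finite(ab)) || any(ab > 1e6)) return(1e10)
    -sum(w * dbeta(x, ab[1], ab[2], log = TRUE))
  }
  op <- optim(start, nll, method = "Nelder-Mead",
              control = list(maxit = 500, reltol = 1e-10))
  list(a = exp(op$par[1]), b = exp(op$par[2]), loglik = -op$value)
}

#' Fit one- and two-component beta models to decoder confidence
#'
#' Tests whether delay-period confidence values are better captured by a
#' single beta distribution (one state) or a two-component beta mixture
#' `w Beta(a, b) + (1 - w) Beta(a', b')` (two states). The one-component
#' model is fit by maximum likelihood from a moment-matched start; the
#' mixture by EM with seeded random restarts. Model comparison uses
#' `dAIC = AIC_2 - AIC_1` and `dBIC = BIC_2 - BIC_1` with 2 and 5
#' parameters: negative values favor the two-state model.
#'
#' @param confidence numeric values; clipped into `[eps, 1 - eps]`.
#' @param n_restarts EM restarts (default 10).
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param seed integer seed for restarts.
#' @param eps clipping bound (default 1e-6).
#' @return list of class `beta_mixture`: `one` (a, b, loglik), `two` (w, a,
#'   b, a2, b2, loglik, n_iter), `dAIC`, `dBIC`, `n`.
#' @export
fit_beta_mixture <- function(confidence, n_restarts = 10, tol = 1e-8,
                             max_iter = 500, seed = 1, eps = 1e-6) {
  x <- pmin(pmax(as.numeric(confidence), eps), 1 - eps)
  n <- length(x)
  if (n < 20) stop("need at least 20 confidence values for a stable fit")
  if (sd(x) == 0) stop("degenerate input: all confidence values are equal")

  one <- beta_wmle(x)

  em_once <- function(split_q) {
    ## initialize responsibilities from a quantile split
    r <- as.numeric(x > quantile(x, split_q))
    r <- pmin(pmax(r + rnorm(n, 0, 0.05), 0.02), 0.98)
    ll_old <- -Inf; ll_trace <- numeric(0)
    par <- NULL
    for (it in seq_len(max_iter)) {
      ## M step: weighted beta MLEs and mixing weight
      w2 <- mean(r)
      f2 <- beta_wmle(x, r)
      f1 <- beta_wmle(x, 1 - r)
      d1 <- dbeta(x, f1$a, f1$b)
      d2 <- dbeta(x, f2$a, f2$b)
      mix <- (1 - w2) * d1 + w2 * d2
      mix <- pmax(mix, 1e-300)
      ll <- sum(log(mix))
      ## E step
      r <- w2 * d2 / mix
      par <- list(w = 1 - w2, a = f1$a, b = f1$b, a2 = f2$a, b2 = f2$b,
                  loglik = ll, n_iter = it)
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && ll < ll_old - 1e-6)
        warning("EM log-likelihood decreased; numerical M-step tolerance")
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    par$ll_trace <- ll_trace
    par
  }

  seeds <- derive_seeds(seed, n_restarts)
  fits <- lapply(seq_len(n_restarts), function(r)
    with_seed(seeds[r], em_once(split_q = runif(1, 0.2, 0.8))))
  two <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]

  k1 <- 2; k2 <- 5
  aic1 <- 2 * k1 - 2 * one$loglik; aic2 <- 2 * k2 - 2 * two$loglik
  bic1 <- k1 * log(n) - 2 * one$loglik; bic2 <- k2 * log(n) - 2 * two$loglik
  structure(list(one = one, two = two, dAIC = aic2 - aic1, dBIC = bic2 - bic1,
                 AIC = c(one = aic1, two = aic2),
                 BIC = c(one = bic1, two = bic2), n = n),
            class = "beta_mixture")
}

#' @export
print.beta_mixture <- function(x, ...) {
  cat(sprintf("<beta_mixture> n = %d\n", x$n))
  cat(sprintf("  one state: Beta(%.3g, %.3g), logLik %.2f\n",
              x$one$a, x$one$b, x$one$loglik))
  cat(sprintf("  two states: %.2f Beta(%.3g, %.3g) + %.2f Beta(%.3g, %.3g), logLik %.2f\n",
              x$two$w, x$two$a, x$two$b, 1 - x$two$w, x$two$a2, x$two$b2,
              x$two$loglik))
  cat(sprintf("  dAIC = %.2f, dBIC = %.2f (negative favors two states)\n",
              x$dAIC, x$dBIC))
  invisible(x)
}

#' @export
logLik.beta_mixture <- function(object, ...) {
  structure(object$two$loglik, df = 5, nobs = object$n, class = "logLik")
}
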