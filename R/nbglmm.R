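#' Fit a negative-binomial mixed model for one gene
#'
#' Maximizes the Laplace-approximate likelihood of a log-link NB model with
#' Gaussian subject random intercepts,
#' \deqn{y_j \sim NB(\mu_j, \phi), \quad \log \mu_j = o_j + x_j' \beta + u_{s(j)},
#'   \quad u_s \sim N(0, \sigma^2).}
#' For fixed \eqn{\sigma^2}, the joint mode of \eqn{(\beta, u)} is found by
#' penalized iteratively reweighted least squares; \eqn{\sigma^2} is then
#' profiled out by Brent search on the Laplace-approximate log-likelihood
#' \deqn{\ell(\sigma^2) = \log p(y \mid \hat\beta, \hat u)
#'   - \hat u'\hat u / 2\sigma^2 - (q/2) \log \sigma^2
#'   - \tfrac12 \log\det(Z'WZ + I/\sigma^2).}
#' The dispersion \eqn{\phi} is held fixed (two-stage fitting; see
#' [estimate_dispersion()]).
#'
#' Wald t statistics use residual degrees of freedom
#' `n_obs - n_fixed - 1`.  With `sigma2 = 0` the fit reduces to an ordinary
#' NB GLM (and to a Poisson GLM as `phi -> 0`).
#'
#' @param y integer counts, one per sample.
#' @param X fixed-effects design matrix (n x p, including intercept).
#' @param subject subject identifier per sample (factor or vector);
#'   `NULL` drops the random effect.
#' @param offset per-sample offset on the log scale (typically
#'   `log(size_factors)`).
#' @param phi NB dispersion (variance `mu + phi mu^2`), >= 0.
#' @param sigma2 random-intercept variance; `NULL` (default) estimates it
#'   by profiling, a number fixes it (0 switches the random effect off).
#' @param max_iter,tol inner IRLS iteration control.
#' @return list with `coefficients` (data frame: term, estimate, se, t, p),
#'   `sigma2`, `phi`, `converged`, `iterations`, `df`, and `u` (posterior
#'   modes of the subject effects).
#' @export
fit_nb_mixed <- function(y, X, subject = NULL, offset = 0, phi = 0,
                         sigma2 = NULL, max_iter = 50L, tol = 1e-10) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  .stop_if(nrow(X) != n, "design rows must match length(y)")
  offset <- rep_len(offset, n)
  .stop_if(any(!is.finite(offset)), "offsets must be finite")
  .stop_if(phi < 0, "phi must be >= 0")
  .stop_if(qr(X)$rank < p, "degenerate fixed-effects design")

  est_sigma2 <- is.null(sigma2)
  use_re <- !is.null(subject) && (est_sigma2 || sigma2 > 0)
  if (use_re) {
    subject <- factor(subject)
    q <- nlevels(subject)
    si <- as.integer(subject)
  } else {
    q <- 0L
    si <- NULL
  }

  loglik <- function(mu) {
    if (phi > 0) sum(stats::dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
    else sum(stats::dpois(y, lambda = mu, log = TRUE))
  }

  # penalized IRLS at fixed s2, exploiting that Z is an indicator matrix:
  # Z'WZ is diagonal, so the joint system is solved by its p x p Schur
  # complement.  Warm start through the enclosing state.
  state <- list(beta = rep(0, p), u = rep(0, q),
                eta = pmin(pmax(log(pmax(y, 0.5)), -30), 30))
  total_iter <- 0L
  inner_fit <- function(s2, need_vcov = FALSE, itol = tol) {
    out <- tryCatch({
      beta <- state$beta; u <- state$u
      eta <- state$eta
      mu <- exp(eta)
      conv <- FALSE
      Sm <- NULL; D <- NULL
      for (it in seq_len(max_iter)) {
        total_iter <<- total_iter + 1L
        w <- mu / (1 + phi * mu)
        z <- (eta - offset) + (y - mu) / mu
        Xw <- X * w
        XtWX <- crossprod(X, Xw)
        XtWz <- crossprod(Xw, z)
        if (q > 0) {
          agg <- rowsum(cbind(w, w * z, Xw), si)    # per-subject sums
          D <- agg[, 1] + 1 / s2                     # diag(Z'WZ) + 1/s2
          ZtWz <- agg[, 2]
          C <- t(agg[, -(1:2), drop = FALSE])        # X'WZ, p x q
          Cd <- C * rep(1 / D, each = p)
          Sm <- XtWX - tcrossprod(Cd, C)
          new_beta <- drop(solve(Sm, XtWz - Cd %*% ZtWz))
          new_u <- (ZtWz - drop(crossprod(C, new_beta))) / D
          eta <- drop(X %*% new_beta) + new_u[si] + offset
        } else {
          Sm <- XtWX
          new_beta <- drop(solve(Sm, XtWz))
          new_u <- numeric()
          eta <- drop(X %*% new_beta) + offset
        }
        if (any(eta > 30 | eta < -30)) eta <- pmin(pmax(eta, -30), 30)
        mu <- exp(eta)
        delta <- max(max(abs(new_beta - beta)),
                     if (q > 0) max(abs(new_u - u)) else 0)
        beta <- new_beta; u <- new_u
        if (delta < itol * (1 + max(abs(beta)))) { conv <- TRUE; break }
      }
      state$beta <<- beta
      state$u <<- u
      state$eta <<- eta
      ll <- loglik(mu)
      lap <- if (q > 0) {
        ll - sum(u^2) / (2 * s2) - q / 2 * log(s2) - 0.5 * sum(log(D))
      } else ll
      list(beta = beta, u = u, mu = mu,
           Sinv = if (need_vcov) solve(Sm) else NULL,
           converged = conv, laplace = as.numeric(lap))
    }, error = function(e) NULL)
    out
  }

  if (use_re && est_sigma2) {
    obj <- function(ls2) {
      f <- inner_fit(exp(ls2), itol = 1e-6)   # coarse fits while profiling
      if (is.null(f)) return(1e10)
      -f$laplace
    }
    opt <- stats::optimize(obj, interval = c(log(1e-4), log(2)), tol = 0.15)
    s2 <- exp(opt$minimum)
  } else {
    s2 <- if (use_re) sigma2 else 0
  }
  fit <- inner_fit(if (use_re) s2 else 1, need_vcov = TRUE)  # s2 unused when q = 0
  if (is.null(fit))
    return(list(coefficients = data.frame(
      term = colnames(X) %||% paste0("b", seq_len(p)),
      estimate = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_),
      sigma2 = NA_real_, phi = phi, converged = FALSE,
      iterations = total_iter, df = n - p - 1L, u = NULL))

  converged <- fit$converged && !is.null(fit$Sinv)
  est <- fit$beta
  se <- if (is.null(fit$Sinv)) rep(NA_real_, p) else
    sqrt(pmax(diag(fit$Sinv), 0))
  df <- n - p - 1L
  tstat <- est / se
  pval <- 2 * pt(-abs(tstat), df = df)
  if (!converged) pval[] <- NA_real_
  coefs <- data.frame(term = colnames(X) %||% paste0("b", seq_len(p)),
                      estimate = est, se = se, t = tstat, p = pval,
                      stringsAsFactors = FALSE)
  list(coefficients = coefs,
       sigma2 = if (use_re) s2 else 0,
       phi = phi, converged = converged, iterations = total_iter, df = df,
       u = if (use_re) setNames(fit$u, levels(subject)) else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Method-of-moments NB dispersion from a Poisson fit
#'
#' Fits a Poisson GLM with the given design and offset and estimates the
#' NB2 dispersion from the Pearson residuals:
#' \deqn{\hat\phi = \frac{1}{n - p} \sum_j \frac{(y_j - \hat\mu_j)^2 - \hat\mu_j}{\hat\mu_j^2},}
#' clamped at zero (underdispersed genes return 0).
#'
#' @param y integer counts.
#' @param X design matrix for the moment fit (may include subject
#'   indicators to absorb the pairing).
#' @param offset log-scale offset.
#' @return non-negative dispersion estimate.
#' @export
estimate_dispersion <- function(y, X, offset = 0) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  .stop_if(qr(X)$rank < p, "degenerate design")
  .stop_if(n - p < 2, "need at least 2 residual degrees of freedom")
  fit <- suppressWarnings(
    glm.fit(X, y, family = poisson(), offset = rep_len(offset, n)))
  mu <- pmax(fit$fitted.values, 1e-10)
  max(0, sum(((y - mu)^2 - mu) / mu^2) / (n - p))
}
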