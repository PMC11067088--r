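#' Standard deviation of a QTL position from its 95% confidence interval
#'
#' Treating the reported 95% CI as `peak +/- 1.96 sigma`, the position
#' standard deviation is `(ci_hi - ci_lo) / 3.92`, floored at `sigma_min` so
#' zero-width intervals cannot produce singular likelihoods.
#'
#' @param ci_lo,ci_hi CI bounds in cM (`ci_hi >= ci_lo`).
#' @param sigma_min floor in cM, default 0.1.
#' @return sigma in cM.
#' @examples
#' sigma_from_ci(0, 3.92)   # 1
#' sigma_from_ci(5, 5)      # 0.1 (floor)
#' @export
sigma_from_ci <- function(ci_lo, ci_hi, sigma_min = 0.1) {
  stopifnot(all(ci_hi >= ci_lo, na.rm = TRUE))
  pmax((ci_hi - ci_lo) / 3.92, sigma_min)
}

# log-sum-exp over matrix rows
.lse <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

.em_once <- function(x, sigma, mu, pi, tol, max_iter) {
  n <- length(x)
  K <- length(mu)
  path <- numeric(0)
  ll_old <- -Inf
  post <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    lphi <- vapply(seq_len(K), function(k) {
      dnorm(x, mu[k], sigma, log = TRUE) + log(pi[k])
    }, numeric(n))
    lphi <- matrix(lphi, n, K)
    lse <- .lse(lphi)
    ll <- sum(lse)
    path <- c(path, ll)
    post <- exp(lphi - lse)
    w <- post / sigma^2
    mu_new <- colSums(w * x) / colSums(w)
    pi_new <- pmax(colMeans(post), 1e-12)
    pi_new <- pi_new / sum(pi_new)
    done <- it > 1 && abs(ll - ll_old) < tol
    mu <- mu_new
    pi <- pi_new
    ll_old <- ll
    if (done) break
  }
  list(mu = mu, pi = pi, logLik = ll_old, posterior = post,
       iterations = length(path), converged = it < max_iter || tol == 0,
       logLik_path = path)
}

#' Fit a heteroscedastic one-dimensional Gaussian mixture to QTL positions
#'
#' The meta-QTL model: projected QTL peak positions `x_i` on one linkage
#' group are modelled as draws from a `K`-component normal mixture
#' `sum_k pi_k N(mu_k, sigma_i^2)` in which each observation's variance is
#' *known* (fixed from its 95% CI via [sigma_from_ci()]) rather than
#' estimated per component. Only the component means and the mixing
#' proportions are free, so the parameter count is `p = 2K - 1`. Fitting is
#' by EM with multiple restarts from quantile-spread initial means; the
#' restart with the highest log-likelihood is kept. For `K = 1` the maximum-
#' likelihood mean is the precision-weighted mean of the observations.
#'
#' @param x numeric vector of positions (cM).
#' @param sigma per-observation standard deviations (cM), recycled if scalar.
#' @param K number of components.
#' @param restarts EM restarts, default 10.
#' @param seed integer seed for the restart jitter (optional but recommended;
#'   restarts are deterministic given it).
#' @param tol convergence tolerance on the log-likelihood, default 1e-6.
#' @param max_iter default 500.
#' @return an object of class `mqtl_mixture`: list with `mean` (sorted
#'   ascending), `pi`, `posterior` (n x K, columns matching `mean`),
#'   `logLik`, `n`, `K`, `p`, `iterations`, `converged`, `logLik_path`
#'   (per-iteration log-likelihood of the winning restart), `x`, `sigma`.
#' @seealso [select_mqtl_model()], [information_criteria()], [build_mqtl()]
#' @examples
#' fit <- mqtl_mixture(c(5, 5.1, 4.9, 80, 79.8, 80.2), sigma = 0.5, K = 2,
#'                     seed = 1)
#' coef(fit)
#' @export
mqtl_mixture <- function(x, sigma, K, restarts = 10, seed = NULL,
                         tol = 1e-6, max_iter = 500) {
  n <- length(x)
  if (length(sigma) == 1) sigma <- rep(sigma, n)
  stopifnot(length(sigma) == n, all(sigma > 0), K >= 1)
  if (K > n) stop("K must not exceed the number of observations")
  if (K > length(unique(x))) {
    stop("K must not exceed the number of distinct positions")
  }
  if (K == 1) {
    w <- 1 / sigma^2
    mu <- sum(w * x) / sum(w)
    fit <- .em_once(x, sigma, mu, 1, tol = 0, max_iter = 1)
    fit$mu <- mu
  } else {
    probs <- (seq_len(K) - 0.5) / K
    base_mu <- unname(quantile(x, probs = probs, type = 7))
    span <- max(diff(range(x)), 1e-6)
    fits <- with_seed(seed, {
      lapply(seq_len(restarts), function(r) {
        mu0 <- if (r == 1) base_mu else
          sort(base_mu + rnorm(K, sd = span / (2 * K)))
        .em_once(x, sigma, mu0, rep(1 / K, K), tol, max_iter)
      })
    })
    fit <- fits[[which.max(vapply(fits, `[[`, 0, "logLik"))]]
  }
  ord <- order(fit$mu)
  out <- list(mean = fit$mu[ord], pi = fit$pi[ord],
              posterior = fit$posterior[, ord, drop = FALSE],
              logLik = fit$logLik, n = n, K = K, p = 2 * K - 1,
              iterations = fit$iterations, converged = fit$converged,
              logLik_path = fit$logLik_path,
              x = x, sigma = sigma, call = match.call())
  class(out) <- "mqtl_mixture"
  out
}

#' @export
print.mqtl_mixture <- function(x, digits = 4, ...) {
  cat(sprintf("Heteroscedastic Gaussian mixture: K = %d, n = %d, logLik = %.4f\n",
              x$K, x$n, x$logLik))
  cat("  means (cM):", paste(signif(x$mean, digits), collapse = ", "), "\n")
  cat("  proportions:", paste(signif(x$pi, digits), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mqtl_mixture <- function(object, ...) {
  post <- object$posterior
  cls <- max.col(post, ties.method = "first")
  prec <- vapply(seq_len(object$K), function(k) {
    sum(post[, k] / object$sigma^2)
  }, 0)
  comp <- data.frame(
    component = seq_len(object$K),
    mean_cm = object$mean,
    proportion = object$pi,
    n_primary = as.integer(tabulate(cls, object$K)),
    se_cm = 1 / sqrt(prec)
  )
  out <- list(components = comp, logLik = object$logLik, n = object$n,
              K = object$K, iterations = object$iterations,
              converged = object$converged,
              criteria = information_criteria(object))
  class(out) <- "summary.mqtl_mixture"
  out
}

#' @export
print.summary.mqtl_mixture <- function(x, ...) {
  cat(sprintf("K = %d components over n = %d QTL (logLik %.4f, %d EM iterations)\n",
              x$K, x$n, x$logLik, x$iterations))
  print(x$components, row.names = FALSE)
  cat("criteria:", paste(names(x$criteria),
                         sprintf("%.2f", x$criteria), sep = "=",
                         collapse = "  "), "\n")
  invisible(x)
}

#' @export
coef.mqtl_mixture <- function(object, ...) {
  list(mean = object$mean, pi = object$pi)
}

#' @export
logLik.mqtl_mixture <- function(object, ...) {
  structure(object$logLik, df = object$p, nobs = object$n, class = "logLik")
}

#' @export
nobs.mqtl_mixture <- function(object, ...) object$n

#' Posterior component membership for (new) observations
#'
#' @param object an `mqtl_mixture`.
#' @param newdata optional list with elements `x` and `sigma`; defaults to
#'   the training observations.
#' @param type `"posterior"` for the n x K posterior matrix, `"class"` for
#'   the maximum-posterior component index.
#' @param ... unused.
#' @export
predict.mqtl_mixture <- function(object, newdata = NULL,
                                 type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    post <- object$posterior
  } else {
    x <- newdata$x
    sigma <- newdata$sigma
    if (length(sigma) == 1) sigma <- rep(sigma, length(x))
    lphi <- vapply(seq_len(object$K), function(k) {
      dnorm(x, object$mean[k], sigma, log = TRUE) + log(object$pi[k])
    }, numeric(length(x)))
    lphi <- matrix(lphi, length(x), object$K)
    post <- exp(lphi - .lse(lphi))
  }
  if (type == "class") max.col(post, ties.method = "first") else post
}

#' Simulate positions from a fitted meta-QTL mixture
#'
#' Draws component labels from the mixing proportions and positions from the
#' component normals; observation noise uses per-draw sigmas resampled from
#' the fitted data's sigma vector.
#'
#' @param object an `mqtl_mixture`.
#' @param nsim number of replicate data sets, default 1.
#' @param seed optional seed.
#' @param n draws per data set, default the training `n`.
#' @param ... unused.
#' @return a data.frame (`nsim = 1`) or list of data.frames with columns
#'   `x`, `sigma`, `component`.
#' @export
simulate.mqtl_mixture <- function(object, nsim = 1, seed = NULL,
                                  n = object$n, ...) {
  sims <- with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      k <- sample.int(object$K, n, replace = TRUE, prob = object$pi)
      sg <- sample(object$sigma, n, replace = TRUE)
      data.frame(x = rnorm(n, object$mean[k], sg), sigma = sg, component = k)
    })
  })
  if (nsim == 1) sims[[1]] else sims
}

#' @export
plot.mqtl_mixture <- function(x, ...) {
  xs <- seq(min(x$x) - 3 * max(x$sigma), max(x$x) + 3 * max(x$sigma),
            length.out = 512)
  sbar <- stats::median(x$sigma)
  dens <- rowSums(vapply(seq_len(x$K), function(k) {
    x$pi[k] * dnorm(xs, x$mean[k], sbar)
  }, numeric(length(xs))))
  plot(xs, dens, type = "l", xlab = "consensus position (cM)",
       ylab = "mixture density (median-sigma profile)", ...)
  rug(x$x)
  abline(v = x$mean, lty = 2, col = "grey40")
  invisible(x)
}

#' Information criteria for a fitted meta-QTL mixture
#'
#' Computes the five model-selection scores used for choosing the number of
#' MQTL: `AIC = -2 lnL + 2p`, `AIC3 = -2 lnL + 3p`,
#' `AICc = AIC + 2p(p+1)/(n-p-1)` (reported as `Inf` when `n <= p + 1`),
#' `BIC = -2 lnL + p ln n`, and `AWE = -2 lnL_c + 2p(3/2 + ln n)` where
#' `lnL_c` is the classification (posterior-weighted complete-data)
#' log-likelihood.
#'
#' @param fit an `mqtl_mixture`.
#' @param n observation count, default `fit$n`.
#' @return named numeric vector `AIC, AIC3, AICc, BIC, AWE`.
#' @export
information_criteria <- function(fit, n = fit$n) {
  p <- fit$p
  ll <- fit$logLik
  lphi <- vapply(seq_len(fit$K), function(k) {
    dnorm(fit$x, fit$mean[k], fit$sigma, log = TRUE) + log(fit$pi[k])
  }, numeric(fit$n))
  lphi <- matrix(lphi, fit$n, fit$K)
  llc <- sum(fit$posterior * lphi, na.rm = TRUE)
  aic <- -2 * ll + 2 * p
  c(AIC = aic,
    AIC3 = -2 * ll + 3 * p,
    AICc = if (n > p + 1) aic + 2 * p * (p + 1) / (n - p - 1) else Inf,
    BIC = -2 * ll + p * log(n),
    AWE = -2 * llc + 2 * p * (3 / 2 + log(n)))
}

#' Choose K from a criteria table by the 3-of-5 vote rule
#'
#' Each criterion votes for the K at which it is minimal (first minimum on
#' ties). The chosen K is any K collecting at least `min_votes` of the votes;
#' if none does, the smallest K among those with the most votes wins.
#'
#' @param criteria_table data.frame with a `K` column and one column per
#'   criterion.
#' @param min_votes default 3.
#' @return list `K` (chosen), `votes` (named integer vector per K).
#' @export
vote_K <- function(criteria_table, min_votes = 3) {
  crit_cols <- setdiff(names(criteria_table), "K")
  winners <- vapply(crit_cols, function(cn) {
    criteria_table$K[which.min(criteria_table[[cn]])]
  }, 0)
  votes <- table(factor(winners, levels = criteria_table$K))
  votes <- setNames(as.integer(votes), names(votes))
  qualified <- as.numeric(names(votes))[votes >= min_votes]
  K <- if (length(qualified)) min(qualified) else {
    top <- as.numeric(names(votes))[votes == max(votes)]
    min(top)
  }
  list(K = K, votes = votes, winners = winners)
}

#' Select the number of meta-QTL on one linkage group
#'
#' Fits [mqtl_mixture()] for `K = 1..K_max` and chooses K by the five-
#' criterion vote ([vote_K()]): a K is accepted when it has the lowest value
#' of at least three of AIC, AIC3, AICc, BIC and AWE.
#'
#' @param x,sigma observations, as in [mqtl_mixture()].
#' @param K_max largest K tried; default `min(n_distinct, 15)`.
#' @param restarts,seed,tol,max_iter passed to [mqtl_mixture()] (the per-K
#'   restart seeds are derived deterministically from `seed`).
#' @return an object of class `mqtl_model_selection`: list with `fit` (the
#'   chosen `mqtl_mixture`), `K`, `criteria` (table K x 5), `votes`, `fits`
#'   (all candidate fits).
#' @export
select_mqtl_model <- function(x, sigma, K_max = NULL, restarts = 10,
                              seed = NULL, tol = 1e-6, max_iter = 500) {
  n <- length(x)
  stopifnot(n >= 2)
  n_distinct <- length(unique(x))
  K_max <- min(K_max %||% 15, n_distinct, 15)
  fits <- lapply(seq_len(K_max), function(K) {
    mqtl_mixture(x, sigma, K, restarts = restarts,
                 seed = if (is.null(seed)) NULL else derive_seed(seed, K),
                 tol = tol, max_iter = max_iter)
  })
  crit <- do.call(rbind, lapply(fits, information_criteria))
  tab <- data.frame(K = seq_len(K_max), crit)
  v <- vote_K(tab)
  out <- list(fit = fits[[v$K]], K = v$K, criteria = tab, votes = v$votes,
              fits = fits)
  class(out) <- "mqtl_model_selection"
  out
}

#' @export
print.mqtl_model_selection <- function(x, ...) {
  cat(sprintf("Meta-QTL model selection: chose K = %d of %d candidates\n",
              x$K, nrow(x$criteria)))
  cat("votes:", paste(names(x$votes)[x$votes > 0],
                      x$votes[x$votes > 0], sep = "=", collapse = "  "), "\n")
  print(x$fit)
  invisible(x)
}
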