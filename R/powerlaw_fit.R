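# Discrete power-law fitting with xmin selection, goodness of fit,
# model comparison against discretized lognormal/exponential, and
# bootstrap confidence intervals.
#
# The discrete power law has pmf p(x) = x^(-alpha) / zeta(alpha, xmin)
# on integers x >= xmin, with zeta(., q) the Hurwitz zeta function.

# Hurwitz zeta zeta(alpha, q) = sum_{k>=0} (q+k)^(-alpha) at integer
# shift q >= 1, alpha > 1. Direct partial sum plus an Euler-Maclaurin
# tail: always positive, no cancellation, ~1e-15 relative error.
hurwitz_zeta <- function(alpha, q) {
  stopifnot(alpha > 1, q >= 1)
  q <- as.numeric(q)
  M <- q + 1000
  head_sum <- sum(seq(q, M - 1)^(-alpha))
  tail <- M^(1 - alpha) / (alpha - 1) + M^(-alpha) / 2 +
    alpha * M^(-alpha - 1) / 12
  head_sum + tail
}

# Vectorised over alpha (used by the likelihood-grid oracle in tests).
hurwitz_zeta_vec <- function(alpha, q) {
  vapply(alpha, hurwitz_zeta, numeric(1), q = q)
}

powerlaw_loglik <- function(alpha, x, xmin) {
  n <- length(x)
  -n * log(hurwitz_zeta(alpha, xmin)) - alpha * sum(log(x))
}

#' Fit a discrete power law by maximum likelihood
#'
#' Fits \eqn{p(x) \propto x^{-\alpha}} on integers \eqn{x \ge x_{min}} by
#' numerical maximization of the Hurwitz-zeta-normalized likelihood.
#' When \code{xmin} is not supplied, candidate cutoffs are scanned over
#' the unique observed values and the cutoff minimizing the
#' Kolmogorov-Smirnov distance between the tail empirical CDF and the
#' fitted CDF is selected (the standard estimator for the lower bound of
#' power-law behaviour in count data).
#'
#' @param values Positive integer observations (e.g. k-mer counts).
#' @param xmin Optional fixed lower cutoff; scanned when NULL.
#' @param alpha_max Upper bound of the exponent search interval.
#' @return A \code{powerlaw_fit} with \code{alpha}, \code{xmin},
#'   \code{ks_stat}, \code{loglik}, \code{n_tail}.
#' @export
fit_powerlaw_discrete <- function(values, xmin = NULL, alpha_max = 20) {
  values <- as.numeric(values)
  stopifnot(all(values >= 1), all(values == floor(values)))
  if (length(unique(values)) < 2) stop("degenerate sample: all values identical")
  fit_at <- function(xm) {
    tail_x <- values[values >= xm]
    n <- length(tail_x)
    if (n < 2 || length(unique(tail_x)) < 2) return(NULL)
    opt <- optimize(function(a) powerlaw_loglik(a, tail_x, xm),
                    interval = c(1 + 1e-8, alpha_max), maximum = TRUE)
    ks <- ks_tail_distance(tail_x, opt$maximum, xm)
    list(alpha = opt$maximum, xmin = xm, ks_stat = ks,
         loglik = opt$objective, n_tail = n)
  }
  if (!is.null(xmin)) {
    out <- fit_at(as.integer(xmin))
    if (is.null(out)) stop("fewer than 2 distinct observations >= xmin")
  } else {
    cands <- sort(unique(values))
    cands <- cands[cands <= sort(values, decreasing = TRUE)[2]]  # keep n_tail >= 2
    fits <- Filter(Negate(is.null), lapply(cands, fit_at))
    if (length(fits) == 0) stop("no feasible xmin candidate")
    out <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ks_stat"))]]
  }
  if (out$n_tail < 10)
    warning("only ", out$n_tail, " observations in the fitted tail")
  structure(out, class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> alpha = %.4f  xmin = %d  KS = %.4f  n_tail = %d\n",
              x$alpha, as.integer(x$xmin), x$ks_stat, x$n_tail))
  invisible(x)
}

# Model CDF of the discrete power law at integer points xs (>= xmin).
powerlaw_cdf <- function(xs, alpha, xmin) {
  z0 <- hurwitz_zeta(alpha, xmin)
  1 - vapply(xs, function(x) hurwitz_zeta(alpha, x + 1), numeric(1)) / z0
}

ks_tail_distance <- function(tail_x, alpha, xmin) {
  # both CDFs are step functions with atoms on the integers, so the
  # sup-norm distance is attained at an observed support point
  xs <- sort(unique(tail_x))
  n <- length(tail_x)
  emp <- vapply(xs, function(v) sum(tail_x <= v), numeric(1)) / n
  mod <- powerlaw_cdf(xs, alpha, xmin)
  max(abs(emp - mod))
}

#' Kolmogorov-Smirnov distance between data and a fitted power law
#'
#' Sup-norm distance between the empirical CDF of the observations at or
#' above the fit's cutoff and the fitted model CDF, evaluated over the
#' observed support.
#'
#' @param values Positive integers.
#' @param fit A \code{powerlaw_fit}.
#' @return The KS statistic in [0, 1].
#' @export
ks_statistic <- function(values, fit) {
  tail_x <- values[values >= fit$xmin]
  ks_tail_distance(tail_x, fit$alpha, fit$xmin)
}

# -- alternatives, discretized by probability mass between consecutive
#    integers and truncated at xmin --------------------------------------

dlnorm_disc_loglik <- function(par, x, xmin) {
  mu <- par[1]; sig <- exp(par[2])
  denom <- stats::plnorm(xmin, mu, sig, lower.tail = FALSE)
  # upper-tail differences stay positive far into the tail
  p <- (stats::plnorm(x, mu, sig, lower.tail = FALSE) -
        stats::plnorm(x + 1, mu, sig, lower.tail = FALSE)) / denom
  lp <- log(pmax(p, .Machine$double.xmin))
  if (!is.finite(sum(lp))) return(-1e18)
  sum(lp)
}

dexp_disc_loglik <- function(lambda, x, xmin) {
  # P(X = x) = (1 - e^-lambda) e^{-lambda (x - xmin)}, x = xmin, xmin+1, ...
  n <- length(x)
  n * log(1 - exp(-lambda)) - lambda * sum(x - xmin)
}

#' Compare the power law with lognormal and exponential alternatives
#'
#' Fits the discrete power law (1 free parameter), a discretized
#' lognormal (2) and a discretized exponential (1) by maximum likelihood
#' on the identical tail sample \eqn{x \ge x_{min}}, and reports AIC and
#' BIC for each together with the winning model under each criterion.
#'
#' @param values Positive integers.
#' @param xmin Lower cutoff defining the common tail (tail size >= 10).
#' @return A \code{model_comparison} with per-model \code{loglik},
#'   \code{aic}, \code{bic}, \code{n_params}, plus \code{best_by_aic},
#'   \code{best_by_bic}, \code{n_tail}.
#' @export
compare_models <- function(values, xmin = 1L) {
  x <- as.numeric(values[values >= xmin])
  n <- length(x)
  if (n < 10) stop("tail size must be >= 10 (got ", n, ")")

  pl <- fit_powerlaw_discrete(x, xmin = xmin)

  mu0 <- mean(log(x)); s0 <- max(sd(log(x)), 0.1)
  opt_ln <- optim(c(mu0, log(s0)), function(p) -dlnorm_disc_loglik(p, x, xmin),
                  method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-10))
  if (opt_ln$convergence != 0)
    stop("lognormal fit failed to converge (code ", opt_ln$convergence, ")")

  lam0 <- log(1 + 1 / max(mean(x) - xmin, 1e-9))   # closed-form MLE
  ll_exp <- dexp_disc_loglik(lam0, x, xmin)

  models <- list(
    powerlaw = list(loglik = pl$loglik, n_params = 1,
                    params = list(alpha = pl$alpha)),
    lognormal = list(loglik = -opt_ln$value, n_params = 2,
                     params = list(meanlog = opt_ln$par[1],
                                   sdlog = exp(opt_ln$par[2]))),
    exponential = list(loglik = ll_exp, n_params = 1,
                       params = list(lambda = lam0))
  )
  for (nm in names(models)) {
    m <- models[[nm]]
    models[[nm]]$aic <- 2 * m$n_params - 2 * m$loglik
    models[[nm]]$bic <- m$n_params * log(n) - 2 * m$loglik
  }
  aics <- vapply(models, `[[`, numeric(1), "aic")
  bics <- vapply(models, `[[`, numeric(1), "bic")
  structure(list(models = models,
                 best_by_aic = names(which.min(aics)),
                 best_by_bic = names(which.min(bics)),
                 n_tail = n, xmin = xmin),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> n_tail =", x$n_tail, " xmin =", x$xmin, "\n")
  for (nm in names(x$models))
    cat(sprintf("  %-12s loglik = %10.2f  AIC = %10.2f  BIC = %10.2f\n",
                nm, x$models[[nm]]$loglik, x$models[[nm]]$aic,
                x$models[[nm]]$bic))
  cat("  best by AIC:", x$best_by_aic, " best by BIC:", x$best_by_bic, "\n")
  invisible(x)
}

#' Bootstrap confidence interval for a tail or Zipf exponent
#'
#' Percentile bootstrap, fully seeded. For plain value vectors the
#' resampling is iid with replacement and the estimator is the discrete
#' power-law MLE (\code{"mle_alpha"}, with \code{xmin} held at the
#' original fit's value). For rank-frequency tables the token counts are
#' resampled multinomially and the estimator is the OLS Zipf exponent
#' (\code{"ols_zeta"}).
#'
#' @param x Integer value vector or a \code{rank_frequency_table}.
#' @param estimator \code{"mle_alpha"} or \code{"ols_zeta"}.
#' @param n_boot Number of bootstrap replicates (1..10000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A \code{bootstrap_result} with \code{estimate}, \code{ci}
#'   (lo, hi), \code{replicates}, \code{n_boot}, \code{seed}.
#' @export
bootstrap_exponent <- function(x, estimator = c("mle_alpha", "ols_zeta"),
                               n_boot = 1000, seed = 1L, conf = 0.95) {
  estimator <- match.arg(estimator)
  if (n_boot < 1 || n_boot > 10000)
    stop("n_boot must be between 1 and 10000")
  if (estimator == "mle_alpha") {
    values <- as.numeric(x)
    fit0 <- fit_powerlaw_discrete(values)
    point <- fit0$alpha
    reps <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      xb <- sample(values, length(values), replace = TRUE)
      tryCatch(fit_powerlaw_discrete(xb, xmin = fit0$xmin)$alpha,
               error = function(e) NA_real_)
    }, numeric(1)))
  } else {
    stopifnot(inherits(x, "rank_frequency_table") ||
              all(c("token", "count") %in% names(x)))
    counts <- x$count
    tokens <- x$token
    total <- sum(counts)
    point <- fit_zipf_ols(x)$zeta
    reps <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      cb <- as.integer(rmultinom(1, total, counts / total))
      names(cb) <- tokens
      tryCatch(fit_zipf_ols(rank_frequency(cb[cb > 0]))$zeta,
               error = function(e) NA_real_)
    }, numeric(1)))
  }
  reps <- reps[!is.na(reps)]
  a <- (1 - conf) / 2
  ci <- if (length(reps) == 1) rep(reps, 2)
        else unname(quantile(reps, c(a, 1 - a), type = 7))
  structure(list(estimate = point, ci = ci, replicates = reps,
                 n_boot = n_boot, seed = seed, estimator = estimator,
                 conf = conf),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s = %.4f  %.0f%% CI [%.4f, %.4f]  (n_boot = %d, seed = %d)\n",
              x$estimator, x$estimate, 100 * x$conf, x$ci[1], x$ci[2],
              x$n_boot, x$seed))
  invisible(x)
}

#' Draw from a discrete power law
#'
#' Exact inverse-CDF sampling over a tabulated support, with the
#' continuous-approximation tail beyond the table (negligible mass for
#' the exponents used here).
#'
#' @param n Sample size.
#' @param alpha Exponent (> 1).
#' @param xmin Lower cutoff (positive integer).
#' @param seed Integer seed.
#' @return Integer vector of length \code{n}.
#' @export
rpowerlaw_discrete <- function(n, alpha, xmin = 1L, seed = 1L) {
  xmax_tab <- 100000L
  xs <- xmin:xmax_tab
  cdf <- cumsum(xs^(-alpha)) / hurwitz_zeta(alpha, xmin)
  with_seed(seed, {
    u <- runif(n)
    out <- xs[findInterval(u, cdf) + 1L]
    over <- is.na(out)
    if (any(over))  # continuous tail approximation beyond the table
      out[over] <- floor((xmin - 0.5) * (1 - u[over])^(-1 / (alpha - 1)) + 0.5)
    as.integer(out)
  })
}
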