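#' Fitting options for the exponential decay model
#'
#' @param tol Convergence tolerance passed to the optimizer (`factr`
#'   is derived from this; default 1e-10 relative).
#' @param max_iter Maximum optimizer iterations per start (default 500).
#' @param restarts Number of jittered restarts after a failed start
#'   (default 3).
#' @param half_life_def Which level defines the half-life:
#'   `"initial"` (default) solves the fitted curve against
#'   `initial_count / 2`, per the assay's definition of RIT50;
#'   `"fitted"` uses the fitted intercept (`log(2)/b`), a sensitivity
#'   variant.
#' @param cov_type Parameter covariance estimator: `"sandwich"`
#'   (default) propagates the binomial-survival covariance of the
#'   repeatedly inspected pod counts through the linearized fit;
#'   `"iid"` is the classical residual-variance Gauss-Newton
#'   covariance, which treats the observations as independent and
#'   badly understates the RIT50 uncertainty for interval-count data
#'   (see the methods vignette).
#' @param level Nominal confidence level for intervals (default 0.95).
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(tol = 1e-10, max_iter = 500L, restarts = 3L,
                        half_life_def = c("initial", "fitted"),
                        cov_type = c("sandwich", "iid"),
                        level = 0.95) {
  half_life_def <- match.arg(half_life_def)
  cov_type <- match.arg(cov_type)
  stopifnot(tol > 0, max_iter >= 1, restarts >= 0,
            level > 0, level < 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts),
                 half_life_def = half_life_def, cov_type = cov_type,
                 level = level),
            class = "fit_options")
}

#' Log-linear starting values for the decay fit
#'
#' Ordinary least squares of `log(intact_count)` on time over the
#' strictly positive counts; zero counts are excluded (log undefined).
#' Returns `A0 = exp(intercept)` and `b0 = max(-slope, floor)` with a
#' small positive floor so the nonlinear fit never starts at rate 0.
#'
#' @param assay An `rit_assay`.
#' @return Named numeric vector `c(A0 = , b0 = )`.
#' @export
loglinear_init <- function(assay) {
  obs <- assay$observations
  keep <- obs$intact_count > 0
  if (sum(keep) < 2)
    stop("cannot initialize: fewer than 2 positive-count observations",
         call. = FALSE)
  fit <- stats::lm(log(intact_count) ~ time_s, data = obs[keep, ])
  co <- stats::coef(fit)
  c(A0 = unname(exp(co[1])), b0 = max(-unname(co[2]), 1e-6))
}

#' Fit the exponential decay model to one RIT assay
#'
#' Minimizes the unweighted residual sum of squares
#' \deqn{\sum_i (y_i - A e^{-b t_i})^2}
#' over the assay's observations (the time-zero anchor included), with
#' the decay rate constrained non-negative. Starting values come from
#' [loglinear_init()]; on optimizer failure up to `restarts` jittered
#' restarts are attempted. The reported covariance is the standard
#' large-sample (Gauss-Newton) covariance at the optimum:
#' \eqn{\hat\sigma^2 (J^\top J)^{-1}} with
#' \eqn{\hat\sigma^2 = RSS/(n-2)}.
#'
#' @param assay An `rit_assay` with at least 3 observations, at least
#'   2 distinct positive times, and some observed decay.
#' @param options A [fit_options()] list.
#' @return An object of class `decay_fit` with fields `A_hat`, `b_hat`,
#'   `cov` (2x2, natural scale), `rss`, `n_obs`, `sigma2`, `converged`,
#'   and the assay's `genotype`/`replicate_id`/`initial_count` labels.
#' @export
#' @examples
#' t <- seq(0, 64, 8)
#' a <- rit_assay("WT", "r1", t, round(20 * exp(-0.1 * t)))
#' fit_decay(a)
fit_decay <- function(assay, options = fit_options()) {
  obs <- assay$observations
  t <- obs$time_s
  y <- obs$intact_count
  if (length(t) < 3)
    stop("need at least 3 observations to fit", call. = FALSE)
  if (length(unique(t[t > 0])) < 2)
    stop("need at least 2 distinct positive times", call. = FALSE)
  if (all(y == assay$initial_count))
    stop("degenerate fit: rate not identifiable (no decay observed)",
         call. = FALSE)

  rss_fn <- function(par) {
    r <- y - par[1] * exp(-par[2] * t)
    sum(r * r)
  }
  grad_fn <- function(par) {
    e <- exp(-par[2] * t)
    r <- y - par[1] * e
    c(-2 * sum(r * e), 2 * par[1] * sum(r * e * t))
  }

  init <- loglinear_init(assay)
  starts <- list(c(init[["A0"]], init[["b0"]]))
  best <- NULL
  for (k in seq_len(1L + options$restarts)) {
    par0 <- starts[[1]]
    if (k > 1) {  # deterministic jitter, no RNG consumed
      f <- 1 + 0.35 * sin(k * c(1.3, 2.7))
      par0 <- pmax(par0 * f, c(1e-6, 1e-6))
    }
    res <- tryCatch(
      stats::optim(par0, rss_fn, grad_fn, method = "L-BFGS-B",
                   lower = c(1e-12, 0), upper = c(Inf, Inf),
                   control = list(maxit = options$max_iter,
                                  factr = options$tol / .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
    if (res$convergence == 0) break
  }

  if (is.null(best))
    stop("optimizer failed on all starts", call. = FALSE)

  # Gauss-Newton polish with step halving: quadratic local convergence
  # sharpens the quasi-Newton solution to (near) machine precision.
  # (L-BFGS-B can abort its line search on zero-residual data; a
  # successfully terminated polish counts as convergence.)
  par <- unname(best$par)
  val <- best$value
  gn_ok <- FALSE
  for (it in 1:100) {
    e <- exp(-par[2] * t)
    r <- y - par[1] * e
    J <- unname(cbind(e, -par[1] * t * e))
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    improved <- FALSE
    for (h in 1:20) {
      cand <- pmax(par + lam * drop(step), c(1e-12, 0))
      cv <- rss_fn(cand)
      if (cv <= val) {
        improved <- val - cv > 1e-15 * (1 + val)
        par <- cand
        val <- cv
        break
      }
      lam <- lam / 2
    }
    if (!improved) {
      gn_ok <- TRUE
      break
    }
  }

  A_hat <- par[1]
  b_hat <- par[2]
  rss <- val
  converged <- (best$convergence == 0 || gn_ok) &&
    is.finite(rss) && A_hat > 0
  n <- length(y)
  sigma2 <- rss / max(n - 2, 1)
  e <- exp(-b_hat * t)
  J <- cbind(e, -A_hat * t * e)
  cv <- tryCatch({
    JtJ_inv <- solve(crossprod(J))
    if (options$cov_type == "sandwich") {
      # Propagate the covariance of repeatedly inspected counts: with
      # survival S(t) = e^{-b t}, Cov(N_i, N_j) = n0 S_hi (1 - S_lo)
      # where S_hi/S_lo are the survivals at the later/earlier time.
      # This accounts for the same pods being re-counted at every
      # interval; the iid-residual formula does not.
      S <- pmin(e, 1)
      lo <- outer(S, S, pmin)
      hi <- outer(S, S, pmax)
      Sigma <- assay$initial_count * lo * (1 - hi)
      JtJ_inv %*% crossprod(J, Sigma %*% J) %*% JtJ_inv
    } else {
      sigma2 * JtJ_inv
    }
  }, error = function(e) NULL)
  if (is.null(cv)) {
    cv <- matrix(NA_real_, 2, 2)
    converged <- FALSE
  }
  cv <- (cv + t(cv)) / 2
  dimnames(cv) <- list(c("A", "b"), c("A", "b"))

  structure(list(A_hat = A_hat, b_hat = b_hat, cov = cv, rss = rss,
                 n_obs = n, sigma2 = sigma2, converged = converged,
                 genotype = assay$genotype,
                 replicate_id = assay$replicate_id,
                 initial_count = assay$initial_count,
                 options = options),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> ", x$genotype, "/", x$replicate_id,
      ": A = ", signif(x$A_hat, 6), ", b = ", signif(x$b_hat, 6),
      " /s, rss = ", signif(x$rss, 4),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' RIT50 half-life with delta-method confidence interval
#'
#' The RIT50 is the time at which half of the *initial* pods have
#' shattered, read off the fitted curve: it solves
#' \eqn{A e^{-b t} = N_0/2}, i.e.
#' \deqn{t_{50} = \log(2A/N_0)/b.}
#' Its standard error is obtained by first-order error propagation
#' (the delta method) from the fit covariance, with gradient
#' \eqn{g = (1/(Ab),\; -t_{50}/b)}, so
#' \eqn{se^2 = g^\top \Sigma g}. The confidence interval is
#' \eqn{t_{50} \pm z_{level} \cdot se}, truncated below at 0.
#'
#' With `half_life_def = "fitted"` the curve is solved against its own
#' intercept (`A/2`), giving the pure exponential half-life
#' \eqn{\log 2 / b} with gradient \eqn{(0, -t_{50}/b)}.
#'
#' @param fit A converged `decay_fit` with `b_hat > 0`.
#' @param initial_count Starting pod count \eqn{N_0}; defaults to the
#'   value carried on the fit.
#' @param level Confidence level in (0,1); defaults to the fit options.
#' @param half_life_def `"initial"` or `"fitted"`; defaults to the fit
#'   options.
#' @return Object of class `half_life_estimate` with fields `rit50_s`,
#'   `se_s`, `ci_low_s`, `ci_high_s`, `level`, `genotype`,
#'   `replicate_id`.
#' @export
half_life <- function(fit, initial_count = fit$initial_count,
                      level = fit$options$level,
                      half_life_def = fit$options$half_life_def) {
  stopifnot(inherits(fit, "decay_fit"), level > 0, level < 1)
  if (!isTRUE(fit$converged))
    stop("half-life undefined: fit did not converge", call. = FALSE)
  A <- fit$A_hat
  b <- fit$b_hat
  if (b <= 0)
    stop("half-life undefined: decay rate is zero", call. = FALSE)
  if (half_life_def == "initial") {
    if (2 * A / initial_count <= 1)
      stop("half-life undefined: fitted curve never reaches ",
           "initial_count/2 (A_hat = ", signif(A, 4), " <= ",
           initial_count / 2, ")", call. = FALSE)
    t50 <- log(2 * A / initial_count) / b
    g <- c(1 / (A * b), -t50 / b)
  } else {
    t50 <- log(2) / b
    g <- c(0, -t50 / b)
  }
  se <- sqrt(max(drop(t(g) %*% fit$cov %*% g), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(rit50_s = t50, se_s = se,
                 ci_low_s = max(t50 - z * se, 0),
                 ci_high_s = t50 + z * se,
                 level = level,
                 genotype = fit$genotype,
                 replicate_id = fit$replicate_id),
            class = "half_life_estimate")
}

#' @export
print.half_life_estimate <- function(x, ...) {
  cat("<half_life_estimate> ", x$genotype, "/", x$replicate_id,
      ": RIT50 = ", signif(x$rit50_s, 5), " s (se ", signif(x$se_s, 4),
      ", ", round(100 * x$level), "% CI [", signif(x$ci_low_s, 5), ", ",
      signif(x$ci_high_s, 5), "])\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.half_life_estimate <- function(x, ...) {
  data.frame(genotype = x$genotype, replicate = x$replicate_id,
             rit50_s = x$rit50_s, se_s = x$se_s,
             ci_low_s = x$ci_low_s, ci_high_s = x$ci_high_s,
             level = x$level, stringsAsFactors = FALSE)
}

#' Parametric-bootstrap standard error and interval for the RIT50
#'
#' Simulates `n_boot` assays from the fitted decay curve using the
#' pathwise exponential break-time model (so counts at each time are
#' marginally Binomial with survival probability \eqn{e^{-\hat b t}}),
#' refits each, and summarizes the bootstrap RIT50 distribution by its
#' standard deviation and percentile interval. Serves as the
#' independent check on the delta-method (error-propagation) interval.
#'
#' @param assay The observed `rit_assay` (supplies the time grid and
#'   `initial_count`).
#' @param fit The converged `decay_fit` for that assay.
#' @param n_boot Number of bootstrap replicates (>= 200).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param level Interval level (default from fit options).
#' @return List with `se_s`, `ci_low_s`, `ci_high_s`, `n_ok` (number of
#'   converged refits) and the vector `rit50_boot`.
#' @export
bootstrap_half_life <- function(assay, fit, n_boot = 500L, seed = 1L,
                                level = fit$options$level) {
  stopifnot(n_boot >= 200, isTRUE(fit$converged), fit$b_hat > 0)
  times <- assay$observations$time_s
  grid <- sort(unique(times[times > 0]))
  n0 <- assay$initial_count
  vals <- rep(NA_real_, n_boot)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (i in seq_len(n_boot)) {
    breaks <- stats::rexp(n0, rate = fit$b_hat)
    counts <- vapply(grid, function(tt) sum(breaks > tt), numeric(1))
    a <- tryCatch(
      rit_assay(assay$genotype, paste0("boot", i),
                time_s = c(0, grid), intact_count = c(n0, counts),
                initial_count = n0, interval_s = assay$interval_s,
                validate = FALSE),
      error = function(e) NULL)
    if (is.null(a)) next
    hl <- tryCatch({
      f <- fit_decay(a, fit$options)
      half_life(f, initial_count = n0, level = level)$rit50_s
    }, error = function(e) NA_real_)
    vals[i] <- hl
  }
  ok <- vals[is.finite(vals)]
  if (length(ok) < 0.8 * n_boot)
    stop("bootstrap unstable: ", n_boot - length(ok), " of ", n_boot,
         " refits failed to converge", call. = FALSE)
  alpha <- (1 - level) / 2
  qs <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(se_s = stats::sd(ok), ci_low_s = qs[1], ci_high_s = qs[2],
       n_ok = length(ok), rit50_boot = ok)
}

# Save/seed helpers: scoped RNG use so package functions that need a
# seed do not clobber the caller's random state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
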