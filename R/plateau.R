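# Exponential decay-to-plateau (cure-fraction) survival model:
#   S(t) = P + (S0 - P) * exp(-k * t)
# fitted by bounded least squares to the Kaplan-Meier survival values.
# The model is parameterised internally in the half-life tau = ln(2)/k so
# that the reported half-life standard error comes straight from the
# Jacobian rather than a delta-method propagation.

TAU_MIN <- log(2) / 1e3   # k upper bound 1e3 per month
TAU_MAX <- log(2) / 1e-6  # k lower bound 1e-6 per month

#' Decay-to-plateau survival function
#'
#' Evaluates `S(t) = plateau + (s0 - plateau) * exp(-k * t)`: survival
#' starts at `s0`, decays at rate `k` (per month) and settles at the
#' plateau, the cure fraction.
#'
#' @param t Time in months, non-negative.
#' @param s0 Survival probability at time zero.
#' @param plateau Asymptotic survival probability, `0 <= plateau <= s0`.
#' @param k Decay rate constant per month, `k >= 0`.
#' @return Numeric vector of survival probabilities.
#' @examples
#' plateau_survival(0, s0 = 1, plateau = 0.6, k = 0.1)    # 1
#' plateau_survival(1e6, s0 = 1, plateau = 0.87, k = 0.1) # 0.87
#' @export
plateau_survival <- function(t, s0 = 1, plateau = 0, k = 0) {
  if (any(t < 0)) {
    stop_cp("`t` must be non-negative.", "cureplateau_validation_error")
  }
  if (k < 0) {
    stop_cp("`k` must be non-negative.", "cureplateau_validation_error")
  }
  if (plateau < 0 || plateau > s0 || s0 > 1) {
    stop_cp("Require 0 <= plateau <= s0 <= 1.",
            "cureplateau_validation_error")
  }
  plateau + (s0 - plateau) * exp(-k * t)
}

#' Half-life of the decay
#'
#' `ln(2) / k`, the time for survival to fall halfway from `s0` to the
#' plateau. A rate of zero means no decay and an infinite half-life.
#'
#' @param k Decay rate constant per month, `k >= 0`.
#' @return Half-life in months (`Inf` when `k = 0`).
#' @examples
#' half_life(log(2))       # 1
#' half_life(log(2) / 4.5) # 4.5
#' @export
half_life <- function(k) {
  if (any(k < 0)) {
    stop_cp("`k` must be non-negative.", "cureplateau_validation_error")
  }
  ifelse(k == 0, Inf, log(2) / k)
}

#' Fit configuration for the plateau model
#'
#' @param s0_mode `"fixed"` (survival from diagnosis starts at 1, the
#'   default) or `"free"` (estimate the intercept within (0, 1\]).
#' @param plateau_mode `"free"` (estimate the plateau in \[0, 1\]) or
#'   `"zero"` (plain exponential decay to zero, the rival no-plateau
#'   model).
#' @param aic `"plain"` for `AIC = N log(RSS/N) + 2K` (K counts free
#'   curve parameters plus one for the error variance) or `"aicc"` for
#'   the small-sample correction `AIC + 2K(K+1)/(N-K-1)`.
#' @param loss `"km"` (default): unweighted least squares on the
#'   Kaplan-Meier survival values, the graphical-package route whose
#'   printed AIC differences this package mirrors. `"mle"`: full
#'   right-censored maximum likelihood of the cure-fraction model
#'   (`AIC = -2 logLik + 2K`, likelihood-ratio p-values), used by the
#'   model-comparison machinery; statistically calibrated, unlike the
#'   least-squares route (see the methods vignette).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(s0_mode = c("fixed", "free"),
                       plateau_mode = c("free", "zero"),
                       aic = c("plain", "aicc"),
                       loss = c("km", "mle")) {
  structure(
    list(
      s0_mode = match.arg(s0_mode),
      plateau_mode = match.arg(plateau_mode),
      aic = match.arg(aic),
      loss = match.arg(loss)
    ),
    class = "fit_config"
  )
}

# ---- censored-data maximum likelihood for the cure-fraction model ----
# S(t) = P + (1 - P) exp(-kt); event density f(t) = (1 - P) k exp(-kt).

cure_loglik <- function(plateau, tau, time, event) {
  k <- log(2) / tau
  s_cens <- plateau + (1 - plateau) * exp(-k * time[!event])
  sum(log(pmax(1 - plateau, 1e-300)) + log(k) - k * time[event]) +
    sum(log(pmax(s_cens, 1e-300)))
}

# Fit the cure model to one group's right-censored times by bounded
# maximum likelihood (multi-start L-BFGS-B over the half-life).
mle_fit_group <- function(time, event) {
  n <- length(time)
  if (sum(event) == 0L) {
    return(list(plateau = 1, tau = Inf, k = 0, loglik = 0,
                se = c(plateau = NA_real_, half_life = NA_real_),
                converged = TRUE, degenerate = TRUE, n = n, k_free = 2L))
  }
  obj <- function(p) -cure_loglik(p[1L], exp(p[2L]), time, event)
  p0_plat <- max(min(1 - mean(event), 0.95), 0.02)
  tau0 <- max(median(time[event]), TAU_MIN * 10)
  best <- NULL
  for (tau_start in pmin(pmax(tau0 * c(1, 0.2, 5), TAU_MIN * 2),
                         TAU_MAX / 2)) {
    res <- tryCatch(
      stats::optim(c(p0_plat, log(tau_start)), obj, method = "L-BFGS-B",
                   lower = c(1e-6, log(TAU_MIN)),
                   upper = c(1 - 1e-9, log(TAU_MAX)),
                   hessian = FALSE),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-10) best <- res
  }
  if (is.null(best)) {
    stop_cp("Likelihood optimization failed at every start.",
            "cureplateau_fit_error")
  }
  plateau <- best$par[1L]
  tau <- exp(best$par[2L])
  # observed-information SEs in (plateau, half-life)
  se <- c(plateau = NA_real_, half_life = NA_real_)
  H <- tryCatch(
    stats::optimHess(c(plateau, tau), function(p) {
      -cure_loglik(p[1L], p[2L], time, event)
    }),
    error = function(e) NULL
  )
  if (!is.null(H)) {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      if (all(is.finite(d)) && all(d >= 0)) {
        se <- c(plateau = sqrt(d[1L]), half_life = sqrt(d[2L]))
      }
    }
  }
  list(plateau = plateau, tau = tau, k = log(2) / tau,
       loglik = -best$value, se = se,
       converged = best$convergence == 0L, degenerate = FALSE,
       n = n, k_free = 2L)
}

# Dress an MLE group fit in plateau_fit clothing so tidy()/print() work.
mle_as_plateau_fit <- function(m, config, endpoint = NULL) {
  structure(
    list(
      s0 = 1, plateau = m$plateau, k = m$k, half_life = m$tau,
      se = c(plateau = m$se[["plateau"]], half_life = m$se[["half_life"]],
             k = NA_real_, s0 = NA_real_),
      rss = NA_real_, n_points = m$n, n_free = m$k_free,
      aic = -2 * m$loglik + 2 * m$k_free,
      aic_plain = -2 * m$loglik + 2 * m$k_free, aicc = NA_real_,
      loglik = m$loglik,
      converged = m$converged, at_boundary = m$degenerate,
      degenerate = m$degenerate,
      config = config,
      points = tibble(time = numeric(), survival = numeric()),
      endpoint = endpoint
    ),
    class = "plateau_fit"
  )
}

# Assemble the fitted point set: KM survival at distinct event times,
# anchored at (0, 1) when s0 is fixed.
fit_points <- function(curve, config) {
  t <- curve$time
  s <- curve$survival
  if (config$s0_mode == "fixed") {
    t <- c(0, t)
    s <- c(1, s)
  }
  list(t = t, s = s)
}

model_eval <- function(t, par, config) {
  s0 <- if (config$s0_mode == "free") par[["s0"]] else 1
  plateau <- if (config$plateau_mode == "free") par[["plateau"]] else 0
  tau <- par[["tau"]]
  plateau + (s0 - plateau) * exp(-log(2) / tau * t)
}

num_jacobian <- function(par, t, config) {
  f0 <- model_eval(t, par, config)
  J <- matrix(NA_real_, nrow = length(t), ncol = length(par),
              dimnames = list(NULL, names(par)))
  for (j in seq_along(par)) {
    h <- max(1e-7, abs(par[[j]]) * 1e-7)
    pp <- par; pp[[j]] <- pp[[j]] + h
    pm <- par; pm[[j]] <- pm[[j]] - h
    J[, j] <- (model_eval(t, pp, config) - model_eval(t, pm, config)) / (2 * h)
  }
  J
}

plateau_bounds <- function(config) {
  lower <- c()
  upper <- c()
  if (config$plateau_mode == "free") {
    lower <- c(lower, plateau = 0)
    upper <- c(upper, plateau = 1)
  }
  lower <- c(lower, tau = TAU_MIN)
  upper <- c(upper, tau = TAU_MAX)
  if (config$s0_mode == "free") {
    lower <- c(lower, s0 = 1e-6)
    upper <- c(upper, s0 = 1)
  }
  list(lower = lower, upper = upper)
}

# Deterministic initial half-life: time at which the KM curve first drops
# below halfway to the provisional plateau; fallback, the median event time.
init_tau <- function(t, s, plateau0) {
  mid <- (1 + plateau0) / 2
  below <- which(s < mid & t > 0)
  tau0 <- if (length(below) > 0L) t[below[1L]] else median(t[t > 0])
  min(max(tau0, TAU_MIN * 10), TAU_MAX / 10)
}

# Bounded Levenberg-Marquardt on an arbitrary (t, s) point set, with the
# deterministic three-point multi-start over the initial half-life.
ls_fit_core <- function(t, s, config) {
  bounds <- plateau_bounds(config)
  plateau0 <- if (config$plateau_mode == "free") {
    min(max(s[which.max(t)], 0), 1)
  } else 0
  tau0 <- init_tau(t, s, plateau0)
  starts <- pmin(pmax(tau0 * c(1, 0.2, 5), TAU_MIN), TAU_MAX)
  start_pairs <- lapply(starts, function(x) c(plateau = plateau0, tau = x))

  # when the plateau is free, also start from the best zero-plateau
  # solution so the richer model can never end up above its nested rival
  if (config$plateau_mode == "free") {
    zero_config <- config
    zero_config$plateau_mode <- "zero"
    zero <- tryCatch(ls_fit_core(t, s, zero_config), error = function(e) NULL)
    if (!is.null(zero)) {
      start_pairs <- c(start_pairs,
                       list(c(plateau = 0, tau = zero$par[["tau"]])))
    }
  }

  best <- NULL
  for (sp in start_pairs) {
    par0 <- c()
    if (config$plateau_mode == "free") par0 <- c(par0, plateau = sp[["plateau"]])
    par0 <- c(par0, tau = sp[["tau"]])
    if (config$s0_mode == "free") par0 <- c(par0, s0 = 1)
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = par0,
        lower = bounds$lower[names(par0)],
        upper = bounds$upper[names(par0)],
        fn = function(p) s - model_eval(t, p, config),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    conv <- res$info %in% c(1L, 2L, 3L, 4L)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(par = res$par, rss = rss, converged = conv)
    }
  }
  if (is.null(best)) {
    stop_cp("Optimizer failed at every start.", "cureplateau_fit_error")
  }
  best$bounds <- bounds
  best
}

#' Fit the decay-to-plateau model to a Kaplan-Meier curve
#'
#' Unweighted least squares of `S(t) = plateau + (s0 - plateau) e^{-kt}`
#' on the Kaplan-Meier survival values at the distinct event times
#' (anchored at `(0, 1)` when `s0` is fixed), via bounded
#' Levenberg-Marquardt with a deterministic three-point multi-start over
#' the initial half-life. Standard errors are the asymptotic
#' `sqrt(diag(RSS/(N-K) (J'J)^{-1}))` at the optimum; the model is
#' parameterised in the half-life, so its SE is reported directly.
#'
#' @param curve A [km_curve()] result (or any data frame with `time` and
#'   `survival` columns).
#' @param config A [fit_config()].
#' @return An object of class `plateau_fit`: estimates (`s0`, `plateau`,
#'   `k`, `half_life`), standard errors, `rss`, `n_points`, `n_free`,
#'   `aic`, `converged` and `at_boundary` flags, and the fitted point set.
#' @examples
#' cv <- tibble::tibble(
#'   time = 1:40,
#'   survival = plateau_survival(1:40, 1, 0.6, 0.1)
#' )
#' fit <- fit_plateau(cv)
#' glance(fit)
#' @export
fit_plateau <- function(curve, config = fit_config()) {
  if (!is.data.frame(curve)) {
    stop_cp("`curve` must be a data frame with `time` and `survival`.",
            "cureplateau_validation_error")
  }
  check_columns(curve, c("time", "survival"), "curve")
  n_free <- (config$plateau_mode == "free") + 1L + (config$s0_mode == "free")
  pts <- fit_points(curve, config)

  # A curve with no events carries no information about the decay: the
  # survival stays at 1, the plateau sits at its upper bound and k is
  # unidentified. Return the degenerate no-decay fit rather than erroring,
  # so that sparse high-plateau groups still enter global comparisons.
  if (nrow(curve) == 0L && config$s0_mode == "fixed") {
    return(structure(
      list(
        s0 = 1,
        plateau = if (config$plateau_mode == "free") 1 else 0,
        k = 0,
        half_life = Inf,
        se = c(plateau = NA_real_, half_life = NA_real_, k = NA_real_,
               s0 = NA_real_),
        rss = 0,
        n_points = length(pts$t),
        n_free = n_free,
        aic = -Inf, aic_plain = -Inf, aicc = NA_real_,
        converged = TRUE,
        at_boundary = TRUE,
        degenerate = TRUE,
        config = config,
        points = tibble(time = pts$t, survival = pts$s),
        endpoint = attr(curve, "endpoint")
      ),
      class = "plateau_fit"
    ))
  }
  if (length(pts$t) < n_free) {
    stop_cp(
      sprintf("Need at least %d fitted points for %d free parameters (got %d).",
              n_free, n_free, length(pts$t)),
      "cureplateau_insufficient_data_error"
    )
  }
  core <- ls_fit_core(pts$t, pts$s, config)

  par <- core$par
  n <- length(pts$t)
  rss <- core$rss
  k_aic <- n_free + 1L  # error variance counts as a parameter
  aic <- if (rss > 0) n * log(rss / n) + 2 * k_aic else -Inf
  aicc <- if (n - k_aic - 1 > 0 && is.finite(aic)) {
    aic + 2 * k_aic * (k_aic + 1) / (n - k_aic - 1)
  } else NA_real_

  # asymptotic SEs from the Jacobian at the optimum
  se <- setNames(rep(NA_real_, length(par)), names(par))
  if (n > n_free && rss > 0) {
    J <- num_jacobian(par, pts$t, config)
    JtJ <- crossprod(J)
    cov <- tryCatch(rss / (n - n_free) * solve(JtJ), error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      se[d >= 0] <- sqrt(d[d >= 0])
    }
  }

  tol <- 1e-6
  at_boundary <- any(
    par <= core$bounds$lower[names(par)] + tol |
    par >= core$bounds$upper[names(par)] - tol
  )

  plateau_hat <- if (config$plateau_mode == "free") par[["plateau"]] else 0
  tau_hat <- par[["tau"]]
  k_hat <- log(2) / tau_hat
  se_k <- if (!is.na(se[["tau"]])) log(2) / tau_hat^2 * se[["tau"]] else NA_real_

  structure(
    list(
      s0 = if (config$s0_mode == "free") par[["s0"]] else 1,
      plateau = plateau_hat,
      k = k_hat,
      half_life = tau_hat,
      se = c(
        plateau = if (config$plateau_mode == "free") se[["plateau"]] else NA_real_,
        half_life = se[["tau"]],
        k = se_k,
        s0 = if (config$s0_mode == "free") se[["s0"]] else NA_real_
      ),
      rss = rss,
      n_points = n,
      n_free = n_free,
      aic = if (config$aic == "aicc") aicc else aic,
      aic_plain = aic,
      aicc = aicc,
      converged = core$converged,
      at_boundary = at_boundary,
      degenerate = n <= n_free,
      config = config,
      points = tibble(time = pts$t, survival = pts$s),
      endpoint = attr(curve, "endpoint")
    ),
    class = "plateau_fit"
  )
}

#' Fit the rival exponential-to-zero model
#'
#' Same machinery as [fit_plateau()] with the plateau pinned at zero
#' (one fewer free parameter): the "no plateau" model used to ask whether
#' a survival plateau is supported by the data at all.
#'
#' @inheritParams fit_plateau
#' @return A `plateau_fit` with `plateau = 0`.
#' @export
fit_exponential_to_zero <- function(curve, config = fit_config()) {
  config$plateau_mode <- "zero"
  fit_plateau(curve, config)
}

#' @export
print.plateau_fit <- function(x, ...) {
  cat("Decay-to-plateau survival fit\n")
  cat(sprintf("  plateau    %.3f%s\n", x$plateau,
              if (!is.na(x$se[["plateau"]]))
                sprintf(" ± %.3f", x$se[["plateau"]]) else ""))
  cat(sprintf("  half-life  %.2f mo%s\n", x$half_life,
              if (!is.na(x$se[["half_life"]]))
                sprintf(" ± %.2f", x$se[["half_life"]]) else ""))
  cat(sprintf("  k          %.4g /mo\n", x$k))
  cat(sprintf("  RSS %.4g on %d points (%d free parameters), AIC %.2f\n",
              x$rss, x$n_points, x$n_free, x$aic))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  if (x$at_boundary) cat("  note: parameter(s) at bounds\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.plateau_fit <- function(x, ...) {
  tibble(
    term = c("s0", "plateau", "k", "half_life"),
    estimate = c(x$s0, x$plateau, x$k, x$half_life),
    std.error = c(x$se[["s0"]], x$se[["plateau"]], x$se[["k"]],
                  x$se[["half_life"]])
  )
}

#' @exportS3Method generics::glance
glance.plateau_fit <- function(x, ...) {
  tibble(
    rss = x$rss, n_points = x$n_points, n_free = x$n_free,
    aic = x$aic, aicc = x$aicc, converged = x$converged,
    at_boundary = x$at_boundary
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.plateau_fit <- function(object, ...) {
  pts <- object$points
  grid <- tibble(
    time = seq(0, max(pts$time), length.out = 200)
  )
  grid$fitted <- plateau_survival(grid$time, object$s0, object$plateau,
                                  object$k)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_line(
      data = grid,
      ggplot2::aes(y = .data$fitted),
      colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  title = "Kaplan-Meier points and fitted plateau model") +
    ggplot2::theme_minimal()
}
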