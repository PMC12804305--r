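# Whole-body kinetics and mother-daughter decay chains.
#
# Effective half-life: whole-body activity versus time is fitted with a
# one-phase (A0 e^{-lambda t}) or two-phase (A1 e^{-l1 t} + A2 e^{-l2 t})
# exponential decay. Model choice by corrected AIC, favouring the simpler
# model unless the biexponential improves AICc by more than 2.
#
# Decay chains: the daughter activity of a mother-daughter pair follows the
# Bateman solution
#   A_d(t) = A_m(0) * lambda_d/(lambda_d - lambda_m) *
#            (e^{-lambda_m t} - e^{-lambda_d t}) * BR,
# with the secular limit (lambda_m -> 0) A_d = A_m(0) (1 - e^{-lambda_d t}) BR
# and, for lambda_d > lambda_m > 0, transient equilibrium at the asymptotic
# ratio lambda_d/(lambda_d - lambda_m) * BR.

#' Daughter activity from the Bateman equation
#'
#' @param A_m0 mother activity at t = 0 (any activity unit; the result has
#'   the same unit).
#' @param lambda_m mother decay constant, 1/h (>= 0).
#' @param lambda_d daughter decay constant, 1/h (> 0).
#' @param t time since separation/elution, h (>= 0); vectorized.
#' @param BR branching ratio mother -> daughter in [0, 1].
#' @return daughter activity at `t`.
#' @details Near-degenerate rates (`|lambda_d - lambda_m| <
#'   1e-12 * lambda_d`) switch to the analytic limit
#'   `A_m0 * lambda * t * exp(-lambda * t) * BR` to avoid catastrophic
#'   cancellation.
#' @export
#' @examples
#' bateman_daughter(100, log(2) / 9.92 / 24, log(2) / (4.80 / 60), 1, BR = 1)
bateman_daughter <- function(A_m0, lambda_m, lambda_d, t, BR = 1) {
  stopifnot(lambda_d > 0, lambda_m >= 0, BR >= 0, BR <= 1, all(t >= 0),
            A_m0 >= 0)
  if (abs(lambda_d - lambda_m) < 1e-12 * lambda_d) {
    lam <- lambda_d
    return(A_m0 * lam * t * exp(-lam * t) * BR)
  }
  # cancellation-free form: e^{-lm t} - e^{-ld t} = -e^{-lm t} expm1(-(ld-lm) t)
  delta <- lambda_d - lambda_m
  A_m0 * lambda_d / delta * exp(-lambda_m * t) * (-expm1(-delta * t)) * BR
}

#' Daughter activity under secular equilibrium
#'
#' Limit of the Bateman equation for a mother so long-lived that
#' `lambda_m ~ 0`: `A_d(t) = A_m0 * (1 - exp(-lambda_d * t)) * BR`, rising
#' to the asymptote `A_m0 * BR` (equal mother and daughter activities for
#' BR = 1). After one daughter half-life the daughter has reached half the
#' asymptote; after about five, equilibrium.
#'
#' @inheritParams bateman_daughter
#' @return daughter activity at `t`.
#' @export
secular_daughter <- function(A_m0, lambda_d, t, BR = 1) {
  stopifnot(lambda_d > 0, BR >= 0, BR <= 1, all(t >= 0), A_m0 >= 0)
  A_m0 * (1 - exp(-lambda_d * t)) * BR
}

#' Time for the daughter to reach a fraction of equilibrium
#'
#' Under secular ingrowth the daughter reaches fraction f of its
#' equilibrium activity at `t = -ln(1 - f) / lambda_d`. Fraction 0.5 is one
#' daughter half-life; 1 - 2^-5 ~ 0.97 corresponds to the usual "about five
#' half-lives" rule.
#'
#' @param lambda_d daughter decay constant, 1/h.
#' @param fraction target fraction of equilibrium, in (0, 1).
#' @return time in the inverse unit of `lambda_d`.
#' @export
time_to_equilibrium <- function(lambda_d, fraction) {
  stopifnot(lambda_d > 0)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  -log(1 - fraction) / lambda_d
}

#' Asymptotic daughter/mother activity ratio in transient equilibrium
#'
#' For `lambda_d > lambda_m > 0` the pair settles into parallel decay with
#' `A_d / A_m -> lambda_d / (lambda_d - lambda_m) * BR`.
#'
#' @inheritParams bateman_daughter
#' @return the asymptotic activity ratio.
#' @export
transient_ratio <- function(lambda_m, lambda_d, BR = 1) {
  stopifnot(lambda_m > 0, BR >= 0, BR <= 1)
  if (lambda_d <= lambda_m) {
    stop("transient equilibrium requires lambda_d > lambda_m ",
         "(daughter shorter-lived than mother)")
  }
  lambda_d / (lambda_d - lambda_m) * BR
}

#' Time of the daughter-activity maximum (transient case)
#'
#' @inheritParams bateman_daughter
#' @return `t_max = ln(lambda_d / lambda_m) / (lambda_d - lambda_m)`.
#' @export
daughter_peak_time <- function(lambda_m, lambda_d) {
  stopifnot(lambda_m > 0, lambda_d > lambda_m)
  log(lambda_d / lambda_m) / (lambda_d - lambda_m)
}

#' Estimate the mother activity from a measured daughter activity
#'
#' Inverts the Bateman equation: `A_m0 = A_d_measured /
#' bateman_daughter(A_m0 = 1, ..., t)`. At large t this reduces to dividing
#' by the equilibrium ratio. Used e.g. to quantify an alpha emitter without
#' detectable gammas from a gamma-emitting daughter, or mother breakthrough
#' from a generator after the eluted daughter has decayed away.
#'
#' @param A_d_measured measured daughter activity at time `t`.
#' @param t time since separation, h.
#' @param lambda_m,lambda_d,BR chain parameters as in [bateman_daughter()].
#' @param min_ingrowth_fraction minimum predicted daughter (relative to its
#'   equilibrium/peak level) below which the inversion is declared
#'   ill-conditioned.
#' @return estimated mother activity at t = 0.
#' @export
mother_from_daughter <- function(A_d_measured, t, lambda_m, lambda_d,
                                 BR = 1, min_ingrowth_fraction = 1e-6) {
  unit <- bateman_daughter(1, lambda_m, lambda_d, t, BR)
  # scale against the achievable daughter level so "too early" is caught
  ref <- if (lambda_m > 0 && lambda_d > lambda_m) {
    bateman_daughter(1, lambda_m, lambda_d,
                     daughter_peak_time(lambda_m, lambda_d), BR)
  } else BR
  if (unit < min_ingrowth_fraction * ref) {
    stop("daughter ingrowth at t = ", t, " is below ",
         min_ingrowth_fraction, " of its equilibrium level; ",
         "inversion is ill-conditioned (measure later)")
  }
  A_d_measured / unit
}

.aicc <- function(rss, n, k) {
  # Gaussian log-likelihood up to constants; k includes the variance term
  rss <- max(rss, 1e-300)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1e-9)
}

.fit_one_phase <- function(t, a, w = rep(1, length(t))) {
  # log-linear initialization (exact on noiseless data)
  pos <- a > 0
  init <- stats::lm(log(a[pos]) ~ t[pos])
  start <- list(A0 = exp(stats::coef(init)[[1]]),
                lambda = max(-stats::coef(init)[[2]], 1e-8))
  fit <- minpack.lm::nlsLM(a ~ A0 * exp(-lambda * t),
                           start = start, weights = w,
                           lower = c(A0 = 0, lambda = 1e-12),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  list(coef = stats::coef(fit), rss = sum(stats::resid(fit)^2))
}

.fit_two_phase <- function(t, a, w = rep(1, length(t))) {
  # initialize by splitting the series at its midpoint: the late half fixes
  # the slow phase, the early-half residual the fast phase
  n <- length(t)
  late <- seq((n %/% 2) + 1L, n)
  early <- seq_len(n %/% 2)
  f_late <- stats::lm(log(pmax(a[late], 1e-12)) ~ t[late])
  l2 <- max(-stats::coef(f_late)[[2]], 1e-8)
  A2 <- exp(stats::coef(f_late)[[1]])
  res <- a[early] - A2 * exp(-l2 * t[early])
  if (all(res > 0)) {
    f_early <- stats::lm(log(res) ~ t[early])
    l1 <- max(-stats::coef(f_early)[[2]], l2 * 2)
    A1 <- exp(stats::coef(f_early)[[1]])
  } else {
    l1 <- l2 * 10
    A1 <- max(a[1] - A2, 0.1 * A2)
  }
  fit <- minpack.lm::nlsLM(
    a ~ A1 * exp(-l1 * t) + A2 * exp(-l2 * t),
    start = list(A1 = A1, l1 = l1, A2 = A2, l2 = l2), weights = w,
    lower = c(A1 = 0, l1 = 1e-12, A2 = 0, l2 = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  co <- stats::coef(fit)
  # order phases so lambda1 > lambda2
  if (co[["l1"]] < co[["l2"]]) {
    co <- c(A1 = co[["A2"]], l1 = co[["l2"]], A2 = co[["A1"]],
            l2 = co[["l1"]])
  }
  list(coef = co, rss = sum(stats::resid(fit)^2))
}

#' Fit the whole-body effective half-life
#'
#' Nonlinear least squares of whole-body activity versus time with a
#' one-phase or two-phase exponential decay model. `model = "auto"`
#' fits both and selects by corrected AIC, keeping the one-phase model
#' unless the two-phase model improves AICc by more than 2 (the simplest
#' adequate model is preferred).
#'
#' @param t_h time since injection, hours (>= 0, strictly increasing).
#' @param activity whole-body activity (e.g. MBq); positive.
#' @param model `"auto"`, `"one_phase"` or `"two_phase"`.
#' @param nuclide optional `nuclide` (or id) whose physical half-life is
#'   used to derive the biological half-life via
#'   `1/t_bio = 1/t_eff - 1/t_phys` (only when `t_eff < t_phys`).
#' @param weights `"none"` (default) for unweighted least squares, or
#'   `"poisson"` for 1/A weights.
#' @return object of class `decay_fit`: `model`, `coefficients`
#'   (`A0`/`lambda` or `A1,lambda1,A2,lambda2` in 1/h), `t_half_eff_h`
#'   (per phase for the biexponential), `rss`, `aicc`, and optionally
#'   `t_half_biological_h`.
#' @export
fit_effective_half_life <- function(t_h, activity,
                                    model = c("auto", "one_phase",
                                              "two_phase"),
                                    nuclide = NULL,
                                    weights = c("none", "poisson")) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  stopifnot(length(t_h) == length(activity), all(diff(t_h) > 0),
            all(t_h >= 0))
  if (any(activity <= 0)) stop("activities must be positive for fitting")
  n <- length(t_h)
  if (n < 3) stop("need at least 3 points for a one-phase fit")
  if (model == "two_phase" && n < 5) {
    stop("need at least 5 points for a two-phase fit")
  }
  sw <- if (weights == "poisson") 1 / activity else rep(1, n)

  fit1 <- fit2 <- NULL
  err1 <- err2 <- NULL
  if (model != "two_phase") {
    fit1 <- tryCatch(.fit_one_phase(t_h, activity, sw),
                     error = function(e) {err1 <<- e; NULL})
  }
  if (model != "one_phase" && n >= 5) {
    fit2 <- tryCatch(.fit_two_phase(t_h, activity, sw),
                     error = function(e) {err2 <<- e; NULL})
  }
  pick <- model
  if (model == "auto") {
    if (is.null(fit1) && is.null(fit2)) {
      stop("neither model converged: ", conditionMessage(err1))
    }
    if (is.null(fit2)) {
      pick <- "one_phase"
    } else if (is.null(fit1)) {
      pick <- "two_phase"
    } else {
      a1 <- .aicc(fit1$rss, n, 3)
      a2 <- .aicc(fit2$rss, n, 5)
      pick <- if (a2 < a1 - 2) "two_phase" else "one_phase"
    }
  }
  if (pick == "one_phase") {
    if (is.null(fit1)) {
      stop("one-phase fit failed to converge; initialization: log-linear ",
           "regression gave lambda ", format(err1), call. = FALSE)
    }
    co <- fit1$coef
    out <- list(model = "one_phase",
                coefficients = c(A0 = co[["A0"]], lambda = co[["lambda"]]),
                t_half_eff_h = log(2) / co[["lambda"]],
                rss = fit1$rss, aicc = .aicc(fit1$rss, n, 3))
  } else {
    if (is.null(fit2)) {
      stop("two-phase fit failed to converge: ", conditionMessage(err2),
           call. = FALSE)
    }
    co <- fit2$coef
    out <- list(model = "two_phase",
                coefficients = c(A1 = co[["A1"]], lambda1 = co[["l1"]],
                                 A2 = co[["A2"]], lambda2 = co[["l2"]]),
                t_half_eff_h = c(phase1 = log(2) / co[["l1"]],
                                 phase2 = log(2) / co[["l2"]]),
                rss = fit2$rss, aicc = .aicc(fit2$rss, n, 5))
  }
  if (!is.null(nuclide)) {
    if (is.character(nuclide)) nuclide <- get_nuclide(nuclide)
    t_phys <- nuclide$half_life_s / 3600
    t_eff <- out$t_half_eff_h[length(out$t_half_eff_h)]  # terminal phase
    out$t_half_physical_h <- t_phys
    if (t_eff < t_phys) {
      out$t_half_biological_h <- 1 / (1 / t_eff - 1 / t_phys)
    }
  }
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s model, RSS = %.4g, AICc = %.4g\n",
              x$model, x$rss, x$aicc))
  if (x$model == "one_phase") {
    cat(sprintf("  A0 = %.6g, lambda = %.6g /h, t1/2(eff) = %.6g h\n",
                x$coefficients[["A0"]], x$coefficients[["lambda"]],
                x$t_half_eff_h))
  } else {
    cat(sprintf("  A1 = %.6g, lambda1 = %.6g /h (t1/2 %.4g h); A2 = %.6g, lambda2 = %.6g /h (t1/2 %.4g h)\n",
                x$coefficients[["A1"]], x$coefficients[["lambda1"]],
                x$t_half_eff_h[["phase1"]], x$coefficients[["A2"]],
                x$coefficients[["lambda2"]], x$t_half_eff_h[["phase2"]]))
  }
  if (!is.null(x$t_half_biological_h)) {
    cat(sprintf("  t1/2(phys) = %.6g h, t1/2(bio) = %.6g h\n",
                x$t_half_physical_h, x$t_half_biological_h))
  }
  invisible(x)
}
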