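# Scoring expected against observed counts, and fitting free parameters of
# the stochastic simulator by bounded derivative-free search under common
# random numbers.

check_pair <- function(observed, expected) {
  stopifnot(inherits(observed, "count_table"), inherits(expected, "count_table"))
  if (!same_layout(observed, expected))
    stop("observed and expected tables must share an identical cell layout")
  if (any(abs(observed$count - round(observed$count)) > 1e-8))
    stop("observed counts must be integers")
  invisible(TRUE)
}

#' Poisson log-likelihood of an expected count table
#'
#' Treats the cells as independent Poisson counts:
#' `sum(O * log(E) - E - log(O!))`. A cell with `O = 0, E = 0` contributes 0;
#' a cell with `O > 0, E = 0` makes the log-likelihood `-Inf` (reported with
#' a warning, not an error, so that an optimizer simply rejects the point).
#'
#' @param observed integer [count_table()].
#' @param expected nonnegative real [count_table()] on the same layout.
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(observed, expected) {
  check_pair(observed, expected)
  O <- observed$count
  E <- expected$count
  if (any(O > 0 & E == 0)) {
    warning("expected count is 0 in a cell with observed > 0; log-likelihood is -Inf")
    return(-Inf)
  }
  pos <- O > 0
  sum(O[pos] * log(E[pos]) - lgamma(O[pos] + 1)) - sum(E)
}

#' Deviance between observed and expected count tables
#'
#' The default Poisson family gives
#' `2 * sum(O * log(O / E) - (O - E))`, the term for a cell with `O = 0`
#' reducing to `E`. This equals twice the gap between the saturated
#' log-likelihood (expected = observed) and the model log-likelihood; zero
#' iff the tables are identical, infinite (with a warning) if any cell has
#' `O > 0, E = 0`. The multinomial family conditions on each arm's observed
#' total: the expected cells are rescaled within each arm to sum to that
#' arm's observed total before the `2 * sum(O * log(O / E'))` terms are
#' accumulated, so only the allocation of diagnoses across cells is scored,
#' not the arms' overall incidence.
#'
#' @inheritParams poisson_loglik
#' @param family `"poisson"` (default) or `"multinomial"` (per trial arm).
#' @return nonnegative scalar deviance.
#' @export
count_deviance <- function(observed, expected, family = c("poisson", "multinomial")) {
  family <- match.arg(family)
  check_pair(observed, expected)
  O <- observed$count
  E <- expected$count
  if (family == "multinomial") {
    for (arm in unique(observed$arm)) {
      i <- observed$arm == arm
      if (sum(E[i]) > 0) E[i] <- E[i] * sum(O[i]) / sum(E[i])
    }
  }
  if (any(O > 0 & E == 0)) {
    warning("expected count is 0 in a cell with observed > 0; deviance is Inf")
    return(Inf)
  }
  pos <- O > 0
  if (family == "multinomial")
    return(2 * sum(O[pos] * log(O[pos] / E[pos])))
  2 * (sum(O[pos] * log(O[pos] / E[pos]) - (O[pos] - E[pos])) + sum(E[!pos]))
}

#' Upper-tail chi-squared probability for a deviance reduction
#'
#' The likelihood-ratio test of a nested model pair: the deviance reduction is
#' referred to the chi-squared distribution with degrees of freedom equal to
#' the number of newly freed parameters.
#'
#' @param dev_reduction nonnegative deviance reduction.
#' @param df positive integer degrees of freedom.
#' @return upper-tail probability.
#' @export
chi2_pvalue <- function(dev_reduction, df) {
  if (any(dev_reduction < 0)) stop("dev_reduction must be nonnegative")
  if (any(df < 1) || any(df != round(df))) stop("df must be a positive integer")
  stats::pchisq(dev_reduction, df = df, lower.tail = FALSE)
}

#' Exact binomial test for an excess of observed diagnoses
#'
#' One-sided upper-tail probability of observing at least `observed_total`
#' diagnoses among `n_at_risk` persons when the per-person diagnosis
#' probability is `expected_total / n_at_risk`.
#'
#' @param observed_total observed number of diagnoses (integer in
#'   `[0, n_at_risk]`).
#' @param expected_total model-expected number of diagnoses (positive, below
#'   `n_at_risk`).
#' @param n_at_risk persons at risk.
#' @return upper-tail probability `P(X >= observed_total)`.
#' @export
binomial_excess_test <- function(observed_total, expected_total, n_at_risk) {
  if (expected_total <= 0) stop("expected_total must be positive")
  if (expected_total >= n_at_risk) stop("expected_total must be below n_at_risk")
  if (observed_total < 0 || observed_total > n_at_risk ||
      observed_total != round(observed_total))
    stop("observed_total must be an integer in [0, n_at_risk]")
  stats::pbinom(observed_total - 1, size = n_at_risk,
                prob = expected_total / n_at_risk, lower.tail = FALSE)
}

# Model specifications ---------------------------------------------------------

model_names <- function() c("Simple", "Sensitivity", "SystematicError",
                            "SensitivityError", "Overdiagnosis", "RiskDifference")

model_aliases <- c(simple = "Simple", sensitivity = "Sensitivity",
                   syserror = "SystematicError", senserror = "SensitivityError",
                   overdx = "Overdiagnosis", riskdiff = "RiskDifference")

#' Specification of one calibration model
#'
#' Each named model frees a subset of the six hypothesis parameters and fixes
#' the rest at their null values (`sens = 1`, `syserr = 0`,
#' `indolent_fraction = 0`, `risk_factor = 1`): `Simple` frees none;
#' `Sensitivity` frees `sens_II`, `sens_III`; `SystematicError` frees
#' `syserr_II`, `syserr_III`; `SensitivityError` frees all four;
#' `Overdiagnosis` frees `indolent_fraction`; `RiskDifference` frees
#' `risk_factor`.
#'
#' @param name model name (canonical, or the short aliases `simple`,
#'   `sensitivity`, `syserror`, `senserror`, `overdx`, `riskdiff`).
#' @param fixed named list overriding the default fixed values.
#' @param bounds named list of `c(lower, upper)` overriding default search
#'   bounds (`[0, 1]` for probabilities, `[0.2, 3]` for the risk factor).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, fixed = list(), bounds = list()) {
  if (name %in% names(model_aliases)) name <- unname(model_aliases[name])
  name <- match.arg(name, model_names())
  free <- switch(name,
    Simple = character(),
    Sensitivity = c("sens_II", "sens_III"),
    SystematicError = c("syserr_II", "syserr_III"),
    SensitivityError = c("sens_II", "sens_III", "syserr_II", "syserr_III"),
    Overdiagnosis = "indolent_fraction",
    RiskDifference = "risk_factor")
  fx <- list(sens_II = 1, sens_III = 1, syserr_II = 0, syserr_III = 0,
             indolent_fraction = 0, risk_factor = 1)
  stopifnot(all(names(fixed) %in% names(fx)))
  fx[names(fixed)] <- fixed
  bd <- list(sens_II = c(0, 1), sens_III = c(0, 1),
             syserr_II = c(0, 1), syserr_III = c(0, 1),
             indolent_fraction = c(0, 1), risk_factor = c(0.2, 3))
  stopifnot(all(names(bounds) %in% names(bd)))
  bd[names(bounds)] <- bounds
  structure(list(name = name, free = free, fixed = fx, bounds = bd),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model '%s': %s\n", x$name,
              if (length(x$free)) paste("free:", paste(x$free, collapse = ", "))
              else "no free parameters"))
  invisible(x)
}

#' Optimizer settings for [fit_model()]
#'
#' @param maxeval total budget of objective evaluations (default 300).
#' @param restarts Nelder-Mead restarts from jittered starts (default 3).
#' @param tol stop restarting once the deviance improves by less than this
#'   (default 1e-3).
#' @return list of settings.
#' @export
fit_control <- function(maxeval = 300, restarts = 3, tol = 1e-3) {
  list(maxeval = maxeval, restarts = restarts, tol = tol)
}

# Build the per-arm objective machinery shared by fit_model and run_suite:
# fixed primitives per arm plus a closure evaluating the deviance at theta.
# The deviance path works on bare count vectors (the within-arm 12-cell
# tabulation mapped onto the observed layout through a precomputed 0/1
# matrix), because the optimizer calls it hundreds of times per fit.
make_objective <- function(observed, config, nh, lt, oversample, seed,
                           need_miss_u, compound = FALSE) {
  strat <- attr(observed, "stratification")
  keys <- ct_keys(strat)
  obs_df <- as.data.frame(observed)
  grid12 <- arm_cell_grid()
  seeds <- derive_seeds(seed, 2)
  arms <- list()
  for (j in seq_along(ct_arms)) {
    arm <- ct_arms[j]
    n_arm <- if (arm == "intervention") config$n_intervention else config$n_control
    n_sim <- max(1L, as.integer(round(n_arm * oversample)))
    policy <- arm_policy(config, arm)
    rows <- which(obs_df$arm == arm)
    # map each of the 12 within-arm cells to its row in the observed layout
    target <- vapply(seq_len(12L), function(k) {
      hit <- rows
      for (key in setdiff(keys, "arm"))
        hit <- hit[obs_df[[key]][hit] == grid12[[key]][k]]
      hit[1]
    }, integer(1))
    M <- matrix(0, nrow = length(rows), ncol = 12L)
    M[cbind(match(target, rows), seq_len(12L))] <- 1
    arms[[arm]] <- list(
      arm = arm, n_arm = n_arm, n_sim = n_sim, rows = rows, M = M,
      prims = draw_arm_primitives(n_sim, nh, lt, policy,
                                  entry_ages = config$entry_ages,
                                  need_miss_u = need_miss_u, seed = seeds[j]))
  }
  expected_vec <- function(theta) {
    e <- numeric(nrow(obs_df))
    for (a in arms) {
      th <- theta
      if (a$arm == "control") th$risk_factor <- 1
      res <- eval_arm_counts(a$prims, th, nh, config$followup_years, a$arm,
                             compound = compound)
      e[a$rows] <- as.vector(a$M %*% res$c12) * (a$n_arm / a$n_sim)
    }
    e
  }
  O <- obs_df$count
  pos <- O > 0
  list(
    expected_at = function(theta) {
      out <- observed
      out$count <- expected_vec(theta)
      out$source <- NULL  # expected tables carry no provenance annotation
      out
    },
    deviance_at = function(theta) {
      E <- tryCatch(expected_vec(theta), error = function(e) {
        # e.g. risk_factor pushing an onset probability above 1: an invalid
        # point the optimizer should simply reject
        if (grepl("invalid probability", conditionMessage(e))) NULL
        else stop(e)
      })
      if (is.null(E)) return(Inf)
      if (any(pos & E == 0)) return(Inf)
      2 * (sum(O[pos] * log(O[pos] / E[pos]) - (O[pos] - E[pos])) + sum(E[!pos]))
    })
}

#' Fit a calibration model to an observed count table
#'
#' Minimizes the Poisson deviance between the observed table and the
#' simulated expected table over the model's free parameters. Common random
#' numbers are mandatory: every candidate parameter vector is evaluated
#' against the same per-arm primitive draws (fixed by `seed`), so the
#' objective is deterministic given the seed and nested models can be
#' compared fairly.
#'
#' Models with one free parameter are fitted by Brent search on the bounded
#' interval; models with several use Nelder-Mead on a logit-rescaled
#' unbounded parameterization, restarted from jittered starts, stopping when
#' a restart improves the deviance by less than `control$tol` or the
#' evaluation budget is exhausted.
#'
#' @param spec a [model_spec()].
#' @param observed integer [count_table()].
#' @param config a [trial_config()].
#' @param nh an `nh_params` object.
#' @param lt a [life_table()].
#' @param oversample simulated persons per arm as a multiple of the arm size.
#' @param seed integer seed fixing the common-random-number schedule.
#' @param control a [fit_control()] list.
#' @return An object of class `fit_result`: `model`, `fitted_values` (named,
#'   free parameters only), `theta` (all six parameters at the optimum),
#'   `deviance`, `loglik`, `n_evals`, `seed`, `converged`, and `expected`
#'   (the expected table at the optimum).
#' @export
fit_model <- function(spec, observed, config, nh = default_natural_history(),
                      lt = make_life_table(), oversample = 20,
                      seed = config$seed, control = fit_control()) {
  stopifnot(inherits(spec, "model_spec"), inherits(observed, "count_table"),
            inherits(config, "trial_config"))
  free <- spec$free
  need_u <- any(c("sens_II", "sens_III", "syserr_II", "syserr_III") %in% free) ||
    spec$fixed$sens_II < 1 || spec$fixed$sens_III < 1
  obj <- make_objective(observed, config, nh, lt, oversample, seed,
                        need_miss_u = need_u)
  n_evals <- 0L
  theta_at <- function(x) {
    th <- spec$fixed
    th[free] <- as.list(x)
    th
  }
  f <- function(x) {
    n_evals <<- n_evals + 1L
    obj$deviance_at(theta_at(x))
  }
  converged <- TRUE
  if (length(free) == 0L) {
    best_x <- numeric(0)
    best_dev <- f(numeric(0))
  } else if (length(free) == 1L) {
    b <- spec$bounds[[free]]
    op <- stats::optimize(f, interval = b, tol = 1e-4 * diff(b))
    best_x <- stats::setNames(op$minimum, free)
    best_dev <- op$objective
    # Brent can sit in the interior when the optimum is at a bound; the null
    # point (the parameter's fixed value) keeps the fit nested in the Simple
    # model by construction.
    for (cand in unique(c(b, spec$fixed[[free]]))) {
      fe <- f(cand)
      if (fe < best_dev) { best_dev <- fe; best_x[] <- cand }
    }
  } else {
    lo <- vapply(spec$bounds[free], `[`, numeric(1), 1)
    hi <- vapply(spec$bounds[free], `[`, numeric(1), 2)
    to_z <- function(x) stats::qlogis(pmin(pmax((x - lo) / (hi - lo), 1e-6), 1 - 1e-6))
    to_x <- function(z) lo + (hi - lo) * stats::plogis(z)
    fz <- function(z) f(to_x(z))
    start <- pmin(pmax(unlist(spec$fixed[free]), lo + 0.05 * (hi - lo)),
                  hi - 0.05 * (hi - lo))
    z0 <- to_z(start)
    best_dev <- Inf
    best_z <- z0
    # deterministic jitter schedule derived from the fit seed
    jit <- matrix(stats::qnorm(stats::runif(control$restarts * length(z0),
                                            min = 0.05, max = 0.95)),
                  nrow = control$restarts)
    for (r in seq_len(control$restarts)) {
      if (n_evals >= control$maxeval) { converged <- FALSE; break }
      zs <- if (r == 1) z0 else best_z + 0.5 * jit[r, ]
      op <- stats::optim(zs, fz, method = "Nelder-Mead",
                         control = list(maxit = min(150L, control$maxeval - n_evals)))
      if (op$value < best_dev - 1e-12) {
        improved <- best_dev - op$value
        best_dev <- op$value
        best_z <- op$par
        if (r > 1 && improved < control$tol) break
      } else if (r > 1) break
    }
    best_x <- stats::setNames(to_x(best_z), free)
    # The null point (all free parameters at their fixed values) is always a
    # candidate, so every extension model is nested in the Simple model by
    # construction even when Nelder-Mead stalls short of a boundary optimum.
    null_x <- stats::setNames(unlist(spec$fixed[free]), free)
    f0 <- f(null_x)
    if (f0 <= best_dev) { best_dev <- f0; best_x <- null_x }
  }
  theta <- theta_at(best_x)
  expected <- obj$expected_at(theta)
  structure(list(model = spec$name,
                 fitted_values = best_x,
                 theta = theta,
                 deviance = best_dev,
                 loglik = suppressWarnings(poisson_loglik(observed, expected)),
                 n_evals = n_evals, seed = seed, converged = converged,
                 expected = expected),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit of the %s model: deviance %.3f (%d evaluations, seed %d)\n",
              x$model, x$deviance, x$n_evals, x$seed))
  if (length(x$fitted_values))
    cat("Fitted:", paste(sprintf("%s = %.4g", names(x$fitted_values),
                                 x$fitted_values), collapse = ", "), "\n")
  else cat("No free parameters\n")
  if (!x$converged) cat("NOTE: evaluation budget exhausted; best-so-far reported\n")
  invisible(x)
}
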