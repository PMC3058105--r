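# Two-arm trial assembly: person-level simulation to diagnosis count tables.

#' Trial configuration
#'
#' Arm sizes, entry-age distribution, follow-up horizon, the between-arm risk
#' factor, and one screening policy per arm. Defaults describe a two-arm
#' radiographic screening trial of 9211 heavy smokers aged 45+: a 4-monthly
#' screening program over six years in the intervention arm and a pure
#' no-screening control arm, with diagnoses counted over 10 years from entry
#' (the screening phase plus interval and post-screening cancers).
#'
#' @param n_intervention,n_control arm sizes (persons).
#' @param entry_ages integer ages sampled uniformly at trial entry.
#' @param followup_years years from entry during which diagnoses are counted.
#' @param risk_factor_intervention multiplicative factor on the lifetime
#'   onset probability in the intervention arm (1 = equal risk).
#' @param policy_intervention,policy_control per-arm [screening_policy()];
#'   the control default is an annual schedule with attendance 0.
#' @param seed integer seed driving every stream of the simulation.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(n_intervention = 4618, n_control = 4593,
                         entry_ages = 45:69, followup_years = 10,
                         risk_factor_intervention = 1,
                         policy_intervention = screening_policy(),
                         policy_control = screening_policy(interval = 1,
                                                           duration = 6,
                                                           attendance_prob = 0),
                         seed = 1L) {
  if (n_intervention <= 0 || n_control <= 0) stop("arm sizes must be positive")
  if (followup_years < 0) stop("followup_years must be nonnegative")
  if (risk_factor_intervention <= 0) stop("risk_factor_intervention must be positive")
  stopifnot(inherits(policy_intervention, "screening_policy"),
            inherits(policy_control, "screening_policy"))
  structure(list(n_intervention = n_intervention, n_control = n_control,
                 entry_ages = as.integer(entry_ages),
                 followup_years = followup_years,
                 risk_factor_intervention = risk_factor_intervention,
                 policy_intervention = policy_intervention,
                 policy_control = policy_control, seed = as.integer(seed)),
            class = "trial_config")
}

arm_policy <- function(config, arm) {
  if (arm == "intervention") config$policy_intervention else config$policy_control
}

arm_risk <- function(config, arm) {
  if (arm == "intervention") config$risk_factor_intervention else 1
}

#' Simulate one person end-to-end
#'
#' Composes [sample_onset()], [sample_disease_path()],
#' [sample_other_cause_death()] and [apply_screening()] for a single person
#' in one trial arm. Diagnoses falling after other-cause death or after the
#' follow-up horizon are censored to `never_diagnosed`; a path that would
#' have surfaced clinically before trial entry contributes no diagnosis (the
#' person would not have enrolled cancer-free).
#'
#' @param config a [trial_config()].
#' @param arm `"intervention"` or `"control"`.
#' @param nh an `nh_params` object.
#' @param test a [test_characteristics()].
#' @param lt a [life_table()].
#' @param seed optional integer seed for a reproducible person.
#' @return A `detection_outcome` (see [apply_screening()]) with the sampled
#'   `path`, `entry_age` and `death_age` attached as attributes.
#' @export
simulate_person <- function(config, arm = c("intervention", "control"),
                            nh = default_natural_history(),
                            test = test_characteristics(),
                            lt = make_life_table(), seed = NULL) {
  stopifnot(inherits(config, "trial_config"))
  arm <- match.arg(arm)
  if (!is.null(seed)) set.seed(seed)
  policy <- arm_policy(config, arm)
  entry <- sample(config$entry_ages, 1)
  type <- sample(cell_types(), 1, prob = nh$mix)
  onset <- sample_onset(nh, type, risk_factor = arm_risk(config, arm))
  death <- sample_other_cause_death(lt, entry)
  never <- structure(list(mode = "never_diagnosed", dx_time = NA_real_,
                          dx_stage_group = NA_character_),
                     class = "detection_outcome")
  if (is.na(onset)) {
    out <- never
    path <- NULL
  } else {
    path <- sample_disease_path(onset, type, nh)
    if (!path$indolent && !is.na(path$clinical_dx_age) &&
        path$clinical_dx_age <= entry) {
      out <- never  # prevalent clinical case: not enrolled
    } else {
      horizon <- min(death, entry + config$followup_years)
      out <- apply_screening(path, horizon, entry, build_schedule(policy),
                             test, policy$attendance_prob)
    }
  }
  attr(out, "path") <- path
  attr(out, "entry_age") <- entry
  attr(out, "death_age") <- death
  out
}

#' Simulate a trial and return expected diagnosis counts
#'
#' Simulates `oversample` times the trial's persons per arm and rescales the
#' realized diagnosis frequencies to the trial arm sizes, yielding a table of
#' model-expected counts with reduced Monte-Carlo variance. The simulation is
#' fully determined by `seed`.
#'
#' @param config a [trial_config()].
#' @param nh an `nh_params` object.
#' @param test a [test_characteristics()].
#' @param lt a [life_table()].
#' @param oversample simulated persons per arm as a multiple of the arm size.
#' @param seed integer; defaults to `config$seed`.
#' @param stratification cell layout of the returned table.
#' @return A [count_table()] of expected counts, with attribute `totals`: a
#'   data.frame per arm of simulated persons, diagnosed and never-diagnosed
#'   counts (conservation: diagnosed + never = persons).
#' @export
simulate_trial <- function(config, nh = default_natural_history(),
                           test = test_characteristics(),
                           lt = make_life_table(), oversample = 20,
                           seed = config$seed,
                           stratification = "by_stage") {
  stopifnot(inherits(config, "trial_config"))
  stratification <- match.arg(stratification, ct_strata)
  seeds <- derive_seeds(seed, 2)
  cells <- NULL
  totals <- NULL
  for (j in seq_along(ct_arms)) {
    arm <- ct_arms[j]
    n_arm <- if (arm == "intervention") config$n_intervention else config$n_control
    n_sim <- max(1L, as.integer(round(n_arm * oversample)))
    policy <- arm_policy(config, arm)
    need_u <- test$sens_II < 1 || test$sens_III < 1
    prims <- draw_arm_primitives(n_sim, nh, lt, policy,
                                 entry_ages = config$entry_ages,
                                 need_miss_u = need_u, seed = seeds[j])
    theta <- theta_from_test(test, risk_factor = arm_risk(config, arm))
    res <- eval_arm_counts(prims, theta, nh, config$followup_years, arm,
                           compound = test$compound)
    arm_cells <- cells_from_c12(arm, res$c12 * (n_arm / n_sim))
    cells <- rbind(cells, arm_cells)
    totals <- rbind(totals, data.frame(arm = arm, n_sim = n_sim,
                                       n_diagnosed = res$n_diagnosed,
                                       n_never = res$n_never))
  }
  if (is.null(cells) || nrow(cells) == 0)
    cells <- data.frame(arm = "intervention", mode = "screen_detected",
                        stage_group = "II_minus", cell_type = "squamous",
                        count = 0)
  ct <- count_table(cells, "by_stage_and_celltype")
  ct <- aggregate_counts(ct, stratification)
  attr(ct, "totals") <- totals
  ct
}
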