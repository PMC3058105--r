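# Vectorized person-level simulation core.
#
# The trial simulator and the calibrator share a two-stage design built for
# common random numbers: `draw_arm_primitives()` draws every random quantity
# a person's history needs (entry age, cell type, onset uniform, Weibull
# onset age, the four stage dwell times, indolence and stage-III uniforms,
# other-cause death age, attendance and per-exam miss uniforms) once from a
# seed, and `eval_arm_counts()` turns those fixed primitives plus a candidate
# parameter vector theta into a diagnosis count table. Because theta only
# moves thresholds against fixed uniforms, the calibration objective is
# deterministic given the seed and varies smoothly enough for derivative-free
# search.

# Inverse-CDF walk through the life table: one uniform per person, death year
# found against the cumulative death probability from that person's integer
# entry age; uniform placement within the death year; survivors of the whole
# table die at the cap age. Distributionally identical to the sequential
# annual Bernoulli walk in sample_other_cause_death().
death_age_from_u <- function(entry_age, u, u_frac, lt) {
  ages <- lt$age
  q <- lt$annual_death_prob
  cap <- ages[length(ages)] + 1
  out <- numeric(length(entry_age))
  logS <- cumsum(log1p(-pmin(q, 1 - 1e-15)))
  exact1 <- q >= 1
  for (e in unique(entry_age)) {
    i0 <- match(e, ages)
    if (is.na(i0)) stop("entry age outside the life-table range")
    idx <- which(entry_age == e)
    # D[j] = P(dead by end of year j-1 after entry), j = 1..M
    seg <- logS[i0:length(ages)] - if (i0 > 1) logS[i0 - 1] else 0
    if (any(exact1[i0:length(ages)])) {
      j1 <- which(exact1[i0:length(ages)])[1]
      seg[j1:length(seg)] <- -Inf
    }
    D <- 1 - exp(seg)
    j <- findInterval(u[idx], D, left.open = TRUE)  # completed years survived
    dead <- j < length(D)
    out[idx] <- ifelse(dead, e + j + u_frac[idx], cap)
  }
  out
}

draw_arm_primitives <- function(n, nh, lt, policy, entry_ages = 45:64,
                                need_miss_u = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  on <- nh$onset
  pr <- nh$progression
  schedule <- build_schedule(policy)
  K <- length(schedule)
  screening_on <- policy$attendance_prob > 0 && K > 0
  entry <- sample(entry_ages, n, replace = TRUE)
  type <- sample.int(3L, n, replace = TRUE, prob = nh$mix)
  u_onset <- stats::runif(n)
  onset_age <- stats::qweibull(stats::runif(n), shape = on$weibull_shape[type],
                               scale = weibull_scale(on$weibull_shape,
                                                     on$weibull_mean)[type])
  dI <- stats::rexp(n, rate = 1 / pr$mean_dwell_I[type])
  dII <- stats::rexp(n, rate = 1 / pr$mean_dwell_II[type])
  dIII <- stats::rexp(n, rate = 1 / pr$mean_dwell_III[type])
  dIV <- stats::rexp(n, rate = 1 / pr$mean_dwell_IV[type])
  u_ind <- stats::runif(n)
  u_stage <- stats::runif(n)
  death_age <- death_age_from_u(entry, stats::runif(n), stats::runif(n), lt)
  attend <- NULL
  u_miss <- NULL
  if (screening_on) {
    attend <- matrix(stats::runif(n * K) < policy$attendance_prob, n, K)
    if (need_miss_u) u_miss <- matrix(stats::runif(n * K), n, K)
  }
  list(n = n, entry = entry, type = type, u_onset = u_onset,
       onset_age = onset_age, dI = dI, dII = dII, dIII = dIII, dIV = dIV,
       u_ind = u_ind, u_stage = u_stage, death_age = death_age,
       schedule = schedule, attend = attend, u_miss = u_miss,
       screening_on = screening_on)
}

# theta: list with sens_II, sens_III, syserr_II, syserr_III, risk_factor,
# and indolent_fraction (scalar overriding all cell types, or NULL to use the
# per-type values in nh$progression).
#
# Returns the diagnosed persons tabulated over the 12 within-arm cells
# (mode x stage group x cell type) as a bare count vector: the hot path of
# the calibration objective, so no data.frame is built here.
arm_cell_grid <- function() {
  expand.grid(cell_type = cell_types(), stage_group = ct_groups,
              mode = ct_modes, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)[, c("mode", "stage_group", "cell_type")]
}

eval_arm_counts <- function(prims, theta, nh, followup, arm_label,
                            compound = FALSE) {
  n <- prims$n
  type <- prims$type
  p_on <- theta$risk_factor * nh$onset$lifetime_onset_prob
  if (any(p_on > 1 + 1e-12))
    stop("risk_factor * lifetime_onset_prob exceeds 1 (invalid probability)")
  f_ind <- if (is.null(theta$indolent_fraction))
    nh$progression$indolent_fraction[type] else theta$indolent_fraction
  has <- prims$u_onset < p_on[type]
  ind <- has & prims$u_ind < f_ind
  t_II <- prims$onset_age + prims$dI
  t_III <- t_II + prims$dII
  at3 <- prims$u_stage < nh$progression$p_clinical_dx_at_III[type]
  dx <- t_III + prims$dIII + (!at3) * prims$dIV
  # Tumors surfacing clinically before trial entry: the person would not have
  # enrolled cancer-free; treated as contributing no diagnosis.
  prevalent_dx <- has & !ind & dx <= prims$entry
  case <- has & !prevalent_dx
  censor <- pmin(prims$death_age, prims$entry + followup)
  det_time <- rep(NA_real_, n)
  det_group <- rep(NA_integer_, n)
  if (prims$screening_on && any(case)) {
    i <- which(case)
    test <- test_characteristics(theta$sens_II, theta$sens_III,
                                 theta$syserr_II, theta$syserr_III,
                                 compound = compound)
    u <- prims$u_miss
    if (is.null(u)) {
      if (theta$sens_II < 1 || theta$sens_III < 1)
        stop("miss uniforms were not drawn but sensitivities are below 1")
      u <- matrix(0, length(i), length(prims$schedule))
      ui <- u
    } else ui <- u[i, , drop = FALSE]
    tIII_i <- t_III[i]
    dx_i <- dx[i]
    ind_i <- ind[i]
    tIII_i[ind_i] <- NA_real_
    dx_i[ind_i] <- NA_real_
    det <- detect_first_hit(
      t_II = t_II[i],
      t_III = tIII_i,
      dx_age = dx_i,
      indolent = ind_i,
      entry_age = prims$entry[i],
      death_age = censor[i],  # exams after death or follow-up cannot count
      schedule = prims$schedule,
      attend = prims$attend[i, , drop = FALSE],
      u = ui, test = test)
    det_time[i] <- det$det_time
    det_group[i] <- det$det_group
  }
  screen <- case & !is.na(det_time)
  clinical <- case & !ind & !screen & dx > prims$entry & dx < censor
  # cell index = (mode - 1) * 6 + (group - 1) * 3 + type, over the fixed
  # within-arm grid of arm_cell_grid()
  idx <- integer(0)
  if (any(screen))
    idx <- c(idx, (det_group[screen] - 1L) * 3L + type[screen])
  if (any(clinical))
    idx <- c(idx, 6L + 3L + type[clinical])  # clinically diagnosed, III_plus
  c12 <- tabulate(idx, nbins = 12L)
  n_dx <- sum(c12)
  list(c12 = c12, n_diagnosed = n_dx, n_never = n - n_dx)
}

# Expand a within-arm 12-cell count vector into count-table cells.
cells_from_c12 <- function(arm_label, c12) {
  g <- arm_cell_grid()
  data.frame(arm = arm_label, g, count = as.numeric(c12))
}

theta_defaults <- function() {
  list(sens_II = 1, sens_III = 1, syserr_II = 0, syserr_III = 0,
       indolent_fraction = NULL, risk_factor = 1)
}

theta_from_test <- function(test, risk_factor = 1, indolent_fraction = NULL) {
  list(sens_II = test$sens_II, sens_III = test$sens_III,
       syserr_II = test$syserr_II, syserr_III = test$syserr_III,
       indolent_fraction = indolent_fraction, risk_factor = risk_factor)
}

derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max, k)
}
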