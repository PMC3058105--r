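# Screening protocol, test characteristics, and per-path detection.

#' Screening policy
#'
#' An exam schedule on the trial clock: exams at times
#' `0, interval, 2*interval, ..., <= duration` (the exam at time 0 is the
#' prevalence screen). Each exam is attended independently with probability
#' `attendance_prob`. The defaults describe a 4-monthly program over six
#' years; an annual policy with `attendance_prob = 0` serves as a pure
#' no-screening control arm.
#'
#' @param interval years between exams (> 0); default 1/3 (4-monthly).
#' @param duration years of the screening program (>= 0); default 6.
#' @param attendance_prob per-exam attendance probability in `[0, 1]`.
#' @return An object of class `screening_policy`.
#' @export
screening_policy <- function(interval = 1 / 3, duration = 6, attendance_prob = 0.75) {
  if (interval <= 0) stop("interval must be positive")
  if (duration < 0) stop("duration must be nonnegative")
  if (attendance_prob < 0 || attendance_prob > 1)
    stop("attendance_prob must lie in [0, 1]")
  structure(list(interval = interval, duration = duration,
                 attendance_prob = attendance_prob),
            class = "screening_policy")
}

#' Screening test characteristics
#'
#' Sensitivity is specific to the stage group of the tumor at the exam:
#' `sens_II` applies while the tumor is in the screen-detectable preclinical
#' stage (stage group II-), `sens_III` while it is in clinical stage III/IV
#' but has not yet surfaced (stage group III+). The systematic negative error
#' is the increment in the probability of a false-negative exam given that a
#' previous exam of the same tumor in the same stage group was
#' false-negative: after the first miss, the per-exam miss probability
#' becomes `min(1, (1 - sens) + syserr)`. With `compound = TRUE` the
#' increment is applied once per previous miss (`min(1, (1 - sens) +
#' k * syserr)` after `k` misses); the default is a single fixed increment.
#'
#' @param sens_II,sens_III stage-group sensitivities in `[0, 1]`.
#' @param syserr_II,syserr_III systematic-error increments in `[0, 1]`.
#' @param compound logical; compound the increment per successive miss.
#' @return An object of class `test_characteristics`.
#' @export
test_characteristics <- function(sens_II = 1, sens_III = 1,
                                 syserr_II = 0, syserr_III = 0,
                                 compound = FALSE) {
  v <- c(sens_II = sens_II, sens_III = sens_III,
         syserr_II = syserr_II, syserr_III = syserr_III)
  if (any(v < 0 | v > 1)) stop("sensitivities and systematic errors must lie in [0, 1]")
  structure(list(sens_II = sens_II, sens_III = sens_III,
                 syserr_II = syserr_II, syserr_III = syserr_III,
                 compound = isTRUE(compound)),
            class = "test_characteristics")
}

#' Exam times implied by a screening policy
#'
#' @param policy a [screening_policy()].
#' @return strictly increasing numeric vector of exam times (trial clock),
#'   `floor(duration / interval) + 1` exams starting at 0.
#' @export
build_schedule <- function(policy) {
  stopifnot(inherits(policy, "screening_policy"))
  k <- floor(policy$duration / policy$interval + 1e-9)
  (0:k) * policy$interval
}

# Core detection walk. Everything is vectorized over persons; exams are
# walked in time order so the miss history (systematic negative error) is
# sequential. All ages in years on the age clock; exam times on the trial
# clock are offset by each person's entry age.
#
# Arguments (length-n vectors unless noted):
#   t_II      age entering screen-detectable preclinical stage (NA = never)
#   t_III     age entering clinical stage III (NA = never / indolent)
#   dx_age    age of clinical surfacing (NA = never / indolent)
#   indolent  logical
#   entry_age trial entry age
#   death_age other-cause death age
#   schedule  exam times, trial clock (length K)
#   attend    n x K logical attendance
#   u         n x K uniforms deciding hit/miss at attended detectable exams
#   test      test_characteristics
# Value: list(det_time (trial clock, NA if none), det_group (1 = II-, 2 = III+))
detect_first_hit <- function(t_II, t_III, dx_age, indolent, entry_age,
                             death_age, schedule, attend, u, test) {
  n <- length(t_II)
  K <- length(schedule)
  det_time <- rep(NA_real_, n)
  det_group <- rep(NA_integer_, n)
  if (K == 0L || n == 0L) return(list(det_time = det_time, det_group = det_group))
  miss_II <- integer(n)   # number of previous misses, per stage group
  miss_III <- integer(n)
  active <- !is.na(t_II)
  end_II <- t_III          # II- window is [t_II, t_III), or [t_II, Inf) when
  end_II[indolent] <- Inf  # the tumor is indolent
  for (k in seq_len(K)) {
    age_k <- entry_age + schedule[k]
    live <- active & attend[, k] & age_k < death_age
    if (!any(live)) next
    iII <- which(live & age_k >= t_II & age_k < end_II)
    iIII <- which(live & age_k >= t_III & age_k < dx_age)
    if (length(iII)) {
      m <- if (test$compound) miss_II[iII] else (miss_II[iII] > 0L)
      hit <- u[cbind(iII, k)] < pmax(0, test$sens_II - m * test$syserr_II)
      d <- iII[hit]
      det_time[d] <- schedule[k]
      det_group[d] <- 1L
      active[d] <- FALSE
      miss_II[iII[!hit]] <- miss_II[iII[!hit]] + 1L
    }
    if (length(iIII)) {
      m <- if (test$compound) miss_III[iIII] else (miss_III[iIII] > 0L)
      hit <- u[cbind(iIII, k)] < pmax(0, test$sens_III - m * test$syserr_III)
      d <- iIII[hit]
      det_time[d] <- schedule[k]
      det_group[d] <- 2L
      active[d] <- FALSE
      miss_III[iIII[!hit]] <- miss_III[iIII[!hit]] + 1L
    }
  }
  list(det_time = det_time, det_group = det_group)
}

#' Apply a screening schedule to one disease path
#'
#' Walks the exams in time order. At an attended exam the tumor is detectable
#' iff it is in the screen-detectable preclinical stage (stage group II-,
#' sensitivity `sens_II`) or in clinical stage III/IV before clinical
#' surfacing (stage group III+, sensitivity `sens_III`). The miss probability
#' at the first attended detectable exam is `1 - sens`; after a miss,
#' subsequent exams in the same stage group miss with probability
#' `min(1, (1 - sens) + syserr)`. The first positive exam before clinical
#' surfacing and before death yields screen detection; otherwise the path
#' surfaces clinically (if surfacing precedes death) or is never diagnosed.
#'
#' Uses the global R random-number generator.
#'
#' @param path a `disease_path` from [sample_disease_path()]; a path of `NULL`
#'   (no onset) yields `never_diagnosed`.
#' @param death_age other-cause death age (years).
#' @param trial_entry_age age at trial time 0.
#' @param schedule exam times on the trial clock, sorted (see
#'   [build_schedule()]).
#' @param test a [test_characteristics()].
#' @param attendance_prob per-exam attendance probability.
#' @return A `detection_outcome` list: `mode` (one of `"screen_detected"`,
#'   `"clinically_diagnosed"`, `"never_diagnosed"`), `dx_time` (trial clock,
#'   `NA` if never), `dx_stage_group` (`"II_minus"`, `"III_plus"`, or `NA`).
#' @export
apply_screening <- function(path, death_age, trial_entry_age, schedule, test,
                            attendance_prob = 1) {
  stopifnot(inherits(test, "test_characteristics"))
  if (is.unsorted(schedule, strictly = TRUE)) stop("schedule must be strictly increasing")
  if (attendance_prob < 0 || attendance_prob > 1)
    stop("attendance_prob must lie in [0, 1]")
  out_never <- structure(list(mode = "never_diagnosed", dx_time = NA_real_,
                              dx_stage_group = NA_character_),
                         class = "detection_outcome")
  if (is.null(path)) return(out_never)
  stopifnot(inherits(path, "disease_path"))
  K <- length(schedule)
  t_II <- path$stage_entry_ages[["PRE_II"]]
  t_III <- path$stage_entry_ages[["CLIN_III"]]
  dx_age <- path$clinical_dx_age
  det <- if (K > 0L) {
    attend <- matrix(stats::runif(K) < attendance_prob, nrow = 1)
    u <- matrix(stats::runif(K), nrow = 1)
    detect_first_hit(t_II, t_III, dx_age, path$indolent, trial_entry_age,
                     death_age, schedule, attend, u, test)
  } else list(det_time = NA_real_, det_group = NA_integer_)
  if (!is.na(det$det_time)) {
    return(structure(list(mode = "screen_detected", dx_time = det$det_time,
                          dx_stage_group = c("II_minus", "III_plus")[det$det_group]),
                     class = "detection_outcome"))
  }
  if (!path$indolent && !is.na(dx_age) && dx_age < death_age &&
      dx_age > trial_entry_age) {
    return(structure(list(mode = "clinically_diagnosed",
                          dx_time = dx_age - trial_entry_age,
                          dx_stage_group = "III_plus"),
                     class = "detection_outcome"))
  }
  out_never
}

#' @export
print.detection_outcome <- function(x, ...) {
  cat("Detection outcome:", x$mode)
  if (!is.na(x$dx_time))
    cat(sprintf(" at trial time %.3f (stage group %s)", x$dx_time, x$dx_stage_group))
  cat("\n")
  invisible(x)
}
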