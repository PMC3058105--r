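#' @keywords internal
"_PACKAGE"

# Canonical labels ------------------------------------------------------------

#' Cell-type and stage labels
#'
#' The model simulates three separate natural-history pathways, one per
#' histological group: squamous cell, adeno/large cell, and small cell lung
#' cancer. Disease progresses through four ordered stages: an undetectable
#' preclinical stage (`PRE_I`), a screen-detectable preclinical stage
#' (`PRE_II`), and two clinical stages (`CLIN_III`, `CLIN_IV`) in which the
#' tumor is both screen-detectable (until it surfaces) and able to surface
#' symptomatically.
#'
#' @return Character vector of the canonical labels, in order.
#' @export
cell_types <- function() c("squamous", "adeno_large", "small")

#' @rdname cell_types
#' @export
stage_ids <- function() c("PRE_I", "PRE_II", "CLIN_III", "CLIN_IV")

# Parameter containers --------------------------------------------------------

#' Natural-history parameter set
#'
#' Bundles, per cell type, the lifetime onset model (Weibull age at onset plus
#' a lifetime onset probability), the stage progression model (exponential
#' mean dwell times per stage, the probability of surfacing clinically in
#' stage III rather than progressing to stage IV, and the indolent fraction),
#' and the cell-type mixture.
#'
#' All values are inputs: the model's onset and dwell parameters are
#' registry-calibrated quantities in real applications and are therefore
#' configuration, not constants. `default_natural_history()` returns a
#' documented fixture set scaled so that a two-arm trial of roughly 4600
#' persons per arm yields on the order of 200 lung cancer diagnoses per arm
#' over a 10-year follow-up — a fixture, not an empirical claim.
#'
#' @param onset data.frame with columns `cell_type`, `weibull_shape`,
#'   `weibull_mean` (years), `lifetime_onset_prob`.
#' @param progression data.frame with columns `cell_type`, `mean_dwell_I`,
#'   `mean_dwell_II`, `mean_dwell_III`, `mean_dwell_IV` (years, exponential
#'   means), `p_clinical_dx_at_III`, `indolent_fraction`.
#' @param mix named numeric of cell-type mixture proportions (sums to 1).
#' @return An object of class `nh_params`.
#' @export
natural_history_params <- function(onset, progression, mix) {
  stopifnot(is.data.frame(onset), is.data.frame(progression))
  need_on <- c("cell_type", "weibull_shape", "weibull_mean", "lifetime_onset_prob")
  need_pr <- c("cell_type", "mean_dwell_I", "mean_dwell_II", "mean_dwell_III",
               "mean_dwell_IV", "p_clinical_dx_at_III", "indolent_fraction")
  if (!all(need_on %in% names(onset)))
    stop("onset table must have columns: ", paste(need_on, collapse = ", "))
  if (!all(need_pr %in% names(progression)))
    stop("progression table must have columns: ", paste(need_pr, collapse = ", "))
  if (!setequal(onset$cell_type, cell_types()) ||
      !setequal(progression$cell_type, cell_types()))
    stop("onset and progression tables must cover exactly the three cell types")
  onset <- onset[match(cell_types(), onset$cell_type), , drop = FALSE]
  progression <- progression[match(cell_types(), progression$cell_type), , drop = FALSE]
  rownames(onset) <- rownames(progression) <- NULL
  if (any(onset$weibull_shape <= 0) || any(onset$weibull_mean <= 0))
    stop("Weibull shape and mean must be positive")
  if (any(onset$lifetime_onset_prob < 0 | onset$lifetime_onset_prob > 1))
    stop("lifetime_onset_prob must lie in [0, 1]")
  dwell <- as.matrix(progression[, c("mean_dwell_I", "mean_dwell_II",
                                     "mean_dwell_III", "mean_dwell_IV")])
  if (any(dwell <= 0)) stop("mean dwell times must be positive")
  if (any(progression$p_clinical_dx_at_III < 0 | progression$p_clinical_dx_at_III > 1))
    stop("p_clinical_dx_at_III must lie in [0, 1]")
  if (any(progression$indolent_fraction < 0 | progression$indolent_fraction > 1))
    stop("indolent_fraction must lie in [0, 1]")
  if (is.null(names(mix)) || !setequal(names(mix), cell_types()))
    stop("mix must be named with the three cell types")
  mix <- mix[cell_types()]
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    stop("mix proportions must be nonnegative and sum to 1")
  structure(list(onset = onset, progression = progression, mix = mix),
            class = "nh_params")
}

#' @rdname natural_history_params
#' @export
default_natural_history <- function() {
  onset <- data.frame(
    cell_type           = cell_types(),
    weibull_shape       = c(5.0, 4.5, 5.0),
    weibull_mean        = c(62, 61, 60),
    lifetime_onset_prob = c(0.23, 0.24, 0.14)
  )
  # Small cell progresses fastest; squamous has the longest screen-detectable
  # window. Values are fixtures at a plausible chest-radiograph scale for
  # persistent heavy smokers (total detectable sojourn on the order of a
  # year; lifetime onset risk around 20%).
  progression <- data.frame(
    cell_type            = cell_types(),
    mean_dwell_I         = c(1.2, 1.2, 0.7),
    mean_dwell_II        = c(0.6, 0.5, 0.3),
    mean_dwell_III       = c(0.4, 0.4, 0.25),
    mean_dwell_IV        = c(0.4, 0.4, 0.25),
    p_clinical_dx_at_III = c(0.40, 0.40, 0.25),
    indolent_fraction    = c(0, 0, 0)
  )
  mix <- c(squamous = 0.35, adeno_large = 0.45, small = 0.20)
  natural_history_params(onset, progression, mix)
}

#' @export
print.nh_params <- function(x, ...) {
  cat("Natural-history parameters (3 cell-type pathways)\n")
  cat("Mixture:", paste(sprintf("%s=%.2f", names(x$mix), x$mix), collapse = ", "), "\n")
  cat("Onset (Weibull):\n"); print(x$onset, row.names = FALSE)
  cat("Progression (exponential dwell, years):\n"); print(x$progression, row.names = FALSE)
  invisible(x)
}

# Life table ------------------------------------------------------------------

#' Other-cause mortality life table
#'
#' A life table gives the annual probability of death from causes other than
#' lung cancer for each integer age. The probability on row `age` applies to
#' the year of age `[age, age + 1)`. A person surviving every tabulated year
#' dies at the cap age `max(ages) + 1` (administrative censoring of the
#' lifespan).
#'
#' @param age integer-valued, strictly increasing, contiguous ages.
#' @param annual_death_prob probabilities in `[0, 1]`, one per age.
#' @return data.frame of class `life_table` with columns `age`,
#'   `annual_death_prob`.
#' @export
life_table <- function(age, annual_death_prob) {
  if (length(age) != length(annual_death_prob) || length(age) < 1)
    stop("age and annual_death_prob must have equal positive length")
  if (any(diff(age) != 1)) stop("ages must be contiguous integers")
  if (any(annual_death_prob < 0 | annual_death_prob > 1))
    stop("annual_death_prob must lie in [0, 1]")
  structure(data.frame(age = as.integer(age),
                       annual_death_prob = as.numeric(annual_death_prob)),
            class = c("life_table", "data.frame"))
}

#' Construct a life table from a named hazard family
#'
#' `kind = "constant"` uses a flat annual death probability `q`;
#' `kind = "gompertz"` uses the Gompertz hazard `h(age) = a * exp(b * age)`
#' converted to an annual probability `1 - exp(-h)`. The default Gompertz
#' parameters approximate the other-cause mortality of older male heavy
#' smokers (median death in the late seventies from age 55).
#'
#' @param kind `"constant"` or `"gompertz"`.
#' @param q constant annual death probability (kind = "constant").
#' @param a,b Gompertz level and log-slope (kind = "gompertz").
#' @param ages integer age grid (default 40..99, cap age 100).
#' @return A [life_table()].
#' @export
make_life_table <- function(kind = c("gompertz", "constant"),
                            q = 0.02, a = 1e-4, b = 0.085, ages = 40:99) {
  kind <- match.arg(kind)
  p <- switch(kind,
    constant = {
      if (q < 0 || q > 1) stop("q must lie in [0, 1]")
      rep(q, length(ages))
    },
    gompertz = {
      if (a <= 0 || b <= 0) stop("gompertz parameters must be positive")
      1 - exp(-a * exp(b * ages))
    }
  )
  life_table(ages, p)
}

#' Read and write life tables as CSV
#'
#' Plain CSV with columns `age,annual_death_prob`.
#'
#' @param path file path.
#' @param lt a [life_table()].
#' @return `read_life_table` returns a [life_table()]; `write_life_table`
#'   returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path)
  life_table(d$age, d$annual_death_prob)
}

#' @rdname read_life_table
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Sampling operations ---------------------------------------------------------

weibull_scale <- function(shape, mean) mean / gamma(1 + 1 / shape)

#' Sample age at preclinical onset
#'
#' With probability `risk_factor * lifetime_onset_prob` (for the given cell
#' type) the person develops preclinical lung cancer at an age drawn from a
#' Weibull distribution parameterized by shape and mean; otherwise the person
#' never develops lung cancer and `NA` is returned. `risk_factor` is a
#' multiplicative factor on the lifetime onset probability, used to give one
#' trial arm a higher a-priori risk than the other.
#'
#' Uses the global R random-number generator; seed with [set.seed()].
#'
#' @param params an `nh_params` object (only the onset table is used).
#' @param cell_type one of [cell_types()].
#' @param risk_factor positive scalar; `risk_factor * lifetime_onset_prob`
#'   must not exceed 1.
#' @param n number of independent draws.
#' @return numeric vector of length `n`: onset ages, `NA` where no onset.
#' @export
sample_onset <- function(params, cell_type, risk_factor = 1, n = 1) {
  stopifnot(inherits(params, "nh_params"))
  cell_type <- match.arg(cell_type, cell_types())
  row <- params$onset[params$onset$cell_type == cell_type, ]
  if (risk_factor <= 0) stop("risk_factor must be positive")
  p <- risk_factor * row$lifetime_onset_prob
  if (p > 1 + 1e-12)
    stop("risk_factor * lifetime_onset_prob exceeds 1 (invalid probability)")
  has <- stats::runif(n) < p
  age <- rep(NA_real_, n)
  if (any(has))
    age[has] <- stats::rweibull(sum(has), shape = row$weibull_shape,
                                scale = weibull_scale(row$weibull_shape, row$weibull_mean))
  age
}

#' Sample a disease path from onset to clinical surfacing
#'
#' Starting from preclinical stage I at `onset_age`, the tumor dwells an
#' exponentially distributed time in each stage. With probability
#' `indolent_fraction` the tumor is indolent: it enters the screen-detectable
#' preclinical stage II and never leaves it (screen-detectable for the rest of
#' life, never symptomatic). Otherwise it enters clinical stage III, where it
#' surfaces clinically at the end of its stage III dwell with probability
#' `p_clinical_dx_at_III`, or progresses to stage IV and surfaces at the end
#' of its stage IV dwell.
#'
#' @param onset_age nonnegative age at onset (years).
#' @param cell_type one of [cell_types()].
#' @param params an `nh_params` object (only the progression table is used).
#' @return A `disease_path` list: `cell_type`, `onset_age`,
#'   `stage_entry_ages` (named numeric, `NA` where never entered),
#'   `clinical_dx_age` (`NA` if never), `clinical_dx_stage` (`NA` if never),
#'   `indolent`.
#' @export
sample_disease_path <- function(onset_age, cell_type, params) {
  stopifnot(inherits(params, "nh_params"))
  if (!is.finite(onset_age) || onset_age < 0) stop("onset_age must be >= 0")
  cell_type <- match.arg(cell_type, cell_types())
  pr <- params$progression[params$progression$cell_type == cell_type, ]
  t_I <- onset_age
  t_II <- t_I + stats::rexp(1, rate = 1 / pr$mean_dwell_I)
  indolent <- stats::runif(1) < pr$indolent_fraction
  entries <- c(PRE_I = t_I, PRE_II = t_II, CLIN_III = NA_real_, CLIN_IV = NA_real_)
  dx_age <- NA_real_
  dx_stage <- NA_character_
  if (!indolent) {
    t_III <- t_II + stats::rexp(1, rate = 1 / pr$mean_dwell_II)
    entries["CLIN_III"] <- t_III
    end_III <- t_III + stats::rexp(1, rate = 1 / pr$mean_dwell_III)
    if (stats::runif(1) < pr$p_clinical_dx_at_III) {
      dx_age <- end_III
      dx_stage <- "CLIN_III"
    } else {
      t_IV <- end_III
      entries["CLIN_IV"] <- t_IV
      dx_age <- t_IV + stats::rexp(1, rate = 1 / pr$mean_dwell_IV)
      dx_stage <- "CLIN_IV"
    }
  }
  structure(list(cell_type = cell_type, onset_age = onset_age,
                 stage_entry_ages = entries, clinical_dx_age = dx_age,
                 clinical_dx_stage = dx_stage, indolent = indolent),
            class = "disease_path")
}

#' @export
print.disease_path <- function(x, ...) {
  cat(sprintf("Disease path (%s%s)\n", x$cell_type,
              if (x$indolent) ", indolent" else ""))
  cat("Stage entry ages:\n")
  print(round(x$stage_entry_ages, 3))
  if (is.na(x$clinical_dx_age)) cat("Never surfaces clinically\n")
  else cat(sprintf("Clinical diagnosis at age %.3f in %s\n",
                   x$clinical_dx_age, x$clinical_dx_stage))
  invisible(x)
}

#' Sample age at death from other causes
#'
#' Walks the life table from `current_age` with one Bernoulli trial per year
#' of age (probability taken from the row of the attained integer age); on
#' the first death the death age is placed uniformly within that year. A
#' person surviving every tabulated year dies at the cap age
#' `max(age) + 1`.
#'
#' @param lt a [life_table()].
#' @param current_age age at which the walk starts; must be covered by `lt`.
#' @return death age (years), `>= current_age`.
#' @export
sample_other_cause_death <- function(lt, current_age) {
  stopifnot(inherits(lt, "life_table"))
  a0 <- floor(current_age)
  if (a0 < lt$age[1] || a0 > lt$age[nrow(lt)])
    stop("current_age outside the life-table range")
  cap <- lt$age[nrow(lt)] + 1
  for (a in a0:lt$age[nrow(lt)]) {
    q <- lt$annual_death_prob[lt$age == a]
    if (stats::runif(1) < q) {
      lo <- max(current_age, a)
      return(lo + stats::runif(1) * (a + 1 - lo))
    }
  }
  cap
}
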