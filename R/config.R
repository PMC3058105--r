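# YAML/JSON configuration round-trip. The on-disk schema mirrors the
# constructors; validation is structural — every block is rebuilt through its
# constructor, so an invalid file fails with the constructor's message.

#' Read and write a full model configuration
#'
#' A configuration file (YAML, or JSON — both parse with the same reader)
#' holds four blocks: `trial` (arm sizes, entry ages, follow-up, risk factor,
#' per-arm policies, seed), `test` (sensitivities and systematic errors),
#' `natural_history` (onset and progression tables plus the cell-type mix)
#' and `life_table` (a hazard family understood by [make_life_table()]).
#' Every block is validated by rebuilding it through the package
#' constructors. An example file ships in
#' `system.file("extdata", "mlp-config.yaml", package = "lungscreensim")`.
#'
#' @param path file path.
#' @param config a [trial_config()].
#' @param nh an `nh_params` object.
#' @param test a [test_characteristics()].
#' @param lt_spec list describing the life table, e.g.
#'   `list(kind = "gompertz", a = 1e-4, b = 0.085)`.
#' @return `read_config` returns a list with elements `config`, `nh`, `test`,
#'   `lt`; `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (block in c("trial", "test", "natural_history", "life_table"))
    if (is.null(raw[[block]])) stop("configuration is missing the '", block, "' block")
  tr <- raw$trial
  pol <- function(p) screening_policy(interval = p$interval, duration = p$duration,
                                      attendance_prob = p$attendance_prob)
  config <- trial_config(
    n_intervention = tr$n_intervention, n_control = tr$n_control,
    entry_ages = tr$entry_age_min:tr$entry_age_max,
    followup_years = tr$followup_years,
    risk_factor_intervention = tr$risk_factor_intervention,
    policy_intervention = pol(tr$policy_intervention),
    policy_control = pol(tr$policy_control),
    seed = tr$seed)
  te <- raw$test
  test <- test_characteristics(sens_II = te$sens_II, sens_III = te$sens_III,
                               syserr_II = te$syserr_II, syserr_III = te$syserr_III,
                               compound = isTRUE(te$compound))
  nhr <- raw$natural_history
  tab <- function(x) as.data.frame(lapply(as.data.frame(do.call(rbind, x)), unlist),
                                   stringsAsFactors = FALSE)
  nh <- natural_history_params(onset = tab(nhr$onset),
                               progression = tab(nhr$progression),
                               mix = unlist(nhr$mix))
  ltr <- raw$life_table
  lt <- do.call(make_life_table, ltr)
  list(config = config, nh = nh, test = test, lt = lt)
}

#' @rdname read_config
#' @export
write_config <- function(config, nh, test,
                         lt_spec = list(kind = "gompertz", a = 1e-4, b = 0.085),
                         path) {
  stopifnot(inherits(config, "trial_config"), inherits(nh, "nh_params"),
            inherits(test, "test_characteristics"))
  pol <- function(p) list(interval = p$interval, duration = p$duration,
                          attendance_prob = p$attendance_prob)
  row_list <- function(d) lapply(seq_len(nrow(d)), function(i) as.list(d[i, ]))
  out <- list(
    trial = list(
      n_intervention = config$n_intervention, n_control = config$n_control,
      entry_age_min = min(config$entry_ages), entry_age_max = max(config$entry_ages),
      followup_years = config$followup_years,
      risk_factor_intervention = config$risk_factor_intervention,
      policy_intervention = pol(config$policy_intervention),
      policy_control = pol(config$policy_control),
      seed = config$seed),
    test = list(sens_II = test$sens_II, sens_III = test$sens_III,
                syserr_II = test$syserr_II, syserr_III = test$syserr_III,
                compound = test$compound),
    natural_history = list(onset = row_list(nh$onset),
                           progression = row_list(nh$progression),
                           mix = as.list(nh$mix)),
    life_table = lt_spec)
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the seed, key problem sizes and package version of a simulation or
#' calibration run next to its outputs, so a result can be tied back to the
#' exact conditions that produced it.
#'
#' @param path output path for the JSON manifest.
#' @param seed integer seed of the run.
#' @param ... further scalar fields to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, ...) {
  jsonlite::write_json(
    c(list(package = "lungscreensim",
           version = as.character(utils::packageVersion("lungscreensim")),
           seed = seed, timestamp = format(Sys.time(), tz = "UTC")),
      list(...)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
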