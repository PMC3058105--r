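# Independent oracles and small builders shared across tests.

# Build a disease path directly from its timeline (bypasses the sampler so
# screening semantics can be tested against known windows).
make_path <- function(t_II, t_III = NA_real_, dx_age = NA_real_,
                      indolent = FALSE, onset_age = t_II - 1,
                      cell_type = "squamous") {
  dx_stage <- if (is.na(dx_age)) NA_character_ else "CLIN_III"
  structure(list(cell_type = cell_type, onset_age = onset_age,
                 stage_entry_ages = c(PRE_I = onset_age, PRE_II = t_II,
                                      CLIN_III = t_III, CLIN_IV = NA_real_),
                 clinical_dx_age = dx_age, clinical_dx_stage = dx_stage,
                 indolent = indolent),
            class = "disease_path")
}

# Brute-force probability of screen detection for a sequence of attended,
# detectable exams. `groups` gives the stage group at each exam ("II" or
# "III"). Detection at exam j requires misses at exams 1..j-1 (each with the
# miss probability implied by the group and the same-group miss history) and
# a hit at j; the total is the sum over j of these mutually exclusive
# hit/miss sequences. Written independently of the package's detection walk.
enum_detect_prob <- function(groups, sens_II, sens_III,
                             syserr_II = 0, syserr_III = 0) {
  k <- length(groups)
  total <- 0
  for (j in seq_len(k)) {
    p_seq <- 1
    mII <- 0L
    mIII <- 0L
    for (i in seq_len(j)) {
      if (groups[i] == "II") {
        hit <- if (mII > 0L) max(0, sens_II - syserr_II) else sens_II
      } else {
        hit <- if (mIII > 0L) max(0, sens_III - syserr_III) else sens_III
      }
      if (i < j) {
        p_seq <- p_seq * (1 - hit)
        if (groups[i] == "II") mII <- mII + 1L else mIII <- mIII + 1L
      } else {
        p_seq <- p_seq * hit
      }
    }
    total <- total + p_seq
  }
  total
}

# Direct evaluation of the Poisson deviance formula, independent of
# count_deviance's implementation.
deviance_ref <- function(O, E) {
  term <- ifelse(O > 0, O * log(O / E) - (O - E), E)
  2 * sum(term)
}

# Small helpers for arm-level totals of a by-stage count table.
arm_total <- function(ct, arm) sum(ct$count[ct$arm == arm])
cell_count <- function(ct, arm, mode, group) {
  ct$count[ct$arm == arm & ct$mode == mode & ct$stage_group == group]
}

# A reduced-size trial configuration used where full trial scale is not the
# point of the test.
small_config <- function(...) {
  trial_config(n_intervention = 1500, n_control = 1500, seed = 1L, ...)
}
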