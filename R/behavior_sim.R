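#' Specification of a synthetic biconditional-discrimination cohort
#'
#' Describes cohorts of auditory biconditional sessions: each session has
#' `trials_per_session` trials (half tone, half click), per-trial
#' correct- and incorrect-lever press counts are Poisson with
#' genotype-, cue- and session-dependent means, and inter-trial
#' intervals are drawn from a 45-180 s distribution with mean 120 s.
#'
#' Press-rate means ramp linearly from a common chance level
#' (`start_rate` on both levers) in session 1 to the genotype- and
#' cue-specific `final_rates` in the last session, emulating acquisition.
#' The default final rates encode the qualitative phenotypes the task is
#' designed to separate: wildtype animals respond correctly to both
#' cues, heterozygous animals are "one-cue learners" (correct to the
#' click, at chance to the tone).
#'
#' @param n_wt,n_het animals per genotype (default 9 and 11).
#' @param n_sessions training sessions (default 8).
#' @param trials_per_session trials per session (default 24; must be
#'   even so each cue type gets half).
#' @param start_rate common session-1 Poisson mean for both levers.
#' @param final_rates named list `WT`/`HET`, each a named list
#'   `tone`/`click` of `c(correct =, incorrect =)` final-session means.
#' @param magazine_rate Poisson mean of magazine entries per trial.
#' @param iti_range,iti_mean ITI support (s) and target mean; ITIs are
#'   drawn as `min + (max - min) * Beta(a, b)` with `a/(a+b)` matching
#'   the target mean.
#' @param seed integer seed.
#' @return An object of class `behavior_cohort_spec`.
#' @export
behavior_cohort_spec <- function(n_wt = 9, n_het = 11, n_sessions = 8,
                                 trials_per_session = 24,
                                 start_rate = 2,
                                 final_rates = list(
                                   WT = list(tone = c(correct = 6, incorrect = 1),
                                             click = c(correct = 6, incorrect = 1)),
                                   HET = list(tone = c(correct = 3, incorrect = 3),
                                              click = c(correct = 6, incorrect = 1))),
                                 magazine_rate = 5,
                                 iti_range = c(45, 180), iti_mean = 120,
                                 seed = 1) {
  if (trials_per_session %% 2 != 0)
    stop("trials_per_session must be even (equal numbers of each cue)")
  rates <- unlist(final_rates)
  if (any(rates < 0) || start_rate < 0 || magazine_rate < 0)
    stop("press rates must be non-negative")
  if (iti_mean < iti_range[1] || iti_mean > iti_range[2])
    stop("iti_mean must lie inside iti_range")
  structure(list(n_wt = n_wt, n_het = n_het, n_sessions = n_sessions,
                 trials_per_session = trials_per_session,
                 start_rate = start_rate, final_rates = final_rates,
                 magazine_rate = magazine_rate, iti_range = iti_range,
                 iti_mean = iti_mean, seed = seed),
            class = "behavior_cohort_spec")
}

#' Simulate a biconditional-discrimination cohort
#'
#' Generates the tidy trial-level session table for every animal in the
#' cohort described by a [behavior_cohort_spec()].  Counterbalancing of
#' cue-lever assignments is alternated within genotype and recorded per
#' animal.  Deterministic for a fixed spec (the seed lives in the spec).
#'
#' @param spec a [behavior_cohort_spec()].
#' @return A data.frame with one row per trial and columns `animal`,
#'   `genotype`, `session`, `trial`, `cue`, `correct_presses`,
#'   `incorrect_presses`, `magazine_entries`, `iti`,
#'   `counterbalance_group`.
#' @export
simulate_behavior_cohort <- function(spec = behavior_cohort_spec()) {
  stopifnot(inherits(spec, "behavior_cohort_spec"))
  set.seed(spec$seed)
  half <- spec$trials_per_session / 2
  # Beta draw on the ITI range with mean matched to the target mean
  frac <- (spec$iti_mean - spec$iti_range[1]) / diff(spec$iti_range)
  beta_a <- 5; beta_b <- beta_a * (1 - frac) / frac

  animals <- data.frame(
    animal = c(sprintf("WT%02d", seq_len(spec$n_wt)),
               sprintf("HET%02d", seq_len(spec$n_het))),
    genotype = c(rep("WT", spec$n_wt), rep("HET", spec$n_het)),
    stringsAsFactors = FALSE)
  animals$counterbalance_group <-
    unlist(lapply(c(spec$n_wt, spec$n_het),
                  function(k) rep(c("A", "B"), length.out = k)))

  rows <- vector("list", nrow(animals) * spec$n_sessions)
  k <- 0L
  for (a in seq_len(nrow(animals))) {
    g <- animals$genotype[a]
    for (s in seq_len(spec$n_sessions)) {
      w <- if (spec$n_sessions > 1) (s - 1) / (spec$n_sessions - 1) else 1
      cues <- sample(rep(c("tone", "click"), half))
      rate <- function(cue, lever) {
        fin <- spec$final_rates[[g]][[cue]][[lever]]
        (1 - w) * spec$start_rate + w * fin
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        animal = animals$animal[a], genotype = g, session = s,
        trial = seq_len(spec$trials_per_session), cue = cues,
        correct_presses = rpois(spec$trials_per_session,
                                vapply(cues, rate, 0, lever = "correct")),
        incorrect_presses = rpois(spec$trials_per_session,
                                  vapply(cues, rate, 0, lever = "incorrect")),
        magazine_entries = rpois(spec$trials_per_session, spec$magazine_rate),
        iti = round(spec$iti_range[1] +
                      diff(spec$iti_range) *
                        rbeta(spec$trials_per_session, beta_a, beta_b), 1),
        counterbalance_group = animals$counterbalance_group[a],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a session table as CSV
#' @param sessions session-table data.frame.
#' @param path CSV file path.
#' @return `path` (write) or the session table (read).
#' @export
write_session_csv <- function(sessions, path) {
  write.csv(sessions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
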