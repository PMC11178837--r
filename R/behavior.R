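check_session_table <- function(sessions) {
  need <- c("animal", "genotype", "session", "trial", "cue",
            "correct_presses", "incorrect_presses")
  miss <- setdiff(need, names(sessions))
  if (length(miss)) stop("session table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(sessions$correct_presses < 0) || any(sessions$incorrect_presses < 0))
    stop("press counts must be non-negative")
  invisible(sessions)
}

#' Biconditional discrimination ratio
#'
#' The discrimination-ratio statistic for one animal-session:
#' with `S+` the per-trial correct-lever press counts and `S-` the
#' per-trial incorrect-lever press counts pooled across both cues,
#' \deqn{ratio = P(S^+ > \mathrm{all}\ S^-) \times P(S^- < \mathrm{all}\ S^+)}
#' i.e. the proportion of S+ trials whose count strictly exceeds every
#' S- trial count, times the proportion of S- trials strictly below
#' every S+ trial count.  The score lies in \[0, 1\]: 1 is perfect
#' correct responding to both cues, 0 is no discrimination.  Strict
#' inequalities mean ties count against discrimination, which makes the
#' "no discrimination" endpoint exact.
#'
#' A per-cue variant (`per_cue = TRUE`) computes the ratio within each
#' cue and averages, for sensitivity analyses.
#'
#' @param trials data.frame of trial rows for a single animal-session
#'   with columns `cue`, `correct_presses`, `incorrect_presses`.
#' @param per_cue compute per cue then average (default `FALSE`: pooled
#'   across cues, the canonical reading).
#' @return A list with `ratio`, the two factors (`prop_splus_above`,
#'   `prop_sminus_below`), and per-cue press totals.
#' @export
discrimination_ratio <- function(trials, per_cue = FALSE) {
  if (!all(c("cue", "correct_presses", "incorrect_presses") %in% names(trials)))
    stop("trials need columns cue, correct_presses, incorrect_presses")
  cues <- unique(trials$cue)
  if (length(cues) < 2)
    stop("discrimination ratio needs trials of both cue types")
  ratio_of <- function(splus, sminus) {
    f1 <- mean(splus > max(sminus))
    f2 <- mean(sminus < min(splus))
    c(f1 = f1, f2 = f2, ratio = f1 * f2)
  }
  if (per_cue) {
    per <- vapply(cues, function(cc) {
      sel <- trials$cue == cc
      ratio_of(trials$correct_presses[sel], trials$incorrect_presses[sel])
    }, numeric(3))
    f <- rowMeans(per)
  } else {
    f <- ratio_of(trials$correct_presses, trials$incorrect_presses)
  }
  totals <- stats::aggregate(
    cbind(correct_presses, incorrect_presses) ~ cue, data = trials, FUN = sum)
  list(ratio = unname(f["ratio"]),
       prop_splus_above = unname(f["f1"]),
       prop_sminus_below = unname(f["f2"]),
       totals = totals)
}

#' Discrimination ratios for every animal-session in a table
#'
#' @param sessions tidy session table (see
#'   [simulate_behavior_cohort()]).
#' @param session restrict to one session index (default: all).
#' @param per_cue passed to [discrimination_ratio()].
#' @return data.frame with columns `animal`, `genotype`, `session`,
#'   `ratio`.
#' @export
session_discrimination <- function(sessions, session = NULL,
                                   per_cue = FALSE) {
  check_session_table(sessions)
  if (!is.null(session)) sessions <- sessions[sessions$session %in% session, ]
  idx <- split(seq_len(nrow(sessions)),
               list(sessions$animal, sessions$session), drop = TRUE)
  out <- lapply(idx, function(i) {
    d <- sessions[i, ]
    data.frame(animal = d$animal[1], genotype = d$genotype[1],
               session = d$session[1],
               ratio = discrimination_ratio(d, per_cue = per_cue)$ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$animal, out$session), ]
  rownames(out) <- NULL
  out
}

#' Acquisition curves: per-genotype per-session press counts
#'
#' Per animal and session, correct- and incorrect-lever presses are
#' summed over all trials (both cues); the output gives the
#' genotype-level mean and SEM per session and lever class, tidy for any
#' external ANOVA package.  With a single animal in a genotype the SEM
#' is `NA` and a warning is raised.
#'
#' @param sessions tidy session table.
#' @return data.frame with columns `genotype`, `session`, `lever`,
#'   `mean_presses`, `sem`, `n_animals`.
#' @export
acquisition_curves <- function(sessions) {
  check_session_table(sessions)
  per_animal <- stats::aggregate(
    cbind(correct = correct_presses, incorrect = incorrect_presses) ~
      animal + genotype + session, data = sessions, FUN = sum)
  # report animals missing sessions rather than imputing
  tab <- table(per_animal$animal)
  if (length(unique(tab)) > 1)
    warning("animals with missing sessions: ",
            paste(names(tab)[tab < max(tab)], collapse = ", "))
  long <- rbind(
    data.frame(per_animal[c("animal", "genotype", "session")],
               lever = "correct", presses = per_animal$correct),
    data.frame(per_animal[c("animal", "genotype", "session")],
               lever = "incorrect", presses = per_animal$incorrect))
  agg <- stats::aggregate(presses ~ genotype + session + lever, data = long,
                          FUN = function(x) c(mean = mean(x),
                                              sem = sd(x) / sqrt(length(x)),
                                              n = length(x)))
  out <- data.frame(agg[c("genotype", "session", "lever")],
                    mean_presses = agg$presses[, "mean"],
                    sem = agg$presses[, "sem"],
                    n_animals = agg$presses[, "n"])
  if (any(out$n_animals == 1))
    warning("single-animal genotype: SEM undefined")
  out <- out[order(out$genotype, out$session, out$lever), ]
  rownames(out) <- NULL
  out
}

#' Per-cue lever-press breakdown for one session
#'
#' Mean and SEM of per-trial correct and incorrect presses split by cue
#' and genotype for the requested session (typically the final one),
#' tidy for external ANOVA.
#'
#' @param sessions tidy session table.
#' @param session session index.
#' @return data.frame with columns `genotype`, `cue`, `lever`,
#'   `mean_presses`, `sem`, `n_animals`.
#' @export
per_cue_breakdown <- function(sessions, session) {
  check_session_table(sessions)
  d <- sessions[sessions$session == session, ]
  if (!nrow(d)) stop("no trials for session ", session)
  per_animal <- stats::aggregate(
    cbind(correct = correct_presses, incorrect = incorrect_presses) ~
      animal + genotype + cue, data = d, FUN = mean)
  long <- rbind(
    data.frame(per_animal[c("animal", "genotype", "cue")],
               lever = "correct", presses = per_animal$correct),
    data.frame(per_animal[c("animal", "genotype", "cue")],
               lever = "incorrect", presses = per_animal$incorrect))
  agg <- stats::aggregate(presses ~ genotype + cue + lever, data = long,
                          FUN = function(x) c(mean = mean(x),
                                              sem = sd(x) / sqrt(length(x)),
                                              n = length(x)))
  out <- data.frame(agg[c("genotype", "cue", "lever")],
                    mean_presses = agg$presses[, "mean"],
                    sem = agg$presses[, "sem"],
                    n_animals = agg$presses[, "n"])
  out <- out[order(out$genotype, out$cue, out$lever), ]
  rownames(out) <- NULL
  out
}
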