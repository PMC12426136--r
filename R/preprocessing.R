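#' Read / write trial tables
#'
#' The trial CSV schema has exact headers
#' `participant,group,block,rt,correct,choice`: participant id, group label,
#' block index (1-based), response time in seconds, correctness (TRUE/FALSE),
#' and the response ("left"/"right").
#'
#' @param path CSV file path.
#' @return `read_trials()` returns the trial data frame.
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "group", "block", "rt", "correct", "choice")
  if (!all(need %in% names(tr)))
    stop("trial CSV must have columns: ", paste(need, collapse = ","),
         call. = FALSE)
  tr$correct <- as.logical(tr$correct)
  tr
}

#' @rdname read_trials
#' @param trials trial data frame in the schema above.
#' @export
write_trials <- function(trials, path) {
  need <- c("participant", "group", "block", "rt", "correct", "choice")
  write.csv(trials[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter trials by response time
#'
#' Removes anticipatory responses (faster than 250 ms) and attention lapses
#' (slower than 10,000 ms). "Faster/slower than" is read strictly, so trials
#' at exactly the cutoffs are retained. Order is preserved and the operation
#' is idempotent.
#'
#' @param trials data frame with an `rt` column (seconds).
#' @param min_rt,max_rt retention bounds in seconds (inclusive).
#' @return The retained trials.
#' @export
filter_trials <- function(trials, min_rt = 0.250, max_rt = 10.0) {
  keep <- trials$rt >= min_rt & trials$rt <= max_rt
  trials[keep, , drop = FALSE]
}

#' Per-participant summaries
#'
#' @param trials trial data frame (typically after [filter_trials()]).
#' @return Data frame with one row per participant: `participant`, `group`,
#'   `n_trials_total`, `accuracy`, `median_rt`, `mean_rt`.
#' @export
participant_summaries <- function(trials) {
  sp <- split(trials, trials$participant)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(participant = d$participant[1], group = d$group[1],
               n_trials_total = nrow(d),
               accuracy = mean(d$correct),
               median_rt = median(d$rt),
               mean_rt = mean(d$rt),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Participant exclusion
#'
#' Excludes participants scoring below the accuracy criterion (default 60%;
#' exactly 60% is retained), and -- for fixed-time designs only, where trial
#' counts vary -- participants who completed fewer than 200 total trials
#' (fewer than ten per block on average, too few for block-by-block threshold
#' analysis). Exclusion reasons are recorded on the returned object.
#'
#' @param summaries output of [participant_summaries()].
#' @param design_type "fixed_trial" or "fixed_time"; either a single value or
#'   one per row of `summaries`.
#' @param min_accuracy,min_trials the exclusion criteria.
#' @return The retained summaries; the dropped rows, with a `reason` column,
#'   are attached as `attr(, "excluded")`.
#' @export
exclude_participants <- function(summaries,
                                 design_type = c("fixed_trial", "fixed_time"),
                                 min_accuracy = 0.60, min_trials = 200) {
  if (!all(design_type %in% c("fixed_trial", "fixed_time")))
    stop("unknown design_type (use \"fixed_trial\" or \"fixed_time\")",
         call. = FALSE)
  if (length(design_type) == 1)
    design_type <- rep(design_type, nrow(summaries))
  low_acc <- summaries$accuracy < min_accuracy
  few_trials <- design_type == "fixed_time" &
    summaries$n_trials_total < min_trials
  reason <- ifelse(low_acc, sprintf("accuracy below %d%%", round(100 * min_accuracy)),
                   ifelse(few_trials,
                          sprintf("fewer than %d total trials (fixed-time)", min_trials),
                          NA_character_))
  drop <- low_acc | few_trials
  excluded <- summaries[drop, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[drop]
  retained <- summaries[!drop, , drop = FALSE]
  attr(retained, "excluded") <- excluded
  retained
}

#' Group-level descriptive summary
#'
#' Computes the descriptive columns of a group summary table: median RT
#' (`mrt`), proportion correct (`pc`), average seconds per 40 trials, average
#' trials per 60 s, and the reward rate. The per-trial wall time used for the
#' throughput columns is `rt + fdt + iti + et * (1 - correct)`; the reward
#' rate is [reward_rate_from_summary()] applied to the tabulated-style
#' (`mrt`, `pc`) pair.
#'
#' @param trials non-empty (filtered) trial data frame for one group.
#' @param timing a [timing_config()] object.
#' @param mrt_type "median" (tabulated convention) or "mean".
#' @return One-row data frame: `n_participants`, `n_trials`, `mrt`, `pc`,
#'   `s_per_40_trials`, `trials_per_60s`, `rr`.
#' @export
summarize_group <- function(trials, timing = timing_config(),
                            mrt_type = c("median", "mean")) {
  if (NROW(trials) == 0) stop("empty group", call. = FALSE)
  mrt_type <- match.arg(mrt_type)
  mrt <- if (mrt_type == "median") median(trials$rt) else mean(trials$rt)
  pc <- mean(trials$correct)
  wall <- trials$rt + timing$fdt + timing$iti + timing$et * (1 - trials$correct)
  data.frame(
    n_participants = length(unique(trials$participant)),
    n_trials = nrow(trials),
    mrt = mrt, pc = pc,
    s_per_40_trials = mean(wall) * 40,
    trials_per_60s = 60 / mean(wall),
    rr = reward_rate_from_summary(pc, mrt, timing)
  )
}

#' Summaries for every group in a trial table
#'
#' @param trials filtered trial data frame with a `group` column.
#' @inheritParams summarize_group
#' @return Data frame with one row per group.
#' @export
summarize_groups <- function(trials, timing = timing_config(),
                             mrt_type = c("median", "mean")) {
  mrt_type <- match.arg(mrt_type)
  sp <- split(trials, trials$group)
  out <- do.call(rbind, lapply(names(sp), function(g) {
    cbind(data.frame(group = g, stringsAsFactors = FALSE),
          summarize_group(sp[[g]], timing, mrt_type))
  }))
  rownames(out) <- NULL
  out
}
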