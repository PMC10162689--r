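#' Percent response over collision trials
#'
#' The dot-avoidance assay presents (by default ten) mock collisions; every
#' trial in which the tadpole darts away from the stimulus is a response.
#'
#' @param trials logical or 0/1 vector of per-trial response flags.
#' @return `100 * responses / trials`.
#' @export
percent_response <- function(trials) {
  if (!length(trials)) stop("empty trial list")
  t <- as.logical(trials)
  if (anyNA(t)) stop("trials must be 0/1 or logical")
  100 * sum(t) / length(t)
}

#' Pre-trial inclusion rule
#'
#' Only animals responding to 50% or more of the pre-crush trials are
#' included in crush experiments (inclusive at 50).
#'
#' @param percent percent response in `[0, 100]`.
#' @param cutoff inclusion cutoff.
#' @return Logical flag.
#' @export
passes_inclusion <- function(percent, cutoff = 50) {
  if (percent < 0 || percent > 100) stop("percent must lie in [0, 100]")
  percent >= cutoff
}

#' Behavior record for one animal and session
#'
#' @param animal_id animal identifier.
#' @param session_label session (e.g. `"pre"`, `"day3"`, `"day6"`).
#' @param trials per-trial response flags (1 to 20 trials; default assay
#'   uses 10).
#' @param group group label.
#' @return An object of class `behavior_record`.
#' @export
behavior_record <- function(animal_id, session_label, trials, group = "all") {
  if (length(trials) < 1 || length(trials) > 20)
    stop("between 1 and 20 trials per session")
  structure(list(animal_id = animal_id, session_label = session_label,
                 trials = as.logical(trials), group = group,
                 percent_response = percent_response(trials)),
            class = "behavior_record")
}

#' Per-group, per-session behavior summary
#'
#' @param records list of [behavior_record()]s.
#' @return A data.frame with one row per (group, session): `n`,
#'   `mean_percent`, `sd_percent`.
#' @export
session_table <- function(records) {
  if (!length(records)) stop("need at least one record")
  df <- data.frame(
    group = vapply(records, function(r) r$group, ""),
    session = vapply(records, function(r) r$session_label, ""),
    percent = vapply(records, function(r) r$percent_response, 0))
  agg <- aggregate(percent ~ group + session, df, function(v)
    c(n = length(v), mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_))
  out <- data.frame(group = agg$group, session = agg$session,
                    n = agg$percent[, "n"], mean_percent = agg$percent[, "mean"],
                    sd_percent = agg$percent[, "sd"])
  out[order(out$group, out$session), , drop = FALSE]
}

#' Read behavior trial records from CSV
#'
#' Expected columns: `animal_id`, `group`, `session`, `trial_index`,
#' `response` (0/1).
#'
#' @param path CSV path.
#' @return List of [behavior_record()]s, one per (animal, session).
#' @export
read_behavior_csv <- function(path) {
  df <- read.csv(path)
  need <- c("animal_id", "group", "session", "trial_index", "response")
  if (!all(need %in% names(df)))
    stop("expected columns: ", paste(need, collapse = ", "))
  keys <- unique(df[, c("animal_id", "group", "session")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$animal_id == keys$animal_id[i] &
                df$session == keys$session[i] &
                df$group == keys$group[i], ]
    sub <- sub[order(sub$trial_index), ]
    behavior_record(keys$animal_id[i], keys$session[i], sub$response,
                    keys$group[i])
  })
}
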