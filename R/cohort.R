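#' Assign a CDR score to one MRI session
#'
#' Clinical Dementia Rating (CDR) assessments rarely coincide with MRI
#' sessions, so each scan is labeled from the subject's CDR history by, in
#' order:
#' 1. if the MRI day lies between two CDR records with equal scores
#'    (inclusive), that score is assigned (`between_equal`);
#' 2. if it lies between two records with different scores, the nearer
#'    record's score is assigned only when its distance is within
#'    `windowDays` (`nearest_within_window`); equidistant ties drop the
#'    session;
#' 3. with records on one side only, the nearest record's score is assigned
#'    when within `windowDays` (`single_within_window`);
#' otherwise the session is dropped. The default window is 45 days.
#'
#' @param day MRI day (days since study entry).
#' @param cdrHistory `data.frame` with columns `day`, `cdr` for one subject.
#' @param windowDays positive tolerance in days (default 45).
#' @return a list with `cdr`, `rule_applied`, `drop_reason` (`NA` unless
#'   dropped).
#' @examples
#' h <- data.frame(day = c(50, 200), cdr = c(0, 0))
#' assignCDR(100, h)$rule_applied          # "between_equal"
#' @export
assignCDR <- function(day, cdrHistory, windowDays = 45L) {
  if (!is.numeric(windowDays) || windowDays <= 0)
    stop("windowDays must be > 0", call. = FALSE)
  dropped <- function(reason)
    list(cdr = NA_real_, rule_applied = NA_character_,
         drop_reason = reason)
  if (is.null(cdrHistory) || nrow(cdrHistory) == 0L)
    return(dropped("no_cdr"))
  h <- cdrHistory[order(cdrHistory$day), , drop = FALSE]
  before <- h[h$day <= day, , drop = FALSE]
  after <- h[h$day >= day, , drop = FALSE]
  if (nrow(before) > 0L && nrow(after) > 0L) {
    prev <- before[nrow(before), ]
    nxt <- after[1L, ]
    if (prev$cdr == nxt$cdr)
      return(list(cdr = prev$cdr, rule_applied = "between_equal",
                  drop_reason = NA_character_))
    dPrev <- day - prev$day
    dNxt <- nxt$day - day
    if (dPrev == dNxt)
      return(dropped("equidistant_tie"))
    nearest <- if (dPrev < dNxt) prev else nxt
    if (min(dPrev, dNxt) <= windowDays)
      return(list(cdr = nearest$cdr, rule_applied = "nearest_within_window",
                  drop_reason = NA_character_))
    return(dropped("nearest_beyond_window"))
  }
  only <- if (nrow(before) > 0L) before[nrow(before), ] else after[1L, ]
  if (abs(only$day - day) <= windowDays)
    return(list(cdr = only$cdr, rule_applied = "single_within_window",
                drop_reason = NA_character_))
  dropped("single_beyond_window")
}

#' Label a table of MRI sessions from a CDR table
#'
#' Applies [assignCDR()] to every session, matching CDR records by subject.
#'
#' @param sessions `data.frame` with columns `subject_id`, `session_id`,
#'   `day` (as from [readSessionTable()]).
#' @param cdrTable `data.frame` with columns `subject_id`, `day`, `cdr`.
#' @param windowDays window passed to [assignCDR()].
#' @return `sessions` with added columns `cdr`, `rule_applied`,
#'   `drop_reason`.
#' @export
labelSessions <- function(sessions, cdrTable, windowDays = 45L) {
  stopifnot(is.data.frame(sessions), is.data.frame(cdrTable))
  out <- sessions
  out$cdr <- NA_real_
  out$rule_applied <- NA_character_
  out$drop_reason <- NA_character_
  for (i in seq_len(nrow(sessions))) {
    h <- cdrTable[cdrTable$subject_id == sessions$subject_id[i], ,
                  drop = FALSE]
    a <- assignCDR(sessions$day[i], h, windowDays)
    out$cdr[i] <- a$cdr
    out$rule_applied[i] <- a$rule_applied
    out$drop_reason[i] <- a$drop_reason
  }
  out
}

#' Build a one-session-per-subject cross-sectional cohort
#'
#' Drops unlabeled sessions, keeps exactly one labeled session per subject
#' (the earliest by day, by default), and assigns the class: `control` for
#' CDR = 0, `dementia` for CDR at or above `dementiaMin` (default 1).
#' Subjects whose retained CDR falls strictly between 0 and `dementiaMin`
#' (i.e. CDR 0.5 under the default) belong to neither class and are
#' excluded with a message -- the class policy is deliberately explicit
#' configuration, since questionable-dementia subjects can be argued either
#' way.
#'
#' @param labeled output of [labelSessions()].
#' @param dementiaMin smallest CDR counted as dementia (default 1).
#' @param keep `"earliest"` or `"latest"` labeled session per subject.
#' @return `data.frame` with one row per subject: `subject_id`,
#'   `session_id`, `day`, `cdr`, `class_label`, `rule_applied`.
#' @export
buildCohort <- function(labeled, dementiaMin = 1, keep = c("earliest",
                                                           "latest")) {
  keep <- match.arg(keep)
  stopifnot(is.data.frame(labeled))
  lab <- labeled[!is.na(labeled$cdr), , drop = FALSE]
  if (nrow(lab) == 0L)
    return(data.frame(subject_id = character(), session_id = character(),
                      day = integer(), cdr = numeric(),
                      class_label = character(), rule_applied = character(),
                      stringsAsFactors = FALSE))
  pick <- do.call(rbind, lapply(split(lab, lab$subject_id), function(s) {
    s <- s[order(s$day), , drop = FALSE]
    if (keep == "earliest") s[1L, ] else s[nrow(s), ]
  }))
  pick$class_label <- ifelse(pick$cdr == 0, "control",
                             ifelse(pick$cdr >= dementiaMin, "dementia",
                                    NA_character_))
  mid <- is.na(pick$class_label)
  if (any(mid))
    message(sum(mid), " subject(s) with 0 < CDR < ", dementiaMin,
            " fall in neither class and are excluded")
  out <- pick[!mid, c("subject_id", "session_id", "day", "cdr",
                      "class_label", "rule_applied"), drop = FALSE]
  rownames(out) <- NULL
  out
}
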