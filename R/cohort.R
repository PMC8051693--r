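#' Paired cohort of recording sessions
#'
#' The within-subject design: every subject contributes one control and one
#' treatment session (hypnogram, optionally EEG). All paired statistics
#' operate on this structure.
#'
#' @param subjects named list; each element is
#'   `list(control = list(hypnogram =, session =), treatment = list(...))`.
#'   Subject IDs (the names) must be unique and both arms present.
#' @return object of class `paired_cohort`.
#' @export
paired_cohort <- function(subjects) {
  ids <- names(subjects)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("subjects must be a named list with unique subject IDs")
  }
  for (id in ids) {
    arms <- subjects[[id]]
    if (!all(c("control", "treatment") %in% names(arms))) {
      stop("subject ", id, " is missing an arm; both arms are required")
    }
  }
  structure(list(subjects = subjects), class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf(
    "<paired_cohort> %d subjects (%s)\n",
    length(x$subjects), paste(names(x$subjects), collapse = ", ")
  ))
  invisible(x)
}

#' Apply a per-session summary over a paired cohort
#'
#' Convenience iterator: calls `f(arm)` for every subject and arm, where
#' `arm` is the `list(hypnogram =, session =)` entry, and returns a tidy
#' data.frame with `subject`, `condition` and the (scalar or one-row)
#' result columns.
#'
#' @param cohort a [paired_cohort()].
#' @param f function of one arm entry returning a scalar, named vector or
#'   one-row data.frame.
#' @return data.frame in long format.
#' @export
cohort_summarize <- function(cohort, f) {
  stopifnot(inherits(cohort, "paired_cohort"))
  rows <- list()
  for (id in names(cohort$subjects)) {
    for (cond in c("control", "treatment")) {
      val <- f(cohort$subjects[[id]][[cond]])
      if (is.data.frame(val)) {
        row <- cbind(data.frame(subject = id, condition = cond), val)
      } else {
        val <- as.list(val)
        if (is.null(names(val)) && length(val) == 1L) names(val) <- "value"
        row <- cbind(data.frame(subject = id, condition = cond),
                     as.data.frame(val))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Extract subject-aligned paired values from a cohort summary
#'
#' @param df data.frame with `subject`, `condition` and `value` columns
#'   (e.g. from [cohort_summarize()]).
#' @param value name of the value column.
#' @return a [paired_sample()] aligned on subject.
#' @export
paired_from_summary <- function(df, value = "value") {
  ctrl <- df[df$condition == "control", c("subject", value)]
  trt <- df[df$condition == "treatment", c("subject", value)]
  m <- merge(ctrl, trt, by = "subject", suffixes = c(".control", ".treatment"))
  paired_sample(
    control = m[[paste0(value, ".control")]],
    treatment = m[[paste0(value, ".treatment")]],
    subject = m$subject
  )
}
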