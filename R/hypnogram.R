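#' Construct a hypnogram
#'
#' A hypnogram is a sequence of vigilance-state labels scored at a fixed
#' epoch length (5 s by default, the standard scoring resolution for rodent
#' polysomnography). Labels are drawn from `W`, `NREM`, `REM` and
#' `ARTIFACT`; artifact epochs mark unscoreable data and are excluded from
#' state statistics downstream.
#'
#' @param labels character vector of state labels (aliases accepted, see
#'   [parse_state_labels()]).
#' @param epoch_s epoch duration in seconds (> 0).
#' @param t0 session start offset in seconds.
#' @return An object of class `hypnogram`: a list with `labels` (character),
#'   `epoch_s` and `t0`.
#' @examples
#' h <- hypnogram(c("W", "W", "NREM", "NREM", "REM"))
#' duration(h)
#' @export
hypnogram <- function(labels, epoch_s = 5, t0 = 0) {
  labels <- parse_state_labels(labels)
  if (length(labels) == 0L) stop("hypnogram must contain at least one epoch")
  if (!is.numeric(epoch_s) || length(epoch_s) != 1L || epoch_s <= 0) {
    stop("epoch_s must be a single positive number")
  }
  structure(
    list(labels = labels, epoch_s = as.numeric(epoch_s), t0 = as.numeric(t0)),
    class = "hypnogram"
  )
}

#' Normalize state tokens to the canonical alphabet
#'
#' Case-insensitive aliases: `W`/`Wake`/`Wakefulness`, `N`/`NREM`/`NREMS`,
#' `R`/`REM`/`REMS`, `A`/`Artifact`/`Art`. Unrecognized tokens are an error
#' that names the offending position.
#'
#' @param tokens character vector.
#' @return character vector over `W`, `NREM`, `REM`, `ARTIFACT`.
#' @export
parse_state_labels <- function(tokens) {
  tokens <- as.character(tokens)
  key <- toupper(trimws(tokens))
  map <- c(
    "W" = "W", "WAKE" = "W", "WAKEFULNESS" = "W",
    "N" = "NREM", "NREM" = "NREM", "NREMS" = "NREM", "NREM SLEEP" = "NREM",
    "R" = "REM", "REM" = "REM", "REMS" = "REM", "REM SLEEP" = "REM",
    "A" = "ARTIFACT", "ART" = "ARTIFACT", "ARTIFACT" = "ARTIFACT"
  )
  out <- unname(map[key])
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    stop(sprintf(
      "unrecognized state token '%s' at position %d",
      tokens[bad[1L]], bad[1L]
    ))
  }
  out
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = STATE_ALPHABET))
  cat(sprintf(
    "<hypnogram> %d epochs x %g s = %g s total\n",
    length(x$labels), x$epoch_s, duration(x)
  ))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "  "), "\n")
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' Total duration of a hypnogram in seconds
#' @param h a [hypnogram()].
#' @return numeric scalar, `length(h) * h$epoch_s`.
#' @export
duration <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  length(h$labels) * h$epoch_s
}

#' Read a hypnogram from a text file
#'
#' The on-disk format is one state token per line with optional
#' `#`-prefixed header lines; a header of the form `# epoch_s: 5` records
#' the epoch length and takes precedence over the `epoch_s` argument.
#'
#' @param path file path.
#' @param epoch_s epoch length in seconds used when the file carries no
#'   `epoch_s` header.
#' @return a [hypnogram()].
#' @seealso [write_hypnogram()]
#' @export
read_hypnogram <- function(path, epoch_s = 5) {
  if (!file.exists(path)) stop("hypnogram file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- grep("^\\s*#", lines)
  for (i in header) {
    m <- regmatches(lines[i], regexec("epoch_s\\s*[:=]\\s*([0-9.]+)", lines[i]))[[1L]]
    if (length(m) == 2L) epoch_s <- as.numeric(m[2L])
  }
  body_idx <- setdiff(seq_along(lines), header)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (length(body_idx) == 0L) stop("empty hypnogram file: ", path)
  tokens <- trimws(lines[body_idx])
  labels <- tryCatch(parse_state_labels(tokens), error = function(e) {
    pos <- as.integer(sub(".*position ([0-9]+)$", "\\1", conditionMessage(e)))
    stop(sprintf(
      "unrecognized state token '%s' on line %d of %s",
      tokens[pos], body_idx[pos], path
    ), call. = FALSE)
  })
  hypnogram(labels, epoch_s = epoch_s)
}

#' Write a hypnogram to a text file
#'
#' One epoch per line, preceded by a comment header carrying the epoch
#' length, so that `read_hypnogram(write_hypnogram(h))` is the identity.
#'
#' @param h a [hypnogram()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  writeLines(c(sprintf("# epoch_s: %g", h$epoch_s), h$labels), path)
  invisible(path)
}
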