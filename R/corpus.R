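#' Construct a post corpus
#'
#' A corpus is an ordered collection of social-media posts, each with a unique
#' id, a source channel, an optional ISO-8601 date, free text, and an optional
#' binary adverse-drug-reaction (ADR) label (`1` = ADR post, `0` = non-ADR
#' post). Iteration order is stable and equals file order on disk.
#'
#' @param id character vector of unique post ids.
#' @param channel character vector, each element one of `"blog"`, `"cafe"`,
#'   `"qna"`, `"synthetic"`. Recycled if length 1.
#' @param text character vector of post bodies; must be non-empty after
#'   whitespace stripping.
#' @param label optional numeric vector of 0/1 labels; `NA` = unlabeled.
#' @param date optional character vector of ISO-8601 dates (provenance only,
#'   never used in computation).
#' @param provenance named list of free-text metadata (source, seed, ...).
#' @return An object of class `adr_corpus`: a list with elements `posts`
#'   (a data.frame with columns id/channel/date/text/label) and `provenance`.
#' @examples
#' corpus(id = c("p1", "p2"), channel = "synthetic",
#'        text = c("took ketotop got a rash", "nice weather"),
#'        label = c(1, 0))
#' @export
corpus <- function(id, channel = "synthetic", text, label = NA_real_,
                   date = NA_character_, provenance = list()) {
  n <- length(id)
  posts <- data.frame(
    id = as.character(id),
    channel = rep_len(as.character(channel), n),
    date = rep_len(as.character(date), n),
    text = as.character(text),
    label = rep_len(as.numeric(label), n),
    stringsAsFactors = FALSE
  )
  validate_posts(posts)
  structure(list(posts = posts, provenance = provenance),
            class = "adr_corpus")
}

CHANNELS <- c("blog", "cafe", "qna", "synthetic")

validate_posts <- function(posts, lines = NULL) {
  where <- function(i) {
    if (is.null(lines)) sprintf("record %d", i) else sprintf("line %d", lines[i])
  }
  problems <- character(0)
  if (anyNA(posts$id) || any(!nzchar(posts$id))) {
    i <- which(is.na(posts$id) | !nzchar(posts$id))[1]
    problems <- c(problems, sprintf("missing required field 'id' at %s", where(i)))
  }
  dup <- duplicated(posts$id)
  if (any(dup)) {
    i <- which(dup)[1]
    problems <- c(problems, sprintf("duplicate id '%s' at %s", posts$id[i], where(i)))
  }
  bad_chan <- !is.na(posts$channel) & !(posts$channel %in% CHANNELS)
  if (any(bad_chan)) {
    i <- which(bad_chan)[1]
    problems <- c(problems, sprintf(
      "invalid channel '%s' at %s (expected one of %s)",
      posts$channel[i], where(i), paste(CHANNELS, collapse = ", ")))
  }
  empty <- is.na(posts$text) | !nzchar(trimws(posts$text))
  if (any(empty)) {
    i <- which(empty)[1]
    problems <- c(problems, sprintf("missing required field 'text' at %s", where(i)))
  }
  bad_lab <- !is.na(posts$label) & !(posts$label %in% c(0, 1))
  if (any(bad_lab)) {
    i <- which(bad_lab)[1]
    problems <- c(problems, sprintf(
      "invalid label '%s' at %s (must be 0 or 1)", format(posts$label[i]), where(i)))
  }
  if (length(problems) > 0)
    abort_adr(paste(problems, collapse = "\n"), "adr_validation_error")
  invisible(posts)
}

#' Read a post corpus from a JSON-lines file
#'
#' The on-disk format is UTF-8 JSON-lines: an optional first metadata line
#' `{"record":"meta","provenance":{...}}` followed by one post object per
#' line with fields `id`, `channel`, `date`, `text`, `label`. Records failing
#' validation are reported with their line numbers.
#'
#' @param path file to read.
#' @param require_labels if `TRUE`, every post must carry a 0/1 label.
#' @return An [corpus()] object; post order equals file order.
#' @export
read_corpus <- function(path, require_labels = FALSE) {
  if (!file.exists(path))
    abort_adr(sprintf("corpus file not found: %s", path), "adr_io_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  provenance <- list()
  recs <- vector("list", length(lines_keep))
  recno <- integer(length(lines_keep))
  k <- 0
  for (j in seq_along(lines_keep)) {
    ln <- lines_keep[j]
    obj <- tryCatch(jsonlite::fromJSON(lines[ln], simplifyVector = TRUE),
                    error = function(e) abort_adr(
                      sprintf("malformed JSON at line %d: %s", ln, conditionMessage(e)),
                      "adr_validation_error"))
    if (identical(obj$record, "meta")) {
      provenance <- obj$provenance %||% list()
      next
    }
    k <- k + 1
    recs[[k]] <- obj
    recno[k] <- ln
  }
  if (k == 0) {
    posts <- data.frame(id = character(0), channel = character(0),
                        date = character(0), text = character(0),
                        label = numeric(0), stringsAsFactors = FALSE)
    return(structure(list(posts = posts, provenance = provenance),
                     class = "adr_corpus"))
  }
  recs <- recs[seq_len(k)]
  recno <- recno[seq_len(k)]
  getf <- function(r, f, default) {
    v <- r[[f]]
    if (is.null(v) || length(v) == 0) default else v[[1]]
  }
  posts <- data.frame(
    id = vapply(recs, getf, "", f = "id", default = NA_character_),
    channel = vapply(recs, function(r) as.character(getf(r, "channel", "synthetic")), ""),
    date = vapply(recs, function(r) as.character(getf(r, "date", NA_character_)), ""),
    text = vapply(recs, function(r) as.character(getf(r, "text", NA_character_)), ""),
    label = vapply(recs, function(r) {
      v <- getf(r, "label", NA_real_)
      if (is.null(v) || is.na(v)) NA_real_ else suppressWarnings(as.numeric(v))
    }, 0),
    stringsAsFactors = FALSE
  )
  validate_posts(posts, lines = recno)
  if (require_labels && anyNA(posts$label)) {
    i <- which(is.na(posts$label))[1]
    abort_adr(sprintf("missing required field 'label' at line %d", recno[i]),
              "adr_validation_error")
  }
  structure(list(posts = posts, provenance = provenance), class = "adr_corpus")
}

#' Write a post corpus to a JSON-lines file
#'
#' Round-trips losslessly through [read_corpus()], including Hangul or any
#' other unicode text (files are UTF-8, no BOM).
#'
#' @param x an `adr_corpus`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "adr_corpus"))
  validate_posts(x$posts)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort_adr(
                    sprintf("cannot write corpus to %s: %s", path, conditionMessage(e)),
                    "adr_io_error"))
  on.exit(close(con))
  meta <- jsonlite::toJSON(list(record = "meta", provenance = x$provenance),
                           auto_unbox = TRUE, null = "null")
  writeLines(meta, con, useBytes = TRUE)
  p <- x$posts
  for (i in seq_len(nrow(p))) {
    rec <- list(id = p$id[i], channel = p$channel[i])
    if (!is.na(p$date[i])) rec$date <- p$date[i]
    rec$text <- p$text[i]
    if (!is.na(p$label[i])) rec$label <- p$label[i]
    writeLines(enc2utf8(jsonlite::toJSON(rec, auto_unbox = TRUE)), con,
               useBytes = TRUE)
  }
  invisible(path)
}

#' Summarize the label composition of a corpus
#'
#' Reports post counts and label shares the way labeled pharmacovigilance
#' datasets are tabulated: total posts, labeled posts, ADR and non-ADR counts
#' and their percentage shares.
#'
#' @param x an `adr_corpus`.
#' @return A list with `n_posts`, `n_labeled`, `n_adr`, `n_non_adr`,
#'   `pct_adr`, `pct_non_adr` (percentages on 0-100), and `by_channel`
#'   (a table of posts per channel).
#' @export
summarize_corpus <- function(x) {
  stopifnot(inherits(x, "adr_corpus"))
  p <- x$posts
  lab <- p$label[!is.na(p$label)]
  n_lab <- length(lab)
  list(
    n_posts = nrow(p),
    n_labeled = n_lab,
    n_adr = sum(lab == 1),
    n_non_adr = sum(lab == 0),
    pct_adr = if (n_lab > 0) 100 * sum(lab == 1) / n_lab else NA_real_,
    pct_non_adr = if (n_lab > 0) 100 * sum(lab == 0) / n_lab else NA_real_,
    by_channel = table(p$channel)
  )
}

#' @export
print.adr_corpus <- function(x, ...) {
  s <- summarize_corpus(x)
  cat(sprintf("<adr_corpus> %d posts (%d labeled", s$n_posts, s$n_labeled))
  if (s$n_labeled > 0)
    cat(sprintf("; %.1f%% ADR", s$pct_adr))
  cat(")\n")
  invisible(x)
}

#' @export
length.adr_corpus <- function(x) nrow(x$posts)
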