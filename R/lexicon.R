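#' Construct a lexicon
#'
#' A lexicon maps surface forms to term entries of one class: drug brand
#' names (with a generic canonical name), ADR terms, or stop words. Surfaces
#' are matched exactly after the same normalization applied to post text
#' (case-folding, whitespace collapse), so lookups are case- and
#' spacing-insensitive. Multiword surfaces (e.g. "muscle pain") are
#' supported; the tokenizer merges adjacent tokens into the longest known
#' surface.
#'
#' @param surface character vector of match forms (non-empty, unique within
#'   the class after normalization).
#' @param term_class one of `"drug"`, `"adr"`, `"stopword"`.
#' @param term_id optional non-negative integer ids, unique within the class.
#'   When absent, ids are assigned by stable enumeration in input order.
#' @param canonical canonical names (generic drug name / preferred ADR term);
#'   defaults to the surface.
#' @param source free-text provenance tag per entry.
#' @return An object of class `adr_lexicon`: a data.frame with columns
#'   `surface`, `norm` (normalized surface), `term_id`, `canonical`,
#'   `source`, and attributes `term_class` and `max_words` (longest surface
#'   in whitespace-delimited words, used for longest-match tokenization).
#' @export
lexicon <- function(surface, term_class = c("drug", "adr", "stopword"),
                    term_id = NULL, canonical = NULL, source = "manual") {
  term_class <- match.arg(term_class)
  surface <- as.character(surface)
  if (any(is.na(surface) | !nzchar(trimws(surface))))
    abort_adr("lexicon surfaces must be non-empty", "adr_validation_error")
  norm <- normalize(surface)
  if (anyDuplicated(norm)) {
    offenders <- unique(surface[duplicated(norm) | duplicated(norm, fromLast = TRUE)])
    abort_adr(sprintf("duplicate surfaces in %s lexicon: %s", term_class,
                      paste(offenders, collapse = ", ")),
              "adr_validation_error")
  }
  if (is.null(term_id)) {
    term_id <- seq_along(surface)  # stable enumeration in file order
  } else {
    term_id <- as.integer(term_id)
    if (anyNA(term_id) || any(term_id < 0))
      abort_adr("term_id must be non-negative integers", "adr_validation_error")
    if (anyDuplicated(term_id))
      abort_adr(sprintf("duplicate term_id in %s lexicon: %s", term_class,
                        paste(unique(term_id[duplicated(term_id)]), collapse = ", ")),
                "adr_validation_error")
  }
  if (is.null(canonical)) canonical <- surface
  df <- data.frame(surface = surface, norm = norm, term_id = term_id,
                   canonical = as.character(canonical),
                   source = rep_len(as.character(source), length(surface)),
                   stringsAsFactors = FALSE)
  structure(df, class = c("adr_lexicon", "data.frame"),
            term_class = term_class,
            max_words = max(1L, lengths(strsplit(norm, " ", fixed = TRUE))))
}

#' Load a lexicon from a tab-separated file
#'
#' Expects a UTF-8 TSV with a header row and columns `surface`, `term_id`,
#' `canonical`, `source` (all but `surface` optional; `term_id` is typically
#' omitted for stop words and assigned by file order).
#'
#' @param path file to read.
#' @param term_class one of `"drug"`, `"adr"`, `"stopword"`.
#' @return An [lexicon()] object.
#' @export
load_lexicon <- function(path, term_class = c("drug", "adr", "stopword")) {
  term_class <- match.arg(term_class)
  if (!file.exists(path))
    abort_adr(sprintf("lexicon file not found: %s", path), "adr_io_error")
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = "character")
  if (nrow(df) == 0)
    abort_adr(sprintf("empty lexicon file: %s", path), "adr_validation_error")
  if (!"surface" %in% names(df))
    abort_adr("lexicon file must have a 'surface' column", "adr_validation_error")
  lexicon(
    surface = df$surface,
    term_class = term_class,
    term_id = if ("term_id" %in% names(df) && any(nzchar(df$term_id)))
      as.integer(df$term_id) else NULL,
    canonical = if ("canonical" %in% names(df)) df$canonical else NULL,
    source = if ("source" %in% names(df)) df$source else "file"
  )
}

#' Write a lexicon to a tab-separated file
#'
#' @param lex an `adr_lexicon`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "adr_lexicon"))
  df <- lex[, c("surface", "term_id", "canonical", "source")]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c("surface\tterm_id\tcanonical\tsource",
                        paste(df$surface, df$term_id, df$canonical, df$source,
                              sep = "\t"))),
             con, useBytes = TRUE)
  invisible(path)
}

#' Look up a surface form in a lexicon
#'
#' The query is normalized the same way post text is, so case and spacing
#' differences do not matter. Never errors on a miss.
#'
#' @param lex an `adr_lexicon`.
#' @param surface a single surface string.
#' @return A one-row list with `surface`, `term_id`, `term_class`,
#'   `canonical`, `source`, or `NULL` when the surface is unknown.
#' @export
lookup <- function(lex, surface) {
  stopifnot(inherits(lex, "adr_lexicon"), length(surface) == 1)
  i <- match(normalize(surface), lex$norm)
  if (is.na(i)) return(NULL)
  list(surface = lex$surface[i], term_id = lex$term_id[i],
       term_class = attr(lex, "term_class"),
       canonical = lex$canonical[i], source = lex$source[i])
}

#' @export
print.adr_lexicon <- function(x, ...) {
  cat(sprintf("<adr_lexicon class=%s> %d entries\n", attr(x, "term_class"), nrow(x)))
  invisible(x)
}

# Cross-lexicon surface checks used at pipeline setup: ADR and stop-word
# lexicons must be disjoint; a drug/ADR overlap resolves to drug (logged).
check_lexicon_collisions <- function(drug, adr, stop) {
  clash <- intersect(adr$norm, stop$norm)
  if (length(clash) > 0)
    abort_adr(sprintf("surfaces present in both ADR and stop-word lexicons: %s",
                      paste(clash, collapse = ", ")),
              "adr_validation_error")
  both <- intersect(drug$norm, adr$norm)
  if (length(both) > 0)
    warn_adr(sprintf("surfaces in both drug and ADR lexicons tagged as drug: %s",
                     paste(both, collapse = ", ")),
             "adr_lexicon_collision")
  invisible(both)
}
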