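#' Normalize post text
#'
#' Removes URLs and unicode control characters, collapses runs of whitespace
#' to single spaces, trims, and case-folds. Idempotent: applying it twice
#' gives the same string. All tokenization offsets refer to the normalized
#' string.
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @examples
#' normalize("Visit  http://x.y/z NOW\t please")  # "visit now please"
#' @export
normalize <- function(text) {
  x <- as.character(text)
  x <- gsub("(https?://|www\\.)[^[:space:]]+", " ", x, perl = TRUE)
  x <- gsub("[\\p{Cc}\\p{Cf}]", " ", x, perl = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  tolower(trimws(x))
}

# Default tokenizer: unicode word characters (letters, digits, underscore).
# Returns 0-based half-open character spans on the normalized string.
default_word_tokenizer <- function(text) {
  m <- gregexpr("[\\p{L}\\p{N}_]+", text, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  len <- attr(m, "match.length")
  data.frame(surface = substring(text, m, m + len - 1),
             start = as.integer(m) - 1L,
             end = as.integer(m) + as.integer(len) - 1L,
             stringsAsFactors = FALSE)
}

#' Tokenize normalized text
#'
#' Splits text into ordered, non-overlapping tokens. The default tokenizer is
#' a unicode word-boundary split followed by greedy longest-match merging of
#' adjacent tokens into known multiword lexicon surfaces (so "muscle pain"
#' becomes one token when it is an ADR lexicon entry). A custom tokenizer can
#' be plugged in: any function taking the text and returning a data.frame
#' with columns `surface`, `start`, `end` (0-based half-open spans). This is
#' the hook where language-specific morphological analysis would slot in.
#'
#' @param text a single normalized string (see [normalize()]).
#' @param lexicons optional list of `adr_lexicon` objects whose multiword
#'   surfaces drive the longest-match merge.
#' @param tokenizer optional tokenizer function replacing the default split.
#' @return data.frame with columns `surface`, `start`, `end`.
#' @export
tokenize <- function(text, lexicons = NULL, tokenizer = NULL) {
  stopifnot(length(text) == 1)
  if (is.null(tokenizer)) {
    toks <- default_word_tokenizer(text)
  } else {
    toks <- tryCatch(tokenizer(text), error = function(e) abort_adr(
      sprintf("tokenizer plugin '%s' failed: %s",
              deparse(substitute(tokenizer))[1], conditionMessage(e)),
      "adr_tokenizer_error"))
    if (!all(c("surface", "start", "end") %in% names(toks)))
      abort_adr("tokenizer plugin must return columns surface/start/end",
                "adr_tokenizer_error")
    if (nrow(toks) > 1 && any(toks$start[-1] < toks$end[-nrow(toks)]))
      abort_adr("tokenizer plugin returned overlapping spans", "adr_tokenizer_error")
  }
  if (nrow(toks) == 0 || is.null(lexicons)) return(toks)

  multi <- unlist(lapply(lexicons, function(l) {
    l$norm[grepl(" ", l$norm, fixed = TRUE)]
  }), use.names = FALSE)
  if (length(multi) == 0) return(toks)
  max_words <- max(lengths(strsplit(multi, " ", fixed = TRUE)))

  # Greedy left-to-right longest match over the token sequence.
  out <- vector("list", nrow(toks))
  k <- 0; i <- 1
  while (i <= nrow(toks)) {
    merged <- FALSE
    for (w in seq(min(max_words, nrow(toks) - i + 1), 2)) {
      cand <- paste(toks$surface[i:(i + w - 1)], collapse = " ")
      if (cand %in% multi) {
        k <- k + 1
        out[[k]] <- data.frame(surface = cand, start = toks$start[i],
                               end = toks$end[i + w - 1], stringsAsFactors = FALSE)
        i <- i + w
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      k <- k + 1
      out[[k]] <- toks[i, , drop = FALSE]
      i <- i + 1
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Render and parse class-annotated tokens
#'
#' Tagged tokens are rendered `surface_id_class` with class exactly `"drug"`
#' or `"ADR"` (e.g. `"blisters_153_ADR"`); plain tokens render as their
#' surface. Parsing is unambiguous because the rendered string must end in
#' `_<digits>_drug` or `_<digits>_ADR`.
#'
#' @param surface token surface.
#' @param term_id integer term id.
#' @param term_class `"drug"` or `"adr"` (rendered as `"ADR"`).
#' @return `render_tag()`: the rendered string. `parse_tag()`: a list with
#'   `surface`, `term_id`, `term_class` (`NA`s for plain tokens).
#' @export
render_tag <- function(surface, term_id, term_class) {
  cls <- ifelse(term_class == "adr", "ADR", term_class)
  paste0(surface, "_", term_id, "_", cls)
}

#' @rdname render_tag
#' @param rendered a rendered token string.
#' @export
parse_tag <- function(rendered) {
  m <- regmatches(rendered, regexec("^(.*)_([0-9]+)_(drug|ADR)$", rendered))[[1]]
  if (length(m) == 0)
    return(list(surface = rendered, term_id = NA_integer_,
                term_class = NA_character_))
  list(surface = m[2], term_id = as.integer(m[3]),
       term_class = if (m[4] == "ADR") "adr" else "drug")
}

is_tagged <- function(rendered) {
  grepl("_[0-9]+_(drug|ADR)$", rendered)
}

#' Tag drug/ADR mentions and drop stop words
#'
#' Applies the three lexicons to a token sequence: stop-word tokens are
#' removed, drug and ADR tokens are annotated with their term id and class
#' (drug takes precedence when a surface is in both lexicons), and all other
#' tokens pass through unchanged.
#'
#' @param tokens data.frame from [tokenize()].
#' @param drug,adr,stop `adr_lexicon` objects.
#' @param post_id id carried through to the result.
#' @param label optional 0/1 label carried through.
#' @return An object of class `adr_tokens`: list with `post_id`, `tokens`
#'   (character vector of rendered token strings, stop words removed) and
#'   `label`.
#' @export
tag_and_filter <- function(tokens, drug, adr, stop, post_id = NA_character_,
                           label = NA_real_) {
  surf <- tokens$surface
  keep <- is.na(match(surf, stop$norm))
  surf <- surf[keep]
  di <- match(surf, drug$norm)
  ai <- match(surf, adr$norm)
  rendered <- surf
  is_drug <- !is.na(di)
  is_adr <- is.na(di) & !is.na(ai)  # drug precedence
  rendered[is_drug] <- render_tag(surf[is_drug], drug$term_id[di[is_drug]], "drug")
  rendered[is_adr] <- render_tag(surf[is_adr], adr$term_id[ai[is_adr]], "adr")
  tokenized_post(post_id, rendered, label)
}

tokenized_post <- function(post_id, tokens, label = NA_real_) {
  structure(list(post_id = as.character(post_id),
                 tokens = as.character(tokens),
                 label = as.numeric(label)),
            class = "adr_tokens")
}

#' Preprocess a whole corpus
#'
#' Runs [normalize()], [tokenize()] and [tag_and_filter()] over every post.
#' Posts whose token sequence is empty after stop-word removal are excluded
#' from the result and counted in the `n_excluded_empty` attribute, mirroring
#' how raw collections shrink during preprocessing.
#'
#' @param x an `adr_corpus`.
#' @param drug,adr,stop `adr_lexicon` objects.
#' @param tokenizer optional tokenizer plugin (see [tokenize()]).
#' @return A list of `adr_tokens` (class `adr_tokens_list`) with attributes
#'   `n_input` and `n_excluded_empty`.
#' @export
preprocess_corpus <- function(x, drug, adr, stop, tokenizer = NULL) {
  stopifnot(inherits(x, "adr_corpus"))
  check_lexicon_collisions(drug, adr, stop)
  p <- x$posts
  lexs <- list(drug, adr, stop)
  out <- vector("list", nrow(p))
  k <- 0
  for (i in seq_len(nrow(p))) {
    toks <- tokenize(normalize(p$text[i]), lexicons = lexs, tokenizer = tokenizer)
    tp <- tag_and_filter(toks, drug, adr, stop, post_id = p$id[i],
                         label = p$label[i])
    if (length(tp$tokens) == 0) next  # excluded downstream, counted below
    k <- k + 1
    out[[k]] <- tp
  }
  structure(out[seq_len(k)], class = "adr_tokens_list",
            n_input = nrow(p), n_excluded_empty = nrow(p) - k)
}

#' Write / read tokenized posts as JSON-lines
#'
#' One `adr_tokens` record per line with fields `post_id`, `tokens`
#' (rendered strings), `label`.
#'
#' @param x an `adr_tokens_list`.
#' @param path file path.
#' @return `write_tokens()`: `path` invisibly; `read_tokens()`: an
#'   `adr_tokens_list`.
#' @export
write_tokens <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (tp in x) {
    rec <- list(post_id = tp$post_id, tokens = tp$tokens)
    if (!is.na(tp$label)) rec$label <- tp$label
    writeLines(enc2utf8(jsonlite::toJSON(rec, auto_unbox = TRUE)), con,
               useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_tokens
#' @export
read_tokens <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    tokenized_post(obj$post_id, as.character(obj$tokens %||% character(0)),
                   obj$label %||% NA_real_)
  })
  structure(out, class = "adr_tokens_list",
            n_input = length(out), n_excluded_empty = 0L)
}
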