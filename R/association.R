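#' Build market-basket transactions from tokenized posts
#'
#' Each post becomes one transaction: the set of distinct tagged drug/ADR
#' terms it contains (rendered strings such as `"ketotop_1_drug"`). Posts
#' with no tagged terms are omitted and counted in the `n_omitted` attribute.
#'
#' @param posts an `adr_tokens_list`.
#' @return A list of transactions (class `adr_transactions`), each a list
#'   with `post_id` and `items` (character set), with attribute `n_omitted`.
#' @export
build_transactions <- function(posts) {
  out <- vector("list", length(posts))
  k <- 0
  for (tp in posts) {
    items <- unique(tp$tokens[is_tagged(tp$tokens)])
    if (length(items) == 0) next
    k <- k + 1
    out[[k]] <- list(post_id = tp$post_id, items = items)
  }
  structure(out[seq_len(k)], class = "adr_transactions",
            n_omitted = length(posts) - k)
}

#' Mine drug-to-ADR association rules
#'
#' Enumerates all single-antecedent, single-consequent rules drug -> ADR over
#' the transactions and keeps those meeting the support and confidence
#' thresholds. Definitions follow standard association analysis:
#' support = n(drug & ADR)/N, confidence = support/support(drug),
#' lift = confidence/support(ADR). Lift is reported but not used for
#' filtering. The defaults are the thresholds used for consumer-post
#' pharmacovigilance screening (support 0.01, confidence 0.6).
#'
#' @param transactions an `adr_transactions` collection (non-empty).
#' @param min_support minimum joint support in (0, 1].
#' @param min_confidence minimum confidence in (0, 1].
#' @return data.frame (class `adr_rules`) with columns `antecedent`,
#'   `consequent`, `support`, `confidence`, `lift`, `n_joint`, sorted by
#'   confidence desc, support desc, then antecedent/consequent
#'   lexicographically.
#' @export
mine_rules <- function(transactions, min_support = 0.01, min_confidence = 0.6) {
  N <- length(transactions)
  if (N == 0)
    abort_adr("cannot mine rules from an empty transaction set", "adr_validation_error")
  stopifnot(min_support > 0, min_support <= 1,
            min_confidence > 0, min_confidence <= 1)

  post_items <- lapply(transactions, `[[`, "items")
  tid <- rep(seq_len(N), lengths(post_items))
  item <- unlist(post_items, use.names = FALSE)
  cls <- ifelse(grepl("_drug$", item), "drug", "adr")

  drug_counts <- table(item[cls == "drug"])
  adr_counts <- table(item[cls == "adr"])
  if (length(drug_counts) == 0 || length(adr_counts) == 0)
    return(empty_rules())

  # joint counts: per transaction, cross its drugs with its ADRs
  dt <- split(item[cls == "drug"], tid[cls == "drug"])
  at <- split(item[cls == "adr"], tid[cls == "adr"])
  common <- intersect(names(dt), names(at))
  if (length(common) == 0) return(empty_rules())
  pairs <- do.call(rbind, lapply(common, function(t)
    expand.grid(antecedent = dt[[t]], consequent = at[[t]],
                stringsAsFactors = FALSE)))
  key <- paste(pairs$antecedent, pairs$consequent, sep = "\r")
  joint <- table(key)

  ante <- sub("\r.*$", "", names(joint))
  cons <- sub("^.*\r", "", names(joint))
  n_joint <- as.integer(joint)
  support <- n_joint / N
  confidence <- n_joint / as.integer(drug_counts[ante])
  lift <- confidence / (as.integer(adr_counts[cons]) / N)

  keep <- support >= min_support & confidence >= min_confidence
  res <- data.frame(antecedent = ante[keep], consequent = cons[keep],
                    support = support[keep], confidence = confidence[keep],
                    lift = lift[keep], n_joint = n_joint[keep],
                    stringsAsFactors = FALSE)
  res <- res[order(-res$confidence, -res$support, res$antecedent, res$consequent), ]
  rownames(res) <- NULL
  structure(res, class = c("adr_rules", "data.frame"), n_transactions = N)
}

empty_rules <- function() {
  structure(data.frame(antecedent = character(0), consequent = character(0),
                       support = numeric(0), confidence = numeric(0),
                       lift = numeric(0), n_joint = integer(0),
                       stringsAsFactors = FALSE),
            class = c("adr_rules", "data.frame"), n_transactions = 0L)
}

#' Filter posts to those containing a significant drug-ADR pair
#'
#' Retains exactly the posts whose tagged-term set contains both members of
#' at least one mined rule; order is preserved. The retained/dropped counts
#' are recorded in attributes for the run report.
#'
#' @param posts an `adr_tokens_list`.
#' @param rules an `adr_rules` data.frame (non-empty).
#' @return The retained `adr_tokens_list` with attributes `n_retained` and
#'   `n_dropped`.
#' @export
filter_posts <- function(posts, rules) {
  stopifnot(inherits(rules, "data.frame"))
  if (nrow(rules) == 0)
    abort_adr("cannot filter with an empty rule set", "adr_validation_error")
  keep <- vapply(posts, function(tp) {
    items <- unique(tp$tokens[is_tagged(tp$tokens)])
    any(rules$antecedent %in% items & rules$consequent %in% items)
  }, logical(1))
  structure(posts[keep], class = "adr_tokens_list",
            n_input = length(posts),
            n_excluded_empty = attr(posts, "n_excluded_empty") %||% 0L,
            n_retained = sum(keep), n_dropped = sum(!keep))
}

#' Write / read a rule report as a tab-separated table
#'
#' @param rules an `adr_rules` data.frame.
#' @param path file path.
#' @return `write_rules()`: `path` invisibly; `read_rules()`: `adr_rules`.
#' @export
write_rules <- function(rules, path) {
  utils::write.table(as.data.frame(rules), path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          encoding = "UTF-8")
  structure(df, class = c("adr_rules", "data.frame"))
}
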