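#' Train skip-gram word embeddings
#'
#' A native implementation of word2vec's skip-gram model with negative
#' sampling, trained by mini-batch SGD with a linearly decaying learning
#' rate. Tagged terms are single vocabulary items, so `"ketotop_1_drug"`
#' gets one vector. Defaults follow common word2vec practice (window 5,
#' min_count 1, 5 epochs, 5 negative samples); the embedding dimension
#' defaults to 300, the setting used for consumer-post ADR corpora.
#' Training is deterministic given the seed.
#'
#' @param posts an `adr_tokens_list` (typically the association-filtered
#'   posts).
#' @param dim embedding dimension (>= 2).
#' @param window symmetric context window in tokens.
#' @param min_count minimum corpus frequency for vocabulary inclusion.
#' @param epochs passes over the pair set.
#' @param negative negative samples per positive pair.
#' @param learning_rate initial SGD step size.
#' @param seed RNG seed for initialization, shuffling and negative sampling.
#' @return An object of class `adr_embedding`: list with `vocab` (character),
#'   `vectors` (|V| x dim numeric matrix, rows named by term) and `params`.
#' @export
train_embeddings <- function(posts, dim = 300, window = 5, min_count = 1,
                             epochs = 5, negative = 5, learning_rate = 0.025,
                             seed = 1) {
  if (length(posts) == 0)
    abort_adr("cannot train embeddings on an empty corpus", "adr_validation_error")
  stopifnot(dim >= 2, window >= 1, min_count >= 1, epochs >= 1, negative >= 1)

  sentences <- lapply(posts, `[[`, "tokens")
  freq <- table(unlist(sentences, use.names = FALSE))
  freq <- freq[freq >= min_count]
  if (length(freq) < 2)
    abort_adr("fewer than 2 vocabulary terms after min_count filtering",
              "adr_validation_error")
  # frequency-desc, lexicographic tie-break: deterministic vocabulary order
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  vocab <- names(freq)[ord]
  counts <- as.numeric(freq)[ord]
  V <- length(vocab)

  # skip-gram training pairs with a fixed symmetric window
  idx_sent <- lapply(sentences, function(s) {
    i <- match(s, vocab)
    i[!is.na(i)]
  })
  centers <- integer(0); contexts <- integer(0)
  cl <- vector("list", length(idx_sent))
  for (si in seq_along(idx_sent)) {
    s <- idx_sent[[si]]
    n <- length(s)
    if (n < 2) next
    cc <- vector("list", n)
    for (i in seq_len(n)) {
      lo <- max(1, i - window); hi <- min(n, i + window)
      ctx <- s[setdiff(lo:hi, i)]
      cc[[i]] <- rbind(rep.int(s[i], length(ctx)), ctx)
    }
    cl[[si]] <- do.call(cbind, cc)
  }
  pairs <- do.call(cbind, cl[!vapply(cl, is.null, logical(1))])
  if (is.null(pairs) || ncol(pairs) == 0)
    abort_adr("no skip-gram training pairs (all posts have < 2 in-vocabulary tokens)",
              "adr_validation_error")
  centers <- pairs[1, ]; contexts <- pairs[2, ]
  P <- length(centers)

  # unigram^0.75 negative-sampling distribution
  neg_prob <- counts^0.75
  neg_prob <- neg_prob / sum(neg_prob)

  set.seed(seed)
  W_in <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim)
  W_out <- matrix(0, V, dim)

  batch <- 256L
  n_batches_total <- epochs * ceiling(P / batch)
  step <- 0L
  for (ep in seq_len(epochs)) {
    perm <- sample.int(P)
    for (b0 in seq(1, P, by = batch)) {
      step <- step + 1L
      lr <- learning_rate * max(1e-4, 1 - (step - 1) / n_batches_total)
      sel <- perm[b0:min(b0 + batch - 1, P)]
      nb <- length(sel)
      c_i <- centers[sel]
      o_i <- contexts[sel]
      negs <- matrix(sample.int(V, nb * negative, replace = TRUE, prob = neg_prob),
                     nb, negative)

      vc <- W_in[c_i, , drop = FALSE]
      # positive pair: label 1
      vo <- W_out[o_i, , drop = FALSE]
      g_pos <- sigmoid(rowSums(vc * vo)) - 1        # dL/dscore
      d_vc <- g_pos * vo
      d_out_rows <- c(o_i)
      d_out_vals <- g_pos * vc
      # negatives: label 0
      for (k in seq_len(negative)) {
        nk <- negs[, k]
        vn <- W_out[nk, , drop = FALSE]
        g_neg <- sigmoid(rowSums(vc * vn))
        d_vc <- d_vc + g_neg * vn
        d_out_rows <- c(d_out_rows, nk)
        d_out_vals <- rbind(d_out_vals, g_neg * vc)
      }
      # aggregate duplicate-row gradients, then apply
      gi <- rowsum(d_vc, group = c_i)
      ri <- as.integer(rownames(gi))
      W_in[ri, ] <- W_in[ri, ] - lr * gi
      go <- rowsum(d_out_vals, group = d_out_rows)
      ro <- as.integer(rownames(go))
      W_out[ro, ] <- W_out[ro, ] - lr * go
    }
  }
  # final vectors: mean of input and output matrices. The input matrix alone
  # encodes paradigmatic similarity (shared contexts); averaging in the
  # output matrix mixes in syntagmatic association, so terms that habitually
  # co-occur (a drug and its ADR) also land near each other -- the behaviour
  # expected of similarity queries over consumer-post corpora.
  W <- (W_in + W_out) / 2
  rownames(W) <- vocab
  structure(list(vocab = vocab, vectors = W,
                 params = list(mode = "skip-gram", dim = dim, window = window,
                               min_count = min_count, epochs = epochs,
                               negative = negative,
                               learning_rate = learning_rate, seed = seed)),
            class = "adr_embedding")
}

check_in_vocab <- function(model, term) {
  i <- match(term, model$vocab)
  if (is.na(i))
    abort_adr(sprintf("term not in embedding vocabulary: '%s'", term),
              "adr_oov_error")
  i
}

#' Cosine similarity between two embedded terms
#'
#' @param model an `adr_embedding`.
#' @param a,b vocabulary terms.
#' @return A number in \[-1, 1\]; symmetric, and `cosine_similarity(m, a, a)`
#'   is 1 within 1e-6. Errors on out-of-vocabulary terms, naming the term.
#' @export
cosine_similarity <- function(model, a, b) {
  va <- model$vectors[check_in_vocab(model, a), ]
  vb <- model$vectors[check_in_vocab(model, b), ]
  sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

#' Nearest neighbors of a term by cosine similarity
#'
#' @param model an `adr_embedding`.
#' @param term query term (excluded from the result).
#' @param k number of neighbors (>= 1).
#' @return data.frame with columns `term` and `similarity`, in non-increasing
#'   similarity order, ties broken lexicographically. `k >= |V| - 1` returns
#'   the full ranking.
#' @export
nearest_neighbors <- function(model, term, k = 10) {
  stopifnot(k >= 1)
  qi <- check_in_vocab(model, term)
  M <- model$vectors
  nrm <- sqrt(rowSums(M^2))
  sims <- as.vector(M %*% M[qi, ]) / (nrm * nrm[qi])
  sims[qi] <- -Inf
  ord <- order(-sims, model$vocab, method = "radix")
  take <- ord[seq_len(min(k, length(model$vocab) - 1))]
  data.frame(term = model$vocab[take], similarity = sims[take],
             stringsAsFactors = FALSE)
}

#' Write / read embeddings in the word2vec text vector format
#'
#' First line `"<count> <dim>"`, then one `term v1 ... vd` line per term.
#'
#' @param model an `adr_embedding`.
#' @param path file path.
#' @return `write_embeddings()`: `path` invisibly; `read_embeddings()`: an
#'   `adr_embedding` (with empty training params).
#' @export
write_embeddings <- function(model, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  V <- length(model$vocab)
  writeLines(sprintf("%d %d", V, ncol(model$vectors)), con, useBytes = TRUE)
  for (i in seq_len(V)) {
    writeLines(enc2utf8(paste(model$vocab[i],
                              paste(format(model$vectors[i, ], digits = 17,
                                           scientific = TRUE, trim = TRUE),
                                    collapse = " "))),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  V <- hdr[1]; d <- hdr[2]
  vocab <- character(V)
  M <- matrix(0, V, d)
  for (i in seq_len(V)) {
    parts <- strsplit(lines[i + 1], " ", fixed = TRUE)[[1]]
    vocab[i] <- parts[1]
    M[i, ] <- as.numeric(parts[-1])
  }
  rownames(M) <- vocab
  structure(list(vocab = vocab, vectors = M, params = list(dim = d)),
            class = "adr_embedding")
}
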