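#' Build a frequency-based integer encoding of the vocabulary
#'
#' Terms are ranked by descending corpus frequency (ties broken
#' lexicographically) and assigned dense integer indices starting at 2;
#' indices 0 and 1 are reserved for padding and out-of-vocabulary tokens.
#' The encoding is deterministic: re-running on the same corpus yields the
#' identical mapping.
#'
#' @param posts an `adr_tokens_list` (non-empty).
#' @return An object of class `adr_encoding`: list with `index` (named
#'   integer vector term -> index) and `vocab_size` (number of indices
#'   including the two reserved ones).
#' @export
build_vocabulary <- function(posts) {
  if (length(posts) == 0)
    abort_adr("cannot build a vocabulary from an empty stream", "adr_validation_error")
  freq <- table(unlist(lapply(posts, `[[`, "tokens"), use.names = FALSE))
  ord <- order(-as.integer(freq), names(freq), method = "radix")
  terms <- names(freq)[ord]
  index <- stats::setNames(seq_along(terms) + 1L, terms)
  structure(list(index = index, vocab_size = length(terms) + 2L),
            class = "adr_encoding")
}

#' Encode tokenized posts as fixed-length padded integer sequences
#'
#' Tokens are mapped through the encoding (unknown terms to the OOV index 1),
#' sequences are left-padded with 0 to length `max_len`, and longer
#' sequences are truncated at the tail.
#'
#' @param posts an `adr_tokens_list`.
#' @param encoding an `adr_encoding` from [build_vocabulary()].
#' @param max_len either `"auto"` (the maximum sequence length in `posts`)
#'   or a positive integer.
#' @return An object of class `adr_encoded`: list with `ids` (n x L integer
#'   matrix), `label` (numeric, `NA` where unlabeled), `post_id`, `max_len`
#'   and `vocab_size`.
#' @export
encode_and_pad <- function(posts, encoding, max_len = "auto") {
  stopifnot(inherits(encoding, "adr_encoding"))
  seqs <- lapply(posts, function(tp) {
    i <- unname(encoding$index[tp$tokens])
    i[is.na(i)] <- 1L  # OOV
    as.integer(i)
  })
  if (identical(max_len, "auto")) {
    L <- max(1L, max(lengths(seqs)))
  } else {
    L <- as.integer(max_len)
    stopifnot(L >= 1)
  }
  ids <- matrix(0L, length(seqs), L)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (length(s) > L) s <- s[seq_len(L)]  # tail truncation
    if (length(s) > 0) ids[i, (L - length(s) + 1L):L] <- s
  }
  structure(list(ids = ids,
                 label = vapply(posts, `[[`, 0, "label"),
                 post_id = vapply(posts, `[[`, "", "post_id"),
                 max_len = L, vocab_size = encoding$vocab_size,
                 index = encoding$index),
            class = "adr_encoded")
}

subset_encoded <- function(x, i) {
  structure(list(ids = x$ids[i, , drop = FALSE], label = x$label[i],
                 post_id = x$post_id[i], max_len = x$max_len,
                 vocab_size = x$vocab_size, index = x$index),
            class = "adr_encoded")
}

#' Stratified train/test split
#'
#' Splits labeled encoded posts into train and test sets at the given ratio,
#' stratified by label so both splits preserve the class balance within
#' rounding. Reproducible under the seed.
#'
#' @param x an `adr_encoded` collection, fully labeled.
#' @param ratio train fraction in (0, 1); the conventional split is 7:3.
#' @param seed RNG seed.
#' @return list with elements `train` and `test`, both `adr_encoded`.
#' @export
split_train_test <- function(x, ratio = 0.7, seed = 1) {
  stopifnot(inherits(x, "adr_encoded"), ratio > 0, ratio < 1)
  if (anyNA(x$label))
    abort_adr("split_train_test requires every post to be labeled",
              "adr_validation_error")
  cls <- split(seq_along(x$label), x$label)
  if (any(lengths(cls) < 2))
    abort_adr(sprintf("each class needs >= 2 members (got %s)",
                      paste(lengths(cls), collapse = "/")),
              "adr_validation_error")
  set.seed(seed)
  # largest-remainder allocation: per-class counts sum to round(ratio * N)
  target <- round(ratio * length(x$label))
  base <- vapply(cls, function(ix) floor(ratio * length(ix)), 0)
  rem <- vapply(cls, function(ix) ratio * length(ix), 0) - base
  extra <- target - sum(base)
  if (extra > 0) {
    give <- order(-rem, names(cls))[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  train_idx <- sort(unlist(Map(function(ix, k) sample(ix)[seq_len(k)],
                               cls, base), use.names = FALSE))
  test_idx <- setdiff(seq_along(x$label), train_idx)
  list(train = subset_encoded(x, train_idx), test = subset_encoded(x, test_idx))
}

#' Classifier configuration
#'
#' Bundles every tunable of the recurrent ADR-post classifier. The defaults
#' are the headline settings for this task: a bidirectional LSTM with 256
#' hidden units per direction, 300-dimensional embeddings, Adam with
#' learning rate 0.001, batch size 64, 50 epochs, decision threshold 0.5 and
#' a 7:3 train/test split.
#'
#' @param architecture `"bilstm"`, `"gru"` (bidirectional), or
#'   `"cnn_bilstm"` (width-3 conv, 128 filters, ReLU, width-2 max-pool, then
#'   the Bi-LSTM).
#' @param hidden_units recurrent state size per direction.
#' @param embedding_dim embedding dimension.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param threshold decision threshold in \[0, 1\].
#' @param split_ratio train fraction in (0, 1).
#' @param seed RNG seed for initialization and batching.
#' @param early_stopping if `TRUE`, monitor a 10\% validation split carved
#'   from the training set and stop after `patience` epochs without
#'   improvement.
#' @param patience early-stopping patience in epochs.
#' @param freeze_embeddings if `TRUE`, do not fine-tune the embedding layer.
#' @param dropout dropout rate on the pooled representation (0 disables).
#' @param cnn_filters convolution filters for the `cnn_bilstm` variant.
#' @return list of class `adr_model_config`.
#' @export
model_config <- function(architecture = c("bilstm", "gru", "cnn_bilstm"),
                         hidden_units = 256, embedding_dim = 300,
                         learning_rate = 0.001, batch_size = 64, epochs = 50,
                         threshold = 0.5, split_ratio = 0.7, seed = 1,
                         early_stopping = FALSE, patience = 5,
                         freeze_embeddings = FALSE, dropout = 0,
                         cnn_filters = 128) {
  architecture <- match.arg(architecture)
  stopifnot(threshold >= 0, threshold <= 1, split_ratio > 0, split_ratio < 1,
            hidden_units >= 1, embedding_dim >= 2, epochs >= 0,
            dropout >= 0, dropout < 1)
  structure(list(architecture = architecture,
                 hidden_units = as.integer(hidden_units),
                 embedding_dim = as.integer(embedding_dim),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), threshold = threshold,
                 split_ratio = split_ratio, seed = as.integer(seed),
                 early_stopping = isTRUE(early_stopping),
                 patience = as.integer(patience),
                 freeze_embeddings = isTRUE(freeze_embeddings),
                 dropout = dropout, cnn_filters = as.integer(cnn_filters)),
            class = "adr_model_config")
}

embedding_init_matrix <- function(encoding, emb, dim) {
  M <- matrix(NA_real_, encoding$vocab_size, dim)
  if (is.null(emb)) return(M)
  if (ncol(emb$vectors) != dim)
    abort_adr(sprintf("embedding dim %d does not match config embedding_dim %d",
                      ncol(emb$vectors), dim), "adr_validation_error")
  hit <- intersect(names(encoding$index), emb$vocab)
  if (length(hit) > 0)
    M[encoding$index[hit] + 1L, ] <- emb$vectors[hit, , drop = FALSE]
  M
}

#' Train the recurrent ADR-post classifier
#'
#' A many-to-one sequence model: embedding layer (optionally initialized from
#' skip-gram vectors where the vocabularies overlap, and fine-tuned unless
#' frozen), recurrent layers in both directions whose final states are
#' concatenated, and a single sigmoid output trained with binary
#' cross-entropy and Adam. Scoring a fixed model is deterministic.
#'
#' @param train an `adr_encoded` training set containing both classes.
#' @param config an [model_config()].
#' @param init_vectors optional `adr_embedding` used to initialize the
#'   embedding layer.
#' @return An object of class `adr_model`: list with `config`, `params`,
#'   `training_log` (data.frame epoch/loss, plus `val_loss` when early
#'   stopping), `trained` flag, and the `vocab_size`/`max_len` the model
#'   expects.
#' @export
train_classifier <- function(train, config = model_config(),
                             init_vectors = NULL) {
  stopifnot(inherits(train, "adr_encoded"), inherits(config, "adr_model_config"))
  if (anyNA(train$label))
    abort_adr("training set must be fully labeled", "adr_validation_error")
  if (length(unique(train$label)) < 2)
    abort_adr("training set contains a single class", "adr_validation_error")

  init_E <- if (is.null(init_vectors)) NULL else
    embedding_init_matrix(list(index = train$index,
                               vocab_size = train$vocab_size),
                          init_vectors, config$embedding_dim)

  params <- nn_init_params(config$architecture, train$vocab_size,
                           config$embedding_dim, config$hidden_units,
                           config$cnn_filters, seed = config$seed,
                           init_E = init_E)

  model <- structure(list(config = config, params = params,
                          training_log = data.frame(epoch = integer(0),
                                                    loss = numeric(0)),
                          trained = FALSE, vocab_size = train$vocab_size,
                          max_len = train$max_len),
                     class = "adr_model")
  if (config$epochs == 0) return(model)  # untrained but scoreable

  ids <- train$ids; y <- train$label
  val <- NULL
  if (config$early_stopping) {
    set.seed(derive_seed(config$seed, 97L))
    n_val <- max(1L, floor(0.1 * length(y)))
    vi <- sample(seq_along(y), n_val)
    val <- list(ids = ids[vi, , drop = FALSE], y = y[vi])
    ids <- ids[-vi, , drop = FALSE]; y <- y[-vi]
  }

  n <- length(y)
  state <- adam_init(params)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    val_loss = numeric(0))
  best_val <- Inf; best_params <- params; bad_epochs <- 0L
  set.seed(derive_seed(config$seed, 11L))
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1, n, by = config$batch_size)) {
      sel <- perm[b0:min(b0 + config$batch_size - 1, n)]
      fw <- nn_forward(ids[sel, , drop = FALSE], params, config$architecture,
                       dropout = config$dropout, train_mode = TRUE)
      ep_loss <- ep_loss + nn_loss(fw$p, y[sel]) * length(sel)
      gr <- nn_backward(y[sel], fw$p, fw$cache, params, config$architecture,
                        freeze_embeddings = config$freeze_embeddings)
      upd <- adam_step(params, gr, state, lr = config$learning_rate)
      params <- upd$params; state <- upd$state
      params$E[1, ] <- 0
    }
    vl <- NA_real_
    if (!is.null(val)) {
      pv <- nn_forward(val$ids, params, config$architecture)$p
      vl <- nn_loss(pv, val$y)
      if (vl < best_val - 1e-6) {
        best_val <- vl; best_params <- params; bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n, val_loss = vl))
    if (!is.null(val) && bad_epochs >= config$patience) {
      params <- best_params
      break
    }
  }
  if (!is.null(val) && best_val < Inf && bad_epochs >= config$patience) {
    # already restored above
  }
  model$params <- params
  model$training_log <- log
  model$trained <- TRUE
  model
}

#' Score encoded posts with a trained model
#'
#' @param model an `adr_model`.
#' @param posts an `adr_encoded` collection encoded with the model's
#'   vocabulary and sequence length.
#' @return numeric vector of sigmoid scores in \[0, 1\], one per post, in
#'   input order. Batch scoring equals one-at-a-time scoring.
#' @export
predict_proba <- function(model, posts) {
  stopifnot(inherits(model, "adr_model"), inherits(posts, "adr_encoded"))
  if (posts$max_len != model$max_len)
    abort_adr(sprintf("sequence length %d does not match the model's %d",
                      posts$max_len, model$max_len), "adr_validation_error")
  n <- nrow(posts$ids)
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  for (b0 in seq(1, n, by = 256)) {
    sel <- b0:min(b0 + 255, n)
    out[sel] <- nn_forward(posts$ids[sel, , drop = FALSE], model$params,
                           model$config$architecture)$p
  }
  out
}

#' Threshold scores into binary predictions
#'
#' @param scores numeric scores in \[0, 1\].
#' @param threshold decision threshold in \[0, 1\]; a post is predicted ADR
#'   (1) iff its score is >= the threshold.
#' @return integer vector of 0/1 predictions.
#' @export
classify <- function(scores, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1)
    abort_adr("threshold must be a single number in [0, 1]", "adr_validation_error")
  stopifnot(all(scores >= 0 & scores <= 1))
  as.integer(scores >= threshold)
}

#' @export
print.adr_model <- function(x, ...) {
  cat(sprintf("<adr_model arch=%s hidden=%d %s>\n", x$config$architecture,
              x$config$hidden_units,
              if (x$trained) sprintf("trained %d epochs", nrow(x$training_log))
              else "UNTRAINED"))
  invisible(x)
}
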