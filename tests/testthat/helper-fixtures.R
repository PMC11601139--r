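# Shared fixtures and independent oracles. Everything is built in code at
# test time; no binary fixtures.

tiny_lexicons <- function() {
  list(
    drug = lexicon(c("ketotop", "antiphlamine"), "drug",
                   term_id = c(1L, 6L),
                   canonical = c("ketoprofen", "ketoprofen")),
    adr = lexicon(c("blisters", "itch", "muscle pain", "rash"), "adr",
                  term_id = c(153L, 156L, 201L, 12L)),
    stop = lexicon(c("and", "the", "i"), "stopword")
  )
}

# build an adr_tokens_list straight from rendered token vectors
tokens_list <- function(..., labels = NULL) {
  seqs <- list(...)
  out <- lapply(seq_along(seqs), function(i)
    adrminer:::tokenized_post(sprintf("p%d", i), seqs[[i]],
                              if (is.null(labels)) NA_real_ else labels[i]))
  structure(out, class = "adr_tokens_list",
            n_input = length(out), n_excluded_empty = 0L)
}

# random transaction fixture for rule-mining oracle comparisons
random_transactions <- function(seed, max_posts = 200, max_terms = 20) {
  set.seed(seed)
  n <- sample(5:max_posts, 1)
  n_drug <- sample(1:(max_terms %/% 2), 1)
  n_adr <- sample(1:(max_terms %/% 2), 1)
  drugs <- sprintf("d%02d_%d_drug", seq_len(n_drug), seq_len(n_drug))
  adrs <- sprintf("a%02d_%d_ADR", seq_len(n_adr), seq_len(n_adr))
  posts <- lapply(seq_len(n), function(i) {
    nd <- sample(0:min(3, n_drug), 1)
    na <- sample(0:min(3, n_adr), 1)
    c(sample(drugs, nd), sample(adrs, na), "filler")
  })
  do.call(tokens_list, posts)
}

# brute-force association-rule oracle: direct counting over every
# drug x ADR pair, no shared code with mine_rules()
oracle_rules <- function(transactions, min_support, min_confidence) {
  items <- lapply(transactions, `[[`, "items")
  N <- length(items)
  drugs <- sort(unique(unlist(lapply(items, function(x) grep("_drug$", x, value = TRUE)))))
  adrs <- sort(unique(unlist(lapply(items, function(x) grep("_ADR$", x, value = TRUE)))))
  res <- list()
  for (d in drugs) for (a in adrs) {
    n_d <- sum(vapply(items, function(x) d %in% x, logical(1)))
    n_a <- sum(vapply(items, function(x) a %in% x, logical(1)))
    n_da <- sum(vapply(items, function(x) d %in% x && a %in% x, logical(1)))
    if (n_d == 0 || n_da == 0) next
    supp <- n_da / N
    conf <- n_da / n_d
    if (supp >= min_support && conf >= min_confidence)
      res[[length(res) + 1]] <- data.frame(
        antecedent = d, consequent = a, support = supp, confidence = conf,
        lift = conf / (n_a / N), n_joint = n_da, stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(antecedent = character(0), consequent = character(0),
                      support = numeric(0), confidence = numeric(0),
                      lift = numeric(0), n_joint = integer(0)))
  df <- do.call(rbind, res)
  df <- df[order(-df$confidence, -df$support, df$antecedent, df$consequent), ]
  rownames(df) <- NULL
  df
}

# Mann-Whitney AUC oracle with tie correction (rank-statistic formulation)
auc_rank_oracle <- function(y, scores) {
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# finite-difference gradient checker for the native networks
fd_gradient_worst_err <- function(arch, seed = 42, n = 4, T_ = 5, V = 12,
                                  d = 4, H = 3) {
  set.seed(seed)
  ids <- matrix(sample(0:(V - 1), n * T_, TRUE), n, T_)
  ids[1, 1:2] <- 0L  # left padding present
  y <- sample(0:1, n, TRUE)
  p <- adrminer:::nn_init_params(arch, V, d, H, cnn_filters = 4, seed = 7)
  fw <- adrminer:::nn_forward(ids, p, arch)
  g <- adrminer:::nn_backward(y, fw$p, fw$cache, p, arch)
  loss_at <- function(pp) adrminer:::nn_loss(adrminer:::nn_forward(ids, pp, arch)$p, y)
  eps <- 1e-6
  worst <- 0
  groups <- c("fwd", "bwd", "out", if (arch == "cnn_bilstm") "conv")
  for (nm1 in groups) {
    for (nm2 in names(p[[nm1]])) {
      x <- p[[nm1]][[nm2]]; gx <- g[[nm1]][[nm2]]
      for (i in sample(length(x), min(5, length(x)))) {
        p2 <- p; p3 <- p
        p2[[nm1]][[nm2]][i] <- x[i] + eps
        p3[[nm1]][[nm2]][i] <- x[i] - eps
        num <- (loss_at(p2) - loss_at(p3)) / (2 * eps)
        worst <- max(worst, abs(num - gx[i]) / max(1e-5, abs(num), abs(gx[i])))
      }
    }
  }
  # embedding rows except the frozen padding row
  nonpad <- setdiff(seq_len(V * d), seq(1, V * d, by = V))
  for (i in sample(nonpad, 10)) {
    p2 <- p; p3 <- p
    p2$E[i] <- p$E[i] + eps; p3$E[i] <- p$E[i] - eps
    num <- (loss_at(p2) - loss_at(p3)) / (2 * eps)
    worst <- max(worst, abs(num - g$E[i]) / max(1e-5, abs(num), abs(g$E[i])))
  }
  worst
}

# small linearly separable encoded dataset: positives carry a sentinel token
sentinel_dataset <- function(n = 60, seed = 1, vocab = 12, len = 8) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  posts <- lapply(seq_len(n), function(i) {
    toks <- sprintf("w%02d", sample(3:vocab, len - 1, TRUE))
    if (y[i] == 1) toks[sample(len - 1, 1)] <- "sentinel"
    adrminer:::tokenized_post(sprintf("p%d", i), toks, y[i])
  })
  posts <- structure(posts, class = "adr_tokens_list")
  enc <- build_vocabulary(posts)
  encode_and_pad(posts, enc)
}
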