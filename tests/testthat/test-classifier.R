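test_that("build_vocabulary ranks by frequency with lexicographic ties", {
  tl <- tokens_list(c("a", "a", "b"), c("a", "c", "b"), c("c"))
  enc <- build_vocabulary(tl)   # counts a:3, b:2, c:2
  expect_equal(unname(enc$index[c("a", "b", "c")]), c(2L, 3L, 4L))
  expect_equal(enc$vocab_size, 5L)

  single <- build_vocabulary(tokens_list(c("only")))
  expect_equal(single$vocab_size, 3L)   # reserved 0/1 plus the term

  expect_identical(build_vocabulary(tl)$index, enc$index)
  expect_error(build_vocabulary(tokens_list()[0]),
               class = "adr_validation_error")
})

test_that("encode_and_pad left-pads, truncates at the tail, and maps OOV to 1", {
  tl <- tokens_list(c("x", "y"), labels = 1)
  enc <- build_vocabulary(tokens_list(c("x", "x", "y")))
  e <- encode_and_pad(tl, enc, max_len = 4)
  expect_equal(e$ids[1, ], c(0L, 0L, enc$index[["x"]], enc$index[["y"]]))

  e2 <- encode_and_pad(tokens_list(c("x", "zz", "y")), enc, max_len = 3)
  expect_equal(e2$ids[1, 2], 1L)        # OOV

  e3 <- encode_and_pad(tokens_list(c("x", "y", "x", "y")), enc, max_len = 2)
  expect_equal(e3$ids[1, ], unname(enc$index[c("x", "y")]))  # tail truncated

  auto <- encode_and_pad(tokens_list(c("x"), c("x", "y", "x")), enc)
  expect_equal(auto$max_len, 3L)
  expect_true(all(apply(auto$ids, 1, length) == 3))
})

test_that("split_train_test stratifies, reproduces, and validates", {
  tl <- do.call(tokens_list, c(rep(list(c("w")), 576),
                               list(labels = rep(c(1, 0), c(244, 332)))))
  e <- encode_and_pad(tl, build_vocabulary(tl))
  sp <- split_train_test(e, 0.7, seed = 3)
  # class proportions preserved within one post of 42.4%
  expect_equal(sum(sp$train$label == 1), round(0.7 * 244))
  expect_equal(sum(sp$test$label == 1), 244 - round(0.7 * 244))
  expect_length(intersect(sp$train$post_id, sp$test$post_id), 0)
  sp2 <- split_train_test(e, 0.7, seed = 3)
  expect_identical(sp$train$post_id, sp2$train$post_id)

  small <- do.call(tokens_list, c(rep(list("w"), 10),
                                  list(labels = rep(c(0, 1), 5))))
  es <- encode_and_pad(small, build_vocabulary(small))
  ss <- split_train_test(es, 0.7, seed = 1)
  expect_equal(length(ss$train$label), 7)
  expect_equal(length(ss$test$label), 3)

  lone <- do.call(tokens_list, c(rep(list("w"), 5),
                                 list(labels = c(1, 0, 0, 0, 0))))
  el <- encode_and_pad(lone, build_vocabulary(lone))
  expect_error(split_train_test(el, 0.7, 1), ">= 2 members",
               class = "adr_validation_error")
})

test_that("BPTT gradients match finite differences for every architecture", {
  for (arch in c("bilstm", "gru", "cnn_bilstm")) {
    expect_lt(fd_gradient_worst_err(arch), 1e-4, label = arch)
  }
})

test_that("the classifier fits a linearly separable sentinel task", {
  for (seed in 1:5) {
    e <- sentinel_dataset(n = 60, seed = seed)
    cfg <- model_config(hidden_units = 8, embedding_dim = 8, epochs = 10,
                        learning_rate = 0.01, batch_size = 16, seed = seed)
    m <- train_classifier(e, cfg)
    acc <- mean(classify(predict_proba(m, e)) == e$label)
    expect_gte(acc, 0.95)
  }
})

test_that("architecture variants share the train/predict contract", {
  e <- sentinel_dataset(n = 60, seed = 2)
  for (arch in c("gru", "cnn_bilstm")) {
    cfg <- model_config(architecture = arch, hidden_units = 8,
                        embedding_dim = 8, epochs = 10, learning_rate = 0.01,
                        batch_size = 16, seed = 2)
    m <- train_classifier(e, cfg)
    sc <- predict_proba(m, e)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_gte(mean(classify(sc) == e$label), 0.9, label = arch)
  }
})

test_that("training is deterministic and epochs=0 gives an untrained scorer", {
  e <- sentinel_dataset(n = 30, seed = 3)
  cfg <- model_config(hidden_units = 6, embedding_dim = 6, epochs = 4,
                      learning_rate = 0.01, batch_size = 8, seed = 9)
  m1 <- train_classifier(e, cfg)
  m2 <- train_classifier(e, cfg)
  expect_lt(abs(tail(m1$training_log$loss, 1) - tail(m2$training_log$loss, 1)),
            1e-4)

  m0 <- train_classifier(e, model_config(hidden_units = 6, embedding_dim = 6,
                                         epochs = 0, seed = 1))
  expect_false(m0$trained)
  sc <- predict_proba(m0, e)
  expect_length(sc, 30)
  expect_true(all(sc >= 0 & sc <= 1))

  one_class <- subset_e <- e
  one_class$label[] <- 1
  expect_error(train_classifier(one_class, cfg), "single class",
               class = "adr_validation_error")
})

test_that("scoring is order-stable, batch-invariant, and validates lengths", {
  e <- sentinel_dataset(n = 20, seed = 4)
  m <- train_classifier(e, model_config(hidden_units = 6, embedding_dim = 6,
                                        epochs = 3, batch_size = 8, seed = 4))
  sc <- predict_proba(m, e)
  # duplicate inputs get identical scores
  dup <- adrminer:::subset_encoded(e, c(1, 1, 5, 5))
  sd <- predict_proba(m, dup)
  expect_equal(sd[1], sd[2])
  expect_equal(sd[3], sd[4])
  # one-at-a-time equals batch
  singles <- vapply(seq_len(20), function(i)
    predict_proba(m, adrminer:::subset_encoded(e, i)), 0)
  expect_lt(max(abs(singles - sc)), 1e-6)

  wrong <- e; wrong$max_len <- e$max_len + 1L
  wrong$ids <- cbind(wrong$ids, 0L)
  expect_error(predict_proba(m, wrong), "length",
               class = "adr_validation_error")
})

test_that("word2vec initialization is accepted and dims are checked", {
  e <- sentinel_dataset(n = 30, seed = 5)
  posts <- tokens_list(c("sentinel", "w03", "w04"), c("w05", "sentinel"))
  emb <- train_embeddings(posts, dim = 6, epochs = 1, seed = 1)
  cfg <- model_config(hidden_units = 4, embedding_dim = 6, epochs = 1,
                      batch_size = 8, seed = 5)
  m <- train_classifier(e, cfg, init_vectors = emb)
  expect_true(m$trained)
  bad <- train_embeddings(posts, dim = 4, epochs = 1, seed = 1)
  expect_error(train_classifier(e, cfg, init_vectors = bad), "dim",
               class = "adr_validation_error")
})

test_that("classify thresholds correctly and is monotone", {
  expect_equal(classify(c(0.4, 0.5, 0.9), 0.5), c(0L, 1L, 1L))
  expect_equal(classify(c(0.2, 0.8, 0.999), 1.0), c(0L, 0L, 0L))
  expect_equal(classify(c(0, 0.3), 0), c(1L, 1L))
  expect_error(classify(c(0.5), 1.5), class = "adr_validation_error")
  set.seed(6)
  s <- runif(50)
  prev <- classify(s, 0)
  for (t in seq(0.1, 1, 0.1)) {
    cur <- classify(s, t)
    expect_true(all(cur <= prev))   # raising t never flips 0 -> 1
    prev <- cur
  }
})
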