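test_that("build_transactions keeps distinct tagged terms only", {
  tl <- tokens_list(c("got", "blisters_153_ADR", "ketotop_1_drug"),
                    c("itch_156_ADR", "itch_156_ADR", "wow"),
                    c("plain", "words", "only"))
  tr <- build_transactions(tl)
  expect_length(tr, 2)
  expect_setequal(tr[[1]]$items, c("blisters_153_ADR", "ketotop_1_drug"))
  expect_equal(tr[[2]]$items, "itch_156_ADR")      # set semantics
  expect_equal(attr(tr, "n_omitted"), 1L)
  expect_length(build_transactions(tokens_list(c("a", "b"))), 0)
})

test_that("mine_rules matches hand-built counting fixtures", {
  # degenerate maximum: every post contains the pair
  all_pair <- do.call(tokens_list, rep(list(c("dx_1_drug", "ay_1_ADR")), 8))
  r <- mine_rules(build_transactions(all_pair))
  expect_equal(nrow(r), 1)
  expect_equal(r$support, 1)
  expect_equal(r$confidence, 1)

  # 100-post fixture: drugX in 10 posts, {drugX, adrY} in 7, adrY in 20 total
  posts <- c(rep(list(c("dx_1_drug", "ay_1_ADR")), 7),
             rep(list("dx_1_drug"), 3),
             rep(list("ay_1_ADR"), 13),
             rep(list("zz_2_ADR"), 77))
  r <- mine_rules(build_transactions(do.call(tokens_list, posts)),
                  min_support = 0.01, min_confidence = 0.6)
  expect_equal(nrow(r), 1)
  expect_equal(r$support, 0.07)
  expect_equal(r$confidence, 0.7)
  expect_equal(r$lift, 0.7 / 0.20)
  expect_equal(r$n_joint, 7L)

  # 5 joint posts out of 1000 at min_support 0.01 -> excluded
  posts <- c(rep(list(c("dx_1_drug", "ay_1_ADR")), 5),
             rep(list("w_9_ADR"), 995))
  r <- mine_rules(build_transactions(do.call(tokens_list, posts)))
  expect_equal(nrow(r), 0)

  expect_error(mine_rules(build_transactions(tokens_list(c("x")))),
               "empty", class = "adr_validation_error")
})

test_that("mine_rules equals the exhaustive-enumeration oracle", {
  for (seed in 1:25) {
    tr <- build_transactions(random_transactions(seed))
    if (length(tr) == 0) next
    ms <- sample(c(0.01, 0.05, 0.2), 1)
    mc <- sample(c(0.3, 0.6), 1)
    got <- as.data.frame(mine_rules(tr, ms, mc))
    want <- oracle_rules(tr, ms, mc)
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE,
                 info = paste("seed", seed))
  }
})

test_that("raising either threshold never adds a rule", {
  for (seed in c(3, 14)) {
    tr <- build_transactions(random_transactions(seed))
    if (length(tr) == 0) next
    base <- mine_rules(tr, 0.01, 0.3)
    key <- function(r) paste(r$antecedent, r$consequent)
    for (ms in c(0.05, 0.1, 0.3)) {
      expect_true(all(key(mine_rules(tr, ms, 0.3)) %in% key(base)))
    }
    for (mc in c(0.5, 0.7, 0.9)) {
      expect_true(all(key(mine_rules(tr, 0.01, mc)) %in% key(base)))
    }
  }
})

test_that("filter_posts retains exactly the posts holding a rule pair", {
  tl <- tokens_list(c("dx_1_drug", "ay_1_ADR", "w"),   # pair -> retained
                    c("dx_1_drug", "w"),               # drug only -> dropped
                    c("ay_1_ADR"),                     # adr only -> dropped
                    c("dx_1_drug", "zz_2_ADR"))        # wrong pair -> dropped
  rules <- structure(data.frame(antecedent = "dx_1_drug",
                                consequent = "ay_1_ADR",
                                support = 0.5, confidence = 1, lift = 2,
                                n_joint = 1L, stringsAsFactors = FALSE),
                     class = c("adr_rules", "data.frame"))
  kept <- filter_posts(tl, rules)
  expect_equal(vapply(kept, `[[`, "", "post_id"), "p1")
  expect_equal(attr(kept, "n_retained"), 1L)
  expect_equal(attr(kept, "n_dropped"), 3L)
  expect_error(filter_posts(tl, adrminer:::empty_rules()),
               class = "adr_validation_error")
})

test_that("filtering equals a brute-force scan on synthetic corpora", {
  b <- generate(generator_config(n_posts = 150, seed = 4))
  toks <- preprocess_corpus(b$corpus, b$drug_lexicon, b$adr_lexicon,
                            b$stop_lexicon)
  rules <- mine_rules(build_transactions(toks))
  kept_ids <- vapply(filter_posts(toks, rules), `[[`, "", "post_id")
  want <- vapply(toks, function(tp) {
    items <- tp$tokens[adrminer:::is_tagged(tp$tokens)]
    any(vapply(seq_len(nrow(rules)), function(i)
      rules$antecedent[i] %in% items && rules$consequent[i] %in% items,
      logical(1)))
  }, logical(1))
  expect_identical(kept_ids, vapply(toks, `[[`, "", "post_id")[want])
})

test_that("rule tables round-trip through TSV", {
  tr <- build_transactions(random_transactions(2))
  r <- mine_rules(tr, 0.01, 0.3)
  f <- withr::local_tempfile()
  write_rules(r, f)
  back <- read_rules(f)
  expect_equal(back$antecedent, r$antecedent)
  expect_equal(back$support, r$support, tolerance = 1e-9)
})
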