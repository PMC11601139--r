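test_that("normalize cleans URLs, control characters and whitespace", {
  expect_equal(normalize("A  B\tC"), "a b c")
  expect_equal(normalize("see http://x.y/z please"), "see please")
  expect_equal(normalize("also www.site.com/a?b=1 here"), "also here")
  expect_equal(normalize("줄바꿈\n테스트"), "줄 바꿈 테스트")
})

test_that("normalize is idempotent on random noisy strings", {
  set.seed(5)
  pieces <- c("Hello", "WORLD", "http://a.b/c", "\t", "  ", "물집",
              "xy", "www.q.r", "a_b-c", "\n")
  for (i in 1:50) {
    t <- paste(sample(pieces, sample(1:12, 1), TRUE), collapse = " ")
    expect_identical(normalize(normalize(t)), normalize(t))
  }
})

test_that("tokenize splits on word boundaries and merges multiword surfaces", {
  lx <- tiny_lexicons()
  expect_equal(tokenize("rash on arm", lexicons = list(lx$adr))$surface,
               c("rash", "on", "arm"))
  t2 <- tokenize("muscle pain today", lexicons = list(lx$adr))
  expect_equal(t2$surface, c("muscle pain", "today"))
  expect_equal(t2$start[1], 0L)
  expect_equal(t2$end[1], 11L)  # 0-based half-open span over "muscle pain"
  expect_equal(nrow(tokenize("", lexicons = list(lx$adr))), 0)
})

test_that("longest-match merging agrees with an exhaustive-span oracle", {
  # oracle: greedy scan trying every span length by brute force
  oracle_merge <- function(words, surfaces) {
    out <- character(0); i <- 1
    while (i <= length(words)) {
      hit <- 0
      for (w in rev(seq_len(length(words) - i + 1))) {
        if (w >= 2 && paste(words[i:(i + w - 1)], collapse = " ") %in% surfaces) {
          hit <- w; break
        }
      }
      if (hit > 0) {
        out <- c(out, paste(words[i:(i + hit - 1)], collapse = " "))
        i <- i + hit
      } else {
        out <- c(out, words[i]); i <- i + 1
      }
    }
    out
  }
  set.seed(9)
  vocabulary <- c("a", "b", "c", "d", "e")
  for (rep in 1:30) {
    multi <- unique(replicate(3, paste(sample(vocabulary, sample(2:3, 1), TRUE),
                                       collapse = " ")))
    lex <- lexicon(c(multi, "zzz"), "adr")
    words <- sample(vocabulary, sample(3:12, 1), TRUE)
    got <- tokenize(paste(words, collapse = " "), lexicons = list(lex))$surface
    expect_identical(got, oracle_merge(words, multi))
  }
})

test_that("tag_and_filter tags drug/ADR terms and drops stop words", {
  lx <- tiny_lexicons()
  toks <- tokenize("i got blisters and itch", lexicons = list(lx$adr))
  tp <- tag_and_filter(toks, lx$drug, lx$adr, lx$stop, post_id = "p1", label = 1)
  expect_equal(tp$tokens, c("got", "blisters_153_ADR", "itch_156_ADR"))

  # all stop words -> empty tokenized post
  tp2 <- tag_and_filter(tokenize("and the i", lexicons = NULL),
                        lx$drug, lx$adr, lx$stop)
  expect_length(tp2$tokens, 0)

  # no lexicon hits -> all plain
  tp3 <- tag_and_filter(tokenize("quiet sunny day", lexicons = NULL),
                        lx$drug, lx$adr, lx$stop)
  expect_equal(tp3$tokens, c("quiet", "sunny", "day"))
  # stop-word removal never increases token count
  expect_lte(length(tp$tokens), nrow(toks))
})

test_that("tag rendering round-trips, including surfaces with underscores", {
  cases <- list(c("blisters", 153, "adr"), c("ketotop", 1, "drug"),
                c("adr_17", 153, "adr"), c("muscle pain", 201, "adr"),
                c("w_9_x", 4, "drug"))
  for (cs in cases) {
    r <- render_tag(cs[1], as.integer(cs[2]), cs[3])
    p <- parse_tag(r)
    expect_equal(p$surface, cs[1])
    expect_equal(p$term_id, as.integer(cs[2]))
    expect_equal(p$term_class, cs[3])
  }
  expect_true(is.na(parse_tag("plainword")$term_class))
  expect_equal(render_tag("blisters", 153L, "adr"), "blisters_153_ADR")
})

test_that("pluggable tokenizers are honoured and failures are wrapped", {
  lx <- tiny_lexicons()
  by_char <- function(text) {
    ch <- strsplit(text, "")[[1]]
    keep <- ch != " "
    data.frame(surface = ch[keep], start = which(keep) - 1L,
               end = which(keep), stringsAsFactors = FALSE)
  }
  got <- tokenize("ab c", tokenizer = by_char)
  expect_equal(got$surface, c("a", "b", "c"))
  boom <- function(text) stop("no parser")
  expect_error(tokenize("x", tokenizer = boom), "tokenizer plugin",
               class = "adr_tokenizer_error")
})

test_that("preprocess_corpus is deterministic and counts empty exclusions", {
  lx <- tiny_lexicons()
  x <- corpus(id = c("a", "b", "c"), text = c("Got Blisters AND itch",
                                              "and the i", "ketotop helped"),
              label = c(1, 0, 0))
  t1 <- preprocess_corpus(x, lx$drug, lx$adr, lx$stop)
  t2 <- preprocess_corpus(x, lx$drug, lx$adr, lx$stop)
  expect_equal(length(t1), 2)                      # post "b" became empty
  expect_equal(attr(t1, "n_excluded_empty"), 1L)
  expect_identical(lapply(t1, unclass), lapply(t2, unclass))
  expect_equal(t1[[2]]$tokens, c("ketotop_1_drug", "helped"))
})

test_that("tokenized posts round-trip through JSON-lines", {
  tl <- tokens_list(c("got", "blisters_153_ADR"), c("ketotop_1_drug"),
                    labels = c(1, NA))
  f <- withr::local_tempfile()
  write_tokens(tl, f)
  back <- read_tokens(f)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$tokens, tl[[1]]$tokens)
  expect_equal(back[[1]]$label, 1)
  expect_true(is.na(back[[2]]$label))
})
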