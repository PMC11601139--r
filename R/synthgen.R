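#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the statistical structure of a labeled
#' pharmacovigilance post collection: drug brand-name mentions, planted
#' drug-ADR co-occurrence pairs in true ADR posts, incidental known-ADR
#' words in non-ADR posts (people discussing a drug's documented side
#' effects without experiencing them -- these are what makes association
#' filtering keep non-ADR posts, so the labeled set is not trivially pure),
#' filler and stop words, optional label noise, and paired annotator labels
#' with tunable agreement.
#'
#' Defaults state the emulated world: 576 posts at 42.4\% ADR prevalence
#' (the composition of the labeled ketoprofen-like dataset), 9 drug brand
#' names, and annotator agreement calibrated so Cohen's kappa is about 0.8.
#'
#' @param n_posts number of posts (>= 10).
#' @param n_drugs drug brand names in the drug lexicon.
#' @param n_adr_terms ADR terms in the ADR lexicon.
#' @param n_filler plain filler vocabulary size.
#' @param n_stopwords stop-word lexicon size.
#' @param adr_prevalence probability a post is a true ADR post.
#' @param pair_matrix n_drugs x n_adr_terms matrix of per-ADR inclusion
#'   probabilities for ADR posts (rows sum <= 1 over the planted block).
#'   Default: drug i always co-occurs with its primary ADR term i.
#' @param extra_adr_mean ADR posts additionally carry `1 + Poisson(mean)`
#'   symptom terms drawn from the non-primary ADR pool; these are the
#'   experiential signal separating true ADR posts from incidental mentions.
#' @param incidental_adr_rate probability a non-ADR post mentions a drug
#'   together with one of that drug's known (planted) ADR words. The default
#'   is high because the emulated collections are drug-targeted searches:
#'   most posts mention the drug, and discussing a drug's documented side
#'   effects without experiencing them is common. It is chosen so the
#'   association-filtered subset has roughly the class balance of the
#'   emulated labeled set (about 42-50\% ADR), not an artificially pure one.
#' @param nonadr_drug_rate probability a non-ADR post mentions a drug with
#'   no ADR word at all.
#' @param post_length integer `c(min, max)` token count per post.
#' @param stopword_rate fraction of filler slots that are stop words.
#' @param label_noise probability the observed label is flipped (truth
#'   records stay exact).
#' @param annotator_agreement target expected observed agreement between the
#'   two simulated annotators; default calibrated for kappa 0.8 at the
#'   default prevalence.
#' @param hangul if `TRUE`, filler tokens carry a Hangul prefix to exercise
#'   unicode handling end to end.
#' @param seed RNG seed; identical seeds give identical bundles.
#' @return list of class `adr_gen_config`.
#' @export
generator_config <- function(n_posts = 576, n_drugs = 9, n_adr_terms = 30,
                             n_filler = 150, n_stopwords = 12,
                             adr_prevalence = 0.424, pair_matrix = NULL,
                             extra_adr_mean = 0.8, incidental_adr_rate = 0.7,
                             nonadr_drug_rate = 0.25,
                             post_length = c(8, 40), stopword_rate = 0.2,
                             label_noise = 0, annotator_agreement = NULL,
                             hangul = FALSE, seed = 1) {
  if (n_posts < 10)
    abort_adr("n_posts must be >= 10", "adr_validation_error")
  fracs <- c(adr_prevalence, incidental_adr_rate, nonadr_drug_rate,
             stopword_rate, label_noise)
  if (any(fracs < 0 | fracs > 1))
    abort_adr("all rate parameters must lie in [0, 1]", "adr_validation_error")
  if (is.null(pair_matrix)) {
    pair_matrix <- matrix(0, n_drugs, n_adr_terms)
    for (i in seq_len(n_drugs))
      pair_matrix[i, ((i - 1) %% n_adr_terms) + 1] <- 1
  }
  stopifnot(nrow(pair_matrix) == n_drugs, ncol(pair_matrix) == n_adr_terms,
            all(pair_matrix >= 0), all(pair_matrix <= 1))
  if (is.null(annotator_agreement))
    annotator_agreement <- kappa_target_agreement(0.8, adr_prevalence)
  if (annotator_agreement < 0.5 || annotator_agreement > 1)
    abort_adr("annotator_agreement must lie in [0.5, 1]", "adr_validation_error")
  stopifnot(length(post_length) == 2, post_length[1] >= 1,
            post_length[2] >= post_length[1])
  # feasibility: a post must be able to hold its planted terms
  max_planted <- 1 + sum(apply(pair_matrix, 1, function(r) sum(r > 0))) /
    max(1, n_drugs) + 1 + 5  # drug + typical pairs + extras headroom
  if (post_length[2] < 4)
    abort_adr("post_length too small to hold drug and ADR terms",
              "adr_validation_error")
  structure(list(n_posts = as.integer(n_posts), n_drugs = as.integer(n_drugs),
                 n_adr_terms = as.integer(n_adr_terms),
                 n_filler = as.integer(n_filler),
                 n_stopwords = as.integer(n_stopwords),
                 adr_prevalence = adr_prevalence, pair_matrix = pair_matrix,
                 extra_adr_mean = extra_adr_mean,
                 incidental_adr_rate = incidental_adr_rate,
                 nonadr_drug_rate = nonadr_drug_rate,
                 post_length = as.integer(post_length),
                 stopword_rate = stopword_rate, label_noise = label_noise,
                 annotator_agreement = annotator_agreement,
                 hangul = isTRUE(hangul), seed = as.integer(seed)),
            class = "adr_gen_config")
}

#' Preset generator configurations
#'
#' Two presets mirror the shipped experiments: `"ketoprofen_like"` (576
#' posts, 42.4\% ADR prevalence, 9 drug brand names) and `"geworin_like"`
#' (236 posts, 27.96\% ADR prevalence -- the harder, more imbalanced
#' extra-drug validation).
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @param ... overrides passed on to [generator_config()].
#' @return an `adr_gen_config`.
#' @export
preset_config <- function(name = c("ketoprofen_like", "geworin_like"),
                          seed = 1, ...) {
  name <- match.arg(name)
  switch(name,
    ketoprofen_like = generator_config(n_posts = 576, adr_prevalence = 0.424,
                                       seed = seed, ...),
    geworin_like = generator_config(n_posts = 236, adr_prevalence = 0.2796,
                                    seed = seed, ...))
}

synth_lexicons <- function(cfg) {
  drug <- lexicon(sprintf("medi%02d", seq_len(cfg$n_drugs)),
                  term_class = "drug",
                  canonical = sprintf("generic%02d", seq_len(cfg$n_drugs)),
                  source = "synthetic")
  adr <- lexicon(sprintf("sympt%03d", seq_len(cfg$n_adr_terms)),
                 term_class = "adr", source = "synthetic")
  stop <- lexicon(sprintf("stw%02d", seq_len(cfg$n_stopwords)),
                  term_class = "stopword", source = "synthetic")
  list(drug = drug, adr = adr, stop = stop)
}

#' Generate a synthetic labeled bundle
#'
#' Produces a corpus, the three matching lexicons, exact per-post ground
#' truth (true label and planted drug/ADR pair), and two simulated annotator
#' label vectors. True ADR posts contain one drug mention, that drug's
#' planted ADR terms per the pair matrix, and additional symptom terms;
#' non-ADR posts are either drug-plus-known-ADR mentions (incidental),
#' drug-only, or drug-free chatter. Label noise, when requested, is applied
#' after planting so the truth records stay exact.
#'
#' @param cfg an [generator_config()].
#' @return An object of class `adr_bundle`: list with `corpus`,
#'   `drug_lexicon`, `adr_lexicon`, `stop_lexicon`, `truth` (data.frame
#'   id/true_label/drug/planted_adr), `annotator_labels` (n x 2 matrix) and
#'   `config`.
#' @export
generate <- function(cfg) {
  stopifnot(inherits(cfg, "adr_gen_config"))
  set.seed(cfg$seed)
  lex <- synth_lexicons(cfg)
  n <- cfg$n_posts
  fill_pool <- sprintf("%sword%03d", if (cfg$hangul) "말" else "",
                       seq_len(cfg$n_filler))
  stop_pool <- lex$stop$surface

  # exact-count label assignment at random positions: keeps the empirical
  # prevalence within rounding of the target at any n (a Bernoulli draw
  # would miss a 3-point band in a nontrivial share of seeds)
  is_adr <- integer(n)
  is_adr[sample.int(n, round(cfg$adr_prevalence * n))] <- 1L
  primary_adr <- apply(cfg$pair_matrix, 1, which.max)
  non_primary <- setdiff(seq_len(cfg$n_adr_terms), unique(primary_adr))
  if (length(non_primary) == 0)
    abort_adr("pair_matrix leaves no non-primary ADR terms for symptom draws",
              "adr_validation_error")

  texts <- character(n)
  truth_drug <- character(n)
  truth_adr <- character(n)
  for (i in seq_len(n)) {
    L <- sample(cfg$post_length[1]:cfg$post_length[2], 1)
    planted <- character(0)
    if (is_adr[i] == 1) {
      d <- sample.int(cfg$n_drugs, 1)
      adr_ids <- which(stats::runif(cfg$n_adr_terms) < cfg$pair_matrix[d, ])
      if (length(adr_ids) == 0) adr_ids <- primary_adr[d]
      n_extra <- 1 + stats::rpois(1, cfg$extra_adr_mean)
      extras <- sample(non_primary, min(n_extra, length(non_primary)))
      planted <- c(lex$drug$surface[d],
                   lex$adr$surface[unique(c(adr_ids, extras))])
      truth_drug[i] <- lex$drug$surface[d]
      truth_adr[i] <- lex$adr$surface[primary_adr[d]]
    } else {
      u <- stats::runif(1)
      if (u < cfg$incidental_adr_rate) {
        d <- sample.int(cfg$n_drugs, 1)
        planted <- c(lex$drug$surface[d], lex$adr$surface[primary_adr[d]])
        truth_drug[i] <- lex$drug$surface[d]
      } else if (u < cfg$incidental_adr_rate + cfg$nonadr_drug_rate) {
        d <- sample.int(cfg$n_drugs, 1)
        planted <- lex$drug$surface[d]
        truth_drug[i] <- lex$drug$surface[d]
      }
    }
    L <- max(L, length(planted) + 2L)
    n_fill <- L - length(planted)
    filler <- ifelse(stats::runif(n_fill) < cfg$stopword_rate,
                     sample(stop_pool, n_fill, replace = TRUE),
                     sample(fill_pool, n_fill, replace = TRUE))
    toks <- character(L)
    if (length(planted) > 0) {
      pos <- sort(sample.int(L, length(planted)))
      toks[pos] <- planted
      toks[-pos] <- filler
    } else {
      toks <- filler
    }
    texts[i] <- paste(toks, collapse = " ")
  }

  label <- is_adr
  if (cfg$label_noise > 0) {
    flip <- stats::runif(n) < cfg$label_noise
    label[flip] <- 1 - label[flip]
  }
  ids <- sprintf("post%05d", seq_len(n))
  corp <- corpus(id = ids, channel = "synthetic", text = texts, label = label,
                 provenance = list(source = "adrminer::generate",
                                   seed = cfg$seed))
  ann <- make_annotators(is_adr, cfg$annotator_agreement,
                         seed = derive_seed(cfg$seed, 2L))
  structure(list(corpus = corp, drug_lexicon = lex$drug,
                 adr_lexicon = lex$adr, stop_lexicon = lex$stop,
                 truth = data.frame(id = ids, true_label = is_adr,
                                    drug = truth_drug,
                                    planted_adr = truth_adr,
                                    stringsAsFactors = FALSE),
                 annotator_labels = ann, config = cfg),
            class = "adr_bundle")
}

#' Simulate two annotators with a target agreement
#'
#' Each annotator independently reports the true label with probability `p`,
#' where `p` solves `p^2 + (1-p)^2 = agreement`, so the expected observed
#' agreement between the two annotators equals `agreement`.
#'
#' @param truth 0/1 vector of true labels.
#' @param agreement target expected observed agreement in \[0.5, 1\].
#' @param seed RNG seed.
#' @return n x 2 integer matrix of annotator labels.
#' @export
make_annotators <- function(truth, agreement, seed = 1) {
  stopifnot(is_binary01(truth), agreement >= 0.5, agreement <= 1)
  p <- (1 + sqrt(2 * agreement - 1)) / 2
  set.seed(seed)
  n <- length(truth)
  a <- ifelse(stats::runif(n) < p, truth, 1 - truth)
  b <- ifelse(stats::runif(n) < p, truth, 1 - truth)
  cbind(annotator_a = as.integer(a), annotator_b = as.integer(b))
}

#' Annotator agreement needed for a target Cohen's kappa
#'
#' Solves analytically for the expected-observed-agreement parameter of
#' [make_annotators()] such that Cohen's kappa between the two annotators
#' equals `kappa` in expectation, given the truth prevalence. Used to
#' calibrate the simulated labeling stage to a reported reliability (e.g.
#' kappa 0.8).
#'
#' @param kappa target kappa in (0, 1\].
#' @param prevalence truth positive rate.
#' @return the agreement value to pass to [make_annotators()].
#' @export
kappa_target_agreement <- function(kappa, prevalence = 0.424) {
  stopifnot(kappa > 0, kappa <= 1, prevalence > 0, prevalence < 1)
  expected_kappa <- function(p) {
    po <- p^2 + (1 - p)^2
    m1 <- prevalence * p + (1 - prevalence) * (1 - p)  # annotator marginal
    pe <- m1^2 + (1 - m1)^2
    (po - pe) / (1 - pe)
  }
  p <- stats::uniroot(function(p) expected_kappa(p) - kappa,
                      interval = c(0.5 + 1e-9, 1 - 1e-9), tol = 1e-12)$root
  p^2 + (1 - p)^2
}

#' Write a synthetic bundle to a directory
#'
#' Writes the corpus (JSON-lines), the three lexicons (TSV), the truth table
#' (TSV) and the annotator labels (TSV) in the package's standard formats.
#'
#' @param bundle an `adr_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "adr_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(bundle$corpus, file.path(dir, "corpus.jsonl"))
  write_lexicon(bundle$drug_lexicon, file.path(dir, "drug_lexicon.tsv"))
  write_lexicon(bundle$adr_lexicon, file.path(dir, "adr_lexicon.tsv"))
  write_lexicon(bundle$stop_lexicon, file.path(dir, "stop_lexicon.tsv"))
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.table(as.data.frame(bundle$annotator_labels),
                     file.path(dir, "annotators.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
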