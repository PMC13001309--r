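test_that("BLEU matches hand n-gram counts on oracle pairs", {
  # identity
  expect_equal(bleu("sweet fruity apple odor", "sweet fruity apple odor",
                    max_n = 1), 100)
  expect_equal(bleu("sweet fruity apple odor", "sweet fruity apple odor",
                    max_n = 4), 100)
  # disjoint unigrams
  expect_equal(bleu("garlic onion", "rose jasmine", max_n = 1), 0)
  # "a b c d" vs "a b x d": p1 = 3/4, equal lengths -> BP = 1
  expect_equal(bleu("a b c d", "a b x d", max_n = 1), 75)
  # "a b c d e" vs "a b c x e": p1 = 4/5; p4 = 0 -> BLEU-4 = 0 unsmoothed
  expect_equal(bleu("a b c d e", "a b c x e", max_n = 1), 80)
  expect_equal(bleu("a b c d e", "a b c x e", max_n = 4), 0)
  # brevity penalty: candidate 3 tokens, reference 6 -> BP = exp(1 - 2)
  expect_equal(bleu("the cat sat", "the cat sat on the mat", max_n = 1),
               100 * exp(-1), tolerance = 1e-12)
  # clipping: "a a a" vs "a b": clipped count 1 of 3, candidate longer -> BP = 1
  expect_equal(bleu("a a a", "a b", max_n = 1), 100 / 3, tolerance = 1e-12)
  # multi-reference: clip takes the max over references
  expect_equal(bleu("a b", c("a x", "y b"), max_n = 1), 100)
})

test_that("BLEU rejects empty inputs", {
  expect_error(bleu("", "a b"), "empty candidate")
  expect_error(bleu("a b", character(0)), "empty reference")
})

test_that("ROUGE-L matches a hand LCS computation", {
  expect_equal(rougeL("sweet apple odor", "sweet apple odor"), 100)
  expect_equal(rougeL("garlic onion", "rose lily"), 0)
  # "a b c d" vs "a c d": LCS 3, P = 3/4, R = 1 -> F1 = 6/7
  expect_equal(rougeL("a b c d", "a c d"), 600 / 7, tolerance = 1e-12)
  # order matters through the LCS: "a b" vs "b a" -> LCS 1, P = R = 1/2
  expect_equal(rougeL("a b", "b a"), 50)
})

test_that("METEOR matches manual alignment arithmetic", {
  # perfect single-chunk match of m tokens: 100 (1 - 0.5 / m^3)
  expect_equal(meteor("a b c", "a b c"), 100 * (1 - 0.5 / 27),
               tolerance = 1e-12)
  expect_equal(meteor("garlic onion", "rose lily"), 0)
  # "a b c d" vs "b a c d": m = 4, F = 1, chunks = 3 (a | b | c d)
  expect_equal(meteor("a b c d", "b a c d"),
               100 * (1 - 0.5 * (3 / 4)^3), tolerance = 1e-12)
  # partial: cand "a b x" vs ref "a b y": m = 2, P = 2/3, R = 2/3, 1 chunk
  f <- 10 * (2/3) * (2/3) / (2/3 + 9 * 2/3)
  expect_equal(meteor("a b x", "a b y"),
               100 * f * (1 - 0.5 * (1 / 2)^3), tolerance = 1e-12)
  # stem stage: "fruity smelling" vs "fruity smell" matches via the stemmer
  expect_gt(meteor("fruity smelling", "fruity smell"), 90)
})

test_that("BERTScore reproduces a hand greedy-matching F1", {
  expect_equal(bertScore("apple pear odor", "apple pear odor"), 100)
  # orthogonal token vectors across texts -> 0 before any rescaling
  expect_equal(bertScore("garlic onion", "rose lily"), 0)
  # hand-set vectors: cand {a, b}, ref {a, c}; a=(1,0), b=(0,1), c=(1,1)/sqrt 2
  lut <- list(a = c(1, 0), b = c(0, 1), c = c(1, 1) / sqrt(2))
  embedder <- function(tokens) do.call(rbind, lut[tokens])
  # R = (1 + cos(c, b)) / 2 = (1 + 1/sqrt 2)/2 = P -> F1 = same
  expect_equal(bertScore("a b", "a c", token_embedder = embedder),
               100 * (1 + 1 / sqrt(2)) / 2, tolerance = 1e-12)
})

test_that("all metrics stay within [0, 100] on random token soup", {
  set.seed(31)
  vocab <- letters[1:6]
  for (i in 1:25) {
    a <- paste(sample(vocab, sample(2:6, 1), replace = TRUE), collapse = " ")
    b <- paste(sample(vocab, sample(2:6, 1), replace = TRUE), collapse = " ")
    for (s in c(bleu(a, b, max_n = 1), bleu(a, b, max_n = 4), rougeL(a, b),
                meteor(a, b), bertScore(a, b))) {
      expect_gte(s, 0); expect_lte(s, 100)
    }
    expect_gte(bleu(a, b, max_n = 1), bleu(a, b, max_n = 4))
  }
})

test_that("the tokenizer is deterministic and shared", {
  expect_identical(tokenizeText("Sweet, FRUITY–apple!  odor"),
                   c("sweet", "fruity", "apple", "odor"))
  expect_identical(tokenizeText("Sweet, FRUITY–apple!  odor"),
                   tokenizeText("Sweet, FRUITY–apple!  odor"))
})

test_that("consensus gap is non-positive when machine equals human", {
  cat_ <- makeOverlapCatalog(c(0, 4, 2))
  pt <- pairTexts(cat_, crossSourcePairs(cat_, "CHD"))
  mh <- data.frame(machine = pt$text_a, human = pt$text_b,
                   stringsAsFactors = FALSE)
  cg <- consensusGap(pt, mh, function(a, b) bleu(a, b, max_n = 1), "bleu1")
  expect_lte(cg$gap, 1e-9)
})

test_that("identical twin texts give S_hh = 100 for BLEU-1", {
  pairs_hh <- data.frame(text_a = c("apple pear odor", "smoky tar odor"),
                         text_b = c("apple pear odor", "smoky tar odor"),
                         stringsAsFactors = FALSE)
  mh <- data.frame(machine = c("x y", "x z"), human = c("a b", "a c"),
                   stringsAsFactors = FALSE)
  cg <- consensusGap(pairs_hh, mh, function(a, b) bleu(a, b, max_n = 1))
  expect_equal(cg$s_hh$mean, 100)
  expect_error(consensusGap(pairs_hh[1, , drop = FALSE], mh, rougeL),
               "at least 2")
})

test_that("random-family machine texts fall below human consensus (lexical)", {
  cfg <- syntheticConfig(n_molecules = 200, n_sources = 2, alpha = 1,
                         seed = 41)
  gen <- generateCatalog(cfg)
  pt <- pairTexts(gen$catalog, crossSourcePairs(gen$catalog, "CHD"))
  d <- descriptions(gen$catalog)
  d <- d[d$kind == "CHD" & !duplicated(d$molecule_id), ]
  set.seed(42)
  machine <- vapply(seq_len(nrow(d)), function(i) {
    fam <- sample(seq_along(odieu:::ODOR_FAMILY_VOCAB), 1)
    paste("This molecule has a",
          paste(sample(odieu:::ODOR_FAMILY_VOCAB[[fam]], 3), collapse = ", "),
          "odor.")
  }, "")
  mh <- data.frame(machine = machine, human = d$text, stringsAsFactors = FALSE)
  cg <- consensusGap(pt, mh, function(a, b) bleu(a, b, max_n = 1), "bleu1")
  tt <- t.test(cg$scores_hh, cg$scores_mh, alternative = "greater")
  expect_gt(cg$gap, 0)
  expect_lt(tt$p.value, 0.01)
})
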