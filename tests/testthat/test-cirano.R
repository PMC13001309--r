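test_that("prefix encoding is deterministic and checks dimensions", {
  enc <- prefixEncoder(input_dim = 5, k = 4, embed_width = 8, seed = 2)
  x <- rnorm(5)
  p1 <- encodePrefix(enc, x)
  p2 <- encodePrefix(enc, x)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(4, 8))
  expect_error(encodePrefix(enc, rnorm(4)), "does not match")
  # zero-initialized final layer gives an all-zero prefix for any input
  enc0 <- prefixEncoder(input_dim = 5, k = 4, embed_width = 8, seed = 2,
                        zero_final = TRUE)
  expect_equal(encodePrefix(enc0, rnorm(5)), matrix(0, 4, 8))
})

test_that("a hand-set 2-layer encoder reproduces manual matrix arithmetic", {
  enc <- prefixEncoder(input_dim = 2, k = 1, embed_width = 2, hidden = 2,
                       n_layers = 2, seed = 1)
  enc@weights[[1]] <- rbind(c(1, 0), c(0, -1))
  enc@biases[[1]] <- c(0.5, 0)
  enc@weights[[2]] <- rbind(c(2, 0), c(1, 1))
  enc@biases[[2]] <- c(0, 1)
  x <- c(0.2, 0.4)
  h <- tanh(c(1 * 0.2 + 0.5, -0.4))          # hidden layer by hand
  out <- c(2 * h[1], h[1] + h[2] + 1)        # linear output layer by hand
  expect_equal(encodePrefix(enc, x), matrix(out, 1, 2), tolerance = 1e-12)
})

test_that("encoder backprop matches finite differences through the LM", {
  set.seed(4)
  lm <- tinyCausalLM(c("apple", "pear", "smoke"), embed_width = 6, seed = 5)
  enc <- prefixEncoder(input_dim = 3, k = 2, embed_width = 6, hidden = 4,
                       seed = 6)
  x <- rnorm(3)
  ids <- odieu:::lmTokenIds(lm, "apple smoke")
  lossAt <- function(e) {
    acts <- odieu:::encoderForward(e, x)
    prefix <- matrix(acts[[length(acts)]], 2, 6, byrow = TRUE)
    odieu:::lmLossAndPrefixGrad(lm, prefix, ids)$loss
  }
  acts <- odieu:::encoderForward(enc, x)
  prefix <- matrix(acts[[length(acts)]], 2, 6, byrow = TRUE)
  lg <- odieu:::lmLossAndPrefixGrad(lm, prefix, ids)
  gr <- odieu:::encoderBackward(enc, acts, lg$dPrefix)
  h <- 1e-6
  for (probe in list(c(1, 1, 2), c(2, 3, 1), c(4, 2, 4))) {
    l <- probe[1]; i <- probe[2]; j <- probe[3]
    ep <- enc; ep@weights[[l]][i, j] <- ep@weights[[l]][i, j] + h
    em <- enc; em@weights[[l]][i, j] <- em@weights[[l]][i, j] - h
    expect_equal(gr$dW[[l]][i, j], (lossAt(ep) - lossAt(em)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("training never mutates the frozen language model", {
  corp <- makeClusterCorpus(n = 10)
  lm <- tinyCausalLM(buildLMVocab(corp$texts), seed = 7)
  fp0 <- lmFingerprint(lm)
  snapshot <- list(lm@tokenEmb, lm@contextW, lm@contextB, lm@outputW)
  model <- trainEncoder(corp$desc, corp$texts, lm,
                        ciranoConfig(epochs = 5, seed = 8))
  expect_identical(lmFingerprint(lm), fp0)
  expect_identical(model$fingerprint, fp0)
  expect_identical(list(lm@tokenEmb, lm@contextW, lm@contextB, lm@outputW),
                   snapshot)
})

test_that("training loss strictly decreases early on a memorizable pair", {
  texts <- c(m1 = "This molecule has a cedar, pine odor.")
  desc <- matrix(rnorm(6), 1, 6, dimnames = list("m1", NULL))
  lm <- tinyCausalLM(buildLMVocab(texts), seed = 9)
  model <- trainEncoder(desc, texts, lm, ciranoConfig(epochs = 12, seed = 10))
  expect_true(all(diff(model$loss_trace[1:10]) < 0))
})

test_that("a zero learning rate leaves the encoder untouched", {
  texts <- c(m1 = "cedar pine odor", m2 = "smoke tar odor")
  desc <- matrix(rnorm(8), 2, 4, dimnames = list(c("m1", "m2"), NULL))
  lm <- tinyCausalLM(buildLMVocab(texts), seed = 11)
  model <- trainEncoder(desc, texts, lm,
                        ciranoConfig(epochs = 5, lr = 0, seed = 12))
  ref <- prefixEncoder(4, k = model$config$k, embed_width = lm@embedWidth,
                       hidden = model$config$hidden, seed = 12)
  expect_equal(model$encoder@weights, ref@weights, tolerance = 1e-12)
})

test_that("greedy decoding is deterministic; sampling is seed-reproducible", {
  corp <- makeClusterCorpus(n = 10)
  lm <- tinyCausalLM(buildLMVocab(corp$texts), seed = 13)
  model <- trainEncoder(corp$desc, corp$texts, lm,
                        ciranoConfig(epochs = 10, seed = 14))
  g1 <- generateDescription(model, corp$desc[1, ])
  g2 <- generateDescription(model, corp$desc[1, ])
  expect_identical(g1, g2)
  s1 <- generateDescription(model, corp$desc[1, ], decoding = "sample",
                            seed = 99)
  s2 <- generateDescription(model, corp$desc[1, ], decoding = "sample",
                            seed = 99)
  expect_identical(s1, s2)
})

test_that("cluster-conditional generation prefers its own cluster's texts", {
  corp <- makeClusterCorpus(n = 30)
  tr <- c(1:12, 16:27); held <- c(13:15, 28:30)
  lm <- tinyCausalLM(buildLMVocab(corp$texts), seed = 3)
  model <- trainEncoder(corp$desc[tr, ], corp$texts[tr], lm,
                        ciranoConfig(epochs = 150, lr = 0.05, seed = 4))
  te <- toyEmbedder(64)
  meanCS <- function(g, idx) {
    eg <- tryCatch(embeddingRows(embedTexts(te, g)), error = function(e) NULL)
    if (is.null(eg)) return(NA_real_)
    mean(vapply(corp$texts[idx], function(t)
      cosineSim(eg[1, ], embeddingRows(embedTexts(te, t))[1, ]), 0))
  }
  own <- vapply(held, function(i) {
    g <- generateDescription(model, corp$desc[i, ], max_len = 8,
                             min_len = 6)
    a <- meanCS(g, tr[corp$fam[tr] == 1])
    b <- meanCS(g, tr[corp$fam[tr] == 2])
    if (is.na(a) || is.na(b)) return(FALSE)
    if (corp$fam[i] == 1) a > b else b > a
  }, logical(1))
  expect_gte(mean(own), 0.8)
})

test_that("an untrained encoder generates at chance against the null", {
  corp <- makeClusterCorpus(n = 24)
  lm <- tinyCausalLM(buildLMVocab(corp$texts), seed = 15)
  model <- trainEncoder(corp$desc, corp$texts, lm,
                        ciranoConfig(epochs = 0, seed = 16))
  te <- toyEmbedder(64)
  safe_cs <- function(a, b) {
    ea <- tryCatch(embeddingRows(embedTexts(te, a)), error = function(e) NULL)
    if (is.null(ea)) return(0)
    cosineSim(ea[1, ], embeddingRows(embedTexts(te, b))[1, ])
  }
  gens <- vapply(seq_len(24), function(i)
    generateDescription(model, corp$desc[i, ]), "")
  paired <- vapply(seq_len(24), function(i) safe_cs(gens[i], corp$texts[i]), 0)
  set.seed(17)
  p <- odieu:::derangement(24)
  null <- vapply(seq_len(24), function(i) safe_cs(gens[i], corp$texts[p[i]]), 0)
  tt <- t.test(paired, null)
  expect_gt(tt$p.value, 0.05)
})

test_that("a trained model round-trips through its JSON serialization", {
  corp <- makeClusterCorpus(n = 10)
  lm <- tinyCausalLM(buildLMVocab(corp$texts), seed = 18)
  model <- trainEncoder(corp$desc, corp$texts, lm,
                        ciranoConfig(epochs = 5, seed = 19))
  f <- withr::local_tempfile(fileext = ".json")
  writeCiranoModel(model, f)
  back <- readCiranoModel(f)
  expect_identical(lmFingerprint(back$lm), model$fingerprint)
  expect_equal(generateDescription(back, corp$desc[3, ]),
               generateDescription(model, corp$desc[3, ]))
})
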