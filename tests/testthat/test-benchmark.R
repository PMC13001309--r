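test_that("similarity distributions: identity pairing gives all-1 paired CS", {
  cat_ <- makeOverlapCatalog(c(0, 6, 0))
  # same embeddings on both sides: paired CS over same-molecule pairs
  d <- descriptions(cat_)
  te <- toyEmbedder(128)
  emb <- embedCatalog(te, cat_, "CHD")
  pi <- crossSourcePairs(cat_, "CHD")
  # make the two sources' texts identical per molecule, disjoint across
  d$text <- sprintf("tok%s alt%s", d$molecule_id, d$molecule_id)
  cat2 <- makeCatalog(d)
  emb2 <- embedCatalog(te, cat2, "CHD")
  sd_ <- similarityDistributions(emb2, emb2, crossSourcePairs(cat2, "CHD"),
                                 seed = 1)
  expect_equal(sd_$paired, rep(1, pairCount(pi)), tolerance = 1e-12)
  # distinct per-molecule tokens -> null pairs orthogonal
  expect_equal(sd_$null, rep(0, pairCount(pi)), tolerance = 1e-12)
})

test_that("the shuffled null is a derangement across many seeds", {
  cat_ <- makeOverlapCatalog(c(0, 50, 0))
  te <- toyEmbedder(256)
  emb <- embedCatalog(te, cat_, "CHD")
  pi <- crossSourcePairs(cat_, "CHD")
  e <- pairEntries(pi)
  for (s in 1:40) {
    set.seed(s)
    p <- odieu:::derangement(nrow(e))
    expect_true(all(p != seq_len(nrow(e))))
  }
  expect_error(similarityDistributions(emb, emb, new("PairIndex", kind = "CHD")),
               "at least 2")
})

test_that("1-D EMD matches trivial cases and the permutation-coupling oracle", {
  expect_equal(emd1d(c(0.2, 0.4, 0.9), c(0.2, 0.4, 0.9)), 0)
  expect_equal(emd1d(c(0, 0), c(1, 1)), 1)
  expect_error(emd1d(numeric(0), 1), "empty")
  set.seed(17)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    a <- runif(n); b <- runif(n)
    expect_equal(emd1d(a, b), emdPermOracle(a, b), tolerance = 1e-12)
  }
  # unequal sizes: replicate to equal mass, then the same oracle applies
  for (i in 1:10) {
    a <- runif(2); b <- runif(sample(c(4, 6), 1))
    L <- length(b)
    expect_equal(emd1d(a, b),
                 emdPermOracle(rep(a, each = L / 2), rep(b, each = 1)),
                 tolerance = 1e-12)
  }
})

test_that("retrieval is perfect for one-hot embeddings and exact at k = gallery", {
  n <- 12
  ids <- sprintf("m%02d", 1:n)
  rec_q <- data.frame(molecule_id = ids, source = "s1", kind = "CHD",
                      text = ids, stringsAsFactors = FALSE)
  rec_g <- data.frame(molecule_id = ids, source = "s2", kind = "CHD",
                      text = ids, stringsAsFactors = FALSE)
  M <- diag(n)
  q <- new("EmbeddingMatrix", matrix = M, records = rec_q,
           embedder = "onehot", normalized = TRUE)
  g <- new("EmbeddingMatrix", matrix = M, records = rec_g,
           embedder = "onehot", normalized = TRUE)
  acc <- topkRetrieval(q, g, ks = c(1, 3, n))
  expect_equal(unname(acc), c(1, 1, 1))
  expect_error(topkRetrieval(q, g, ks = n + 1), "exceeds")
  # self-record exclusion: gallery containing the query record itself
  acc2 <- topkRetrieval(q, q, ks = 1)
  expect_true(is.finite(acc2))  # runs with n-1 effective gallery
})

test_that("retrieval accuracy is non-decreasing in k", {
  cfg <- syntheticConfig(n_molecules = 40, alpha = 0.7, seed = 3)
  gen <- generateCatalog(cfg)
  emb <- embedCatalog(toyEmbedder(), gen$catalog, "CHD")
  acc <- topkRetrieval(emb, emb, ks = c(1, 2, 5, 10, 20))
  expect_true(all(diff(acc) >= 0))
})

test_that("consensus comparison is antisymmetric and guards degenerate input", {
  set.seed(5)
  hh <- rnorm(50, 0.6, 0.1); mh <- rnorm(50, 0.4, 0.1)
  v1 <- compareToConsensus(hh, mh)
  v2 <- compareToConsensus(mh, hh)
  expect_equal(v1$t, -v2$t)
  expect_equal(v1$gap, -v2$gap)
  expect_equal(v1$verdict, "below")
  expect_equal(v2$verdict, "above")
  same <- compareToConsensus(hh, hh + rnorm(50, 0, 1e-3))
  expect_equal(same$verdict, "at")
  expect_error(compareToConsensus(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("averaged embeddings: full and leave-source-out arithmetic", {
  rec <- data.frame(molecule_id = rep("m1", 2), source = c("s1", "s2"),
                    kind = "CHD", text = c("x", "y"), stringsAsFactors = FALSE)
  M <- rbind(c(1, 0), c(0, 1))
  emb <- new("EmbeddingMatrix", matrix = M, records = rec,
             embedder = "toy", normalized = TRUE)
  avg <- averageEmbeddings(emb, "full")
  # two orthogonal unit sources: renormalized mean has CS = 1/sqrt 2 to each
  expect_equal(sum(embeddingRows(avg)[1, ] * M[1, ]), 1 / sqrt(2),
               tolerance = 1e-12)
  # identical sources: average equals them
  emb2 <- new("EmbeddingMatrix", matrix = rbind(c(1, 0), c(1, 0)),
              records = rec, embedder = "toy", normalized = TRUE)
  expect_equal(embeddingRows(averageEmbeddings(emb2, "full"))[1, ], c(1, 0))
  # 3-source hand computation for leave-source-out
  rec3 <- data.frame(molecule_id = "m1", source = c("s1", "s2", "s3"),
                     kind = "CHD", text = c("x", "y", "z"),
                     stringsAsFactors = FALSE)
  M3 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  emb3 <- new("EmbeddingMatrix", matrix = M3, records = rec3,
              embedder = "toy", normalized = TRUE)
  loso <- averageEmbeddings(emb3, "leave_source_out")
  lrec <- embeddingRecords(loso)
  # excluding s1: mean of e2, e3 renormalized = (0, 1, 1)/sqrt 2
  row_s1 <- which(lrec$source == "s1")
  expect_equal(embeddingRows(loso)[row_s1, ], c(0, 1, 1) / sqrt(2),
               tolerance = 1e-12)
  # single-source molecule -> error
  solo <- new("EmbeddingMatrix", matrix = M3[1, , drop = FALSE],
              records = rec3[1, ], embedder = "toy", normalized = TRUE)
  expect_error(averageEmbeddings(solo, "leave_source_out"), ">= 2 sources")
})

test_that("full-average CS to members exceeds leave-source-out CS on average", {
  cfg <- syntheticConfig(n_molecules = 80, alpha = 0.7, seed = 37)
  gen <- generateCatalog(cfg)
  emb <- embedCatalog(toyEmbedder(), gen$catalog, "CHD")
  r <- embeddingRecords(emb); M <- embeddingRows(emb)
  full <- averageEmbeddings(emb, "full")
  loso <- averageEmbeddings(emb, "leave_source_out")
  fr <- embeddingRecords(full); lr <- embeddingRecords(loso)
  cs_full <- cs_loso <- numeric(0)
  for (i in seq_len(nrow(r))) {
    fi <- which(fr$molecule_id == r$molecule_id[i])
    li <- which(lr$molecule_id == r$molecule_id[i] & lr$source == r$source[i])
    cs_full <- c(cs_full, sum(M[i, ] * embeddingRows(full)[fi, ]))
    cs_loso <- c(cs_loso, sum(M[i, ] * embeddingRows(loso)[li, ]))
  }
  expect_gt(mean(cs_full), mean(cs_loso))
})

test_that("EMD(paired, null) is at chance when embeddings carry no molecule information", {
  set.seed(53)
  n <- 150
  ids <- sprintf("m%03d", 1:n)
  rec <- rbind(data.frame(molecule_id = ids, source = "s1", kind = "CHD",
                          text = "a", stringsAsFactors = FALSE),
               data.frame(molecule_id = ids, source = "s2", kind = "CHD",
                          text = "b", stringsAsFactors = FALSE))
  M <- matrix(rnorm(2 * n * 16), 2 * n, 16)
  M <- M / sqrt(rowSums(M^2))
  emb <- new("EmbeddingMatrix", matrix = M, records = rec,
             embedder = "random", normalized = TRUE)
  e <- data.frame(molecule_id = ids, source_a = "s1", source_b = "s2",
                  stringsAsFactors = FALSE)
  pi <- new("PairIndex", entries = e, kind = "CHD")
  sd_ <- similarityDistributions(emb, emb, pi, seed = 9)
  expect_lt(emd1d(sd_$paired, sd_$null), 0.1)
})

test_that("benchmark report ties the pieces together on synthetic data", {
  cfg <- syntheticConfig(n_molecules = 60, alpha = 0.9, seed = 61)
  gen <- generateCatalog(cfg)
  cat2 <- addCompletedDescriptions(gen$catalog, "HL")
  te <- toyEmbedder()
  embs <- list(CHD = embedCatalog(te, cat2, "CHD"),
               CHL = embedCatalog(te, cat2, "CHL"))
  rep_ <- benchmarkReport(cat2, embs, reference_kind = "CHD",
                          ks = c(1, 5), seed = 3)
  expect_s3_class(rep_, "BenchmarkReport")
  expect_true(rep_$s_hh$mean >= 0 && rep_$s_hh$mean <= 100)
  expect_true(all(diff(rep_$retrieval) >= 0))
  expect_true("CHL" %in% names(rep_$machine))
  tmp_csv <- withr::local_tempfile(fileext = ".csv")
  tmp_json <- withr::local_tempfile(fileext = ".json")
  writeBenchmarkReport(rep_, tmp_csv, tmp_json)
  expect_true(file.exists(tmp_csv) && file.exists(tmp_json))
  back <- jsonlite::read_json(tmp_json)
  expect_equal(back$s_hh$mean, rep_$s_hh$mean, tolerance = 1e-9)
})
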