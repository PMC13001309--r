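test_that("Procrustes exactly recovers a known similarity transform", {
  set.seed(3)
  Q <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(sprintf("o%02d", 1:20), NULL))
  W <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  E <- 1.7 * Q %*% t(W) + rep(1, 20) %o% c(3, -2, 0.5, 1)
  rownames(E) <- rownames(Q)
  fit <- fitProcrustes(Q, E)
  expect_lt(fit$residual, 1e-9)
  expect_equal(fit$map@scale, 1.7, tolerance = 1e-9)
  expect_lt(max(abs(crossprod(fit$map@rotation) - diag(4))), 1e-8)
  pred <- applyAlignment(fit$map, Q)
  expect_equal(pred, E, tolerance = 1e-9)
  # self-alignment is the identity
  self <- fitProcrustes(Q, Q)
  expect_equal(self$residual, 0, tolerance = 1e-12)
  expect_equal(self$map@rotation, diag(4), tolerance = 1e-9)
  expect_equal(self$map@scale, 1, tolerance = 1e-9)
})

test_that("closed-form Procrustes matches a numeric optimizer on n=6, d=3", {
  set.seed(7)
  for (rep in 1:3) {
    Q <- matrix(rnorm(18), 6, 3, dimnames = list(sprintf("o%d", 1:6), NULL))
    E <- matrix(rnorm(18), 6, 3, dimnames = list(sprintf("o%d", 1:6), NULL))
    fit <- fitProcrustes(Q, E)
    Qc <- scale(Q, scale = FALSE); Ec <- scale(E, scale = FALSE)
    # brute force over rotations (Euler angles), both chirality branches; the
    # scale is profiled out in closed form given the rotation
    obj <- function(par, refl) {
      a <- par[1]; b <- par[2]; g <- par[3]
      Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
      Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
      Rx <- rbind(c(1, 0, 0), c(0, cos(g), -sin(g)), c(0, sin(g), cos(g)))
      R <- Rz %*% Ry %*% Rx
      if (refl) R <- R %*% diag(c(1, 1, -1))
      A <- Qc %*% t(R)
      s <- max(0, sum(Ec * A) / sum(A^2))
      sum((Ec - s * A)^2)
    }
    best <- Inf
    for (refl in c(FALSE, TRUE))
      for (start in 1:30) {
        set.seed(100 * rep + start)
        o <- optim(runif(3, -pi, pi), obj, refl = refl,
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14))
        o <- optim(o$par, obj, refl = refl, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
        best <- min(best, o$value)
      }
    expect_equal(fit$residual * sum(Ec^2), best, tolerance = 1e-6)
  }
})

test_that("Procrustes residual is invariant under a common rotation", {
  set.seed(11)
  Q <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(sprintf("o%02d", 1:15), NULL))
  E <- Q %*% matrix(rnorm(9), 3) + matrix(rnorm(45, sd = 0.3), 15, 3)
  rownames(E) <- rownames(Q)
  r0 <- fitProcrustes(Q, E)$residual
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  Qr <- Q %*% t(R); Er <- E %*% t(R)
  rownames(Qr) <- rownames(Er) <- rownames(Q)
  expect_equal(fitProcrustes(Qr, Er)$residual, r0, tolerance = 1e-9)
})

test_that("Procrustes agrees with the vegan implementation where comparable", {
  skip_if_not_installed("vegan")
  set.seed(13)
  Q <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(sprintf("o%02d", 1:12), NULL))
  E <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(sprintf("o%02d", 1:12), NULL))
  fit <- fitProcrustes(Q, E)
  vg <- vegan::procrustes(E, Q, scale = TRUE, symmetric = FALSE)
  expect_equal(fit$residual * sum(scale(E, scale = FALSE)^2),
               sum(stats::residuals(vg)^2), tolerance = 1e-8)
})

test_that("degenerate Procrustes inputs are rejected", {
  Q <- matrix(0, 5, 3, dimnames = list(sprintf("o%d", 1:5), NULL))
  E <- matrix(rnorm(15), 5, 3, dimnames = list(sprintf("o%d", 1:5), NULL))
  expect_error(fitProcrustes(Q, E), "degenerate")
  expect_error(fitProcrustes(E[1:2, ], E[1:2, ]), ">= 3")
  expect_error(fitProcrustes(E, cbind(E, E[, 1])), "dimension mismatch")
})

test_that("LOOCV on a noiseless linear link gives near-perfect CS", {
  set.seed(17)
  Q <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(sprintf("o%02d", 1:20), NULL))
  W <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  E <- 2 * Q %*% t(W) + 1
  rownames(E) <- rownames(Q)
  rep_ <- loocvProcrustes(Q, E, seed = 1)
  expect_gt(mean(rep_$paired), 0.99)
})

test_that("shuffled labels drive LOOCV CS to the random-direction level", {
  set.seed(19)
  n <- 40; d <- 8
  Q <- matrix(rnorm(n * d), n, d, dimnames = list(sprintf("o%02d", 1:n), NULL))
  E <- matrix(rnorm(n * d), n, d, dimnames = list(sprintf("o%02d", 1:n), NULL))
  rep_ <- loocvProcrustes(Q, E, seed = 2)
  # independent Q and E: paired CS behaves like the null
  expect_lt(abs(mean(rep_$paired)),
            abs(mean(rep_$null)) + 3 * (sd(rep_$null) / sqrt(n)) + 0.15)
})

test_that("latent-linked Q and E beat the derangement null decisively", {
  cfg <- syntheticConfig(n_molecules = 59, latent_dim = 6, noise_sigma = 0.3,
                         seed = 23)
  gen <- generateCatalog(cfg)
  Q <- generateNeuralResponses(gen$truth)
  E <- moleculeEmbeddings(toyEmbedder(64), gen$catalog)
  rep_ <- loocvProcrustes(Q, E, seed = 3)
  tt <- t.test(rep_$paired, rep_$null, alternative = "greater")
  expect_lt(tt$p.value, 1e-3)
})

test_that("the invertible embedder round-trips token multisets", {
  inv <- invertibleEmbedder()
  t1 <- "apple apple pear smoke"
  e1 <- invEmbed(inv, t1)
  expect_equal(sort(strsplit(invDecode(inv, e1[1, ]), " ")[[1]]),
               sort(tokenizeText(t1)))
  # catalogue sentence: stopwords are not part of the vocabulary
  t2 <- "This molecule has a cedar, pine odor."
  e2 <- invEmbed(inv, t2)
  expect_setequal(strsplit(invDecode(inv, e2[1, ]), " ")[[1]],
                  c("cedar", "pine"))
  expect_error(invDecode(inv, c(1, 2)), "dimension")
})

test_that("noiseless end-to-end decoding recovers target token multisets", {
  cfg <- syntheticConfig(n_molecules = 20, n_families = 2, latent_dim = 3,
                         seed = 29)
  gen <- generateCatalog(cfg)
  d <- descriptions(gen$catalog)
  d <- d[d$kind == "CHD" & !duplicated(d$molecule_id), ]
  texts <- setNames(d$text, d$molecule_id)
  # small vocabulary so the training embeddings span the whole count space and
  # the left-out prediction is exact
  inv <- invertibleEmbedder(unlist(odieu:::ODOR_FAMILY_VOCAB[1:2],
                                   use.names = FALSE))
  E <- invEmbed(inv, texts)
  rownames(E) <- names(texts)
  # Q is an exact similarity image of the embeddings: predictions are exact
  set.seed(30)
  W <- qr.Q(qr(matrix(rnorm(ncol(E)^2), ncol(E))))
  Q <- 0.5 * E %*% t(W) + 2
  rownames(Q) <- rownames(E)
  res <- neuralToText(Q, texts, inv, seed = 4)
  for (id in names(texts)) {
    got <- sort(strsplit(res$decoded[[id]], " ")[[1]])
    want <- sort(intersect(tokenizeText(texts[[id]]), inv@vocab))
    expect_equal(got, want)
  }
})
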