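# Neural-to-text: align neural response vectors (Q-vectors) with a sentence
# embedding space by a similarity Procrustes transform, evaluate by LOOCV
# against a seeded derangement null, and decode predicted embeddings to text
# through an invertible embedder.

# Match two row-named matrices on shared ids, in a common order.
matchRows <- function(Q, E) {
  if (is.null(rownames(Q)) || is.null(rownames(E)))
    stop("Q and E need molecule/odorant ids as rownames")
  ids <- intersect(rownames(Q), rownames(E))
  if (!length(ids)) stop("no shared odorant ids")
  list(ids = ids, Q = Q[ids, , drop = FALSE], E = E[ids, , drop = FALSE])
}

#' Fit a similarity Procrustes alignment
#'
#' Finds the translation, isotropic scale and orthogonal matrix minimizing
#' ||s W (q - muQ) + muE - e||_F over matched rows, in closed form via the SVD
#' of the centered cross-covariance. Reflections are admitted (orthogonal, not
#' special-orthogonal). Source and target must have equal dimensionality; use
#' \code{\link{loocvProcrustes}} for the PCA-matched high-dimensional case.
#'
#' @param Q numeric n x d neural response matrix with odorant-id rownames.
#' @param E numeric n x d embedding matrix with odorant-id rownames.
#' @return list: map (an \linkS4class{AlignmentMap}), residual (normalized:
#'   ||error||_F^2 / ||E_centered||_F^2), n.
#' @export
fitProcrustes <- function(Q, E) {
  mm <- matchRows(Q, E)
  Q <- mm$Q; E <- mm$E
  n <- nrow(Q)
  if (n < 3) stop("need >= 3 matched odorants")
  if (ncol(Q) != ncol(E))
    stop("dimension mismatch (", ncol(Q), " vs ", ncol(E),
         "); reduce the embedding side first")
  muQ <- colMeans(Q); muE <- colMeans(E)
  Qc <- sweep(Q, 2, muQ); Ec <- sweep(E, 2, muE)
  if (sum(Qc^2) == 0 || sum(Ec^2) == 0)
    stop("degenerate (zero-variance) input")
  C <- crossprod(Ec, Qc)                 # d x d
  sv <- svd(C)
  W <- sv$u %*% t(sv$v)                  # maps Q-space into E-space
  s <- sum(sv$d) / sum(Qc^2)
  fit <- s * Qc %*% t(W)
  residual <- sum((Ec - fit)^2) / sum(Ec^2)
  map <- new("AlignmentMap", rotation = W, scale = s, centerSource = muQ,
             centerTarget = muE, sourceDim = ncol(Q), targetDim = ncol(E))
  list(map = map, residual = residual, n = n)
}

#' Apply an AlignmentMap to rows of a source-space matrix
#' @param map an \linkS4class{AlignmentMap}.
#' @param X numeric matrix (rows in the source space).
#' @return numeric matrix in the target space.
#' @export
applyAlignment <- function(map, X) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, map@centerSource)
  sweep(map@scale * Xc %*% t(map@rotation), 2, map@centerTarget, `+`)
}

#' Leave-one-out Procrustes evaluation with a derangement null
#'
#' For each odorant, the similarity Procrustes map is fitted on the remaining
#' n-1 odorants and applied to the left-out one; the cosine similarity between
#' the predicted and true embeddings is recorded. When the embedding dimension
#' exceeds the neural dimension, the embeddings are reduced to the neural
#' dimension by PCA fitted on the training odorants only, and predictions are
#' mapped back through the transposed loadings before scoring. The null runs
#' the identical protocol with the embedding rows deranged (seeded; no odorant
#' keeps its own embedding).
#'
#' @param Q numeric n x d_q neural matrix (odorant-id rownames).
#' @param E numeric n x D embedding matrix (odorant-id rownames), D >= d_q.
#' @param seed derangement seed.
#' @return list of class "LoocvReport": paired, null (per-odorant CS),
#'   predicted (matrix of predicted embeddings), ids, seed.
#' @export
loocvProcrustes <- function(Q, E, seed = 1L) {
  mm <- matchRows(Q, E)
  Q <- mm$Q; E <- mm$E
  n <- nrow(Q)
  if (n < 4) stop("need >= 4 matched odorants for LOOCV")
  paired_pred <- loocvPredict(Q, E)
  paired <- vapply(seq_len(n), function(i) cosineSim(paired_pred[i, ], E[i, ]), 0)
  set.seed(seed)
  p <- derangement(n)
  Ep <- E[p, , drop = FALSE]
  rownames(Ep) <- rownames(E)
  null_pred <- loocvPredict(Q, Ep)
  null <- vapply(seq_len(n), function(i) cosineSim(null_pred[i, ], Ep[i, ]), 0)
  structure(list(paired = paired, null = null, predicted = paired_pred,
                 ids = mm$ids, seed = seed),
            class = "LoocvReport")
}

# One LOOCV sweep: per left-out odorant, match dimensions by PCA fitted on the
# training odorants only (reducing whichever side exceeds the common rank),
# fit Procrustes on the rest, and predict the left-out embedding in the
# original embedding space via the transposed loadings.
loocvPredict <- function(Q, E) {
  n <- nrow(Q); dq <- ncol(Q); dE <- ncol(E)
  pred <- matrix(0, n, dE, dimnames = dimnames(E))
  r <- min(dq, dE, n - 2L)   # common rank after centering n-1 training rows
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    qs <- pcaProject(Q[tr, , drop = FALSE], Q[i, , drop = FALSE], r)
    es <- pcaProject(E[tr, , drop = FALSE], E[i, , drop = FALSE], r)
    fit <- fitProcrustes(qs$train, es$train)
    sc <- applyAlignment(fit$map, qs$test)
    pred[i, ] <- as.numeric(sc %*% t(es$V)) + es$mu
  }
  pred
}

# Train-only PCA to r components (identity when r == ncol). Returns projected
# train/test rows plus the loadings and mean needed to map back.
pcaProject <- function(train, test, r) {
  d <- ncol(train)
  rn_tr <- rownames(train); rn_te <- rownames(test)
  if (r >= d) {
    V <- diag(d); mu <- rep(0, d)
    return(list(train = train, test = test, V = V, mu = mu))
  }
  mu <- colMeans(train)
  sv <- svd(sweep(train, 2, mu), nu = 0)
  V <- sv$v[, seq_len(r), drop = FALSE]
  tr <- sweep(train, 2, mu) %*% V
  te <- sweep(test, 2, mu) %*% V
  rownames(tr) <- rn_tr; rownames(te) <- rn_te
  list(train = tr, test = te, V = V, mu = mu)
}

#' @export
print.LoocvReport <- function(x, ...) {
  cat(sprintf("Procrustes LOOCV: paired CS = %.3f (SEM %.3f), null CS = %.3f (n = %d)\n",
              mean(x$paired), sem(x$paired), mean(x$null), length(x$paired)))
  invisible(x)
}

#' Toy invertible sentence embedder
#'
#' The embedding of a text is its token-count vector over a fixed vocabulary
#' (stopwords and out-of-vocabulary tokens ignored); inversion rounds the
#' counts and rebuilds the token multiset, so \code{invDecode(inv,
#' invEmbed(inv, t))} reproduces the token multiset of any in-vocabulary text.
#'
#' @param vocab character token vocabulary; default: all built-in odor-family
#'   vocabularies.
#' @return an \linkS4class{InvertibleEmbedder}.
#' @export
invertibleEmbedder <- function(vocab = unlist(ODOR_FAMILY_VOCAB, use.names = FALSE)) {
  new("InvertibleEmbedder", vocab = unique(vocab))
}

#' Embed texts with an invertible embedder
#' @param inv an \linkS4class{InvertibleEmbedder}.
#' @param texts character vector.
#' @return numeric matrix (texts x |vocab|), rownames preserved from texts'
#'   names.
#' @export
invEmbed <- function(inv, texts) {
  V <- inv@vocab
  m <- matrix(0, length(texts), length(V),
              dimnames = list(names(texts), V))
  for (i in seq_along(texts)) {
    toks <- tokenizeText(texts[i])
    toks <- toks[toks %in% V]
    if (length(toks)) {
      tb <- table(toks)
      m[i, names(tb)] <- as.integer(tb)
    }
  }
  m
}

#' Decode an embedding back to text
#' @param inv an \linkS4class{InvertibleEmbedder}.
#' @param embedding numeric vector of length |vocab| (counts, possibly noisy).
#' @return character scalar: the reconstructed tokens joined by spaces (empty
#'   string if all rounded counts are zero).
#' @export
invDecode <- function(inv, embedding) {
  if (length(embedding) != length(inv@vocab))
    stop("embedding dimension does not match the embedder vocabulary")
  counts <- pmax(0L, as.integer(round(embedding)))
  paste(rep(inv@vocab, counts), collapse = " ")
}

#' Full neural-to-text prediction: LOOCV Procrustes then decoding
#'
#' @param Q neural matrix (odorant-id rownames).
#' @param texts named character vector of target sentences (names = odorant
#'   ids).
#' @param inv an \linkS4class{InvertibleEmbedder}.
#' @param seed null-derangement seed.
#' @return list: report (a "LoocvReport"), decoded (named character vector of
#'   predicted texts per odorant).
#' @export
neuralToText <- function(Q, texts, inv = invertibleEmbedder(), seed = 1L) {
  E <- invEmbed(inv, texts)
  rownames(E) <- names(texts)
  rep_ <- loocvProcrustes(Q, E, seed = seed)
  decoded <- vapply(seq_along(rep_$ids), function(i)
    invDecode(inv, rep_$predicted[i, ]), "")
  names(decoded) <- rep_$ids
  list(report = rep_, decoded = decoded)
}
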