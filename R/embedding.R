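#' Embedder dimensionality
#' @param x an \linkS4class{Embedder}.
#' @return integer embedding width.
#' @export
embedderDim <- function(x) x@dim

#' @rdname embedderDim
#' @export
embedderName <- function(x) x@name

# Hashed bag-of-content-words feature vector shared by the toy and trainable
# embedders: stopwords removed, tokens hashed into `dim` buckets, counts.
textFeatures <- function(texts, dim) {
  m <- matrix(0, length(texts), dim)
  for (i in seq_along(texts)) {
    toks <- setdiff(tokenizeText(texts[i]), ODIEU_STOPWORDS)
    if (!length(toks)) next
    idx <- hashString(toks, dim) + 1L
    for (j in idx) m[i, j] <- m[i, j] + 1
  }
  m
}

#' Construct a trainable linear text embedder
#'
#' @param dim embedding dimensionality (must be even: the AnglE-style loss
#'   pairs coordinates into complex numbers).
#' @param featureDim hashed-feature dimensionality.
#' @param seed seed for the Gaussian weight initialization.
#' @return a \linkS4class{LinearTextEmbedder}.
#' @export
linearTextEmbedder <- function(dim = 32L, featureDim = 256L, seed = 1L) {
  if (dim %% 2L != 0L) stop("dim must be even")
  set.seed(seed)
  W <- matrix(rnorm(dim * featureDim, sd = 1 / sqrt(featureDim)),
              dim, featureDim)
  new("LinearTextEmbedder",
      name = sprintf("linear-%dx%d", dim, featureDim),
      dim = as.integer(dim), featureDim = as.integer(featureDim), weights = W)
}

setGeneric("rawEmbed", function(embedder, texts) standardGeneric("rawEmbed"))

setMethod("rawEmbed", "HashEmbedder", function(embedder, texts) {
  textFeatures(texts, embedder@dim)
})

setMethod("rawEmbed", "LinearTextEmbedder", function(embedder, texts) {
  textFeatures(texts, embedder@featureDim) %*% t(embedder@weights)
})

#' Embed a list of texts
#'
#' One row per text, unit-normalized. Backend failures are reported with the
#' index of the offending text.
#'
#' @param embedder an \linkS4class{Embedder}.
#' @param texts character vector (non-empty).
#' @param records optional data.frame of per-text metadata (same row count).
#' @return an \linkS4class{EmbeddingMatrix}.
#' @export
embedTexts <- function(embedder, texts, records = NULL) {
  stopifnot(is(embedder, "Embedder"), length(texts) >= 1)
  m <- tryCatch(rawEmbed(embedder, texts), error = function(e)
    stop("embedding backend failed: ", conditionMessage(e)))
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0))
    stop("embedding backend produced a zero vector for text index ",
         which(nrm == 0)[1L])
  m <- m / nrm
  if (is.null(records))
    records <- data.frame(molecule_id = NA_character_, source = NA_character_,
                          kind = NA_character_, text = texts,
                          stringsAsFactors = FALSE)
  new("EmbeddingMatrix", matrix = m, records = records,
      embedder = embedder@name, normalized = TRUE)
}

#' Embed all descriptions of one kind in a catalogue
#'
#' @param embedder an \linkS4class{Embedder}.
#' @param catalog an \linkS4class{OdorCatalog}.
#' @param kind description kind to embed.
#' @return an \linkS4class{EmbeddingMatrix} whose records carry molecule_id,
#'   source, kind and text.
#' @export
embedCatalog <- function(embedder, catalog, kind) {
  d <- descriptions(catalog)
  d <- d[d$kind == kind, c("molecule_id", "source", "kind", "text")]
  if (!nrow(d)) stop("no descriptions of kind ", kind)
  embedTexts(embedder, d$text, records = d)
}

#' Embedding matrix accessors
#' @param x an \linkS4class{EmbeddingMatrix}.
#' @export
embeddingRows <- function(x) x@matrix

#' @rdname embeddingRows
#' @export
embeddingRecords <- function(x) x@records

#' Build labeled contrastive pairs from a catalogue
#'
#' Positives are all cross-source same-molecule pairs of the given kind;
#' negatives are different-molecule pairs sampled uniformly at a configurable
#' ratio, seeded.
#'
#' @param catalog an \linkS4class{OdorCatalog}.
#' @param kind description kind.
#' @param negative_ratio negatives per positive (default 1).
#' @param seed sampling seed.
#' @return data.frame with columns molecule_a, molecule_b, text_a, text_b,
#'   is_positive.
#' @export
buildContrastivePairs <- function(catalog, kind, negative_ratio = 1, seed = 1L) {
  pi <- crossSourcePairs(catalog, kind)
  if (pairCount(pi) == 0)
    stop("no cross-source positives for kind ", kind)
  pt <- pairTexts(catalog, pi)
  pos <- data.frame(molecule_a = pt$molecule_id, molecule_b = pt$molecule_id,
                    text_a = pt$text_a, text_b = pt$text_b,
                    is_positive = TRUE, stringsAsFactors = FALSE)
  d <- descriptions(catalog)
  d <- d[d$kind == kind, ]
  n_neg <- round(negative_ratio * nrow(pos))
  set.seed(seed)
  neg_list <- vector("list", 0)
  made <- 0L
  while (made < n_neg) {
    i <- sample.int(nrow(d), n_neg - made, replace = TRUE)
    j <- sample.int(nrow(d), n_neg - made, replace = TRUE)
    ok <- d$molecule_id[i] != d$molecule_id[j]
    if (!any(ok)) next
    neg_list[[length(neg_list) + 1L]] <- data.frame(
      molecule_a = d$molecule_id[i[ok]], molecule_b = d$molecule_id[j[ok]],
      text_a = d$text[i[ok]], text_b = d$text[j[ok]],
      is_positive = FALSE, stringsAsFactors = FALSE)
    made <- made + sum(ok)
  }
  out <- rbind(pos, do.call(rbind, neg_list))
  rownames(out) <- NULL
  out
}

#' Fine-tuning configuration
#'
#' @param n_folds cross-validation folds partitioning molecules (default 5).
#' @param loss "angle" (AnglE-style: logistic contrast on cosine similarity
#'   plus logistic contrast on the complex-phase angle distance) or "cosine"
#'   (cosine term only).
#' @param epochs full-batch gradient steps (default 30).
#' @param lr Adam learning rate.
#' @param tau softmax temperature of the ranking losses.
#' @param w_angle weight of the angle objective relative to the cosine one.
#' @param margin center of the logistic contrast for loss = "cosine".
#' @param seed training / fold-assignment seed.
#' @return list of class "FinetuneConfig".
#' @export
finetuneConfig <- function(n_folds = 5L, loss = c("angle", "cosine"),
                           epochs = 30L, lr = 0.05, tau = 0.05,
                           w_angle = 1, margin = 0.5, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(n_folds >= 2, epochs >= 0, lr > 0, tau > 0)
  structure(list(n_folds = as.integer(n_folds), loss = loss,
                 epochs = as.integer(epochs), lr = lr, tau = tau,
                 w_angle = w_angle, margin = margin, seed = as.integer(seed)),
            class = "FinetuneConfig")
}

ANGLE_MARGIN <- 0.4  # angle-distance margin; 0.5 is the random-phase level

# ---- contrastive loss + analytic gradient -----------------------------------
# Pairs are embedded unnormalized (u = W xa, v = W xb); cosine and the
# per-coordinate complex-phase angle distance are both scale-invariant, so
# normalization is deferred to inference.

cosineAndGrad <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  s <- sum(u * v) / (nu * nv)
  list(s = s,
       du = v / (nu * nv) - s * u / nu^2,
       dv = u / (nu * nv) - s * v / nv^2)
}

# Angle distance in [0, 1]: coordinates are paired into complex numbers
# (first half real, second half imaginary); per coordinate the 2-D cosine of
# the phase difference is computed and averaged.
angleAndGrad <- function(u, v, eps = 1e-12) {
  m <- length(u) %/% 2L
  pu <- cbind(u[1:m], u[(m + 1):(2 * m)])
  pv <- cbind(v[1:m], v[(m + 1):(2 * m)])
  nu <- sqrt(rowSums(pu^2)) + eps
  nv <- sqrt(rowSums(pv^2)) + eps
  cj <- rowSums(pu * pv) / (nu * nv)
  a <- mean((1 - cj) / 2)
  dc_du <- pv / (nu * nv) - (cj / nu^2) * pu
  dc_dv <- pu / (nu * nv) - (cj / nv^2) * pv
  fac <- -1 / (2 * m)
  list(a = a,
       du = fac * c(dc_du[, 1], dc_du[, 2]),
       dv = fac * c(dc_dv[, 1], dc_dv[, 2]))
}

# Full-batch loss and gradient wrt W for a labeled pair set.
contrastiveLossGrad <- function(W, Xa, Xb, positive, config) {
  n <- nrow(Xa)
  U <- Xa %*% t(W)
  V <- Xb %*% t(W)
  dU <- matrix(0, n, nrow(W)); dV <- matrix(0, n, nrow(W))
  s <- numeric(n); a <- numeric(n)
  gs <- vector("list", n); ga <- vector("list", n)
  for (i in seq_len(n)) {
    cg <- cosineAndGrad(U[i, ], V[i, ])
    s[i] <- cg$s; gs[[i]] <- cg
    if (config$loss == "angle") {
      agr <- angleAndGrad(U[i, ], V[i, ])
      a[i] <- agr$a; ga[[i]] <- agr
    }
  }
  loss <- 0
  ds <- numeric(n); da <- numeric(n)
  tau <- config$tau
  y <- ifelse(positive, 1, -1)
  # cosine objective: logistic contrast around the margin
  z <- -y * (s - config$margin) / tau
  loss <- loss + sum(log1p(exp(z)))
  ds <- ds - y / tau * stats::plogis(z)
  if (config$loss == "angle") {
    # angle objective: positives should sit below the angle-distance margin
    # (0.5 is the chance level for random phases), negatives above it
    za <- y * (a - ANGLE_MARGIN) / tau
    loss <- loss + config$w_angle * sum(log1p(exp(za)))
    da <- da + config$w_angle * y / tau * stats::plogis(za)
  }
  for (i in seq_len(n)) {
    if (ds[i] != 0) {
      dU[i, ] <- dU[i, ] + ds[i] * gs[[i]]$du
      dV[i, ] <- dV[i, ] + ds[i] * gs[[i]]$dv
    }
    if (da[i] != 0) {
      dU[i, ] <- dU[i, ] + da[i] * ga[[i]]$du
      dV[i, ] <- dV[i, ] + da[i] * ga[[i]]$dv
    }
  }
  gradW <- t(dU) %*% Xa + t(dV) %*% Xb
  list(loss = loss, grad = gradW)
}

# Adam on the projection matrix; full batch, `epochs` steps.
trainProjection <- function(W, Xa, Xb, positive, config) {
  mW <- W * 0; vW <- W * 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(config$epochs)
  for (t in seq_len(config$epochs)) {
    lg <- contrastiveLossGrad(W, Xa, Xb, positive, config)
    trace[t] <- lg$loss
    mW <- b1 * mW + (1 - b1) * lg$grad
    vW <- b2 * vW + (1 - b2) * lg$grad^2
    W <- W - config$lr * (mW / (1 - b1^t)) / (sqrt(vW / (1 - b2^t)) + eps)
  }
  list(W = W, trace = trace)
}

#' Contrastively fine-tune an embedder with molecule-level cross-validation
#'
#' Molecules are partitioned into folds; each fold's model is trained only on
#' pairs whose molecules are both out-of-fold, so every molecule is evaluated
#' exactly once, by the model that never saw it. Training is seeded and
#' deterministic.
#'
#' @param embedder a trainable embedder (\linkS4class{LinearTextEmbedder});
#'   non-trainable embedders raise a capability error.
#' @param pairs labeled pair data.frame from
#'   \code{\link{buildContrastivePairs}}.
#' @param config a \code{\link{finetuneConfig}}.
#' @return list of class "FinetunedEmbedder": \code{models} (one per fold),
#'   \code{fold} (named integer: molecule -> held-out fold), \code{config},
#'   \code{traces} (per-fold loss traces).
#' @export
finetuneEmbedder <- function(embedder, pairs, config = finetuneConfig()) {
  if (!is(embedder, "LinearTextEmbedder"))
    stop("embedder does not support gradient training")
  mols <- sort(unique(c(pairs$molecule_a, pairs$molecule_b)))
  if (length(mols) < config$n_folds)
    stop("fewer molecules than folds")
  set.seed(config$seed)
  fold <- setNames(sample(rep_len(seq_len(config$n_folds), length(mols))),
                   mols)
  models <- vector("list", config$n_folds)
  traces <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    train <- pairs[fold[pairs$molecule_a] != f & fold[pairs$molecule_b] != f, ]
    W <- embedder@weights
    if (config$epochs > 0 && nrow(train) > 0) {
      Xa <- textFeatures(train$text_a, embedder@featureDim)
      Xb <- textFeatures(train$text_b, embedder@featureDim)
      fit <- trainProjection(W, Xa, Xb, train$is_positive, config)
      W <- fit$W; traces[[f]] <- fit$trace
    } else traces[[f]] <- numeric(0)
    e <- embedder
    e@weights <- W
    e@name <- sprintf("%s-ft-fold%d", embedder@name, f)
    models[[f]] <- e
  }
  structure(list(models = models, fold = fold, config = config,
                 traces = traces, base = embedder),
            class = "FinetunedEmbedder")
}

#' Embed catalogue descriptions with held-out fold models
#'
#' Evaluation hygiene: each description is embedded by the fold model for which
#' its molecule was held out, so no reported similarity involves a model that
#' saw the molecule in training.
#'
#' @param finetuned a "FinetunedEmbedder" from \code{\link{finetuneEmbedder}}.
#' @param catalog an \linkS4class{OdorCatalog}.
#' @param kind description kind.
#' @return an \linkS4class{EmbeddingMatrix}.
#' @export
heldOutEmbed <- function(finetuned, catalog, kind) {
  d <- descriptions(catalog)
  d <- d[d$kind == kind, c("molecule_id", "source", "kind", "text")]
  if (!nrow(d)) stop("no descriptions of kind ", kind)
  f <- finetuned$fold[d$molecule_id]
  if (any(is.na(f)))
    stop("molecule(s) not covered by the fold assignment: ",
         paste(head(unique(d$molecule_id[is.na(f)])), collapse = ", "))
  D <- embedderDim(finetuned$models[[1]])
  m <- matrix(0, nrow(d), D)
  for (k in sort(unique(f))) {
    idx <- which(f == k)
    m[idx, ] <- embeddingRows(embedTexts(finetuned$models[[k]], d$text[idx]))
  }
  new("EmbeddingMatrix", matrix = m, records = d,
      embedder = sprintf("%s-ft-heldout", finetuned$base@name),
      normalized = TRUE)
}
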