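# Structure-to-text by prefix tuning: a trainable 4-layer MLP encoder projects
# molecular descriptor vectors into the token-embedding space of a frozen
# causal language model; gradients flow through the language model into the
# encoder, never into the language model's own weights.

#' Build a tiny randomly-initialized causal language model
#'
#' A miniature word-level causal LM (a few thousand parameters) exercising the
#' full prefix-tuning contract on one CPU: the context state at position t
#' mixes the prefix mean (fixed weight, so the conditioning never washes out
#' during generation) with a recency-decayed mean of the preceding token
#' embeddings, then goes through a tanh layer and a projection to vocabulary
#' logits. Its parameters are frozen: training never touches them, which
#' \code{\link{lmFingerprint}} certifies.
#'
#' @param vocab character token vocabulary ("<bos>"/"<eos>" added if absent).
#' @param embed_width token-embedding width E (default 16).
#' @param seed initialization seed.
#' @return a \linkS4class{TinyCausalLM}.
#' @export
tinyCausalLM <- function(vocab, embed_width = 16L, seed = 1L) {
  vocab <- unique(c("<bos>", "<eos>", vocab))
  set.seed(seed)
  V <- length(vocab); E <- as.integer(embed_width)
  new("TinyCausalLM", vocab = vocab,
      tokenEmb = matrix(rnorm(V * E, sd = 0.5), V, E,
                        dimnames = list(vocab, NULL)),
      contextW = matrix(rnorm(E * E, sd = 1 / sqrt(E)), E, E),
      contextB = rnorm(E, sd = 0.1),
      outputW = matrix(rnorm(V * E, sd = 1 / sqrt(E)), V, E,
                       dimnames = list(vocab, NULL)),
      embedWidth = E)
}

LM_DECAY <- 0.6   # recency decay of the token-context mean
LM_PREFIX_MIX <- 0.5  # weight of the prefix mean in the context state

#' Fingerprint of a language model's weights
#'
#' FNV-1a hash over the serialized parameter tensors; identical before and
#' after any encoder training run (the freeze contract).
#'
#' @param lm a \linkS4class{TinyCausalLM}.
#' @return character scalar (8 hex digits).
#' @export
lmFingerprint <- function(lm) {
  # hash a canonical text rendering (12 significant digits) so the fingerprint
  # survives text-based serialization while catching any training-sized change
  vals <- c(as.numeric(lm@tokenEmb), as.numeric(lm@contextW),
            lm@contextB, as.numeric(lm@outputW))
  fnv1a(c(lm@vocab, sprintf("%.12g", vals)))
}

#' Build an LM vocabulary from a text corpus
#' @param texts character vector.
#' @return character vector of unique tokens.
#' @export
buildLMVocab <- function(texts) {
  unique(unlist(lapply(texts, tokenizeText)))
}

lmTokenIds <- function(lm, text) {
  toks <- tokenizeText(text)
  unknown <- setdiff(toks, lm@vocab)
  if (length(unknown))
    stop("text contains tokens outside the LM vocabulary: ",
         paste(head(unknown, 3), collapse = ", "))
  match(toks, lm@vocab)
}

# Context state at a decoding position: a fixed-weight mix of the prefix mean
# (persistent conditioning on the molecule) and a recency-decayed mean of the
# token embeddings seen so far.
lmContext <- function(prefix, tokenRows) {
  cn <- nrow(tokenRows)
  w <- LM_DECAY^((cn - 1):0)
  w <- w / sum(w)
  list(g = LM_PREFIX_MIX * colMeans(prefix) +
         (1 - LM_PREFIX_MIX) * as.numeric(w %*% tokenRows),
       w = w)
}

# Teacher-forced next-token loss of `target_ids` (+ <eos>) conditioned on the
# prefix matrix; returns loss (mean NLL over target positions only) and the
# gradient wrt the prefix rows. Prefix positions condition every step but are
# excluded from the loss.
lmLossAndPrefixGrad <- function(lm, prefix, target_ids) {
  k <- nrow(prefix); E <- lm@embedWidth
  bos <- match("<bos>", lm@vocab); eos <- match("<eos>", lm@vocab)
  y <- c(target_ids, eos)
  Tn <- length(y)
  toks <- rbind(lm@tokenEmb[bos, , drop = FALSE],
                lm@tokenEmb[y[-Tn], , drop = FALSE])
  loss <- 0
  dPrefix <- matrix(0, k, E)
  for (t in seq_len(Tn)) {
    ctx <- lmContext(prefix, toks[seq_len(t), , drop = FALSE])
    h <- tanh(lm@contextW %*% ctx$g + lm@contextB)
    z <- as.numeric(lm@outputW %*% h)
    z <- z - max(z)
    p <- exp(z) / sum(exp(z))
    loss <- loss - log(p[y[t]])
    dz <- p; dz[y[t]] <- dz[y[t]] - 1
    dh <- as.numeric(t(lm@outputW) %*% dz)
    dg <- as.numeric(t(lm@contextW) %*% (dh * (1 - as.numeric(h)^2)))
    # every prefix row enters the context with weight LM_PREFIX_MIX / k
    dPrefix <- dPrefix + (LM_PREFIX_MIX / k) * rep(1, k) %o% dg
  }
  list(loss = loss / Tn, dPrefix = dPrefix / Tn)
}

#' Construct a prefix encoder
#'
#' A 4-layer tanh multilayer perceptron (the final layer linear) mapping a
#' molecular descriptor to k prefix slots of width E. Only these parameters
#' are trainable.
#'
#' @param input_dim descriptor length.
#' @param k number of prefix slots (default 10).
#' @param embed_width LM token-embedding width E.
#' @param hidden hidden-layer width (default 32).
#' @param n_layers number of layers (default 4).
#' @param seed initialization seed.
#' @param zero_final initialize the final layer at zero (all-zero prefix for
#'   any descriptor), default FALSE.
#' @return a \linkS4class{PrefixEncoder}.
#' @export
prefixEncoder <- function(input_dim, k = 10L, embed_width = 16L, hidden = 32L,
                          n_layers = 4L, seed = 1L, zero_final = FALSE) {
  stopifnot(n_layers >= 2)
  set.seed(seed)
  dims <- c(input_dim, rep(hidden, n_layers - 1L), k * embed_width)
  weights <- list(); biases <- list()
  for (l in seq_len(n_layers)) {
    weights[[l]] <- matrix(rnorm(dims[l + 1] * dims[l], sd = 1 / sqrt(dims[l])),
                           dims[l + 1], dims[l])
    biases[[l]] <- numeric(dims[l + 1])
  }
  if (zero_final) weights[[n_layers]][] <- 0
  new("PrefixEncoder", weights = weights, biases = biases, k = as.integer(k),
      embedWidth = as.integer(embed_width), inputDim = as.integer(input_dim),
      center = numeric(input_dim), scaleVec = rep(1, input_dim))
}

encoderForward <- function(encoder, x) {
  x <- (x - encoder@center) / encoder@scaleVec
  L <- length(encoder@weights)
  acts <- vector("list", L + 1L)
  acts[[1]] <- x
  for (l in seq_len(L)) {
    z <- as.numeric(encoder@weights[[l]] %*% acts[[l]] + encoder@biases[[l]])
    acts[[l + 1]] <- if (l < L) tanh(z) else z
  }
  acts
}

#' Encode a descriptor into a prefix matrix
#'
#' Deterministic forward pass through the encoder MLP; the output vector is
#' reshaped to k rows of width E.
#'
#' @param encoder a \linkS4class{PrefixEncoder}.
#' @param descriptor numeric vector of length \code{encoder@inputDim}.
#' @return numeric k x E prefix matrix.
#' @export
encodePrefix <- function(encoder, descriptor) {
  if (length(descriptor) != encoder@inputDim)
    stop("descriptor length ", length(descriptor),
         " does not match encoder input dim ", encoder@inputDim)
  out <- encoderForward(encoder, as.numeric(descriptor))
  matrix(out[[length(out)]], encoder@k, encoder@embedWidth, byrow = TRUE)
}

# Backprop the prefix gradient through the MLP; returns per-layer gradients.
encoderBackward <- function(encoder, acts, dPrefix) {
  L <- length(encoder@weights)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- as.numeric(t(dPrefix))      # matches byrow reshape in encodePrefix
  for (l in L:1) {
    dW[[l]] <- outer(delta, acts[[l]])
    db[[l]] <- delta
    if (l > 1) {
      delta <- as.numeric(t(encoder@weights[[l]]) %*% delta)
      delta <- delta * (1 - acts[[l]]^2)   # through tanh
    }
  }
  list(dW = dW, db = db)
}

#' CIRANO training configuration
#'
#' @param k prefix slots; @param hidden encoder hidden width; @param n_layers
#'   encoder depth; @param epochs training epochs; @param lr Adam learning
#'   rate; @param max_len decoding length cap; @param seed seed.
#' @return list of class "CiranoConfig".
#' @export
ciranoConfig <- function(k = 10L, hidden = 32L, n_layers = 4L, epochs = 50L,
                         lr = 0.02, max_len = 20L, seed = 1L) {
  structure(list(k = as.integer(k), hidden = as.integer(hidden),
                 n_layers = as.integer(n_layers), epochs = as.integer(epochs),
                 lr = lr, max_len = as.integer(max_len),
                 seed = as.integer(seed)),
            class = "CiranoConfig")
}

#' Train a prefix encoder against a frozen language model
#'
#' Minimizes the teacher-forced next-token negative log-likelihood of each
#' target text conditioned on its molecule's prefix, over the encoder
#' parameters only. Descriptors are z-scored per dimension with training-set
#' statistics stored in the encoder. The LM weight fingerprint is checked
#' before and after; any mutation is a hard failure.
#'
#' @param descriptors numeric matrix (molecules x d) with molecule-id
#'   rownames.
#' @param texts named character vector of target texts (names = molecule ids).
#' @param lm a \linkS4class{TinyCausalLM} whose vocabulary covers the texts.
#' @param config a \code{\link{ciranoConfig}}.
#' @return list of class "CiranoModel": encoder, lm, loss_trace (mean NLL per
#'   epoch), fingerprint, config.
#' @export
trainEncoder <- function(descriptors, texts, lm, config = ciranoConfig()) {
  ids <- intersect(rownames(descriptors), names(texts))
  if (length(ids) < 1) stop("no molecules shared by descriptors and texts")
  X <- descriptors[ids, , drop = FALSE]
  fp0 <- lmFingerprint(lm)
  enc <- prefixEncoder(ncol(X), k = config$k, embed_width = lm@embedWidth,
                       hidden = config$hidden, n_layers = config$n_layers,
                       seed = config$seed)
  enc@center <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[!is.finite(sdv) | sdv <= 0] <- 1   # single-pair or constant dimensions
  enc@scaleVec <- sdv
  token_ids <- lapply(texts[ids], function(tx) lmTokenIds(lm, tx))

  L <- length(enc@weights)
  mW <- lapply(enc@weights, function(w) w * 0)
  vW <- mW
  mb <- lapply(enc@biases, function(b) b * 0)
  vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  trace <- numeric(config$epochs)
  set.seed(config$seed)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(seq_along(ids))
    ep_loss <- 0
    for (i in ord) {
      acts <- encoderForward(enc, X[i, ])
      prefix <- matrix(acts[[length(acts)]], config$k, lm@embedWidth,
                       byrow = TRUE)
      lg <- lmLossAndPrefixGrad(lm, prefix, token_ids[[i]])
      ep_loss <- ep_loss + lg$loss
      gr <- encoderBackward(enc, acts, lg$dPrefix)
      step <- step + 1L
      for (l in seq_len(L)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gr$dW[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gr$dW[[l]]^2
        enc@weights[[l]] <- enc@weights[[l]] - config$lr *
          (mW[[l]] / (1 - b1^step)) / (sqrt(vW[[l]] / (1 - b2^step)) + eps)
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gr$db[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gr$db[[l]]^2
        enc@biases[[l]] <- enc@biases[[l]] - config$lr *
          (mb[[l]] / (1 - b1^step)) / (sqrt(vb[[l]] / (1 - b2^step)) + eps)
      }
    }
    trace[ep] <- ep_loss / length(ids)
  }
  if (!identical(lmFingerprint(lm), fp0))
    stop("freeze contract violated: language model weights changed")
  structure(list(encoder = enc, lm = lm, loss_trace = trace,
                 fingerprint = fp0, config = config),
            class = "CiranoModel")
}

#' Generate a description from a molecular descriptor
#'
#' Decodes from the frozen LM conditioned on the encoder's prefix. Greedy
#' decoding (default) is deterministic; "sample" draws from the softmax with
#' the given seed. An immediate end-of-sequence yields an empty string with
#' attribute \code{empty = TRUE} (flagged, not fatal).
#'
#' @param model a "CiranoModel" from \code{\link{trainEncoder}} (or a list
#'   with encoder + lm).
#' @param descriptor numeric descriptor vector.
#' @param decoding "greedy" or "sample".
#' @param max_len maximum generated tokens.
#' @param min_len tokens to emit before end-of-sequence is admissible.
#' @param seed sampling seed (ignored for greedy).
#' @return character scalar.
#' @export
generateDescription <- function(model, descriptor,
                                decoding = c("greedy", "sample"),
                                max_len = 20L, min_len = 4L, seed = 1L) {
  decoding <- match.arg(decoding)
  lm <- model$lm; enc <- model$encoder
  prefix <- encodePrefix(enc, descriptor)
  bos <- match("<bos>", lm@vocab); eos <- match("<eos>", lm@vocab)
  toks <- lm@tokenEmb[bos, , drop = FALSE]
  if (decoding == "sample") set.seed(seed)
  out <- integer(0)
  for (t in seq_len(max_len)) {
    g <- lmContext(prefix, toks)$g
    h <- tanh(lm@contextW %*% g + lm@contextB)
    z <- as.numeric(lm@outputW %*% h)
    z[bos] <- -Inf                      # never re-emit <bos>
    if (length(out) < min_len) z[eos] <- -Inf
    # no-repeat constraint under greedy decoding: a small frozen model easily
    # reaches fixed points of its context recursion, so each token is emitted
    # at most once
    if (decoding == "greedy" && length(out)) z[out] <- -Inf
    nxt <- if (decoding == "greedy") which.max(z) else {
      zz <- z - max(z[is.finite(z)])
      p <- exp(zz); p[!is.finite(p)] <- 0
      sample.int(length(z), 1, prob = p / sum(p))
    }
    if (nxt == eos) break
    out <- c(out, nxt)
    toks <- rbind(toks, lm@tokenEmb[nxt, , drop = FALSE])
  }
  txt <- paste(lm@vocab[out], collapse = " ")
  if (!length(out)) attr(txt, "empty") <- TRUE
  txt
}
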