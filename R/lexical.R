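# Model-free sentence-similarity metrics on the 0-100 scale, all built on the
# shared tokenizer (tokenizeText). Implementations follow the original metric
# definitions; design choices where the definitions leave room (tokenizer,
# smoothing, ROUGE-L beta, METEOR matcher) are documented per function and in
# the methods vignette.

ngrams <- function(tokens, n) {
  if (length(tokens) < n) return(character(0))
  if (n == 1) return(tokens)
  vapply(seq_len(length(tokens) - n + 1L),
         function(i) paste(tokens[i:(i + n - 1L)], collapse = " "), "")
}

#' BLEU score
#'
#' Modified n-gram precision with brevity penalty, geometric mean over orders
#' 1..\code{max_n}, times 100. Unsmoothed by default (any zero precision gives
#' a 0 score, as in the original definition); \code{smooth = "add1"} applies
#' add-one smoothing to orders above 1 for corpora of very short texts.
#'
#' @param candidate candidate text.
#' @param references character vector of one or more reference texts.
#' @param max_n highest n-gram order, 1 or 4 (default 4).
#' @param smooth "none" (default) or "add1".
#' @return score in [0, 100].
#' @examples
#' bleu("a b c d", "a b x d", max_n = 1) # 75
#' @export
bleu <- function(candidate, references, max_n = 4L, smooth = c("none", "add1")) {
  smooth <- match.arg(smooth)
  stopifnot(max_n %in% c(1L, 4L) || (max_n >= 1 && max_n <= 9))
  cand <- tokenizeText(candidate)
  if (!length(cand)) stop("empty candidate after tokenization")
  if (!length(references)) stop("empty reference list")
  refs <- lapply(references, tokenizeText)
  if (any(!vapply(refs, length, 0L))) stop("empty reference after tokenization")

  logp <- numeric(max_n)
  for (n in seq_len(max_n)) {
    cgrams <- ngrams(cand, n)
    total <- length(cgrams)
    if (total == 0) { logp[n] <- -Inf; next }
    ctab <- table(cgrams)
    clip <- rep(0, length(ctab))
    for (r in refs) {
      rtab <- table(ngrams(r, n))
      hit <- pmin(as.integer(ctab),
                  as.integer(rtab[names(ctab)]) * (names(ctab) %in% names(rtab)))
      hit[is.na(hit)] <- 0
      clip <- pmax(clip, hit)
    }
    num <- sum(clip); den <- total
    if (smooth == "add1" && n > 1) { num <- num + 1; den <- den + 1 }
    logp[n] <- if (num == 0) -Inf else log(num / den)
  }
  if (any(!is.finite(logp))) return(0)
  # brevity penalty against the closest reference length (ties -> shorter)
  rl <- vapply(refs, length, 0L)
  r <- rl[order(abs(rl - length(cand)), rl)][1L]
  bp <- if (length(cand) > r) 1 else exp(1 - r / length(cand))
  100 * bp * exp(mean(logp))
}

# longest common subsequence length via dynamic programming
lcsLength <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' ROUGE-L score
#'
#' Longest-common-subsequence F-measure times 100, with the harmonic mean
#' (beta = 1) of LCS precision and recall.
#'
#' @param candidate,reference texts.
#' @return score in [0, 100].
#' @examples
#' rougeL("a b c d", "a c d") # 2*(3/4)*(3/3)/(3/4 + 3/3) * 100
#' @export
rougeL <- function(candidate, reference) {
  cand <- tokenizeText(candidate); ref <- tokenizeText(reference)
  if (!length(cand)) stop("empty candidate after tokenization")
  if (!length(ref)) stop("empty reference after tokenization")
  l <- lcsLength(cand, ref)
  if (l == 0) return(0)
  p <- l / length(cand); r <- l / length(ref)
  100 * 2 * p * r / (p + r)
}

# Lightweight English suffix stemmer used by METEOR's stem-match stage.
lightStem <- function(tokens) {
  out <- tokens
  for (suf in c("ingly", "edly", "ing", "ed", "ly", "ies", "es", "s")) {
    hit <- endsWith(out, suf) & nchar(out) > nchar(suf) + 2L
    out[hit] <- substr(out[hit], 1L, nchar(out[hit]) - nchar(suf))
  }
  out
}

#' METEOR score
#'
#' Unigram alignment in two stages (exact match, then lightweight suffix-stem
#' match), harmonic-mean F (recall weighted 9:1), and the fragmentation
#' penalty 0.5 (chunks / matches)^3; score = F * (1 - penalty) * 100. The
#' alignment is greedy left-to-right (each candidate token takes the first
#' unmatched matching reference token), which is deterministic.
#'
#' @param candidate,reference texts.
#' @return score in [0, 100]. An identity pair scores
#'   \code{100 * (1 - 0.5 / m^3)} for m matched tokens (single chunk).
#' @export
meteor <- function(candidate, reference) {
  cand <- tokenizeText(candidate); ref <- tokenizeText(reference)
  if (!length(cand)) stop("empty candidate after tokenization")
  if (!length(ref)) stop("empty reference after tokenization")

  match_ref <- rep(NA_integer_, length(cand))
  used <- logical(length(ref))
  for (stage in 1:2) {
    cc <- if (stage == 1) cand else lightStem(cand)
    rr <- if (stage == 1) ref else lightStem(ref)
    for (i in seq_along(cand)) {
      if (!is.na(match_ref[i])) next
      j <- which(!used & rr == cc[i])
      if (length(j)) { match_ref[i] <- j[1L]; used[j[1L]] <- TRUE }
    }
  }
  m <- sum(!is.na(match_ref))
  if (m == 0) return(0)
  p <- m / length(cand); r <- m / length(ref)
  fmean <- 10 * p * r / (r + 9 * p)
  mi <- which(!is.na(match_ref))
  chunks <- 1L
  if (length(mi) > 1L) {
    for (t in 2:length(mi)) {
      contiguous <- mi[t] == mi[t - 1L] + 1L &&
        match_ref[mi[t]] == match_ref[mi[t - 1L]] + 1L
      if (!contiguous) chunks <- chunks + 1L
    }
  }
  penalty <- 0.5 * (chunks / m)^3
  100 * fmean * (1 - penalty)
}

#' Hashed one-hot token embedder for BERTScore tests
#'
#' Maps each token to a one-hot vector at its hash bucket; collision-free for
#' small vocabularies, making greedy-match cosine equal to exact token match.
#'
#' @param dim bucket count (default 1024).
#' @return function(tokens) -> matrix (tokens x dim).
#' @export
toyTokenEmbedder <- function(dim = 1024L) {
  force(dim)
  function(tokens) {
    m <- matrix(0, length(tokens), dim)
    if (length(tokens)) m[cbind(seq_along(tokens), hashString(tokens, dim) + 1L)] <- 1
    m
  }
}

#' BERTScore F1
#'
#' Greedy cosine matching between per-token embeddings: recall is the mean over
#' reference tokens of the best cosine to any candidate token, precision the
#' converse; F1 = 2PR/(P+R), times 100. The token embedder is pluggable; no
#' baseline rescaling is applied.
#'
#' @param candidate,reference texts.
#' @param token_embedder function(tokens) -> matrix (tokens x dim); default
#'   \code{\link{toyTokenEmbedder}()}.
#' @return score in [0, 100].
#' @export
bertScore <- function(candidate, reference, token_embedder = toyTokenEmbedder()) {
  cand <- tokenizeText(candidate); ref <- tokenizeText(reference)
  if (!length(cand)) stop("empty candidate after tokenization")
  if (!length(ref)) stop("empty reference after tokenization")
  Ec <- normalizeRows(token_embedder(cand))
  Er <- normalizeRows(token_embedder(ref))
  S <- Er %*% t(Ec)                     # ref x cand cosine matrix
  r <- mean(apply(S, 1, max))
  p <- mean(apply(S, 2, max))
  if (p + r == 0) return(0)
  100 * 2 * p * r / (p + r)
}

#' MetricScore summary
#' @param scores numeric per-pair scores on the 0-100 scale.
#' @param metric metric name.
#' @return list of class "MetricScore": metric, mean, sem, n.
#' @export
metricScore <- function(scores, metric) {
  stopifnot(length(scores) >= 1)
  structure(list(metric = metric, mean = mean(scores),
                 sem = if (length(scores) > 1) sem(scores) else 0,
                 n = length(scores)),
            class = "MetricScore")
}

#' @export
print.MetricScore <- function(x, ...) {
  cat(sprintf("%s: %.2f (SEM %.2f, n = %d)\n", x$metric, x$mean, x$sem, x$n))
  invisible(x)
}

#' Resolve a PairIndex to text pairs
#'
#' @param catalog an \linkS4class{OdorCatalog}.
#' @param pairs a \linkS4class{PairIndex} for a kind present in the catalogue.
#' @return data.frame with columns molecule_id, source_a, source_b, text_a,
#'   text_b.
#' @export
pairTexts <- function(catalog, pairs) {
  e <- pairEntries(pairs)
  d <- descriptions(catalog)
  d <- d[d$kind == pairs@kind, ]
  key <- paste(d$molecule_id, d$source, sep = "\r")
  lut <- setNames(d$text, key)
  e$text_a <- unname(lut[paste(e$molecule_id, e$source_a, sep = "\r")])
  e$text_b <- unname(lut[paste(e$molecule_id, e$source_b, sep = "\r")])
  e
}

#' Consensus gap between human-human and machine-human similarity
#'
#' Computes the benchmark statistic: the average human-to-human score S_hh over
#' same-molecule cross-source pairs (symmetrized as the mean of the two
#' directions) minus the average machine-to-human score S_mh. A high-quality
#' predictor closes the gap.
#'
#' @param pairs_hh data.frame with columns text_a, text_b (human-human pairs;
#'   see \code{\link{pairTexts}}).
#' @param pairs_mh data.frame with columns machine, human.
#' @param metric function(candidate, reference) -> score in [0, 100].
#' @param metric_name label for reporting.
#' @return list of class "ConsensusGap": s_hh, s_mh (MetricScore), gap, and the
#'   per-pair score vectors (scores_hh, scores_mh).
#' @export
consensusGap <- function(pairs_hh, pairs_mh, metric, metric_name = "metric") {
  if (nrow(pairs_hh) < 2 || nrow(pairs_mh) < 2)
    stop("need at least 2 pairs in each set")
  s_hh <- vapply(seq_len(nrow(pairs_hh)), function(i) {
    mean(c(metric(pairs_hh$text_a[i], pairs_hh$text_b[i]),
           metric(pairs_hh$text_b[i], pairs_hh$text_a[i])))
  }, 0)
  s_mh <- vapply(seq_len(nrow(pairs_mh)), function(i) {
    metric(pairs_mh$machine[i], pairs_mh$human[i])
  }, 0)
  structure(list(s_hh = metricScore(s_hh, metric_name),
                 s_mh = metricScore(s_mh, metric_name),
                 gap = mean(s_hh) - mean(s_mh),
                 scores_hh = s_hh, scores_mh = s_mh),
            class = "ConsensusGap")
}

#' @export
print.ConsensusGap <- function(x, ...) {
  cat(sprintf("S_hh = %.2f (SEM %.2f), S_mh = %.2f (SEM %.2f), gap = %.2f\n",
              x$s_hh$mean, x$s_hh$sem, x$s_mh$mean, x$s_mh$sem, x$gap))
  invisible(x)
}
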