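#' @import methods
NULL

#' Tokenize a description
#'
#' Shared tokenizer for all lexical metrics and toy embedders: Unicode NFC
#' normalization, lowercasing, split on runs of non-alphanumeric characters.
#' Deterministic across runs and platforms.
#'
#' @param text character scalar.
#' @return character vector of tokens (possibly empty).
#' @examples
#' tokenizeText("This molecule has a Sweet, fruity odor.")
#' @export
tokenizeText <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) return(character(0))
  x <- stringi_nfc(text)
  x <- tolower(x)
  toks <- strsplit(x, "[^a-z0-9]+")[[1L]]
  toks[nzchar(toks)]
}

# NFC normalization without a stringi dependency: enc2utf8 + iconv round-trip
# keeps ASCII untouched; composed forms via iconv where the platform supports
# it, otherwise the input is returned unchanged (ASCII fixtures are unaffected).
stringi_nfc <- function(x) {
  x <- enc2utf8(x)
  y <- tryCatch(iconv(x, from = "UTF-8", to = "UTF-8"), error = function(e) x)
  if (is.na(y)) x else y
}

# Small English stopword list: tokens carrying no odor content, excluded by the
# toy bag-of-content-words embedders (not by the lexical metrics).
ODIEU_STOPWORDS <- c(
  "a", "an", "the", "this", "that", "it", "is", "has", "have", "of", "and",
  "or", "with", "to", "in", "on", "its", "odor", "odour", "smell", "smells",
  "molecule", "note", "notes"
)

#' Deterministic string hash
#'
#' Polynomial rolling hash over UTF-8 bytes, reduced modulo \code{mod}.
#' Platform independent (pure double arithmetic below 2^53).
#'
#' @param s character vector.
#' @param mod positive integer modulus.
#' @return integer vector in [0, mod).
#' @keywords internal
hashString <- function(s, mod) {
  vapply(s, function(si) {
    b <- as.integer(charToRaw(enc2utf8(si)))
    h <- 0
    for (v in b) h <- (h * 31 + v) %% 2147483647
    as.integer(h %% mod)
  }, integer(1), USE.NAMES = FALSE)
}

# FNV-1a over serialized R objects; used as the frozen-LM weight fingerprint.
fnv1a <- function(object) {
  bytes <- as.integer(serialize(object, connection = NULL, version = 2L))
  h <- 2166136261
  for (v in bytes) {
    h <- bitwXor_dbl(h, v)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

# XOR of a double-held 32-bit value with a byte, in double arithmetic.
bitwXor_dbl <- function(h, v) {
  lo <- h %% 256
  bitwXor(as.integer(lo), as.integer(v)) + (h - lo)
}

# Moore-Penrose pseudoinverse (MASS).
pinv <- function(x) MASS::ginv(x)

#' L2-normalize matrix rows
#' @param m numeric matrix.
#' @return matrix with unit-norm rows; zero rows left untouched with a warning.
#' @keywords internal
normalizeRows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) warning("zero-norm rows left unnormalized")
  nz <- which(nrm > 0)
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

#' Cosine similarity between two vectors
#'
#' @param u,v numeric vectors of equal length with positive norm.
#' @return numeric scalar in [-1, 1].
#' @examples
#' cosineSim(c(1, 1, 0), c(1, 0, 1)) # 0.5
#' @export
cosineSim <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vectors")
  s <- sum(u * v) / (nu * nv)
  min(1, max(-1, s))
}

# Seeded derangement of 1..n (no fixed points), by rejection sampling.
derangement <- function(n, seed = NULL) {
  if (n < 2) stop("derangement needs n >= 2")
  if (!is.null(seed)) set.seed(seed)
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

# Standard error of the mean.
sem <- function(x) stats::sd(x) / sqrt(length(x))

# Write a JSON run manifest (config + seeds + package version).
writeManifest <- function(path, fields) {
  fields$package <- "odieu"
  fields$version <- as.character(utils::packageVersion("odieu"))
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
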