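#' @importFrom stats sd cor t.test prcomp cmdscale dist optim rnorm runif setNames
#' @importFrom utils read.csv write.csv head packageVersion
NULL

# Closed enumeration of description provenance kinds. GEN is reserved for
# artifact-generated texts outside the established taxonomy.
DESCRIPTION_KINDS <- c("HD", "CHD", "HL", "CHL", "CDL",
                       "S_ZS", "S_HD", "S_CHD", "S_CHL", "MD", "GEN")

CATALOG_SCHEMA_VERSION <- "1.0"

#' OdorCatalog: a multi-source odor-description catalogue
#'
#' Holds per-molecule records (id, SMILES, name, optional structure path) and
#' description records (one text or label set about one molecule, from one
#' source, typed by provenance kind). Sources live in a registry; three human
#' sources are declared by default and machine sources can be registered.
#'
#' Validity enforces: unique molecule ids; every description's molecule and
#' source known; (molecule_id, source, kind) unique; kinds from the closed
#' enumeration; HL records carry at least one label; non-HL records carry
#' non-empty text.
#'
#' @slot molecules data.frame with columns molecule_id, smiles, name,
#'   structure_path.
#' @slot descriptions data.frame with columns molecule_id, source, kind, text,
#'   raw_text, labels (";"-joined tokens, "" if none).
#' @slot sources character vector: the source registry.
#' @slot schema_version character scalar.
#' @export
setClass("OdorCatalog",
  representation(molecules = "data.frame", descriptions = "data.frame",
                 sources = "character", schema_version = "character"),
  prototype(
    molecules = data.frame(molecule_id = character(), smiles = character(),
                           name = character(), structure_path = character(),
                           stringsAsFactors = FALSE),
    descriptions = data.frame(molecule_id = character(), source = character(),
                              kind = character(), text = character(),
                              raw_text = character(), labels = character(),
                              stringsAsFactors = FALSE),
    sources = character(),
    schema_version = CATALOG_SCHEMA_VERSION
  )
)

setValidity("OdorCatalog", function(object) {
  m <- object@molecules; d <- object@descriptions
  need_m <- c("molecule_id", "smiles", "name", "structure_path")
  need_d <- c("molecule_id", "source", "kind", "text", "raw_text", "labels")
  if (!all(need_m %in% names(m))) return("molecules: missing columns")
  if (!all(need_d %in% names(d))) return("descriptions: missing columns")
  if (anyDuplicated(m$molecule_id))
    return("duplicate molecule_id in molecules")
  if (nrow(d)) {
    if (!all(d$molecule_id %in% m$molecule_id))
      return("description refers to unknown molecule_id")
    if (!all(d$source %in% object@sources))
      return(sprintf("unregistered source(s): %s",
                     paste(setdiff(d$source, object@sources), collapse = ", ")))
    if (!all(d$kind %in% DESCRIPTION_KINDS))
      return(sprintf("unknown description kind(s): %s",
                     paste(setdiff(d$kind, DESCRIPTION_KINDS), collapse = ", ")))
    key <- paste(d$molecule_id, d$source, d$kind, sep = "\r")
    if (anyDuplicated(key)) {
      i <- which(duplicated(key))[1L]
      return(sprintf("duplicate (molecule_id, source, kind): (%s, %s, %s)",
                     d$molecule_id[i], d$source[i], d$kind[i]))
    }
    hl <- d$kind == "HL"
    if (any(hl & !nzchar(d$labels)))
      return("HL records must carry at least one label")
    if (any(!hl & !nzchar(d$text)))
      return("non-HL records must carry non-empty text")
  }
  TRUE
})

#' PairIndex: unordered cross-source same-molecule description pairs
#'
#' @slot entries data.frame with columns molecule_id, source_a, source_b where
#'   source_a < source_b under the fixed lexicographic source ordering.
#' @slot kind character scalar: the description kind the pairs refer to.
#' @export
setClass("PairIndex",
  representation(entries = "data.frame", kind = "character"),
  prototype(entries = data.frame(molecule_id = character(),
                                 source_a = character(),
                                 source_b = character(),
                                 stringsAsFactors = FALSE),
            kind = NA_character_)
)

setValidity("PairIndex", function(object) {
  e <- object@entries
  if (!all(c("molecule_id", "source_a", "source_b") %in% names(e)))
    return("entries: missing columns")
  if (nrow(e)) {
    if (any(e$source_a >= e$source_b))
      return("entries must satisfy source_a < source_b")
    key <- paste(e$molecule_id, e$source_a, e$source_b, sep = "\r")
    if (anyDuplicated(key)) return("duplicate pair entries")
  }
  TRUE
})

#' Embedder: virtual sentence-embedder contract
#'
#' Embedding is a pure function of (embedder state, text); output length equals
#' \code{embedderDim(x)}. Concrete backends: \linkS4class{HashEmbedder} (the
#' deterministic, training-free toy) and \linkS4class{LinearTextEmbedder}
#' (trainable by contrastive fine-tuning).
#'
#' @slot name character scalar.
#' @slot dim integer embedding dimensionality.
#' @export
setClass("Embedder", representation("VIRTUAL",
  name = "character", dim = "integer"))

#' HashEmbedder: hashed bag-of-content-words toy embedder
#'
#' Deterministic, training-free: tokens (stopwords removed) are hashed into
#' \code{dim} buckets; the bucket-count vector is L2-normalized. Identical
#' texts give identical embeddings.
#'
#' @slot name,dim see \linkS4class{Embedder}.
#' @export
setClass("HashEmbedder", contains = "Embedder")

#' LinearTextEmbedder: trainable linear projection over hashed features
#'
#' Features are hashed bag-of-content-words counts of dimension
#' \code{featureDim}; the embedding is the L2-normalized image under the
#' trainable projection \code{weights} (dim x featureDim). Supports gradient
#' training with the contrastive losses in \code{\link{finetuneEmbedder}}.
#'
#' @slot featureDim integer hashed-feature dimensionality.
#' @slot weights numeric matrix dim x featureDim.
#' @export
setClass("LinearTextEmbedder", contains = "Embedder",
  representation(featureDim = "integer", weights = "matrix"))

setValidity("LinearTextEmbedder", function(object) {
  if (!identical(dim(object@weights),
                 c(as.integer(object@dim), object@featureDim)))
    return("weights must be dim x featureDim")
  TRUE
})

#' EmbeddingMatrix: row-aligned embeddings for a list of description records
#'
#' @slot matrix numeric n x D matrix, one row per text.
#' @slot records data.frame describing each row (at least molecule_id, source,
#'   kind, text; extra columns allowed).
#' @slot embedder character: name of the producing embedder.
#' @slot normalized logical: whether rows are unit-normalized.
#' @export
setClass("EmbeddingMatrix",
  representation(matrix = "matrix", records = "data.frame",
                 embedder = "character", normalized = "logical"))

setValidity("EmbeddingMatrix", function(object) {
  if (nrow(object@matrix) != nrow(object@records))
    return("matrix rows must match records rows")
  if (isTRUE(object@normalized) && nrow(object@matrix)) {
    n <- sqrt(rowSums(object@matrix^2))
    if (any(abs(n - 1) > 1e-6)) return("rows not unit-normalized")
  }
  TRUE
})

#' OdorSpace: molecules-by-coordinates representation of an odor space
#'
#' @slot name character scalar.
#' @slot ids character molecule ids (unique).
#' @slot coords numeric n x d coordinate matrix, no missing values.
#' @slot provenance character note on where the coordinates came from.
#' @export
setClass("OdorSpace",
  representation(name = "character", ids = "character", coords = "matrix",
                 provenance = "character"),
  prototype(provenance = ""))

setValidity("OdorSpace", function(object) {
  if (anyDuplicated(object@ids)) return("molecule ids must be unique")
  if (length(object@ids) != nrow(object@coords))
    return("ids length must equal coordinate rows")
  if (ncol(object@coords) < 1) return("need at least one coordinate")
  if (any(!is.finite(object@coords))) return("coordinates must be finite")
  TRUE
})

#' AlignmentMap: similarity transform from a neural space into an embedding space
#'
#' Maps x to \code{scale * rotation \%*\% (x - centerSource) + centerTarget}.
#' The matrix is orthogonal to 1e-8.
#'
#' @slot rotation numeric d x d orthogonal matrix.
#' @slot scale positive numeric scalar.
#' @slot centerSource,centerTarget numeric centering vectors.
#' @slot sourceDim,targetDim integer dims of the aligned spaces.
#' @export
setClass("AlignmentMap",
  representation(rotation = "matrix", scale = "numeric",
                 centerSource = "numeric", centerTarget = "numeric",
                 sourceDim = "integer", targetDim = "integer"))

setValidity("AlignmentMap", function(object) {
  W <- object@rotation
  if (max(abs(crossprod(W) - diag(ncol(W)))) > 1e-8)
    return("rotation matrix not orthogonal to 1e-8")
  if (object@scale <= 0) return("scale must be positive")
  TRUE
})

#' PrefixEncoder: multilayer perceptron mapping descriptors to LM prefixes
#'
#' A 4-layer (by default) tanh MLP whose output is reshaped to k prefix slots
#' of width E (the language model's token-embedding width). Only these
#' parameters are trainable; the language model stays frozen.
#'
#' @slot weights list of weight matrices (layer output x layer input).
#' @slot biases list of bias vectors.
#' @slot k integer number of prefix slots.
#' @slot embedWidth integer E, the LM token-embedding width.
#' @slot inputDim integer descriptor length.
#' @slot center,scaleVec numeric per-dimension descriptor standardization
#'   statistics (training-set z-score).
#' @export
setClass("PrefixEncoder",
  representation(weights = "list", biases = "list", k = "integer",
                 embedWidth = "integer", inputDim = "integer",
                 center = "numeric", scaleVec = "numeric"))

#' TinyCausalLM: a miniature frozen causal language model
#'
#' Word-level causal language model small enough to train through on one CPU:
#' the context state at each position mixes the mean of the prefix slots
#' (persistent conditioning) with a recency-decayed mean of the preceding
#' token embeddings, passed through a tanh layer and projected to vocabulary
#' logits. Exposes a differentiable token-level next-token loss given prefix
#' embeddings, as prefix tuning requires. Model parameters are never updated
#' by training; \code{lmFingerprint} hashes them.
#'
#' @slot vocab character token vocabulary (includes "<bos>" and "<eos>").
#' @slot tokenEmb numeric V x E token-embedding matrix.
#' @slot contextW numeric E x E context layer; @slot contextB bias.
#' @slot outputW numeric V x E output projection.
#' @slot embedWidth integer E.
#' @export
setClass("TinyCausalLM",
  representation(vocab = "character", tokenEmb = "matrix",
                 contextW = "matrix", contextB = "numeric",
                 outputW = "matrix", embedWidth = "integer"))

#' InvertibleEmbedder: paired text-to-vector and vector-to-text mappings
#'
#' Toy backend: the embedding is the (unnormalized) count vector of a fixed
#' token vocabulary; inversion reconstructs the token multiset by rounding
#' counts. \code{invert(embed(t))} reproduces the token multiset of any
#' in-vocabulary text.
#'
#' @slot vocab character token vocabulary.
#' @export
setClass("InvertibleEmbedder", representation(vocab = "character"))

setMethod("show", "OdorCatalog", function(object) {
  d <- object@descriptions
  cat("OdorCatalog:", nrow(object@molecules), "molecules,",
      nrow(d), "descriptions\n")
  cat("  sources:", paste(object@sources, collapse = ", "), "\n")
  if (nrow(d)) {
    tb <- table(d$kind)
    cat("  kinds:", paste(sprintf("%s=%d", names(tb), as.integer(tb)),
                          collapse = ", "), "\n")
  }
})

setMethod("show", "PairIndex", function(object) {
  cat("PairIndex:", nrow(object@entries), "cross-source pairs (kind",
      object@kind, ")\n")
})

setMethod("show", "EmbeddingMatrix", function(object) {
  cat("EmbeddingMatrix:", nrow(object@matrix), "texts x",
      ncol(object@matrix), "dims; embedder:", object@embedder,
      if (isTRUE(object@normalized)) "(unit rows)" else "", "\n")
})

setMethod("show", "OdorSpace", function(object) {
  cat("OdorSpace '", object@name, "': ", length(object@ids), " molecules x ",
      ncol(object@coords), " dims\n", sep = "")
})

setMethod("show", "AlignmentMap", function(object) {
  cat("AlignmentMap:", object@sourceDim, "->", object@targetDim,
      "dims; scale =", signif(object@scale, 4), "\n")
})

setMethod("show", "TinyCausalLM", function(object) {
  cat("TinyCausalLM: |V| =", length(object@vocab),
      ", E =", object@embedWidth,
      ", fingerprint", lmFingerprint(object), "\n")
})
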