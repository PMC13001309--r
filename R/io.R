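# Persistence for embedding matrices: CSV (id + D columns) with a JSON sidecar
# recording the embedder name, dimensionality, normalization flag and seed.

#' Write / read an EmbeddingMatrix
#'
#' @param emb an \linkS4class{EmbeddingMatrix}.
#' @param path CSV path; the sidecar is written to \code{<path>.json}.
#' @param seed seed recorded in the sidecar (provenance only).
#' @return the path (write) or an \linkS4class{EmbeddingMatrix} (read).
#' @export
writeEmbeddings <- function(emb, path, seed = NA_integer_) {
  r <- embeddingRecords(emb)
  df <- data.frame(molecule_id = r$molecule_id, source = r$source,
                   kind = r$kind, text = r$text,
                   embeddingRows(emb), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("molecule_id", "source", "kind", "text",
                    sprintf("e%03d", seq_len(ncol(embeddingRows(emb)))))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(embedder = emb@embedder, dim = ncol(embeddingRows(emb)),
         normalized = emb@normalized, seed = seed),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeEmbeddings
#' @export
readEmbeddings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list(embedder = "unknown", normalized = FALSE)
  ecols <- grep("^e[0-9]+$", names(df))
  new("EmbeddingMatrix", matrix = as.matrix(df[, ecols, drop = FALSE]),
      records = df[, c("molecule_id", "source", "kind", "text")],
      embedder = meta$embedder, normalized = isTRUE(meta$normalized))
}

# JSON serialization of a trained CIRANO model (encoder + frozen LM), so the
# command-line workflow stays text-only and portable.

#' Write / read a CIRANO model as JSON
#' @param model a "CiranoModel" from \code{\link{trainEncoder}}.
#' @param path JSON file path.
#' @return the path (write) or a "CiranoModel" (read).
#' @export
writeCiranoModel <- function(model, path) {
  enc <- model$encoder; lm <- model$lm
  obj <- list(
    fingerprint = model$fingerprint,
    config = unclass(model$config),
    loss_trace = model$loss_trace,
    encoder = list(
      k = enc@k, embedWidth = enc@embedWidth, inputDim = enc@inputDim,
      center = enc@center, scaleVec = enc@scaleVec,
      weights = lapply(enc@weights, function(w)
        list(nrow = nrow(w), data = as.numeric(w))),
      biases = enc@biases),
    lm = list(vocab = lm@vocab, embedWidth = lm@embedWidth,
              tokenEmb = as.numeric(lm@tokenEmb),
              contextW = as.numeric(lm@contextW),
              contextB = lm@contextB,
              outputW = as.numeric(lm@outputW)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCiranoModel
#' @export
readCiranoModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  E <- o$lm$embedWidth
  V <- length(o$lm$vocab)
  lm <- new("TinyCausalLM", vocab = o$lm$vocab,
            tokenEmb = matrix(o$lm$tokenEmb, V, E,
                              dimnames = list(o$lm$vocab, NULL)),
            contextW = matrix(o$lm$contextW, E, E),
            contextB = o$lm$contextB,
            outputW = matrix(o$lm$outputW, V, E,
                             dimnames = list(o$lm$vocab, NULL)),
            embedWidth = as.integer(E))
  weights <- lapply(o$encoder$weights, function(w)
    matrix(w$data, nrow = w$nrow))
  biases <- if (is.list(o$encoder$biases)) o$encoder$biases else
    list(o$encoder$biases)
  enc <- new("PrefixEncoder", weights = weights, biases = biases,
             k = as.integer(o$encoder$k),
             embedWidth = as.integer(o$encoder$embedWidth),
             inputDim = as.integer(o$encoder$inputDim),
             center = o$encoder$center, scaleVec = o$encoder$scaleVec)
  structure(list(encoder = enc, lm = lm, loss_trace = o$loss_trace,
                 fingerprint = o$fingerprint,
                 config = structure(o$config, class = "CiranoConfig")),
            class = "CiranoModel")
}
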