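# Description augmentation through a pluggable text-completion backend:
# raw human descriptions -> completed sentences (HD -> CHD), label sets ->
# completed sentences (HL -> CHL), machine-predicted labels -> CDL, and
# SMILES zero/few-shot prompt assembly. The deterministic template backend is
# used in tests; an external-LLM backend can be plugged behind the same
# interface. The shipped prompt wordings are reconstructions, not verbatim
# copies of any particular model's prompts.

#' Prompt templates for the augmentation tasks
#'
#' @param task one of "complete_description", "labels_to_sentence",
#'   "smiles_describe".
#' @param n_shot number of in-prompt examples (0 or 50 are the defaults used
#'   in practice).
#' @return list of class "PromptTemplate": task, template, n_shot. Templates
#'   carry \code{{content}}, \code{{examples}} and \code{{query}} slots, all
#'   of which must be filled before dispatch.
#' @export
promptTemplate <- function(task = c("complete_description",
                                    "labels_to_sentence", "smiles_describe"),
                           n_shot = 0L) {
  task <- match.arg(task)
  template <- switch(task,
    complete_description = paste0(
      "Rewrite the following odor description as one short complete ",
      "sentence, keeping every descriptor word.\nCONTENT: {content}\n"),
    labels_to_sentence = paste0(
      "Write one short complete sentence describing an odor with exactly ",
      "these qualities.\nCONTENT: {content}\n"),
    smiles_describe = paste0(
      "{examples}Describe the odor of the molecule with this SMILES string ",
      "in one short sentence.\nSMILES: {query}\n"))
  structure(list(task = task, template = template, n_shot = as.integer(n_shot)),
            class = "PromptTemplate")
}

#' Deterministic template completion backend
#'
#' Fills the catalogue's sentence template with the content tokens found on
#' the prompt's CONTENT line; no external service, fully reproducible. Used
#' wherever tests need a completion backend.
#'
#' @return list of class "CompletionBackend" with fields name and
#'   \code{invoke(prompt) -> text}.
#' @export
templateBackend <- function() {
  structure(list(
    name = "template",
    invoke = function(prompt) {
      m <- regmatches(prompt, regexec("CONTENT: ([^\n]*)", prompt))[[1]]
      if (length(m) < 2) stop("template backend: prompt has no CONTENT line")
      toks <- strsplit(m[2], "[;,]\\s*")[[1]]
      toks <- toks[nzchar(toks)]
      if (!length(toks)) stop("template backend: empty content")
      familySentence(toks)
    }), class = "CompletionBackend")
}

# kinds a completion can start from, and what they become
AUGMENT_KIND_MAP <- c(HD = "CHD", HL = "CHL", CDL = "CDL", GEN = "CDL")

#' Complete a description record into a full sentence
#'
#' HD records are completed into CHD, HL label sets into CHL, and
#' machine-predicted label records into CDL. The output must contain every
#' input content word / label; a missing one triggers a validation warning.
#' Backend failures are retried \code{retries} times before erroring.
#'
#' @param record a one-row data.frame with columns molecule_id, source, kind
#'   and text or labels (a row of \code{descriptions(catalog)}).
#' @param backend a "CompletionBackend" (default the deterministic template
#'   engine).
#' @param retries backend retry count.
#' @return a one-row data.frame with the completed kind and text.
#' @export
completeDescription <- function(record, backend = templateBackend(),
                                retries = 2L) {
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  stopifnot(nrow(record) == 1)
  kind_in <- record$kind
  if (!kind_in %in% names(AUGMENT_KIND_MAP))
    stop("cannot complete records of kind ", kind_in)
  content <- if (kind_in == "HL" || (nzchar(record$labels %||% ""))) {
    strsplit(record$labels, ";", fixed = TRUE)[[1]]
  } else {
    setdiff(tokenizeText(record$text), ODIEU_STOPWORDS)
  }
  content <- content[nzchar(content)]
  if (!length(content)) stop("record has no content words/labels to complete")
  tpl <- promptTemplate(if (kind_in == "HD") "complete_description"
                        else "labels_to_sentence")
  prompt <- sub("{content}", paste(content, collapse = "; "), tpl$template,
                fixed = TRUE)
  out <- NULL
  for (attempt in seq_len(retries + 1L)) {
    out <- tryCatch(backend$invoke(prompt), error = function(e) e)
    if (!inherits(out, "error")) break
  }
  if (inherits(out, "error"))
    stop("completion backend failed after ", retries + 1L, " attempts: ",
         conditionMessage(out))
  out_toks <- tokenizeText(out)
  missing_lab <- setdiff(tolower(content), out_toks)
  if (length(missing_lab))
    warning("completed text misses input label(s): ",
            paste(missing_lab, collapse = ", "))
  data.frame(molecule_id = record$molecule_id, source = record$source,
             kind = unname(AUGMENT_KIND_MAP[kind_in]), text = out,
             labels = "", stringsAsFactors = FALSE)
}

#' Add completed descriptions to a catalogue
#'
#' Runs \code{\link{completeDescription}} over every record of
#' \code{from_kind}; augmented records are added alongside the originals,
#' never overwriting them.
#'
#' @param catalog an \linkS4class{OdorCatalog}.
#' @param from_kind kind to complete ("HD" or "HL").
#' @param backend a "CompletionBackend".
#' @return an \linkS4class{OdorCatalog} with the new records appended.
#' @export
addCompletedDescriptions <- function(catalog, from_kind = "HL",
                                     backend = templateBackend()) {
  d <- descriptions(catalog)
  src <- d[d$kind == from_kind, ]
  if (!nrow(src)) stop("no records of kind ", from_kind)
  done <- do.call(rbind, lapply(seq_len(nrow(src)), function(i)
    completeDescription(src[i, ], backend)))
  OdorCatalog(molecules(catalog),
              rbind(d[, c("molecule_id", "source", "kind", "text", "labels")],
                    done),
              sources = catalogSources(catalog))
}

#' Assemble a SMILES zero/few-shot prompt
#'
#' Builds the prompt for describing a novel molecule from its SMILES string,
#' optionally preceded by \code{n_shot} seeded example blocks. The query must
#' not appear among the examples (leakage error).
#'
#' @param query_smiles SMILES string of the query molecule.
#' @param examples data.frame with columns smiles, text (the example pool).
#' @param n_shot number of example blocks, 0..nrow(examples).
#' @param seed example-selection seed.
#' @return character scalar: the assembled prompt.
#' @export
fewshotSmilesPrompt <- function(query_smiles, examples = NULL, n_shot = 0L,
                                seed = 1L) {
  if (n_shot > 0) {
    stopifnot(!is.null(examples), n_shot <= nrow(examples))
    if (query_smiles %in% examples$smiles)
      stop("leakage: query SMILES present in the example pool")
    set.seed(seed)
    pick <- sample.int(nrow(examples), n_shot)
    blocks <- sprintf("SMILES: %s\nDescription: %s\n",
                      examples$smiles[pick], examples$text[pick])
    ex <- paste0(paste(blocks, collapse = "\n"), "\n")
  } else ex <- ""
  tpl <- promptTemplate("smiles_describe", n_shot = n_shot)
  prompt <- sub("{examples}", ex, tpl$template, fixed = TRUE)
  sub("{query}", query_smiles, prompt, fixed = TRUE)
}
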