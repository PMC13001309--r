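#' Construct an OdorCatalog
#'
#' @param molecules data.frame with columns molecule_id, smiles and optionally
#'   name, structure_path.
#' @param descriptions data.frame with columns molecule_id, source, kind and
#'   text and/or labels (labels as a ";"-joined string or list column).
#' @param sources character source registry; defaults to the sources present.
#' @return a validated \linkS4class{OdorCatalog}. Text is whitespace-collapsed
#'   and NFC-normalized at construction; the raw text is retained in the
#'   \code{raw_text} column.
#' @export
OdorCatalog <- function(molecules, descriptions = NULL, sources = NULL) {
  molecules <- as.data.frame(molecules, stringsAsFactors = FALSE)
  if (is.null(molecules$name))
    molecules$name <- rep(NA_character_, nrow(molecules))
  if (is.null(molecules$structure_path))
    molecules$structure_path <- rep(NA_character_, nrow(molecules))
  molecules <- molecules[, c("molecule_id", "smiles", "name", "structure_path")]
  molecules$molecule_id <- as.character(molecules$molecule_id)

  if (is.null(descriptions)) {
    descriptions <- data.frame(molecule_id = character(), source = character(),
                               kind = character(), text = character(),
                               stringsAsFactors = FALSE)
  }
  descriptions <- as.data.frame(descriptions, stringsAsFactors = FALSE)
  if (is.null(descriptions$text))
    descriptions$text <- rep("", nrow(descriptions))
  if (is.null(descriptions$labels))
    descriptions$labels <- rep("", nrow(descriptions))
  if (is.list(descriptions$labels))
    descriptions$labels <- vapply(descriptions$labels, paste, "", collapse = ";")
  descriptions$text[is.na(descriptions$text)] <- ""
  descriptions$labels[is.na(descriptions$labels)] <- ""
  descriptions$raw_text <- as.character(descriptions$text)
  descriptions$text <- vapply(descriptions$raw_text, normalizeDescriptionText,
                              "", USE.NAMES = FALSE)
  descriptions <- descriptions[, c("molecule_id", "source", "kind", "text",
                                   "raw_text", "labels")]
  for (cc in names(descriptions))
    descriptions[[cc]] <- as.character(descriptions[[cc]])
  if (is.null(sources)) sources <- sort(unique(descriptions$source))
  new("OdorCatalog", molecules = molecules, descriptions = descriptions,
      sources = sort(sources), schema_version = CATALOG_SCHEMA_VERSION)
}

# Whitespace collapse + Unicode NFC; applied once at load so every metric sees
# stable tokenization.
normalizeDescriptionText <- function(x) {
  x <- stringi_nfc(x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Accessors for OdorCatalog
#' @param x an \linkS4class{OdorCatalog}.
#' @return \code{molecules()} and \code{descriptions()} return data.frames;
#'   \code{catalogSources()} the source registry.
#' @export
molecules <- function(x) x@molecules

#' @rdname molecules
#' @export
descriptions <- function(x) x@descriptions

#' @rdname molecules
#' @export
catalogSources <- function(x) x@sources

#' Load a catalogue from CSV or JSON
#'
#' CSV schema: columns molecule_id, smiles, name, source, kind, text, labels
#' (";"-joined). JSON schema: object with fields \code{schema_version},
#' \code{molecules} (records) and \code{descriptions} (records). Malformed
#' files raise errors naming the offending row/field; duplicate
#' (molecule, source, kind) combinations raise a uniqueness error.
#'
#' @param path CSV (.csv) or JSON (.json) file.
#' @return a validated \linkS4class{OdorCatalog}.
#' @export
loadCatalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$molecules)) stop("JSON catalogue missing 'molecules' field")
    mol <- as.data.frame(obj$molecules, stringsAsFactors = FALSE)
    des <- if (!is.null(obj$descriptions) && length(obj$descriptions))
      as.data.frame(obj$descriptions, stringsAsFactors = FALSE) else NULL
    return(OdorCatalog(mol, des))
  }
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("molecule_id", "smiles", "source", "kind", "text")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("catalogue CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!nrow(df)) {
    return(OdorCatalog(data.frame(molecule_id = character(),
                                  smiles = character(),
                                  stringsAsFactors = FALSE)))
  }
  bad <- which(!nzchar(df$molecule_id))
  if (length(bad))
    stop("catalogue CSV row ", bad[1L] + 1L, ": empty molecule_id")
  mol <- unique(df[, intersect(c("molecule_id", "smiles", "name"), names(df))])
  if (anyDuplicated(mol$molecule_id))
    stop("molecule_id with conflicting smiles/name: ",
         mol$molecule_id[duplicated(mol$molecule_id)][1L])
  des <- df[, intersect(c("molecule_id", "source", "kind", "text", "labels"),
                        names(df))]
  OdorCatalog(mol, des)
}

#' Write a catalogue to CSV or JSON
#'
#' Inverse of \code{\link{loadCatalog}}: saving then loading reproduces an
#' identical catalogue (normalized text is written).
#'
#' @param x an \linkS4class{OdorCatalog}.
#' @param path output file, .csv or .json.
#' @return \code{path}, invisibly.
#' @export
writeCatalog <- function(x, path) {
  stopifnot(is(x, "OdorCatalog"))
  d <- x@descriptions
  m <- x@molecules
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(schema_version = x@schema_version,
           molecules = m,
           descriptions = d[, c("molecule_id", "source", "kind", "text",
                                "labels")]),
      path, auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(path))
  }
  out <- merge(d[, c("molecule_id", "source", "kind", "text", "labels")],
               m[, c("molecule_id", "smiles", "name")],
               by = "molecule_id", sort = FALSE)
  out <- out[order(out$molecule_id, out$source, out$kind),
             c("molecule_id", "smiles", "name", "source", "kind", "text",
               "labels")]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Enumerate cross-source same-molecule description pairs
#'
#' Returns every unordered pair of sources that both describe the same molecule
#' with records of the requested kind; pair orientation is fixed by
#' lexicographic source order, making the index deterministic. The pair count
#' equals the sum over molecules of choose(m_i, 2) where m_i is the number of
#' sources holding that kind for molecule i.
#'
#' @param catalog an \linkS4class{OdorCatalog}.
#' @param kind a description kind present in the catalogue.
#' @return a \linkS4class{PairIndex}.
#' @export
crossSourcePairs <- function(catalog, kind) {
  stopifnot(is(catalog, "OdorCatalog"))
  if (!kind %in% DESCRIPTION_KINDS) stop("unknown description kind: ", kind)
  d <- catalog@descriptions[catalog@descriptions$kind == kind, ]
  if (!nrow(d)) {
    return(new("PairIndex", kind = kind))
  }
  sp <- split(d$source, d$molecule_id)
  rows <- lapply(names(sp), function(mid) {
    ss <- sort(unique(sp[[mid]]))
    if (length(ss) < 2) return(NULL)
    cmb <- utils::combn(ss, 2)
    data.frame(molecule_id = mid, source_a = cmb[1, ], source_b = cmb[2, ],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule_id = character(), source_a = character(),
               source_b = character(), stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  new("PairIndex", entries = entries, kind = kind)
}

#' Number of pairs in a PairIndex
#' @param x a \linkS4class{PairIndex}.
#' @export
pairCount <- function(x) nrow(x@entries)

#' @rdname pairCount
#' @param x a \linkS4class{PairIndex}.
#' @export
pairEntries <- function(x) x@entries

#' Source-multiplicity overlap summary
#'
#' Counts molecules described by exactly 1, 2, 3, ... sources with the given
#' kind; the counts sum to the number of molecules having that kind.
#'
#' @inheritParams crossSourcePairs
#' @return named integer vector: multiplicity -> molecule count.
#' @export
overlapSummary <- function(catalog, kind) {
  stopifnot(is(catalog, "OdorCatalog"))
  if (!kind %in% DESCRIPTION_KINDS) stop("unknown description kind: ", kind)
  d <- catalog@descriptions[catalog@descriptions$kind == kind, ]
  if (!nrow(d)) return(setNames(integer(0), character(0)))
  mult <- vapply(split(d$source, d$molecule_id),
                 function(s) length(unique(s)), integer(1))
  tb <- table(mult)
  setNames(as.integer(tb), names(tb))
}

#' Merge molecules by canonical SMILES (optional utility)
#'
#' Off by default everywhere: molecule identity is the caller-supplied key, so
#' stereoisomers with distinct ids are never silently merged. When requested,
#' canonical SMILES are computed with ChemmineOB (OpenBabel) and molecules
#' whose canonical forms coincide are merged under the first id encountered.
#'
#' @param catalog an \linkS4class{OdorCatalog}.
#' @return an \linkS4class{OdorCatalog} with merged molecule ids.
#' @export
canonicalSmilesMerge <- function(catalog) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("canonicalSmilesMerge requires the ChemmineOB package")
  m <- catalog@molecules
  can <- vapply(m$smiles, function(s) {
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")),
                    error = function(e) s)
    strsplit(trimws(out), "[[:space:]]+")[[1L]][1L]
  }, "", USE.NAMES = FALSE)
  keep_id <- tapply(m$molecule_id, can, function(x) x[1L])
  remap <- setNames(keep_id[can], m$molecule_id)
  m$molecule_id <- unname(remap[m$molecule_id])
  m <- m[!duplicated(m$molecule_id), ]
  d <- catalog@descriptions
  d$molecule_id <- unname(remap[d$molecule_id])
  key <- paste(d$molecule_id, d$source, d$kind, sep = "\r")
  d <- d[!duplicated(key), ]
  new("OdorCatalog", molecules = m, descriptions = d,
      sources = catalog@sources, schema_version = catalog@schema_version)
}
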