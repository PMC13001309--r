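# Built-in family vocabularies themed on odor descriptors. Families are
# disjoint so that token overlap across molecules is governed purely by the
# agreement parameter alpha.
ODOR_FAMILY_VOCAB <- list(
  fruity     = c("apple", "pear", "banana", "berry", "peach", "apricot",
                 "melon", "grape"),
  floral     = c("rose", "jasmine", "lilac", "violet", "lavender", "geranium",
                 "honeysuckle", "lily"),
  sulfurous  = c("garlic", "onion", "skunky", "eggy", "cabbage", "pungent",
                 "alliaceous", "rotten"),
  woody      = c("cedar", "sandalwood", "pine", "oak", "resinous", "balsamic",
                 "bark", "forest"),
  citrus     = c("lemon", "orange", "lime", "bergamot", "grapefruit", "zesty",
                 "mandarin", "citral"),
  minty      = c("mint", "menthol", "cooling", "peppermint", "spearmint",
                 "camphor", "icy", "fresh"),
  earthy     = c("soil", "musty", "mushroom", "damp", "mossy", "dusty",
                 "loamy", "truffle"),
  spicy      = c("clove", "cinnamon", "pepper", "nutmeg", "ginger", "warm",
                 "anise", "cardamom"),
  nutty      = c("almond", "hazelnut", "walnut", "roasted", "toasted",
                 "marzipan", "praline", "buttery"),
  smoky      = c("smoke", "tar", "burnt", "charred", "phenolic", "leathery",
                 "ash", "campfire")
)

#' Configuration for the synthetic-data generator
#'
#' The generator emulates a multi-source odor-description catalogue with known
#' latent structure: each molecule carries a latent vector clustered by
#' perceptual family; each present source writes one sentence whose tokens come
#' from the molecule's true family with probability \code{alpha}, otherwise
#' from a uniformly random family; descriptor and neural vectors are seeded
#' full-rank linear images of the latent plus Gaussian noise.
#'
#' @param n_molecules number of molecules.
#' @param n_sources number of human sources (default 3, as in the catalogue
#'   the package targets).
#' @param n_families number of perceptual families (<= 10 built-in
#'   vocabularies).
#' @param latent_dim latent dimensionality.
#' @param alpha inter-observer agreement in [0, 1].
#' @param descriptor_dim molecular-descriptor dimensionality
#'   (>= \code{latent_dim} so the linear map can be full column rank).
#' @param neural_dim neural response (Q-vector) dimensionality, default 30.
#' @param noise_sigma Gaussian noise s.d. on descriptors/neural vectors.
#' @param tokens_per_description tokens drawn into each sentence.
#' @param presence_counts optional named integer vector mapping source
#'   multiplicity to molecule count, e.g. \code{c("2" = 1762, "3" = 854)};
#'   must sum to \code{n_molecules}. Default: all molecules in all sources.
#' @param kinds description kinds emitted per present source (subset of
#'   CHD, HL).
#' @param seed integer seed controlling every random draw.
#' @return a validated list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(n_molecules, n_sources = 3L, n_families = 6L,
                            latent_dim = 8L, alpha = 0.8,
                            descriptor_dim = 32L, neural_dim = 30L,
                            noise_sigma = 0.1, tokens_per_description = 3L,
                            presence_counts = NULL,
                            kinds = c("CHD", "HL"), seed = 1L) {
  stopifnot(n_molecules >= 1, n_sources >= 1, n_families >= 1,
            latent_dim >= 1, descriptor_dim >= 1, neural_dim >= 1,
            alpha >= 0, alpha <= 1, noise_sigma >= 0,
            tokens_per_description >= 1)
  if (n_families > length(ODOR_FAMILY_VOCAB))
    stop("n_families exceeds the ", length(ODOR_FAMILY_VOCAB),
         " built-in family vocabularies")
  if (descriptor_dim < latent_dim || neural_dim < latent_dim)
    stop("descriptor_dim and neural_dim must be >= latent_dim")
  if (!is.null(presence_counts)) {
    if (sum(presence_counts) != n_molecules)
      stop("presence_counts must sum to n_molecules")
    if (any(as.integer(names(presence_counts)) > n_sources))
      stop("presence multiplicity exceeds n_sources")
  }
  stopifnot(all(kinds %in% c("CHD", "HL")))
  structure(list(n_molecules = as.integer(n_molecules),
                 n_sources = as.integer(n_sources),
                 n_families = as.integer(n_families),
                 latent_dim = as.integer(latent_dim), alpha = alpha,
                 descriptor_dim = as.integer(descriptor_dim),
                 neural_dim = as.integer(neural_dim),
                 noise_sigma = noise_sigma,
                 tokens_per_description = as.integer(tokens_per_description),
                 presence_counts = presence_counts, kinds = kinds,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Generate a synthetic catalogue with known latent structure
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with elements \code{catalog} (an \linkS4class{OdorCatalog})
#'   and \code{truth} (class \code{"SyntheticTruth"}: per-molecule latent
#'   matrix, family ids, and the seeded linear maps used downstream). The
#'   truth is retained for recovery tests only and is never read by any method
#'   under test.
#' @export
generateCatalog <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  n <- config$n_molecules
  fam_names <- names(ODOR_FAMILY_VOCAB)[seq_len(config$n_families)]

  family <- sample.int(config$n_families, n, replace = TRUE)
  centers <- matrix(rnorm(config$n_families * config$latent_dim, sd = 2),
                    config$n_families, config$latent_dim)
  latent <- centers[family, , drop = FALSE] +
    matrix(rnorm(n * config$latent_dim, sd = 0.5), n, config$latent_dim)
  ids <- sprintf("mol%04d", seq_len(n))
  rownames(latent) <- ids

  # Seeded full-rank maps for descriptors (A) and neural responses (B); drawn
  # once per seed so repeated calls are byte-identical.
  A <- fullRankMap(config$descriptor_dim, config$latent_dim)
  B <- fullRankMap(config$neural_dim, config$latent_dim)

  # presence: which sources describe each molecule
  sources <- sprintf("source_%s", letters[seq_len(config$n_sources)])
  if (is.null(config$presence_counts)) {
    mult <- rep(config$n_sources, n)
  } else {
    mult <- rep(as.integer(names(config$presence_counts)),
                times = config$presence_counts)
  }
  present <- lapply(mult, function(m) sort(sample(sources, m)))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    per_source <- lapply(present[[i]], function(src) {
      toks <- drawFamilyTokens(family[i], config)
      out <- NULL
      if ("CHD" %in% config$kinds)
        out <- rbind(out, data.frame(
          molecule_id = ids[i], source = src, kind = "CHD",
          text = familySentence(toks), labels = "", stringsAsFactors = FALSE))
      if ("HL" %in% config$kinds)
        out <- rbind(out, data.frame(
          molecule_id = ids[i], source = src, kind = "HL",
          text = "", labels = paste(toks, collapse = ";"),
          stringsAsFactors = FALSE))
      out
    })
    rows[[i]] <- do.call(rbind, per_source)
  }
  des <- do.call(rbind, rows)
  mol <- data.frame(molecule_id = ids,
                    smiles = sprintf("C%s", strrep("C", family)),
                    name = ids, stringsAsFactors = FALSE)
  catalog <- OdorCatalog(mol, des, sources = sources)
  truth <- structure(list(latent = latent, family = setNames(family, ids),
                          family_names = fam_names, A = A, B = B,
                          config = config),
                     class = "SyntheticTruth")
  list(catalog = catalog, truth = truth)
}

# Draw sentence tokens: each token comes from the true family with probability
# alpha, else from a uniformly random family; distinct tokens within a sentence.
drawFamilyTokens <- function(family_id, config) {
  toks <- character(config$tokens_per_description)
  for (j in seq_along(toks)) {
    fam <- if (runif(1) < config$alpha) family_id else
      sample.int(config$n_families, 1)
    pool <- setdiff(ODOR_FAMILY_VOCAB[[fam]], toks)
    if (!length(pool)) pool <- ODOR_FAMILY_VOCAB[[fam]]
    toks[j] <- sample(pool, 1)
  }
  toks
}

# Sentence template mirroring completed-human-description style.
familySentence <- function(tokens) {
  if (length(tokens) == 1)
    return(sprintf("This molecule has a %s odor.", tokens))
  head_toks <- paste(tokens[-length(tokens)], collapse = ", ")
  sprintf("This molecule has a %s odor with %s notes.",
          head_toks, tokens[length(tokens)])
}

# Seeded random full-column-rank map (rows x cols, rows >= cols): Gaussian
# matrix re-drawn until numerically full rank (immediate w.p. 1).
fullRankMap <- function(rows, cols) {
  repeat {
    M <- matrix(rnorm(rows * cols), rows, cols)
    if (qr(M)$rank == cols) return(M)
  }
}

#' Generate molecular descriptor vectors from synthetic truth
#'
#' descriptor = A latent + sigma noise, with A the seeded full-rank map drawn
#' by \code{\link{generateCatalog}}; deterministic for a given truth and seed.
#'
#' @param truth a \code{"SyntheticTruth"} from \code{\link{generateCatalog}}.
#' @param config the matching \code{\link{syntheticConfig}}.
#' @return numeric matrix (molecules x descriptor_dim), rownames molecule ids.
#' @export
generateDescriptors <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  set.seed(config$seed + 1000003L)
  n <- nrow(truth$latent)
  D <- truth$latent %*% t(truth$A) +
    config$noise_sigma * matrix(rnorm(n * config$descriptor_dim), n,
                                config$descriptor_dim)
  rownames(D) <- rownames(truth$latent)
  D
}

#' Generate neural response vectors (Q-vectors) from synthetic truth
#'
#' Q = B latent + sigma noise with an independent seeded full-rank map B;
#' emulates 30-dimensional glomerular population response embeddings.
#'
#' @inheritParams generateDescriptors
#' @return numeric matrix (molecules x neural_dim), rownames molecule ids.
#' @export
generateNeuralResponses <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  set.seed(config$seed + 2000003L)
  n <- nrow(truth$latent)
  Q <- truth$latent %*% t(truth$B) +
    config$noise_sigma * matrix(rnorm(n * config$neural_dim), n,
                                config$neural_dim)
  rownames(Q) <- rownames(truth$latent)
  Q
}

#' The deterministic, training-free toy embedder
#'
#' Hashed bag-of-content-words: tokens (stopwords removed) are hashed into
#' \code{dim} buckets, counted, and the count vector is L2-normalized.
#' Identical texts give identical embeddings; under a collision-free hash the
#' cosine similarity equals the cosine of the raw token-count vectors.
#'
#' @param dim embedding dimensionality (default 256).
#' @return a \linkS4class{HashEmbedder}.
#' @export
toyEmbedder <- function(dim = 256L) {
  new("HashEmbedder", name = sprintf("toy-hash-%d", dim), dim = as.integer(dim))
}

#' Write synthetic descriptor / neural matrices as CSV
#' @param m numeric matrix with molecule-id rownames.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeVectorCSV <- function(m, path) {
  df <- data.frame(molecule_id = rownames(m), m, stringsAsFactors = FALSE,
                   row.names = NULL, check.names = FALSE)
  colnames(df) <- c("molecule_id", sprintf("v%03d", seq_len(ncol(m))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor / neural matrix CSV written by \code{writeVectorCSV}
#' @param path CSV path.
#' @return numeric matrix with molecule-id rownames.
#' @export
readVectorCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
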