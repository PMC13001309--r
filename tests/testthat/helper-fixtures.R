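# Shared fixture builders; everything is generated in code at test time.

# Minimal catalogue: explicit molecules/descriptions for hand-checkable cases.
makeCatalog <- function(descriptions, smiles = "CCO") {
  mol <- data.frame(molecule_id = unique(descriptions$molecule_id),
                    smiles = smiles, stringsAsFactors = FALSE)
  OdorCatalog(mol, descriptions)
}

# Catalogue with a given overlap profile: counts[i] molecules in exactly
# i sources (kind CHD), texts distinct per record.
makeOverlapCatalog <- function(counts, kind = "CHD") {
  mult <- rep(seq_along(counts), counts)
  ids <- sprintf("m%05d", seq_along(mult))
  mid <- rep(ids, mult)
  src <- unlist(lapply(mult, function(m) paste0("s", seq_len(m))))
  makeCatalog(data.frame(
    molecule_id = mid, source = src, kind = kind,
    text = sprintf("apple pear text %s %s", mid, src),
    stringsAsFactors = FALSE))
}

# All permutations of 1..n (n <= 8), one per row.
allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# Exhaustive optimal-transport oracle for 1-D EMD between equal-mass empirical
# samples: minimum over all permutation couplings (contains the optimum).
emdPermOracle <- function(a, b) {
  stopifnot(length(a) == length(b))
  P <- allPerms(length(a))
  min(vapply(seq_len(nrow(P)), function(r) mean(abs(a - b[P[r, ]])), 0))
}

# Two-cluster structure-to-text corpus: descriptor clusters tied to disjoint
# vocabularies, for prefix-tuning tests.
makeClusterCorpus <- function(n = 30, seed = 5) {
  set.seed(seed)
  fam <- rep(1:2, each = n / 2)
  ids <- sprintf("m%03d", seq_len(n))
  vocabs <- list(c("apple", "pear", "banana", "berry"),
                 c("smoke", "tar", "burnt", "ash"))
  texts <- vapply(seq_len(n), function(i) {
    v <- sample(vocabs[[fam[i]]], 2)
    sprintf("This molecule has a %s, %s odor.", v[1], v[2])
  }, "")
  names(texts) <- ids
  desc <- matrix(rnorm(n * 8, mean = ifelse(fam == 1, 2, -2)), n, 8)
  rownames(desc) <- ids
  list(ids = ids, fam = fam, texts = texts, desc = desc)
}

# Unique-molecule embedding matrix (one row per molecule) from a catalogue.
moleculeEmbeddings <- function(embedder, catalog, kind = "CHD") {
  emb <- embedCatalog(embedder, catalog, kind)
  r <- embeddingRecords(emb)
  keep <- !duplicated(r$molecule_id)
  m <- embeddingRows(emb)[keep, , drop = FALSE]
  rownames(m) <- r$molecule_id[keep]
  m
}
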