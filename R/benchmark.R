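# The model-based benchmark: cosine-similarity distributions against shuffled
# nulls, 1-D earth-mover distance, top-k retrieval, and consensus comparison.

# Resolve (molecule_id, source) keys of an EmbeddingMatrix to row indices.
embRowIndex <- function(emb) {
  r <- embeddingRecords(emb)
  setNames(seq_len(nrow(r)), paste(r$molecule_id, r$source, sep = "\r"))
}

#' Paired and shuffled-null cosine-similarity distributions
#'
#' The paired sample is the CS over true cross-source same-molecule pairs; the
#' null sample applies a seeded derangement to one side of the pairing, so no
#' pair is accidentally matched with itself.
#'
#' @param emb_a,emb_b \linkS4class{EmbeddingMatrix} objects whose records carry
#'   molecule_id and source (may be the same object).
#' @param pairing a \linkS4class{PairIndex}; side a resolves (molecule,
#'   source_a) in \code{emb_a}, side b resolves (molecule, source_b) in
#'   \code{emb_b}.
#' @param seed derangement seed.
#' @return list of class "SimilarityDistribution": paired, null (numeric CS
#'   samples), seed.
#' @export
similarityDistributions <- function(emb_a, emb_b, pairing, seed = 1L) {
  e <- pairEntries(pairing)
  if (nrow(e) < 2) stop("need at least 2 pairs")
  ia <- embRowIndex(emb_a)[paste(e$molecule_id, e$source_a, sep = "\r")]
  ib <- embRowIndex(emb_b)[paste(e$molecule_id, e$source_b, sep = "\r")]
  if (any(is.na(ia)) || any(is.na(ib)))
    stop("pairing entries not resolvable to embedding rows")
  A <- embeddingRows(emb_a)[ia, , drop = FALSE]
  B <- embeddingRows(emb_b)[ib, , drop = FALSE]
  paired <- rowSums(A * B) / (sqrt(rowSums(A^2)) * sqrt(rowSums(B^2)))
  # null: derangement over pair rows, rejecting same-molecule coincidences
  set.seed(seed)
  repeat {
    p <- derangement(nrow(e))
    if (all(e$molecule_id != e$molecule_id[p])) break
  }
  Bp <- B[p, , drop = FALSE]
  null <- rowSums(A * Bp) / (sqrt(rowSums(A^2)) * sqrt(rowSums(Bp^2)))
  structure(list(paired = paired, null = null, seed = seed),
            class = "SimilarityDistribution")
}

#' 1-D earth-mover (1-Wasserstein) distance
#'
#' Equal-size samples: mean absolute difference of the sorted samples (the
#' monotone optimal coupling). Unequal sizes: exact integral of the absolute
#' difference of the two empirical CDFs.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return non-negative scalar.
#' @examples
#' emd1d(c(0, 0), c(1, 1)) # 1
#' @export
emd1d <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("empty sample")
  n <- length(sample_a); m <- length(sample_b)
  if (n == m) return(mean(abs(sort(sample_a) - sort(sample_b))))
  br <- sort(c(sample_a, sample_b))
  x <- br[-length(br)]
  w <- diff(br)
  Fa <- vapply(x, function(t) mean(sample_a <= t), 0)
  Fb <- vapply(x, function(t) mean(sample_b <= t), 0)
  sum(abs(Fa - Fb) * w)
}

#' Top-k retrieval accuracy
#'
#' For each query embedding, gallery items are ranked by cosine similarity
#' (ties broken by stable gallery order); the accuracy at k is the fraction of
#' queries whose true molecule supplies a gallery item within the top k.
#' Gallery rows that are the query record itself (same molecule, source and
#' kind) are excluded.
#'
#' @param query_embs,gallery_embs \linkS4class{EmbeddingMatrix} objects.
#' @param ks integer vector of cutoffs.
#' @param truth optional character vector of true gallery molecule ids per
#'   query (default: the query's own molecule_id).
#' @return named numeric vector: accuracy per k.
#' @export
topkRetrieval <- function(query_embs, gallery_embs, ks, truth = NULL) {
  Q <- embeddingRows(query_embs); G <- embeddingRows(gallery_embs)
  qr <- embeddingRecords(query_embs); gr <- embeddingRecords(gallery_embs)
  if (is.null(truth)) truth <- qr$molecule_id
  stopifnot(length(truth) == nrow(Q))
  qkey <- paste(qr$molecule_id, qr$source, qr$kind, sep = "\r")
  gkey <- paste(gr$molecule_id, gr$source, gr$kind, sep = "\r")
  eff_gallery <- min(vapply(seq_len(nrow(Q)), function(i)
    sum(gkey != qkey[i]), 0L))
  if (any(ks > eff_gallery))
    stop("k exceeds effective gallery size (", eff_gallery, ")")
  miss <- !truth %in% gr$molecule_id
  if (any(miss))
    stop("query without any gallery item for its molecule: ",
         truth[which(miss)[1L]])
  S <- Q %*% t(G)
  hitrank <- vapply(seq_len(nrow(Q)), function(i) {
    keep <- which(gkey != qkey[i])
    # stable order: ties resolved by gallery position
    ord <- keep[order(-S[i, keep], keep)]
    hit <- which(gr$molecule_id[ord] == truth[i])
    if (length(hit)) hit[1L] else Inf
  }, 0)
  setNames(vapply(ks, function(k) mean(hitrank <= k), 0),
           paste0("k", ks))
}

#' Compare machine-human similarity with the human consensus
#'
#' Welch two-sample t-test between the per-pair human-human CS sample and the
#' machine-human CS sample. The verdict states whether the machine sits below,
#' at, or above the human consensus at the given alpha.
#'
#' @param cs_hh,cs_mh numeric per-pair cosine-similarity samples.
#' @param alpha significance level (default 0.01).
#' @return list of class "ConsensusVerdict": gap (mean hh - mean mh), t, p,
#'   verdict.
#' @export
compareToConsensus <- function(cs_hh, cs_mh, alpha = 0.01) {
  if (length(cs_hh) < 2 || length(cs_mh) < 2) stop("need >= 2 scores per side")
  if (sd(cs_hh) == 0 && sd(cs_mh) == 0)
    stop("degenerate (constant) similarity samples")
  tt <- t.test(cs_hh, cs_mh, var.equal = FALSE)
  gap <- mean(cs_hh) - mean(cs_mh)
  verdict <- if (tt$p.value >= alpha) "at" else if (gap > 0) "below" else "above"
  structure(list(gap = gap, t = unname(tt$statistic), p = tt$p.value,
                 alpha = alpha, verdict = verdict),
            class = "ConsensusVerdict")
}

#' @export
print.ConsensusVerdict <- function(x, ...) {
  cat(sprintf("machine is %s consensus: gap = %.4f, t = %.3f, p = %.3g\n",
              x$verdict, x$gap, x$t, x$p))
  invisible(x)
}

#' Per-molecule averaged description embeddings
#'
#' \code{mode = "full"}: for each molecule, the renormalized mean of its
#' source embeddings (the dataset-averaged embedding). \code{mode =
#' "leave_source_out"}: for each (molecule, source), the renormalized mean
#' over the other sources, for evaluation against that source without the
#' self-inclusion inflation.
#'
#' @param emb an \linkS4class{EmbeddingMatrix} with molecule_id and source in
#'   its records.
#' @param mode "full" or "leave_source_out".
#' @return an \linkS4class{EmbeddingMatrix}; for "full" the records carry one
#'   row per molecule, for "leave_source_out" one row per (molecule, excluded
#'   source).
#' @export
averageEmbeddings <- function(emb, mode = c("full", "leave_source_out")) {
  mode <- match.arg(mode)
  r <- embeddingRecords(emb); M <- embeddingRows(emb)
  sp <- split(seq_len(nrow(r)), r$molecule_id)
  if (mode == "full") {
    rows <- t(vapply(sp, function(ix)
      colMeans(M[ix, , drop = FALSE]), numeric(ncol(M))))
    rows <- normalizeRows(rows)
    rec <- data.frame(molecule_id = names(sp), source = "average",
                      kind = "GEN", text = NA_character_,
                      stringsAsFactors = FALSE)
    return(new("EmbeddingMatrix", matrix = unname(rows), records = rec,
               embedder = paste0(emb@embedder, "-avg"), normalized = TRUE))
  }
  out <- list(); rec <- list()
  for (mid in names(sp)) {
    ix <- sp[[mid]]
    if (length(unique(r$source[ix])) < 2)
      stop("leave_source_out needs >= 2 sources per molecule (", mid, ")")
    for (s in unique(r$source[ix])) {
      keep <- ix[r$source[ix] != s]
      out[[length(out) + 1L]] <- colMeans(M[keep, , drop = FALSE])
      rec[[length(rec) + 1L]] <- data.frame(
        molecule_id = mid, source = s, kind = "GEN", text = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  rows <- normalizeRows(do.call(rbind, out))
  new("EmbeddingMatrix", matrix = rows, records = do.call(rbind, rec),
      embedder = paste0(emb@embedder, "-avg-loso"), normalized = TRUE)
}

#' Run the model-based benchmark on a catalogue
#'
#' Computes, for one embedder and a reference description kind (the human
#' ground truth): the human-human consensus S_hh over cross-source pairs, the
#' paired-vs-null EMD, top-k retrieval accuracy, and for each machine kind the
#' machine-human similarity S_mh with a Welch t-test against consensus.
#'
#' @param catalog an \linkS4class{OdorCatalog}.
#' @param emb_by_kind named list of \linkS4class{EmbeddingMatrix}, one per
#'   description kind; must include \code{reference_kind}.
#' @param reference_kind the human ground-truth kind (default "CHD").
#' @param machine_kinds kinds evaluated against the reference (default: all
#'   other names of \code{emb_by_kind}).
#' @param ks retrieval cutoffs.
#' @param seed null-pairing seed.
#' @return list of class "BenchmarkReport": s_hh (MetricScore on the 0-100
#'   scale), emd, retrieval, and per machine kind s_mh, verdict.
#' @export
benchmarkReport <- function(catalog, emb_by_kind, reference_kind = "CHD",
                            machine_kinds = NULL, ks = c(1, 5, 10, 20),
                            seed = 1L) {
  stopifnot(reference_kind %in% names(emb_by_kind))
  ref <- emb_by_kind[[reference_kind]]
  pairing <- crossSourcePairs(catalog, reference_kind)
  sdist <- similarityDistributions(ref, ref, pairing, seed = seed)
  emd <- emd1d(sdist$paired, sdist$null)
  ks_eff <- ks[ks <= nrow(embeddingRows(ref)) - 1]
  retr <- topkRetrieval(ref, ref, ks = ks_eff)
  if (is.null(machine_kinds))
    machine_kinds <- setdiff(names(emb_by_kind), reference_kind)
  machine <- list()
  for (kind in machine_kinds) {
    cs <- machineHumanCS(emb_by_kind[[kind]], ref)
    machine[[kind]] <- list(
      s_mh = metricScore(100 * cs, paste0("CS:", kind)),
      verdict = compareToConsensus(sdist$paired, cs))
  }
  structure(list(reference_kind = reference_kind,
                 s_hh = metricScore(100 * sdist$paired, "CS:hh"),
                 distribution = sdist, emd = emd, retrieval = retr,
                 machine = machine, seed = seed),
            class = "BenchmarkReport")
}

# CS between every machine record and every same-molecule reference record.
machineHumanCS <- function(emb_machine, emb_ref) {
  rm_ <- embeddingRecords(emb_machine); rr <- embeddingRecords(emb_ref)
  Mm <- embeddingRows(emb_machine); Mr <- embeddingRows(emb_ref)
  cs <- numeric(0)
  ref_by_mol <- split(seq_len(nrow(rr)), rr$molecule_id)
  for (i in seq_len(nrow(rm_))) {
    ix <- ref_by_mol[[rm_$molecule_id[i]]]
    if (is.null(ix)) next
    cs <- c(cs, as.numeric(Mr[ix, , drop = FALSE] %*% Mm[i, ]))
  }
  if (!length(cs)) stop("no same-molecule machine/reference record pairs")
  cs
}

#' @export
print.BenchmarkReport <- function(x, ...) {
  cat("ODIEU model-based benchmark (reference:", x$reference_kind, ")\n")
  cat(sprintf("  S_hh = %.2f (SEM %.2f, n = %d); EMD(paired, null) = %.3f\n",
              x$s_hh$mean, x$s_hh$sem, x$s_hh$n, x$emd))
  cat("  retrieval:", paste(sprintf("%s=%.2f", names(x$retrieval),
                                    x$retrieval), collapse = " "), "\n")
  for (kind in names(x$machine)) {
    m <- x$machine[[kind]]
    cat(sprintf("  %s: S_mh = %.2f (SEM %.2f), gap = %.2f, p = %.3g (%s)\n",
                kind, m$s_mh$mean, m$s_mh$sem, x$s_hh$mean - m$s_mh$mean,
                m$verdict$p, m$verdict$verdict))
  }
  invisible(x)
}

#' Write a benchmark report as CSV (scores) and JSON (full, with seeds)
#'
#' @param report a "BenchmarkReport".
#' @param csv_path,json_path output paths (either may be NULL).
#' @return invisibly, the paths written.
#' @export
writeBenchmarkReport <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    rows <- data.frame(kind = "hh", mean = report$s_hh$mean,
                       sem = report$s_hh$sem, n = report$s_hh$n,
                       stringsAsFactors = FALSE)
    for (kind in names(report$machine)) {
      m <- report$machine[[kind]]$s_mh
      rows <- rbind(rows, data.frame(kind = kind, mean = m$mean, sem = m$sem,
                                     n = m$n, stringsAsFactors = FALSE))
    }
    write.csv(rows, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    out <- list(reference_kind = report$reference_kind,
                s_hh = unclass(report$s_hh), emd = report$emd,
                retrieval = as.list(report$retrieval), seed = report$seed,
                machine = lapply(report$machine, function(m)
                  list(s_mh = unclass(m$s_mh),
                       gap = m$verdict$gap, t = m$verdict$t,
                       p = m$verdict$p, verdict = m$verdict$verdict)))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(c(csv = csv_path, json = json_path))
}
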