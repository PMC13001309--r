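#' Construct an OdorSpace
#'
#' @param name space name.
#' @param coords numeric molecules x dims matrix with molecule-id rownames, or
#'   ids supplied separately.
#' @param ids character molecule ids (default: rownames of coords).
#' @param provenance free-text note on the coordinates' origin.
#' @return an \linkS4class{OdorSpace}.
#' @export
odorSpace <- function(name, coords, ids = rownames(coords), provenance = "") {
  coords <- as.matrix(coords)
  if (is.null(ids)) stop("molecule ids required (rownames or ids=)")
  rownames(coords) <- NULL
  new("OdorSpace", name = name, ids = as.character(ids), coords = coords,
      provenance = provenance)
}

#' OdorSpace accessors
#' @param x an \linkS4class{OdorSpace}.
#' @export
spaceIds <- function(x) x@ids

#' @rdname spaceIds
#' @export
spaceCoords <- function(x) { m <- x@coords; rownames(m) <- x@ids; m }

#' @rdname spaceIds
#' @export
spaceName <- function(x) x@name

#' Read / write OdorSpace CSV with a JSON sidecar
#'
#' CSV columns: molecule_id + one column per coordinate; the sidecar
#' (\code{<path>.json}) records name and provenance.
#'
#' @param x an \linkS4class{OdorSpace}; \code{path} a .csv path.
#' @return \code{writeOdorSpace}: the path, invisibly; \code{readOdorSpace}:
#'   an \linkS4class{OdorSpace}.
#' @param path CSV path.
#' @export
writeOdorSpace <- function(x, path) {
  writeVectorCSV(spaceCoords(x), path)
  jsonlite::write_json(list(name = x@name, provenance = x@provenance),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeOdorSpace
#' @export
readOdorSpace <- function(path) {
  m <- readVectorCSV(path)
  colnames(m) <- NULL
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else
    list(name = basename(path), provenance = "")
  odorSpace(meta$name, m, provenance = meta$provenance %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Metric MDS reduction of an odor space
#'
#' Classical scaling of the Euclidean distance matrix followed by SMACOF
#' majorization steps (monotonically non-increasing stress). Reports Kruskal
#' stress-1: sqrt(sum (d - dhat)^2 / sum d^2). High-dimensional embedding
#' spaces are reduced this way (e.g. to 50 dimensions) before cross-space
#' comparison.
#'
#' @param space an \linkS4class{OdorSpace} with d > target_dim and
#'   n > target_dim.
#' @param target_dim output dimensionality.
#' @param n_iter SMACOF refinement iterations (default 20).
#' @param seed reserved for stochastic initializers; the default classical
#'   initialization is deterministic.
#' @return list: space (the reduced \linkS4class{OdorSpace}), stress.
#' @export
reduceMDS <- function(space, target_dim, n_iter = 20L, seed = 1L) {
  X <- spaceCoords(space)
  n <- nrow(X); d <- ncol(X)
  if (target_dim >= d) stop("target_dim must be < space dimensionality")
  if (n <= target_dim) stop("need more molecules than target_dim")
  D <- as.matrix(dist(X))
  Y <- cmdscale(D, k = target_dim)
  if (ncol(Y) < target_dim)  # degenerate spectra: pad with zeros
    Y <- cbind(Y, matrix(0, n, target_dim - ncol(Y)))
  # SMACOF majorization on raw stress; each step cannot increase stress
  for (it in seq_len(n_iter)) {
    Dy <- as.matrix(dist(Y))
    ratio <- ifelse(Dy > 0, D / Dy, 0)
    Bz <- -ratio
    diag(Bz) <- 0
    diag(Bz) <- -rowSums(Bz)
    Y <- (Bz %*% Y) / n
  }
  Dy <- as.matrix(dist(Y))
  stress <- sqrt(sum((D - Dy)^2) / sum(D^2))
  list(space = odorSpace(sprintf("%s-mds%d", space@name, target_dim), Y,
                         ids = spaceIds(space),
                         provenance = sprintf("metric MDS of '%s' (%d -> %d)",
                                              space@name, d, target_dim)),
       stress = stress)
}

# Restrict two spaces to their overlapping molecules, in a common id order.
overlapSpaces <- function(space_a, space_b) {
  ids <- intersect(spaceIds(space_a), spaceIds(space_b))
  list(ids = ids,
       A = spaceCoords(space_a)[ids, , drop = FALSE],
       B = spaceCoords(space_b)[ids, , drop = FALSE])
}

#' Shared dimensions between two odor spaces by CCA
#'
#' Canonical correlation analysis on the overlapping molecules; the sum of
#' squared canonical correlations quantifies the effective number of shared
#' dimensions, weighted by the alignment strength in each. Rank-deficient or
#' n < d inputs are first projected onto their top min(d, n-1) principal
#' components, and a small ridge stabilizes the covariance blocks.
#'
#' @param space_a,space_b \linkS4class{OdorSpace} objects with >= 3
#'   overlapping molecules.
#' @param ridge relative covariance ridge (scaled by the mean covariance
#'   diagonal; default 1e-8).
#' @return list of class "SharedStructureReport": rho (canonical correlations,
#'   descending), sum_sq (sum of squared correlations), n, dims.
#' @export
ccaSharedDims <- function(space_a, space_b, ridge = 1e-8) {
  ov <- overlapSpaces(space_a, space_b)
  n <- length(ov$ids)
  if (n < 3) stop("need >= 3 overlapping molecules (have ", n, ")")
  A <- scale(ov$A, center = TRUE, scale = FALSE)
  B <- scale(ov$B, center = TRUE, scale = FALSE)
  A <- pcaReduce(A, min(ncol(A), n - 1L))
  B <- pcaReduce(B, min(ncol(B), n - 1L))
  Saa <- crossprod(A) / (n - 1)
  Sbb <- crossprod(B) / (n - 1)
  # ridge only when a covariance block is ill-conditioned, so well-posed
  # full-rank comparisons stay exactly invariant under linear transforms
  Saa <- ridgeIfNeeded(Saa, ridge)
  Sbb <- ridgeIfNeeded(Sbb, ridge)
  Sab <- crossprod(A, B) / (n - 1)
  Wa <- matInvSqrt(Saa); Wb <- matInvSqrt(Sbb)
  rho <- svd(Wa %*% Sab %*% Wb)$d
  rho <- pmin(pmax(rho, 0), 1)
  m <- min(ncol(A), ncol(B))
  rho <- sort(rho, decreasing = TRUE)[seq_len(m)]
  structure(list(rho = rho, sum_sq = sum(rho^2), n = n,
                 dims = c(ncol(ov$A), ncol(ov$B))),
            class = "SharedStructureReport")
}

# Project centered data onto its top-r principal components (drops null
# directions; CCA is invariant to this basis change on the retained rank).
pcaReduce <- function(Xc, r) {
  s <- svd(Xc, nu = 0)
  keep <- which(s$d > max(s$d) * 1e-10)
  keep <- keep[seq_len(min(length(keep), r))]
  Xc %*% s$v[, keep, drop = FALSE]
}

ridgeIfNeeded <- function(S, ridge) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-9 * max(ev))
    S <- S + ridge * mean(diag(S)) * diag(ncol(S))
  S
}

# Symmetric inverse square root via eigendecomposition.
matInvSqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(v), length(v)) %*% t(e$vectors)
}

#' @export
print.SharedStructureReport <- function(x, ...) {
  cat(sprintf("CCA shared structure: sum of squared correlations = %.3f over n = %d (dims %d x %d)\n",
              x$sum_sq, x$n, x$dims[1], x$dims[2]))
  invisible(x)
}

#' Cross-space predictive linear map
#'
#' Fits a least-squares (pseudoinverse) linear map from a base space to a
#' target space on a seeded train split of the overlapping molecules, with
#' both spaces centered using training-set means only, and reports the mean
#' per-coordinate Pearson correlation between predicted and true target
#' coordinates on the held-out molecules.
#'
#' @param base,target \linkS4class{OdorSpace} objects with >= 5 overlapping
#'   molecules.
#' @param train_frac training fraction in (0, 1), default 0.8.
#' @param seed split seed.
#' @return list of class "MapReport": R (mean held-out Pearson correlation),
#'   per_coord (per-coordinate correlations), n_train, n_test, seed.
#' @export
linearMapPredict <- function(base, target, train_frac = 0.8, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  ov <- overlapSpaces(base, target)
  n <- length(ov$ids)
  if (n < 5) stop("need >= 5 overlapping molecules")
  set.seed(seed)
  n_train <- floor(train_frac * n)
  if (n - n_train < 2) stop("held-out set smaller than 2 molecules")
  tr <- sort(sample.int(n, n_train))
  te <- setdiff(seq_len(n), tr)
  mu_b <- colMeans(ov$A[tr, , drop = FALSE])
  mu_t <- colMeans(ov$B[tr, , drop = FALSE])
  Xtr <- sweep(ov$A[tr, , drop = FALSE], 2, mu_b)
  Ytr <- sweep(ov$B[tr, , drop = FALSE], 2, mu_t)
  Xte <- sweep(ov$A[te, , drop = FALSE], 2, mu_b)
  Yte <- sweep(ov$B[te, , drop = FALSE], 2, mu_t)
  M <- pinv(Xtr) %*% Ytr
  pred <- Xte %*% M
  per_coord <- vapply(seq_len(ncol(Yte)), function(j) {
    if (sd(Yte[, j]) == 0 || sd(pred[, j]) == 0) return(0)
    cor(pred[, j], Yte[, j])
  }, 0)
  structure(list(R = mean(per_coord), per_coord = per_coord,
                 n_train = n_train, n_test = length(te),
                 train_frac = train_frac, seed = seed),
            class = "MapReport")
}

#' @export
print.MapReport <- function(x, ...) {
  cat(sprintf("predictive map: held-out R = %.4f (train %d / test %d)\n",
              x$R, x$n_train, x$n_test))
  invisible(x)
}
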