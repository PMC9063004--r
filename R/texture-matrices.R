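# 3D texture matrix construction over the 26-neighborhood.
#
# All builders take a QuantizedROI whose `levels` array holds integer gray
# levels in-mask and NA out-of-mask. Aggregation follows the merged-3D
# convention: per-direction counts over the 13 unique displacement vectors
# of the 26-neighborhood are summed into a single matrix before feature
# computation (IBSI codes IAZD for GLCM/GLRLM; GLSZM and NGTDM are single
# per-volume matrices, KOBO). Displacements act on the index grid; no
# physical-distance weighting is applied.

#' The 13 unique displacement vectors of the 26-neighborhood
#'
#' Half of the 26 nearest-neighbor offsets, modulo sign: each vector's
#' first nonzero component is +1, so no two offsets are negations of each
#' other. Co-occurrence and run-length accumulation over these 13 vectors
#' in both orientations covers the full 26-neighborhood.
#'
#' @return A 13 x 3 integer matrix of (di, dj, dk) displacements.
#' @export
directionSet3D <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  first_nonzero_pos <- apply(g, 1L, function(v) v[which(v != 0)[1]] > 0)
  o <- g[first_nonzero_pos, , drop = FALSE]
  storage.mode(o) <- "integer"
  rownames(o) <- NULL
  o
}

# Aligned index blocks for an offset: linear indices `from` such that
# `from + offset` is in bounds, paired with the shifted indices `to`.
.shiftBlocks <- function(dims, offset) {
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, 1L - offset[a]); hi <- min(dims[a], dims[a] - offset[a])
    if (lo > hi) return(NULL)
    lo:hi
  })
  if (any(vapply(rng, is.null, logical(1)))) return(NULL)
  lin <- array(seq_len(prod(dims)), dim = dims)
  list(from = as.vector(lin[rng[[1]], rng[[2]], rng[[3]]]),
       to = as.vector(lin[rng[[1]] + offset[1], rng[[2]] + offset[2],
                          rng[[3]] + offset[3]]))
}

#' Build the merged-direction gray-level co-occurrence matrix
#'
#' Counts co-occurring in-mask level pairs at the given voxel displacement
#' along all 13 unique directions and both orientations, then normalizes.
#' The result is symmetric and sums to one.
#'
#' @param roi A [QuantizedROI-class].
#' @param displacement Integer voxel displacement, default 1.
#' @param directions Integer matrix of displacement vectors, default
#'   [directionSet3D()].
#' @return A [GLCMatrix-class].
#' @export
buildGLCM <- function(roi, displacement = 1L, directions = directionSet3D()) {
  stopifnot(methods::is(roi, "QuantizedROI"))
  L <- roi@levels
  G <- roi@nLevels
  dims <- dim(L)
  counts <- numeric(G * G)
  for (r in seq_len(nrow(directions))) {
    blk <- .shiftBlocks(dims, directions[r, ] * as.integer(displacement))
    if (is.null(blk)) next
    a <- L[blk$from]; b <- L[blk$to]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    a <- a[ok]; b <- b[ok]
    counts <- counts + tabulate((a - 1L) * G + b, nbins = G * G) +
      tabulate((b - 1L) * G + a, nbins = G * G)
  }
  tot <- sum(counts)
  if (tot == 0) stop("no in-mask voxel pair at the given displacement; GLCM undefined")
  P <- matrix(counts / tot, nrow = G, ncol = G, byrow = TRUE)
  methods::new("GLCMatrix", P = P, displacement = as.integer(displacement))
}

# Maximal same-level runs along one direction. Voxels on a scan line are
# identified by the anchor (coordinate minus position * offset), which is
# invariant along the line; the coordinate at the offset's first nonzero
# component (always +1) orders voxels within the line.
.runsOneDirection <- function(L, offset) {
  dims <- dim(L)
  ii <- slice.index(L, 1L); jj <- slice.index(L, 2L); kk <- slice.index(L, 3L)
  cpos <- which(offset != 0)[1]
  pos <- switch(cpos, ii, jj, kk)
  a1 <- ii - pos * offset[1]; a2 <- jj - pos * offset[2]; a3 <- kk - pos * offset[3]
  M <- max(dims) + 1L
  key <- (a1 + M) + (a2 + M) * (3L * M) + (a3 + M) * (9L * M * M)
  ord <- order(key, pos)
  l <- as.vector(L)[ord]; g <- key[ord]
  n <- length(l)
  newrun <- rep(TRUE, n)
  if (n > 1L) {
    same <- g[-1] == g[-n] & !is.na(l[-1]) & !is.na(l[-n]) & l[-1] == l[-n]
    newrun[-1] <- !same
  }
  id <- cumsum(newrun)
  keep <- !is.na(l)
  if (!any(keep)) return(NULL)
  len <- tabulate(id[keep])
  lev <- l[keep][!duplicated(id[keep])]
  cbind(level = lev, length = len[len > 0])
}

#' Build the merged-direction gray-level run-length matrix
#'
#' Maximal constant-level runs are enumerated along every scan line of each
#' of the 13 directions (out-of-mask voxels break runs) and the 13
#' per-direction matrices are summed (merged aggregation). Voxel
#' conservation then reads \eqn{\sum R(g,l)\,l = N_v \times 13}.
#'
#' @param roi A [QuantizedROI-class].
#' @param directions Integer matrix of displacement vectors, default
#'   [directionSet3D()].
#' @return A [GLRLMatrix-class].
#' @export
buildGLRLM <- function(roi, directions = directionSet3D()) {
  stopifnot(methods::is(roi, "QuantizedROI"))
  L <- roi@levels
  G <- roi@nLevels
  nv <- sum(!is.na(L))
  if (nv == 0L) stop("empty ROI")
  allruns <- do.call(rbind, lapply(seq_len(nrow(directions)), function(r)
    .runsOneDirection(L, directions[r, ])))
  Lmax <- max(allruns[, "length"])
  R <- matrix(0, nrow = G, ncol = Lmax)
  idx <- (allruns[, "length"] - 1L) * G + allruns[, "level"]
  cnt <- tabulate(idx, nbins = G * Lmax)
  R[] <- cnt
  methods::new("GLRLMatrix", R = R, nVoxels = as.integer(nv),
               nDirections = nrow(directions))
}

#' Build the gray-level size-zone matrix (26-connectivity)
#'
#' Labels 26-connected constant-level zones (two same-level voxels sharing
#' a face, edge or corner are connected) and counts zones by (gray level,
#' size). Zone sizes partition the ROI.
#'
#' @param roi A [QuantizedROI-class].
#' @return A [GLSZMatrix-class].
#' @export
buildGLSZM <- function(roi) {
  stopifnot(methods::is(roi, "QuantizedROI"))
  L <- roi@levels
  G <- roi@nLevels
  dims <- dim(L)
  maskIdx <- which(!is.na(L))
  nv <- length(maskIdx)
  if (nv == 0L) stop("empty ROI")
  vid <- array(NA_integer_, dim = dims)
  vid[maskIdx] <- seq_len(nv)
  dirs <- directionSet3D()
  edges <- vector("list", nrow(dirs))
  for (r in seq_len(nrow(dirs))) {
    blk <- .shiftBlocks(dims, dirs[r, ])
    a <- L[blk$from]; b <- L[blk$to]
    ok <- !is.na(a) & !is.na(b) & a == b
    if (any(ok)) edges[[r]] <- rbind(vid[blk$from[ok]], vid[blk$to[ok]])
  }
  e <- do.call(cbind, edges)
  memb <- if (is.null(e)) {
    seq_len(nv)
  } else {
    gr <- igraph::make_graph(edges = as.vector(e), n = nv, directed = FALSE)
    igraph::components(gr)$membership
  }
  sizes <- tabulate(memb)
  lv <- L[maskIdx]
  zlev <- lv[match(seq_along(sizes), memb)]
  Smax <- max(sizes)
  Z <- matrix(0, nrow = G, ncol = Smax)
  cnt <- tabulate((sizes - 1L) * G + zlev, nbins = G * Smax)
  Z[] <- cnt
  methods::new("GLSZMatrix", Z = Z, nVoxels = as.integer(nv))
}

#' Build the neighborhood gray-tone difference matrix
#'
#' For every in-mask voxel with at least one in-mask 26-neighbor, the
#' absolute difference between its level and the mean level of its in-mask
#' neighbors is accumulated into \code{s[level]}; \code{n[level]} counts
#' the contributing voxels. Isolated in-mask voxels (no in-mask neighbor,
#' possible at mask edges) are excluded so that masked boundaries do not
#' fabricate differences.
#'
#' @param roi A [QuantizedROI-class].
#' @return A [NGTDMatrix-class].
#' @export
buildNGTDM <- function(roi) {
  stopifnot(methods::is(roi, "QuantizedROI"))
  L <- roi@levels
  G <- roi@nLevels
  dims <- dim(L)
  nv <- sum(!is.na(L))
  if (nv == 0L) stop("empty ROI")
  S <- array(0, dim = dims)
  C <- array(0L, dim = dims)
  Lz <- L; Lz[is.na(Lz)] <- 0L
  inm <- !is.na(L)
  dirs <- directionSet3D()
  for (r in seq_len(nrow(dirs))) {
    blk <- .shiftBlocks(dims, dirs[r, ])
    # neighbor `to` contributes to voxel `from`, and vice versa
    S[blk$from] <- S[blk$from] + Lz[blk$to]
    C[blk$from] <- C[blk$from] + inm[blk$to]
    S[blk$to] <- S[blk$to] + Lz[blk$from]
    C[blk$to] <- C[blk$to] + inm[blk$from]
  }
  use <- inm & C > 0L
  lev <- L[use]
  dif <- abs(lev - S[use] / C[use])
  s <- numeric(G); n <- numeric(G)
  n[seq_len(G)] <- tabulate(lev, nbins = G)
  agg <- rowsum(dif, group = lev)
  s[as.integer(rownames(agg))] <- agg[, 1]
  methods::new("NGTDMatrix", s = s, n = n, nVoxels = as.integer(nv))
}
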