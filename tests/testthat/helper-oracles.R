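# Independent brute-force oracles for the texture matrices and features.
# Everything here is written as plain voxel/pair loops with no shared code
# with the package implementation.

oracle_dirs <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  g[apply(g, 1, function(v) v[which(v != 0)[1]] > 0), , drop = FALSE]
}

.at <- function(L, co) L[co[1], co[2], co[3]]
.inb <- function(co, dims) all(co >= 1) && all(co <= dims)

oracle_glcm <- function(L, G) {
  dims <- dim(L)
  dirs <- oracle_dirs()
  cnt <- matrix(0, G, G)
  idx <- which(!is.na(L))
  co <- arrayInd(idx, dims)
  for (r in seq_len(nrow(co))) {
    a <- .at(L, co[r, ])
    for (d in seq_len(nrow(dirs))) for (sgn in c(1, -1)) {
      nb <- co[r, ] + sgn * dirs[d, ]
      if (.inb(nb, dims)) {
        b <- .at(L, nb)
        if (!is.na(b)) cnt[a, b] <- cnt[a, b] + 1
      }
    }
  }
  cnt / sum(cnt)
}

# runs along one direction: start where the predecessor is absent, walk on
oracle_glrlm_dir <- function(L, G, d) {
  dims <- dim(L)
  runs <- list()
  idx <- which(!is.na(L))
  co <- arrayInd(idx, dims)
  for (r in seq_len(nrow(co))) {
    v <- co[r, ]
    lv <- .at(L, v)
    prev <- v - d
    starts <- !.inb(prev, dims) || is.na(.at(L, prev)) || .at(L, prev) != lv
    if (!starts) next
    len <- 1
    nxt <- v + d
    while (.inb(nxt, dims) && !is.na(.at(L, nxt)) && .at(L, nxt) == lv) {
      len <- len + 1
      nxt <- nxt + d
    }
    runs[[length(runs) + 1]] <- c(lv, len)
  }
  if (!length(runs)) return(matrix(0, G, 1))
  m <- do.call(rbind, runs)
  R <- matrix(0, G, max(m[, 2]))
  for (r in seq_len(nrow(m))) R[m[r, 1], m[r, 2]] <- R[m[r, 1], m[r, 2]] + 1
  R
}

oracle_glrlm <- function(L, G) {
  dirs <- oracle_dirs()
  mats <- lapply(seq_len(nrow(dirs)), function(i) oracle_glrlm_dir(L, G, dirs[i, ]))
  Lmax <- max(vapply(mats, ncol, 1L))
  R <- matrix(0, G, Lmax)
  for (m in mats) R[, seq_len(ncol(m))] <- R[, seq_len(ncol(m))] + m
  R
}

# flood fill over the 26-neighborhood
oracle_glszm <- function(L, G) {
  dims <- dim(L)
  dirs <- rbind(oracle_dirs(), -oracle_dirs())
  seen <- array(FALSE, dims)
  zones <- list()
  idx <- which(!is.na(L))
  co <- arrayInd(idx, dims)
  for (r in seq_len(nrow(co))) {
    v <- co[r, ]
    if (seen[v[1], v[2], v[3]]) next
    lv <- .at(L, v)
    queue <- list(v)
    seen[v[1], v[2], v[3]] <- TRUE
    size <- 0
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (d in seq_len(nrow(dirs))) {
        nb <- cur + dirs[d, ]
        if (.inb(nb, dims) && !seen[nb[1], nb[2], nb[3]] &&
            !is.na(.at(L, nb)) && .at(L, nb) == lv) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lv, size)
  }
  m <- do.call(rbind, zones)
  Z <- matrix(0, G, max(m[, 2]))
  for (r in seq_len(nrow(m))) Z[m[r, 1], m[r, 2]] <- Z[m[r, 1], m[r, 2]] + 1
  Z
}

oracle_ngtdm <- function(L, G) {
  dims <- dim(L)
  dirs <- rbind(oracle_dirs(), -oracle_dirs())
  s <- numeric(G); n <- numeric(G)
  idx <- which(!is.na(L))
  co <- arrayInd(idx, dims)
  for (r in seq_len(nrow(co))) {
    v <- co[r, ]
    lv <- .at(L, v)
    nb <- c()
    for (d in seq_len(nrow(dirs))) {
      u <- v + dirs[d, ]
      if (.inb(u, dims) && !is.na(.at(L, u))) nb <- c(nb, .at(L, u))
    }
    if (length(nb)) {
      n[lv] <- n[lv] + 1
      s[lv] <- s[lv] + abs(lv - mean(nb))
    }
  }
  list(s = s, n = n)
}

# direct, loop-written feature formulas (unmodified IBSI forms)

oracle_glcm_features <- function(P) {
  G <- nrow(P)
  mu <- 0; for (i in 1:G) for (j in 1:G) mu <- mu + i * P[i, j]
  sig2 <- 0; for (i in 1:G) for (j in 1:G) sig2 <- sig2 + (i - mu)^2 * P[i, j]
  f <- c(contrast = 0, dissimilarity = 0, homogeneity = 0, correlation = 0,
         energy = 0, variance = 0, entropy = 0, sum_average = 0)
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    f["contrast"] <- f["contrast"] + p * (i - j)^2
    f["dissimilarity"] <- f["dissimilarity"] + p * abs(i - j)
    f["homogeneity"] <- f["homogeneity"] + p / (1 + abs(i - j))
    f["energy"] <- f["energy"] + p^2
    f["variance"] <- f["variance"] + p * (i - mu)^2
    if (p > 0) f["entropy"] <- f["entropy"] - p * log2(p)
    f["sum_average"] <- f["sum_average"] + p * (i + j)
    f["correlation"] <- f["correlation"] + p * i * j
  }
  f["correlation"] <- if (sig2 > 0) (f[["correlation"]] - mu^2) / sig2 else NaN
  f
}

oracle_glrlm_features <- function(R, nv, ndir) {
  G <- nrow(R); Lm <- ncol(R); Nr <- sum(R)
  acc <- function(w) { s <- 0; for (g in 1:G) for (l in 1:Lm) s <- s + R[g, l] * w(g, l); s / Nr }
  mg <- acc(function(g, l) g); ml <- acc(function(g, l) l)
  c(short_run_emphasis = acc(function(g, l) 1 / l^2),
    long_run_emphasis = acc(function(g, l) l^2),
    gray_level_nonuniformity = sum(rowSums(R)^2) / Nr,
    run_length_nonuniformity = sum(colSums(R)^2) / Nr,
    run_percentage = Nr / (nv * ndir),
    low_gray_level_run_emphasis = acc(function(g, l) 1 / g^2),
    high_gray_level_run_emphasis = acc(function(g, l) g^2),
    short_run_low_gray_level_emphasis = acc(function(g, l) 1 / (g^2 * l^2)),
    short_run_high_gray_level_emphasis = acc(function(g, l) g^2 / l^2),
    long_run_low_gray_level_emphasis = acc(function(g, l) l^2 / g^2),
    long_run_high_gray_level_emphasis = acc(function(g, l) g^2 * l^2),
    gray_level_variance = acc(function(g, l) (g - mg)^2),
    run_length_variance = acc(function(g, l) (l - ml)^2))
}

oracle_glszm_features <- function(Z, nv) {
  G <- nrow(Z); Sm <- ncol(Z); Nz <- sum(Z)
  acc <- function(w) { s <- 0; for (g in 1:G) for (z in 1:Sm) s <- s + Z[g, z] * w(g, z); s / Nz }
  mg <- acc(function(g, z) g); ms <- acc(function(g, z) z)
  c(small_zone_emphasis = acc(function(g, z) 1 / z^2),
    large_zone_emphasis = acc(function(g, z) z^2),
    gray_level_nonuniformity = sum(rowSums(Z)^2) / Nz,
    zone_size_nonuniformity = sum(colSums(Z)^2) / Nz,
    zone_percentage = Nz / nv,
    low_gray_level_zone_emphasis = acc(function(g, z) 1 / g^2),
    high_gray_level_zone_emphasis = acc(function(g, z) g^2),
    small_zone_low_gray_level_emphasis = acc(function(g, z) 1 / (g^2 * z^2)),
    small_zone_high_gray_level_emphasis = acc(function(g, z) g^2 / z^2),
    large_zone_low_gray_level_emphasis = acc(function(g, z) z^2 / g^2),
    large_zone_high_gray_level_emphasis = acc(function(g, z) g^2 * z^2),
    gray_level_variance = acc(function(g, z) (g - mg)^2),
    zone_size_variance = acc(function(g, z) (z - ms)^2))
}

oracle_ngtdm_features <- function(s, n) {
  N <- sum(n); p <- n / N
  act <- which(p > 0); Ngp <- length(act)
  ps <- sum(p * s)
  coarse <- if (ps > 0) 1 / ps else NaN
  contrast <- 0; busy_den <- 0; complexity <- 0; str_num <- 0
  if (Ngp > 1) {
    for (i in act) for (j in act) {
      contrast <- contrast + p[i] * p[j] * (i - j)^2
      busy_den <- busy_den + abs(i * p[i] - j * p[j])
      complexity <- complexity + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
      str_num <- str_num + (p[i] + p[j]) * (i - j)^2
    }
    contrast <- contrast / (Ngp * (Ngp - 1)) * sum(s) / N
    complexity <- complexity / N
  }
  c(coarseness = coarse,
    contrast = contrast,
    busyness = if (busy_den > 0) ps / busy_den else NaN,
    complexity = complexity,
    strength = if (sum(s) > 0) str_num / sum(s) else 0)
}

# random small quantized ROIs for oracle-equivalence sweeps; guarantees at
# least one co-occurring in-mask pair
random_small_roi <- function(maxdim = 4, maxG = 4) {
  repeat {
    dims <- sample(1:maxdim, 3, replace = TRUE)
    if (prod(dims) < 2) next
    G <- sample(2:maxG, 1)
    L <- array(sample(1:G, prod(dims), replace = TRUE), dims)
    drop <- runif(prod(dims)) < 0.2
    L[drop] <- NA_integer_
    if (sum(!is.na(L)) < 2) next
    q <- try(quantizedROI(L, nLevels = G), silent = TRUE)
    if (inherits(q, "try-error")) next
    g <- try(buildGLCM(q), silent = TRUE)
    if (inherits(g, "try-error")) next
    return(q)
  }
}

# small correlated-field ROI for feature-level tests
random_field_roi <- function(dim = 10, seed = 1) {
  set.seed(seed)
  img <- array(rnorm(dim^3), rep(dim, 3))
  k <- c(1, 2, 1) / 4
  sm <- function(x) {
    for (i in 1:3) {
      d <- dim(x)
      x <- apply(x, c(2, 3), function(v) stats::filter(c(v[1], v, v[length(v)]), k, sides = 2)[2:(length(v) + 1)])
      dim(x) <- d
      x <- aperm(x, c(2, 3, 1))
    }
    x
  }
  img <- sm(img)
  ctr <- (dim + 1) / 2
  g <- seq_len(dim)
  msk <- outer(outer((g - ctr)^2, (g - ctr)^2, "+"), (g - ctr)^2, "+") <= (dim / 2.2)^2
  maskedROI(img, msk)
}
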