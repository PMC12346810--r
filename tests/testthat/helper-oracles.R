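# Independent brute-force oracles used to verify the feature engine and the
# evaluation metrics. These deliberately share no code with the package
# implementation: plain loops and direct enumeration only.

oracle_directions <- function() {
  list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
       c(1, 1, 0), c(1, -1, 0),
       c(1, 0, 1), c(1, 0, -1),
       c(0, 1, 1), c(0, 1, -1),
       c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# symmetric GLCM counts by enumerating every in-ROI voxel and its offset
# partner in both orientations
oracle_glcm_counts <- function(bins, offset) {
  d <- dim(bins)
  ng <- max(bins)
  counts <- matrix(0, ng, ng)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    a <- bins[x, y, z]
    if (a == 0) next
    for (s in c(1, -1)) {
      x2 <- x + s * offset[1]; y2 <- y + s * offset[2]; z2 <- z + s * offset[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3])
        next
      b <- bins[x2, y2, z2]
      if (b == 0) next
      counts[a, b] <- counts[a, b] + 1
    }
  }
  counts
}

oracle_glcm_features_one <- function(counts) {
  if (sum(counts) == 0) return(NULL)
  p <- counts / sum(counts)
  ng <- nrow(p)
  je <- jent <- contrast <- idm <- ct <- sij <- 0
  px <- rowSums(p)
  mu <- sum(seq_len(ng) * px)
  v <- sum((seq_len(ng) - mu)^2 * px)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    pij <- p[i, j]
    je <- je + pij^2
    if (pij > 0) jent <- jent - pij * log2(pij)
    contrast <- contrast + (i - j)^2 * pij
    idm <- idm + pij / (1 + (i - j)^2)
    ct <- ct + (i + j - 2 * mu)^2 * pij
    sij <- sij + i * j * pij
  }
  corr <- if (v > 0) (sij - mu^2) / v else 1
  c(joint_energy = je, joint_entropy = jent, contrast = contrast,
    correlation = corr, idm = idm, cluster_tendency = ct)
}

oracle_glcm_features <- function(bins) {
  per <- list()
  for (off in oracle_directions()) {
    f <- oracle_glcm_features_one(oracle_glcm_counts(bins, off))
    if (!is.null(f)) per[[length(per) + 1]] <- f
  }
  Reduce(`+`, per) / length(per)
}

# run scanner: walk every line in the direction, collecting maximal runs
oracle_glrlm_matrix <- function(bins, offset) {
  d <- dim(bins)
  ng <- max(bins)
  maxlen <- max(d)
  m <- matrix(0, ng, maxlen)
  inb <- function(x, y, z) x >= 1 && x <= d[1] && y >= 1 && y <= d[2] &&
    z >= 1 && z <= d[3]
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    g <- bins[x, y, z]
    if (g == 0) next
    px <- x - offset[1]; py <- y - offset[2]; pz <- z - offset[3]
    if (inb(px, py, pz) && bins[px, py, pz] == g) next  # not a run start
    len <- 1
    nx <- x + offset[1]; ny <- y + offset[2]; nz <- z + offset[3]
    while (inb(nx, ny, nz) && bins[nx, ny, nz] == g) {
      len <- len + 1
      nx <- nx + offset[1]; ny <- ny + offset[2]; nz <- nz + offset[3]
    }
    m[g, len] <- m[g, len] + 1
  }
  m
}

oracle_glrlm_features <- function(bins) {
  nv <- sum(bins > 0)
  per <- list()
  for (off in oracle_directions()) {
    m <- oracle_glrlm_matrix(bins, off)
    nr <- sum(m)
    g <- seq_len(nrow(m)); l <- seq_len(ncol(m))
    per[[length(per) + 1]] <- c(
      sre = sum(sweep(m, 2, l^2, `/`)) / nr,
      lre = sum(sweep(m, 2, l^2, `*`)) / nr,
      gln = sum(rowSums(m)^2) / nr,
      rln = sum(colSums(m)^2) / nr,
      run_pct = nr / nv,
      lglre = sum(rowSums(m) / g^2) / nr,
      hglre = sum(rowSums(m) * g^2) / nr)
  }
  Reduce(`+`, per) / length(per)
}

# 26-connected flood fill over equal-bin voxels
oracle_glszm_zones <- function(bins) {
  d <- dim(bins)
  seen <- array(FALSE, d)
  zones <- list()
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (bins[x, y, z] == 0 || seen[x, y, z]) next
    g <- bins[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        w <- v + c(dx, dy, dz)
        if (any(w < 1) || any(w > d)) next
        if (!seen[w[1], w[2], w[3]] && bins[w[1], w[2], w[3]] == g) {
          seen[w[1], w[2], w[3]] <- TRUE
          queue[[length(queue) + 1]] <- w
        }
      }
    }
    zones[[length(zones) + 1]] <- c(gray = g, size = size)
  }
  zones
}

oracle_glszm_features <- function(bins) {
  zs <- oracle_glszm_zones(bins)
  gray <- vapply(zs, `[[`, 0, "gray")
  size <- vapply(zs, `[[`, 0, "size")
  nz <- length(zs)
  nv <- sum(bins > 0)
  ng <- max(bins)
  zg <- vapply(seq_len(ng), function(g) sum(gray == g), 0)
  ms <- max(size)
  zsz <- vapply(seq_len(ms), function(s) sum(size == s), 0)
  c(sae = sum(zsz / seq_len(ms)^2) / nz,
    lae = sum(zsz * seq_len(ms)^2) / nz,
    zone_pct = nz / nv,
    gln = sum(zg^2) / nz,
    szn = sum(zsz^2) / nz)
}

oracle_auc <- function(labels, probs) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

oracle_confusion <- function(pred, truth) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
  }
  c(accuracy = (tp + tn) / length(pred),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

# random small binned ROI array for oracle comparisons
random_binned_roi <- function(seed, max_dim = 6L, ngray = 4L) {
  set.seed(seed)
  d <- sample(2:max_dim, 3, replace = TRUE)
  bins <- array(sample(0:ngray, prod(d), replace = TRUE,
                       prob = c(0.3, rep(0.7 / ngray, ngray))), dim = d)
  if (all(bins == 0)) bins[1, 1, 1] <- 1L
  storage.mode(bins) <- "integer"
  bins
}
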