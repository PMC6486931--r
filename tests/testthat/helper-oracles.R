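# Independent brute-force oracles, written plainly and kept free of any
# package internals so they can disagree with the implementation.

# All 26 unit offsets, spelled out by triple loop.
bf_offsets26 <- local({
  out <- NULL
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    if (dx != 0 || dy != 0 || dz != 0) out <- rbind(out, c(dx, dy, dz))
  out
})

# Spatial GLCM counts by exhaustive pair enumeration (pre-normalisation).
bf_glcm_spatial <- function(volume, mask, bins) {
  vals <- volume[mask > 0]
  lo <- min(vals); hi <- max(vals)
  binof <- function(v) {
    if (hi == lo) return(1L)
    min(bins, floor((v - lo) / (hi - lo) * bins) + 1L)
  }
  d <- dim(volume)
  counts <- matrix(0, bins, bins)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (mask[x, y, z] == 0) next
    for (o in seq_len(nrow(bf_offsets26))) {
      nx <- x + bf_offsets26[o, 1]; ny <- y + bf_offsets26[o, 2]; nz <- z + bf_offsets26[o, 3]
      if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3]) next
      if (mask[nx, ny, nz] == 0) next
      a <- binof(volume[x, y, z]); b <- binof(volume[nx, ny, nz])
      counts[a, b] <- counts[a, b] + 1
    }
  }
  counts
}

# Temporal GLCM counts: one pair per in-mask voxel, shared pooled binning.
bf_glcm_temporal <- function(va, vb, mask, bins) {
  inb <- which(mask > 0)
  lo <- min(c(va[inb], vb[inb])); hi <- max(c(va[inb], vb[inb]))
  binof <- function(v) {
    if (hi == lo) return(1L)
    min(bins, floor((v - lo) / (hi - lo) * bins) + 1L)
  }
  counts <- matrix(0, bins, bins)
  for (i in inb) {
    a <- binof(va[i]); b <- binof(vb[i])
    counts[a, b] <- counts[a, b] + 1
  }
  counts
}

# Textbook recomputation of the 13 Haralick statistics from a normalised GLCM.
bf_haralick <- function(p) {
  ng <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mx <- sum((1:ng) * px); my <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mx)^2 * px)); sy <- sqrt(sum(((1:ng) - my)^2 * py))
  asm <- 0; con <- 0; cor <- 0; va <- 0; idm <- 0; ent <- 0
  psum <- rep(0, 2 * ng); pdif <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    asm <- asm + pij^2
    con <- con + (i - j)^2 * pij
    if (sx > 0 && sy > 0) cor <- cor + (i - mx) * (j - my) * pij / (sx * sy)
    va <- va + (i - mx)^2 * pij
    idm <- idm + pij / (1 + (i - j)^2)
    if (pij > 0) ent <- ent - pij * log(pij)
    psum[i + j] <- psum[i + j] + pij
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + pij
  }
  sa <- sum((1:(2 * ng))[2:(2 * ng)] * psum[2:(2 * ng)])
  sv <- sum(((2:(2 * ng)) - sa)^2 * psum[2:(2 * ng)])
  se <- -sum(psum[psum > 0] * log(psum[psum > 0]))
  da <- sum((0:(ng - 1)) * pdif)
  dv <- sum(((0:(ng - 1)) - da)^2 * pdif)
  de <- -sum(pdif[pdif > 0] * log(pdif[pdif > 0]))
  hx <- -sum(px[px > 0] * log(px[px > 0])); hy <- -sum(py[py > 0] * log(py[py > 0]))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * py[j]
    if (q > 0) {
      hxy1 <- hxy1 - p[i, j] * log(q)
      hxy2 <- hxy2 - q * log(q)
    }
  }
  imc1 <- if (max(hx, hy) == 0) 0 else (ent - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(energy = asm, contrast = con, correlation = cor, variance = va,
    homogeneity = idm, sum_average = sa, sum_variance = sv, sum_entropy = se,
    entropy = ent, difference_variance = dv, difference_entropy = de,
    imc1 = imc1, imc2 = imc2)
}

# AUC by exhaustive positive-negative pair counting (ties count half).
bf_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# 6-connected components by breadth-first flood fill.
bf_components6 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (mask[x, y, z] == 0 || lab[x, y, z] > 0) next
    cur <- cur + 1L
    queue <- list(c(x, y, z))
    lab[x, y, z] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
        n <- v + o
        if (any(n < 1) || any(n > d)) next
        if (mask[n[1], n[2], n[3]] > 0 && lab[n[1], n[2], n[3]] == 0L) {
          lab[n[1], n[2], n[3]] <- cur
          queue[[length(queue) + 1]] <- n
        }
      }
    }
  }
  lab
}

# Discrete mutual information in nats, by direct probability sums.
bf_mi <- function(a, b) {
  ta <- table(a); tb <- table(b); tab <- table(a, b)
  n <- length(a)
  s <- 0
  for (i in rownames(tab)) for (j in colnames(tab)) {
    pij <- tab[i, j] / n
    if (pij > 0) s <- s + pij * log(pij / ((ta[i] / n) * (tb[j] / n)))
  }
  as.numeric(s)
}
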