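# Independent brute-force oracles: plain R loops over voxels, pairs and
# candidate thresholds, written without reference to the package internals.

oracle_offsets <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

.in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

oracle_glcm_matrix <- function(lev, ng) {
  d <- dim(lev)
  acc <- matrix(0, ng, ng); nvalid <- 0
  for (o in seq_len(nrow(oracle_offsets))) {
    cnt <- matrix(0, ng, ng)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      li <- lev[x, y, z]
      if (li == 0) next
      q <- c(x, y, z) + oracle_offsets[o, ]
      if (!.in_bounds(q, d)) next
      lj <- lev[q[1], q[2], q[3]]
      if (lj == 0) next
      cnt[li, lj] <- cnt[li, lj] + 1
      cnt[lj, li] <- cnt[lj, li] + 1
    }
    if (sum(cnt) > 0) { acc <- acc + cnt / sum(cnt); nvalid <- nvalid + 1 }
  }
  if (nvalid > 0) acc / nvalid else acc
}

oracle_glcm_features <- function(lev, ng) {
  P <- oracle_glcm_matrix(lev, ng)
  mu_i <- 0; mu_j <- 0
  for (i in 1:ng) for (j in 1:ng) { mu_i <- mu_i + i * P[i, j]; mu_j <- mu_j + j * P[i, j] }
  var_i <- 0; var_j <- 0
  for (i in 1:ng) for (j in 1:ng) {
    var_i <- var_i + (i - mu_i)^2 * P[i, j]
    var_j <- var_j + (j - mu_j)^2 * P[i, j]
  }
  f <- c(contrast = 0, dissimilarity = 0, entropy = 0, correlation = 0,
         energy = 0, homogeneity = 0, idm = 0, shade = 0, prominence = 0,
         autocorr = 0, maxp = max(P), javg = mu_i)
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    f["contrast"] <- f["contrast"] + (i - j)^2 * p
    f["dissimilarity"] <- f["dissimilarity"] + abs(i - j) * p
    if (p > 0) f["entropy"] <- f["entropy"] - p * log2(p)
    f["energy"] <- f["energy"] + p^2
    f["homogeneity"] <- f["homogeneity"] + p / (1 + abs(i - j))
    f["idm"] <- f["idm"] + p / (1 + (i - j)^2)
    f["shade"] <- f["shade"] + (i + j - mu_i - mu_j)^3 * p
    f["prominence"] <- f["prominence"] + (i + j - mu_i - mu_j)^4 * p
    f["autocorr"] <- f["autocorr"] + i * j * p
  }
  f["correlation"] <- if (var_i > 0 && var_j > 0) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng)
      s <- s + (i - mu_i) * (j - mu_j) * P[i, j]
    s / sqrt(var_i * var_j)
  } else 1
  f
}

# run-length matrix for one direction by walking every maximal run
oracle_glrlm_matrix <- function(lev, ng, off) {
  d <- dim(lev)
  m <- matrix(0, ng, max(d))
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    li <- lev[x, y, z]
    if (li == 0) next
    p <- c(x, y, z) - off
    if (.in_bounds(p, d) && lev[p[1], p[2], p[3]] == li) next
    len <- 1; q <- c(x, y, z) + off
    while (.in_bounds(q, d) && lev[q[1], q[2], q[3]] == li) {
      len <- len + 1; q <- q + off
    }
    m[li, len] <- m[li, len] + 1
  }
  m
}

oracle_glrlm_features <- function(lev, ng) {
  np <- sum(lev > 0)
  acc <- NULL; nvalid <- 0
  for (o in seq_len(nrow(oracle_offsets))) {
    m <- oracle_glrlm_matrix(lev, ng, oracle_offsets[o, ])
    nr <- sum(m)
    if (nr == 0) next
    f <- c(sre = 0, lre = 0, lglre = 0, hglre = 0, srlgle = 0, srhgle = 0,
           lrlgle = 0, lrhgle = 0, gln = 0, rlv = 0, rp = nr / np)
    mu_r <- 0
    for (i in 1:nrow(m)) for (r in 1:ncol(m)) mu_r <- mu_r + r * m[i, r] / nr
    for (i in 1:nrow(m)) {
      for (r in 1:ncol(m)) {
        c_ <- m[i, r]
        if (c_ == 0) next
        f["sre"] <- f["sre"] + c_ / r^2
        f["lre"] <- f["lre"] + c_ * r^2
        f["lglre"] <- f["lglre"] + c_ / i^2
        f["hglre"] <- f["hglre"] + c_ * i^2
        f["srlgle"] <- f["srlgle"] + c_ / (i^2 * r^2)
        f["srhgle"] <- f["srhgle"] + c_ * i^2 / r^2
        f["lrlgle"] <- f["lrlgle"] + c_ * r^2 / i^2
        f["lrhgle"] <- f["lrhgle"] + c_ * i^2 * r^2
        f["rlv"] <- f["rlv"] + (c_ / nr) * (r - mu_r)^2
      }
      f["gln"] <- f["gln"] + sum(m[i, ])^2
    }
    for (nm in c("sre", "lre", "lglre", "hglre", "srlgle", "srhgle",
                 "lrlgle", "lrhgle", "gln"))
      f[nm] <- f[nm] / nr
    acc <- if (is.null(acc)) f else acc + f
    nvalid <- nvalid + 1
  }
  acc / nvalid
}

# 26-connected zones by repeated flood fill
oracle_glszm_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- NULL
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (lev[x, y, z] == 0 || seen[x, y, z]) next
    li <- lev[x, y, z]
    frontier <- matrix(c(x, y, z), 1)
    seen[x, y, z] <- TRUE
    size <- 0
    while (nrow(frontier) > 0) {
      cur <- frontier[1, ]; frontier <- frontier[-1, , drop = FALSE]
      size <- size + 1
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- cur + c(dx, dy, dz)
        if (!.in_bounds(q, d)) next
        if (!seen[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == li) {
          seen[q[1], q[2], q[3]] <- TRUE
          frontier <- rbind(frontier, q)
        }
      }
    }
    zones <- rbind(zones, c(li, size))
  }
  zones
}

oracle_glszm_features <- function(lev, ng) {
  zones <- oracle_glszm_zones(lev)
  np <- sum(lev > 0); nz <- nrow(zones)
  i <- zones[, 1]; z <- zones[, 2]
  mu_i <- mean(i)
  glc <- sapply(1:ng, function(l) sum(i == l))
  zsc <- sapply(sort(unique(z)), function(s) sum(z == s))
  c(sae = mean(1 / z^2), lae = mean(z^2),
    gln = sum(glc^2) / nz, zsn = sum(zsc^2) / nz,
    szlge = mean(1 / (i^2 * z^2)), szhge = mean(i^2 / z^2),
    lzlge = mean(z^2 / i^2), lzhge = mean(i^2 * z^2),
    glv = mean((i - mu_i)^2), zp = nz / np)
}

oracle_ngtdm_features <- function(lev, ng) {
  d <- dim(lev)
  n_i <- rep(0, ng); s_i <- rep(0, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    li <- lev[x, y, z]
    if (li == 0) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!.in_bounds(q, d)) next
      lj <- lev[q[1], q[2], q[3]]
      if (lj > 0) nb <- c(nb, lj)
    }
    n_i[li] <- n_i[li] + 1
    if (length(nb)) s_i[li] <- s_i[li] + abs(li - mean(nb))
  }
  N <- sum(n_i); p_i <- n_i / N
  occ <- which(p_i > 0); ngp <- length(occ)
  coars <- if (sum(p_i * s_i) > 0) 1 / sum(p_i * s_i) else 1e6
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  if (ngp > 1) {
    for (a in occ) for (b in occ) {
      contrast <- contrast + p_i[a] * p_i[b] * (a - b)^2
      busy_den <- busy_den + abs(a * p_i[a] - b * p_i[b])
      complexity <- complexity +
        abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
      strength <- strength + (p_i[a] + p_i[b]) * (a - b)^2
    }
    contrast <- contrast / (ngp * (ngp - 1)) * sum(s_i) / N
    complexity <- complexity / N
    strength <- if (sum(s_i) > 0) strength / sum(s_i) else 0
  }
  busy <- if (ngp > 1 && busy_den > 0) sum(p_i * s_i) / busy_den else 0
  c(coarseness = coars, contrast = contrast, busyness = busy,
    complexity = complexity, strength = strength)
}

# literal re-implementation of the iterative correlation rule
oracle_corr_filter <- function(X, cutoff = 0.9) {
  keep <- colnames(X)
  repeat {
    if (length(keep) < 2) break
    C <- abs(cor(X[, keep, drop = FALSE]))
    diag(C) <- 0
    if (max(C) <= cutoff) break
    best <- c(NA, NA); best_r <- -1
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      if (a >= b) next
      if (C[a, b] > best_r + 1e-15) { best_r <- C[a, b]; best <- c(a, b) }
    }
    ma <- mean(C[best[1], -best[1]])
    mb <- mean(C[best[2], -best[2]])
    drop_i <- if (ma > mb) best[1] else if (mb > ma) best[2] else max(best)
    keep <- keep[-drop_i]
  }
  keep
}

# AUC by exhaustive pair counting with half-credit ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# exhaustive Youden search over unique scores and their midpoints
oracle_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- sort(unique(c(u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  best_j <- -Inf; best_t <- NA
  for (t in cand) {
    sens <- sum(scores >= t & labels == 1) / sum(labels == 1)
    spec <- sum(scores < t & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  best_t
}
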