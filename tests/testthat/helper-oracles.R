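# Independent brute-force oracles. These deliberately share no code with the
# package implementation: explicit loops, no vectorized shifting, no shared
# marginal computations.

# MTV by voxel-by-voxel threshold scan
oracle_mtv <- function(vol_arr, search_arr, fraction) {
  d <- dim(vol_arr)
  smax <- -Inf
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    if (search_arr[i, j, k] == 1 && vol_arr[i, j, k] > smax)
      smax <- vol_arr[i, j, k]
  thr <- fraction * smax
  out <- array(0L, dim = d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    if (search_arr[i, j, k] == 1 && vol_arr[i, j, k] >= thr)
      out[i, j, k] <- 1L
  out
}

# GLCM by exhaustive pair enumeration (both orderings)
oracle_glcm <- function(levels_arr, offset, ng) {
  d <- dim(levels_arr)
  P <- matrix(0, ng, ng)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- levels_arr[i, j, k]
    if (a == 0) next
    i2 <- i + offset[1]; j2 <- j + offset[2]; k2 <- k + offset[3]
    if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3]) next
    b <- levels_arr[i2, j2, k2]
    if (b == 0) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  if (sum(P) == 0) return(NULL)
  P / sum(P)
}

# all 16 Haralick features by naive double loops over the matrix
oracle_haralick <- function(P) {
  ng <- nrow(P)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx <- 0; sy <- 0
  for (i in 1:ng) { sx <- sx + (i - mux)^2 * px[i]; sy <- sy + (i - muy)^2 * py[i] }
  sx <- sqrt(sx); sy <- sqrt(sy)
  psum <- numeric(2 * ng); pdif <- numeric(ng)  # psum[k] = p_{x+y}(k), k in 2..2ng; pdif[k+1] = p_{x-y}(k)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + P[i, j]
  }
  ent <- 0; asm <- 0; con <- 0; hom <- 0; idm <- 0; mp <- 0; cs <- 0; cp <- 0
  crossij <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    asm <- asm + p^2
    con <- con + (i - j)^2 * p
    hom <- hom + p / (1 + abs(i - j))
    idm <- idm + p / (1 + (i - j)^2)
    cs <- cs + (i + j - mux - muy)^3 * p
    cp <- cp + (i + j - mux - muy)^4 * p
    crossij <- crossij + i * j * p
    if (p > mp) mp <- p
    if (p > 0) ent <- ent - p * log(p)
  }
  corr <- if (sx * sy == 0) 1 else (crossij - mux * muy) / (sx * sy)
  sa <- 0; se <- 0
  for (k in 2:(2 * ng)) {
    sa <- sa + k * psum[k]
    if (psum[k] > 0) se <- se - psum[k] * log(psum[k])
  }
  sv <- 0
  for (k in 2:(2 * ng)) sv <- sv + (k - sa)^2 * psum[k]
  de <- 0; mud <- 0
  for (k in 0:(ng - 1)) {
    mud <- mud + k * pdif[k + 1]
    if (pdif[k + 1] > 0) de <- de - pdif[k + 1] * log(pdif[k + 1])
  }
  dv <- 0
  for (k in 0:(ng - 1)) dv <- dv + (k - mud)^2 * pdif[k + 1]
  hx <- 0; hy <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) if (px[i] > 0) hx <- hx - px[i] * log(px[i])
  for (j in 1:ng) if (py[j] > 0) hy <- hy - py[j] * log(py[j])
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * py[j]
    if (q > 0) {
      hxy1 <- hxy1 - P[i, j] * log(q)
      hxy2 <- hxy2 - q * log(q)
    }
  }
  imc1 <- if (max(hx, hy) == 0) 0 else (ent - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(entropy = ent, homogeneity = hom, contrast = con, correlation = corr,
    angular_second_moment = asm, difference_entropy = de,
    difference_variance = dv, inverse_difference_moment = idm,
    sum_average = sa, sum_entropy = se, sum_variance = sv,
    cluster_prominence = cp, cluster_shade = cs, maximum_probability = mp,
    imc1 = imc1, imc2 = imc2)
}

# SUVpeak by explicit whole-grid sphere enumeration around the max voxel
oracle_suv_peak <- function(vol_arr, mtv_arr, spacing, radius = 6.2) {
  d <- dim(vol_arr)
  best <- -Inf; bi <- c(1, 1, 1)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    if (mtv_arr[i, j, k] == 1 && vol_arr[i, j, k] > best) {
      best <- vol_arr[i, j, k]; bi <- c(i, j, k)
    }
  acc <- c(); n <- 0
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    dist2 <- ((i - bi[1]) * spacing[1])^2 + ((j - bi[2]) * spacing[2])^2 +
      ((k - bi[3]) * spacing[3])^2
    if (dist2 <= radius^2) acc <- c(acc, vol_arr[i, j, k])
  }
  mean(acc)
}

# AUC by exhaustive pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# stochastic-matrix generator for feature-level tests
random_symmetric_stochastic <- function(ng) {
  M <- matrix(stats::runif(ng * ng), ng, ng)
  M <- M + t(M)
  M / sum(M)
}
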