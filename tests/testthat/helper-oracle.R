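# Independent single-region reference implementation of the 77-feature
# catalog, written directly from the feature definitions in plain R. Used
# to validate the sliding-window engine on arbitrary voxel sets
# (window-intersect-ROI regions). Conventions shared with the engine:
# population moments, percentile type 7, log2 with eps guard inside
# matrix-based entropies, GLCM/GLRLM accumulated over the 13 unique 3D
# directions, GLDM dependence = equal-level 26-neighbours + 1 (alpha = 0),
# NGTDM over the 26-neighbourhood, all-zero GLCM block when no voxel pair
# exists at distance 1.

oracle_dirs <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), ]
  # keep one of each +/- pair
  keep <- d[, 1] > 0 | (d[, 1] == 0 & d[, 2] > 0) |
    (d[, 1] == 0 & d[, 2] == 0 & d[, 3] > 0)
  d[keep, , drop = FALSE]
}

oracle_eps <- 2.220446049250313e-16

# region is a list(lev = 3D int (0 = excluded), raw = 3D dbl)
oracle_features <- function(lev, raw, n_levels, voxvol) {
  d <- dim(lev)
  inreg <- which(lev > 0)
  stopifnot(length(inreg) >= 2)
  vals <- raw[inreg]
  lv <- lev[inreg]
  L <- n_levels

  # ---------- first order ----------
  n <- length(vals)
  mu <- mean(vals)
  m2 <- mean((vals - mu)^2); m3 <- mean((vals - mu)^3); m4 <- mean((vals - mu)^4)
  p10 <- unname(quantile(vals, 0.10, type = 7))
  p90 <- unname(quantile(vals, 0.90, type = 7))
  rv <- vals[vals >= p10 & vals <= p90]
  hist_p <- tabulate(lv, nbins = L) / n
  hp <- hist_p[hist_p > 0]
  fo <- c(
    Energy = sum(vals^2),
    TotalEnergy = voxvol * sum(vals^2),
    Entropy = -sum(hp * log2(hp)),
    Minimum = min(vals),
    Percentile10 = p10,
    Percentile90 = p90,
    Maximum = max(vals),
    Mean = mu,
    Median = unname(quantile(vals, 0.5, type = 7)),
    InterquartileRange = unname(quantile(vals, 0.75, type = 7) -
                                  quantile(vals, 0.25, type = 7)),
    Range = max(vals) - min(vals),
    MeanAbsoluteDeviation = mean(abs(vals - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(rv)) mean(abs(rv - mean(rv))) else 0,
    RootMeanSquared = sqrt(mean(vals^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(hp^2)
  )

  dirs <- oracle_dirs()
  at <- function(ix) lev[matrix(ix, ncol = 3)]
  coords <- arrayInd(inreg, d)

  # ---------- GLCM ----------
  P <- matrix(0, L, L)
  for (k in seq_len(nrow(dirs))) {
    nb <- sweep(coords, 2, dirs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    b <- at(nb[ok, , drop = FALSE])
    a <- lv[ok]
    good <- b > 0
    for (ii in which(good)) {
      P[a[ii], b[ii]] <- P[a[ii], b[ii]] + 1
      P[b[ii], a[ii]] <- P[b[ii], a[ii]] + 1
    }
  }
  glcm <- oracle_glcm_features(P, L)

  # ---------- GLDM + NGTDM ----------
  alld <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  alld <- alld[rowSums(abs(alld)) > 0, ]
  D <- matrix(0, L, 27)
  s_i <- numeric(L); n_i <- numeric(L)
  for (r in seq_len(nrow(coords))) {
    nb <- sweep(alld, 2, coords[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    bl <- at(nb[ok, , drop = FALSE])
    bl <- bl[bl > 0]
    dep <- sum(bl == lv[r]) + 1L   # centre voxel included
    D[lv[r], dep] <- D[lv[r], dep] + 1
    if (length(bl) > 0) {
      s_i[lv[r]] <- s_i[lv[r]] + abs(lv[r] - mean(bl))
      n_i[lv[r]] <- n_i[lv[r]] + 1
    }
  }
  gldm <- oracle_gldm_features(D, L)
  ngtdm <- oracle_ngtdm_features(s_i, n_i, L)

  # ---------- GLRLM ----------
  maxlen <- max(d)
  R <- matrix(0, L, maxlen)
  inside <- function(ix) all(ix >= 1 & ix <= d)
  for (k in seq_len(nrow(dirs))) {
    dk <- dirs[k, ]
    for (r in seq_len(nrow(coords))) {
      pos <- coords[r, ]
      prev <- pos - dk
      if (inside(prev) && lev[matrix(prev, ncol = 3)] == lv[r]) next
      len <- 1
      nxt <- pos + dk
      while (inside(nxt) && lev[matrix(nxt, ncol = 3)] == lv[r]) {
        len <- len + 1
        nxt <- nxt + dk
      }
      R[lv[r], min(len, maxlen)] <- R[lv[r], min(len, maxlen)] + 1
    }
  }
  glrlm <- oracle_glrlm_features(R, L, maxlen, Np = n)

  out <- c(fo, glcm, gldm, glrlm, ngtdm)
  names(out) <- catalog_names_oracle()
  out
}

catalog_names_oracle <- function() {
  paste(
    rep(c("FIRSTORDER", "GLCM", "GLDM", "GLRLM", "NGTDM"),
        times = c(18, 24, 14, 16, 5)),
    c("Energy", "TotalEnergy", "Entropy", "Minimum", "Percentile10",
      "Percentile90", "Maximum", "Mean", "Median", "InterquartileRange",
      "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
      "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity",
      "Autocorrelation", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
      "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
      "JointEntropy", "MaximumProbability", "MCC", "SumAverage",
      "SumEntropy", "SumSquares",
      "SmallDependenceEmphasis", "LargeDependenceEmphasis",
      "GrayLevelNonUniformity", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "GrayLevelVariance",
      "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
      "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
      "SmallDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis",
      "LargeDependenceHighGrayLevelEmphasis",
      "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis",
      "Coarseness", "Contrast", "Busyness", "Complexity", "Strength"),
    sep = "_")
}

oracle_glcm_features <- function(P, L) {
  eps <- oracle_eps
  tot <- sum(P)
  nm <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
          "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
          "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
          "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
          "JointEnergy", "JointEntropy", "MaximumProbability", "MCC",
          "SumAverage", "SumEntropy", "SumSquares")
  if (tot <= 0) return(setNames(rep(0, 24), nm))
  p <- P / tot
  px <- rowSums(p)
  present <- which(px > 0)
  Ng <- length(present)
  gi <- matrix(seq_len(L), L, L)            # row gray value
  gj <- t(gi)                               # col gray value
  mux <- sum(px * seq_len(L))
  sx2 <- sum(px * (seq_len(L) - mux)^2)
  cb <- gi + gj - 2 * mux
  ad <- abs(gi - gj)
  pk_diff <- vapply(0:(L - 1), function(k) sum(p[ad == k]), numeric(1))
  pk_sum <- vapply(2:(2 * L), function(k) sum(p[(gi + gj) == k]), numeric(1))
  da <- sum((0:(L - 1)) * pk_diff)
  hxy <- -sum(p * log2(p + eps))
  pxy <- outer(px, px)
  hx <- -sum(px[present] * log2(px[present] + eps))
  hxy1 <- -sum(p * log2(pxy + eps))
  hxy2 <- -sum(pxy[present, present] * log2(pxy[present, present] + eps))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  e2 <- -2 * (hxy2 - hxy)
  imc2 <- if (e2 < 0 && (1 - exp(e2)) > 0) sqrt(1 - exp(e2)) else 0
  mcc <- 1
  if (Ng > 1) {
    Q <- matrix(0, Ng, Ng)
    for (a in seq_len(Ng)) for (b in seq_len(Ng)) {
      i <- present[a]; j <- present[b]
      den <- px[i] * px[present]
      Q[a, b] <- sum(ifelse(den > 0, p[i, present] * p[j, present] / den, 0))
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(min(max(ev[2], 0), 1))
  }
  offd <- ad > 0
  setNames(c(
    sum(p * gi * gj),
    sum(p * cb^4),
    sum(p * cb^3),
    sum(p * cb^2),
    sum(p * (gi - gj)^2),
    if (sx2 > 0) (sum(p * gi * gj) - mux^2) / sx2 else 1,
    da,
    -sum(pk_diff[pk_diff > 0] * log2(pk_diff[pk_diff > 0] + eps)),
    sum(pk_diff * ((0:(L - 1)) - da)^2),
    sum(p / (1 + ad)),
    sum(p / (1 + (gi - gj)^2)),
    sum(p / (1 + (gi - gj)^2 / Ng^2)),
    sum(p / (1 + ad / Ng)),
    imc1, imc2,
    sum(p[offd] / ad[offd]^2),
    mux,
    sum(p^2),
    hxy,
    max(p),
    mcc,
    sum((2:(2 * L)) * pk_sum),
    -sum(pk_sum[pk_sum > 0] * log2(pk_sum[pk_sum > 0] + eps)),
    sum(p * (gi - mux)^2)
  ), nm)
}

oracle_gldm_features <- function(D, L) {
  eps <- oracle_eps
  Nz <- sum(D)
  pm <- D / Nz
  gi <- matrix(seq_len(L), L, 27)
  jj <- matrix(rep(1:27, each = L), L, 27)
  mu_i <- sum(pm * gi); mu_j <- sum(pm * jj)
  c(SmallDependenceEmphasis = sum(D / jj^2) / Nz,
    LargeDependenceEmphasis = sum(D * jj^2) / Nz,
    GrayLevelNonUniformity = sum(rowSums(D)^2) / Nz,
    DependenceNonUniformity = sum(colSums(D)^2) / Nz,
    DependenceNonUniformityNormalized = sum(colSums(D)^2) / Nz^2,
    GrayLevelVariance = sum(pm * (gi - mu_i)^2),
    DependenceVariance = sum(pm * (jj - mu_j)^2),
    DependenceEntropy = -sum(pm[pm > 0] * log2(pm[pm > 0] + eps)),
    LowGrayLevelEmphasis = sum(D / gi^2) / Nz,
    HighGrayLevelEmphasis = sum(D * gi^2) / Nz,
    SmallDependenceLowGrayLevelEmphasis = sum(D / (gi^2 * jj^2)) / Nz,
    SmallDependenceHighGrayLevelEmphasis = sum(D * gi^2 / jj^2) / Nz,
    LargeDependenceLowGrayLevelEmphasis = sum(D * jj^2 / gi^2) / Nz,
    LargeDependenceHighGrayLevelEmphasis = sum(D * gi^2 * jj^2) / Nz)
}

oracle_glrlm_features <- function(R, L, maxlen, Np) {
  eps <- oracle_eps
  Nr <- sum(R)
  pr <- R / Nr
  gi <- matrix(seq_len(L), L, maxlen)
  rl <- matrix(rep(seq_len(maxlen), each = L), L, maxlen)
  mu_i <- sum(pr * gi); mu_l <- sum(pr * rl)
  c(ShortRunEmphasis = sum(R / rl^2) / Nr,
    LongRunEmphasis = sum(R * rl^2) / Nr,
    GrayLevelNonUniformity = sum(rowSums(R)^2) / Nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(R)^2) / Nr^2,
    RunLengthNonUniformity = sum(colSums(R)^2) / Nr,
    RunLengthNonUniformityNormalized = sum(colSums(R)^2) / Nr^2,
    RunPercentage = Nr / (Np * 13),
    GrayLevelVariance = sum(pr * (gi - mu_i)^2),
    RunVariance = sum(pr * (rl - mu_l)^2),
    RunEntropy = -sum(pr[pr > 0] * log2(pr[pr > 0] + eps)),
    LowGrayLevelRunEmphasis = sum(R / gi^2) / Nr,
    HighGrayLevelRunEmphasis = sum(R * gi^2) / Nr,
    ShortRunLowGrayLevelEmphasis = sum(R / (gi^2 * rl^2)) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(R * gi^2 / rl^2) / Nr,
    LongRunLowGrayLevelEmphasis = sum(R * rl^2 / gi^2) / Nr,
    LongRunHighGrayLevelEmphasis = sum(R * gi^2 * rl^2) / Nr)
}

oracle_ngtdm_features <- function(s_i, n_i, L) {
  Nvp <- sum(n_i)
  nm <- c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  if (Nvp <= 0) return(setNames(rep(0, 5), nm))
  p_i <- n_i / Nvp
  pres <- which(p_i > 0)
  Ngp <- length(pres)
  ps_sum <- sum(p_i * s_i)
  ssum <- sum(s_i)
  contrast <- 0; busy_den <- 0; cmplx <- 0; strn <- 0
  for (a in pres) for (b in pres) {
    contrast <- contrast + p_i[a] * p_i[b] * (a - b)^2
    busy_den <- busy_den + abs(a * p_i[a] - b * p_i[b])
    cmplx <- cmplx + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
      (p_i[a] + p_i[b])
    strn <- strn + (p_i[a] + p_i[b]) * (a - b)^2
  }
  setNames(c(
    if (ps_sum > 0) 1 / ps_sum else 1e6,
    if (Ngp > 1) contrast / (Ngp * (Ngp - 1)) * (ssum / Nvp) else 0,
    if (Ngp > 1 && busy_den > 0) ps_sum / busy_den else 0,
    cmplx / Nvp,
    if (ssum > 0) strn / ssum else 0
  ), nm)
}

# extract the window-intersect-ROI sub-cube around a ROI voxel
oracle_window_region <- function(lev, raw, roi, center, window) {
  h <- window %/% 2
  d <- dim(lev)
  rng <- lapply(1:3, function(a)
    max(1, center[a] - h):min(d[a], center[a] + h))
  wl <- lev[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  wr <- raw[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  wm <- roi[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  wl[!wm | is.na(wl)] <- 0L
  # embed in a full window-sized cube so run/pair geometry matches
  full_l <- array(0L, rep(window, 3))
  full_r <- array(0, rep(window, 3))
  off <- vapply(1:3, function(a) as.integer(rng[[a]][1] - (center[a] - h)),
                integer(1))
  ix <- lapply(1:3, function(a) seq_along(rng[[a]]) + off[a])
  full_l[ix[[1]], ix[[2]], ix[[3]]] <- wl
  full_r[ix[[1]], ix[[2]], ix[[3]]] <- wr
  list(lev = full_l, raw = full_r)
}
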