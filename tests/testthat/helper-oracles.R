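# Independent naive reference implementations used as oracles. These are
# deliberately written with plain loops and textbook formulas, sharing no
# code with the package's compiled paths.

# clamped (replicate-padding) sliding-window statistics
naive_window_stats <- function(arr, radii) {
  d <- dim(arr)
  out <- array(NA_real_, c(d, 4))
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    vals <- c()
    for (dz in -radii[3]:radii[3]) for (dy in -radii[2]:radii[2]) for (dx in -radii[1]:radii[1]) {
      xx <- min(max(x + dx, 1), d[1])
      yy <- min(max(y + dy, 1), d[2])
      zz <- min(max(z + dz, 1), d[3])
      vals <- c(vals, arr[xx, yy, zz])
    }
    out[x, y, z, ] <- c(mean(vals), median(vals), sd(vals), max(vals) - min(vals))
  }
  out
}

# equal-width quantization over the ROI, 0 outside
naive_quantize <- function(arr, mask, levels) {
  v <- arr[mask > 0]
  lo <- min(v); hi <- max(v)
  lab <- array(0L, dim(arr))
  if (hi <= lo) {
    lab[mask > 0] <- 1L
  } else {
    q <- floor((arr[mask > 0] - lo) / (hi - lo) * levels) + 1
    lab[mask > 0] <- as.integer(pmin(q, levels))
  }
  lab
}

# textbook 13 Haralick statistics (log2) from a normalized GLCM
naive_haralick13 <- function(P) {
  L <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  I <- row(P); J <- col(P)
  lg <- function(x) ifelse(x > 0, log2(x), 0)
  energy <- sum(P^2)
  contrast <- sum((I - J)^2 * P)
  mux <- sum((1:L) * px); muy <- sum((1:L) * py)
  sx <- sqrt(sum(((1:L) - mux)^2 * px)); sy <- sqrt(sum(((1:L) - muy)^2 * py))
  correlation <- if (sx > 0 && sy > 0) (sum(I * J * P) - mux * muy) / (sx * sy) else 0
  variance <- sum(((1:L) - mux)^2 * px)
  idm <- sum(P / (1 + (I - J)^2))
  pxy <- sapply(2:(2 * L), function(k) sum(P[(I + J) == k]))
  sumavg <- sum((2:(2 * L)) * pxy)
  sumvar <- sum(((2:(2 * L)) - sumavg)^2 * pxy)
  sument <- -sum(pxy * lg(pxy))
  entropy <- -sum(P * lg(P))
  pd <- sapply(0:(L - 1), function(k) sum(P[abs(I - J) == k]))
  dmu <- sum((0:(L - 1)) * pd)
  dvar <- sum(((0:(L - 1)) - dmu)^2 * pd)
  dent <- -sum(pd * lg(pd))
  hx <- -sum(px * lg(px)); hy <- -sum(py * lg(py))
  pp <- outer(px, py)
  hxy1 <- -sum(P * lg(pp))
  hxy2 <- -sum(pp * lg(pp))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  arg <- 1 - exp(-2 * (hxy2 - entropy))
  imc2 <- if (arg > 0) sqrt(arg) else 0
  c(energy, contrast, correlation, variance, idm, sumavg, sumvar, sument,
    entropy, dvar, dent, imc1, imc2)
}

# symmetric normalized GLCM of the labels inside a clipped window
naive_window_glcm <- function(lab, center, radii, offsets, levels) {
  d <- dim(lab)
  lo <- pmax(center - radii, 1)
  hi <- pmin(center + radii, d)
  P <- matrix(0, levels, levels)
  for (z in lo[3]:hi[3]) for (y in lo[2]:hi[2]) for (x in lo[1]:hi[1]) {
    for (o in seq_len(nrow(offsets))) {
      q <- c(x, y, z) + offsets[o, ]
      if (any(q < lo) || any(q > hi)) next
      la <- lab[x, y, z]; lb <- lab[q[1], q[2], q[3]]
      if (la > 0 && lb > 0) {
        P[la, lb] <- P[la, lb] + 1
        P[lb, la] <- P[lb, la] + 1
      }
    }
  }
  if (sum(P) == 0) return(NULL)
  P / sum(P)
}

# direct (non-separable) correlation with an assembled 3D kernel, replicate
# padding
naive_conv3 <- function(arr, kernel3) {
  d <- dim(arr)
  kd <- dim(kernel3)
  r <- (kd - 1) %/% 2
  out <- array(0, d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    acc <- 0
    for (kz in 1:kd[3]) for (ky in 1:kd[2]) for (kx in 1:kd[1]) {
      xx <- min(max(x + kx - r[1] - 1, 1), d[1])
      yy <- min(max(y + ky - r[2] - 1, 1), d[2])
      zz <- min(max(z + kz - r[3] - 1, 1), d[3])
      acc <- acc + kernel3[kx, ky, kz] * arr[xx, yy, zz]
    }
    out[x, y, z] <- acc
  }
  out
}

# all-pairs 95th-percentile symmetric surface distance
brute_hd95 <- function(maskA, maskB, spacing, probs = 0.95) {
  surf <- function(m) {
    d <- dim(m)
    pts <- NULL
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      if (m[x, y, z] == 0) next
      bdry <- FALSE
      for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        q <- c(x, y, z) + o
        if (any(q < 1) || any(q > d) || m[q[1], q[2], q[3]] == 0) { bdry <- TRUE; break }
      }
      if (bdry) pts <- rbind(pts, c(x, y, z))
    }
    pts
  }
  A <- surf(maskA); B <- surf(maskB)
  Ap <- sweep(A, 2, spacing, `*`); Bp <- sweep(B, 2, spacing, `*`)
  dAB <- apply(Ap, 1, function(p) min(sqrt(colSums((t(Bp) - p)^2))))
  dBA <- apply(Bp, 1, function(p) min(sqrt(colSums((t(Ap) - p)^2))))
  unname(quantile(c(dAB, dBA), probs = probs, type = 7))
}

# direct-formula weighted kappa on integer scores 1..L
oracle_weighted_kappa <- function(s1, s2, L, quadratic = FALSE) {
  O <- matrix(0, L, L)
  for (i in seq_along(s1)) O[s1[i], s2[i]] <- O[s1[i], s2[i]] + 1
  O <- O / length(s1)
  E <- outer(rowSums(O), colSums(O))
  W <- if (quadratic) outer(1:L, 1:L, function(i, j) (i - j)^2) else
    outer(1:L, 1:L, function(i, j) abs(i - j))
  1 - sum(W * O) / sum(W * E)
}

# textbook Cochran's Q
oracle_cochran_q <- function(calls) {
  k <- ncol(calls)
  Cj <- colSums(calls); Ri <- rowSums(calls)
  (k - 1) * (k * sum(Cj^2) - sum(Cj)^2) / (k * sum(Ri) - sum(Ri^2))
}

# equal-frequency binning + plug-in mutual information matching the stated
# selection contract (ceiling(sqrt(n)) bins capped at 10), written
# independently of the compiled path
oracle_bin <- function(v, n_bins) {
  r <- rank(v, ties.method = "first")
  as.integer(floor((r - 1) / length(v) * n_bins)) + 1L
}

oracle_mi <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  s <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  }
  s
}

# R reference for the greedy redundancy filter (same stated rule, naive
# implementation)
oracle_redundancy_filter <- function(X, threshold) {
  rho <- abs(cor(X, method = "spearman"))
  diag(rho) <- 0
  alive <- rep(TRUE, ncol(X))
  repeat {
    idx <- which(alive)
    if (length(idx) < 2) break
    sub <- rho[idx, idx, drop = FALSE]
    mx <- max(sub)
    if (mx < threshold) break
    hit <- which(sub == mx, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    a <- idx[hit[1, 1]]; b <- idx[hit[1, 2]]
    mean_a <- mean(rho[a, setdiff(idx, a)])
    mean_b <- mean(rho[b, setdiff(idx, b)])
    alive[if (mean_a > mean_b) a else b] <- FALSE
  }
  which(alive)
}

# simple mean silhouette for 2 clusters
mean_silhouette <- function(xy, cl) {
  n <- nrow(xy)
  dmat <- as.matrix(dist(xy))
  s <- numeric(n)
  for (i in 1:n) {
    own <- dmat[i, cl == cl[i] & seq_len(n) != i]
    oth <- dmat[i, cl != cl[i]]
    a <- mean(own); b <- mean(oth)
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small seeded cohort shared across tests
tiny_cohort <- function(n = 10, effect = 2, seed = 7, n_centers = 2) {
  generate_cohort(synth_config(
    n_subjects = n, n_centers = n_centers, class_balance = 0.5,
    effect_size = effect, seed = seed
  ))
}

# flood fill connectivity check (6-connectivity)
is_connected <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  d <- dim(mask)
  lab <- array(FALSE, d)
  queue <- list(idx[1, ])
  lab[idx[1, 1], idx[1, 2], idx[1, 3]] <- TRUE
  count <- 1L
  offs <- list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (o in offs) {
      q <- p + o
      if (any(q < 1) || any(q > d)) next
      if (mask[q[1], q[2], q[3]] > 0 && !lab[q[1], q[2], q[3]]) {
        lab[q[1], q[2], q[3]] <- TRUE
        count <- count + 1L
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  count == nrow(idx)
}
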