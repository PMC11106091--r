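# Independent brute-force reference implementations used as oracles.
# Deliberately naive: nested loops, no shared code with the package.

# Count occupied eps x eps boxes for one grid offset by scanning every box.
bf_box_count <- function(skel, eps, oy, ox) {
  H <- nrow(skel); W <- ncol(skel)
  n_occ <- 0
  # grid origin at (-oy, -ox), 0-based pixel coordinates
  by_start <- -oy
  bx_start <- -ox
  by <- by_start
  while (by < H) {
    bx <- bx_start
    while (bx < W) {
      rows <- max(by, 0):min(by + eps - 1, H - 1) + 1
      cols <- max(bx, 0):min(bx + eps - 1, W - 1) + 1
      if (any(skel[rows, cols])) n_occ <- n_occ + 1
      bx <- bx + eps
    }
    by <- by + eps
  }
  n_occ
}

# Gliding-box lacunarity by direct enumeration of all window positions.
bf_gliding_box <- function(skel, r) {
  H <- nrow(skel); W <- ncol(skel)
  masses <- numeric((H - r + 1) * (W - r + 1))
  k <- 0
  for (i in 1:(H - r + 1)) {
    for (j in 1:(W - r + 1)) {
      k <- k + 1
      masses[k] <- sum(skel[i:(i + r - 1), j:(j + r - 1)])
    }
  }
  m1 <- mean(masses); m2 <- mean(masses^2)
  if (m1 == 0) return(NA_real_)
  m2 / m1^2
}

# Otsu by exhaustive search over all 255 candidate splits, computing the
# between-class variance from first principles (class means).
bf_otsu <- function(pixels) {
  v <- as.integer(pixels)
  best_t <- NA_integer_; best_s <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# Disk median filter by direct per-pixel neighbourhood enumeration with
# edge replication.
bf_disk_median <- function(img, radius) {
  H <- nrow(img); W <- ncol(img)
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  out <- img * 0
  for (i in 1:H) {
    for (j in 1:W) {
      ii <- pmin(pmax(i + offs$dy, 1), H)
      jj <- pmin(pmax(j + offs$dx, 1), W)
      out[i, j] <- median(img[cbind(ii, jj)])
    }
  }
  out
}

# 8-connected component count by flood fill (BFS).
bf_n_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  ncomp <- 0
  for (s in which(mask & !seen)) {
    if (seen[s]) next
    ncomp <- ncomp + 1
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      i <- (k - 1) %% H + 1; j <- (k - 1) %/% H + 1
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > H || jj < 1 || jj > W) next
        kk <- (jj - 1) * H + ii
        if (mask[kk] && !seen[kk]) { seen[kk] <- TRUE; queue <- c(queue, kk) }
      }
    }
  }
  ncomp
}

# TRUE if some 2x2 block of the mask is entirely true.
bf_has_2x2_block <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  any(mask[-H, -W] & mask[-1, -W] & mask[-H, -1] & mask[-1, -1])
}
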