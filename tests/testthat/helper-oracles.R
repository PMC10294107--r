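# Independent brute-force oracles. Each reimplements the operation it
# checks from its mathematical definition, sharing no code with the
# package paths under test.

# mirror-reflection of a 0-based index into [0, n), period 2n
reflect_fold <- function(i, n) {
  p <- 2 * n
  i <- i %% p
  ifelse(i < n, i, p - 1 - i)
}

# dense O(n^2 k^2) convolution with the sampled-and-normalized Gaussian
# kernel, truncated at 3 sigma, reflection boundary
oracle_gaussian_conv <- function(channel, sigma) {
  n <- nrow(channel); m <- ncol(channel)
  r <- ceiling(3 * sigma)
  e <- exp(-((-r:r)^2) / (2 * sigma^2))
  k2 <- outer(e, e)
  k2 <- k2 / sum(k2)
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- reflect_fold(i - 1 + di, n) + 1
      jj <- reflect_fold(j - 1 + dj, m) + 1
      acc <- acc + k2[di + r + 1, dj + r + 1] * channel[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# erosion as the per-pixel neighborhood AND over all kernel offsets
oracle_erode <- function(mask, k) {
  r <- (k - 1) %/% 2
  n <- nrow(mask); m <- ncol(mask)
  padded <- matrix(FALSE, n + 2 * r, m + 2 * r)
  padded[r + 1:n, r + 1:m] <- mask
  out <- matrix(TRUE, n, m)
  for (di in 0:(k - 1)) for (dj in 0:(k - 1))
    out <- out & padded[di + 1:n, dj + 1:m]
  out
}

# exhaustive scan of all 256 candidate thresholds, class statistics
# recomputed from scratch at each candidate
oracle_otsu <- function(h) {
  lev <- 0:255
  n <- sum(h)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:254) {
    lo <- lev <= t
    w0 <- sum(h[lo]); w1 <- sum(h[!lo])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[lo] * lev[lo]) / w0
    mu1 <- sum(h[!lo] * lev[!lo]) / w1
    v <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (v > best) { best <- v; bt <- t }
  }
  bt
}

# exhaustive component walk: BFS over 8-neighborhoods in plain R,
# boxes as per-component min/max coordinate scans
oracle_boxes <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  seen <- matrix(FALSE, n, m)
  res <- NULL
  for (i in 1:n) for (j in 1:m) {
    if (!mask[i, j] || seen[i, j]) next
    seen[i, j] <- TRUE
    frontier <- matrix(c(i, j), ncol = 2)
    rows <- i; cols <- j
    while (nrow(frontier) > 0) {
      nxt <- NULL
      for (q in seq_len(nrow(frontier))) {
        for (di in -1:1) for (dj in -1:1) {
          ii <- frontier[q, 1] + di; jj <- frontier[q, 2] + dj
          if (ii >= 1 && ii <= n && jj >= 1 && jj <= m &&
              mask[ii, jj] && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            nxt <- rbind(nxt, c(ii, jj))
            rows <- c(rows, ii); cols <- c(cols, jj)
          }
        }
      }
      frontier <- if (is.null(nxt)) matrix(numeric(0), ncol = 2) else nxt
    }
    res <- rbind(res, data.frame(x = min(cols) - 1, y = min(rows) - 1,
                                 w = diff(range(cols)) + 1,
                                 h = diff(range(rows)) + 1,
                                 area = length(rows)))
  }
  if (is.null(res)) return(res)
  res <- res[order(res$y, res$x), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# size of the optimal one-to-one matching with IoU >= thr, by
# exhaustive recursion (use only on small instances)
oracle_max_matching <- function(iou, thr) {
  np <- nrow(iou); nt <- ncol(iou)
  rec <- function(i, used) {
    if (i > np) return(0)
    b <- rec(i + 1, used)
    for (j in seq_len(nt)) {
      if (!used[j] && iou[i, j] >= thr) {
        used[j] <- TRUE
        b <- max(b, 1 + rec(i + 1, used))
        used[j] <- FALSE
      }
    }
    b
  }
  rec(1L, logical(nt))
}

# straight-line MSRCR reference: dense convolution oracle plus explicit
# log / color-restoration / percentile arithmetic, no shared code with
# the package implementation
oracle_msrcr <- function(scene, scales, weights, alpha, beta, lo, hi) {
  x <- unclass(scene)
  storage.mode(x) <- "double"
  log_sum <- log(x[, , 1] + x[, , 2] + x[, , 3] + 1)
  out <- array(0, dim(x))
  for (i in 1:3) {
    resp <- 0
    for (n in seq_along(scales))
      resp <- resp + weights[n] *
        (log(x[, , i] + 1) - log(oracle_gaussian_conv(x[, , i], scales[n]) + 1))
    v <- beta * (log(alpha * x[, , i] + 1) - log_sum) * resp
    q <- quantile(v, c(lo, hi), names = FALSE, type = 7)
    v <- (v - q[1]) / (q[2] - q[1]) * 255
    v <- round(v)
    v[v < 0] <- 0; v[v > 255] <- 255
    out[, , i] <- v
  }
  out
}
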