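# Fixture builders and independent brute-force oracles. The oracles are
# deliberately written with different machinery than the package code
# (base R built-ins, shift-based set arithmetic, fixed-point iteration)
# so that agreement is evidence, not tautology.

uniform_image <- function(v, h = 8, w = 8) {
  if (length(v) == 1) v <- rep(v, 3)
  array(rep(v, each = h * w), dim = c(h, w, 3))
}

gray_image <- function(m) {
  array(rep(m, 3), dim = c(nrow(m), ncol(m), 3))
}

random_image <- function(seed, h = 32, w = 32) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

# a random image with a bright blob, closer to real content than iid noise
blob_image <- function(seed, h = 32, w = 32) {
  set.seed(seed)
  base <- matrix(sample(40:120, h * w, replace = TRUE), h, w)
  cy <- sample(8:(h - 8), 1); cx <- sample(8:(w - 8), 1)
  r2 <- outer(seq_len(h), seq_len(w),
              function(r, c) (r - cy)^2 + (c - cx)^2)
  v <- sample(200:255, 1)
  m <- base
  m[r2 <= 9] <- v
  gray_image(m)
}

# hollow axis-aligned square ring mask
square_ring <- function(h, w, r1, r2, c1, c2) {
  m <- matrix(FALSE, h, w)
  m[r1:r2, c1] <- TRUE; m[r1:r2, c2] <- TRUE
  m[r1, c1:c2] <- TRUE; m[r2, c1:c2] <- TRUE
  m
}

# ---- shift-based morphology (oracle machinery) -------------------------

shift_mask <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

dilate_with <- function(m, offsets) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (k in seq_len(nrow(offsets))) {
    out <- out | shift_mask(m, offsets[k, 1], offsets[k, 2])
  }
  out
}

erode_with <- function(m, offsets) {
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (k in seq_len(nrow(offsets))) {
    # out-of-bounds neighbours count as background
    out <- out & shift_mask(m, offsets[k, 1], offsets[k, 2])
  }
  out
}

neigh8 <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
neigh8 <- neigh8[!(neigh8[, 1] == 0 & neigh8[, 2] == 0), ]
neigh4 <- matrix(c(-1, 0, 1, 0, 0, -1, 0, 1), ncol = 2, byrow = TRUE)

# ---- independent oracles ----------------------------------------------

# fixed-point region growing: seed plus 8-reachable pixels above thr
oracle_grow <- function(gray, seed, thr) {
  eligible <- gray > thr
  acc <- seed
  repeat {
    nxt <- acc | (dilate_with(acc, neigh8) & eligible)
    if (identical(nxt, acc)) return(acc)
    acc <- nxt
  }
}

# fixed-point border flood fill of the complement (4-connectivity)
oracle_flood_outside <- function(blocked) {
  h <- nrow(blocked); w <- ncol(blocked)
  reached <- matrix(FALSE, h, w)
  reached[1, ] <- TRUE; reached[h, ] <- TRUE
  reached[, 1] <- TRUE; reached[, w] <- TRUE
  reached <- reached & !blocked
  repeat {
    nxt <- reached | (dilate_with(reached, neigh4) & !blocked)
    if (identical(nxt, reached)) return(reached)
    reached <- nxt
  }
}

# per-pixel cone membership straight from the projection formula
oracle_cone <- function(img, x0, a) {
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      v <- c(img[r, c, 1], img[r, c, 2], img[r, c, 3])
      n <- c(1, 1, 1)
      proj_len <- sum(n * v) / sqrt(sum(n * n))
      pvec <- proj_len * n / sqrt(sum(n * n))
      out[r, c] <- sqrt(sum((v - pvec)^2)) < a * (proj_len - x0)
    }
  }
  out
}

# specular-peak pipeline recomputed with base R tools: rgb2hsv for the
# saturation channel, table-free counting, an explicit kernel-sum loop for
# smoothing, and an exhaustive scan over all thresholds
oracle_peak_segment <- function(img, t_min, sigma) {
  h <- dim(img)[1]; w <- dim(img)[2]
  flat <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                as.vector(img[, , 3]))
  s <- grDevices::rgb2hsv(flat, maxColorValue = 255)["s", ]
  y <- numeric(h * w)
  for (i in seq_len(h * w)) {
    ti <- (1 - s[i]) * flat[, i]
    y[i] <- sum(c(0.299, 0.587, 0.114) * ti)
  }
  counts <- numeric(256)
  for (i in seq_len(h * w)) {
    b <- round(y[i])
    counts[b + 1] <- counts[b + 1] + 1
  }
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  sm <- numeric(256)
  for (t in 1:256) {
    for (j in (-r):r) {
      idx <- t + j
      while (idx < 1 || idx > 256) {
        if (idx < 1) idx <- 2 - idx
        if (idx > 256) idx <- 2 * 256 - idx
      }
      sm[t] <- sm[t] + k[j + r + 1] * counts[idx]
    }
  }
  h1 <- function(t) if (sm[t + 1] - sm[t + 2] > 0) 1 else 0
  cand <- c()
  for (t in 0:253) {
    if (h1(t) == 1 && h1(t + 1) == 0 && sum(sm[(t + 2):256]) > 0) {
      cand <- c(cand, t)
    }
  }
  cand <- cand[cand > t_min]
  t_spec <- if (length(cand) == 0) NA else max(cand)
  if (is.na(t_spec)) return(matrix(FALSE, h, w))
  matrix(y > t_spec, h, w)
}

truth_union <- function(scene) {
  Reduce(`|`, scene$labels$mask,
         matrix(FALSE, nrow(scene$labels$mask[[1]]),
                ncol(scene$labels$mask[[1]])))
}
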