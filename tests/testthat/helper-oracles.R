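# Independent brute-force oracles: plain double loops, no shared code with
# the package implementations.

rand_img <- function(h, w = h) matrix(stats::runif(h * w), h, w)

# clamp an index to [1, n] (edge-repeating reflection, pad width 1)
.cl <- function(i, n) pmin(pmax(i, 1L), n)

oracle_grayscale <- function(arr, w = c(0.299, 0.587, 0.114)) {
  out <- matrix(0, dim(arr)[1], dim(arr)[2])
  for (i in seq_len(dim(arr)[1])) {
    for (j in seq_len(dim(arr)[2])) {
      out[i, j] <- sum(w * arr[i, j, ])
    }
  }
  out
}

oracle_mean_threshold <- function(m) {
  mu <- sum(m) / length(m)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    out[i, j] <- m[i, j] > mu
  }
  out
}

oracle_sobel <- function(m) {
  kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  ky <- t(kx)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      v <- m[.cl(i + di, h), .cl(j + dj, w)]
      gx <- gx + kx[di + 2, dj + 2] * v
      gy <- gy + ky[di + 2, dj + 2] * v
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

oracle_roberts <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    a <- m[i, j]
    b <- m[i, .cl(j + 1, w)]
    cc <- m[.cl(i + 1, h), j]
    d <- m[.cl(i + 1, h), .cl(j + 1, w)]
    out[i, j] <- sqrt((a - d)^2 + (b - cc)^2)
  }
  out
}

oracle_window <- function(edges, window, stride, thr, minc) {
  h <- nrow(edges); w <- ncol(edges)
  rs <- unique(c(seq.int(1L, h - window + 1L, by = stride), h - window + 1L))
  cs <- unique(c(seq.int(1L, w - window + 1L, by = stride), w - window + 1L))
  out <- matrix(FALSE, h, w)
  for (r in rs) for (cl in cs) {
    sub <- edges[r:(r + window - 1L), cl:(cl + window - 1L)]
    if (sum(sub > thr) >= minc) {
      out[r:(r + window - 1L), cl:(cl + window - 1L)] <- TRUE
    }
  }
  out
}

.offsets <- function(r, shape) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  if (shape == "disc") g <- g[g$dy^2 + g$dx^2 <= r^2, ]
  g
}

# plane semantics: outside the frame is background
oracle_dilate <- function(m, r, shape = "disc") {
  off <- .offsets(r, shape)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    for (k in seq_len(nrow(off))) {
      ii <- i + off$dy[k]; jj <- j + off$dx[k]
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && m[ii, jj]) {
        out[i, j] <- TRUE
        break
      }
    }
  }
  out
}

oracle_erode <- function(m, r, shape = "disc") {
  off <- .offsets(r, shape)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ok <- TRUE
    for (k in seq_len(nrow(off))) {
      ii <- i + off$dy[k]; jj <- j + off$dx[k]
      if (ii < 1 || ii > h || jj < 1 || jj > w || !m[ii, jj]) {
        ok <- FALSE
        break
      }
    }
    out[i, j] <- ok
  }
  out
}

oracle_close <- function(m, r, shape = "disc") {
  pad <- r + 1L
  h <- nrow(m); w <- ncol(m)
  big <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  big[pad + seq_len(h), pad + seq_len(w)] <- m
  out <- oracle_erode(oracle_dilate(big, r, shape), r, shape)
  out[pad + seq_len(h), pad + seq_len(w)]
}

oracle_cv_energy <- function(img, phi, c1, c2) {
  e <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    e <- e + if (phi[i, j] > 0) (img[i, j] - c1)^2 else (img[i, j] - c2)^2
  }
  e
}

# closed-form simple OLS
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  ssr <- sum((y - (a + b * x))^2)
  sst <- sum((y - mean(y))^2)
  list(slope = b, intercept = a, r_squared = 1 - ssr / sst)
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# small, quick-to-render phantom for unit tests
small_phantom <- function(lattice_type = "cube", designed_bi = 0.5,
                          seed = 1L, canvas = 160L, pore_px = 30L,
                          strut_px = 8L) {
  render_phantom(lattice_phantom(lattice_type, canvas = canvas,
                                 pore_px = pore_px, strut_px = strut_px,
                                 designed_bi = designed_bi, seed = seed))
}

# stage-1 defaults scaled to the small phantom's 30 px pores
small_stage1 <- function() stage1_config(close_radius = 18L)

small_config <- function() pipeline_config(stage1 = small_stage1())
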