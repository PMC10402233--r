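# Shared fixtures: small masks, a reduced-resolution generator config (same
# statistical structure as the defaults, smaller raster for fast tests), and
# independent pure-R oracles.

solidSquare <- function(n = 3, pad = 1) {
  m <- matrix(0L, n + 2 * pad, n + 2 * pad)
  m[pad + seq_len(n), pad + seq_len(n)] <- 1L
  m
}

randomMask <- function(nr, nc, p = 0.5) {
  matrix(as.integer(runif(nr * nc) < p), nr, nc)
}

# Reduced-raster generator used throughout the tests; the statistical
# parameters are the package defaults.
testConfig <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg))
      cfg <<- generatorConfig(canvas = c(300L, 400L), pxPerDeg = 10)
    cfg
  }
})

# Brute-force raw moment by an explicit double loop (oracle).
bruteMoment <- function(mask, i, j) {
  acc <- 0
  for (r in seq_len(nrow(mask)))
    for (c in seq_len(ncol(mask)))
      if (mask[r, c] != 0) acc <- acc + (c - 1)^i * (r - 1)^j
  acc
}

# Pure-R BFS connected-component labeling, 8-connected (oracle).
bfsLabel8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (mask[r0, c0] != 0 && lab[r0, c0] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(r0, c0)); lab[r0, c0] <- nxt
      while (length(queue)) {
        rc <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          r <- rc[1] + dr; c <- rc[2] + dc
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              mask[r, c] != 0 && lab[r, c] == 0L) {
            lab[r, c] <- nxt
            queue[[length(queue) + 1]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# Flood fill of the background from the border (oracle for hole filling):
# returns the mask with every enclosed background pixel set to 1.
floodFillHoles <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  outside <- matrix(FALSE, nr, nc)
  seeds <- rbind(cbind(1, seq_len(nc)), cbind(nr, seq_len(nc)),
                 cbind(seq_len(nr), 1), cbind(seq_len(nr), nc))
  queue <- lapply(seq_len(nrow(seeds)), function(i) seeds[i, ])
  for (q in queue) if (mask[q[1], q[2]] == 0) outside[q[1], q[2]] <- TRUE
  repeat {
    grew <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (outside[r, c]) next
      if (mask[r, c] != 0) next
      nb <- FALSE
      if (r > 1 && outside[r - 1, c]) nb <- TRUE
      if (!nb && r < nr && outside[r + 1, c]) nb <- TRUE
      if (!nb && c > 1 && outside[r, c - 1]) nb <- TRUE
      if (!nb && c < nc && outside[r, c + 1]) nb <- TRUE
      if (nb) { outside[r, c] <- TRUE; grew <- TRUE }
    }
    if (!grew) break
  }
  matrix(as.integer(mask != 0 | !outside), nr, nc)
}

# Dense-sampling axonal distance oracle: resample the reference bundle at
# 1 um and take brute-force vertex minima.
denseAxonOracle <- function(map, temporal, nasal) {
  b <- axonBundle(map, temporal)
  s <- c(0, cumsum(sqrt(diff(b[, 1])^2 + diff(b[, 2])^2)))
  ss <- seq(0, max(s), by = 1)
  bx <- approx(s, b[, 1], ss)$y
  by <- approx(s, b[, 2], ss)$y
  dN <- sqrt((bx - nasal[1])^2 + (by - nasal[2])^2)
  dT <- sqrt((bx - temporal[1])^2 + (by - temporal[2])^2)
  list(between = min(dN),
       along = abs(ss[which.min(dN)] - ss[which.min(dT)]))
}

# Independent per-pixel recomputation of the weighted border-pixel perimeter
# (explicit loops over each border pixel's neighborhood).
loopedPerimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(r, c) if (r < 1 || r > nr || c < 1 || c > nc) 0L else mask[r, c]
  border <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] != 0 &&
        !(at(r - 1, c) && at(r + 1, c) && at(r, c - 1) && at(r, c + 1)))
      border[r, c] <- 1L
  }
  atb <- function(r, c) if (r < 1 || r > nr || c < 1 || c > nc) 0L else border[r, c]
  w <- numeric(50)
  w[c(5, 7, 15, 17, 25, 27) + 1] <- 1
  w[c(21, 33) + 1] <- sqrt(2)
  w[c(13, 23) + 1] <- (1 + sqrt(2)) / 2
  total <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (border[r, c] == 0L) next
    ortho <- atb(r - 1, c) + atb(r + 1, c) + atb(r, c - 1) + atb(r, c + 1)
    diag4 <- atb(r - 1, c - 1) + atb(r - 1, c + 1) +
      atb(r + 1, c - 1) + atb(r + 1, c + 1)
    total <- total + w[1 + 1 + 2 * ortho + 10 * diag4]
  }
  total
}
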