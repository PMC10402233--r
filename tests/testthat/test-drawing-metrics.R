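test_that("raw moments follow the column-row convention and match brute force", {
  m <- matrix(0L, 10, 10); m[8, 4] <- 1L  # (x = 3, y = 7)
  expect_equal(rawMoment(m, 0, 0), 1)
  expect_equal(rawMoment(m, 1, 0), 3)
  expect_equal(rawMoment(m, 0, 1), 7)
  blk <- matrix(0L, 4, 4); blk[1:2, 1:2] <- 1L
  expect_equal(rawMoment(blk, 0, 0), 4)
  set.seed(11)
  for (rep in 1:10) {
    msk <- randomMask(5, 5)
    for (ij in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 0), c(0, 2)))
      expect_equal(rawMoment(msk, ij[1], ij[2]),
                   bruteMoment(msk, ij[1], ij[2]))
  }
  expect_error(rawMoment(m, -1, 0), "non-negative")
  expect_error(rawMoment(matrix(0.5, 2, 2), 0, 0), "binary")
})

test_that("shape descriptors match closed-form and eigen oracles", {
  sq <- solidSquare(3)
  d <- shapeDescriptors(sq)
  expect_equal(d$area, 9)
  expect_equal(unname(d$centroid), c(2, 2))  # center of the 3x3 block
  expect_equal(d$perimeter, 8)               # polyline through 8 border centers
  # horizontal 1x9 line: zero vertical variance
  line <- matrix(0L, 3, 11); line[2, 2:10] <- 1L
  dl <- shapeDescriptors(line)
  expect_equal(dl$minor, 0)
  expect_equal(dl$major, 4 * sqrt(60 / 9))
  # random masks: eigen-decomposition oracle for the axis lengths
  set.seed(22)
  for (rep in 1:10) {
    msk <- randomMask(7, 9, 0.6)
    msk[3, 5] <- 1L  # non-empty
    one <- matrix(as.integer(bfsLabel8(msk) == 1), nrow(msk), ncol(msk))
    d <- shapeDescriptors(one)
    idx <- which(one != 0, arr.ind = TRUE)
    x <- idx[, 2] - 1; y <- idx[, 1] - 1
    cv <- matrix(c(mean(x^2) - mean(x)^2, mean(x * y) - mean(x) * mean(y),
                   mean(x * y) - mean(x) * mean(y), mean(y^2) - mean(y)^2),
                 2, 2)
    ev <- eigen(cv, symmetric = TRUE)$values
    expect_equal(d$major, 4 * sqrt(max(ev[1], 0)), tolerance = 1e-12)
    expect_equal(d$minor, 4 * sqrt(max(ev[2], 0)), tolerance = 1e-12)
    expect_gte(d$major, d$minor)
    expect_gte(d$minor, 0)
  }
  expect_error(shapeDescriptors(matrix(0L, 3, 3)), "empty")
})

test_that("perimeter reproduces the weighted border-count reference values", {
  # values cross-checked against an independent implementation of the same
  # border-weighting algorithm
  line <- matrix(0L, 3, 11); line[2, 2:10] <- 1L
  expect_equal(perimeterWeighted(line), 7)
  disc <- outer(0:8, 0:8, function(r, c)
    as.integer((c - 4)^2 + (r - 4)^2 <= 9))
  expect_equal(perimeterWeighted(disc), 19.31370849898476)
  rand8 <- matrix(as.integer(c(
    1,1,1,0,0,1,0,1,
    1,0,0,0,0,0,1,1,
    1,1,1,1,0,0,1,0,
    0,1,0,1,1,1,0,0,
    0,0,1,0,0,0,1,0,
    0,1,1,1,1,1,0,1,
    1,1,0,1,0,0,0,0,
    1,0,1,1,1,1,1,0)), 8, 8, byrow = TRUE)
  expect_equal(perimeterWeighted(rand8), 27.65685424949238)
  # independent looped recomputation on random masks
  set.seed(33)
  for (rep in 1:8) {
    msk <- randomMask(9, 9, 0.45)
    expect_equal(perimeterWeighted(msk), loopedPerimeter(msk))
  }
  # degenerate single pixel: a polyline through one point has zero length
  one <- matrix(0L, 3, 3); one[2, 2] <- 1L
  expect_equal(perimeterWeighted(one), 0)
})

test_that("labeling is 8-connected and matches a BFS oracle", {
  m <- matrix(0L, 5, 5)
  m[1, 1] <- 1L; m[2, 2] <- 1L  # diagonal touch: one region
  expect_equal(max(labelRegions(m)), 1)
  set.seed(44)
  for (rep in 1:10) {
    msk <- randomMask(12, 12, 0.4)
    lab <- labelRegions(msk)
    oracle <- bfsLabel8(msk)
    expect_equal(max(lab), max(oracle))
    # identical partitions (labels assigned in the same scan order)
    expect_equal(lab, oracle)
  }
})

test_that("drawing validation closes gapped outlines and fills interiors", {
  sq <- solidSquare(5)
  expect_equal(unclass(validateDrawing(sq))[, ], sq[, ])
  z <- matrix(0L, 4, 4)
  vz <- validateDrawing(z)
  expect_true(attr(vz, "empty"))
  expect_equal(sum(vz), 0)
  # 1-px-wide circle outline with a single 1-px gap
  th <- seq(0, 2 * pi, length.out = 200)
  ring <- matrix(0L, 21, 21)
  ring[cbind(round(11 + 8 * sin(th)), round(11 + 8 * cos(th)))] <- 1L
  ring[11, 19] <- 0L
  v <- validateDrawing(ring, closeRadius = 1)
  expect_equal(max(labelRegions(v)), 1)
  # hole filling agrees with a brute-force flood fill of the closed outline
  closedOnly <- validateDrawing(ring, closeRadius = 1, fillHoles = FALSE)
  oracle <- floodFillHoles(unclass(closedOnly)[, ])
  expect_equal(sum(v), sum(oracle))
  expect_gt(sum(v), sum(ring))  # interior got filled
  expect_error(validateDrawing(matrix(c(0, 0.4, 1, 1), 2, 2)), "binary")
})

test_that("small-spec filter follows the 10 px / 50 percent rules", {
  big <- matrix(0L, 30, 30); big[3:12, 3:12] <- 1L      # 100 px
  spec <- big; spec[25:26, 25] <- spec[25, 26] <- 1L    # + 3 px spec (< 10)
  # spec present in 2 of 10 trials: not counted
  t1 <- c(replicate(8, big, simplify = FALSE), replicate(2, spec, simplify = FALSE))
  ex1 <- extractPhosphenes(t1)
  expect_false(ex1$keptSmall)
  expect_true(all(ex1$summary$n_phosphenes == 1))
  # spec present in all 10 trials: counted as a second phosphene
  t2 <- replicate(10, spec, simplify = FALSE)
  ex2 <- extractPhosphenes(t2)
  expect_true(ex2$keptSmall)
  expect_true(all(ex2$summary$n_phosphenes == 2))
  # two large regions: both counted, totals are sums over both
  two <- matrix(0L, 30, 30)
  two[3:12, 3:12] <- 1L; two[18:27, 18:27] <- 1L
  ex3 <- extractPhosphenes(replicate(5, two, simplify = FALSE))
  expect_true(all(ex3$summary$n_phosphenes == 2))
  oneRegion <- matrix(0L, 30, 30); oneRegion[3:12, 3:12] <- 1L
  d1 <- shapeDescriptors(oneRegion)
  expect_equal(ex3$summary$area[1], 2 * d1$area)
  expect_equal(ex3$summary$perimeter[1], 2 * d1$perimeter)
  expect_error(extractPhosphenes(list()), "non-empty")
})

test_that("the spec filter is idempotent", {
  set.seed(55)
  trialSet <- replicate(6, {
    m <- matrix(0L, 40, 40)
    m[5:20, 5:20] <- 1L
    if (runif(1) < 0.3) m[35, 35] <- 1L  # occasional 1-px speck
    m
  }, simplify = FALSE)
  ex <- extractPhosphenes(trialSet)
  # rebuild masks from the surviving regions and re-extract
  rebuilt <- lapply(seq_along(trialSet), function(i) {
    m <- matrix(0L, 40, 40)
    lab <- labelRegions(trialSet[[i]])
    for (l in ex$regions[[i]]$label) m[lab == l] <- 1L
    m
  })
  ex2 <- extractPhosphenes(rebuilt)
  expect_equal(ex2$summary[, -1], ex$summary[, -1])
})

test_that("descriptors are translation invariant and rotation swaps the axes", {
  set.seed(66)
  base <- matrix(0L, 20, 20)
  base[4:9, 3:14] <- 1L  # 6 x 12 rectangle
  d0 <- shapeDescriptors(base)
  shifted <- phosphenes:::.shiftMask(base, 3, 4)
  d1 <- shapeDescriptors(shifted)
  expect_equal(d1$area, d0$area)
  expect_equal(d1$perimeter, d0$perimeter)
  expect_equal(d1$major, d0$major)
  expect_equal(d1$minor, d0$minor)
  expect_equal(unname(d1$centroid - d0$centroid), c(3, 4))
  rot <- t(base)[, nrow(base):1]  # 90 degree rotation of the grid
  storage.mode(rot) <- "integer"
  d2 <- shapeDescriptors(rot)
  expect_equal(d2$area, d0$area)
  expect_equal(sort(c(d2$major, d2$minor)), sort(c(d0$major, d0$minor)))
})

test_that("mean images align percepts at the shared center of mass", {
  blob <- matrix(0L, 25, 25); blob[10:15, 8:13] <- 1L
  same <- replicate(4, blob, simplify = FALSE)
  expect_equal(meanImage(same), blob + 0)
  # an even translation keeps the mean center of mass on the pixel grid,
  # so alignment removes it exactly
  shifted <- list(blob, phosphenes:::.shiftMask(blob, 4, -2))
  mi <- meanImage(shifted)
  expect_equal(sort(unique(as.vector(mi))), c(0, 1))  # perfect overlap
  expect_equal(sum(mi), sum(blob))
  # jittered discs: support of the mean lies between intersection and union
  set.seed(77)
  discs <- replicate(6, {
    d <- round(rnorm(2, 0, 1.5))
    phosphenes:::.shiftMask(blob, d[1], d[2])
  }, simplify = FALSE)
  mi2 <- meanImage(discs)
  coms <- t(vapply(discs, function(m) {
    idx <- which(m != 0, arr.ind = TRUE)
    c(mean(idx[, 2] - 1), mean(idx[, 1] - 1))
  }, numeric(2)))
  target <- colMeans(coms)
  aligned <- lapply(seq_along(discs), function(i) {
    d <- round(target - coms[i, ])
    phosphenes:::.shiftMask(discs[[i]], d[1], d[2])
  })
  inter <- Reduce(`*`, aligned)
  uni <- pmin(Reduce(`+`, aligned), 1)
  expect_gte(sum(mi2 > 0), sum(inter))
  expect_lte(sum(mi2 > 0), sum(uni))
  expect_error(meanImage(list(matrix(0L, 5, 5))), "empty")
})
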