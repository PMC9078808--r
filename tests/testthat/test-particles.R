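test_that("particle initialization honours spread, counts and determinism", {
  box <- ceus_box(20, 20, 10, 8)
  p0 <- init_particles(box, c(64, 64), n = 50, spread = 0, seed = 1)
  expect_true(all(p0$centers[, 1] == box_center(box)[1]))
  expect_true(all(p0$centers[, 2] == box_center(box)[2]))
  expect_equal(p0$weights, rep(1 / 50, 50))
  p1 <- init_particles(box, c(64, 64), n = 1, seed = 1)
  expect_equal(nrow(p1$centers), 1L)
  expect_equal(p1$weights, 1)
  a <- init_particles(box, c(64, 64), n = 30, seed = 9)
  b <- init_particles(box, c(64, 64), n = 30, seed = 9)
  expect_identical(a$centers, b$centers)
  expect_error(init_particles(ceus_box(1, 1, 100, 100), c(64, 64)), "inside")
})

test_that("flow similarity is the bounded cosine of the two vectors", {
  expect_equal(flow_similarity(c(3, 4), c(3, 4)), 1)
  expect_equal(flow_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(flow_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_equal(flow_similarity(c(0, 0), c(1, 0)), 0)   # zero-vector convention
  expect_equal(flow_similarity(c(1, 0), c(-1, 0)), -1)
})

test_that("the weighting kernel reproduces the hand-evaluated two-particle case", {
  # Consi = {1.0, 0.6}, eps = 0.2 -> raw {1, e^-2} -> normalized {0.8808, 0.1192}
  consi <- c(1.0, 0.6)
  raw <- exp(-(consi - max(consi))^2 / (2 * 0.2^2))
  expect_equal(raw, c(1, exp(-2)))
  w <- raw / sum(raw)
  expect_equal(round(w, 4), c(0.8808, 0.1192))

  # same numbers through weigh_particles: two particles whose regional flows
  # have cosine similarity 1.0 and 0.6 against the reference
  vr <- matrix(0, 40, 40); vc <- matrix(0, 40, 40)
  vr[11:20, 11:20] <- 0; vc[11:20, 11:20] <- 1          # aligned with ref (1 0)... cols
  vr[11:20, 26:35] <- 0.8; vc[11:20, 26:35] <- 0.6      # cosine 0.6 vs (0, 1)
  fl <- structure(list(vr = vr, vc = vc), class = "flow_field")
  pset <- init_particles(ceus_box(11, 11, 10, 10), c(40, 40), n = 2, spread = 0,
                         epsilon = 0.2, seed = 1)
  pset$centers <- rbind(c(15.5, 15.5), c(15.5, 30.5))
  model <- flow_model(0.5, h = c(0, 1))
  out <- weigh_particles(pset, model, fl)
  expect_equal(unname(attr(out, "consi")), c(1, 0.6), tolerance = 1e-12)
  expect_equal(out$weights, c(0.880797, 0.119203), tolerance = 1e-5)
})

test_that("weights always normalize to one", {
  set.seed(11)
  for (rep in 1:20) {
    vr <- matrix(rnorm(1600), 40, 40); vc <- matrix(rnorm(1600), 40, 40)
    fl <- structure(list(vr = vr, vc = vc), class = "flow_field")
    pset <- init_particles(ceus_box(15, 15, 8, 8), c(40, 40), n = 25)
    out <- weigh_particles(pset, flow_model(0.5, h = rnorm(2)), fl)
    expect_lt(abs(sum(out$weights) - 1), 1e-9)
  }
})

test_that("identical particles get uniform weights", {
  fl <- structure(list(vr = matrix(1, 40, 40), vc = matrix(0, 40, 40)),
                  class = "flow_field")
  pset <- init_particles(ceus_box(15, 15, 8, 8), c(40, 40), n = 10, spread = 0)
  out <- weigh_particles(pset, flow_model(0.5, h = c(1, 0)), fl)
  expect_equal(out$weights, rep(0.1, 10))
  expect_equal(max(exp(-(attr(out, "consi") - max(attr(out, "consi")))^2 /
                         (2 * pset$epsilon^2))), 1)  # kernel at zero
})

test_that("systematic resampling is deterministic and degenerate weights collapse", {
  pset <- init_particles(ceus_box(15, 15, 8, 8), c(40, 40), n = 20, seed = 3)
  pset$weights <- c(1, rep(0, 19))
  r1 <- resample_particles(pset, seed = 5, jitter_sd = 0)
  expect_true(all(r1$centers[, 1] == pset$centers[1, 1]))
  expect_true(all(r1$centers[, 2] == pset$centers[1, 2]))
  r2 <- resample_particles(pset, seed = 8)
  r3 <- resample_particles(pset, seed = 8)
  expect_identical(r2$centers, r3$centers)
})

test_that("resampling is unbiased: offspring counts and spatial mean (Monte Carlo)", {
  n <- 10
  pset <- init_particles(ceus_box(15, 15, 8, 8), c(40, 40), n = n, seed = 2)
  pset$weights <- rep(1 / n, n)
  set.seed(7)
  counts <- numeric(n)
  for (rep in 1:10000) {
    r <- resample_particles(pset, jitter_sd = 0)
    counts <- counts + tabulate(attr(r, "parents"), nbins = n)
  }
  # uniform weights: each particle expects 1 offspring per draw, sd of the
  # mean over 10,000 systematic draws is far below the 3-sigma bound of a
  # multinomial (p = 1/n), which we use as the conservative envelope
  expect_true(all(abs(counts / 10000 - 1) < 3 * sqrt((1 - 1 / n)) / sqrt(10000)))

  # weighted case: post-resample mean equals the weighted mean
  pset$weights <- (1:n) / sum(1:n)
  set.seed(8)
  means <- matrix(0, 2000, 2)
  for (rep in 1:2000) {
    r <- resample_particles(pset, jitter_sd = 0)
    means[rep, ] <- colMeans(r$centers)
  }
  target <- colSums(pset$centers * pset$weights)
  se <- apply(means, 2, sd) / sqrt(2000)
  expect_true(all(abs(colMeans(means) - target) < 3 * pmax(se, 1e-6)))
})

test_that("candidate extraction honours k, ties and deduplication", {
  pset <- init_particles(ceus_box(15, 15, 8, 8), c(40, 40), n = 6, seed = 4)
  pset$centers <- rbind(c(10, 10), c(20, 20), c(30, 30),
                        c(10.5, 10.5), c(25, 25), c(35, 35))
  pset$weights <- c(0.3, 0.3, 0.2, 0.1, 0.05, 0.05)
  all6 <- candidates(pset, k = 6)
  expect_equal(length(all6$boxes), 5L)     # (10.5,10.5) deduplicated (< 1 px)
  top1 <- candidates(pset, k = 1)
  expect_equal(top1$index, 1L)             # weight tie 1 vs 2 -> lower index
  expect_error(candidates(pset, k = 10), "exceed")
})

test_that("argmax-weight particle locks onto a uniquely moving lesion within 5 frames", {
  # fixed synthetic flow inputs: a disk moving right at 1 px/frame
  mkflow <- function(center) {
    vr <- matrix(0, 60, 60); vc <- matrix(0, 60, 60)
    for (r in 1:60) for (c in 1:60)
      if ((r - center[1])^2 + (c - center[2])^2 <= 49) vc[r, c] <- 1
    structure(list(vr = vr, vc = vc), class = "flow_field")
  }
  ctr <- c(30, 25)
  pset <- init_particles(ceus_box(23, 18, 14, 14), c(60, 60), n = 80, seed = 6)
  model <- flow_model(0.5, h = c(0, 1))
  for (s in 1:5) {
    ctr <- ctr + c(0, 1)
    fl <- mkflow(ctr)
    pset$centers <- pset$centers + flow_at(fl, pset$centers)
    pset$centers <- flow_mean_shift(fl, pset$centers, pset$box_size)
    pset <- weigh_particles(pset, model, fl)
    best <- pset$centers[which.max(pset$weights), ]
    pset <- resample_particles(pset)
  }
  expect_lt(sqrt(sum((best - ctr)^2)), 2)
})
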