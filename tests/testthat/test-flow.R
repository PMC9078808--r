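test_that("identical frames give zero flow", {
  pat <- textured_pattern(60)
  fl <- compute_flow(pat, pat)
  expect_true(all(fl$vr == 0))
  expect_true(all(fl$vc == 0))
})

test_that("known translations are recovered within 0.2 px over the interior", {
  pat <- textured_pattern(120)
  interior <- 11:110
  for (sh in list(c(0, 1), c(1, 0), c(0, 2), c(2, 0), c(1, 1))) {
    fl <- compute_flow(pat, shift_image(pat, sh[1], sh[2]))
    expect_lt(abs(mean(fl$vr[interior, interior]) - sh[1]), 0.2)
    expect_lt(abs(mean(fl$vc[interior, interior]) - sh[2]), 0.2)
  }
})

test_that("doubling a small shift roughly doubles the mean flow", {
  pat <- textured_pattern(120)
  interior <- 11:110
  f1 <- compute_flow(pat, shift_image(pat, 0, 1))
  f2 <- compute_flow(pat, shift_image(pat, 0, 2))
  ratio <- mean(f2$vc[interior, interior]) / mean(f1$vc[interior, interior])
  expect_gt(ratio, 1.6); expect_lt(ratio, 2.4)
})

test_that("frame shape mismatches are rejected", {
  expect_error(compute_flow(matrix(0, 10, 10), matrix(0, 12, 10)), "shape")
})

test_that("region_flow sums components and computes motion intensity", {
  fl <- structure(list(vr = matrix(0, 20, 20), vc = matrix(2, 20, 20)),
                  class = "flow_field")
  out <- region_flow(fl, ceus_box(5, 5, 10, 10))
  expect_equal(unname(out), c(0, 200, 2))
  # zero flow
  fl0 <- structure(list(vr = matrix(0, 20, 20), vc = matrix(0, 20, 20)),
                   class = "flow_field")
  expect_equal(unname(region_flow(fl0, ceus_box(5, 5, 10, 10))), c(0, 0, 0))
  # Pythagorean magnitude: u=3, v=4 constant -> w = 5 regardless of N
  fl34 <- structure(list(vr = matrix(4, 20, 20), vc = matrix(3, 20, 20)),
                    class = "flow_field")
  for (b in list(ceus_box(1, 1, 4, 4), ceus_box(2, 3, 7, 11)))
    expect_equal(unname(region_flow(fl34, b)[3]), 5)
  expect_error(region_flow(fl, ceus_box(15, 15, 10, 10)), "outside")
})

test_that("region_flow sums are additive over a partition", {
  set.seed(4)
  fl <- structure(list(vr = matrix(rnorm(400), 20, 20),
                       vc = matrix(rnorm(400), 20, 20)),
                  class = "flow_field")
  whole <- region_flow(fl, ceus_box(3, 3, 10, 10))
  top <- region_flow(fl, ceus_box(3, 3, 5, 10))
  bottom <- region_flow(fl, ceus_box(8, 3, 5, 10))
  expect_equal(whole[["sum_r"]], top[["sum_r"]] + bottom[["sum_r"]])
  expect_equal(whole[["sum_c"]], top[["sum_c"]] + bottom[["sum_c"]])
})

test_that("flow model update blends as an exponential moving average", {
  m <- flow_model(beta = 1, h = c(2, 0))
  expect_equal(unname(update_flow_model(m, c(4, 2, 1))$h), c(4, 2))
  m <- flow_model(beta = 0, h = c(2, 0))
  expect_equal(unname(update_flow_model(m, c(4, 2, 1))$h), c(2, 0))
  m <- flow_model(beta = 0.5, h = c(2, 0))
  up <- update_flow_model(m, c(4, 2, 1))
  expect_equal(unname(up$h), c(3, 1))
  expect_equal(up$w, 1)                       # w is replaced, not blended
  # constant input is a fixed point for every beta
  for (beta in c(0, 0.25, 0.5, 1)) {
    m <- flow_model(beta = beta, h = c(5, -3))
    expect_equal(unname(update_flow_model(m, c(5, -3, 2))$h), c(5, -3))
  }
  expect_error(flow_model(beta = 1.5), "beta")
})

test_that("flow sampling and mean-shift move points onto a moving blob", {
  # synthetic flow: uniform motion inside a disk at (30, 40), zero elsewhere
  vr <- matrix(0, 60, 60); vc <- matrix(0, 60, 60)
  for (r in 1:60) for (c in 1:60)
    if ((r - 30)^2 + (c - 40)^2 <= 64) { vr[r, c] <- 0.5; vc[r, c] <- 1 }
  fl <- structure(list(vr = vr, vc = vc), class = "flow_field")
  expect_equal(unname(flow_at(fl, rbind(c(30, 40)))[1, ]), c(0.5, 1))
  expect_equal(unname(flow_at(fl, rbind(c(5, 5)))[1, ]), c(0, 0))
  pts <- rbind(c(25, 35), c(34, 44), c(5, 5))
  moved <- flow_mean_shift(fl, pts, window = c(16, 16), iterations = 3)
  # points near the blob converge toward its center, far points stay
  expect_lt(sqrt(sum((moved[1, ] - c(30, 40))^2)),
            sqrt(sum((pts[1, ] - c(30, 40))^2)))
  expect_equal(moved[3, ], pts[3, ])
})
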