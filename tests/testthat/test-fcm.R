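test_that("degenerate and symmetric cases follow the update equations", {
  set.seed(41)
  x <- matrix(rnorm(30), ncol = 3)
  m1 <- fcm_fit(x, k = 1, seed = 1)
  expect_equal(unname(m1$centers[1, ]), unname(colMeans(x)))
  expect_true(all(m1$memberships == 1))

  # a point equidistant from the two centers gets 0.5 / 0.5
  two <- matrix(c(0, 0, 2, 0), 2, byrow = TRUE)
  m2 <- fcm_fit(two, k = 2, seed = 2)
  pr <- fcm_predict(m2, matrix(c(1, 0), 1))
  expect_equal(unname(pr$memberships[1, ]), c(0.5, 0.5))
  # a center itself gets full membership
  at_center <- fcm_predict(m2, m2$centers[1, , drop = FALSE])
  expect_equal(unname(at_center$memberships[1, ]), c(1, 0))

  expect_error(fcm_fit(x, k = 20), "k <= n")
  expect_error(fcm_fit(matrix(c(1, NA), 1), k = 1), "non-finite")
  expect_error(fcm_predict(m2, matrix(1, 1, 3)), "columns")
})

test_that("well-separated blobs are recovered and the objective is monotone", {
  set.seed(42)
  blob <- function(cx, cy) cbind(rnorm(50, cx, 0.5), rnorm(50, cy, 0.5))
  x <- rbind(blob(0, 0), blob(10, 10))
  m <- fcm_fit(x, k = 2, seed = 7)
  centers <- m$centers[order(m$centers[, 1]), ]
  expect_lt(max(abs(centers[1, ] - colMeans(x[1:50, ]))), 0.3)
  expect_lt(max(abs(centers[2, ] - colMeans(x[51:100, ]))), 0.3)
  expect_true(all(diff(m$objective_trace) <= 1e-10))
  expect_true(all(abs(rowSums(m$memberships) - 1) < 1e-12))
  expect_true(m$converged)

  # deterministic under seed
  expect_identical(m$centers, fcm_fit(x, k = 2, seed = 7)$centers)

  # memberships and objective agree with direct formula evaluation
  u <- fcm_membership_direct(x, m$centers, m$b)
  expect_lt(max(abs(u - fcm_predict(m, x)$memberships)), 1e-12)
  expect_equal(m$objective, fcm_objective_direct(x, u, m$centers, m$b),
               tolerance = 1e-10)
})

test_that("fit agrees with an independent FCM implementation", {
  skip_if_not_installed("e1071")
  set.seed(43)
  x <- rbind(cbind(rnorm(60, 0, 1), rnorm(60, 0, 1)),
             cbind(rnorm(60, 6, 1), rnorm(60, 6, 1)))
  ours <- fcm_fit(x, k = 2, seed = 3)
  ref <- e1071::cmeans(x, centers = 2, m = 2)
  ref_centers <- ref$centers[order(ref$centers[, 1]), ]
  our_centers <- ours$centers[order(ours$centers[, 1]), ]
  expect_lt(max(abs(ref_centers - our_centers)), 0.05)
})

test_that("membership rows sum to 1 at every iteration", {
  # instrumented re-run: step the update equations manually
  set.seed(44)
  x <- matrix(rnorm(60), ncol = 2)
  centers <- x[sample(30, 3), ]
  u <- slfomark:::fcm_memberships(x, centers, 2)
  for (it in 1:15) {
    expect_true(all(abs(rowSums(u) - 1) < 1e-12))
    centers <- slfomark:::fcm_centers(x, u, 2)
    u <- slfomark:::fcm_memberships(x, centers, 2)
  }
})
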