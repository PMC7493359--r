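test_that("problem validation accepts consistent instances and relabels groups", {
  pr <- sgp_problem(y = c(1, 2, 3, 4), Z = matrix(1:12 / 10, 4, 3),
                    groups = c("a", "a", "b"))
  expect_s3_class(pr, "sgp_problem")
  expect_equal(length(pr$group_sizes), 2L)
  expect_equal(pr$group_sizes, c(2L, 1L))
  expect_equal(pr$group_index, c(1L, 1L, 2L))
  expect_equal(pr$group_labels, c("a", "b"))
  expect_equal(pr$feature_weights, rep(1, 3))
  # first-appearance order is kept for arbitrary labels
  pr2 <- sgp_problem(c(1, 2), matrix(1:6 / 7, 2, 3), groups = c(9, 2, 9))
  expect_equal(pr2$group_labels, c("9", "2"))
  expect_equal(pr2$group_index, c(1L, 2L, 1L))
})

test_that("problem validation raises distinct named errors", {
  Z <- matrix(rnorm(9), 3, 3)
  expect_error(sgp_problem(rep(0, 4), Z, groups = c(1, 1, 2)),
               class = "sgp_dimension_error")
  expect_error(sgp_problem(rep(1, 3), Z, groups = c(1, 1)),
               class = "sgp_dimension_error")
  expect_error(sgp_problem(rep(1, 3), Z, groups = c(1, 1, 2),
                           feature_weights = c(1, 0, 1)),
               class = "sgp_weight_error")
  expect_error(sgp_problem(c(1, NA, 3), Z, groups = c(1, 1, 2)),
               class = "sgp_nonfinite_error")
  Z[1, 1] <- Inf
  expect_error(sgp_problem(rep(1, 3), Z, groups = c(1, 1, 2)),
               class = "sgp_nonfinite_error")
})

test_that("group weights follow sqrt(p_l * mean feature weight)", {
  expect_equal(unname(group_weights(rep(1, 4), rep("g", 4))), 2)
  expect_equal(unname(group_weights(c(1, 2, 3), rep("g", 3))), sqrt(6))
  # unit feature weights recover the classical sqrt(p_l) factor
  withr::local_seed(11)
  sizes <- c(1, 3, 5, 2)
  groups <- rep(letters[1:4], times = sizes)
  gw <- group_weights(rep(1, sum(sizes)), groups)
  expect_equal(unname(gw), sqrt(sizes))
  expect_equal(names(gw), letters[1:4])
})

test_that("objective matches hand-computed values", {
  # zero state: penalty vanishes, (1/2n)||y||^2
  pr <- sgp_problem(c(3, 4), matrix(c(1, 0, 0, 1), 2, 2), groups = c(1, 2))
  expect_equal(sgp_objective(pr, numeric(0), c(0, 0), 1, 0.5), 25 / 4)
  # lambda = 0 with an exact fit gives 0
  expect_equal(sgp_objective(pr, numeric(0), c(3, 4), 0, 0.5), 0)
  # hand arithmetic: n = 2, y = (1,2), Z = I, u = (1,1), one group,
  # alpha = 0.5, lambda = 1: 1/4 * 1 + 0.5*2 + 0.5*sqrt(2)*sqrt(2) = 2.25
  pr2 <- sgp_problem(c(1, 2), diag(2), groups = c(1, 1))
  expect_equal(sgp_objective(pr2, numeric(0), c(1, 1), 1, 0.5), 2.25)
})

test_that("alpha limits switch off the complementary penalty term", {
  withr::local_seed(21)
  for (i in 1:5) {
    pr <- rand_instance(100 + i)
    u <- rnorm(pr$p)
    b <- rnorm(pr$q)
    lam <- runif(1, 0.1, 2)
    smooth <- sgp_objective(pr, b, u, 0, 0.5)
    l1 <- sum(pr$feature_weights * abs(u))
    grp <- sum(pr$group_weights *
                 sqrt(drop(rowsum(u^2, pr$group_index))))
    expect_equal(sgp_objective(pr, b, u, lam, 1), smooth + lam * l1)
    expect_equal(sgp_objective(pr, b, u, lam, 0), smooth + lam * grp)
  }
})

test_that("objective is convex along random segments", {
  withr::local_seed(31)
  pr <- rand_instance(55, n = 12, p = 8, L = 3, q = 2)
  for (i in 1:20) {
    b1 <- rnorm(pr$q); u1 <- rnorm(pr$p)
    b2 <- rnorm(pr$q); u2 <- rnorm(pr$p)
    tt <- runif(1)
    lam <- runif(1, 0, 2); al <- runif(1)
    f1 <- sgp_objective(pr, b1, u1, lam, al)
    f2 <- sgp_objective(pr, b2, u2, lam, al)
    fm <- sgp_objective(pr, tt * b1 + (1 - tt) * b2,
                        tt * u1 + (1 - tt) * u2, lam, al)
    expect_lte(fm, tt * f1 + (1 - tt) * f2 + 1e-10)
  }
})

test_that("smooth gradient matches central finite differences", {
  withr::local_seed(41)
  h <- 1e-6
  for (i in 1:5) {
    pr <- rand_instance(200 + i, n = 5, p = 3, L = 2, q = i %% 3)
    b <- rnorm(pr$q); u <- rnorm(pr$p)
    gr <- sgp_gradient(pr, b, u)
    g <- c(gr$b, gr$u)
    fd <- vapply(seq_len(pr$q + pr$p), function(j) {
      e <- numeric(pr$q + pr$p); e[j] <- h
      bp <- b + e[seq_len(pr$q)]; up <- u + e[pr$q + seq_len(pr$p)]
      bm <- b - e[seq_len(pr$q)]; um <- u - e[pr$q + seq_len(pr$p)]
      (sgp_objective(pr, bp, up, 0, 1) -
         sgp_objective(pr, bm, um, 0, 1)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd)) / max(1, max(abs(g))), 1e-5)
  }
  # r = 0 gives a zero gradient; at the origin the gradient is -X'y/n, -Z'y/n
  pr <- rand_instance(999, n = 6, p = 4, L = 2, q = 2)
  bfit <- qr.solve(crossprod(cbind(pr$X, pr$Z)),
                   crossprod(cbind(pr$X, pr$Z), pr$y))
  gr0 <- sgp_gradient(pr, bfit[1:2], bfit[3:6])
  expect_lt(max(abs(c(gr0$b, gr0$u))), 1e-10)
  gr <- sgp_gradient(pr, rep(0, 2), rep(0, 4))
  expect_equal(gr$b, -drop(crossprod(pr$X, pr$y)) / pr$n)
  expect_equal(gr$u, -drop(crossprod(pr$Z, pr$y)) / pr$n)
})
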