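# independent sums-of-squares oracle for the q statistic
q_oracle <- function(y, s) {
  sst <- sum((y - mean(y))^2)
  ssw <- 0
  for (lev in unique(s)) {
    ys <- y[s == lev]
    ssw <- ssw + sum((ys - mean(ys))^2)
  }
  1 - ssw / sst
}

test_that("q equals its analytic extremes", {
  expect_equal(q_statistic(c(1, 1, 2, 2), c("a", "a", "b", "b"))$q, 1)
  expect_equal(q_statistic(c(1, 2, 1, 2), c("a", "a", "b", "b"))$q, 0)
  expect_error(q_statistic(rep(3, 6), rep(1:2, 3)), "variance is zero")
  expect_error(q_statistic(1:4, rep("a", 4)), "at least 2 strata")
})

test_that("q matches the brute-force variance decomposition", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(10:40, 1L)
    y <- stats::rnorm(n)
    s <- sample(letters[1:sample(2:5, 1L)], n, replace = TRUE)
    if (length(unique(s)) < 2L) next
    qc <- q_statistic(y, s)
    expect_equal(qc$q, q_oracle(y, s), tolerance = 1e-12)
    expect_equal(qc$q,
                 1 - sum(qc$stratum_counts * qc$stratum_variances) /
                   (qc$overall_count * qc$overall_variance),
                 tolerance = 1e-12)
  }
})

test_that("refining a stratification never decreases q", {
  set.seed(91)
  for (i in 1:50) {
    n <- 60L
    y <- stats::rnorm(n)
    s <- sample(1:4, n, replace = TRUE)
    q0 <- q_statistic(y, s)$q
    s2 <- s
    big <- as.integer(names(which.max(table(s))))
    members <- which(s == big)
    half <- sample(members, floor(length(members) / 2))
    s2[half] <- 99L
    if (length(unique(s2)) < 2L || !length(half)) next
    expect_gte(q_statistic(y, s2)$q, q0 - 1e-12)
  }
})

test_that("q is invariant to relabeling and affine response transforms", {
  set.seed(12)
  y <- stats::rnorm(50); s <- sample(1:3, 50, replace = TRUE)
  q0 <- q_statistic(y, s)$q
  expect_equal(q_statistic(y, c("x", "y", "z")[s])$q, q0, tolerance = 1e-12)
  expect_equal(q_statistic(3 * y - 7, s)$q, q0, tolerance = 1e-12)
})

test_that("permutation p-values detect perfect stratification", {
  set.seed(1)
  y <- rep(c(0, 5), each = 20) + 0.01 * stats::rnorm(40)
  s <- rep(c("a", "b"), each = 20)
  qc <- q_significance(q_statistic(y, s), permutations = 999L, seed = 2L)
  expect_lte(qc$p_value, 0.01)
  qc2 <- q_significance(q_statistic(y, s), permutations = 999L, seed = 2L)
  expect_identical(qc$p_value, qc2$p_value)
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(33)
  pv <- vapply(1:120, function(i) {
    y <- stats::rnorm(30)
    s <- sample(1:3, 30, replace = TRUE)
    q_significance(q_statistic(y, s), permutations = 199L,
                   seed = 100 + i)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif")$p.value), 0.01)
})

test_that("discretizers implement their method semantics", {
  d <- discretize(1:10, "equal", 2)
  expect_identical(split(1:10, d), split(1:10, rep(1:2, each = 5)))
  set.seed(4)
  u <- stats::runif(100)
  dq <- discretize(u, "quantile", 4)
  expect_true(all(abs(table(dq) - 25) <= 1))
  expect_error(discretize(rep(1:2, 5), "equal", 5), "distinct")
  g <- discretize(exp(seq(0, 5, length.out = 50)), "geometric", 4)
  expect_identical(length(unique(g)), 4L)
  s <- discretize(stats::rnorm(200), "sd", 4)
  expect_gte(length(unique(s)), 3L)
})

test_that("natural breaks match exhaustive minimisation on small inputs", {
  sse_part <- function(x, cuts) { # cuts: last index of classes 1..k-1
    idx <- c(0, cuts, length(x))
    tot <- 0
    for (i in seq_len(length(idx) - 1L)) {
      seg <- x[(idx[i] + 1L):idx[i + 1L]]
      tot <- tot + sum((seg - mean(seg))^2)
    }
    tot
  }
  set.seed(10)
  for (rep in 1:5) {
    x <- sort(stats::rnorm(20))
    ends <- oasiscarbon:::.fisher_jenks(x, 3L)
    best <- Inf
    for (i in 1:18) for (j in (i + 1):19)
      best <- min(best, sse_part(x, c(i, j)))
    expect_equal(sse_part(x, ends[1:2]), best, tolerance = 1e-10)
  }
  # three well-separated clusters are recovered exactly
  set.seed(2)
  v <- c(stats::rnorm(10), stats::rnorm(10, 10), stats::rnorm(10, 20))
  lab <- discretize(v, "natural_breaks", 3)
  expect_identical(as.integer(lab), rep(1:3, each = 10L))
})

test_that("discretization optimisation maximises q over the grid", {
  set.seed(21)
  drv <- stats::runif(300)
  resp <- as.numeric(cut(drv, c(-Inf, 0.33, 0.66, Inf))) * 5
  spec <- optimize_discretization(drv, resp)
  expect_equal(spec$q, 1, tolerance = 1e-12)
  expect_identical(spec$k, 3L)
  # returned maximum equals an independent re-evaluation of the grid
  set.seed(22)
  drv2 <- stats::rnorm(200); resp2 <- drv2^2 + stats::rnorm(200, sd = 0.5)
  spec2 <- optimize_discretization(drv2, resp2)
  qs <- c()
  for (m in c("equal", "quantile", "natural_breaks", "geometric", "sd"))
    for (k in 3:8) {
      lab <- tryCatch(discretize(drv2, m, k), error = function(e) NULL)
      if (!is.null(lab) && length(unique(lab)) >= 2L)
        qs <- c(qs, q_oracle(resp2, lab))
    }
  expect_equal(spec2$q, max(qs), tolerance = 1e-12)
  # singleton grid returns that spec
  s1 <- optimize_discretization(drv2, resp2, methods = "equal", k_range = 2L)
  expect_identical(s1$method, "equal")
  expect_identical(s1$k, 2L)
})

test_that("interaction categories follow the comparison rules", {
  set.seed(7)
  y <- stats::rnorm(80)
  s1 <- sample(1:3, 80, replace = TRUE)
  # duplicated driver: q12 = q1, boundary assigned to univariate weaken
  ir <- interaction_detect(y, s1, s1)
  expect_equal(ir$q12, ir$q1, tolerance = 1e-12)
  expect_identical(ir$category, "univariate_weaken")
  # response explained only by the pair (XOR design): nonlinear enhance
  a <- rep(c(1L, 1L, 2L, 2L), 25)
  b <- rep(c(1L, 2L, 1L, 2L), 25)
  yx <- as.numeric(xor(a == 2L, b == 2L))
  ir2 <- interaction_detect(yx, a, b)
  expect_equal(ir2$q12, 1, tolerance = 1e-12)
  expect_lt(ir2$q1 + ir2$q2, 1e-12)
  expect_identical(ir2$category, "nonlinear_enhance")
})

test_that("factor detection bands follow the printed cutpoints", {
  expect_identical(oasiscarbon:::band_q(0.356), "main")
  expect_identical(oasiscarbon:::band_q(0.202), "strong")
  expect_identical(oasiscarbon:::band_q(0.12), "medium")
  expect_identical(oasiscarbon:::band_q(0.05), "weak")
})
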