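test_that("M/A statistics match direct evaluation of their formulas", {
  m <- matrix(c(10, 100, 1000, 20, 100, 880), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("k", "r")))
  x <- count_matrix(m)
  ma <- compute_ma(x, "k", "r")
  nk <- 1110; nr <- 1000
  yk <- c(10, 100, 1000); yr <- c(20, 100, 880)
  expect_equal(ma$M, log2((yk / nk) / (yr / nr)), tolerance = 1e-14)
  expect_equal(ma$A, 0.5 * log2((yk / nk) * (yr / nr)), tolerance = 1e-14)
  expect_equal(ma$var_M,
               (nk - yk) / (nk * yk) + (nr - yr) / (nr * yr),
               tolerance = 1e-14)
  expect_true(all(ma$valid))
  expect_true(all(ma$weight > 0))
})

test_that("self-comparison gives M = 0 and A = log2 proportion", {
  m <- random_count_matrix(50, 2, seed = 3)
  x <- count_matrix(m)
  ma <- compute_ma(x, "lib1", "lib1")
  ok <- ma$valid
  expect_true(any(ok))
  expect_identical(unique(ma$M[ok]), 0)
  expect_equal(ma$A[ok], unname(log2(m[ok, 1] / sum(m[, 1]))),
               tolerance = 1e-14)
})

test_that("genes with a zero count in either library are flagged invalid", {
  m <- matrix(c(0, 5, 9, 4, 0, 9), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("k", "r")))
  ma <- compute_ma(count_matrix(m), "k", "r")
  expect_identical(ma$valid, c(FALSE, FALSE, TRUE))
  expect_true(all(is.na(ma$M[!ma$valid])))
  expect_error(compute_ma(count_matrix(m), "k", "nope"), "unknown library")
})

test_that("double trimming follows the per-tail floor rank rule", {
  m <- random_count_matrix(60, 2, seed = 5, zero_prop = 0)
  ma <- compute_ma(count_matrix(m), "lib1", "lib2")

  # no trim keeps every valid gene
  expect_setequal(doubly_trim(ma, trim_params(0, 0)), ma$gene[ma$valid])

  # 10 genes, 30% M trim: 3 lowest and 3 highest M removed
  ma10 <- ma[1:10, ]
  class(ma10) <- class(ma)
  kept <- doubly_trim(ma10, trim_params(0.3, 0))
  ord <- order(ma10$M)
  expect_setequal(kept, ma10$gene[sort(ord[4:7])])
  expect_length(kept, 4L)

  # an a_min bound removes low-abundance genes before trimming
  bound <- median(ma$A[ma$valid])
  kept_b <- doubly_trim(ma, trim_params(0, 0, a_min = bound))
  expect_true(all(ma$A[match(kept_b, ma$gene)] >= bound))

  expect_error(doubly_trim(ma, trim_params(0.49, 0.49)), "smaller")
})

test_that("doubly_trim matches a brute-force sort-and-slice oracle", {
  for (seed in c(101, 202, 303)) {
    m <- random_count_matrix(100, 2, seed = seed, zero_prop = 0)
    x <- count_matrix(m)
    ma <- compute_ma(x, "lib1", "lib2")
    kept <- doubly_trim(ma, trim_params())
    # oracle: first-principles mid-ranks over the same candidate pool
    idx <- which(ma$valid)
    n <- length(idx)
    mid <- function(v) vapply(v, function(x)
      sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
    in_band <- function(v, f) {
      r <- mid(v)
      r >= floor(n * f) + 1 & r <= n - floor(n * f)
    }
    sel <- in_band(ma$M[idx], 0.30) & in_band(ma$A[idx], 0.05)
    expect_setequal(kept, ma$gene[idx[sel]])
  }
})

test_that("tmm_pair equals the straight-line oracle on random matrices", {
  for (seed in 1:5) {
    m <- random_count_matrix(200, 2, seed = seed)
    x <- count_matrix(m)
    fit <- tmm_pair(x, "lib1", "lib2")
    expect_equal(fit$log2_factor, oracle_tmm_log2(m, "lib1", "lib2"),
                 tolerance = 1e-12)
    # unweighted variant too
    fitu <- tmm_pair(x, "lib1", "lib2", trim_params(weighted = FALSE))
    expect_equal(fitu$log2_factor,
                 oracle_tmm_log2(m, "lib1", "lib2", weighted = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("tmm_pair agrees with the edgeR reference implementation", {
  # edgeR breaks rank ties differently at the trim boundary, so agreement
  # is close but not bitwise on tied Poisson counts
  edgeR_tmm <- getFromNamespace(".calcFactorTMM", "edgeR")
  for (seed in c(7, 77)) {
    m <- random_count_matrix(400, 2, seed = seed)
    mine <- tmm_pair(count_matrix(m), "lib1", "lib2")$factor
    theirs <- edgeR_tmm(m[, 1], m[, 2], sum(m[, 1]), sum(m[, 2]))
    expect_equal(mine, unname(theirs), tolerance = 0.01)
  }
})

test_that("self-normalization is exactly 1 and uniform scaling leaves it 1", {
  m <- random_count_matrix(150, 2, seed = 9)
  x <- count_matrix(m)
  self <- tmm_pair(x, "lib1", "lib1")
  expect_identical(self$factor, 1)
  expect_identical(self$log2_factor, 0)

  tripled <- m
  tripled[, 2] <- m[, 1] * 3
  fit <- tmm_pair(count_matrix(tripled), "lib1", "lib2")
  expect_equal(fit$factor, 1, tolerance = 1e-9)
})

test_that("log2 factors are antisymmetric and scale-invariant", {
  for (seed in 11:20) {
    m <- random_count_matrix(120, 2, seed = seed)
    x <- count_matrix(m)
    f_kr <- tmm_pair(x, "lib1", "lib2")$log2_factor
    f_rk <- tmm_pair(x, "lib2", "lib1")$log2_factor
    expect_equal(f_kr, -f_rk, tolerance = 1e-12)

    # scaling every count by c: M, A and trim unchanged, weights scale
    # uniformly by 1/c, so the weighted mean is invariant
    f_s <- tmm_pair(count_matrix(m * 7), "lib1", "lib2")$log2_factor
    expect_equal(f_s, f_kr, tolerance = 1e-9)

    # scaling a single library only preserves the unweighted mean exactly
    # (the delta-method variance sums per-library terms, so per-gene
    # weights shift when one library is rescaled)
    one <- m; one[, 1] <- m[, 1] * 7
    pu <- trim_params(weighted = FALSE)
    f_u <- tmm_pair(x, "lib1", "lib2", pu)$log2_factor
    f_us <- tmm_pair(count_matrix(one), "lib1", "lib2", pu)$log2_factor
    expect_equal(f_us, f_u, tolerance = 1e-9)
  }
})

test_that("tmm() fits every library against the chosen reference", {
  m <- random_count_matrix(200, 3, seed = 21)
  m[, 2] <- m[, 1] * 2          # uniform scalings of lib1
  m[, 3] <- m[, 1] * 5
  fit <- tmm(count_matrix(m))
  expect_identical(fit$reference, "lib1")
  expect_identical(unname(fit$factors["lib1"]), 1)
  expect_equal(unname(fit$factors), c(1, 1, 1), tolerance = 1e-9)
  expect_equal(fit$effective_sizes, lib_sizes(count_matrix(m)) * fit$factors)

  # consistency with the pairwise operation
  m2 <- random_count_matrix(200, 3, seed = 22)
  x2 <- count_matrix(m2)
  fit2 <- tmm(x2, reference = "lib2")
  expect_identical(unname(fit2$factors["lib3"]),
                   tmm_pair(x2, "lib3", "lib2")$factor)
  expect_identical(coef(fit2), fit2$factors)
  s <- summary(fit2)
  expect_true(is.na(s$n_kept[s$library == "lib2"]))
  expect_error(tmm(count_matrix(m2[, 1, drop = FALSE])), "two libraries")

  # auto reference selection is deterministic
  expect_identical(tmm(x2, reference = "auto")$reference,
                   tmm(x2, reference = "auto")$reference)
})

test_that("two-sample effective sizes implement the square-root split", {
  expect_identical(effective_sizes_two_sample(1e6, 2e6, 1), c(1e6, 2e6))
  expect_equal(effective_sizes_two_sample(1e6, 1e6, 0.25), c(5e5, 2e6))
  # the split preserves the product and scales the ratio by the factor
  for (f in c(0.1, 0.68, 1.7)) {
    e <- effective_sizes_two_sample(3e6, 1.2e6, f)
    expect_equal(e[1] * e[2], 3e6 * 1.2e6, tolerance = 1e-9)
    expect_equal(e[1] / e[2], (3e6 / 1.2e6) * f, tolerance = 1e-12)
  }
  expect_error(effective_sizes_two_sample(0, 1, 1))
})
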