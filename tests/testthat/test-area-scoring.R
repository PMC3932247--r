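test_that("pairwise overlap and inclusion formulas are literal", {
  expect_equal(pairwise_phi(c(0, 2), c(1, 3)), 1)
  expect_equal(pairwise_phi(c(0, 1), c(2, 3)), 0)
  # inclusion configuration: the literal overlap formula spans past the
  # intersection (4 - 1 = 3, not the intersection length 1)
  expect_equal(pairwise_phi(c(0, 4), c(1, 2)), 3)

  expect_equal(pairwise_psi(c(0, 4), c(1, 2)), 1)
  expect_equal(pairwise_psi(c(0, 2), c(1, 3)), 0)
  expect_equal(pairwise_psi(c(0, 2), c(0.5, 0.5)), 0)  # zero-width inclusion
  expect_error(pairwise_phi(c(2, 0), c(1, 3)), "lower <= upper")
})

test_that("area decomposition matches hand-computed pair sums", {
  # three classes already sorted by lower bound
  r <- range_table(c(0, 1, 2.5), c(2, 3, 4))
  a <- area_decomposition(r)
  expect_equal(unname(a$oa), 1.5)   # 1.0 + 0 + 0.5
  expect_equal(unname(a$ia), 0)
  expect_equal(unname(a$ac), 1.5 / 4)

  # disjoint classes: no overlap, no inclusion, AC = 0
  a2 <- area_decomposition(range_table(c(0, 2), c(1, 3)))
  expect_equal(unname(a2$oa), 0)
  expect_equal(unname(a2$ia), 0)
  expect_equal(unname(a2$ac), 0)
  expect_equal(unname(a2$nac), 1)  # all-zero AC convention

  # inclusion configuration counts the nested width, and SA keeps the
  # as-printed double count unless exclusive mode is requested
  r3 <- range_table(c(0, 1), c(4, 2))
  a3 <- area_decomposition(r3)
  expect_equal(unname(a3$oa), 3)
  expect_equal(unname(a3$ia), 1)
  expect_equal(unname(a3$sa), 4)
  a3x <- area_decomposition(r3, exclusive = TRUE)
  expect_equal(unname(a3x$oa), 2)
  expect_equal(unname(a3x$sa), 3)
})

test_that("sorted mode orients pairs left-to-right; literal mode does not", {
  # same geometry as the three-class example but scrambled class order
  r <- range_table(c(2.5, 0, 1), c(4, 2, 3))
  expect_equal(unname(area_decomposition(r, mode = "sorted")$oa), 1.5)
  # literal order: phi(1,2) = 4 - 0, phi(1,3) = 4 - 1, phi(2,3) = 2 - 1
  lit <- area_decomposition(r, mode = "literal")
  expect_equal(unname(lit$oa), 8)
  expect_equal(unname(lit$ia), 2 + 2)  # psi(1,2) and psi(1,3) fire
})

test_that("normalized area coefficient inverts and rescales AC", {
  expect_equal(ifser:::.inv_max_norm(c(0.5, 1.0, 0.0)), c(0.5, 0, 1))
  expect_equal(ifser:::.inv_max_norm(c(0, 0, 0)), c(1, 1, 1))
  # zero-width hull (all class ranges the same point) -> AC 0 by convention
  a <- area_decomposition(range_table(cbind(c(5, 0), c(5, 2)),
                                      cbind(c(5, 1), c(5, 3))))
  expect_equal(unname(a$ac[1]), 0)
})

test_that("ERGS weights are the overlap-only normalized coefficients", {
  r <- range_table(cbind(c(0, 0), c(2, 1)), cbind(c(1, 2), c(3, 3)))
  w <- ergs_weights(r)
  expect_equal(unname(w), c(1, 0))  # AC = (0, 1/3) -> NAC = (1, 0)
  # single feature: weight 1 iff its AC is 0
  expect_equal(unname(ergs_weights(range_table(c(0, 2), c(1, 3)))), 1)
  expect_equal(unname(ergs_weights(range_table(c(0, 1), c(2, 3)))), 0)
  # reduction identity: when no feature has any inclusion, ergs equals the
  # nac of the full decomposition
  for (seed in 1:20) {
    data <- rand_instance(seed, d = 4L)
    r <- effective_ranges(compute_class_stats(data))
    keep <- !vapply(seq_len(4L), function(i) has_inclusion(r, i), logical(1))
    if (!any(keep)) next
    sub <- range_table(r$lower[keep, , drop = FALSE],
                       r$upper[keep, , drop = FALSE])
    expect_equal(ergs_weights(sub), area_decomposition(sub)$nac)
  }
})

test_that("overlap area agrees with intersection and Monte-Carlo oracles", {
  set.seed(99)
  n_checked <- 0L
  for (seed in 1:50) {
    data <- rand_instance(seed)
    r <- effective_ranges(compute_class_stats(data))
    a <- area_decomposition(r)
    for (i in seq_along(a$oa)) {
      hull <- max(r$upper[i, ]) - min(r$lower[i, ])
      if (has_inclusion(r, i)) {
        # literal formula counts past the intersection in inclusion regimes
        expect_gte(a$oa[[i]], oa_intersection_sum(r, i) - 1e-12)
      } else {
        expect_equal(a$oa[[i]], oa_intersection_sum(r, i))
        expect_lt(abs(a$oa[[i]] - oa_monte_carlo(r, i, m = 4000L)),
                  0.15 * hull)
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 20L)  # both regimes actually exercised
})

test_that("areas are scale-equivariant and shift-invariant", {
  for (seed in 1:10) {
    data <- rand_instance(seed, d = 4L)
    a <- area_decomposition(effective_ranges(compute_class_stats(data)))

    scaled <- labeled_matrix(data$values * 3.7, data$labels)
    as <- area_decomposition(effective_ranges(compute_class_stats(scaled)))
    expect_equal(as$oa, 3.7 * a$oa)
    expect_equal(as$ia, 3.7 * a$ia)
    expect_equal(as$sa, 3.7 * a$sa)
    expect_equal(as$ac, a$ac)
    expect_equal(as$nac, a$nac)

    shifted_values <- data$values
    shifted_values[, 2] <- shifted_values[, 2] + 100
    sh <- area_decomposition(effective_ranges(compute_class_stats(
      labeled_matrix(shifted_values, data$labels))))
    expect_equal(sh$oa, a$oa)
    expect_equal(sh$ac, a$ac)
    expect_equal(sh$nac, a$nac)

    # anti-monotonicity of the normalization
    ord <- order(a$ac)
    expect_true(all(diff(a$nac[ord]) <= 1e-12))
  }
})
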