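test_that("final weights compose area and proportion scores", {
  set.seed(3)
  g <- generate_labeled_matrix(synthetic_spec(n_per_class = c(8, 8),
                                              d_total = 12, d_informative = 3,
                                              seed = 3))
  w <- ifser_weights(g$data)
  expect_s3_class(w, "feature_weights")
  expect_equal(w$method, "ifser")
  expect_equal(w$w, w$v * w$z)
  expect_true(all(w$w >= 0 & w$w <= 2))
  expect_equal(w$v, w$areas$nac)
  expect_equal(w$z, w$proportions$nh + w$proportions$gh)

  e <- rank_features(g$data, method = "ergs")
  expect_equal(e$method, "ergs")
  expect_true(all(e$w >= 0 & e$w <= 1))
  expect_equal(unname(e$z), rep(1, 12))
})

test_that("a feature with disjoint, empty-region classes scores the maximum", {
  # separated feature: V = 1 (AC 0), Z = 2 (no trapped samples), W = 2
  set.seed(5)
  x <- cbind(sep = c(rnorm(10, -5), rnorm(10, 5)), noise = rnorm(20))
  d <- labeled_matrix(x, rep(c("A", "B"), each = 10))
  w <- ifser_weights(d)
  expect_equal(unname(w$w["sep"]), 2)
  expect_lt(unname(w$w["noise"]), 2)
  expect_equal(w$ranking[1], 1L)
})

test_that("top-k selection is stable with ascending-index tie break", {
  fake <- structure(list(w = c(0.2, 0.9, 0.9, 0.1),
                         ranking = order(-c(0.2, 0.9, 0.9, 0.1), 1:4)),
                    class = "feature_weights")
  expect_equal(select_top_k(fake, 2), c(2L, 3L))
  expect_equal(select_top_k(fake, 4), c(2L, 3L, 1L, 4L))
  tied <- structure(list(w = rep(1, 5), ranking = order(-rep(1, 5), 1:5)),
                    class = "feature_weights")
  expect_equal(select_top_k(tied, 3), 1:3)
  expect_error(select_top_k(fake, 0), "between 1 and 4")
  expect_error(select_top_k(fake, 5), "between 1 and 4")
  expect_error(select_top_k(fake, 2.5), "between 1 and 4")
})

test_that("IFSER reduces to ERGS when inclusion and proportions are off", {
  for (seed in 1:25) {
    data <- rand_instance(seed, d = 5L)
    reduced <- ifser_weights(data, include_ia = FALSE,
                             use_proportions = FALSE)
    ranges <- effective_ranges(compute_class_stats(data))
    expect_identical(unname(reduced$w), unname(ergs_weights(ranges)))
    expect_identical(reduced$w, rank_features(data, method = "ergs")$w)
  }
})

test_that("weights are equivariant to feature permutation and invariant to sample order", {
  for (seed in 1:8) {
    data <- rand_instance(seed, d = 5L)
    w <- ifser_weights(data)

    perm <- sample(5L)
    pdata <- labeled_matrix(data$values[, perm, drop = FALSE], data$labels,
                            data$feature_names[perm])
    wp <- ifser_weights(pdata)
    expect_equal(unname(wp$w), unname(w$w[perm]))

    sperm <- sample(nrow(data$values))
    sdata <- labeled_matrix(data$values[sperm, , drop = FALSE],
                            data$labels[sperm], data$feature_names)
    ws <- ifser_weights(sdata)
    expect_equal(ws$w, w$w)
  }
})

test_that("planted well-separated features outrank noise end to end", {
  g <- generate_labeled_matrix(synthetic_spec(n_per_class = c(20, 20),
                                              d_total = 40, d_informative = 5,
                                              separation = 4, seed = 8))
  w <- ifser_weights(g$data)
  expect_setequal(select_top_k(w, 5), g$shift_features)
})

test_that("inclusion configurations are penalized against equal-overlap partial overlap", {
  # Two features with identical overlapping area, one a nested (inclusion)
  # configuration, one a plain partial overlap. The overlap-only ERGS
  # weighting cannot tell them apart; the inclusion area and the trapped
  # inner-class samples push the nested feature down, which is the point of
  # the refined weighting.
  set.seed(21)
  n <- 40
  inner <- rnorm(n, 0, 1)          # class A nested inside class B
  outer <- rnorm(n, 0, 4)
  left <- rnorm(n, 0, 3)           # partial overlap tuned to a similar OA
  right <- rnorm(n, 0.87, 3)
  x <- cbind(nested = c(inner, outer), partial = c(left, right))
  d <- labeled_matrix(x, rep(c("A", "B"), each = n))

  r <- effective_ranges(compute_class_stats(d))
  a <- area_decomposition(r)
  # comparable overlapping areas by construction (within 25%)
  expect_lt(abs(a$oa[["nested"]] - a$oa[["partial"]]) /
              max(a$oa), 0.25)
  expect_gt(a$ia[["nested"]], 0)
  expect_equal(a$ia[["partial"]], 0, ignore_attr = TRUE)

  w_ifser <- ifser_weights(d)
  w_ergs <- rank_features(d, method = "ergs")
  # ERGS sees similar weights; IFSER demotes the nested feature
  expect_lt(w_ifser$w[["nested"]], w_ifser$w[["partial"]])
  expect_lt(abs(w_ergs$w[["nested"]] - w_ergs$w[["partial"]]),
            w_ifser$w[["partial"]] - w_ifser$w[["nested"]])
})
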