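test_that("phantom geometry, painting order and determinism", {
  spec <- phantom_spec(size = c(64L, 64L), background = 40L,
                       regions = list(list(shape = "ellipse", gray = 200L,
                                           center = c(32, 32),
                                           radii = c(10, 14))),
                       noise_sigma = 0, seed = 1)
  ph <- phantom_generate(spec)
  h <- gray_histogram(ph$image)
  expect_equal(which(h$counts > 0) - 1L, c(40L, 200L))
  expect_setequal(unique(as.integer(ph$truth)), 0:1)
  expect_true(all(ph$image[ph$truth == 1] == 200L))
  # later regions overwrite earlier ones
  spec2 <- phantom_spec(size = c(20L, 20L), background = 0L,
                        regions = list(
                          list(shape = "rectangle", gray = 100L,
                               corner = c(1, 1), extent = c(20, 20)),
                          list(shape = "rectangle", gray = 200L,
                               corner = c(5, 5), extent = c(5, 5))),
                        noise_sigma = 0)
  ph2 <- phantom_generate(spec2)
  expect_equal(as.integer(ph2$image[7, 7]), 200L)
  expect_equal(ph2$truth[7, 7], 2L)
  # fixed seed: identical noise realization
  s <- phantom_spec(noise_sigma = 5, seed = 77)
  expect_identical(phantom_generate(s)$image, phantom_generate(s)$image)
  expect_error(phantom_spec(regions = list(list(shape = "ellipse",
                                                gray = 40L,
                                                center = c(45, 50),
                                                radii = c(5, 5)))),
               "distinct")
  expect_error(phantom_spec(size = c(30L, 30L),
                            regions = list(list(shape = "ellipse",
                                                gray = 200L,
                                                center = c(28, 28),
                                                radii = c(5, 5)))),
               "bounds")
})

test_that("noise spreads the histogram around the base-gray modes", {
  spec <- phantom_spec(size = c(64L, 64L), background = 40L,
                       regions = list(list(shape = "ellipse", gray = 200L,
                                           center = c(32, 32),
                                           radii = c(10, 14))),
                       noise_sigma = 5, seed = 3)
  h <- gray_histogram(phantom_generate(spec)$image)
  expect_gt(sum(h$counts > 0), 2L)
  present <- which(h$counts > 0) - 1L
  low <- present[present < 120]
  high <- present[present >= 120]
  expect_equal(low[which.max(h$counts[low + 1L])], 40L, tolerance = 1)
  expect_equal(high[which.max(h$counts[high + 1L])], 200L, tolerance = 1)
})

test_that("Hungarian matching equals the brute-force permutation oracle", {
  set.seed(111)
  for (rep in 1:40) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    conf <- matrix(sample(0:50, n * m, replace = TRUE), n, m)
    sq <- max(n, m)
    padded <- matrix(0, sq, sq)
    padded[seq_len(n), seq_len(m)] <- conf
    a <- foadpc:::solve_assignment(max(padded) - padded)
    got <- sum(padded[cbind(a, seq_len(sq))])
    expect_equal(got, oracle_best_matching(conf))
  }
})

test_that("matched accuracy scores permutations, chance and degenerates", {
  truth <- matrix(sample(0:2, 400, replace = TRUE), 20)
  perm <- c(2L, 0L, 1L)
  pred <- matrix(perm[truth + 1L], 20)
  expect_equal(match_and_score(pred, truth), 1.0)
  expect_equal(match_and_score(truth, truth, one_to_one = FALSE), 1.0)
  # independent balanced 2-class labels agree about half the time
  set.seed(121)
  accs <- replicate(100, {
    t2 <- matrix(sample(0:1, 900, replace = TRUE), 30)
    p2 <- matrix(sample(0:1, 900, replace = TRUE), 30)
    match_and_score(p2, t2)
  })
  expect_equal(mean(accs), 0.5, tolerance = 0.05)
  # single-class vs single-class
  expect_equal(match_and_score(matrix(0L, 2, 2), matrix(0L, 2, 2)), 1.0)
  expect_error(match_and_score(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               "shapes")
})

test_that("many-to-one merging never scores below one-to-one matching", {
  set.seed(131)
  for (rep in 1:20) {
    truth <- matrix(sample(0:2, 100, replace = TRUE), 10)
    pred <- matrix(sample(0:6, 100, replace = TRUE), 10)
    expect_gte(match_and_score(pred, truth, one_to_one = FALSE),
               match_and_score(pred, truth) - 1e-12)
  }
})
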