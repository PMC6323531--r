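make_hist <- function(...) {
  counts <- rep(0L, 256)
  spec <- c(...)
  counts[as.integer(names(spec)) + 1L] <- as.integer(spec)
  hist_from_counts(counts)
}

test_that("chi is the strict negative-part indicator", {
  expect_identical(chi(-1), 1L)
  expect_identical(chi(0), 0L)
  expect_identical(chi(3.5), 0L)
  expect_identical(chi(c(-0.001, 0, 5)), c(1L, 0L, 0L))
  expect_error(chi(Inf), "finite")
})

test_that("density is the frequency-weighted strict-window count", {
  h <- make_hist("10" = 5, "11" = 3, "50" = 4, "51" = 6)
  d <- dpc_density(h, 2)
  expect_equal(d$levels, c(10L, 11L, 50L, 51L))
  expect_equal(d$rho, c(8, 8, 10, 10))
  # d_c = 1: only the level itself is within strict distance 1
  d1 <- dpc_density(h, 1)
  expect_equal(d1$rho, c(5, 3, 4, 6))
  # single level: density is its own count for any d_c
  expect_equal(dpc_density(make_hist("77" = 100), 10)$rho, 100)
  expect_error(dpc_density(h, 0.5), "\\[1, 10\\]")
})

test_that("density is non-decreasing in d_c at every level", {
  set.seed(21)
  for (rep in 1:30) {
    h <- hist_from_counts(random_hist_counts())
    dcs <- sort(runif(5, 1, 10))
    rhos <- sapply(dcs, function(dc) dpc_density(h, dc)$rho)
    expect_true(all(diff(t(rhos)) >= 0))
  }
})

test_that("delta follows the documented ranking with max-distance top", {
  h <- make_hist("10" = 5, "11" = 3, "50" = 4, "51" = 6)
  p <- dpc_profile(h, 2)
  # rank order by (rho desc, counts desc, gray asc): 51, 50, 10, 11
  expect_equal(p$levels[p$rank_order], c(51L, 50L, 10L, 11L))
  expect_equal(p$delta[match(c(51, 50, 10, 11), p$levels)], c(41, 1, 40, 1))
  expect_equal(p$gamma[match(c(51, 50, 10, 11), p$levels)],
               c(410, 10, 320, 8))
  # equal-count equal-rho pair: gray ascending breaks the tie
  h2 <- make_hist("0" = 1, "255" = 1)
  p2 <- dpc_profile(h2, 1)
  expect_equal(p2$levels[p2$rank_order], c(0L, 255L))
  expect_equal(p2$delta, c(255, 255))
  # singleton histogram: delta = 1 by convention
  p3 <- dpc_profile(make_hist("9" = 4), 3)
  expect_equal(p3$delta, 1)
  expect_true(is.na(p3$nn_higher))
})

test_that("centers are the top-gamma levels with deterministic tie-breaks", {
  h <- make_hist("10" = 5, "11" = 3, "50" = 4, "51" = 6)
  p <- dpc_profile(h, 2)
  expect_equal(dpc_select_centers(p, 2), c(51L, 10L))
  # k clamped to the number of present levels
  expect_equal(sort(dpc_select_centers(p, 40)), c(10L, 11L, 50L, 51L))
  # equal gamma and rho: lower gray first
  p2 <- dpc_profile(make_hist("0" = 1, "255" = 1), 1)
  expect_equal(dpc_select_centers(p2, 2), c(0L, 255L))
  expect_error(dpc_select_centers(p, 1), ">= 2")
})

test_that("label propagation follows the nearest denser neighbor chain", {
  h <- make_hist("10" = 5, "11" = 3, "50" = 4, "51" = 6)
  m <- dpc_fit(h, 2, 2)
  lab <- m$level_label
  expect_equal(lab[51 + 1], lab[50 + 1])  # 50 joins center 51
  expect_equal(lab[10 + 1], lab[11 + 1])  # 11 joins center 10
  expect_equal(lab[51 + 1], 0L)           # largest gamma gets label 0
  expect_equal(lab[10 + 1], 1L)
  # k = #levels: identity clustering
  m4 <- dpc_fit(h, 2, 4)
  expect_equal(sort(unique(m4$level_label[c(11, 12, 51, 52)])), 0:3)
  expect_equal(m4$effective_k, 4L)
})

test_that("every center outranks every non-center in gamma", {
  set.seed(31)
  for (rep in 1:50) {
    h <- hist_from_counts(random_hist_counts())
    k <- sample(2:40, 1)
    m <- dpc_fit(h, runif(1, 1, 10), k)
    g <- m$profile$gamma
    is_center <- m$profile$levels %in% m$centers
    if (any(!is_center))
      expect_gte(min(g[is_center]), max(g[!is_center]))
  }
})

test_that("module labels equal the brute-force pairwise oracle", {
  set.seed(41)
  for (rep in 1:60) {
    counts <- random_hist_counts()
    d_c <- runif(1, 1, 10)
    k <- sample(2:40, 1)
    h <- hist_from_counts(counts)
    m <- dpc_fit(h, d_c, k)
    o <- oracle_dpc(counts, d_c, k)
    expect_equal(m$profile$levels, o$levels)
    expect_equal(m$profile$rho, o$rho)
    expect_equal(m$profile$delta, o$delta)
    expect_equal(m$centers, o$centers)
    expect_equal(m$level_label[o$levels + 1L], o$label)
  }
})

test_that("results depend only on the histogram, not pixel order", {
  set.seed(51)
  counts <- random_hist_counts()
  img <- image_from_counts(counts)
  perm <- matrix(sample(as.integer(img)), nrow = nrow(img))
  h1 <- gray_histogram(img)
  h2 <- gray_histogram(gray_image(perm))
  expect_identical(h1$counts, h2$counts)
  m1 <- dpc_fit(h1, 3.7, 5)
  m2 <- dpc_fit(h2, 3.7, 5)
  expect_identical(m1$level_label, m2$level_label)
  expect_identical(m1$centers, m2$centers)
})

test_that("decision graph lists one row per level, sorted by gray", {
  h <- make_hist("10" = 5, "11" = 3, "50" = 4, "51" = 6)
  p <- dpc_profile(h, 2)
  dg <- decision_graph(p)
  expect_equal(dg$gray, c(10, 11, 50, 51))
  expect_equal(dg$rho, c(8, 8, 10, 10))
  expect_named(dg, c("gray", "rho", "delta", "gamma"))
  f <- tempfile(fileext = ".csv")
  decision_graph(p, f)
  expect_identical(readLines(f)[1], "gray,rho,delta,gamma")
  expect_equal(nrow(decision_graph(dpc_profile(make_hist("3" = 2), 1))), 1L)
})
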