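make_partition <- function(values, high) {
  # wrap a value vector as a 1-voxel-deep volume with a two-class partition
  n <- length(values)
  dims <- c(n, 1L, 1L)
  vol <- voxel_volume(array(values, dim = dims), diag(4), "ms")
  hm <- array(high, dim = dims)
  list(volume = vol,
       partition = structure(list(
         tn_volume = voxel_volume(array(2, dim = dims), diag(4), "ratio"),
         high_mask = mask_volume(hm, diag(4)),
         low_mask = mask_volume(array(!high, dim = dims), diag(4)),
         n_high = sum(high), n_low = sum(!high), cutoff = 1.5),
         class = "tn_partition"))
}

test_that("binning is half-open with B spanning the pooled range", {
  w <- make_partition(c(50, 149), c(TRUE, TRUE))
  # both voxels high; a low voxel is needed too, put it in the second bin
  w <- make_partition(c(50, 149, 120), c(TRUE, TRUE, FALSE))
  pair <- build_histogram_pair(w$volume, w$partition, 100)
  expect_equal(pair$bin_left, c(0, 100))
  expect_equal(pair$n_high, c(1L, 1L))
  expect_equal(pair$n_low, c(0L, 1L))
  expect_identical(attr(pair, "B"), 2L)

  # a value exactly on an edge belongs to the right-hand bin
  w2 <- make_partition(c(100, 10), c(TRUE, FALSE))
  pair2 <- build_histogram_pair(w2$volume, w2$partition, 100)
  expect_equal(pair2$n_high, c(0L, 1L))

  # interior empty bins still count toward B
  w3 <- make_partition(c(50, 450), c(TRUE, FALSE))
  pair3 <- build_histogram_pair(w3$volume, w3$partition, 100)
  expect_identical(attr(pair3, "B"), 5L)
})

test_that("histogram totals are conserved", {
  set.seed(21)
  vals <- runif(500, 800, 3500)
  high <- runif(500) < 0.4
  w <- make_partition(vals, high)
  pair <- build_histogram_pair(w$volume, w$partition, 100)
  expect_identical(sum(pair$n_high), attr(pair, "NH"))
  expect_identical(sum(pair$n_low), attr(pair, "NL"))
  expect_identical(sum(pair$n_high) + sum(pair$n_low), 500L)
})

test_that("non-finite voxels are dropped with a message", {
  vals <- c(100, NA, 250, Inf, 400)
  w <- make_partition(vals, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_message(pair <- build_histogram_pair(w$volume, w$partition, 100),
                 "2 non-finite")
  expect_identical(attr(pair, "NH") + attr(pair, "NL"), 3L)
})

test_that("likeliness matches hand-computed values at the boundaries", {
  # equal per-class proportions cancel
  pair <- pair_from_counts(c(10), c(20))
  attr(pair, "NH") <- 100L; attr(pair, "NL") <- 200L
  expect_equal(compute_likeliness(pair)$likeliness, 0)
  # one-sided bins sit at +/-1; (0.3 - 0.1)/(0.3 + 0.1) = 0.5
  pair2 <- pair_from_counts(c(30, 70, 0), c(10, 40, 50))
  prof2 <- compute_likeliness(pair2)
  expect_equal(prof2$likeliness[1], 0.5)
  expect_equal(prof2$likeliness[3], -1)
  pair3 <- pair_from_counts(c(5, 5), c(0, 10))
  expect_equal(compute_likeliness(pair3)$likeliness[1], 1)
})

test_that("likeliness equals the exact rational oracle on random pairs", {
  set.seed(33)
  for (rep in 1:200) {
    nb <- sample(2:10, 1)
    nh <- rpois(nb, sample(1:50, 1))
    nl <- rpois(nb, sample(1:50, 1))
    if (sum(nh) == 0) nh[1] <- 1L
    if (sum(nl) == 0) nl[1] <- 1L
    pair <- pair_from_counts(nh, nl)
    got <- compute_likeliness(pair)$likeliness
    want <- likeliness_oracle(nh, nl, sum(nh), sum(nl))
    expect_identical(is.na(got), is.na(want))
    expect_lt(max(abs(got - want), 0, na.rm = TRUE), 1e-12)
  }
})

test_that("likeliness is antisymmetric and scale-invariant", {
  set.seed(34)
  for (rep in 1:50) {
    nh <- rpois(8, 20); nl <- rpois(8, 30)
    if (sum(nh) == 0) nh[1] <- 1L
    if (sum(nl) == 0) nl[1] <- 1L
    l1 <- compute_likeliness(pair_from_counts(nh, nl))$likeliness
    l2 <- compute_likeliness(pair_from_counts(nl, nh))$likeliness
    expect_equal(l1, -l2)
    k <- sample(2:7, 1)
    l3 <- compute_likeliness(pair_from_counts(k * nh, k * nl))$likeliness
    expect_equal(l1, l3)
  }
})

test_that("likeliness is non-decreasing in the high count", {
  nl <- 10L; NL <- 100L
  vals <- vapply(0:40, function(nh) {
    pair <- pair_from_counts(c(nh, 50 - nh), c(nl, NL - nl))
    compute_likeliness(pair)$likeliness[1]
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("exclusion threshold is 0.1 / B on the summed proportions", {
  # B = 20 bins; a bin summing to just under 0.005 goes, just over stays
  nh <- rep(50L, 20); nl <- rep(50L, 20)
  NH <- sum(nh); NL <- sum(nl)       # 1000 each; per-bin mass 0.1 >> 0.005
  pair <- pair_from_counts(nh, nl)
  prof <- apply_exclusion_rule(pair, compute_likeliness(pair))
  expect_true(all(prof$included))    # uniform pair excludes nothing: 2/B >= 0.1/B
  nh[3] <- 2L; nl[3] <- 2L           # mass 4/1000 = 0.004 < 0.005
  pair2 <- pair_from_counts(nh, nl)
  prof2 <- apply_exclusion_rule(pair2, compute_likeliness(pair2))
  expect_false(prof2$included[3])
  expect_true(is.na(prof2$likeliness[3]))
})

test_that("exclusion matches the rule for random bin counts B in [5, 200]", {
  set.seed(35)
  for (rep in 1:60) {
    B <- sample(5:200, 1)
    nh <- rpois(B, 3); nl <- rpois(B, 3)
    if (sum(nh) == 0) nh[1] <- 1L
    if (sum(nl) == 0) nl[1] <- 1L
    pair <- pair_from_counts(nh, nl)
    prof <- apply_exclusion_rule(pair, compute_likeliness(pair))
    mass <- nh / sum(nh) + nl / sum(nl)
    expect_identical(prof$included, mass >= 0.1 / B)
  }
})

test_that("bins empty in both classes are excluded outright", {
  pair <- pair_from_counts(c(5, 0, 5), c(5, 0, 5))
  prof <- apply_exclusion_rule(pair, compute_likeliness(pair))
  expect_false(prof$included[2])
  expect_true(is.na(prof$likeliness[2]))
})

test_that("positive range is the longest run of positive included bins", {
  mk_prof <- function(lik, included = rep(TRUE, length(lik)),
                      nh = rep(10L, length(lik)),
                      nl = rep(10L, length(lik))) {
    structure(data.frame(
      bin_left = (seq_along(lik) - 1) * 100, bin_right = seq_along(lik) * 100,
      n_high = nh, n_low = nl, likeliness = lik, included = included),
      NH = sum(nh), NL = sum(nl), B = length(lik), bin_width = 100,
      bin_origin = 0, units = "ms",
      class = c("likeliness_profile", "data.frame"))
  }
  expect_equal(extract_positive_range(mk_prof(c(-0.2, 0.1, 0.4, -0.1))),
               c(100, 300))
  expect_identical(extract_positive_range(mk_prof(c(-0.5, 0, -1))),
                   numeric(0))
  # runs of length 2 and 3: the longer one wins regardless of order
  expect_equal(extract_positive_range(
    mk_prof(c(0.9, 0.9, -1, 0.1, 0.1, 0.1))), c(300, 600))
  # equal lengths: larger summed included mass wins
  tie <- mk_prof(c(0.5, 0.5, -1, 0.5, 0.5),
                 nh = c(1L, 1L, 1L, 40L, 40L, 1L)[1:5],
                 nl = c(1L, 1L, 1L, 40L, 40L, 1L)[1:5])
  expect_equal(extract_positive_range(tie), c(300, 500))
  # an excluded bin breaks a run
  broken <- mk_prof(c(0.5, 0.5, 0.5, -1), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(extract_positive_range(broken), c(0, 100))
})

test_that("tumor-load probabilities are the equal-prior posterior per bin", {
  prof <- structure(data.frame(
    bin_left = c(0, 100, 200, 300), bin_right = c(100, 200, 300, 400),
    n_high = c(10L, 10L, 10L, 0L), n_low = c(10L, 10L, 10L, 5L),
    likeliness = c(0, 1, 0.5, NA), included = c(TRUE, TRUE, TRUE, FALSE)),
    NH = 30L, NL = 35L, B = 4L, bin_width = 100, bin_origin = 0,
    units = "ms", class = c("likeliness_profile", "data.frame"))
  map <- voxel_volume(array(c(50, 150, 250, 350, 950), dim = c(5, 1, 1)),
                      diag(4), "ms")
  out <- synthesize_tumor_load_map(map, prof)
  expect_equal(as.numeric(out$probability$data),
               c(0.5, 1, 0.75, 0, 0))
  expect_identical(as.logical(out$valid$data),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(out$probability$units, "probability")
  wrong <- voxel_volume(array(1, dim = c(1, 1, 1)), diag(4), "mm2_per_s")
  expect_error(synthesize_tumor_load_map(wrong, prof),
               class = "relaxo_units_mismatch")
})

test_that("profiles round-trip through CSV", {
  pair <- pair_from_counts(c(3, 9, 1), c(5, 2, 8))
  prof <- apply_exclusion_rule(pair, compute_likeliness(pair))
  f <- file.path(tempdir(), "profile.csv")
  write_profile(prof, f)
  back <- read_profile(f)
  expect_equal(back$likeliness, prof$likeliness)
  expect_equal(attr(back, "NH"), attr(prof, "NH"))
  expect_equal(attr(back, "bin_width"), attr(prof, "bin_width"))
})
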