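test_that("relative collection time reproduces every defined printed row", {
  # (strain X, chimera, strain Y) -> printed 2-decimal value
  rows <- list(
    ab1 = c(310, 310, 320, 0.00), ab2 = c(300, 285, 285, 0.00),
    cd1 = c(285, 285, 300, 0.00), cd2 = c(270, 270, 240, 1.00),
    cd3 = c(257, 276, 290, 0.58), ef1 = c(332, 292, 302, -0.33),
    ef2 = c(312, 297, 280, 0.53), ef3 = c(371, 344, 322, 0.45),
    gh1 = c(240, 248, 260, 0.40), gh2 = c(234, 254, 278, 0.45),
    gh3 = c(273, 280, 286, 0.54))
  for (nm in names(rows)) {
    r <- rows[[nm]]
    out <- relative_collection_time(r[1], r[2], r[3])
    expect_true(out$defined, info = nm)
    expect_equal(out$value, r[4], info = nm)
  }
})

test_that("equal strain times make the statistic undefined, not an error", {
  out <- relative_collection_time(270, 280, 270)
  expect_false(out$defined)
  expect_true(is.na(out$value))
  expect_error(relative_collection_time(-1, 2, 3), "positive")
})

test_that("time-point labels recode to their ordinal position", {
  labs <- c("00", "01", "02", "03", "04", "05", "06", "07", "08", "09",
            "10", "11", "12", "14", "16", "18", "20", "22", "24")
  hr <- recode_timepoints(labs)
  expect_equal(unname(hr[c("00", "11", "24")]), c(1, 12, 19))
  expect_equal(length(hr), 19)
  expect_error(recode_timepoints(c("a", "a")), "duplicate")
})

test_that("distance profile averages per-replicate Euclidean distances", {
  withr::with_seed(10, {
    genes <- paste0("g", 1:30)
    ref <- matrix(rnorm(30 * 6), 30,
                  dimnames = list(genes, paste0("t", 1:3, "_r", rep(1:2, 3))))
    ref_meta <- data.frame(sample = colnames(ref),
                           time_index = rep(1:3, each = 2))
    # reorder columns so sample names, not positions, drive the lookup
    ref_meta <- ref_meta[c(1, 3, 5, 2, 4, 6), ]
    q <- matrix(rnorm(30 * 2), 30, dimnames = list(genes, c("q1", "q2")))
    prof <- reference_distance_profile(q, ref, ref_meta)
    # oracle: direct mean of the two distances
    for (s in 1:2) for (t in 1:3) {
      reps <- ref_meta$sample[ref_meta$time_index == t]
      d <- mean(vapply(reps, function(rr) sqrt(sum((q[, s] - ref[, rr])^2)),
                       numeric(1)))
      expect_equal(prof$distance[s, t], d)
    }
  })
})

test_that("a query equal to a single-replicate reference has distance zero there", {
  genes <- paste0("g", 1:10)
  ref <- matrix(rnorm(40), 10, dimnames = list(genes, paste0("t", 1:4)))
  meta <- data.frame(sample = colnames(ref), time_index = 1:4)
  q <- ref[, 3, drop = FALSE]; colnames(q) <- "q"
  prof <- reference_distance_profile(q, ref, meta)
  expect_equal(prof$distance[1, 3], 0)
  expect_true(all(prof$distance[1, -3] > 0))
})

test_that("distance profile is gene-order invariant and scales linearly", {
  withr::with_seed(11, {
    genes <- paste0("g", 1:25)
    ref <- matrix(rnorm(50), 25, dimnames = list(genes, c("t1", "t2")))
    meta <- data.frame(sample = c("t1", "t2"), time_index = 1:2)
    q <- matrix(rnorm(25), 25, dimnames = list(genes, "q"))
    p1 <- reference_distance_profile(q, ref, meta)
    shuffle <- sample(genes)
    p2 <- reference_distance_profile(q[shuffle, , drop = FALSE],
                                     ref[shuffle, ], meta)
    expect_equal(p1$distance, p2$distance)
    p3 <- reference_distance_profile(3 * q, 3 * ref, meta)
    expect_equal(p3$distance, 3 * p1$distance)
    # constant genes carry no signal: flat profile
    qc <- ref * 0 + 1
    colnames(qc) <- colnames(ref)
    pc <- reference_distance_profile(qc[, 1, drop = FALSE] * 0 + 5,
                                     qc * 0 + 2, meta)
    expect_equal(diff(range(pc$distance)), 0)
    expect_error(reference_distance_profile(
      matrix(1, 2, 1, dimnames = list(c("a", "b"), "q")),
      matrix(1, 2, 1, dimnames = list(c("c", "d"), "t1")), meta),
      "no genes")
  })
})
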