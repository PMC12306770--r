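test_that("tolerance windows govern co-clustering", {
  f <- tibble::tibble(
    digest = c("d1", "d2", "d3"),
    mz = c(500.0000, 500.0030, 500.0030),
    rt_min = c(1.00, 1.05, 1.25),
    mode = "negative"
  )
  al <- align_ions(f)
  # 6.0 ppm apart and 0.05 min: together; 0.25 min away: separate
  expect_equal(al$cluster[1], al$cluster[2])
  expect_false(al$cluster[1] == al$cluster[3])

  far_rt <- tibble::tibble(
    digest = c("d1", "d2"), mz = c(500, 500),
    rt_min = c(1.0, 1.2), mode = "negative"
  )
  expect_equal(dplyr::n_distinct(align_ions(far_rt)$cluster), 2L)
})

test_that("mixed ionization modes require an explicit override", {
  f <- tibble::tibble(
    digest = c("d1", "d2"), mz = c(500, 500.001),
    rt_min = c(1, 1), mode = c("negative", "positive")
  )
  expect_error(align_ions(f), "mix")
  al <- align_ions(f, allow_mixed_mode = TRUE)
  # aligned separately per mode: never one cluster across modes
  expect_equal(dplyr::n_distinct(al$cluster), 2L)
})

test_that("alignment equals brute-force single linkage on random features", {
  withr::with_seed(55, {
    for (rep in 1:5) {
      n <- sample(40:100, 1)
      base <- runif(n %/% 2, 60, 1600)
      f <- tibble::tibble(
        digest = sample(c("d1", "d2", "d3"), n, replace = TRUE),
        mz = sample(base, n, replace = TRUE) *
          (1 + runif(n, -10e-6, 10e-6)),
        rt_min = round(runif(n, 0, 3), 2),
        mode = "negative"
      )
      got <- align_ions(f)$cluster
      want <- oracle_align(f)
      expect_true(same_partition(got, want))
    }
  })
})

test_that("alignment output is invariant to input order", {
  withr::with_seed(56, {
    f <- tibble::tibble(
      digest = sample(c("d1", "d2"), 60, replace = TRUE),
      mz = runif(60, 60, 1600) * (1 + runif(60, -6e-6, 6e-6)),
      rt_min = round(runif(60, 0, 3), 2),
      mode = "negative"
    )
    perm <- sample(nrow(f))
  })
  a <- align_ions(f)
  b <- align_ions(f[perm, ])
  b_unperm <- b[order(perm), ]
  expect_equal(a$cluster, b_unperm$cluster)
})

test_that("category fractions per m/z bin sum to one", {
  ds <- generate_dataset(digest_scenario(seed = 21))
  res <- classify_table(ds)
  dist <- mz_category_distribution(res)
  sums <- tapply(dist$fraction, dist$bin, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # a single bin covering everything reproduces the overall proportions
  one <- mz_category_distribution(res, bin_edges = c(0, Inf))
  overall <- res$counts[c("decreased", "bell", "increased")]
  expect_equal(
    stats::setNames(one$n, one$category)[names(overall)],
    overall
  )
  expect_error(mz_category_distribution(res, bin_edges = c(400, 200)),
               "ascending")
})

test_that("default m/z bins include the 1,600-1,800 top bin", {
  edges <- default_mz_bins()
  expect_equal(utils::tail(edges, 2), c(1600, 1800))
  expect_equal(edges[1], 50)
})

test_that("sharing fractions reflect the planted cross-digest structure", {
  ds <- generate_dataset(digest_scenario(seed = 23))
  res <- classify_table(ds)
  inc <- dplyr::filter(res$ions, category == "increased")
  al <- align_ions(ion_features(ds))
  sharing <- sharing_by_mz(dplyr::semi_join(al, inc, by = "ion_id"))
  low <- sharing$shared_fraction[sharing$bin_low == 50]
  high <- sharing$shared_fraction[sharing$bin_low == 1400]
  # shared terminal monomers dominate the low-mass bin; high-mass terminal
  # fragments are digest-specific
  expect_gte(low, high)
  expect_gt(low, 0.5)
  expect_true(all(sharing$shared_fraction >= 0 & sharing$shared_fraction <= 1))
})

test_that("every ion unique to one digest gives zero sharing", {
  f <- tibble::tibble(
    digest = c("d1", "d2", "d3"),
    mz = c(100, 500, 900), rt_min = c(1, 2, 3), mode = "negative"
  )
  sharing <- sharing_by_mz(align_ions(f))
  expect_true(all(sharing$shared_fraction == 0))
})
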