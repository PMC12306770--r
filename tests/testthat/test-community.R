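test_that("Bray-Curtis follows its formula and bounds", {
  expect_equal(bray_curtis(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(0.7, 0.3, 0), c(0.2, 0.3, 0.5)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 0), c(1, 0, 0)), "universe")

  withr::with_seed(77, {
    for (rep in 1:20) {
      u <- runif(8)
      v <- runif(8)
      bc <- bray_curtis(u, v)
      expect_equal(bc, bray_curtis(v, u))
      expect_gte(bc, 0)
      expect_lte(bc, 1)
    }
  })
})

test_that("Bray-Curtis agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  withr::with_seed(78, {
    mat <- matrix(runif(40), nrow = 4)
    ours <- c(
      bray_curtis(mat[1, ], mat[2, ]), bray_curtis(mat[1, ], mat[3, ]),
      bray_curtis(mat[1, ], mat[4, ]), bray_curtis(mat[2, ], mat[3, ]),
      bray_curtis(mat[2, ], mat[4, ]), bray_curtis(mat[3, ], mat[4, ])
    )
    theirs <- as.vector(vegan::vegdist(mat, method = "bray"))
    expect_equal(ours, theirs, tolerance = 1e-12)
  })
})

test_that("pairwise dissimilarities cover every sample pair", {
  tab <- tibble::tibble(
    species = c("a", "b", "c"),
    s1 = c(0.7, 0.3, 0), s2 = c(0.2, 0.3, 0.5), s3 = c(0.1, 0.1, 0.8)
  )
  pairs <- bray_curtis_pairs(tab)
  expect_equal(nrow(pairs), 3L)
  expect_equal(
    pairs$bray_curtis[pairs$sample_1 == "s1" & pairs$sample_2 == "s2"], 0.5
  )
})

test_that("fold changes floor the inoculum and mask absences", {
  tab <- tibble::tibble(
    species = c("V. gigantis", "steady", "vanishing", "newcomer"),
    inoculum = c(0.01, 0.2, 0.1, 0),
    eps1 = c(0.07, 0.2, 0, 0.05)
  )
  fc <- fold_changes(tab, inoculum = "inoculum")
  expect_equal(
    fc$log2_fc[fc$species == "V. gigantis"], log2(7), tolerance = 1e-12
  )
  expect_equal(round(fc$log2_fc[fc$species == "V. gigantis"], 3), 2.807)
  expect_equal(fc$log2_fc[fc$species == "steady"], 0)
  expect_true(is.na(fc$log2_fc[fc$species == "vanishing"]))
  expect_true(fc$absent[fc$species == "vanishing"])
  # species undetected in the inoculum hit the read-depth floor
  expect_equal(
    fc$log2_fc[fc$species == "newcomer"], log2(0.05 * 30000)
  )
  expect_error(fold_changes(tab, inoculum = "nope"), "unknown inoculum")
})

test_that("fold changes are invariant to uniform rescaling of both samples", {
  tab <- tibble::tibble(
    species = letters[1:4],
    inoculum = c(0.1, 0.2, 0.3, 0.4),
    cond = c(0.4, 0.3, 0.2, 0.1)
  )
  f1 <- fold_changes(tab, "inoculum", floor = 1e-9)
  tab2 <- dplyr::mutate(
    tab, inoculum = inoculum * 0.5, cond = cond * 0.5
  )
  f2 <- fold_changes(tab2, "inoculum", floor = 1e-9)
  expect_equal(f1$log2_fc, f2$log2_fc)
})

test_that("Ward clustering merges identical rows first", {
  fc <- tibble::tibble(
    species = rep(c("a", "b", "c", "d"), each = 2),
    condition = rep(c("x", "y"), 4),
    log2_fc = c(1, 1, 5, -3, 1, 1, -4, 6)
  )
  wc <- ward_cluster(fc)
  first <- sort(wc$hclust$merge[1, ])
  labs <- wc$labels
  expect_setequal(labs[-first], c("a", "c"))
})

test_that("Ward merges equal the exhaustive greedy oracle on small matrices", {
  withr::with_seed(88, {
    for (rep in 1:5) {
      n <- sample(5:8, 1)
      mat <- matrix(rnorm(n * 6), nrow = n)
      rownames(mat) <- paste0("sp", seq_len(n))
      fc <- tibble::as_tibble(as.data.frame(mat)) |>
        dplyr::mutate(species = rownames(mat)) |>
        tidyr::pivot_longer(-species, names_to = "condition",
                            values_to = "log2_fc")
      wc <- ward_cluster(fc)
      want <- oracle_ward(wc$data)
      got_sets <- hclust_merge_sets(wc$hclust)
      expect_equal(got_sets, want$merges)
      expect_equal(wc$hclust$height, want$heights, tolerance = 1e-9)
    }
  })
})

test_that("Ward merge heights are non-decreasing and masked rows error", {
  withr::with_seed(89, {
    mat <- matrix(rnorm(48), nrow = 8)
  })
  fc <- tibble::tibble(
    species = rep(paste0("sp", 1:8), each = 6),
    condition = rep(paste0("c", 1:6), 8),
    log2_fc = as.vector(t(mat))
  )
  wc <- ward_cluster(fc)
  expect_true(all(diff(wc$hclust$height) >= -1e-12))

  fc$log2_fc[fc$species == "sp1"] <- NA
  expect_error(ward_cluster(fc), "no finite fold change")
})

test_that("tree topology is invariant to row order and exports to newick", {
  withr::with_seed(90, {
    mat <- matrix(rnorm(30), nrow = 6)
  })
  fc <- tibble::tibble(
    species = rep(paste0("sp", 1:6), each = 5),
    condition = rep(paste0("c", 1:5), 6),
    log2_fc = as.vector(t(mat))
  )
  wc1 <- ward_cluster(fc)
  perm <- c(4, 1, 6, 2, 5, 3)
  fc2 <- dplyr::arrange(fc, match(species, paste0("sp", perm)))
  wc2 <- ward_cluster(fc2)
  t1 <- ape::read.tree(text = as_newick(wc1))
  t2 <- ape::read.tree(text = as_newick(wc2))
  expect_true(ape::all.equal.phylo(t1, t2, use.edge.length = FALSE))

  path <- withr::local_tempfile(fileext = ".nwk")
  as_newick(wc1, path)
  expect_true(file.exists(path))
})

test_that("top taxa keep the remainder as other", {
  withr::with_seed(91, {
    ab <- runif(10)
  })
  tab <- tibble::tibble(species = paste0("sp", 1:10), s1 = ab / sum(ab))
  top <- top_taxa(tab, n = 6)
  expect_equal(nrow(top), 7L)
  expect_equal(sum(top$abundance), 1)
  expect_equal(top$species[7], "other")

  all_rows <- top_taxa(tab, n = 20)
  expect_equal(all_rows$abundance[all_rows$species == "other"], 0)

  tied <- tibble::tibble(species = c("b", "a", "c"), s1 = c(1, 1, 1) / 3)
  expect_equal(top_taxa(tied, n = 2)$species[1:2], c("a", "b"))
})

test_that("abundance normalization accepts partial sums and rejects zeros", {
  tab <- tibble::tibble(species = c("a", "b"), s1 = c(0.3, 0.3))
  norm <- normalize_abundance(tab)
  expect_equal(sum(norm$s1), 1)
  expect_error(
    normalize_abundance(tibble::tibble(species = "a", s1 = 0)),
    "zero"
  )
})
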