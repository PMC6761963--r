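test_that("pair gaps bin as edge-to-edge distances", {
  isl <- tibble::tibble(chrom = "chrI", start = c(0, 500000),
                        end = c(10000, 510000))
  h <- pair_gap_distribution(isl)
  expect_equal(h$bin_start, 400000)
  expect_equal(h$n_pairs, 1L)
  # overlapping islands have gap zero
  ovl <- tibble::tibble(chrom = "chrI", start = c(0, 5000),
                        end = c(10000, 20000))
  h0 <- pair_gap_distribution(ovl)
  expect_equal(h0$bin_start, 0)
})

test_that("pair-gap histogram equals an all-pairs loop", {
  withr::with_seed(3, {
    n <- 20
    isl <- tibble::tibble(chrom = sample(c("chrI", "chrII"), n, TRUE),
                          start = floor(runif(n, 0, 5e6)))
    isl$end <- isl$start + floor(runif(n, 1e4, 1e5))
  })
  h <- pair_gap_distribution(isl)
  gaps <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    if (isl$chrom[i] == isl$chrom[j]) {
      gaps <- c(gaps, max(0, max(isl$start[i], isl$start[j]) -
                            min(isl$end[i], isl$end[j])))
    }
  }
  expect_equal(sum(h$n_pairs), length(gaps))
  for (k in seq_len(nrow(h))) {
    expect_equal(h$n_pairs[k],
                 sum(gaps >= h$bin_start[k] & gaps < h$bin_end[k]))
  }
  expect_equal(count_close_pairs(isl), sum(gaps < 1e6))
})

test_that("close pairs count same-chromosome pairs within 1 Mb", {
  isl <- tibble::tibble(chrom = "chrI", start = c(0, 3e5, 9e5),
                        end = c(1e5, 4e5, 1e6))
  expect_equal(count_close_pairs(isl), 3L)    # C(3, 2)
  far <- tibble::tibble(chrom = c("chrI", "chrII", "chrIII"),
                        start = c(0, 0, 0), end = c(1e5, 1e5, 1e5))
  expect_equal(count_close_pairs(far), 0L)
})

test_that("per-chromosome count variance uses the full layout", {
  g <- genome_layout(c("chrI", "chrII", "chrIII"), rep(1e6, 3))
  isl <- tibble::tibble(chrom = c("chrI", "chrI", "chrI", "chrII", "chrIII",
                                  "chrIII"),
                        start = seq(0, 5e5, 1e5))
  isl$end <- isl$start + 1e4
  expect_equal(chromosome_count_variance(isl, g), stats::var(c(3, 1, 2)))
  expect_equal(chromosome_count_variance(isl, g), 1.0)
  # zero-count chromosomes are included
  g4 <- genome_layout(paste0("chr", as.roman(1:4)), rep(1e6, 4))
  expect_equal(chromosome_count_variance(isl, g4), stats::var(c(3, 1, 2, 0)))
  # equal counts give zero
  eq <- tibble::tibble(chrom = g$chrom, start = 0, end = 1e4)
  expect_equal(chromosome_count_variance(eq, g), 0)
  expect_error(chromosome_count_variance(isl, genome_layout("chrI", 1e6)),
               "two chromosomes")
})

test_that("archipelagos form by single linkage below 1 Mb", {
  isl <- tibble::tibble(chrom = "chrI",
                        start = c(0, 6e5, 15e5),     # A-B 0.5, B-C 0.8 Mb
                        end = c(1e5, 7e5, 16e5))
  cl <- archipelago_clusters(isl)
  expect_equal(nrow(cl), 3)
  expect_equal(length(unique(cl$cluster)), 1)
  # isolated islands yield no clusters
  iso <- tibble::tibble(chrom = c("chrI", "chrII"), start = c(0, 0),
                        end = c(1e4, 1e4))
  expect_equal(nrow(archipelago_clusters(iso)), 0)
})

test_that("archipelago partitions match union-find and close-pair counts", {
  withr::with_seed(14, {
    n <- 25
    isl <- tibble::tibble(chrom = sample(paste0("chr", as.roman(1:4)), n, TRUE),
                          start = floor(runif(n, 0, 1e7)))
    isl$end <- isl$start + floor(runif(n, 1e4, 1e5))
  })
  cl <- archipelago_clusters(isl)
  orc <- oracle_cluster(isl$chrom, isl$start, isl$end, 1e6, strict = TRUE)
  sizes <- table(orc)
  big <- sizes[sizes >= 2]
  expect_equal(nrow(cl), sum(big))
  expect_equal(length(unique(cl$cluster)), length(big))

  # on transitive fixtures (clusters are cliques), close pairs = sum C(s,2)
  clique <- tibble::tibble(
    chrom = rep(c("chrI", "chrII"), c(3, 2)),
    start = c(0, 2e5, 4e5, 0, 9e5))
  clique$end <- clique$start + 1e5
  cc <- archipelago_clusters(clique)
  per_cluster <- table(cc$cluster)
  expect_equal(sum(choose(per_cluster, 2)), count_close_pairs(clique))
})

test_that("strata are quintiles of 1 Mb mean rho with coordinate ties", {
  g <- genome_layout("chrI", 5e6)
  map <- tibble::tibble(chrom = "chrI", start = seq(0, 5e6 - 1e4, 1e4))
  map$end <- map$start + 1e4
  map$rho <- rep(c(5, 1, 4, 2, 3), each = 100)   # distinct 1 Mb means
  st <- build_strata(map, g)
  expect_equal(nrow(st), 5)
  expect_equal(st$bin, c(5L, 1L, 4L, 2L, 3L))
  # constant rho: ties broken by coordinate order
  map$rho <- 1
  st2 <- build_strata(map, g)
  expect_equal(st2$bin, 1:5)
  # 100 windows split 20 per bin
  g2 <- genome_layout("chrI", 1e8)
  map2 <- tibble::tibble(chrom = "chrI", start = seq(0, 1e8 - 1e4, 1e4))
  map2$end <- map2$start + 1e4
  withr::with_seed(2, map2$rho <- runif(nrow(map2)))
  st3 <- build_strata(map2, g2)
  expect_equal(unname(table(st3$bin)), rep(20L, 5), ignore_attr = TRUE)
})

test_that("islands take the bin of their larger part; ties go low", {
  g <- genome_layout("chrI", 3e6)
  strata <- tibble::tibble(chrom = "chrI", start = c(0, 1e6, 2e6),
                           end = c(1e6, 2e6, 3e6), mean_rho = c(1, 2, 3),
                           bin = c(1L, 2L, 3L))
  inside <- tibble::tibble(chrom = "chrI", start = 1.2e6, end = 1.4e6)
  expect_equal(assign_island_bins(inside, strata)$islands$bin, 2L)
  # 70/30 split across the chrI 1 Mb boundary: bin of the 70% side,
  # and the 30% window is relabelled for the shuffle geometry
  split70 <- tibble::tibble(chrom = "chrI", start = 0.93e6, end = 1.63e6)
  ab <- assign_island_bins(split70, strata)
  expect_equal(ab$islands$bin, 2L)
  expect_equal(ab$strata$bin, c(2L, 2L, 3L))
  # exact 50/50: lower-coordinate side wins
  split50 <- tibble::tibble(chrom = "chrI", start = 0.9e6, end = 1.1e6)
  expect_equal(assign_island_bins(split50, strata)$islands$bin, 1L)
})

test_that("shuffling conserves lengths and respects strata and bounds", {
  g <- genome_layout(c("chrI", "chrII"), c(4e6, 2e6))
  withr::with_seed(6, {
    chrom <- sample(g$chrom, 12, TRUE)
    len <- floor(runif(12, 2e4, 1e5))
    start <- floor(runif(12) * (g$length[match(chrom, g$chrom)] - len))
    isl <- tibble::tibble(chrom = chrom, start = start, end = start + len)
  })
  sh <- shuffle_islands(isl, g, seed = 31)
  expect_equal(sort(sh$end - sh$start), sort(isl$end - isl$start))
  expect_true(all(sh$start >= 0))
  expect_true(all(sh$end <= g$length[match(sh$chrom, g$chrom)]))
  # no overlaps
  o <- dplyr::arrange(sh, .data$chrom, .data$start)
  same <- o$chrom[-1] == o$chrom[-nrow(o)]
  expect_true(all(!same | o$start[-1] >= o$end[-nrow(o)]))
  # determinism
  expect_identical(sh, shuffle_islands(isl, g, seed = 31))

  # stratified: every island stays in regions of its own bin
  map <- tibble::tibble(
    chrom = rep(g$chrom, times = g$length / 1e4),
    start = c(seq(0, 4e6 - 1e4, 1e4), seq(0, 2e6 - 1e4, 1e4)))
  map$end <- map$start + 1e4
  withr::with_seed(9, map$rho <- runif(nrow(map)))
  st <- build_strata(map, g, window = 1e6, n_bins = 3)
  ab <- assign_island_bins(isl, st)
  shs <- shuffle_islands(isl, g, strata = st, seed = 32)
  expect_equal(sort(shs$end - shs$start), sort(isl$end - isl$start))
  for (i in seq_len(nrow(shs))) {
    w <- ab$strata[ab$strata$chrom == shs$chrom[i] &
                     ab$strata$start < shs$end[i] &
                     ab$strata$end > shs$start[i], ]
    expect_true(all(w$bin == shs$bin[i]))
  }
})

test_that("a forced placement lands at the only feasible spot", {
  g <- genome_layout("chrI", 50000)
  isl <- tibble::tibble(chrom = "chrI", start = 0, end = 50000)
  sh <- shuffle_islands(isl, g, seed = 1)
  expect_equal(sh$start, 0)
  expect_equal(sh$end, 50000)
  # infeasible layouts error rather than silently relaxing
  too_big <- tibble::tibble(chrom = "chrI", start = c(0, 0),
                            end = c(40000, 30000))
  expect_error(shuffle_islands(too_big, g, seed = 1, max_retries = 50),
               "feasible")
})

test_that("permutation tests are deterministic and calibrated in shape", {
  g <- genome_layout(paste0("chr", as.roman(1:6)), rep(2e7, 6))
  withr::with_seed(44, {
    isl <- tibble::tibble(chrom = sample(g$chrom, 15, TRUE),
                          start = floor(runif(15, 0, 1.8e7)))
    isl$end <- isl$start + 5e4
  })
  pt <- permutation_test(isl, g, "close_pairs", n = 100, seed = 5)
  pt2 <- permutation_test(isl, g, "close_pairs", n = 100, seed = 5)
  expect_identical(pt$null_draws, pt2$null_draws)
  expect_identical(pt$p_value, pt2$p_value)
  expect_equal(length(pt$null_draws), 100)
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  expect_equal(pt$expected, mean(pt$null_draws))
  # tidy/glance accessors
  expect_equal(nrow(tidy(pt)), 100)
  expect_equal(glance(pt)$observed, pt$observed)

  # one-bin strata reproduce the unstratified null exactly
  map <- tibble::tibble(chrom = rep(g$chrom, each = 2000),
                        start = rep(seq(0, 2e7 - 1e4, 1e4), 6))
  map$end <- map$start + 1e4
  map$rho <- 1
  st1 <- build_strata(map, g, n_bins = 1)
  pt_st <- permutation_test(isl, g, "close_pairs", strata = st1,
                            n = 100, seed = 5)
  expect_identical(pt$null_draws, pt_st$null_draws)
})

test_that("null close-pair counts fall as the genome grows", {
  isl <- tibble::tibble(chrom = "chrI", start = seq(0, 29) * 1e5)
  isl$end <- isl$start + 5e4
  g_small <- genome_layout(paste0("c", 1:10), rep(2e7, 10))
  g_big <- genome_layout(paste0("c", 1:10), rep(4e7, 10))
  isl$chrom <- "c1"
  pt_s <- permutation_test(isl, g_small, "close_pairs", n = 150, seed = 3)
  pt_b <- permutation_test(isl, g_big, "close_pairs", n = 150, seed = 3)
  expect_gt(pt_s$expected, pt_b$expected)
})
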