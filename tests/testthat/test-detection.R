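test_that("scan_windows counts markers and averages frequencies", {
  # 10 markers at 0.9 inside one 10 Kb span qualify; their windows mean 0.9
  pos <- seq(50010, 59010, by = 1000)
  mk <- make_marker_table(pos, matrix(0.9, 10, 1), "F01")
  w <- scan_windows(mk, "F01")
  expect_gt(nrow(w), 0)
  expect_true(all(w$n_markers >= 10))
  expect_true(all(abs(w$mean_fresh_freq - 0.9) < 1e-12))
  expect_true(any(w$n_markers == 10))

  # 9 markers never qualify under "at least 10"
  mk9 <- make_marker_table(pos[1:9], matrix(0.9, 9, 1), "F01")
  expect_equal(nrow(scan_windows(mk9, "F01")), 0)
})

test_that("scan_windows agrees with a brute-force recount", {
  withr::with_seed(17, {
    pos <- sort(sample.int(1e5, 300))
    fr <- runif(300)
    fr[sample.int(300, 30)] <- NA
  })
  mk <- make_marker_table(pos, cbind(fr), "F01")
  w <- scan_windows(mk, "F01", min_markers = 10)
  starts <- seq(0, 1e5, by = 1000)
  or <- oracle_scan(pos, fr, starts)
  or <- or[or$n_markers >= 10, ]
  expect_equal(w$start, or$start)
  expect_equal(w$n_markers, or$n_markers)
  expect_equal(w$mean_fresh_freq, or$mean_fresh_freq, tolerance = 1e-12)
})

test_that("seed-and-extend stops at the 30% decline and matches the oracle", {
  # plateau of 0.9-mean windows flanked by 0.5-mean windows (0.5 < 0.63)
  starts <- seq(0, 40000, by = 1000)
  means <- ifelse(starts >= 10000 & starts <= 20000, 0.9, 0.5)
  w <- make_windows(starts, means)
  isl <- detect_population_islands(w)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 10000)
  expect_equal(isl$end, 30000)   # outer edge of last passing window
  expect_equal(isl$seed_start, 10000)  # ties go to the lowest coordinate

  orc <- oracle_detect(starts, means)
  expect_equal(isl$start, unname(orc[1, "start"]))
  expect_equal(isl$end, unname(orc[1, "end"]))

  # graded decline: extension runs until the first window below threshold
  means2 <- pmax(0.9 - 0.03 * abs(starts - 20000) / 1000, 0.05)
  w2 <- make_windows(starts, means2)
  isl2 <- detect_population_islands(w2)
  orc2 <- oracle_detect(starts, means2)
  expect_equal(nrow(isl2), nrow(orc2))
  expect_equal(isl2$start, unname(orc2[, "start"]))
  expect_equal(isl2$end, unname(orc2[, "end"]))

  # random window landscapes match the oracle exactly
  withr::with_seed(23, {
    for (rep in 1:5) {
      mm <- runif(length(starts), 0.2, 1)
      wr <- make_windows(starts, mm)
      got <- detect_population_islands(wr)
      orc <- oracle_detect(starts, mm)
      expect_equal(nrow(got), nrow(orc))
      o <- order(got$start)
      expect_equal(got$start[o], unname(sort(orc[, "start"])))
    }
  })
})

test_that("no seeds emerge below the 0.5 frequency rule", {
  w <- make_windows(seq(0, 20000, 1000), rep(0.45, 21))
  expect_equal(nrow(detect_population_islands(w)), 0)
  # exactly 0.5 is not a seed (strict)
  w2 <- make_windows(seq(0, 20000, 1000), rep(0.5, 21))
  expect_equal(nrow(detect_population_islands(w2)), 0)
})

test_that("a single qualifying window becomes a 10 Kb island", {
  w <- make_windows(50000, 0.8)
  isl <- detect_population_islands(w)
  expect_equal(isl$start, 50000)
  expect_equal(isl$end, 60000)
})

test_that("cross-population merging follows the 15 Kb / 30 Kb rules", {
  mk <- function(pop, s, e) tibble::tibble(population = pop, chrom = "chrI",
                                           start = s, end = e,
                                           seed_start = s, seed_mean = 0.9)
  # gap 25 Kb < 30 Kb: one candidate spanning both
  two <- dplyr::bind_rows(mk("F01", 100000, 130000), mk("F02", 155000, 180000))
  m <- merge_across_populations(two)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 100000)
  expect_equal(m$end, 180000)
  # gap 35 Kb: two candidates
  m2 <- merge_across_populations(dplyr::bind_rows(
    mk("F01", 100000, 130000), mk("F02", 165000, 190000)))
  expect_equal(nrow(m2), 2)
  # short fragments (<15 Kb) cannot seed merges
  m3 <- merge_across_populations(dplyr::bind_rows(
    mk("F01", 100000, 130000), mk("F02", 140000, 150000)))
  expect_equal(m3$end, 130000)
  # transitive chain: A-B 20 Kb, B-C 20 Kb, A-C > 30 Kb: one candidate
  chain <- dplyr::bind_rows(mk("F01", 0, 20000), mk("F02", 40000, 60000),
                            mk("F03", 80000, 100000))
  mc <- merge_across_populations(chain)
  expect_equal(nrow(mc), 1)
  expect_equal(mc$n_fragments, 3L)
})

test_that("merging equals a union-find oracle on random interval sets", {
  withr::with_seed(41, {
    n <- 50
    chrom <- sample(c("chrI", "chrII"), n, replace = TRUE)
    start <- floor(runif(n, 0, 2e6))
    len <- floor(runif(n, 15000, 60000))
    pd <- tibble::tibble(population = "F01", chrom = chrom, start = start,
                         end = start + len, seed_start = start,
                         seed_mean = 0.9)
  })
  m <- merge_across_populations(pd)
  cl <- oracle_cluster(pd$chrom, pd$start, pd$end, 30000)
  expect_equal(nrow(m), length(unique(cl)))
  orc <- dplyr::arrange(dplyr::summarise(
    dplyr::group_by(dplyr::mutate(pd, cl = cl), .data$cl),
    chrom = chrom[1], start = min(start), end = max(end), .groups = "drop"),
    chrom, start)
  expect_equal(m$start, orc$start)
  expect_equal(m$end, orc$end)
})

test_that("the density filter applies its strict union-marker threshold", {
  cand <- tibble::tibble(chrom = "chrI", start = 95000, end = 125000)
  mk51 <- make_marker_table(seq(100100, 100100 + 50 * 150, by = 150),
                            matrix(0.9, 51, 1), "F01")
  expect_equal(nrow(apply_density_filter(cand, mk51)), 1)
  expect_equal(apply_density_filter(cand, mk51)$peak_markers, 51L)
  mk50 <- make_marker_table(seq(100100, 100100 + 49 * 150, by = 150),
                            matrix(0.9, 50, 1), "F01")
  expect_equal(nrow(apply_density_filter(cand, mk50)), 0)
  # sensitivity threshold 40: a 45-marker window passes
  mk45 <- make_marker_table(seq(100100, 100100 + 44 * 150, by = 150),
                            matrix(0.9, 45, 1), "F01")
  expect_equal(nrow(apply_density_filter(cand, mk45,
                                         min_any_pop_markers = 40)), 1)
  expect_equal(nrow(apply_density_filter(cand, mk45)), 0)
})

test_that("island frequency averages the top 20% of windows", {
  # identical window means: the top-20% mean is that value
  pos <- seq(1000, 19000, by = 250)
  mk <- make_marker_table(pos, matrix(0.7, length(pos), 1), "F01")
  isl <- list(chrom = "chrI", start = 0, end = 19000)
  expect_equal(island_frequency(isl, "F01", mk), 0.7)

  # a single sub-window island uses itself as the only window
  isl1 <- list(chrom = "chrI", start = 1000, end = 6000)
  mk1 <- make_marker_table(c(2000, 3000), c(0.6, 0.8), "F01")
  expect_equal(island_frequency(isl1, "F01", mk1), 0.7)

  # ceiling rule and ordering against a plain sort oracle
  withr::with_seed(19, {
    for (rep in 1:5) {
      pos <- sort(sample(1001:30000, 120))
      fr <- runif(120)
      mk <- make_marker_table(pos, cbind(fr), "F01")
      isl <- list(chrom = "chrI", start = 1000, end = 30000)
      got <- island_frequency(isl, "F01", mk)
      starts <- seq(1000, 20000, by = 1000)
      wm <- oracle_scan(pos, fr, starts)$mean_fresh_freq
      wm <- wm[oracle_scan(pos, fr, starts)$n_markers > 0]
      k <- ceiling(0.2 * length(wm))
      expect_equal(got, mean(sort(wm, decreasing = TRUE)[1:k]),
                   tolerance = 1e-12)
    }
  })

  # no scorable windows: missing
  mkNA <- make_marker_table(c(2000, 3000), c(NA_real_, NA_real_), "F01")
  expect_true(is.na(island_frequency(isl1, "F01", mkNA)))
})

test_that("core and periphery decompose an island", {
  isl <- list(start = 0, end = 150)
  cp <- core_periphery(isl, tibble::tibble(start = c(0, 50), end = c(100, 150)))
  expect_equal(cp$core_start, 50)
  expect_equal(cp$core_end, 100)
  expect_equal(cp$periphery_length, 100)
  # identical members: core = member
  cp2 <- core_periphery(isl, tibble::tibble(start = c(20, 20), end = c(90, 90)))
  expect_equal(cp2$core_start, 20)
  expect_equal(cp2$periphery_length, 150 - 70)
  # disjoint members: empty core, periphery = island length
  cp3 <- core_periphery(isl, tibble::tibble(start = c(0, 100), end = c(40, 150)))
  expect_true(is.na(cp3$core_start))
  expect_equal(cp3$periphery_length, 150)
  expect_error(core_periphery(isl, tibble::tibble(start = numeric(),
                                                  end = numeric())),
               "no members")
})

test_that("member assignment merges fragments and applies the 0.5 rule", {
  islands <- tibble::tibble(id = "I-1", chrom = "chrI", start = 0, end = 60000)
  pd <- tibble::tibble(population = c("F01", "F01", "F02"), chrom = "chrI",
                       start = c(5000, 40000, 10000),
                       end = c(20000, 55000, 30000),
                       seed_start = c(5000, 40000, 10000), seed_mean = 0.9)
  pos <- seq(1000, 59000, by = 500)
  mk <- make_marker_table(pos, cbind(rep(0.9, length(pos)),
                                     rep(0.49, length(pos))),
                          c("F01", "F02"))
  mem <- assign_population_islands(islands, pd, mk)
  # two F01 fragments form one member spanning both
  expect_equal(nrow(mem), 1)
  expect_equal(mem$population, "F01")
  expect_equal(mem$start, 5000)
  expect_equal(mem$end, 55000)
  # F02 discarded: island frequency 0.49 is below 0.5
  expect_false("F02" %in% mem$population)
})

test_that("detection is deterministic and recovers implanted islands", {
  cfg <- small_scenario(seed = 42)
  sim <- simulate_scenario(cfg)
  mk <- call_marker_snps(sim$sites, "MAR", cfg$fresh_ids)
  res1 <- detect_islands(mk, cfg$genome, populations = cfg$fresh_ids)
  res2 <- detect_islands(mk, cfg$genome, populations = cfg$fresh_ids)
  expect_identical(res1$islands, res2$islands)
  expect_equal(nrow(res1$islands), 3)
  for (i in 1:3) {
    tr <- cfg$islands[i, ]
    d <- res1$islands[res1$islands$chrom == tr$chrom, ]
    expect_equal(nrow(d), 1)
    expect_lt(abs(d$start - tr$start), 2000)
    expect_lt(abs(d$end - tr$end), 2000)
  }
  # detected pervasiveness equals the implanted response fractions
  impl <- dplyr::summarise(dplyr::group_by(sim$truth$responses, .data$island_id),
                           p = mean(.data$responding))
  expect_equal(sort(res1$islands$pervasiveness), sort(impl$p))
})

test_that("raising the density threshold never adds islands, and a larger
           decline tolerance never shortens a population island", {
  cfg <- small_scenario(seed = 52)
  sim <- simulate_scenario(cfg)
  mk <- call_marker_snps(sim$sites, "MAR", cfg$fresh_ids)
  n50 <- nrow(detect_islands(mk, cfg$genome, cfg$fresh_ids)$islands)
  n80 <- nrow(detect_islands(mk, cfg$genome, cfg$fresh_ids,
                             min_any_pop_markers = 80)$islands)
  n40 <- nrow(detect_islands(mk, cfg$genome, cfg$fresh_ids,
                             min_any_pop_markers = 40)$islands)
  expect_lte(n80, n50)
  expect_lte(n50, n40)

  starts <- seq(0, 40000, by = 1000)
  means <- pmax(0.9 - 0.03 * abs(starts - 20000) / 1000, 0.05)
  w <- make_windows(starts, means)
  a <- detect_population_islands(w, decline = 0.30)
  b <- detect_population_islands(w, decline = 0.40)
  expect_lte(b$start[1], a$start[1])
  expect_gte(b$end[1], a$end[1])
})

test_that("every kept island satisfies the filter postcondition globally", {
  cfg <- small_scenario(seed = 66)
  sim <- simulate_scenario(cfg)
  mk <- call_marker_snps(sim$sites, "MAR", cfg$fresh_ids)
  res <- detect_islands(mk, cfg$genome, cfg$fresh_ids)
  refiltered <- apply_density_filter(res$islands[, c("chrom", "start", "end")],
                                     mk)
  expect_equal(nrow(refiltered), nrow(res$islands))
})
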