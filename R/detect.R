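# Sliding-window marker statistics and the seed-and-extend island scan.
#
# Windows are 10 Kb wide on a 1 Kb grid. A window's marker count is the
# number of marker SNPs (sites that are markers in >=1 population) it
# contains; the per-population mean is that population's freshwater-allele
# frequency averaged over those sites. The count uses the global marker set
# deliberately: conditioning on the scanned population's own markers would
# force every window mean above the 0.8 marker threshold and make the >0.5
# seed rule and the 30% decline rule vacuous.

#' Sliding marker-SNP windows for one population
#'
#' Traverses each chromosome in `window`-wide windows advancing by `step`,
#' keeping windows that carry at least `min_markers` marker SNPs, with the
#' mean freshwater-allele frequency of the given population over those
#' markers (missing frequencies excluded from the mean).
#'
#' @param markers Long marker table ([call_marker_snps()]).
#' @param population Population id to average frequencies for.
#' @param genome Optional genome layout; bounds window starts.
#' @param window,step Window width and step in bp (10000 / 1000).
#' @param min_markers Minimum marker SNPs per retained window (10).
#' @return Tibble `population`, `chrom`, `start`, `end`, `n_markers`,
#'   `mean_fresh_freq` (NA when every marker is coverage-missing for the
#'   population), ordered by position.
#' @export
scan_windows <- function(markers, population, genome = NULL,
                         window = 10000, step = 1000, min_markers = 10) {
  mk <- markers[markers$population == population, ]
  out <- vector("list", length(unique(mk$chrom)))
  chroms <- unique(mk$chrom)
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    sub <- mk[mk$chrom == ch, ]
    p0 <- pos_to_zero(sub$pos)
    o <- order(p0)
    p0 <- p0[o]
    fr <- sub$fresh_freq[o]
    lo_start <- max(0, ceiling((p0[1] - window + 1) / step) * step)
    hi_start <- floor(p0[length(p0)] / step) * step
    if (!is.null(genome)) {
      L <- genome$length[match(ch, genome$chrom)]
      if (!is.na(L)) hi_start <- min(hi_start, floor((L - window) / step) * step)
    }
    if (hi_start < lo_start) next
    starts <- seq(lo_start, hi_start, by = step)
    lo <- findInterval(starts - 0.5, p0)
    hi <- findInterval(starts + window - 0.5, p0)
    n <- hi - lo
    keep <- n >= min_markers
    if (!any(keep)) next
    ok <- !is.na(fr)
    cs_f <- cumsum(ifelse(ok, fr, 0))
    cs_n <- cumsum(ok)
    csf0 <- c(0, cs_f); csn0 <- c(0, cs_n)
    n_ok <- csn0[hi + 1] - csn0[lo + 1]
    mean_f <- ifelse(n_ok > 0, (csf0[hi + 1] - csf0[lo + 1]) / n_ok, NA_real_)
    out[[ci]] <- tibble::tibble(
      population = population, chrom = ch,
      start = starts[keep], end = starts[keep] + window,
      n_markers = n[keep], mean_fresh_freq = mean_f[keep])
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(population = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_markers = integer(), mean_fresh_freq = numeric())
  }
  res
}

#' Seed-and-extend detection of population-level divergence islands
#'
#' Greedy scan over the qualifying windows of one population: the window
#' with the highest mean freshwater-allele frequency (ties: lowest genomic
#' coordinate) seeds an island if its mean exceeds `seed_min_freq`. The
#' island is extended outwards one `step` at a time; each shifted window
#' must itself qualify (windows absent from `windows` carry fewer than the
#' minimum markers and terminate the extension) and must not have declined
#' by more than `decline` relative to the seed mean (strictly below
#' `(1 - decline) * seed_mean` stops). The island boundary is the outer
#' edge of the last passing window. Windows overlapping a detected island
#' become ineligible as seeds and the procedure repeats until no eligible
#' seed remains.
#'
#' @param windows Qualifying windows for a single population
#'   ([scan_windows()]).
#' @param decline Maximum tolerated relative decline vs the seed (0.30).
#' @param seed_min_freq Minimum seed window mean (0.5, strict).
#' @param window,step Must match the values used in [scan_windows()].
#' @return Tibble `population`, `chrom`, `start`, `end`, `seed_start`,
#'   `seed_mean`, ordered by position.
#' @export
detect_population_islands <- function(windows, decline = 0.30,
                                      seed_min_freq = 0.5,
                                      window = 10000, step = 1000) {
  if (nrow(windows) == 0) {
    return(tibble::tibble(population = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          seed_start = numeric(), seed_mean = numeric()))
  }
  stopifnot(length(unique(windows$population)) == 1)
  res <- list()
  for (ch in unique(windows$chrom)) {
    sub <- windows[windows$chrom == ch & !is.na(windows$mean_fresh_freq), ]
    if (nrow(sub) == 0) next
    means <- stats::setNames(sub$mean_fresh_freq, sprintf("%.0f", sub$start))
    ord <- order(-sub$mean_fresh_freq, sub$start)
    taken_s <- numeric(0)   # island starts
    taken_e <- numeric(0)   # island ends
    for (k in ord) {
      m0 <- sub$mean_fresh_freq[k]
      if (m0 <= seed_min_freq) break   # sorted descending: no seeds left
      s <- sub$start[k]
      if (length(taken_s) &&
          any(s < taken_e & s + window > taken_s)) next
      thr <- (1 - decline) * m0
      pass <- function(t) {
        mm <- means[sprintf("%.0f", t)]
        !is.na(mm) && mm >= thr
      }
      right <- s
      while (pass(right + step)) right <- right + step
      left <- s
      while (pass(left - step)) left <- left - step
      taken_s <- c(taken_s, left)
      taken_e <- c(taken_e, right + window)
      res[[length(res) + 1]] <- tibble::tibble(
        population = sub$population[k], chrom = ch,
        start = left, end = right + window,
        seed_start = s, seed_mean = m0)
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(population = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          seed_start = numeric(), seed_mean = numeric()))
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Merge population-level islands across populations
#'
#' Population-level islands of length `min_len` or more are merged across
#' all populations by single-linkage: islands on the same chromosome whose
#' edge-to-edge gap is at most `merge_gap` fall in one candidate, and the
#' candidate interval is the envelope (union span) of its members. Shorter
#' population-level islands do not seed merges (they may still be assigned
#' to a final island later).
#'
#' @param pop_dis Population-level islands from
#'   [detect_population_islands()], any number of populations bound
#'   together.
#' @param min_len Minimum length to enter the merge (15000 bp).
#' @param merge_gap Maximum gap joining two islands (30000 bp).
#' @return Tibble `chrom`, `start`, `end`, `n_fragments`.
#' @export
merge_across_populations <- function(pop_dis, min_len = 15000,
                                     merge_gap = 30000) {
  keep <- pop_dis[(pop_dis$end - pop_dis$start) >= min_len, ]
  merge_intervals(keep, merge_gap)
}

# Single-linkage interval merging at a maximum gap (gap <= merge_gap joins).
#' @keywords internal
merge_intervals <- function(x, merge_gap = 0) {
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_fragments = integer()))
  }
  x <- dplyr::arrange(x, .data$chrom, .data$start)
  out <- list()
  for (ch in unique(x$chrom)) {
    s <- x$start[x$chrom == ch]
    e <- x$end[x$chrom == ch]
    run_end <- cummax_running(e)
    new_cluster <- c(TRUE, s[-1] > run_end[-length(run_end)] + merge_gap)
    cl <- cumsum(new_cluster)
    out[[ch]] <- tibble::tibble(
      chrom = ch,
      start = as.numeric(tapply(s, cl, min)),
      end = as.numeric(tapply(e, cl, max)),
      n_fragments = as.integer(table(cl)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' @keywords internal
cummax_running <- function(e) cummax(e)

#' Filter candidate islands by peak marker density
#'
#' Keeps a candidate only if at least one `window`-wide window inside it
#' (on the `step` grid) contains strictly more than `min_any_pop_markers`
#' sites that are marker SNPs in at least one population. The published
#' default is 50; 40 reproduces the sensitivity variant.
#'
#' @param candidates Tibble `chrom`, `start`, `end`.
#' @param markers Long marker table.
#' @param window,step Window geometry (10000 / 1000).
#' @param min_any_pop_markers Strict lower bound on the peak union-marker
#'   count (50).
#' @return The kept candidates with an extra `peak_markers` column.
#' @export
apply_density_filter <- function(candidates, markers, window = 10000,
                                 step = 1000, min_any_pop_markers = 50) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, peak_markers = integer()))
  }
  sites <- dplyr::distinct(markers, .data$chrom, .data$pos)
  peak <- vapply(seq_len(nrow(candidates)), function(i) {
    p0 <- sort(pos_to_zero(
      sites$pos[sites$chrom == candidates$chrom[i] &
                  sites$pos > candidates$start[i] &
                  sites$pos <= candidates$end[i]]))
    if (length(p0) == 0) return(0L)
    a <- candidates$start[i]; b <- candidates$end[i]
    starts <- seq(ceiling(a / step) * step,
                  max(ceiling(a / step) * step, floor((b - window) / step) * step),
                  by = step)
    starts <- starts[starts >= a & starts + window <= b]
    if (length(starts) == 0) starts <- a   # candidate narrower than a window
    lo <- findInterval(starts - 0.5, p0)
    hi <- findInterval(starts + window - 0.5, p0)
    max(hi - lo)
  }, integer(1))
  out <- dplyr::mutate(candidates, peak_markers = peak)
  out[peak > min_any_pop_markers, ]
}

#' Freshwater-allele frequency of an island in one population
#'
#' The island frequency is the mean, over the top `top_fraction` (by mean
#' frequency; count rounded up) of the island's scorable sliding windows,
#' of the window mean freshwater-allele frequency. Windows are the same
#' `window`/`step` sliding set restricted to (fully contained in) the
#' island; when no grid window fits, the island itself is the single
#' window. A window is scorable when it contains at least one marker with
#' a non-missing frequency for the population.
#'
#' @param island One-row data frame or list with `chrom`, `start`, `end`.
#' @param population Population id.
#' @param markers Long marker table.
#' @param window,step Window geometry (10000 / 1000).
#' @param top_fraction Fraction of windows averaged (0.2).
#' @return Scalar frequency, or `NA` when no window is scorable.
#' @export
island_frequency <- function(island, population, markers, window = 10000,
                             step = 1000, top_fraction = 0.2) {
  mk <- markers[markers$population == population &
                  markers$chrom == island$chrom &
                  markers$pos > island$start & markers$pos <= island$end, ]
  mk <- mk[!is.na(mk$fresh_freq), ]
  if (nrow(mk) == 0) return(NA_real_)
  p0 <- sort(pos_to_zero(mk$pos))
  fr <- mk$fresh_freq[order(pos_to_zero(mk$pos))]
  w_means <- window_means_in_interval(p0, fr, island$start, island$end,
                                      window, step)
  if (length(w_means) == 0) return(NA_real_)
  k <- ceiling(top_fraction * length(w_means))
  mean(sort(w_means, decreasing = TRUE)[seq_len(k)])
}

# Mean frequency of the step-grid windows fully inside [a, b); windows with
# no scorable marker are dropped. Falls back to one [a, b) window.
#' @keywords internal
window_means_in_interval <- function(p0, fr, a, b, window, step) {
  s_lo <- ceiling(a / step) * step
  s_hi <- floor((b - window) / step) * step
  if (s_hi < s_lo) {
    starts <- a
    window <- b - a
  } else {
    starts <- seq(s_lo, s_hi, by = step)
  }
  lo <- findInterval(starts - 0.5, p0)
  hi <- findInterval(starts + window - 0.5, p0)
  csf0 <- c(0, cumsum(fr))
  n <- hi - lo
  means <- (csf0[hi + 1] - csf0[lo + 1]) / n
  means[n > 0]
}

#' Did an island respond in a population?
#'
#' TRUE when the island frequency ([island_frequency()]) strictly exceeds
#' 0.5, FALSE when it does not, NA when the frequency is missing.
#'
#' @inheritParams island_frequency
#' @param threshold Response threshold (0.5, strict).
#' @return Logical scalar or NA.
#' @export
response <- function(island, population, markers, threshold = 0.5,
                     window = 10000, step = 1000, top_fraction = 0.2) {
  f <- island_frequency(island, population, markers, window, step,
                        top_fraction)
  if (is.na(f)) return(NA)
  f > threshold
}

#' Pervasiveness of an island
#'
#' The proportion of populations with a non-missing response in which the
#' island responded.
#'
#' @param responded Logical vector of responses (NA = missing).
#' @return Scalar in \[0, 1\]; errors if every response is missing.
#' @export
pervasiveness <- function(responded) {
  n <- sum(!is.na(responded))
  if (n == 0) stop("no population has a non-missing response", call. = FALSE)
  sum(responded, na.rm = TRUE) / n
}

#' Core and periphery of an island
#'
#' The core is the intersection of all present member intervals (empty when
#' they are disjoint); the periphery length is the island length minus the
#' core length.
#'
#' @param island One-row data frame or list with `start`, `end`.
#' @param members Data frame of member intervals (`start`, `end`), one row
#'   per population present.
#' @return List with `core_start`, `core_end` (NA when empty),
#'   `core_length`, `periphery_length`.
#' @export
core_periphery <- function(island, members) {
  if (nrow(members) == 0) stop("island has no members", call. = FALSE)
  cs <- max(members$start)
  ce <- min(members$end)
  if (cs >= ce) {
    cs <- NA_real_; ce <- NA_real_; core_len <- 0
  } else {
    core_len <- ce - cs
  }
  list(core_start = cs, core_end = ce, core_length = core_len,
       periphery_length = (island$end - island$start) - core_len)
}

#' Assign population-level islands to final islands
#'
#' For each final island and population, all of that population's
#' population-level islands overlapping the final interval are merged into
#' one member interval, irrespective of the distance between them, and
#' clipped to the island. The member is kept only if the island frequency
#' for that population is at least `keep_min_freq` (members below 0.5 are
#' discarded). `from_short_fragment` flags members built solely from
#' fragments under 15 Kb, which could not have seeded a merge.
#'
#' @param islands Tibble of final island intervals with an `id` column.
#' @param pop_dis All populations' population-level islands.
#' @param markers Long marker table.
#' @param keep_min_freq Member retention threshold (0.5).
#' @param window,step,top_fraction Passed to [island_frequency()].
#' @param short_len Length defining a short fragment (15000 bp).
#' @return Tibble `island_id`, `population`, `start`, `end`, `fresh_freq`,
#'   `from_short_fragment`.
#' @export
assign_population_islands <- function(islands, pop_dis, markers,
                                      keep_min_freq = 0.5, window = 10000,
                                      step = 1000, top_fraction = 0.2,
                                      short_len = 15000) {
  out <- list()
  for (i in seq_len(nrow(islands))) {
    isl <- islands[i, ]
    frag <- pop_dis[pop_dis$chrom == isl$chrom &
                      pop_dis$start < isl$end & pop_dis$end > isl$start, ]
    if (nrow(frag) == 0) next
    for (pop in unique(frag$population)) {
      fp <- frag[frag$population == pop, ]
      ff <- island_frequency(isl, pop, markers, window, step, top_fraction)
      if (is.na(ff) || ff < keep_min_freq) next
      out[[length(out) + 1]] <- tibble::tibble(
        island_id = isl$id, population = pop,
        start = max(isl$start, min(fp$start)),
        end = min(isl$end, max(fp$end)),
        fresh_freq = ff,
        from_short_fragment = all(fp$end - fp$start < short_len))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(island_id = character(), population = character(),
                          start = numeric(), end = numeric(),
                          fresh_freq = numeric(),
                          from_short_fragment = logical()))
  }
  dplyr::bind_rows(out)
}

#' Detect divergence islands end to end
#'
#' Runs the full detection pipeline on a marker table: per-population
#' sliding-window scan ([scan_windows()]), seed-and-extend detection
#' ([detect_population_islands()]), cross-population merging
#' ([merge_across_populations()]; disabled by `cross_merge = FALSE`, the
#' published sensitivity variant, in which each population's islands are
#' merged only within that population), the peak marker-density filter
#' ([apply_density_filter()]), member assignment, core/periphery
#' decomposition, and per-population response/pervasiveness.
#'
#' Final island envelopes are trimmed to the outermost marker SNP they
#' contain (`trim_to_markers`): coordinates beyond the outermost marker
#' carry no evidence for divergence, and the untrimmed envelope carries the
#' full sliding-window width past it.
#'
#' @param markers Long marker table ([call_marker_snps()]).
#' @param genome Genome layout.
#' @param populations Populations scanned for island detection (default:
#'   all populations in `markers`).
#' @param window,step,min_markers,seed_min_freq,decline,min_len,merge_gap,min_any_pop_markers
#'   Stage parameters with the published defaults (10 Kb, 1 Kb, 10, 0.5,
#'   0.30, 15 Kb, 30 Kb, 50).
#' @param cross_merge Merge population-level islands across populations
#'   (TRUE).
#' @param trim_to_markers Trim final envelopes to the outermost marker
#'   (TRUE).
#' @param top_fraction Fraction of windows in the island-frequency mean
#'   (0.2).
#' @param inversions Optional tibble of known inversion intervals
#'   (`chrom`, `start`, `end`); islands overlapping one are flagged.
#' @return A `di_result` list: `islands` (id, interval, pervasiveness,
#'   responses, core/periphery), `members`, `responses`, `pop_islands`,
#'   `params`. `tidy()` returns the island table, `glance()` a one-row
#'   summary.
#' @export
detect_islands <- function(markers, genome, populations = NULL,
                           window = 10000, step = 1000, min_markers = 10,
                           seed_min_freq = 0.5, decline = 0.30,
                           min_len = 15000, merge_gap = 30000,
                           min_any_pop_markers = 50, cross_merge = TRUE,
                           trim_to_markers = TRUE, top_fraction = 0.2,
                           inversions = NULL) {
  check_genome(genome)
  if (is.null(populations)) populations <- allele_table_populations(markers)
  pop_dis <- dplyr::bind_rows(lapply(populations, function(pop) {
    w <- scan_windows(markers, pop, genome, window, step, min_markers)
    detect_population_islands(w, decline, seed_min_freq, window, step)
  }))

  if (cross_merge) {
    candidates <- merge_across_populations(pop_dis, min_len, merge_gap)
  } else {
    candidates <- dplyr::distinct(dplyr::bind_rows(lapply(
      split(pop_dis, pop_dis$population), merge_across_populations,
      min_len = min_len, merge_gap = merge_gap)),
      .data$chrom, .data$start, .data$end, .keep_all = TRUE)
  }
  kept <- apply_density_filter(candidates, markers, window, step,
                               min_any_pop_markers)

  if (trim_to_markers && nrow(kept) > 0) {
    sites <- dplyr::distinct(markers, .data$chrom, .data$pos)
    for (i in seq_len(nrow(kept))) {
      p <- sites$pos[sites$chrom == kept$chrom[i] &
                       sites$pos > kept$start[i] & sites$pos <= kept$end[i]]
      kept$start[i] <- pos_to_zero(min(p))
      kept$end[i] <- max(p)
    }
  }

  kept <- dplyr::arrange(kept, match(.data$chrom, genome$chrom), .data$start)
  if (nrow(kept) > 0) {
    ord_in_chrom <- stats::ave(seq_len(nrow(kept)), kept$chrom,
                               FUN = seq_along)
    kept$id <- paste0(chrom_label(kept$chrom), "-", ord_in_chrom)
  } else {
    kept$id <- character(0)
  }

  members <- assign_population_islands(kept, pop_dis, markers,
                                       keep_min_freq = 0.5, window, step,
                                       top_fraction)

  responses <- dplyr::bind_rows(lapply(seq_len(nrow(kept)), function(i) {
    tibble::tibble(
      island_id = kept$id[i], population = populations,
      fresh_freq = vapply(populations, function(p) {
        island_frequency(kept[i, ], p, markers, window, step, top_fraction)
      }, numeric(1)))
  }))
  if (nrow(responses)) {
    responses$responded <- ifelse(is.na(responses$fresh_freq), NA,
                                  responses$fresh_freq > 0.5)
  } else {
    responses <- tibble::tibble(island_id = character(),
                                population = character(),
                                fresh_freq = numeric(), responded = logical())
  }

  islands <- kept
  islands$length <- islands$end - islands$start
  islands$n_members <- 0L
  islands$pervasiveness <- NA_real_
  islands$n_responded <- NA_integer_
  islands$core_start <- NA_real_
  islands$core_end <- NA_real_
  islands$core_length <- NA_real_
  islands$periphery_length <- NA_real_
  for (i in seq_len(nrow(islands))) {
    mm <- members[members$island_id == islands$id[i], ]
    islands$n_members[i] <- nrow(mm)
    rr <- responses$responded[responses$island_id == islands$id[i]]
    if (any(!is.na(rr))) {
      islands$pervasiveness[i] <- pervasiveness(rr)
      islands$n_responded[i] <- sum(rr, na.rm = TRUE)
    }
    if (nrow(mm) > 0) {
      cp <- core_periphery(islands[i, ], mm)
      islands$core_start[i] <- cp$core_start
      islands$core_end[i] <- cp$core_end
      islands$core_length[i] <- cp$core_length
      islands$periphery_length[i] <- cp$periphery_length
    }
  }
  islands$in_inversion <- FALSE
  if (!is.null(inversions) && nrow(islands) > 0) {
    for (i in seq_len(nrow(islands))) {
      islands$in_inversion[i] <- any(
        inversions$chrom == islands$chrom[i] &
          inversions$start < islands$end[i] &
          inversions$end > islands$start[i])
    }
  }

  structure(list(
    islands = islands, members = members, responses = responses,
    pop_islands = pop_dis, candidates = candidates,
    params = list(window = window, step = step, min_markers = min_markers,
                  seed_min_freq = seed_min_freq, decline = decline,
                  min_len = min_len, merge_gap = merge_gap,
                  min_any_pop_markers = min_any_pop_markers,
                  cross_merge = cross_merge,
                  trim_to_markers = trim_to_markers,
                  top_fraction = top_fraction,
                  populations = populations)
  ), class = "di_result")
}

#' @export
print.di_result <- function(x, ...) {
  cat("Divergence-island scan:", nrow(x$islands), "islands,",
      nrow(x$members), "population-level members over",
      length(x$params$populations), "populations\n")
  print(x$islands[, intersect(c("id", "chrom", "start", "end", "length",
                                "pervasiveness", "core_length"),
                              names(x$islands))])
  invisible(x)
}
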