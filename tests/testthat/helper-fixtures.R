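# Shared fixtures and independent oracles. Oracles deliberately use naive
# loops / enumeration, never the package's vectorized code paths.

# Write sync lines to a temp file and return its path.
write_sync <- function(lines) {
  path <- withr::local_tempfile(fileext = ".sync",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Long allele table straight from a matrix of alternate-allele frequencies
# (sites x populations), with exact counts at the given coverage.
make_allele_table <- function(pos, freq, pops, chrom = "chrI",
                              coverage = 1000) {
  freq <- rbind(freq)
  stopifnot(length(pos) == nrow(freq), length(pops) == ncol(freq))
  n <- length(pos)
  cb <- round(freq * coverage)
  out <- tibble::tibble(
    chrom = rep(rep(chrom, length.out = n), each = length(pops)),
    pos = rep(pos, each = length(pops)),
    allele_A = "A", allele_B = "T",
    population = rep(pops, times = n),
    count_A = as.integer(t(coverage - cb)),
    count_B = as.integer(t(cb)),
    coverage = as.integer(coverage)
  )
  attr(out, "populations") <- pops
  out
}

# Long marker table from a freshwater-allele frequency matrix
# (sites x populations); NA = coverage-missing.
make_marker_table <- function(pos, fresh_freq, pops, chrom = "chrI",
                              marine_freq = 0.1, high = 0.8) {
  fresh_freq <- rbind(fresh_freq)
  n <- length(pos)
  out <- tibble::tibble(
    chrom = chrom,
    pos = rep(pos, each = length(pops)),
    freshwater_allele = "T",
    marine_freq = rep(marine_freq, length.out = n * length(pops)),
    population = rep(pops, times = n),
    fresh_freq = as.vector(t(fresh_freq))
  )
  out$is_marker <- !is.na(out$fresh_freq) & out$fresh_freq > high
  attr(out, "populations") <- pops
  out
}

# Scan-window table built directly (one population).
make_windows <- function(starts, means, n_markers = 10, pop = "F01",
                         chrom = "chrI", window = 10000) {
  tibble::tibble(population = pop, chrom = chrom, start = starts,
                 end = starts + window,
                 n_markers = rep(n_markers, length.out = length(starts)),
                 mean_fresh_freq = means)
}

# Brute-force window recount: marker count and population mean for every
# step-grid window, looping over sites.
oracle_scan <- function(pos, freq, starts, window = 10000) {
  n <- integer(length(starts))
  m <- numeric(length(starts))
  for (i in seq_along(starts)) {
    inw <- (pos - 1) >= starts[i] & (pos - 1) < starts[i] + window
    n[i] <- sum(inw)
    f <- freq[inw]
    m[i] <- if (any(!is.na(f))) mean(f, na.rm = TRUE) else NA_real_
  }
  tibble::tibble(start = starts, n_markers = n, mean_fresh_freq = m)
}

# Independent greedy seed-and-extend on a full window-mean lookup table,
# written as plain loops over candidate boundaries.
oracle_detect <- function(starts, means, decline = 0.3, seed_min = 0.5,
                          window = 10000, step = 1000) {
  avail <- rep(TRUE, length(starts))
  islands <- list()
  repeat {
    elig <- which(avail & !is.na(means) & means > seed_min)
    if (length(elig) == 0) break
    k <- elig[order(-means[elig], starts[elig])][1]
    thr <- (1 - decline) * means[k]
    left <- starts[k]
    repeat {
      j <- which(starts == left - step)
      if (length(j) == 0 || is.na(means[j]) || means[j] < thr) break
      left <- left - step
    }
    right <- starts[k]
    repeat {
      j <- which(starts == right + step)
      if (length(j) == 0 || is.na(means[j]) || means[j] < thr) break
      right <- right + step
    }
    islands[[length(islands) + 1]] <-
      c(start = left, end = right + window, seed = starts[k])
    avail <- avail & !(starts < right + window & starts + window > left)
  }
  do.call(rbind, islands)
}

# Union-find clustering of intervals at a gap threshold.
oracle_cluster <- function(chrom, start, end, gap, strict = FALSE) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j]) {
      g <- max(0, max(start[i], start[j]) - min(end[i], end[j]))
      joined <- if (strict) g < gap else g <= gap
      if (joined) parent[max(find(i), find(j))] <- min(find(i), find(j))
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Enumeration oracle for the marker-overlap statistic.
oracle_overlap <- function(freq, min_markers = 20, high = 0.8,
                           band_low = 0.5) {
  pops <- colnames(freq)
  member <- function(p) which(!is.na(freq[, p]) & freq[, p] > high)
  band <- function(p) which(!is.na(freq[, p]) & freq[, p] >= band_low &
                              freq[, p] < high)
  elig <- pops[vapply(pops, function(p) length(member(p)), 1L) >= min_markers]
  if (length(elig) < 2) return(NA_real_)
  Rs <- c()
  for (i in seq_along(elig)) for (j in seq_along(elig)) {
    if (i < j) {
      A <- union(member(elig[i]), intersect(member(elig[j]), band(elig[i])))
      B <- union(member(elig[j]), intersect(member(elig[i]), band(elig[j])))
      Rs <- c(Rs, length(intersect(A, B)) / min(length(A), length(B)))
    }
  }
  mean(Rs)
}

# Small ready-made scenario used by several tests.
small_scenario <- function(seed = 42, exact = TRUE, n_fresh = 6,
                           offtarget = 0.45, overlap = 0.8,
                           fresh_mean = 0.95, marine_beta = c(1, 9)) {
  g <- genome_layout(paste0("chr", as.roman(1:3)), rep(5e6, 3))
  isl <- tibble::tibble(
    chrom = c("chrI", "chrII", "chrIII"),
    start = c(1e6, 2e6, 3e6), end = c(1.06e6, 2.1e6, 3.04e6),
    pervasiveness_target = c(1, 0.5, 0.8))
  scenario_config(g, isl, n_fresh_pops = n_fresh,
                  exact_frequencies = exact, overlap_target = overlap,
                  offtarget_freq_mean = offtarget,
                  fresh_freq_mean = fresh_mean, marine_beta = marine_beta,
                  seed = seed)
}
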