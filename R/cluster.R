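# Genomic clustering of islands and recombination-stratified permutation
# nulls. Gaps are edge-to-edge distances (bedtools convention); overlapping
# intervals have gap 0.

# Same-chromosome pair gaps as a numeric vector.
#' @keywords internal
pair_gaps <- function(islands) {
  gaps <- numeric(0)
  for (ch in unique(islands$chrom)) {
    s <- islands$start[islands$chrom == ch]
    e <- islands$end[islands$chrom == ch]
    k <- length(s)
    if (k < 2) next
    g <- pmax(outer(s, s, pmax) - outer(e, e, pmin), 0)
    gaps <- c(gaps, g[upper.tri(g)])
  }
  gaps
}

#' Distribution of distances between same-chromosome island pairs
#'
#' Edge-to-edge gaps of every unordered pair of islands on the same
#' chromosome, binned at `bin_width` (default 200 Kb). Overlapping islands
#' count as gap 0.
#'
#' @param islands Tibble `chrom`, `start`, `end`.
#' @param bin_width Histogram bin width in bp (200000).
#' @return Tibble `bin_start`, `bin_end`, `n_pairs` (only non-empty bins).
#' @export
pair_gap_distribution <- function(islands, bin_width = 200000) {
  gaps <- pair_gaps(islands)
  if (length(gaps) == 0) {
    return(tibble::tibble(bin_start = numeric(), bin_end = numeric(),
                          n_pairs = integer()))
  }
  b <- floor(gaps / bin_width) * bin_width
  tb <- table(b)
  tibble::tibble(bin_start = as.numeric(names(tb)),
                 bin_end = as.numeric(names(tb)) + bin_width,
                 n_pairs = as.integer(tb))
}

#' Number of close same-chromosome island pairs
#'
#' Counts unordered pairs of islands on the same chromosome whose
#' edge-to-edge gap is strictly below `max_gap` (default 1 Mb).
#'
#' @inheritParams pair_gap_distribution
#' @param max_gap Gap threshold in bp (1e6).
#' @return Integer count.
#' @export
count_close_pairs <- function(islands, max_gap = 1e6) {
  sum(pair_gaps(islands) < max_gap)
}

#' Variance of island counts per chromosome
#'
#' Sample variance (n - 1 denominator by default) of the number of islands
#' per chromosome over all chromosomes of the layout, zero-count
#' chromosomes included.
#'
#' @param islands Tibble `chrom`, `start`, `end`.
#' @param genome Genome layout (defines the chromosome universe).
#' @param denominator `"sample"` (n - 1, default) or `"population"` (n).
#' @return Scalar variance; errors with fewer than two chromosomes.
#' @export
chromosome_count_variance <- function(islands, genome,
                                      denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  check_genome(genome)
  if (nrow(genome) < 2) stop("need at least two chromosomes", call. = FALSE)
  counts <- as.numeric(table(factor(islands$chrom, levels = genome$chrom)))
  v <- stats::var(counts)
  if (denominator == "population") v <- v * (length(counts) - 1) / length(counts)
  v
}

#' Archipelagos: single-linkage clusters of islands
#'
#' Groups same-chromosome islands whose closest-member gap is strictly
#' below `max_gap` (single linkage) and returns clusters of two or more
#' islands.
#'
#' @inheritParams count_close_pairs
#' @return Tibble of member islands with a `cluster` id column; zero rows
#'   when every island is isolated.
#' @export
archipelago_clusters <- function(islands, max_gap = 1e6) {
  if (nrow(islands) == 0) {
    return(dplyr::mutate(tibble::as_tibble(islands), cluster = character()))
  }
  x <- dplyr::arrange(tibble::as_tibble(islands), .data$chrom, .data$start)
  out <- list()
  for (ch in unique(x$chrom)) {
    sub <- x[x$chrom == ch, ]
    run_end <- cummax(sub$end)
    # strict: gap >= max_gap starts a new cluster
    new_cl <- c(TRUE, sub$start[-1] >= run_end[-nrow(sub)] + max_gap)
    sub$cluster <- paste0(ch, "_", cumsum(new_cl))
    out[[ch]] <- sub
  }
  res <- dplyr::bind_rows(out)
  sizes <- table(res$cluster)
  res[res$cluster %in% names(sizes)[sizes >= 2], ]
}

#' Stratify the genome into recombination-rate bins
#'
#' Averages the 10 Kb rho values within each 1 Mb genomic window and
#' partitions the windows into `n_bins` equal-count classes (quintiles by
#' default) of increasing recombination rate; rank ties are broken by
#' coordinate order. Windows with no rho data get bin `NA` and are
#' excluded from stratified shuffling.
#'
#' @param recomb_map Tibble from [read_recomb_map()] or
#'   [generate_recomb_map()].
#' @param genome Genome layout.
#' @param window Stratum window width in bp (1e6).
#' @param n_bins Number of classes (5).
#' @return Tibble `chrom`, `start`, `end`, `mean_rho`, `bin`.
#' @export
build_strata <- function(recomb_map, genome, window = 1e6, n_bins = 5) {
  check_genome(genome)
  out <- list()
  for (i in seq_len(nrow(genome))) {
    starts <- seq(0, genome$length[i] - 1, by = window)
    ends <- pmin(starts + window, genome$length[i])
    sub <- recomb_map[recomb_map$chrom == genome$chrom[i], ]
    idx <- findInterval(sub$start, starts)
    mean_rho <- rep(NA_real_, length(starts))
    if (nrow(sub)) {
      agg <- tapply(sub$rho, idx, mean)
      mean_rho[as.integer(names(agg))] <- agg
    }
    out[[i]] <- tibble::tibble(chrom = genome$chrom[i], start = starts,
                               end = ends, mean_rho = mean_rho)
  }
  st <- dplyr::bind_rows(out)
  st$bin <- NA_integer_
  ok <- which(!is.na(st$mean_rho))
  if (length(ok)) {
    ord <- ok[order(st$mean_rho[ok])]        # stable sort: coordinate ties
    st$bin[ord] <- as.integer(ceiling(seq_along(ord) * n_bins / length(ord)))
  }
  st
}

#' Assign each island to one recombination bin
#'
#' An island takes the bin of the stratum window holding the larger part
#' of it (50/50 ties go to the lower-coordinate window), and the windows
#' carrying its smaller parts are relabelled to that bin so the island fits
#' entirely inside its own stratum during shuffling.
#'
#' @param islands Tibble `chrom`, `start`, `end`.
#' @param strata From [build_strata()].
#' @return List: `islands` (input plus `bin`), `strata` (relabelled).
#' @export
assign_island_bins <- function(islands, strata) {
  islands <- tibble::as_tibble(islands)
  islands$bin <- NA_integer_
  for (i in seq_len(nrow(islands))) {
    w <- strata[strata$chrom == islands$chrom[i] &
                  strata$start < islands$end[i] &
                  strata$end > islands$start[i], ]
    if (nrow(w) == 0 || anyNA(w$bin)) {
      stop("island ", i, " not covered by binned strata", call. = FALSE)
    }
    ov <- pmin(w$end, islands$end[i]) - pmax(w$start, islands$start[i])
    pick <- which(ov == max(ov))[1]          # ties: lower coordinate wins
    islands$bin[i] <- w$bin[pick]
    strata$bin[strata$chrom == islands$chrom[i] &
                 strata$start %in% w$start] <- w$bin[pick]
  }
  list(islands = islands, strata = strata)
}

# Region table used by the shuffler: maximal runs of same-bin windows
# (stratified) or whole chromosomes (unstratified).
#' @keywords internal
shuffle_regions <- function(genome, strata = NULL) {
  if (is.null(strata)) {
    return(tibble::tibble(chrom = genome$chrom, start = 0,
                          end = genome$length, bin = NA_integer_))
  }
  st <- strata[!is.na(strata$bin), ]
  st <- dplyr::arrange(st, match(.data$chrom, genome$chrom), .data$start)
  brk <- c(TRUE, st$chrom[-1] != st$chrom[-nrow(st)] |
             st$start[-1] != st$end[-nrow(st)] |
             st$bin[-1] != st$bin[-nrow(st)])
  run <- cumsum(brk)
  tibble::tibble(
    chrom = tapply(st$chrom, run, `[`, 1),
    start = as.numeric(tapply(st$start, run, min)),
    end = as.numeric(tapply(st$end, run, max)),
    bin = as.integer(tapply(st$bin, run, `[`, 1)))
}

# One shuffle trial over a prepared region table. lengths/bins per island;
# returns matrix cbind(chrom_idx, start, end) or NULL on failure.
#' @keywords internal
shuffle_once <- function(lengths, bins, regions, chrom_index, max_retries) {
  n <- length(lengths)
  ord <- order(-lengths)
  pc <- integer(n); ps <- numeric(n); pe <- numeric(n)
  placed <- integer(0)
  for (i in ord) {
    L <- lengths[i]
    cand <- if (is.na(bins[i])) seq_len(nrow(regions)) else
      which(regions$bin == bins[i])
    cand <- cand[regions$end[cand] - regions$start[cand] >= L]
    if (length(cand) == 0) return(NULL)
    wts <- regions$end[cand] - regions$start[cand] - L + 1
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      r <- cand[sample.int(length(cand), 1L, prob = wts)]
      s <- regions$start[r] +
        floor(stats::runif(1) * (regions$end[r] - regions$start[r] - L + 1))
      e <- s + L
      ci <- chrom_index[[regions$chrom[r]]]
      if (!any(pc[placed] == ci & s < pe[placed] & e > ps[placed])) {
        pc[i] <- ci; ps[i] <- s; pe[i] <- e
        placed <- c(placed, i)
        ok <- TRUE
        break
      }
    }
    if (!ok) return(NULL)
  }
  cbind(chrom = pc, start = ps, end = pe)
}

#' Randomly relocate islands, preserving their lengths
#'
#' Places every island uniformly at random (no overlaps, no crossing of
#' region ends) within the allowed regions: the whole genome, or -- when
#' `strata` is given -- only the regions of each island's own
#' recombination bin, mirroring shuffleBed with `-noOverlapping`.
#' Placement uses rejection sampling with a retry cap; an infeasible
#' layout is an error, never a silent relaxation.
#'
#' @param islands Tibble `chrom`, `start`, `end` (a `bin` column is used
#'   when present, otherwise bins are computed from `strata`).
#' @param genome Genome layout.
#' @param strata Optional [build_strata()] output for stratified shuffling.
#' @param seed Optional integer; when `NULL` the ambient RNG stream is
#'   used (so a caller can seed once for many trials).
#' @param max_retries Retry cap per island (10000).
#' @return Tibble `chrom`, `start`, `end` with the same multiset of
#'   lengths as the input.
#' @export
shuffle_islands <- function(islands, genome, strata = NULL, seed = NULL,
                            max_retries = 10000) {
  run <- function() {
    bins <- rep(NA_integer_, nrow(islands))
    if (!is.null(strata)) {
      if (!"bin" %in% names(islands)) {
        islands <- assign_island_bins(islands, strata)$islands
      }
      bins <- islands$bin
      strata <- assign_island_bins(islands, strata)$strata
    }
    regions <- shuffle_regions(genome, strata)
    chrom_index <- stats::setNames(seq_len(nrow(genome)), genome$chrom)
    m <- shuffle_once(islands$end - islands$start, bins, regions,
                      chrom_index, max_retries)
    if (is.null(m)) {
      stop("no feasible placement after ", max_retries, " retries",
           call. = FALSE)
    }
    tibble::tibble(chrom = genome$chrom[m[, "chrom"]],
                   start = unname(m[, "start"]), end = unname(m[, "end"]),
                   bin = bins)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Permutation test of island clustering
#'
#' Compares the observed clustering statistic (close same-chromosome pairs
#' or the per-chromosome count variance) with its distribution over `n`
#' random relocations of the islands ([shuffle_islands()]), optionally
#' constrained to each island's recombination stratum. Strong clustering
#' gives a small upper-tail p-value, `(1 + #[null >= observed]) / (1 + n)`.
#'
#' @param islands Tibble `chrom`, `start`, `end`.
#' @param genome Genome layout.
#' @param statistic `"close_pairs"` or `"count_variance"`.
#' @param strata Optional strata for recombination-aware shuffling.
#' @param n Number of permutation trials (1000).
#' @param seed Integer seed (mandatory: the null is stochastic).
#' @param max_gap Close-pair threshold in bp (1e6).
#' @param max_retries Per-island retry cap in each trial.
#' @return A `permutation_result`: `statistic_name`, `observed`,
#'   `null_draws`, `expected` (null mean), `p_value`, `n_permutations`,
#'   `seed`, `stratified`. Supports `tidy()`, `glance()`, `autoplot()`.
#' @export
permutation_test <- function(islands, genome,
                             statistic = c("close_pairs", "count_variance"),
                             strata = NULL, n = 1000, seed = 1,
                             max_gap = 1e6, max_retries = 10000) {
  statistic <- match.arg(statistic)
  check_genome(genome)
  chrom_levels <- genome$chrom
  stat_fun <- function(chrom_idx, s, e) {
    if (statistic == "close_pairs") {
      cnt <- 0L
      for (ch in unique(chrom_idx)) {
        ss <- s[chrom_idx == ch]; ee <- e[chrom_idx == ch]
        k <- length(ss)
        if (k < 2) next
        g <- pmax(outer(ss, ss, pmax) - outer(ee, ee, pmin), 0)
        cnt <- cnt + sum(g[upper.tri(g)] < max_gap)
      }
      cnt
    } else {
      counts <- tabulate(chrom_idx, nbins = length(chrom_levels))
      stats::var(counts)
    }
  }
  ci_obs <- match(islands$chrom, chrom_levels)
  observed <- stat_fun(ci_obs, islands$start, islands$end)

  bins <- rep(NA_integer_, nrow(islands))
  strata_re <- NULL
  if (!is.null(strata)) {
    ab <- assign_island_bins(islands, strata)
    bins <- ab$islands$bin
    strata_re <- ab$strata
  }
  regions <- shuffle_regions(genome, strata_re)
  chrom_index <- stats::setNames(seq_len(nrow(genome)), genome$chrom)
  lengths <- islands$end - islands$start

  null_draws <- numeric(n)
  withr::with_seed(seed, {
    for (t in seq_len(n)) {
      m <- shuffle_once(lengths, bins, regions, chrom_index, max_retries)
      if (is.null(m)) {
        stop("no feasible placement after ", max_retries,
             " retries in trial ", t, call. = FALSE)
      }
      null_draws[t] <- stat_fun(m[, "chrom"], m[, "start"], m[, "end"])
    }
  })
  structure(list(
    statistic_name = statistic, observed = observed,
    null_draws = null_draws, expected = mean(null_draws),
    p_value = (1 + sum(null_draws >= observed)) / (1 + n),
    n_permutations = n, seed = seed, stratified = !is.null(strata)
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test of island clustering (", x$statistic_name,
      if (x$stratified) ", recombination-stratified" else "", ")\n",
      "  observed = ", format(x$observed), ", null mean = ",
      format(round(x$expected, 3)), ", p = ", format(x$p_value),
      " (", x$n_permutations, " trials, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
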