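# Marker-SNP overlap R and island-level comparative statistics.

#' Marker set of an island in one population
#'
#' The sites inside the island at which the population carries the
#' freshwater allele at a frequency strictly above `high`.
#'
#' @param island One-row data frame or list with `chrom`, `start`, `end`.
#' @param markers Long marker table.
#' @param population Population id.
#' @param high Membership threshold (0.8, strict).
#' @return Sorted integer vector of 1-based positions.
#' @export
marker_sets <- function(island, markers, population, high = 0.8) {
  mk <- markers[markers$population == population &
                  markers$chrom == island$chrom &
                  markers$pos > island$start & markers$pos <= island$end, ]
  sort(mk$pos[!is.na(mk$fresh_freq) & mk$fresh_freq > high])
}

# Frequency matrix (sites x populations) of marker SNPs inside an interval.
#' @keywords internal
island_freq_matrix <- function(island, markers, populations) {
  mk <- markers[markers$chrom == island$chrom &
                  markers$pos > island$start & markers$pos <= island$end &
                  markers$population %in% populations, ]
  if (nrow(mk) == 0) {
    return(matrix(numeric(0), 0, length(populations),
                  dimnames = list(NULL, populations)))
  }
  wide <- tidyr::pivot_wider(mk[, c("pos", "population", "fresh_freq")],
                             names_from = "population",
                             values_from = "fresh_freq")
  wide <- dplyr::arrange(wide, .data$pos)
  M <- matrix(NA_real_, nrow(wide), length(populations),
              dimnames = list(as.character(wide$pos), populations))
  for (p in intersect(populations, names(wide))) M[, p] <- wide[[p]]
  M
}

#' Marker-SNP overlap R of an island
#'
#' For every unordered pair of eligible populations (those with at least
#' `min_markers` marker SNPs above `high` in the island), R is the number
#' of shared marker SNPs divided by the size of the smaller of the two
#' sets, after the sharing correction: a site above `high` in one
#' population but in the \[`band_low`, `high`) frequency band in the other
#' is considered present in both (which can bias R upward). `R_mean`
#' averages over the pairs; per-population values average over the pairs
#' involving that population.
#'
#' @param island One-row data frame or list with `chrom`, `start`, `end`.
#' @param markers Long marker table.
#' @param populations Populations considered.
#' @param min_markers Eligibility minimum (20 for whole islands, 5 for
#'   segments).
#' @param high Membership threshold (0.8, strict above).
#' @param band_low Lower edge of the correction band (0.5).
#' @return List with `R_mean`, `R_by_population` (named vector, `NA` for
#'   ineligible populations), `n_pairs_used`, and the per-pair tibble
#'   `pairs`. `R_mean` is `NA` with fewer than two eligible populations.
#' @export
overlap_R <- function(island, markers, populations, min_markers = 20,
                      high = 0.8, band_low = 0.5) {
  M <- island_freq_matrix(island, markers, populations)
  B <- !is.na(M) & M > high                       # membership
  D <- !is.na(M) & M >= band_low & M < high       # correction band
  sizes <- colSums(B)
  eligible <- names(sizes)[sizes >= min_markers]
  empty <- list(R_mean = NA_real_,
                R_by_population = stats::setNames(
                  rep(NA_real_, length(populations)), populations),
                n_pairs_used = 0L,
                pairs = tibble::tibble(pop_a = character(),
                                       pop_b = character(), R = numeric()))
  if (length(eligible) < 2) return(empty)
  prs <- utils::combn(eligible, 2)
  R <- numeric(ncol(prs))
  for (k in seq_len(ncol(prs))) {
    i <- prs[1, k]; j <- prs[2, k]
    Ai <- B[, i] | (B[, j] & D[, i])
    Aj <- B[, j] | (B[, i] & D[, j])
    R[k] <- sum(Ai & Aj) / min(sum(Ai), sum(Aj))
  }
  pairs <- tibble::tibble(pop_a = prs[1, ], pop_b = prs[2, ], R = R)
  by_pop <- vapply(populations, function(p) {
    use <- pairs$pop_a == p | pairs$pop_b == p
    if (!any(use)) NA_real_ else mean(pairs$R[use])
  }, numeric(1))
  list(R_mean = mean(R), R_by_population = by_pop,
       n_pairs_used = length(R), pairs = pairs)
}

#' Marker-SNP overlap along island segments
#'
#' Splits the island into `n_bins` equal-length bins (integer-floor
#' boundaries; the last bin absorbs the remainder) and computes
#' [overlap_R()] independently per bin, with the relaxed segment minimum of
#' `min_markers` (5) marker SNPs per population.
#'
#' @inheritParams overlap_R
#' @param n_bins Number of segments (4).
#' @param min_markers Per-segment eligibility minimum (5).
#' @return Numeric vector of length `n_bins` (NA where fewer than two
#'   populations are eligible).
#' @export
segment_overlap <- function(island, markers, populations, n_bins = 4,
                            min_markers = 5, high = 0.8, band_low = 0.5) {
  len <- island$end - island$start
  w <- floor(len / n_bins)
  vapply(seq_len(n_bins), function(b) {
    s <- island$start + (b - 1) * w
    e <- if (b == n_bins) island$end else island$start + b * w
    seg <- list(chrom = island$chrom, start = s, end = e)
    overlap_R(seg, markers, populations, min_markers, high, band_low)$R_mean
  }, numeric(1))
}

#' Overlap statistics for every island of a scan
#'
#' @param result A `di_result` from [detect_islands()].
#' @param markers Long marker table.
#' @param min_markers,segment_min_markers Whole-island and per-segment
#'   eligibility minima (20 / 5).
#' @param n_bins Segments per island (4).
#' @return List of two tibbles: `islands` (`island_id`, `R_mean`,
#'   `n_pairs_used`, `R_q1`..`R_q<n_bins>`) and `by_population`
#'   (`island_id`, `population`, `R`).
#' @export
island_overlap <- function(result, markers, min_markers = 20,
                           segment_min_markers = 5, n_bins = 4) {
  stopifnot(inherits(result, "di_result"))
  pops <- result$params$populations
  isl <- result$islands
  rows <- vector("list", nrow(isl))
  by_pop <- vector("list", nrow(isl))
  for (i in seq_len(nrow(isl))) {
    ov <- overlap_R(isl[i, ], markers, pops, min_markers)
    segs <- segment_overlap(isl[i, ], markers, pops, n_bins,
                            segment_min_markers)
    row <- tibble::tibble(island_id = isl$id[i], R_mean = ov$R_mean,
                          n_pairs_used = ov$n_pairs_used)
    for (b in seq_len(n_bins)) row[[paste0("R_q", b)]] <- segs[b]
    rows[[i]] <- row
    by_pop[[i]] <- tibble::tibble(island_id = isl$id[i],
                                  population = pops,
                                  R = unname(ov$R_by_population))
  }
  list(islands = dplyr::bind_rows(rows),
       by_population = dplyr::bind_rows(by_pop))
}

#' Summary of universal versus other islands
#'
#' Among non-inversion islands, compares universal islands (pervasiveness
#' 1: responded in every population) with the rest on three statistics:
#' mean freshwater-allele frequency across the populations where the
#' island responded, marker-SNP density in the core (union marker SNPs per
#' Kb of core), and mean core length.
#'
#' @param result A `di_result`.
#' @param markers Long marker table.
#' @return Tibble with one row per class (`universal`, `other`):
#'   `n_islands`, `mean_responded_freq`, `core_marker_density_per_kb`,
#'   `mean_core_length_kb`.
#' @export
universal_summary <- function(result, markers) {
  stopifnot(inherits(result, "di_result"))
  isl <- result$islands[!result$islands$in_inversion, ]
  sites <- dplyr::distinct(markers, .data$chrom, .data$pos)
  core_density <- function(rows) {
    dens <- numeric(0)
    for (i in seq_len(nrow(rows))) {
      if (is.na(rows$core_start[i]) || rows$core_length[i] <= 0) next
      n <- sum(sites$chrom == rows$chrom[i] &
                 sites$pos > rows$core_start[i] &
                 sites$pos <= rows$core_end[i])
      dens <- c(dens, n / (rows$core_length[i] / 1000))
    }
    if (length(dens)) mean(dens) else NA_real_
  }
  one_class <- function(rows, label) {
    resp <- result$responses[result$responses$island_id %in% rows$id &
                               !is.na(result$responses$responded) &
                               result$responses$responded, ]
    tibble::tibble(
      class = label, n_islands = nrow(rows),
      mean_responded_freq = if (nrow(resp)) mean(resp$fresh_freq) else NA_real_,
      core_marker_density_per_kb = core_density(rows),
      mean_core_length_kb = if (nrow(rows))
        mean(rows$core_length, na.rm = TRUE) / 1000 else NA_real_)
  }
  uni <- isl[!is.na(isl$pervasiveness) & isl$pervasiveness == 1, ]
  oth <- isl[!is.na(isl$pervasiveness) & isl$pervasiveness < 1, ]
  dplyr::bind_rows(one_class(uni, "universal"), one_class(oth, "other"))
}
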