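#' Per-population allele frequencies with a coverage floor
#'
#' Adds the alternate-allele frequency `freq_B = count_B / (count_A +
#' count_B)` to a long allele table. Populations with fewer than
#' `min_coverage` allele-supporting reads at a site get `NA` (explicitly
#' missing, never zero).
#'
#' @param sites Long allele table ([read_allele_table()]).
#' @param min_coverage Minimum reads per population per site (default 5).
#' @return `sites` with an extra `freq_B` column.
#' @export
add_frequencies <- function(sites, min_coverage = 5) {
  n <- sites$count_A + sites$count_B
  sites$freq_B <- ifelse(n >= min_coverage, sites$count_B / n, NA_real_)
  sites
}

#' Polarize a single site
#'
#' The freshwater allele is whichever allele is rare (frequency strictly
#' below `low`) in the marine pool while common (strictly above `high`) in
#' at least one freshwater population. At most one allele can satisfy this
#' (both alleles cannot be below 0.2 in the marine pool).
#'
#' @param marine_counts Numeric length-2 vector `c(count_A, count_B)` for
#'   the marine pool.
#' @param fresh_counts Matrix or data frame with two columns (`count_A`,
#'   `count_B`), one row per freshwater population.
#' @param low,high Marker thresholds (defaults 0.2 and 0.8, strict).
#' @param min_coverage Coverage floor per population (default 5 reads).
#' @return `"A"`, `"B"`, or `NA_character_` when no allele qualifies or the
#'   marine pool is unscorable.
#' @export
polarize_site <- function(marine_counts, fresh_counts, low = 0.2, high = 0.8,
                          min_coverage = 5) {
  fresh_counts <- rbind(fresh_counts)
  nm <- sum(marine_counts)
  if (nm < min_coverage) return(NA_character_)
  fm_B <- marine_counts[2] / nm
  nf <- fresh_counts[, 1] + fresh_counts[, 2]
  ff_B <- ifelse(nf >= min_coverage, fresh_counts[, 2] / nf, NA_real_)
  if (fm_B < low && any(ff_B > high, na.rm = TRUE)) return("B")
  if ((1 - fm_B) < low && any((1 - ff_B) > high, na.rm = TRUE)) return("A")
  NA_character_
}

#' Call marker SNPs across all sites
#'
#' A site is a marker SNP when the marine pool carries one allele at a
#' frequency strictly below `low` and at least one of the freshwater
#' populations in `fresh_ids` carries the same allele at a frequency
#' strictly above `high`; that allele is the freshwater allele. Only the
#' populations in `fresh_ids` (the older freshwater populations) define
#' markers; additional populations listed in `score_ids` are scored for
#' frequencies but cannot create markers.
#'
#' @param sites Long allele table.
#' @param marine_id Marine population identifier.
#' @param fresh_ids Freshwater populations used for the marker definition.
#' @param score_ids Extra populations to report frequencies for (default
#'   none).
#' @param low,high Thresholds, strict (defaults 0.2 / 0.8).
#' @param min_coverage Coverage floor (default 5 reads).
#' @return Long marker table: one row per marker site and reported
#'   population, columns `chrom`, `pos`, `freshwater_allele` (base),
#'   `marine_freq` (freshwater-allele frequency in the marine pool),
#'   `population`, `fresh_freq` (freshwater-allele frequency, `NA` when
#'   coverage-missing), `is_marker` (does this population satisfy the
#'   definition). Attribute `n_sites_scored` records how many input sites
#'   had a scorable marine pool.
#' @export
call_marker_snps <- function(sites, marine_id, fresh_ids, score_ids = NULL,
                             low = 0.2, high = 0.8, min_coverage = 5) {
  pops <- allele_table_populations(sites)
  stopifnot(marine_id %in% pops, all(fresh_ids %in% pops))
  sites <- add_frequencies(sites, min_coverage)

  wide <- tidyr::pivot_wider(
    sites[, c("chrom", "pos", "population", "freq_B")],
    names_from = "population", values_from = "freq_B")
  fm <- wide[[marine_id]]
  FF <- as.matrix(wide[, fresh_ids, drop = FALSE])

  is_B <- !is.na(fm) & fm < low &
    rowSums(FF > high, na.rm = TRUE) > 0
  is_A <- !is.na(fm) & (1 - fm) < low &
    rowSums((1 - FF) > high, na.rm = TRUE) > 0
  marker <- is_A | is_B

  report_ids <- c(fresh_ids, setdiff(score_ids, fresh_ids))
  if (!any(marker)) {
    out <- tibble::tibble(chrom = character(), pos = integer(),
                          freshwater_allele = character(),
                          marine_freq = numeric(), population = character(),
                          fresh_freq = numeric(), is_marker = logical())
    attr(out, "populations") <- report_ids
    attr(out, "n_sites_scored") <- sum(!is.na(fm))
    return(out)
  }

  w <- wide[marker, ]
  fwB <- is_B[marker]                  # freshwater allele is B, else A
  site_tbl <- sites[!duplicated(paste(sites$chrom, sites$pos)), ]
  alle <- site_tbl[match(paste(w$chrom, w$pos),
                         paste(site_tbl$chrom, site_tbl$pos)), ]
  fw_base <- ifelse(fwB, alle$allele_B, alle$allele_A)
  marine_freq <- ifelse(fwB, fm[marker], 1 - fm[marker])

  RF <- as.matrix(w[, report_ids, drop = FALSE])
  fresh_freq <- RF
  fresh_freq[!fwB, ] <- 1 - RF[!fwB, , drop = FALSE]
  is_m <- matrix(FALSE, nrow(w), length(report_ids),
                 dimnames = list(NULL, report_ids))
  is_m[, fresh_ids] <- fresh_freq[, match(fresh_ids, report_ids)] > high
  is_m[is.na(is_m)] <- FALSE

  npop <- length(report_ids)
  out <- tibble::tibble(
    chrom = rep(w$chrom, each = npop),
    pos = rep(w$pos, each = npop),
    freshwater_allele = rep(fw_base, each = npop),
    marine_freq = rep(marine_freq, each = npop),
    population = rep(report_ids, times = nrow(w)),
    fresh_freq = as.vector(t(fresh_freq)),
    is_marker = as.vector(t(is_m))
  )
  out <- dplyr::arrange(out, match(.data$chrom, unique(sites$chrom)), .data$pos)
  attr(out, "populations") <- report_ids
  attr(out, "n_sites_scored") <- sum(!is.na(fm))
  out
}

#' Per-site between-population diversity Dxy
#'
#' `dxy = p11 * p22 + p12 * p21`, where `p11`/`p12` are the two allele
#' frequencies in one population and `p21`/`p22` the frequencies of the same
#' alleles in the other. Symmetric in the two populations; equals
#' `2 * p * (1 - p)` when both populations share frequency `p`.
#'
#' @param p11,p12 Allele frequencies in population 1 (must sum to 1).
#' @param p21,p22 Frequencies of the same two alleles in population 2.
#' @return Numeric vector in \[0, 1\].
#' @export
site_dxy <- function(p11, p12, p21, p22) {
  check_freq(c(p11, p12, p21, p22))
  if (any(abs(p11 + p12 - 1) > 1e-9) || any(abs(p21 + p22 - 1) > 1e-9)) {
    stop("allele frequencies within a population must sum to 1", call. = FALSE)
  }
  p11 * p22 + p12 * p21
}

#' Per-site nucleotide diversity pi
#'
#' `pi = 1 - (p1^2 + p2^2)` for a diallelic site; 0 at monomorphic sites and
#' at most 0.5 at p = 0.5.
#'
#' @param p1,p2 The two allele frequencies (must sum to 1).
#' @return Numeric vector in \[0, 0.5\].
#' @export
site_pi <- function(p1, p2) {
  check_freq(c(p1, p2))
  if (any(abs(p1 + p2 - 1) > 1e-9)) {
    stop("allele frequencies must sum to 1", call. = FALSE)
  }
  1 - (p1^2 + p2^2)
}

#' @keywords internal
check_freq <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("allele frequency outside [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Windowed Dxy or pi over non-overlapping genomic windows
#'
#' Averages the per-site statistic over all scorable sites of each
#' non-overlapping window (default 5 Kb). With two populations the window
#' value is mean Dxy between them; with one, mean pi. Sites missing in a
#' required population are skipped; windows with no scorable site are
#' absent from the result. Monomorphic sites contribute 0 unless the two
#' populations are fixed for different alleles.
#'
#' @param sites Long allele table.
#' @param pop_x Population id.
#' @param pop_y Optional second population; triggers Dxy.
#' @param window Window width in bp (default 5000).
#' @param min_coverage Coverage floor (default 5).
#' @return Tibble `chrom`, `start`, `end`, `n_sites`, and `dxy` or `pi`.
#' @export
window_popgen <- function(sites, pop_x, pop_y = NULL, window = 5000,
                          min_coverage = 5) {
  sites <- add_frequencies(sites, min_coverage)
  x <- sites[sites$population == pop_x, c("chrom", "pos", "freq_B")]
  if (is.null(pop_y)) {
    x <- x[!is.na(x$freq_B), ]
    x$value <- site_pi(1 - x$freq_B, x$freq_B)
    name <- "pi"
  } else {
    y <- sites[sites$population == pop_y, c("chrom", "pos", "freq_B")]
    stopifnot(nrow(x) == nrow(y), all(x$pos == y$pos))
    ok <- !is.na(x$freq_B) & !is.na(y$freq_B)
    xb <- x$freq_B[ok]
    yb <- y$freq_B[ok]
    x <- x[ok, ]
    x$value <- site_dxy(1 - xb, xb, 1 - yb, yb)
    name <- "dxy"
  }
  if (nrow(x) == 0) {
    out <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_sites = integer(), value = numeric())
    names(out)[names(out) == "value"] <- name
    return(out)
  }
  x$start <- floor(pos_to_zero(x$pos) / window) * window
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$chrom, .data$start),
    n_sites = dplyr::n(), value = mean(.data$value), .groups = "drop")
  out$end <- out$start + window
  out <- out[, c("chrom", "start", "end", "n_sites", "value")]
  names(out)[names(out) == "value"] <- name
  dplyr::arrange(out, .data$chrom, .data$start)
}
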