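NUCS <- c("A", "T", "C", "G")

#' Read a pooled allele-frequency table from a sync file
#'
#' Parses the popoolation2-style sync format produced downstream of samtools
#' mpileup: tab-separated columns chromosome, 1-based position, reference
#' allele, then one `A:T:C:G:N:del` count string per population. Sites with
#' more than two nucleotide alleles segregating across all populations are
#' excluded (the classic "1 or 2 alleles" rule) and counted in the
#' `n_excluded_multiallelic` attribute; sites with no nucleotide reads at all
#' are excluded and counted in `n_excluded_nodata`.
#'
#' @param path Path to the sync TSV. The file has no header; column order of
#'   the count strings must match `population_ids`, marine population first
#'   by convention.
#' @param population_ids Character vector naming the populations, one per
#'   count column, unique.
#' @return A long tibble with one row per retained site and population:
#'   columns `chrom`, `pos` (1-based), `allele_A` (reference allele when
#'   observed), `allele_B` (alternate allele or `NA` at monomorphic sites),
#'   `population`, `count_A`, `count_B`, `coverage` (nucleotide reads).
#'   Attributes: `populations`, `n_excluded_multiallelic`, `n_excluded_nodata`.
#' @export
read_allele_table <- function(path, population_ids) {
  population_ids <- as.character(population_ids)
  if (length(population_ids) < 1 || anyDuplicated(population_ids)) {
    stop("`population_ids` must be non-empty and unique", call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  npop <- length(population_ids)
  empty <- empty_allele_table(population_ids)
  if (length(lines) == 0) return(empty)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 3 + npop)
  if (length(bad)) {
    stop("malformed sync row at line ", bad[1], ": expected ", 3 + npop,
         " tab-separated fields, found ", nf[bad[1]], call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 3 + npop, byrow = TRUE)
  chrom <- m[, 1]
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) {
    stop("malformed sync row at line ", which(is.na(pos))[1],
         ": position is not an integer", call. = FALSE)
  }
  ref <- toupper(m[, 3])

  cnt_ok <- grepl("^[0-9]+(:[0-9]+){5}$", m[, 4:(3 + npop)])
  if (!all(cnt_ok)) {
    bad_line <- ((which(!cnt_ok)[1] - 1) %% nrow(m)) + 1
    stop("malformed sync row at line ", bad_line,
         ": count field is not six colon-separated integers", call. = FALSE)
  }

  # counts[site, pop, nuc] for A/T/C/G (N and del ignored throughout)
  n_site <- nrow(m)
  counts <- array(0L, dim = c(n_site, npop, 4L))
  for (j in seq_len(npop)) {
    parts <- matrix(as.integer(unlist(
      strsplit(m[, 3 + j], ":", fixed = TRUE))), ncol = 6, byrow = TRUE)
    counts[, j, ] <- parts[, 1:4]
  }
  total <- apply(counts, c(1, 3), sum)          # site x nucleotide
  n_alleles <- rowSums(total > 0)

  keep <- n_alleles %in% c(1L, 2L)
  n_multi <- sum(n_alleles > 2L)
  n_nodata <- sum(n_alleles == 0L)

  if (!any(keep)) {
    out <- empty
    attr(out, "n_excluded_multiallelic") <- n_multi
    attr(out, "n_excluded_nodata") <- n_nodata
    return(out)
  }

  counts <- counts[keep, , , drop = FALSE]
  total <- total[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]
  n_site <- sum(keep)

  # allele_A = reference when observed, else the first observed nucleotide;
  # allele_B = the other observed nucleotide (NA if monomorphic).
  obs <- total > 0
  first_obs <- NUCS[apply(obs, 1, which.max)]
  ref_obs <- obs[cbind(seq_len(n_site), match(ref, NUCS))]
  ref_obs[is.na(ref_obs)] <- FALSE
  allele_A <- ifelse(ref_obs, ref, first_obs)
  allele_B <- rep(NA_character_, n_site)
  two <- rowSums(obs) == 2L
  if (any(two)) {
    oi <- which(two)
    other <- vapply(oi, function(i) {
      nn <- NUCS[obs[i, ]]
      setdiff(nn, allele_A[i])[1]
    }, character(1))
    allele_B[oi] <- other
  }

  iA <- match(allele_A, NUCS)
  iB <- match(allele_B, NUCS)
  count_A <- matrix(0L, n_site, npop)
  count_B <- matrix(0L, n_site, npop)
  for (j in seq_len(npop)) {
    count_A[, j] <- counts[cbind(seq_len(n_site), j, iA)]
    hasB <- !is.na(iB)
    count_B[hasB, j] <- counts[cbind(which(hasB), j, iB[hasB])]
  }

  ord <- order(match(chrom, unique(chrom)), pos)
  if (anyDuplicated(paste(chrom, pos))) {
    stop("duplicate site (chrom, pos) in sync file", call. = FALSE)
  }
  cov_mat <- count_A + count_B
  out <- tibble::tibble(
    chrom = rep(chrom[ord], each = npop),
    pos = rep(pos[ord], each = npop),
    allele_A = rep(allele_A[ord], each = npop),
    allele_B = rep(allele_B[ord], each = npop),
    population = rep(population_ids, times = n_site),
    count_A = as.integer(t(count_A[ord, , drop = FALSE])),
    count_B = as.integer(t(count_B[ord, , drop = FALSE])),
    coverage = as.integer(t(cov_mat[ord, , drop = FALSE]))
  )
  attr(out, "populations") <- population_ids
  attr(out, "n_excluded_multiallelic") <- n_multi
  attr(out, "n_excluded_nodata") <- n_nodata
  out
}

#' @keywords internal
empty_allele_table <- function(population_ids) {
  out <- tibble::tibble(
    chrom = character(), pos = integer(), allele_A = character(),
    allele_B = character(), population = character(),
    count_A = integer(), count_B = integer(), coverage = integer()
  )
  attr(out, "populations") <- population_ids
  attr(out, "n_excluded_multiallelic") <- 0L
  attr(out, "n_excluded_nodata") <- 0L
  out
}

#' Write a pooled allele-frequency table to a sync file
#'
#' Inverse of [read_allele_table()]: emits chrom, pos, ref and one
#' `A:T:C:G:N:del` string per population (N and del always 0).
#'
#' @param sites Long allele table as returned by [read_allele_table()] or
#'   [simulate_pool_frequencies()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_table <- function(sites, path) {
  pops <- allele_table_populations(sites)
  wide <- dplyr::arrange(sites, match(.data$chrom, unique(.data$chrom)),
                         .data$pos, match(.data$population, pops))
  n <- nrow(wide) / length(pops)
  stopifnot(n == floor(n))
  cnt <- matrix("", nrow = n, ncol = length(pops))
  zeros <- function(k) integer(k)
  for (j in seq_along(pops)) {
    sub <- wide[wide$population == pops[j], ]
    vals <- matrix(0L, nrow(sub), 6)
    iA <- match(sub$allele_A, NUCS)
    vals[cbind(seq_len(nrow(sub)), iA)] <- sub$count_A
    hasB <- !is.na(sub$allele_B)
    iB <- match(sub$allele_B[hasB], NUCS)
    vals[cbind(which(hasB), iB)] <- sub$count_B[hasB]
    cnt[, j] <- apply(vals, 1, paste, collapse = ":")
  }
  site <- wide[wide$population == pops[1], c("chrom", "pos", "allele_A")]
  df <- cbind(site, as.data.frame(cnt))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @keywords internal
allele_table_populations <- function(sites) {
  pops <- attr(sites, "populations")
  if (is.null(pops)) pops <- unique(sites$population)
  pops
}

#' Write divergence islands to a BED file
#'
#' BED6, 0-based half-open; the name column is the island id and the score is
#' pervasiveness scaled by 1000 (0 when absent). Overlapping intervals are
#' written as-is, never merged.
#'
#' @param islands Tibble with columns `chrom`, `start`, `end`, and optionally
#'   `id` and `pervasiveness`.
#' @param path Output path.
#' @param genome Optional genome layout for bounds validation.
#' @return `path`, invisibly.
#' @export
write_islands_bed <- function(islands, path, genome = NULL) {
  validate_intervals(islands, genome)
  id <- if ("id" %in% names(islands)) islands$id else
    paste0("island_", seq_len(nrow(islands)))
  score <- if ("pervasiveness" %in% names(islands)) {
    as.integer(round(islands$pervasiveness * 1000))
  } else rep(0L, nrow(islands))
  df <- data.frame(chrom = islands$chrom,
                   start = format(islands$start, scientific = FALSE, trim = TRUE),
                   end = format(islands$end, scientific = FALSE, trim = TRUE),
                   name = id, score = score, strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read islands from a BED file
#'
#' @param path BED3+ file; columns beyond the sixth are ignored.
#' @param genome Optional genome layout for bounds validation.
#' @return Tibble with columns `chrom`, `start`, `end`, `id`,
#'   `pervasiveness` (score / 1000, `NA` when the file has no score column).
#' @export
read_islands_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), id = character(),
                          pervasiveness = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- min(lengths(fields))
  if (nf < 3) stop("BED file needs at least 3 columns", call. = FALSE)
  get <- function(k) vapply(fields, `[[`, character(1), k)
  out <- tibble::tibble(
    chrom = get(1),
    start = as.numeric(get(2)),
    end = as.numeric(get(3)),
    id = if (nf >= 4) get(4) else paste0("island_", seq_along(fields)),
    pervasiveness = if (nf >= 5) as.numeric(get(5)) / 1000 else NA_real_
  )
  validate_intervals(out, genome)
  out
}

#' Read a 10-Kb recombination map
#'
#' The map holds population-scaled recombination rates rho = 4\*Ne\*r per
#' 10 Kb window, tab-separated as chromosome, 0-based window start, rho.
#' Tiling against the genome layout is checked; 10 Kb windows of the layout
#' that are absent from the file are recorded in the `missing_windows`
#' attribute (absent, not zero) with a message.
#'
#' @param path TSV path (no header): chrom, start, rho.
#' @param genome Optional genome layout; enables the tiling check.
#' @param window Window width in bp (default 10000).
#' @return Tibble with columns `chrom`, `start`, `end`, `rho`.
#' @export
read_recomb_map <- function(path, genome = NULL, window = 10000) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric", "numeric"),
                          col.names = c("chrom", "start", "rho"))
  if (any(df$rho < 0)) {
    stop("negative rho at row ", which(df$rho < 0)[1], call. = FALSE)
  }
  if (any(df$start %% window != 0)) {
    stop("window start not a multiple of ", window, " at row ",
         which(df$start %% window != 0)[1], call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  out$end <- out$start + window
  out <- out[, c("chrom", "start", "end", "rho")]
  if (anyDuplicated(paste(out$chrom, out$start))) {
    stop("duplicate recombination window", call. = FALSE)
  }
  missing <- tibble::tibble(chrom = character(), start = numeric())
  if (!is.null(genome)) {
    check_genome(genome)
    for (i in seq_len(nrow(genome))) {
      starts <- seq(0, genome$length[i] - 1, by = window)
      have <- out$start[out$chrom == genome$chrom[i]]
      gap <- setdiff(starts, have)
      if (length(gap)) {
        missing <- dplyr::bind_rows(
          missing, tibble::tibble(chrom = genome$chrom[i], start = gap))
      }
    }
    if (nrow(missing)) {
      message(nrow(missing), " recombination windows absent from map ",
              "(recorded as missing, not zero)")
    }
  }
  attr(out, "missing_windows") <- missing
  out
}

#' Write a recombination map to TSV
#'
#' @param map Tibble with columns `chrom`, `start`, `rho` (as produced by
#'   [generate_recomb_map()] or [read_recomb_map()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recomb_map <- function(map, path) {
  utils::write.table(map[, c("chrom", "start", "rho")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
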