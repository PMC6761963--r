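#' Build a genome layout
#'
#' A genome layout is the ordered table of chromosome names and lengths that
#' every coordinate in the package is validated against. Internal coordinates
#' are 0-based half-open; site positions in allele tables are 1-based
#' (mpileup convention); BED output is 0-based half-open.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Integer vector of chromosome lengths in bp (positive).
#' @return A tibble with columns `chrom` and `length`, ordered as given.
#' @examples
#' genome_layout(c("chrI", "chrII"), c(28185914, 23295652))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != base::length(length)) {
    stop("`chrom` and `length` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome name: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(length)) || any(length <= 0) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers", call. = FALSE)
  }
  tibble::tibble(chrom = chrom, length = length)
}

#' Read a genome layout from a two-column TSV
#'
#' @param path Path to a headerless TSV with columns chromosome name and
#'   length in bp. Chromosomes keep file order.
#' @return A tibble with columns `chrom` and `length`.
#' @export
read_genome_layout <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric"),
                          col.names = c("chrom", "length"))
  genome_layout(df$chrom, df$length)
}

#' Write a genome layout to TSV
#'
#' @param genome A genome layout tibble (see [genome_layout()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_layout <- function(genome, path) {
  utils::write.table(genome, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @keywords internal
check_genome <- function(genome) {
  stopifnot(is.data.frame(genome), all(c("chrom", "length") %in% names(genome)))
  genome
}

#' Validate genomic intervals against a layout
#'
#' Intervals are 0-based half-open. Errors if any interval falls outside its
#' chromosome or has non-positive width.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`.
#' @param genome Optional genome layout; if supplied, interval ends must not
#'   exceed chromosome lengths.
#' @return `intervals`, invisibly, as a tibble.
#' @export
validate_intervals <- function(intervals, genome = NULL) {
  intervals <- tibble::as_tibble(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  bad <- which(!(intervals$start >= 0 & intervals$start < intervals$end))
  if (length(bad)) {
    stop("invalid interval (need 0 <= start < end) at row ", bad[1], call. = FALSE)
  }
  if (!is.null(genome)) {
    check_genome(genome)
    len <- genome$length[match(intervals$chrom, genome$chrom)]
    if (anyNA(len)) {
      stop("interval chromosome not in genome layout: ",
           intervals$chrom[which(is.na(len))[1]], call. = FALSE)
    }
    over <- which(intervals$end > len)
    if (length(over)) {
      stop("interval extends past chromosome end at row ", over[1], call. = FALSE)
    }
  }
  invisible(intervals)
}

#' Convert 1-based positions to 0-based coordinates and back
#'
#' Site positions in allele tables are 1-based; island intervals and BED
#' records are 0-based half-open. These two helpers are exact inverses.
#'
#' @param pos Integer vector of 1-based positions.
#' @return `pos_to_zero()`: 0-based positions; `zero_to_pos()`: 1-based.
#' @export
pos_to_zero <- function(pos) pos - 1L

#' @rdname pos_to_zero
#' @param zero Integer vector of 0-based positions.
#' @export
zero_to_pos <- function(zero) zero + 1L

# Short chromosome label: "chrIV" -> "IV", used for DI identifiers.
#' @keywords internal
chrom_label <- function(chrom) sub("^chr", "", chrom)
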