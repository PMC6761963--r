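#' Run the full divergence-island pipeline
#'
#' Orchestrates simulate (optional) -> marker calling -> island detection
#' -> island statistics -> clustering test as one reproducible run. The
#' configuration is a nested list (or path to a YAML file with the same
#' shape); every stage parameter defaults to the published value, and the
#' effective configuration is echoed into the run manifest together with
#' input checksums, the seed, and per-stage counts.
#'
#' Configuration shape (all `params` entries optional):
#' \preformatted{
#' seed: 1
#' out_dir: runs/a
#' input:                      # either a sync file...
#'   sync: sim/sites.sync
#'   genome: sim/genome.tsv
#'   marine: MAR
#'   fresh: [F01, F02, ...]
#'   recomb: sim/recomb.tsv    # optional
#' scenario:                   # ...or a built-in synthetic scenario
#'   n_chrom: 4
#'   chrom_length: 5000000
#'   n_fresh_pops: 6
#'   islands: {n: 4, min_len: 30000, max_len: 80000}
#' params:
#'   markers: {low: 0.2, high: 0.8, min_coverage: 5}
#'   detect:  {min_markers: 10, seed_min_freq: 0.5, decline: 0.3,
#'             min_len: 15000, merge_gap: 30000, min_any_pop_markers: 50,
#'             cross_merge: true, trim_to_markers: true}
#'   cluster: {run: true, statistic: close_pairs, n: 200, stratify: false}
#' }
#'
#' @param config Nested list or path to a YAML file.
#' @return Invisibly, a list with `manifest` (also written as
#'   `manifest.json`), `result` (the `di_result`), `markers`, and output
#'   paths. Stage errors abort with non-zero status in scripts; outputs
#'   written before the failure are renamed with a `.partial` suffix.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  if (is.null(config$out_dir)) stop("config$out_dir is missing", call. = FALSE)
  has_input <- !is.null(config$input)
  has_scen <- !is.null(config$scenario)
  if (!has_input && !has_scen) {
    stop("config needs either `input` (sync + genome) or `scenario`",
         call. = FALSE)
  }
  if (has_input && (is.null(config$input$genome) || is.null(config$input$sync))) {
    stop("config$input needs `sync` and `genome` paths", call. = FALSE)
  }

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(writer, path) {
    writer(path)
    written <<- c(written, path)
    path
  }
  on_fail <- function(e) {
    for (p in written) file.rename(p, paste0(p, ".partial"))
    stop("pipeline stage failed: ", conditionMessage(e), call. = FALSE)
  }

  tryCatch({
    counts <- list()
    checksums <- list()
    if (has_input) {
      genome <- read_genome_layout(config$input$genome)
      pops <- c(config$input$marine, unlist(config$input$fresh))
      sites <- read_allele_table(config$input$sync, pops)
      marine_id <- config$input$marine
      fresh_ids <- unlist(config$input$fresh)
      checksums$sync <- unname(tools::md5sum(config$input$sync))
      checksums$genome <- unname(tools::md5sum(config$input$genome))
      recomb <- if (!is.null(config$input$recomb)) {
        checksums$recomb <- unname(tools::md5sum(config$input$recomb))
        read_recomb_map(config$input$recomb, genome)
      }
    } else {
      sc <- config$scenario
      n_chrom <- sc$n_chrom %||% 4
      clen <- sc$chrom_length %||% 5e6
      genome <- genome_layout(paste0("chr", as.roman(seq_len(n_chrom))),
                              rep(clen, n_chrom))
      isl <- default_scenario_islands(genome, sc$islands$n %||% 4,
                                      sc$islands$min_len %||% 30000,
                                      sc$islands$max_len %||% 80000,
                                      config$seed)
      scfg <- scenario_config(
        genome, isl, n_fresh_pops = sc$n_fresh_pops %||% 6,
        exact_frequencies = isTRUE(sc$exact_frequencies),
        seed = config$seed)
      sim <- simulate_scenario(scfg)
      sites <- sim$sites
      recomb <- sim$recomb
      marine_id <- scfg$marine_id
      fresh_ids <- scfg$fresh_ids
      emit(function(p) write_allele_table(sites, p),
           file.path(out_dir, "sites.sync"))
      emit(function(p) write_genome_layout(genome, p),
           file.path(out_dir, "genome.tsv"))
      emit(function(p) write_recomb_map(recomb, p),
           file.path(out_dir, "recomb.tsv"))
      emit(function(p) write_islands_bed(
        dplyr::mutate(sim$truth$islands, id = .data$island_id,
                      pervasiveness = .data$pervasiveness_target),
        p, genome), file.path(out_dir, "truth.bed"))
      counts$sim_true_islands <- nrow(sim$truth$islands)
    }
    counts$sites <- nrow(dplyr::distinct(sites, .data$chrom, .data$pos))

    pm <- config$params$markers %||% list()
    markers <- call_marker_snps(sites, marine_id, fresh_ids,
                                low = pm$low %||% 0.2,
                                high = pm$high %||% 0.8,
                                min_coverage = pm$min_coverage %||% 5)
    counts$marker_snps <- nrow(dplyr::distinct(markers, .data$chrom, .data$pos))
    emit(function(p) readr::write_tsv(markers, p),
         file.path(out_dir, "markers.tsv"))

    pd <- config$params$detect %||% list()
    result <- detect_islands(
      markers, genome, populations = fresh_ids,
      window = pd$window %||% 10000, step = pd$step %||% 1000,
      min_markers = pd$min_markers %||% 10,
      seed_min_freq = pd$seed_min_freq %||% 0.5,
      decline = pd$decline %||% 0.30,
      min_len = pd$min_len %||% 15000,
      merge_gap = pd$merge_gap %||% 30000,
      min_any_pop_markers = pd$min_any_pop_markers %||% 50,
      cross_merge = pd$cross_merge %||% TRUE,
      trim_to_markers = pd$trim_to_markers %||% TRUE)
    counts$candidates <- nrow(result$candidates)
    counts$islands_kept <- nrow(result$islands)
    counts$population_level_islands <- nrow(result$pop_islands)
    emit(function(p) write_islands_bed(result$islands, p, genome),
         file.path(out_dir, "islands.bed"))
    emit(function(p) readr::write_tsv(result$members, p),
         file.path(out_dir, "members.tsv"))

    ov <- island_overlap(result, markers)
    stats_tbl <- dplyr::left_join(tidy(result), ov$islands, by = "island_id")
    emit(function(p) readr::write_tsv(stats_tbl, p),
         file.path(out_dir, "stats.tsv"))

    pc <- config$params$cluster %||% list()
    cluster <- NULL
    if (isTRUE(pc$run %||% TRUE) && nrow(result$islands) >= 2) {
      strata <- if (isTRUE(pc$stratify) && !is.null(recomb)) {
        build_strata(recomb, genome)
      }
      cluster <- permutation_test(
        result$islands, genome,
        statistic = pc$statistic %||% "close_pairs", strata = strata,
        n = pc$n %||% 1000, seed = config$seed,
        max_gap = pc$max_gap %||% 1e6)
      emit(function(p) jsonlite::write_json(
        glance(cluster), p, auto_unbox = TRUE, digits = NA),
        file.path(out_dir, "cluster.json"))
    }

    manifest <- list(
      seed = config$seed,
      config = config,
      checksums = checksums,
      counts = counts,
      outputs = written
    )
    json <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, json, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    invisible(list(manifest = manifest, manifest_path = json,
                   result = result, markers = markers, cluster = cluster,
                   genome = genome, out_dir = out_dir))
  }, error = on_fail)
}

# Evenly spaced non-overlapping island intervals for the built-in scenario.
#' @keywords internal
default_scenario_islands <- function(genome, n, min_len, max_len, seed) {
  withr::with_seed(seed, {
    chrom <- rep(genome$chrom, length.out = n)
    lens <- round(stats::runif(n, min_len, max_len) / 1000) * 1000
    start <- numeric(n)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      L <- genome$length[match(ch, genome$chrom)]
      gap <- floor(L / (length(idx) + 1))
      start[idx] <- gap * seq_along(idx)
    }
    tibble::tibble(chrom = chrom, start = start, end = start + lens,
                   pervasiveness_target = rep(c(1, 0.8, 0.6, 0.5),
                                              length.out = n))
  })
}

#' Compare two pipeline runs
#'
#' Reads the island sets of two run manifests (or accepts `di_result`
#' objects) and reports, for every island of run A, the Jaccard overlap
#' with its best-matching island of run B, plus islands private to either
#' run and the global length-weighted Jaccard of the two interval sets.
#'
#' @param a,b Paths to `manifest.json` files, or `di_result` objects.
#' @return List with `per_island` (tibble: id, best-match id, jaccard),
#'   `only_a`, `only_b` (character ids), `global_jaccard`.
#' @export
compare_runs <- function(a, b) {
  get_islands <- function(x) {
    if (inherits(x, "di_result")) return(x$islands)
    mf <- jsonlite::read_json(x)
    bed <- file.path(dirname(x), "islands.bed")
    read_islands_bed(bed)
  }
  ia <- get_islands(a)
  ib <- get_islands(b)
  jac <- function(s1, e1, s2, e2) {
    inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
    inter / (pmax(e1, e2) - pmin(s1, s2))
  }
  per <- vector("list", nrow(ia))
  for (i in seq_len(nrow(ia))) {
    cand <- ib[ib$chrom == ia$chrom[i], ]
    if (nrow(cand) == 0) {
      per[[i]] <- tibble::tibble(id_a = ia$id[i], id_b = NA_character_,
                                 jaccard = 0)
      next
    }
    jj <- jac(ia$start[i], ia$end[i], cand$start, cand$end)
    k <- which.max(jj)
    per[[i]] <- tibble::tibble(id_a = ia$id[i],
                               id_b = if (jj[k] > 0) cand$id[k] else NA_character_,
                               jaccard = jj[k])
  }
  per <- dplyr::bind_rows(per)
  matched_b <- per$id_b[!is.na(per$id_b)]
  total_len <- function(x) sum(x$end - x$start)
  inter_len <- 0
  for (i in seq_len(nrow(ia))) {
    cand <- ib[ib$chrom == ia$chrom[i], ]
    if (nrow(cand)) {
      inter_len <- inter_len +
        sum(pmax(0, pmin(ia$end[i], cand$end) - pmax(ia$start[i], cand$start)))
    }
  }
  union_len <- total_len(ia) + total_len(ib) - inter_len
  list(per_island = per,
       only_a = per$id_a[per$jaccard == 0],
       only_b = setdiff(ib$id, matched_b),
       global_jaccard = if (union_len > 0) inter_len / union_len else 1)
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x
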