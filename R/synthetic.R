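#' Describe a synthetic marine/freshwater pool-seq scenario
#'
#' A scenario emulates the study design behind a divergence-island scan: one
#' marine population carrying freshwater alleles at low frequency, and
#' `n_fresh_pops` independently derived freshwater populations in which
#' implanted islands carry freshwater alleles at high frequency in the
#' populations that "responded". Islands are described one per row of
#' `islands`; per-island columns override the scenario-wide defaults.
#'
#' The frequency model, per site and population:
#' * background (non-island) sites: one allele frequency drawn from
#'   `Beta(marine_beta[1], marine_beta[2])` and shared by every population,
#'   so background divergence between populations comes from sampling noise
#'   only;
#' * marker sites, marine population: independent draws from the same Beta
#'   (mean 0.1 with the default `c(1, 9)`, matching the low frequency at
#'   which marine pools carry freshwater alleles);
#' * marker sites carried by a responding population: one frequency per
#'   island and population drawn from a Beta with mean `fresh_freq_mean` and
#'   concentration `fresh_freq_conc`, shared by all that population's marker
#'   sites in the island (a haplotype-block abstraction -- the pipeline
#'   consumes frequencies, not haplotypes);
#' * marker sites recruited only by *other* responding populations: per-site
#'   draws with mean `offtarget_freq_mean`, the intermediate frequencies
#'   that motivate the 0.5-0.8 sharing correction of [overlap_R()];
#' * any island site in a non-responding population: marine-like draws.
#'
#' Observed counts are binomial in the pool coverage
#' (`coverage ~ Poisson(mean_coverage)` per population), or exact relative
#' frequencies when `exact_frequencies = TRUE`.
#'
#' @param genome Genome layout ([genome_layout()]).
#' @param islands Tibble with columns `chrom`, `start`, `end` and optionally
#'   `pervasiveness_target`, `marker_density` (marker SNPs per Kb per
#'   responding population), `overlap_target` (intended pairwise marker
#'   sharing R*), `fresh_freq_mean`, `offtarget_freq_mean`. Islands must not
#'   overlap.
#' @param n_fresh_pops Number of freshwater populations (default 10).
#' @param pervasiveness_target,marker_density,overlap_target,fresh_freq_mean,offtarget_freq_mean
#'   Scenario-wide defaults for the per-island columns: fraction of
#'   populations responding (1), markers per Kb per population (3), intended
#'   sharing fraction (0.8), mean freshwater-allele frequency at recruited
#'   sites in responding populations (0.95), and mean frequency at sites
#'   recruited only by other populations (0.45).
#' @param background_snp_density Background SNPs per Kb outside islands
#'   (default 0.05).
#' @param marine_beta Beta shape parameters for marine / background
#'   frequencies, default `c(1, 9)` (mean 0.1).
#' @param fresh_freq_conc,offtarget_conc Beta concentrations (a+b) for the
#'   responding-population and off-target frequency draws (100 and 10).
#' @param mean_coverage Mean pool coverage per population; recycled to
#'   `n_fresh_pops + 1` values (marine first), default 36.
#' @param pool_sizes Fish per pool (metadata only; pool-size-aware
#'   estimators are out of scope), default 20.
#' @param exact_frequencies If TRUE, observed frequencies equal the drawn
#'   frequencies exactly (the infinite-coverage limit); counts are scaled
#'   reals, not reads.
#' @param marine_id,fresh_ids Population identifiers; marine first in all
#'   outputs.
#' @param rho_background_mean,rho_island_ratio,rho_shape Recombination map
#'   model: background 10 Kb windows draw rho from a Gamma with this mean
#'   and shape; windows overlapping islands use mean
#'   `rho_background_mean * rho_island_ratio` (default 6.63/8.24, the
#'   island-vs-genome ratio reported for stickleback).
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A `scenario_config` list, validated.
#' @export
scenario_config <- function(genome, islands,
                            n_fresh_pops = 10,
                            pervasiveness_target = 1,
                            marker_density = 3,
                            overlap_target = 0.8,
                            fresh_freq_mean = 0.95,
                            offtarget_freq_mean = 0.45,
                            background_snp_density = 0.05,
                            marine_beta = c(1, 9),
                            fresh_freq_conc = 100,
                            offtarget_conc = 10,
                            mean_coverage = 36,
                            pool_sizes = 20,
                            exact_frequencies = FALSE,
                            marine_id = "MAR",
                            fresh_ids = NULL,
                            rho_background_mean = 8.24,
                            rho_island_ratio = 6.63 / 8.24,
                            rho_shape = 4,
                            seed = 1) {
  check_genome(genome)
  islands <- tibble::as_tibble(islands)
  validate_intervals(islands, genome)
  fill <- function(col, default) {
    if (!col %in% names(islands)) islands[[col]] <<- default
    islands[[col]][is.na(islands[[col]])] <<- default
  }
  fill("pervasiveness_target", pervasiveness_target)
  fill("marker_density", marker_density)
  fill("overlap_target", overlap_target)
  fill("fresh_freq_mean", fresh_freq_mean)
  fill("offtarget_freq_mean", offtarget_freq_mean)
  if (!"island_id" %in% names(islands)) {
    islands$island_id <- paste0("sim_", seq_len(nrow(islands)))
  }
  stopifnot(n_fresh_pops >= 1,
            all(islands$overlap_target >= 0 & islands$overlap_target <= 1),
            all(islands$pervasiveness_target >= 0 &
                  islands$pervasiveness_target <= 1),
            all(islands$marker_density > 0),
            all(islands$fresh_freq_mean > 0.5 & islands$fresh_freq_mean <= 1),
            background_snp_density > 0, length(marine_beta) == 2,
            all(marine_beta > 0))
  # islands must not overlap (same chromosome)
  ord <- order(islands$chrom, islands$start)
  si <- islands[ord, ]
  same <- si$chrom[-1] == si$chrom[-nrow(si)]
  if (nrow(si) > 1 && any(same & si$start[-1] < si$end[-nrow(si)])) {
    stop("islands overlap", call. = FALSE)
  }
  if (is.null(fresh_ids)) {
    fresh_ids <- sprintf("F%02d", seq_len(n_fresh_pops))
  }
  stopifnot(length(fresh_ids) == n_fresh_pops,
            !marine_id %in% fresh_ids, !anyDuplicated(fresh_ids))
  mean_coverage <- rep_len(mean_coverage, n_fresh_pops + 1)
  structure(list(
    genome = genome, islands = islands, n_fresh_pops = n_fresh_pops,
    background_snp_density = background_snp_density,
    marine_beta = marine_beta, fresh_freq_conc = fresh_freq_conc,
    offtarget_conc = offtarget_conc, mean_coverage = mean_coverage,
    pool_sizes = pool_sizes, exact_frequencies = exact_frequencies,
    marine_id = marine_id, fresh_ids = fresh_ids,
    rho_background_mean = rho_background_mean,
    rho_island_ratio = rho_island_ratio, rho_shape = rho_shape,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

# Beta draw parameterized by mean and concentration; mean 1 is a point mass.
#' @keywords internal
rbeta_mean <- function(n, mean, conc) {
  if (mean >= 1) return(rep(1, n))
  if (mean <= 0) return(rep(0, n))
  stats::rbeta(n, conc * mean, conc * (1 - mean))
}

#' Generate the ground truth of a synthetic scenario
#'
#' Chooses, for every island, which freshwater populations respond
#' (`round(pervasiveness_target * n_fresh_pops)` of them) and the marker
#' sites each responding population carries: a shared set (fraction
#' `overlap_target` of the per-population marker count) common to all
#' responding populations, plus disjoint population-private sets, so the
#' intended pairwise sharing equals `overlap_target`.
#'
#' @param config A [scenario_config()].
#' @return A `synthetic_truth` list with elements `islands` (tibble with
#'   `island_id`, interval, `n_responding`), `responses` (island x
#'   population flags), and `markers` (long tibble: `island_id`, `chrom`,
#'   `pos`, `population`, `shared`), deterministic given `config$seed`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  withr::with_seed(config$seed, {
    isl <- config$islands
    n_pop <- config$n_fresh_pops
    responses <- vector("list", nrow(isl))
    markers <- vector("list", nrow(isl))
    n_resp <- integer(nrow(isl))
    for (i in seq_len(nrow(isl))) {
      len_kb <- (isl$end[i] - isl$start[i]) / 1000
      m <- max(1L, round(isl$marker_density[i] * len_kb))
      s <- round(isl$overlap_target[i] * m)
      k <- round(isl$pervasiveness_target[i] * n_pop)
      n_resp[i] <- k
      resp <- sort(sample.int(n_pop, k))
      responses[[i]] <- tibble::tibble(
        island_id = isl$island_id[i], population = config$fresh_ids,
        responding = seq_len(n_pop) %in% resp)
      if (k == 0) next
      n_sites <- s + k * (m - s)
      span <- isl$end[i] - isl$start[i]
      if (n_sites > span) {
        stop("island ", isl$island_id[i], " too short for requested marker",
             " density", call. = FALSE)
      }
      pos <- sort(sample.int(span, n_sites)) + isl$start[i]  # 1-based in (start, end]
      shared_idx <- sort(sample.int(n_sites, s))
      shared_pos <- pos[shared_idx]
      rest <- pos[setdiff(seq_len(n_sites), shared_idx)]
      rest <- rest[sample.int(length(rest))]
      per_pop <- vector("list", k)
      for (j in seq_len(k)) {
        priv <- if (m - s > 0) rest[((j - 1) * (m - s) + 1):(j * (m - s))] else integer()
        per_pop[[j]] <- tibble::tibble(
          island_id = isl$island_id[i], chrom = isl$chrom[i],
          pos = c(shared_pos, priv),
          population = config$fresh_ids[resp[j]],
          shared = c(rep(TRUE, s), rep(FALSE, length(priv))))
      }
      markers[[i]] <- dplyr::bind_rows(per_pop)
    }
    out <- list(
      islands = dplyr::mutate(isl, n_responding = n_resp),
      responses = dplyr::bind_rows(responses),
      markers = dplyr::bind_rows(markers),
      config = config
    )
    class(out) <- "synthetic_truth"
    out
  })
}

#' Simulate pooled allele frequencies for a scenario
#'
#' Draws per-site population allele frequencies under the model described in
#' [scenario_config()] and samples read counts from them, returning a long
#' allele table in the same shape as [read_allele_table()]. The drawn
#' frequencies are attached as attribute `true_freq` for validation.
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param config The same [scenario_config()]; defaults to the one stored in
#'   `truth`.
#' @return Long tibble: `chrom`, `pos`, `allele_A`, `allele_B`,
#'   `population`, `count_A`, `count_B`, `coverage`. The alternate allele
#'   ("T") is the freshwater allele at marker sites. With
#'   `exact_frequencies`, counts are scaled so `count_B / (count_A +
#'   count_B)` equals the drawn frequency exactly.
#' @export
simulate_pool_frequencies <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  withr::with_seed(config$seed + 1L, {
    genome <- config$genome
    pops <- c(config$marine_id, config$fresh_ids)
    npop <- length(pops)

    # --- site list: background + island marker sites ---------------------
    bg <- vector("list", nrow(genome))
    isl <- config$islands
    for (i in seq_len(nrow(genome))) {
      n_bg <- round(config$background_snp_density * genome$length[i] / 1000)
      if (n_bg == 0) next
      p <- sort(sample.int(genome$length[i], n_bg))
      ii <- isl[isl$chrom == genome$chrom[i], ]
      if (nrow(ii)) {
        inside <- rep(FALSE, length(p))
        for (r in seq_len(nrow(ii))) {
          inside <- inside | (p > ii$start[r] & p <= ii$end[r])
        }
        p <- p[!inside]
      }
      bg[[i]] <- tibble::tibble(chrom = genome$chrom[i], pos = p)
    }
    bg <- dplyr::bind_rows(bg)

    mk <- truth$markers
    mk_sites <- dplyr::distinct(mk, .data$island_id, .data$chrom, .data$pos)

    # --- frequency matrix (site x population) ----------------------------
    site <- dplyr::bind_rows(
      dplyr::mutate(bg, island_id = NA_character_),
      mk_sites[, c("chrom", "pos", "island_id")]
    )
    site <- dplyr::arrange(site, match(.data$chrom, genome$chrom), .data$pos)
    ns <- nrow(site)
    P <- matrix(NA_real_, ns, npop, dimnames = list(NULL, pops))

    is_bg <- is.na(site$island_id)
    if (any(is_bg)) {
      p_shared <- stats::rbeta(sum(is_bg), config$marine_beta[1],
                               config$marine_beta[2])
      P[is_bg, ] <- matrix(rep(p_shared, npop), ncol = npop)
    }

    # marine + default fresh draws at marker sites: marine-like, independent
    n_mk <- sum(!is_bg)
    if (n_mk) {
      P[!is_bg, ] <- matrix(
        stats::rbeta(n_mk * npop, config$marine_beta[1], config$marine_beta[2]),
        ncol = npop)
    }

    # responding populations: one frequency per island x population at
    # recruited sites; off-target (other pops' markers) intermediate draws
    key <- function(chrom, pos) paste(chrom, pos)
    site_index <- stats::setNames(seq_len(ns), key(site$chrom, site$pos))
    resp <- truth$responses[truth$responses$responding, , drop = FALSE]
    for (r in seq_len(nrow(resp))) {
      iid <- resp$island_id[r]; pop <- resp$population[r]
      irow <- which(config$islands$island_id == iid)
      all_sites <- mk_sites[mk_sites$island_id == iid, ]
      own <- mk[mk$island_id == iid & mk$population == pop, ]
      idx_all <- site_index[key(all_sites$chrom, all_sites$pos)]
      idx_own <- site_index[key(own$chrom, own$pos)]
      jj <- match(pop, pops)
      # off-target first, then overwrite own sites with the block frequency
      P[idx_all, jj] <- rbeta_mean(length(idx_all),
                                   config$islands$offtarget_freq_mean[irow],
                                   config$offtarget_conc)
      p_block <- rbeta_mean(1, config$islands$fresh_freq_mean[irow],
                            config$fresh_freq_conc)
      P[idx_own, jj] <- p_block
    }

    # --- read sampling ---------------------------------------------------
    if (config$exact_frequencies) {
      S <- 2^20
      count_B <- P * S
      count_A <- S - count_B
      coverage <- matrix(S, ns, npop)
    } else {
      coverage <- matrix(
        stats::rpois(ns * npop, rep(config$mean_coverage, each = ns)),
        ns, npop)
      count_B <- matrix(
        stats::rbinom(ns * npop, as.vector(coverage), as.vector(P)), ns, npop)
      count_A <- coverage - count_B
    }

    out <- tibble::tibble(
      chrom = rep(site$chrom, each = npop),
      pos = rep(site$pos, each = npop),
      allele_A = "A", allele_B = "T",
      population = rep(pops, times = ns),
      count_A = as.vector(t(count_A)),
      count_B = as.vector(t(count_B)),
      coverage = as.vector(t(coverage))
    )
    attr(out, "populations") <- pops
    attr(out, "true_freq") <- tibble::tibble(
      chrom = rep(site$chrom, each = npop),
      pos = rep(site$pos, each = npop),
      population = rep(pops, times = ns),
      p = as.vector(t(P))
    )
    out
  })
}

#' Generate a synthetic 10-Kb recombination map
#'
#' Tiles the genome with 10 Kb windows and draws rho from a Gamma
#' distribution; windows overlapping implanted islands use a mean reduced by
#' `rho_island_ratio`, emulating the tendency of divergence islands to sit
#' in low-recombination regions.
#'
#' @inheritParams simulate_pool_frequencies
#' @param window Window width in bp (default 10000).
#' @return Tibble `chrom`, `start`, `end`, `rho`, deterministic given
#'   `config$seed`.
#' @export
generate_recomb_map <- function(truth, config = truth$config, window = 10000) {
  withr::with_seed(config$seed + 2L, {
    genome <- config$genome
    maps <- vector("list", nrow(genome))
    isl <- config$islands
    for (i in seq_len(nrow(genome))) {
      starts <- seq(0, genome$length[i] - 1, by = window)
      ends <- pmin(starts + window, genome$length[i])
      in_island <- rep(FALSE, length(starts))
      ii <- isl[isl$chrom == genome$chrom[i], ]
      for (r in seq_len(nrow(ii))) {
        in_island <- in_island | (starts < ii$end[r] & ends > ii$start[r])
      }
      mu <- ifelse(in_island,
                   config$rho_background_mean * config$rho_island_ratio,
                   config$rho_background_mean)
      rho <- stats::rgamma(length(starts), shape = config$rho_shape,
                           rate = config$rho_shape / mu)
      maps[[i]] <- tibble::tibble(chrom = genome$chrom[i], start = starts,
                                  end = ends, rho = rho)
    }
    dplyr::bind_rows(maps)
  })
}

#' Run a full synthetic scenario
#'
#' Convenience wrapper: [generate_truth()], [simulate_pool_frequencies()]
#' and [generate_recomb_map()] in one call.
#'
#' @param config A [scenario_config()].
#' @return List with elements `truth`, `sites`, `recomb` and `config`,
#'   of class `archipelago_sim`.
#' @export
simulate_scenario <- function(config) {
  truth <- generate_truth(config)
  sites <- simulate_pool_frequencies(truth, config)
  recomb <- generate_recomb_map(truth, config)
  structure(list(truth = truth, sites = sites, recomb = recomb,
                 config = config), class = "archipelago_sim")
}
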