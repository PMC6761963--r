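# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a divergence-island scan
#'
#' @param x A `di_result` from [detect_islands()].
#' @param ... Unused.
#' @return The island table: one row per island with interval, length,
#'   pervasiveness, core and periphery.
#' @method tidy di_result
#' @export
tidy.di_result <- function(x, ...) {
  out <- x$islands
  names(out)[names(out) == "id"] <- "island_id"
  tibble::as_tibble(out)
}

#' @rdname tidy.di_result
#' @method glance di_result
#' @export
glance.di_result <- function(x, ...) {
  isl <- x$islands
  tibble::tibble(
    n_islands = nrow(isl),
    n_universal = sum(isl$pervasiveness == 1, na.rm = TRUE),
    mean_pervasiveness = mean(isl$pervasiveness, na.rm = TRUE),
    total_length = sum(isl$length),
    mean_core_length = mean(isl$core_length, na.rm = TRUE),
    n_populations = length(x$params$populations)
  )
}

#' Tidy a permutation test
#'
#' @param x A `permutation_result` from [permutation_test()].
#' @param ... Unused.
#' @return `tidy()`: one row per permutation draw; `glance()`: a one-row
#'   summary with the observed value, null mean, and p-value.
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(trial = seq_along(x$null_draws), value = x$null_draws)
}

#' @rdname tidy.permutation_result
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic_name,
    observed = x$observed,
    null_mean = x$expected,
    p_value = x$p_value,
    n_permutations = x$n_permutations,
    stratified = x$stratified,
    seed = x$seed
  )
}
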