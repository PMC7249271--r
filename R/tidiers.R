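#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-individual calls of a marker screen
#'
#' @param x An `ssr_screen` object from [screen_markers()].
#' @param ... Unused.
#' @return Tibble with one row per (marker, individual) call, carrying the
#'   marker status.
#' @export
tidy.ssr_screen <- function(x, ...) {
  as_tibble(x) |>
    mutate(calls = purrr::map(.data$calls, function(cc) {
      cc[setdiff(names(cc), "marker_id")]
    })) |>
    select("marker_id", "status", "ref_n_repeats", "calls") |>
    tidyr::unnest("calls")
}

#' @rdname tidy.ssr_screen
#' @return `glance()` returns a one-row tibble of per-status marker counts.
#' @export
glance.ssr_screen <- function(x, ...) {
  tibble(
    n_markers = nrow(x),
    n_polymorphic = sum(x$status == "POLYMORPHIC"),
    n_monomorphic = sum(x$status == "MONOMORPHIC"),
    n_insufficient = sum(x$status == "INSUFFICIENT"),
    mean_valid_calls = mean(x$n_valid)
  )
}

#' Tidy and summarise a diversity panel
#'
#' @param x An `ssr_diversity` tibble from [diversity_table()].
#' @param ... Unused.
#' @return `tidy()` returns the panel in long form (one row per population,
#'   locus and statistic); `glance()` a one-row summary.
#' @export
tidy.ssr_diversity <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(c("A", "Ap", "Ho", "Hs", "hwe_p"),
                        names_to = "statistic", values_to = "value")
}

#' @rdname tidy.ssr_diversity
#' @export
glance.ssr_diversity <- function(x, ...) {
  per_pop <- filter(as_tibble(x), .data$population != "All")
  tibble(
    n_loci = length(unique(x$locus)),
    n_populations = length(unique(per_pop$population)),
    Ho_min = min(per_pop$Ho, na.rm = TRUE),
    Ho_max = max(per_pop$Ho, na.rm = TRUE),
    Hs_min = min(per_pop$Hs, na.rm = TRUE),
    Hs_max = max(per_pop$Hs, na.rm = TRUE),
    prop_hwe_rejected = mean(per_pop$hwe_p < 0.05, na.rm = TRUE)
  )
}

#' Tidy and summarise a linkage-disequilibrium panel
#'
#' @param x An `ssr_ld` tibble from [ld_table()].
#' @param ... Unused.
#' @return `tidy()` returns the underlying tibble; `glance()` the observed
#'   range of `rbar_d` and the fraction of significant pairs per the
#'   permutation test.
#' @export
tidy.ssr_ld <- function(x, ...) as_tibble(x)

#' @rdname tidy.ssr_ld
#' @export
glance.ssr_ld <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    rbar_d_min = suppressWarnings(min(x$rbar_d, na.rm = TRUE)),
    rbar_d_max = suppressWarnings(max(x$rbar_d, na.rm = TRUE)),
    prop_significant = mean(x$perm_p < 0.05, na.rm = TRUE)
  )
}
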