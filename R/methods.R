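# tidy()/glance()/autoplot() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trio HMM decode into its segment table
#' @param x a `trio_decode` from [viterbi_decode()].
#' @param ... unused.
#' @return segment tibble `chrom, start, end, state, n_sites`.
#' @exportS3Method generics::tidy
tidy.trio_decode <- function(x, ...) x$segments

#' One-row summary of a trio HMM decode
#' @param x a `trio_decode`.
#' @param ... unused.
#' @return tibble with observation/segment counts and the fraction of sites
#'   in each state.
#' @exportS3Method generics::glance
glance.trio_decode <- function(x, ...) {
  n <- nrow(x$path)
  tibble(
    n_obs = n,
    n_segments = nrow(x$segments),
    n_chrom = length(unique(x$path$chrom)),
    frac_good = mean(x$path$state == "GOOD"),
    frac_compression = mean(x$path$state == "COMPRESSION"),
    frac_mia_rich = mean(x$path$state == "MIA_RICH")
  )
}

#' Plot decoded inheritance segments along the genome
#' @param object a `trio_decode`.
#' @param ... unused.
#' @return a ggplot: one horizontal track per chromosome, segments colored by
#'   state, observed sites as ticks.
#' @exportS3Method ggplot2::autoplot
autoplot.trio_decode <- function(object, ...) {
  seg <- object$segments
  ggplot2::ggplot(seg) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start / 1e6, xmax = .data$end / 1e6,
      ymin = 0, ymax = 1, fill = .data$state
    )) +
    ggplot2::geom_point(
      data = object$path,
      ggplot2::aes(x = .data$pos / 1e6, y = -0.15,
                   shape = .data$symbol),
      size = 0.5, alpha = 0.5
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom)) +
    ggplot2::scale_fill_manual(values = c(
      GOOD = "#4daf4a", COMPRESSION = "#377eb8", MIA_RICH = "#e41a1c"
    )) +
    ggplot2::labs(x = "position (Mb)", y = NULL, fill = "state",
                  shape = "symbol") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Tidy star-allele calls (one row per candidate diplotype)
#' @param x a `star_calls` tibble from [call_star_alleles()].
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.star_calls <- function(x, ...) {
  tidyr::unnest(
    select(as_tibble(x), "gene", "status", "candidates"),
    "candidates", keep_empty = TRUE
  ) %>% rename(diplotype = "candidates")
}

#' One-row-per-gene summary of star-allele calls
#' @param x a `star_calls` tibble.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.star_calls <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_resolved = sum(x$status == "RESOLVED"),
    n_ambiguous = sum(x$status == "AMBIGUOUS"),
    n_unassigned = sum(x$status == "UNASSIGNED")
  )
}

#' Bar chart of tier counts per track
#' @param tiers output of [assign_tiers()] or [prioritize_variants()].
#' @return a ggplot.
#' @export
plot_tier_summary <- function(tiers) {
  ggplot2::ggplot(tier_summary(tiers)) +
    ggplot2::geom_col(ggplot2::aes(x = factor(.data$tier), y = .data$n,
                                   fill = .data$track),
                      position = "dodge") +
    ggplot2::labs(x = "tier", y = "variants", fill = "track") +
    ggplot2::theme_minimal()
}
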