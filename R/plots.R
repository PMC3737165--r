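#' Plot a per-category classification summary
#'
#' Bar chart of SNP counts per category for each family and overall.
#'
#' @param object A [summarize_classes()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nullscan_summary <- function(object, ...) {
  fams <- attr(object, "families") %||% c("family 1", "family 2")
  long <- object |>
    dplyr::select("category", "n_family1", "n_family2", "n_overall") |>
    tidyr::pivot_longer(-"category", names_to = "scope", values_to = "n") |>
    dplyr::mutate(scope = dplyr::recode(.data$scope,
                                        n_family1 = paste("family", fams[[1L]]),
                                        n_family2 = paste("family", fams[[2L]]),
                                        n_overall = "overall"),
                  category = factor(.data$category, levels = CATEGORIES))
  ggplot2::ggplot(dplyr::filter(long, .data$category != "consistent"),
                  ggplot2::aes(x = .data$category, y = .data$n,
                               fill = .data$scope)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "SNPs", fill = NULL,
                  title = "Null-allele classes and error categories") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot candidate deletion regions along the genome
#'
#' @param object A [call_deletions()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deletion_calls <- function(object, ...) {
  df <- dplyr::mutate(object,
                      label = paste0("region", .data$region, " (",
                                     round(.data$size_kb, 1), " kb)"))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$chrom)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$pos1 / 1e6,
                                       xend = .data$pos2 / 1e6,
                                       yend = .data$chrom),
                          linewidth = 3, colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(x = .data$pos2 / 1e6, label = .data$label),
                       hjust = -0.1, size = 3) +
    ggplot2::labs(x = "position (Mb)", y = "chromosome",
                  title = "Candidate deletions from linked null alleles") +
    ggplot2::theme_minimal()
}
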