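#' Violin/box summary of LED distributions per species
#'
#' @param led data.frame with columns `led_x`, `led_y`, `led_z` (raw or
#'   per-generation scaled).
#' @param species three species labels, in x/y/z order.
#' @return a ggplot object, or NULL with a warning when ggplot2 is not
#'   installed.
#' @export
plotLedDistributions <- function(led, species = c("species_x", "species_y",
                                                  "species_z")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; skipping plot")
    return(invisible(NULL))
  }
  long <- data.frame(
    species = factor(rep(species, each = nrow(led)), levels = species),
    led = c(led$led_x, led$led_y, led$led_z)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = species, y = led)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.12, notch = TRUE, outlier.size = 0.3) +
    ggplot2::labs(y = "LED", x = NULL)
}

#' Hanging chi-gram of primary-tissue enrichment
#'
#' Bars show (observed - expected) / sqrt(expected) per tissue for the
#' top-fraction gene set; positive bars are overrepresented tissues.
#'
#' @param enrichment_table the `table` element of [tissueEnrichment()] (or
#'   one species' rows of the pipeline's tissue_enrichment.tsv).
#' @return a ggplot object, or NULL with a warning when ggplot2 is missing.
#' @export
plotChiGram <- function(enrichment_table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; skipping plot")
    return(invisible(NULL))
  }
  df <- enrichment_table
  df$tissue <- factor(df$tissue, levels = df$tissue)
  ggplot2::ggplot(df, ggplot2::aes(x = tissue, y = chi_component)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(y = expression((O - E) / sqrt(E)), x = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
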