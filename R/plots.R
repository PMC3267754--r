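# ggplot2 views of the package's result tables.

#' Bar chart of annotated variants per miRNA region
#'
#' @param annotated tibble from [annotate_variants()].
#' @return a ggplot object.
#' @export
plot_variant_regions <- function(annotated) {
  d <- annotated %>%
    filter(!.data$derived) %>%
    distinct(.data$id, .data$hairpin, .data$mature, .keep_all = TRUE) %>%
    count(.data$region)
  d$region <- factor(d$region,
                     levels = c("seed", "mature_nonseed", "precursor", "outside"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "miRNA region", y = "annotations",
                  title = "Variant annotations by miRNA region") +
    ggplot2::theme_minimal()
}

#' Genotype-by-sex phenotype summary plot
#'
#' Cell means with standard-deviation error bars for one trait, split by
#' genotype and (when present) sex -- the lean-vs-fat strain comparison
#' figure for a seed-variant genotype.
#'
#' @param records phenotype tibble.
#' @param trait trait identifier.
#' @return a ggplot object.
#' @export
plot_genotype_means <- function(records, trait) {
  d <- genotype_group_summary(records, trait)
  has_sex <- "sex" %in% names(d)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = "genotype", y = trait,
                  title = sprintf("%s by seed-variant genotype", trait)) +
    ggplot2::theme_minimal()
  if (has_sex) p <- p + ggplot2::facet_wrap(~sex)
  p
}

#' Plot significant association counts per trait group
#'
#' @param object a `seedvar_scan` tibble from [scan_traits()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.seedvar_scan <- function(object, ...) {
  d <- summarize_scan(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$group, .data$n_significant),
                                  y = .data$n_significant)) +
    ggplot2::geom_col(fill = "darkred") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("traits with p < %s", attr(object, "alpha")),
                  title = "Significant genotype associations per trait group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
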