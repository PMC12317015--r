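#' Published benchmark summary tables
#'
#' Accessor for the benchmark summary tables shipped with the package
#' (architecture-level generative precision/recall, quality-diversity
#' scores, classification before/after augmentation, minority-class and
#' robustness summaries). These are inputs for the derived-arithmetic
#' checks: the package recomputes their derived columns (F1, combined
#' scores, relative improvements, improvement ratios, robustness scores)
#' from the primary columns.
#'
#' @param name one of `"quality_diversity"`, `"gen_precision_recall"`,
#'   `"classification_before_after"`, `"minority_class"`,
#'   `"gan_minority_comparison"`, `"robustness"`.
#' @return a tibble.
#' @export
reference_table <- function(name = c("quality_diversity",
                                     "gen_precision_recall",
                                     "classification_before_after",
                                     "minority_class",
                                     "gan_minority_comparison",
                                     "robustness")) {
  name <- match.arg(name)
  file <- c(quality_diversity = "quality_diversity_scores.csv",
            gen_precision_recall = "generative_precision_recall.csv",
            classification_before_after = "classification_before_after.csv",
            minority_class = "minority_class_performance.csv",
            gan_minority_comparison = "gan_minority_comparison.csv",
            robustness = "robustness_generalization.csv")[[name]]
  path <- system.file("extdata", file, package = "dualgland",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
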