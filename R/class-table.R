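#' Subcellular localization classes and their dataset frequencies
#'
#' The 19 protein localization classes used throughout the package (18
#' specific compartments plus a negative/unspecific class), together with
#' their relative frequency in a large weakly labelled fluorescence imaging
#' dataset (multi-label, so the raw percentages sum to more than 100; the
#' `prob` column renormalizes them into sampling probabilities). Each class
#' is assigned to a painter family used by the simulator: `nuclear` patterns
#' fill the nucleus, `cytosolic` patterns fill the cytoplasm, `organellar`
#' patterns co-locate with a specific organelle mask, `punctate` patterns are
#' rendered as bright foci, and `negative` leaves the protein channel empty.
#'
#' @return A tibble with columns `class_id` (0-18), `name`, `percentage`
#'   (as printed for the source dataset), `prob` (normalized sampling
#'   probability, sums to 1), `family`, and `target` (organelle mask the
#'   painter uses: one of `"nucleus"`, `"cytoplasm"`, `"mitochondria"`,
#'   `"er"`, `"other"`, `"punctate"`, `"none"`).
#' @export
#' @examples
#' tab <- hpa_class_table()
#' sum(tab$prob)
hpa_class_table <- function() {
  tab <- tibble::tribble(
    ~class_id, ~name,                        ~percentage, ~family,     ~target,
    0L,  "Nucleoplasm",                      27.4, "nuclear",   "nucleus",
    16L, "Cytosol",                          19.2, "cytosolic", "cytoplasm",
    14L, "Mitochondria",                     12.8, "organellar","mitochondria",
    6L,  "Endoplasmic reticulum",             9.4, "organellar","er",
    13L, "Plasma membrane",                   8.6, "cytosolic", "cytoplasm",
    17L, "Vesicles and punctate cytosolic patterns", 6.3, "punctate", "punctate",
    7L,  "Golgi apparatus",                   4.1, "organellar","other",
    2L,  "Nucleoli",                          3.7, "nuclear",   "nucleus",
    1L,  "Nuclear membrane",                  2.9, "nuclear",   "nucleus",
    4L,  "Nuclear speckles",                  2.1, "nuclear",   "nucleus",
    9L,  "Actin filaments",                   1.9, "cytosolic", "cytoplasm",
    10L, "Microtubules",                      1.8, "cytosolic", "cytoplasm",
    5L,  "Nuclear bodies",                    1.6, "nuclear",   "nucleus",
    12L, "Centrosome",                        1.5, "punctate",  "punctate",
    8L,  "Intermediate filaments",            1.4, "cytosolic", "cytoplasm",
    3L,  "Nucleoli fibrillar center",         1.4, "nuclear",   "nucleus",
    15L, "Aggresome",                         1.3, "organellar","other",
    11L, "Mitotic spindle",                   1.3, "cytosolic", "cytoplasm",
    18L, "Negative",                          1.3, "negative",  "none"
  )
  tab$prob <- tab$percentage / sum(tab$percentage)
  dplyr::arrange(tab, .data$class_id)
}

#' Draw localization classes from the dataset frequency table
#'
#' @param n number of draws.
#' @param table frequency table as returned by [hpa_class_table()]; any
#'   tibble with `class_id` and `prob` columns works.
#' @param seed integer seed; draws are reproducible.
#' @return integer vector of class ids of length `n`.
#' @export
sample_classes <- function(n, table = hpa_class_table(), seed = 1L) {
  stopifnot(abs(sum(table$prob) - 1) < 1e-9)
  withr::with_seed(seed,
    sample(table$class_id, n, replace = TRUE, prob = table$prob))
}
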