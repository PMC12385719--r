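#' The fixed 34-trait registry for upland cotton quality evaluation
#'
#' The evaluation pipeline operates on a fixed panel of 34 traits measured on
#' cottonseed kernels and fiber: protein and oil content (% of kernel dry
#' weight), 16 amino acids (% of kernel dry weight), 8 fatty acids (% of
#' total fatty acids) and 8 fiber traits (3 yield traits: 20-boll weight BW,
#' lint percentage LP, seed index SI; 5 quality traits: fiber length FL,
#' uniformity FU, strength FS, micronaire FM, elongation FE).
#'
#' Each entry carries a `desirability` orientation used only by the
#' deterministic sign convention of [pcafmf()]: `higher_better` traits are
#' those a breeder selecting for nutritional plus fiber quality wants large
#' (protein, amino acids, the polyunsaturated C18:2/C18:3, fiber yield and
#' quality), `lower_better` marks the saturated fatty acids and oil (oil is
#' oriented downward solely because of its strong trade-off with protein in
#' the composite; it is not an undesirable trait per se), and `neutral`
#' traits (C16:1, C18:1, SI, FM) do not vote on component orientation.
#'
#' @return A data.frame with 34 rows and columns `code`, `long_name`,
#'   `family` (one of `protein`, `oil`, `amino_acid`, `fatty_acid`,
#'   `fiber_yield`, `fiber_quality`), `units`, `desirability` and the
#'   convenience logical `is_percent` (trait bounded in \[0, 100\]).
#' @examples
#' reg <- trait_registry()
#' table(reg$family)
#' @export
trait_registry <- function() {
  aa <- c("Asp", "Thr", "Ser", "Glu", "Gly", "Ala", "Val", "Met",
          "Ile", "Leu", "Tyr", "Phe", "Lys", "His", "Arg", "Pro")
  aa_long <- c("Aspartic acid", "Threonine", "Serine", "Glutamic acid",
               "Glycine", "Alanine", "Valine", "Methionine", "Isoleucine",
               "Leucine", "Tyrosine", "Phenylalanine", "Lysine", "Histidine",
               "Arginine", "Proline")
  fa <- c("C14_0", "C16_0", "C16_1", "C18_0", "C18_1", "C18_2", "C18_3", "C20_0")
  fa_long <- c("Myristic acid (C14:0)", "Palmitic acid (C16:0)",
               "Palmitoleic acid (C16:1)", "Stearic acid (C18:0)",
               "Oleic acid (C18:1)", "Linoleic acid (C18:2)",
               "alpha-Linolenic acid (C18:3)", "Arachidic acid (C20:0)")
  reg <- data.frame(
    code = c("protein", "oil", aa, fa,
             "BW", "LP", "SI", "FL", "FU", "FS", "FM", "FE"),
    long_name = c("Protein content", "Oil content", aa_long, fa_long,
                  "20-boll weight", "Lint percentage", "Seed index",
                  "Fiber length", "Fiber uniformity", "Fiber strength",
                  "Fiber micronaire", "Fiber elongation"),
    family = c("protein", "oil", rep("amino_acid", 16), rep("fatty_acid", 8),
               rep("fiber_yield", 3), rep("fiber_quality", 5)),
    units = c(rep("% kernel dry weight", 18), rep("% total fatty acids", 8),
              "g", "%", "g", "mm", "%", "cN/tex", "index", "%"),
    desirability = c(
      "higher_better",                      # protein
      "lower_better",                       # oil (protein trade-off)
      rep("higher_better", 16),             # amino acids
      "lower_better", "lower_better",       # C14:0, C16:0
      "neutral",                            # C16:1
      "lower_better",                       # C18:0
      "neutral",                            # C18:1
      "higher_better", "higher_better",     # C18:2, C18:3
      "lower_better",                       # C20:0
      "higher_better", "higher_better",     # BW, LP
      "neutral",                            # SI
      "higher_better", "higher_better", "higher_better",  # FL, FU, FS
      "neutral",                            # FM
      "higher_better"                       # FE
    ),
    stringsAsFactors = FALSE
  )
  reg$is_percent <- grepl("%", reg$units, fixed = TRUE)
  stopifnot(nrow(reg) == 34L, !anyDuplicated(reg$code))
  reg
}

#' @rdname trait_registry
#' @format NULL
#' @keywords internal
.registry_codes <- function(registry = trait_registry()) registry$code

#' Trait codes belonging to a registry family
#'
#' @param family One of `"protein"`, `"oil"`, `"amino_acid"`, `"fatty_acid"`,
#'   `"fiber_yield"`, `"fiber_quality"`, or the derived groups `"sfa"`
#'   (saturated fatty acids C14:0, C16:0, C18:0, C20:0), `"ufa"` (unsaturated
#'   C16:1, C18:1, C18:2, C18:3), `"fiber"` (all 8 fiber traits) and
#'   `"nutritional"` (the 26 nutritional traits).
#' @param registry A registry as returned by [trait_registry()].
#' @return Character vector of trait codes in registry order.
#' @export
family_codes <- function(family, registry = trait_registry()) {
  base <- unique(registry$family)
  derived <- list(
    sfa = c("C14_0", "C16_0", "C18_0", "C20_0"),
    ufa = c("C16_1", "C18_1", "C18_2", "C18_3"),
    fiber = registry$code[registry$family %in% c("fiber_yield", "fiber_quality")],
    nutritional = registry$code[registry$family %in%
                                  c("protein", "oil", "amino_acid", "fatty_acid")]
  )
  if (family %in% base) return(registry$code[registry$family == family])
  if (family %in% names(derived)) return(derived[[family]])
  stop("unknown trait family: '", family, "'", call. = FALSE)
}

# Origin and breeding-period factor levels used throughout the package.
.origin_levels <- function() c("YZR", "YER", "NER", "NIR", "LAN", "FOR")
.period_levels <- function() {
  c("foreign_introduction", "1953-2000", "2001-2010", "2011-2022")
}
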