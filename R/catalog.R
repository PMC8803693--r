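#' Biolog EcoPlate substrate catalog
#'
#' The 31 carbon sources of a Biolog EcoPlate together with their assignment
#' to five substrate guilds: amines (2), amino acids (6), carbohydrates (10),
#' carboxylic acids (9) and polymers (4). This grouping is the one used
#' throughout the package for guild-level activity profiles; note that other
#' published EcoPlate groupings differ (e.g. some place the phosphorylated
#' carbohydrates elsewhere) -- the catalog here is fixed and closed.
#'
#' @return A data frame with columns `substrate` (character, unique) and
#'   `group` (factor with levels amines, amino_acids, carbohydrates,
#'   carboxylic_acids, polymers).
#' @examples
#' cat31 <- default_catalog()
#' table(cat31$group)
#' substrate_group("Tween 40")
#' @export
default_catalog <- function() {
  entries <- list(
    amines = c("Phenylethylamine", "Putrescine"),
    amino_acids = c(
      "Glycyl-L-glutamic acid", "L-Arginine", "L-Asparagine",
      "L-Phenylalanine", "L-Serine", "L-Threonine"
    ),
    carbohydrates = c(
      "alpha-D-Lactose", "D-Cellobiose", "D-Galactonic acid gamma-Lactone",
      "D-Mannitol", "D-Xylose", "D,L-alpha-Glycerol phosphate",
      "Glucose-1-phosphate", "i-Erythritol", "N-Acetyl-D-glucosamine",
      "beta-Methyl-D-glucoside"
    ),
    carboxylic_acids = c(
      "2-Hydroxy benzoic acid", "4-Hydroxy benzoic acid",
      "D-Galacturonic acid", "D-Glucosaminic acid", "D-Malic acid",
      "gamma-Hydroxybutyric acid", "Itaconic acid",
      "Pyruvic acid methyl ester", "alpha-Ketobutyric acid"
    ),
    polymers = c("alpha-Cyclodextrin", "Glycogen", "Tween 40", "Tween 80")
  )
  out <- data.frame(
    substrate = unlist(entries, use.names = FALSE),
    group = factor(rep(names(entries), lengths(entries)),
                   levels = substrate_groups()),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  stopifnot(nrow(out) == 31L, !anyDuplicated(out$substrate))
  out
}

#' Substrate guild names
#'
#' @return Character vector of the five guild labels in canonical order.
#' @export
substrate_groups <- function() {
  c("amines", "amino_acids", "carbohydrates", "carboxylic_acids", "polymers")
}

#' Reserved token identifying blank (water) wells
#' @export
BLANK <- "BLANK"

#' Look up the guild of a substrate
#'
#' @param substrate Character vector of substrate names.
#' @param catalog Catalog data frame, by default [default_catalog()].
#' @return Character vector of guild labels.
#' @export
substrate_group <- function(substrate, catalog = default_catalog()) {
  idx <- match(substrate, catalog$substrate)
  if (anyNA(idx)) {
    bad <- substrate[is.na(idx)]
    stop(unknown_substrate_message(bad, catalog), call. = FALSE)
  }
  as.character(catalog$group[idx])
}

# Error text for unresolved substrate names, with near-match suggestions
# based on edit distance (case- and punctuation-tolerant).
unknown_substrate_message <- function(bad, catalog) {
  sugg <- vapply(unique(bad), function(b) {
    d <- utils::adist(tolower(b), tolower(catalog$substrate))
    cands <- catalog$substrate[d <= max(3L, ceiling(nchar(b) / 4))]
    if (length(cands) == 0L) "(no close match)" else
      paste(utils::head(cands, 3L), collapse = ", ")
  }, character(1))
  paste0(
    "unknown substrate name(s) not in catalog:\n",
    paste0("  '", unique(bad), "' -- did you mean: ", sugg, collapse = "\n")
  )
}
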