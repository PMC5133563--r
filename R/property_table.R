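# The 14-scale physicochemical property table used by the AAIndex-style
# feature block.

.malsite_env <- new.env(parent = emptyenv())

#' Read a physicochemical property table
#'
#' The table is a headered TSV with a `residue` column covering the 20
#' amino acids and exactly 14 numeric property columns. The dummy residue
#' is not listed: it contributes 0 for every property by definition.
#'
#' @param path Path to the TSV.
#' @return Numeric 20 x 14 matrix, rows named by residue, columns by
#'   property, of class `property_table`.
#' @export
read_property_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("property table not found: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"residue" %in% names(df))
    stop("property table must have a 'residue' column")
  props <- setdiff(names(df), "residue")
  if (length(props) != 14L)
    stop(sprintf("property table must have exactly 14 property columns, found %d",
                 length(props)))
  if (!setequal(df$residue, amino_acids()) || anyDuplicated(df$residue))
    stop("property table must have one row per amino acid (20 rows)")
  m <- as.matrix(df[, props])
  if (!is.numeric(m) || anyNA(m)) stop("property values must be numeric and complete")
  rownames(m) <- df$residue
  m <- m[amino_acids(), , drop = FALSE]
  class(m) <- c("property_table", class(m))
  m
}

#' The default physicochemical property table
#'
#' Fourteen amino-acid scales: hydrophobicity, polarity, polarizability,
#' solvent accessibility, net charge index of side chains, molecular
#' weight, pK of the alpha-amino group (pK_N), pK of the alpha-carboxyl
#' group (pK_C), melting point, optical rotation, entropy of formation,
#' heat capacity, absolute entropy, and hydrophilicity. Values are standard
#' literature scales shipped as an editable TSV
#' (`system.file("extdata", "property_table.tsv", package = "malsite")`);
#' substitute your own table via [read_property_table()].
#'
#' @return A `property_table` matrix (20 x 14).
#' @export
default_property_table <- function() {
  if (is.null(.malsite_env$property_table)) {
    path <- system.file("extdata", "property_table.tsv", package = "malsite")
    .malsite_env$property_table <- read_property_table(path)
  }
  .malsite_env$property_table
}
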