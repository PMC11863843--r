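#' The 17-group functional-group catalog
#'
#' Ordered catalog of the 17 functional groups the classifier predicts,
#' each with the SMARTS pattern used to derive ground-truth labels from a
#' SMILES string. The order is fixed and every label vector produced or
#' consumed by this package is aligned to it.
#'
#' The ether entry uses a corrected pattern,
#' `[OD2]([#6;!$(C=O)])([#6;!$(C=O)])`, which requires both carbons flanking
#' the ether oxygen to be non-carbonyl. The naive `[OD2]([#6])[#6]` pattern
#' also fires on the C(=O)-O-C oxygen of every ester, so esters would be
#' mislabeled as ethers without the correction.
#'
#' The remaining 16 patterns are pinned catalog constants following standard
#' substructure-query conventions for these group definitions, chosen so
#' that:
#' \itemize{
#'   \item `alkane` means an sp3 carbon bonded only to carbon or hydrogen,
#'     so a methoxy carbon is methyl but not alkane;
#'   \item `alkyl halides` matches any carbon-halogen bond, including
#'     halogens on aromatic carbons (an aryl fluoride counts, as in
#'     4-fluoroanisole) and the halogen of an acyl halide;
#'   \item `amines` covers primary and secondary amines but excludes
#'     amides, nitro nitrogens and nitriles;
#'   \item `ketones`, `aldehydes`, `esters`, `carboxylic acids`,
#'     `acyl halides` and `amides` partition the carbonyl chemotypes by the
#'     carbonyl carbon's other substituent.
#' }
#'
#' @return A data.frame with columns `name` and `smarts`, exactly 17 rows,
#'   in catalog order.
#' @examples
#' fg_catalog()
#' @export
fg_catalog <- function() {
  data.frame(
    name = c(
      "alkane", "methyl", "alkene", "alkyne", "alcohols", "amines",
      "nitriles", "aromatics", "alkyl halides", "esters", "ketones",
      "aldehydes", "carboxylic acids", "ether", "acyl halides",
      "amides", "nitro"
    ),
    smarts = c(
      "[CX4;!$([CX4][!#6;!#1])]",
      "[CH3]",
      "[CX3]=[CX3]",
      "[CX2]#[CX2]",
      "[OX2H][#6;!$([CX3]=[OX1])]",
      "[NX3;H2,H1;!$(NC=O)]",
      "[NX1]#[CX2]",
      "c",
      "[#6][F,Cl,Br,I]",
      "[#6][CX3](=O)[OX2H0][#6]",
      "[#6][CX3](=[OX1])[#6]",
      "[CX3H1](=O)[#6]",
      "[CX3](=O)[OX2H1]",
      "[OD2]([#6;!$(C=O)])([#6;!$(C=O)])",
      "[CX3](=[OX1])[F,Cl,Br,I]",
      "[CX3](=[OX1])[NX3]",
      "[$([NX3](=O)=O),$([NX3+](=[OX1])[O-])][!#8]"
    ),
    stringsAsFactors = FALSE
  )
}

#' Functional-group names in catalog order
#'
#' @return Character vector of length 17.
#' @export
fg_names <- function() fg_catalog()$name

#' Number of functional groups in the catalog
#' @return The integer 17.
#' @export
fg_count <- function() nrow(fg_catalog())

#' Version hash of the functional-group catalog
#'
#' MD5 digest of the serialized (name, SMARTS) table. Model checkpoints
#' store this hash and refuse to load against a different catalog, so a
#' trained model can never silently be paired with re-defined labels.
#'
#' @return A 32-character hex string.
#' @export
fg_catalog_hash <- function() {
  cat_txt <- paste(fg_catalog()$name, fg_catalog()$smarts,
                   sep = "\t", collapse = "\n")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(cat_txt, tmp)
  unname(tools::md5sum(tmp))
}

#' Export the catalog as a plain-text SMARTS table
#'
#' Writes a tab-separated (name, smarts) table for audit.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fg_catalog <- function(path) {
  utils::write.table(fg_catalog(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
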