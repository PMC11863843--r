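#' Canonicalize a SMILES string
#'
#' Converts a SMILES string to its canonical form via Open Babel, so that
#' different valid writings of the same molecule (e.g. "OCC" and "CCO")
#' collapse to one representation. Canonicalization is idempotent.
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES string.
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles)
  )
  out <- sub("[ \t].*$", "", sub("\n.*$", "", out))
  out <- trimws(out)
  if (!nzchar(out)) {
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  }
  out
}

#' Label the functional groups of a molecule
#'
#' Maps a SMILES string to the 17-element binary label vector by matching
#' each catalog SMARTS pattern against the molecule. Bit i is 1 exactly when
#' pattern i has at least one substructure match; match counts are not used.
#'
#' @param smiles A single SMILES string.
#' @return Named integer vector of length 17 (0/1), names in catalog order.
#' @examples
#' \dontrun{
#' label_functional_groups("COc1ccc(F)cc1")  # methyl, aromatics,
#'                                           # alkyl halides, ether
#' }
#' @export
label_functional_groups <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  # forEachMol silently yields nothing on a malformed SMILES; validate first
  canonicalize_smiles(smiles)
  cat_df <- fg_catalog()
  hits <- ChemmineOB::forEachMol("SMILES", smiles, function(mol) {
    vapply(cat_df$smarts,
           function(p) ChemmineOB::smartsSearch_OB(list(mol), p) > 0,
           logical(1))
  })[[1]]
  bits <- as.integer(hits)
  names(bits) <- cat_df$name
  bits
}

#' Label many molecules at once
#'
#' @param smiles Character vector of SMILES strings.
#' @return Integer matrix, one row per molecule, 17 columns in catalog order.
#' @export
label_functional_groups_many <- function(smiles) {
  out <- t(vapply(smiles, label_functional_groups, integer(fg_count())))
  rownames(out) <- NULL
  out
}
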