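# Residue template dictionary for the 20 standard amino acids.
# Heavy atoms only; the inter-residue peptide link is C -> N of the next
# residue and is added at graph-building time.

.templateCache <- new.env(parent = emptyenv())

#' Residue template dictionary
#'
#' Embedded chemical descriptions of the 20 standard amino acids (heavy atoms,
#' elements and intra-residue bonds), playing the role a chemical component
#' dictionary plays when parsing polymer structures into atom graphs. Shipped
#' as a versioned data file inside the package.
#'
#' @return named list, one entry per 3-letter residue code, each with
#'   \code{atoms} (data.frame: atomName, element), \code{bonds} (data.frame:
#'   a1, a2, order), and \code{backbone} = c("N","CA","C","O").
#' @examples
#' tpl <- residueTemplates()
#' nrow(tpl$TRP$atoms)  # 14 heavy atoms
#' @export
residueTemplates <- function() {
  if (!is.null(.templateCache$tpl)) return(.templateCache$tpl)
  atomFile <- system.file("extdata", "residue_templates_v1.tsv",
                          package = "AtomEnsembles", mustWork = TRUE)
  bondFile <- system.file("extdata", "residue_bonds_v1.tsv",
                          package = "AtomEnsembles", mustWork = TRUE)
  at <- utils::read.delim(atomFile, stringsAsFactors = FALSE)
  bd <- utils::read.delim(bondFile, stringsAsFactors = FALSE)
  res <- sort(unique(at$resname))
  stopifnot(length(res) == 20L)
  tpl <- lapply(res, function(r) {
    a <- at[at$resname == r, c("atomName", "element")]
    b <- bd[bd$resname == r, c("a1", "a2", "order")]
    rownames(a) <- NULL; rownames(b) <- NULL
    stopifnot(all(c("N", "CA", "C", "O") %in% a$atomName),
              all(b$a1 %in% a$atomName), all(b$a2 %in% a$atomName))
    list(atoms = a, bonds = b, backbone = c("N", "CA", "C", "O"))
  })
  names(tpl) <- res
  .templateCache$tpl <- tpl
  tpl
}
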