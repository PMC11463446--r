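# PDB reading (bio3d-backed) and multi-MODEL ensemble writing.

# element from a PDB atom name when the element column is absent/blank
.elementFromName <- function(nm) {
  nm <- toupper(trimws(nm))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CA", "CU", "SE"),
         paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))),
         substr(nm, 1, 1))
}

.waterNames <- c("HOH", "WAT", "DOD")

#' Read a PDB file into polymer residues and hetero molecule records
#'
#' Polymer chains (ATOM records) are returned residue-by-residue with atom
#' names and coordinates; each HETATM group (non-water) becomes a separate
#' \code{\link{MolRecord}} without bonds -- ligand bonds are assigned later
#' from residue templates or from a companion SDF, never perceived from
#' distances. Only the first MODEL of a multi-model file is read; the number
#' of skipped models is reported. Alternate locations keep the highest
#' occupancy, ties resolved by file order. Insertion codes are preserved in
#' the residue identifiers.
#'
#' @param path PDB file path
#' @return list with elements \code{residues} (data.frame: chain, resno,
#'   insert, resname, atomName, element, x, y, z), \code{hetero} (list of
#'   MolRecord with chain/resno attributes), \code{missingBackbone}
#'   (data.frame of flagged polymer residues), \code{skippedModels} (integer).
#' @export
readPDB <- function(path) {
  nModels <- length(grep("^MODEL", readLines(path, warn = FALSE)))
  skipped <- max(0L, nModels - 1L)
  if (skipped > 0L)
    message("readPDB: multi-model file, reading first model, skipping ",
            skipped, " model(s)")
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  a$elesy <- ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                    .elementFromName(a$elety), trimws(a$elesy))
  a$elesy <- paste0(toupper(substr(a$elesy, 1, 1)),
                    tolower(substr(a$elesy, 2, 2)))
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  # altloc: highest occupancy, ties by file order
  key <- paste(a$chain, a$resno, a$insert, a$resid, a$elety, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    idx[which.max(a$o[idx])]
  }), use.names = FALSE)
  a <- a[sort(keep), , drop = FALSE]

  pol <- a[a$type == "ATOM", , drop = FALSE]
  residues <- data.frame(
    chain = pol$chain, resno = pol$resno, insert = pol$insert,
    resname = pol$resid, atomName = trimws(pol$elety),
    element = pol$elesy, x = pol$x, y = pol$y, z = pol$z,
    stringsAsFactors = FALSE)

  missingBackbone <- data.frame(chain = character(), resno = integer(),
                                resname = character(), stringsAsFactors = FALSE)
  if (nrow(residues)) {
    rkey <- paste(residues$chain, residues$resno, residues$insert)
    for (grp in split(seq_len(nrow(residues)), rkey)) {
      heavy <- residues$atomName[grp][residues$element[grp] != "H"]
      if (!all(c("N", "CA", "C", "O") %in% heavy)) {
        missingBackbone <- rbind(missingBackbone, data.frame(
          chain = residues$chain[grp[1]], resno = residues$resno[grp[1]],
          resname = residues$resname[grp[1]], stringsAsFactors = FALSE))
      }
    }
    if (nrow(missingBackbone))
      warning("readPDB: ", nrow(missingBackbone),
              " residue(s) with missing backbone atoms (flagged, not dropped)")
  }

  het <- a[a$type == "HETATM" & !a$resid %in% .waterNames, , drop = FALSE]
  hetero <- list()
  if (nrow(het)) {
    hkey <- paste(het$chain, het$resno, het$insert, het$resid)
    for (grp in split(seq_len(nrow(het)), hkey)) {
      g <- het[grp, , drop = FALSE]
      m <- MolRecord(
        name = g$resid[1],
        atoms = data.frame(element = g$elesy, charge = 0L,
                           stringsAsFactors = FALSE),
        bonds = data.frame(i = integer(0), j = integer(0), order = integer(0)),
        coords = cbind(g$x, g$y, g$z))
      m$atomName <- trimws(g$elety)
      attr(m, "chain") <- g$chain[1]
      attr(m, "resno") <- g$resno[1]
      hetero[[length(hetero) + 1L]] <- m
    }
  }
  list(residues = residues, hetero = hetero,
       missingBackbone = missingBackbone, skippedModels = skipped)
}

#' Write a conformational ensemble as a multi-MODEL PDB file
#'
#' One MODEL/ENDMDL block per sample. Atom metadata (chain, residue, atom
#' name, role) comes from the system's \linkS4class{ChemGraph}; ligand atoms
#' are written as HETATM. When per-atom confidence values are supplied, the
#' predicted deviation sigma (Angstrom) is stored in the B-factor column.
#'
#' @param models list of \linkS4class{Conformation}, all with the system's
#'   atom count
#' @param graph the system's \linkS4class{ChemGraph}
#' @param path output path
#' @param sigmas optional list of per-atom sigma vectors (one per model)
#' @export
writePDBEnsemble <- function(models, graph, path, sigmas = NULL) {
  if (is(models, "Conformation")) models <- list(models)
  if (!length(models)) stop("writePDBEnsemble: no models to write")
  n <- natoms(graph)
  for (m in models)
    if (nrow(coords(m)) != n)
      stop("writePDBEnsemble: model atom count (", nrow(coords(m)),
           ") does not match system (", n, ")")
  at <- atomTable(graph)
  rectype <- ifelse(at$role == "ligand", "HETATM", "ATOM")
  # PDB v3 name justification: 1-2 char names start in column 14
  nm <- vapply(at$atomName, function(s) {
    if (nchar(s) >= 4L) substr(s, 1, 4) else sprintf(" %-3s", s)
  }, "")
  chain <- ifelse(nzchar(at$chain), substr(at$chain, 1, 1), "A")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(models)) {
    writeLines(sprintf("MODEL %8d", k), con)
    xyz <- coords(models[[k]])
    bfac <- if (!is.null(sigmas)) pmin(999.99, sigmas[[k]]) else rep(0, n)
    lines <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rectype, seq_len(n) %% 100000L, nm, "",
                     substr(at$resname, 1, 3), chain, at$resno %% 10000L, "",
                     xyz[, 1], xyz[, 2], xyz[, 3], 1.00, bfac,
                     toupper(at$element))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(NULL)
}
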