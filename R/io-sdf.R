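# SDF/MOL V2000 reading (ChemmineR-backed) and writing.

.knownElements <- c(
  "H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I", "Se",
  "Na", "K", "Mg", "Ca", "Zn", "Fe", "Mn", "Cu", "Co", "Ni", "Mo", "Li"
)

#' Construct a molecule record
#'
#' A lightweight container for one small molecule: element symbols, formal
#' charges, a symmetric bond list stored once per pair, and optional 3D
#' coordinates in Angstrom.
#'
#' @param name molecule name
#' @param atoms data.frame with columns \code{element}, \code{charge}
#' @param bonds data.frame with columns \code{i}, \code{j}, \code{order}
#'   (1, 2, 3 or 4 = aromatic)
#' @param coords optional n x 3 matrix
#' @export
MolRecord <- function(name, atoms, bonds, coords = NULL) {
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  n <- nrow(atoms)
  if (nrow(bonds)) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("MolRecord: bond indices reference non-existing atoms")
    if (any(bonds$i == bonds$j)) stop("MolRecord: self-bonds are not allowed")
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    if (anyDuplicated(bonds[, c("i", "j")]))
      stop("MolRecord: duplicate bonds")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3)
      stop("MolRecord: coords must be n x 3")
  }
  structure(list(name = name, atoms = atoms, bonds = bonds, coords = coords),
            class = "MolRecord")
}

#' @export
print.MolRecord <- function(x, ...) {
  cat(sprintf("MolRecord '%s': %d atoms, %d bonds, coords: %s\n",
              x$name, nrow(x$atoms), nrow(x$bonds),
              if (is.null(x$coords)) "none" else "3D"))
  invisible(x)
}

# old-style atom-block charge codes (superseded by M  CHG when present)
.chargeCodeToValue <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                        `5` = -1L, `6` = -2L, `7` = -3L)

#' Read an SDF/MOL V2000 file
#'
#' Parses every record into a \code{\link{MolRecord}}: atoms with element and
#' formal charge, bonds with orders, and 3D coordinates when present.
#' Hydrogens are retained at this stage (they are stripped when building a
#' \linkS4class{ChemGraph}). Formal charges honour \code{M  CHG} property
#' lines, which supersede the atom-block charge column.
#'
#' @param path SDF/MOL file path
#' @return list of \code{MolRecord}
#' @export
readSDF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) return(list())
  # split into records on $$$$ (a lone MOL file is one record)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  recs <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    if (length(block) < 4L || all(!nzchar(trimws(block)))) next
    recs[[length(recs) + 1L]] <- .parseMolBlock(block, starts[k])
  }
  recs
}

.parseMolBlock <- function(block, fileLine) {
  name <- trimws(block[1])
  counts <- block[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 0 ||
      length(block) < 4 + na + nb)
    stop(sprintf("readSDF: malformed counts line at file line %d: '%s'",
                 fileLine + 3L, counts))
  atomLines <- block[4 + seq_len(na)]
  element <- trimws(substr(atomLines, 32, 34))
  bad <- !element %in% .knownElements
  if (any(bad))
    stop("readSDF: unknown element symbol(s): ",
         paste(unique(element[bad]), collapse = ", "))
  xyz <- cbind(as.numeric(substr(atomLines, 1, 10)),
               as.numeric(substr(atomLines, 11, 20)),
               as.numeric(substr(atomLines, 21, 30)))
  code <- suppressWarnings(as.integer(substr(atomLines, 37, 39)))
  charge <- ifelse(is.na(code) | code == 0L, 0L,
                   .chargeCodeToValue[as.character(code)])
  charge[is.na(charge)] <- 0L
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  if (nb > 0) {
    bondLines <- block[4 + na + seq_len(nb)]
    bonds <- data.frame(
      i = as.integer(substr(bondLines, 1, 3)),
      j = as.integer(substr(bondLines, 4, 6)),
      order = as.integer(substr(bondLines, 7, 9)))
    if (anyNA(bonds))
      stop(sprintf("readSDF: malformed bond block in record starting at line %d",
                   fileLine))
  }
  chg <- grep("^M  CHG", block, value = TRUE)
  if (length(chg)) {
    charge <- rep(0L, na)  # M CHG resets all atom-block charges
    for (ln in chg) {
      nent <- as.integer(substr(ln, 7, 9))
      for (e in seq_len(nent)) {
        off <- 10 + (e - 1) * 8
        ai <- as.integer(substr(ln, off, off + 3))
        cv <- as.integer(substr(ln, off + 4, off + 7))
        charge[ai] <- cv
      }
    }
  }
  if (all(abs(xyz) < 1e-8) && na > 1) xyz3d <- NULL else xyz3d <- xyz
  MolRecord(name = name,
            atoms = data.frame(element = element, charge = as.integer(charge)),
            bonds = bonds, coords = xyz3d)
}

#' Write molecules to an SDF V2000 file
#'
#' @param mols a \code{MolRecord} or list of them (coordinates required)
#' @param path output path
#' @export
writeSDF <- function(mols, path) {
  if (inherits(mols, "MolRecord")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mols) {
    if (is.null(m$coords)) stop("writeSDF: record '", m$name, "' has no coordinates")
    na <- nrow(m$atoms); nb <- nrow(m$bonds)
    writeLines(c(m$name, "  AtomEnsembles", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb), con)
    for (i in seq_len(na)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         m$coords[i, 1], m$coords[i, 2], m$coords[i, 3],
                         m$atoms$element[i]), con)
    }
    for (b in seq_len(nb)) {
      writeLines(sprintf("%3d%3d%3d  0", m$bonds$i[b], m$bonds$j[b],
                         m$bonds$order[b]), con)
    }
    charged <- which(m$atoms$charge != 0L)
    if (length(charged)) {
      for (grp in split(charged, ceiling(seq_along(charged) / 8))) {
        writeLines(paste0("M  CHG", sprintf("%3d", length(grp)),
                          paste0(sprintf("%4d%4d", grp, m$atoms$charge[grp]),
                                 collapse = "")), con)
      }
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(NULL)
}
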