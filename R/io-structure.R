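#' Construct a structure ensemble
#'
#' A structure ensemble is an ordered list of models (conformers), each a
#' data.frame of atoms with author chain/residue numbering preserved:
#' columns `chain`, `resnum`, `resname`, `atom`, `x`, `y`, `z` (coordinates
#' in Angstrom).
#'
#' @param models list of atom data.frames (one per model).
#' @param label free-text label.
#' @return Object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(models, label = "") {
  if (length(models) < 1) stop("ensemble needs at least one model")
  cols <- c("chain", "resnum", "resname", "atom", "x", "y", "z")
  models <- lapply(models, function(m) {
    stopifnot(is.data.frame(m), all(cols %in% names(m)))
    m$chain <- as.character(m$chain)
    m$resnum <- as.integer(m$resnum)
    m$atom <- as.character(m$atom)
    rownames(m) <- NULL
    m[, cols]
  })
  structure(list(models = models, label = label),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  m1 <- x$models[[1]]
  cat("Structure ensemble", if (nzchar(x$label)) paste0("'", x$label, "'"),
      "\n  models:", length(x$models),
      "\n  atoms/model:", nrow(m1),
      "\n  chains:", paste(unique(m1$chain), collapse = " "), "\n")
  invisible(x)
}

#' @export
length.structure_ensemble <- function(x) length(x$models)

#' Read a structure (PDB or mmCIF) into an ensemble
#'
#' All models of a multi-model file are loaded; author chain identifiers and
#' residue numbers are preserved (no renumbering). Parsing is delegated to
#' bio3d (`read.pdb` / `read.cif`).
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return A [structure_ensemble()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "cif" else "pdb"
  pdb <- if (format == "cif")
    suppressWarnings(bio3d::read.cif(path, multi = TRUE, verbose = FALSE))
  else
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type %in% c("ATOM", "HETATM")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no atom records in ", path)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_atoms <- nrow(pdb$atom)
  models <- lapply(seq_len(nrow(xyz)), function(i) {
    co <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
    data.frame(chain = ifelse(is.na(at$chain), ".", at$chain),
               resnum = as.integer(at$resno),
               resname = at$resid,
               atom = at$elety,
               x = co[, 1], y = co[, 2], z = co[, 3],
               stringsAsFactors = FALSE)
  })
  if (length(models) == 0) stop("zero models in ", path)
  structure_ensemble(models, label = basename(path))
}

#' Write a structure ensemble as a (multi-model) PDB file
#'
#' Minimal fixed-width PDB writer: MODEL/ATOM/ENDMDL/END records only, with
#' coordinates at the format's 0.001 A precision.
#'
#' @param x a [structure_ensemble()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "structure_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(x$models) > 1
  for (i in seq_along(x$models)) {
    m <- x$models[[i]]
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    serial <- seq_len(nrow(m))
    name <- ifelse(nchar(m$atom) < 4, sprintf(" %-3s", m$atom),
                   sprintf("%-4s", m$atom))
    lines <- sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      serial, name, m$resname, substr(m$chain, 1, 1), m$resnum,
      m$x, m$y, m$z, 1.0, 0.0)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
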