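#' Read CYANA upper-limit distance restraints
#'
#' Parses the CYANA `.upl` dialect: one restraint per data line,
#' `resnum resname atom  resnum resname atom  upper_limit` with optional
#' trailing annotations; `#` starts a comment. The dialect uses a single
#' continuous residue numbering, so chain identity is resolved either from
#' an explicit trailing chain annotation (`chain A B`) or from a
#' user-supplied chain map of residue ranges (see [chain_map()]).
#'
#' Malformed lines are an error reported with their line number; restraints
#' referencing residues outside the chain map are an error too.
#'
#' @param path `.upl` file.
#' @param chain_map optional [chain_map()] used to resolve chains.
#' @return Object of class `restraint_list` (a data.frame with columns
#'   `resnum_a`, `resname_a`, `atom_a`, `resnum_b`, `resname_b`, `atom_b`,
#'   `upper`, `chain_a`, `chain_b`).
#' @export
read_cyana_restraints <- function(path, chain_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 7)
      stop("malformed restraint line ", i, " in ", path, ": '",
           trimws(lines[i]), "'")
    suppressWarnings({
      ra <- as.integer(f[1]); rb <- as.integer(f[4])
      up <- as.numeric(f[7])
    })
    if (is.na(ra) || is.na(rb) || is.na(up) || up <= 0)
      stop("malformed restraint line ", i, " in ", path, ": '",
           trimws(lines[i]), "'")
    ca <- cb <- NA_character_
    if (length(f) >= 10 && tolower(f[8]) == "chain") {
      ca <- f[9]; cb <- f[10]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      resnum_a = ra, resname_a = f[2], atom_a = f[3],
      resnum_b = rb, resname_b = f[5], atom_b = f[6],
      upper = up, chain_a = ca, chain_b = cb,
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(resnum_a = integer(), resname_a = character(),
               atom_a = character(), resnum_b = integer(),
               resname_b = character(), atom_b = character(),
               upper = numeric(), chain_a = character(),
               chain_b = character(), stringsAsFactors = FALSE)
  same <- df$resnum_a == df$resnum_b & df$atom_a == df$atom_b &
    (is.na(df$chain_a) | is.na(df$chain_b) | df$chain_a == df$chain_b)
  if (any(same))
    stop("restraint between an atom and itself at data row ",
         which(same)[1])
  if (!is.null(chain_map)) {
    df$chain_a <- ifelse(is.na(df$chain_a),
                         resolve_chain(df$resnum_a, chain_map), df$chain_a)
    df$chain_b <- ifelse(is.na(df$chain_b),
                         resolve_chain(df$resnum_b, chain_map), df$chain_b)
  }
  structure(df, source = path, class = c("restraint_list", "data.frame"))
}

#' Chain map: residue ranges per chain
#'
#' CYANA restraint files use one continuous numbering across all molecules
#' of a complex; a chain map assigns each residue-number range to a chain
#' label so restraints can be classified as intra- or intermolecular.
#'
#' @param ... named ranges, e.g. `A = c(1, 50), B = c(51, 100)`.
#' @return Object of class `chain_map`.
#' @examples
#' cm <- chain_map(A = c(1, 44), B = c(101, 144), C = c(201, 320))
#' @export
chain_map <- function(...) {
  ranges <- list(...)
  if (length(ranges) == 0 || is.null(names(ranges)) ||
      any(!nzchar(names(ranges))))
    stop("chain_map needs named residue ranges")
  for (r in ranges)
    if (length(r) != 2 || any(is.na(r)) || r[1] > r[2])
      stop("each range must be c(first, last) with first <= last")
  structure(ranges, class = "chain_map")
}

resolve_chain <- function(resnum, map) {
  stopifnot(inherits(map, "chain_map"))
  out <- rep(NA_character_, length(resnum))
  for (ch in names(map)) {
    r <- map[[ch]]
    out[resnum >= r[1] & resnum <= r[2]] <- ch
  }
  if (any(is.na(out)))
    stop("residue(s) outside the chain map: ",
         paste(unique(resnum[is.na(out)]), collapse = ", "))
  out
}

#' Read a chain map from a YAML file
#'
#' The file maps chain labels to `[first, last]` residue ranges.
#'
#' @param path YAML file.
#' @return A [chain_map()].
#' @export
read_chain_map <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(chain_map, lapply(y, function(r) as.numeric(unlist(r))))
}

#' @export
print.restraint_list <- function(x, ...) {
  cat("Restraint list with", nrow(x), "distance restraints",
      if (!is.null(attr(x, "source"))) paste0("(", attr(x, "source"), ")"),
      "\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}
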