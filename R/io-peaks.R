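#' Construct a per-residue peak table
#'
#' A peak table holds one row per residue of a single spectrum (HSQC, HNCO,
#' IPAP component, ...): peak positions in ppm and, when measured, peak
#' height and volume in arbitrary intensity units. Residues are addressed by
#' author numbering (`chain`, `resnum`); for single-chain peak lists the
#' chain label defaults to the sentinel `"."`.
#'
#' Missing optional values (e.g. no carbonyl shift, no volume) are `NA`,
#' never 0: a shift difference of 0 ppm is legal data.
#'
#' @param data data.frame with columns `resnum` (integer) and at least one of
#'   `shift_H`, `shift_N`, `shift_C`; optional `chain`, `resname`, `height`,
#'   `volume`.
#' @param label free-text label for the spectrum.
#' @return Object of class `peak_table` (a data.frame).
#' @export
peak_table <- function(data, label = "") {
  stopifnot(is.data.frame(data))
  if (!"resnum" %in% names(data))
    stop("peak table needs a 'resnum' column")
  cols <- c("chain", "resnum", "resname", "shift_H", "shift_N", "shift_C",
            "height", "volume")
  if (!"chain" %in% names(data)) data$chain <- "."
  if (!"resname" %in% names(data)) data$resname <- NA_character_
  for (nm in c("shift_H", "shift_N", "shift_C", "height", "volume"))
    if (!nm %in% names(data)) data[[nm]] <- NA_real_
  data$chain <- as.character(data$chain)
  data$chain[is.na(data$chain) | data$chain == ""] <- "."
  data$resnum <- as.integer(data$resnum)
  for (nm in c("shift_H", "shift_N", "shift_C", "height", "volume"))
    data[[nm]] <- as.numeric(data[[nm]])
  data <- data[, cols]
  if (any(bad <- is.na(data$resnum)))
    stop(sum(bad), " row(s) with unparsable residue number")
  key <- paste(data$chain, data$resnum)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate residue key(s) in peak table: ",
         paste(dups, collapse = ", "))
  }
  no_shift <- is.na(data$shift_H) & is.na(data$shift_N) & is.na(data$shift_C)
  if (any(no_shift))
    stop("peak(s) without any chemical shift: residue ",
         paste(key[no_shift], collapse = ", "))
  if (any(!is.na(data$height) & data$height < 0))
    stop("negative peak height")
  data <- data[order(data$chain, data$resnum), , drop = FALSE]
  rownames(data) <- NULL
  structure(data, label = label, class = c("peak_table", "data.frame"))
}

#' @export
print.peak_table <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Peak table", if (nzchar(lab)) paste0("'", lab, "'"), "with",
      nrow(x), "peaks\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

peak_key <- function(x) paste(x$chain, x$resnum, sep = ":")

#' Read a peak table from disk
#'
#' Two dialects are supported. `"tsv"` is the canonical interchange format:
#' UTF-8, tab-separated, `#` comments, a header row naming the columns
#' (`chain`, `resnum`, `resname`, `shift_H`, `shift_N`, `shift_C`, `height`,
#' `volume`; missing cells allowed). `"nmrstar"` reads the assigned chemical
#' shift loop of an NMR-STAR file (as deposited at the BMRB) and folds the
#' backbone H, N and C' shifts of each residue into one peak; it is
#' read-only.
#'
#' Rows whose residue number cannot be parsed are rejected and reported, so
#' that `parsed + rejected` always accounts for every data line.
#'
#' @param path file to read.
#' @param dialect `"tsv"` or `"nmrstar"`.
#' @param label spectrum label; defaults to the file name.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, dialect = c("tsv", "nmrstar"),
                            label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE, sep = "\t")
    if (nrow(df) == 0) stop("no parsable rows in ", path)
    suppressWarnings(rn <- as.integer(df$resnum))
    bad <- is.na(rn)
    if (all(bad)) stop("no parsable rows in ", path)
    if (any(bad)) {
      warning(sum(bad), " row(s) with unparsable residue number rejected")
      df <- df[!bad, , drop = FALSE]
    }
    peak_table(df, label = label)
  } else {
    read_star_shifts(path, label = label)
  }
}

#' Write a peak table as tsv
#'
#' @param x a [peak_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(x, path) {
  stopifnot(inherits(x, "peak_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# peak table: ", attr(x, "label")), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# Minimal NMR-STAR reader restricted to the assigned chemical shift loop
# (_Atom_chem_shift). Handles both NMR-STAR 3.x dotted tags and the bare
# loop layout; everything else in the file is ignored.
read_star_shifts <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  i <- 1L
  n <- length(lines)
  recs <- list()
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L
      tags <- character(0)
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, sub("^\\s*(\\S+).*$", "\\1", lines[j]))
        j <- j + 1L
      }
      if (any(grepl("_Atom_chem_shift\\.", tags, ignore.case = TRUE)) ||
          any(grepl("^_Atom_shift_assign", tags, ignore.case = TRUE))) {
        short <- tolower(sub("^.*\\.", "", tags))
        k <- j
        while (k <= n && !grepl("^\\s*(stop_|loop_)\\s*$", lines[k]) &&
               !grepl("^\\s*_", lines[k])) {
          ln <- trimws(lines[k])
          if (nzchar(ln) && !startsWith(ln, "#")) {
            f <- strsplit(ln, "\\s+")[[1]]
            if (length(f) == length(short)) {
              names(f) <- short
              recs[[length(recs) + 1L]] <- f
            }
          }
          k <- k + 1L
        }
        i <- k
      } else i <- j
    }
    i <- i + 1L
  }
  if (length(recs) == 0) stop("no assigned chemical shift loop in ", path)
  g <- function(f, keys) {
    for (kk in keys) if (kk %in% names(f)) return(f[[kk]])
    NA_character_
  }
  df <- do.call(rbind, lapply(recs, function(f) {
    data.frame(chain   = g(f, c("auth_asym_id", "entity_assembly_id")),
               resnum  = g(f, c("auth_seq_id", "seq_id", "comp_index_id")),
               resname = g(f, c("comp_id")),
               atom    = g(f, c("atom_id")),
               val     = g(f, c("val")),
               stringsAsFactors = FALSE)
  }))
  df$chain[is.na(df$chain) | df$chain %in% c(".", "?")] <- "."
  suppressWarnings(df$resnum <- as.integer(df$resnum))
  suppressWarnings(df$val <- as.numeric(df$val))
  df <- df[!is.na(df$resnum) & !is.na(df$val), , drop = FALSE]
  if (nrow(df) == 0) stop("no parsable shifts in ", path)
  key <- paste(df$chain, df$resnum)
  pick <- function(sub, atoms) {
    hit <- sub$val[sub$atom %in% atoms]
    if (length(hit)) hit[1] else NA_real_
  }
  rows <- lapply(split(df, key), function(sub) {
    data.frame(chain = sub$chain[1], resnum = sub$resnum[1],
               resname = sub$resname[1],
               shift_H = pick(sub, c("H", "HN")),
               shift_N = pick(sub, "N"),
               shift_C = pick(sub, "C"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[!(is.na(out$shift_H) & is.na(out$shift_N) & is.na(out$shift_C)), ,
             drop = FALSE]
  peak_table(out, label = label)
}
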