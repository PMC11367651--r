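#' Per-residue peak-broadening profile (I/I0)
#'
#' Residues of a disordered protein that become part of a large, slowly
#' tumbling complex broaden dramatically, so the ratio of a residue's peak
#' height in the complex (I) to its height in the free protein (I0) maps the
#' binding region. This computes I/I0 per residue, matching peaks by
#' chain/residue number.
#'
#' A peak present in the free spectrum but absent from the bound one is read
#' as broadening beyond the detection limit - the strongest evidence of
#' binding - and gets ratio 0 with flag `missing_in_bound`. A peak present
#' only in the bound table gets flag `missing_in_free` and no ratio.
#'
#' @param free [peak_table()] of the free protein (heights required).
#' @param bound [peak_table()] of the complex.
#' @return Object of class `broadening_profile`: a data.frame with columns
#'   `chain`, `resnum`, `resname`, `ratio`, `flag`
#'   (`measured`/`missing_in_bound`/`missing_in_free`).
#' @export
compute_broadening_profile <- function(free, bound) {
  stopifnot(inherits(free, "peak_table"), inherits(bound, "peak_table"))
  kf <- peak_key(free)
  kb <- peak_key(bound)
  common <- intersect(kf, kb)
  mf <- match(common, kf)
  mb <- match(common, kb)
  hf <- free$height[mf]
  hb <- bound$height[mb]
  if (any(is.na(hf)) || any(is.na(hb)))
    stop("peak heights required in both tables for matched residues")
  if (any(hf <= 0))
    stop("zero or negative free-state height for residue ",
         paste(common[hf <= 0], collapse = ", "))
  rows <- data.frame(chain = free$chain[mf], resnum = free$resnum[mf],
                     resname = free$resname[mf], ratio = hb / hf,
                     flag = "measured", stringsAsFactors = FALSE)
  only_free <- setdiff(kf, kb)
  if (length(only_free)) {
    m <- match(only_free, kf)
    rows <- rbind(rows, data.frame(
      chain = free$chain[m], resnum = free$resnum[m],
      resname = free$resname[m], ratio = 0, flag = "missing_in_bound",
      stringsAsFactors = FALSE))
  }
  only_bound <- setdiff(kb, kf)
  if (length(only_bound)) {
    m <- match(only_bound, kb)
    rows <- rbind(rows, data.frame(
      chain = bound$chain[m], resnum = bound$resnum[m],
      resname = bound$resname[m], ratio = NA_real_, flag = "missing_in_free",
      stringsAsFactors = FALSE))
  }
  rows <- rows[order(rows$chain, rows$resnum), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, class = c("broadening_profile", "data.frame"))
}

#' Call contiguous binding regions from a broadening profile
#'
#' Returns maximal runs of consecutive residue numbers whose ratio falls
#' below `threshold` (peaks missing in the bound state count as fully
#' broadened). Disordered-protein profiles are punctuated by prolines and
#' unassigned residues, so runs may bridge up to `gap_tolerance` consecutive
#' unmeasured residues; a measured residue at or above threshold always
#' breaks a run. Runs shorter than `min_run` below-threshold residues are
#' dropped.
#'
#' @param profile a [compute_broadening_profile()] result.
#' @param threshold ratio below which a residue counts as broadened
#'   (default 0.5, i.e. peak height reduced below 50 percent).
#' @param min_run minimum number of below-threshold residues per region.
#' @param gap_tolerance number of consecutive unmeasured residues a run may
#'   bridge.
#' @return data.frame with columns `chain`, `first`, `last`, `n_below`.
#' @export
call_binding_regions <- function(profile, threshold = 0.5, min_run = 3,
                                 gap_tolerance = 1) {
  stopifnot(inherits(profile, "broadening_profile"))
  if (nrow(profile) == 0) stop("empty broadening profile")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  if (min_run < 1) stop("min_run must be >= 1")
  out <- list()
  for (ch in unique(profile$chain)) {
    p <- profile[profile$chain == ch, , drop = FALSE]
    below_res <- p$resnum[(p$flag == "measured" & p$ratio < threshold) |
                            p$flag == "missing_in_bound"]
    above_res <- p$resnum[p$flag == "measured" & p$ratio >= threshold]
    if (length(below_res) == 0) next
    below_res <- sort(below_res)
    start <- below_res[1]
    last <- below_res[1]
    cnt <- 1L
    flush <- function(first, last, cnt) {
      if (cnt >= min_run)
        out[[length(out) + 1L]] <<- data.frame(
          chain = ch, first = first, last = last, n_below = cnt,
          stringsAsFactors = FALSE)
    }
    for (r in below_res[-1]) {
      gap <- seq_len(max(r - last - 1L, 0L)) + last
      joinable <- sum(gap %in% above_res) == 0 && length(gap) <= gap_tolerance
      # gaps longer than gap_tolerance, or interrupted by a measured
      # above-threshold residue, break the run
      if (joinable || length(gap) == 0) {
        last <- r
        cnt <- cnt + 1L
      } else {
        flush(start, last, cnt)
        start <- r; last <- r; cnt <- 1L
      }
    }
    flush(start, last, cnt)
  }
  if (length(out) == 0)
    return(data.frame(chain = character(), first = integer(),
                      last = integer(), n_below = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chain, res$first), , drop = FALSE]
}

#' Write a broadening profile (with region calls) as tsv
#'
#' @param profile a [compute_broadening_profile()] result.
#' @param path output file.
#' @param regions optional [call_binding_regions()] result used to mark the
#'   `in_region` column.
#' @return `path`, invisibly.
#' @export
write_broadening_profile <- function(profile, path, regions = NULL) {
  df <- as.data.frame(profile)
  df$in_region <- FALSE
  if (!is.null(regions) && nrow(regions))
    for (i in seq_len(nrow(regions)))
      df$in_region <- df$in_region |
        (df$chain == regions$chain[i] & df$resnum >= regions$first[i] &
           df$resnum <= regions$last[i])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
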