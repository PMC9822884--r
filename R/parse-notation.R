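# Parsers for the compact cytogenetic-style notation used in clinical CNV and
# repeat-expansion reporting, e.g. "15q26.1(93494184-93499518)x1" and
# "X:146993568_146993628CGG[94]". Coordinates are 1-based inclusive throughout
# the package (the VCF convention).

#' Parse an ISCN-like copy-number string
#'
#' Clinical reports describe copy-number variants as
#' `band(start-end)xN`: a cytogenetic band, 1-based inclusive genomic
#' coordinates, and an integer copy number. Both copy-number dialects found in
#' practice are accepted: a trailing `xN` (e.g. `"...x1"`) and a trailing `Nx`
#' (e.g. `"...3x"`).
#'
#' @param x Character vector of ISCN-like strings.
#' @return A tibble with one row per input string and columns `band`, `chrom`
#'   (derived from the band), `start`, `end` (1-based inclusive),
#'   `copy_number` and `length_bp` (`end - start + 1`).
#' @examples
#' parse_iscn_cnv("15q26.1(93494184-93499518)x1")
#' parse_iscn_cnv("16p11.2(29591089-30199431)3x")
#' @export
parse_iscn_cnv <- function(x) {
  stopifnot(is.character(x))
  # band(start-end)xN  |  band(start-end)Nx
  pat <- "^([0-9XYM]{1,2}[pq][0-9.]*)\\((\\d+)-(\\d+)\\)(?:x(\\d+)|(\\d+)x)$"
  m <- stringr::str_match(x, pat)
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort(paste0(
      "malformed ISCN-like CNV string: ",
      paste(sprintf("'%s'", x[bad]), collapse = ", "),
      " (expected band(start-end)xN or band(start-end)Nx)"
    ), class = "triotriage_parse_error")
  }
  start <- as.numeric(m[, 3])
  end <- as.numeric(m[, 4])
  if (any(start > end)) {
    off <- which(start > end)[1]
    abort(sprintf("start > end in '%s'", x[off]), class = "triotriage_parse_error")
  }
  cn <- as.integer(ifelse(is.na(m[, 5]), m[, 6], m[, 5]))
  band <- m[, 2]
  tibble(
    band = band,
    chrom = stringr::str_extract(band, "^[0-9XYM]{1,2}"),
    start = start,
    end = end,
    copy_number = cn,
    length_bp = end - start + 1
  )
}

#' Parse repeat-expansion notation
#'
#' Repeat genotypes are reported as `chrom:start_end MOTIF[n]`, e.g.
#' `"X:146993568_146993628CGG[94]"`: the reference region of the repeat
#' locus, the repeat motif, and the number of repeat units observed.
#'
#' A region length that is not a whole multiple of the motif length raises a
#' warning (reference repeat tracts are frequently interrupted or trimmed in
#' reporting), never an error.
#'
#' @param x Character vector of repeat-notation strings.
#' @return A tibble with columns `chrom`, `start`, `end`, `motif`,
#'   `repeat_units`.
#' @examples
#' parse_str_notation("X:146993568_146993628CGG[94]")
#' @export
parse_str_notation <- function(x) {
  stopifnot(is.character(x))
  pat <- "^([0-9XYM]{1,2}|chr[0-9XYM]{1,2}):(\\d+)_(\\d+)([ACGT]+)\\[(\\d+)\\]$"
  m <- stringr::str_match(x, pat)
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort(paste0(
      "malformed repeat notation: ",
      paste(sprintf("'%s'", x[bad]), collapse = ", "),
      " (expected chrom:start_end MOTIF[n])"
    ), class = "triotriage_parse_error")
  }
  out <- tibble(
    chrom = sub("^chr", "", m[, 2]),
    start = as.numeric(m[, 3]),
    end = as.numeric(m[, 4]),
    motif = m[, 5],
    repeat_units = as.integer(m[, 6])
  )
  if (any(out$start > out$end)) {
    abort("start > end in repeat region", class = "triotriage_parse_error")
  }
  span <- out$end - out$start + 1
  off <- span %% nchar(out$motif) != 0
  if (any(off)) {
    warn(sprintf(
      "repeat region length not a multiple of motif length for: %s",
      paste(x[off], collapse = ", ")
    ))
  }
  out
}

#' Human-readable CNV size label
#'
#' Formats a CNV length the way clinical tables print it: events of at least
#' 100 kb are rounded half-up to the nearest 0.1 Mb (printed as `"1.3 Mb"`,
#' `"0.6 Mb"`); smaller events are rounded half-up to the nearest kb
#' (`"5 kb"`, `"36 kb"`).
#'
#' @param start,end 1-based inclusive coordinates (vectors).
#' @return Character vector of size labels.
#' @examples
#' cnv_report_size(93494184, 93499518) # "5 kb"
#' cnv_report_size(486287, 1783151)    # "1.3 Mb"
#' @export
cnv_report_size <- function(start, end) {
  len <- end - start + 1
  stopifnot(all(len >= 1))
  half_up <- function(v) floor(v + 0.5)
  ifelse(
    len >= 1e5,
    sprintf("%g Mb", half_up(len / 1e5) / 10),
    sprintf("%d kb", as.integer(half_up(len / 1e3)))
  )
}
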