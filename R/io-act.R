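# Artemis Comparison Tool (ACT) interchange: MSPcrunch-style comparison files
# and EMBL feature tables (.tab entries). Both formats are 1-based inclusive
# on disk; the as_crunch()/tab_feature() constructors perform the one and only
# conversion from the package's 0-based half-open coordinates.

#' Build crunch rows from internal half-open coordinates
#'
#' Converts alignment coordinates from the package's 0-based half-open
#' convention to the 1-based inclusive convention of crunch files. A
#' minus-strand match is encoded by swapping the subject coordinates so that
#' sstart > send; query coordinates always satisfy qstart <= qend.
#'
#' @param score Integer chain scores (matched bases).
#' @param percent_id Percent identities (0-100).
#' @param qstart,qend 0-based half-open query intervals.
#' @param q_id Query molecule id(s).
#' @param sstart,send 0-based half-open subject intervals.
#' @param s_id Subject molecule id(s).
#' @param strand "+" or "-" per hit.
#' @return A data.frame of crunch rows ready for [write_crunch()].
#' @export
as_crunch <- function(score, percent_id, qstart, qend, q_id,
                      sstart, send, s_id, strand) {
  s1 <- ifelse(strand == "-", send, sstart + 1L)
  s2 <- ifelse(strand == "-", sstart + 1L, send)
  data.frame(score = as.integer(round(score)),
             percent_id = round(percent_id, 1),
             qstart = as.integer(qstart + 1L), qend = as.integer(qend),
             q_id = q_id,
             sstart = as.integer(s1), send = as.integer(s2),
             s_id = s_id, stringsAsFactors = FALSE)
}

#' Write an ACT crunch comparison file
#'
#' One line per hit, single-space separated:
#' `score percent_id qstart qend q_id sstart send s_id`.
#'
#' @param hits Data.frame of crunch rows (see [as_crunch()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crunch <- function(hits, path) {
  lines <- sprintf("%d %s %d %d %s %d %d %s",
                   hits$score, formatC(hits$percent_id, format = "f", digits = 1),
                   hits$qstart, hits$qend, hits$q_id,
                   hits$sstart, hits$send, hits$s_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read an ACT crunch comparison file
#'
#' @param path Path to a crunch file written by [write_crunch()].
#' @return A data.frame with the eight crunch columns (1-based inclusive,
#'   minus strand encoded as sstart > send).
#' @export
read_crunch <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(score = integer(), percent_id = numeric(),
                      qstart = integer(), qend = integer(), q_id = character(),
                      sstart = integer(), send = integer(), s_id = character(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  if (ncol(parts) != 8L) stopf("malformed crunch file: %s", path)
  data.frame(score = as.integer(parts[, 1L]),
             percent_id = as.numeric(parts[, 2L]),
             qstart = as.integer(parts[, 3L]), qend = as.integer(parts[, 4L]),
             q_id = parts[, 5L],
             sstart = as.integer(parts[, 6L]), send = as.integer(parts[, 7L]),
             s_id = parts[, 8L], stringsAsFactors = FALSE)
}

#' Construct an EMBL feature-table feature
#'
#' @param key Feature key (e.g. `"misc_feature"`).
#' @param start,end 0-based half-open coordinates on the molecule.
#' @param strand `"+"` or `"-"`; minus strand is rendered as
#'   `complement(start..end)`.
#' @param qualifiers Named character vector of qualifiers
#'   (e.g. `c(label = "contig_3", colour = "4")`); values that are not plain
#'   integers are quoted on output.
#' @return A one-element list holding the feature (append with `c()`).
#' @export
tab_feature <- function(key, start, end, strand = "+", qualifiers = character()) {
  stopifnot(start < end, strand %in% c("+", "-"))
  list(list(key = key, start = as.integer(start + 1L), end = as.integer(end),
            strand = strand, qualifiers = qualifiers))
}

#' Write features as an EMBL feature table (Artemis .tab entry)
#'
#' Each feature is rendered as `FT   <key><location>` with the key padded to
#' 16 columns and one `FT` continuation line per qualifier.
#'
#' @param features List of features built with [tab_feature()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tab <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in features) {
    loc <- sprintf("%d..%d", f$start, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("FT   %-16s%s", f$key, loc), con)
    q <- f$qualifiers
    for (nm in names(q)) {
      val <- q[[nm]]
      if (!grepl("^-?\\d+$", val)) val <- sprintf("\"%s\"", gsub("\"", "'", val))
      writeLines(sprintf("FT%s/%s=%s", strrep(" ", 19L), nm, val), con)
    }
  }
  invisible(path)
}
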