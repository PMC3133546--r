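# NCBI PTT protein tables: two free-text header lines, a tab-separated column
# header, then one row per CDS. Only Location/Strand/PID/Gene/Product are
# used downstream.

#' Read an NCBI PTT protein table
#'
#' @param path Path to a `.ptt` file.
#' @param ref_id Replicon id the table belongs to (recorded in the result;
#'   PTT files do not carry one).
#' @return A data.frame with columns `ref_id`, `start`, `end` (1-based
#'   inclusive reference coordinates, as printed in the file), `strand`,
#'   `pid`, `gene`, `product`. Rows with an unparsable Location are skipped
#'   with a warning.
#' @export
read_ptt <- function(path, ref_id = NA_character_) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  ptt_empty <- function() data.frame(
    ref_id = character(), start = integer(), end = integer(),
    strand = character(), pid = character(), gene = character(),
    product = character(), stringsAsFactors = FALSE)
  hdr_i <- grep("^Location\t", lines)
  if (!length(hdr_i))
    stopf("not a PTT file (no 'Location' column header): %s", path)
  hdr_i <- hdr_i[[1L]]
  cols <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1L]]
  need <- c("Location", "Strand", "PID")
  if (!all(need %in% cols))
    stopf("PTT column header missing %s in %s",
          paste(setdiff(need, cols), collapse = "/"), path)
  rows <- lines[seq.int(hdr_i + 1L, length.out = max(0L, length(lines) - hdr_i))]
  rows <- rows[nzchar(rows)]
  if (!length(rows)) return(ptt_empty())
  parts <- strsplit(rows, "\t", fixed = TRUE)
  get_col <- function(p, name) {
    i <- match(name, cols)
    if (is.na(i) || i > length(p)) "" else p[[i]]
  }
  loc <- vapply(parts, get_col, "", name = "Location")
  ok <- grepl("^\\d+\\.\\.\\d+$", loc)
  if (any(!ok))
    warnf("skipping %d PTT row(s) with unparsable Location in %s",
          sum(!ok), path)
  parts <- parts[ok]
  loc <- loc[ok]
  if (!length(parts)) return(ptt_empty())
  se <- do.call(rbind, strsplit(loc, "..", fixed = TRUE))
  data.frame(
    ref_id = ref_id,
    start = as.integer(se[, 1L]),
    end = as.integer(se[, 2L]),
    strand = vapply(parts, get_col, "", name = "Strand"),
    pid = vapply(parts, get_col, "", name = "PID"),
    gene = vapply(parts, get_col, "", name = "Gene"),
    product = vapply(parts, get_col, "", name = "Product"),
    stringsAsFactors = FALSE)
}

#' Write protein features as an NCBI PTT table
#'
#' @param features Data.frame as returned by [read_ptt()].
#' @param path Output path.
#' @param title First header line (free text).
#' @return `path`, invisibly.
#' @export
write_ptt <- function(features, path, title = "synthetic replicon") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, sprintf("%d proteins", nrow(features)),
               paste(c("Location", "Strand", "Length", "PID", "Gene",
                       "Synonym", "Code", "COG", "Product"),
                     collapse = "\t")), con)
  if (nrow(features)) {
    aa_len <- (features$end - features$start + 1L) %/% 3L - 1L
    writeLines(sprintf("%d..%d\t%s\t%d\t%s\t%s\t-\t-\t-\t%s",
                       features$start, features$end, features$strand,
                       pmax(aa_len, 0L), features$pid,
                       ifelse(nzchar(features$gene), features$gene, "-"),
                       features$product), con)
  }
  invisible(path)
}

#' Attach protein sequences to PTT features by translating the reference
#'
#' Translates each feature's reference span (reverse-complemented for minus
#' strand) under the bacterial genetic code. Features whose span length is
#' not a multiple of 3 (e.g. pseudogenes) are skipped with a warning; a
#' trailing stop codon is trimmed from the protein.
#'
#' @param features Data.frame from [read_ptt()].
#' @param replicon A single record data.frame (the reference replicon).
#' @return `features` restricted to translatable rows, with an `aa` column.
#' @export
translate_features <- function(features, replicon) {
  stopifnot(nrow(replicon) == 1L)
  len <- features$end - features$start + 1L
  ok <- len %% 3L == 0L & features$start >= 1L &
    features$end <= nchar(replicon$sequence)
  if (any(!ok))
    warnf("skipping %d feature(s) with span not a multiple of 3 or out of range",
          sum(!ok))
  features <- features[ok, , drop = FALSE]
  aa <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    nt <- substr(replicon$sequence, features$start[i], features$end[i])
    if (features$strand[i] == "-") nt <- reverse_complement(nt)
    p <- translate_dna(nt)
    aa[i] <- sub("\\*$", "", p)
  }
  features$aa <- aa
  features
}
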