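# FASTA reading/writing.
#
# Record sets are plain data.frames (columns id, description, sequence), the
# lightest container that keeps ids, free-text descriptions and sequences
# together; helpers below convert to/from disk.

#' Read a (multi-)FASTA file
#'
#' Parses a FASTA file into a data.frame with one row per record. Sequences
#' are uppercased and line breaks removed; the record id is the first
#' whitespace-delimited word of the header, the rest is the description.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `description`, `sequence`.
#'   An empty file yields a zero-row data.frame.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">ctg_1 a draft contig", "ACGTacgt"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | cumsum(grepl("^>", lines)) > 0]
  if (!length(lines)) return(empty_records())
  if (!startsWith(lines[[1L]], ">"))
    stopf("not a FASTA file (first non-blank line must start with '>'): %s",
          path)
  hdr <- grepl("^>", lines)
  rec <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids  <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(split(lines[!hdr], factor(rec[!hdr], levels = seq_along(ids))),
                 function(x) paste(x, collapse = ""), character(1))
  seqs <- toupper(gsub("\\s", "", seqs))
  if (any(!nzchar(ids))) stopf("FASTA record with empty id in %s", path)
  if (any(!nzchar(seqs)))
    stopf("FASTA record '%s' has an empty sequence", ids[!nzchar(seqs)][1L])
  for (i in seq_along(ids)) validate_dna(seqs[[i]], ids[[i]])
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records A data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  width <- assert_scalar_int(width, "width", min = 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$description[i]))
      paste0(">", records$id[i], " ", records$description[i])
    else paste0(">", records$id[i])
    writeLines(hdr, con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
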