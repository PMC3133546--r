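# Internal helpers shared across modules.
#
# Coordinate convention: all in-memory coordinates are 0-based half-open
# [start, end); conversion to the 1-based inclusive coordinates used by the
# on-disk formats (FASTA-adjacent tables, crunch, EMBL feature tables) happens
# exactly once, at the write boundary (see io-act.R).

# IUPAC nucleotide alphabet accepted on input; letters other than A/C/G/T/N
# are preserved but never seeded or counted as matches by the aligner.
IUPAC_DNA <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
               "V", "H", "D", "B", "N")

IUPAC_FROM <- "ACGTMRWSYKVHDBN"
IUPAC_TO   <- "TGCAKYWSRMBDHVN"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards, so deterministic generators do not perturb user code.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_int <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stopf("'%s' must be a single integer >= %s", name, min)
  as.integer(x)
}

# Fast string reversal (used by reverse_complement on long replicons).
str_rev <- function(s) intToUtf8(rev(utf8ToInt(s)))

validate_dna <- function(seq, id = "<sequence>") {
  bad <- regmatches(seq, regexpr(sprintf("[^%s]", IUPAC_FROM), seq))
  if (length(bad) && nzchar(bad))
    stopf("record '%s' contains non-IUPAC character '%s'", id, bad)
  invisible(seq)
}

# One sequence record; a set of records is a plain data.frame with columns
# id / description / sequence (see read_fasta).
seq_record <- function(id, sequence, description = "") {
  data.frame(id = as.character(id), description = as.character(description),
             sequence = as.character(sequence), stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(id = character(), description = character(),
             sequence = character(), stringsAsFactors = FALSE)
}
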