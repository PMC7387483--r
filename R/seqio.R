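#' Read sequences from a FASTA file
#'
#' Reads a protein or DNA FASTA file into a record table. IDs are the first
#' whitespace-delimited token of the header; the full header is kept as the
#' description. Sequences are uppercased and validated against the alphabet:
#' the 20 standard amino acids plus `X` for proteins (records containing `X`
#' are flagged and fail every physicochemical gate downstream), or `ACGTN`
#' for DNA.
#'
#' @param path FASTA file path.
#' @param alphabet `"protein"` or `"dna"`.
#' @param allow_gaps Also accept `-` and `.` (aligned FASTA input).
#' @return A data.frame with columns `id`, `description`, `seq`, `length`
#'   and (protein only) `has_x`. Row order follows file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "WWLSRRRSSLFYWR"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"),
                       allow_gaps = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    if (alphabet == "protein") {
      Biostrings::readBStringSet(path)
    } else {
      Biostrings::readBStringSet(path)
    },
    error = function(e) {
      stop("FASTA parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(headers))) {
    stop("FASTA parse error in '", path, "': entry with empty header",
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  allowed <- if (alphabet == "protein") c(AA20, "X") else c("A","C","G","T","N")
  if (allow_gaps) allowed <- c(allowed, "-", ".")
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad)) {
      stop("illegal ", alphabet, " character '", bad[1], "' in record '",
           ids[i], "'", call. = FALSE)
    }
    if (nchar(seqs[[i]]) < 1L) {
      stop("empty sequence in record '", ids[i], "'", call. = FALSE)
    }
  }
  out <- data.frame(id = ids, description = unname(headers),
                    seq = unname(seqs), length = nchar(seqs),
                    stringsAsFactors = FALSE)
  if (alphabet == "protein") {
    out$has_x <- grepl("X", out$seq, fixed = TRUE)
  } else {
    long <- out$length > 2000L
    if (any(long)) {
      warning("upstream record(s) longer than 2,000 bp: ",
              paste(out$id[long], collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Write a record table to FASTA
#'
#' Round-trip companion to [read_fasta()]: IDs and sequences are reproduced
#' exactly (the description, when distinct from the id, is written after it).
#'
#' @param records Data.frame with `id`, `seq` and optionally `description`.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  headers <- records$id
  if (!is.null(records$description)) {
    extra <- records$description != records$id
    headers[extra] <- records$description[extra]
  }
  set <- Biostrings::BStringSet(setNames(records$seq, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Keep records within a length range
#'
#' Both bounds are inclusive; input order is preserved. The default bounds
#' are the precursor-length gate of the screen (50-100 residues).
#'
#' @param records Record table from [read_fasta()].
#' @param min_len,max_len Inclusive bounds in residues.
#' @return The filtered record table.
#' @export
length_filter <- function(records, min_len = 50L, max_len = 100L) {
  if (min_len > max_len) stop("min_len > max_len", call. = FALSE)
  records[records$length >= min_len & records$length <= max_len, ,
          drop = FALSE]
}

#' Write a screening report as TSV
#'
#' One row per input record, tab-separated, in input order. Coordinates are
#' 1-based inclusive on the precursor sequence.
#'
#' @param report Candidate report from [run_funnel()].
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  ok <- tryCatch({
    write.table(report, path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write report to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}
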