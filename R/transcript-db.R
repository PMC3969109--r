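#' Transcript sequence databases
#'
#' A transcript database is a FASTA file whose headers encode the transcript
#' class (biotype) in-band: headers are underscore-delimited with the biotype
#' as the final field and a human-readable display name as the penultimate
#' field, e.g. `ENSG0_ENST0_ACTB_mRNA` or `MIMAT0000062_hsa-let-7a_microRNA`.
#' This keeps the database a plain FASTA while letting the chimera caller
#' reason about transcript classes (miRNA vs mRNA).
#'
#' @param path FASTA file of transcript sequences.
#' @return a `transcript_db` object: list with
#'   \describe{
#'     \item{seq}{named character vector of uppercase sequences, keyed by full id}
#'     \item{info}{data.table with `full_id`, `display_name`, `biotype`, `length`}
#'   }
#' @export
read_transcript_db <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(x) == 0) stop("empty transcript database: ", path)
  ids <- sub("\\s.*$", "", names(x))
  transcript_db(setNames(toupper(as.character(x)), ids))
}

#' @param seqs named character vector of sequences (names are full ids).
#' @rdname read_transcript_db
#' @export
transcript_db <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("transcript sequences must be named")
  if (anyDuplicated(ids))
    stop("duplicated transcript id(s): ",
         paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  parts <- strsplit(ids, "_", fixed = TRUE)
  nf <- lengths(parts)
  biotype <- ifelse(nf >= 2, vapply(parts, tail, "", n = 1L), NA_character_)
  display <- ifelse(nf >= 2, vapply(parts, function(p) p[length(p) - 1L], ""), ids)
  info <- data.table(full_id = ids, display_name = display, biotype = biotype,
                     length = nchar(seqs))
  structure(list(seq = seqs, info = info), class = "transcript_db")
}

#' Write a transcript database to FASTA
#' @param db a `transcript_db`.
#' @param path output FASTA path.
#' @export
write_transcript_db <- function(db, path) {
  x <- Biostrings::DNAStringSet(db$seq)
  Biostrings::writeXStringSet(x, path, width = 20000L)
  invisible(path)
}

#' @export
print.transcript_db <- function(x, ...) {
  cat(sprintf("transcript_db: %d entries, %d nt total\n",
              length(x$seq), sum(x$info$length)))
  print(x$info[, .N, by = biotype])
  invisible(x)
}

db_biotype <- function(db, ids) {
  db$info$biotype[match(ids, db$info$full_id)]
}

db_length <- function(db, ids) {
  db$info$length[match(ids, db$info$full_id)]
}

db_subseq <- function(db, id, start, end) {
  if (!id %in% names(db$seq)) stop("transcript not in database: ", id)
  s <- db$seq[[id]]
  if (start < 1 || end > nchar(s) || start > end)
    stop(sprintf("coordinates [%d,%d] out of range for %s (length %d)",
                 start, end, id, nchar(s)))
  substr(s, start, end)
}
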