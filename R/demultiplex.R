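#' 5' barcode handling
#'
#' CLASH 5' barcodes combine a sample-specific multiplexing code with random
#' positions (written `N`) used to monitor PCR amplification. A barcode file
#' has two whitespace-separated columns, `pattern sample`, with `#` comments,
#' e.g. `NNNACGT sample1`. All patterns must have the same length; the coded
#' (non-N) positions identify the sample.
#'
#' @param path barcode file.
#' @return data.table with columns `sample` and `pattern`.
#' @export
read_barcodes <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no barcodes in ", path)
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) != 2))
    stop("barcode file lines must be 'pattern sample'")
  m <- do.call(rbind, fields)
  barcode_specs(sample = m[, 2], pattern = m[, 1])
}

#' @param sample,pattern equal-length character vectors; patterns over
#'   \{A,C,G,T,N\} with N marking random positions.
#' @rdname read_barcodes
#' @export
barcode_specs <- function(sample, pattern) {
  pattern <- toupper(pattern)
  if (any(grepl("[^ACGTN]", pattern))) stop("barcode patterns must be over {A,C,G,T,N}")
  if (length(unique(nchar(pattern))) != 1) stop("all barcode patterns must have the same length")
  if (anyDuplicated(sample)) stop("duplicated sample name(s)")
  data.table(sample = sample, pattern = pattern)
}

#' Build the barcode lookup table
#'
#' Enumerates every read prefix compatible with one of the barcode patterns
#' under at most `mismatches` substitutions at coded positions (never at N
#' positions, and no indels), so that demultiplexing needs a single substring
#' extraction and one hash lookup per read.
#'
#' @param specs barcode table from [barcode_specs()] / [read_barcodes()].
#' @param mismatches allowed substitutions in the multiplexing code, 0
#'   (default) or 1.
#' @return a `barcode_table` object (lookup environment plus per-sample
#'   random-position masks).
#' @export
build_barcode_table <- function(specs, mismatches = 0L) {
  stopifnot(mismatches %in% c(0L, 1L))
  len <- nchar(specs$pattern[1])
  # pairwise distance check at coded positions: codes must differ at more
  # than 2*mismatches positions or assignment would be ambiguous
  pats <- strsplit(specs$pattern, "")
  for (i in seq_along(pats)) for (j in seq_len(i - 1L)) {
    coded <- pats[[i]] != "N" & pats[[j]] != "N"
    d <- sum(pats[[i]][coded] != pats[[j]][coded]) +
      sum(pats[[i]] == "N" & pats[[j]] != "N") + sum(pats[[j]] == "N" & pats[[i]] != "N")
    if (d <= 2L * mismatches)
      stop(sprintf("barcodes '%s' and '%s' are ambiguous at %d mismatch(es)",
                   specs$pattern[i], specs$pattern[j], mismatches))
  }
  bases <- c("A", "C", "G", "T")
  keys <- character(0); vals <- character(0)
  for (i in seq_len(nrow(specs))) {
    p <- pats[[i]]
    variants <- specs$pattern[i]
    if (mismatches == 1L) {
      coded <- which(p != "N")
      for (pos in coded) for (b in setdiff(bases, p[pos])) {
        v <- p; v[pos] <- b
        variants <- c(variants, paste(v, collapse = ""))
      }
    }
    for (v in variants) {
      vp <- strsplit(v, "")[[1]]
      ns <- which(vp == "N")
      if (length(ns) == 0) {
        expanded <- v
      } else {
        fills <- do.call(expand.grid, c(rep(list(bases), length(ns)),
                                        stringsAsFactors = FALSE))
        expanded <- vapply(seq_len(nrow(fills)), function(k) {
          w <- vp; w[ns] <- unlist(fills[k, ]); paste(w, collapse = "")
        }, character(1))
      }
      keys <- c(keys, expanded)
      vals <- c(vals, rep(specs$sample[i], length(expanded)))
    }
  }
  # a prefix compatible with two samples is unassignable
  dup <- keys[duplicated(keys)]
  if (length(dup)) {
    amb <- unique(dup)
    drop <- keys %in% amb
    keys <- keys[!drop]; vals <- vals[!drop]
  }
  env <- new.env(hash = TRUE, parent = emptyenv(), size = max(length(keys), 16L))
  for (k in seq_along(keys)) assign(keys[k], vals[k], envir = env)
  masks <- lapply(seq_len(nrow(specs)), function(i) which(pats[[i]] == "N"))
  names(masks) <- specs$sample
  structure(list(env = env, length = len, masks = masks,
                 samples = specs$sample, n_keys = length(keys)),
            class = "barcode_table")
}

#' Demultiplex reads by 5' barcode
#'
#' Splits reads into per-sample sets using the precomputed lookup table. The
#' barcode is removed from sequence and qualities; the random part of the
#' barcode is stored in `random_tag` and appended to the read identifier.
#' Reads with no table entry (or shorter than the barcode) are routed to
#' `"unassigned"`, so the output is an exact partition of the input.
#'
#' @param reads a [clash_reads] table.
#' @param table a `barcode_table` from [build_barcode_table()].
#' @return named list of [clash_reads] tables, one per sample plus
#'   `"unassigned"`.
#' @export
demultiplex <- function(reads, table) {
  stopifnot(inherits(table, "barcode_table"))
  L <- table$length
  prefix <- substr(reads$seq, 1L, L)
  sample <- vapply(prefix, function(p)
    get0(p, envir = table$env, ifnotfound = NA_character_),
    character(1), USE.NAMES = FALSE)
  short <- nchar(reads$seq) <= L
  if (any(short)) {
    warning(sum(short), " read(s) shorter than the barcode; routed to unassigned")
    sample[short] <- NA_character_
  }
  out <- list()
  for (s in table$samples) {
    sel <- which(!is.na(sample) & sample == s)
    sub <- reads[sel]
    if (nrow(sub) > 0) {
      mask <- table$masks[[s]]
      tag <- if (length(mask)) {
        vapply(strsplit(substr(sub$seq, 1L, L), ""),
               function(ch) paste(ch[mask], collapse = ""), character(1))
      } else rep("", nrow(sub))
      sub[, random_tag := tag]
      sub[, id := if (all(tag == "")) id else paste0(id, ":", tag)]
      sub[, seq := substr(seq, L + 1L, nchar(seq))]
      sub[, qual := ifelse(is.na(qual), qual, substr(qual, L + 1L, nchar(qual)))]
    }
    out[[s]] <- sub
  }
  out[["unassigned"]] <- reads[which(is.na(sample))]
  out
}
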