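#' Nearest-neighbor duplex energy parameters
#'
#' Turner-style RNA stacking free energies at 37 degrees C (kcal/mol) for
#' Watson-Crick and GU wobble pairs, assembled into a 6x6 matrix over the
#' pair types AU, UA, CG, GC, GU, UG. `stacks[p, q]` is the free-energy
#' increment of pair q stacked 3' (on strand 1) of pair p. The matrix
#' respects the physical strand-flip symmetry
#' `G[p, q] == G[rev(q), rev(p)]` (rev swaps the two bases of a pair), which
#' makes the duplex energy invariant under exchanging the two strands.
#' Interior and bulge loops carry an affine penalty
#' `loop_a + loop_b * n_unpaired` (a documented simplification of the full
#' tabulated loop model), duplex initiation costs `init`, and loops longer
#' than `max_loop` unpaired nt are disallowed.
#'
#' @return list with elements `stacks` (6x6 numeric matrix), `init`,
#'   `loop_a`, `loop_b`, `max_loop`.
#' @export
duplex_energy_params <- function() {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  rev_pair <- c(AU = "UA", UA = "AU", CG = "GC", GC = "CG", GU = "UG", UG = "GU")
  G <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  set <- function(p, q, v) {
    G[p, q] <<- v
    G[rev_pair[q], rev_pair[p]] <<- v
  }
  # Watson-Crick / Watson-Crick (Xia et al. style values)
  set("AU", "AU", -0.93)
  set("AU", "UA", -1.10)
  set("UA", "AU", -1.33)
  set("CG", "UA", -2.08)   # 5'CU3'/3'GA5'
  set("CG", "AU", -2.11)   # 5'CA3'/3'GU5'
  set("GC", "UA", -2.24)   # 5'GU3'/3'CA5'
  set("GC", "AU", -2.35)   # 5'GA3'/3'CU5'
  set("CG", "GC", -2.36)
  set("GC", "GC", -3.26)   # == CG,CG by symmetry
  set("GC", "CG", -3.42)
  # GU wobble stacks (representative published values)
  set("AU", "GU", -0.55)
  set("AU", "UG", -1.36)
  set("CG", "GU", -1.41)
  set("CG", "UG", -2.11)
  set("GC", "GU", -1.53)
  set("GC", "UG", -2.51)
  set("UA", "GU", -1.00)
  set("UA", "UG", -1.27)
  set("GU", "AU", -1.27)
  set("GU", "CG", -2.51)
  set("GU", "GC", -2.11)
  set("GU", "UA", -1.36)
  set("GU", "GU", -0.50)
  set("GU", "UG", 1.29)
  set("UG", "GU", 0.30)
  set("UG", "UG", -0.50)
  stopifnot(!anyNA(G))
  list(stacks = G, init = 4.09, loop_a = 2.0, loop_b = 0.5, max_loop = 30L)
}

#' Fold two RNA fragments as an intermolecular duplex
#'
#' Computes the minimum-free-energy hybridization of two sequences under a
#' nearest-neighbor stacking model with intermolecular pairs only (no
#' hairpins): Watson-Crick and GU pairs, affine interior/bulge-loop
#' penalties, and a duplex initiation penalty (see
#' [duplex_energy_params()]). T is read as U; N positions never pair. The
#' result is deterministic and symmetric in the two strands:
#' `dG(s1, s2) == dG(s2, s1)`.
#'
#' @param seq1,seq2 sequences over \{A,C,G,T,U,N\} (length >= 1).
#' @param par energy parameters, [duplex_energy_params()] by default.
#' @return a `duplex_result` list: `seq1`, `seq2`, `structure` (dot-bracket
#'   of length `nchar(seq1) + 1 + nchar(seq2)` with `(` in strand 1, `)` in
#'   strand 2 and `&` between), `dG` (kcal/mol, <= 0; 0 iff no pairs), and
#'   `n_pairs`.
#' @examples
#' duplex_fold("ACGUACGUAC", "GUACGUACGU")  # perfect 10-bp duplex
#' @export
duplex_fold <- function(seq1, seq2, par = duplex_energy_params()) {
  stopifnot(nchar(seq1) >= 1, nchar(seq2) >= 1)
  if (grepl("[^ACGTUNacgtun]", seq1) || grepl("[^ACGTUNacgtun]", seq2))
    stop("sequences must be over {A,C,G,T,U,N}")
  res <- cpp_duplex_fold(toupper(seq1), toupper(seq2), par$stacks,
                         par$init, par$loop_a, par$loop_b, par$max_loop)
  structure(list(seq1 = seq1, seq2 = seq2,
                 structure = res$structure,
                 dG = round(res$dG, 2), n_pairs = res$n_pairs),
            class = "duplex_result")
}

#' @export
print.duplex_result <- function(x, ...) {
  cat(x$seq1, "&", x$seq2, "\n", sep = "")
  cat(x$structure, "\n")
  cat(sprintf("dG = %s kcal/mol (%d pairs)\n", fmt_num(x$dG), x$n_pairs))
  invisible(x)
}

#' Recompute the energy of a given duplex structure
#'
#' Independent structure-scoring routine: given the two sequences and a
#' dot-bracket duplex structure, sums the initiation penalty, stacking
#' terms and loop penalties of [duplex_energy_params()]. Used to verify
#' that reported structures are scored consistently with the reported dG.
#'
#' @param seq1,seq2 the two sequences.
#' @param structure dot-bracket string with `&` separator.
#' @param par energy parameters.
#' @return energy in kcal/mol (0 for the empty structure).
#' @export
duplex_energy <- function(seq1, seq2, structure, par = duplex_energy_params()) {
  n1 <- nchar(seq1); n2 <- nchar(seq2)
  if (nchar(structure) != n1 + 1 + n2) stop("structure/sequence length mismatch")
  ch <- strsplit(structure, "")[[1]]
  if (ch[n1 + 1] != "&") stop("missing '&' separator in structure")
  open <- which(ch[seq_len(n1)] == "(")
  close <- which(ch[(n1 + 2):(n1 + 1 + n2)] == ")")
  if (length(open) != length(close)) stop("unbalanced duplex structure")
  if (length(open) == 0) return(0)
  # nesting: k-th '(' (5'->3' in strand 1) pairs the k-th ')' counted from
  # the 3' end of strand 2
  j <- rev(close)
  s1 <- chartr("T", "U", toupper(seq1)); s2 <- chartr("T", "U", toupper(seq2))
  b1 <- strsplit(s1, "")[[1]]; b2 <- strsplit(s2, "")[[1]]
  ptype <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% rownames(par$stacks)) key else NA_character_
  }
  e <- par$init
  prev <- NULL
  for (k in seq_along(open)) {
    p <- ptype(b1[open[k]], b2[j[k]])
    if (is.na(p)) stop("unpairable bases paired at position ", open[k])
    if (!is.null(prev)) {
      un1 <- open[k] - open[k - 1] - 1L
      un2 <- j[k - 1] - j[k] - 1L
      if (un2 < 0) stop("crossing pairs in duplex structure")
      if (un1 + un2 > par$max_loop) stop("loop longer than max_loop")
      e <- e + if (un1 == 0 && un2 == 0) par$stacks[prev, p]
      else par$loop_a + par$loop_b * (un1 + un2)
    }
    prev <- p
  }
  e
}

#' Extract the transcript subsequences of a chimera for folding
#'
#' Folding uses transcript sequences extracted from the database at the
#' call's (possibly extended) coordinates, never the read sequence, because
#' reads may carry crosslinking-induced substitutions and deletions that are
#' irrelevant to in vivo pairing.
#'
#' @param call one-row `hyb_calls` table (or a row index into `calls`).
#' @param db the `transcript_db`.
#' @return character vector `c(seq1, seq2)`.
#' @export
extract_fold_sequences <- function(call, db) {
  c(db_subseq(db, call$tx1, call$s1_start, call$s1_end),
    db_subseq(db, call$tx2, call$s2_start, call$s2_end))
}

#' Fold all chimera calls
#'
#' Adds the duplex folding energy (`dG`, written to .hyb column 3) and the
#' dot-bracket structure to every call. Calls sharing a transcript pair and
#' identical coordinates are folded once and share the identical result.
#' Alternatively, externally produced foldings in viennad format can be
#' imported (`backend = "viennad-import"`).
#'
#' @param calls a `hyb_calls` table.
#' @param db the `transcript_db`.
#' @param backend `"builtin"` (default) or `"viennad-import"`.
#' @param viennad path to an existing viennad file when importing.
#' @param par energy parameters for the builtin backend.
#' @return the calls with `dG`, `seq1`, `seq2`, `structure` columns filled.
#' @export
fold_chimeras <- function(calls, db, backend = c("builtin", "viennad-import"),
                          viennad = NULL, par = duplex_energy_params()) {
  backend <- match.arg(backend)
  out <- copy(as_hyb_calls(calls))
  if (nrow(out) == 0) {
    out[, `:=`(seq1 = character(), seq2 = character(), structure = character())]
    return(out[])
  }
  if (backend == "viennad-import") {
    if (is.null(viennad)) stop("viennad-import backend needs a viennad= file")
    v <- read_viennad(viennad)
    m <- match(out$read_id, v$read_id)
    if (anyNA(m)) stop("viennad file lacks fold for read(s): ",
                       paste(head(out$read_id[is.na(m)], 3), collapse = ", "))
    out[, `:=`(dG = v$dG[m], seq1 = v$seq1[m], seq2 = v$seq2[m],
               structure = v$structure[m])]
    return(out[])
  }
  key <- paste(out$tx1, out$s1_start, out$s1_end,
               out$tx2, out$s2_start, out$s2_end)
  uk <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    sq <- extract_fold_sequences(out[i], db)
    fr <- duplex_fold(sq[1], sq[2], par)
    assign(key[i], list(dG = fr$dG, seq1 = sq[1], seq2 = sq[2],
                        structure = fr$structure), envir = cache)
  }
  res <- lapply(key, get, envir = cache)
  out[, `:=`(dG = vapply(res, `[[`, numeric(1), "dG"),
             seq1 = vapply(res, `[[`, character(1), "seq1"),
             seq2 = vapply(res, `[[`, character(1), "seq2"),
             structure = vapply(res, `[[`, character(1), "structure"))]
  out[]
}
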