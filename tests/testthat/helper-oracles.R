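# Independent oracles used to validate the compiled implementations.

# Exhaustive Smith-Waterman local alignment score, affine gaps (a gap of
# length L costs open + L * ext). Plain full-matrix dynamic program in R,
# written independently of the seed-and-extend implementation.
sw_oracle_score <- function(query, subject, match = 1, mismatch = -2,
                            open = 5, ext = 1) {
  q <- strsplit(toupper(query), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  n <- length(q); m <- length(s)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (q[i - 1] == s[j - 1] && q[i - 1] %in% c("A", "C", "G", "T"))
        match else mismatch
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Exhaustive duplex MFE by memoized enumeration of all chains of nested
# intermolecular pairs, anchored at the FIRST pair (smallest i, largest j) --
# the reverse of the implementation's recursion. Shares only the energy
# tables with the implementation.
duplex_oracle_mfe <- function(s1, s2, par = duplex_energy_params()) {
  b1 <- strsplit(chartr("Tt", "Uu", toupper(s1)), "")[[1]]
  b2 <- strsplit(chartr("Tt", "Uu", toupper(s2)), "")[[1]]
  n1 <- length(b1); n2 <- length(b2)
  ptype <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% rownames(par$stacks)) key else NA_character_
  }
  P <- matrix(NA_character_, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) P[i, j] <- ptype(b1[i], b2[j])
  memo <- matrix(NA_real_, n1, n2)
  ext_from <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- 0  # chain may end here
    if (i < n1) for (k in (i + 1):n1) {
      un1 <- k - i - 1
      if (un1 > par$max_loop) break
      for (l in rev(seq_len(j - 1))) {
        un2 <- j - l - 1
        if (un1 + un2 > par$max_loop) break
        if (is.na(P[k, l])) next
        step <- if (un1 == 0 && un2 == 0) par$stacks[P[i, j], P[k, l]]
        else par$loop_a + par$loop_b * (un1 + un2)
        cand <- step + ext_from(k, l)
        if (cand < best) best <- cand
      }
    }
    memo[i, j] <<- best
    best
  }
  mfe <- 0
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (is.na(P[i, j])) next
    e <- par$init + ext_from(i, j)
    if (e < mfe) mfe <- e
  }
  mfe
}

# Brute-force seed-site scan: does the Watson-Crick complement of miRNA
# nt 2-7 occur in the target? (position-by-position comparison)
seed_match_oracle <- function(mirna, target) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  m <- strsplit(chartr("u", "U", toupper(mirna)), "")[[1]]
  if (length(m) < 7) return(FALSE)
  site <- rev(unname(comp[m[2:7]]))
  t <- strsplit(chartr("Uu", "TT", toupper(target)), "")[[1]]
  if (length(t) < 6) return(FALSE)
  for (p in 1:(length(t) - 5)) {
    if (all(t[p:(p + 5)] == site)) return(TRUE)
  }
  FALSE
}

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                  collapse = "")
random_rna <- function(len) paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
                                  collapse = "")

# mutate a sequence at k random positions
mutate_seq <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), min(k, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# small deterministic transcript db used by several suites
toy_db <- function(seed = 42) make_transcript_db(
  n_mrna = 12, n_mirna = 4, mrna_len_range = c(200L, 400L),
  redundancy = 1, seed = seed)
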