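# Independent brute-force oracles, kept deliberately separate from the
# package's implementation paths.

.oracle_bond_table <- function() {
  b <- matrix(0L, 4L, 4L, dimnames = list(c("A","C","G","U"),
                                          c("A","C","G","U")))
  b["G","C"] <- b["C","G"] <- 3L
  b["A","U"] <- b["U","A"] <- 2L
  b["G","U"] <- b["U","G"] <- 1L
  b["A","C"] <- b["C","A"] <- 1L
  b
}

# score one window by an explicit per-position loop
oracle_score <- function(mirna, window) {
  b <- .oracle_bond_table()
  m <- strsplit(mirna, "")[[1]]
  w <- strsplit(window, "")[[1]]
  L <- length(m)
  total <- 0L
  for (k in seq_len(L)) {
    mb <- m[[L - k + 1L]]  # antiparallel partner
    wb <- w[[k]]
    if (mb %in% rownames(b) && wb %in% rownames(b)) {
      total <- total + b[wb, mb]
    }
  }
  total
}

oracle_max_bonds <- function(mirna) {
  m <- strsplit(mirna, "")[[1]]
  sum(ifelse(m %in% c("G", "C"), 3L, 2L))
}

# score every window independently (one lookup-sum per window, no sliding
# accumulation shared with the scanner), filter by unrounded ratio threshold
oracle_scan <- function(mirna, transcript_seq, threshold) {
  b <- .oracle_bond_table()
  b5 <- rbind(cbind(b, N = 0L), N = 0L)  # N pairs with nothing
  alph <- c("A", "C", "G", "U", "N")
  L <- nchar(mirna)
  mb <- oracle_max_bonds(mirna)
  q <- rev(match(strsplit(mirna, "")[[1]], alph))
  t_idx <- match(strsplit(transcript_seq, "")[[1]], alph)
  starts <- integer(0)
  ratios <- numeric(0)
  for (s in seq_len(nchar(transcript_seq) - L + 1L)) {
    tot <- sum(b5[cbind(t_idx[s:(s + L - 1L)], q)])
    r <- 100 * tot / mb
    if (r >= threshold - 1e-9) {
      starts <- c(starts, s)
      ratios <- c(ratios, r)
    }
  }
  data.frame(start = starts, ratio = ratios)
}

# O(n^2) transitive closure of interval overlap
oracle_clusters <- function(starts, lengths) {
  n <- length(starts)
  ends <- starts + lengths - 1L
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          starts[i] <= ends[j] && starts[j] <= ends[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp[order(starts)]))
}

# exhaustive global alignment score for tiny strings (all alignments)
oracle_global_score <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i > nchar(a) && j > nchar(b)) return(0)
    best <- -Inf
    if (i <= nchar(a) && j <= nchar(b)) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L))
    }
    if (i <= nchar(a)) best <- max(best, gap + rec(i + 1L, j))
    if (j <= nchar(b)) best <- max(best, gap + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}

make_transcript <- function(sequence, utr5_end = 0L, cds_end = 0L,
                            rpkm = 1, id = "tx1", gene = "G1") {
  data.frame(transcript_id = id, gene = gene, sequence = sequence,
             utr5_end = as.integer(utr5_end), cds_end = as.integer(cds_end),
             rpkm = rpkm, stringsAsFactors = FALSE)
}

make_mirna <- function(sequence, id = "miR-x") {
  data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE)
}
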