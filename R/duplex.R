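# Hydrogen-bond duplex scoring model.
#
# Bond counts per unordered mRNA/miRNA base pair: G-C 3, A-U 2, G-U 1, A-C 1,
# everything else (including any pair with N) 0. dG = -e_hb * total bonds;
# dGm is dG of the miRNA against its perfect Watson-Crick complement, so the
# quality ratio dG/dGm = total_bonds / max_bonds is independent of e_hb.

.RNA_BASES <- c("A", "C", "G", "U", "N")

.BOND <- local({
  m <- matrix(0L, 5L, 5L, dimnames = list(.RNA_BASES, .RNA_BASES))
  m["G", "C"] <- m["C", "G"] <- 3L
  m["A", "U"] <- m["U", "A"] <- 2L
  m["G", "U"] <- m["U", "G"] <- 1L
  m["A", "C"] <- m["C", "A"] <- 1L
  m
})

# byte -> base index (1..5), NA for anything else
.ENC <- local({
  e <- rep(NA_integer_, 256L)
  e[utf8ToInt("A")] <- 1L
  e[utf8ToInt("C")] <- 2L
  e[utf8ToInt("G")] <- 3L
  e[utf8ToInt("U")] <- 4L
  e[utf8ToInt("N")] <- 5L
  e
})

stop_mirbind <- function(msg, class) {
  stop(structure(
    class = c(class, "mirbind_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Encode a normalized RNA string as base indices
#'
#' Internal workhorse: maps A,C,G,U,N to 1..5 and fails on anything else.
#' @noRd
encode_rna <- function(sequence, what = "sequence") {
  idx <- .ENC[utf8ToInt(sequence)]
  if (anyNA(idx)) {
    bad <- unique(strsplit(sequence, "")[[1]][is.na(idx)])
    stop_mirbind(
      sprintf("invalid character(s) %s in %s (alphabet is A,C,G,U,N)",
              paste(sQuote(bad), collapse = ", "), what),
      "mirbind_alphabet_error"
    )
  }
  idx
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Upper-cases and converts T to U, so DNA- and RNA-alphabet records are
#' interchangeable on input. Characters outside A,C,G,U,N raise an alphabet
#' error naming `what`.
#'
#' @param sequence character string.
#' @param what label used in error messages.
#' @return normalized character string over A,C,G,U,N.
#' @export
normalize_rna <- function(sequence, what = "sequence") {
  s <- chartr("t", "u", toupper(sequence))
  s <- chartr("T", "U", s)
  encode_rna(s, what = what)
  s
}

#' Reverse complement of an RNA string
#'
#' @param sequence RNA string over A,C,G,U,N (N complements to N).
#' @return reverse complement, 5'->3'.
#' @export
revcomp_rna <- function(sequence) {
  s <- chartr("ACGUN", "UGCAN", sequence)
  paste(rev(strsplit(s, "")[[1]]), collapse = "")
}

#' Hydrogen bonds formed by one mRNA/miRNA base pair
#'
#' G-C pairs form 3 bonds, A-U 2, and the non-canonical G-U (wobble) and A-C
#' pairs 1 each; all other pairings (including any pair with N) form none.
#' Symmetric in its arguments and vectorized.
#'
#' @param mrna_base,mirna_base single bases (vectors recycle) in A,C,G,U,N.
#' @return integer vector of bond counts in 0..3.
#' @export
pair_bonds <- function(mrna_base, mirna_base) {
  i <- .ENC[utf8ToInt(paste(mrna_base, collapse = ""))]
  j <- .ENC[utf8ToInt(paste(mirna_base, collapse = ""))]
  if (anyNA(i) || anyNA(j)) {
    stop_mirbind("bases must be one of A, C, G, U, N",
                 "mirbind_alphabet_error")
  }
  unname(.BOND[cbind(i, j)])
}

#' Maximum hydrogen bonds of a miRNA (its dGm in bond units)
#'
#' The bond total of the miRNA paired with its perfect Watson-Crick
#' complement: G and C contribute 3 bonds each, A and U contribute 2.
#' A miRNA containing N has no defined perfect duplex and is rejected.
#'
#' @param mirna miRNA sequence (RNA string).
#' @return integer bond total.
#' @export
max_bonds <- function(mirna) {
  idx <- encode_rna(mirna, what = "miRNA")
  if (any(idx == 5L)) {
    stop_mirbind("miRNA contains N: dGm is undefined for ambiguous queries",
                 "mirbind_validation_error")
  }
  sum(ifelse(idx == 2L | idx == 3L, 3L, 2L))
}

#' Energy model for duplex free energy
#'
#' dG is modeled as proportional to the hydrogen-bond total:
#' dG = -e_hb * bonds (kJ/mol). The default e_hb = 2.1 kJ/mol per bond
#' reproduces the magnitude of typical reported site energies (a GC-rich
#' ~22-mer has dGm near -130 kJ/mol). The inter-base distances are carried
#' as documented metadata only; no geometry is computed from them.
#'
#' @param e_hb free energy per hydrogen bond, kJ/mol (positive).
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(e_hb = 2.1) {
  if (!is.numeric(e_hb) || length(e_hb) != 1L || !is.finite(e_hb) || e_hb <= 0) {
    stop_mirbind("e_hb must be a single positive number", "mirbind_config_error")
  }
  structure(
    list(
      e_hb = e_hb,
      inter_base_distance_nm = c("A-C" = 1.04, "G-C" = 1.03,
                                 "A-U" = 1.03, "G-U" = 1.02)
    ),
    class = "energy_model"
  )
}

#' Score one miRNA/mRNA window as a gapless antiparallel duplex
#'
#' Pairs mRNA window position k (5'->3') with miRNA position L+1-k
#' (antiparallel), counts hydrogen bonds per position, and derives
#' dG = -e_hb * total and the quality ratio 100 * total / max_bonds(miRNA).
#' No gaps or bulges are ever introduced: the model is a strict
#' position-by-position helix.
#'
#' @param mirna miRNA sequence (no N allowed).
#' @param window mRNA window, same length as `mirna`; N scores 0 bonds.
#' @param model an [energy_model()].
#' @param mirna_id optional identifier carried into the result.
#' @return object of class `duplex_scheme` with fields `mirna_id`, `mirna`,
#'   `window`, `per_position_bonds`, `total_bonds`, `max_bonds`, `delta_g`,
#'   `ratio`.
#' @export
score_window <- function(mirna, window, model = energy_model(),
                         mirna_id = NULL) {
  if (nchar(mirna) != nchar(window)) {
    stop_mirbind(
      sprintf("window length (%d) must equal miRNA length (%d)",
              nchar(window), nchar(mirna)),
      "mirbind_contract_error"
    )
  }
  mb <- max_bonds(mirna)
  q <- rev(encode_rna(mirna, "miRNA"))
  w <- encode_rna(window, "window")
  bonds <- unname(.BOND[cbind(w, q)])
  total <- sum(bonds)
  structure(
    list(
      mirna_id = mirna_id,
      mirna = mirna,
      window = window,
      per_position_bonds = bonds,
      total_bonds = total,
      max_bonds = mb,
      delta_g = -model$e_hb * total,
      ratio = 100 * total / mb
    ),
    class = "duplex_scheme"
  )
}

#' Render a duplex scheme as a three-line text diagram
#'
#' Top line: mRNA window 5'->3'; middle line: one pairing glyph per position
#' ("|" 3 bonds, ":" 2, "." 1, space 0); bottom line: miRNA 3'->5'.
#'
#' @param scheme a `duplex_scheme` from [score_window()].
#' @return character vector of three fixed-width lines.
#' @export
render_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "duplex_scheme"))
  glyphs <- c(" ", ".", ":", "|")[scheme$per_position_bonds + 1L]
  mirna_rev <- paste(rev(strsplit(scheme$mirna, "")[[1]]), collapse = "")
  c(
    paste0("5'-", scheme$window, "-3' mRNA"),
    paste0("   ", paste(glyphs, collapse = "")),
    paste0("3'-", mirna_rev, "-5' miRNA")
  )
}

#' @export
print.duplex_scheme <- function(x, ...) {
  cat(render_scheme(x), sep = "\n")
  cat(sprintf("bonds %d/%d  dG %.1f kJ/mol  dG/dGm %.1f%%\n",
              x$total_bonds, x$max_bonds, x$delta_g, x$ratio))
  invisible(x)
}

#' Bond totals of every window of a transcript against one miRNA
#'
#' Vectorized sliding scan: position i of the result is the gapless
#' antiparallel bond total of the window starting at i (1-based).
#'
#' @param mirna miRNA sequence (no N).
#' @param transcript_seq transcript sequence (may contain N).
#' @return integer vector of length `nchar(transcript_seq) - nchar(mirna) + 1`.
#' @export
scan_bonds <- function(mirna, transcript_seq) {
  L <- nchar(mirna)
  N <- nchar(transcript_seq)
  if (N < L) {
    stop_mirbind(
      sprintf("transcript (%d nt) is shorter than miRNA (%d nt)", N, L),
      "mirbind_scan_error"
    )
  }
  q <- rev(encode_rna(mirna, "miRNA"))
  m <- encode_rna(transcript_seq, "transcript")
  n_win <- N - L + 1L
  tot <- integer(n_win)
  flat <- as.integer(.BOND)  # column-major 5x5
  for (k in seq_len(L)) {
    tot <- tot + flat[m[k:(k + n_win - 1L)] + 5L * (q[k] - 1L)]
  }
  tot
}
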