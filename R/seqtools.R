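# Pairwise sequence statistics and CRAC motif scanning.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X")

#' BLOSUM62 substitution matrix
#'
#' Fetched once from Biostrings and cached for the session.
#' @return integer matrix with amino-acid row/column names.
#' @export
blosum62 <- function() {
  if (is.null(.sitedock_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .sitedock_env$blosum62 <- e$BLOSUM62
  }
  .sitedock_env$blosum62
}

check_protein <- function(seq, what, alphabet) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    sd_stop(what, " must be a non-empty string")
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad))
    sd_stop(what, ": illegal character '", chars[bad[1]], "' at position ", bad[1])
  chars
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman–Wunsch/Gotoh global alignment; a gap of length L costs
#' `gap_open + gap_extend * (L - 1)` and end gaps are penalized.  Traceback
#' ties are broken deterministically: diagonal, then up (gap in `seq_b`),
#' then left (gap in `seq_a`).  Defaults are the classic ClustalW protein
#' settings (BLOSUM62, open 10, extend 0.5).
#'
#' @param seq_a,seq_b amino-acid strings (standard alphabet plus B/Z/X).
#' @param substitution substitution matrix; default [blosum62()].
#' @param gap_open,gap_extend gap penalties (positive numbers).
#' @return an `AlignmentResult`: `aligned_a`, `aligned_b` (gapped strings of
#'   equal length), `score`, `identity_pct`, `similarity_pct`.
#' @export
align_global <- function(seq_a, seq_b, substitution = blosum62(),
                         gap_open = 10, gap_extend = 0.5) {
  alpha <- rownames(substitution)
  ca <- check_protein(toupper(seq_a), "seq_a", alpha)
  cb <- check_protein(toupper(seq_b), "seq_b", alpha)
  ia <- match(ca, alpha) - 1L
  ib <- match(cb, alpha) - 1L
  res <- .gotoh_align(ia, ib, substitution, gap_open, gap_extend)
  ga <- ifelse(res$a_idx == 0L, "-", ca[pmax(res$a_idx, 1L)])
  gb <- ifelse(res$b_idx == 0L, "-", cb[pmax(res$b_idx, 1L)])
  out <- structure(list(
    aligned_a = paste(ga, collapse = ""),
    aligned_b = paste(gb, collapse = ""),
    score = res$score,
    identity_pct = NA_real_, similarity_pct = NA_real_,
    substitution = substitution
  ), class = "AlignmentResult")
  stats <- identity_similarity(out, substitution)
  out$identity_pct <- stats[["identity_pct"]]
  out$similarity_pct <- stats[["similarity_pct"]]
  out
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("<AlignmentResult: length %d, score %.1f, identity %.1f%%, similarity %.1f%%>\n",
              nchar(x$aligned_a), x$score, x$identity_pct, x$similarity_pct))
  invisible(x)
}

#' Percent identity and similarity of a pairwise alignment
#'
#' Identity is the fraction of identical residue pairs among columns where
#' both sequences carry a residue (gap-free columns); similarity additionally
#' counts pairs with a positive substitution score.  Both are returned as
#' percentages.
#'
#' @param alignment an `AlignmentResult`, or a list with `aligned_a` and
#'   `aligned_b` gapped strings of equal length.
#' @param substitution substitution matrix; default [blosum62()].
#' @return named numeric vector `c(identity_pct=, similarity_pct=)`.
#' @export
identity_similarity <- function(alignment, substitution = blosum62()) {
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  if (length(a) != length(b)) sd_stop("gapped strings differ in length")
  both <- a != "-" & b != "-"
  n <- sum(both)
  if (n == 0L) sd_stop("alignment has no gap-free columns; identity undefined")
  ident <- sum(a[both] == b[both])
  scores <- substitution[cbind(match(a[both], rownames(substitution)),
                               match(b[both], colnames(substitution)))]
  simil <- sum(scores > 0)
  c(identity_pct = 100 * ident / n, similarity_pct = 100 * simil / n)
}

#' Scan a protein sequence for CRAC cholesterol-recognition motifs
#'
#' The CRAC consensus, read N- to C-terminal, is
#' `(L/V) - X(1..5) - Y - X(1..5) - (R/K)`.  Overlapping matches are allowed;
#' one hit is reported per distinct central tyrosine, taking the shortest
#' match (the nearest flanking L/V and R/K) for that tyrosine.
#'
#' @param sequence amino-acid string.
#' @return data frame with columns `start`, `end`, `tyrosine_pos`
#'   (1-based inclusive positions) and `pattern_id`; zero rows when no match.
#' @export
scan_crac <- function(sequence) {
  chars <- check_protein(toupper(sequence), "sequence", AA_ALPHABET)
  n <- length(chars)
  hits <- list()
  for (i in which(chars == "Y")) {
    if (i - 2L < 1L || i + 2L > n) next
    up <- seq.int(max(1L, i - 6L), i - 2L)
    up <- up[chars[up] %in% c("L", "V")]
    down <- seq.int(i + 2L, min(n, i + 6L))
    down <- down[chars[down] %in% c("R", "K")]
    if (!length(up) || !length(down)) next
    hits[[length(hits) + 1L]] <- data.frame(
      start = max(up), end = min(down), tyrosine_pos = i,
      pattern_id = "CRAC", stringsAsFactors = FALSE
    )
  }
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      tyrosine_pos = integer(0), pattern_id = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' One-row TSV-ready summary of a pairwise alignment
#'
#' @param id_a,id_b sequence identifiers.
#' @param alignment an `AlignmentResult`.
#' @return one-row data frame (ids, score, identity, similarity).
#' @export
alignment_report_row <- function(id_a, id_b, alignment) {
  data.frame(id_a = id_a, id_b = id_b, score = alignment$score,
             identity_pct = alignment$identity_pct,
             similarity_pct = alignment$similarity_pct,
             stringsAsFactors = FALSE)
}
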