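# Independent brute-force oracles and small fixture builders.  Oracles are
# deliberately written as plain loops / direct formulas, not by calling the
# code paths they check.

# --- alignment ---------------------------------------------------------------

# Exhaustively enumerate every global alignment of a and b (move sequences of
# diagonal / up / left), score each with the package's affine convention
# (a gap run of length L costs open + extend * (L - 1)), return the maximum.
bf_align_score <- function(a, b, sub, open, extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, gapstate) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1L, j + 1L, score + sub[ca[i], cb[j]], 0L)
    if (i <= length(ca))   # gap in b
      rec(i + 1L, j, score - if (gapstate == 1L) extend else open, 1L)
    if (j <= length(cb))   # gap in a
      rec(i, j + 1L, score - if (gapstate == 2L) extend else open, 2L)
  }
  rec(1L, 1L, 0, 0L)
  best
}

# Column-by-column identity/similarity hand count.
bf_identity_similarity <- function(ga, gb, sub) {
  a <- strsplit(ga, "")[[1]]; b <- strsplit(gb, "")[[1]]
  n_both <- 0L; n_id <- 0L; n_sim <- 0L
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") next
    n_both <- n_both + 1L
    if (a[k] == b[k]) n_id <- n_id + 1L
    if (sub[a[k], b[k]] > 0) n_sim <- n_sim + 1L
  }
  c(identity_pct = 100 * n_id / n_both, similarity_pct = 100 * n_sim / n_both)
}

random_protein <- function(n, alphabet = rownames(blosum62())[1:20]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- contacts ----------------------------------------------------------------

# All-pairs distance scan: a residue is a contact iff any of its heavy atoms
# is within cutoff of any ligand atom.
bf_contacts <- function(lig, receptor, cutoff, frame = 1L) {
  a <- receptor$atoms
  xyz <- receptor$coords[[frame]]
  hits <- character(0)
  for (i in seq_len(nrow(a))) {
    if (!a$is_heavy[i]) next
    for (k in seq_len(nrow(lig))) {
      d <- sqrt(sum((xyz[i, ] - lig[k, ])^2))
      if (d <= cutoff) {
        hits <- c(hits, paste(a$chain[i], a$resname[i], a$resid[i]))
        break
      }
    }
  }
  sort(unique(hits))
}

# Direct restatement of the assignment rule from per-site counts.
bf_label <- function(counts) {
  if (all(counts == 0L)) return("unassigned")
  top <- sort(names(counts)[counts == max(counts)])
  if (length(top) == 1L) return(top)
  if (length(top) == 2L) {
    key <- paste(top, collapse = "+")
    overlap <- c("S1+S2" = "S1-2", "S2+S3" = "S2-3", "S1+S3" = "S1-3")
    if (key %in% names(overlap)) return(unname(overlap[key]))
  }
  "unassigned"
}

# --- misc --------------------------------------------------------------------

bf_block_average <- function(v, w) {
  out <- numeric(0)
  i <- 1L
  while (i <= length(v)) {
    j <- min(i + w - 1L, length(v))
    out <- c(out, sum(v[i:j]) / (j - i + 1L))
    i <- j + 1L
  }
  out
}

# Two-CA structure whose frame-t distance is exactly script[t].
scripted_distance_structure <- function(script) {
  atoms <- data.frame(
    serial = 1:2, name = "CA", element = "C", resname = "ALA",
    chain = "A", resid = 1:2, icode = " ", is_heavy = TRUE,
    stringsAsFactors = FALSE
  )
  coords <- lapply(script, function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
  sitedock:::new_structure("scripted", atoms, coords)
}

# Tiny peptide with explicit side-chain atoms, for truncation tests.
peptide_with_sidechains <- function() {
  res <- list(
    list(resname = "ARG", side = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2")),
    list(resname = "ALA", side = "CB"),
    list(resname = "GLY", side = character(0)),
    list(resname = "PRO", side = c("CB", "CG", "CD")),
    list(resname = "LEU", side = c("CB", "CG", "CD1", "CD2"))
  )
  rows <- list(); coords <- list()
  serial <- 0L
  for (i in seq_along(res)) {
    names_i <- c("N", "CA", "C", "O", res[[i]]$side)
    for (nm in names_i) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = nm,
        element = substr(gsub("[0-9]", "", nm), 1, 1),
        resname = res[[i]]$resname, chain = "A", resid = i, icode = " ",
        is_heavy = TRUE, stringsAsFactors = FALSE
      )
      coords[[serial]] <- c(i * 4, serial %% 3, (serial %% 5) / 2)
    }
  }
  sitedock:::new_structure("peptide", do.call(rbind, rows),
                           list(do.call(rbind, coords)))
}
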