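# Structure / pose / sequence I/O.
#
# The coordinate model is deliberately simple: a Structure holds one atom
# table (identity columns, constant across frames) plus a list of n_atoms x 3
# coordinate matrices, one per model/frame.  Multi-model PDB files double as
# a lightweight trajectory dialect.

TWO_LETTER_ELEMENTS <- c(
  "FE", "MG", "ZN", "CL", "BR", "NA", "MN", "CU", "SE", "CO", "NI", "CD"
)

#' Infer the chemical element from a PDB atom-name field
#'
#' PDBQT writers often leave the element column blank; the element is then
#' derived from the atom-name field per PDB convention: a leading digit marks
#' a hydrogen variant ("1HB1"), a name filling column 13 may carry a
#' two-letter element ("FE"), otherwise the first letter after stripping
#' digits is the element.
#'
#' @param name atom name as printed (up to 4 characters, possibly padded).
#' @param col13_filled logical; `TRUE` when the raw record had a non-blank
#'   character in column 13 (four-character name field).
#' @return single-character element symbol, upper case.
#' @keywords internal
infer_element <- function(name, col13_filled = FALSE) {
  raw <- toupper(trimws(name))
  if (!nzchar(raw)) sd_format_error("cannot infer element from empty atom name")
  if (grepl("^[0-9]", raw)) return("H")
  if (col13_filled && nchar(raw) >= 2 &&
      substr(raw, 1, 2) %in% TWO_LETTER_ELEMENTS) {
    return(substr(raw, 1, 2))
  }
  stripped <- gsub("[^A-Z]", "", raw)
  if (!nzchar(stripped)) sd_format_error("cannot infer element from atom name '", name, "'")
  substr(stripped, 1, 1)
}

new_structure <- function(id, atoms, coords) {
  stopifnot(is.data.frame(atoms), is.list(coords), length(coords) >= 1L)
  n <- nrow(atoms)
  for (i in seq_along(coords)) {
    m <- coords[[i]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3L)
      sd_format_error("model ", i, ": coordinate block does not match atom table")
    if (!all(is.finite(m)))
      sd_format_error("model ", i, ": non-finite coordinates")
  }
  structure(list(id = id, atoms = atoms, coords = coords), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("<Structure '%s': %d atoms, %d model(s)>\n",
              x$id, nrow(x$atoms), length(x$coords)))
  invisible(x)
}

#' Number of frames (models) in a Structure
#' @param structure a `Structure`.
#' @export
n_frames <- function(structure) length(structure$coords)

#' Number of atoms in a Structure
#' @param structure a `Structure`.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

parse_atom_lines <- function(lines, source = "input") {
  # fixed PDB columns; PDBQT shares them
  rec <- substr(lines, 1, 6)
  serial <- suppressWarnings(as.integer(substr(lines, 7, 11)))
  name_raw <- substr(lines, 13, 16)
  altloc <- substr(lines, 17, 17)
  resname <- trimws(substr(lines, 18, 21))
  chain <- substr(lines, 22, 22)
  resid <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  icode <- substr(lines, 27, 27)
  x <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  occ <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  elem <- toupper(trimws(substr(lines, 77, 78)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(resid))
  if (length(bad))
    sd_format_error(source, ": malformed ATOM/HETATM record: '", lines[bad[1]], "'")
  col13 <- substr(lines, 13, 13) != " "
  name <- trimws(name_raw)
  for (i in which(!nzchar(elem))) elem[i] <- infer_element(name[i], col13[i])
  data.frame(
    record = trimws(rec), serial = serial, name = name, altloc = altloc,
    element = elem, resname = resname, chain = chain, resid = resid,
    icode = icode, x = x, y = y, z = z, occ = occ,
    stringsAsFactors = FALSE
  )
}

# Alternate locations: keep the highest-occupancy conformer per
# (chain, resid, icode, name); ties resolved in file order.
drop_altlocs <- function(df) {
  if (all(df$altloc %in% c(" ", ""))) return(df)
  key <- paste(df$chain, df$resid, df$icode, df$name, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(idx) {
    idx[which.max(df$occ[idx])]
  }), use.names = FALSE)
  df[sort(keep), , drop = FALSE]
}

finalize_atoms <- function(df) {
  atoms <- df[, c("serial", "name", "element", "resname", "chain", "resid", "icode")]
  atoms$is_heavy <- atoms$element != "H"
  rownames(atoms) <- NULL
  atoms
}

#' Read a (possibly multi-model) PDB file
#'
#' MODEL/ENDMDL blocks map to frames; files without MODEL records yield a
#' single frame.  Alternate locations keep the highest-occupancy conformer
#' (ties: first in file).  Hydrogens are read but flagged `is_heavy = FALSE`
#' and excluded from all downstream distance/contact computations.
#'
#' @param path file path.
#' @param model_policy `"all"` (every model becomes a frame; atom tables must
#'   agree across models) or `"first"` (first model only).
#' @param id structure id; defaults to the file name without extension.
#' @return a `Structure`.
#' @export
read_pdb <- function(path, model_policy = c("all", "first"), id = NULL) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) sd_stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))

  model_starts <- grep("^MODEL", lines)
  blocks <- if (length(model_starts) == 0L) {
    list(grep("^(ATOM  |HETATM)", lines, value = TRUE))
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(model_starts)) ends <- c(ends, length(lines) + 1L)
    lapply(seq_along(model_starts), function(i) {
      seg <- lines[(model_starts[i] + 1L):(ends[i] - 1L)]
      grep("^(ATOM  |HETATM)", seg, value = TRUE)
    })
  }
  blocks <- Filter(length, blocks)
  if (length(blocks) == 0L) sd_format_error(path, ": no ATOM/HETATM records")
  if (model_policy == "first") blocks <- blocks[1]

  parsed <- lapply(blocks, function(b) drop_altlocs(parse_atom_lines(b, path)))
  ref <- parsed[[1]]
  key0 <- paste(ref$chain, ref$resid, ref$icode, ref$name)
  if (anyDuplicated(key0))
    sd_format_error(path, ": duplicate (chain, resid, name) within a model: ",
                    key0[duplicated(key0)][1])
  coords <- vector("list", length(parsed))
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    if (nrow(p) != nrow(ref) || any(paste(p$chain, p$resid, p$icode, p$name) != key0))
      sd_format_error(path, ": model ", i,
                      " has a different atom count or ordering than model 1")
    coords[[i]] <- unname(cbind(p$x, p$y, p$z))
  }
  new_structure(id, finalize_atoms(ref), coords)
}

format_atom_line <- function(serial, name, resname, chain, resid, icode,
                             xyz, element, record = "ATOM") {
  # standard alignment: 1-3 character names start in column 14
  name_field <- if (nchar(name) >= 4L) substr(name, 1, 4) else paste0(" ", name)
  sprintf("%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_field, resname, chain, resid,
          ifelse(nzchar(trimws(icode)), icode, " "),
          xyz[1], xyz[2], xyz[3], 1, 0, element)
}

#' Write a Structure as a (multi-model) PDB file
#'
#' Fixed-width records; output is byte-identical across runs for identical
#' input.  Single-frame structures are written without MODEL/ENDMDL.
#'
#' @param structure a `Structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "Structure"))
  a <- structure$atoms
  out <- character(0)
  multi <- n_frames(structure) > 1L
  for (f in seq_len(n_frames(structure))) {
    xyz <- structure$coords[[f]]
    body <- vapply(seq_len(nrow(a)), function(i) {
      format_atom_line(a$serial[i], a$name[i], a$resname[i], a$chain[i],
                       a$resid[i], a$icode[i], xyz[i, ], a$element[i])
    }, character(1))
    out <- c(out, if (multi) sprintf("MODEL %8d", f), body,
             if (multi) "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Read docked poses from an AutoDock Vina PDBQT output file
#'
#' One `Pose` per MODEL block; the predicted affinity (kcal/mol) is the first
#' numeric field of the block's `REMARK VINA RESULT` line.  Only heavy atoms
#' are retained, since all downstream contact analysis is heavy-atom only.
#'
#' @param path PDBQT file with MODEL blocks and REMARK VINA RESULT lines.
#' @param ligand_id ligand identifier.
#' @param category `"substrate"`, `"non-substrate"` or `"unknown"`.
#' @param receptor_conformation_id id of the receptor conformation the poses
#'   were docked against.
#' @return a `PoseSet`.
#' @export
read_pdbqt_poses <- function(path, ligand_id,
                             category = c("unknown", "substrate", "non-substrate"),
                             receptor_conformation_id = "conf1") {
  category <- match.arg(category)
  if (!file.exists(path)) sd_stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) sd_format_error(path, ": no MODEL records")
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines) + 1L)

  poses <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    seg <- lines[starts[i]:(ends[i] - 1L)]
    res_line <- grep("^REMARK VINA RESULT", seg, value = TRUE)
    if (length(res_line) == 0L)
      sd_format_error(path, ": MODEL ", i, " has no REMARK VINA RESULT line")
    fields <- strsplit(sub("^REMARK VINA RESULT:?", "", res_line[1]), "\\s+")[[1]]
    fields <- fields[nzchar(fields)]
    affinity <- suppressWarnings(as.numeric(fields[1]))
    if (!is.finite(affinity))
      sd_format_error(path, ": MODEL ", i, ": cannot parse affinity from '",
                      res_line[1], "'")
    atoms <- parse_atom_lines(grep("^(ATOM  |HETATM)", seg, value = TRUE), path)
    heavy <- atoms[atoms$element != "H", , drop = FALSE]
    if (nrow(heavy) == 0L)
      sd_format_error(path, ": MODEL ", i, " contains no heavy atoms")
    model_index <- suppressWarnings(as.integer(trimws(sub("^MODEL", "", lines[starts[i]]))))
    poses[[i]] <- new_pose(
      model_index = if (is.na(model_index)) i else model_index,
      coords = unname(cbind(heavy$x, heavy$y, heavy$z)),
      affinity = affinity, rank = i
    )
  }
  new_pose_set(ligand_id, category, poses, receptor_conformation_id)
}

new_pose <- function(model_index, coords, affinity, rank) {
  if (rank < 1L) sd_stop("pose rank must be >= 1")
  if (!all(is.finite(coords))) sd_stop("pose coordinates must be finite")
  structure(list(model_index = model_index, coords = coords,
                 affinity = affinity, rank = rank), class = "Pose")
}

new_pose_set <- function(ligand_id, category, poses, receptor_conformation_id) {
  ranks <- vapply(poses, `[[`, integer(1), "rank")
  if (!identical(ranks, seq_along(poses)))
    sd_stop("pose ranks must be consecutive from 1")
  aff <- vapply(poses, `[[`, numeric(1), "affinity")
  if (is.unsorted(aff))
    warning("affinities are not non-decreasing with rank for ligand '",
            ligand_id, "'", call. = FALSE)
  structure(list(ligand_id = ligand_id, category = category, poses = poses,
                 receptor_conformation_id = receptor_conformation_id),
            class = "PoseSet")
}

#' @export
print.PoseSet <- function(x, ...) {
  cat(sprintf("<PoseSet '%s' (%s): %d poses vs %s>\n", x$ligand_id,
              x$category, length(x$poses), x$receptor_conformation_id))
  invisible(x)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of upper-cased sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) sd_stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) sd_format_error(path, ": empty file")
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) sd_format_error(path, ": no FASTA headers")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1), 1)
  bounds <- c(hdr, length(lines) + 1L)
  seqs <- vapply(seq_along(hdr), function(i) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (bounds[i] + 1L > bounds[i + 1L] - 1L) ""
    else toupper(gsub("\\s", "", paste(block, collapse = "")))
  }, character(1))
  if (any(!nzchar(seqs)))
    sd_format_error(path, ": record '", ids[which(!nzchar(seqs))[1]],
                    "' has an empty sequence")
  setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  out <- unlist(lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    c(paste0(">", names(seqs)[i]),
      substring(s, seq(1, nchar(s), width), pmin(seq(1, nchar(s), width) + width - 1L, nchar(s))))
  }))
  writeLines(out, path)
  invisible(path)
}
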