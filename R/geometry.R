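# Superposition, RMSD and distance series, smoothing, membrane-depth
# annotation, and simple side-chain truncation.

#' Select atom indices in a Structure
#'
#' @param structure a `Structure`.
#' @param chain,resid,name optional filters (vectors allowed).
#' @param heavy_only drop hydrogens (default TRUE).
#' @return integer vector of row indices into `structure$atoms`.
#' @export
select_atoms <- function(structure, chain = NULL, resid = NULL, name = NULL,
                         heavy_only = TRUE) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (heavy_only) keep <- keep & a$is_heavy
  which(keep)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `ref` via SVD of the
#' cross-covariance matrix; the returned rotation is proper
#' (determinant +1).  The transform maps a coordinate row `p` to
#' `p %*% rotation + translation`.
#'
#' @param mobile,ref n x 3 coordinate matrices, equal n >= 3.
#' @return list with `rotation` (3x3), `translation` (length-3), and `rmsd`
#'   (Angstrom, after transformation).
#' @export
kabsch_superpose <- function(mobile, ref) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  if (nrow(mobile) != nrow(ref) || ncol(mobile) != 3L || ncol(ref) != 3L)
    sd_stop("mobile and ref must be n x 3 matrices with equal n")
  if (nrow(mobile) < 3L) sd_stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(ref)
  pm <- sweep(mobile, 2, cm); pr <- sweep(ref, 2, cr)
  s <- svd(crossprod(pm, pr))           # t(pm) %*% pr = U D V'
  d <- sign(det(s$u) * det(s$v))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- cr - drop(cm %*% rot)
  moved <- mobile %*% rot
  moved <- sweep(moved, 2, trans, `+`)
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums((moved - ref)^2))))
}

#' Per-frame RMSD of a trajectory against a reference frame
#'
#' Each frame's selection is superposed (Kabsch) onto the reference frame's
#' selection before the deviation is measured; the same selection is used
#' for fitting and measurement.
#'
#' @param structure multi-frame `Structure`.
#' @param ref_frame_index 1-based reference frame (default 1).
#' @param selection integer atom indices (e.g. from [select_atoms()]).
#' @return numeric vector, one RMSD (Angstrom) per frame; exactly 0 at the
#'   reference index.
#' @export
rmsd_series <- function(structure, ref_frame_index = 1L, selection) {
  stopifnot(inherits(structure, "Structure"))
  if (length(selection) == 0L) sd_stop("empty selection")
  nf <- n_frames(structure)
  if (ref_frame_index < 1L || ref_frame_index > nf)
    sd_stop("ref_frame_index out of range")
  ref <- structure$coords[[ref_frame_index]][selection, , drop = FALSE]
  out <- vapply(seq_len(nf), function(f) {
    if (f == ref_frame_index) return(0)
    kabsch_superpose(structure$coords[[f]][selection, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  out
}

new_distance_series <- function(pair, values, replicate_id = "rep1") {
  if (any(!is.finite(values)) || any(values < 0))
    sd_stop("distance values must be finite and non-negative")
  structure(list(pair = pair, values = as.numeric(values),
                 replicate_id = replicate_id), class = "DistanceSeries")
}

#' @export
print.DistanceSeries <- function(x, ...) {
  cat(sprintf("<DistanceSeries %s: %d frames, mean %.2f A (%s)>\n",
              paste(vapply(x$pair, function(p) paste0(p$chain, p$resid), ""),
                    collapse = " - "),
              length(x$values), mean(x$values), x$replicate_id))
  invisible(x)
}

#' C-alpha to C-alpha distance per frame
#'
#' @param structure a `Structure` (possibly multi-frame).
#' @param pair list of two residue selectors, each `list(chain=, resid=)`.
#' @param replicate_id label stored on the series.
#' @return a `DistanceSeries` (Angstrom per frame).
#' @export
ca_distance_series <- function(structure, pair, replicate_id = "rep1") {
  stopifnot(inherits(structure, "Structure"), length(pair) == 2L)
  idx <- vapply(pair, function(p) {
    i <- select_atoms(structure, chain = p$chain, resid = p$resid, name = "CA")
    if (length(i) != 1L)
      sd_stop("residue ", p$chain, p$resid,
              if (length(i)) " has multiple CA atoms" else " has no CA atom")
    i
  }, integer(1))
  vals <- vapply(structure$coords, function(xyz) {
    sqrt(sum((xyz[idx[1], ] - xyz[idx[2], ])^2))
  }, numeric(1))
  new_distance_series(pair, vals, replicate_id)
}

#' Block-average smoothing
#'
#' Consecutive non-overlapping blocks of `window` values are replaced by
#' their mean; a final partial block is averaged over its actual length, so
#' the output has `ceiling(n / window)` values.
#'
#' @param values numeric vector.
#' @param window block size (>= 1; default 10).
#' @return numeric vector of block means; empty input gives empty output.
#' @export
block_average <- function(values, window = 10L) {
  if (window < 1L) sd_stop("window must be >= 1")
  n <- length(values)
  if (n == 0L) return(numeric(0))
  grp <- (seq_len(n) - 1L) %/% window
  as.numeric(tapply(values, grp, mean))
}

#' Membrane slab definition
#'
#' The hydrophobic core lies between the two boundary planes `z_lower` and
#' `z_upper` (membrane normal along z, as in OPM-oriented structures);
#' `headgroup_width` is the thickness of the polar headgroup layer outside
#' each plane.
#'
#' @param z_lower,z_upper core boundary planes (Angstrom), `z_lower < z_upper`.
#' @param headgroup_width headgroup layer thickness (Angstrom, > 0);
#'   default 8, a typical phosphocholine headgroup extent.
#' @return a `MembraneSlab`.
#' @export
membrane_slab <- function(z_lower = -15, z_upper = 15, headgroup_width = 8) {
  if (!(z_lower < z_upper)) sd_stop("z_lower must be < z_upper")
  if (!(headgroup_width > 0)) sd_stop("headgroup_width must be > 0")
  structure(list(z_lower = z_lower, z_upper = z_upper,
                 headgroup_width = headgroup_width), class = "MembraneSlab")
}

#' Annotate residues by membrane depth
#'
#' Each residue is labelled from its C-alpha z coordinate:
#' `hydrophobic_core` inside `[z_lower, z_upper]`, `headgroup` within
#' `headgroup_width` outside either plane, `aqueous` otherwise.
#'
#' @param structure single-frame `Structure` (or `frame` selects one).
#' @param slab a [membrane_slab()].
#' @param frame frame index (default 1).
#' @return data frame: `chain`, `resid`, `resname`, `z`, `region`.
#' @export
annotate_depth <- function(structure, slab, frame = 1L) {
  stopifnot(inherits(structure, "Structure"), inherits(slab, "MembraneSlab"))
  ca <- select_atoms(structure, name = "CA")
  if (length(ca) == 0L) sd_stop("structure has no CA atoms")
  a <- structure$atoms[ca, ]
  z <- structure$coords[[frame]][ca, 3]
  region <- ifelse(
    z >= slab$z_lower & z <= slab$z_upper, "hydrophobic_core",
    ifelse((z >= slab$z_lower - slab$headgroup_width & z < slab$z_lower) |
             (z > slab$z_upper & z <= slab$z_upper + slab$headgroup_width),
           "headgroup", "aqueous")
  )
  data.frame(chain = a$chain, resid = a$resid, resname = a$resname,
             z = z, region = region, stringsAsFactors = FALSE)
}

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

#' Truncate a residue side chain to glycine or alanine
#'
#' Emulates simple in-silico mutagenesis by side-chain truncation: target
#' `GLY` keeps only backbone atoms (N, CA, C, O, OXT); target `ALA`
#' additionally keeps CB.  The backbone is untouched, the residue is renamed
#' and atom serials renumbered.
#'
#' @param structure a `Structure`.
#' @param chain,resid residue to mutate.
#' @param target `"GLY"` or `"ALA"`.
#' @return modified `Structure`.
#' @export
truncate_sidechain <- function(structure, chain, resid, target = c("GLY", "ALA")) {
  target <- match.arg(target)
  stopifnot(inherits(structure, "Structure"))
  a <- structure$atoms
  in_res <- a$chain == chain & a$resid == resid
  if (!any(in_res)) sd_stop("residue ", chain, resid, " not found")
  resname <- unique(a$resname[in_res])[1]
  if (resname == "PRO")
    sd_stop("proline cannot be truncated (ring shares backbone atoms)")
  keep_names <- c(BACKBONE_NAMES, if (target == "ALA") "CB")
  if (target == "ALA" && !any(a$name[in_res] == "CB") && resname != "GLY")
    sd_stop("residue ", chain, resid, " has no CB atom; cannot truncate to ALA")
  if (target == "ALA" && resname == "GLY")
    sd_stop("glycine has no side chain to truncate to ALA")
  drop <- in_res & !(a$name %in% keep_names)
  keep <- !drop
  atoms <- a[keep, , drop = FALSE]
  atoms$resname[atoms$chain == chain & atoms$resid == resid] <- target
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  coords <- lapply(structure$coords, function(xyz) xyz[keep, , drop = FALSE])
  new_structure(structure$id, atoms, coords)
}
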