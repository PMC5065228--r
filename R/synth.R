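# Deterministic synthetic-data generator.  Emulates every input the
# pipeline consumes -- helix-bundle receptor coordinates, pose clouds
# concentrated at declared residue sets, category-shifted affinity scores,
# and replicate distance time series -- with no physical realism beyond
# geometry (no force field, no sterics).

HELIX_RISE <- 1.5      # Angstrom per residue along the axis
HELIX_TWIST <- 100     # degrees per residue
HELIX_RADIUS <- 2.3    # C-alpha ring radius, Angstrom
LIGAND_RADIUS <- 2.5   # dummy-ligand octahedron vertex distance
SITE_CAPTURE_RADIUS <- 6.0  # C-alpha within this distance of a site anchor

AA3_CYCLE <- unname(AA1TO3[c("A", "L", "S", "V", "T", "I", "F", "G", "E", "K",
                             "R", "D", "N", "Q", "M", "W", "Y", "H", "C", "P")])

# deterministic sub-stream seed, kept inside the 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2000003) * 1009 + k) %% 2147483647L
}

rotation_to_axis <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  s <- sqrt(sum(v^2)); cth <- sum(z * axis)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))        # antiparallel: flip about x
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

#' Ideal alpha-helix C-alpha trace with minimal backbone
#'
#' Canonical alpha-helix geometry: 1.5 A rise and 100 degree twist per
#' residue on a 2.3 A C-alpha ring (consecutive C-alpha distance about
#' 3.8 A).  N, C and O atoms are placed at idealized offsets around each
#' C-alpha; they are geometric stand-ins, not physically refined positions.
#'
#' @param n_res number of residues (>= 4).
#' @param origin helix center (mid-height), length-3.
#' @param axis helix axis direction (default z).
#' @param chain chain id.
#' @param resid_start first residue number.
#' @param phase starting azimuth in degrees.
#' @param id structure id.
#' @return single-frame `Structure`.
#' @export
ideal_helix <- function(n_res, origin = c(0, 0, 0), axis = c(0, 0, 1),
                        chain = "A", resid_start = 1L, phase = 0,
                        id = "helix") {
  if (n_res < 4L) sd_stop("an ideal helix needs at least 4 residues")
  k <- seq_len(n_res) - 1L
  theta <- (phase + k * HELIX_TWIST) * pi / 180
  zc <- k * HELIX_RISE - (n_res - 1L) * HELIX_RISE / 2
  place <- function(r, dth, dz) {
    cbind(r * cos(theta + dth * pi / 180), r * sin(theta + dth * pi / 180),
          zc + dz)
  }
  per_res <- list(N = place(1.6, -26, -0.9), CA = place(HELIX_RADIUS, 0, 0),
                  C = place(1.7, 26, 0.9), O = place(2.2, 34, 1.9))
  names_per <- names(per_res)
  rows <- lapply(seq_len(n_res), function(i) {
    do.call(rbind, lapply(per_res, function(m) m[i, ]))
  })
  xyz <- do.call(rbind, rows)
  rot <- rotation_to_axis(axis)
  xyz <- xyz %*% t(rot)
  xyz <- sweep(xyz, 2, origin, `+`)
  resid <- rep(resid_start + k, each = length(names_per))
  atoms <- data.frame(
    serial = seq_len(nrow(xyz)),
    name = rep(names_per, n_res),
    element = rep(c("N", "C", "C", "O"), n_res),
    resname = AA3_CYCLE[((resid - 1L) %% length(AA3_CYCLE)) + 1L],
    chain = chain, resid = resid, icode = " ",
    is_heavy = TRUE, stringsAsFactors = FALSE
  )
  new_structure(id, atoms, list(unname(xyz)))
}

#' Specification for the synthetic world
#'
#' Defaults emulate the shape of the study's inputs: a six-helix
#' transmembrane-like bundle per monomer, duplicated into a two-chain
#' homodimer, with four declared binding sites.
#'
#' @param seed integer; the single global seed all streams derive from.
#' @param n_helices helices per monomer (default 6).
#' @param residues_per_helix residues per helix (default 30).
#' @param bundle_radius circle radius the helix axes sit on (A, default 10).
#' @return a `SynthSpec` list.
#' @export
synth_spec <- function(seed = 1L, n_helices = 6L, residues_per_helix = 30L,
                       bundle_radius = 10) {
  stopifnot(n_helices >= 2L, residues_per_helix >= 4L, bundle_radius > 0)
  structure(list(seed = as.integer(seed), n_helices = n_helices,
                 residues_per_helix = residues_per_helix,
                 bundle_radius = bundle_radius), class = "SynthSpec")
}

#' Helix-bundle receptor with declared binding sites
#'
#' Places `n_helices` ideal helices on a circle, duplicates the bundle as a
#' second chain to emulate the homodimer, and declares four binding sites
#' (S1-S4) at geometric anchor points between adjacent helix pairs at
#' different membrane depths.  A site's residues are all residues whose
#' C-alpha lies within 6 A of its anchor; declared residues of one site are
#' validated to be mutually within 15 A.
#'
#' @param spec a [synth_spec()].
#' @return list with `structure` (two-chain single-frame `Structure`),
#'   `sites` (named list of `SiteDefinition`), and `anchors` (site anchor
#'   coordinates).
#' @export
helix_bundle <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "SynthSpec"))
  nh <- spec$n_helices; npr <- spec$residues_per_helix; R <- spec$bundle_radius
  phis <- (seq_len(nh) - 1L) * 360 / nh
  helices <- lapply(seq_len(nh), function(h) {
    ideal_helix(npr,
                origin = c(R * cos(phis[h] * pi / 180),
                           R * sin(phis[h] * pi / 180), 0),
                chain = "A", resid_start = (h - 1L) * npr + 1L,
                phase = phis[h] + 180,   # residue 1 faces the bundle center
                id = sprintf("helix%d", h))
  })
  atoms <- do.call(rbind, lapply(helices, `[[`, "atoms"))
  xyz <- do.call(rbind, lapply(helices, function(s) s$coords[[1]]))
  # homodimer partner: same monomer translated along +x
  shift <- c(2 * R + 15, 0, 0)
  atoms_b <- atoms; atoms_b$chain <- "B"
  xyz_b <- sweep(xyz, 2, shift, `+`)
  all_atoms <- rbind(atoms, atoms_b)
  all_atoms$serial <- seq_len(nrow(all_atoms))
  rownames(all_atoms) <- NULL
  st <- new_structure("synthetic-bundle", all_atoms, list(rbind(xyz, xyz_b)))

  zmax <- (npr - 1L) * HELIX_RISE / 2
  z_levels <- c(-0.35, 0, 0, 0.35) * 2 * zmax
  pairs <- list(c(1L, 2L), c(2L, 3L), c(4L, 5L), c(5L, 6L))
  pairs <- lapply(pairs, function(p) ((p - 1L) %% nh) + 1L)
  anchors <- lapply(seq_along(pairs), function(s) {
    p <- pairs[[s]]
    ctr <- colMeans(rbind(
      c(R * cos(phis[p[1]] * pi / 180), R * sin(phis[p[1]] * pi / 180), 0),
      c(R * cos(phis[p[2]] * pi / 180), R * sin(phis[p[2]] * pi / 180), 0)))
    c(ctr[1], ctr[2], z_levels[s])
  })
  names(anchors) <- paste0("S", seq_along(anchors))

  ca_idx <- select_atoms(st, chain = "A", name = "CA")
  ca_xyz <- st$coords[[1]][ca_idx, , drop = FALSE]
  ca_atoms <- st$atoms[ca_idx, ]
  sites <- lapply(setNames(nm = names(anchors)), function(sid) {
    a <- anchors[[sid]]
    d <- sqrt(rowSums(sweep(ca_xyz, 2, a)^2))
    sel <- which(d <= SITE_CAPTURE_RADIUS)
    if (length(sel) == 0L)
      sd_stop("site ", sid, ": no residues within ", SITE_CAPTURE_RADIUS,
              " A of its anchor; inconsistent site plan")
    res <- ca_atoms[sel, c("resname", "resid")]
    pd <- as.matrix(dist(ca_xyz[sel, , drop = FALSE]))
    if (max(pd) > 15)
      sd_stop("site ", sid, ": declared residues not mutually within 15 A")
    site_definition(sid, res)
  })
  list(structure = st, sites = sites, anchors = anchors)
}

octahedron_ligand <- function(center, radius = LIGAND_RADIUS) {
  sweep(rbind(c(radius, 0, 0), c(-radius, 0, 0), c(0, radius, 0),
              c(0, -radius, 0), c(0, 0, radius), c(0, 0, -radius)),
        2, center, `+`)
}

site_centroid <- function(structure, site, frame = 1L) {
  idx <- select_atoms(structure, chain = "A", resid = site$residues$resid,
                      name = "CA")
  colMeans(structure$coords[[frame]][idx, , drop = FALSE])
}

#' Generate docked-pose sets around declared binding sites
#'
#' Each pose is a rigid 6-atom octahedral dummy ligand centered on the
#' centroid of its target site's C-alpha atoms plus isotropic Gaussian
#' jitter; per-pose affinities are drawn from the ligand's Normal
#' distribution and written sorted ascending with ranks 1..n (best first,
#' as a docking engine would).
#'
#' @param structure receptor `Structure` (from [helix_bundle()]).
#' @param sites named list of `SiteDefinition`.
#' @param pose_plan data frame, one row per ligand: `ligand_id`, `category`,
#'   `n_poses`, `target_site`, `jitter_sd`, `affinity_mean`, `affinity_sd`.
#' @param seed integer seed.
#' @param dir optional output directory: writes one PDBQT per ligand plus
#'   `truth.tsv` and `categories.tsv` (all headed by the seed).
#' @param receptor_conformation_id conformation label for the PoseSets.
#' @param frame receptor frame used for site centroids.
#' @return list with `pose_sets` (list of `PoseSet`) and `truth`
#'   (data frame: ligand, category, rank, target site, affinity).
#' @export
synth_poses <- function(structure, sites, pose_plan, seed = 1L, dir = NULL,
                        receptor_conformation_id = "conf1", frame = 1L) {
  need <- c("ligand_id", "category", "n_poses", "target_site", "jitter_sd",
            "affinity_mean", "affinity_sd")
  if (!all(need %in% names(pose_plan)))
    sd_stop("pose_plan needs columns ", paste(need, collapse = ", "))
  if (!all(pose_plan$target_site %in% names(sites)))
    sd_stop("pose_plan targets unknown site(s): ",
            paste(setdiff(pose_plan$target_site, names(sites)), collapse = ", "))
  set.seed(seed)
  centroids <- lapply(sites, function(s) site_centroid(structure, s, frame))
  pose_sets <- vector("list", nrow(pose_plan))
  truth <- vector("list", nrow(pose_plan))
  for (i in seq_len(nrow(pose_plan))) {
    pl <- pose_plan[i, ]
    ctr <- centroids[[pl$target_site]]
    # rounded to the 3 decimals the PDBQT result line carries, so in-memory
    # and on-disk affinities agree exactly
    aff <- round(sort(rnorm(pl$n_poses, pl$affinity_mean, pl$affinity_sd)), 3)
    poses <- lapply(seq_len(pl$n_poses), function(r) {
      jitter <- rnorm(3, 0, pl$jitter_sd)
      new_pose(model_index = r,
               coords = octahedron_ligand(ctr + jitter),
               affinity = aff[r], rank = r)
    })
    pose_sets[[i]] <- new_pose_set(pl$ligand_id, pl$category, poses,
                                   receptor_conformation_id)
    truth[[i]] <- data.frame(
      ligand_id = pl$ligand_id, category = pl$category,
      conformation_id = receptor_conformation_id,
      rank = seq_len(pl$n_poses), target_site = pl$target_site,
      affinity = aff, stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (ps in pose_sets) {
      write_pdbqt_poses(ps, file.path(dir, paste0(ps$ligand_id, ".pdbqt")),
                        seed = seed)
    }
    write_tsv_seeded(truth, file.path(dir, "truth.tsv"), seed)
    write_tsv_seeded(unique(truth[, c("ligand_id", "category")]),
                     file.path(dir, "categories.tsv"), seed)
  }
  list(pose_sets = pose_sets, truth = truth)
}

#' Write a PoseSet as a Vina-dialect PDBQT file
#'
#' @param pose_set a `PoseSet`.
#' @param path output path.
#' @param seed optional seed recorded in a REMARK header.
#' @return `path`, invisibly.
#' @export
write_pdbqt_poses <- function(pose_set, path, seed = NULL) {
  out <- character(0)
  if (!is.null(seed)) out <- sprintf("REMARK  SEED %d", as.integer(seed))
  for (p in pose_set$poses) {
    out <- c(out, sprintf("MODEL %8d", p$rank),
             sprintf("REMARK VINA RESULT:  %8.3f      0.000      0.000",
                     p$affinity))
    for (k in seq_len(nrow(p$coords))) {
      out <- c(out, format_atom_line(k, paste0("C", k), "LIG", "L", 1L, " ",
                                     p$coords[k, ], "C", record = "HETATM"))
    }
    out <- c(out, "ENDMDL")
  }
  writeLines(out, path)
  invisible(path)
}

write_tsv_seeded <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Multi-frame trajectory by per-frame Gaussian jitter
#'
#' Frame 1 is the input conformation; every later frame adds i.i.d.
#' Gaussian noise (sd `frame_jitter_sd` per coordinate) to it, emulating an
#' equilibrated, stable trajectory.
#'
#' @param structure single-frame `Structure`.
#' @param n_frames total frames (>= 1).
#' @param frame_jitter_sd per-coordinate noise, Angstrom.
#' @param seed integer seed.
#' @return multi-frame `Structure`.
#' @export
synth_trajectory <- function(structure, n_frames, frame_jitter_sd, seed = 1L) {
  stopifnot(inherits(structure, "Structure"), n_frames >= 1L)
  set.seed(seed)
  base <- structure$coords[[1]]
  coords <- c(list(base), lapply(seq_len(n_frames - 1L), function(f) {
    base + matrix(rnorm(length(base), 0, frame_jitter_sd), nrow(base), 3)
  }))
  new_structure(structure$id, structure$atoms, coords)
}

#' Replicate distance time series with stated mean/variance per condition
#'
#' Per condition, `n_replicates` i.i.d. Gaussian series of `n_frames` values
#' at the stated mean and sd; an optional `drift` adds a linear ramp of that
#' total magnitude over the series (divergence scenarios).
#'
#' @param distance_plan data frame, one row per condition: `condition`,
#'   `mean`, `sd`, `n_frames`, `n_replicates`, optional `drift`.
#' @param seed integer seed.
#' @return named list (by condition) of lists of `DistanceSeries`.
#' @export
synth_distance_traj <- function(distance_plan, seed = 1L) {
  need <- c("condition", "mean", "sd", "n_frames", "n_replicates")
  if (!all(need %in% names(distance_plan)))
    sd_stop("distance_plan needs columns ", paste(need, collapse = ", "))
  if (is.null(distance_plan$drift)) distance_plan$drift <- 0
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(distance_plan))) {
    pl <- distance_plan[i, ]
    reps <- lapply(seq_len(pl$n_replicates), function(r) {
      v <- rnorm(pl$n_frames, pl$mean, pl$sd) +
        seq(0, pl$drift, length.out = pl$n_frames)
      v[v < 0] <- 0     # distances cannot be negative
      new_distance_series(
        pair = list(list(chain = "A", resid = NA_integer_),
                    list(chain = "A", resid = NA_integer_)),
        values = v, replicate_id = sprintf("%s_rep%d", pl$condition, r)
      )
    })
    out[[pl$condition]] <- reps
  }
  out
}

#' Synthetic docking cohort shaped like the study's
#'
#' Builds the helix-bundle receptor, perturbs it into `n_conformations`
#' receptor conformations (coordinate jitter of 0.25 A, keeping the
#' conformations within about 1 A RMSD of each other), and docks
#' `n_substrates` + `n_nonsubstrates` dummy ligands with `n_poses` poses per
#' ligand per conformation.  Substrates preferentially target Site 2
#' (probabilities S2/S1/S3 = 0.6/0.2/0.2), non-substrates mostly avoid it
#' (0.1/0.45/0.45); affinities are category-shifted, substrates N(-9, 1)
#' and non-substrates N(-7, 1) kcal/mol.
#'
#' @param seed integer seed.
#' @param n_substrates,n_nonsubstrates cohort sizes (defaults 25 and 14).
#' @param n_poses poses per ligand per conformation (default 20).
#' @param n_conformations receptor conformations (default 6).
#' @param jitter_sd pose positional jitter, Angstrom (default 1).
#' @param spec bundle geometry, a [synth_spec()].
#' @return list: `conformations` (list of `Structure`), `sites`,
#'   `pose_sets` (flat list over conformation x ligand), `truth`,
#'   `categories`, and the generation parameters.
#' @export
synth_cohort <- function(seed = 1L, n_substrates = 25L, n_nonsubstrates = 14L,
                         n_poses = 20L, n_conformations = 6L, jitter_sd = 1,
                         spec = synth_spec(seed)) {
  bundle <- helix_bundle(spec)
  set.seed(seed)
  base <- bundle$structure$coords[[1]]
  conformations <- lapply(seq_len(n_conformations), function(cid) {
    xyz <- if (cid == 1L) base else
      base + matrix(rnorm(length(base), 0, 0.25), nrow(base), 3)
    st <- new_structure(sprintf("conf%d", cid), bundle$structure$atoms,
                        list(xyz))
    st
  })
  ligand_ids <- c(sprintf("sub%02d", seq_len(n_substrates)),
                  sprintf("non%02d", seq_len(n_nonsubstrates)))
  category <- rep(c("substrate", "non-substrate"),
                  c(n_substrates, n_nonsubstrates))
  target <- character(length(ligand_ids))
  is_sub <- category == "substrate"
  target[is_sub] <- sample(c("S2", "S1", "S3"), sum(is_sub), replace = TRUE,
                           prob = c(0.6, 0.2, 0.2))
  target[!is_sub] <- sample(c("S2", "S1", "S3"), sum(!is_sub), replace = TRUE,
                            prob = c(0.1, 0.45, 0.45))
  plan <- data.frame(
    ligand_id = ligand_ids, category = category, n_poses = n_poses,
    target_site = target, jitter_sd = jitter_sd,
    affinity_mean = ifelse(is_sub, -9, -7), affinity_sd = 1,
    stringsAsFactors = FALSE
  )
  pose_sets <- list(); truth <- list()
  for (cid in seq_len(n_conformations)) {
    res <- synth_poses(conformations[[cid]], bundle$sites, plan,
                       seed = derive_seed(spec$seed, cid),
                       receptor_conformation_id = sprintf("conf%d", cid))
    pose_sets <- c(pose_sets, res$pose_sets)
    truth[[cid]] <- res$truth
  }
  list(conformations = conformations, sites = bundle$sites,
       pose_sets = pose_sets, truth = do.call(rbind, truth),
       categories = data.frame(ligand_id = ligand_ids, category = category,
                               stringsAsFactors = FALSE),
       n_poses = n_poses, n_conformations = n_conformations, seed = seed,
       plan = plan)
}

#' Assign every pose of a cohort and tabulate occupancy
#'
#' Convenience wrapper: runs [find_contacts()] and [assign_pose()] for every
#' pose of every `PoseSet` against its receptor conformation, then builds
#' the normalized [occupancy_table()].
#'
#' @param cohort result of [synth_cohort()] (or a compatible list).
#' @param cutoff contact cutoff, Angstrom.
#' @return list: `assignments` (data frame, one row per pose) and
#'   `occupancy` (`OccupancyTable`).
#' @export
assign_cohort <- function(cohort, cutoff = 4.5) {
  conf_of <- setNames(cohort$conformations,
                      vapply(cohort$conformations, `[[`, "", "id"))
  rows <- lapply(cohort$pose_sets, function(ps) {
    receptor <- conf_of[[ps$receptor_conformation_id]]
    labs <- vapply(ps$poses, function(p) {
      assign_pose(find_contacts(p, receptor, cutoff = cutoff),
                  cohort$sites)$label
    }, character(1))
    data.frame(ligand_id = ps$ligand_id,
               conformation_id = ps$receptor_conformation_id,
               rank = seq_along(ps$poses), label = labs,
               affinity = vapply(ps$poses, `[[`, numeric(1), "affinity"),
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  occ <- occupancy_table(assignments, cohort$categories,
                         n_poses_per_molecule = cohort$n_poses,
                         n_conformations = cohort$n_conformations)
  list(assignments = assignments, occupancy = occ)
}
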