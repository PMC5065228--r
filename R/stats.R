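# Occupancy normalization, affinity summaries, and WT-vs-mutant
# distance-dynamics comparison.  Deliberately descriptive: MD frames are
# autocorrelated, so no p-values are emitted anywhere.

SITE_LABELS <- c("S1", "S2", "S3", "S4", "S1-2", "S2-3", "S1-3", "unassigned")

#' Normalized site-occupancy table
#'
#' Raw counts of poses per (site label, ligand category) are normalized to
#' `n_molecules(category) * n_poses_per_molecule * n_conformations`, so a
#' cell value of 1 means "every pose of every molecule of that category, in
#' every receptor conformation, landed in this site".  Unassigned poses are
#' tracked as their own row.
#'
#' @param assignments data frame with columns `ligand_id`,
#'   `conformation_id`, `rank`, `label` (one row per pose).
#' @param categories data frame with columns `ligand_id`, `category`.
#' @param n_poses_per_molecule poses docked per molecule per conformation.
#' @param n_conformations number of receptor conformations.
#' @return an `OccupancyTable` with matrices `normalized` and `raw_counts`
#'   (site labels x categories) plus the normalization metadata.
#' @export
occupancy_table <- function(assignments, categories, n_poses_per_molecule,
                            n_conformations) {
  need <- c("ligand_id", "conformation_id", "rank", "label")
  if (!all(need %in% names(assignments)))
    sd_stop("assignments needs columns ", paste(need, collapse = ", "))
  if (!all(c("ligand_id", "category") %in% names(categories)))
    sd_stop("categories needs columns ligand_id, category")
  cat_of <- setNames(categories$category, categories$ligand_id)
  missing <- setdiff(unique(assignments$ligand_id), names(cat_of))
  if (length(missing))
    sd_stop("no category for ligand(s): ", paste(missing, collapse = ", "))
  cats <- sort(unique(categories$category))
  n_mol <- vapply(cats, function(cc) {
    length(unique(categories$ligand_id[categories$category == cc]))
  }, integer(1))
  if (any(n_mol == 0L)) sd_stop("a category has zero molecules")
  labels <- union(SITE_LABELS, unique(assignments$label))
  raw <- matrix(0L, length(labels), length(cats),
                dimnames = list(labels, cats))
  tab <- table(assignments$label, cat_of[assignments$ligand_id])
  raw[rownames(tab), colnames(tab)] <- tab
  denom <- n_mol * n_poses_per_molecule * n_conformations
  normalized <- sweep(raw, 2, denom, `/`)
  structure(list(
    normalized = normalized, raw_counts = raw,
    n_molecules = n_mol, n_conformations = n_conformations,
    n_poses_per_molecule = n_poses_per_molecule
  ), class = "OccupancyTable")
}

#' @export
print.OccupancyTable <- function(x, ...) {
  cat(sprintf("<OccupancyTable: %d poses over %s molecules x %d poses x %d conformations>\n",
              sum(x$raw_counts),
              paste(x$n_molecules, collapse = "+"),
              x$n_poses_per_molecule, x$n_conformations))
  print(round(x$normalized, 4))
  invisible(x)
}

#' Flatten an occupancy table to long-format data frame
#' @param x an `OccupancyTable`.
#' @return data frame: `label`, `category`, `raw`, `normalized`.
#' @export
occupancy_long <- function(x) {
  stopifnot(inherits(x, "OccupancyTable"))
  g <- expand.grid(label = rownames(x$raw_counts),
                   category = colnames(x$raw_counts),
                   stringsAsFactors = FALSE)
  g$raw <- x$raw_counts[cbind(g$label, g$category)]
  g$normalized <- x$normalized[cbind(g$label, g$category)]
  g
}

#' Per-category binding-affinity summary
#'
#' Point summaries (mean, median, min, n) per ligand category plus, when a
#' category has at least two poses, a kernel density over the affinity axis
#' (Gaussian kernel, Silverman's rule-of-thumb bandwidth, recorded in the
#' output).
#'
#' @param pose_sets list of `PoseSet`.
#' @return an `AffinitySummary`: data frame `summary` and named list
#'   `densities` (each with `x`, `y`, `bw`, `bw_rule`).
#' @export
affinity_summary <- function(pose_sets) {
  if (!length(pose_sets)) sd_stop("need at least one PoseSet")
  aff <- lapply(pose_sets, function(ps)
    data.frame(category = ps$category,
               affinity = vapply(ps$poses, `[[`, numeric(1), "affinity"),
               stringsAsFactors = FALSE))
  aff <- do.call(rbind, aff)
  cats <- sort(unique(aff$category))
  summ <- do.call(rbind, lapply(cats, function(cc) {
    v <- aff$affinity[aff$category == cc]
    data.frame(category = cc, n = length(v), mean = mean(v),
               median = median(v), min = min(v), stringsAsFactors = FALSE)
  }))
  densities <- lapply(setNames(nm = cats), function(cc) {
    v <- aff$affinity[aff$category == cc]
    if (length(v) < 2L) return(NULL)
    d <- density(v, bw = "nrd0")
    list(x = d$x, y = d$y, bw = d$bw, bw_rule = "Silverman (nrd0)")
  })
  structure(list(summary = summ, densities = densities),
            class = "AffinitySummary")
}

#' @export
print.AffinitySummary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Compare distance dynamics between two conditions
#'
#' Each replicate series is block-averaged with `window`
#' ([block_average()]); block values are then pooled per condition.
#' Reported are per-condition means and standard deviations, the mean shift
#' `delta_mean = mutant - wild-type` and the variance ratio
#' `var(mutant) / var(wild-type)`.  Descriptive only; no p-values.
#'
#' @param wt_replicates,mut_replicates lists of `DistanceSeries` (or plain
#'   numeric vectors), one per replicate run.
#' @param window block-average window (default 10 frames).
#' @return a `DynamicsComparison`.
#' @export
compare_dynamics <- function(wt_replicates, mut_replicates, window = 10L) {
  pool <- function(reps, cond) {
    if (!length(reps)) sd_stop(cond, ": empty replicate list")
    lapply(reps, function(r) {
      v <- if (inherits(r, "DistanceSeries")) r$values else as.numeric(r)
      block_average(v, window)
    })
  }
  wt <- pool(wt_replicates, "wild-type")
  mut <- pool(mut_replicates, "mutant")
  wt_all <- unlist(wt); mut_all <- unlist(mut)
  structure(list(
    window = window,
    n_replicates = c(wt = length(wt), mut = length(mut)),
    replicate_means = list(wt = vapply(wt, mean, numeric(1)),
                           mut = vapply(mut, mean, numeric(1))),
    mean = c(wt = mean(wt_all), mut = mean(mut_all)),
    sd = c(wt = sd(wt_all), mut = sd(mut_all)),
    delta_mean = mean(mut_all) - mean(wt_all),
    variance_ratio = var(mut_all) / var(wt_all)
  ), class = "DynamicsComparison")
}

#' @export
print.DynamicsComparison <- function(x, ...) {
  cat(sprintf(paste0(
    "<DynamicsComparison (window %d)>\n",
    "  wt : mean %.2f A, sd %.2f A (%d replicates)\n",
    "  mut: mean %.2f A, sd %.2f A (%d replicates)\n",
    "  delta_mean %.2f A, variance ratio %.2f\n"),
    x$window, x$mean["wt"], x$sd["wt"], x$n_replicates["wt"],
    x$mean["mut"], x$sd["mut"], x$n_replicates["mut"],
    x$delta_mean, x$variance_ratio))
  invisible(x)
}
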