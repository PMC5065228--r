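# Binding-site definitions, residue-contact detection and pose-to-site
# assignment -- the core classification of the pipeline.

# The four published ABCG2 site residue lists, transcribed verbatim
# including duplicates (a duplicated entry is the same position contributed
# by both monomers of the homodimer); builtin_sites() de-duplicates.
SITE_RESIDUES_RAW <- list(
  S1 = c("Q126", "D127", "D128", "D128", "V129", "V129", "V130", "V130",
         "M131", "M131", "G132", "G132", "T133", "T133", "L134", "V178",
         "V178", "G179", "G179", "T180", "T180", "Q181", "F182", "F182",
         "I183", "I183", "R191", "R191", "N387", "N387", "L388", "G390",
         "N391", "N391", "P392", "Q393", "Q393", "A394", "A394", "A397",
         "Q398", "S443", "A444", "E446", "L447", "L447", "F448", "V449",
         "V449", "V450", "V450", "E451", "K452", "K453", "K453", "L454",
         "I456", "K473", "D477"),
  S2 = c("L388", "A394", "A397", "Q398", "I399", "V401", "T402", "L405",
         "Q437", "C438", "S440", "S441", "V442", "S443", "A444", "V445",
         "E446", "L447", "F448", "V450", "K473", "D477", "L478", "M481",
         "R482", "P485", "S486", "A517", "A520", "S521", "A524"),
  S3 = c("A397", "V401", "F439", "F439", "S440", "V442", "V442", "S443",
         "S443", "V445", "V445", "E446", "E446", "L447", "V449", "V533",
         "V534", "V534", "S535", "S535", "V536", "A537", "T538", "T538",
         "L539", "L540", "M541", "M541", "T542", "I543", "F545"),
  S4 = c("Y413", "I423", "Q424", "Q424", "N425", "A427", "A427", "G428",
         "G553", "G553", "L554", "L554", "L555", "L555", "V556", "N557",
         "N557", "F578", "F586", "P602", "C603", "N604", "Y605", "A606",
         "T607", "L614", "Q617", "G618", "I619", "L621")
)

AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

parse_res_token <- function(tok) {
  one <- substr(tok, 1, 1)
  resid <- as.integer(substr(tok, 2, nchar(tok)))
  data.frame(resname = unname(AA1TO3[one]), resid = resid,
             stringsAsFactors = FALSE)
}

#' Construct a binding-site definition
#'
#' @param site_id site label, e.g. `"S1"`.
#' @param residues data frame with `resname` (3-letter) and `resid` columns;
#'   duplicates are removed.
#' @param chain_scope only `"both_chains"` is supported: residue matching
#'   ignores chain identity, as appropriate for a symmetric homodimer.
#' @return a `SiteDefinition`.
#' @export
site_definition <- function(site_id, residues, chain_scope = "both_chains") {
  stopifnot(is.data.frame(residues), all(c("resname", "resid") %in% names(residues)))
  residues <- unique(residues[, c("resname", "resid")])
  if (nrow(residues) == 0L) sd_stop("site ", site_id, ": empty residue set")
  if (any(residues$resid <= 0L)) sd_stop("site ", site_id, ": resids must be positive")
  rownames(residues) <- NULL
  structure(list(site_id = site_id, residues = residues,
                 chain_scope = chain_scope), class = "SiteDefinition")
}

#' @export
print.SiteDefinition <- function(x, ...) {
  cat(sprintf("<SiteDefinition %s: %d residues>\n", x$site_id, nrow(x$residues)))
  invisible(x)
}

#' The four built-in ABCG2 binding-site residue lists
#'
#' Sites 1 and 2 flank the cytosolic entry, Site 3 sits between the two
#' monomers on the translocation path, Site 4 is an extracellular off-site.
#' Author residue numbering; duplicated entries (a position contributed by
#' both monomers) are collapsed, and matching ignores chain identity.
#'
#' @return named list of four `SiteDefinition` objects (S1-S4).
#' @export
builtin_sites <- function() {
  lapply(setNames(nm = names(SITE_RESIDUES_RAW)), function(id) {
    site_definition(id, do.call(rbind, lapply(SITE_RESIDUES_RAW[[id]], parse_res_token)))
  })
}

#' Residue contacts between a docked pose and the receptor
#'
#' A receptor residue is a contact iff any of its heavy atoms lies within
#' `cutoff` Angstrom (inclusive) of any ligand heavy atom; the minimum
#' distance per contacted residue is recorded.  Pose and receptor must share
#' a coordinate frame.
#'
#' @param pose a `Pose` (heavy-atom coordinates).
#' @param receptor a `Structure`.
#' @param cutoff contact cutoff in Angstrom (> 0); default 4.5, a standard
#'   heavy-atom protein-ligand contact convention.
#' @param frame receptor frame index (default 1).
#' @param pose_ref optional identifier list carried through to the result.
#' @return a `ContactSet`: data frame `contacts` with `chain`, `resname`,
#'   `resid`, `min_distance`.
#' @export
find_contacts <- function(pose, receptor, cutoff = 4.5, frame = 1L,
                          pose_ref = NULL) {
  stopifnot(inherits(receptor, "Structure"))
  if (cutoff <= 0) sd_stop("cutoff must be > 0")
  lig <- if (inherits(pose, "Pose")) pose$coords else as.matrix(pose)
  if (is.null(lig) || nrow(lig) == 0L) sd_stop("empty pose")
  heavy <- select_atoms(receptor, heavy_only = TRUE)
  a <- receptor$atoms[heavy, ]
  xyz <- receptor$coords[[frame]][heavy, , drop = FALSE]
  # squared distance of every receptor heavy atom to its nearest ligand atom
  rec2 <- rowSums(xyz^2)
  min_d2 <- rep(Inf, nrow(xyz))
  for (k in seq_len(nrow(lig))) {
    d2 <- rec2 - 2 * (xyz %*% lig[k, ]) + sum(lig[k, ]^2)
    min_d2 <- pmin(min_d2, d2)
  }
  min_d2[min_d2 < 0] <- 0
  key <- paste(a$chain, a$resname, a$resid, sep = "\r")
  per_res <- tapply(min_d2, key, min)
  hit <- per_res <= cutoff^2 + 1e-9
  parts <- do.call(rbind, strsplit(names(per_res)[hit], "\r"))
  contacts <- if (is.null(parts)) {
    data.frame(chain = character(0), resname = character(0),
               resid = integer(0), min_distance = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chain = parts[, 1], resname = parts[, 2],
               resid = as.integer(parts[, 3]),
               min_distance = sqrt(unname(per_res[hit])),
               stringsAsFactors = FALSE)
  }
  contacts <- contacts[order(contacts$chain, contacts$resid), , drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(pose_ref = pose_ref, contacts = contacts, cutoff = cutoff),
            class = "ContactSet")
}

#' @export
print.ContactSet <- function(x, ...) {
  cat(sprintf("<ContactSet: %d contacted residues (cutoff %.2f A)>\n",
              nrow(x$contacts), x$cutoff))
  invisible(x)
}

OVERLAP_LABELS <- c("S1.S2" = "S1-2", "S2.S3" = "S2-3", "S1.S3" = "S1-3")

#' Assign a docked pose to a binding site from its residue contacts
#'
#' Counts, per site, the contacted residues whose (resname, resid) belongs
#' to the site (chain ignored).  The label is the unique argmax site; a
#' two-way tie between sites with a defined overlap region (S1-2, S2-3,
#' S1-3) yields that overlap label; any other tie, or no contacts in any
#' site, yields `"unassigned"`.
#'
#' @param contacts a `ContactSet` (or a data frame of contacts).
#' @param site_defs list of `SiteDefinition` with distinct ids.
#' @return a `SiteAssignment`: `label` and named integer `per_site_counts`.
#' @export
assign_pose <- function(contacts, site_defs) {
  cdf <- if (inherits(contacts, "ContactSet")) contacts$contacts else contacts
  ids <- vapply(site_defs, `[[`, character(1), "site_id")
  if (anyDuplicated(ids)) sd_stop("site_defs must have distinct ids")
  ckey <- unique(paste(cdf$resname, cdf$resid))
  counts <- vapply(site_defs, function(s) {
    sum(ckey %in% paste(s$residues$resname, s$residues$resid))
  }, integer(1))
  names(counts) <- ids
  label <- "unassigned"
  if (any(counts > 0L)) {
    top <- sort(names(counts)[counts == max(counts)])
    if (length(top) == 1L) {
      label <- top
    } else if (length(top) == 2L) {
      label <- OVERLAP_LABELS[paste(top[1], top[2], sep = ".")]
      if (is.na(label)) label <- "unassigned"
      label <- unname(label)
    }
  }
  structure(list(
    pose_ref = if (inherits(contacts, "ContactSet")) contacts$pose_ref else NULL,
    label = label, per_site_counts = counts
  ), class = "SiteAssignment")
}

#' Axis-aligned docking box around a selection
#'
#' @param receptor a `Structure`.
#' @param selection integer atom indices (e.g. [select_atoms()]).
#' @param margin expansion per face, Angstrom (default 0).
#' @param frame frame index.
#' @return list with `min` and `max` corner coordinates (length-3 each).
#' @export
docking_box <- function(receptor, selection, margin = 0, frame = 1L) {
  if (length(selection) == 0L) sd_stop("empty selection")
  xyz <- receptor$coords[[frame]][selection, , drop = FALSE]
  list(min = apply(xyz, 2, min) - margin, max = apply(xyz, 2, max) + margin)
}

#' Read custom site definitions from a TSV file
#'
#' Expected columns: `site_id`, `resname`, `resid`.
#'
#' @param path TSV file.
#' @return named list of `SiteDefinition`.
#' @export
read_sites_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("site_id", "resname", "resid")
  if (!all(need %in% names(df)))
    sd_format_error(path, ": site TSV needs columns ", paste(need, collapse = ", "))
  lapply(split(df, df$site_id), function(d) {
    site_definition(d$site_id[1], d[, c("resname", "resid")])
  })
}
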