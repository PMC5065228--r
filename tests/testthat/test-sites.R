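# Contact detection, pose assignment, docking box, site definitions.

test_that("site definitions are de-duplicated and validated", {
  s <- site_definition("S9", data.frame(resname = c("ALA", "ALA", "GLY"),
                                        resid = c(5L, 5L, 7L)))
  expect_equal(nrow(s$residues), 2L)
  expect_error(site_definition("S9", data.frame(resname = "ALA", resid = -1L)),
               "positive")
  expect_error(site_definition("S9", data.frame(resname = character(0),
                                                resid = integer(0))), "empty")
})

test_that("builtin sites use author numbering with known members", {
  sites <- builtin_sites()
  expect_named(sites, c("S1", "S2", "S3", "S4"))
  s2 <- sites$S2$residues
  expect_true(any(s2$resname == "ARG" & s2$resid == 482))
  expect_true(any(s2$resname == "PRO" & s2$resid == 485))
  expect_true(any(s2$resname == "THR" & s2$resid == 402))
  # the extracellular off-site holds the CRAC tyrosine 413
  expect_true(any(sites$S4$residues$resname == "TYR" &
                    sites$S4$residues$resid == 413))
  for (s in sites) expect_false(anyDuplicated(s$residues) > 0)
})

test_that("find_contacts matches a brute-force all-pairs scan", {
  b <- helix_bundle(synth_spec(seed = 21, n_helices = 6, residues_per_helix = 10))
  box <- docking_box(b$structure, select_atoms(b$structure), margin = 2)
  set.seed(21)
  for (k in 1:25) {
    center <- runif(3, box$min, box$max)
    lig <- sitedock:::octahedron_ligand(center)
    cs <- find_contacts(lig, b$structure, cutoff = 4.5)
    got <- sort(paste(cs$contacts$chain, cs$contacts$resname, cs$contacts$resid))
    expect_equal(got, bf_contacts(lig, b$structure, 4.5))
    # recorded min distances respect the cutoff
    expect_true(all(cs$contacts$min_distance <= 4.5 + 1e-9))
  }
})

test_that("find_contacts boundary is inclusive and far ligands give no contacts", {
  atoms <- data.frame(serial = 1L, name = "CA", element = "C", resname = "ALA",
                      chain = "A", resid = 1L, icode = " ", is_heavy = TRUE,
                      stringsAsFactors = FALSE)
  rec <- sitedock:::new_structure("pt", atoms, list(rbind(c(0, 0, 0))))
  exactly <- rbind(c(4.5, 0, 0))
  expect_equal(nrow(find_contacts(exactly, rec, cutoff = 4.5)$contacts), 1L)
  expect_equal(nrow(find_contacts(rbind(c(50, 0, 0)), rec, 4.5)$contacts), 0L)
  expect_error(find_contacts(matrix(numeric(0), 0, 3), rec, 4.5), "empty pose")
  expect_error(find_contacts(rbind(c(1, 1, 1)), rec, cutoff = 0), "cutoff")
})

test_that("enlarging the cutoff never shrinks a contact set", {
  b <- helix_bundle(synth_spec(seed = 22, n_helices = 6, residues_per_helix = 10))
  set.seed(22)
  for (k in 1:10) {
    lig <- sitedock:::octahedron_ligand(runif(3, -12, 12))
    prev <- character(0)
    for (cutoff in c(2, 4, 6, 9)) {
      cur <- with(find_contacts(lig, b$structure, cutoff)$contacts,
                  paste(chain, resname, resid))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("assign_pose follows the argmax/overlap/tie rule", {
  sites <- builtin_sites()
  contacts_of <- function(df) structure(list(pose_ref = NULL, contacts = df,
                                             cutoff = 4.5), class = "ContactSet")
  # contacts only within S2
  only_s2 <- data.frame(chain = "A", resname = c("ARG", "PRO", "SER"),
                        resid = c(482L, 485L, 486L), min_distance = 3)
  expect_equal(assign_pose(contacts_of(only_s2), sites)$label, "S2")

  # equal nonzero counts for S1 and S2, above the others -> overlap S1-2
  tie12 <- data.frame(chain = "A",
                      resname = c("GLN", "ASP", "ARG", "PRO"),
                      resid = c(126L, 127L, 482L, 485L), min_distance = 3)
  asn <- assign_pose(contacts_of(tie12), sites)
  expect_equal(unname(asn$per_site_counts[c("S1", "S2")]), c(2L, 2L))
  expect_equal(asn$label, "S1-2")

  # zero contacts everywhere -> unassigned
  none <- data.frame(chain = character(0), resname = character(0),
                     resid = integer(0), min_distance = numeric(0))
  expect_equal(assign_pose(contacts_of(none), sites)$label, "unassigned")

  # a tie with S4 has no overlap label -> unassigned
  tie14 <- data.frame(chain = "A", resname = c("GLN", "TYR"),
                      resid = c(126L, 413L), min_distance = 3)
  expect_equal(assign_pose(contacts_of(tie14), sites)$label, "unassigned")

  expect_error(assign_pose(contacts_of(none), c(sites, sites["S1"])),
               "distinct")
})

test_that("assign_pose equals the brute-force rule and ignores site order", {
  sites <- builtin_sites()
  all_res <- unique(do.call(rbind, lapply(sites, `[[`, "residues")))
  set.seed(23)
  for (k in 1:200) {
    n <- sample(0:12, 1)
    pick <- all_res[sample(nrow(all_res), n), , drop = FALSE]
    df <- if (n == 0) data.frame(chain = character(0), resname = character(0),
                                 resid = integer(0), min_distance = numeric(0))
          else data.frame(chain = "A", pick, min_distance = 3)
    asn <- assign_pose(df, sites)
    counts <- vapply(sites, function(s) {
      sum(paste(pick$resname, pick$resid) %in%
            paste(s$residues$resname, s$residues$resid))
    }, integer(1))
    expect_equal(unname(asn$per_site_counts), unname(counts))
    expect_equal(asn$label, bf_label(counts))
    # permutation invariance in site order
    perm <- sample(length(sites))
    expect_equal(assign_pose(df, sites[perm])$label, asn$label)
  }
})

test_that("docking_box is the margin-expanded bounding box", {
  atoms <- data.frame(serial = 1L, name = "CA", element = "C", resname = "ALA",
                      chain = "A", resid = 1L, icode = " ", is_heavy = TRUE,
                      stringsAsFactors = FALSE)
  one <- sitedock:::new_structure("pt", atoms, list(rbind(c(0, 0, 0))))
  bx <- docking_box(one, 1L, margin = 5)
  expect_equal(bx$min, c(-5, -5, -5))
  expect_equal(bx$max, c(5, 5, 5))

  b <- helix_bundle(synth_spec(seed = 24, n_helices = 6, residues_per_helix = 8))
  sel <- select_atoms(b$structure, chain = "A")
  bx2 <- docking_box(b$structure, sel, margin = 0)
  xyz <- b$structure$coords[[1]][sel, ]
  expect_equal(bx2$min, apply(xyz, 2, min))
  expect_equal(bx2$max, apply(xyz, 2, max))
  expect_error(docking_box(b$structure, integer(0)), "empty selection")
})
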