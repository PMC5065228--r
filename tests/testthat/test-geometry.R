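# Superposition, series, smoothing, depth annotation, truncation.

rigid_move <- function(P, axis_angle = c(0, 0, 1), theta = 1, shift = c(0, 0, 0)) {
  u <- axis_angle / sqrt(sum(axis_angle^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
  sweep(P %*% t(R), 2, shift, `+`)
}

test_that("kabsch_superpose recovers exact rigid motions", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(P, P)$rmsd, 0, tolerance = 1e-10)

  Q <- rigid_move(P, c(0, 0, 1), pi / 2, c(4, -2, 7))
  fit <- kabsch_superpose(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  # moving P by the returned transform reproduces Q
  moved <- sweep(P %*% fit$rotation, 2, fit$translation, `+`)
  expect_equal(moved, Q, tolerance = 1e-9)
  # the recovered rotation is the inverse of the applied one (rows-as-points
  # convention: rigid_move applied t(Rz), so the fit must recover Rz^-1 = Rz')
  Rz <- matrix(c(cos(pi / 2), -sin(pi / 2), 0,
                 sin(pi / 2), cos(pi / 2), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(fit$rotation %*% Rz, diag(3), tolerance = 1e-9)

  expect_error(kabsch_superpose(P, P[1:5, ]), "equal")
})

test_that("kabsch rmsd is the least-squares optimum (stochastic bound)", {
  set.seed(2)
  P <- matrix(rnorm(15), 5, 3)
  Q <- P + matrix(rnorm(15, 0, 0.4), 5, 3)
  fit <- kabsch_superpose(P, Q)
  moved <- sweep(P %*% fit$rotation, 2, fit$translation, `+`)
  expect_equal(fit$rmsd, sqrt(mean(rowSums((moved - Q)^2))), tolerance = 1e-12)
  for (k in 1:1000) {
    cand <- rigid_move(P, rnorm(3), runif(1, 0, 2 * pi), rnorm(3, 0, 2))
    cand <- sweep(cand, 2, colMeans(Q) - colMeans(cand), `+`)
    expect_gte(sqrt(mean(rowSums((cand - Q)^2))) + 1e-12, fit$rmsd)
  }
})

test_that("kabsch rmsd is invariant under rigid pre-motion of the mobile set", {
  set.seed(3)
  P <- matrix(rnorm(24), 8, 3)
  Q <- P + matrix(rnorm(24, 0, 0.5), 8, 3)
  base <- kabsch_superpose(P, Q)$rmsd
  for (k in 1:5) {
    P2 <- rigid_move(P, rnorm(3), runif(1, 0, 2 * pi), rnorm(3, 0, 10))
    expect_equal(kabsch_superpose(P2, Q)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("rmsd_series is zero for identical/translated frames, matches jitter", {
  b <- helix_bundle(synth_spec(seed = 4, n_helices = 6, residues_per_helix = 15))
  st <- b$structure
  xyz <- st$coords[[1]]
  still <- sitedock:::new_structure(st$id, st$atoms, list(xyz, xyz, xyz))
  sel <- select_atoms(still, chain = "A", name = "CA")
  expect_equal(rmsd_series(still, 1, sel), c(0, 0, 0))

  shifted <- sitedock:::new_structure(st$id, st$atoms,
                                      list(xyz, sweep(xyz, 2, c(5, 6, 7), `+`)))
  expect_equal(rmsd_series(shifted, 1, sel), c(0, 0), tolerance = 1e-9)
  expect_error(rmsd_series(still, 1, integer(0)), "empty selection")

  # analytic expectation: per-coordinate N(0, sigma) jitter on every atom
  # gives RMSD about sigma * sqrt(3) after superposition
  sigma <- 0.5
  tr <- synth_trajectory(st, n_frames = 101, frame_jitter_sd = sigma, seed = 5)
  vals <- rmsd_series(tr, 1, sel)[-1]
  expect_equal(mean(vals), sigma * sqrt(3), tolerance = 0.1)
})

test_that("ca_distance_series measures per-frame CA-CA distances", {
  st <- scripted_distance_structure(c(5, 1, 2.5))
  ds <- ca_distance_series(st, list(list(chain = "A", resid = 1),
                                    list(chain = "A", resid = 2)))
  expect_equal(ds$values, c(5, 1, 2.5), tolerance = 1e-6)

  self <- ca_distance_series(st, list(list(chain = "A", resid = 1),
                                      list(chain = "A", resid = 1)))
  expect_equal(self$values, c(0, 0, 0))

  expect_error(
    ca_distance_series(st, list(list(chain = "A", resid = 1),
                                list(chain = "B", resid = 9))),
    "no CA"
  )

  set.seed(6)
  script <- runif(200, 2, 30)
  rec <- ca_distance_series(scripted_distance_structure(script),
                            list(list(chain = "A", resid = 1),
                                 list(chain = "A", resid = 2)))
  expect_equal(rec$values, script, tolerance = 1e-6)
})

test_that("block_average: blocks, partial tail, mean preservation", {
  expect_equal(block_average(1:10, 10), 5.5)
  expect_length(block_average(rnorm(5000), 10), 500L)
  expect_equal(block_average(numeric(0)), numeric(0))
  expect_equal(block_average(c(1, 2, 3, 10), 3), c(2, 10))  # partial tail averaged
  expect_error(block_average(1:5, 0), "window")

  set.seed(7)
  for (k in 1:20) {
    v <- rnorm(sample(1:97, 1))
    w <- sample(1:12, 1)
    expect_equal(block_average(v, w), bf_block_average(v, w), tolerance = 1e-12)
  }
  v <- rnorm(60)
  expect_equal(mean(block_average(v, 10)), mean(v), tolerance = 1e-12)
})

test_that("annotate_depth labels regions and partitions residues", {
  slab <- membrane_slab(-15, 15, headgroup_width = 8)
  expect_error(membrane_slab(3, -3), "z_lower")
  expect_error(membrane_slab(-3, 3, 0), "headgroup_width")

  mk <- function(zs) {
    atoms <- data.frame(serial = seq_along(zs), name = "CA", element = "C",
                        resname = "ALA", chain = "A", resid = seq_along(zs),
                        icode = " ", is_heavy = TRUE, stringsAsFactors = FALSE)
    sitedock:::new_structure("z", atoms, list(cbind(0, 0, zs)))
  }
  lab <- annotate_depth(mk(c(0, 19, -19, 24, -24, 15, -15, 23, -23)), slab)
  expect_equal(lab$region,
               c("hydrophobic_core", "headgroup", "headgroup", "aqueous",
                 "aqueous", "hydrophobic_core", "hydrophobic_core",
                 "headgroup", "headgroup"))

  set.seed(8)
  zs <- runif(300, -40, 40)
  got <- annotate_depth(mk(zs), slab)$region
  want <- vapply(zs, function(z) {
    if (z >= -15 && z <= 15) "hydrophobic_core"
    else if (abs(z) <= 23) "headgroup"
    else "aqueous"
  }, character(1))
  expect_equal(got, want)          # brute-force conditional agreement
  expect_true(all(got %in% c("hydrophobic_core", "headgroup", "aqueous")))
})

test_that("truncate_sidechain trims to GLY/ALA correctly", {
  st <- peptide_with_sidechains()
  g <- truncate_sidechain(st, "A", 1, "GLY")       # ARG -> GLY
  res1 <- g$atoms[g$atoms$resid == 1, ]
  expect_setequal(res1$name, c("N", "CA", "C", "O"))
  expect_equal(unique(res1$resname), "GLY")
  expect_equal(g$atoms$serial, seq_len(nrow(g$atoms)))  # renumbered

  a <- truncate_sidechain(st, "A", 1, "ALA")       # ARG -> ALA keeps CB
  expect_setequal(a$atoms$name[a$atoms$resid == 1], c("N", "CA", "C", "O", "CB"))

  ala <- truncate_sidechain(st, "A", 2, "ALA")     # ALA -> ALA is identity
  expect_equal(ala$atoms[, -1], st$atoms[, -1])
  expect_equal(ala$coords[[1]], st$coords[[1]])

  expect_error(truncate_sidechain(st, "A", 4, "GLY"), "proline")
  expect_error(truncate_sidechain(st, "A", 3, "ALA"), "side chain")
  expect_error(truncate_sidechain(st, "A", 99, "GLY"), "not found")

  # enumeration: GLY-truncating every non-PRO/GLY residue leaves exactly the
  # backbone atom count for that residue
  for (r in c(1, 2, 5)) {
    tr <- truncate_sidechain(st, "A", r, "GLY")
    expect_equal(sum(tr$atoms$resid == r), 4L)
    # backbone untouched: coordinates of kept atoms unchanged
    kept <- tr$atoms$resid == r
    orig <- st$atoms$resid == r & st$atoms$name %in% c("N", "CA", "C", "O")
    expect_equal(tr$coords[[1]][kept, ], st$coords[[1]][orig, ])
  }
})
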