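test_that("synthetic volumes are deterministic in the seed and record extent", {
  a <- synthesize_structure(dims = c(30, 30, 40), pitch_nm = c(70, 70, 70), seed = 7)
  b <- synthesize_structure(dims = c(30, 30, 40), pitch_nm = c(70, 70, 70), seed = 7)
  expect_identical(a$flags, b$flags)
  d <- synthesize_structure(dims = c(30, 30, 40), pitch_nm = c(70, 70, 70), seed = 8)
  expect_false(identical(a$flags, d$flags))

  # z-extent bookkeeping: 357 slices at 50 nm span 17.85 um
  v <- synthesize_structure(dims = c(8, 8, 357), pitch_nm = c(350, 350, 50), seed = 1)
  expect_equal(v$meta$extent_um[3], 17.85)
})

test_that("structure synthesis rejects sub-pitch spacings", {
  expect_error(synthesize_structure(dims = c(10, 10, 10), pitch_nm = c(350, 350, 350),
                                    tt_spacing = 0.2, seed = 1), "pitch")
  expect_error(synthesize_structure(dims = c(10, 10, 10), pitch_nm = c(350, 350, 350),
                                    sr_strand_spacing = 0.1, seed = 1), "pitch")
})

test_that("jSR marker placement follows the requested Bernoulli rate", {
  v0 <- synthesize_structure(dims = c(40, 40, 60), pitch_nm = c(70, 70, 70),
                             jsr_rate = 0, seed = 5)
  expect_identical(sum(v0$flags == 3L), 0L)

  # marker count over 20 seeds within 4 binomial SD of rate * candidates
  rate <- 0.1
  tot_m <- 0; tot_k <- 0
  for (s in 1:20) {
    base <- synthesize_structure(dims = c(40, 40, 60), pitch_nm = c(70, 70, 70),
                                 jsr_rate = 0, seed = s)
    k <- length(caspatial:::tt_adjacent_sr(base$flags, base$dims))
    m <- sum(synthesize_structure(dims = c(40, 40, 60), pitch_nm = c(70, 70, 70),
                                  jsr_rate = rate, seed = s)$flags == 3L)
    tot_m <- tot_m + m; tot_k <- tot_k + k
  }
  expect_gt(tot_k, 0)
  sd4 <- 4 * sqrt(tot_k * rate * (1 - rate))
  expect_lt(abs(tot_m - rate * tot_k), sd4)
})

test_that("a straight thick tube reduces to a single chain of strand nodes", {
  tube <- tube_volume(len = 140, thick = 3, pitch = 50)  # 7 um long
  net <- reduce_sr_to_strands(tube)
  n_expect <- ceiling(140 * 50 / 350)
  expect_equal(nrow(net$coords), n_expect)
  deg <- lengths(net$nbr)
  expect_equal(sum(deg == 1L), 2L)              # two chain ends
  expect_true(all(deg[deg != 1L] == 2L))        # interior nodes: exactly 2
  expect_equal(net$n_components, 1L)
  # volume conserved exactly
  expect_equal(nrow(net$coords) * net$v_vox_nsr, net$total_sr_volume_um3)
  expect_equal(net$total_sr_volume_um3, sum(tube$flags == 2L) * 50^3 / 1e9)
})

test_that("spatially adjacent but unconnected SR stays uncoupled after reduction", {
  # two parallel 1-voxel tubes in 6-adjacent coarse voxels, never touching
  dims <- c(70L, 14L, 5L)
  fl <- array(0L, dims)
  fl[, 7, 3] <- 2L    # last fine row of coarse row j = 0 (pitch 50, coarse 350)
  fl[, 9, 3] <- 2L    # second fine row of coarse row j = 1; gap at row 8
  net <- reduce_sr_to_strands(full_res_volume(fl, c(50, 50, 50)))
  expect_equal(net$n_components, 2L)
  rows <- net$coords[, 2]
  for (q in seq_along(net$nbr))
    expect_true(all(rows[net$nbr[[q]]] == rows[q]))  # links never cross tubes
})

test_that("membrane and dyad maps follow the shell, TT and merge rules", {
  dims <- c(10L, 10L, 10L)
  fl <- array(0L, dims)
  vol <- full_res_volume(fl, c(350, 350, 350))
  g <- derive_maps(vol)
  expect_equal(g$dims, dims)
  expect_equal(length(g$ss_m), 10^3 - 8^3)   # 488 outer-shell voxels

  # single straight TT line through the interior
  fl2 <- fl; fl2[, 6, 6] <- 1L
  g2 <- derive_maps(full_res_volume(fl2, c(350, 350, 350)))
  expect_equal(length(g2$tt_m), 10L)
  interior <- setdiff(g2$tt_m, g2$ss_m)
  expect_gt(length(interior), 0)

  # two jSR markers inside one coarse voxel merge into one dyad
  fl3 <- fl
  fl3[3, 3, 3] <- 3L
  fl3[4, 3, 3] <- 3L
  g3 <- derive_maps(full_res_volume(fl3, c(175, 175, 175)))  # coarse voxel = 2^3 fine
  expect_equal(nrow(g3$dyads), 1L)
})

test_that("tessellation reproduces the whole-cell dimensions and maps", {
  q <- quarter_geometry()
  expect_equal(q$dims, c(50L, 26L, 52L))
  w6 <- tessellate_whole_cell(q, 6)
  expect_equal(w6$dims, c(100L, 52L, 312L))
  w8_dims <- c(100L, 52L, 8L * 52L)
  expect_equal(tessellate_whole_cell(q, 8)$dims, w8_dims)
  expect_equal(nrow(w6$dyads), 4L * 6L * nrow(q$dyads))

  # mirror symmetry about every reflection plane
  m <- w6$mask
  expect_identical(m, m[dim(m)[1]:1, , ])
  expect_identical(m, m[, dim(m)[2]:1, ])
  expect_identical(m[, , 1:52], m[, , 104:53])

  # network SR continuous across seams: links exist between copies
  kz <- w6$sr$coords[, 3]
  for (q2 in seq_along(w6$sr$nbr)) {
    if (kz[q2] != 51L) next
    if (any(kz[w6$sr$nbr[[q2]]] == 52L)) { seam_found <- TRUE; break }
  }
  expect_true(exists("seam_found"))

  # map round-trips are identities on their domains
  tm <- theta_maps(w6)
  m_idx <- seq_len(nrow(w6$dyads))
  expect_equal(tm$theta_inv(tm$theta(m_idx)), m_idx)
  q_idx <- seq_len(nrow(w6$sr$coords))
  expect_equal(tm$theta_sr_inv(tm$theta_sr(q_idx)), q_idx)
  p_idx <- seq_along(sort(unique(c(w6$ss_m, w6$tt_m))))
  expect_equal(tm$theta_mem_inv(tm$theta_mem(p_idx)), p_idx)
})

test_that("semi-idealised lattices match detailed dyad density", {
  # lattice-count oracle: dyads on a regular 0.7 um lattice in a box
  dims <- c(40L, 20L, 20L)
  mask <- array(TRUE, dims)
  co <- as.matrix(expand.grid(i = seq(1, 39, 2), j = seq(1, 19, 2), k = seq(1, 19, 2)))
  vox <- caspatial:::lin_index(co[, 1], co[, 2], co[, 3], dims)
  g <- structure(list(
    dims = dims, pitch_um = 0.35, mask = mask, v_cyto_vox = 0.0314,
    ss_m = caspatial:::shell_voxels(mask), tt_m = integer(0),
    sr = caspatial:::grid_network(mask, 50, 0.35),
    dyads = caspatial:::make_dyad_table(sort(vox), dims, NULL, 1e-3, 2e-2, 100L, 15L),
    mode = "detailed", meta = list()), class = "cell_geometry")
  nn <- nearest_neighbor_distances(g)
  expect_equal(mean(nn$distances), 0.7, tolerance = 1e-8)
  si <- build_semi_idealized(g)
  n_expect <- prod(dims) * 0.35^3 / 0.7^3   # box volume / (0.7 um)^3 = 2000
  expect_lt(abs(nrow(si$dyads) - n_expect) / n_expect, 0.05)
  expect_lt(abs(nrow(si$dyads) - nrow(g$dyads)) / nrow(g$dyads), 0.05)

  # idempotent, and density preserved on realistic geometry too
  expect_identical(si, build_semi_idealized(si))
  gd <- small_geometry()
  sd2 <- build_semi_idealized(gd)
  expect_lt(abs(nrow(sd2$dyads) - nrow(gd$dyads)) / nrow(gd$dyads), 0.05)
  expect_identical(sd2$mode, "semi-idealised")
})

test_that("structure perturbations follow the exact bookkeeping rules", {
  g <- small_geometry()
  n <- nrow(g$dyads)
  p <- perturb_structure(g, list(dyad_density_factor = 0.5), seed = 2)
  expect_equal(nrow(p$dyads), round(0.5 * n))
  expect_true(all(p$dyads$voxel %in% g$dyads$voxel))

  # two seeds give different (but equally sized) subsets; same seed reproduces
  p2 <- perturb_structure(g, list(dyad_density_factor = 0.5), seed = 3)
  expect_equal(nrow(p2$dyads), round(0.5 * n))
  expect_identical(perturb_structure(g, list(dyad_density_factor = 0.5), seed = 2)$dyads,
                   p$dyads)

  # link removal: count decreases exactly, symmetry preserved
  before <- caspatial:::n_links(g$sr$nbr)
  pl <- perturb_structure(g, list(sr_link_removal_fraction = 0.2), seed = 4)
  k <- pl$meta$removed_links
  expect_gt(k, 0)
  expect_equal(caspatial:::n_links(pl$sr$nbr), before - k)
  sym_ok <- vapply(seq_along(pl$sr$nbr), function(q)
    all(vapply(pl$sr$nbr[[q]], function(w) q %in% pl$sr$nbr[[w]], logical(1))),
    logical(1))
  expect_true(all(sym_ok))

  # heavy removal may disconnect the SR; components are reported
  ph <- perturb_structure(g, list(sr_link_removal_fraction = 0.6), seed = 4)
  expect_gte(ph$sr$n_components, pl$sr$n_components)
  expect_equal(length(ph$sr$component), nrow(ph$sr$coords))
})

test_that("dyad addition saturates at available SR/TT junction sites", {
  g <- small_geometry()
  avail <- length(setdiff(intersect(g$sr$node_voxel, g$tt_m), g$dyads$voxel))
  expect_warning(
    pbig <- perturb_structure(g, list(dyad_density_factor = 1000), seed = 1),
    "available")
  expect_equal(nrow(pbig$dyads), nrow(g$dyads) + avail)
})

test_that("nearest-neighbour distances and histogram follow the geometry", {
  mk <- function(co) data.frame(voxel = seq_len(nrow(co)), i = co[, 1],
                                j = co[, 2], k = co[, 3], sr_node = NA,
                                v_ds = 1e-3, v_jsr = 2e-2, n_ryr = 100L, n_ltcc = 15L)
  tri <- mk(cbind(c(0, 2, 4), 0, 0))
  nn <- nearest_neighbor_distances(tri, pitch_um = 0.35)
  expect_equal(nn$distances, rep(0.7, 3))

  diag2 <- mk(cbind(c(0, 1), c(0, 1), c(0, 1)))
  nn2 <- nearest_neighbor_distances(diag2, pitch_um = 0.35)
  expect_equal(nn2$distances, rep(0.35 * sqrt(3), 2), tolerance = 1e-12)

  expect_error(nearest_neighbor_distances(mk(cbind(0, 0, 0))), "2 dyads")

  g <- small_geometry()
  nng <- nearest_neighbor_distances(g)
  expect_equal(sum(nng$histogram$counts), nrow(g$dyads))
})
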