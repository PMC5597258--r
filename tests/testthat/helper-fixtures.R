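# Shared fixtures, generated in code.

# Small synthetic full-resolution volume (coarse synth pitch keeps it fast).
small_volume <- function(seed = 3, jsr_rate = 0.1) {
  synthesize_structure(dims = c(60, 60, 120), pitch_nm = c(70, 70, 70),
                       tt_spacing = 1.8, sr_strand_spacing = 0.7,
                       jsr_rate = jsr_rate, seed = seed)
}

small_geometry <- function(seed = 3) derive_maps(small_volume(seed))

# A straight SR tube of given thickness along x, for chain oracles.
tube_volume <- function(len = 140, thick = 3, pitch = 50) {
  dims <- c(len, 2L * thick + 3L, 2L * thick + 3L)
  fl <- array(0L, dims)
  mid <- (dims[2] - thick) %/% 2 + 1
  fl[, mid:(mid + thick - 1), mid:(mid + thick - 1)] <- 2L
  full_res_volume(fl, rep(pitch, 3))
}

# Quarter-portion geometry at coarse synthesis pitch (dims are exact voxels).
quarter_geometry <- function(dims = c(50, 26, 52), seed = 11) {
  v <- synthesize_structure(dims = dims, pitch_nm = c(350, 350, 350),
                            tt_spacing = 1.8, sr_strand_spacing = 0.7,
                            jsr_rate = 0.1, seed = seed)
  derive_maps(v)
}

# Minimal box geometry: full cytoplasm mask, full-grid SR network, dyads at
# the given 0-based voxel coordinates.
box_geometry <- function(dims, dyad_ijk = NULL, params = default_params()) {
  dims <- as.integer(dims)
  mask <- array(TRUE, dims)
  sr <- caspatial:::grid_network(mask, 0.00305 * prod(dims), params$pitch_um)
  vox <- if (is.null(dyad_ijk)) integer(0) else
    caspatial:::lin_index(dyad_ijk[, 1], dyad_ijk[, 2], dyad_ijk[, 3], dims)
  dyads <- caspatial:::make_dyad_table(sort(vox), dims, sr,
                                       v_ds = params$channels$v_ds,
                                       v_jsr = params$channels$v_jsr,
                                       n_ryr = params$channels$n_ryr,
                                       n_ltcc = params$channels$n_ltcc)
  structure(list(
    dims = dims, pitch_um = params$pitch_um, mask = mask,
    v_cyto_vox = params$transport$v_cyto_vox,
    ss_m = caspatial:::shell_voxels(mask), tt_m = as.integer(vox),
    sr = sr, dyads = dyads, mode = "detailed", meta = list()
  ), class = "cell_geometry")
}

# parameter set with all stochastic channel transitions frozen (rates zero),
# so engine steps are fully deterministic
frozen_channel_params <- function(params = default_params()) {
  params$channels$ryr[c("komax", "kclose", "kimax", "k_ir", "k_rc",
                        "k_basal")] <- 0
  params$channels$ltcc$a_open <- 0
  params$channels$ltcc$b_open <- 0
  params$channels$ltcc$tau_d <- 1e12
  params$channels$ltcc$tau_f_in <- 1e12
  params$channels$ltcc$tau_f_rec <- 1e12
  params$channels$ltcc$k_fca <- 0
  params$channels$ltcc$k_ca_rec <- 0
  params
}
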