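# Configuration, file formats, manifests: plain-text geometry and Recording
# containers (JSON + CSV), legacy-VTK volumetric snapshots, AP-clamp CSV.

#' Load and validate a run configuration
#'
#' Reads a structured plain-text (YAML-style `key: value`) configuration.
#' Recognised keys are the [protocol_config()] options (case-insensitive,
#' e.g. `BCL`, `Jup_scale`, `LTCC_open_scale`), `protocol`, and the parameter
#' blocks `channels`, `transport`, `membrane`, `force`, `const` whose entries
#' override [default_params()]. Unknown keys are rejected with an error
#' naming them; an empty file yields the full default set.
#'
#' @param path configuration file.
#' @return list with `protocol` (name), `config` (validated
#'   `protocol_config`) and `params` (full parameter list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  raw <- list()
  block <- NULL
  for (ln in txt) {
    if (grepl("^\\S.*:\\s*$", ln)) { block <- sub(":\\s*$", "", ln); next }
    m <- regmatches(ln, regexec("^(\\s*)([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 0) stop("cannot parse config line: ", ln)
    key <- m[3]; val <- m[4]
    num <- suppressWarnings(as.numeric(strsplit(val, "[,;]\\s*")[[1]]))
    parsed <- if (!any(is.na(num))) num else val
    if (nzchar(m[2]) && !is.null(block)) {
      raw[[block]][[key]] <- parsed
    } else {
      block <- NULL
      raw[[key]] <- parsed
    }
  }
  params <- default_params()
  proto <- "paced"
  cfg_over <- list()
  alias <- c(bcl = "bcl", jup_scale = "jup_scale",
             ltcc_open_scale = "ltcc_open_scale", ncx_scale = "ncx_scale",
             d_nsr_scale = "d_nsr_scale", d_rbss_override = "d_rbss_override",
             n_beats = "n_beats", n_prebeats = "n_prebeats",
             quiescent_ms = "quiescent_ms", ca_nsr0 = "ca_nsr0",
             ca_cyto0 = "ca_cyto0", n_tot_dyads = "n_tot_dyads",
             seed = "seed", record_every = "record_every",
             snapshot_every = "snapshot_every", sr_loads = "sr_loads",
             add_dyad_factor = "add_dyad_factor")
  for (key in names(raw)) {
    lk <- tolower(key)
    if (lk == "protocol") { proto <- raw[[key]]; next }
    if (lk %in% names(alias)) { cfg_over[[alias[[lk]]]] <- raw[[key]]; next }
    if (lk %in% c("channels", "transport", "membrane", "force", "const")) {
      blk <- raw[[key]]
      unknown <- setdiff(names(blk), names(params[[lk]]))
      if (length(unknown))
        stop("unknown ", lk, " parameter(s): ", paste(unknown, collapse = ", "))
      params[[lk]][names(blk)] <- blk
      next
    }
    stop("unknown configuration key(s): ", key)
  }
  cfg <- do.call(protocol_config, cfg_over)
  list(protocol = proto, config = cfg, params = params)
}

#' Write a volumetric snapshot as legacy VTK structured points
#'
#' Writes the three concentration fields on the full voxel grid (ASCII legacy
#' VTK, one `SCALARS` block per field). Network-SR node values are placed at
#' their host voxels; voxels without a value (outside the cytoplasm or
#' without an SR node) carry the sentinel -1. Values are written with full
#' precision so that write-then-read reproduces them bitwise.
#'
#' @param fields list with `ca_cyto`, `ca_rbss` (per cytoplasm voxel) and
#'   `ca_nsr` (per SR node).
#' @param geom a `cell_geometry`.
#' @param time snapshot time (ms), stored in the header.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(fields, geom, time, path) {
  dims <- geom$dims
  n <- prod(dims)
  full <- function(vals, idx) {
    out <- rep(-1, n)
    out[idx] <- vals
    out
  }
  vox <- which(geom$mask)
  lines <- c(
    "# vtk DataFile Version 3.0",
    sprintf("caspatial snapshot t=%.17g pitch=%.17g", time, geom$pitch_um),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
    "ORIGIN 0 0 0",
    sprintf("SPACING %.17g %.17g %.17g", geom$pitch_um, geom$pitch_um, geom$pitch_um),
    sprintf("POINT_DATA %d", n))
  vals <- list(ca_cyto = full(fields$ca_cyto, vox),
               ca_rbss = full(fields$ca_rbss, vox),
               ca_nsr = full(fields$ca_nsr, geom$sr$node_voxel))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  for (nm in names(vals)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(paste(formatC(vals[[nm]], format = "g", digits = 17),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a legacy-VTK snapshot written by [write_snapshot()]
#'
#' @param path snapshot file.
#' @return list with `fields` (named list of full-grid numeric arrays with
#'   sentinel -1 outside their domain), `time`, `pitch_um`, `dims`.
#' @export
read_snapshot <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) < 8 || !grepl("^# vtk DataFile", ln[1]))
    stop("not a legacy VTK snapshot file: ", path)
  hd <- regmatches(ln[2], regexec("t=([-0-9.eg+]+) pitch=([-0-9.eg+]+)", ln[2]))[[1]]
  if (length(hd) != 3) stop("malformed snapshot header: ", ln[2])
  dims <- as.integer(strsplit(sub("DIMENSIONS ", "", ln[5]), " ")[[1]])
  fields <- list()
  i <- 9
  while (i <= length(ln)) {
    if (grepl("^SCALARS", ln[i])) {
      nm <- strsplit(ln[i], " ")[[1]][2]
      vals <- as.numeric(strsplit(trimws(ln[i + 2]), "\\s+")[[1]])
      if (length(vals) != prod(dims))
        stop("field ", nm, " has ", length(vals), " values, expected ", prod(dims))
      fields[[nm]] <- array(vals, dim = dims)
      i <- i + 3
    } else i <- i + 1
  }
  list(fields = fields, time = as.numeric(hd[2]), pitch_um = as.numeric(hd[3]),
       dims = dims)
}

#' Write / read a cell geometry container (JSON)
#'
#' Plain-text hierarchical container: cytoplasm mask, membrane maps, SR
#' strand nodes and links, dyad table, and attributes (pitch, volumes, mode).
#'
#' @param geom a `cell_geometry`.
#' @param path output file.
#' @return `path` invisibly / the restored `cell_geometry`.
#' @export
write_geometry <- function(geom, path) {
  obj <- list(
    dims = geom$dims, pitch_um = geom$pitch_um,
    mask = which(geom$mask), v_cyto_vox = geom$v_cyto_vox,
    ss_m = geom$ss_m, tt_m = geom$tt_m, mode = geom$mode,
    dyads = geom$dyads,
    sr = if (is.null(geom$sr)) NULL else list(
      coords = geom$sr$coords, links = adj_to_links(geom$sr$nbr),
      node_voxel = geom$sr$node_voxel, v_vox_nsr = geom$sr$v_vox_nsr,
      total_sr_volume_um3 = geom$sr$total_sr_volume_um3),
    meta = geom$meta[!vapply(geom$meta, is.function, logical(1))]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- as.integer(obj$dims)
  mask <- array(FALSE, dims)
  mask[as.integer(obj$mask)] <- TRUE
  sr <- NULL
  if (!is.null(obj$sr) && length(obj$sr)) {
    coords <- matrix(as.integer(obj$sr$coords), ncol = 3)
    colnames(coords) <- c("i", "j", "k")
    links <- if (length(obj$sr$links))
      matrix(as.integer(obj$sr$links), ncol = 2) else matrix(integer(0), ncol = 2)
    nbr <- links_to_adj(links, nrow(coords))
    comp <- adj_components(nbr)
    sr <- structure(list(
      coords = coords, nbr = nbr,
      node_voxel = as.integer(obj$sr$node_voxel),
      v_vox_nsr = obj$sr$v_vox_nsr, coarse_dims = dims,
      pitch_um = obj$pitch_um,
      total_sr_volume_um3 = obj$sr$total_sr_volume_um3,
      n_components = max(comp), component = comp
    ), class = "strand_network")
  }
  dyads <- as.data.frame(obj$dyads)
  structure(list(
    dims = dims, pitch_um = obj$pitch_um, mask = mask,
    v_cyto_vox = obj$v_cyto_vox, ss_m = as.integer(obj$ss_m),
    tt_m = as.integer(obj$tt_m), sr = sr, dyads = dyads, mode = obj$mode,
    meta = as.list(obj$meta)
  ), class = "cell_geometry")
}

#' Write / read a Recording container (CSV + JSON)
#'
#' Traces go to `traces.csv`, protocol metadata and stimulus markers to
#' `meta.json`, snapshots (when present) to `snap_*.csv`, all inside `dir`.
#'
#' @param rec a `ca_recording`.
#' @param dir output directory (created if missing).
#' @return `dir` invisibly / the restored `ca_recording`.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- rec$traces
  for (cn in names(tr))
    if (is.numeric(tr[[cn]])) tr[[cn]] <- formatC(tr[[cn]], format = "g", digits = 17)
  write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(stim_times = rec$stim_times, geometry = rec$geometry,
         meta = rec$meta),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(rec$snapshots)) {
    write.table(rec$snapshots$ca_cyto, file.path(dir, "snap_ca.csv"),
                row.names = FALSE, col.names = FALSE, sep = ",")
    write.table(rec$snapshots$ca_nsr, file.path(dir, "snap_nsr.csv"),
                row.names = FALSE, col.names = FALSE, sep = ",")
    write.table(rec$snapshots$t, file.path(dir, "snap_t.csv"),
                row.names = FALSE, col.names = FALSE, sep = ",")
  }
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  snapshots <- NULL
  if (file.exists(file.path(dir, "snap_ca.csv"))) {
    snapshots <- list(
      ca_cyto = as.matrix(read.csv(file.path(dir, "snap_ca.csv"), header = FALSE)),
      ca_nsr = as.matrix(read.csv(file.path(dir, "snap_nsr.csv"), header = FALSE)),
      t = read.csv(file.path(dir, "snap_t.csv"), header = FALSE)[, 1])
    dimnames(snapshots$ca_cyto) <- NULL
    dimnames(snapshots$ca_nsr) <- NULL
  }
  geo <- meta$geometry
  geo$dims <- as.integer(geo$dims)
  geo$vox <- as.integer(geo$vox)
  structure(list(
    traces = read.csv(file.path(dir, "traces.csv")),
    snapshots = snapshots,
    stim_times = as.numeric(meta$stim_times),
    geometry = geo, meta = meta$meta
  ), class = "ca_recording")
}

#' Read an AP-clamp waveform from a two-column CSV
#'
#' @param path CSV with columns time (ms) and Vm (mV).
#' @return A function of time (ms) returning the commanded Vm, constant
#'   extrapolation outside the sampled range.
#' @export
read_ap_clamp <- function(path) {
  d <- read.csv(path)
  if (ncol(d) < 2) stop("AP clamp file needs two columns: time (ms), Vm (mV)")
  function(t) stats::approx(d[[1]], d[[2]], xout = t, rule = 2)$y
}

#' Run manifest
#'
#' Written before a simulation starts: content hashes of the configuration
#' and geometry, seeds, package version and wall-clock start time. Identical
#' manifests imply identical outputs for the deterministic protocols.
#'
#' @param config a `protocol_config`.
#' @param geom a `cell_geometry`.
#' @param seed integer seed.
#' @param path optional file to write the manifest JSON to.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(config, geom, seed, path = NULL) {
  hash_of <- function(obj) {
    f <- tempfile()
    on.exit(unlink(f), add = TRUE)
    saveRDS(obj, f, version = 2)
    unname(tools::md5sum(f))
  }
  man <- list(
    config_hash = hash_of(unclass(config)),
    geometry_hash = hash_of(unclass(geom)),
    seed = seed,
    package_version = as.character(utils::packageVersion("caspatial")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = unclass(config)
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
    return(invisible(man))
  }
  man
}

#' Import the published structure dataset (converter stub)
#'
#' Optional converter for the paper-distributed voxel dataset of the quarter
#' cell portion. Expects a JSON file with `dims`, `pitch_nm` and `flags`;
#' validates that the portion has the documented dimensions 60 x 31 x 52 at
#' the coarse pitch before constructing a [full_res_volume()]. Building and
#' testing this package never requires the external dataset; the synthetic
#' generator stands in for it.
#'
#' @param path dataset file (JSON).
#' @return A `full_res_volume`.
#' @export
import_s1_portion <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- as.integer(obj$dims)
  if (!identical(dims, c(60L, 31L, 52L)))
    stop("expected a 60 x 31 x 52 quarter-portion dataset, got ",
         paste(dims, collapse = " x "))
  full_res_volume(array(as.integer(obj$flags), dim = dims),
                  as.numeric(obj$pitch_nm))
}
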