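#' Export a solved plan-view flow field
#'
#' Writes `u`, `v` (um/s) and `p` (Pa) as normalized 32-bit TIFFs plus a
#' JSON sidecar holding the normalization scales and grid metadata.
#'
#' @param field A plan-view `flow_field`.
#' @param prefix Output path prefix.
#' @return Invisibly, the file paths.
#' @export
write_flow_field <- function(field, prefix) {
  comps <- list(u = field$u, v = field$v, p = field$p)
  scales <- lapply(comps, function(m) max(abs(m), 1e-300))
  paths <- character(0)
  for (nm in names(comps)) {
    pth <- paste0(prefix, "_", nm, ".tif")
    tiff::writeTIFF((comps[[nm]] / scales[[nm]] + 1) / 2, pth,
                    bits.per.sample = 32L)
    paths <- c(paths, pth)
  }
  meta <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(scales = scales, spacing = field$spacing,
         flow_rate = field$flow_rate, plane = field$plane),
    meta, auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, meta))
}

#' Build a deterministic synthetic fixture bundle
#'
#' Generates, under one seed, a self-contained directory of synthetic study
#' data: the microtrap geometry (depth map), plan-view flow solutions at the
#' low and high flow rates (0.5 and 3.0 uL min^-1), a short tracer-particle
#' fluorescence video with ground truth, one biofilm image per localization
#' regime, and a manifest listing every file with its MD5 hash. The same
#' seed always reproduces a byte-identical bundle.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param grid_spacing Depth-map grid spacing in um (coarser than the
#'   analysis default to keep fixtures small).
#' @param video_frames Number of video frames.
#' @return Invisibly, the manifest as a tibble (`file`, `md5`).
#' @export
make_fixture_bundle <- function(seed, dir, grid_spacing = 4,
                                video_frames = 40) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ch <- channel_spec(grid_spacing = grid_spacing)
  trap <- build_microtrap(microtrap_spec(), ch)
  write_depth_map(trap, file.path(dir, "microtrap_depth"))

  for (rate in c(0.5, 3.0)) {
    fl <- solve_depth_averaged(trap, rate)
    write_flow_field(fl, file.path(dir, sprintf("flow_%.1f", rate)))
  }

  # tracer video over a plain-channel field at the low flow rate
  plain <- build_channel(channel_spec(grid_spacing = grid_spacing),
                         area = c(200, 120))
  fl0 <- solve_depth_averaged(plain, 0.5)
  optics <- optics_spec(frame_count = video_frames, frame_rate = 25)
  traj <- advect(fl0, particle_spec(diameter = 2), n_particles = 40,
                 duration = video_frames / optics$frame_rate, dt = 5e-3,
                 rng_seed = seed, record_every = 8L)
  vid <- render_video(traj, optics, origin = c(0, 0),
                      dim_px = c(128, 96), rng_seed = seed + 1L)
  write_frame_stack(vid, file.path(dir, "tracer_video.tif"))
  utils::write.csv(vid$truth, file.path(dir, "tracer_video_truth.csv"),
                   row.names = FALSE)

  # biofilm images: all three regimes
  bio_optics <- optics_spec(pixel_size = grid_spacing)
  for (pat in c("walls", "corners", "cavity_centers")) {
    bi <- generate_biofilm_image(regime_spec(pat, rng_seed = seed + 10L),
                                 trap, bio_optics)
    tiff::writeTIFF(bi$image / (2^bio_optics$bit_depth - 1),
                    file.path(dir, sprintf("biofilm_%s.tif", pat)),
                    bits.per.sample = 8L)
    utils::write.csv(bi$truth, file.path(dir, sprintf("biofilm_%s_truth.csv",
                                                      pat)),
                     row.names = FALSE)
  }

  files <- sort(setdiff(list.files(dir), "manifest.json"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files)))
  )
  jsonlite::write_json(
    list(seed = seed, grid_spacing = grid_spacing,
         files = manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

#' Verify a fixture bundle against its manifest
#'
#' @param dir Bundle directory.
#' @return TRUE if every listed file matches its recorded MD5 hash.
#' @export
verify_fixture_bundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  now <- unname(tools::md5sum(file.path(dir, man$files$file)))
  all(now == man$files$md5)
}
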