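## Readers/writers for the package's container formats.
##
## Phantom and k-space bundles are stored as single-file RDS containers with
## a fixed logical layout (named datasets plus an attribute list carrying
## seeds and configuration), reconstructions as NIfTI magnitude volumes with
## the frame spacing in the header plus an RDS sidecar holding bases,
## objective trace and config echo. AIFs and bootstrap tables are CSV,
## metrics reports JSON.

bundle_write <- function(obj, path, kind) {
  obj$.kind <- kind
  obj$.package_version <- as.character(utils::packageVersion("elitedce"))
  saveRDS(obj, path)
  invisible(path)
}

bundle_read <- function(path, kind) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  obj <- readRDS(path)
  if (!identical(obj$.kind, kind))
    stop_invalid("%s is not a '%s' bundle", path, kind)
  obj
}

#' Write / read a phantom bundle
#'
#' Layout: `labels` (integer H x W), `coils` (complex C x H x W), `truth`
#' (H x W x T), `time` (T), `attrs` (seed, kinetics, region names).
#'
#' @param phantom a [dro_phantom]
#' @param truth the rendered [dynamic_series] (or NULL)
#' @param path output file path
#' @return the path, invisibly
#' @export
write_phantom_bundle <- function(phantom, truth, path) {
  bundle_write(list(
    labels = phantom$partition$label_map,
    coils = unclass(phantom$coils),
    truth = if (is.null(truth)) NULL else truth$data,
    time = phantom$time_grid,
    attrs = list(seed = phantom$seed,
                 region_names = phantom$partition$region_names,
                 kinetics = phantom$kinetics,
                 heterogeneity = phantom$heterogeneity)
  ), path, "phantom")
}

#' @rdname write_phantom_bundle
#' @export
read_phantom_bundle <- function(path) {
  b <- bundle_read(path, "phantom")
  partition <- region_partition(b$labels, b$attrs$region_names)
  phantom <- structure(list(partition = partition, kinetics = b$attrs$kinetics,
                            coils = structure(b$coils, class = "coil_sensitivities"),
                            time_grid = b$time, seed = b$attrs$seed,
                            heterogeneity = b$attrs$heterogeneity),
                       class = "dro_phantom")
  truth <- if (is.null(b$truth)) NULL else dynamic_series(b$truth, b$time)
  list(phantom = phantom, truth = truth)
}

#' Write / read a k-space bundle
#'
#' Layout: `kspace` (complex C x S x R), `angles` (S), `frame` (S),
#' `weights`, `attrs` (scan time, seed, noise). A bundle without weights is
#' accepted on read; they are recomputed from the trajectory.
#'
#' @param ksp a [multicoil_kspace]
#' @param path output file path
#' @param attrs extra attributes (seed, scan_time, ...) to embed
#' @return the path, invisibly
#' @export
write_kspace_bundle <- function(ksp, path, attrs = list()) {
  bundle_write(list(
    kspace = ksp$data,
    angles = ksp$trajectory$angles,
    n_readout = ksp$trajectory$n_readout,
    frame = ksp$frame_of_spoke,
    weights = as.numeric(ksp$weights),
    weights_scale = attr(ksp$weights, "scale"),
    attrs = attrs
  ), path, "kspace")
}

#' @rdname write_kspace_bundle
#' @export
read_kspace_bundle <- function(path) {
  b <- bundle_read(path, "kspace")
  traj <- golden_angle_trajectory(length(b$angles), b$n_readout)
  w <- if (is.null(b[["weights"]])) NULL
       else structure(b[["weights"]], scale = b[["weights_scale"]])
  ksp <- multicoil_kspace(b$kspace, traj, b$frame, w)
  attr(ksp, "attrs") <- b$attrs
  ksp
}

#' Write a reconstruction as NIfTI plus sidecar
#'
#' Magnitude volume `H x W x T` with the frame spacing in the header; the
#' sidecar RDS carries the objective trace, config echo, optional bases and
#' coefficients.
#'
#' @param series a [dynamic_series]
#' @param path NIfTI output path (`.nii` or `.nii.gz`)
#' @param sidecar optional sidecar path (default: `path` + `.meta.rds`)
#' @param extra named list merged into the sidecar
#' @return the path, invisibly
#' @export
write_recon_nifti <- function(series, path, sidecar = NULL, extra = list()) {
  x <- Mod(series$data)
  dt <- if (length(series$frame_times) > 1L) diff(series$frame_times[1:2]) else 1
  img <- RNifti::asNifti(x, pixdim = c(1, 1, dt))
  RNifti::writeNifti(img, path)
  if (is.null(sidecar)) sidecar <- paste0(path, ".meta.rds")
  meta <- c(list(frame_times = series$frame_times,
                 objective = attr(series, "objective"),
                 config = attr(series, "config")), extra)
  saveRDS(meta, sidecar)
  invisible(path)
}

#' Read a reconstruction NIfTI written by [write_recon_nifti]
#' @param path NIfTI path
#' @return a [dynamic_series] (frame times from the sidecar when present)
#' @export
read_recon_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  x <- array(as.numeric(img), dim(img))
  sidecar <- paste0(path, ".meta.rds")
  ft <- if (file.exists(sidecar)) readRDS(sidecar)$frame_times
        else seq_len(dim(x)[3L])
  dynamic_series(x, ft)
}

#' Write / read an AIF as two-column CSV (t, Ca)
#' @param a an [aif]
#' @param path CSV path
#' @return the path (write) or an [aif] (read)
#' @export
write_aif_csv <- function(a, path) {
  utils::write.csv(data.frame(t = a$t, Ca = a$Ca), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aif_csv
#' @export
read_aif_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("AIF file not found: %s", path)
  d <- utils::read.csv(path)
  if (!all(c("t", "Ca") %in% names(d)))
    stop_invalid("AIF CSV must have columns t and Ca")
  aif(d$t, d$Ca)
}

#' Write bootstrap replicates as CSV (replicate x parameter)
#' @param boot a `pkm_bootstrap`
#' @param path CSV path
#' @return the path, invisibly
#' @export
write_bootstrap_csv <- function(boot, path) {
  utils::write.csv(as.data.frame(boot$replicates), path, row.names = FALSE)
  invisible(path)
}

#' Write a metrics fold-change table as JSON
#' @param folds data.frame from [fold_change]
#' @param path JSON path
#' @param attrs extra attributes embedded in the report
#' @return the path, invisibly
#' @export
write_metrics_json <- function(folds, path, attrs = list()) {
  jsonlite::write_json(c(list(metrics = folds), attrs), path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
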