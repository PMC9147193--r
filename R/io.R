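# fastMRI-dialect HDF5 reading and writing. R has no HDF5 bindings in this
# stack, so the package bridges to the `h5py` library of the python
# interpreter on PATH: arrays are exchanged as raw little-endian buffers
# with a JSON manifest, and the bridge script performs the axis transpose
# between R's (rows, cols, coils, slices) column-major layout and the
# fastMRI on-disk order (slice, coil, row, col).

h5_python <- function() {
  py <- Sys.getenv("NEUMANNMRI_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found for the HDF5 bridge")
  py
}

h5_bridge <- function(...) {
  script <- system.file("python", "h5bridge.py", package = "neumannmri")
  if (!nzchar(script)) stop("h5bridge.py not found in the installed package")
  res <- suppressWarnings(system2(h5_python(), c(shQuote(script), ...),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop("HDF5 bridge failed: ", paste(res, collapse = "\n"))
  invisible(NULL)
}

#' Write datasets to a fastMRI-dialect HDF5 file
#'
#' Each array is stored under its name with the axis order reversed on disk
#' (so a `(rows, cols, coils, slices)` R array becomes the fastMRI
#' `(slice, coil, row, col)` dataset). Complex arrays are stored as native
#' complex HDF5 data.
#'
#' @param path Output file.
#' @param datasets Named list of numeric/complex arrays.
#' @param attrs Named list of scalar file attributes.
#' @return `path`, invisibly.
#' @export
write_h5 <- function(path, datasets, attrs = list()) {
  stopifnot(length(datasets) >= 1L, !is.null(names(datasets)))
  tmp <- tempfile("h5w")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  entries <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    a <- datasets[[i]]
    kind <- if (is.complex(a)) "complex" else "real"
    bin <- file.path(tmp, sprintf("d%d.bin", i))
    con <- file(bin, "wb")
    writeBin(as.vector(if (kind == "real") as.double(a) else a), con,
             size = NA_integer_, endian = "little")
    close(con)
    entries[[i]] <- list(name = names(datasets)[i], kind = kind,
                         dims = I(as.integer(dim(a) %||% length(a))), bin = bin)
  }
  manifest <- file.path(tmp, "manifest.json")
  jsonlite::write_json(list(datasets = entries, attrs = attrs), manifest,
                       auto_unbox = TRUE, digits = NA)
  h5_bridge("pack", shQuote(manifest), shQuote(path))
  invisible(path)
}

#' Read a fastMRI-dialect HDF5 file
#'
#' @param path Input file.
#' @return Named list of arrays (R axis order: reversed on-disk order), with
#'   file attributes attached as attribute `"h5attrs"`.
#' @export
read_h5 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tmp <- tempfile("h5r")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  manifest <- file.path(tmp, "manifest.json")
  h5_bridge("unpack", shQuote(path), shQuote(manifest))
  mf <- jsonlite::read_json(manifest, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  out <- list()
  for (ds in mf$datasets) {
    dims <- as.integer(unlist(ds$dims))
    n <- prod(dims)
    con <- file(ds$bin, "rb")
    a <- if (ds$kind == "complex") readBin(con, "complex", n, endian = "little")
         else readBin(con, "double", n, endian = "little")
    close(con)
    if (length(dims) > 1L) dim(a) <- dims
    out[[ds$name]] <- a
  }
  attr(out, "h5attrs") <- mf$attrs
  out
}

#' Read a multi-coil k-space volume
#'
#' Expects at least a `"kspace"` dataset (fastMRI axis order
#' `slice, coil, row, col` on disk); an absent `"reconstruction_rss"`
#' reference is flagged, not fatal. Coil counts are taken from the data, so
#' any number of receiver coils loads.
#'
#' @param path HDF5 file.
#' @return Object of class `volume_record`: list with `kspace`
#'   (`rows, cols, coils, slices` complex array), optional `reference`
#'   (`rows, cols, slices`), optional `sensitivity_maps`, `num_coils`,
#'   `num_slices`, `has_reference`, and any stored `mask` vector.
#' @export
read_volume <- function(path) {
  raw <- read_h5(path)
  if (is.null(raw$kspace)) stop("dataset 'kspace' missing from ", path)
  k <- raw$kspace
  if (length(dim(k)) == 3L) dim(k) <- c(dim(k), 1L)
  if (length(dim(k)) != 4L) stop("'kspace' must have (slice, coil, row, col) axes")
  ref <- raw$reconstruction_rss
  if (!is.null(ref) && length(dim(ref)) == 2L) dim(ref) <- c(dim(ref), 1L)
  structure(list(kspace = k, reference = ref,
                 sensitivity_maps = raw$sensitivity_maps,
                 mask = raw$mask_sampled,
                 mask_meta = raw$mask_meta,
                 num_coils = dim(k)[3L], num_slices = dim(k)[4L],
                 has_reference = !is.null(ref),
                 attrs = attr(raw, "h5attrs")),
            class = "volume_record")
}

#' Write a multi-coil k-space volume
#'
#' Inverse of [read_volume()]; round-trips bit-exactly.
#'
#' @param path Output file.
#' @param kspace Complex `(rows, cols, coils, slices)` (or 3-D single-slice)
#'   array.
#' @param reference Optional `(rows, cols, slices)` RSS reference images.
#' @param sensitivity_maps Optional complex maps array.
#' @param mask Optional `sampling_mask` (stored as a 0/1 vector plus its
#'   geometry).
#' @param attrs Named scalar attributes.
#' @return `path`, invisibly.
#' @export
write_volume <- function(path, kspace, reference = NULL,
                         sensitivity_maps = NULL, mask = NULL, attrs = list()) {
  if (length(dim(kspace)) == 3L) dim(kspace) <- c(dim(kspace), 1L)
  ds <- list(kspace = kspace)
  if (!is.null(reference)) {
    if (length(dim(reference)) == 2L) dim(reference) <- c(dim(reference), 1L)
    ds$reconstruction_rss <- reference
  }
  if (!is.null(sensitivity_maps)) ds$sensitivity_maps <- sensitivity_maps
  if (!is.null(mask)) {
    ds$mask_sampled <- as.double(mask$sampled)
    ds$mask_meta <- as.double(c(mask$acceleration, mask$acs_fraction,
                                mask$offset, mask$acs_start, mask$acs_end))
  }
  write_h5(path, ds, attrs)
}

mask_from_volume <- function(vol) {
  if (is.null(vol$mask) || is.null(vol$mask_meta)) return(NULL)
  mm <- vol$mask_meta
  m <- make_equispaced_mask(length(vol$mask), mm[1L], mm[2L], mm[3L])
  m$sampled <- vol$mask > 0
  m
}

#' Export images as 8-bit grayscale PNG
#'
#' Writes a reconstruction (and, when a reference is given, the
#' reference and the absolute difference map) as PNG files. Images are
#' min-max scaled independently; the difference map is scaled relative to
#' the reference's dynamic range so error magnitudes are comparable across
#' methods.
#'
#' @param pred Real image matrix.
#' @param path Output PNG path for the reconstruction.
#' @param ref Optional reference image; writes `<path>_ref.png` and
#'   `<path>_diff.png` alongside.
#' @return Invisibly, the paths written.
#' @export
write_png <- function(pred, path, ref = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  scale01 <- function(img, rg = range(img)) {
    if (diff(rg) == 0) return(img * 0)
    pmin(pmax((img - rg[1L]) / diff(rg), 0), 1)
  }
  paths <- path
  png::writePNG(scale01(pred), path)
  if (!is.null(ref)) {
    base <- sub("\\.png$", "", path)
    p_ref <- paste0(base, "_ref.png")
    p_diff <- paste0(base, "_diff.png")
    png::writePNG(scale01(ref), p_ref)
    png::writePNG(scale01(abs(pred - ref), c(0, diff(range(ref)))), p_diff)
    paths <- c(paths, p_ref, p_diff)
  }
  invisible(paths)
}
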