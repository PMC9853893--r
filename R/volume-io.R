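#' Grey-matter volume images
#'
#' A `gm_volume` is a 3D scalar grid of modulated grey-matter volume values
#' together with its voxel size in millimetres. Values must be finite and
#' non-negative (modulated GM maps preserve local tissue volume and cannot
#' be negative). All volumes entering a joint analysis must share one
#' reference grid; mismatched grids are a hard error, no resampling is
#' attempted.
#'
#' @param data numeric 3D array of GMV values.
#' @param voxel_size_mm positive voxel edge lengths in mm; a scalar is
#'   recycled to the three axes.
#' @return A `gm_volume` object.
#' @examples
#' v <- gm_volume(array(1, c(4, 4, 4)), voxel_size_mm = 2)
#' dim(v$data)
#' @export
gm_volume <- function(data, voxel_size_mm = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop_gm("gm_volume: 'data' must be a 3D array", class = "gmprog_shape_error")
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  if (length(voxel_size_mm) != 3 || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop_gm("gm_volume: 'voxel_size_mm' must be 3 positive reals",
            class = "gmprog_validation_error")
  if (any(!is.finite(data)))
    stop_gm("gm_volume: data contain non-finite values",
            class = "gmprog_validation_error")
  if (min(data) < 0)
    stop_gm("gm_volume: GMV values must be non-negative",
            class = "gmprog_validation_error")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "gm_volume")
}

#' @export
print.gm_volume <- function(x, ...) {
  cat("<gm_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_size_mm, 4), collapse = " x "),
      " mm\n  range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

voxel_volume_mm3 <- function(vol) prod(vol$voxel_size_mm)

#' Read and write GMV volumes as NIfTI-1
#'
#' `write_volume()` stores a [gm_volume] as a NIfTI-1 file (`.nii` or
#' `.nii.gz`); `read_volume()` reads one back. The round trip preserves the
#' data to machine precision (data are written at 64-bit float precision)
#' and the voxel size exactly.
#'
#' @param path file path of a NIfTI-1 image.
#' @param img a [gm_volume].
#' @return `read_volume()` returns a [gm_volume]; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop_gm("read_volume: file not found: ", path, class = "gmprog_io_error")
  nii <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_gm("read_volume: cannot parse '",
                                              path, "': ", conditionMessage(e),
                                              class = "gmprog_io_error"))
  arr <- as.array(nii)
  attributes(arr) <- list(dim = dim(arr))   # drop NIfTI bookkeeping attrs
  if (length(dim(arr)) != 3)
    stop_gm("read_volume: expected a 3D image, got ",
            length(dim(arr)), "D: ", path, class = "gmprog_shape_error")
  gm_volume(arr, voxel_size_mm = RNifti::pixdim(nii)[1:3])
}

#' @rdname read_volume
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "gm_volume"))
  a <- img$data
  attr(a, "pixdim") <- img$voxel_size_mm
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "double"), path)
  invisible(path)
}

#' Load a cohort of volumes aligned to a phenotype table
#'
#' Reconciles a directory of per-scan NIfTI volumes with a phenotype CSV.
#' Every phenotype row must have exactly one matching volume file named
#' `<subject_id>_<timepoint>.nii[.gz]`, and vice versa; any orphan on
#' either side is an error listing the offenders. Records are returned in
#' a stable order (subject id, then timepoint) regardless of file-system
#' ordering, and all grids are checked for equality.
#'
#' @param volume_dir directory containing one NIfTI file per scan.
#' @param phenotype_csv path to a phenotype CSV with the columns of
#'   [generate_phenotypes()] output (missing MoCA encoded as empty field).
#' @return A list with `volumes` (named list of [gm_volume]), `phenotypes`
#'   (data frame, same order), and `ids` (scan identifiers).
#' @export
load_cohort <- function(volume_dir, phenotype_csv) {
  phen <- utils::read.csv(phenotype_csv, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "timepoint")
  if (!all(needed %in% names(phen)))
    stop_gm("load_cohort: phenotype CSV lacks columns: ",
            paste(setdiff(needed, names(phen)), collapse = ", "),
            class = "gmprog_validation_error")
  scan_id <- paste0(phen$subject_id, "_", phen$timepoint)
  if (anyDuplicated(scan_id))
    stop_gm("load_cohort: duplicate (subject, timepoint) rows: ",
            paste(unique(scan_id[duplicated(scan_id)]), collapse = ", "),
            class = "gmprog_validation_error")
  files <- list.files(volume_dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  file_id <- sub("\\.nii(\\.gz)?$", "", basename(files))
  orphan_rows <- setdiff(scan_id, file_id)
  orphan_files <- setdiff(file_id, scan_id)
  if (length(orphan_rows) || length(orphan_files))
    stop_gm("load_cohort: unmatched records; phenotype rows without volume: [",
            paste(orphan_rows, collapse = ", "), "]; volumes without row: [",
            paste(orphan_files, collapse = ", "), "]",
            class = "gmprog_reconciliation_error")
  ord <- order(phen$subject_id, phen$timepoint)
  phen <- phen[ord, , drop = FALSE]
  scan_id <- scan_id[ord]
  vols <- lapply(files[match(scan_id, file_id)], read_volume)
  names(vols) <- scan_id
  check_same_grid(lapply(vols, function(v) dim(v$data)), "cohort volumes")
  rownames(phen) <- NULL
  list(volumes = vols, phenotypes = phen, ids = scan_id)
}
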