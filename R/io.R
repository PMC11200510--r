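## Readers and writers: NIfTI-1 volumes and masks (via RNifti), FSL-style
## single-line .bval text, CSV feature tables / labels, JSON configs.

#' Read a 4D DWI volume with its b-value table
#'
#' @param volumePath NIfTI file (`.nii` / `.nii.gz`) holding a 4D volume.
#' @param bvalPath Whitespace-separated b-value text file (FSL dialect).
#' @return A [DWIVolume-class]; spacing is taken from the NIfTI header.
#' @export
readDwi <- function(volumePath, bvalPath) {
  img <- RNifti::readNifti(volumePath)
  arr <- array(as.vector(img), dim = dim(img))
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4D volume, got %d dimensions", length(dim(arr))))
  bvals <- scan(bvalPath, what = numeric(), quiet = TRUE)
  if (any(bvals < 0)) stop("negative b-values in bval file")
  if (length(bvals) != dim(arr)[4])
    stop(sprintf("b-value count (%d) does not match 4th dimension (%d)",
                 length(bvals), dim(arr)[4]))
  sp <- RNifti::pixdim(img)[1:3]
  dwiVolume(arr, bvals, sp)
}

#' Write a DWI volume and its b-value table
#'
#' @param dwi A [DWIVolume-class].
#' @param volumePath,bvalPath Output paths; b-values are written on a single
#'   space-separated line.
#' @return Invisibly, `c(volumePath, bvalPath)`.
#' @export
writeDwi <- function(dwi, volumePath, bvalPath) {
  stopifnot(is(dwi, "DWIVolume"))
  validObject(dwi)
  img <- RNifti::asNifti(dwi@intensities)
  RNifti::pixdim(img) <- c(dwi@spacing, 1)
  RNifti::writeNifti(img, volumePath)
  writeLines(paste(format(dwi@bvalues, trim = TRUE, scientific = FALSE),
                   collapse = " "), bvalPath)
  invisible(c(volumePath, bvalPath))
}

#' Read zone masks into a validated [ZoneMaskSet-class]
#'
#' Voxels are thresholded at 0.5 (any value above reads as foreground); the
#' set's invariants (CZ and PZ disjoint, zones inside the prostate, one
#' shape) are enforced on construction.
#'
#' @param prostatePath,czPath,pzPath,lesionPath NIfTI mask files;
#'   `lesionPath` may be `NULL` for an empty lesion mask.
#' @return A [ZoneMaskSet-class].
#' @export
readMasks <- function(prostatePath, czPath, pzPath, lesionPath = NULL) {
  rd <- function(p) {
    img <- RNifti::readNifti(p)
    if (length(dim(img)) != 3L) stop(sprintf("mask %s is not 3D", p))
    array(as.vector(img), dim = dim(img))
  }
  prost <- rd(prostatePath)
  cz <- rd(czPath); pz <- rd(pzPath)
  les <- if (is.null(lesionPath)) NULL else rd(lesionPath)
  shapes <- lapply(Filter(Negate(is.null), list(prost, cz, pz, les)), dim)
  if (!all(vapply(shapes, identical, TRUE, shapes[[1]])))
    stop("mask shapes do not match the reference grid")
  zoneMaskSet(prost, cz, pz, les)
}

#' Write zone masks as 0/1 NIfTI volumes
#'
#' @param masks A [ZoneMaskSet-class].
#' @param dir Output directory (created if needed).
#' @param spacing Voxel spacing recorded in the headers, mm.
#' @return Invisibly, the named vector of paths.
#' @export
writeMasks <- function(masks, dir, spacing = c(3, 3, 3.5)) {
  stopifnot(is(masks, "ZoneMaskSet"))
  validObject(masks)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(prostate = file.path(dir, "prostate.nii.gz"),
             cz = file.path(dir, "cz.nii.gz"),
             pz = file.path(dir, "pz.nii.gz"),
             lesion = file.path(dir, "lesion.nii.gz"))
  arrays <- list(masks@prostate, masks@cz, masks@pz, masks@lesion)
  for (i in seq_along(paths)) {
    img <- RNifti::asNifti(array(as.numeric(arrays[[i]]), dim(arrays[[i]])))
    RNifti::pixdim(img) <- c(spacing, 1)
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Write a phantom cohort to disk
#'
#' One subdirectory per case with `dwi.nii.gz`, `dwi.bval` and the four zone
#' masks, plus a top-level `labels.csv` (`case_id,label`).
#'
#' @param cases List of [PhantomCase-class] objects.
#' @param dir Output directory.
#' @return Invisibly, the labels data.frame.
#' @export
writeCohort <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- data.frame(
    case_id = vapply(cases, function(cs) cs@caseId, ""),
    label = vapply(cases, function(cs) cs@label, ""))
  for (cs in cases) {
    cdir <- file.path(dir, cs@caseId)
    dir.create(cdir, showWarnings = FALSE)
    writeDwi(cs@dwi, file.path(cdir, "dwi.nii.gz"), file.path(cdir, "dwi.bval"))
    writeMasks(cs@masks, cdir, spacing = cs@dwi@spacing)
  }
  write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(labels)
}

#' Write / read a per-case feature table as CSV
#'
#' Layout: header row, `case_id` first column, `label` last.
#'
#' @param table Feature data.frame (see [extractFeatures()]).
#' @param path CSV path.
#' @return `readFeatureTable`: the validated data.frame.
#' @export
writeFeatureTable <- function(table, path) {
  checkFeatureTable(table)
  ord <- c("case_id", setdiff(names(table), c("case_id", "label")), "label")
  write.csv(table[, ord], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  checkFeatureTable(tab)
  tab
}

#' Validate a feature table
#'
#' Requires unique case ids, unique feature names, no missing values and a
#' `label` column restricted to PCa / BPH.
#'
#' @param table A data.frame with `case_id`, numeric features and `label`.
#' @return Invisibly `TRUE`; errors describe the violation.
#' @export
checkFeatureTable <- function(table) {
  if (!all(c("case_id", "label") %in% names(table)))
    stop("feature table must have case_id and label columns")
  if (anyDuplicated(table$case_id)) stop("case_ids must be unique")
  if (anyDuplicated(names(table))) stop("feature names must be unique")
  if (!all(table$label %in% c("PCa", "BPH")))
    stop("labels must be PCa or BPH")
  featCols <- setdiff(names(table), c("case_id", "label"))
  if (length(featCols) == 0L) stop("feature table has no feature columns")
  vals <- as.matrix(table[, featCols, drop = FALSE])
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("feature values must be numeric and finite (no missing values)")
  invisible(TRUE)
}
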