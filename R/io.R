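#' Read a NIfTI-1 volume
#'
#' Reads a NIfTI-1 file and reorients the data to the RAS convention
#' (first axis left-to-right, second posterior-to-anterior, third
#' inferior-to-superior) so the midsagittal plane is always `x = 0` in world
#' coordinates.
#'
#' @param path path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(sprintf("not a readable file: %s", path), call. = FALSE)
  im <- tryCatch(RNifti::readNifti(path),
                 error = function(e)
                   stop(sprintf("failed to read NIfTI file %s: %s",
                                path, conditionMessage(e)), call. = FALSE))
  if (length(dim(im)) != 3L)
    stop(sprintf("%s: expected a 3D volume, got %d dimensions",
                 path, length(dim(im))), call. = FALSE)
  RNifti::orientation(im) <- "RAS"
  m <- RNifti::xform(im)
  attributes(m) <- list(dim = c(4L, 4L))
  image_volume(array(as.numeric(im), dim(im)), world_from_voxel = m,
               description = basename(path))
}

#' Write a volume as NIfTI-1
#'
#' @param vol an [image_volume].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @param datatype NIfTI storage type; `"double"` (the default) round-trips
#'   bit-exactly, `"float"` halves the file size.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  assert_volume(vol)
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)),
         call. = FALSE)
  im <- RNifti::asNifti(
    vol$data,
    reference = list(pixdim = c(-1, vol$voxel_size, 0, 0, 0, 0)))
  m <- vol$world_from_voxel
  RNifti::sform(im) <- structure(m, code = 2L)
  RNifti::qform(im) <- structure(m, code = 2L)
  tryCatch(RNifti::writeNifti(im, path, datatype = datatype),
           error = function(e)
             stop(sprintf("failed to write %s: %s", path,
                          conditionMessage(e)), call. = FALSE))
  invisible(path)
}

#' AC/PC/interhemispheric landmark triple
#'
#' World-coordinate (mm) positions of the anterior commissure, posterior
#' commissure, and a third point on the interhemispheric fissure, used to
#' define the canonical AC-PC orientation.
#'
#' @param AC,PC,IH length-3 numeric world coordinates in mm.
#' @return An object of class `landmarks`.
#' @export
landmarks <- function(AC, PC, IH) {
  pts <- list(AC = as.numeric(AC), PC = as.numeric(PC), IH = as.numeric(IH))
  for (nm in names(pts))
    if (length(pts[[nm]]) != 3L || any(!is.finite(pts[[nm]])))
      stop(sprintf("landmark %s must be 3 finite coordinates", nm),
           call. = FALSE)
  if (sqrt(sum((pts$AC - pts$PC)^2)) < 1e-6)
    stop("AC and PC coincide", call. = FALSE)
  y <- pts$AC - pts$PC
  v <- pts$IH - pts$AC
  cr <- c(y[2] * v[3] - y[3] * v[2],
          y[3] * v[1] - y[1] * v[3],
          y[1] * v[2] - y[2] * v[1])
  if (sqrt(sum(cr^2)) < 1e-6 * sqrt(sum(y^2)))
    stop("IH landmark is collinear with the AC-PC line", call. = FALSE)
  structure(pts, class = "landmarks")
}

#' Read landmarks from a JSON file
#'
#' The file must contain objects `AC`, `PC`, `IH`, each a 3-vector of world
#' millimetre coordinates.
#' @param path JSON file path.
#' @return A [landmarks] object.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop(sprintf("not a readable file: %s", path), call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("AC", "PC", "IH") %in% names(j)))
    stop(sprintf("%s: landmark file needs AC, PC and IH entries", path),
         call. = FALSE)
  landmarks(j$AC, j$PC, j$IH)
}

#' Write landmarks to a JSON file
#' @param lm a [landmarks] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmarks"))
  jsonlite::write_json(lapply(unclass(lm), as.numeric), path, digits = NA)
  invisible(path)
}
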