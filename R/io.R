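#' Read a segmented label volume
#'
#' Reads a 3D integer label image from NIfTI-1 (`.nii`, `.nii.gz`) or from a
#' compressed-array dump (`.npz`, one array, key `vol` preferred). NIfTI
#' voxel spacing is taken from the header; `.npz` carries no header, so
#' spacing defaults to 1 mm isotropic. FreeSurfer `.mgz` is not parsed
#' natively: convert to NIfTI (e.g. `mri_convert`) first.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"nifti"` or `"npz"`.
#' @return a [LabelVolume-class].
#' @seealso [writeLabelVolume()], [labelVolume()]
#' @export
readLabelVolume <- function(path, format = c("auto", "nifti", "npz")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.npz$", path, ignore.case = TRUE)) "npz"
      else if (grepl("\\.(nii|nii\\.gz)$", path, ignore.case = TRUE)) "nifti"
      else if (grepl("\\.mgz$", path, ignore.case = TRUE))
        stop(".mgz is not parsed natively; convert to NIfTI first",
             call. = FALSE)
      else stop("cannot infer format from extension of '", path,
                "'; pass format=", call. = FALSE)
  }
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L)
      stop("expected a 3D volume, got ", length(dim(arr)), "D: ", path,
           call. = FALSE)
    labelVolume(arr, spacing = RNifti::pixdim(img)[1:3])
  } else {
    arr <- .readNpz(path)
    if (length(dim(arr)) != 3L)
      stop("expected a 3D volume, got ", length(dim(arr)), "D: ", path,
           call. = FALSE)
    labelVolume(arr, spacing = c(1, 1, 1))
  }
}

#' Write a label volume
#'
#' Writes NIfTI-1 (`int32`, spacing in the header) or a stored-`.npz`
#' archive holding the array under key `vol` (`int32`, Fortran order; the
#' npz dialect has no spacing field).
#'
#' @param volume a [LabelVolume-class].
#' @param path destination; extension picks the format unless given.
#' @param format `"auto"`, `"nifti"` or `"npz"`.
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(volume, path,
                             format = c("auto", "nifti", "npz")) {
  stopifnot(is(volume, "LabelVolume"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.npz$", path, ignore.case = TRUE)) "npz"
      else if (grepl("\\.(nii|nii\\.gz)$", path, ignore.case = TRUE)) "nifti"
      else stop("cannot infer format from extension of '", path, "'",
                call. = FALSE)
  }
  if (format == "nifti") {
    img <- RNifti::asNifti(volume@data)
    RNifti::pixdim(img) <- volume@spacing
    RNifti::writeNifti(img, path, datatype = "int32")
  } else {
    .writeStoredZip(path, list(vol.npy = .npyBytes(volume@data)))
  }
  invisible(path)
}

#' Parse and format OASIS-style session identifiers
#'
#' Session ids follow `SUBJECT_MR_dDAYS`, e.g. `OAS30001_MR_d0129`: the
#' subject id, the modality tag `MR`, and the number of days since the
#' subject entered the study (zero-padded). `parseSessionId()` accepts a
#' vector and returns one record per id; `formatSessionId()` is its inverse
#' (days are zero-padded to at least 4 digits).
#'
#' @param sessionId character vector of session ids.
#' @return a `data.frame` with columns `subject_id`, `session_id`, `day`.
#' @examples
#' parseSessionId("OAS30001_MR_d0129")
#' formatSessionId("OAS30109", 2310)
#' @export
parseSessionId <- function(sessionId) {
  pat <- "^([A-Za-z0-9]+)_MR_d([0-9]+)$"
  bad <- !grepl(pat, sessionId)
  if (any(bad))
    stop("malformed session id(s): ",
         paste(utils::head(sessionId[bad], 5L), collapse = ", "),
         call. = FALSE)
  data.frame(subject_id = sub(pat, "\\1", sessionId),
             session_id = sessionId,
             day = as.integer(sub(pat, "\\2", sessionId)),
             stringsAsFactors = FALSE)
}

#' @rdname parseSessionId
#' @param subjectId subject id(s), e.g. `"OAS30001"`.
#' @param day non-negative integer day(s) since study entry.
#' @export
formatSessionId <- function(subjectId, day) {
  day <- as.integer(day)
  if (anyNA(day) || any(day < 0))
    stop("day must be a non-negative integer", call. = FALSE)
  sprintf("%s_MR_d%04d", subjectId, day)
}

#' Read session and CDR metadata tables
#'
#' `readSessionTable()` reads a CSV with at least a `session_id` column
#' (subject and day are derived from the id; an existing `subject_id` column
#' is checked for consistency). `readCDRTable()` reads a CSV with columns
#' `subject_id`, `day`, `cdr` and validates the scores against the standard
#' Clinical Dementia Rating values 0, 0.5, 1, 2, 3.
#'
#' @param path CSV file with a header row.
#' @return a `data.frame`.
#' @export
readSessionTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"session_id" %in% names(tab))
    stop("session table needs a 'session_id' column", call. = FALSE)
  parsed <- parseSessionId(tab$session_id)
  if ("subject_id" %in% names(tab) &&
      !all(tab$subject_id == parsed$subject_id))
    stop("subject_id column disagrees with session_id prefixes",
         call. = FALSE)
  parsed
}

#' @rdname readSessionTable
#' @export
readCDRTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "day", "cdr")
  if (!all(need %in% names(tab)))
    stop("CDR table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab$day <- as.integer(tab$day)
  if (anyNA(tab$day) || any(tab$day < 0))
    stop("CDR day must be a non-negative integer", call. = FALSE)
  if (!all(tab$cdr %in% c(0, 0.5, 1, 2, 3)))
    stop("cdr scores must be in {0, 0.5, 1, 2, 3}", call. = FALSE)
  tab[need]
}

#' Region label maps
#'
#' A label map names the integer labels of a segmentation. The default
#' carries the four structures used throughout the worked examples:
#' third ventricle (26), right putamen (27), right thalamus proper (23) and
#' left ventral DC (24). Unnamed labels in 1--40 remain addressable by
#' number. `readLabelMap()` loads a YAML or JSON mapping `name: label` and
#' validates uniqueness and range.
#'
#' @return named integer vector mapping region name to label.
#' @examples
#' defaultLabelMap()
#' @export
defaultLabelMap <- function() {
  c(right_thalamus_proper = 23L, left_ventral_dc = 24L,
    third_ventricle = 26L, right_putamen = 27L)
}

#' @rdname defaultLabelMap
#' @param path YAML (`.yml`/`.yaml`) or JSON file of `name: label` entries.
#' @export
readLabelMap <- function(path) {
  entries <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  labels <- vapply(entries, function(v) as.integer(v[[1]]), integer(1))
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("label map entries must be named", call. = FALSE)
  if (anyDuplicated(names(labels)))
    stop("duplicate region names in label map", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate labels in label map", call. = FALSE)
  if (any(labels < 1L) || any(labels > 40L))
    stop("labels must lie in 1..40", call. = FALSE)
  labels
}
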