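# NIfTI case IO. A case is a directory holding one gzipped NIfTI file per
# modality channel plus an optional label file, named
# <case_id>_{t1,t1gd,t2,flair,seg}.nii.gz (the BraTS-style suffix t1ce is
# accepted as an alias for t1gd). Volumes are read as stored; the affine
# is retained in the case record and channel geometry mismatches are
# rejected rather than resampled.

.channel_suffixes <- list(t1 = c("t1"), t1gd = c("t1gd", "t1ce"),
                          t2 = c("t2"), flair = c("flair"))

.find_channel_file <- function(directory, suffixes) {
  files <- list.files(directory, full.names = TRUE)
  for (sfx in suffixes) {
    hit <- files[grepl(sprintf("_%s\\.nii(\\.gz)?$", sfx), basename(files),
                       ignore.case = TRUE)]
    if (length(hit) == 1L) return(hit)
    if (length(hit) > 1L) {
      stop_validation(sprintf("multiple files match channel '%s' in %s",
                              sfx, directory), field = sfx)
    }
  }
  NULL
}

#' Read a multi-modal case directory
#'
#' Reads the four modality channels (stacked in fixed order t1, t1gd, t2,
#' flair) and the label file if present. All channels must share shape,
#' spacing and affine within tolerance 1e-4; label values outside
#' \{0,1,2,3\} are rejected.
#'
#' @param directory case directory.
#' @return list with `volume` ([multimodal_volume()]), `labels`
#'   ([label_map()] or NULL) and `record` (the `case_record`).
#' @export
read_case <- function(directory) {
  if (!dir.exists(directory)) {
    stop_validation(sprintf("case directory not found: %s", directory),
                    field = "directory")
  }
  paths <- list()
  for (ch in names(.channel_suffixes)) {
    p <- .find_channel_file(directory, .channel_suffixes[[ch]])
    if (is.null(p)) {
      stop_validation(sprintf("missing channel '%s' in %s", ch, directory),
                      field = ch)
    }
    paths[[ch]] <- p
  }
  imgs <- lapply(paths, RNifti::readNifti)
  d0 <- dim(imgs[[1L]])
  sp0 <- RNifti::pixdim(imgs[[1L]])
  af0 <- RNifti::xform(imgs[[1L]])
  for (ch in names(imgs)[-1L]) {
    if (!identical(dim(imgs[[ch]]), d0)) {
      stop_validation(sprintf("channel '%s' shape differs from t1", ch),
                      field = ch)
    }
    if (max(abs(RNifti::pixdim(imgs[[ch]]) - sp0)) > 1e-4 ||
        max(abs(RNifti::xform(imgs[[ch]]) - af0)) > 1e-4) {
      stop_validation(sprintf("channel '%s' geometry differs from t1", ch),
                      field = ch)
    }
  }
  data <- array(0, dim = c(4L, d0))
  for (i in seq_along(imgs)) data[i, , , ] <- as.array(imgs[[i]])
  vol <- multimodal_volume(data, spacing_mm = as.numeric(sp0)[1:3],
                           affine = unclass(af0))
  labels <- NULL
  label_path <- .find_channel_file(directory, "seg")
  if (!is.null(label_path)) {
    seg <- as.array(RNifti::readNifti(label_path))
    if (!identical(dim(seg), d0)) {
      stop_validation("label shape differs from the channels", field = "seg")
    }
    if (!all(seg %in% 0:3)) {
      bad <- setdiff(unique(as.vector(seg)), 0:3)
      stop_validation(sprintf("label values outside {0,1,2,3}: %s",
                              paste(bad, collapse = ", ")), field = "seg")
    }
    labels <- label_map(array(as.integer(seg), dim = d0))
  }
  record <- structure(list(case_id = basename(normalizePath(directory)),
                           channel_paths = paths, label_path = label_path,
                           spacing_mm = vol$spacing_mm, shape = d0,
                           affine = vol$affine),
                      class = "case_record")
  list(volume = vol, labels = labels, record = record)
}

#' Write a case directory
#'
#' Writes one gzipped NIfTI file per channel (suffixes t1, t1gd, t2,
#' flair) plus a seg file when labels are given, preserving spacing and
#' affine.
#'
#' @param vol a [multimodal_volume()].
#' @param labels a [label_map()] or NULL.
#' @param directory target directory (created if needed).
#' @return The `case_record`, invisibly.
#' @export
write_case <- function(vol, labels = NULL, directory) {
  if (!inherits(vol, "multimodal_volume")) {
    stop_validation("'vol' must be a multimodal_volume", field = "vol")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop(sprintf("cannot create directory %s", directory))
  }
  case_id <- basename(directory)
  paths <- list()
  for (i in seq_along(names(.channel_suffixes))) {
    ch <- names(.channel_suffixes)[i]
    arr <- array(vol$data[i, , , ], dim = dim(vol$data)[-1L])
    paths[[ch]] <- file.path(directory,
                             sprintf("%s_%s.nii.gz", case_id, ch))
    .write_nifti(arr, vol, paths[[ch]])
  }
  label_path <- NULL
  if (!is.null(labels)) {
    if (!inherits(labels, "label_map")) labels <- label_map(labels)
    label_path <- file.path(directory, sprintf("%s_seg.nii.gz", case_id))
    .write_nifti(labels$labels, vol, label_path, datatype = "int16")
  }
  invisible(structure(list(case_id = case_id, channel_paths = paths,
                           label_path = label_path,
                           spacing_mm = vol$spacing_mm,
                           shape = dim(vol$data)[-1L], affine = vol$affine),
                      class = "case_record"))
}

.write_nifti <- function(arr, vol, path, datatype = "double") {
  A <- unclass(vol$affine)
  hdr <- list(pixdim = c(-1, vol$spacing_mm, 0, 0, 0, 0),
              srow_x = A[1, ], srow_y = A[2, ], srow_z = A[3, ],
              sform_code = 2L, qform_code = 0L)
  img <- RNifti::asNifti(arr, reference = hdr, datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Remap an external label vocabulary to the internal one
#'
#' Applies a total mapping from observed label values to the internal
#' vocabulary \{0 background, 1 FHR, 2 ER, 3 NENR\} (external corpora such
#' as BraTS use different codings). Any observed value absent from the
#' mapping is an error.
#'
#' @param labels integer array (any external coding).
#' @param mapping named numeric vector, names = external values, values =
#'   internal classes in \{0,1,2,3\}.
#' @return A [label_map()] in the internal vocabulary.
#' @export
remap_external_labels <- function(labels, mapping) {
  arr <- if (inherits(labels, "label_map")) labels$labels else labels
  vals <- unique(as.vector(arr))
  unmapped <- setdiff(as.character(vals), names(mapping))
  if (length(unmapped)) {
    stop_validation(sprintf("unmapped label value(s): %s",
                            paste(unmapped, collapse = ", ")),
                    field = "mapping")
  }
  out <- array(as.integer(mapping[as.character(arr)]), dim = dim(arr))
  label_map(out)
}

#' Load every case directory under a dataset root
#'
#' @param root directory whose sub-directories are cases.
#' @return list of cases (each list(case_id, volume, labels)).
#' @export
read_dataset <- function(root) {
  dirs <- list.dirs(root, recursive = FALSE)
  if (!length(dirs)) {
    stop_validation(sprintf("no case directories under %s", root),
                    field = "root")
  }
  lapply(dirs, function(d) {
    rc <- read_case(d)
    list(case_id = rc$record$case_id, volume = rc$volume, labels = rc$labels)
  })
}
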