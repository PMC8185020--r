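# File formats: ROI runs and feedback traces as TSV, statistic maps,
# template sets and atlases as NIfTI (one volume per map/region), run
# manifests as JSON.

#' Read and write ROI runs
#'
#' TSV columns: `frame`, `time_s`, `condition`, `target`, `background`,
#' `displacement`.
#'
#' @param run An `nf_run`.
#' @param path TSV file path.
#' @param schedule Schedule to attach on read.
#' @export
write_run <- function(run, path) {
  readr::write_tsv(as_tibble(run), path)
  invisible(path)
}

#' @rdname write_run
#' @export
read_run <- function(path, schedule = NULL) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("frame", "target", "background")
  if (!all(need %in% names(tb))) {
    abort(paste0("Run TSV must contain columns: ", paste(need, collapse = ", ")),
          class = "rtnf_data_error")
  }
  structure(tb, class = c("nf_run", class(tb)), schedule = schedule)
}

#' Read and write statistic maps as NIfTI
#'
#' @param map An `nf_statmap`.
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @export
write_statmap <- function(map, path) {
  stopifnot(inherits(map, "nf_statmap"))
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_statmap
#' @param mask Optional logical array to attach as the mask on read.
#' @param stat_type Statistic type to record on read.
#' @export
read_statmap <- function(path, mask = NULL, stat_type = "z") {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  statmap(array(as.numeric(img), dim = dim(img)), mask = mask,
          voxel_mm = vox, stat_type = stat_type)
}

#' Read and write template sets as 4D NIfTI plus a labels TSV
#'
#' @param templates An `nf_template_set`.
#' @param path NIfTI path; labels are stored next to it as
#'   `<path>.labels.tsv`.
#' @export
write_template_set <- function(templates, path) {
  stopifnot(inherits(templates, "nf_template_set"))
  RNifti::writeNifti(RNifti::asNifti(templates$maps), path)
  readr::write_tsv(tibble(template = seq_along(templates$labels),
                          label = templates$labels),
                   paste0(path, ".labels.tsv"))
  invisible(path)
}

#' @rdname write_template_set
#' @export
read_template_set <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  labels_path <- paste0(path, ".labels.tsv")
  labels <- if (file.exists(labels_path)) {
    readr::read_tsv(labels_path, show_col_types = FALSE)$label
  } else {
    sprintf("template_%02d", seq_len(dim(arr)[4]))
  }
  structure(list(maps = arr, mask = array(TRUE, dim(arr)[1:3]), labels = labels),
            class = "nf_template_set")
}

#' Write a run manifest linking artifacts to their seeds
#'
#' @param manifest A tibble (e.g. `nf_study$manifest`).
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
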