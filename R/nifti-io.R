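# NIfTI-1 and JSON-manifest I/O for phantom datasets.

#' Write a labeled volume as NIfTI files
#'
#' One `.nii.gz` per channel with suffixes `_t1`, `_t1ce`, `_t2`, `_flair`,
#' plus `_mask` (brain mask) and `_regions` (region labels).
#'
#' @param vol A `labeled_volume`.
#' @param dir Output directory (created if needed).
#' @param id File stem.
#' @return Named character vector of the written paths.
#' @export
write_volume_nifti <- function(vol, dir, id) {
  stopifnot(inherits(vol, "labeled_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr <- function(arr, suffix) {
    p <- file.path(dir, paste0(id, "_", suffix, ".nii.gz"))
    img <- RNifti::asNifti(arr, pixdim = vol$spacing)
    RNifti::writeNifti(img, p)
    paths[suffix] <<- p
    p
  }
  for (s in names(vol$channels)) wr(vol$channels[[s]], s)
  wr(vol$brain_mask, "mask")
  wr(vol$region_mask, "regions")
  paths
}

#' Read a labeled volume back from NIfTI files
#'
#' @param dir Directory holding the files written by [write_volume_nifti()].
#' @param id File stem.
#' @param class_label,domain,anatomy_seed Metadata restored from the
#'   manifest by the caller.
#' @return A `labeled_volume`.
#' @export
read_volume_nifti <- function(dir, id, class_label = NA_integer_,
                              domain = NA_integer_, anatomy_seed = NA_integer_) {
  rd <- function(suffix) {
    img <- RNifti::readNifti(file.path(dir, paste0(id, "_", suffix, ".nii.gz")))
    a <- as.array(img)
    attr(a, "pixdim") <- RNifti::pixdim(img)
    a
  }
  channels <- stats::setNames(lapply(SEQ_NAMES, rd), SEQ_NAMES)
  spacing <- attr(channels[[1]], "pixdim")[1:3]
  channels <- lapply(channels, function(a) { attributes(a) <- list(dim = dim(a)); a })
  mask <- rd("mask"); regions <- rd("regions")
  attributes(mask) <- list(dim = dim(mask))
  attributes(regions) <- list(dim = dim(regions))
  new_labeled_volume(channels, spacing, array(as.integer(round(mask)), dim(mask)),
                     array(as.integer(round(regions)), dim(regions)),
                     ifelse(is.na(class_label), 0L, class_label),
                     ifelse(is.na(anatomy_seed), 0L, anatomy_seed),
                     domain = domain)
}

#' Write a phantom dataset (NIfTI volumes + JSON manifest)
#'
#' @param dataset A `phantom_dataset` from [build_dataset()].
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  files <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    paths <- write_volume_nifti(dataset$volumes[[i]], dir, man$id[i])
    files[i] <- unname(paths[1])
  }
  man$file <- files
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, mp, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a phantom dataset from disk
#'
#' @param dir Directory written by [write_dataset()].
#' @return List with `volumes` and `manifest` (same layout as
#'   [build_dataset()]).
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  volumes <- lapply(seq_len(nrow(man)), function(i)
    read_volume_nifti(dir, man$id[i], class_label = man$class[i],
                      domain = man$domain[i], anatomy_seed = man$anatomy_seed[i]))
  structure(list(volumes = volumes, manifest = man), class = "phantom_dataset")
}
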