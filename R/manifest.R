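# Dataset manifests: ordered modality names, class names, and one record per
# sample pointing at the per-modality image files (plus optional lesion-mask
# files for synthetic data).  Canonical serialization is JSON; a flat CSV
# export is provided for inspection.  Paths inside a manifest are relative
# to the manifest's directory.

#' Create a dataset manifest
#'
#' @param modality_names ordered character vector of modality names (length n).
#' @param class_names ordered character vector of class names (length C).
#' @param records tibble with columns `sample_id` (unique character),
#'   `label` (integer in 0..C-1), `images` (list column: named character
#'   vector of n per-modality paths), optionally `masks` (same shape) and
#'   `bits` (synthetic ground-truth attribute string).
#' @param root directory the record paths are relative to.
#' @return a `switchnet_manifest` object.
#' @export
manifest <- function(modality_names, class_names, records, root = ".") {
  m <- structure(list(modality_names = as.character(modality_names),
                      class_names = as.character(class_names),
                      records = tibble::as_tibble(records),
                      root = root),
                 class = "switchnet_manifest")
  validate_manifest(m, check_files = FALSE)
  m
}

#' @export
print.switchnet_manifest <- function(x, ...) {
  cat("<switchnet_manifest>", nrow(x$records), "samples,",
      length(x$modality_names), "modalities,",
      length(x$class_names), "classes\n")
  cat("  modalities:", paste(x$modality_names, collapse = ", "), "\n")
  cat("  classes:", paste(x$class_names, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a manifest
#'
#' Checks structural invariants (unique ids, label range, one path per
#' modality) and optionally that every referenced file exists.
#'
#' @param m a `switchnet_manifest`.
#' @param check_files verify referenced image/mask files on disk.
#' @return the manifest, invisibly; errors name the offending records.
#' @export
validate_manifest <- function(m, check_files = TRUE) {
  rec <- m$records
  stopifnot(is.character(m$modality_names), is.character(m$class_names))
  if (nrow(rec) == 0) stop("manifest has no records")
  if (anyDuplicated(rec$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(rec$sample_id[duplicated(rec$sample_id)]), collapse = ", "))
  }
  n_classes <- length(m$class_names)
  bad <- rec$sample_id[rec$label < 0 | rec$label >= n_classes]
  if (length(bad) > 0) {
    stop("label out of range 0..", n_classes - 1, " for: ",
         paste(bad, collapse = ", "))
  }
  n_mod <- length(m$modality_names)
  cnt <- vapply(rec$images, length, integer(1))
  if (any(cnt != n_mod)) {
    stop("records with wrong modality path count (expected ", n_mod, "): ",
         paste(rec$sample_id[cnt != n_mod], collapse = ", "))
  }
  if (check_files) {
    all_paths <- unlist(rec$images, use.names = FALSE)
    if (!is.null(rec[["masks"]])) {
      all_paths <- c(all_paths, unlist(rec[["masks"]], use.names = FALSE))
    }
    missing <- all_paths[!file.exists(file.path(m$root, all_paths))]
    if (length(missing) > 0) {
      stop("referenced files missing (first shown): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  invisible(m)
}

#' Write a manifest to JSON (with CSV sidecar)
#'
#' @param m a `switchnet_manifest`.
#' @param path output JSON file path; a `.csv` with the same stem is written
#'   alongside.
#' @param csv also write the flat CSV export.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path, csv = TRUE) {
  validate_manifest(m, check_files = FALSE)
  rec <- m$records
  out <- list(
    modality_names = m$modality_names,
    class_names = m$class_names,
    records = lapply(seq_len(nrow(rec)), function(i) {
      r <- list(sample_id = rec$sample_id[i],
                label = rec$label[i],
                images = as.list(rec$images[[i]]))
      if (!is.null(rec[["masks"]])) r$masks <- as.list(rec[["masks"]][[i]])
      if (!is.null(rec[["bits"]])) r$bits <- rec[["bits"]][i]
      r
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (csv) {
    readr::write_csv(manifest_to_table(m), sub("\\.json$", ".csv", path),
                     progress = FALSE)
  }
  invisible(path)
}

#' Flat per-sample table view of a manifest
#'
#' @param m a `switchnet_manifest`.
#' @return tibble: sample_id, label, class_name, one `<modality>_path`
#'   column per modality (and `<modality>_mask` when masks exist).
#' @export
manifest_to_table <- function(m) {
  rec <- m$records
  tab <- tibble::tibble(sample_id = rec$sample_id, label = rec$label,
                        class_name = m$class_names[rec$label + 1L])
  for (j in seq_along(m$modality_names)) {
    tab[[paste0(m$modality_names[j], "_path")]] <-
      vapply(rec$images, `[[`, character(1), j)
  }
  if (!is.null(rec[["masks"]])) {
    for (j in seq_along(m$modality_names)) {
      tab[[paste0(m$modality_names[j], "_mask")]] <-
        vapply(rec[["masks"]], `[[`, character(1), j)
    }
  }
  tab
}

#' Read a manifest from JSON
#'
#' @param path JSON manifest path.
#' @param check_files verify that referenced files exist.
#' @return a `switchnet_manifest` rooted at `dirname(path)`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  j <- jsonlite::read_json(path)
  recs <- j$records
  has_masks <- !is.null(recs[[1]]$masks)
  has_bits <- !is.null(recs[[1]]$bits)
  rec <- tibble::tibble(
    sample_id = vapply(recs, function(r) r$sample_id, character(1)),
    label = vapply(recs, function(r) as.integer(r$label), integer(1)),
    images = lapply(recs, function(r) unlist(r$images))
  )
  if (has_masks) rec$masks <- lapply(recs, function(r) unlist(r$masks))
  if (has_bits) rec$bits <- vapply(recs, function(r) r$bits, character(1))
  m <- manifest(unlist(j$modality_names), unlist(j$class_names), rec,
                root = dirname(path))
  if (check_files) validate_manifest(m, check_files = TRUE)
  m
}

#' Load one sample's images (and masks) from disk
#'
#' Images are returned as (H, W, 3) arrays with values in 0..255; masks as
#' binary (H, W) matrices.
#'
#' @param m a `switchnet_manifest`.
#' @param sample_id the record to load.
#' @return list(sample_id, label, images, masks).
#' @export
load_sample <- function(m, sample_id) {
  i <- match(sample_id, m$records$sample_id)
  if (is.na(i)) stop("unknown sample_id: ", sample_id)
  rec <- m$records[i, ]
  imgs <- lapply(rec$images[[1]], function(p) {
    x <- png::readPNG(file.path(m$root, p))
    if (length(dim(x)) == 2) x <- array(rep(x, 3), dim = c(dim(x), 3))
    x[, , 1:3, drop = FALSE] * 255
  })
  masks <- NULL
  if (!is.null(rec[["masks"]])) {
    masks <- lapply(rec[["masks"]][[1]], function(p) {
      mm <- png::readPNG(file.path(m$root, p))
      if (length(dim(mm)) == 3) mm <- mm[, , 1]
      (mm > 0.5) * 1
    })
  }
  list(sample_id = rec$sample_id, label = rec$label,
       images = imgs, masks = masks)
}
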