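#' Write a synthetic cohort to disk
#'
#' Writes one 16-bit grayscale TIFF per channel per case, one contour CSV
#' (columns x,y; 0-based pixel coordinates) per case, a manifest CSV linking
#' everything to the metadata, and a key-value echo of the generating
#' configuration. Images are stored losslessly: a round-trip read reproduces
#' pixel values exactly.
#'
#' @param cohort a [simulate_cohort()] result
#' @param out_dir output directory (created if absent)
#' @return path of the manifest CSV, invisibly
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)

  rel <- function(id, what, ext) file.path(what, paste0(id, ".", ext))
  for (d in c("density", "contrast", "contours"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)

  for (cs in cohort$cases) {
    tiff::writeTIFF(cs$density_image / FULL_SCALE,
                    file.path(out_dir, rel(cs$case_id, "density", "tif")),
                    bits.per.sample = 16)
    tiff::writeTIFF(cs$contrast_image / FULL_SCALE,
                    file.path(out_dir, rel(cs$case_id, "contrast", "tif")),
                    bits.per.sample = 16)
    utils::write.csv(cs$contour,
                     file.path(out_dir, rel(cs$case_id, "contours", "csv")),
                     row.names = FALSE)
  }
  ids <- vapply(cohort$cases, `[[`, "", "case_id")
  manifest <- cbind(
    data.frame(case_id = ids,
               density_path = rel(ids, "density", "tif"),
               contrast_path = rel(ids, "contrast", "tif"),
               contour_path = rel(ids, "contours", "csv"),
               stringsAsFactors = FALSE),
    cohort$metadata[, setdiff(names(cohort$metadata), "case_id"),
                    drop = FALSE]
  )
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  write_config_echo(cohort$config_used, file.path(out_dir, "config.toml"))
  invisible(manifest_path)
}

# flat TOML-style key = value echo of a cohort_config
write_config_echo <- function(config, path) {
  flat <- c(config[setdiff(names(config), "covariate_params")],
            stats::setNames(config$covariate_params,
                            paste0("covariate_params.",
                                   names(config$covariate_params))))
  fmt <- function(v) {
    if (is.character(v) || !is.null(names(v)) && is.character(names(v)) &&
        any(nzchar(names(v)))) {
      if (!is.null(names(v)) && any(nzchar(names(v))))
        paste0("{ ", paste(sprintf('"%s" = %s', names(v),
                                   vapply(v, format, "", digits = 15)),
                           collapse = ", "), " }")
      else sprintf('"%s"', v)
    } else if (length(v) > 1) {
      paste0("[", paste(vapply(v, format, "", digits = 15), collapse = ", "),
             "]")
    } else format(v, digits = 15)
  }
  lines <- vapply(names(flat), function(k) sprintf("%s = %s", k,
                                                   fmt(flat[[k]])), "")
  writeLines(lines, path)
  invisible(path)
}

#' Validate a cohort manifest against the files on disk
#'
#' @param manifest manifest data.frame (as written by [write_cohort()])
#' @param base_dir directory the manifest paths are relative to
#' @return TRUE invisibly; errors naming the first case with a missing file
#' @export
validate_manifest <- function(manifest, base_dir) {
  for (col in c("density_path", "contrast_path", "contour_path")) {
    ok <- file.exists(file.path(base_dir, manifest[[col]]))
    if (!all(ok)) {
      bad <- manifest$case_id[!ok][1]
      stop(sprintf("missing file for case '%s': %s", bad,
                   manifest[[col]][!ok][1]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read one case from a manifest row
#'
#' Reads both channel images and the contour, validates the geometry, and
#' attaches the covariates with their dichotomized analysis codings
#' (White vs. all other races; non-dense vs. dense; minimal/moderate vs.
#' marked background parenchymal enhancement; pre- vs. post-menopausal).
#'
#' @param manifest_row one-row data.frame from the manifest
#' @param base_dir directory the manifest paths are relative to
#' @return a validated `cem_case` list
#' @export
read_case <- function(manifest_row, base_dir) {
  stopifnot(nrow(manifest_row) == 1L)
  rd <- function(p) {
    img <- tiff::readTIFF(file.path(base_dir, p))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    round(img * FULL_SCALE)
  }
  den <- rd(manifest_row$density_path)
  con <- rd(manifest_row$contrast_path)
  if (!identical(dim(den), dim(con)))
    stop(sprintf("case '%s': density image is %s but contrast image is %s",
                 manifest_row$case_id, paste(dim(den), collapse = "x"),
                 paste(dim(con), collapse = "x")), call. = FALSE)
  contour <- utils::read.csv(file.path(base_dir, manifest_row$contour_path))
  if (!all(c("x", "y") %in% names(contour)))
    stop("contour file must have columns x,y", call. = FALSE)
  if (any(contour$x < 0 | contour$x > ncol(den) - 1 |
          contour$y < 0 | contour$y > nrow(den) - 1))
    stop(sprintf("case '%s': contour vertices outside image bounds",
                 manifest_row$case_id), call. = FALSE)

  cls <- manifest_row$class
  if (!cls %in% FINDING_CLASSES)
    stop(sprintf("case '%s': unknown class '%s'", manifest_row$case_id, cls),
         call. = FALSE)
  inv <- manifest_row$invasive_flag
  if (cls == "malignant" && is.na(inv))
    stop(sprintf("case '%s': malignant finding lacks invasive_flag",
                 manifest_row$case_id), call. = FALSE)
  if (cls != "malignant") inv <- NA

  covs <- code_covariates(manifest_row)

  structure(list(
    case_id = manifest_row$case_id,
    density_image = den, contrast_image = con,
    contour = contour[, c("x", "y")],
    box = c(row0 = 0, col0 = 0, row1 = nrow(den) - 1, col1 = ncol(den) - 1),
    class_label = cls, invasive_flag = inv,
    covariates = cbind(manifest_row[, c("age", "race", "history", "menopause",
                                        "density_category", "bpe")],
                       covs[, c("race_other", "postmenopausal", "dense",
                                "bpe_marked")])
  ), class = "cem_case")
}

#' Read an entire cohort from a manifest
#'
#' @param manifest_path path to the manifest CSV
#' @return list of `cem_case` objects, plus the manifest as an attribute
#' @export
read_cohort <- function(manifest_path) {
  base_dir <- dirname(manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  validate_manifest(manifest, base_dir)
  cases <- lapply(seq_len(nrow(manifest)), function(i)
    read_case(manifest[i, , drop = FALSE], base_dir))
  attr(cases, "manifest") <- manifest
  cases
}
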