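# Text and voxel-image exchange.

#' Write a flow-rate series as delimited text
#'
#' Tab-separated columns `time_s`, `iolet`, `q_m3s` (plus any extra
#' columns present).
#'
#' @param series A series tibble (e.g. `run$series`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_series <- function(series, path) {
  utils::write.table(series, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_series
#' @export
import_series <- function(path) {
  tibble::as_tibble(utils::read.delim(path))
}

#' Export a per-site scalar field as a voxel image
#'
#' Writes a NIfTI volume (spacing metadata set to the lattice dx in mm)
#' with the scalar field scattered onto the full grid, `NA` outside the
#' wet region. Suitable for standard scientific visualisation tools.
#' Requires the suggested RNifti package.
#'
#' @param values Numeric vector over the wet sites (e.g.
#'   `velocity_magnitude()$speed_m_s`), or a field tibble with `i, j, k`
#'   and a final value column.
#' @param domain The `voxel_domain` the field lives on.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
export_field_nifti <- function(values, domain, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort_config("Field export requires the RNifti package.")
  }
  arr <- array(NA_real_, domain$shape)
  if (is.data.frame(values)) {
    lin <- values$i + (values$j - 1L) * domain$shape[1] +
      (values$k - 1L) * domain$shape[1] * domain$shape[2]
    arr[lin] <- values[[ncol(values)]]
  } else {
    wet_lin <- which(domain$labels > 0L)
    arr[wet_lin] <- values
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(domain$dx * 1000, 3)  # mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a voxel label mask as delimited text
#'
#' Plain-text exchange of a classified lattice: a header line
#' `# shape nx ny nz dx origin ox oy oz` followed by one `i j k label
#' iolet` row per non-solid site. Iolet metadata travels separately via
#' the network spec.
#'
#' @param domain A `voxel_domain`.
#' @param path File path.
#' @return `export_voxel_mask()` returns `path` invisibly;
#'   `import_voxel_mask()` a list with `labels`, `iolet_id`, `dx`,
#'   `origin`.
#' @export
export_voxel_mask <- function(domain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# shape %d %d %d dx %.12g origin %.12g %.12g %.12g",
                     domain$shape[1], domain$shape[2], domain$shape[3],
                     domain$dx, domain$origin[1], domain$origin[2],
                     domain$origin[3]), con)
  df <- data.frame(domain$sites, label = domain$labels[domain$labels > 0L],
                   iolet = domain$iolet_of)
  utils::write.table(df, con, sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname export_voxel_mask
#' @export
import_voxel_mask <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), "\\s+")[[1]]
  shape <- as.integer(hdr[3:5])
  dx <- as.numeric(hdr[7])
  origin <- as.numeric(hdr[9:11])
  df <- utils::read.table(path, skip = 1)
  labels <- array(0L, shape)
  iolet <- array(0L, shape)
  lin <- df[[1]] + (df[[2]] - 1L) * shape[1] + (df[[3]] - 1L) * shape[1] * shape[2]
  labels[lin] <- as.integer(df[[4]])
  iolet[lin] <- as.integer(df[[5]])
  list(labels = labels, iolet_id = iolet, dx = dx, origin = origin)
}
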