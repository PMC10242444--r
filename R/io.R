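# TIFF + sidecar I/O for image stacks, and TSV helpers for records.

#' Write an image stack as multi-page TIFF with a YAML sidecar
#'
#' Pages hold the DAPI z-slices first, then the foci z-slices; the sidecar
#' records the pixel size and the channel-to-page map so the file is
#' self-describing. Intensities (arbitrary units on a 16-bit range) are
#' stored as 16-bit samples.
#'
#' @param stack An `irif_stack` (see [generate_area_image()]).
#' @param tiff_path Output TIFF path.
#' @param yaml_path Output sidecar path (default: `tiff_path` with a
#'   `.yml` extension).
#' @return Invisibly, `tiff_path`.
#' @export
write_area_stack <- function(stack, tiff_path,
                             yaml_path = sub("\\.tiff?$", ".yml",
                                             tiff_path)) {
  nz <- dim(stack$dapi)[3]
  # quantize to integer grey levels first: integer / 65535 samples survive
  # the 16-bit encoding exactly
  pages <- c(lapply(seq_len(nz), function(z) round(stack$dapi[, , z]) / 65535),
             lapply(seq_len(nz), function(z) round(stack$foci[, , z]) / 65535))
  pages <- lapply(pages, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = stack$pixel_size_um,
               n_z = nz,
               intensity_scale = 65535,
               channels = list(dapi = list(pages = seq_len(nz)),
                               foci = list(pages = nz + seq_len(nz))))
  yaml::write_yaml(meta, yaml_path)
  invisible(tiff_path)
}

#' Read an image stack written by [write_area_stack()]
#'
#' @param tiff_path TIFF path.
#' @param yaml_path Sidecar path (default derived from `tiff_path`).
#' @return An `irif_stack`.
#' @export
read_area_stack <- function(tiff_path,
                            yaml_path = sub("\\.tiff?$", ".yml",
                                            tiff_path)) {
  meta <- yaml::read_yaml(yaml_path)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  scale <- meta$intensity_scale
  get_channel <- function(ch) {
    ix <- unlist(meta$channels[[ch]]$pages)
    arr <- array(0, dim = c(dim(pages[[1]]), length(ix)))
    for (k in seq_along(ix)) arr[, , k] <- round(pages[[ix[k]]] * scale)
    arr
  }
  structure(list(dapi = get_channel("dapi"),
                 foci = get_channel("foci"),
                 pixel_size_um = meta$pixel_size_um),
            class = "irif_stack")
}

#' Write cell records, focus calls or area summaries as TSV
#'
#' Plain tab-separated output with a header row; list-columns (focus pixel
#' sets) are dropped.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_record_tsv <- function(records, path) {
  keep <- !vapply(records, is.list, logical(1))
  write_records(records[, keep, drop = FALSE], path)
}

#' Read a TSV written by [write_record_tsv()]
#'
#' @param path Input path.
#' @return A data.frame.
#' @export
read_record_tsv <- function(path) {
  read_records(path)
}
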