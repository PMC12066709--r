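# External formats: outline and site CSVs, ratio stacks as per-channel
# multi-page 16-bit TIFF with a JSON sidecar, model configuration as YAML.

#' Write / read grain outlines as CSV
#'
#' Columns `x_um`, `y_um`, `grain_id`; one polygon per grain id.
#'
#' @param outlines a single outline data frame or a list of them (from
#'   [make_grain_outline()]).
#' @param path CSV file path.
#' @return `write_outline_csv`: the path, invisibly.  `read_outline_csv`:
#'   a named list of outline data frames keyed by grain id.
#' @export
write_outline_csv <- function(outlines, path) {
  if (is.data.frame(outlines)) outlines <- list(outlines)
  rows <- lapply(seq_along(outlines), function(i) {
    o <- outlines[[i]]
    id <- attr(o, "grain_id")
    if (is.null(id)) id <- i
    data.frame(x_um = o$x_um, y_um = o$y_um, grain_id = id)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outline_csv
#' @export
read_outline_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df[, c("x_um", "y_um")], df$grain_id), function(o) {
    rownames(o) <- NULL
    o
  })
}

#' Write / read a site table as CSV
#'
#' @param sites site-record data frame (see [validate_site_record()]).
#' @param path CSV file path.
#' @return the path (write) or the validated data frame (read).
#' @export
write_site_csv <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_csv
#' @export
read_site_csv <- function(path) {
  tbl <- utils::read.csv(path)
  for (i in seq_len(nrow(tbl))) validate_site_record(tbl[i, , drop = FALSE])
  tbl
}

#' Write / read a two-channel ratio stack
#'
#' Each channel is stored as a multi-page 16-bit TIFF; frame times (hours)
#' and the pixel size (um) go to a JSON sidecar.  Intensities are scaled
#' by a stored factor to use the 16-bit range.
#'
#' @param stack a ratio stack (see [make_ratio_series()]).
#' @param prefix path prefix; writes `<prefix>_red.tif`,
#'   `<prefix>_green.tif` and `<prefix>_meta.json`.
#' @return the prefix (write) or the reconstructed stack (read).
#' @export
write_ratio_stack <- function(stack, prefix) {
  reds <- lapply(stack$frames, `[[`, "red")
  greens <- lapply(stack$frames, `[[`, "green")
  peak <- max(unlist(lapply(c(reds, greens), max)), 1e-12)
  scale <- 65535 / peak
  to16 <- function(m) clamp(m * scale, 0, 65535) / 65535  # tiff wants [0,1]
  tiff::writeTIFF(lapply(reds, to16), paste0(prefix, "_red.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(lapply(greens, to16), paste0(prefix, "_green.tif"),
                  bits.per.sample = 16)
  meta <- list(frame_times_h = vapply(stack$frames, `[[`, 0, "time_h"),
               pixel_size_um = stack$pixel_size_um,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_ratio_stack
#' @export
read_ratio_stack <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  reds <- tiff::readTIFF(paste0(prefix, "_red.tif"), all = TRUE)
  greens <- tiff::readTIFF(paste0(prefix, "_green.tif"), all = TRUE)
  unscale <- 65535 / meta$intensity_scale
  frames <- lapply(seq_along(reds), function(k)
    list(time_h = meta$frame_times_h[k],
         red = reds[[k]] * unscale, green = greens[[k]] * unscale))
  list(frames = frames, pixel_size_um = meta$pixel_size_um)
}

#' Write / read a grain model configuration as YAML
#'
#' Field names and units mirror [grain_model_config()].
#'
#' @param cfg a [grain_model_config()].
#' @param path YAML file path.
#' @return the path (write) or a validated config (read).
#' @export
write_grain_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "grain_model_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_grain_config
#' @export
read_grain_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(grain_model_config, vals)
}
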