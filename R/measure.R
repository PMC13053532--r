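#' Measure texture metrics on image files
#'
#' Reads each image, crops its ROI and computes the paired non-zoomed /
#' zoomed metric bundles. ROIs follow the package's 0-based half-open
#' convention and can be given as `"row0,col0,height,width"` strings (the
#' CLI form) or as [roi_rect] objects; `NULL` uses each full image.
#'
#' @param paths character vector of image files (DICOM/PNG/TIFF).
#' @param rois `NULL`, a single ROI, or a list of ROIs (recycled rules: one
#'   per image).
#' @param zoom_factor,kernel digital-zoom settings for the zoomed bundle.
#' @param power_p,power_scale,log_base index settings.
#' @return Data frame, one row per image, with the six metric values.
#' @export
measure_images <- function(paths, rois = NULL, zoom_factor = 1.25,
                           kernel = "bilinear", power_p = 2,
                           power_scale = 10, log_base = exp(1)) {
  parse_roi <- function(x) {
    if (is.null(x) || inherits(x, "roi_rect")) return(x)
    v <- as.integer(strsplit(as.character(x), ",")[[1]])
    if (length(v) != 4L || anyNA(v))
      stop("ROI must be 'row0,col0,height,width'", call. = FALSE)
    roi_rect(v[1], v[2], v[3], v[4])
  }
  if (!is.null(rois) && !is.list(rois)) rois <- list(rois)
  if (!is.null(rois) && length(rois) == 1L)
    rois <- rep(rois, length(paths))
  if (!is.null(rois) && length(rois) != length(paths))
    stop("need one ROI per image (or a single shared ROI)", call. = FALSE)
  rows <- lapply(seq_along(paths), function(i) {
    img <- read_image(paths[i])
    rect <- if (is.null(rois)) NULL else parse_roi(rois[[i]])
    roi <- if (is.null(rect)) img else crop_roi(img, rect)
    b <- metrics_bundle(roi, zoom_factor = zoom_factor, kernel = kernel,
                        power_p = power_p, power_scale = power_scale,
                        log_base = log_base)
    data.frame(path = paths[i],
               xpar_non_zoomed = b$non_zoomed$xpar,
               power_xpar_non_zoomed = b$non_zoomed$power_xpar,
               pixel_count_non_zoomed = b$non_zoomed$pixel_count,
               xpar_zoomed = b$zoomed$xpar,
               power_xpar_zoomed = b$zoomed$power_xpar,
               pixel_count_zoomed = b$zoomed$pixel_count,
               zoom_factor = zoom_factor, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
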