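#' Imaging pipeline configuration
#'
#' @param crop_rows pixels removed from the bottom edge to discard the
#'   instrument databar (default 65)
#' @param base_diameter_px expected particle diameter in pixels, used to
#'   set the minimum seed separation of the watershed backend (default 30)
#' @param min_area_px instances smaller than this many pixels are dropped
#'   as sub-resolution specks (default 9)
#' @param backend segmentation backend name or function; see
#'   [segment_instances()]
#' @return an `imaging_config` list
#' @export
imaging_config <- function(crop_rows = 65, base_diameter_px = 30,
                           min_area_px = 9, backend = "watershed") {
  if (crop_rows < 0) stop_cap("crop_rows must be >= 0")
  if (base_diameter_px <= 0) stop_cap("base_diameter_px must be > 0")
  structure(list(crop_rows = crop_rows,
                 base_diameter_px = base_diameter_px,
                 min_area_px = min_area_px, backend = backend),
            class = "imaging_config")
}

#' Remove the instrument databar from the bottom of a micrograph
#'
#' @param img a [micrograph]
#' @param crop_rows rows to remove from the bottom edge
#' @return the cropped [micrograph]; metadata preserved except
#'   `databar_height`, which is reduced by the rows removed
#' @export
crop_databar <- function(img, crop_rows = 65) {
  stopifnot(inherits(img, "micrograph"))
  H <- nrow(img$data)
  if (crop_rows >= H) {
    stop_cap("crop_rows (", crop_rows, ") must be smaller than the image height (", H, ")")
  }
  if (crop_rows == 0) return(img)
  out <- img
  out$data <- img$data[seq_len(H - crop_rows), , drop = FALSE]
  out$databar_height <- max(0L, img$databar_height - crop_rows)
  out
}

#' Min-max contrast normalization to the 0-255 range
#'
#' Affine rescaling of intensities so the output spans exactly 0-255
#' (8-bit). A constant image cannot be rescaled and maps to all zeros with
#' a warning.
#'
#' @param img a [micrograph]
#' @return an 8-bit [micrograph] with min 0 and max 255
#' @export
normalize_contrast <- function(img) {
  stopifnot(inherits(img, "micrograph"))
  x <- img$data
  if (length(x) == 0) stop_cap("empty image")
  lo <- min(x); hi <- max(x)
  out <- img
  if (hi == lo) {
    warning("constant image: normalized to all zeros", call. = FALSE)
    out$data <- matrix(0L, nrow(x), ncol(x))
  } else {
    out$data <- matrix(as.integer(round((x - lo) / (hi - lo) * 255)),
                       nrow(x), ncol(x))
  }
  out$bit_depth <- 8
  out
}

#' Default classical segmentation backend
#'
#' Otsu threshold, hole filling, Euclidean distance transform, seed
#' detection at distance-map maxima with a minimum separation of
#' `base_diameter_px / 2` (closer maxima merge into one seed), and
#' seeded watershed. Touching particles with distinct distance maxima
#' are split; heavily fused agglomerates may legitimately remain
#' unsplit. Foreground components that receive no seed (sub-resolution
#' slivers) are labeled whole.
#'
#' @param data intensity matrix (0-255)
#' @param config an [imaging_config]
#' @return integer label matrix (0 = background)
#' @export
watershed_backend <- function(data, config) {
  x <- data / 255
  thr <- EBImage::otsu(EBImage::Image(x))
  bw <- x > thr
  if (!any(bw)) return(matrix(0L, nrow(data), ncol(data)))
  bw <- EBImage::fillHull(bw)
  dm <- EBImage::imageData(EBImage::distmap(bw))
  sep <- max(3L, round(config$base_diameter_px / 2))
  dil <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(dm), EBImage::makeBrush(2L * sep + 1L, "disc")))
  seeds_mask <- bw & (dm >= dil - 1e-9) & (dm > 1)
  # plateau maxima closer than `sep` become one seed
  seeds_lab <- EBImage::bwlabel(
    EBImage::dilate(EBImage::Image(seeds_mask),
                    EBImage::makeBrush(sep + (1L - sep %% 2L), "disc")))
  seeds_lab <- EBImage::imageData(seeds_lab) * seeds_mask
  m <- EBImage::imageData(
    EBImage::propagate(EBImage::Image(x), seeds = EBImage::Image(seeds_lab),
                       mask = bw))
  storage.mode(m) <- "integer"
  # components the seeding missed keep their own labels
  comp <- EBImage::imageData(EBImage::bwlabel(bw))
  missed <- setdiff(unique(comp[bw & m == 0]), 0)
  if (length(missed)) {
    base <- max(m)
    sel <- comp %in% missed & m == 0
    m[sel] <- base + match(comp[sel], missed)
  }
  m
}

#' Segment particle instances in a cropped, normalized micrograph
#'
#' The segmentation model is an injectable contract: any function mapping
#' an intensity matrix and config to an integer label mask can stand in
#' (the study-grade deep-learning model, or the classical
#' [watershed_backend()] default). Instances smaller than
#' `config$min_area_px` are dropped and labels compacted to `1..K`.
#'
#' @param img a [micrograph], already cropped and normalized
#' @param config an [imaging_config]
#' @param backend overrides `config$backend`; a backend name
#'   (`"watershed"`) or a `function(data, config)` returning a label matrix
#' @return integer label matrix, same shape as the image content
#' @export
segment_instances <- function(img, config = imaging_config(),
                              backend = NULL) {
  stopifnot(inherits(img, "micrograph"))
  be <- backend %||% config$backend
  if (is.character(be)) {
    be_name <- be
    be <- switch(be,
                 watershed = watershed_backend,
                 stop_cap("unknown segmentation backend: ", be))
  } else {
    be_name <- "custom"
  }
  mask <- tryCatch(be(img$data, config), error = function(e) {
    stop_cap("segmentation backend '", be_name, "' failed: ",
             conditionMessage(e))
  })
  if (!identical(dim(mask), dim(img$data))) {
    stop_cap("segmentation backend '", be_name,
             "' returned a mask of the wrong shape")
  }
  compact_labels(drop_small_instances(mask, config$min_area_px))
}

drop_small_instances <- function(mask, min_area_px) {
  if (min_area_px <= 1) return(mask)
  tab <- tabulate(mask[mask > 0])
  small <- which(tab > 0 & tab < min_area_px)
  if (length(small)) mask[mask %in% small] <- 0L
  mask
}

compact_labels <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs)) return(matrix(0L, nrow(mask), ncol(mask)))
  lut <- integer(max(labs))
  lut[labs] <- seq_along(labs)
  out <- mask
  out[out > 0] <- lut[out[out > 0]]
  storage.mode(out) <- "integer"
  out
}

#' Flag instances intersecting the image boundary
#'
#' Any instance with at least one pixel in the first/last row or
#' first/last column of the content region is excluded (`border`), since a
#' truncated particle would bias the diameter downward.
#'
#' @param mask integer label matrix
#' @return data frame with columns `label`, `excluded_reason`
#'   (`"none"` or `"border"`)
#' @export
exclude_border_particles <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs)) {
    return(data.frame(label = integer(0), excluded_reason = character(0)))
  }
  edge <- unique(c(mask[1, ], mask[nrow(mask), ], mask[, 1], mask[, ncol(mask)]))
  edge <- edge[edge > 0]
  data.frame(label = labs,
             excluded_reason = ifelse(labs %in% edge, "border", "none"))
}

#' Physical calibration from the scale bar
#'
#' @param scalebar_px scale-bar length in pixels
#' @param scalebar_um scale-bar physical length in micrometers
#' @return a `scale` object with `um_per_px = scalebar_um / scalebar_px`
#' @export
calibrate_scale <- function(scalebar_px, scalebar_um) {
  if (scalebar_px <= 0 || scalebar_um <= 0) {
    stop_cap("scale-bar lengths must be positive")
  }
  structure(list(um_per_px = scalebar_um / scalebar_px), class = "scale")
}

# outer boundary pixels of one label, given its pixel coordinates:
# label pixels with a 4-neighbor outside the label (or the image)
label_boundary <- function(coords) {
  r0 <- min(coords[, 1]); r1 <- max(coords[, 1])
  c0 <- min(coords[, 2]); c1 <- max(coords[, 2])
  h <- r1 - r0 + 1L; w <- c1 - c0 + 1L
  sub <- matrix(FALSE, h, w)
  sub[cbind(coords[, 1] - r0 + 1L, coords[, 2] - c0 + 1L)] <- TRUE
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- sub
  core <- pad[2:(h + 1), 2:(w + 1)]
  interior <- core &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  b <- which(core & !interior, arr.ind = TRUE)
  cbind(row = b[, 1] + r0 - 1, col = b[, 2] + c0 - 1)
}

#' Measure particle diameters from a label mask
#'
#' For every instance, the outer boundary pixel centers are extracted and
#' the minimum enclosing circle fitted; `diameter_px` is twice its radius
#' and `diameter_um = diameter_px * um_per_px`. Border-excluded instances
#' are kept in the table with their exclusion reason and no physical
#' diameter.
#'
#' @param mask integer label matrix
#' @param scale a `scale` from [calibrate_scale()]
#' @param config an [imaging_config]
#' @return a `particle_table` data frame: `label`, `area_px`,
#'   `center_row`, `center_col`, `diameter_px`, `diameter_um`,
#'   `excluded_reason`; contours are attached as the `"contours"`
#'   attribute (list of point matrices, indexed by label)
#' @export
measure_particles <- function(mask, scale, config = imaging_config()) {
  stopifnot(inherits(scale, "scale"))
  excl <- exclude_border_particles(mask)
  n <- nrow(excl)
  out <- data.frame(label = excl$label,
                    area_px = rep(NA_integer_, n),
                    center_row = rep(NA_real_, n),
                    center_col = rep(NA_real_, n),
                    diameter_px = rep(NA_real_, n),
                    diameter_um = rep(NA_real_, n),
                    excluded_reason = excl$excluded_reason)
  contours <- vector("list", n)
  if (n == 0) {
    attr(out, "contours") <- contours
    class(out) <- c("particle_table", class(out))
    return(out)
  }
  pos <- which(mask > 0)
  rc <- arrayInd(pos, dim(mask))
  coords_by_label <- split.data.frame(rc, mask[pos])
  for (i in seq_len(n)) {
    lab <- excl$label[i]
    coords <- coords_by_label[[as.character(lab)]]
    out$area_px[i] <- nrow(coords)
    contour <- label_boundary(coords)
    contours[[i]] <- contour
    circ <- min_enclosing_circle(contour)
    out$center_row[i] <- circ$center[1]
    out$center_col[i] <- circ$center[2]
    out$diameter_px[i] <- 2 * circ$radius
    if (out$excluded_reason[i] == "none") {
      out$diameter_um[i] <- out$diameter_px[i] * scale$um_per_px
    }
  }
  attr(out, "contours") <- contours
  attr(out, "um_per_px") <- scale$um_per_px
  class(out) <- c("particle_table", class(out))
  out
}

#' Summarize a particle table into size-distribution descriptors
#'
#' Retained particles only. Mean and SD use the sample (n-1) convention;
#' D10/D50/D90 are linear-interpolation percentiles; the histogram uses
#' 0.5 um bins starting at 0.
#'
#' @param table a `particle_table` from [measure_particles()]
#' @param bin_width_um histogram bin width (default 0.5)
#' @return a `size_summary` list: `valid_n`, `mean_um`, `sd_um`, `d10_um`,
#'   `d50_um`, `d90_um`, `histogram` (data frame of bin edges and counts)
#' @export
summarize_sizes <- function(table, bin_width_um = 0.5) {
  d <- table$diameter_um[table$excluded_reason == "none"]
  d <- d[!is.na(d)]
  if (!length(d)) stop_cap("no retained particles: size summary is undefined")
  qs <- stats::quantile(d, c(0.1, 0.5, 0.9), type = 7, names = FALSE)
  edges <- seq(0, (floor(max(d) / bin_width_um) + 1) * bin_width_um,
               by = bin_width_um)
  counts <- graphics::hist(d, breaks = edges, plot = FALSE, right = FALSE)$counts
  structure(list(
    valid_n = length(d),
    mean_um = mean(d),
    sd_um = stats::sd(d),
    d10_um = qs[1], d50_um = qs[2], d90_um = qs[3],
    histogram = data.frame(bin_lo_um = edges[-length(edges)],
                           bin_hi_um = edges[-1],
                           count = counts)
  ), class = "size_summary")
}

#' @export
print.size_summary <- function(x, ...) {
  cat(sprintf("<size_summary> valid N = %d | %.2f +/- %.2f um | D10 %.2f, D50 %.2f, D90 %.2f um\n",
              x$valid_n, x$mean_um, x$sd_um, x$d10_um, x$d50_um, x$d90_um))
  invisible(x)
}

#' Overlay a label mask on a micrograph
#'
#' Background pixels keep the grayscale intensity; each instance is tinted
#' with a deterministic per-label hue at fixed alpha, for visual
#' verification of segmentation and border exclusion.
#'
#' @param img a [micrograph]
#' @param mask integer label matrix of the same shape
#' @param alpha tint opacity in `[0, 1]`
#' @return an `height x width x 3` numeric array in `[0, 1]`
#' @export
render_overlay <- function(img, mask, alpha = 0.4) {
  stopifnot(inherits(img, "micrograph"))
  if (!identical(dim(img$data), dim(mask))) {
    stop_cap("image and mask dimensions differ")
  }
  g <- img$data / (2^img$bit_depth - 1)
  out <- array(g, c(dim(g), 3))
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs)) {
    hues <- ((labs - 1) * 0.61803398875) %% 1  # golden-ratio palette
    cols <- grDevices::hsv(hues, 0.9, 1)
    rgb <- grDevices::col2rgb(cols) / 255
    for (i in seq_along(labs)) {
      sel <- mask == labs[i]
      for (ch in 1:3) {
        plane <- out[, , ch]
        plane[sel] <- (1 - alpha) * plane[sel] + alpha * rgb[ch, i]
        out[, , ch] <- plane
      }
    }
  }
  out
}

#' Size particles in one micrograph, end to end
#'
#' Convenience wrapper chaining [crop_databar()], [normalize_contrast()],
#' [segment_instances()], [measure_particles()] and [summarize_sizes()]
#' with the calibration taken from the micrograph metadata.
#'
#' @param img a [micrograph] (databar still attached)
#' @param config an [imaging_config]
#' @param backend optional backend override
#' @return list with `table` (particle table), `summary` (size summary),
#'   `mask` (label matrix), `scale`
#' @export
size_particles <- function(img, config = imaging_config(), backend = NULL) {
  cropped <- crop_databar(img, config$crop_rows)
  norm <- normalize_contrast(cropped)
  mask <- segment_instances(norm, config, backend)
  scale <- calibrate_scale(img$scalebar_px, img$scalebar_um)
  table <- measure_particles(mask, scale, config)
  summary <- if (any(table$excluded_reason == "none")) {
    summarize_sizes(table)
  } else NULL
  list(table = table, summary = summary, mask = mask, scale = scale)
}
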