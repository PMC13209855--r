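#' Parameters for the SEM-style micrograph simulator
#'
#' Describes the synthetic imaging conditions: content-region geometry, the
#' instrument databar strip, the scale-bar calibration, and the particle
#' population. Particle diameters are drawn from a log-normal distribution
#' parameterized by its median (micrometers) and log-scale SD, the shape
#' spray-dried microcapsule populations show (unimodal, right-skewed, with
#' a long tail of large granules).
#'
#' @param image_width,image_height content-region size in pixels
#'   (excluding the databar)
#' @param databar_height databar strip height in pixels
#' @param scalebar_px,scalebar_um scale-bar length in pixels and micrometers
#' @param n_particles number of particles to place
#' @param median_um median of the log-normal diameter distribution (um)
#' @param sigma_log SD of log-diameter
#' @param allow_border if `FALSE`, particles are placed fully inside the
#'   content region; if `TRUE`, centers are uniform over the region and
#'   disks may cross the boundary
#' @param max_overlap_fraction maximum allowed pairwise overlap, as a
#'   fraction of the smaller disk's area, in `[0, 1)`
#' @param min_gap_px minimum edge-to-edge gap (pixels) enforced between
#'   disks when `max_overlap_fraction` is 0, so disjoint disks stay
#'   separable at pixel resolution (rendered disks occupy every pixel
#'   whose center lies inside them, so two disks closer than ~2 px can
#'   share adjacent pixels and fuse into one connected component)
#' @param background_level,particle_level background and particle-center
#'   intensities (0-255)
#' @param noise_sd additive Gaussian noise SD in intensity units
#' @param seed integer seed; the simulator is a pure function of
#'   parameters and seed
#' @return a `micrograph_sim_params` list
#' @export
micrograph_sim_params <- function(image_width = 1024, image_height = 1024,
                                  databar_height = 65,
                                  scalebar_px = 229, scalebar_um = 20,
                                  n_particles = 300,
                                  median_um = 3.7, sigma_log = 0.45,
                                  allow_border = FALSE,
                                  max_overlap_fraction = 0,
                                  min_gap_px = 2,
                                  background_level = 30,
                                  particle_level = 200,
                                  noise_sd = 6, seed = 1) {
  p <- list(image_width = image_width, image_height = image_height,
            databar_height = databar_height,
            scalebar_px = scalebar_px, scalebar_um = scalebar_um,
            n_particles = n_particles,
            median_um = median_um, sigma_log = sigma_log,
            allow_border = allow_border,
            max_overlap_fraction = max_overlap_fraction,
            min_gap_px = min_gap_px,
            background_level = background_level,
            particle_level = particle_level,
            noise_sd = noise_sd, seed = seed)
  if (p$image_width <= 0 || p$image_height <= 0 || p$databar_height < 0 ||
      p$scalebar_px <= 0 || p$scalebar_um <= 0) {
    stop_cap("pixel dimensions and scale-bar lengths must be positive")
  }
  if (p$noise_sd < 0) stop_cap("noise_sd must be >= 0")
  if (p$max_overlap_fraction < 0 || p$max_overlap_fraction >= 1) {
    stop_cap("max_overlap_fraction must be in [0, 1)")
  }
  if (p$min_gap_px < 0) stop_cap("min_gap_px must be >= 0")
  if (p$median_um <= 0 || p$sigma_log < 0) {
    stop_cap("diameter distribution needs median > 0 and sigma_log >= 0")
  }
  if (p$n_particles < 0) stop_cap("n_particles must be >= 0")
  structure(p, class = "micrograph_sim_params")
}

# area of the lens of intersection of two circles at center distance d
circle_overlap_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - a3
}

#' Simulate an SEM-style micrograph with known ground truth
#'
#' Renders shaded disks (brighter center, linear radial falloff, mimicking
#' secondary-electron contrast on spherical particles) on a uniform
#' background, adds Gaussian noise, and appends a solid databar strip
#' carrying a white scale bar of exactly `scalebar_px` pixels. Particle
#' positions are drawn by rejection sampling under the pairwise overlap
#' constraint. Identical parameters and seed give an identical image and
#' truth table.
#'
#' @param params a [micrograph_sim_params] object
#' @return a list with elements
#'   \item{image}{a [micrograph] of size
#'     `(image_height + databar_height) x image_width`}
#'   \item{truth}{data frame with one row per rendered particle: `id`,
#'     `row`, `col` (center, pixels), `diameter_um`, `diameter_px`,
#'     `touches_border`, `fully_visible` (interior and non-overlapped)}
#' @export
simulate_micrograph <- function(params) {
  stopifnot(inherits(params, "micrograph_sim_params"))
  p <- params
  H <- p$image_height; W <- p$image_width
  um_per_px <- p$scalebar_um / p$scalebar_px

  truth <- with_seed(p$seed, {
    rows <- numeric(0); cols <- numeric(0); rad <- numeric(0)
    if (p$n_particles > 0) {
      for (i in seq_len(p$n_particles)) {
        d_um <- stats::rlnorm(1, log(p$median_um), p$sigma_log)
        r <- d_um / um_per_px / 2
        placed <- FALSE
        for (attempt in seq_len(3000L)) {
          if (p$allow_border) {
            rr <- stats::runif(1, 1, H); cc <- stats::runif(1, 1, W)
          } else {
            if (2 * r + 2 > min(H, W)) next  # cannot fit fully inside
            rr <- stats::runif(1, r + 1, H - r)
            cc <- stats::runif(1, r + 1, W - r)
          }
          if (length(rows)) {
            d <- sqrt((rows - rr)^2 + (cols - cc)^2)
            if (p$max_overlap_fraction == 0) {
              if (any(d < rad + r + p$min_gap_px)) next
            } else {
              ov <- mapply(circle_overlap_area, rad, r, d)
              amin <- pi * pmin(rad, r)^2
              if (any(ov > p$max_overlap_fraction * amin)) next
            }
          }
          rows <- c(rows, rr); cols <- c(cols, cc); rad <- c(rad, r)
          placed <- TRUE
          break
        }
        if (!placed) {
          stop_cap("could not place particle ", i, " of ", p$n_particles,
                   " under the overlap constraint (", i - 1L, " placed); ",
                   "reduce n_particles or enlarge the image")
        }
      }
    }
    list(rows = rows, cols = cols, rad = rad)
  })

  rows <- truth$rows; cols <- truth$cols; rad <- truth$rad
  n <- length(rows)

  img <- matrix(as.numeric(p$background_level), H, W)
  for (i in seq_len(n)) {
    r <- rad[i]
    r0 <- max(1L, floor(rows[i] - r)); r1 <- min(H, ceiling(rows[i] + r))
    c0 <- max(1L, floor(cols[i] - r)); c1 <- min(W, ceiling(cols[i] + r))
    if (r0 > r1 || c0 > c1) next
    rs <- r0:r1; cs <- c0:c1
    rho <- sqrt(outer((rs - rows[i])^2, (cs - cols[i])^2, "+"))
    shade <- p$background_level +
      (p$particle_level - p$background_level) * (1 - 0.4 * rho / r)
    shade[rho > r] <- -Inf
    img[rs, cs] <- pmax(img[rs, cs], shade)
  }

  if (p$noise_sd > 0) {
    img <- img + with_seed(p$seed + 1L,
                           stats::rnorm(H * W, 0, p$noise_sd))
  }
  img <- matrix(pmin(pmax(round(img), 0), 255), H, W)

  if (p$databar_height > 0) {
    bar <- matrix(70, p$databar_height, W)
    if (p$scalebar_px <= W) {
      sb_rows <- max(1L, round(p$databar_height / 2) - 2L):
        min(p$databar_height, round(p$databar_height / 2) + 2L)
      sb_cols <- 20L:(20L + p$scalebar_px - 1L)
      sb_cols <- sb_cols[sb_cols <= W]
      bar[sb_rows, sb_cols] <- 255
    }
    img <- rbind(img, bar)
  }

  # a disk owns a pixel center in the outermost rows/columns iff its
  # extent reaches within 1 px of them; this matches the border-exclusion
  # rule applied to the rendered mask
  touches <- (rows - rad) <= 1 | (rows + rad) >= H |
    (cols - rad) <= 1 | (cols + rad) >= W
  overlapped <- rep(FALSE, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      d <- sqrt((rows[(i + 1):n] - rows[i])^2 + (cols[(i + 1):n] - cols[i])^2)
      hit <- d < rad[(i + 1):n] + rad[i]
      overlapped[i] <- overlapped[i] || any(hit)
      overlapped[(i + 1):n][hit] <- TRUE
    }
  }

  list(
    image = micrograph(img, bit_depth = 8,
                       databar_height = p$databar_height,
                       scalebar_px = p$scalebar_px,
                       scalebar_um = p$scalebar_um),
    truth = data.frame(
      id = seq_len(n),
      row = rows, col = cols,
      diameter_um = 2 * rad * um_per_px,
      diameter_px = 2 * rad,
      touches_border = touches,
      fully_visible = !touches & !overlapped
    )
  )
}

#' Write a ground-truth table as CSV
#'
#' @param truth truth data frame from [simulate_micrograph()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(
    truth[, c("id", "row", "col", "diameter_um", "touches_border")],
    path, row.names = FALSE)
  invisible(path)
}

#' Simulate replicate bench-assay measurements
#'
#' Draws `n_replicates` values per formulation from
#' `Normal(true_mean, replicate_sd)`, emulating independent analytical
#' replicates from a single production batch.
#'
#' @param params data frame with columns `formulation`, `true_mean`,
#'   `replicate_sd` and optionally `n_replicates` (default 3)
#' @param seed integer seed
#' @return data frame with columns `formulation`, `replicate`, `value`
#' @export
simulate_assay_replicates <- function(params, seed = 1) {
  stopifnot(is.data.frame(params),
            all(c("formulation", "true_mean", "replicate_sd") %in% names(params)))
  if (nrow(params) < 1) stop_cap("at least one formulation is required")
  if (is.null(params$n_replicates)) params$n_replicates <- 3L
  if (any(params$replicate_sd < 0)) stop_cap("replicate_sd must be >= 0")
  if (any(params$n_replicates < 2)) stop_cap("n_replicates must be >= 2")
  with_seed(seed, {
    out <- lapply(seq_len(nrow(params)), function(i) {
      n <- params$n_replicates[i]
      data.frame(formulation = params$formulation[i],
                 replicate = seq_len(n),
                 value = stats::rnorm(n, params$true_mean[i],
                                      params$replicate_sd[i]))
    })
    do.call(rbind, out)
  })
}

#' Simulate chromatographic peak areas from a calibration line
#'
#' Generates `area = slope * amount + intercept + Normal(0, noise_sd)` for
#' each injected amount, with retention times jittered around the
#' reference. With `noise_sd = 0` the areas lie exactly on the line, so
#' [quantify_injection()] recovers the amounts exactly.
#'
#' @param amounts_ng injected amounts (ng/injection), all `>= 0`
#' @param curve a [calibration_curve] (or any list with `slope` and
#'   `intercept`)
#' @param noise_sd additive area noise SD
#' @param seed integer seed
#' @param reference_rt reference retention time (min)
#' @param rt_jitter_sd SD of retention-time jitter (min)
#' @return data frame with columns `retention_time`, `area`, `amount_true`
#' @export
simulate_peak_areas <- function(amounts_ng, curve, noise_sd = 0, seed = 1,
                                reference_rt = 3.85, rt_jitter_sd = 0.01) {
  if (any(amounts_ng < 0)) stop_cap("amounts must be >= 0")
  with_seed(seed, {
    n <- length(amounts_ng)
    area <- curve$slope * amounts_ng + curve$intercept
    if (noise_sd > 0) area <- area + stats::rnorm(n, 0, noise_sd)
    rt <- reference_rt + if (rt_jitter_sd > 0) {
      stats::rnorm(n, 0, rt_jitter_sd)
    } else 0
    data.frame(retention_time = rt, area = area, amount_true = amounts_ng)
  })
}
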