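#' Minimum enclosing circle of a point set
#'
#' Exact smallest circle containing all input points, by the randomized
#' incremental (move-to-front) construction: expected linear time, with a
#' deterministic internal shuffle so a fixed point set always yields the
#' same circle. Used to recover the diameter of spherical particles from
#' segmented contours, where it compensates for minor lateral occlusion
#' (the visible arc still pins down the full circle).
#'
#' @param points numeric matrix or data frame with two columns
#'   (row, col) — at least one point
#' @return list of class `circle` with `center` (length-2 numeric,
#'   row/col) and `radius`; every input point lies within
#'   `radius * (1 + 1e-7)` of the center
#' @export
min_enclosing_circle <- function(points) {
  pts <- as.matrix(points)
  if (length(pts) == 0 || nrow(pts) == 0) {
    stop_cap("min_enclosing_circle needs at least one point")
  }
  if (ncol(pts) != 2) stop_cap("points must have two columns (row, col)")
  storage.mode(pts) <- "double"
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 1) {
    return(structure(list(center = pts[1, ], radius = 0), class = "circle"))
  }
  pts <- pts[.det_shuffle(n), , drop = FALSE]

  eps <- 1e-10
  inside <- function(circ, p) {
    sqrt(sum((p - circ$center)^2)) <= circ$radius * (1 + 1e-7) + eps
  }
  circ2 <- function(a, b) {
    ctr <- (a + b) / 2
    list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
  }
  circ3 <- function(a, b, c) {
    # circumcircle; collinear points fall back to the widest pair diameter
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) {
      cand <- list(circ2(a, b), circ2(a, c), circ2(b, c))
      r <- vapply(cand, `[[`, numeric(1), "radius")
      return(cand[[which.max(r)]])
    }
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
             sum(c^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
             sum(c^2) * (b[1] - a[1])) / d
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
  }

  circ <- circ2(pts[1, ], pts[2, ])
  if (n > 2) {
    for (i in 3:n) {
      pi_ <- pts[i, ]
      if (inside(circ, pi_)) next
      # pi_ is on the boundary of the new circle
      circ <- circ2(pts[1, ], pi_)
      for (j in 2:(i - 1)) {
        pj <- pts[j, ]
        if (inside(circ, pj)) next
        circ <- circ2(pi_, pj)
        if (j > 1) {
          for (k in seq_len(j - 1)) {
            pk <- pts[k, ]
            if (inside(circ, pk)) next
            circ <- circ3(pi_, pj, pk)
          }
        }
      }
    }
  }
  structure(circ, class = "circle")
}

# Deterministic permutation of 1..n via a fixed linear congruential stream;
# keeps the geometry independent of the global RNG state.
.det_shuffle <- function(n) {
  x <- 48271
  keys <- numeric(n)
  for (i in seq_len(n)) {
    x <- (1103515245 * (x %% 65536) + 12345) %% 2147483648
    keys[i] <- x
  }
  order(keys)
}

#' @export
print.circle <- function(x, ...) {
  cat(sprintf("<circle> center (%.3f, %.3f), radius %.4f\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}
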