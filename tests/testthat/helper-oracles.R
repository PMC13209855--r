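# Independent oracles and fixture builders used across the suite.

# Brute-force minimum enclosing circle: the optimal circle is determined
# either by two points (diametral) or by three points (circumcircle);
# enumerate all of them and keep the smallest that covers the set.
brute_force_mec <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n == 1) return(list(center = pts[1, ], radius = 0))
  covers <- function(ctr, r) all(sqrt(colSums((t(pts) - ctr)^2)) <= r + 1e-9)
  best <- NULL
  consider <- function(ctr, r) {
    if (covers(ctr, r) && (is.null(best) || r < best$radius)) {
      best <<- list(center = ctr, radius = r)
    }
  }
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ctr <- (pts[i, ] + pts[j, ]) / 2
      consider(ctr, sqrt(sum((pts[i, ] - ctr)^2)))
    }
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
      d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
               sum(c^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
               sum(c^2) * (b[1] - a[1])) / d
      ctr <- c(ux, uy)
      consider(ctr, sqrt(sum((a - ctr)^2)))
    }
  }
  best
}

# Lens (intersection) area of two circles, for building overlap fixtures.
lens_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
    r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
    0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
}

# Center distance at which circle r2 hides `frac` of circle r1's area.
distance_for_overlap <- function(r1, r2, frac) {
  stats::uniroot(function(d) lens_area(r1, r2, d) - frac * pi * r1^2,
                 c(abs(r1 - r2) + 1e-9, r1 + r2 - 1e-9))$root
}

# Paint a disk into an integer matrix (pixel centers within radius).
paint_disk <- function(m, row, col, radius, value) {
  rs <- max(1, floor(row - radius)):min(nrow(m), ceiling(row + radius))
  cs <- max(1, floor(col - radius)):min(ncol(m), ceiling(col + radius))
  rho2 <- outer((rs - row)^2, (cs - col)^2, "+")
  sub <- m[rs, cs, drop = FALSE]
  sub[rho2 <= radius^2] <- value
  m[rs, cs] <- sub
  m
}

# Summary-form group data from a packaged study table.
study_groups <- function(table, mean_col, sd_col) {
  tb <- study_table(table)
  group_data(data.frame(label = tb$formulation, mean = tb[[mean_col]],
                        sd = tb[[sd_col]], n = tb$n))
}

# Replicates with exact sample mean and SD (for summary/raw equivalence).
exact_replicates <- function(mean, sd, n) {
  v <- scale(seq_len(n))[, 1]
  mean + sd * v / stats::sd(v)
}
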