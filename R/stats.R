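#' Group data for one-way comparisons
#'
#' Raw form: a named list of replicate vectors. Summary form: a data
#' frame with columns `label`, `mean`, `sd`, `n` — the form printed in
#' bench reports (mean +/- SD with n = 3), accepted as a first-class
#' input because raw replicates are often unavailable.
#'
#' @param x named list of numeric vectors, or a summary data frame
#' @return a `group_data` object
#' @export
group_data <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("label", "mean", "sd", "n") %in% names(x)))
    if (nrow(x) < 2) stop_cap("need at least two groups")
    if (any(x$n < 2)) stop_cap("each group needs n >= 2")
    if (any(x$sd < 0)) stop_cap("sd cannot be negative")
    structure(list(raw = NULL, summary = x[, c("label", "mean", "sd", "n")]),
              class = "group_data")
  } else if (is.list(x)) {
    if (is.null(names(x)) || any(names(x) == "")) {
      stop_cap("raw groups must be a named list")
    }
    if (length(x) < 2) stop_cap("need at least two groups")
    if (any(lengths(x) < 2)) stop_cap("each group needs n >= 2")
    smry <- data.frame(
      label = names(x),
      mean = vapply(x, mean, numeric(1)),
      sd = vapply(x, stats::sd, numeric(1)),
      n = lengths(x)
    )
    rownames(smry) <- NULL
    structure(list(raw = x, summary = smry), class = "group_data")
  } else {
    stop_cap("x must be a named list of replicates or a summary data frame")
  }
}

as_group_data <- function(x) {
  if (inherits(x, "group_data")) x else group_data(x)
}

#' Normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per group and Levene's test (classical, mean-centered)
#' across groups. Advisory only: results are reported, never used to
#' block the ANOVA. Requires raw replicates; summary-only input returns
#' a not-applicable marker.
#'
#' @param g raw-form [group_data] (or named list)
#' @return list with `normality` (data frame `label`, `p`; `NA` where the
#'   test is undefined, e.g. identical values) and `homogeneity_p`; or a
#'   list with `applicable = FALSE` for summary-only input
#' @export
check_assumptions <- function(g) {
  g <- as_group_data(g)
  if (is.null(g$raw)) {
    return(list(applicable = FALSE,
                note = "raw replicates unavailable: assumption checks skipped"))
  }
  if (any(lengths(g$raw) < 3)) {
    stop_cap("Shapiro-Wilk needs at least 3 values per group")
  }
  norm_p <- vapply(g$raw, function(v) {
    if (length(unique(v)) == 1) return(NA_real_)  # degenerate: undefined
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  df <- data.frame(value = unlist(g$raw, use.names = FALSE),
                   group = factor(rep(names(g$raw), lengths(g$raw))))
  lev <- car::leveneTest(value ~ group, data = df, center = "mean")
  list(applicable = TRUE,
       normality = data.frame(label = names(g$raw), p = unname(norm_p)),
       homogeneity_p = lev[["Pr(>F)"]][1])
}

#' One-way analysis of variance
#'
#' Classical decomposition. For summary input, the within-group mean
#' square is pooled from the group SDs, `MS_w = sum((n_i - 1) s_i^2) /
#' sum(n_i - 1)`, and the between-group sum of squares uses the group
#' means directly — algebraically identical to the raw-data ANOVA when
#' raw data match the summaries.
#'
#' @param g a [group_data], named list, or summary data frame
#' @return list: `f`, `p`, `ms_between`, `ms_within`, `df_between`,
#'   `df_within`, `k` (groups), `n_total`
#' @export
anova_oneway <- function(g) {
  g <- as_group_data(g)
  s <- g$summary
  k <- nrow(s)
  n_tot <- sum(s$n)
  df_b <- k - 1
  df_w <- n_tot - k
  grand <- sum(s$n * s$mean) / n_tot
  ms_b <- sum(s$n * (s$mean - grand)^2) / df_b
  ms_w <- sum((s$n - 1) * s$sd^2) / df_w
  if (ms_w == 0 && ms_b == 0) {
    stop_cap("all values identical across groups: F is undefined")
  }
  f <- ms_b / ms_w
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       ms_between = ms_b, ms_within = ms_w,
       df_between = df_b, df_within = df_w,
       k = k, n_total = n_tot)
}

#' Tukey HSD pairwise comparisons
#'
#' All `k(k-1)/2` pairwise mean comparisons with the studentized-range
#' distribution; the Tukey-Kramer standard error
#' `sqrt(MS_w/2 * (1/n_i + 1/n_j))` handles unequal group sizes. Works
#' from raw replicates or printed mean/SD/n summaries identically.
#'
#' @param g a [group_data], named list, or summary data frame
#' @param alpha family-wise significance level (default 0.05)
#' @return data frame of class `tukey_comparisons`: `label_1`, `label_2`,
#'   `diff` (mean_1 - mean_2), `se`, `q_stat`, `p_adj`, `significant`
#' @export
tukey_hsd <- function(g, alpha = 0.05) {
  g <- as_group_data(g)
  an <- anova_oneway(g)
  if (an$ms_within == 0) {
    stop_cap("zero within-group variance: Tukey comparisons are degenerate")
  }
  s <- g$summary
  k <- nrow(s)
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    label_1 = s$label[pairs[1, ]],
    label_2 = s$label[pairs[2, ]],
    diff = s$mean[pairs[1, ]] - s$mean[pairs[2, ]],
    se = sqrt(an$ms_within / 2 *
                (1 / s$n[pairs[1, ]] + 1 / s$n[pairs[2, ]]))
  )
  out$q_stat <- abs(out$diff) / out$se
  out$p_adj <- stats::ptukey(out$q_stat, k, an$df_within, lower.tail = FALSE)
  out$significant <- out$p_adj <= alpha
  attr(out, "alpha") <- alpha
  attr(out, "means") <- stats::setNames(s$mean, s$label)
  class(out) <- c("tukey_comparisons", class(out))
  out
}

#' Compact letter display of homogeneous groups
#'
#' Insert-and-absorb letter assignment: groups sharing at least one
#' letter are not significantly different, groups sharing none are.
#' Letters are ordered by descending mean, so "a" marks the largest-mean
#' homogeneous group — the convention of bench-report tables.
#'
#' @param comparisons a `tukey_comparisons` data frame (all pairs)
#' @param means named numeric vector of group means; defaults to the
#'   means attached to `comparisons`
#' @return named character vector: letter string per group label
#' @export
compact_letter_display <- function(comparisons, means = NULL) {
  means <- means %||% attr(comparisons, "means")
  if (is.null(means)) stop_cap("group means are required for letter ordering")
  labels <- names(sort(means, decreasing = TRUE))
  npairs <- choose(length(labels), 2)
  if (nrow(comparisons) < npairs) {
    stop_cap("comparisons must cover all group pairs")
  }
  # start with one set holding every group; split on each significant pair
  sets <- list(labels)
  sig <- comparisons[comparisons$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$label_1[i]; b <- sig$label_2[i]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (p in seq_along(new_sets)) {
      for (q in seq_along(new_sets)) {
        if (p != q && keep[q] &&
            all(new_sets[[p]] %in% new_sets[[q]]) &&
            (length(new_sets[[p]]) < length(new_sets[[q]]) || p > q)) {
          keep[p] <- FALSE
          break
        }
      }
    }
    sets <- new_sets[keep]
  }
  sets <- sets[lengths(sets) > 0]
  # order letter sets by the largest member mean, descending
  set_rank <- vapply(sets, function(s) max(means[s]), numeric(1))
  sets <- sets[order(-set_rank)]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- stats::setNames(rep("", length(labels)), labels)
  for (i in seq_along(sets)) {
    for (lbl in sets[[i]]) {
      out[lbl] <- paste0(out[lbl], letters_pool[i])
    }
  }
  out[names(means)]
}

#' Run ANOVA + Tukey + letters for one metric
#'
#' @param g a [group_data], named list, or summary data frame
#' @param alpha significance level
#' @return list: `anova`, `comparisons`, `letters`, `assumptions`
#' @export
homogeneous_groups <- function(g, alpha = 0.05) {
  g <- as_group_data(g)
  assum <- if (!is.null(g$raw) && all(lengths(g$raw) >= 3)) {
    check_assumptions(g)
  } else {
    list(applicable = FALSE)
  }
  an <- anova_oneway(g)
  cmp <- tukey_hsd(g, alpha)
  list(anova = an, comparisons = cmp,
       letters = compact_letter_display(cmp), assumptions = assum)
}

#' Format mean +/- SD with letter superscripts
#'
#' @param mean,sd numeric vectors
#' @param letters character vector of group letters ("" for none)
#' @param digits decimals (half-up rounding, report convention)
#' @return character vector like `"3.43 +/- 0.06 a"`
#' @export
format_mean_sd <- function(mean, sd, letters = "", digits = 2) {
  fmt <- function(v) formatC(round_half_up(v, digits), digits = digits,
                             format = "f")
  trimws(paste0(fmt(mean), " ± ", fmt(sd),
                ifelse(nzchar(letters), paste0(" ", letters), "")))
}

#' Render report tables and figures
#'
#' Writes the supplied per-metric QC tables (mean +/- SD with Tukey
#' letters), particle-size summaries, and histogram CSVs into an output
#' directory, plus a plain-text metadata log. Sections whose inputs are
#' absent are noted, not errors. Identical inputs produce byte-identical
#' CSVs.
#'
#' @param out_dir output directory (created if needed)
#' @param qc_tables named list of data frames with columns `formulation`,
#'   `mean`, `sd`, `n` and optionally `letters`
#' @param size_summaries named list of `size_summary` objects
#' @param metadata named list written to `run_log.txt`
#' @return character vector of files written, invisibly
#' @export
render_report <- function(out_dir, qc_tables = list(),
                          size_summaries = list(), metadata = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  notes <- character(0)

  if (length(qc_tables)) {
    for (nm in names(qc_tables)) {
      tb <- qc_tables[[nm]]
      letters <- tb$letters %||% rep("", nrow(tb))
      out <- data.frame(formulation = tb$formulation,
                        value = format_mean_sd(tb$mean, tb$sd, letters),
                        n = tb$n)
      names(out)[2] <- nm
      f <- file.path(out_dir, paste0("qc_", nm, ".csv"))
      utils::write.csv(out, f, row.names = FALSE)
      written <- c(written, f)
    }
  } else {
    notes <- c(notes, "qc section absent: no assay tables supplied")
  }

  if (length(size_summaries)) {
    sz <- do.call(rbind, lapply(names(size_summaries), function(nm) {
      s <- size_summaries[[nm]]
      data.frame(formulation = nm, valid_n = s$valid_n,
                 diameter = format_mean_sd(s$mean_um, s$sd_um),
                 d10_um = round_half_up(s$d10_um, 2),
                 d50_um = round_half_up(s$d50_um, 2),
                 d90_um = round_half_up(s$d90_um, 2))
    }))
    f <- file.path(out_dir, "size_summary.csv")
    utils::write.csv(sz, f, row.names = FALSE)
    written <- c(written, f)
    for (nm in names(size_summaries)) {
      f <- file.path(out_dir, paste0("histogram_", nm, ".csv"))
      utils::write.csv(size_summaries[[nm]]$histogram, f, row.names = FALSE)
      written <- c(written, f)
    }
  } else {
    notes <- c(notes, "size section absent: no particle tables supplied")
  }

  log_f <- file.path(out_dir, "run_log.txt")
  meta_lines <- c(
    paste0("capmetrics ", as.character(utils::packageVersion("capmetrics"))),
    vapply(names(metadata), function(k) {
      paste0(k, ": ", paste(format(metadata[[k]]), collapse = " "))
    }, character(1)),
    if (length(notes)) paste0("note: ", notes)
  )
  writeLines(meta_lines, log_f)
  written <- c(written, log_f)
  invisible(written)
}
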