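test_that("group data validates its two input forms", {
  expect_error(group_data(list(1:3, 4:6)), "named")
  expect_error(group_data(list(a = 1:3)), "two groups")
  expect_error(group_data(list(a = 1, b = 1:3)), "n >= 2")
  gd <- group_data(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(gd$summary$mean, c(2, 5))
  sm <- group_data(data.frame(label = c("a", "b"), mean = c(1, 2),
                              sd = c(0.1, 0.2), n = 3))
  expect_null(sm$raw)
})

test_that("assumption checks report normality and homogeneity", {
  set.seed(31)
  g <- list(a = rnorm(30), b = rnorm(30))
  ck <- check_assumptions(g)
  expect_true(ck$applicable)
  expect_gt(ck$homogeneity_p, 0.05)
  # identical values: normality undefined, reported as NA
  ck2 <- check_assumptions(list(a = c(1, 1, 1), b = c(1, 2, 3)))
  expect_true(is.na(ck2$normality$p[1]))
  expect_false(is.na(ck2$normality$p[2]))
  # summary-only input: not applicable, never an error
  sm <- group_data(data.frame(label = c("a", "b"), mean = 1:2,
                              sd = c(1, 1), n = 3))
  expect_false(check_assumptions(sm)$applicable)
  expect_error(group_data(list(a = 1, b = 2:4)), "n >= 2")
})

test_that("summary-based ANOVA equals the raw-data decomposition", {
  raw <- list(A = exact_replicates(3.43, 0.06, 3),
              B = exact_replicates(2.45, 0.05, 3),
              C = exact_replicates(1.96, 0.04, 4))
  a_raw <- anova_oneway(raw)
  smry <- data.frame(label = c("A", "B", "C"), mean = c(3.43, 2.45, 1.96),
                     sd = c(0.06, 0.05, 0.04), n = c(3, 3, 4))
  a_sum <- anova_oneway(group_data(smry))
  expect_equal(a_raw$f, a_sum$f, tolerance = 1e-9)
  expect_equal(a_raw$ms_within, a_sum$ms_within, tolerance = 1e-9)
  # independent oracle: stats::aov on the raw replicates
  df <- data.frame(y = unlist(raw), g = factor(rep(names(raw), lengths(raw))))
  ao <- summary(stats::aov(y ~ g, df))[[1]]
  expect_equal(a_raw$f, ao[["F value"]][1], tolerance = 1e-9)
  expect_equal(a_raw$p, ao[["Pr(>F)"]][1], tolerance = 1e-9)
})

test_that("degenerate ANOVA inputs are rejected or give F = 0", {
  same <- group_data(data.frame(label = c("a", "b"), mean = c(5, 5),
                                sd = c(1, 1), n = 3))
  expect_equal(anova_oneway(same)$f, 0)
  allsame <- group_data(data.frame(label = c("a", "b"), mean = c(5, 5),
                                   sd = c(0, 0), n = 3))
  expect_error(anova_oneway(allsame), "undefined")
})

test_that("Tukey comparisons agree with stats::TukeyHSD on raw data", {
  set.seed(5)
  raw <- list(A = rnorm(4, 0), B = rnorm(5, 1), C = rnorm(3, 3))
  cmp <- tukey_hsd(raw)
  df <- data.frame(y = unlist(raw), g = factor(rep(names(raw), lengths(raw))))
  ref <- stats::TukeyHSD(stats::aov(y ~ g, df))$g
  # match pairs (TukeyHSD reports B-A style differences)
  for (i in seq_len(nrow(cmp))) {
    key <- paste0(cmp$label_2[i], "-", cmp$label_1[i])
    expect_equal(cmp$p_adj[i], ref[key, "p adj"], tolerance = 1e-6)
    expect_equal(-cmp$diff[i], ref[key, "diff"], tolerance = 1e-9)
  }
})

test_that("Tukey at k = 2 reduces to the two-sample pooled t-test", {
  set.seed(9)
  g <- list(a = rnorm(6), b = rnorm(8, 0.5))
  cmp <- tukey_hsd(g)
  tt <- stats::t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(cmp$p_adj, tt$p.value, tolerance = 1e-9)
})

test_that("obvious separations and identical groups behave as expected", {
  big <- group_data(data.frame(label = c("lo", "hi"), mean = c(0, 100),
                               sd = 1, n = 3))
  expect_true(tukey_hsd(big)$significant)
  same <- tukey_hsd(group_data(data.frame(label = c("a", "b"), mean = 5,
                                          sd = 1, n = 3)))
  expect_false(same$significant)
  degenerate <- group_data(data.frame(label = c("a", "b"), mean = c(1, 2),
                                      sd = 0, n = 3))
  expect_error(tukey_hsd(degenerate), "degenerate")
})

test_that("letters reproduce the published moisture grouping", {
  hg <- homogeneous_groups(study_groups("moisture_solubility",
                                        "moisture_mean", "moisture_sd"))
  lt <- hg$letters
  expect_equal(length(unique(lt)), 5)  # five homogeneous groups
  expect_equal(unname(lt["CON"]), "a")
  expect_equal(sum(lt == "a"), 1)      # CON alone in the top group
  bottom <- names(lt)[lt == "e"]
  expect_setequal(bottom, c("STA", "CTA", "CHS"))
  expect_equal(unname(lt["ETA"]), "b")
  expect_setequal(names(lt)[lt == "c"], c("EHS", "SHS", "GHS"))
  expect_equal(unname(lt["GTA"]), "d")
})

test_that("encapsulation-efficiency summaries yield one significant pair", {
  cmp <- tukey_hsd(study_groups("oil_ee", "ee_mean", "ee_sd"))
  sig <- cmp[cmp$significant, ]
  expect_equal(nrow(sig), 1)
  expect_setequal(c(sig$label_1, sig$label_2), c("SHS", "ETA"))
})

test_that("letter display satisfies the sharing contract on random cases", {
  share <- function(a, b) length(intersect(strsplit(a, "")[[1]],
                                           strsplit(b, "")[[1]])) > 0
  set.seed(77)
  for (rep in 1:20) {
    k <- sample(3:10, 1)
    smry <- data.frame(label = paste0("G", 1:k),
                       mean = rnorm(k, 0, 2), sd = runif(k, 0.3, 1.5),
                       n = sample(3:5, k, replace = TRUE))
    cmp <- tukey_hsd(group_data(smry))
    lt <- compact_letter_display(cmp)
    for (i in seq_len(nrow(cmp))) {
      shared <- share(lt[cmp$label_1[i]], lt[cmp$label_2[i]])
      expect_equal(shared, !cmp$significant[i])
    }
  }
})

test_that("letter display edge cases: none or all pairs significant", {
  none <- tukey_hsd(group_data(data.frame(label = c("a", "b", "c"),
                                          mean = c(1, 1.01, 0.99),
                                          sd = 1, n = 3)))
  expect_true(all(compact_letter_display(none) == "a"))
  all_sig <- tukey_hsd(group_data(data.frame(label = c("x", "y", "z"),
                                             mean = c(0, 50, 100),
                                             sd = 1, n = 3)))
  lt <- compact_letter_display(all_sig)
  expect_equal(unname(lt[c("z", "y", "x")]), c("a", "b", "c"))
})

test_that("report rendering is deterministic and notes absent sections", {
  qc <- list(moisture = data.frame(formulation = c("A", "B"),
                                   mean = c(3.43, 1.96), sd = c(0.06, 0.04),
                                   n = 3, letters = c("a", "b")))
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  render_report(d1, qc_tables = qc)
  render_report(d2, qc_tables = qc)
  f1 <- readLines(file.path(d1, "qc_moisture.csv"))
  expect_identical(f1, readLines(file.path(d2, "qc_moisture.csv")))
  expect_match(f1[2], "3.43 ± 0.06 a")
  log <- readLines(file.path(d1, "run_log.txt"))
  expect_true(any(grepl("size section absent", log)))
})

test_that("mean-sd formatting rounds half up at report precision", {
  expect_equal(format_mean_sd(1.685, 0.005), "1.69 ± 0.01")
  expect_equal(format_mean_sd(3.43, 0.06, "a"), "3.43 ± 0.06 a")
})
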