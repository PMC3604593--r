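cls_of <- function(ids, labels) {
  out <- data.frame(gene_id = ids, label = labels, stringsAsFactors = FALSE)
  class(out) <- c("gene_classification", "data.frame")
  out
}

test_that("confusion counts follow the classification-accuracy reading", {
  truth <- c(g1 = "A", g2 = "A", g3 = "B", g4 = "none", g5 = "none",
             g6 = "B", g7 = "A", g8 = "none")
  cls <- cls_of(names(truth),
                c("A", "B", "B", "A", "none", "none", "A", "none"))
  cc <- confusion(cls, truth)
  expect_identical(c(cc$tp, cc$fp, cc$tn, cc$fn), c(3L, 2L, 2L, 1L))
  expect_identical(cc$r, 5L)

  perfect <- cls_of(names(truth), unname(truth))
  cp <- confusion(perfect, truth)
  expect_identical(c(cp$fp, cp$fn), c(0L, 0L))

  none <- cls_of(names(truth), rep("none", 8))
  cn <- confusion(none, truth)
  expect_identical(c(cn$tp, cn$fp), c(0L, 0L))

  expect_error(confusion(cls_of("gX", "A"), truth), "missing from truth")
})

test_that("the false discovery proportion follows the V/R definition", {
  cc <- function(tp, fp) structure(list(tp = tp, fp = fp, tn = 0, fn = 0,
                                        r = tp + fp),
                                   class = "confusion_counts")
  expect_equal(fdr(cc(6, 2)), 0.25)
  expect_identical(fdr(cc(0, 0)), 0)    # zero-when-empty rule
  expect_equal(fdr(cc(0, 5)), 1)
  expect_equal(fdr(cc(8, 2)), 0.2)
  # hand-checked: 8 condition-labeled genes of which 2 wrong
  truth <- setNames(rep(c("A", "B"), each = 5), sprintf("g%d", 1:10))
  lab <- unname(truth); lab[c(1, 6)] <- c("B", "A"); lab[c(5, 10)] <- "none"
  expect_equal(fdr(confusion(cls_of(names(truth), lab), truth)), 0.25)
})

test_that("the default grid is the documented progression", {
  g <- cd_threshold_grid()
  expect_equal(g, c(0.970, 0.974, 0.978, 0.982, 0.986, 0.990, 0.994,
                    0.998, 0.999), tolerance = 1e-12)
  expect_true(!is.unsorted(g, strictly = TRUE))
})

test_that("the best threshold is the largest minimizer", {
  g <- cd_threshold_grid()
  fdrs <- c(0.5, 0.4, 0.2, 0.2, 0.3, 0.2, 0.6, NA, NA)
  expect_equal(best_threshold(fdrs, g), 0.990)  # ties resolve upward
  expect_equal(best_threshold(rep(0.1, 9), g), 0.999)
  expect_true(is.na(best_threshold(rep(NA_real_, 9), g)))
})

sweep_args <- list(mode = "sim2", scenario = "F", method = "cd",
                   reps = 5, seed = 42, n1 = 60, n2 = 60, n0 = 120,
                   p1 = 4, p2 = 4)

test_that("a sweep produces an ordered, reproducible report", {
  rep1 <- do.call(threshold_sweep, c(sweep_args, list(grid = c(0.97))))
  expect_s3_class(rep1, "eval_report")
  expect_identical(rep1$n_reps, 5L)
  s <- attr(rep1, "samples")
  expect_length(s$fdr, 5L)
  expect_true(rep1$fdr_p2.5 <= rep1$fdr_p50 &
                rep1$fdr_p50 <= rep1$fdr_p97.5)
  expect_true(rep1$mean_fdr >= 0 & rep1$mean_fdr <= 1)
  # single-point grid: every replicate's best threshold is that point,
  # reported on the 1 - Cd scale
  expect_equal(rep1$mean_threshold, 1 - 0.97, tolerance = 1e-12)

  rep2 <- do.call(threshold_sweep, c(sweep_args, list(grid = c(0.97))))
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))

  full <- do.call(threshold_sweep, c(sweep_args,
                                     list(grid = cd_threshold_grid())))
  expect_true(full$mean_threshold >= 0.001 - 1e-12 &
                full$mean_threshold <= 0.03 + 1e-12)
  expect_error(do.call(threshold_sweep,
                       c(sweep_args, list(grid = c(0.99, 0.97)))),
               "increasing")
})

test_that("reports use the conventional column layouts and round-trip", {
  rep1 <- do.call(threshold_sweep, c(sweep_args,
                                     list(grid = cd_threshold_grid())))
  fdr_tab <- format_eval_report(rep1, "fdr")
  expect_identical(names(fdr_tab),
                   c("Method and scenario", "Mean FDR", "FDR Sd",
                     "FDR p_2.5", "FDR p_50", "FDR p_97.5"))
  expect_identical(fdr_tab[["Method and scenario"]], "cd-F")
  thr_tab <- format_eval_report(rep1, "threshold")
  expect_identical(names(thr_tab),
                   c("Method and scenario", "Mean threshold", "Threshold Sd",
                     "Threshold p_2.5", "Threshold p_50", "Threshold p_97.5"))

  p <- tempfile()
  write_eval_report(rep1, p)
  back <- read_eval_report(p)
  for (col in c("mean_fdr", "sd_fdr", "fdr_p50", "mean_threshold"))
    expect_equal(back[[col]], rep1[[col]], tolerance = 1e-9)
})

test_that("replicate FDR matrices are reproducible and well-formed", {
  m1 <- fdr_replicates("sim1", "F", methods = c("dapc", "cd"),
                       threshold = 0.99, reps = 3, seed = 7,
                       n1 = 60, n2 = 60, n0 = 120, p1 = 4, p2 = 4)
  m2 <- fdr_replicates("sim1", "F", methods = c("dapc", "cd"),
                       threshold = 0.99, reps = 3, seed = 7,
                       n1 = 60, n2 = 60, n0 = 120, p1 = 4, p2 = 4)
  expect_identical(m1, m2)
  expect_identical(dim(m1), c(3L, 2L))
  expect_true(all(m1 >= 0 & m1 <= 1, na.rm = TRUE))
})
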