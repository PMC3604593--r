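#' Confusion counts of a classification against simulation truth
#'
#' True positives are genes assigned to their true condition; false
#' positives are genes assigned to a condition that is not their true label
#' (wrong condition, or truly non-differential); true negatives are
#' non-differential genes left unassigned; false negatives are
#' differentially expressed genes left unassigned.
#'
#' @param cls A `gene_classification`.
#' @param truth Named character vector, gene id to `"A"`-style condition
#'   label or `"none"`, as produced by the simulators.
#' @return Object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn` and `r` (= tp + fp, the number of condition-labeled genes).
#' @export
confusion <- function(cls, truth) {
  stopifnot(inherits(cls, "gene_classification"))
  missing_truth <- setdiff(cls$gene_id, names(truth))
  if (length(missing_truth))
    stop("gene(s) missing from truth: ",
         paste(utils::head(missing_truth, 3L), collapse = ", "))
  tr <- truth[cls$gene_id]
  pos <- cls$label != "none"
  tp <- sum(pos & cls$label == tr)
  fp <- sum(pos & cls$label != tr)
  tn <- sum(!pos & tr == "none")
  fn <- sum(!pos & tr != "none")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, r = tp + fp),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: Tp %d, Fp %d, Tn %d, Fn %d (R = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$r))
  invisible(x)
}

#' Empirical false discovery proportion of a classification
#'
#' `Fp / (Fp + Tp)` over the genes assigned to either condition, and 0 when
#' no gene is assigned. Genes classified as `"none"` (no differential gene
#' expression) do not enter the ratio. This is a descriptive accuracy
#' measure of a classification, not a multiple-testing adjustment.
#'
#' @param counts A [confusion()] result.
#' @return A value in \[0, 1\].
#' @examples
#' fdr(structure(list(tp = 6, fp = 2, tn = 0, fn = 0, r = 8),
#'               class = "confusion_counts"))
#' @export
fdr <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp + counts$fp == 0) return(0)
  counts$fp / (counts$fp + counts$tp)
}

#' The default closeness-threshold grid
#'
#' An arithmetic progression from 0.970 by steps of 0.004 up to 0.998, with
#' the terminal value 0.999 appended.
#'
#' @return Numeric vector of thresholds.
#' @export
cd_threshold_grid <- function() {
  c(seq(0.970, 0.998, by = 0.004), 0.999)
}

#' Best threshold of a sweep: the largest minimizer
#'
#' Among grid thresholds whose FDR was computable, returns the largest one
#' attaining the minimal FDR (a higher cutoff classifies fewer genes with
#' equal error, so ties resolve upward).
#'
#' @param fdrs Numeric FDR per grid point (`NA` where uncomputable).
#' @param grid The threshold grid, same length.
#' @return The selected threshold, or `NA` if no grid point was computable.
#' @export
best_threshold <- function(fdrs, grid) {
  stopifnot(length(fdrs) == length(grid))
  ok <- !is.na(fdrs)
  if (!any(ok)) return(NA_real_)
  m <- min(fdrs[ok])
  max(grid[ok & fdrs == m])
}

.strategy_names <- c("dapc", "cd", "cd_with_dapc", "cd_inter_dapc")

# Classify one simulated replicate with each requested strategy at each
# threshold and return the FDR matrix (thresholds x methods). The PC space,
# directions, closeness table and full-data DAPC are shared across
# thresholds and methods.
.eval_replicate <- function(sim, methods, grid, n_components = 2,
                            filter_quantile = 0.25, k = 3, k_subset = 3,
                            seed = 1) {
  space <- fit_pca(sim$matrix, n_components)
  directions <- build_directions(space)
  cd <- apply_norm_filter(compute_cd(space, directions), filter_quantile)
  out <- matrix(NA_real_, length(grid), length(methods),
                dimnames = list(NULL, methods))
  dapc_cls <- NULL
  if (any(c("dapc", "cd_inter_dapc") %in% methods))
    dapc_cls <- classify_dapc_only(
      map_clusters_to_conditions(run_dapc(space, k, seed), directions))
  for (ti in seq_along(grid)) {
    t <- grid[ti]
    for (m in methods) {
      cls <- tryCatch(switch(m,
        dapc = dapc_cls,
        cd = classify_cd_only(cd, t),
        cd_with_dapc = classify_cd_with_dapc(cd, space, directions, t,
                                             k = k_subset, seed = seed),
        cd_inter_dapc = classify_cd_inter_dapc(classify_cd_only(cd, t),
                                               dapc_cls),
        stop("unknown method '", m, "'")),
        error = function(e) NULL)
      if (!is.null(cls))
        out[ti, m] <- fdr(confusion(cls, sim$truth))
    }
  }
  out
}

#' FDR of one or more strategies over repeated simulations
#'
#' Simulates `reps` independent data sets of one scenario, classifies each
#' with every requested strategy at a fixed closeness threshold, and returns
#' the per-replicate FDR values. This is the workhorse behind the scenario
#' benchmarks; summaries (means over replicates) are left to the caller.
#'
#' @param mode,scenario Scenario selectors, as in [scenario_defaults()].
#' @param methods Character vector of strategies (see
#'   [classify_genes()]); default all four.
#' @param threshold Closeness cutoff shared by the closeness-based
#'   strategies.
#' @param reps Number of simulation replicates.
#' @param seed Master seed; per-replicate seeds are drawn from it.
#' @param ... Passed to [scenario_defaults()] (dimensions, scenario
#'   parameter overrides).
#' @param n_components,filter_quantile,k,k_subset Analysis settings, as in
#'   [classify_genes()].
#' @return A `reps` x `length(methods)` matrix of FDR values (`NA` where a
#'   strategy failed on a replicate, e.g. too few genes passed the
#'   threshold), with the replicate seeds in attribute `seeds`.
#' @export
fdr_replicates <- function(mode, scenario, methods = .strategy_names,
                           threshold = 0.99, reps = 20, seed = 1, ...,
                           n_components = 2, filter_quantile = 0.25,
                           k = 3, k_subset = 3) {
  stopifnot(all(methods %in% .strategy_names), reps >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  out <- matrix(NA_real_, reps, length(methods),
                dimnames = list(NULL, methods))
  for (r in seq_len(reps)) {
    cfg <- scenario_defaults(mode, scenario, seed = rep_seeds[r], ...)
    sim <- simulate_scenario(cfg)
    out[r, ] <- .eval_replicate(sim, methods, threshold,
                                n_components = n_components,
                                filter_quantile = filter_quantile,
                                k = k, k_subset = k_subset,
                                seed = rep_seeds[r])[1L, ]
  }
  attr(out, "seeds") <- rep_seeds
  out
}

.pctl <- function(x, p) stats::quantile(x, probs = p, names = FALSE, type = 7)

#' Threshold sweep with best-threshold selection
#'
#' For each of `reps` simulated replicates of one scenario: classify with
#' the given strategy at every grid threshold, compute the FDR against
#' truth, and select the replicate's best threshold (the largest grid value
#' attaining the minimal FDR). Replicates on which every grid point fails
#' (e.g. no gene passes any threshold) are dropped with a warning; more than
#' 20% failures abort the sweep. The pooled report summarizes the FDR at the
#' best threshold and the best thresholds themselves (reported on the
#' `1 - Cd` scale, as threshold tables conventionally are) by mean, standard
#' deviation and 2.5/50/97.5 percentiles.
#'
#' @inheritParams fdr_replicates
#' @param method A single strategy name.
#' @param grid Increasing threshold grid, default [cd_threshold_grid()].
#' @return A one-row data frame of class `eval_report` with columns
#'   `method`, `scenario`, `mode`, `n_reps`, `mean_fdr`, `sd_fdr`,
#'   `fdr_p2.5`, `fdr_p50`, `fdr_p97.5`, `mean_threshold`, `sd_threshold`,
#'   `threshold_p2.5`, `threshold_p50`, `threshold_p97.5` (threshold columns
#'   on the `1 - Cd` scale; `NA` for the threshold-free DAPC strategy).
#'   Per-replicate samples are kept in attribute `samples`. Reports for
#'   several method/scenario combinations can be combined with `rbind`.
#' @export
threshold_sweep <- function(mode, scenario, method, grid = cd_threshold_grid(),
                            reps = 20, seed = 1, ...,
                            n_components = 2, filter_quantile = 0.25,
                            k = 3, k_subset = 3) {
  stopifnot(length(method) == 1L, method %in% .strategy_names)
  if (is.unsorted(grid, strictly = TRUE) || any(grid <= 0) || any(grid >= 1))
    stop("`grid` must be strictly increasing within (0, 1)")
  if (reps < 2L) stop("`reps` must be at least 2")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  fdr_best <- thr_best <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    cfg <- scenario_defaults(mode, scenario, seed = rep_seeds[r], ...)
    sim <- simulate_scenario(cfg)
    fdrs <- tryCatch(
      .eval_replicate(sim, method, grid, n_components = n_components,
                      filter_quantile = filter_quantile, k = k,
                      k_subset = k_subset, seed = rep_seeds[r])[, 1L],
      error = function(e) rep(NA_real_, length(grid)))
    tb <- best_threshold(fdrs, grid)
    if (is.na(tb)) next
    thr_best[r] <- tb
    fdr_best[r] <- min(fdrs, na.rm = TRUE)
  }
  ok <- !is.na(fdr_best)
  if (sum(!ok) > 0.2 * reps)
    stop("more than 20% of sweep replicates failed (", sum(!ok), "/", reps, ")")
  if (any(!ok))
    warning(sum(!ok), " sweep replicate(s) failed and were excluded")
  f <- fdr_best[ok]
  has_thr <- method != "dapc"
  tt <- if (has_thr) 1 - thr_best[ok] else rep(NA_real_, sum(ok))
  out <- data.frame(
    method = method, scenario = scenario, mode = mode, n_reps = sum(ok),
    mean_fdr = mean(f), sd_fdr = stats::sd(f),
    fdr_p2.5 = .pctl(f, 0.025), fdr_p50 = .pctl(f, 0.5),
    fdr_p97.5 = .pctl(f, 0.975),
    mean_threshold = if (has_thr) mean(tt) else NA_real_,
    sd_threshold = if (has_thr) stats::sd(tt) else NA_real_,
    threshold_p2.5 = if (has_thr) .pctl(tt, 0.025) else NA_real_,
    threshold_p50 = if (has_thr) .pctl(tt, 0.5) else NA_real_,
    threshold_p97.5 = if (has_thr) .pctl(tt, 0.975) else NA_real_,
    stringsAsFactors = FALSE)
  attr(out, "samples") <- list(fdr = fdr_best, threshold = thr_best)
  attr(out, "seeds") <- rep_seeds
  attr(out, "grid") <- grid
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Format an evaluation report in the conventional table layout
#'
#' @param report An `eval_report` (one or more rows).
#' @param table `"fdr"` for the FDR summary layout (`Method and scenario`,
#'   `Mean FDR`, `FDR Sd`, `FDR p_2.5`, `FDR p_50`, `FDR p_97.5`) or
#'   `"threshold"` for the best-threshold layout on the `1 - Cd` scale
#'   (`Mean threshold`, `Threshold Sd`, `Threshold p_2.5`, `Threshold p_50`,
#'   `Threshold p_97.5`).
#' @return A data frame with the display column names.
#' @export
format_eval_report <- function(report, table = c("fdr", "threshold")) {
  stopifnot(inherits(report, "eval_report") || is.data.frame(report))
  table <- match.arg(table)
  key <- paste0(report$method, "-", report$scenario)
  if (table == "fdr") {
    data.frame(`Method and scenario` = key,
               `Mean FDR` = report$mean_fdr, `FDR Sd` = report$sd_fdr,
               `FDR p_2.5` = report$fdr_p2.5, `FDR p_50` = report$fdr_p50,
               `FDR p_97.5` = report$fdr_p97.5,
               check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    keep <- report$method != "dapc"
    data.frame(`Method and scenario` = key[keep],
               `Mean threshold` = report$mean_threshold[keep],
               `Threshold Sd` = report$sd_threshold[keep],
               `Threshold p_2.5` = report$threshold_p2.5[keep],
               `Threshold p_50` = report$threshold_p50[keep],
               `Threshold p_97.5` = report$threshold_p97.5[keep],
               check.names = FALSE, stringsAsFactors = FALSE)
  }
}

#' Write an evaluation report to a delimited text file
#'
#' Writes the full internal columns (round-trippable with
#' [read_eval_report()]); use [format_eval_report()] for the display
#' layouts.
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return Invisibly, `report`.
#' @export
write_eval_report <- function(report, path, sep = "\t") {
  df <- as.data.frame(report)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Read an evaluation report written by [write_eval_report()]
#'
#' @param path Input path.
#' @param sep Field delimiter.
#' @return An `eval_report` data frame.
#' @export
read_eval_report <- function(path, sep = "\t") {
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("eval_report", "data.frame")
  out
}
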