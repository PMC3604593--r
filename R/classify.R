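.new_classification <- function(gene_id, label, strategy, threshold = NULL) {
  out <- data.frame(gene_id = gene_id, label = label,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "strategy") <- strategy
  attr(out, "threshold") <- threshold
  class(out) <- c("gene_classification", "data.frame")
  out
}

#' @export
print.gene_classification <- function(x, ...) {
  cat("gene_classification (strategy ", attr(x, "strategy"), "):\n", sep = "")
  print(table(x$label))
  invisible(x)
}

#' Strategy 1: classification by DAPC alone
#'
#' Copies the condition labels from a mapped three-group DAPC: two groups of
#' genes far from the origin, one per experimental condition, and one group
#' around the origin labeled `"none"` (no differential gene expression).
#'
#' @param dapc A [map_clusters_to_conditions()] result with `k = 3`.
#' @return A `gene_classification` with labels in the two condition labels or
#'   `"none"`.
#' @export
classify_dapc_only <- function(dapc) {
  stopifnot(inherits(dapc, "dapc_result"))
  if (is.null(dapc$mapped_label))
    stop("clusters are not mapped to conditions; run map_clusters_to_conditions()")
  if (attr(dapc, "k") != 3L)
    stop("the DAPC-only strategy requires k = 3")
  .new_classification(dapc$gene_id, dapc$mapped_label, "dapc")
}

#' Strategy 2: classification by the closeness measure alone
#'
#' Assigns each unfiltered gene whose largest absolute closeness value
#' exceeds the threshold to the corresponding condition, without using the
#' DAPC groups.
#'
#' @param cd A filtered [apply_norm_filter()] result.
#' @param threshold Closeness cutoff(s), as in [assign_by_cd()].
#' @return A `gene_classification`.
#' @export
classify_cd_only <- function(cd, threshold) {
  a <- assign_by_cd(cd, threshold)
  .new_classification(a$gene_id, a$assigned, "cd",
                      threshold = attr(a, "threshold"))
}

#' Strategy 3: DAPC restricted to the closeness zone of interest
#'
#' Runs DAPC only on the genes the closeness measure places in a zone of
#' interest (largest absolute closeness value above the threshold), then maps
#' the resulting clusters to conditions; all other genes are labeled
#' `"none"`. The closeness value is norm-free, so the thresholded set still
#' contains low-norm background genes whose angle happens to fall in a cone;
#' the subset DAPC therefore keeps a no-expression group by default
#' (`k = 3`, the near-origin cluster mapping to `"none"`), which is where
#' most of this strategy's robustness over closeness-only classification
#' comes from. `k = 2` (conditions only) is available by argument.
#'
#' @param cd A filtered [apply_norm_filter()] result.
#' @param space The `pc_space` the closeness values were computed in.
#' @param directions The [build_directions()] result.
#' @param threshold Closeness cutoff in (0, 1) (single shared value).
#' @param k Groups for the subset DAPC, default 3.
#' @param seed Seed for the subset k-means.
#' @return A `gene_classification`.
#' @export
classify_cd_with_dapc <- function(cd, space, directions, threshold,
                                  k = 3, seed = 1) {
  stopifnot(inherits(cd, "cd_result"), inherits(space, "pc_space"))
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie strictly inside (0, 1)")
  conds <- attr(cd, "conditions")
  best_abs <- pmax(abs(cd[[paste0("cd_", conds[1L])]]),
                   abs(cd[[paste0("cd_", conds[2L])]]))
  pass <- which(!cd$filtered & best_abs > threshold)
  if (length(pass) < 10L * k)
    stop("only ", length(pass), " genes pass the closeness threshold ",
         threshold, "; DAPC needs at least ", 10L * k)
  sub <- run_dapc(space, k = k, seed = seed, genes = cd$gene_id[pass])
  sub <- map_clusters_to_conditions(sub, directions)
  label <- rep("none", nrow(cd))
  label[pass] <- sub$mapped_label[match(cd$gene_id[pass], sub$gene_id)]
  .new_classification(cd$gene_id, label, "cd_with_dapc", threshold = threshold)
}

#' Strategy 4: intersection of the closeness and DAPC classifications
#'
#' A gene is assigned to a condition only when the closeness-only and
#' DAPC-only classifications independently agree on that condition; any
#' disagreement or half-assignment yields `"none"`.
#'
#' @param cd_cls `gene_classification` from [classify_cd_only()].
#' @param dapc_cls `gene_classification` from [classify_dapc_only()].
#' @return A `gene_classification`.
#' @export
classify_cd_inter_dapc <- function(cd_cls, dapc_cls) {
  stopifnot(inherits(cd_cls, "gene_classification"),
            inherits(dapc_cls, "gene_classification"))
  if (!setequal(cd_cls$gene_id, dapc_cls$gene_id) ||
      nrow(cd_cls) != nrow(dapc_cls))
    stop("the two classifications cover different gene sets")
  other <- dapc_cls$label[match(cd_cls$gene_id, dapc_cls$gene_id)]
  agree <- cd_cls$label == other & cd_cls$label != "none"
  .new_classification(cd_cls$gene_id,
                      ifelse(agree, cd_cls$label, "none"),
                      "cd_inter_dapc", threshold = attr(cd_cls, "threshold"))
}

#' Run one classification strategy end to end on an expression matrix
#'
#' Convenience wrapper: fits the PC space, builds the condition directions,
#' computes and filters the closeness values, and applies the requested
#' strategy.
#'
#' @param x An [expression_matrix()].
#' @param method One of `"dapc"`, `"cd"`, `"cd_with_dapc"`,
#'   `"cd_inter_dapc"`.
#' @param threshold Closeness cutoff for the closeness-based strategies
#'   (default 0.99).
#' @param n_components Retained PC axes (default 2).
#' @param filter_quantile Norm-filter quantile (default 0.25).
#' @param k Groups for the full-data DAPC (default 3).
#' @param k_subset Groups for the subset DAPC of `"cd_with_dapc"`
#'   (default 3).
#' @param seed Seed for the k-means restarts.
#' @return A `gene_classification`.
#' @examples
#' sim <- simulate_scenario(scenario_defaults("sim2", "F", seed = 1))
#' cls <- classify_genes(sim$matrix, "cd", threshold = 0.99)
#' table(cls$label)
#' @export
classify_genes <- function(x, method = c("cd", "dapc", "cd_with_dapc",
                                         "cd_inter_dapc"),
                           threshold = 0.99, n_components = 2,
                           filter_quantile = 0.25, k = 3, k_subset = 3,
                           seed = 1) {
  method <- match.arg(method)
  space <- fit_pca(x, n_components)
  directions <- build_directions(space)
  cd <- apply_norm_filter(compute_cd(space, directions), filter_quantile)
  switch(method,
    cd = classify_cd_only(cd, threshold),
    dapc = classify_dapc_only(
      map_clusters_to_conditions(run_dapc(space, k, seed), directions)),
    cd_with_dapc = classify_cd_with_dapc(cd, space, directions, threshold,
                                         k = k_subset, seed = seed),
    cd_inter_dapc = classify_cd_inter_dapc(
      classify_cd_only(cd, threshold),
      classify_dapc_only(
        map_clusters_to_conditions(run_dapc(space, k, seed), directions))))
}

#' Write a classification to a delimited text file
#'
#' @param cls A `gene_classification`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return Invisibly, `cls`.
#' @export
write_classification <- function(cls, path, sep = "\t") {
  stopifnot(inherits(cls, "gene_classification"))
  utils::write.table(as.data.frame(cls), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(cls)
}
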