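#' Discriminant analysis on principal components (minimal DAPC)
#'
#' Groups the gene scores of a fitted PC space without any a-priori
#' structure: k-means (25 random restarts, best within-cluster sum of
#' squares) proposes `k` groups, then a linear discriminant analysis trained
#' on those groups re-assigns every gene to the group with the highest
#' posterior membership. The discriminant step uses all axes already
#' retained in the space; no second dimension-reduction is applied.
#'
#' @param space A fitted [fit_pca()] space.
#' @param k Number of groups (default 3: one per condition plus a
#'   no-differential-expression group near the origin).
#' @param seed Integer seed making the k-means restarts reproducible.
#' @param genes Optional subset of genes to cluster: indices into the
#'   space's gene order, or gene identifiers.
#' @return Object of class `dapc_result`: data frame with columns `gene_id`,
#'   `cluster` (1..k), `membership` (posterior probability of the assigned
#'   group); attributes `k`, `centroids` (k x K matrix of per-cluster mean
#'   scores after reassignment) and `seed`. Cluster indices are arbitrary
#'   until mapped with [map_clusters_to_conditions()].
#' @examples
#' sim <- simulate_scenario(scenario_defaults("sim1", "F", seed = 1))
#' sp <- fit_pca(sim$matrix)
#' dp <- run_dapc(sp, k = 3, seed = 1)
#' table(dp$cluster)
#' @export
run_dapc <- function(space, k = 3, seed = 1, genes = NULL) {
  stopifnot(inherits(space, "pc_space"))
  if (length(k) != 1L || k < 2L) stop("`k` must be an integer >= 2")
  k <- as.integer(k)
  scores <- space$gene_scores
  rownames(scores) <- space$gene_ids
  if (!is.null(genes)) scores <- scores[genes, , drop = FALSE]
  n <- nrow(scores)
  if (n < 10L * k)
    stop("DAPC needs at least 10*k = ", 10L * k, " genes, got ", n)
  set.seed(seed)
  km <- tryCatch(
    stats::kmeans(scores, centers = k, nstart = 25, iter.max = 100),
    error = function(e) stop("k-means failed (", conditionMessage(e),
                             "); try a smaller k", call. = FALSE))
  grp <- factor(km$cluster, levels = seq_len(k))
  fit <- MASS::lda(scores, grouping = grp)
  pred <- stats::predict(fit, as.data.frame(scores))
  cluster <- as.integer(as.character(pred$class))
  if (length(unique(cluster)) < k)
    stop("empty cluster after discriminant reassignment; try a smaller k")
  membership <- pred$posterior[cbind(seq_len(n), cluster)]
  centroids <- t(vapply(seq_len(k), function(j)
    colMeans(scores[cluster == j, , drop = FALSE]),
    numeric(ncol(scores))))
  out <- data.frame(gene_id = rownames(scores), cluster = cluster,
                    membership = as.numeric(membership),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "k") <- k
  attr(out, "centroids") <- centroids
  attr(out, "seed") <- seed
  class(out) <- c("dapc_result", "data.frame")
  out
}

#' Name DAPC clusters after biological conditions
#'
#' Raw cluster indices are arbitrary; evaluation must happen on condition
#' labels. With `k = 3`, the cluster whose centroid is nearest the origin is
#' labeled `"none"` (no differential gene expression); each remaining
#' cluster takes the condition whose direction its centroid matches best in
#' absolute cosine (sign-blind, as for the closeness measure). With `k = 2`
#' both clusters are condition clusters. Clusters prefer their conditions
#' independently, so several clusters may share one label — this happens
#' when k-means split a single condition's genes in two (both halves then
#' correctly keep that condition) or when the conditions are confounded; a
#' warning reports the condition left without a cluster.
#'
#' @param dapc A [run_dapc()] result with `k` of 2 or 3.
#' @param directions A [build_directions()] result.
#' @return The `dapc_result` with an added `mapped_label` column and the
#'   cluster-to-label map in attribute `mapping`.
#' @export
map_clusters_to_conditions <- function(dapc, directions) {
  stopifnot(inherits(dapc, "dapc_result"), inherits(directions, "cd_directions"))
  k <- attr(dapc, "k")
  if (!k %in% c(2L, 3L))
    stop("cluster-to-condition mapping is defined for k = 2 or 3")
  centroids <- attr(dapc, "centroids")
  mapping <- rep(NA_character_, k)
  cond_clusters <- seq_len(k)
  if (k == 3L) {
    null_cluster <- which.min(sqrt(rowSums(centroids^2)))
    mapping[null_cluster] <- "none"
    cond_clusters <- setdiff(cond_clusters, null_cluster)
  }
  labs <- directions$labels
  cosm <- matrix(NA_real_, length(cond_clusters), 2L,
                 dimnames = list(NULL, labs))
  for (i in seq_along(cond_clusters)) for (lab in labs)
    cosm[i, lab] <- abs(.cosine(centroids[cond_clusters[i], ],
                                directions$vectors[lab, ]))
  pref <- labs[apply(cosm, 1L, which.max)]
  mapping[cond_clusters] <- pref
  orphan <- setdiff(labs, pref)
  if (length(orphan))
    warning("all condition clusters best match condition '",
            setdiff(labs, orphan)[1L],
            "'; no cluster mapped to condition '", orphan, "'")
  dapc$mapped_label <- mapping[dapc$cluster]
  attr(dapc, "mapping") <- mapping
  dapc
}

#' Write DAPC results to a delimited text file
#'
#' Columns: `gene_id`, `cluster`, `mapped_label` (when mapped),
#' `membership`.
#'
#' @param dapc A `dapc_result`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return Invisibly, `dapc`.
#' @export
write_dapc_results <- function(dapc, path, sep = "\t") {
  stopifnot(inherits(dapc, "dapc_result"))
  utils::write.table(as.data.frame(dapc), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(dapc)
}
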