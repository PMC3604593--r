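#' Signed closeness of a gene vector to a condition direction
#'
#' The closeness measure is the signed ratio of the norm of the orthogonal
#' projection of the gene vector `g` onto the direction `d` to the norm of
#' `g` itself — i.e. the signed cosine of the angle between them:
#' `sign(<g, d>) * ||proj_d(g)|| / ||g||`. It is exactly +/-1 iff `g` is a
#' non-zero multiple of `d` (collinearity) and 0 iff `g` is orthogonal to
#' `d`. Sign encodes which side of the origin the gene falls on, not
#' strength: -1 and +1 both mean a tight relationship with the direction.
#'
#' @param gene_vector Numeric gene coordinates in PC space.
#' @param direction Numeric direction coordinates (same length, non-zero).
#' @return A scalar in \[-1, 1\]. A zero-norm gene returns 0 (origin-noise
#'   interpretation; such genes are removed by the norm filter anyway).
#' @examples
#' cd_value(c(2, 1), c(4, 2))   # collinear: 1
#' cd_value(c(1, 1), c(1, 0))   # cos 45 degrees
#' @export
cd_value <- function(gene_vector, direction) {
  if (length(gene_vector) != length(direction))
    stop("`gene_vector` and `direction` must have the same length")
  nd <- .vnorm(direction)
  if (nd == 0) stop("`direction` has zero norm")
  ng <- .vnorm(gene_vector)
  if (ng == 0) return(0)
  val <- sum(gene_vector * direction) / (ng * nd)
  max(-1, min(1, val))
}

#' Compute closeness values of every gene to both condition directions
#'
#' @param space A fitted [fit_pca()] space.
#' @param directions A [build_directions()] result.
#' @return A data frame of class `cd_result` with columns `gene_id`, `norm`
#'   (gene-score norm in the retained PC space), `cd_<label>` for each of the
#'   two condition labels, `filtered` (all `FALSE`; see
#'   [apply_norm_filter()]) and `assigned` (all `"none"`; see
#'   [assign_by_cd()]). Condition labels are kept in attribute `conditions`.
#' @export
compute_cd <- function(space, directions) {
  stopifnot(inherits(space, "pc_space"), inherits(directions, "cd_directions"))
  scores <- space$gene_scores
  norms <- sqrt(rowSums(scores^2))
  out <- data.frame(gene_id = space$gene_ids, norm = norms,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (lab in directions$labels) {
    d <- directions$vectors[lab, ]
    raw <- as.numeric(scores %*% d) / (norms * .vnorm(d))
    raw[norms == 0] <- 0
    out[[paste0("cd_", lab)]] <- pmax(-1, pmin(1, raw))
  }
  out$filtered <- FALSE
  out$assigned <- "none"
  attr(out, "conditions") <- directions$labels
  class(out) <- c("cd_result", "data.frame")
  out
}

#' Filter genes near the origin by their score-vector norm
#'
#' Most genes do not change between conditions and sit near the center of the
#' factorial map; their angles are noise. Genes whose PC-score norm falls
#' strictly below the given empirical quantile of all gene norms (default the
#' first quartile, i.e. the 25% smallest norms) have both closeness values
#' fixed to 0 and are excluded from assignment. The quantile is computed with
#' linear interpolation (`stats::quantile`, type 7); under heavy ties nothing
#' may fall strictly below the cutoff, in which case no gene is filtered.
#'
#' @param cd A [compute_cd()] result.
#' @param quantile Filtering quantile in (0, 1), default 0.25.
#' @return The `cd_result` with `filtered` set and filtered rows zeroed; the
#'   number of filtered genes is in attribute `n_filtered`, the cutoff in
#'   attribute `norm_cutoff`.
#' @export
apply_norm_filter <- function(cd, quantile = 0.25) {
  stopifnot(inherits(cd, "cd_result"))
  if (length(quantile) != 1L || !is.finite(quantile) ||
      quantile <= 0 || quantile >= 1)
    stop("`quantile` must lie strictly inside (0, 1)")
  cutoff <- stats::quantile(cd$norm, probs = quantile, names = FALSE, type = 7)
  filt <- cd$norm < cutoff
  conds <- attr(cd, "conditions")
  for (lab in conds) cd[[paste0("cd_", lab)]][filt] <- 0
  cd$filtered <- filt
  cd$assigned[filt] <- "none"
  attr(cd, "n_filtered") <- sum(filt)
  attr(cd, "norm_cutoff") <- cutoff
  cd
}

#' Assign genes to conditions by thresholding the closeness measure
#'
#' Each unfiltered gene is assigned to the condition for which its absolute
#' closeness value is largest, provided that value exceeds the threshold;
#' otherwise it stays `"none"`. Sign is ignored: -1 and +1 both mean a tight
#' relationship with the direction. Exact ties between the two conditions are
#' left unassigned (counted in attribute `n_ties`). Thresholds may be set per
#' condition by passing a length-2 vector named by condition label.
#'
#' @param cd A filtered [apply_norm_filter()] result.
#' @param threshold Closeness cutoff(s) in (0, 1); a single shared value or a
#'   named length-2 vector.
#' @return The `cd_result` with the `assigned` column filled; the thresholds
#'   used are stored in attribute `threshold`.
#' @export
assign_by_cd <- function(cd, threshold) {
  stopifnot(inherits(cd, "cd_result"))
  conds <- attr(cd, "conditions")
  if (!all(is.finite(threshold)) || any(threshold <= 0) || any(threshold >= 1))
    stop("`threshold` must lie strictly inside (0, 1)")
  if (length(threshold) == 1L) {
    threshold <- stats::setNames(rep(threshold, 2L), conds)
  } else if (length(threshold) == 2L) {
    if (is.null(names(threshold)) || !setequal(names(threshold), conds))
      stop("per-condition thresholds must be named by condition label")
    threshold <- threshold[conds]
  } else stop("`threshold` must have length 1 or 2")
  a1 <- abs(cd[[paste0("cd_", conds[1L])]])
  a2 <- abs(cd[[paste0("cd_", conds[2L])]])
  tie <- !cd$filtered & a1 == a2 & a1 > 0
  best_lab <- ifelse(a1 >= a2, conds[1L], conds[2L])
  best_abs <- pmax(a1, a2)
  ok <- !cd$filtered & !tie & best_abs > threshold[best_lab]
  cd$assigned <- ifelse(ok, best_lab, "none")
  attr(cd, "threshold") <- threshold
  attr(cd, "n_ties") <- sum(tie)
  cd
}

#' Write closeness results to a delimited text file
#'
#' Columns: `gene_id`, `norm`, one `cd_<label>` per condition, `filtered`,
#' `assigned`.
#'
#' @param cd A `cd_result`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return Invisibly, `cd`.
#' @export
write_cd_results <- function(cd, path, sep = "\t") {
  stopifnot(inherits(cd, "cd_result"))
  utils::write.table(as.data.frame(cd), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(cd)
}
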