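#' Fit the principal-component space of an expression matrix
#'
#' Runs a correlation PCA (replicate columns centered and scaled to unit
#' variance) with genes as observations and replicate arrays as variables.
#' Gene row scores give the factorial map on which the closeness measure
#' operates; replicate variable coordinates are correlation-circle
#' coordinates, i.e. the correlations of each replicate with the retained
#' components (loading times the component standard deviation), so every
#' variable vector lies inside the unit disk.
#'
#' Principal axes carry an arbitrary sign; for reproducible output each
#' retained axis is flipped, when needed, so that the mean variable coordinate
#' of the first condition (the condition of the first replicate column) is
#' non-negative on that axis.
#'
#' @param x An [expression_matrix()].
#' @param n_components Number of principal axes to retain (default 2, the
#'   plane on which the scenario benchmarks and the closeness measure are
#'   defined; raise it for robustness studies).
#' @return An object of class `pc_space`: list with `n_components`,
#'   `eigenvalues` (all `p` axis variances, non-increasing), `gene_scores`
#'   (genes x K), `variable_coords` (replicates x K correlation-circle
#'   coordinates), `sdev` (component standard deviations of retained axes),
#'   `center`, `scale`, `conditions`, `gene_ids`, `replicate_ids`.
#' @examples
#' sim <- simulate_scenario(scenario_defaults("sim2", "F", seed = 1))
#' sp <- fit_pca(sim$matrix)
#' sp$eigenvalues[1:2]
#' @export
fit_pca <- function(x, n_components = 2) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  n <- nrow(v)
  p <- ncol(v)
  if (p < 2L) stop("at least 2 replicate columns are required")
  if (length(n_components) != 1L || n_components < 1L ||
      n_components > min(n, p))
    stop("`n_components` must be in 1..min(#genes, #replicates) = ",
         min(n, p))
  n_components <- as.integer(n_components)
  sds <- apply(v, 2L, stats::sd)
  if (any(sds < .Machine$double.eps^0.5))
    stop("constant (zero-variance) replicate column: ",
         paste(colnames(v)[sds < .Machine$double.eps^0.5], collapse = ", "))
  pr <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  eigenvalues <- pr$sdev^2
  k <- seq_len(n_components)
  scores <- pr$x[, k, drop = FALSE]
  # correlation-circle coordinates: loading * sqrt(eigenvalue)
  vc <- sweep(pr$rotation[, k, drop = FALSE], 2L, pr$sdev[k], `*`)
  cond1 <- x$conditions[[1L]]
  m1 <- colMeans(vc[x$conditions == cond1, , drop = FALSE])
  flip <- ifelse(m1 < 0, -1, 1)
  scores <- sweep(scores, 2L, flip, `*`)
  vc <- sweep(vc, 2L, flip, `*`)
  structure(list(
    n_components = n_components,
    eigenvalues = eigenvalues,
    gene_scores = scores,
    variable_coords = vc,
    sdev = pr$sdev[k],
    center = pr$center,
    scale = pr$scale,
    conditions = x$conditions,
    gene_ids = rownames(v),
    replicate_ids = colnames(v)
  ), class = "pc_space")
}

#' @export
print.pc_space <- function(x, ...) {
  expl <- 100 * x$eigenvalues[seq_len(x$n_components)] / sum(x$eigenvalues)
  cat("pc_space: ", length(x$gene_ids), " genes, ",
      length(x$replicate_ids), " replicates, ", x$n_components,
      " retained axes (", paste(sprintf("%.1f%%", expl), collapse = ", "),
      " of variance)\n", sep = "")
  invisible(x)
}

.vnorm <- function(v) sqrt(sum(v^2))

.cosine <- function(a, b) {
  na <- .vnorm(a)
  nb <- .vnorm(b)
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Build one direction per condition in PC space
#'
#' Each biological condition is represented by the arithmetic mean of the
#' correlation-circle coordinate vectors of its replicate arrays. The
#' direction's scale is irrelevant to the closeness measure (which is a
#' cosine); only its orientation matters.
#'
#' @param space A fitted [fit_pca()] space.
#' @param x The `expression_matrix` the space was fitted on (optional; the
#'   condition map stored in `space` is used when omitted).
#' @return Object of class `cd_directions`: list with `labels` (the two
#'   condition labels), `vectors` (2 x K matrix, one row per condition) and
#'   `members` (list of replicate ids per condition).
#' @export
build_directions <- function(space, x = NULL) {
  stopifnot(inherits(space, "pc_space"))
  conditions <- if (is.null(x)) space$conditions else {
    stopifnot(inherits(x, "expression_matrix"))
    if (!identical(names(x$conditions), space$replicate_ids))
      stop("`x` does not match the replicates the space was fitted on")
    x$conditions
  }
  labels <- unique(conditions)
  if (length(labels) != 2L) stop("exactly 2 condition labels required")
  vectors <- matrix(NA_real_, 2L, space$n_components,
                    dimnames = list(labels, colnames(space$variable_coords)))
  members <- vector("list", 2L)
  names(members) <- labels
  for (lab in labels) {
    reps <- names(conditions)[conditions == lab]
    if (!length(reps)) stop("condition '", lab, "' has no replicates")
    vectors[lab, ] <- colMeans(space$variable_coords[reps, , drop = FALSE])
    if (.vnorm(vectors[lab, ]) == 0)
      stop("direction for condition '", lab, "' has zero norm")
    members[[lab]] <- reps
  }
  structure(list(labels = labels, vectors = vectors, members = members),
            class = "cd_directions")
}

#' @export
print.cd_directions <- function(x, ...) {
  cat("cd_directions for conditions:", paste(x$labels, collapse = ", "), "\n")
  print(round(x$vectors, 4))
  cat("between-direction cosine:",
      round(.cosine(x$vectors[1L, ], x$vectors[2L, ]), 4), "\n")
  invisible(x)
}

#' Diagnose whether conditions form coherent, distinct directions
#'
#' A mean direction is a trustworthy proxy for a condition only when that
#' condition's replicate vectors are mutually correlated (coherent) and the
#' two conditions are not confounded on the factorial plane. This diagnostic
#' reports, per condition, the mean cosine between each member replicate
#' vector and the condition direction, and the cosine between the two
#' directions, raising warning flags when cohesion is low or the directions
#' nearly coincide.
#'
#' @param space A fitted `pc_space`.
#' @param directions A [build_directions()] result.
#' @param min_cohesion Warn when a condition's mean member-to-direction
#'   cosine falls below this value (default 0.7).
#' @param max_between Warn when the absolute cosine between the two
#'   directions exceeds this ceiling (default 0.6, i.e. directions closer
#'   than about 53 degrees: the angular margin around a high closeness
#'   cone has collapsed and the conditions are treated as confounded).
#' @return Object of class `coherence_report`: list with `within` (named mean
#'   cosines per condition), `between_cosine`, `warn_within` (named logical),
#'   `warn_confound` (logical), `any_warning`.
#' @export
check_direction_coherence <- function(space, directions,
                                      min_cohesion = 0.7,
                                      max_between = 0.6) {
  stopifnot(inherits(space, "pc_space"), inherits(directions, "cd_directions"))
  within <- vapply(directions$labels, function(lab) {
    d <- directions$vectors[lab, ]
    mean(vapply(directions$members[[lab]], function(r)
      .cosine(space$variable_coords[r, ], d), numeric(1)))
  }, numeric(1))
  between <- .cosine(directions$vectors[1L, ], directions$vectors[2L, ])
  warn_within <- within < min_cohesion
  warn_confound <- abs(between) > max_between
  structure(list(within = within, between_cosine = between,
                 warn_within = warn_within, warn_confound = warn_confound,
                 any_warning = any(warn_within) || warn_confound),
            class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  for (lab in names(x$within))
    cat(sprintf("condition %s: within-condition mean cosine %.3f%s\n", lab,
                x$within[[lab]], if (x$warn_within[[lab]]) " [WARN]" else ""))
  cat(sprintf("between-direction cosine %.3f%s\n", x$between_cosine,
              if (x$warn_confound) " [WARN: conditions confounded]" else ""))
  invisible(x)
}
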