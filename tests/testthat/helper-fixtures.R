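# Small in-code fixtures shared across the suite.

# 3 genes x 4 replicates toy matrix with an A/A/B/B design
toy_matrix <- function() {
  m <- matrix(c(1.0, 2.0, 3.0, 4.0,
                2.0, 1.5, 0.5, 1.0,
                0.1, 0.4, 0.2, 0.9), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("r1", "r2", "r3", "r4")))
  expression_matrix(m, c(r1 = "A", r2 = "A", r3 = "B", r4 = "B"))
}

# write an expression matrix + design to temp files, return the paths
write_toy_files <- function(x, sep = "\t") {
  mp <- tempfile(fileext = ".tsv")
  dp <- tempfile(fileext = ".tsv")
  write_expression(x, mp, dp, sep = sep)
  list(matrix = mp, design = dp)
}

# minimal cd_result built directly from norms and closeness values, for
# exercising the filter/assignment operations on controlled geometry
make_cd_result <- function(norm, cd_A, cd_B = rep(0, length(norm))) {
  out <- data.frame(gene_id = sprintf("g%03d", seq_along(norm)),
                    norm = norm, cd_A = cd_A, cd_B = cd_B,
                    filtered = logical(length(norm)),
                    assigned = rep("none", length(norm)),
                    stringsAsFactors = FALSE)
  attr(out, "conditions") <- c("A", "B")
  class(out) <- c("cd_result", "data.frame")
  out
}

# minimal pc_space carrying only gene scores, for controlled DAPC geometry
make_space <- function(scores, conditions = c(r1 = "A", r2 = "A",
                                              r3 = "B", r4 = "B")) {
  rownames(scores) <- sprintf("g%04d", seq_len(nrow(scores)))
  structure(list(
    n_components = ncol(scores),
    eigenvalues = rep(1, length(conditions)),
    gene_scores = scores,
    variable_coords = matrix(0, length(conditions), ncol(scores),
                             dimnames = list(names(conditions), NULL)),
    conditions = conditions,
    gene_ids = rownames(scores),
    replicate_ids = names(conditions)
  ), class = "pc_space")
}

# minimal direction pair from two explicit vectors
make_directions <- function(vA, vB) {
  vectors <- rbind(A = vA, B = vB)
  structure(list(labels = c("A", "B"), vectors = vectors,
                 members = list(A = "r1", B = "r3")),
            class = "cd_directions")
}

# minimal dapc_result from an assignment vector and centroid matrix
make_dapc <- function(cluster, centroids, k = nrow(centroids)) {
  out <- data.frame(gene_id = sprintf("g%04d", seq_along(cluster)),
                    cluster = cluster, membership = 1,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- k
  attr(out, "centroids") <- centroids
  class(out) <- c("dapc_result", "data.frame")
  out
}

# independent closeness oracle: explicit orthogonal projection, kept free
# of the cosine shortcut used by the implementation
oracle_cd <- function(g, d) {
  ip <- sum(g * d)
  proj <- (ip / sum(d * d)) * d
  if (sqrt(sum(g^2)) == 0) return(0)
  sign(ip) * sqrt(sum(proj^2)) / sqrt(sum(g^2))
}
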