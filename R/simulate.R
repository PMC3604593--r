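# Scenario parameter sets. The generative FORM (base multivariate normal
# with near-identity correlation; correlated block effects for the
# gene-confusion regime; truncated-normal effects with cross-condition
# leakage for the replicate-confusion regime) follows the benchmark design;
# the NUMERIC values below are this package's own calibration, fixed so that
# the favorable -> very-bad sweep moves the factorial map from cleanly
# separated groups to near-total confusion and preserves the expected
# ordering of the four strategies. They are constants of the package, not
# published values.
.sim1_params <- list(
  F = list(block_mean = 4, block_rho = 0.8, block_kappa = 0.0),
  N = list(block_mean = 4, block_rho = 0.8, block_kappa = 0.3),
  U = list(block_mean = 4, block_rho = 0.8, block_kappa = 0.6),
  B = list(block_mean = 4, block_rho = 0.8, block_kappa = 0.8)
)
.sim2_params <- list(
  F = list(lambda = 0.00),
  N = list(lambda = 0.30),
  U = list(lambda = 0.42),
  B = list(lambda = 0.52)
)

#' Default configuration of a simulation scenario
#'
#' Builds the parameter set of one benchmark scenario. Two regimes are
#' available: `"sim1"` progressively confounds the gene groups (block
#' effects of shrinking mean and correlation) and `"sim2"` progressively
#' confounds the replicates of the two conditions (a growing fraction of
#' each gene's effect leaks into the other condition's arrays). Scenario
#' codes are `"F"` (favorable), `"N"` (normal), `"U"` (unfavorable) and
#' `"B"` (very bad).
#'
#' Default dimensions are 250 differentially expressed genes per condition,
#' 500 background genes and 8 replicate arrays per condition (the replicate
#' count of a typical two-condition microarray series).
#'
#' @param mode `"sim1"` or `"sim2"`.
#' @param scenario One of `"F"`, `"N"`, `"U"`, `"B"`.
#' @param n1,n2 Differentially expressed genes belonging to condition 1 / 2.
#' @param n0 Background (non-differential) genes; may be 0.
#' @param p1,p2 Replicate arrays per condition (>= 2).
#' @param base_jitter Magnitude of the random symmetric perturbation applied
#'   to the base correlation matrix (0 = no perturbation).
#' @param base_rho Exchangeable correlation shared by all arrays in the base
#'   noise; 0 (the default) gives independent base noise.
#' @param null_shared_frac Fraction of the background genes that carry a
#'   gene-specific intensity component shared by ALL arrays (non-differential
#'   co-regulation / intensity drift, a standard feature of real series);
#'   such genes lie far from the origin on the factorial map yet belong to
#'   neither condition.
#' @param null_shared_sd Standard deviation of that shared component.
#' @param seed Integer seed; the generated matrix is a deterministic
#'   function of the full configuration.
#' @param ... Overrides for the scenario parameters: `block_mean`,
#'   `block_rho`, `block_kappa` (sim1; each a scalar shared by both gene
#'   groups or a length-2 vector, one value per group); `lambda`,
#'   `effect_mean`, `effect_sd` (sim2).
#' @return A list of class `scenario_config`.
#' @examples
#' scenario_defaults("sim2", "B", seed = 7)$lambda
#' @export
scenario_defaults <- function(mode = c("sim1", "sim2"),
                              scenario = c("F", "N", "U", "B"),
                              n1 = 250, n2 = 250, n0 = 500,
                              p1 = 8, p2 = 8,
                              base_jitter = 0.05, base_rho = 0,
                              null_shared_frac = NULL, null_shared_sd = 3.2,
                              seed = 1, ...) {
  mode <- match.arg(mode)
  if (length(scenario) != 1L || !scenario %in% c("F", "N", "U", "B"))
    stop("unknown scenario code '", paste(scenario, collapse = ","),
         "'; use one of F, N, U, B")
  if (n1 < 1L || n2 < 1L || n0 < 0L)
    stop("`n1` and `n2` must be positive, `n0` non-negative")
  if (p1 < 2L || p2 < 2L) stop("`p1` and `p2` must be at least 2")
  cfg <- list(mode = mode, scenario = scenario,
              n1 = as.integer(n1), n2 = as.integer(n2), n0 = as.integer(n0),
              p1 = as.integer(p1), p2 = as.integer(p2),
              base_jitter = base_jitter, base_rho = base_rho,
              null_shared_frac = null_shared_frac,
              null_shared_sd = null_shared_sd,
              seed = as.integer(seed))
  if (is.null(null_shared_frac))
    cfg$null_shared_frac <- if (mode == "sim2") 0.3 else 0
  if (mode == "sim1") {
    cfg <- c(cfg, .sim1_params[[scenario]])
  } else {
    cfg <- c(cfg, .sim2_params[[scenario]],
             list(leak_sd = 0.32, effect_mean = 5, effect_sd = 0.5))
  }
  dots <- list(...)
  allowed <- if (mode == "sim1") c("block_mean", "block_rho", "block_kappa")
    else c("lambda", "leak_sd", "effect_mean", "effect_sd")
  bad <- setdiff(names(dots), allowed)
  if (length(bad))
    stop("unknown parameter(s) for mode ", mode, ": ",
         paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario_config: mode ", x$mode, ", scenario ", x$scenario,
      ", genes ", x$n1, "+", x$n2, "+", x$n0, ", replicates ",
      x$p1, "+", x$p2, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# base correlation: exchangeable(base_rho) + symmetric uniform jitter,
# projected back to a valid (positive definite) correlation matrix
.near_identity_correlation <- function(p, jitter, rho = 0) {
  c0 <- matrix(rho, p, p)
  diag(c0) <- 1
  if (jitter == 0) return(c0)
  e <- matrix(stats::runif(p * p, -jitter, jitter), p, p)
  e <- (e + t(e)) / 2
  diag(e) <- 0
  c0 <- c0 + e
  dec <- eigen(c0, symmetric = TRUE)
  vals <- pmax(dec$values, 1e-6)
  stats::cov2cor(dec$vectors %*% (vals * t(dec$vectors)))
}

.exchangeable_correlation <- function(p, rho) {
  w <- matrix(rho, p, p)
  diag(w) <- 1
  if (min(eigen(w, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("block correlation matrix is not positive definite (rho = ",
         rho, ", p = ", p, ")")
  w
}

# inverse-CDF sampler of a normal truncated below at `lower`
.rtruncnorm <- function(n, mean, sd, lower = 0) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

.sim_base <- function(cfg) {
  n <- cfg$n1 + cfg$n2 + cfg$n0
  p <- cfg$p1 + cfg$p2
  cb <- .near_identity_correlation(p, cfg$base_jitter, cfg$base_rho)
  x <- MASS::mvrnorm(n, rep(0, p), cb)
  # a fraction of the background genes varies coherently across ALL arrays
  # (non-differential co-regulation / intensity drift); these genes are far
  # from the origin on the factorial map yet tied to neither condition
  n_sh <- round(cfg$null_shared_frac * cfg$n0)
  if (n_sh > 0) {
    rows <- cfg$n1 + cfg$n2 + seq_len(n_sh)
    x[rows, ] <- x[rows, ] + stats::rnorm(n_sh, 0, cfg$null_shared_sd)
  }
  dimnames(x) <- list(sprintf("g%05d", seq_len(n)),
                      c(paste0("A_", seq_len(cfg$p1)),
                        paste0("B_", seq_len(cfg$p2))))
  x
}

.sim_finish <- function(cfg, x) {
  conditions <- stats::setNames(rep(c("A", "B"), c(cfg$p1, cfg$p2)),
                                colnames(x))
  truth <- stats::setNames(rep(c("A", "B", "none"),
                               c(cfg$n1, cfg$n2, cfg$n0)), rownames(x))
  list(matrix = expression_matrix(x, conditions), truth = truth,
       config = cfg)
}

#' Simulate a two-condition matrix under the gene-confusion regime
#'
#' Base intensities are drawn from a zero-mean multivariate normal whose
#' correlation matrix is approximately the identity (exact identity plus a
#' small random symmetric jitter controlling the noise level). The block of
#' condition-1 genes x condition-1 arrays then receives an additive draw
#' from a multivariate normal with mean `block_mean` and exchangeable
#' correlation `block_rho`; the condition-2 block likewise. Gene confusion
#' is controlled by `block_kappa`: a `block_kappa`-scaled independent block
#' draw is also added to each group's OTHER-condition arrays, so that from
#' the favorable to the very-bad scenario the two gene groups' mean effect
#' directions — and with them the gene clouds on the factorial map —
#' progressively converge onto each other.
#'
#' @param config A `scenario_config` with mode `"sim1"`.
#' @return A list with `matrix` (an [expression_matrix()]), `truth` (named
#'   character vector, gene id to `"A"`, `"B"` or `"none"`) and `config`.
#' @export
simulate_sim1 <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$mode != "sim1") stop("`config` is not a sim1 configuration")
  mu <- rep_len(config$block_mean, 2L)
  rho <- rep_len(config$block_rho, 2L)
  kap <- rep_len(config$block_kappa, 2L)
  if (any(!is.finite(kap)) || any(kap < 0) || any(kap > 1))
    stop("`block_kappa` must lie in [0, 1], got ",
         paste(kap, collapse = ", "))
  w1 <- .exchangeable_correlation(config$p1, rho[1L])
  w2 <- .exchangeable_correlation(config$p2, rho[2L])
  set.seed(config$seed)
  x <- .sim_base(config)
  i1 <- seq_len(config$n1)
  i2 <- config$n1 + seq_len(config$n2)
  j1 <- seq_len(config$p1)
  j2 <- config$p1 + seq_len(config$p2)
  x[i1, j1] <- x[i1, j1] +
    MASS::mvrnorm(config$n1, rep(mu[1L], config$p1), w1)
  x[i2, j2] <- x[i2, j2] +
    MASS::mvrnorm(config$n2, rep(mu[2L], config$p2), w2)
  if (kap[1L] > 0)
    x[i1, j2] <- x[i1, j2] +
      kap[1L] * MASS::mvrnorm(config$n1, rep(mu[1L], config$p2), w2)
  if (kap[2L] > 0)
    x[i2, j1] <- x[i2, j1] +
      kap[2L] * MASS::mvrnorm(config$n2, rep(mu[2L], config$p1), w1)
  .sim_finish(config, x)
}

#' Simulate a two-condition matrix under the replicate-confusion regime
#'
#' Base intensities as in [simulate_sim1()]. Each differentially expressed
#' gene of condition *i* receives a positive effect size drawn from a normal
#' truncated below at 0 (inverse-CDF sampling), added to all of its own
#' condition's arrays; a gene-specific fraction of the same effect is added
#' to the other condition's arrays. The per-gene fraction is
#' `N(lambda, leak_sd)` truncated to `[0, 1]`, so genes scatter in an
#' angular fan around their condition's mean leak level: `lambda = 0` means
#' essentially no leakage (cleanly separated conditions) and `lambda = 1`
#' means every gene affects both conditions identically (total confusion;
#' the two direction vectors coincide). As `lambda` grows from the
#' favorable to the very-bad scenario the replicate vectors of the two
#' conditions become progressively correlated and the condition directions
#' collapse onto each other.
#'
#' @param config A `scenario_config` with mode `"sim2"`.
#' @return As [simulate_sim1()].
#' @export
simulate_sim2 <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$mode != "sim2") stop("`config` is not a sim2 configuration")
  if (!is.finite(config$lambda) || config$lambda < 0 || config$lambda > 1)
    stop("`lambda` must lie in [0, 1], got ", config$lambda)
  set.seed(config$seed)
  x <- .sim_base(config)
  i1 <- seq_len(config$n1)
  i2 <- config$n1 + seq_len(config$n2)
  j1 <- seq_len(config$p1)
  j2 <- config$p1 + seq_len(config$p2)
  e1 <- .rtruncnorm(config$n1, config$effect_mean, config$effect_sd)
  e2 <- .rtruncnorm(config$n2, config$effect_mean, config$effect_sd)
  l1 <- pmin(1, pmax(0, stats::rnorm(config$n1, config$lambda,
                                     config$leak_sd)))
  l2 <- pmin(1, pmax(0, stats::rnorm(config$n2, config$lambda,
                                     config$leak_sd)))
  x[i1, j1] <- x[i1, j1] + e1
  x[i1, j2] <- x[i1, j2] + l1 * e1
  x[i2, j2] <- x[i2, j2] + e2
  x[i2, j1] <- x[i2, j1] + l2 * e2
  .sim_finish(config, x)
}

#' Simulate a scenario, dispatching on the configured regime
#'
#' @param config A `scenario_config` from [scenario_defaults()].
#' @return As [simulate_sim1()].
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  switch(config$mode,
         sim1 = simulate_sim1(config),
         sim2 = simulate_sim2(config))
}

#' Write a simulated data set to delimited text files
#'
#' Writes the expression matrix, the design table, the ground-truth table
#' (`gene_id`, `true_label`) and, optionally, the fully resolved
#' configuration as JSON for provenance.
#'
#' @param sim A [simulate_scenario()] result.
#' @param matrix_path,design_path,truth_path Output paths.
#' @param config_path Optional JSON output path for the configuration.
#' @param sep Field delimiter.
#' @return Invisibly, `sim`.
#' @export
write_simulation <- function(sim, matrix_path, design_path, truth_path,
                             config_path = NULL, sep = "\t") {
  write_expression(sim$matrix, matrix_path, design_path, sep = sep)
  utils::write.table(
    data.frame(gene_id = names(sim$truth), true_label = unname(sim$truth),
               stringsAsFactors = FALSE),
    truth_path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(config_path))
    jsonlite::write_json(unclass(sim$config), config_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(sim)
}
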