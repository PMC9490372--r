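#' Simulate a balanced multi-environment trial with known structure
#'
#' Generates plot-level data
#' \deqn{Y_{ijr} = \mu + g_i + e_j + \sum_k \lambda_k \gamma_{ik} \delta_{jk} + \epsilon_{ijr}}
#' with centered genotype and environment main effects, a low-rank
#' multiplicative interaction whose score vectors are orthonormal and
#' orthogonal to the intercept (the identifiability constraints of the
#' AMMI model), and i.i.d. normal replicate error. In \code{slope_mode}
#' the interaction is instead generated as genotype-specific regression
#' responses \eqn{(b_i - 1) e_j} to the environment effect, the data
#' structure assumed by joint-regression stability analysis; the slopes
#' are centered so their mean is exactly 1.
#'
#' Environments are laid out as a locations x years grid so the dataset
#' carries the location and year factors the pooled ANOVA partitions.
#'
#' The defaults emulate a wheat variety trial measuring plot grain yield
#' (kg/plot): 13 genotypes across 4 locations and 2 years with 3
#' replicates, a grand mean of 2.8, and main-effect, interaction and
#' error scales matching the relative magnitudes such trials typically
#' show (interaction comparable to the environment signal, genotype
#' signal smaller).
#'
#' @param g Number of genotypes.
#' @param n_locations,n_years Environment grid; e = n_locations * n_years.
#' @param r Replicates per cell.
#' @param grand_mean Overall mean, trait units.
#' @param genotype_sd,environment_sd Standard deviations of the centered
#'   main-effect draws, trait units.
#' @param interaction_rank Number of multiplicative interaction components
#'   (0 for purely additive data); must be <= min(g-1, e-1).
#' @param interaction_sds Length-\code{interaction_rank} singular-value
#'   scales of the interaction on the cell-mean basis.
#' @param slope_mode If TRUE, generate interaction as genotype regression
#'   slopes on the environment effect instead of free bilinear terms.
#' @param slopes Optional length-g numeric slopes (only with
#'   \code{slope_mode}); drawn as N(1, 0.25^2) then centered to mean 1 if
#'   omitted.
#' @param error_sd Replicate error standard deviation.
#' @param trait Trait label for the generated records.
#' @param seed Integer seed; the draw order is fixed so a seed fully
#'   determines the dataset and the truth record.
#' @return A list with \code{data} (a \code{\link{met_data}} object) and
#'   \code{truth} (list of the drawn \code{grand_mean},
#'   \code{genotype_effects}, \code{environment_effects},
#'   \code{singular_values}, \code{genotype_scores},
#'   \code{environment_scores}, \code{slopes}, \code{cell_means}).
#' @examples
#' sim <- simulate_met(g = 5, n_locations = 2, n_years = 2, r = 2, seed = 1)
#' sim$data
#' @export
simulate_met <- function(g = 13L, n_locations = 4L, n_years = 2L, r = 3L,
                         grand_mean = 2.8, genotype_sd = 0.24,
                         environment_sd = 0.48, interaction_rank = 2L,
                         interaction_sds = c(4.8, 2.9) / sqrt(13 * 8) *
                           sqrt(g * n_locations * n_years),
                         slope_mode = FALSE, slopes = NULL,
                         error_sd = 0.15, trait = "yield", seed = 1L) {
  e <- n_locations * n_years
  stopifnot(g >= 2L, e >= 2L, r >= 1L, genotype_sd >= 0,
            environment_sd >= 0, error_sd >= 0)
  if (slope_mode) {
    interaction_rank <- 0L
  } else if (!is.null(slopes)) {
    stop("slopes are only meaningful with slope_mode = TRUE", call. = FALSE)
  }
  interaction_rank <- as.integer(interaction_rank)
  if (interaction_rank > min(g - 1L, e - 1L)) {
    stop("interaction_rank must be <= min(g-1, e-1) = ",
         min(g - 1L, e - 1L), call. = FALSE)
  }
  if (interaction_rank > 0L) {
    interaction_sds <- rep_len(interaction_sds, interaction_rank)
    if (any(interaction_sds < 0)) stop("negative interaction sd",
                                       call. = FALSE)
  }

  set.seed(as.integer(seed))
  # fixed draw order: genotype effects, environment effects, interaction
  # scores (or slopes), then errors — so truth is reproducible per seed
  alpha <- stats::rnorm(g, 0, genotype_sd)
  alpha <- alpha - mean(alpha)
  beta <- stats::rnorm(e, 0, environment_sd)
  beta <- beta - mean(beta)

  gamma <- delta <- NULL
  lambda <- numeric(0)
  b <- NULL
  inter <- matrix(0, g, e)
  if (slope_mode) {
    if (is.null(b <- slopes)) b <- stats::rnorm(g, 1, 0.25)
    if (length(b) != g) stop("slopes must have length g", call. = FALSE)
    b <- b - mean(b) + 1  # joint-regression constraint: mean slope 1
    inter <- outer(b - 1, beta)
  } else if (interaction_rank > 0L) {
    gamma <- .orthonormal_scores(g, interaction_rank)
    delta <- .orthonormal_scores(e, interaction_rank)
    lambda <- interaction_sds
    inter <- gamma %*% (lambda * t(delta))
  }

  genotypes <- sprintf("G%02d", seq_len(g))
  locations <- sprintf("L%d", seq_len(n_locations))
  years <- sprintf("Y%d", seq_len(n_years))
  cellmeans <- grand_mean + outer(alpha, beta, "+") + inter
  dimnames(cellmeans) <- list(genotypes, sprintf("ENV%d", seq_len(e)))

  # environment j = location within year (ENV1..ENVL = year 1, ...)
  grid <- expand.grid(location = locations, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  records <- expand.grid(rep = seq_len(r), genotype = genotypes,
                         env = seq_len(e), KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  records$location <- grid$location[records$env]
  records$year <- grid$year[records$env]
  mu_cell <- cellmeans[cbind(match(records$genotype, genotypes),
                             records$env)]
  records$value <- mu_cell + stats::rnorm(nrow(records), 0, error_sd)
  records$trait <- trait

  data <- met_data(records[c("genotype", "location", "year", "rep",
                             "trait", "value")])
  truth <- list(grand_mean = grand_mean,
                genotype_effects = stats::setNames(alpha, genotypes),
                environment_effects = stats::setNames(beta, colnames(cellmeans)),
                singular_values = lambda,
                genotype_scores = gamma,
                environment_scores = delta,
                slopes = if (slope_mode) stats::setNames(b, genotypes),
                cell_means = cellmeans)
  list(data = data, truth = truth)
}

# k columns orthonormal and orthogonal to the all-ones vector, via QR of
# [1 | standard normal draws]
.orthonormal_scores <- function(n, k) {
  if (k > n - 1L) stop("rank too large", call. = FALSE)
  raw <- matrix(stats::rnorm(n * k), n, k)
  q <- qr.Q(qr(cbind(1, raw)))[, -1L, drop = FALSE]
  # fix signs for reproducibility: largest-magnitude element positive
  for (j in seq_len(k)) {
    i <- which.max(abs(q[, j]))
    if (q[i, j] < 0) q[, j] <- -q[, j]
  }
  q
}

#' Write the ground-truth record of a simulated MET alongside its data
#'
#' @param truth The \code{truth} element returned by
#'   \code{\link{simulate_met}}.
#' @param path Output path (tab-delimited key-value text).
#' @return \code{path}, invisibly.
#' @export
write_met_truth <- function(truth, path) {
  lines <- c(sprintf("grand_mean\t%.15g", truth$grand_mean),
             sprintf("genotype_effect\t%s\t%.15g",
                     names(truth$genotype_effects), truth$genotype_effects),
             sprintf("environment_effect\t%s\t%.15g",
                     names(truth$environment_effects),
                     truth$environment_effects))
  if (length(truth$singular_values) > 0L) {
    lines <- c(lines, sprintf("singular_value\t%d\t%.15g",
                              seq_along(truth$singular_values),
                              truth$singular_values))
  }
  if (!is.null(truth$slopes)) {
    lines <- c(lines, sprintf("slope\t%s\t%.15g", names(truth$slopes),
                              truth$slopes))
  }
  writeLines(lines, path)
  invisible(path)
}
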