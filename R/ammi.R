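#' Fit the AMMI model to a two-way table
#'
#' Additive Main effects and Multiplicative Interaction: the cell means
#' decompose as
#' \deqn{x_{ij} = \mu + \alpha_i + \beta_j + \sum_n \lambda_n \gamma_{in} \delta_{jn}}
#' where the multiplicative part is the singular value decomposition of
#' the double-centered interaction matrix
#' \eqn{z_{ij} = x_{ij} - X_{i.} - X_{.j} + X_{..}}. Score columns are
#' orthonormal; components are ordered by decreasing singular value and
#' each component's sign is fixed so its largest-magnitude environment
#' score is positive (a deterministic convention — SVD signs are
#' otherwise arbitrary).
#'
#' On the \code{"plot"} basis the interaction matrix is scaled by
#' \eqn{\sqrt{r}} before decomposition so that the squared singular
#' values sum to the plot-level interaction sum of squares; on the
#' \code{"means"} basis they sum to the means-level interaction SS.
#'
#' @param table A \code{two_way_table} with g >= 3 and e >= 3.
#' @param basis "means" (default; biplot coordinates are conventionally
#'   on this scale) or "plot".
#' @return Object of class \code{ammi_model}: list with
#'   \code{grand_mean}, \code{genotype_effects} (sum 0),
#'   \code{environment_effects} (sum 0), \code{singular_values},
#'   \code{genotype_scores} (g x n), \code{environment_scores} (e x n),
#'   \code{basis}, \code{replicates}, \code{table}.
#' @export
fit_ammi <- function(table, basis = c("means", "plot")) {
  basis <- match.arg(basis)
  g <- length(table$genotypes)
  e <- length(table$environments)
  if (g < 3L || e < 3L) stop("AMMI needs g >= 3 and e >= 3", call. = FALSE)
  z <- interaction_residuals(table)
  if (basis == "plot") z <- z * sqrt(table$replicates)
  dec <- svd(z)
  n <- min(g - 1L, e - 1L)
  lambda <- dec$d[seq_len(n)]
  lambda[lambda < 1e-12 * max(lambda, 1)] <- 0
  u <- dec$u[, seq_len(n), drop = FALSE]
  v <- dec$v[, seq_len(n), drop = FALSE]
  for (k in seq_len(n)) {
    i <- which.max(abs(v[, k]))
    if (v[i, k] < 0) {
      v[, k] <- -v[, k]
      u[, k] <- -u[, k]
    }
  }
  dimnames(u) <- list(table$genotypes, paste0("IPCA", seq_len(n)))
  dimnames(v) <- list(table$environments, paste0("IPCA", seq_len(n)))
  structure(list(
    grand_mean = table$grand_mean,
    genotype_effects = table$genotype_means - table$grand_mean,
    environment_effects = table$environment_means - table$grand_mean,
    singular_values = lambda,
    genotype_scores = u,
    environment_scores = v,
    basis = basis,
    replicates = table$replicates,
    table = table
  ), class = "ammi_model")
}

#' @export
print.ammi_model <- function(x, ...) {
  cat(sprintf("AMMI model (%s basis): %d genotypes x %d environments\n",
              x$basis, nrow(x$genotype_scores), nrow(x$environment_scores)))
  pct <- 100 * x$singular_values^2 / sum(x$singular_values^2)
  cat("IPCA % of interaction SS:",
      paste(sprintf("%.1f", utils::head(pct, 4)), collapse = ", "), "...\n")
  invisible(x)
}

#' Gollob degrees of freedom for the n-th interaction principal component
#'
#' \deqn{df_n = g + e - 1 - 2n}
#'
#' @param g,e Genotype and environment counts.
#' @param n Component index (vectorised).
#' @return Integer degrees of freedom.
#' @export
gollob_df <- function(g, e, n) {
  as.integer(g + e - 1 - 2 * n)
}

#' AMMI analysis of variance with the IPCA partition
#'
#' Extends the G / E / G x E table with one row per retained interaction
#' principal component (df per Gollob, \eqn{g + e - 1 - 2n}) plus a
#' residual row pooling the remaining components. Each IPCA's percentage
#' explained is its share of the interaction SS. On the plot basis all
#' terms are tested against the pooled error mean square.
#'
#' @param model An \code{ammi_model}.
#' @param n_axes Number of IPCA rows to report (default 2).
#' @return An \code{anova_table} with rows Environment, Genotype, G x E,
#'   IPCA1..IPCAn, Residual (and Error on the plot basis). The
#'   \code{pct_explained} column holds the share of total G+E+GE SS for
#'   the main rows and the share of the interaction SS for IPCA rows.
#' @export
ammi_anova <- function(model, n_axes = 2L) {
  table <- model$table
  g <- length(table$genotypes)
  e <- length(table$environments)
  n_max <- min(g - 1L, e - 1L)
  n_axes <- as.integer(n_axes)
  if (n_axes > n_max) {
    stop("n_axes exceeds available components (", n_max, ")", call. = FALSE)
  }
  base <- env_collapsed_anova(table, basis = model$basis)
  ss_ge <- base$ss[match("G x E", base$source)]
  lam2 <- model$singular_values^2
  ipca_ss <- lam2[seq_len(n_axes)]
  ipca_df <- gollob_df(g, e, seq_len(n_axes))
  resid_ss <- ss_ge - sum(ipca_ss)
  resid_df <- (g - 1L) * (e - 1L) - sum(ipca_df)

  src <- c("Environment", "Genotype", "G x E",
           paste0("IPCA", seq_len(n_axes)), "Residual")
  df <- c(base$df[1:3], ipca_df, resid_df)
  ss <- c(base$ss[1:3], ipca_ss, resid_ss)
  pct <- c(base$pct_explained[1:3], 100 * ipca_ss / ss_ge,
           100 * resid_ss / ss_ge)
  use_error <- model$basis == "plot" && table$error_df > 0L
  if (use_error) {
    src <- c(src, "Error")
    df <- c(df, table$error_df)
    ss <- c(ss, table$pooled_error_ms * table$error_df)
    pct <- c(pct, NA_real_)
  }
  out <- anova_table(src, df, ss,
                     error_ms = if (use_error) table$pooled_error_ms,
                     error_df = if (use_error) table$error_df,
                     pct = pct, basis = model$basis)
  out$f[out$source == "Error"] <- NA_real_
  out$p[out$source == "Error"] <- NA_real_
  out
}

# scaled scores: lambda^s to genotypes, lambda^(1-s) to environments
.ammi_scaled <- function(model, s = 0.5) {
  list(gen = sweep(model$genotype_scores, 2L, model$singular_values^s, `*`),
       env = sweep(model$environment_scores, 2L,
                   model$singular_values^(1 - s), `*`))
}

#' AMMI1 biplot coordinates: main effect against IPCA1
#'
#' Genotype abscissae are \eqn{\mu + \alpha_g} and environment abscissae
#' \eqn{\mu + \beta_e} (the main effects on the trait scale); ordinates
#' are the first interaction scores under symmetric singular-value
#' scaling (\eqn{\lambda_1^{0.5}} to each side).
#'
#' @param model An \code{ammi_model}.
#' @param scaling Score-scaling exponent in [0, 1] assigned to the
#'   genotype side (default 0.5, symmetric).
#' @return data.frame with columns \code{entity} ("genotype" /
#'   "environment"), \code{label}, \code{mean}, \code{ipca1}.
#' @export
ammi1_coords <- function(model, scaling = 0.5) {
  sc <- .ammi_scaled(model, scaling)
  data.frame(
    entity = rep(c("genotype", "environment"),
                 c(nrow(sc$gen), nrow(sc$env))),
    label = c(rownames(sc$gen), rownames(sc$env)),
    mean = c(model$grand_mean + model$genotype_effects,
             model$grand_mean + model$environment_effects),
    ipca1 = c(sc$gen[, 1L], sc$env[, 1L]),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' AMMI2 biplot coordinates and origin-distance stability ranking
#'
#' The first two scaled interaction score pairs for genotypes and
#' environments. A genotype's Euclidean distance from the origin in
#' this plane summarises its interaction load; genotypes are ranked by
#' ascending distance (rank 1 = most stable). Distances are invariant
#' to the SVD sign convention.
#'
#' @param model An \code{ammi_model} with at least 2 components.
#' @param scaling Score-scaling exponent (default 0.5, symmetric).
#' @return data.frame with columns \code{entity, label, ipca1, ipca2,
#'   distance, stability_rank} (rank only for genotypes).
#' @export
ammi2_coords <- function(model, scaling = 0.5) {
  if (length(model$singular_values) < 2L) {
    stop("AMMI2 needs at least 2 interaction components", call. = FALSE)
  }
  sc <- .ammi_scaled(model, scaling)
  out <- data.frame(
    entity = rep(c("genotype", "environment"),
                 c(nrow(sc$gen), nrow(sc$env))),
    label = c(rownames(sc$gen), rownames(sc$env)),
    ipca1 = c(sc$gen[, 1L], sc$env[, 1L]),
    ipca2 = c(sc$gen[, 2L], sc$env[, 2L]),
    stringsAsFactors = FALSE, row.names = NULL)
  out$distance <- sqrt(out$ipca1^2 + out$ipca2^2)
  out$stability_rank <- NA_integer_
  gi <- out$entity == "genotype"
  out$stability_rank[gi] <- rank(out$distance[gi], ties.method = "first")
  out
}

#' Reconstruct cell means from an AMMI model truncated at n components
#'
#' @param model An \code{ammi_model}.
#' @param n_axes Components to retain (default all).
#' @return g x e matrix of fitted cell means (on the means scale).
#' @export
ammi_fitted <- function(model, n_axes = length(model$singular_values)) {
  k <- seq_len(n_axes)
  inter <- model$genotype_scores[, k, drop = FALSE] %*%
    (model$singular_values[k] * t(model$environment_scores[, k,
                                                           drop = FALSE]))
  if (model$basis == "plot") inter <- inter / sqrt(model$replicates)
  model$grand_mean + outer(model$genotype_effects,
                           model$environment_effects, "+") + inter
}

#' Plot an AMMI1 or AMMI2 biplot
#'
#' @param x An \code{ammi_model}.
#' @param type 1 (mean vs IPCA1) or 2 (IPCA1 vs IPCA2).
#' @param ... Passed to \code{plot}.
#' @return Invisibly, the coordinate data.frame that was drawn.
#' @export
plot.ammi_model <- function(x, type = 1, ...) {
  if (type == 1) {
    co <- ammi1_coords(x)
    xv <- co$mean; yv <- co$ipca1
    xlab <- sprintf("Mean (%s)", x$table$trait); ylab <- "IPCA1"
  } else {
    co <- ammi2_coords(x)
    xv <- co$ipca1; yv <- co$ipca2
    xlab <- "IPCA1"; ylab <- "IPCA2"
  }
  graphics::plot(xv, yv, type = "n", xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, v = if (type == 1) mean(xv) else 0,
                   col = "grey70", lty = 2)
  graphics::text(xv, yv, co$label,
                 col = ifelse(co$entity == "genotype", "black", "blue"),
                 cex = 0.8)
  invisible(co)
}
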