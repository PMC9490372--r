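#' Environment index for joint-regression stability analysis
#'
#' The index of environment j is its mean over genotypes minus the grand
#' mean, \eqn{I_j = X_{.j} - X_{..}}; the indices sum to zero on a
#' balanced table.
#'
#' @param table A \code{two_way_table}.
#' @return Named numeric vector of length e.
#' @export
environment_index <- function(table) {
  table$environment_means - table$grand_mean
}

#' Eberhart-Russell joint regression per genotype
#'
#' Fits \eqn{Y_{ij} = \mu_i + \beta_i I_j + \delta_{ij}} for each
#' genotype by least squares on the environment index. The slope is
#' \eqn{b_i = \sum_j x_{ij} I_j / \sum_j I_j^2}; the deviation mean
#' square is \eqn{S^2_{di} = \sum_j \hat\delta_{ij}^2 / (e - 2)}, minus
#' \code{pooled_error_ms / r} when the classical error correction is
#' requested, so that a genotype tracking the environment means exactly
#' has expected deviation zero.
#'
#' @param table A \code{two_way_table} with e >= 3.
#' @param index Optional environment index (defaults to
#'   \code{\link{environment_index}}).
#' @param error_correction Subtract \code{pooled_error_ms / r} from the
#'   raw deviation mean square (default TRUE).
#' @return data.frame with columns \code{genotype, mean, bi, s2di},
#'   plus \code{t_bi} and \code{p_bi} testing H0: bi = 1 against the
#'   regression deviation, and (when pooled error is available)
#'   \code{f_s2di, p_s2di} testing H0: S2di = 0.
#' @export
er_regression <- function(table, index = NULL, error_correction = TRUE) {
  e <- length(table$environments)
  if (e < 3L) stop("need at least 3 environments for deviation df",
                   call. = FALSE)
  if (is.null(index)) index <- environment_index(table)
  ss_i <- sum(index^2)
  if (ss_i <= 0) {
    stop("undefined slope: environment index has no variance",
         call. = FALSE)
  }
  x <- table$means
  bi <- as.numeric(x %*% index) / ss_i
  fitted <- outer(table$genotype_means, rep(1, e)) + outer(bi, index)
  dev_ss <- rowSums((x - fitted)^2)
  dev_ms <- dev_ss / (e - 2L)
  correction <- if (error_correction) {
    table$pooled_error_ms / table$replicates
  } else 0
  se_bi <- sqrt(dev_ms / ss_i)
  t_bi <- ifelse(se_bi > 0, (bi - 1) / se_bi, NA_real_)
  p_bi <- 2 * stats::pt(abs(t_bi), e - 2L, lower.tail = FALSE)
  out <- data.frame(genotype = table$genotypes,
                    mean = as.numeric(table$genotype_means),
                    bi = bi, s2di = dev_ms - correction,
                    t_bi = t_bi, p_bi = p_bi,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (table$error_df > 0L) {
    mse_mean <- table$pooled_error_ms / table$replicates
    out$f_s2di <- dev_ms / mse_mean
    out$p_s2di <- stats::pf(out$f_s2di, e - 2L, table$error_df,
                            lower.tail = FALSE)
  }
  out
}

#' Perkins-Jinks regression of interaction deviations
#'
#' Regresses each genotype's interaction deviation
#' \eqn{x_{ij} - X_{i.} - X_{.j} + X_{..}} on the environment index.
#' The slope \eqn{B_i} equals the Eberhart-Russell slope minus one
#' (\eqn{B_i = b_i - 1}); the deviation mean square \eqn{DJ_i} is the
#' raw residual mean square (no error correction), so across genotypes
#' \eqn{DJ_i - S^2_{di}} is the constant \code{pooled_error_ms / r}.
#'
#' @inheritParams er_regression
#' @return data.frame with columns \code{genotype, Bi, dji}.
#' @export
pj_regression <- function(table, index = NULL) {
  e <- length(table$environments)
  if (e < 3L) stop("need at least 3 environments for deviation df",
                   call. = FALSE)
  if (is.null(index)) index <- environment_index(table)
  ss_i <- sum(index^2)
  if (ss_i <= 0) {
    stop("undefined slope: environment index has no variance",
         call. = FALSE)
  }
  z <- interaction_residuals(table)
  Bi <- as.numeric(z %*% index) / ss_i
  resid <- z - outer(Bi, index)
  data.frame(genotype = table$genotypes, Bi = Bi,
             dji = rowSums(resid^2) / (e - 2L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Wricke's ecovalence
#'
#' Each genotype's contribution to the genotype x environment
#' interaction: \eqn{W_i = \sum_j (x_{ij} - X_{i.} - X_{.j} + X_{..})^2}.
#' The ecovalences sum to the interaction sum of squares of the means
#' table.
#'
#' @param table A \code{two_way_table}.
#' @return Named numeric vector of length g.
#' @export
wricke_ecovalence <- function(table) {
  z <- interaction_residuals(table)
  stats::setNames(rowSums(z^2), table$genotypes)
}

#' Francis-Kannenberg stability: per-genotype SD and CV of environment means
#'
#' @param table A \code{two_way_table} with e >= 2.
#' @return data.frame with columns \code{genotype, sd, cv} where
#'   \code{sd} is the sample standard deviation over the genotype's
#'   environment means and \code{cv = 100 * sd / mean} (percent).
#' @export
francis_kannenberg <- function(table) {
  if (length(table$environments) < 2L) {
    stop("need at least 2 environments", call. = FALSE)
  }
  sd <- apply(table$means, 1L, stats::sd)
  m <- table$genotype_means
  if (any(m == 0)) stop("cv undefined: zero genotype mean", call. = FALSE)
  data.frame(genotype = table$genotypes, sd = as.numeric(sd),
             cv = as.numeric(100 * sd / m),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Adaptation class from the joint-regression slope and mean performance
#'
#' Slopes above \code{1 + tol} mark genotypes responsive to (adapted to)
#' favorable environments, slopes below \code{1 - tol} mark adaptation
#' to unfavorable environments, and slopes within the band mark average
#' (general) adaptation. The slope class is crossed with whether the
#' genotype mean exceeds the trait grand mean.
#'
#' @param bi Numeric vector of joint-regression slopes.
#' @param genotype_means Numeric vector of genotype means.
#' @param grand_mean Trait grand mean.
#' @param tol Half-width of the "average" slope band (default 0.05).
#' @return data.frame with columns \code{slope_class} (favorable /
#'   average / unfavorable), \code{performance} (above-average /
#'   below-average) and \code{adaptation} (the combined verbal label).
#' @export
classify_adaptation <- function(bi, genotype_means, grand_mean,
                                tol = 0.05) {
  slope_class <- ifelse(bi > 1 + tol, "favorable",
                        ifelse(bi < 1 - tol, "unfavorable", "average"))
  performance <- ifelse(genotype_means > grand_mean, "above-average",
                        "below-average")
  adaptation <- paste0(performance, ", ",
                       c(favorable = "adapted to favorable environments",
                         unfavorable = "adapted to unfavorable environments",
                         average = "average adaptation")[slope_class])
  data.frame(slope_class = slope_class, performance = performance,
             adaptation = adaptation, stringsAsFactors = FALSE)
}

#' Full univariate stability table
#'
#' Assembles the four univariate stability families for one trait:
#' Francis-Kannenberg (Sd, CV), Eberhart-Russell (bi, S2di),
#' Perkins-Jinks (Bi, DJi) and Wricke's ecovalence (Wi), together with
#' the adaptation classification.
#'
#' @param table A \code{two_way_table}.
#' @param error_correction Passed to \code{\link{er_regression}}.
#' @param tol Passed to \code{\link{classify_adaptation}}.
#' @return Object of class \code{stability_table}: data.frame with one
#'   row per genotype and columns \code{genotype, mean, sd, cv, bi,
#'   s2di, Bi, dji, wi, t_bi, p_bi} (and \code{f_s2di, p_s2di} when
#'   pooled error is available) plus the classification columns.
#' @export
stability_table <- function(table, error_correction = TRUE, tol = 0.05) {
  fk <- francis_kannenberg(table)
  er <- er_regression(table, error_correction = error_correction)
  pj <- pj_regression(table)
  wi <- wricke_ecovalence(table)
  cls <- classify_adaptation(er$bi, er$mean, table$grand_mean, tol = tol)
  out <- cbind(er[c("genotype", "mean")], fk[c("sd", "cv")],
               er[setdiff(names(er), c("genotype", "mean"))],
               pj[c("Bi", "dji")], wi = as.numeric(wi), cls)
  ord <- c("genotype", "mean", "sd", "cv", "bi", "s2di", "Bi", "dji",
           "wi")
  out <- out[c(ord, setdiff(names(out), ord))]
  structure(out, class = c("stability_table", "data.frame"),
            trait = table$trait, grand_mean = table$grand_mean)
}

#' @export
print.stability_table <- function(x, digits = 4, ...) {
  cat(sprintf("Univariate stability measures for '%s' (grand mean %.4f)\n",
              attr(x, "trait"), attr(x, "grand_mean")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df[c("genotype", "mean", "sd", "cv", "bi", "s2di", "Bi", "dji",
             "wi", "adaptation")], row.names = FALSE)
  invisible(x)
}
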