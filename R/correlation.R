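#' Pairwise Pearson correlation among traits
#'
#' Computes \eqn{r = \mathrm{cov}(A,B) / \sqrt{\mathrm{var}(A)\,\mathrm{var}(B)}}
#' for every trait pair on a chosen observational basis, with two-sided
#' p-values from the t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on
#' n - 2 degrees of freedom.
#'
#' @param data A \code{met_data} object.
#' @param traits Traits to correlate (default: all traits in the data).
#' @param basis Observational unit: \code{"cell-means"} (default; the
#'   g x e genotype-by-environment cell means pooled across all
#'   environments), \code{"genotype-means"} (g overall genotype means),
#'   or \code{"plot"} (raw plot records).
#' @param adjust p-value adjustment method passed to
#'   \code{\link[stats]{p.adjust}} (default \code{"none"};
#'   \code{"bonferroni"} available).
#' @return Object of class \code{correlation_matrix}: list with
#'   \code{traits}, \code{r} (symmetric, unit diagonal), \code{p}
#'   (symmetric, NA diagonal), \code{n}, \code{basis}.
#' @export
pearson_matrix <- function(data, traits = NULL,
                           basis = c("cell-means", "genotype-means",
                                     "plot"),
                           adjust = "none") {
  stopifnot(inherits(data, "met_data"))
  basis <- match.arg(basis)
  if (is.null(traits)) traits <- met_traits(data)
  missing_tr <- setdiff(traits, met_traits(data))
  if (length(missing_tr) > 0L) {
    stop("unknown trait(s): ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  obs <- sapply(traits, function(tr) {
    sub <- data[data$trait == tr, , drop = FALSE]
    switch(basis,
      "plot" = {
        key <- order(sub$genotype, sub$location, sub$year, sub$rep)
        sub$value[key]
      },
      "cell-means" = {
        tw <- cell_means(data, tr)
        as.numeric(tw$means)
      },
      "genotype-means" = {
        tw <- cell_means(data, tr)
        as.numeric(tw$genotype_means)
      })
  })
  if (!is.matrix(obs)) obs <- matrix(obs, ncol = length(traits))
  n <- nrow(obs)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  zero_var <- apply(obs, 2L, stats::sd) == 0
  if (any(zero_var)) {
    warning("zero-variance trait(s), correlations reported as NA: ",
            paste(traits[zero_var], collapse = ", "), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(obs))
  diag(r) <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  p[is.na(r)] <- NA_real_
  diag(p) <- NA_real_
  if (adjust != "none") {
    lower <- lower.tri(p)
    p[lower] <- stats::p.adjust(p[lower], method = adjust)
    p[upper.tri(p)] <- t(p)[upper.tri(p)]
  }
  dimnames(r) <- dimnames(p) <- list(traits, traits)
  structure(list(traits = traits, r = r, p = p, n = n, basis = basis),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlation (%s basis, n = %d)\n", x$basis, x$n))
  disp <- matrix(paste0(formatC(x$r, digits = digits, format = "f"),
                        p_stars(x$p)),
                 nrow(x$r), dimnames = dimnames(x$r))
  diag(disp) <- "1"
  print(disp, quote = FALSE)
  invisible(x)
}
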