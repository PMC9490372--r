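#' Assemble an ANOVA table with mean squares, F tests and percentages
#'
#' Low-level constructor shared by the pooled and collapsed ANOVA
#' routines. Mean squares are \code{ss/df}; F and p are computed against
#' the supplied error mean square when present.
#'
#' @param source Character vector of source labels.
#' @param df Integer degrees of freedom.
#' @param ss Sums of squares.
#' @param error_ms,error_df Error mean square and df used as the F-test
#'   denominator; \code{NULL} suppresses F and p.
#' @param pct Optional percentage-explained column (NA where not
#'   applicable).
#' @param basis "plot" or "means".
#' @return Object of class \code{anova_table}: a data.frame with columns
#'   \code{source, df, ss, ms, f, p, pct_explained}.
#' @export
anova_table <- function(source, df, ss, error_ms = NULL, error_df = NULL,
                        pct = NULL, basis = "plot") {
  stopifnot(length(source) == length(df), length(df) == length(ss))
  df <- unname(df)
  ss <- unname(ss)
  ms <- ifelse(df > 0, ss / df, NA_real_)
  if (!is.null(error_ms) && error_ms > 0) {
    f <- ms / error_ms
    p <- stats::pf(f, df, error_df, lower.tail = FALSE)
  } else {
    f <- p <- rep(NA_real_, length(ss))
  }
  if (is.null(pct)) pct <- rep(NA_real_, length(ss))
  out <- data.frame(source = source, df = as.integer(df), ss = ss, ms = ms,
                    f = f, p = p, pct_explained = pct,
                    stringsAsFactors = FALSE)
  structure(out, class = c("anova_table", "data.frame"), basis = basis)
}

#' Significance stars at the 0.05 / 0.01 / 0.001 thresholds
#' @param p Numeric vector of p-values.
#' @return Character vector: "***", "**", "*" or "ns" ("" for NA).
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' @export
print.anova_table <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  df$ss <- round(df$ss, digits + 2)
  df$ms <- round(df$ms, digits + 2)
  df$f <- round(df$f, 2)
  df$stars <- p_stars(df$p)
  df$p <- signif(df$p, 3)
  df$pct_explained <- round(df$pct_explained, 2)
  cat(sprintf("ANOVA (%s basis)\n", attr(x, "basis")))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Pooled factorial ANOVA over genotype, location and year
#'
#' Classical fixed-effects partition of plot-level data into genotype
#' (G), location (L), year (Y), all two- and three-way interactions, and
#' pooled error. On a balanced design the sequential sums of squares
#' equal the textbook mean-contrast sums, and every term is tested
#' against the pooled error mean square. Replicate blocks are pooled
#' into error.
#'
#' @param data A \code{met_data} object.
#' @param trait Trait to analyse.
#' @param g_over_ge If TRUE, test the genotype term over the pooled
#'   G x L, G x Y and G x L x Y interaction instead of pooled error.
#' @return An \code{anova_table} with rows Genotype, Location, Year,
#'   G x Y, G x L, Y x L, G x Y x L, Error, Total.
#' @export
pooled_anova <- function(data, trait, g_over_ge = FALSE) {
  stopifnot(inherits(data, "met_data"))
  if (!trait %in% data$trait) stop("unknown trait: ", trait, call. = FALSE)
  sub <- data[data$trait == trait, , drop = FALSE]
  r <- attr(data, "r")
  G <- factor(sub$genotype)
  L <- factor(sub$location)
  Y <- factor(sub$year)
  fit <- stats::aov(sub$value ~ G + L + Y + G:Y + G:L + Y:L + G:L:Y)
  tab <- summary(fit)[[1L]]
  term <- trimws(rownames(tab))
  pick <- function(lbl) {
    i <- match(lbl, term)
    c(df = tab[i, "Df"], ss = tab[i, "Sum Sq"])
  }
  rows <- rbind(Genotype = pick("G"), Location = pick("L"),
                Year = pick("Y"), `G x Y` = pick("G:Y"),
                `G x L` = pick("G:L"), `Y x L` = pick("L:Y"),
                `G x Y x L` = pick("G:L:Y"))
  has_error <- "Residuals" %in% term && r > 1L
  if (has_error) {
    err <- pick("Residuals")
  } else {
    warning("single replicate: no error df; F and p omitted",
            call. = FALSE)
    err <- c(df = 0, ss = 0)
  }
  out <- anova_table(
    source = c(rownames(rows), "Error", "Total"),
    df = c(rows[, "df"], err["df"], sum(rows[, "df"]) + err["df"]),
    ss = c(rows[, "ss"], err["ss"], sum(rows[, "ss"]) + err["ss"]),
    error_ms = if (has_error) err["ss"] / err["df"],
    error_df = if (has_error) err["df"],
    basis = "plot")
  if (g_over_ge && has_error) {
    gi <- match(c("G x Y", "G x L", "G x Y x L"), out$source)
    ge_ms <- sum(out$ss[gi]) / sum(out$df[gi])
    k <- match("Genotype", out$source)
    out$f[k] <- out$ms[k] / ge_ms
    out$p[k] <- stats::pf(out$f[k], out$df[k], sum(out$df[gi]),
                          lower.tail = FALSE)
  }
  out$f[out$source %in% c("Error", "Total")] <- NA_real_
  out$p[out$source %in% c("Error", "Total")] <- NA_real_
  out
}

#' Genotype, environment and G x E ANOVA from a two-way table
#'
#' Partitions the genotype x environment mean table into G, E and G x E
#' with degrees of freedom (g-1), (e-1) and (g-1)(e-1). On the plot
#' basis, sums of squares are the means-based sums multiplied by the
#' replicate count and each term is tested against the pooled error mean
#' square; on the means basis no F test is attached. The percentage
#' explained of each term is its share of SS_G + SS_E + SS_GE.
#'
#' @param table A \code{two_way_table}.
#' @param basis "plot" (default) or "means".
#' @return An \code{anova_table} with rows Environment, Genotype, G x E
#'   (plus Error on the plot basis).
#' @export
env_collapsed_anova <- function(table, basis = c("plot", "means")) {
  basis <- match.arg(basis)
  g <- length(table$genotypes)
  e <- length(table$environments)
  ss_g <- e * sum((table$genotype_means - table$grand_mean)^2)
  ss_e <- g * sum((table$environment_means - table$grand_mean)^2)
  ss_ge <- sum(interaction_residuals(table)^2)
  scale <- if (basis == "plot") table$replicates else 1
  ss <- c(ss_e, ss_g, ss_ge) * scale
  total <- sum(ss)
  src <- c("Environment", "Genotype", "G x E")
  df <- c(e - 1L, g - 1L, (g - 1L) * (e - 1L))
  use_error <- basis == "plot" && table$error_df > 0L
  if (use_error) {
    src <- c(src, "Error")
    df <- c(df, table$error_df)
    ss <- c(ss, table$pooled_error_ms * table$error_df)
  }
  anova_table(src, df, ss,
              error_ms = if (use_error) table$pooled_error_ms,
              error_df = if (use_error) table$error_df,
              pct = c(100 * c(ss_e, ss_g, ss_ge) * scale / total,
                      if (use_error) NA_real_),
              basis = basis)
}
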