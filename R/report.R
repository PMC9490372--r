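#' Run the full GEI analysis pipeline and write a report bundle
#'
#' For each selected trait: pooled ANOVA, the collapsed G/E/GxE ANOVA,
#' the univariate stability table, the AMMI ANOVA with AMMI1/AMMI2
#' coordinates, the GGE views (which-won-where, mean-vs-stability,
#' ranking, discriminativeness/representativeness), and — across traits
#' — the Pearson correlation matrix. All tables are written as
#' tab-delimited text named \code{<trait>__<analysis>.tsv}, plus a
#' plain-text \code{summary.txt} naming the top-ranked stable genotypes
#' per trait. Outputs are deterministic for a given input.
#'
#' @param data A \code{met_data} object.
#' @param out_dir Output directory (created if needed).
#' @param traits Traits to analyse (default all).
#' @param coding Optional environment coding.
#' @param basis Basis for the AMMI ANOVA ("plot" or "means").
#' @param error_correction Passed to \code{\link{stability_table}}.
#' @param plots If TRUE, also write PNG biplots per trait.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list per trait of the computed objects,
#'   plus \code{correlation} and \code{files} (paths written).
#' @export
run_report <- function(data, out_dir, traits = NULL, coding = NULL,
                       basis = c("plot", "means"),
                       error_correction = TRUE, plots = FALSE,
                       quiet = FALSE) {
  stopifnot(inherits(data, "met_data"))
  basis <- match.arg(basis)
  if (is.null(traits)) traits <- met_traits(data)
  if (is.null(coding)) coding <- environment_coding(data)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)
  emit <- function(df, trait, what) {
    path <- file.path(out_dir, paste0(trait, "__", what, ".tsv"))
    out <- as.data.frame(df)
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v) round(v, 6))
    if ("p" %in% names(out)) out$stars <- p_stars(out$p)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
    path
  }

  results <- list()
  summary_lines <- character(0)
  for (tr in traits) {
    say("trait %s: two-way table and ANOVA", tr)
    tw <- cell_means(data, tr, coding)
    res <- list(table = tw)
    if (attr(data, "r") >= 2L) {
      res$pooled_anova <- pooled_anova(data, tr)
      emit(res$pooled_anova, tr, "pooled_anova")
    }
    res$ge_anova <- env_collapsed_anova(tw, basis = basis)
    emit(res$ge_anova, tr, "ge_anova")

    say("trait %s: univariate stability", tr)
    res$stability <- stability_table(tw,
                                     error_correction = error_correction)
    emit(res$stability, tr, "stability")

    say("trait %s: AMMI", tr)
    res$ammi <- fit_ammi(tw, basis = basis)
    res$ammi_anova <- ammi_anova(res$ammi, n_axes = 2L)
    emit(res$ammi_anova, tr, "ammi_anova")
    emit(ammi1_coords(res$ammi), tr, "ammi1_coords")
    res$ammi2 <- ammi2_coords(res$ammi)
    emit(res$ammi2, tr, "ammi2_coords")

    say("trait %s: GGE views", tr)
    degenerate <- sum(wricke_ecovalence(tw)) <
      1e-10 * max(tw$grand_mean^2, 1)
    if (degenerate) {
      say("trait %s: no interaction signal; GGE geometry degenerate", tr)
      summary_lines <- c(summary_lines, sprintf(
        "%s: all genotypes maximally stable (Wi = 0); GGE geometry degenerate",
        tr))
      res$gge <- NULL
    } else {
      www <- which_won_where(fit_gge(tw, svp = "symmetric"))
      gmod <- fit_gge(tw, svp = "genotype")
      ms <- mean_vs_stability(gmod)
      rk <- rank_genotypes(gmod)
      dr <- discrimination_representativeness(
        fit_gge(tw, svp = "environment"))
      res$gge <- list(www = www, mean_vs_stability = ms, ranking = rk,
                      discrimination = dr)
      emit(www$winners, tr, "gge_www_winners")
      emit(www$sectors, tr, "gge_www_sectors")
      emit(ms$scores, tr, "gge_mean_vs_stability")
      emit(rk, tr, "gge_ranking")
      emit(dr, tr, "gge_discrimination")
      top <- utils::head(rk$genotype, 3L)
      stable <- utils::head(
        res$stability$genotype[order(res$stability$wi)], 3L)
      summary_lines <- c(summary_lines, sprintf(
        "%s: biplot ranking %s; lowest-ecovalence genotypes %s; ideal test environment %s",
        tr, paste(top, collapse = " > "),
        paste(stable, collapse = ", "),
        dr$environment[dr$ideal]))
      if (plots) {
        png_path <- file.path(out_dir, paste0(tr, "__gge_biplot.png"))
        grDevices::png(png_path, width = 720, height = 720)
        plot(gmod, view = "meanstab",
             main = sprintf("GGE mean vs stability: %s", tr))
        grDevices::dev.off()
        files <- c(files, png_path)
      }
    }
    results[[tr]] <- res
  }

  if (length(traits) >= 2L) {
    say("correlation across %d traits", length(traits))
    results$correlation <- pearson_matrix(data, traits)
    rmat <- as.data.frame(results$correlation$r)
    rmat <- cbind(trait = rownames(rmat), rmat)
    path <- file.path(out_dir, "correlation_r.tsv")
    utils::write.table(round_numeric(rmat, 6), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pmat <- as.data.frame(results$correlation$p)
    pmat <- cbind(trait = rownames(pmat), pmat)
    path2 <- file.path(out_dir, "correlation_p.tsv")
    utils::write.table(round_numeric(pmat, 6), path2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, path, path2)
  }

  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(c(sprintf("MET report: %d genotypes x %d environments x %d replicates",
                       attr(data, "g"), attr(data, "e"), attr(data, "r")),
               summary_lines), summary_path)
  files <- c(files, summary_path)
  results$files <- files
  invisible(results)
}

round_numeric <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  df
}
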