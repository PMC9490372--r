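#' Fit a GGE model (environment-centered SVD with singular-value partitioning)
#'
#' Centers the genotype x environment mean table by environment
#' (column) means, removing the environment main effect while keeping
#' the genotype main effect plus the interaction (G + GE), optionally
#' scales each column by its standard deviation, and decomposes the
#' result by SVD. Rank-2 biplot markers are formed under one of three
#' singular-value partitionings (SVP): genotype-focused (singular
#' values absorbed into genotype markers), environment-focused, or
#' symmetric (square root to each side).
#'
#' @param table A \code{two_way_table} with g >= 3 and e >= 3.
#' @param scaling "none" (default; the decomposed matrix keeps the trait
#'   scale so the squared singular values sum to SS_G + SS_GE of the
#'   means table) or "sd" (each environment column divided by its
#'   standard deviation).
#' @param svp "symmetric", "genotype" or "environment".
#' @return Object of class \code{gge_model}: list with \code{centered}
#'   (g x e matrix), \code{singular_values}, \code{genotype_markers}
#'   (g x 2), \code{environment_markers} (e x 2), \code{svp},
#'   \code{scaling}, \code{gof} (PC1+PC2 share of the total squared
#'   singular values), \code{table}.
#' @export
fit_gge <- function(table, scaling = c("none", "sd"),
                    svp = c("symmetric", "genotype", "environment")) {
  scaling <- match.arg(scaling)
  svp <- match.arg(svp)
  g <- length(table$genotypes)
  e <- length(table$environments)
  if (g < 3L || e < 3L) stop("GGE needs g >= 3 and e >= 3", call. = FALSE)
  centered <- sweep(table$means, 2L, table$environment_means)
  if (scaling == "sd") {
    sds <- apply(table$means, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("environment(s) with zero variance under sd-scaling: ",
           paste(table$environments[sds == 0], collapse = ", "),
           call. = FALSE)
    }
    centered <- sweep(centered, 2L, sds, `/`)
  }
  dec <- svd(centered)
  # deterministic sign: largest-magnitude environment loading positive
  for (k in seq_along(dec$d)) {
    i <- which.max(abs(dec$v[, k]))
    if (dec$v[i, k] < 0) {
      dec$v[, k] <- -dec$v[, k]
      dec$u[, k] <- -dec$u[, k]
    }
  }
  d2 <- dec$d[1:2]
  gpow <- switch(svp, genotype = 1, environment = 0, symmetric = 0.5)
  gen <- sweep(dec$u[, 1:2, drop = FALSE], 2L, d2^gpow, `*`)
  env <- sweep(dec$v[, 1:2, drop = FALSE], 2L, d2^(1 - gpow), `*`)
  dimnames(gen) <- list(table$genotypes, c("PC1", "PC2"))
  dimnames(env) <- list(table$environments, c("PC1", "PC2"))
  structure(list(
    centered = centered,
    singular_values = dec$d,
    genotype_markers = gen,
    environment_markers = env,
    svp = svp,
    scaling = scaling,
    gof = sum(dec$d[1:2]^2) / sum(dec$d^2),
    table = table
  ), class = "gge_model")
}

#' @export
print.gge_model <- function(x, ...) {
  cat(sprintf("GGE model: %d genotypes x %d environments (scaling = %s, SVP = %s)\n",
              nrow(x$genotype_markers), nrow(x$environment_markers),
              x$scaling, x$svp))
  cat(sprintf("PC1 + PC2 explain %.1f%% of G + GE\n", 100 * x$gof))
  invisible(x)
}

#' Which-won-where: convex-hull sectors and mega-environments
#'
#' Draws the convex hull of the genotype markers, splits the plane into
#' angular sectors by the rays from the origin perpendicular to each
#' hull edge, and assigns every environment to the sector containing
#' its marker's angle. The hull vertex inside a sector is the winning
#' (top-performing) genotype for the environments of that sector; a
#' group of environments sharing a winner is a mega-environment.
#' Sector boundaries are half-open (a marker exactly on a boundary ray
#' is assigned counterclockwise) so ties are deterministic.
#'
#' @param model A \code{gge_model} (symmetric SVP is conventional for
#'   this view).
#' @return Object of class \code{www_partition}: list with \code{hull}
#'   (ordered counterclockwise vertex labels), \code{sectors}
#'   (data.frame of vertex_genotype, environments per sector, including
#'   empty sectors), and \code{winners} (data.frame environment ->
#'   winning genotype).
#' @export
which_won_where <- function(model) {
  gm <- model$genotype_markers
  em <- model$environment_markers
  ref <- gm[which.max(rowSums(gm^2)), ]
  cross <- abs(gm[, 1L] * ref[2L] - gm[, 2L] * ref[1L])
  if (max(cross) < 1e-6 * max(sum(ref^2), .Machine$double.eps)) {
    stop("degenerate geometry: genotype markers are collinear; ",
         "check the rank of the centered matrix", call. = FALSE)
  }
  hull_idx <- grDevices::chull(gm[, 1L], gm[, 2L])  # clockwise
  hull_idx <- rev(hull_idx)                          # counterclockwise
  nv <- length(hull_idx)
  verts <- gm[hull_idx, , drop = FALSE]

  # boundary ray k separates vertex k from vertex k+1: perpendicular to
  # the edge, oriented so both endpoints project positively onto it
  angles <- numeric(nv)
  for (k in seq_len(nv)) {
    a <- verts[k, ]
    b <- verts[if (k == nv) 1L else k + 1L, ]
    edge <- b - a
    n <- c(-edge[2L], edge[1L])
    if (sum(n * a) < 0) n <- -n
    angles[k] <- atan2(n[2L], n[1L]) %% (2 * pi)
  }

  env_angle <- atan2(em[, 2L], em[, 1L]) %% (2 * pi)
  # vertex k+1 owns the half-open arc [angles[k], angles[k+1])
  winner_idx <- integer(nrow(em))
  for (j in seq_len(nrow(em))) {
    th <- env_angle[j]
    k <- NA_integer_
    for (s in seq_len(nv)) {
      lo <- angles[s]
      hi <- angles[if (s == nv) 1L else s + 1L]
      inside <- if (lo <= hi) (th >= lo && th < hi) else (th >= lo || th < hi)
      if (inside) {
        k <- if (s == nv) 1L else s + 1L
        break
      }
    }
    winner_idx[j] <- k
  }
  winners <- data.frame(environment = rownames(em),
                        winner = rownames(verts)[winner_idx],
                        stringsAsFactors = FALSE, row.names = NULL)
  sectors <- data.frame(
    vertex_genotype = rownames(verts),
    environments = vapply(rownames(verts), function(vg) {
      paste(winners$environment[winners$winner == vg], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(hull = rownames(verts), sectors = sectors,
                 winners = winners),
            class = "www_partition")
}

#' @export
print.www_partition <- function(x, ...) {
  cat("Which-won-where partition\n")
  cat("Hull (counterclockwise):", paste(x$hull, collapse = " > "), "\n")
  occ <- x$sectors[nzchar(x$sectors$environments), , drop = FALSE]
  for (i in seq_len(nrow(occ))) {
    cat(sprintf("  mega-environment {%s}: winner %s\n",
                occ$environments[i], occ$vertex_genotype[i]))
  }
  invisible(x)
}

# AEC direction: unit vector through the mean of the environment markers
.aec_direction <- function(model) {
  m <- colMeans(model$environment_markers)
  len <- sqrt(sum(m^2))
  if (len < 1e-10 * max(abs(model$environment_markers), 1)) {
    stop("AEC direction undefined: mean environment marker is at the ",
         "origin (data are interaction-dominated)", call. = FALSE)
  }
  m / len
}

#' Mean-versus-stability view: AEC projections per genotype
#'
#' The average environment coordinate (AEC) axis runs from the origin
#' through the mean of the environment markers. Each genotype marker
#' decomposes into its signed projection on the AEC (mean performance)
#' and its signed perpendicular component (instability; smaller
#' magnitude = more stable).
#'
#' @param model A \code{gge_model} (genotype-focused SVP is
#'   conventional for this view).
#' @return Object of class \code{gge_meanstab}: list with
#'   \code{direction} (unit 2-vector) and \code{scores}, a data.frame
#'   with columns \code{genotype, mean_projection, stability_projection,
#'   mean_rank, stability_rank}, sorted by descending mean projection
#'   with stability as tie-break.
#' @export
mean_vs_stability <- function(model) {
  d <- .aec_direction(model)
  gm <- model$genotype_markers
  proj <- as.numeric(gm %*% d)
  perp <- as.numeric(gm[, 1L] * (-d[2L]) + gm[, 2L] * d[1L])
  scores <- data.frame(genotype = rownames(gm), mean_projection = proj,
                       stability_projection = perp,
                       stringsAsFactors = FALSE, row.names = NULL)
  scores$mean_rank <- rank(-proj, ties.method = "first")
  scores$stability_rank <- rank(abs(perp), ties.method = "first")
  scores <- scores[order(-scores$mean_projection,
                         abs(scores$stability_projection)), ]
  rownames(scores) <- NULL
  structure(list(direction = d, scores = scores),
            class = "gge_meanstab")
}

#' @export
print.gge_meanstab <- function(x, digits = 4, ...) {
  cat(sprintf("Mean vs stability (AEC direction %.3f, %.3f)\n",
              x$direction[1L], x$direction[2L]))
  df <- x$scores
  df$mean_projection <- round(df$mean_projection, digits)
  df$stability_projection <- round(df$stability_projection, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Rank genotypes against the ideal point on the AEC axis
#'
#' The ideal genotype sits on the positive AEC direction at the
#' distance of the longest genotype projection (best mean performance
#' with perfect stability). Genotypes are ranked by ascending Euclidean
#' distance of their markers to this point.
#'
#' @param model A \code{gge_model} (genotype-focused SVP is
#'   conventional).
#' @return data.frame with columns \code{rank, genotype, distance,
#'   ideal_x, ideal_y} sorted by rank.
#' @export
rank_genotypes <- function(model) {
  d <- .aec_direction(model)
  gm <- model$genotype_markers
  proj <- as.numeric(gm %*% d)
  ideal <- d * max(proj)
  dist <- sqrt((gm[, 1L] - ideal[1L])^2 + (gm[, 2L] - ideal[2L])^2)
  out <- data.frame(genotype = rownames(gm), distance = as.numeric(dist),
                    ideal_x = ideal[1L], ideal_y = ideal[2L],
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$distance), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[c("rank", "genotype", "distance", "ideal_x", "ideal_y")]
}

#' Environment discriminativeness and representativeness
#'
#' Discriminativeness is the length of an environment's marker vector
#' (under environment-focused SVP and no scaling its square is the
#' environment's share of G + GE captured in rank 2, i.e. proportional
#' to the genotype standard deviation within that environment);
#' representativeness is the cosine of the angle between the marker and
#' the AEC axis. The environment maximizing their product is flagged as
#' the ideal test environment.
#'
#' @param model A \code{gge_model} (environment-focused SVP is
#'   conventional for this view).
#' @return data.frame with columns \code{environment, vector_length,
#'   cos_angle, score, ideal} (logical; TRUE for the best environment).
#'   \code{cos_angle} is NA for a zero-length vector.
#' @export
discrimination_representativeness <- function(model) {
  d <- .aec_direction(model)
  em <- model$environment_markers
  len <- sqrt(rowSums(em^2))
  cosang <- ifelse(len > 0, as.numeric(em %*% d) / len, NA_real_)
  score <- ifelse(is.na(cosang), -Inf, len * cosang)
  out <- data.frame(environment = rownames(em),
                    vector_length = as.numeric(len),
                    cos_angle = as.numeric(cosang),
                    score = as.numeric(score),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$ideal <- seq_len(nrow(out)) == which.max(out$score)
  out$score[!is.finite(out$score)] <- NA_real_
  out
}

#' Plot a GGE biplot view
#'
#' @param x A \code{gge_model}.
#' @param view "markers" (plain biplot), "www" (with convex hull), or
#'   "meanstab" (with the AEC axis).
#' @param ... Passed to \code{plot}.
#' @return The model, invisibly.
#' @export
plot.gge_model <- function(x, view = c("markers", "www", "meanstab"),
                           ...) {
  view <- match.arg(view)
  gm <- x$genotype_markers
  em <- x$environment_markers
  all_xy <- rbind(gm, em)
  graphics::plot(all_xy, type = "n",
                 xlab = sprintf("PC1 (%.1f%%)",
                                100 * x$singular_values[1L]^2 /
                                  sum(x$singular_values^2)),
                 ylab = sprintf("PC2 (%.1f%%)",
                                100 * x$singular_values[2L]^2 /
                                  sum(x$singular_values^2)), ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 2)
  graphics::text(gm, rownames(gm), cex = 0.8)
  graphics::text(em, rownames(em), col = "blue", cex = 0.8)
  if (view == "www") {
    hull <- grDevices::chull(gm[, 1L], gm[, 2L])
    graphics::polygon(gm[hull, 1L], gm[hull, 2L], border = "red")
  } else if (view == "meanstab") {
    d <- .aec_direction(x)
    lim <- max(abs(all_xy)) * 1.1
    graphics::arrows(-lim * d[1L], -lim * d[2L], lim * d[1L],
                     lim * d[2L], col = "red", length = 0.1)
  }
  invisible(x)
}
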