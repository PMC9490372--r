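#' Construct and validate a multi-environment trial dataset
#'
#' A MET dataset holds one record per genotype x location x year x replicate
#' x trait combination. The design must be balanced for every trait: each
#' genotype x location x year cell carries the same number of replicates.
#'
#' @param records A data.frame with columns \code{genotype}, \code{location},
#'   \code{year}, \code{rep}, \code{trait}, \code{value} (long format).
#' @return An object of class \code{met_data}: the validated long-format
#'   data.frame with attributes \code{g} (genotype count), \code{e}
#'   (environment count, locations x years), and \code{r} (replicates).
#' @examples
#' d <- expand.grid(genotype = c("G1", "G2"), location = "L1",
#'                  year = c("Y1", "Y2"), rep = 1, trait = "yield",
#'                  stringsAsFactors = FALSE)
#' d$value <- seq_len(nrow(d))
#' met_data(d)
#' @export
met_data <- function(records) {
  required <- c("genotype", "location", "year", "rep", "trait", "value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[required]
  for (col in c("genotype", "location", "year", "trait")) {
    records[[col]] <- as.character(records[[col]])
  }
  records$rep <- as.integer(records$rep)
  if (anyNA(records$rep) || any(records$rep < 1L)) {
    stop("parse error: 'rep' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(records$value)) {
    bad <- suppressWarnings(as.numeric(records$value))
    if (anyNA(bad)) {
      stop("parse error: non-numeric value at record(s) ",
           paste(utils::head(which(is.na(bad)), 5L), collapse = ", "),
           call. = FALSE)
    }
    records$value <- bad
  }
  if (anyNA(records$value)) {
    stop("parse error: missing trait values are not allowed", call. = FALSE)
  }

  key <- do.call(paste, c(records[c("genotype", "location", "year",
                                    "rep", "trait")], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (genotype, location, year, rep, trait) key(s), e.g. ",
         gsub("\r", " / ", key[which(duplicated(key))[1L]]), call. = FALSE)
  }

  g <- length(unique(records$genotype))
  env_key <- unique(paste(records$location, records$year, sep = "\r"))
  e <- length(env_key)
  if (g < 2L) stop("need at least 2 genotypes, got ", g, call. = FALSE)
  if (e < 2L) stop("need at least 2 environments (location x year), got ",
                   e, call. = FALSE)

  # balance per trait: every genotype x location x year cell present with
  # the same replicate count
  r <- .check_balance(records)

  structure(records, class = c("met_data", "data.frame"),
            g = g, e = e, r = r)
}

.check_balance <- function(records) {
  counts <- NULL
  for (tr in unique(records$trait)) {
    sub <- records[records$trait == tr, , drop = FALSE]
    tab <- table(genotype = sub$genotype,
                 env = paste(sub$location, sub$year, sep = " / "))
    if (length(unique(as.vector(tab))) > 1L || any(tab == 0L)) {
      cells <- which(tab != max(tab), arr.ind = TRUE)
      offenders <- apply(cells, 1L, function(ix) {
        paste0(rownames(tab)[ix[1L]], " in ", colnames(tab)[ix[2L]])
      })
      stop("balance error for trait '", tr, "': unequal replication in ",
           "cell(s): ", paste(utils::head(offenders, 5L), collapse = "; "),
           call. = FALSE)
    }
    counts <- c(counts, max(tab))
  }
  if (length(unique(counts)) > 1L) {
    stop("balance error: traits carry different replicate counts",
         call. = FALSE)
  }
  as.integer(counts[1L])
}

#' @export
print.met_data <- function(x, ...) {
  cat(sprintf("MET dataset: %d genotypes x %d environments x %d replicates, %d trait(s), %d records\n",
              attr(x, "g"), attr(x, "e"), attr(x, "r"),
              length(unique(x$trait)), nrow(x)))
  invisible(x)
}

#' Traits present in a MET dataset
#' @param data A \code{met_data} object.
#' @return Character vector of trait labels.
#' @export
met_traits <- function(data) unique(data$trait)

#' Deterministic environment coding for location x year combinations
#'
#' Each (location, year) pair is coded as an environment ENV1, ENV2, ...
#' with locations enumerated within year: ENV1..ENVL are the locations of
#' the first year (in \code{location_order}), the next block the second
#' year, and so on. This composite coding treats year and location jointly
#' as the trial environment.
#'
#' @param data A \code{met_data} object.
#' @param location_order Optional character vector fixing location order;
#'   defaults to sorted unique locations.
#' @param year_order Optional character vector fixing year order; defaults
#'   to sorted unique years.
#' @return A data.frame with columns \code{location}, \code{year},
#'   \code{env}, one row per observed pair, in coding order.
#' @export
environment_coding <- function(data, location_order = NULL,
                               year_order = NULL) {
  locs <- unique(data$location)
  yrs <- unique(data$year)
  if (is.null(location_order)) location_order <- sort(locs)
  if (is.null(year_order)) year_order <- sort(yrs)
  if (!setequal(location_order, locs)) {
    stop("location_order must be a permutation of observed locations",
         call. = FALSE)
  }
  if (!setequal(year_order, yrs)) {
    stop("year_order must be a permutation of observed years", call. = FALSE)
  }
  grid <- expand.grid(location = location_order, year = year_order,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  observed <- unique(paste(data$location, data$year, sep = "\r"))
  grid <- grid[paste(grid$location, grid$year, sep = "\r") %in% observed, ,
               drop = FALSE]
  grid$env <- paste0("ENV", seq_len(nrow(grid)))
  rownames(grid) <- NULL
  grid
}

#' Read a MET dataset from delimited text
#'
#' Accepts comma- or tab-delimited files (auto-detected from the header
#' line) with a header row. Two layouts are supported: long format with
#' columns \code{genotype, location, year, rep, trait, value}, or wide
#' format with the four key columns plus one numeric column per trait
#' (converted to long).
#'
#' @param path Path to the delimited text file.
#' @param sep Field separator; \code{NULL} (default) auto-detects comma
#'   versus tab from the header line.
#' @return A validated \code{met_data} object.
#' @export
read_met <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  keys <- c("genotype", "location", "year", "rep")
  missing_cols <- setdiff(keys, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(c("trait", "value") %in% names(df))) {
    trait_cols <- setdiff(names(df), keys)
    if (length(trait_cols) == 0L) {
      stop("schema error: no trait columns found", call. = FALSE)
    }
    long <- lapply(trait_cols, function(tc) {
      out <- df[keys]
      out$trait <- tc
      out$value <- df[[tc]]
      out
    })
    df <- do.call(rbind, long)
  }
  met_data(df)
}

#' Write a MET dataset as delimited text
#'
#' @param data A \code{met_data} object.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
write_met <- function(data, path, sep = "\t") {
  df <- as.data.frame(data)
  df$value <- formatC(df$value, format = "g", digits = 15)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-way genotype x environment table of cell means
#'
#' Averages replicates within each genotype x environment cell for one
#' trait and records the pooled within-cell error mean square, the grand
#' mean, and the marginal means that all downstream stability and biplot
#' analyses consume.
#'
#' @param data A \code{met_data} object.
#' @param trait Trait label to tabulate.
#' @param coding Optional environment coding from
#'   \code{\link{environment_coding}}; computed with defaults if omitted.
#' @return An object of class \code{two_way_table}: a list with elements
#'   \code{trait}, \code{genotypes}, \code{environments}, \code{means}
#'   (g x e matrix), \code{replicates}, \code{pooled_error_ms},
#'   \code{error_df}, \code{grand_mean}, \code{genotype_means},
#'   \code{environment_means}, \code{coding}.
#' @export
cell_means <- function(data, trait, coding = NULL) {
  stopifnot(inherits(data, "met_data"))
  if (!trait %in% data$trait) {
    stop("unknown trait: ", trait, call. = FALSE)
  }
  if (is.null(coding)) coding <- environment_coding(data)
  sub <- data[data$trait == trait, , drop = FALSE]
  sub$env <- coding$env[match(paste(sub$location, sub$year),
                              paste(coding$location, coding$year))]
  genotypes <- sort(unique(sub$genotype))
  environments <- coding$env
  r <- attr(data, "r")

  means <- tapply(sub$value, list(factor(sub$genotype, genotypes),
                                  factor(sub$env, environments)), mean)
  means <- matrix(as.numeric(means), nrow = length(genotypes),
                  dimnames = list(genotypes, environments))

  if (r > 1L) {
    fitted <- means[cbind(match(sub$genotype, genotypes),
                          match(sub$env, environments))]
    ss_within <- sum((sub$value - fitted)^2)
    error_df <- length(genotypes) * length(environments) * (r - 1L)
    pooled_error_ms <- ss_within / error_df
  } else {
    warning("single replicate: pooled error mean square set to 0",
            call. = FALSE)
    pooled_error_ms <- 0
    error_df <- 0L
  }

  structure(list(
    trait = trait,
    genotypes = genotypes,
    environments = environments,
    means = means,
    replicates = r,
    pooled_error_ms = pooled_error_ms,
    error_df = error_df,
    grand_mean = mean(means),
    genotype_means = rowMeans(means),
    environment_means = colMeans(means),
    coding = coding
  ), class = "two_way_table")
}

#' Build a two-way table directly from a matrix of cell means
#'
#' Convenience constructor for analyses that start from an already
#' summarised genotype x environment matrix (e.g. published tables).
#'
#' @param means Numeric g x e matrix; dimnames supply labels (generated if
#'   absent).
#' @param trait Trait label.
#' @param replicates Replicate count behind each mean (default 1).
#' @param pooled_error_ms Pooled error mean square from the replicates
#'   (default 0).
#' @param error_df Error degrees of freedom (default 0).
#' @return A \code{two_way_table}.
#' @export
two_way_table <- function(means, trait = "trait", replicates = 1L,
                          pooled_error_ms = 0, error_df = 0L) {
  means <- as.matrix(means)
  if (is.null(rownames(means))) {
    rownames(means) <- sprintf("G%02d", seq_len(nrow(means)))
  }
  if (is.null(colnames(means))) {
    colnames(means) <- sprintf("ENV%d", seq_len(ncol(means)))
  }
  stopifnot(pooled_error_ms >= 0, replicates >= 1L)
  structure(list(
    trait = trait,
    genotypes = rownames(means),
    environments = colnames(means),
    means = means,
    replicates = as.integer(replicates),
    pooled_error_ms = pooled_error_ms,
    error_df = as.integer(error_df),
    grand_mean = mean(means),
    genotype_means = rowMeans(means),
    environment_means = colMeans(means),
    coding = NULL
  ), class = "two_way_table")
}

#' @export
print.two_way_table <- function(x, ...) {
  cat(sprintf("Two-way table '%s': %d genotypes x %d environments (r = %d, pooled error MS = %.5g)\n",
              x$trait, length(x$genotypes), length(x$environments),
              x$replicates, x$pooled_error_ms))
  print(round(x$means, 4))
  invisible(x)
}

# interaction residuals z_ij = x_ij - Xi. - X.j + X..; the double-centered
# matrix every interaction analysis (Wricke, AMMI) decomposes
interaction_residuals <- function(table) {
  sweep(sweep(table$means, 1L, table$genotype_means),
        2L, table$environment_means) + table$grand_mean
}
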