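# Shared fixtures, built in code.

# long-format data.frame for a fully enumerated small design
make_long <- function(values, g, e_loc, e_yr, r, trait = "yield") {
  grid <- expand.grid(rep = seq_len(r),
                      genotype = sprintf("G%d", seq_len(g)),
                      location = sprintf("L%d", seq_len(e_loc)),
                      year = sprintf("Y%d", seq_len(e_yr)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$trait <- trait
  grid$value <- values
  grid[c("genotype", "location", "year", "rep", "trait", "value")]
}

# random balanced two-way table of cell means
random_table <- function(g, e, seed, error_df = 0L, pooled_error_ms = 0) {
  set.seed(seed)
  m <- matrix(rnorm(g * e, mean = 10, sd = 2), g, e)
  two_way_table(m, replicates = 1L, error_df = error_df,
                pooled_error_ms = pooled_error_ms)
}

# brute-force factorial sums of squares from first principles: SS of a
# factor = sum over its levels of n_level * (level mean - grand mean)^2,
# interactions by subtraction of contained terms from the cell SS
brute_ss <- function(df, factors) {
  gm <- mean(df$value)
  ss_of <- function(fs) {
    key <- interaction(df[fs], drop = TRUE)
    agg <- tapply(df$value, key, mean)
    cnt <- tapply(df$value, key, length)
    sum(cnt * (agg - gm)^2)
  }
  # full cell SS minus all lower-order components (Moebius-style)
  subsets <- unlist(lapply(seq_along(factors), function(k) {
    utils::combn(factors, k, simplify = FALSE)
  }), recursive = FALSE)
  comp <- list()
  for (s in subsets) {
    lower <- Filter(function(t) all(t %in% s) && length(t) < length(s),
                    subsets)
    comp[[paste(s, collapse = ":")]] <-
      ss_of(s) - sum(unlist(lapply(lower, function(t) {
        comp[[paste(t, collapse = ":")]]
      })))
  }
  comp
}

# per-genotype least-squares oracle for joint regression via stats::lm
lm_slopes <- function(table) {
  idx <- table$environment_means - mean(table$means)
  t(apply(table$means, 1L, function(row) {
    fit <- stats::lm(row ~ idx)
    c(bi = unname(stats::coef(fit)[2L]),
      dev_ms = sum(stats::resid(fit)^2) / (length(row) - 2L))
  }))
}
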