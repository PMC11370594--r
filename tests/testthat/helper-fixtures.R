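# shared fixture builders and independent oracles

# random point on the k-simplex
rsimplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

# brute-force pairwise-difference Gini oracle (independent of the package's
# vectorized implementation)
gini_oracle <- function(p, normalize = TRUE) {
  k <- length(p)
  acc <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) acc <- acc + abs(p[i] - p[j])
  g <- acc / (2 * k * sum(p))
  if (normalize) g * k / (k - 1) else g
}

# minimal cells table: one row per cell with the six fraction columns
make_cells <- function(n, specimen = rep(c("sA", "sB"), length.out = n),
                       fractions = NULL) {
  panel <- glycan_panel()
  f <- matrix(0.01, n, length(panel$glycans))
  colnames(f) <- vapply(panel$glycans, glycosig:::frac_col, "")
  if (!is.null(fractions))
    for (g in names(fractions)) f[, glycosig:::frac_col(g)] <- fractions[[g]]
  cbind(data.frame(cell_id = sprintf("c%04d", seq_len(n)),
                   specimen_id = specimen,
                   cluster_id = specimen, roi_id = specimen,
                   x_um = stats::runif(n, 0, 100),
                   y_um = stats::runif(n, 0, 100),
                   stringsAsFactors = FALSE),
        as.data.frame(f, check.names = FALSE),
        data.frame(histology = "PDAC", stringsAsFactors = FALSE))
}

# named threshold vector covering the coding order
flat_thresholds <- function(theta = 0.2) {
  panel <- glycan_panel()
  stats::setNames(rep(theta, length(panel$glycans)), panel$glycans)
}

# wide blood matrix of a synthetic cohort, plus sample class and specimen
blood_wide <- function(cohort) {
  m <- glycosig:::blood_matrix(cohort$blood)
  cls <- tapply(cohort$blood$class, cohort$blood$sample_id,
                function(v) v[1])[rownames(m)]
  spec <- tapply(cohort$blood$specimen_id, cohort$blood$sample_id,
                 function(v) v[1])[rownames(m)]
  list(m = m, class = cls, specimen = spec)
}
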