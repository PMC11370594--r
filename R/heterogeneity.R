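## Within-cluster uniformity (categorical Gini), between-cluster dispersion
## (distance to the geometric median), tumor typing, quadrant classes, and
## survival comparison between quadrant classes.

#' Gini index of a categorical composition
#'
#' Inequality of a composition over k signature categories,
#' \eqn{G = \sum_i \sum_j |p_i - p_j| / (2 k \sum_i p_i)}. The normalized
#' form (default) rescales by \eqn{k/(k-1)} so that a one-hot composition —
#' all cells in one category, complete homogeneity — scores exactly 1 and
#' the uniform composition scores 0.
#'
#' @param p Non-negative composition over at least two categories; need not
#'   be normalized.
#' @param normalize Rescale so one-hot = 1 (default TRUE).
#' @return Gini index in [0, 1].
#' @examples
#' gini_index(c(1, 0, 0, 0))   # 1: completely homogeneous
#' gini_index(rep(1/4, 4))     # 0: perfectly even
#' @export
gini_index <- function(p, normalize = TRUE) {
  k <- length(p)
  if (k < 2) stop("composition needs at least 2 categories")
  if (any(p < 0)) stop("composition must be non-negative")
  s <- sum(p)
  if (s == 0) stop("empty composition: Gini undefined")
  g <- sum(abs(outer(p, p, "-"))) / (2 * k * s)
  if (normalize) g <- g * k / (k - 1)
  min(max(g, 0), 1)
}

#' Classify cluster uniformity from its Gini index
#'
#' A spatial cluster is "uniform" (one predominant subpopulation) when its
#' Gini index reaches the cutoff, inclusively; otherwise "mixed". The mixed
#' rule is an independent cutoff rather than the literal complement: with
#' \code{mixed_cutoff} below \code{cutoff}, clusters between the two are
#' labeled "intermediate".
#'
#' @param gini Numeric Gini values.
#' @param cutoff Uniformity cutoff (default 0.8, inclusive).
#' @param mixed_cutoff Strict upper bound for "mixed" (default:
#'   \code{cutoff}, making the two classes exhaustive).
#' @return Character vector over "uniform", "mixed", "intermediate".
#' @export
classify_cluster <- function(gini, cutoff = 0.8, mixed_cutoff = cutoff) {
  stopifnot(mixed_cutoff <= cutoff)
  ifelse(gini >= cutoff, "uniform",
         ifelse(gini < mixed_cutoff, "mixed", "intermediate"))
}

#' Assign a tumor type from its signature-code fractions
#'
#' Sums the tumor's cell fractions into the three subpopulation burdens —
#' sTRA-exclusive (1010, 1011), CA19-9-exclusive (1100, 1101, 0100) and
#' dual-expressing (0110, 1110, 1111) — and applies a dominance rule: the
#' tumor takes the type of the largest burden only if it exceeds
#' \code{dominance_ratio} times the runner-up; otherwise (or when the dual
#' burden leads) it is "mixed".
#'
#' @param fractions Named numeric vector of per-code cell fractions.
#' @param dominance_ratio Dominance multiple (default 2).
#' @return One of "sTRA", "CA19-9", "mixed", or NA (with a warning) when
#'   all burdens are zero.
#' @export
tumor_type <- function(fractions, dominance_ratio = 2) {
  sp <- subpopulation_codes()
  burden <- function(codes) sum(fractions[intersect(codes, names(fractions))])
  b <- c("sTRA" = burden(sp$stra_exclusive),
         "CA19-9" = burden(sp$ca199_exclusive),
         "mixed" = burden(sp$dual))
  if (sum(b) == 0) {
    warning("all subpopulation burdens zero: tumor type undefined")
    return(NA_character_)
  }
  o <- order(b, decreasing = TRUE)
  top <- names(b)[o[1]]
  if (top == "mixed") return("mixed")
  if (b[o[1]] < dominance_ratio * b[o[2]]) return("mixed")
  top
}

#' Geometric median (Weiszfeld iteration)
#'
#' The multivariate median: the point minimizing the summed Euclidean
#' distances to the rows of \code{X}. Iterates the Weiszfeld update from
#' the centroid, with a small floor on distances so iterates may pass
#' through data points.
#'
#' @param X Numeric matrix (points in rows).
#' @param tol Convergence tolerance on the iterate displacement.
#' @param maxit Iteration cap.
#' @return Numeric vector, the geometric median.
#' @export
geometric_median <- function(X, tol = 1e-8, maxit = 1000L) {
  X <- as.matrix(X)
  if (nrow(X) == 1) return(drop(X))
  y <- colMeans(X)
  for (it in seq_len(maxit)) {
    d <- sqrt(rowSums(sweep(X, 2, y)^2))
    d <- pmax(d, 1e-12)
    w <- 1 / d
    y_new <- colSums(X * w) / sum(w)
    if (sqrt(sum((y_new - y)^2)) < tol) return(y_new)
    y <- y_new
  }
  y
}

#' Between-cluster dispersion of one tumor
#'
#' Average Euclidean distance of a tumor's cluster composition vectors to
#' their geometric median (the multivariate median minimizing summed
#' distances). A single cluster gives dispersion 0 by convention, flagged
#' via the \code{"single_cluster"} attribute.
#'
#' @param X Matrix of cluster compositions (clusters in rows).
#' @param tol Weiszfeld tolerance.
#' @return Non-negative dispersion; attribute \code{centroid} holds the
#'   geometric median.
#' @export
between_cluster_dispersion <- function(X, tol = 1e-8) {
  X <- as.matrix(X)
  if (nrow(X) < 2) {
    out <- 0
    attr(out, "single_cluster") <- TRUE
    attr(out, "centroid") <- drop(X)
    return(out)
  }
  ctr <- geometric_median(X, tol = tol)
  out <- mean(sqrt(rowSums(sweep(X, 2, ctr)^2)))
  attr(out, "single_cluster") <- FALSE
  attr(out, "centroid") <- ctr
  out
}

#' Quadrant classification of tumors
#'
#' Splits the cohort at the medians of mean within-cluster Gini
#' ("uniform" axis) and between-cluster dispersion ("heterogeneous" axis):
#' tumors above both medians are heterogeneous-uniform (several distinct
#' high-purity clonal outgrowths); ties at a median fall to the lower
#' class deterministically.
#'
#' @param mean_gini Per-tumor mean within-cluster Gini.
#' @param dispersion Per-tumor between-cluster dispersion.
#' @return Character vector over \{"homogeneous-mixed",
#'   "homogeneous-uniform", "heterogeneous-mixed", "heterogeneous-uniform"\}.
#' @export
classify_quadrant <- function(mean_gini, dispersion) {
  stopifnot(length(mean_gini) == length(dispersion))
  if (length(mean_gini) < 2) stop("at least 2 tumors required")
  mg <- stats::median(mean_gini); md <- stats::median(dispersion)
  if (all(mean_gini == mean_gini[1]) && all(dispersion == dispersion[1]))
    warning("degenerate cohort: all tumors identical; lower classes assigned")
  uni <- mean_gini > mg
  het <- dispersion > md
  paste0(ifelse(het, "heterogeneous", "homogeneous"), "-",
         ifelse(uni, "uniform", "mixed"))
}

#' Per-cluster heterogeneity profiles
#'
#' Restricts each cluster to its cells bearing cancer-associated codes,
#' computes the composition over those codes, its Gini index, and the
#' uniformity class.
#'
#' @param codes Character per-cell signature codes.
#' @param cluster Per-cell cluster identifier.
#' @param specimen Per-cell specimen identifier.
#' @param cancer_codes Category set for the composition.
#' @param gini_cutoff Uniformity cutoff.
#' @param min_cells Clusters with fewer cancer-code cells are dropped.
#' @return Data frame: cluster_id, specimen_id, n_cells, gini, uniformity,
#'   plus one fraction column per cancer code.
#' @export
cluster_profiles <- function(codes, cluster, specimen, cancer_codes,
                             gini_cutoff = 0.8, min_cells = 5L) {
  keep <- codes %in% cancer_codes
  if (!any(keep)) stop("no cells bearing cancer-associated codes")
  tab <- table(cluster = cluster[keep],
               code = factor(codes[keep], cancer_codes))
  n <- rowSums(tab)
  ok <- n >= min_cells
  tab <- tab[ok, , drop = FALSE]; n <- n[ok]
  frac <- sweep(unclass(tab), 1, n, "/")
  spec_of <- vapply(split(as.character(specimen[keep]), cluster[keep]),
                    function(v) v[1], "")[rownames(tab)]
  g <- apply(frac, 1, gini_index)
  data.frame(cluster_id = rownames(tab), specimen_id = spec_of,
             n_cells = as.integer(n), gini = g,
             uniformity = classify_cluster(g, gini_cutoff),
             as.data.frame(frac, check.names = FALSE),
             row.names = NULL, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Per-tumor heterogeneity profiles
#'
#' Aggregates cluster profiles to tumors: per-tumor cell fractions over the
#' cancer-associated codes, tumor type by the dominance rule, mean
#' within-cluster Gini, between-cluster dispersion, and (when the cohort
#' has at least two tumors) the quadrant class.
#'
#' @inheritParams cluster_profiles
#' @param dominance_ratio Passed to \code{\link{tumor_type}}.
#' @return Data frame: specimen_id, n_clusters, type, mean_cluster_gini,
#'   dispersion, quadrant, plus per-code fraction columns.
#' @export
tumor_profiles <- function(codes, cluster, specimen, cancer_codes,
                           gini_cutoff = 0.8, min_cells = 5L,
                           dominance_ratio = 2) {
  cp <- cluster_profiles(codes, cluster, specimen, cancer_codes,
                         gini_cutoff, min_cells)
  keep <- codes %in% cancer_codes
  tab <- table(specimen = specimen[keep],
               code = factor(codes[keep], cancer_codes))
  frac <- sweep(unclass(tab), 1, rowSums(tab), "/")
  specs <- rownames(tab)
  mg <- tapply(cp$gini, cp$specimen_id, mean)[specs]
  disp <- vapply(specs, function(s) {
    X <- composition_matrix(
      within(cp[cp$specimen_id == s, , drop = FALSE], unit <- cluster_id),
      cancer_codes)
    as.numeric(between_cluster_dispersion(X))
  }, 0)
  ncl <- as.integer(table(factor(cp$specimen_id, specs)))
  type <- apply(frac, 1, tumor_type, dominance_ratio = dominance_ratio)
  out <- data.frame(specimen_id = specs, n_clusters = ncl, type = type,
                    mean_cluster_gini = as.numeric(mg), dispersion = disp,
                    as.data.frame(frac, check.names = FALSE),
                    row.names = NULL, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (nrow(out) >= 2)
    out$quadrant <- classify_quadrant(out$mean_cluster_gini, out$dispersion)
  out
}

#' Compare survival between the heterogeneous-uniform class and the rest
#'
#' Kaplan-Meier curves with right censoring, median survival and 2-year
#' survival per group, a log-rank test on overall survival, and a Wilcoxon
#' rank-sum test on survival after progression (time minus progression
#' time, among progressors).
#'
#' @param time_days Follow-up time (days).
#' @param event Event indicator (1 = death observed).
#' @param group Logical: TRUE for the heterogeneous-uniform class.
#' @param progression_days Optional progression times (NA for
#'   non-progressors).
#' @return List: \code{fit} (survfit object), \code{median_days} and
#'   \code{surv_2yr} per group, \code{logrank_p},
#'   \code{after_progression_p}, \code{km} (coordinate table).
#' @export
survival_compare <- function(time_days, event, group,
                             progression_days = NULL) {
  stopifnot(length(time_days) == length(event),
            length(time_days) == length(group))
  if (any(time_days < 0)) stop("negative survival times")
  grp <- factor(ifelse(as.logical(group), "heterogeneous-uniform", "other"),
                c("heterogeneous-uniform", "other"))
  if (any(tapply(event, grp, sum) == 0))
    warning("a group has no events; log-rank may be uninformative")
  sf <- survival::survfit(survival::Surv(time_days, event) ~ grp)
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ grp)
  logrank_p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1,
                             lower.tail = FALSE)
  tb <- summary(sf)$table
  med <- tb[, "median"]
  s2 <- summary(sf, times = 730, extend = TRUE)$surv
  sap_p <- NA_real_
  if (!is.null(progression_days)) {
    prog <- !is.na(progression_days)
    if (any(progression_days[prog] > time_days[prog]))
      stop("progression time exceeds survival time")
    sap <- time_days - progression_days
    if (length(unique(grp[prog])) == 2)
      sap_p <- stats::wilcox.test(sap[prog] ~ grp[prog], exact = FALSE)$p.value
  }
  km <- data.frame(group = rep(sub("^grp=", "", summary(sf, censored = TRUE)$strata),
                               times = 1),
                   time = summary(sf, censored = TRUE)$time,
                   surv = summary(sf, censored = TRUE)$surv)
  list(fit = sf, median_days = stats::setNames(med, sub("^grp=", "", rownames(tb))),
       surv_2yr = stats::setNames(s2, levels(grp)[seq_along(s2)]),
       logrank_p = logrank_p, after_progression_p = sap_p, km = km)
}
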