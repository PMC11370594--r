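## Dichotomization of per-cell glycan fractions and 4-bit signature coding.
##
## Thresholds come from the first split on each glycan in a CART tree
## trained to separate cancer from non-cancer cells, aggregated (median)
## over cross-validation folds. Positivity is strict (> threshold), which
## keeps the all-zero control case stable.

fold_ids <- function(n, k) sample(rep_len(seq_len(k), n))

## root-split cutpoint of a single-glycan CART tree (the glycan's first
## split); NA when no split clears the complexity threshold
root_split <- function(x, y, ctrl) {
  fit <- rpart::rpart(y ~ x, data = data.frame(y = y, x = x),
                      method = "class", control = ctrl,
                      parms = list(prior = c(0.5, 0.5), split = "gini"))
  if (is.null(fit$splits) || nrow(fit$splits) == 0) return(NA_real_)
  unname(fit$splits[1, "index"])
}

fractions_matrix <- function(cells, glycans) {
  cols <- vapply(glycans, frac_col, "")
  miss <- setdiff(cols, names(cells))
  if (length(miss))
    stop("cells table lacks fraction columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(cells[, cols, drop = FALSE])
  colnames(m) <- glycans
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop("fraction-positive values must lie in [0,1]")
  m
}

#' Fit per-glycan dichotomization thresholds from classification trees
#'
#' For each glycan and each cross-validation fold, grows a CART tree
#' (Gini impurity, balanced class priors, minimum leaf size
#' \code{min_bucket}) on that glycan's fraction-positive values alone to
#' distinguish cancer from non-cancer cells, and takes the glycan's
#' threshold as the median over folds of the tree's first (root) split —
#' the marginal optimal cutpoint. A glycan whose trees never split (its
#' values carry no class information at the complexity threshold
#' \code{cp}) is flagged and gets no threshold.
#'
#' @param cells Cells table with \code{frac_*} columns (see
#'   \code{\link{generate_cohort}}).
#' @param labels Logical (or coercible) per-cell cancer indicator.
#' @param panel A \code{\link{glycan_panel}}.
#' @param cv_folds Number of cross-validation folds.
#' @param seed Integer seed for the fold split.
#' @param min_bucket Minimum cells per leaf.
#' @param cp rpart complexity parameter; splits improving impurity by less
#'   than this fraction of the root risk are not made.
#' @return Object of class \code{threshold_set}: list with
#'   \code{thresholds} (named numeric, NA when flagged), \code{per_fold}
#'   (fold x glycan matrix), \code{flagged} (glycans without any split),
#'   \code{cv_folds}, \code{seed}.
#' @export
fit_thresholds <- function(cells, labels, panel = glycan_panel(),
                           cv_folds = 5L, seed = 1L,
                           min_bucket = 50L, cp = 0.01) {
  labels <- as.logical(labels)
  if (length(labels) != nrow(cells)) stop("labels must match cells rows")
  if (length(unique(labels)) < 2) stop("both cancer and non-cancer cells required")
  if (length(unique(cells$specimen_id)) < 2)
    stop("at least 2 specimens required")
  X <- fractions_matrix(cells, panel$glycans)
  df <- data.frame(y = factor(labels, c(FALSE, TRUE), c("noncancer", "cancer")),
                   X, check.names = TRUE)
  gly_syn <- make.names(panel$glycans)          # rpart-safe variable names
  names(gly_syn) <- panel$glycans
  set.seed(seed)
  folds <- fold_ids(nrow(df), cv_folds)
  per_fold <- matrix(NA_real_, cv_folds, length(panel$glycans),
                     dimnames = list(paste0("fold", seq_len(cv_folds)),
                                     panel$glycans))
  ctrl <- rpart::rpart.control(minbucket = min_bucket, cp = cp,
                               maxsurrogate = 0, maxcompete = 0, xval = 0,
                               maxdepth = 1)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    for (g in panel$glycans)
      per_fold[f, g] <- root_split(df[[gly_syn[g]]][tr], df$y[tr], ctrl)
  }
  med <- apply(per_fold, 2, stats::median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  med <- pmin(pmax(med, .Machine$double.eps), 1 - .Machine$double.eps)
  flagged <- names(med)[is.na(med) | colSums(!is.na(per_fold)) == 0]
  med[flagged] <- NA_real_
  structure(list(thresholds = med, per_fold = per_fold, flagged = flagged,
                 cv_folds = cv_folds, seed = seed),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("Glycan thresholds (median over", x$cv_folds, "folds, seed", x$seed, "):\n")
  print(round(x$thresholds, 4))
  if (length(x$flagged))
    cat("flagged (no informative split):", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a threshold set as structured text
#'
#' @param thresholds A \code{threshold_set}.
#' @param path File path (YAML).
#' @return \code{read_thresholds} returns a \code{threshold_set}.
#' @export
write_thresholds <- function(thresholds, path) {
  x <- unclass(thresholds)
  x$thresholds <- as.list(x$thresholds)
  x$per_fold <- as.data.frame(x$per_fold)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- yaml::read_yaml(path)
  pf <- as.matrix(as.data.frame(x$per_fold, check.names = FALSE))
  rownames(pf) <- paste0("fold", seq_len(nrow(pf)))
  thr <- vapply(x$thresholds, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
  structure(list(thresholds = thr, per_fold = pf,
                 flagged = as.character(unlist(x$flagged)),
                 cv_folds = x$cv_folds, seed = x$seed),
            class = "threshold_set")
}

cv_accuracy <- function(df, folds, ctrl) {
  acc <- 0
  for (f in sort(unique(folds))) {
    fit <- rpart::rpart(y ~ ., data = df[folds != f, , drop = FALSE],
                        method = "class", control = ctrl,
                        parms = list(prior = c(0.5, 0.5), split = "gini"))
    pred <- predict(fit, df[folds == f, , drop = FALSE], type = "class")
    acc <- acc + sum(pred == df$y[folds == f])
  }
  acc / nrow(df)
}

#' Prune uninformative glycan channels
#'
#' Repeatedly removes the glycan with the lowest CART variable-importance
#' score, but only if the cross-validated classification accuracy
#' (cancer vs non-cancer) drops by no more than \code{tol} relative to the
#' full panel. Importance ties are broken toward the glycan earlier in
#' panel order.
#'
#' @inheritParams fit_thresholds
#' @param tol Maximum tolerated accuracy drop (fraction; default 0.005 =
#'   0.5 percentage points).
#' @return List with \code{retained}, \code{pruned}, \code{importance}
#'   (named, full model), \code{baseline_accuracy} and a \code{report}
#'   data frame (one row per pruning decision).
#' @export
prune_glycans <- function(cells, labels, panel = glycan_panel(),
                          cv_folds = 5L, seed = 1L, tol = 0.005,
                          min_bucket = 50L, cp = 1e-4) {
  labels <- as.logical(labels)
  X <- fractions_matrix(cells, panel$glycans)
  df <- data.frame(y = factor(labels, c(FALSE, TRUE), c("noncancer", "cancer")),
                   X, check.names = TRUE)
  gly_syn <- make.names(panel$glycans)
  names(gly_syn) <- panel$glycans
  ctrl <- rpart::rpart.control(minbucket = min_bucket, cp = cp,
                               maxsurrogate = 0, xval = 0)
  set.seed(seed)
  folds <- fold_ids(nrow(df), cv_folds)
  full_fit <- rpart::rpart(y ~ ., data = df, method = "class", control = ctrl,
                           parms = list(prior = c(0.5, 0.5), split = "gini"))
  imp_of <- function(fit, glycans) {
    vi <- fit$variable.importance
    out <- stats::setNames(rep(0, length(glycans)), glycans)
    if (!is.null(vi)) {
      hit <- match(names(vi), gly_syn[glycans])
      ok <- !is.na(hit)
      out[hit[ok]] <- vi[ok]
    }
    out
  }
  importance <- imp_of(full_fit, panel$glycans)
  base_acc <- cv_accuracy(df, folds, ctrl)
  retained <- panel$glycans
  pruned <- character(0)
  report <- list()
  repeat {
    if (length(retained) <= 1) break
    imp <- imp_of(rpart::rpart(
      y ~ ., data = df[, c("y", gly_syn[retained])], method = "class",
      control = ctrl, parms = list(prior = c(0.5, 0.5), split = "gini")),
      retained)
    cand <- retained[order(imp, match(retained, panel$glycans))][1]
    rest <- setdiff(retained, cand)
    acc <- cv_accuracy(df[, c("y", gly_syn[rest])], folds, ctrl)
    drop <- base_acc - acc
    report[[length(report) + 1L]] <-
      data.frame(glycan = cand, importance = unname(imp[cand]),
                 accuracy_without = acc, accuracy_change = drop,
                 pruned = drop <= tol, stringsAsFactors = FALSE)
    if (drop > tol) break
    retained <- rest
    pruned <- c(pruned, cand)
  }
  list(retained = retained, pruned = pruned, importance = importance,
       baseline_accuracy = base_acc,
       report = do.call(rbind, report))
}

#' Assign 4-bit signature codes to cells
#'
#' Bit g of a cell's code is 1 exactly when its fraction-positive value for
#' glycan g strictly exceeds that glycan's threshold; bits follow the
#' panel's coding order (default VVL, CA19-9, sTRA, GM2), so \code{"0100"}
#' means CA19-9 alone.
#'
#' @param cells Cells table with \code{frac_*} columns.
#' @param thresholds A \code{threshold_set} or named numeric vector of
#'   thresholds covering the coding order.
#' @param panel A \code{\link{glycan_panel}}.
#' @return Character vector of codes, one per cell.
#' @examples
#' cells <- data.frame(frac_VVL = 0, "frac_CA19-9" = 0.5, frac_sTRA = 0,
#'                     frac_GM2 = 0, check.names = FALSE)
#' encode_cells(cells, c("VVL" = .2, "CA19-9" = .2, "sTRA" = .2, "GM2" = .2))
#' @export
encode_cells <- function(cells, thresholds, panel = glycan_panel()) {
  thr <- if (inherits(thresholds, "threshold_set")) thresholds$thresholds
         else thresholds
  miss <- setdiff(panel$code_order, names(thr)[!is.na(thr)])
  if (length(miss))
    stop("thresholds missing for coded glycans: ", paste(miss, collapse = ", "))
  X <- fractions_matrix(cells, panel$code_order)
  bits <- sweep(X, 2, thr[panel$code_order], ">")
  apply(bits, 1, function(b) paste(as.integer(b), collapse = ""))
}

#' Per-unit composition over the 16 signature codes
#'
#' Tallies, within each unit (ROI, cluster, or tumor), the fraction of
#' cells carrying each of the 16 signature codes. Fractions sum to 1 per
#' unit; cell counts are retained. Units with zero cells cannot arise from
#' grouping and units whose id is missing are dropped with a warning.
#'
#' @param codes Character vector of per-cell codes.
#' @param unit Per-cell unit identifier (e.g. \code{roi_id}).
#' @param specimen Optional per-cell specimen identifier, carried through.
#' @param histology Optional per-cell histology label; the unit keeps the
#'   majority label.
#' @return Data frame: \code{unit}, \code{specimen_id}, \code{histology},
#'   \code{n_cells}, and one fraction column per code.
#' @export
roi_composition <- function(codes, unit, specimen = NULL, histology = NULL) {
  stopifnot(length(codes) == length(unit))
  keep <- !is.na(unit) & unit != ""
  if (!all(keep)) {
    warning(sum(!keep), " cells without a unit id excluded")
    codes <- codes[keep]; unit <- unit[keep]
    if (!is.null(specimen)) specimen <- specimen[keep]
    if (!is.null(histology)) histology <- histology[keep]
  }
  if (!length(codes)) stop("no cells with unit ids")
  cds <- all_codes(nchar(codes[1]))
  tab <- table(unit = unit, code = factor(codes, cds))
  n <- rowSums(tab)
  frac <- sweep(unclass(tab), 1, n, "/")
  out <- data.frame(unit = rownames(tab), n_cells = as.integer(n),
                    stringsAsFactors = FALSE)
  maj <- function(v) names(sort(table(v), decreasing = TRUE))[1]
  out$specimen_id <- if (!is.null(specimen))
    vapply(split(as.character(specimen), unit)[out$unit], maj, "") else NA_character_
  out$histology <- if (!is.null(histology))
    vapply(split(as.character(histology), unit)[out$unit], maj, "") else NA_character_
  cbind(out[, c("unit", "specimen_id", "histology", "n_cells")],
        as.data.frame(frac, check.names = FALSE))
}

## fraction columns (the 16 codes) of a composition data frame, as a matrix
composition_matrix <- function(comp, codes = NULL) {
  if (is.null(codes))
    codes <- grep("^[01]+$", names(comp), value = TRUE)
  m <- as.matrix(comp[, codes, drop = FALSE])
  rownames(m) <- comp$unit
  m
}
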