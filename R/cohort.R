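#' Configuration for a synthetic cohort
#'
#' Defines the generative conditions for a synthetic multiplexed-glycan
#' cohort: tumor-type mixture, spatial cluster structure, the bimodal
#' beta model for per-glycan fraction-positive values, the blood-assay
#' model linking RFU to tumor signature burden, and the survival model.
#' Defaults emulate a study of 34 PDAC tumors and 4 non-cancer pancreata
#' with three tumor types (CA19-9-type, sTRA-type, mixed), scaled to
#' desk-size cell counts.
#'
#' @param n_tumors Number of tumor specimens.
#' @param n_normals Number of non-cancer specimens.
#' @param tumor_type_weights Named probabilities over
#'   \code{c("CA19-9", "sTRA", "mixed")}; must sum to 1.
#' @param n_clusters_per_tumor Integer range (length 2) of cancer-cell
#'   clusters per tumor.
#' @param cells_per_cluster Integer range of cells per cluster.
#' @param n_noncancer_clusters Integer range of non-cancer clusters per
#'   specimen (tumors and normals alike).
#' @param cluster_purity_range Interval in [0,1]: the mixing fraction of a
#'   cluster's dominant signature code.
#' @param type_codes Named list: the signature-code pool of each tumor type.
#' @param histology_codes Named list: single-glycan code pool of each
#'   non-cancer histology (acinar, islet, duct).
#' @param noncancer_purity Mixing fraction of a non-cancer cluster's
#'   dominant histology code (normal structures are coherent: a CA19-9+
#'   duct is a region, not a per-cell lottery).
#' @param dominant_concentration Probability that a cluster of a tumor not
#'   planted as heterogeneous-uniform adopts the tumor-level dominant code
#'   (tumors are typically predominated by one subpopulation).
#' @param noise List with \code{mean_high}, \code{mean_low}, \code{conc}:
#'   beta-distribution means for the positive/negative state of a glycan and
#'   the shared concentration (shape1 + shape2).
#' @param tra_agreement Probability that the TRA channel copies the sTRA
#'   bit (TRA is generated as a noisy copy of sTRA; GSL-II as background).
#' @param spatial List with \code{cluster_sd_um} (isotropic Gaussian blob
#'   s.d.) and \code{field_um} (side of the square field holding cluster
#'   centers).
#' @param het_uniform List with \code{prob} (probability a tumor is planted
#'   as heterogeneous-uniform: several distinct, high-purity clonal
#'   outgrowths) and \code{purity_range} used for such tumors.
#' @param blood_model List: \code{assays} (capture.detect identifiers),
#'   \code{baseline} and \code{slope} per assay (RFU), \code{sigma_subject}
#'   (s.d. of the shared per-subject log-normal factor),
#'   \code{sigma_assay} (s.d. of per-assay log-normal noise),
#'   \code{n_controls}, and \code{assay_signatures} (named list mapping each
#'   assay to the codes whose cell burden drives it).
#' @param survival_model List: per-class exponential hazards (per day)
#'   \code{hazard_het_uniform} and \code{hazard_other}, administrative
#'   censoring \code{censor_days}, and \code{progression_range} (progression
#'   time as a uniform fraction of survival time).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config including this seed.
#' @return An object of class \code{cohort_config} (a validated list).
#' @examples
#' cfg <- cohort_config(n_tumors = 4, n_normals = 1, seed = 1)
#' @export
cohort_config <- function(n_tumors = 34L,
                          n_normals = 4L,
                          tumor_type_weights = c("CA19-9" = 1/3, "sTRA" = 1/3,
                                                 "mixed" = 1/3),
                          n_clusters_per_tumor = c(3L, 8L),
                          cells_per_cluster = c(80L, 250L),
                          n_noncancer_clusters = c(2L, 5L),
                          cluster_purity_range = c(0.6, 0.95),
                          type_codes = list(
                            "CA19-9" = c("1100", "1101", "0100"),
                            "sTRA"   = c("1010", "1011"),
                            "mixed"  = c("1100", "1101", "0100", "1010",
                                         "1011", "0110", "1110", "1111")),
                          histology_codes = list(
                            acinar = c("1000", "0001"),
                            islet  = "0001",
                            duct   = c("1000", "0100", "0001")),
                          noncancer_purity = 0.95,
                          dominant_concentration = 0.8,
                          noise = list(mean_high = 0.7, mean_low = 0.02,
                                       conc = 20),
                          tra_agreement = 0.9,
                          spatial = list(cluster_sd_um = 60, field_um = 4000),
                          het_uniform = list(prob = 0.25,
                                             purity_range = c(0.85, 0.98)),
                          blood_model = list(
                            assays = c("CA19-9.CA19-9", "TR4.sTRA",
                                       "CA19-9.sTRA", "sTRA.CA19-9"),
                            baseline = c(100, 100, 100, 100),
                            slope = c(400, 400, 400, 400),
                            sigma_subject = 0.6,
                            sigma_assay = 0.15,
                            n_controls = 60L,
                            assay_signatures = NULL),
                          survival_model = list(
                            hazard_het_uniform = log(2) / 324,
                            hazard_other = log(2) / 1991,
                            censor_days = 3000,
                            progression_range = c(0.2, 0.8)),
                          seed = 1L) {
  cfg <- list(n_tumors = as.integer(n_tumors),
              n_normals = as.integer(n_normals),
              tumor_type_weights = tumor_type_weights,
              n_clusters_per_tumor = as.integer(n_clusters_per_tumor),
              cells_per_cluster = as.integer(cells_per_cluster),
              n_noncancer_clusters = as.integer(n_noncancer_clusters),
              cluster_purity_range = cluster_purity_range,
              type_codes = type_codes,
              histology_codes = histology_codes,
              noncancer_purity = noncancer_purity,
              dominant_concentration = dominant_concentration,
              noise = noise,
              tra_agreement = tra_agreement,
              spatial = spatial,
              het_uniform = het_uniform,
              blood_model = blood_model,
              survival_model = survival_model,
              seed = as.integer(seed))
  if (is.null(cfg$blood_model$assay_signatures)) {
    ## each assay tracks the burden of one subpopulation family, emulating
    ## the observed type-specific elevation of the hybrid assays
    sp <- subpopulation_codes()
    cfg$blood_model$assay_signatures <- list(
      "CA19-9.CA19-9" = sp$ca199_exclusive,
      "TR4.sTRA"      = sp$stra_exclusive,
      "CA19-9.sTRA"   = sp$dual,
      "sTRA.CA19-9"   = sp$dual)
    names(cfg$blood_model$assay_signatures) <- cfg$blood_model$assays
  }
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (abs(sum(cfg$tumor_type_weights) - 1) > 1e-8)
    stop("tumor_type_weights must sum to 1")
  if (any(cfg$tumor_type_weights < 0))
    stop("tumor_type_weights must be non-negative")
  rng <- cfg$cluster_purity_range
  if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 0 || rng[2] > 1)
    stop("cluster_purity_range must be an interval within [0,1]")
  counts <- c(cfg$n_tumors, cfg$n_clusters_per_tumor, cfg$cells_per_cluster)
  if (any(counts < 1))
    stop("tumor, cluster and cell counts must be positive")
  if (length(cfg$seed) != 1 || is.na(cfg$seed))
    stop("a single integer seed is required")
  if (!setequal(names(cfg$tumor_type_weights), names(cfg$type_codes)))
    stop("tumor_type_weights and type_codes must name the same types")
  bad <- setdiff(unlist(cfg$type_codes), all_codes())
  if (length(bad)) stop("unknown signature codes in type_codes: ",
                        paste(bad, collapse = ", "))
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort config:", x$n_tumors, "tumors,", x$n_normals,
      "normal specimens, seed", x$seed, "\n")
  cat("  type weights:",
      paste(sprintf("%s=%.2f", names(x$tumor_type_weights),
                    x$tumor_type_weights), collapse = ", "), "\n")
  cat("  purity range: [", x$cluster_purity_range[1], ",",
      x$cluster_purity_range[2], "]\n")
  invisible(x)
}

rbeta_state <- function(n, positive, noise) {
  m <- ifelse(positive, noise$mean_high, noise$mean_low)
  stats::rbeta(n, m * noise$conc, (1 - m) * noise$conc)
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic cohort
#'
#' Draws a full synthetic cohort — per-cell glycan fraction-positive tables
#' with spatial coordinates, matched blood-assay measurements, and survival
#' records — from a \code{\link{cohort_config}}. Cancer cells are laid out
#' in spatial clusters, each dominated by one signature code at a purity
#' drawn from the configured range; fraction-positive values follow a
#' bimodal beta model (high mode when the cell's code bit is 1, low mode
#' when 0); TRA is a noisy copy of sTRA and GSL-II pure background, so the
#' glycan-pruning step has channels to discard. Blood RFU increases with the
#' fraction of tumor cells bearing each assay's signature; survival time is
#' exponential with a higher hazard for tumors planted as
#' heterogeneous-uniform (multiple distinct high-purity clonal outgrowths).
#'
#' @param config A \code{\link{cohort_config}}.
#' @return An object of class \code{synthetic_cohort}: list with data frames
#'   \code{cells}, \code{blood}, \code{survival} and a \code{truth} list
#'   (\code{cells}: true code per cell; \code{clusters}: dominant code,
#'   purity, histology; \code{tumors}: planted type and risk class).
#' @examples
#' coh <- generate_cohort(cohort_config(n_tumors = 3, n_normals = 1, seed = 7))
#' head(coh$cells)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("config must be a cohort_config object")
  validate_cohort_config(config)
  set.seed(config$seed)

  panel <- glycan_panel()
  types <- names(config$tumor_type_weights)
  spec_ids <- c(sprintf("T%03d", seq_len(config$n_tumors)),
                if (config$n_normals > 0) sprintf("N%03d", seq_len(config$n_normals)))
  is_tumor <- grepl("^T", spec_ids)
  tumor_type <- rep(NA_character_, length(spec_ids))
  tumor_type[is_tumor] <- sample(types, config$n_tumors, replace = TRUE,
                                 prob = config$tumor_type_weights)
  het_flag <- rep(FALSE, length(spec_ids))
  het_flag[is_tumor] <- stats::runif(config$n_tumors) < config$het_uniform$prob

  cell_rows <- list()
  clus_rows <- list()
  histologies <- names(config$histology_codes)

  draw_cluster <- function(spec, cid, n, code_pool, dominant, purity, hist,
                           cancer) {
    center <- stats::runif(2, 0, config$spatial$field_um)
    x <- stats::rnorm(n, center[1], config$spatial$cluster_sd_um)
    y <- stats::rnorm(n, center[2], config$spatial$cluster_sd_um)
    take <- stats::runif(n) < purity
    alt <- setdiff(code_pool, dominant)
    codes <- ifelse(take, dominant,
                    if (length(alt)) sample(alt, n, replace = TRUE) else dominant)
    bits <- code_bits(all_codes())[codes, , drop = FALSE]
    fr <- matrix(NA_real_, n, length(panel$glycans),
                 dimnames = list(NULL, panel$glycans))
    for (j in seq_along(panel$code_order))
      fr[, panel$code_order[j]] <- rbeta_state(n, bits[, j], config$noise)
    tra_bit <- ifelse(stats::runif(n) < config$tra_agreement, bits[, 3], !bits[, 3])
    fr[, "TRA"] <- rbeta_state(n, tra_bit, config$noise)
    fr[, "GSL-II"] <- rbeta_state(n, FALSE, config$noise)
    cl_id <- sprintf("%s_c%02d", spec, cid)
    list(cells = data.frame(cell_id = sprintf("%s_%04d", cl_id, seq_len(n)),
                            specimen_id = spec, cluster_id = cl_id,
                            roi_id = cl_id, x_um = x, y_um = y,
                            fr, histology = hist, true_code = codes,
                            check.names = FALSE, stringsAsFactors = FALSE),
         cluster = data.frame(cluster_id = cl_id, specimen_id = spec,
                              dominant_code = dominant, purity = purity,
                              histology = hist, is_cancer = cancer,
                              stringsAsFactors = FALSE))
  }

  for (s in seq_along(spec_ids)) {
    spec <- spec_ids[s]
    cid <- 0L
    if (is_tumor[s]) {
      pool <- config$type_codes[[tumor_type[s]]]
      ncl <- rint(1, config$n_clusters_per_tumor)
      prange <- if (het_flag[s]) config$het_uniform$purity_range
                else config$cluster_purity_range
      if (het_flag[s]) {
        dominants <- sample(pool, ncl, replace = TRUE)
        if (length(unique(dominants)) < 2 && length(pool) >= 2)
          dominants[1:2] <- sample(pool, 2)
      } else {
        tumor_dom <- sample(pool, 1)
        dominants <- ifelse(stats::runif(ncl) < config$dominant_concentration,
                            tumor_dom, sample(pool, ncl, replace = TRUE))
      }
      for (k in seq_len(ncl)) {
        cid <- cid + 1L
        cl <- draw_cluster(spec, cid, rint(1, config$cells_per_cluster), pool,
                           dominants[k], stats::runif(1, prange[1], prange[2]),
                           "PDAC", cancer = TRUE)
        cell_rows[[length(cell_rows) + 1L]] <- cl$cells
        clus_rows[[length(clus_rows) + 1L]] <- cl$cluster
      }
    }
    nnc <- rint(1, config$n_noncancer_clusters)
    for (k in seq_len(nnc)) {
      cid <- cid + 1L
      hist <- sample(histologies, 1)
      pool_nc <- config$histology_codes[[hist]]
      cl <- draw_cluster(spec, cid, rint(1, config$cells_per_cluster),
                         pool_nc, sample(pool_nc, 1),
                         config$noncancer_purity, hist, cancer = FALSE)
      cell_rows[[length(cell_rows) + 1L]] <- cl$cells
      clus_rows[[length(clus_rows) + 1L]] <- cl$cluster
    }
  }

  cells <- do.call(rbind, cell_rows)
  rownames(cells) <- NULL
  truth_cells <- cells[, c("cell_id", "true_code")]
  cells$true_code <- NULL
  names(cells)[match(panel$glycans, names(cells))] <-
    vapply(panel$glycans, frac_col, "")
  clusters <- do.call(rbind, clus_rows)
  rownames(clusters) <- NULL
  tumors <- data.frame(specimen_id = spec_ids, is_tumor = is_tumor,
                       type = tumor_type, het_uniform = het_flag,
                       stringsAsFactors = FALSE)

  ## blood: one case sample per tumor plus unmatched controls
  bm <- config$blood_model
  burden_of <- function(spec, codes_set) {
    idx <- cells$specimen_id == spec & cells$histology == "PDAC"
    if (!any(idx)) return(0)
    mean(truth_cells$true_code[idx] %in% codes_set)
  }
  blood_rows <- list()
  for (spec in spec_ids[is_tumor]) {
    subj <- stats::rnorm(1, 0, bm$sigma_subject)
    rfu <- vapply(seq_along(bm$assays), function(a) {
      b <- burden_of(spec, bm$assay_signatures[[bm$assays[a]]])
      (bm$baseline[a] + bm$slope[a] * b) *
        exp(subj + stats::rnorm(1, 0, bm$sigma_assay))
    }, 0)
    blood_rows[[length(blood_rows) + 1L]] <-
      data.frame(sample_id = paste0("B_", spec), specimen_id = spec,
                 assay_id = bm$assays, rfu = rfu, class = "case",
                 stringsAsFactors = FALSE)
  }
  for (i in seq_len(bm$n_controls)) {
    subj <- stats::rnorm(1, 0, bm$sigma_subject)
    rfu <- bm$baseline * exp(subj + stats::rnorm(length(bm$assays), 0, bm$sigma_assay))
    blood_rows[[length(blood_rows) + 1L]] <-
      data.frame(sample_id = sprintf("C%03d", i), specimen_id = NA_character_,
                 assay_id = bm$assays, rfu = rfu, class = "control",
                 stringsAsFactors = FALSE)
  }
  blood <- do.call(rbind, blood_rows)
  rownames(blood) <- NULL

  ## survival for tumor specimens
  sm <- config$survival_model
  haz <- ifelse(het_flag[is_tumor], sm$hazard_het_uniform, sm$hazard_other)
  t_true <- stats::rexp(sum(is_tumor), haz)
  event <- as.integer(t_true <= sm$censor_days)
  time <- pmin(t_true, sm$censor_days)
  prog <- ifelse(event == 1,
                 stats::runif(sum(is_tumor), sm$progression_range[1],
                              sm$progression_range[2]) * time, NA_real_)
  surv <- data.frame(specimen_id = spec_ids[is_tumor], time_days = time,
                     event = event, progression_days = prog,
                     stringsAsFactors = FALSE)

  structure(list(cells = cells, blood = blood, survival = surv,
                 truth = list(cells = truth_cells, clusters = clusters,
                              tumors = tumors),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$cells), "cells,",
      length(unique(x$cells$specimen_id)), "specimens,",
      length(unique(x$blood$sample_id)), "blood samples\n")
  invisible(x)
}

#' Write / read a cohort as delimited text
#'
#' \code{write_cohort} writes \code{cells.csv}, \code{blood.csv},
#' \code{survival.csv}, \code{truth.csv} (per-cell true codes),
#' \code{truth_clusters.csv}, \code{truth_tumors.csv} and
#' \code{config.yaml} into a directory; \code{read_cohort} reads them back.
#' The round trip reproduces the cohort up to numeric text precision.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param dir Directory path (created if absent).
#' @return \code{write_cohort}: the directory, invisibly.
#'   \code{read_cohort}: a \code{synthetic_cohort}.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) stop("not a synthetic_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f)
    utils::write.csv(df, file.path(dir, f), row.names = FALSE,
                     fileEncoding = "UTF-8")
  wr(cohort$cells, "cells.csv")
  wr(cohort$blood, "blood.csv")
  wr(cohort$survival, "survival.csv")
  wr(cohort$truth$cells, "truth.csv")
  wr(cohort$truth$clusters, "truth_clusters.csv")
  wr(cohort$truth$tumors, "truth_tumors.csv")
  cfg <- unclass(cohort$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(basename(path), ": missing columns ", paste(miss, collapse = ", "))
  df
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  panel <- glycan_panel()
  fcols <- vapply(panel$glycans, frac_col, "")
  cells <- read_table_checked(file.path(dir, "cells.csv"),
                              c("cell_id", "specimen_id", "cluster_id",
                                "roi_id", "x_um", "y_um", fcols, "histology"))
  bad <- which(!stats::complete.cases(cells[, c("cell_id", "specimen_id")]))
  if (length(bad))
    stop("cells.csv: malformed rows at index ", paste(utils::head(bad), collapse = ", "))
  blood <- read_table_checked(file.path(dir, "blood.csv"),
                              c("sample_id", "assay_id", "rfu"))
  surv <- read_table_checked(file.path(dir, "survival.csv"),
                             c("specimen_id", "time_days", "event"))
  truth_cells <- read_table_checked(file.path(dir, "truth.csv"),
                                    c("cell_id", "true_code"))
  truth_cells$true_code <- formatC(truth_cells$true_code, width = 4, flag = "0")
  truth_clusters <- read_table_checked(file.path(dir, "truth_clusters.csv"),
                                       c("cluster_id", "specimen_id"))
  if (nrow(truth_clusters) && "dominant_code" %in% names(truth_clusters)) {
    keep <- !is.na(truth_clusters$dominant_code)
    truth_clusters$dominant_code[keep] <-
      formatC(truth_clusters$dominant_code[keep], width = 4, flag = "0")
  }
  truth_tumors <- read_table_checked(file.path(dir, "truth_tumors.csv"),
                                     c("specimen_id", "is_tumor"))
  cfg_path <- file.path(dir, "config.yaml")
  norm_codes <- function(x) formatC(x, width = 4, flag = "0")
  config <- if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    cfg$type_codes <- lapply(cfg$type_codes, norm_codes)
    cfg$histology_codes <- lapply(cfg$histology_codes, norm_codes)
    cfg$blood_model$assay_signatures <-
      lapply(cfg$blood_model$assay_signatures, norm_codes)
    structure(cfg, class = "cohort_config")
  } else NULL
  structure(list(cells = cells, blood = blood, survival = surv,
                 truth = list(cells = truth_cells, clusters = truth_clusters,
                              tumors = truth_tumors),
                 config = config),
            class = "synthetic_cohort")
}
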