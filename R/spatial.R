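## Spatial segmentation: per-glycan kernel density on a shared grid,
## quantile-thresholded dense regions, and conversion of the overlap
## pattern of the regions into signature-coded ROIs.

#' Shared spatial grid for a set of cells
#'
#' Regular grid (spacing in micrometers) whose extent covers all cells plus
#' a padding margin. The origin is anchored at \code{min - pad}, so
#' translating all cells translates the grid — and everything derived from
#' it — identically.
#'
#' @param x,y Cell coordinates (micrometers).
#' @param spacing Node spacing (micrometers).
#' @param pad Margin beyond the cell bounding box.
#' @return List with node vectors \code{x}, \code{y} and \code{spacing}.
#' @export
spatial_grid <- function(x, y, spacing = 10, pad = 150) {
  stopifnot(length(x) == length(y), length(x) > 0)
  gx <- seq(min(x) - pad, max(x) + pad + spacing, by = spacing)
  gy <- seq(min(y) - pad, max(y) + pad + spacing, by = spacing)
  list(x = gx, y = gy, spacing = spacing)
}

#' Gaussian kernel density of glycan-positive cells on a grid
#'
#' Isotropic Gaussian kernel density evaluated at the nodes of a regular
#' grid, under the mass convention: the density integrates (sum times node
#' area) to approximately the number of positive cells. Zero positive cells
#' give an all-zero surface, not an error.
#'
#' @param x,y Coordinates of the cells positive for the glycan.
#' @param bandwidth Kernel standard deviation (micrometers).
#' @param grid A grid from \code{\link{spatial_grid}}; required when
#'   \code{x} is empty, otherwise derived from the cells if missing.
#' @return Object of class \code{density_surface}: list with \code{x},
#'   \code{y}, matrix \code{z} (rows follow \code{x}), \code{bandwidth}
#'   and \code{spacing}.
#' @export
glycan_density <- function(x, y, bandwidth = 50, grid = NULL) {
  if (is.null(grid)) {
    if (!length(x)) stop("a grid is required for an empty cell set")
    grid <- spatial_grid(x, y, pad = 3 * bandwidth)
  }
  nx <- length(grid$x); ny <- length(grid$y)
  if (!length(x)) {
    z <- matrix(0, nx, ny)
  } else {
    kx <- exp(-outer(grid$x, x, "-")^2 / (2 * bandwidth^2))
    ky <- exp(-outer(grid$y, y, "-")^2 / (2 * bandwidth^2))
    z <- (kx %*% t(ky)) / (2 * pi * bandwidth^2)
  }
  structure(list(x = grid$x, y = grid$y, z = z, bandwidth = bandwidth,
                 spacing = grid$spacing),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat("Density surface:", length(x$x), "x", length(x$y), "nodes, bandwidth",
      x$bandwidth, "um, total mass",
      round(sum(x$z) * x$spacing^2, 2), "\n")
  invisible(x)
}

## nearest-node index of each cell on a grid (clamped to the grid)
cell_nodes <- function(x, y, grid) {
  ix <- pmin(pmax(round((x - grid$x[1]) / grid$spacing) + 1L, 1L), length(grid$x))
  iy <- pmin(pmax(round((y - grid$y[1]) / grid$spacing) + 1L, 1L), length(grid$y))
  cbind(ix, iy)
}

## label connected components (8-connectivity) of equal non-background
## values in an integer matrix; returns an integer label matrix (0 = none)
label_regions <- function(vals, background = 0L) {
  nr <- nrow(vals); nc <- ncol(vals)
  lab <- matrix(0L, nr, nc)
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  cur <- 0L
  seeds <- which(vals != background)
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    v <- vals[s]
    frontier <- s
    lab[s] <- cur
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nbr <- integer(0)
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (any(ok)) nbr <- c(nbr, (cc[ok] - 1L) * nr + rr[ok])
      }
      nbr <- unique(nbr)
      nbr <- nbr[vals[nbr] == v & lab[nbr] == 0L]
      lab[nbr] <- cur
      frontier <- nbr
    }
  }
  lab
}

#' Spatially dense regions of a density surface
#'
#' Binary mask of grid nodes whose density is at or above the q-th quantile
#' of the positive-node densities (nodes carrying non-negligible mass).
#' Connected components containing fewer than \code{min_cells} member cells
#' are dropped when cell coordinates are supplied.
#'
#' @param surface A \code{density_surface}.
#' @param q Density quantile in [0, 1).
#' @param min_cells Minimum member cells per component (0 disables).
#' @param cells Optional two-column matrix/data frame of the positive
#'   cells' coordinates, used for the minimum-size filter.
#' @return Logical matrix mask over the surface grid.
#' @export
dense_regions <- function(surface, q = 0.75, min_cells = 0L, cells = NULL) {
  z <- surface$z
  mx <- max(z)
  if (mx <= 0) return(matrix(FALSE, nrow(z), ncol(z)))
  pos <- z > 1e-8 * mx
  thr <- stats::quantile(z[pos], q, names = FALSE)
  mask <- z >= thr
  if (min_cells > 0 && !is.null(cells) && nrow(cells) > 0) {
    lab <- label_regions(matrix(as.integer(mask), nrow(mask)), 0L)
    nd <- cell_nodes(cells[[1]], cells[[2]],
                     list(x = surface$x, y = surface$y,
                          spacing = surface$spacing))
    counts <- table(factor(lab[nd], seq_len(max(lab))))
    drop <- as.integer(names(counts))[counts < min_cells]
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  mask
}

#' Convert overlapping dense-region masks into signature-coded ROIs
#'
#' Every maximal connected region with a constant pattern of mask
#' membership becomes one ROI whose code has bit 1 exactly for the glycans
#' whose mask covers it. Cells are assigned to the ROI containing their
#' nearest grid node; cells falling outside all regions are counted as
#' unassigned.
#'
#' @param masks Named list of logical matrices (one per coded glycan, in
#'   coding order) sharing one grid.
#' @param cells Data frame with \code{cell_id}, \code{x_um}, \code{y_um}.
#' @param grid The shared grid.
#' @param specimen_id Optional specimen identifier stamped on the ROIs.
#' @return List: \code{rois} (roi_id, code, n_nodes, n_cells),
#'   \code{assignment} (cell_id, roi_id; NA when unassigned),
#'   \code{labels} (integer ROI-label matrix), \code{pattern} (integer
#'   bit-pattern matrix), \code{n_unassigned}.
#' @export
overlap_to_rois <- function(masks, cells, grid, specimen_id = NA_character_) {
  k <- length(masks)
  stopifnot(k >= 1)
  dims <- vapply(masks, dim, c(0L, 0L))
  if (any(dims != dims[, 1])) stop("masks must share one grid")
  pattern <- matrix(0L, dims[1, 1], dims[2, 1])
  for (j in seq_len(k))
    pattern <- pattern + as.integer(masks[[j]]) * 2L^(k - j)
  lab <- label_regions(pattern, 0L)
  nlab <- max(lab)
  code_of <- function(v)
    paste(as.integer(intToBits(v))[k:1], collapse = "")
  roi_codes <- character(nlab)
  n_nodes <- integer(nlab)
  if (nlab > 0) {
    for (l in seq_len(nlab)) {
      idx <- which(lab == l)
      roi_codes[l] <- code_of(pattern[idx[1]])
      n_nodes[l] <- length(idx)
    }
  }
  nd <- cell_nodes(cells$x_um, cells$y_um, grid)
  cell_lab <- lab[cbind(nd[, 1], nd[, 2])]
  roi_ids <- if (nlab > 0) sprintf("%s_roi%03d",
                                   ifelse(is.na(specimen_id), "s", specimen_id),
                                   seq_len(nlab)) else character(0)
  assignment <- data.frame(cell_id = cells$cell_id,
                           roi_id = ifelse(cell_lab > 0, roi_ids[pmax(cell_lab, 1)],
                                           NA_character_),
                           stringsAsFactors = FALSE)
  n_cells <- as.integer(table(factor(cell_lab, seq_len(nlab))))
  list(rois = data.frame(roi_id = roi_ids,
                         specimen_id = rep(specimen_id, nlab),
                         code = roi_codes, n_nodes = n_nodes,
                         n_cells = n_cells, stringsAsFactors = FALSE),
       assignment = assignment, labels = lab, pattern = pattern,
       n_unassigned = sum(cell_lab == 0))
}

#' Segment every specimen of a coded cells table into spatial ROIs
#'
#' Per specimen: computes one density surface per coded glycan from the
#' cells positive for that glycan, thresholds each at the density quantile
#' \code{q}, and converts the overlap pattern into signature-coded ROIs.
#'
#' @param cells Cells table (needs \code{specimen_id}, \code{x_um},
#'   \code{y_um}, \code{cell_id}).
#' @param codes Character per-cell signature codes.
#' @param bandwidth,q,min_cells Segmentation controls (see
#'   \code{\link{glycan_density}}, \code{\link{dense_regions}}).
#' @param spacing Grid spacing (micrometers).
#' @param panel A \code{\link{glycan_panel}}.
#' @return List with \code{rois} and \code{assignment} data frames pooled
#'   over specimens.
#' @export
spatial_segment <- function(cells, codes, bandwidth = 50, q = 0.75,
                            min_cells = 20L, spacing = 10,
                            panel = glycan_panel()) {
  bits <- code_bits(all_codes())[codes, , drop = FALSE]
  rois <- list(); assignment <- list()
  for (spec in unique(cells$specimen_id)) {
    i <- cells$specimen_id == spec
    sub <- cells[i, , drop = FALSE]
    grid <- spatial_grid(sub$x_um, sub$y_um, spacing = spacing,
                         pad = 3 * bandwidth)
    masks <- vector("list", length(panel$code_order))
    names(masks) <- panel$code_order
    for (j in seq_along(panel$code_order)) {
      pos <- bits[i, j]
      surf <- glycan_density(sub$x_um[pos], sub$y_um[pos], bandwidth, grid)
      masks[[j]] <- dense_regions(surf, q, min_cells,
                                  sub[pos, c("x_um", "y_um")])
    }
    seg <- overlap_to_rois(masks, sub, grid, specimen_id = spec)
    rois[[spec]] <- seg$rois
    assignment[[spec]] <- seg$assignment
  }
  list(rois = do.call(rbind, c(rois, list(make.row.names = FALSE))),
       assignment = do.call(rbind, c(assignment, list(make.row.names = FALSE))))
}

#' Randomly sample ROIs per specimen
#'
#' Uniform sample without replacement of at most \code{n} ROIs from each
#' specimen (all ROIs when fewer are available).
#'
#' @param rois Data frame with \code{roi_id} and \code{specimen_id}.
#' @param n Target ROIs per specimen.
#' @param seed Integer seed.
#' @return Subset of \code{rois}.
#' @export
sample_rois <- function(rois, n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  take <- unlist(lapply(split(seq_len(nrow(rois)), rois$specimen_id),
                        function(i) if (length(i) <= n) i else sample(i, n)),
                 use.names = FALSE)
  rois[sort(take), , drop = FALSE]
}
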