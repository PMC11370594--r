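#' Glycan panel definition
#'
#' A glycan panel holds the ordered set of stained glycan channels and the
#' ordered subset used for binary signature coding. The coding order is fixed
#' by convention — VVL, CA19-9, sTRA, GM2 — so that, for example, the code
#' \code{"0100"} always means "CA19-9 alone".
#'
#' @param glycans Character vector of channel names, in staining order.
#' @param code_order Character vector, the ordered subset used for the 4-bit
#'   code. Must be contained in \code{glycans}.
#' @return An object of class \code{glycan_panel}: a list with elements
#'   \code{glycans} and \code{code_order}.
#' @examples
#' glycan_panel()
#' @export
glycan_panel <- function(glycans = c("VVL", "CA19-9", "sTRA", "GM2", "TRA", "GSL-II"),
                         code_order = c("VVL", "CA19-9", "sTRA", "GM2")) {
  stopifnot(is.character(glycans), is.character(code_order))
  if (anyDuplicated(glycans) || anyDuplicated(code_order))
    stop("glycan names must be unique")
  missing <- setdiff(code_order, glycans)
  if (length(missing))
    stop("code_order glycans not in panel: ", paste(missing, collapse = ", "))
  structure(list(glycans = glycans, code_order = code_order),
            class = "glycan_panel")
}

#' @export
print.glycan_panel <- function(x, ...) {
  cat("Glycan panel:", paste(x$glycans, collapse = ", "), "\n")
  cat("Code order: ", paste(x$code_order, collapse = ", "), "\n")
  invisible(x)
}

## column name for a glycan's fraction-positive value in a cells table;
## "CA19-9" keeps its hyphen, "GSL-II" is written GSLII
frac_col <- function(glycan) paste0("frac_", sub("^GSL-II$", "GSLII", glycan))

#' All signature codes over a coding order
#'
#' @param k Number of coded glycans (default 4).
#' @return Character vector of the \eqn{2^k} codes, "0000" first.
#' @examples
#' all_codes()
#' @export
all_codes <- function(k = 4L) {
  apply(as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE]),
        1L, paste, collapse = "")
}

## code -> logical bit matrix (rows codes, cols positions)
code_bits <- function(codes) {
  m <- do.call(rbind, strsplit(codes, ""))
  storage.mode(m) <- "integer"
  rownames(m) <- codes
  m == 1L
}

## codes (character) with bit for `glycan` set, given a code order
codes_with_bit <- function(glycan, code_order = glycan_panel()$code_order,
                           k = length(code_order)) {
  pos <- match(glycan, code_order)
  if (is.na(pos)) stop("glycan not in code order: ", glycan)
  cds <- all_codes(k)
  cds[substr(cds, pos, pos) == "1"]
}

#' Canonical subpopulation code sets
#'
#' The three cancer-cell subpopulation families used for tumor typing:
#' sTRA-exclusive cells (sTRA without CA19-9), CA19-9-exclusive cells
#' (CA19-9 without sTRA), and dual-expressing cells (both).
#'
#' @return Named list of character vectors of codes.
#' @examples
#' subpopulation_codes()
#' @export
subpopulation_codes <- function() {
  list(
    stra_exclusive  = c("1010", "1011"),
    ca199_exclusive = c("1100", "1101", "0100"),
    dual            = c("0110", "1110", "1111")
  )
}
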