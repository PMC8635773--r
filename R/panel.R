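#' Define an X-STR marker panel
#'
#' A panel groups named loci into linkage groups (LGs) and places them on the
#' female X genetic map. Positions are in centimorgans (cM); loci within each
#' group are kept in map order.
#'
#' @param locus character vector of unique locus names.
#' @param linkage_group character vector of group labels, one per locus.
#' @param position_cM numeric vector of map positions in cM (nonnegative,
#'   finite). Positions are absolute coordinates on one map, so distances
#'   between loci of different groups are meaningful.
#' @return An object of class `xstr_panel` (a data frame with columns
#'   `locus`, `linkage_group`, `position_cM`), ordered by position.
#' @examples
#' xstr_panel(c("A", "B"), c("LG1", "LG1"), c(0, 0.5))
#' @export
xstr_panel <- function(locus, linkage_group, position_cM) {
  locus <- as.character(locus)
  linkage_group <- as.character(linkage_group)
  position_cM <- as.numeric(position_cM)
  if (length(locus) != length(linkage_group) ||
      length(locus) != length(position_cM))
    stop("locus, linkage_group and position_cM must have equal length")
  if (anyDuplicated(locus)) stop("duplicate locus name in panel")
  if (any(!is.finite(position_cM)) || any(position_cM < 0))
    stop("position_cM must be finite and nonnegative")
  p <- data.frame(locus = locus, linkage_group = linkage_group,
                  position_cM = position_cM, stringsAsFactors = FALSE)
  p <- p[order(p$position_cM, p$locus), , drop = FALSE]
  rownames(p) <- NULL
  class(p) <- c("xstr_panel", "data.frame")
  p
}

#' Split a panel into its linkage groups
#'
#' @param panel an [xstr_panel()].
#' @return Named list of panel subsets, one per linkage group, each in map
#'   order; groups ordered by the map position of their first locus.
#' @export
panel_groups <- function(panel) {
  stopifnot(inherits(panel, "xstr_panel"))
  g <- split(seq_len(nrow(panel)), panel$linkage_group)
  g <- g[order(vapply(g, function(i) min(panel$position_cM[i]), 0))]
  lapply(g, function(i) {
    s <- panel[i, , drop = FALSE]
    class(s) <- c("xstr_panel", "data.frame")
    s
  })
}

#' Read a genetic map table
#'
#' Expects a UTF-8 tab-separated file with header
#' `locus linkage_group position_cM`; lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return An [xstr_panel()].
#' @export
read_map_table <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("locus", "linkage_group", "position_cM")
  if (!all(need %in% names(d)))
    stop("map table must have columns: ", paste(need, collapse = ", "))
  xstr_panel(d$locus, d$linkage_group, d$position_cM)
}

#' Write a genetic map table
#'
#' Output is bit-stable for identical input.
#'
#' @param panel an [xstr_panel()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_map_table <- function(panel, path) {
  stopifnot(inherits(panel, "xstr_panel"))
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.xstr_panel <- function(x, ...) {
  cat("X-STR panel:", nrow(x), "loci in",
      length(unique(x$linkage_group)), "linkage group(s)\n")
  print.data.frame(x, ...)
  invisible(x)
}
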