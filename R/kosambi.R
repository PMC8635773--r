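#' Kosambi mapping function: map distance to recombination fraction
#'
#' \eqn{\theta = \tfrac{1}{2}\tanh(2d)} with d in Morgans; input is in
#' centimorgans. The Kosambi function allows for positive crossover
#' interference at short distances and saturates at 1/2.
#'
#' @param distance_cM nonnegative genetic distance(s) in cM.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' kosambi_theta(37.60) # ~0.318
#' @export
kosambi_theta <- function(distance_cM) {
  if (any(is.na(distance_cM)) || any(distance_cM < 0))
    stop("distance_cM must be nonnegative")
  0.5 * tanh(2 * distance_cM / 100)
}

#' Inverse Kosambi mapping function
#'
#' \eqn{d = \tfrac{1}{4}\ln\frac{1+2\theta}{1-2\theta}} Morgans, returned in
#' centimorgans. Exact inverse of [kosambi_theta()] on `[0, 0.5)`.
#'
#' @param theta recombination fraction(s) in `[0, 0.5)`.
#' @return Genetic distance(s) in cM.
#' @export
kosambi_distance <- function(theta) {
  if (any(is.na(theta)) || any(theta < 0) || any(theta >= 0.5))
    stop("theta must lie in [0, 0.5)")
  25 * log((1 + 2 * theta) / (1 - 2 * theta))
}

#' Map-predicted recombination fractions for a panel
#'
#' Converts cM distances into Kosambi recombination fractions for every
#' locus pair (absolute map-position differences) and for every linkage
#' group: intragroup over the group's full span (first to last locus),
#' intergroup between group midpoints (default) or nearest edges.
#'
#' @param panel an [xstr_panel()] with positions for all loci.
#' @param intergroup `"midpoint"` or `"edge"`: the endpoints used for the
#'   between-group distance.
#' @return List with `locus_theta` (symmetric locus x locus matrix),
#'   `group_theta` (group x group; diagonal holds the intragroup span
#'   fraction) and `group_span_cM`.
#' @export
pairwise_map_theta <- function(panel, intergroup = c("midpoint", "edge")) {
  intergroup <- match.arg(intergroup)
  if (any(is.na(panel$position_cM))) stop("missing map positions")
  pos <- setNames(panel$position_cM, panel$locus)
  locus_theta <- kosambi_theta(abs(outer(pos, pos, "-")))
  groups <- panel_groups(panel)
  gn <- names(groups)
  k <- length(groups)
  span <- vapply(groups, function(g) diff(range(g$position_cM)), 0)
  mid <- vapply(groups, function(g) mean(range(g$position_cM)), 0)
  gt <- matrix(NA_real_, k, k, dimnames = list(gn, gn))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { gt[i, j] <- kosambi_theta(span[i]); next }
    d <- if (intergroup == "midpoint") abs(mid[i] - mid[j]) else
      max(0, min(abs(outer(groups[[i]]$position_cM,
                           groups[[j]]$position_cM, "-"))))
    gt[i, j] <- kosambi_theta(d)
  }
  list(locus_theta = locus_theta, group_theta = gt,
       group_span_cM = span)
}
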