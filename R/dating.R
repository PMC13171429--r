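# Calibration-based node dating: a simplified relative-rate method. Node
# depth is the mean root-to-tip path length below the node (substitutions
# per site); a single substitution rate is fitted through the origin by
# least squares against the calibration ages, and every node age is its
# depth divided by that rate. Confidence intervals are propagated by
# refitting the rate at the calibration CI bounds.

# mean path length (substitutions/site) from each node to its descendant
# tips; on non-clock trees the raw mean is not monotone along root-to-tip
# paths, so parent depths are floored at their children's depths to keep
# ages consistent (no-op on clock-like trees)
monotone_depths <- function(tree, h) {
  eo <- reorder(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1]; chi <- eo$edge[k, 2]
    h[par] <- max(h[par], h[chi])
  }
  h
}

mean_path_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  sums <- numeric(n)
  cnts <- integer(n)
  cnts[seq_len(ntip)] <- 1L
  eo <- reorder(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1]; chi <- eo$edge[k, 2]
    sums[par] <- sums[par] + sums[chi] + eo$edge.length[k] * cnts[chi]
    cnts[par] <- cnts[par] + cnts[chi]
  }
  sums / cnts
}

resolve_calibration_node <- function(tree, tips) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing) > 0) {
    abort(sprintf("calibration tip(s) not in tree: %s",
                  paste(missing, collapse = ", ")))
  }
  if (length(tips) < 2) abort("calibration node is a tip")
  ape::getMRCA(tree, tips)
}

#' Date tree nodes from calibration points
#'
#' Fits a substitution rate `r` (substitutions/site/Ma) through the origin
#' by least squares against the calibration ages,
#' `r = sum(h_c a_c) / sum(a_c^2)` over calibration nodes `c` with mean
#' path depth `h_c` and age `a_c`, and dates every node as `h(v)/r`.
#' Confidence intervals come from refitting `r` at the lower/upper
#' calibration bounds. On a clock-like tree a single calibration is
#' recovered exactly. On non-clock trees the raw mean path depth can dip
#' below a child's depth, so parent depths are floored at their children's
#' (guaranteeing child age <= parent age; a no-op on clock-like trees).
#'
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param calibrations List of calibration points, each a list with `tips`
#'   (character vector defining an MRCA), `age` (Ma) and optional `ci`
#'   (length-2, Ma).
#' @return Object of class `"node_dating"`: `ages` tibble (`node`,
#'   `depth`, `age_ma`, `age_lo`, `age_hi`), `rate`, `rate_ci`,
#'   `calibration_nodes`. `tidy()` returns the age table.
#' @export
date_nodes <- function(tree, calibrations) {
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  if (length(calibrations) == 0) abort("at least one calibration required")
  h <- monotone_depths(tree, mean_path_depths(tree))
  calib <- purrr::map_dfr(calibrations, function(cp) {
    node <- resolve_calibration_node(tree, cp$tips)
    ci <- cp$ci %||% c(cp$age, cp$age)
    if (cp$age < min(ci) || cp$age > max(ci)) {
      abort("calibration age outside its CI")
    }
    tibble(node = node, age = cp$age, ci_lo = min(ci), ci_hi = max(ci))
  })
  if (any(h[calib$node] == 0)) abort("zero-depth calibration node")
  fit_rate <- function(ages) sum(h[calib$node] * ages) / sum(ages^2)
  r <- fit_rate(calib$age)
  r_hi <- fit_rate(calib$ci_lo)  # younger calibrations -> faster rate
  r_lo <- fit_rate(calib$ci_hi)
  ntip <- length(tree$tip.label)
  ages <- tibble(
    node = seq_along(h),
    is_tip = seq_along(h) <= ntip,
    depth = h,
    age_ma = h / r,
    age_lo = h / r_hi,
    age_hi = h / r_lo
  )
  structure(
    list(ages = ages, rate = r, rate_ci = c(lo = r_lo, hi = r_hi),
         calibration_nodes = calib, tree = tree),
    class = "node_dating"
  )
}

#' @export
print.node_dating <- function(x, ...) {
  cat(sprintf(
    "Relative-rate node dating: rate = %.4g subs/site/Ma (CI %.4g-%.4g)\n  root age = %.1f Ma\n",
    x$rate, x$rate_ci[["lo"]], x$rate_ci[["hi"]],
    x$ages$age_ma[length(x$tree$tip.label) + 1]))
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
tidy.node_dating <- function(x, ...) x$ages

#' @export
#' @exportS3Method generics::glance
glance.node_dating <- function(x, ...) {
  tibble(rate = x$rate, rate_lo = x$rate_ci[["lo"]],
         rate_hi = x$rate_ci[["hi"]],
         root_age_ma = x$ages$age_ma[length(x$tree$tip.label) + 1],
         n_calibrations = nrow(x$calibration_nodes))
}

#' Age of the MRCA of a set of tips
#'
#' @param dating A [date_nodes()] result.
#' @param tips Character vector of tip labels (>= 2).
#' @return One-row tibble with the node and its age estimate and CI.
#' @export
clade_age <- function(dating, tips) {
  node <- resolve_calibration_node(dating$tree, tips)
  dating$ages[dating$ages$node == node, ]
}
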