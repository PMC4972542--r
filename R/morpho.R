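# canonical depth spans: MCL -> [0, 0.25], EPL -> [0.25, 0.75], GL -> [0.75, 1]
# (0 = deep/mitral-cell-layer side, 1 = superficial/glomerular-layer surface)
.canonical_spans <- c(mcl_epl = 0.25, epl_gl = 0.75)

#' Normalize a cell's gemmule depth distribution
#'
#' Gemmule depths measured along the mitral-cell-layer-to-glomerular-layer
#' axis are rescaled piecewise linearly so that each layer occupies a fixed
#' canonical span (MCL `[0, 0.25]`, EPL `[0.25, 0.75]`, GL `[0.75, 1]`),
#' making cells recorded at different absolute layer thicknesses comparable.
#' A normalized histogram over `n_bins` equal depth bins is attached; it is
#' the feature vector used for clustering.
#'
#' @param raw_depths Gemmule depths in recording units (e.g. um), measured
#'   from the deep MCL border toward the GL.
#' @param layer_bounds Increasing numeric of length 4: start of MCL,
#'   MCL/EPL border, EPL/GL border, end of GL.
#' @param cell_id Optional identifier.
#' @param n_bins Histogram bins over `[0, 1]` (default 20).
#' @return A `gemmule_profile` with `depths` (normalized), `histogram`
#'   (sums to 1), `breaks`, and `cell_id`.
#' @export
normalize_profile <- function(raw_depths, layer_bounds, cell_id = NA,
                              n_bins = 20L) {
  if (length(raw_depths) < 1L) stop("need at least one gemmule")
  stopifnot(length(layer_bounds) == 4L, all(diff(layer_bounds) > 0))
  if (any(raw_depths < layer_bounds[1] | raw_depths > layer_bounds[4])) {
    stop("gemmule depths must lie within the layer bounds")
  }
  canon <- c(0, .canonical_spans[["mcl_epl"]], .canonical_spans[["epl_gl"]], 1)
  seg <- findInterval(raw_depths, layer_bounds, rightmost.closed = TRUE,
                      all.inside = TRUE)
  frac <- (raw_depths - layer_bounds[seg]) /
    (layer_bounds[seg + 1L] - layer_bounds[seg])
  depths <- canon[seg] + frac * (canon[seg + 1L] - canon[seg])
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  h <- graphics::hist(depths, breaks = breaks, plot = FALSE)$counts
  structure(list(cell_id = cell_id, depths = depths,
                 histogram = h / sum(h), breaks = breaks),
            class = "gemmule_profile")
}

# stack profile histograms into a cells x bins matrix
.profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  stopifnot(all(vapply(profiles, inherits, TRUE, "gemmule_profile")))
  x <- do.call(rbind, lapply(profiles, `[[`, "histogram"))
  rownames(x) <- vapply(seq_along(profiles), function(i) {
    id <- profiles[[i]]$cell_id
    if (is.na(id)) paste0("cell", i) else as.character(id)
  }, character(1))
  x
}

#' Cluster granule-cell morphologies
#'
#' Ward agglomerative clustering (on Euclidean distances between normalized
#' gemmule histograms) with the number of clusters chosen by the gap
#' statistic: `B` uniform reference sets drawn in the principal-component
#' rotation of the data (the `scaledPCA` null, which respects the strong
#' linear constraints of histogram features; a plain bounding-box null
#' systematically inflates `k_hat` here), within-cluster dispersion on
#' squared distances, and the one-standard-error selection rule. The tree is
#' cut at the selected `k_hat`.
#'
#' @param profiles List of [normalize_profile()] outputs, or a cells x bins
#'   histogram matrix.
#' @param k_max Largest cluster count examined (>= 1).
#' @param B Reference sets for the gap statistic.
#' @param seed Integer seed for the reference draws.
#' @return A `cluster_result`: `tree` (an `hclust`), `k_hat`, `labels`
#'   (integers in `1:k_hat`, in input cell order), and `gap` (the
#'   `clusGap` table, `NULL` in the degenerate all-identical case).
#' @export
cluster_profiles <- function(profiles, k_max = 8L, B = 100L, seed = 1L) {
  x <- .profile_matrix(profiles)
  if (nrow(x) < 3L) stop("need at least 3 cells to cluster")
  if (k_max < 1L) stop("`k_max` must be at least 1")
  k_max <- min(k_max, nrow(x) - 1L)
  tree <- stats::hclust(stats::dist(x), method = "ward.D2")
  if (max(stats::dist(x)) == 0) {
    # all cells identical: a single cluster, no dispersion to compare
    return(structure(list(tree = tree, k_hat = 1L,
                          labels = rep(1L, nrow(x)), gap = NULL),
                     class = "cluster_result"))
  }
  hclust_cut <- function(x, k) {
    list(cluster = stats::cutree(stats::hclust(stats::dist(x), "ward.D2"), k))
  }
  set.seed(child_seed(seed, "gap"))
  gap <- cluster::clusGap(x, FUNcluster = hclust_cut, K.max = k_max, B = B,
                          d.power = 2, spaceH0 = "scaledPCA", verbose = FALSE)
  k_hat <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                          method = "Tibs2001SEmax")
  structure(list(tree = tree, k_hat = as.integer(k_hat),
                 labels = unname(stats::cutree(tree, k_hat)), gap = gap$Tab),
            class = "cluster_result")
}

#' Classify a granule cell as superficial or deep from its EPL gemmules
#'
#' The mass-weighted mean normalized depth of gemmules lying inside the EPL
#' decides the label: deep granule cells (dGC) concentrate gemmules in the
#' deep half of the EPL (toward the mitral cell layer, i.e. below the EPL
#' midpoint), superficial granule cells (sGC) in the superficial half. A
#' mean exactly at the midpoint resolves to sGC (fixed, documented
#' tie-break).
#'
#' @param profile A `gemmule_profile`.
#' @return `"sGC"` or `"dGC"`.
#' @export
depth_rule_classify <- function(profile) {
  stopifnot(inherits(profile, "gemmule_profile"))
  lo <- .canonical_spans[["mcl_epl"]]
  hi <- .canonical_spans[["epl_gl"]]
  epl <- profile$depths[profile$depths >= lo & profile$depths <= hi]
  if (!length(epl)) stop("no gemmules in the EPL: depth rule undefined")
  mid <- (lo + hi) / 2
  if (mean(epl) < mid - 1e-9) "dGC" else "sGC"
}

#' Generate a synthetic cohort of granule-cell morphologies
#'
#' Draws gemmule depths (in um on a fixed layer geometry: MCL 0-50, EPL
#' 50-350, GL 350-450) for three morphological groups: superficial GCs
#' centered in the superficial EPL, deep GCs centered in the deep EPL, and
#' an optional small group of superficial GCs with prominent deep
#' glomerular-layer innervation. Group separation relative to the
#' within-group spread controls task difficulty for cluster recovery.
#'
#' @param n_sgc,n_dgc,n_gl Cells per group.
#' @param within_sd Within-cell depth spread around the group center (um).
#' @param n_gemmules Mean gemmule count per cell (Poisson, floored at 5).
#' @param seed Integer seed.
#' @return List with `profiles` (list of `gemmule_profile`), `labels`
#'   (character ground truth), and `layer_bounds`.
#' @export
generate_gc_cohort <- function(n_sgc = 19L, n_dgc = 11L, n_gl = 4L,
                               within_sd = 40, n_gemmules = 30,
                               seed = 1L) {
  bounds <- c(0, 50, 350, 450)
  set.seed(child_seed(seed, "gc-cohort"))
  centers <- c(sGC = 275, dGC = 125)
  labels <- c(rep("sGC", n_sgc), rep("dGC", n_dgc), rep("sGC-GL", n_gl))
  profiles <- lapply(seq_along(labels), function(i) {
    lab <- labels[i]
    m <- max(5L, stats::rpois(1L, n_gemmules))
    d <- if (lab == "sGC-GL") {
      n_deep <- round(0.6 * m)
      c(stats::rnorm(n_deep, 410, 20),
        stats::rnorm(m - n_deep, centers[["sGC"]], within_sd))
    } else {
      stats::rnorm(m, centers[[lab]], within_sd)
    }
    d <- pmin(pmax(d, bounds[1]), bounds[4])
    normalize_profile(d, bounds, cell_id = sprintf("%s_%02d", lab, i))
  })
  list(profiles = profiles, labels = labels, layer_bounds = bounds)
}

#' Write a clustering tree in newick format
#'
#' @param result A `cluster_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cluster_tree <- function(result, path) {
  stopifnot(inherits(result, "cluster_result"))
  ape::write.tree(ape::as.phylo(result$tree), file = path)
  invisible(path)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: ", length(x$labels), " cells, k_hat = ", x$k_hat,
      " (sizes: ", paste(table(x$labels), collapse = ", "), ")\n", sep = "")
  invisible(x)
}
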