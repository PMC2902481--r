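## Quantitative evaluation of projected regions and of the retrieval
## ranking: Dice overlap, surface distances (reported in cm), agreement
## between the feature-space ranking R_F and the registration-outcome
## ranking R_I, and the correlation between feature distance D_F and
## post-registration Hausdorff distance D_H.

#' Dice similarity coefficient between two mask labels
#'
#' `DSC = 2 |A and B| / (|A| + |B|)` on voxel counts.  Symmetric.  When both
#' regions are empty the coefficient is defined as 1 (agreement on absence);
#' the ratio is otherwise 0/0 there.
#'
#' @param truth,candidate [region_mask()]s on the same geometry.
#' @param label label (integer or name) to compare; default 1.  May be a
#'   vector of two to compare differently labelled regions.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(truth, candidate, label = 1L) {
  if (!geometry_equal(truth$geometry, candidate$geometry))
    stop("dice: masks have different geometries")
  label <- rep_len(label, 2L)
  a <- truth$labels == mask_label_of(truth, label[[1]])
  b <- candidate$labels == mask_label_of(candidate, label[[2]])
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Surface distances between a projected region and the ground truth
#'
#' Meshes both labels with [extract_isosurface()] and measures the
#' directional (projected to truth) Hausdorff and mean surface distance with
#' [hausdorff_mesh_distance()] and NO ICP prealignment: both regions already
#' live in the common target frame, and prealigning would hide exactly the
#' registration error being measured.  Distances are reported in cm.
#'
#' @param projected,truth [region_mask()]s in the target frame.
#' @param label region label or name present in both.
#' @param n_samples surface samples.
#' @param seed sampling seed.
#' @return named vector `c(hausdorff = , mean = )` in cm.
#' @export
region_surface_distances <- function(projected, truth, label = 1L,
                                     n_samples = 2000L, seed = 1L) {
  mp <- extract_isosurface(projected, label)
  mt <- extract_isosurface(truth, label)
  hausdorff_mesh_distance(mp, mt, prealign = FALSE,
                          n_samples = n_samples, seed = seed) / 10
}

#' Rank references by registration outcome (R_I)
#'
#' Orders references ascending by the Hausdorff distance `D_H` between each
#' reference's projected region and the target's expert-drawn region (the
#' smallest value has the highest rank); ties keep the input order.  The
#' ranking may differ per region.
#'
#' @param d_h named numeric vector of `D_H` values, one per reference id
#'   (already computed from projected vs truth regions), or a list of
#'   per-reference [region_mask()] projections plus `truth` and `label`.
#' @param truth,label used when `d_h` is a list of projections.
#' @param n_samples,seed passed to [region_surface_distances()].
#' @return data.frame `id`, `D_H`, `rank`.
#' @export
build_ranking_RI <- function(d_h, truth = NULL, label = 1L,
                             n_samples = 2000L, seed = 1L) {
  if (is.list(d_h) && !is.numeric(d_h)) {
    if (is.null(names(d_h))) stop("projection list must be named by reference id")
    if (is.null(truth)) stop("truth mask required with a projection list")
    d_h <- vapply(d_h, function(p)
      region_surface_distances(p, truth, label, n_samples, seed)[["hausdorff"]],
      numeric(1))
  }
  if (any(is.na(d_h))) stop("missing D_H for: ",
                            paste(names(d_h)[is.na(d_h)], collapse = ", "))
  ord <- order(d_h)
  data.frame(id = names(d_h)[ord], D_H = as.numeric(d_h)[ord],
             rank = seq_along(d_h), stringsAsFactors = FALSE)
}

#' Agreement between the feature ranking R_F and the outcome ranking R_I
#'
#' For each target, finds at which position x of R_I the top-1 reference of
#' R_F appears, and reports the empirical frequencies binned as
#' x = 1, 2, 3, > 3.  With R_F identical to R_I the mass is all at x = 1;
#' with a random R_F the top-1 lands uniformly, so P(x = 1) tends to 1/n.
#'
#' @param R_F list (one per target) of rankings: data.frames with `id` and
#'   `rank`, or simply character vectors of ids in rank order.
#' @param R_I list of the same length/structure over the same reference
#'   sets.
#' @return named numeric vector of probabilities
#'   `c("1" = , "2" = , "3" = , ">3" = )`, summing to 1.
#' @export
rank_agreement <- function(R_F, R_I) {
  as_ids <- function(r) if (is.data.frame(r)) r$id[order(r$rank)] else r
  stopifnot(length(R_F) == length(R_I), length(R_F) > 0)
  pos <- vapply(seq_along(R_F), function(i) {
    f <- as_ids(R_F[[i]]); g <- as_ids(R_I[[i]])
    if (!setequal(f, g))
      stop("rankings for target ", i, " cover different reference sets")
    match(f[1], g)
  }, numeric(1))
  counts <- c(`1` = sum(pos == 1), `2` = sum(pos == 2),
              `3` = sum(pos == 3), `>3` = sum(pos > 3))
  counts / length(pos)
}

#' Correlation between feature distance and registration outcome
#'
#' Pearson correlation of (D_F, D_H) pairs; Spearman is available as an
#' option.
#'
#' @param pairs two-column matrix or data.frame of (D_F, D_H), >= 3 rows.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
distance_correlation <- function(pairs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 3) stop("need at least 3 (D_F, D_H) pairs")
  if (stats::sd(pairs[, 1]) == 0 || stats::sd(pairs[, 2]) == 0)
    stop("correlation undefined: a coordinate is constant")
  stats::cor(pairs[, 1], pairs[, 2], method = method)
}

#' Cohort evaluation report
#'
#' Convenience aggregation: per-region DSC and surface distances for a set
#' of projected/truth mask pairs, plus cohort averages.
#'
#' @param projections named list (by target or pair id) of [region_mask()]s.
#' @param truths matching named list of ground-truth [region_mask()]s.
#' @param labels region labels to evaluate (default: names of the first
#'   truth mask's labels).
#' @param n_samples,seed passed to [region_surface_distances()].
#' @return data.frame with columns `pair`, `region`, `dsc`, `hausdorff_cm`,
#'   `mean_cm`.
#' @export
evaluate_projections <- function(projections, truths, labels = NULL,
                                 n_samples = 1500L, seed = 1L) {
  stopifnot(length(projections) == length(truths))
  if (is.null(labels)) labels <- names(truths[[1]]$label_names)
  rows <- list()
  for (i in seq_along(projections)) {
    for (lb in labels) {
      ds <- dice(truths[[i]], projections[[i]], lb)
      sd_ <- tryCatch(
        region_surface_distances(projections[[i]], truths[[i]], lb,
                                 n_samples, seed),
        error = function(e) c(hausdorff = NA_real_, mean = NA_real_))
      rows[[length(rows) + 1L]] <-
        data.frame(pair = names(projections)[i] %||% as.character(i),
                   region = lb, dsc = ds,
                   hausdorff_cm = sd_[["hausdorff"]],
                   mean_cm = sd_[["mean"]])
    }
  }
  do.call(rbind, rows)
}
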