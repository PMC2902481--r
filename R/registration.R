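## Multi-resolution mutual-information registration.
##
## Convention (stated because forward/inverse mix-ups are the classic
## registration bug): the fitted transform g(x) takes a point x in the
## TARGET frame to the corresponding point in the REFERENCE frame, i.e. it
## is the resampling map -- the registered reference at target voxel x is
## reference(g(x)), and region projection looks reference labels up at g(x).
## The control grid therefore spans the target geometry, and landmark pairs
## fed to the engine must have their points in the target frame with
## deformations pointing to the matched reference locations (use
## swap_landmarks() on correspondences estimated the other way round).
##
## The metric is Parzen-window mutual information (zero-order kernel on the
## target intensities, cubic B-spline kernel on the interpolated reference
## intensities) over a seeded random voxel subset, with an analytic gradient
## with respect to the deformation coefficients through the sparse B-spline
## basis matrix.

#' Registration configuration
#'
#' @param resolution_schedule list of control-grid resolutions, coarse to
#'   fine, non-decreasing per axis.  Default `[6,6,5] -> [10,10,8] ->
#'   [15,15,11]`.
#' @param mi_bins histogram bins for the mutual-information metric (>= 8).
#' @param sample_fraction fraction of target voxels used by the metric.
#' @param iterations optimizer iterations per level (recycled over levels).
#' @param tolerance relative metric-improvement stopping tolerance.
#' @param proximity_radius mm radius within which a control point adopts the
#'   deformation of its closest landmark; `NULL` means one control-grid
#'   spacing at the current level.
#' @param use_landmarks logical; initialize each level's grid from landmark
#'   correspondences.
#' @param step_mm initial optimizer step, as the largest control-point
#'   coefficient update in mm.
#' @param rigid_downsample downsampling factor for the coarse rigid stage.
#' @param seed integer seed (voxel sampling).
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(resolution_schedule = list(c(6, 6, 5),
                                                           c(10, 10, 8),
                                                           c(15, 15, 11)),
                                mi_bins = 50L,
                                sample_fraction = 0.05,
                                iterations = 30L,
                                tolerance = 1e-4,
                                proximity_radius = NULL,
                                use_landmarks = FALSE,
                                step_mm = 2,
                                rigid_downsample = 2L,
                                seed = 1L) {
  sched <- lapply(resolution_schedule, as.integer)
  if (length(sched) > 1) {
    for (l in seq_len(length(sched) - 1))
      if (any(sched[[l + 1]] < sched[[l]]))
        stop("resolution schedule must be non-decreasing per axis")
  }
  if (mi_bins < 8) stop("mi_bins must be >= 8")
  if (sample_fraction <= 0 || sample_fraction > 1)
    stop("sample_fraction must be in (0, 1]")
  structure(list(resolution_schedule = sched, mi_bins = as.integer(mi_bins),
                 sample_fraction = sample_fraction,
                 iterations = rep_len(as.integer(iterations), length(sched)),
                 tolerance = tolerance, proximity_radius = proximity_radius,
                 use_landmarks = use_landmarks, step_mm = step_mm,
                 rigid_downsample = as.integer(rigid_downsample),
                 seed = as.integer(seed)),
            class = "registration_config")
}

## ---- mutual information internals ----

mi_setup <- function(fixed_vals, moving_range, nbins) {
  fr <- range(fixed_vals)
  if (diff(fr) <= 0) stop("degenerate (constant) target image: MI undefined")
  if (diff(moving_range) <= 0)
    stop("degenerate (constant) reference image: MI undefined")
  f_idx <- pmin(pmax(floor((fixed_vals - fr[1]) / diff(fr) * nbins), 0),
                nbins - 1)
  list(f_idx = as.integer(f_idx), nbins = as.integer(nbins),
       m_off = moving_range[1], m_scale = (nbins - 3) / diff(moving_range))
}

# cubic B-spline Parzen MI and its derivative w.r.t. the moving intensities
mi_value <- function(setup, m, grad = FALSE) {
  nb <- setup$nbins
  n <- length(m)
  mb <- (m - setup$m_off) * setup$m_scale + 1
  mb <- pmin(pmax(mb, 1), nb - 2)
  i0 <- pmin(pmax(floor(mb), 1L), nb - 3L)
  t <- mb - i0
  w <- bspline_weights(t)
  idx0 <- setup$f_idx + 1L           # fixed bin, 1-based
  H <- numeric(nb * nb)
  for (k in 0:3) {
    ii <- idx0 + nb * (i0 - 1L + k)  # column-major (fixed, moving)
    H <- H + .colsum_at(ii, w[, k + 1], nb * nb)
  }
  P <- H / n
  dim(P) <- c(nb, nb)
  pF <- rowSums(P); pM <- colSums(P)
  nz <- P > 0
  denom <- outer(pF, pM)
  mi <- sum(P[nz] * log(P[nz] / denom[nz]))
  if (!grad) return(list(mi = mi))
  # d MI / d m_i through the moving Parzen window
  t2 <- t * t
  dw <- cbind(-(1 - t)^2 / 2,
              (9 * t2 - 12 * t) / 6,
              (-9 * t2 + 6 * t + 3) / 6,
              t2 / 2)
  eps <- 1e-12
  gm <- numeric(n)
  logPM <- log(pmax(pM, eps))
  for (k in 0:3) {
    col <- i0 + k                    # 1-based moving bin
    pj <- P[cbind(idx0, col)]
    gm <- gm + dw[, k + 1] * (log(pmax(pj, eps)) - logPM[col])
  }
  list(mi = mi, grad_m = gm * setup$m_scale / n)
}

.colsum_at <- function(idx, w, size) {
  out <- numeric(size)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

down_sample_volume <- function(vol, factor = 2L) {
  d <- vol$geometry$dims
  nd <- d %/% factor
  a <- vol$values[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                  seq_len(nd[3] * factor), drop = FALSE]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  m <- apply(a, c(2, 4, 6), mean)
  volume_image(m, volume_geometry(nd, vol$geometry$spacing * factor,
                                  vol$geometry$origin +
                                    (factor - 1) / 2 * vol$geometry$spacing))
}

sample_points_of <- function(geometry, fraction, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- prod(geometry$dims)
  k <- max(200L, ceiling(n * fraction))
  idx <- sample.int(n, min(k, n)) - 1L
  d <- geometry$dims
  i <- idx %% d[1]
  j <- (idx %/% d[1]) %% d[2]
  kk <- idx %/% (d[1] * d[2])
  voxel_to_world(cbind(i, j, kk), geometry)
}

#' Rigid mutual-information registration
#'
#' Maximizes Parzen-window mutual information between the target and the
#' rigidly mapped reference over the 6 rigid parameters (Euler angles +
#' translation about the target volume centre), with a downsampled coarse
#' stage followed by full-resolution refinement.  Deterministic given
#' `config$seed`.
#'
#' @param reference,target [volume_image()]s with overlapping fields of view.
#' @param config a [registration_config()].
#' @return A [rigid_parameters()].
#' @export
rigid_register <- function(reference, target, config = registration_config()) {
  center <- target$geometry$origin +
    (target$geometry$dims - 1) * target$geometry$spacing / 2
  fit_stage <- function(ref, tgt, par0, fraction, explore) {
    pts <- sample_points_of(tgt$geometry, fraction, config$seed)
    f <- interp_volume(tgt, pts)
    ok <- !is.na(f)
    pts <- pts[ok, , drop = FALSE]; f <- f[ok]
    setup <- mi_setup(f, range(ref$values), config$mi_bins)
    floor_val <- min(ref$values)
    neg_mi <- function(p) {
      rp <- rigid_parameters(p[1:3], p[4:6], center)
      m <- interp_volume(ref, apply_rigid(pts, rp), outside = floor_val)
      -mi_value(setup, m)$mi
    }
    if (explore) {
      # simplex search with generous scaling escapes the ridge where
      # translation partially compensates a rotation
      par0 <- stats::optim(par0, neg_mi, method = "Nelder-Mead",
                           control = list(maxit = 2000,
                                          parscale = c(rep(0.3, 3),
                                                       rep(8, 3))))$par
    }
    stats::optim(par0, neg_mi, method = "BFGS",
                 control = list(maxit = 100, reltol = 1e-10,
                                parscale = c(rep(0.1, 3), rep(2, 3))))$par
  }
  ds <- config$rigid_downsample
  par <- rep(0, 6)
  coarse_ok <- ds > 1L && all(target$geometry$dims >= 2L * ds)
  if (coarse_ok) {
    par <- fit_stage(down_sample_volume(reference, ds),
                     down_sample_volume(target, ds),
                     par, min(1, config$sample_fraction * ds), TRUE)
  }
  par <- fit_stage(reference, target, par, config$sample_fraction, !coarse_ok)
  rigid_parameters(par[1:3], par[4:6], center)
}

#' Landmark-based control-grid initialization
#'
#' Every control point with at least one landmark within
#' `proximity_radius` adopts the deformation of its closest landmark; all
#' other control points keep their current deformation value.  The grid
#' coefficients are then refit so the field interpolates the new values.
#'
#' @param grid a `control_grid` (its current field supplies the values away
#'   from landmarks).
#' @param landmarks a [landmark_pairs()] in the grid's frame.
#' @param proximity_radius mm; default one control-grid spacing.
#' @return a `control_grid`.
#' @export
initialize_deformation_from_landmarks <- function(grid, landmarks,
                                                  proximity_radius = NULL) {
  if (is.null(proximity_radius)) proximity_radius <- max(grid$spacing)
  if (is.null(landmarks) || nrow(landmarks$points) == 0L) return(grid)
  cp <- control_point_positions(grid)
  vals <- evaluate_deformation(cp, grid, clamp = TRUE)
  lp <- landmarks$points
  # nearest landmark per control point (chunked squared distances)
  nn_idx <- integer(nrow(cp)); nn_d2 <- numeric(nrow(cp))
  chunk <- max(1L, floor(4e6 / nrow(lp)))
  for (s in seq(1L, nrow(cp), by = chunk)) {
    ii <- s:min(nrow(cp), s + chunk - 1L)
    d2 <- outer(rowSums(cp[ii, , drop = FALSE]^2), rowSums(lp^2), `+`) -
      2 * cp[ii, , drop = FALSE] %*% t(lp)
    j <- max.col(-d2, ties.method = "first")
    nn_idx[ii] <- j
    nn_d2[ii] <- d2[cbind(seq_along(ii), j)]
  }
  close_by <- nn_d2 <= proximity_radius^2
  vals[close_by, ] <- landmarks$deformations[nn_idx[close_by], , drop = FALSE]
  fit_coefficients_from_values(vals, grid)
}

#' Multi-resolution deformable registration
#'
#' Per level: the control grid is refined from the previous level (zeros at
#' the first), optionally re-initialized from landmark correspondences at
#' the in-radius control points, and the negative mutual information is
#' minimised over the deformation coefficients by gradient descent with
#' backtracking line search (the rigid part stays frozen).  The
#' landmark-induced field need not be smooth; the following MI optimisation
#' smooths it out.
#'
#' @param reference,target [volume_image()]s.
#' @param init a [transform_parameters()] (typically from
#'   [rigid_register()]), or a [rigid_parameters()], or `NULL` for identity.
#' @param config a [registration_config()].
#' @param landmarks optional [landmark_pairs()] in the target frame
#'   (required when `config$use_landmarks`).
#' @return An object of class `ffd_registration` with elements `params`
#'   ([transform_parameters()]), `converged`, `failed`, `final_metric`
#'   (negative MI) and `trace` (per-level accepted metric values).
#' @export
deformable_register <- function(reference, target, init = NULL,
                                config = registration_config(),
                                landmarks = NULL) {
  if (config$use_landmarks && is.null(landmarks))
    stop("use_landmarks is set but no landmarks were supplied")
  rigid <- if (is.null(init)) {
    center <- target$geometry$origin +
      (target$geometry$dims - 1) * target$geometry$spacing / 2
    rigid_parameters(center = center)
  } else if (inherits(init, "transform_parameters")) init$rigid
  else init
  geom <- target$geometry
  pts <- sample_points_of(geom, config$sample_fraction, config$seed + 1L)
  f <- interp_volume(target, pts)
  ok <- !is.na(f)
  pts <- pts[ok, , drop = FALSE]; f <- f[ok]
  setup <- mi_setup(f, range(reference$values), config$mi_bins)
  floor_val <- min(reference$values)
  base <- apply_rigid(pts, rigid)    # rigid part frozen after rigid stage
  gstep <- reference$geometry$spacing / 2
  trace <- list()
  grid <- NULL
  converged <- FALSE
  for (lev in seq_along(config$resolution_schedule)) {
    res <- config$resolution_schedule[[lev]]
    grid <- if (is.null(grid)) build_control_grid(res, geom)
            else refine_grid(grid, res)
    if (config$use_landmarks) {
      radius <- config$proximity_radius %||% max(grid$spacing)
      grid <- initialize_deformation_from_landmarks(grid, landmarks, radius)
    }
    W <- deformation_basis_matrix(pts, grid)
    coef <- matrix(grid$coefficients, ncol = 3)
    metric_at <- function(coef, grad = FALSE) {
      y <- base + as.matrix(W %*% coef)
      m <- interp_volume(reference, y, outside = floor_val)
      v <- mi_value(setup, m, grad = grad)
      if (!is.finite(v$mi))
        stop("non-finite registration metric at level ", lev)
      if (!grad) return(list(metric = -v$mi))
      G <- matrix(0, nrow(y), 3)
      for (a in 1:3) {
        e <- c(0, 0, 0); e[a] <- gstep[a]
        mp <- interp_volume(reference, sweep(y, 2, e, `+`), outside = floor_val)
        mm <- interp_volume(reference, sweep(y, 2, e, `-`), outside = floor_val)
        G[, a] <- v$grad_m * (mp - mm) / (2 * gstep[a])
      }
      # metric is negative MI, so its gradient is minus the MI gradient
      list(metric = -v$mi, grad = -as.matrix(Matrix::crossprod(W, G)))
    }
    cur <- metric_at(coef, grad = TRUE)
    lev_trace <- cur$metric
    step <- config$step_mm
    for (it in seq_len(config$iterations[lev])) {
      gmax <- max(abs(cur$grad))
      if (gmax == 0) { converged <- TRUE; break }
      dir <- -cur$grad / gmax       # steepest descent, scaled to max 1 mm
      accepted <- FALSE
      s <- step
      for (bt in 1:8) {
        cand <- coef + s * dir
        mtry <- metric_at(cand)
        if (mtry$metric < cur$metric) { accepted <- TRUE; break }
        s <- s / 2
      }
      if (!accepted) break
      improve <- cur$metric - mtry$metric
      coef <- cand
      cur <- metric_at(coef, grad = TRUE)
      lev_trace <- c(lev_trace, cur$metric)
      step <- min(max(s * 1.5, 1e-3), 4 * config$step_mm)
      if (improve < config$tolerance * abs(cur$metric)) {
        converged <- TRUE
        break
      }
    }
    grid$coefficients <- array(coef, c(res, 3L))
    trace[[lev]] <- lev_trace
  }
  res <- structure(list(params = transform_parameters(rigid, grid),
                        converged = converged,
                        failed = FALSE,
                        final_metric = trace[[length(trace)]][length(trace[[length(trace)]])],
                        trace = trace,
                        config = config,
                        target_geometry = geom),
                   class = "ffd_registration")
  res
}

#' End-to-end registration of a reference to a target
#'
#' Convenience front end: runs [rigid_register()] then
#' [deformable_register()], the usual way the tool is driven.
#'
#' @inheritParams deformable_register
#' @return An `ffd_registration`.
#' @export
ffd_register <- function(reference, target, config = registration_config(),
                         landmarks = NULL) {
  rigid <- rigid_register(reference, target, config)
  deformable_register(reference, target, rigid, config, landmarks)
}

#' Project a reference-frame region mask into the target frame
#'
#' For each target voxel centre x the projected label is the reference label
#' at g(x) (nearest-neighbour; labels are never intensity-interpolated).
#' Voxels mapping outside the reference become background.
#'
#' @param region a [region_mask()] in the reference frame.
#' @param params a [transform_parameters()] or `ffd_registration`.
#' @param target_geometry the target [volume_geometry()].
#' @return a [region_mask()] in the target frame.
#' @export
project_region <- function(region, params, target_geometry) {
  if (inherits(params, "ffd_registration")) params <- params$params
  pts <- voxel_center_grid(target_geometry)
  src <- apply_rigid(pts, params$rigid) +
    evaluate_deformation(pts, params$grid, clamp = TRUE)
  region_mask(array(lookup_labels(region, src), target_geometry$dims),
              target_geometry, region$label_names)
}

#' Resample the reference volume into the target frame
#'
#' @param reference a [volume_image()].
#' @param params a [transform_parameters()] or `ffd_registration`.
#' @param target_geometry the target [volume_geometry()].
#' @param outside intensity for voxels mapping outside the reference.
#' @return a [volume_image()] on `target_geometry`.
#' @export
resample_volume <- function(reference, params, target_geometry,
                            outside = min(reference$values)) {
  if (inherits(params, "ffd_registration")) params <- params$params
  pts <- voxel_center_grid(target_geometry)
  src <- apply_rigid(pts, params$rigid) +
    evaluate_deformation(pts, params$grid, clamp = TRUE)
  volume_image(array(interp_volume(reference, src, outside = outside),
                     target_geometry$dims),
               target_geometry)
}

## ---- S3 methods for the fitted registration ----

#' @export
print.ffd_registration <- function(x, ...) {
  cat("Deformable B-spline registration (mutual information)\n")
  print(x$params)
  cat(sprintf("  final metric (negative MI): %.5f; converged: %s\n",
              x$final_metric, x$converged))
  invisible(x)
}

#' @export
summary.ffd_registration <- function(object, ...) {
  cat("Deformable B-spline registration (mutual information)\n")
  print(object$params)
  for (lev in seq_along(object$trace))
    cat(sprintf("  level %d (%s): %d accepted steps, metric %.5f -> %.5f\n",
                lev, paste(object$config$resolution_schedule[[lev]],
                           collapse = "x"),
                length(object$trace[[lev]]) - 1L,
                object$trace[[lev]][1],
                object$trace[[lev]][length(object$trace[[lev]])]))
  cat(sprintf("  converged: %s\n", object$converged))
  invisible(object)
}

#' @export
coef.ffd_registration <- function(object, ...) {
  c(object$params$rigid$angles, object$params$rigid$translation,
    as.numeric(object$params$grid$coefficients))
}

#' Transform points or resample images with a fitted registration
#'
#' `predict` on an `ffd_registration` maps target-frame points to the
#' reference frame (`newdata` an n x 3 matrix), or resamples a reference
#' [volume_image()] / projects a reference [region_mask()] onto the target
#' grid.
#'
#' @param object an `ffd_registration`.
#' @param newdata points matrix, `volume_image` or `region_mask`.
#' @param ... unused.
#' @export
predict.ffd_registration <- function(object, newdata, ...) {
  if (inherits(newdata, "volume_image"))
    resample_volume(newdata, object, object$target_geometry)
  else if (inherits(newdata, "region_mask"))
    project_region(newdata, object, object$target_geometry)
  else
    transform_point(as.matrix(newdata), object$params)
}

#' Plot the optimizer trace of a fitted registration
#'
#' @param x an `ffd_registration`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ffd_registration <- function(x, ...) {
  all_tr <- unlist(x$trace)
  graphics::plot(seq_along(all_tr), all_tr, type = "b",
                 xlab = "accepted step", ylab = "negative mutual information",
                 main = "registration metric trace", ...)
  brk <- cumsum(vapply(x$trace, length, numeric(1)))
  graphics::abline(v = brk[-length(brk)] + 0.5, lty = 3)
  invisible(x)
}
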