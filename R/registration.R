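#' Intensity centre of mass
#'
#' Thresholds the volume into a binary object mask and returns the mask's
#' first moments in world mm. Used to initialize the registration
#' translation.
#'
#' @param v a [volume()].
#' @param threshold voxels strictly above this intensity belong to the
#'   object; defaults to the volume mean.
#' @return Length-3 world coordinate (mm) of the centre of mass.
#' @export
center_of_mass <- function(v, threshold = NULL) {
  stopifnot_volume(v)
  if (is.null(threshold)) threshold <- mean(v$data)
  mask <- v$data > threshold
  n <- sum(mask)
  if (n == 0) stop("empty object: no voxel above threshold", call. = FALSE)
  d <- dim(v$data)
  idx <- which(mask) - 1L
  i <- idx %% d[1]
  j <- (idx %/% d[1]) %% d[2]
  k <- idx %/% (d[1] * d[2])
  com_vox <- c(mean(i), mean(j), mean(k))
  v$origin + com_vox * v$spacing
}

#' Translation aligning two centres of mass
#'
#' Returns the pure translation `t = COM(target) - COM(reference)` as an
#' [affine_transform()]. Under the registration convention used here (the
#' transform maps reference world coordinates to target sampling positions),
#' this translation superimposes the two objects.
#'
#' @param ref,target [volume()]s.
#' @param threshold passed to [center_of_mass()] for both volumes.
#' @return An [affine_transform()] (pure translation).
#' @export
com_align <- function(ref, target, threshold = NULL) {
  translation_matrix(center_of_mass(target, threshold) -
                       center_of_mass(ref, threshold))
}

#' Coarse-to-fine resolution pyramid
#'
#' Builds one volume per subsampling factor. Each level is Gaussian
#' prefiltered (`sigma = factor / 2` voxels, isotropic) and then sampled on
#' a grid of `round(length / factor)` voxels per axis with spacing scaled by
#' the factor; factor 1 returns the input itself. Levels whose smallest axis
#' would fall below 4 voxels are dropped with a message.
#'
#' @param v an isotropic [volume()].
#' @param factors integer subsampling factors, default `c(8, 4, 2, 1)`.
#' @param spec [kernel_spec()] used for the on-grid decimation sampling.
#' @return Named list of [volume()]s (`"8"`, `"4"`, ...), coarsest first.
#' @export
build_pyramid <- function(v, factors = c(8, 4, 2, 1),
                          spec = kernel_spec("trilinear")) {
  stopifnot_volume(v)
  factors <- sort(unique(as.integer(factors)), decreasing = TRUE)
  d <- dim(v$data)
  keep <- vapply(factors, function(f) all(round(d / f) >= 4), logical(1))
  if (!all(keep)) {
    message("dropping pyramid factor(s) ", paste(factors[!keep], collapse = ", "),
            ": axis would collapse below 4 voxels")
    factors <- factors[keep]
  }
  if (length(factors) == 0) stop("no usable pyramid level", call. = FALSE)
  out <- lapply(factors, function(f) {
    if (f == 1L) return(v)
    arr <- v$data
    sigma <- f / 2
    radius <- ceiling(2 * sigma)
    for (a in 1:3) arr <- blur_axis(arr, a, sigma, radius)
    blurred <- volume(arr, spacing = v$spacing, origin = v$origin)
    resample_volume(blurred, pmax(4L, as.integer(round(d / f))),
                    v$spacing * f, identity_transform(), spec)
  })
  names(out) <- as.character(factors)
  out
}

#' The coarse rotation search grid
#'
#' Cartesian product of five angles per axis spanning -30..30 degrees, in
#' lexicographic order with the z angle varying fastest: the first row is
#' `(-30, -30, -30)`, the second `(-30, -30, -15)`, the last
#' `(30, 30, 30)` -- 125 configurations in total.
#'
#' @param values angles (degrees) each axis may take.
#' @return A 125 x 3 numeric matrix with columns `rx`, `ry`, `rz`.
#' @export
coarse_rotation_grid <- function(values = c(-30, -15, 0, 15, 30)) {
  g <- expand.grid(rz = values, ry = values, rx = values,
                   KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g[, c("rx", "ry", "rz")])
  dimnames(m) <- list(NULL, c("rx", "ry", "rz"))
  m
}

#' Candidate set of local minima
#'
#' Holds ranked `(parameters, cost)` pairs carried between optimization
#' stages. Entries are kept sorted ascending by cost with ties broken by
#' insertion order.
#'
#' @param entries list of `list(params = dof_params, cost = numeric)`.
#' @param retained_fraction fraction kept by [retain_top_fraction()].
#' @return A `candidate_set`.
#' @export
candidate_set <- function(entries, retained_fraction = 0.2) {
  if (length(entries)) {
    costs <- vapply(entries, function(e) e$cost, numeric(1))
    entries <- entries[order(costs)]  # stable sort: ties keep insertion order
  }
  structure(list(entries = entries, retained_fraction = retained_fraction),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d entries (retain %.0f%%)\n",
              length(x$entries), 100 * x$retained_fraction))
  if (length(x$entries))
    cat(sprintf("  best cost %.6g\n", x$entries[[1]]$cost))
  invisible(x)
}

#' Keep the best fraction of a candidate set
#'
#' Retains the first `ceil(fraction * n)` entries (minimum 1) of the sorted
#' set.
#'
#' @param c a [candidate_set()].
#' @return The pruned [candidate_set()].
#' @export
retain_top_fraction <- function(c) {
  if (!inherits(c, "candidate_set"))
    stop("`c` must be a candidate_set", call. = FALSE)
  n <- length(c$entries)
  if (n == 0) stop("empty candidate set", call. = FALSE)
  keep <- max(1L, as.integer(ceiling(c$retained_fraction * n)))
  candidate_set(c$entries[seq_len(min(keep, n))], c$retained_fraction)
}

# --- free-parameter bookkeeping ------------------------------------------

# Free parameter names: t1..t3 (mm), r1..r3 (deg), sg (global scale),
# s1..s3 (per-axis scale), h1..h3 (shear).
free_names_for_dof <- function(dof) {
  switch(as.character(dof),
         "3" = c("t1", "t2", "t3"),
         "4" = c("t1", "t2", "t3", "sg"),
         "6" = c("t1", "t2", "t3", "r1", "r2", "r3"),
         "7" = c("t1", "t2", "t3", "r1", "r2", "r3", "sg"),
         "9" = c("t1", "t2", "t3", "r1", "r2", "r3", "s1", "s2", "s3"),
         "12" = c("t1", "t2", "t3", "r1", "r2", "r3", "s1", "s2", "s3",
                  "h1", "h2", "h3"),
         stop("`dof` must be one of 3, 4, 6, 7, 9, 12", call. = FALSE))
}

param_component <- function(name) {
  switch(substr(name, 1, 1), t = "translation", r = "rotation",
         s = "scale", h = "shear")
}

get_free <- function(p, name) {
  if (name == "sg") return(p$scale[1])
  i <- as.integer(substr(name, 2, 2))
  switch(substr(name, 1, 1),
         t = p$translation[i], r = p$rotation[i],
         s = p$scale[i], h = p$shear[i])
}

set_free <- function(p, name, value) {
  if (name == "sg") { p$scale <- rep(value, 3); return(p) }
  i <- as.integer(substr(name, 2, 2))
  switch(substr(name, 1, 1),
         t = p$translation[i] <- value,
         r = p$rotation[i] <- value,
         s = p$scale[i] <- value,
         h = p$shear[i] <- value)
  p
}

# Raw parameter carrier without per-DOF neutrality checks (used while a
# stage holds some components frozen at non-neutral values).
raw_params <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                       scale = c(1, 1, 1), shear = c(0, 0, 0), dof = 12L) {
  structure(list(translation = as.double(translation),
                 rotation = as.double(rotation),
                 scale = as.double(scale), shear = as.double(shear),
                 dof = as.integer(dof)),
            class = "dof_params")
}

#' Optimizer step-size schedule
#'
#' Initial and floor step sizes for the derivative-free coordinate descent,
#' by parameter component. Translation steps are in voxels of the working
#' isotropic grid (converted to mm internally), rotations in degrees,
#' scales and shears dimensionless. Steps are halved whenever a full sweep
#' yields no improvement, down to the floors.
#'
#' @param translation,rotation,scale,shear initial steps.
#' @param floor_translation,floor_rotation,floor_scale,floor_shear smallest
#'   steps tried before the descent stops.
#' @return A named list used by [local_optimize()] and [register_volumes()].
#' @export
optim_steps <- function(translation = 4, rotation = 4, scale = 0.1,
                        shear = 0.05, floor_translation = 0.1,
                        floor_rotation = 0.1, floor_scale = 0.005,
                        floor_shear = 0.005) {
  list(init = c(translation = translation, rotation = rotation,
                scale = scale, shear = shear),
       floor = c(translation = floor_translation, rotation = floor_rotation,
                 scale = floor_scale, shear = floor_shear))
}

# Coordinate descent with step halving over the named free parameters.
# `f` maps a dof_params carrier to a scalar cost; only strict improvements
# are accepted, so the cost trace is non-increasing. Deterministic.
coord_descent <- function(f, par, free, steps, unit_mm = 1,
                          max_evals = 5000L) {
  comp <- vapply(free, param_component, character(1))
  s <- steps$init[comp]
  s[comp == "translation"] <- s[comp == "translation"] * unit_mm
  fl <- steps$floor[comp]
  fl[comp == "translation"] <- fl[comp == "translation"] * unit_mm
  n_evals <- 0L
  fcur <- f(par); n_evals <- n_evals + 1L
  if (!is.finite(fcur)) stop("cost is not finite at the initial parameters",
                             call. = FALSE)
  trace <- fcur
  repeat {
    improved <- FALSE
    for (i in seq_along(free)) {
      for (dir in c(1, -1)) {
        cand <- set_free(par, free[i], propose(par, free[i], dir * s[i]))
        fc <- f(cand); n_evals <- n_evals + 1L
        if (is.finite(fc) && fc < fcur) {
          par <- cand; fcur <- fc; improved <- TRUE
          trace <- c(trace, fcur)
          # greedy continuation in the accepted direction
          reps <- 0L
          while (reps < 8L && n_evals < max_evals) {
            cand <- set_free(par, free[i], propose(par, free[i], dir * s[i]))
            fc <- f(cand); n_evals <- n_evals + 1L
            if (is.finite(fc) && fc < fcur) {
              par <- cand; fcur <- fc; trace <- c(trace, fcur)
              reps <- reps + 1L
            } else break
          }
          break  # do not also try the opposite direction
        }
        if (n_evals >= max_evals) break
      }
      if (n_evals >= max_evals) break
    }
    if (n_evals >= max_evals) break
    if (!improved) {
      if (all(s <= fl)) break
      s <- pmax(s / 2, fl)
    }
  }
  list(params = par, cost = fcur, n_evals = n_evals, trace = trace)
}

propose <- function(par, name, delta) {
  v <- get_free(par, name) + delta
  if (substr(name, 1, 1) == "s") v <- max(v, 0.1)  # keep scales positive
  v
}

#' Derivative-free local optimization of a cost over DOF parameters
#'
#' Coordinate descent with step halving (accept-only-improvement), varying
#' only the parameters declared by `dof`. Deterministic for fixed inputs;
#' the returned cost never exceeds the cost at `init`.
#'
#' @param cost_fn function taking a [dof_params()] and returning a finite
#'   scalar cost (may return `Inf` away from the feasible region).
#' @param init a [dof_params()]; must have finite cost.
#' @param dof number of free parameters (3, 4, 6, 7, 9, 12); defaults to
#'   `init$dof`.
#' @param steps an [optim_steps()] schedule.
#' @param max_evals evaluation budget.
#' @return `list(params, cost, n_evals, trace)`; `trace` is the
#'   non-increasing sequence of accepted costs.
#' @export
local_optimize <- function(cost_fn, init, dof = init$dof,
                           steps = optim_steps(), max_evals = 5000L) {
  if (!inherits(init, "dof_params"))
    stop("`init` must be dof_params", call. = FALSE)
  free <- free_names_for_dof(dof)
  res <- coord_descent(cost_fn, init, free, steps, unit_mm = 1,
                       max_evals = max_evals)
  res$params$dof <- as.integer(dof)
  res
}

#' Registration search controls
#'
#' Tunables of the coarse-to-fine search: the coarse rotation grid, the
#' retained candidate fraction, the narrow second rotation pass
#' (offsets of `+/- narrow_step` degrees per axis around each candidate),
#' the level-4 perturbations (rotation offsets of `+/- rot_perturb` degrees
#' and absolute global scale factors), the minimum overlap fraction below
#' which a transform is rejected with an infinite cost, and per-level step
#' schedules.
#'
#' @param coarse_values angles for [coarse_rotation_grid()].
#' @param retained_fraction candidate fraction kept after each stage.
#' @param narrow_step degrees for the narrow rotation pass at level 8.
#' @param rot_perturb degrees for the level-4 rotation perturbations.
#' @param scale_perturb global scale factors tried at level 4.
#' @param min_overlap minimum fraction of reference voxels whose pull-back
#'   must land inside the moving image.
#' @param steps_coarse,steps_mid,steps_fine [optim_steps()] schedules for
#'   levels 8/4, level 2, and level 1. The coarse floors are deliberately
#'   coarse: sub-voxel precision is pointless on the factor-8 grid.
#' @param max_evals_stage evaluation budget per individual coarse descent.
#' @param max_evals_fine evaluation budget for each level-2 descent.
#' @param max_evals_full evaluation budget for the full-resolution polish;
#'   full-resolution evaluations are by far the most expensive, and the
#'   level-2 solution is already close, so this stays small.
#' @param full_stride reference-voxel stride for the full-resolution cost:
#'   the cost is evaluated at every `full_stride`-th full-resolution voxel
#'   position (unsmoothed, so sub-voxel phase is preserved) to bound the
#'   per-evaluation cost of the wide kernels.
#' @param jitter_seed seed for the fixed sub-voxel jitter applied to the
#'   full-resolution sample positions. The jitter is drawn once per
#'   registration and held constant, keeping the objective deterministic
#'   while preventing interpolation phase artifacts (histogram costs
#'   otherwise reward transforms that sample the moving image off-grid,
#'   where interpolation averages voxel noise).
#' @param mask_threshold optional reference intensity threshold; when set,
#'   cost is computed only over reference voxels above it.
#' @return A list of controls for [register_volumes()].
#' @export
register_control <- function(coarse_values = c(-30, -15, 0, 15, 30),
                             retained_fraction = 0.2,
                             narrow_step = 7.5,
                             rot_perturb = 6,
                             scale_perturb = c(0.8, 0.9, 1.0, 1.1, 1.2),
                             min_overlap = 0.25,
                             steps_coarse = optim_steps(
                               floor_translation = 1, floor_rotation = 1,
                               floor_scale = 0.02, floor_shear = 0.02),
                             steps_mid = optim_steps(translation = 2,
                                                     rotation = 2,
                                                     scale = 0.05,
                                                     shear = 0.02),
                             steps_fine = optim_steps(translation = 0.5,
                                                      rotation = 0.5,
                                                      scale = 0.01,
                                                      shear = 0.005,
                                                      floor_scale = 0.002,
                                                      floor_shear = 0.002),
                             max_evals_stage = 400L,
                             max_evals_fine = 2000L,
                             max_evals_full = 80L,
                             full_stride = 2L,
                             jitter_seed = 20231L,
                             mask_threshold = NULL) {
  list(coarse_values = coarse_values,
       retained_fraction = retained_fraction,
       narrow_step = narrow_step, rot_perturb = rot_perturb,
       scale_perturb = scale_perturb, min_overlap = min_overlap,
       steps_coarse = steps_coarse, steps_mid = steps_mid,
       steps_fine = steps_fine,
       max_evals_stage = as.integer(max_evals_stage),
       max_evals_fine = as.integer(max_evals_fine),
       max_evals_full = as.integer(max_evals_full),
       full_stride = as.integer(full_stride),
       jitter_seed = as.integer(jitter_seed),
       mask_threshold = mask_threshold)
}

#' Coarse-to-fine affine registration
#'
#' Registers `target` to `ref` by minimizing an intensity cost over affine
#' parameters, FLIRT-style: both volumes are resampled to isotropic voxels,
#' translation is initialized from the centres of mass, a coarse rotation
#' grid with 4-DOF local optimization and top-20% candidate retention is
#' searched on the factor-8 pyramid level, candidates are refined with
#' 7 DOF (plus rotation/scale perturbations) on the factor-4 level, the best
#' candidate is refined 7 -> 9 -> 12 DOF (capped at `max_dof`) on the
#' factor-2 level, and one full-resolution optimization at `max_dof`
#' finishes the search.
#'
#' The estimated transform maps reference world coordinates to target
#' sampling positions: `target(T(x)) ~ ref(x)`. Its parameters are directly
#' comparable to motion applied to the target by [degrade()].
#'
#' @param ref reference [volume()] (fixed image).
#' @param target moving [volume()].
#' @param cost a [cost_spec()].
#' @param kernel [kernel_spec()] used to sample the moving image during the
#'   full-resolution stage (the subsampled search levels always use
#'   trilinear: their Gaussian prefilter washes out kernel differences, and
#'   higher-order kernels are much more expensive per evaluation).
#' @param max_dof final model size: 6, 7, 9 or 12.
#' @param control a [register_control()].
#' @return A `registration_result`: list with `final_transform`
#'   ([affine_transform()]), `final_params` ([dof_params()]), `final_cost`
#'   (cost of the final parameters at full resolution), `center` (rotation
#'   centre used, world mm), `level_traces` (per-level diagnostics:
#'   candidate costs, retained set sizes, evaluation counts) and `n_evals`.
#' @export
register_volumes <- function(ref, target, cost = cost_spec("NMI"),
                             kernel = kernel_spec("trilinear"),
                             max_dof = 12, control = register_control()) {
  stopifnot_volume(ref, "ref"); stopifnot_volume(target, "target")
  max_dof <- as.integer(max_dof)
  if (!max_dof %in% c(6L, 7L, 9L, 12L))
    stop("`max_dof` must be 6, 7, 9 or 12", call. = FALSE)
  if (!inherits(cost, "cost_spec")) stop("`cost` must be a cost_spec", call. = FALSE)
  if (!inherits(kernel, "kernel_spec")) stop("`kernel` must be a kernel_spec", call. = FALSE)

  ref_iso <- make_isotropic(ref)
  tgt_iso <- make_isotropic(target)
  s_iso <- min(ref_iso$spacing)
  ctr <- volume_center_world(ref_iso)

  ref_pyr <- build_pyramid(ref_iso)
  tgt_pyr <- build_pyramid(tgt_iso)
  levels_avail <- intersect(names(ref_pyr), names(tgt_pyr))

  total_evals <- 0L
  # cost closure factory for one pyramid factor; reference-side binning and
  # the moving image's histogram range are fixed per level so the objective
  # is stable under the changing transform
  search_kernel <- kernel_spec("trilinear")
  make_cost <- function(factor, spec = search_kernel, stride = 1L) {
    # the full-resolution stage samples with the mirror boundary regardless
    # of the reformat kernel's policy: clamp replication gives out-of-field
    # samples artificially low entropy, which histogram costs reward by
    # inflating scales until reference voxels sample beyond the moving
    # image's edge. Mirroring keeps out-of-field statistics interior-like.
    # (The coarse search levels keep clamp: mirroring there would create
    # reflected copies of the head that attract the global search.)
    if (stride > 1L) spec$boundary <- "mirror"
    key <- as.character(factor)
    if (!key %in% levels_avail) key <- levels_avail[1]
    rlv <- ref_pyr[[key]]
    tlv <- tgt_pyr[[key]]
    pts <- NULL
    if (stride > 1L) {
      # full-resolution stage: evaluate on a sub-lattice of reference sample
      # positions with a fixed random sub-voxel jitter. The jitter is drawn
      # once (deterministically) and held constant across evaluations, so
      # the objective is still deterministic; because no affine transform
      # can align all jittered positions with the moving grid at once, the
      # interpolation phase artifact (sampling on-grid preserves voxel noise
      # while off-grid sampling averages it, which biases histogram costs
      # toward slight scale changes) cancels out.
      d <- dim(rlv$data)
      idx <- as.matrix(expand.grid(x = seq(0L, d[1] - 1L, stride),
                                   y = seq(0L, d[2] - 1L, stride),
                                   z = seq(0L, d[3] - 1L, stride)))
      jit <- with_seed(control$jitter_seed, {
        matrix(stats::runif(length(idx), -0.5, 0.5), ncol = 3)
      })
      pts <- sweep((idx + jit) %*% diag(rlv$spacing), 2, rlv$origin, `+`)
      rvec <- sample_volume(rlv, idx + jit, search_kernel)
    } else {
      rvec <- as.vector(rlv$data)
    }
    keep0 <- if (!is.null(control$mask_threshold))
      rvec > control$mask_threshold else rep(TRUE, length(rvec))
    bins <- cost$bins
    rbin <- if (cost$name %in% c("CR", "NMI"))
      bin_indices(rvec, bins, on_degenerate = "single-bin")$bin else NULL
    trange <- range(tlv$data)
    td <- dim(tlv$data)
    function(p) {
      total_evals <<- total_evals + 1L
      tf <- params_to_matrix_raw(p, ctr)
      if (is.null(pts)) {
        res <- resample_core(tlv, dim(rlv$data), rlv$spacing, rlv$origin,
                             tf, spec)
        vals <- res$values
        inside <- mean(res$inside)
      } else {
        tp <- apply_transform(tf, pts)
        vox <- sweep(tp, 2, tlv$origin, `-`) %*% diag(1 / tlv$spacing)
        inside <- mean(vox[, 1] >= -0.5 & vox[, 1] < td[1] - 0.5 &
                       vox[, 2] >= -0.5 & vox[, 2] < td[2] - 0.5 &
                       vox[, 3] >= -0.5 & vox[, 3] < td[3] - 0.5)
        vals <- sample_volume(tlv, vox, spec)
      }
      if (inside < control$min_overlap) return(Inf)
      # evaluate over the full reference field of view (out-of-field samples
      # follow the kernel's boundary policy): if the overlap region itself
      # depended on the transform, histogram costs could be driven down by
      # shrinking it to exclude awkward voxels (scale-inflation bias)
      a <- rvec[keep0]; b <- vals[keep0]
      switch(cost$name,
             LS = mean((a - b)^2),
             NCC = cost_ncc(a, b),
             CR = cost_cr_binned(rbin[keep0], b, bins),
             NMI = cost_nmi_binned(rbin[keep0],
                                   fixed_bin(b, trange[1], trange[2], bins),
                                   bins))
    }
  }

  # centre-of-mass translation initialization
  t0 <- tryCatch(center_of_mass(tgt_iso) - center_of_mass(ref_iso),
                 error = function(e) c(0, 0, 0))

  traces <- list()

  # ---- level 8: coarse rotation search -----------------------------------
  f8 <- make_cost(8)
  grid <- coarse_rotation_grid(control$coarse_values)
  entries <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p0 <- raw_params(translation = t0, rotation = grid[g, ])
    r <- try(coord_descent(f8, p0, c("t1", "t2", "t3", "sg"),
                           control$steps_coarse, unit_mm = s_iso,
                           max_evals = control$max_evals_stage),
             silent = TRUE)
    entries[[g]] <- if (inherits(r, "try-error"))
      list(params = p0, cost = Inf) else list(params = r$params, cost = r$cost)
  }
  if (all(!is.finite(vapply(entries, function(e) e$cost, numeric(1)))))
    stop("registration failed: no coarse candidate with usable overlap",
         call. = FALSE)
  cs <- candidate_set(entries, control$retained_fraction)
  n_initial <- length(cs$entries)
  cs <- retain_top_fraction(cs)
  n_retained1 <- length(cs$entries)

  # narrow rotation pass around each retained candidate
  offs <- as.matrix(expand.grid(dz = c(-1, 0, 1), dy = c(-1, 0, 1),
                                dx = c(-1, 0, 1)))[, 3:1] * control$narrow_step
  cs$entries <- lapply(cs$entries, function(e) {
    best <- e
    for (o in seq_len(nrow(offs))) {
      if (all(offs[o, ] == 0)) next
      p <- e$params; p$rotation <- p$rotation + offs[o, ]
      fc <- f8(p)
      if (is.finite(fc) && fc < best$cost) best <- list(params = p, cost = fc)
    }
    best
  })
  # 7-DOF refinement of each survivor
  cs$entries <- lapply(cs$entries, function(e) {
    r <- coord_descent(f8, e$params,
                       c("t1", "t2", "t3", "r1", "r2", "r3", "sg"),
                       control$steps_coarse, unit_mm = s_iso,
                       max_evals = control$max_evals_stage)
    list(params = r$params, cost = r$cost)
  })
  cs <- candidate_set(cs$entries, control$retained_fraction)
  cs <- retain_top_fraction(cs)
  n_retained2 <- length(cs$entries)
  traces$level8 <- list(level = 8L, n_initial = n_initial,
                        n_retained = c(n_retained1, n_retained2),
                        costs = vapply(cs$entries, `[[`, numeric(1), "cost"),
                        n_evals = total_evals)

  # ---- level 4: 7-DOF refinement + perturbations -------------------------
  f4 <- make_cost(4)
  evals_before <- total_evals
  pool <- list()
  for (e in cs$entries) {
    r <- coord_descent(f4, e$params,
                       c("t1", "t2", "t3", "r1", "r2", "r3", "sg"),
                       control$steps_coarse, unit_mm = s_iso,
                       max_evals = control$max_evals_stage)
    pool <- c(pool, list(list(params = r$params, cost = r$cost)))
    # rotation perturbations
    for (ax in 1:3) for (dd in c(-1, 1)) {
      p <- r$params
      p$rotation[ax] <- p$rotation[ax] + dd * control$rot_perturb
      fc <- f4(p)
      pool <- c(pool, list(list(params = p, cost = fc)))
    }
    # global scale perturbations
    for (sc in control$scale_perturb) {
      if (sc == 1) next
      p <- r$params
      p$scale <- p$scale * sc
      fc <- f4(p)
      pool <- c(pool, list(list(params = p, cost = fc)))
    }
  }
  cs <- retain_top_fraction(candidate_set(pool, control$retained_fraction))
  traces$level4 <- list(level = 4L, n_pool = length(pool),
                        n_retained = length(cs$entries),
                        costs = vapply(cs$entries, `[[`, numeric(1), "cost"),
                        n_evals = total_evals - evals_before)

  # ---- level 2: best candidate, 7 -> 9 -> 12 DOF capped at max_dof -------
  f2 <- make_cost(2)
  evals_before <- total_evals
  best <- cs$entries[[1]]
  dof_chain <- c(7L, 9L, 12L)
  dof_chain <- dof_chain[dof_chain <= max(max_dof, 7L)]
  if (max_dof == 6L) dof_chain <- 6L
  p <- best$params
  for (dd in dof_chain) {
    r <- coord_descent(f2, p, free_names_for_dof(dd), control$steps_mid,
                       unit_mm = s_iso, max_evals = control$max_evals_fine)
    p <- r$params
  }
  traces$level2 <- list(level = 2L, dof_chain = dof_chain, cost = r$cost,
                        n_evals = total_evals - evals_before)

  # ---- level 1: full-resolution polish at max_dof with the requested
  # kernel (the search levels use trilinear; interpolation differences only
  # carry real signal at full resolution, where evaluations are costly) ----
  f1 <- make_cost(1, kernel, stride = control$full_stride)
  evals_before <- total_evals
  r <- coord_descent(f1, p, free_names_for_dof(max_dof), control$steps_fine,
                     unit_mm = s_iso, max_evals = control$max_evals_full)
  traces$level1 <- list(level = 1L, dof = max_dof, cost = r$cost,
                        n_evals = total_evals - evals_before)

  final_params <- r$params
  final_params$dof <- max_dof
  structure(list(final_transform = params_to_matrix_raw(final_params, ctr),
                 final_params = final_params,
                 final_cost = r$cost,
                 center = ctr,
                 cost = cost, kernel = kernel,
                 level_traces = traces,
                 n_evals = total_evals),
            class = "registration_result")
}

# params_to_matrix without dof neutrality validation, built with direct
# arithmetic (same composition T . C . Rz Ry Rx . S . H . C^-1); this sits
# on the optimizer's hot path so it avoids the classed-matrix constructors.
params_to_matrix_raw <- function(p, center) {
  a <- p$rotation * (pi / 180)
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  R <- matrix(c(cz * cy, cz * sy * sx - sz * cx, cz * sy * cx + sz * sx,
                sz * cy, sz * sy * sx + cz * cx, sz * sy * cx - cz * sx,
                -sy,     cy * sx,                cy * cx),
              nrow = 3, byrow = TRUE)
  s <- p$scale; h <- p$shear
  U <- matrix(c(s[1], s[1] * h[1], s[1] * h[2],
                0,    s[2],        s[2] * h[3],
                0,    0,           s[3]),
              nrow = 3, byrow = TRUE)
  B <- R %*% U
  m <- diag(4)
  m[1:3, 1:3] <- B
  m[1:3, 4] <- p$translation + center - as.vector(B %*% center)
  structure(m, class = c("affine_transform", "matrix", "array"))
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result>\n")
  cat(sprintf("  cost %s / kernel %s, %d evaluations\n",
              x$cost$name, x$kernel$name, x$n_evals))
  cat(sprintf("  final cost %.6g at %d DOF\n", x$final_cost,
              x$final_params$dof))
  print(x$final_params)
  invisible(x)
}

#' Reformat the moving image with an estimated transform
#'
#' Resamples `target` onto the reference grid through the registration
#' result's final transform, using any interpolation kernel (the reformat
#' kernel need not match the one used during optimization).
#'
#' @param result a `registration_result` from [register_volumes()].
#' @param target the moving [volume()] that was registered.
#' @param ref the reference [volume()] whose grid to reproduce.
#' @param spec [kernel_spec()] for the final reformat; defaults to the
#'   kernel used during registration.
#' @return A [volume()] on the reference grid.
#' @export
apply_registration <- function(result, target, ref, spec = result$kernel) {
  if (!inherits(result, "registration_result"))
    stop("`result` must be a registration_result", call. = FALSE)
  res <- resample_core(target, dim(ref$data), ref$spacing, ref$origin,
                       unclass(result$final_transform), spec)
  out <- volume(array(res$values, dim(ref$data)), spacing = ref$spacing,
                origin = ref$origin)
  attr(out, "inside_fraction") <- mean(res$inside)
  out
}
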