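# Seeded phantom generator: multi-organ style images with controlled
# background fraction, plus perturbation and augmentation utilities.
# Everything is deterministic under the seed carried in its spec; RNG
# state of the caller is restored on exit.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specify a synthetic multi-organ phantom
#'
#' Phantoms emulate the geometry of abdominal-organ slices: a dominant
#' uniform background and `C - 1` elliptical "organs", one per grid cell so
#' they never overlap, sized to hit a target background fraction. Each
#' class has its own mean intensity; Gaussian noise is added on top. With
#' `noise_sd = 0` intensities separate classes perfectly, so a threshold
#' classifier can reach IoU 1.
#'
#' @param size Image side in pixels (square images). Default 64.
#' @param C Number of classes including background. Default 5 (background
#'   plus four organs).
#' @param bg_frac Target background fraction in (0,1). Default 0.95,
#'   the canonical imbalance regime of medical segmentation.
#' @param noise_sd Intensity noise standard deviation. Default 0.02.
#' @param intensity_means Optional length-`C` vector of class mean
#'   intensities in \[0,1\] (background first); defaults to an even spread.
#' @param jitter Relative jitter applied to ellipse radii and aspect
#'   (0 = perfect circles of identical size). Default 0.25.
#' @param exact_bg If `TRUE`, organ boundaries are trimmed or grown pixel
#'   by pixel after rendering so the realised background count equals
#'   `round(bg_frac * size^2)` exactly (useful when an illustration needs
#'   an exact imbalance ratio). Default `FALSE` (within +/- 5 percentage
#'   points of the target).
#' @param seed Integer seed; fixed seed reproduces identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 64, C = 5, bg_frac = 0.95, noise_sd = 0.02,
                         intensity_means = NULL, jitter = 0.25,
                         exact_bg = FALSE, seed = 1) {
  stopifnot(size >= 8, C >= 2, bg_frac > 0, bg_frac < 1, noise_sd >= 0,
            jitter >= 0, jitter < 1)
  if (is.null(intensity_means))
    intensity_means <- seq(0.1, 0.9, length.out = C)
  if (length(intensity_means) != C) stop("need one intensity mean per class")
  structure(list(size = size, C = C, bg_frac = bg_frac, noise_sd = noise_sd,
                 intensity_means = intensity_means, jitter = jitter,
                 exact_bg = isTRUE(exact_bg), seed = seed),
            class = "phantom_spec")
}

shift_mat <- function(m, dy, dx, fill) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  ys <- seq_len(n) - dy; xs <- seq_len(p) - dx
  oky <- ys >= 1 & ys <= n; okx <- xs >= 1 & xs <= p
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

# Trim or grow foreground boundaries, in scan order, until the background
# pixel count equals target_bg exactly. No class is eliminated.
adjust_bg_count <- function(lab, target_bg, background = 0L) {
  repeat {
    cur_bg <- sum(lab == background)
    if (cur_bg == target_bg) return(lab)
    shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    if (cur_bg < target_bg) {
      # too much foreground: peel fg pixels that touch background
      touches_bg <- Reduce(`|`, lapply(shifts, function(s)
        shift_mat(lab == background, s[1], s[2], TRUE)))
      counts <- table(lab[lab != background])
      cand <- which(lab != background & touches_bg &
                      lab %in% as.integer(names(counts[counts > 3])))
      need <- target_bg - cur_bg
      if (!length(cand)) stop("cannot reach exact background fraction")
      lab[cand[seq_len(min(need, length(cand)))]] <- background
    } else {
      # too little foreground: grow fg into adjacent background
      for (s in shifts) {
        nb <- shift_mat(lab, s[1], s[2], background)
        cand <- which(lab == background & nb != background)
        need <- cur_bg - target_bg
        if (length(cand)) {
          take <- cand[seq_len(min(need, length(cand)))]
          lab[take] <- nb[take]
          cur_bg <- sum(lab == background)
        }
        if (cur_bg == target_bg) break
      }
      if (cur_bg > target_bg && !any(lab != background))
        stop("cannot reach exact background fraction")
    }
  }
}

# Sample per-organ ellipse parameters (centres, radii, orientation) on a
# grid layout. Errors if the requested area cannot fit in a cell.
sample_ellipses <- function(spec) {
  n_fg <- spec$C - 1L
  g <- ceiling(sqrt(n_fg))
  cell <- spec$size / g
  area_per <- (1 - spec$bg_frac) * spec$size^2 / n_fg
  r0 <- sqrt(area_per / pi)
  rmax <- r0 * sqrt(1 + spec$jitter)
  if (rmax + 1 > cell / 2)
    stop("infeasible geometry: organs of radius ", round(rmax, 1),
         " px cannot fit in ", round(cell, 1), " px grid cells")
  cells <- utils::head(expand.grid(cx = seq_len(g), cy = seq_len(g)), n_fg)
  lapply(seq_len(n_fg), function(k) {
    aspect <- exp(stats::runif(1, -spec$jitter, spec$jitter))
    ra <- max(1, r0 * aspect)
    rb <- max(1, r0 / aspect)
    slack <- cell / 2 - max(ra, rb) - 1
    ctr <- c((cells$cy[k] - 0.5) * cell, (cells$cx[k] - 0.5) * cell) +
      stats::runif(2, -max(slack, 0), max(slack, 0))
    list(center = ctr, ra = ra, rb = rb, theta = stats::runif(1, 0, pi))
  })
}

render_phantom <- function(params, spec) {
  n <- spec$size
  lab <- matrix(0L, n, n)
  yy <- matrix(rep(seq_len(n), n), n, n)        # row coordinate
  xx <- t(yy)                                   # column coordinate
  for (k in seq_along(params)) {
    p <- params[[k]]
    dy <- yy - p$center[1]; dx <- xx - p$center[2]
    u <- dy * cos(p$theta) + dx * sin(p$theta)
    v <- -dy * sin(p$theta) + dx * cos(p$theta)
    inside <- (u / p$ra)^2 + (v / p$rb)^2 <= 1
    lab[inside] <- k
  }
  if (isTRUE(spec$exact_bg))
    lab <- adjust_bg_count(lab, round(spec$bg_frac * n^2))
  img <- matrix(spec$intensity_means[lab + 1L], n, n)
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
  list(image = img,
       labelmap = labelmap(lab, class_set(0:(spec$C - 1L))))
}

#' Generate a phantom image and its groundtruth labelmap
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (numeric intensity matrix) and `labelmap`
#'   (groundtruth [labelmap()] containing every class).
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' mean(ph$labelmap == 0)   # close to the 0.95 background target
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    out <- render_phantom(sample_ellipses(spec), spec)
  })
  if (!all(0:(spec$C - 1L) %in% unique(as.integer(out$labelmap))))
    stop("degenerate phantom: some class has no pixels")
  out
}

#' Specify a prediction perturbation
#'
#' Describes how to corrupt a groundtruth labelmap into a fake "prediction"
#' with a known error structure, for exercising evaluation code: per-class
#' morphological erosion (creates false negatives only) or dilation
#' (false positives only), plus random label flips at boundary pixels or
#' anywhere.
#'
#' @param erode_radius,dilate_radius Disc radius in pixels, either one
#'   number for all foreground classes or a vector named by class id.
#' @param boundary_flip_rate,label_flip_rate Probability that a boundary
#'   pixel / any pixel is flipped to a random other class.
#' @param seed Integer seed.
#' @return An object of class `perturb_spec`.
#' @export
perturb_spec <- function(erode_radius = 0, dilate_radius = 0,
                         boundary_flip_rate = 0, label_flip_rate = 0,
                         seed = 1) {
  stopifnot(all(erode_radius >= 0), all(dilate_radius >= 0),
            boundary_flip_rate >= 0, boundary_flip_rate <= 1,
            label_flip_rate >= 0, label_flip_rate <= 1)
  structure(list(erode_radius = erode_radius, dilate_radius = dilate_radius,
                 boundary_flip_rate = boundary_flip_rate,
                 label_flip_rate = label_flip_rate, seed = seed),
            class = "perturb_spec")
}

radius_for <- function(r, class_id) {
  if (is.null(names(r))) r[1]
  else if (as.character(class_id) %in% names(r)) r[[as.character(class_id)]]
  else 0
}

boundary_pixels <- function(m) {
  n1 <- rbind(m[-1, , drop = FALSE], m[nrow(m), ])
  n2 <- rbind(m[1, ], m[-nrow(m), , drop = FALSE])
  n3 <- cbind(m[, -1, drop = FALSE], m[, ncol(m)])
  n4 <- cbind(m[, 1], m[, -ncol(m), drop = FALSE])
  m != n1 | m != n2 | m != n3 | m != n4
}

#' Perturb a groundtruth labelmap into a synthetic prediction
#'
#' Erosion of class c by radius r yields FNc > 0 and FPc = 0 against the
#' original; dilation yields FPc > 0 and FNc = 0. Flip perturbations add
#' unstructured noise. A class that vanishes entirely under erosion is
#' flagged with a warning.
#'
#' @param gnd Groundtruth [labelmap()].
#' @param spec A [perturb_spec()].
#' @return The perturbed [labelmap()].
#' @export
perturb <- function(gnd, spec) {
  stopifnot(inherits(gnd, "labelmap"), inherits(spec, "perturb_spec"))
  cs <- lm_class_set(gnd)
  out <- unclass(gnd)
  fg <- setdiff(cs$labels, cs$background)
  with_seed(spec$seed, {
    for (cl in fg) {
      r <- radius_for(spec$erode_radius, cl)
      if (r > 0) {
        mask <- (out == cl) * 1
        er <- EBImage::erode(mask, EBImage::makeBrush(2 * floor(r) + 1, "disc"))
        out[out == cl & er < 0.5] <- cs$background
        if (!any(out == cl))
          warning("class ", cl, " vanished entirely under erosion")
      }
      r <- radius_for(spec$dilate_radius, cl)
      if (r > 0) {
        mask <- (out == cl) * 1
        di <- EBImage::dilate(mask, EBImage::makeBrush(2 * floor(r) + 1, "disc"))
        out[di > 0.5] <- cl
      }
    }
    if (spec$boundary_flip_rate > 0) {
      idx <- which(boundary_pixels(out) & stats::runif(length(out)) < spec$boundary_flip_rate)
      for (i in idx)
        out[i] <- sample(setdiff(cs$labels, out[i]), 1)
    }
    if (spec$label_flip_rate > 0) {
      idx <- which(stats::runif(length(out)) < spec$label_flip_rate)
      for (i in idx)
        out[i] <- sample(setdiff(cs$labels, out[i]), 1)
    }
  })
  labelmap(out, cs)
}

#' Generate a cohort of synthetic patients with correlated slices
#'
#' Each patient gets its own organ geometry (sampled once per patient);
#' the patient's slices re-render that geometry with small per-slice
#' jitter of centres and radii. Slices from one patient are therefore more
#' similar to each other than slices across patients — the structure that
#' makes patient-wise (rather than slice-wise) cross-validation necessary.
#'
#' @param n_patients Number of patients.
#' @param slices_per_patient Slices per patient.
#' @param spec A [phantom_spec()]; its seed seeds the whole cohort.
#' @return List of records, each a list with `patient` (id string),
#'   `slice` (index), `image` and `labelmap`.
#' @export
generate_patient_series <- function(n_patients, slices_per_patient = 3,
                                    spec = phantom_spec()) {
  stopifnot(n_patients >= 1, slices_per_patient >= 1)
  with_seed(spec$seed, {
    recs <- list()
    for (p in seq_len(n_patients)) {
      base <- sample_ellipses(spec)
      for (sl in seq_len(slices_per_patient)) {
        params <- lapply(base, function(e) {
          e$center <- e$center + stats::runif(2, -1, 1)
          sc <- exp(stats::runif(1, -0.05, 0.05))
          e$ra <- max(1, e$ra * sc); e$rb <- max(1, e$rb * sc)
          e
        })
        recs[[length(recs) + 1L]] <-
          c(list(patient = sprintf("P%03d", p), slice = sl),
            render_phantom(params, spec))
      }
    }
    recs
  })
}

#' Specify random geometric augmentation
#'
#' Random affine perturbations in the style used to augment scarce medical
#' training data: translation, rotation, shear and isotropic scaling, each
#' sampled uniformly up to its maximum.
#'
#' @param max_translation Maximum |translation| per axis, pixels. Default 10.
#' @param max_rotation Maximum |rotation|, degrees. Default 10.
#' @param max_shear Maximum |shear displacement|, pixels. Default 10.
#' @param max_scale Maximum relative scale change. Default 0.10.
#' @param seed Integer seed.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(max_translation = 10, max_rotation = 10,
                         max_shear = 10, max_scale = 0.10, seed = 1) {
  stopifnot(max_translation >= 0, max_rotation >= 0, max_shear >= 0,
            max_scale >= 0, max_scale < 1)
  structure(list(max_translation = max_translation,
                 max_rotation = max_rotation, max_shear = max_shear,
                 max_scale = max_scale, seed = seed),
            class = "augment_spec")
}

# Inverse-mapped affine resampling about the image centre. The labelmap is
# sampled nearest-neighbour (interpolation must never invent class ids);
# the image bilinearly. Out-of-canvas regions are filled with background.
affine_resample <- function(img, lab, mat, shift, background = 0L) {
  n <- nrow(lab); m <- ncol(lab)
  ctr <- c((n + 1) / 2, (m + 1) / 2)
  inv <- solve(mat)
  yy <- matrix(rep(seq_len(n), m), n, m)
  xx <- matrix(rep(seq_len(m), each = n), n, m)
  dy <- yy - ctr[1] - shift[1]
  dx <- xx - ctr[2] - shift[2]
  sy <- inv[1, 1] * dy + inv[1, 2] * dx + ctr[1]
  sx <- inv[2, 1] * dy + inv[2, 2] * dx + ctr[2]
  # nearest neighbour for labels
  ry <- round(sy); rx <- round(sx)
  inb <- ry >= 1 & ry <= n & rx >= 1 & rx <= m
  lab_out <- matrix(background, n, m)
  lab_out[inb] <- lab[cbind(ry[inb], rx[inb])]
  # bilinear for intensities, 0 fill
  img_out <- matrix(0, n, m)
  fy <- as.vector(pmin(pmax(sy, 1), n)); fx <- as.vector(pmin(pmax(sx, 1), m))
  y0 <- floor(fy); x0 <- floor(fx)
  y1 <- pmin(y0 + 1, n); x1 <- pmin(x0 + 1, m)
  wy <- fy - y0; wx <- fx - x0
  v <- (1 - wy) * (1 - wx) * img[cbind(y0, x0)] +
    (1 - wy) * wx * img[cbind(y0, x1)] +
    wy * (1 - wx) * img[cbind(y1, x0)] +
    wy * wx * img[cbind(y1, x1)]
  img_out[inb] <- v[as.vector(inb)]
  list(image = img_out, labelmap = lab_out)
}

#' Apply one random augmentation to an image/labelmap pair
#'
#' Samples a single affine transform (translation, rotation, shear, scale
#' within the spec's maxima) and applies the identical transform to both
#' the image and the labelmap; labels are resampled nearest-neighbour and
#' uncovered canvas is filled with background. A spec with all maxima 0 is
#' the identity.
#'
#' @param image Numeric intensity matrix.
#' @param lab Matching [labelmap()].
#' @param spec An [augment_spec()].
#' @return List with transformed `image` and `labelmap`.
#' @export
augment <- function(image, lab, spec) {
  stopifnot(inherits(lab, "labelmap"), all(dim(image) == dim(lab)),
            inherits(spec, "augment_spec"))
  cs <- lm_class_set(lab)
  with_seed(spec$seed, {
    tr <- stats::runif(2, -spec$max_translation, spec$max_translation)
    th <- stats::runif(1, -spec$max_rotation, spec$max_rotation) * pi / 180
    sh <- stats::runif(1, -spec$max_shear, spec$max_shear) / nrow(lab)
    sc <- 1 + stats::runif(1, -spec$max_scale, spec$max_scale)
  })
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  shear <- matrix(c(1, sh, 0, 1), 2, 2, byrow = TRUE)
  mat <- (rot %*% shear) * sc
  out <- affine_resample(image, unclass(lab), mat, tr,
                         background = cs$background)
  list(image = out$image, labelmap = labelmap(out$labelmap, cs))
}
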