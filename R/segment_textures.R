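# Stage 2: partition the implant region into three textures -- smooth bright
# metal, rough mid-gray ingrown bone, and dark smooth pore holes.
#
# Holes are outlined first by a Chan-Vese active contour restricted to the
# implant region (they are the darkest, smoothest structures); the remainder
# is split into bone and metal by the local average of the Roberts gradient
# magnitude (rough = bone, smooth = metal).

#' Default stage-2 parameters
#'
#' @param mu,tol,max_iter,init Chan-Vese settings (see [evolve_contour()]).
#'   `init` is `"threshold"` (seed the contour with pixels darker than
#'   `hole_seed_max`) or `"checkerboard"`.
#' @param hole_seed_max Intensity below which a pixel seeds the hole contour.
#' @param hole_mean_max Sanity cap: if the converged dark region's mean
#'   intensity exceeds this, the contour latched onto tissue rather than
#'   voids and an empty holes mask is returned with a warning.
#' @param min_hole_px Connected hole components smaller than this (8-connected)
#'   are discarded as segmentation noise.
#' @param neighborhood Side of the square window over which Roberts gradient
#'   magnitudes are averaged for the roughness score (odd, in pixels).
#' @param roughness_threshold Fixed roughness cut; `NULL` (default) selects it
#'   per image as the Otsu split of the averaged magnitudes.
#' @param min_roughness Lower floor on the roughness cut, so that a nearly
#'   texture-free remainder (e.g. a solid implant) is not split by noise.
#' @param bone_opening Radius of a morphological opening applied to the raw
#'   bone mask (0 disables); removes isolated few-pixel bone specks caused by
#'   noise on smooth metal.
#' @param bone_intensity_max Intensity gate for bone: `"otsu"` (default)
#'   splits the remaining-region intensities into bright polished metal vs
#'   mid-gray tissue and only lets pixels below the split be bone; a numeric
#'   value fixes the cut; `NULL` disables the gate. Without it, the intensity
#'   jump at the metal/bone interface produces a ridge of high Roberts
#'   magnitudes that the averaging window smears onto the (bright) metal
#'   side.
#' @return Named list of stage-2 parameters.
#' @export
stage2_config <- function(mu = 0.1, tol = 1e-4, max_iter = 300L,
                          init = c("threshold", "checkerboard"),
                          hole_seed_max = 0.30, hole_mean_max = 0.45,
                          min_hole_px = 20L, neighborhood = 9L,
                          roughness_threshold = NULL, min_roughness = 0.08,
                          bone_opening = 2L, bone_intensity_max = "otsu") {
  list(mu = mu, tol = tol, max_iter = as.integer(max_iter),
       init = match.arg(init),
       hole_seed_max = hole_seed_max, hole_mean_max = hole_mean_max,
       min_hole_px = as.integer(min_hole_px),
       neighborhood = as.integer(neighborhood),
       roughness_threshold = roughness_threshold,
       min_roughness = min_roughness,
       bone_opening = as.integer(bone_opening),
       bone_intensity_max = bone_intensity_max)
}

#' Detect non-osseointegrated pore holes inside the implant region
#'
#' Evolves a Chan-Vese contour restricted to the implant mask and returns the
#' darker of the two converged regions (lower mean intensity) as the holes
#' mask, after small-object removal. If the contour collapses, no dark seed
#' exists, or the "dark" region is not actually dark (mean above
#' `hole_mean_max`), an empty mask is returned with a warning.
#'
#' @param image Grayscale micrograph matrix.
#' @param implant [segment_implant()] result (or a logical implant mask).
#' @param config Parameter list from [stage2_config()].
#' @return Logical holes mask.
#' @export
detect_holes <- function(image, implant, config = stage2_config()) {
  gray <- to_grayscale(image)
  domain <- implant_mask_of(implant)
  check_same_shape(gray, domain)
  empty <- domain & FALSE
  if (!any(domain)) return(empty)

  init <- if (config$init == "checkerboard") {
    checkerboard_mask(dim(gray), period = 10L) & domain
  } else {
    (gray < config$hole_seed_max) & domain
  }
  if (sum(init) == 0L || sum(init) == sum(domain)) {
    warning("hole contour has no valid seed; returning empty holes mask")
    return(empty)
  }

  st <- evolve_contour(gray, init, domain = domain, mu = config$mu,
                       tol = config$tol, max_iter = config$max_iter)
  if (st$collapsed) {
    warning("hole contour collapsed; returning empty holes mask")
    return(empty)
  }
  dark <- if (st$c1 <= st$c2) st$inside else (domain & !st$inside)
  dark_mean <- mean(gray[dark])
  if (!is.finite(dark_mean) || dark_mean > config$hole_mean_max) {
    warning(sprintf(
      "darker contour region has mean intensity %.2f > %.2f; treating as no holes",
      dark_mean, config$hole_mean_max))
    return(empty)
  }
  remove_small_components(dark, config$min_hole_px)
}

#' Classify remaining implant pixels as bone or metal by texture roughness
#'
#' Roughness is the Roberts gradient magnitude averaged over the square
#' `neighborhood` around each pixel; bone is where the average strictly
#' exceeds the threshold. Only gradients whose full 2x2 Roberts support lies
#' inside `remaining` enter the average, so intensity jumps across the hole
#' boundary do not leak into the score.
#'
#' @param image Grayscale micrograph matrix.
#' @param remaining Logical mask: implant region minus holes.
#' @param config Parameter list from [stage2_config()].
#' @return List with disjoint logical masks `bone` and `metal`
#'   (`bone | metal == remaining`) and the `threshold` used.
#' @export
classify_roughness <- function(image, remaining, config = stage2_config()) {
  gray <- to_grayscale(image)
  check_same_shape(gray, remaining)
  if (!any(remaining)) {
    return(list(bone = remaining, metal = remaining, threshold = NA_real_))
  }
  h <- nrow(gray); w <- ncol(gray)
  mag <- roberts_edges(gray)
  # 2x2 support of the Roberts response anchored at (r, c): (r,c), (r,c+1),
  # (r+1,c), (r+1,c+1), with the last row/column reflected
  pm <- remaining[c(seq_len(h), h), c(seq_len(w), w)]
  valid <- pm[seq_len(h), seq_len(w)] & pm[seq_len(h), 1L + seq_len(w)] &
    pm[1L + seq_len(h), seq_len(w)] & pm[1L + seq_len(h), 1L + seq_len(w)]
  r <- (config$neighborhood - 1L) %/% 2L
  num <- box_sum(mag * valid, r)
  den <- box_sum(valid * 1, r)
  avg <- ifelse(den > 0, num / pmax(den, 1), 0)

  thr <- config$roughness_threshold
  if (is.null(thr)) {
    vals <- avg[remaining]
    thr <- max(otsu_threshold(vals), config$min_roughness)
  }
  bone <- remaining & (avg > thr)
  icut <- config$bone_intensity_max
  if (!is.null(icut)) {
    if (identical(icut, "otsu")) icut <- otsu_threshold(gray[remaining])
    bone <- bone & (gray < icut)
    # the gate drops isolated speckle-bright pixels inside bone tissue;
    # a radius-1 closing reabsorbs these interior salt holes
    if (any(bone)) bone <- morphological_close(bone, 1L) & remaining
  }
  if (config$bone_opening > 0L && any(bone)) {
    bone <- binary_dilate(binary_erode(bone, config$bone_opening),
                          config$bone_opening) & remaining
  }
  list(bone = bone, metal = remaining & !bone, threshold = thr)
}

#' Three-way texture partition of the implant region
#'
#' Runs [detect_holes()] then [classify_roughness()] on the remainder and
#' returns the disjoint metal / bone / holes partition of the implant region
#' (their union is asserted to equal the implant mask exactly).
#'
#' @param image Grayscale or color micrograph.
#' @param implant [segment_implant()] result (or a logical implant mask).
#' @param config Parameter list from [stage2_config()].
#' @return An object of class `segmentation_result`: list with logical masks
#'   `implant_metal`, `bone`, `holes`, and `params` (including the roughness
#'   threshold actually used).
#' @export
segment_textures <- function(image, implant, config = stage2_config()) {
  gray <- to_grayscale(image)
  domain <- implant_mask_of(implant)
  holes <- detect_holes(gray, domain, config)
  remaining <- domain & !holes
  cls <- classify_roughness(gray, remaining, config)
  res <- structure(
    list(implant_metal = cls$metal, bone = cls$bone, holes = holes,
         params = c(config, list(roughness_threshold_used = cls$threshold))),
    class = "segmentation_result"
  )
  assert_partition(res, domain)
  res
}

# partition invariant checked on every run
assert_partition <- function(seg, implant_mask) {
  un <- seg$implant_metal | seg$bone | seg$holes
  if (!identical(un, implant_mask)) {
    stop("internal error: partition does not tile the implant region")
  }
  if (any(seg$implant_metal & seg$bone) || any(seg$implant_metal & seg$holes) ||
      any(seg$bone & seg$holes)) {
    stop("internal error: partition masks overlap")
  }
  invisible(TRUE)
}

implant_mask_of <- function(implant) {
  if (inherits(implant, "implant_region")) implant$mask
  else if (is.matrix(implant) && is.logical(implant)) implant
  else stop("expected an implant_region or a logical mask")
}

checkerboard_mask <- function(dm, period = 10L) {
  r <- matrix(seq_len(dm[1]), dm[1], dm[2])
  cc <- matrix(seq_len(dm[2]), dm[1], dm[2], byrow = TRUE)
  ((r %/% period) + (cc %/% period)) %% 2L == 0L
}

#' @export
print.segmentation_result <- function(x, ...) {
  a <- c(metal = sum(x$implant_metal), bone = sum(x$bone), holes = sum(x$holes))
  tot <- sum(a)
  cat("implant-region texture partition:\n")
  for (nm in names(a)) {
    cat(sprintf("  %-6s %8d px (%5.1f%%)\n", nm, a[[nm]], 100 * a[[nm]] / tot))
  }
  invisible(x)
}
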