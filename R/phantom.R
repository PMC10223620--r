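# Synthetic ground-truthed micrographs of porous implant cross-sections.
#
# Each phantom is a disc-shaped implant footprint carrying one of six lattice
# strut patterns (or solid), with the pore space partly filled by "bone".
# Intensity conventions mimic optical micrographs of ground sections: bright
# smooth polished metal, mid-gray speckled bone tissue, dark smooth voids,
# darker flat background. Bone fills each pore inward from the strut walls
# (apposition-like growth), with per-pore filled fractions jittered around
# the designed global ingrowth fraction and the global pixel total
# constrained to it exactly (up to rounding to one pixel).
#
# The default scale maps the 600 um design pore to 60 px (10 um/px); this
# magnification is a free choice of the generator and is recorded in the
# phantom spec.

#' Specify a synthetic lattice phantom
#'
#' @param lattice_type One of `"gyroid"`, `"cube"`, `"cylinder"`,
#'   `"tetrahedron"`, `"double_pyramid"`, `"voronoi"`, `"solid"`.
#' @param canvas Image side in pixels (square canvas).
#' @param pore_px Design pore size in pixels (>= 8; default 60 px = 600 um at
#'   10 um/px).
#' @param strut_px Strut thickness in pixels.
#' @param designed_bi Designed global bone-ingrowth fraction in `[0, 1]`.
#' @param seed RNG seed making the render fully deterministic.
#' @param pixel_size_um Physical pixel pitch recorded as metadata.
#' @param shell Draw a thin solid rim at the implant boundary (the machined
#'   outer contour), which also closes pores cut open by the section edge.
#' @param intensities Named list overriding the texture intensity model:
#'   `metal_level`, `metal_var`, `bone_level`, `bone_speckle`, `hole_level`,
#'   `hole_var`, `background`.
#' @return An object of class `lattice_phantom` (a validated parameter list).
#' @export
lattice_phantom <- function(lattice_type = "cube", canvas = 320L,
                            pore_px = 60L, strut_px = 14L,
                            designed_bi = 0.5, seed = 1L,
                            pixel_size_um = 10, shell = TRUE,
                            intensities = list()) {
  lattice_type <- match.arg(lattice_type,
    c("gyroid", "cube", "cylinder", "tetrahedron", "double_pyramid",
      "voronoi", "solid"))
  canvas <- as.integer(canvas); pore_px <- as.integer(pore_px)
  strut_px <- as.integer(strut_px)
  if (pore_px < 8L) stop("pore_px must be >= 8 to be resolvable")
  if (strut_px < 2L) stop("strut_px must be >= 2")
  if (canvas < 2L * (pore_px + strut_px)) {
    stop("canvas too small to render the lattice pattern")
  }
  if (designed_bi < 0 || designed_bi > 1) stop("designed_bi must be in [0, 1]")
  defaults <- list(metal_level = 0.85, metal_var = 0.03,
                   bone_level = 0.55, bone_speckle = 0.15,
                   hole_level = 0.15, hole_var = 0.02,
                   background = 0.08)
  unknown <- setdiff(names(intensities), names(defaults))
  if (length(unknown)) stop("unknown intensity keys: ",
                            paste(unknown, collapse = ", "))
  defaults[names(intensities)] <- intensities
  structure(
    list(lattice_type = lattice_type, canvas = canvas, pore_px = pore_px,
         strut_px = strut_px, designed_bi = designed_bi,
         seed = as.integer(seed), pixel_size_um = pixel_size_um,
         shell = isTRUE(shell), intensities = defaults),
    class = "lattice_phantom"
  )
}

#' Rasterize a lattice cross-section strut pattern
#'
#' Returns the metal strut mask of a disc-shaped implant footprint. Periodic
#' patterns use period `pore_px + strut_px`; diagonal families (tetrahedron,
#' double pyramid) scale the period by `sqrt(2)` so the pore width between
#' diagonal struts stays near `pore_px`. The gyroid is a thresholded band of
#' the 2D slice of the TPMS implicit surface
#' `sin x cos y + sin y cos z0 + sin z0 cos x`. The Voronoi pattern thickens
#' the ridge skeleton of a seeded random point set.
#'
#' @param lattice_type See [lattice_phantom()].
#' @param pore_px,strut_px,canvas Geometry in pixels.
#' @param seed Seed for the Voronoi point set (ignored by the deterministic
#'   patterns).
#' @param shell Add the solid outer rim.
#' @return List with logical matrices `metal` (struts, inside the footprint)
#'   and `footprint` (implant disc).
#' @export
lattice_cross_section <- function(lattice_type, pore_px = 60L, strut_px = 14L,
                                  canvas = 320L, seed = 1L, shell = TRUE) {
  n <- as.integer(canvas)
  x <- matrix(seq_len(n), n, n, byrow = TRUE)  # column index
  y <- matrix(seq_len(n), n, n)                # row index
  cx <- (n + 1) / 2
  rad <- sqrt((x - cx)^2 + (y - cx)^2)
  R <- 0.44 * n
  footprint <- rad <= R
  p <- pore_px + strut_px
  pd <- round(p * sqrt(2))
  s <- strut_px
  pattern <- switch(lattice_type,
    solid = matrix(TRUE, n, n),
    cube = (x %% p) < s | (y %% p) < s,
    cylinder = {
      dxc <- ((x + p / 2) %% p) - p / 2
      dyc <- ((y + p / 2) %% p) - p / 2
      dxc^2 + dyc^2 > (pore_px / 2)^2
    },
    tetrahedron = ((x + y) %% pd) < s | ((x - y) %% pd) < s,
    double_pyramid = ((x + y) %% pd) < s | ((x - y) %% pd) < s |
      (x %% p) < s,
    gyroid = {
      w <- 2 * pi / p
      z0 <- 0.7
      f <- sin(w * x) * cos(w * y) + sin(w * y) * cos(z0) +
        sin(z0) * cos(w * x)
      abs(f) < 0.55 * s * w
    },
    voronoi = {
      withr::with_seed(seed, {
        npts <- max(8L, round(n^2 / p^2))
        px <- stats::runif(npts, 1, n)
        py <- stats::runif(npts, 1, n)
        d1 <- matrix(Inf, n, n); d2 <- matrix(Inf, n, n)
        for (i in seq_len(npts)) {
          d <- sqrt((x - px[i])^2 + (y - py[i])^2)
          closer <- d < d1
          d2 <- pmin(d2, ifelse(closer, d1, d))
          d1 <- pmin(d1, d)
        }
        (d2 - d1) < s
      })
    },
    stop("unknown lattice_type: ", lattice_type)
  )
  metal <- pattern & footprint
  if (shell && lattice_type != "solid") {
    metal <- metal | (footprint & rad > R - max(3, round(s / 2)))
  }
  list(metal = metal, footprint = footprint)
}

#' Render a ground-truthed synthetic micrograph
#'
#' Deterministic given the phantom spec (all randomness runs under
#' `spec$seed`). Metal pixels are bright with only a smooth low-frequency
#' intensity drift, bone pixels carry high-frequency speckle at mid
#' intensity, holes are dark and smooth, and the background surrounds the
#' implant footprint. A fraction `designed_bi` of the pore pixels is bone,
#' exact up to one-pixel rounding.
#'
#' @param spec A [lattice_phantom()] specification.
#' @return List with `image` (numeric matrix in `[0, 1]`) and the exact
#'   ground-truth masks `metal`, `bone`, `hole`, `footprint`, plus `spec`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "lattice_phantom"))
  withr::with_seed(spec$seed, {
    cs <- lattice_cross_section(spec$lattice_type, spec$pore_px,
                                spec$strut_px, spec$canvas,
                                seed = spec$seed, shell = spec$shell)
    metal <- cs$metal
    footprint <- cs$footprint
    pore <- footprint & !metal
    bone <- pore & FALSE
    if (any(pore) && spec$designed_bi > 0) {
      bone <- fill_pores(pore, spec$designed_bi)
    }
    hole <- pore & !bone
    img <- render_intensities(metal, bone, hole, footprint, spec$intensities)
    list(image = img, metal = metal, bone = bone, hole = hole,
         footprint = footprint, spec = spec)
  })
}

# distribute round(bi * pore area) bone pixels over the pores: per-pore
# fractions jittered around bi, shifted in common to hit the global target.
# Within a pore, bone grows as a crescent from a random point on the pore
# wall (ingrowth is one-sided and patchy in real sections; it also keeps
# bone regions compact and resolvable at any filled fraction).
fill_pores <- function(pore, bi) {
  lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(pore), nrow(pore))))
  npores <- max(lab)
  idx_by_pore <- split(which(lab > 0), lab[lab > 0])
  a <- lengths(idx_by_pore)
  total <- sum(a)
  target <- round(bi * total)
  if (target == 0L) return(pore & FALSE)
  if (target == total) return(pore)
  f <- pmin(pmax(bi + stats::rnorm(npores, 0, 0.12), 0), 1)
  g <- function(d) sum(pmin(pmax(f + d, 0), 1) * a) - target
  delta <- stats::uniroot(g, c(-1, 1), tol = 1e-9)$root
  ff <- pmin(pmax(f + delta, 0), 1)
  ni <- floor(ff * a)
  rem <- target - sum(ni)
  if (rem > 0) {
    pri <- order(ff * a - ni, decreasing = TRUE)
    for (k in pri) {
      if (rem == 0) break
      if (ni[k] < a[k]) { ni[k] <- ni[k] + 1L; rem <- rem - 1L }
    }
  } else if (rem < 0) {
    pri <- order(ff * a - ni)
    for (k in pri) {
      if (rem == 0) break
      if (ni[k] > 0L) { ni[k] <- ni[k] - 1L; rem <- rem + 1L }
    }
  }
  d <- as.matrix(EBImage::distmap(matrix(as.numeric(pore), nrow(pore))))
  nr <- nrow(pore)
  bone <- pore & FALSE
  for (k in seq_len(npores)) {
    if (ni[k] == 0L) next
    idx <- idx_by_pore[[k]]
    wall <- idx[d[idx] <= 1.5]            # pore pixels touching the wall
    b <- if (length(wall)) wall[sample.int(length(wall), 1L)] else
      idx[sample.int(length(idx), 1L)]
    br <- (b - 1L) %% nr + 1L
    bc <- (b - 1L) %/% nr + 1L
    rr <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    db <- sqrt((rr - br)^2 + (cc - bc)^2) +
      stats::runif(length(idx), 0, 0.5)
    ord <- order(db)
    bone[idx[ord[seq_len(ni[k])]]] <- TRUE
  }
  bone
}

render_intensities <- function(metal, bone, hole, footprint, iv) {
  n <- nrow(metal)
  x <- matrix(seq_len(n), n, n, byrow = TRUE) / n
  y <- matrix(seq_len(n), n, n) / n
  smooth1 <- sin(2 * pi * (1.7 * x + stats::runif(1))) *
    sin(2 * pi * (1.3 * y + stats::runif(1)))
  smooth2 <- sin(2 * pi * (1.1 * x + stats::runif(1))) *
    sin(2 * pi * (1.9 * y + stats::runif(1)))
  img <- matrix(iv$background, n, n)
  img[metal] <- iv$metal_level + iv$metal_var * smooth1[metal]
  img[hole] <- iv$hole_level + iv$hole_var * smooth2[hole]
  nb <- sum(bone)
  if (nb > 0) {
    img[bone] <- iv$bone_level + stats::runif(nb, -iv$bone_speckle,
                                              iv$bone_speckle)
  }
  pmin(pmax(img, 0), 1)
}

#' Add seeded Gaussian noise and optional linear shading
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param sigma Gaussian noise standard deviation (0 = none).
#' @param illumination_gradient Peak-to-center amplitude of a horizontal
#'   linear shading ramp, as an intensity fraction (0 = none).
#' @param seed RNG seed.
#' @return Noisy image, clipped to `[0, 1]`. With `sigma = 0` and no gradient
#'   the input is returned unchanged.
#' @export
add_noise <- function(image, sigma, illumination_gradient = 0, seed = 1L) {
  check_grayscale01(image)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0 && illumination_gradient == 0) return(image)
  h <- nrow(image); w <- ncol(image)
  out <- image
  if (illumination_gradient != 0) {
    ramp <- matrix((seq_len(w) - (w + 1) / 2) / (w - 1), h, w, byrow = TRUE)
    out <- out + illumination_gradient * ramp
  }
  if (sigma > 0) {
    out <- out + withr::with_seed(seed, matrix(stats::rnorm(h * w, 0, sigma),
                                               h, w))
  }
  pmin(pmax(out, 0), 1)
}

#' Ground-truth BI of a rendered phantom
#'
#' @param phantom A [render_phantom()] result.
#' @return Bone fraction of the pore space, `NA` for solid phantoms.
#' @export
phantom_bi <- function(phantom) {
  bi_formula(sum(phantom$bone), sum(phantom$hole))
}
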