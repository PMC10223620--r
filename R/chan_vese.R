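# Chan-Vese active contour on a level set, used to outline the dark,
# non-osseointegrated pore holes inside the implant region.
#
# The energy is the discrete two-phase Chan-Vese functional
#   E = sum_inside (I - c1)^2 + sum_outside (I - c2)^2 + mu * length(C),
# where c1 and c2 are the exact mean intensities of the current inside and
# outside regions and length(C) counts 4-neighbor pixel pairs whose labels
# differ. The contour C is the zero level set of phi; "inside" is phi > 0.
# Updates are explicit gradient-descent steps on phi with backtracking: a
# step is accepted only if it does not increase E (with c1, c2 re-optimised
# for the candidate partition), so the accepted energy history is
# non-increasing by construction.

#' Discrete Chan-Vese energy of a partition
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param phi Level-set matrix of the same shape; inside is `phi > 0`.
#' @param c1,c2 Mean intensities imputed to the inside / outside regions.
#' @param mu Weight of the contour-length regularization (0 disables it).
#' @param domain Optional logical matrix restricting the computation; pixels
#'   outside the domain contribute nothing.
#' @return Scalar energy value.
#' @export
chan_vese_energy <- function(image, phi, c1, c2, mu = 0, domain = NULL) {
  check_same_shape(image, phi)
  inside <- phi > 0
  if (is.null(domain)) domain <- matrix(TRUE, nrow(image), ncol(image))
  e <- sum((image[inside & domain] - c1)^2) +
    sum((image[!inside & domain] - c2)^2)
  if (mu > 0) e <- e + mu * contour_length(inside, domain)
  e
}

# number of 4-neighbor pixel pairs (both in domain) with differing labels
contour_length <- function(inside, domain) {
  h <- nrow(inside); w <- ncol(inside)
  v <- (inside[-h, ] != inside[-1L, ]) & domain[-h, ] & domain[-1L, ]
  hh <- (inside[, -w] != inside[, -1L]) & domain[, -w] & domain[, -1L]
  sum(v) + sum(hh)
}

# energy and optimal region means for a candidate inside mask; NULL if a
# region is empty (degenerate partition)
partition_energy <- function(image, inside, domain, mu) {
  iv <- image[inside]
  ov <- image[domain & !inside]
  if (length(iv) == 0L || length(ov) == 0L) return(NULL)
  c1 <- mean(iv); c2 <- mean(ov)
  e <- sum((iv - c1)^2) + sum((ov - c2)^2)
  if (mu > 0) e <- e + mu * contour_length(inside, domain)
  list(energy = e, c1 = c1, c2 = c2)
}

signed_distance <- function(inside) {
  din <- as.matrix(EBImage::distmap(matrix(as.numeric(inside), nrow(inside))))
  dout <- as.matrix(EBImage::distmap(matrix(as.numeric(!inside), nrow(inside))))
  din[!is.finite(din)] <- max(dim(inside))
  dout[!is.finite(dout)] <- max(dim(inside))
  din - dout + ifelse(inside, -0.5, 0.5)
}

# mean curvature of the level set, central differences, clamped to +-1
curvature <- function(phi) {
  h <- nrow(phi); w <- ncol(phi)
  p <- phi[c(1L, seq_len(h), h), c(1L, seq_len(w), w)]
  ri <- 1L + seq_len(h); ci <- 1L + seq_len(w)
  px <- (p[ri, ci + 1L] - p[ri, ci - 1L]) / 2
  py <- (p[ri + 1L, ci] - p[ri - 1L, ci]) / 2
  pxx <- p[ri, ci + 1L] - 2 * p[ri, ci] + p[ri, ci - 1L]
  pyy <- p[ri + 1L, ci] - 2 * p[ri, ci] + p[ri - 1L, ci]
  pxy <- (p[ri + 1L, ci + 1L] - p[ri + 1L, ci - 1L] -
            p[ri - 1L, ci + 1L] + p[ri - 1L, ci - 1L]) / 4
  k <- (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) /
    ((px^2 + py^2)^1.5 + 1e-8)
  pmin(pmax(k, -1), 1)
}

#' Evolve a Chan-Vese contour to convergence
#'
#' Iterates explicit level-set updates with backtracking line search until the
#' relative energy change falls below `tol` or `max_iter` is reached. Region
#' means `c1` (inside) and `c2` (outside) are recomputed exactly at every
#' accepted step, so the recorded energy history is non-increasing.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param init Logical matrix: initial inside region. Must be neither empty
#'   nor full (within `domain`).
#' @param domain Optional logical matrix restricting evolution to a region of
#'   interest (e.g. the implant mask); pixels outside it are ignored.
#' @param mu Contour-length regularization weight (default 0.1; 0 disables).
#' @param tol Relative energy-change convergence tolerance; convergence is
#'   declared after `patience` consecutive accepted steps below it (a single
#'   small step, e.g. right after a symmetric initialization, is not yet
#'   convergence).
#' @param max_iter Maximum number of accepted iterations.
#' @param patience Number of consecutive sub-tolerance steps required.
#' @param eps Width parameter of the smoothed Dirac delta localising the
#'   update around the contour.
#' @param reinit_every Re-initialise phi to a signed distance function every
#'   this many accepted iterations (preserves the partition exactly).
#' @return An object of class `contour_state`: list with `phi`, `inside`,
#'   `c1`, `c2`, `energy`, `energy_history`, `iterations`, `converged`,
#'   `collapsed`.
#' @export
evolve_contour <- function(image, init, domain = NULL, mu = 0.1, tol = 1e-4,
                           max_iter = 500L, eps = 1.5, reinit_every = 5L,
                           patience = 5L) {
  check_grayscale01(image)
  check_same_shape(image, init)
  if (is.null(domain)) domain <- matrix(TRUE, nrow(image), ncol(image))
  init <- init & domain
  nd <- sum(domain)
  if (sum(init) == 0L || sum(init) == nd) {
    stop("degenerate initialization: inside region is empty or full")
  }
  phi <- signed_distance(init)
  cur <- partition_energy(image, init, domain, mu)
  history <- cur$energy
  converged <- FALSE
  streak <- 0L
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    inside <- phi > 0 & domain
    # threshold move: assign every pixel to the nearer region mean (the
    # exact minimiser of the data term at fixed c1, c2); accepted under the
    # same monotone energy rule, it clears misclassified pixels far from the
    # contour that the delta-localised PDE step cannot reach
    thr_in <- ((image - cur$c1)^2 <= (image - cur$c2)^2) & domain
    if (!identical(thr_in, inside)) {
      cand <- partition_energy(image, thr_in, domain, mu)
      if (!is.null(cand) && cand$energy < cur$energy - 1e-12) {
        rel <- (cur$energy - cand$energy) / max(abs(cur$energy), 1e-12)
        phi <- signed_distance(thr_in)
        cur <- cand
        history <- c(history, cand$energy)
        streak <- if (rel < tol) streak + 1L else 0L
        if (streak >= patience) { converged <- TRUE; break }
        next
      }
    }
    kap <- if (mu > 0) curvature(phi) else 0
    force <- (eps / (pi * (eps^2 + phi^2))) *
      (mu * kap - (image - cur$c1)^2 + (image - cur$c2)^2)
    force[!domain] <- 0
    mf <- max(abs(force))
    if (mf < 1e-14) { converged <- TRUE; break }
    # line search over a descending step ladder: large steps let weakly
    # forced pixels cross the zero level too; the energy check keeps the
    # accepted sequence monotone regardless
    accepted <- FALSE
    for (dt in 2^(3:-4) / mf) {
      cand_phi <- phi + dt * force
      cand_in <- cand_phi > 0 & domain
      if (identical(cand_in, inside)) next  # no pixel flips at this step
      cand <- partition_energy(image, cand_in, domain, mu)
      if (!is.null(cand) && cand$energy <= cur$energy + 1e-12) {
        rel <- (cur$energy - cand$energy) / max(abs(cur$energy), 1e-12)
        phi <- cand_phi
        cur <- cand
        history <- c(history, cand$energy)
        accepted <- TRUE
        streak <- if (rel < tol) streak + 1L else 0L
        if (streak >= patience) converged <- TRUE
        break
      }
    }
    if (!accepted) { converged <- TRUE; break }
    if (converged) break
    if (it %% reinit_every == 0L) phi <- signed_distance(phi > 0)
  }
  inside <- phi > 0 & domain
  collapsed <- sum(inside) == 0L || sum(inside) == nd
  structure(
    list(phi = phi, inside = inside, c1 = cur$c1, c2 = cur$c2,
         energy = cur$energy, energy_history = history, iterations = it,
         converged = converged, collapsed = collapsed),
    class = "contour_state"
  )
}

#' @export
print.contour_state <- function(x, ...) {
  cat("Chan-Vese contour state\n")
  cat(sprintf("  iterations: %d (%s)\n", x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  c1 (inside mean):  %.4f\n", x$c1))
  cat(sprintf("  c2 (outside mean): %.4f\n", x$c2))
  cat(sprintf("  energy: %.6g over %d accepted steps\n",
              x$energy, length(x$energy_history)))
  invisible(x)
}
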