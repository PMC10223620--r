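# Bone-ingrowth quantification and agreement statistics.
#
# BI = A_Oss / (A_Oss + A_Hole): the fraction of the original pore space
# (bone + holes; metal never enters the ratio) that has been filled by bone.
# For solid implants A_Oss + A_Hole = 0 and BI is undefined -- reported as NA
# with defined = FALSE, never silently 0.

# single implementation of the BI formula, shared by the algorithmic and
# manual paths
bi_formula <- function(a_oss, a_hole) {
  if (a_oss + a_hole > 0) a_oss / (a_oss + a_hole) else NA_real_
}

new_bi_result <- function(a_oss, a_hole, method, image_id, lattice_type,
                          timepoint) {
  structure(
    list(image_id = image_id, lattice_type = lattice_type,
         timepoint = timepoint, method = method,
         a_oss = as.integer(a_oss), a_hole = as.integer(a_hole),
         bi = bi_formula(a_oss, a_hole),
         defined = (a_oss + a_hole) > 0),
    class = "bi_result"
  )
}

#' Bone-ingrowth ratio of a segmentation result
#'
#' @param seg A `segmentation_result` from [segment_textures()].
#' @param image_id,lattice_type,timepoint Provenance labels carried into
#'   reports.
#' @return An object of class `bi_result` with fields `a_oss`, `a_hole`,
#'   `bi` (fraction in `[0, 1]`, `NA` when undefined), `defined`, and the
#'   provenance labels.
#' @export
compute_bi <- function(seg, image_id = "image", lattice_type = "unknown",
                       timepoint = "n/a") {
  stopifnot(inherits(seg, "segmentation_result"))
  new_bi_result(sum(seg$bone), sum(seg$holes), "algorithm",
                image_id, lattice_type, timepoint)
}

#' Bone-ingrowth ratio from manually outlined masks
#'
#' Applies the same BI formula to human-drawn bone and hole masks (e.g.
#' exported from an annotation tool); the result is labeled
#' `method = "manual"`.
#'
#' @param bone_mask,hole_mask Aligned, disjoint logical matrices.
#' @param image_id,lattice_type,timepoint Provenance labels.
#' @return A `bi_result` with `method = "manual"`.
#' @export
bi_from_manual_mask <- function(bone_mask, hole_mask, image_id = "image",
                                lattice_type = "unknown", timepoint = "n/a") {
  check_same_shape(bone_mask, hole_mask)
  if (any(bone_mask & hole_mask)) {
    stop("manual bone and hole masks overlap")
  }
  new_bi_result(sum(bone_mask), sum(hole_mask), "manual",
                image_id, lattice_type, timepoint)
}

#' @export
print.bi_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("%s [%s, %s, %s]: BI = %.2f%% (A_Oss = %d px, A_Hole = %d px)\n",
                x$image_id, x$lattice_type, x$timepoint, x$method,
                100 * x$bi, x$a_oss, x$a_hole))
  } else {
    cat(sprintf("%s [%s, %s, %s]: BI undefined (no pore area)\n",
                x$image_id, x$lattice_type, x$timepoint, x$method))
  }
  invisible(x)
}

#' @export
as.data.frame.bi_result <- function(x, ...) {
  data.frame(image_id = x$image_id, lattice_type = x$lattice_type,
             timepoint = x$timepoint, method = x$method,
             A_Oss_px = x$a_oss, A_Hole_px = x$a_hole,
             BI_percent = round(100 * x$bi, 2),
             stringsAsFactors = FALSE)
}

bi_results_frame <- function(results) {
  if (inherits(results, "bi_result")) results <- list(results)
  do.call(rbind, lapply(results, as.data.frame))
}

#' Agreement between algorithmic and manual BI measurements
#'
#' Pairs the two result lists by `image_id` and fits ordinary least squares
#' of the manual BI on the algorithmic BI. The regression direction is a
#' convention; R-squared is symmetric for simple OLS.
#'
#' @param algorithm,manual Lists of `bi_result` objects (each id present in
#'   both lists; at least 2 defined pairs).
#' @return An object of class `agreement_report`: list with `pairs`
#'   (data frame of paired BI fractions), `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
agreement <- function(algorithm, manual) {
  if (inherits(algorithm, "bi_result")) algorithm <- list(algorithm)
  if (inherits(manual, "bi_result")) manual <- list(manual)
  aid <- vapply(algorithm, `[[`, character(1), "image_id")
  mid <- vapply(manual, `[[`, character(1), "image_id")
  if (anyDuplicated(aid) || anyDuplicated(mid)) {
    stop("duplicate image_id within a result list")
  }
  if (!setequal(aid, mid)) {
    stop("unpaired image ids: ",
         paste(union(setdiff(aid, mid), setdiff(mid, aid)), collapse = ", "))
  }
  x <- vapply(algorithm, `[[`, numeric(1), "bi")
  y <- vapply(manual, `[[`, numeric(1), "bi")[match(aid, mid)]
  ids <- aid
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least 2 defined BI pairs for a fit")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  degenerate <- stats::var(x) == 0 || stats::var(y) == 0
  # no variance explained when either side is constant
  r2 <- if (degenerate) 0 else sm$r.squared
  pv <- if (degenerate) NA_real_ else stats::coef(sm)[2L, 4L]
  structure(
    list(pairs = data.frame(image_id = ids[keep],
                            algorithm_bi = x, manual_bi = y),
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2,
         p_value = pv,
         n = length(x)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("algorithm vs manual BI agreement (n = %d)\n", x$n))
  cat(sprintf("  manual = %.3f + %.3f * algorithm\n", x$intercept, x$slope))
  cat(sprintf("  R^2 = %.3f", x$r_squared))
  if (is.finite(x$p_value)) cat(sprintf(", p = %.3g", x$p_value))
  cat("\n")
  invisible(x)
}

#' Summarise BI results per lattice type and timepoint
#'
#' Mean BI, count, standard deviation and 95% confidence half-width (Student
#' t) per group. Undefined BI values (solid implants) are excluded from the
#' statistics; the half-width is `NA` for groups of one.
#'
#' @param results List of `bi_result` objects (or a single one).
#' @return A data frame with columns `lattice_type`, `timepoint`, `n`,
#'   `mean_BI_percent`, `sd_BI_percent`, `ci95_half_percent`.
#' @export
batch_report <- function(results) {
  df <- bi_results_frame(results)
  df <- df[is.finite(df$BI_percent), , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(lattice_type = character(), timepoint = character(),
                      n = integer(), mean_BI_percent = numeric(),
                      sd_BI_percent = numeric(),
                      ci95_half_percent = numeric()))
  }
  groups <- split(df, list(df$lattice_type, df$timepoint), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    n <- nrow(g)
    m <- mean(g$BI_percent)
    s <- if (n > 1L) stats::sd(g$BI_percent) else NA_real_
    ci <- if (n > 1L) stats::qt(0.975, n - 1L) * s / sqrt(n) else NA_real_
    data.frame(lattice_type = g$lattice_type[1L], timepoint = g$timepoint[1L],
               n = n, mean_BI_percent = m, sd_BI_percent = s,
               ci95_half_percent = ci, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$lattice_type, out$timepoint), , drop = FALSE]
}

#' Write per-image BI results to CSV
#'
#' Columns: `image_id`, `lattice_type`, `timepoint`, `method`, `A_Oss_px`,
#' `A_Hole_px`, `BI_percent` (two decimals; empty for undefined BI).
#'
#' @param results List of `bi_result` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  utils::write.csv(bi_results_frame(results), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
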