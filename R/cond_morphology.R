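#' Discrete disk structuring element
#'
#' The `size x size` binary disk `{(i, j) : i^2 + j^2 <= r^2}`, `r = (size
#' - 1) / 2`.  The default 5 x 5 disk has 13 pixels, matched to the shape
#' and size of the smallest objects being corrected.
#'
#' @param size odd side length (default 5).
#' @return logical matrix.
#' @export
disk_se <- function(size = 5L) {
  hs_assert(size >= 1 && size %% 2 == 1, "hs_parameter_error",
            "structuring element size must be odd")
  r <- (size - 1) / 2
  off <- seq(-r, r)
  outer(off, off, function(i, j) i^2 + j^2 <= r^2)
}

#' Conditional morphology specification
#'
#' Parameters of conditional erosion/dilation.  `p_we` and `p_wd` steer the
#' operator intensity: at `p_we = p_wd = 0` both factors `(1 - p_we)` and
#' `(1 + p_wd)` equal 1 and the conditional operators are at their most
#' active; at `p_we = 1` erosion can never fire, while `p_wd = 1` makes
#' dilation fire most readily.  `p_mn` is the brightness threshold the
#' local mean of the guide image is compared against (here taken constant
#' over the image, typically the selected segmentation threshold `p_w`).
#'
#' @param p_mn threshold, a scalar or an `M x N` matrix.
#' @param p_we erosion effectiveness constant in `[0, 1]`.
#' @param p_wd dilation effectiveness constant in `[0, 1]`.
#' @param se binary structuring element (default 5 x 5 disk).
#' @param iterations rounds of erosion and of dilation (default 5).
#' @param order `"sequential"`: all erosions then all dilations;
#'   `"alternating"`: erode/dilate pairs.
#' @return a `cond_morph_spec` object.
#' @export
cond_morph_spec <- function(p_mn, p_we = 0.5, p_wd = 0.5, se = disk_se(5L),
                            iterations = 5L,
                            order = c("sequential", "alternating")) {
  order <- match.arg(order)
  hs_assert(is.numeric(p_mn) && all(is.finite(p_mn)), "hs_parameter_error",
            "p_mn must be numeric and finite")
  hs_assert(p_we >= 0 && p_we <= 1, "hs_parameter_error", "p_we must be in [0, 1]")
  hs_assert(p_wd >= 0 && p_wd <= 1, "hs_parameter_error", "p_wd must be in [0, 1]")
  hs_assert(is.matrix(se) && all(dim(se) %% 2 == 1), "hs_parameter_error",
            "se must be a matrix with odd dimensions")
  hs_assert(isTRUE(all(se == se[rev(seq_len(nrow(se))), rev(seq_len(ncol(se)))])),
            "hs_parameter_error", "se must be point-symmetric")
  hs_assert(iterations >= 1, "hs_parameter_error", "iterations must be >= 1")
  structure(list(p_mn = p_mn, p_we = p_we, p_wd = p_wd,
                 se = matrix(as.logical(se), nrow(se)),
                 iterations = as.integer(iterations), order = order),
            class = "cond_morph_spec")
}

.se_check <- function(mask, se) {
  hs_assert(nrow(se) <= nrow(mask) && ncol(se) <= ncol(mask),
            "hs_parameter_error", "structuring element larger than the image")
}

.p_mn_field <- function(p_mn, mask) {
  if (is.matrix(p_mn)) {
    hs_assert(all(dim(p_mn) == dim(mask)), "hs_parameter_error",
              "p_mn field must match the mask dimensions")
    p_mn
  } else matrix(p_mn, nrow(mask), ncol(mask))
}

#' Local means of the guide image inside and outside the mask
#'
#' `s_re(m,n)` is the mean of `guide` over the SE neighbourhood
#' intersected with the mask (the area erosion looks at); `s_rd(m,n)` the
#' mean over the neighbourhood intersected with the mask complement (the
#' area dilation grows into).  Where the intersection is empty the field
#' is `NA` and any condition on it evaluates to false.
#'
#' @param guide numeric matrix, typically the spectral [distance_map()].
#' @param mask logical matrix congruent with `guide`.
#' @param se binary structuring element.
#' @return list with matrices `s_re` and `s_rd`.
#' @export
local_means <- function(guide, mask, se = disk_se(5L)) {
  hs_assert(all(dim(guide) == dim(mask)), "hs_parameter_error",
            "guide and mask must be congruent")
  .se_check(mask, se)
  sel <- matrix(as.logical(se), nrow(se))
  list(s_re = .cpp_local_mean(guide, mask, sel, FALSE),
       s_rd = .cpp_local_mean(guide, mask, sel, TRUE))
}

#' Conditional erosion
#'
#' Classical erosion by the structuring element is applied at pixel
#' `(m, n)` only where `s_re(m,n) * (1 - p_we) > p_mn(m,n)`; elsewhere the
#' pixel keeps its input value.  The output is always a subset of the
#' input.  At `p_we = 1` the condition can never hold and the mask is
#' returned unchanged; at `p_we = 0`, `p_mn = 0` with a positive guide the
#' result is exactly classical erosion.
#'
#' @param mask logical matrix.
#' @param guide numeric matrix steering the condition (the deviation map).
#' @param spec a [cond_morph_spec()].
#' @return eroded logical matrix.
#' @export
conditional_erode <- function(mask, guide, spec) {
  .se_check(mask, spec$se)
  s_re <- .cpp_local_mean(guide, mask, spec$se, FALSE)
  cond <- !is.na(s_re) & s_re * (1 - spec$p_we) > .p_mn_field(spec$p_mn, mask)
  er <- .cpp_erode(mask, spec$se)
  out <- mask
  out[cond] <- er[cond]
  out
}

#' Conditional dilation
#'
#' Classical dilation is applied where `s_rd(m,n) * (1 + p_wd) >
#' p_mn(m,n)`; elsewhere the input value is kept.  The output always
#' contains the input.
#'
#' @inheritParams conditional_erode
#' @return dilated logical matrix.
#' @export
conditional_dilate <- function(mask, guide, spec) {
  .se_check(mask, spec$se)
  s_rd <- .cpp_local_mean(guide, mask, spec$se, TRUE)
  cond <- !is.na(s_rd) & s_rd * (1 + spec$p_wd) > .p_mn_field(spec$p_mn, mask)
  di <- .cpp_dilate(mask, spec$se)
  out <- mask
  out[cond] <- di[cond]
  out
}

#' Conditional refinement of a multi-class label map
#'
#' Each class mask is put through `iterations` conditional erosions and
#' dilations guided by its own deviation map, then the masks are
#' reassembled: pixels claimed by several classes go to the class of
#' minimal spectral deviation, and pixels claimed by none are likewise
#' assigned to their nearest class, so the refined map contains no
#' unclassified pixels.
#'
#' @param lm a [label_map()], e.g. from [multiclass_segment()].
#' @param guides named list of per-class [distance_map()]s covering every
#'   class of `lm`; defaults to the maps [multiclass_segment()] attached.
#' @param spec a [cond_morph_spec()].
#' @return the refined [label_map()] (no `distance_maps` attribute).
#' @export
refine_labels <- function(lm, guides = attr(lm, "distance_maps"), spec) {
  hs_assert(!is.null(guides) && all(lm$classes %in% names(guides)),
            "hs_config_error", "need one guide distance map per class")
  d <- dim(lm$labels)
  C <- length(lm$classes)
  masks <- vector("list", C)
  for (ci in seq_len(C)) {
    m <- lm$labels == ci
    g <- unclass(guides[[lm$classes[ci]]])
    if (spec$order == "sequential") {
      for (i in seq_len(spec$iterations)) m <- conditional_erode(m, g, spec)
      for (i in seq_len(spec$iterations)) m <- conditional_dilate(m, g, spec)
    } else {
      for (i in seq_len(spec$iterations)) {
        m <- conditional_erode(m, g, spec)
        m <- conditional_dilate(m, g, spec)
      }
    }
    masks[[ci]] <- m
  }
  dm <- vapply(lm$classes, function(cl) as.vector(unclass(guides[[cl]])),
               numeric(prod(d)))
  covered <- vapply(masks, as.vector, logical(prod(d)))
  cand <- dm
  cand[!covered] <- Inf
  lab <- max.col(-cand, ties.method = "first")
  none <- !matrixRowAny(covered)
  if (any(none)) lab[none] <- max.col(-dm[none, , drop = FALSE],
                                      ties.method = "first")
  label_map(matrix(lab, d[1], d[2]), lm$classes)
}

# rowAny without matrixStats
matrixRowAny <- function(m) rowSums(m) > 0
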