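#' Menger curvature of three points
#'
#' The Menger curvature of a point triple is the reciprocal of the
#' circumradius of the circle through the three points, equal to four times
#' the triangle area divided by the product of the three side lengths. It is
#' zero exactly for collinear triples, invariant under rigid motions, and
#' scales as `1/s` under uniform scaling by `s` — hence sequences are
#' normalised before knee detection (see [turning_point()]).
#'
#' @param p_prev,p,p_next Numeric length-2 `(x, y)` points.
#' @return Non-negative curvature (1 / circumradius units).
#' @examples
#' menger_curvature(c(1, 0), c(0, 1), c(-1, 0))  # unit circle -> 1
#' @export
menger_curvature <- function(p_prev, p, p_next) {
  pts <- rbind(p_prev, p, p_next)
  if (!is.numeric(pts) || ncol(pts) != 2 || any(!is.finite(pts))) {
    abort("Points must be finite numeric (x, y) pairs.",
          class = "flowabc_invalid_argument")
  }
  pq <- pts[2, ] - pts[1, ]
  qr <- pts[3, ] - pts[2, ]
  rp <- pts[1, ] - pts[3, ]
  a <- sqrt(sum(pq^2)); b <- sqrt(sum(qr^2)); c <- sqrt(sum(rp^2))
  if (a == 0 || b == 0 || c == 0) {
    abort("Coincident points have no defined curvature.",
          class = "flowabc_invalid_argument")
  }
  # 4 * area / (abc); the cross product gives twice the signed area
  cross <- pq[1] * qr[2] - pq[2] * qr[1]
  2 * abs(cross) / (a * b * c)
}

#' Turning point of a rising sequence
#'
#' Locates the convex turning point (knee) of an ordered `(rank, value)`
#' sequence as the interior point of maximal Menger curvature,
#' `D = max{DC(x_i), i = 2..n-1}`. Because curvature is scale-dependent and
#' rank units are incommensurable with expression units, both axes are
#' min-max normalised to \[0, 1\] first (set `normalize = FALSE` to work on
#' raw axes). Ties go to the smallest index. A perfectly linear sequence has
#' all-zero curvature and yields a no-turning-point result (`index = NA`).
#'
#' @param x A data frame with columns `rank` and `value`, or the numeric
#'   values themselves (ranks taken as `seq_along`).
#' @param normalize Min-max normalise both axes before computing curvature.
#' @param tol Curvatures at or below `tol` count as zero.
#' @return A `turning_point` object: `index` (position in the sequence, or
#'   `NA`), `curvature` (value at the index) and `curvatures`, a tibble of all
#'   interior-point curvatures.
#' @export
turning_point <- function(x, normalize = TRUE, tol = 1e-12) {
  if (is.data.frame(x)) {
    if (!all(c("rank", "value") %in% names(x))) {
      abort("`x` needs columns rank and value.", class = "flowabc_invalid_argument")
    }
    rank <- as.numeric(x$rank); value <- as.numeric(x$value)
  } else {
    value <- as.numeric(x); rank <- seq_along(value)
  }
  n <- length(value)
  if (n < 3) {
    abort("A turning point needs at least 3 points.",
          class = "flowabc_invalid_argument")
  }

  xs <- rank; ys <- value
  if (normalize) {
    norm01 <- function(v) {
      r <- range(v)
      if (r[1] == r[2]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
    }
    xs <- norm01(xs); ys <- norm01(ys)
  }

  idx <- 2:(n - 1)
  curv <- vapply(idx, function(i) {
    menger_curvature(c(xs[i - 1], ys[i - 1]), c(xs[i], ys[i]),
                     c(xs[i + 1], ys[i + 1]))
  }, numeric(1))

  curvatures <- tibble(index = idx, curvature = curv)
  if (all(curv <= tol)) {
    res <- list(index = NA_integer_, curvature = NA_real_,
                curvatures = curvatures, normalized = normalize)
  } else {
    best <- idx[which.max(curv)]            # which.max takes the first maximum
    res <- list(index = best, curvature = max(curv),
                curvatures = curvatures, normalized = normalize)
  }
  structure(res, class = "turning_point")
}

#' @export
print.turning_point <- function(x, ...) {
  if (is.na(x$index)) {
    cat("<turning_point> none (sequence has no convex knee)\n")
  } else {
    cat(sprintf("<turning_point> index %d (curvature %.4g%s)\n",
                x$index, x$curvature,
                if (x$normalized) ", normalised axes" else ""))
  }
  invisible(x)
}

#' @method tidy turning_point
#' @export
tidy.turning_point <- function(x, ...) x$curvatures
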