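# 3D spline curves fitted to ordered nodal points, with arc length by
# adaptive quadrature. Used for free edges, basal attachments and the
# projected perimeter contour.

#' Fit a 3D spline curve through ordered nodes and measure its length
#'
#' Fits a cubic spline per coordinate against the chord-length parameter.
#' With `smoothing = 0` the spline interpolates the nodes (natural cubic);
#' positive `smoothing` is passed to [stats::smooth.spline()] as `spar`.
#' Arc length is computed by adaptive quadrature of the speed.
#'
#' @param nodes ordered n x 3 matrix of points (um), n >= 4.
#' @param smoothing 0 for interpolation, or a `spar` value in (0, 1].
#' @param closed if `TRUE` the curve is periodic (first node is also the
#'   last); used for the projected valve perimeter contour.
#' @param role optional role tag (`"free_edge"`, `"basal_attachment"`,
#'   `"perimeter_contour"`, `"cross_section"`).
#' @return An object of class `curve3d` with fields `nodes`, `length` (um),
#'   `eval(t)` on the chord parameter, and `point_at(frac)` by arc length.
#' @export
fit_curve_and_length <- function(nodes, smoothing = 0, closed = FALSE,
                                 role = NULL) {
  nodes <- rbind3(nodes)
  if (closed && vec_norm(nodes[1, ] - nodes[nrow(nodes), ]) > 1e-9) {
    nodes <- rbind(nodes, nodes[1, , drop = FALSE])
  }
  if (nrow(nodes) < 4) {
    stop("insufficient data: need at least 4 nodes to fit a spline curve")
  }
  t <- polyline_cumlen(nodes)
  keep <- c(TRUE, diff(t) > 1e-9)
  nodes <- nodes[keep, , drop = FALSE]
  t <- t[keep]
  method <- if (closed) "periodic" else "natural"
  funs <- lapply(1:3, function(ax) {
    y <- nodes[, ax]
    if (smoothing > 0 && length(t) > 6) {
      ss <- smooth.spline(t, y, spar = smoothing)
      list(f = function(u) predict(ss, u)$y,
           df = function(u) predict(ss, u, deriv = 1)$y)
    } else {
      sf <- splinefun(t, y, method = method)
      list(f = function(u) sf(u), df = function(u) sf(u, deriv = 1))
    }
  })
  speed <- function(u) {
    sqrt(funs[[1]]$df(u)^2 + funs[[2]]$df(u)^2 + funs[[3]]$df(u)^2)
  }
  total_t <- t[length(t)]
  len <- integrate(speed, 0, total_t, rel.tol = 1e-9, subdivisions = 1000L,
                   stop.on.error = FALSE)$value
  eval_fun <- function(u) {
    cbind(funs[[1]]$f(u), funs[[2]]$f(u), funs[[3]]$f(u))
  }
  # arc-length reparametrization on a dense grid
  ug <- seq(0, total_t, length.out = 2001)
  al <- polyline_cumlen(eval_fun(ug))
  point_at <- function(frac) {
    u <- approx(al, ug, xout = frac * al[length(al)], ties = "ordered")$y
    drop(eval_fun(u))
  }
  structure(list(nodes = nodes, param = t, length = len, eval = eval_fun,
                 speed = speed, point_at = point_at, closed = closed,
                 role = role),
            class = "curve3d")
}

#' @export
print.curve3d <- function(x, ...) {
  cat(sprintf("<curve3d>%s %d nodes, length %.4g um%s\n",
              if (is.null(x$role)) "" else paste0(" [", x$role, "]"),
              nrow(x$nodes), x$length, if (x$closed) " (closed)" else ""))
  invisible(x)
}

#' Arc-length midpoint of a curve
#' @param curve a `curve3d`.
#' @return 3-vector (um).
#' @export
curve_midpoint <- function(curve) curve$point_at(0.5)
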