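polar_ellipse_r <- function(theta_deg, a, b, phi_deg) {
  d <- (theta_deg - phi_deg) * pi / 180
  a * b / sqrt(b^2 * cos(d)^2 + a^2 * sin(d)^2)
}

#' Fit a polar ellipse to per-angle metric values
#'
#' Models the variation of a VisR metric across imaging angles as an
#' origin-centred polar ellipse with 180-degree symmetry,
#' `r(theta) = a b / sqrt(b^2 cos^2(theta - phi) + a^2 sin^2(theta - phi))`,
#' by least squares with a multi-start over orientation.  The degree of
#' anisotropy (DoA) is the major/minor axis ratio `a / b >= 1`; `a >= b` is
#' enforced by axis swap and a 90-degree rotation of `phi`.  `r2` is
#' `1 - SS_res / SS_tot` over the supplied values; when all values are equal
#' (`SS_tot = 0`) the fit is degenerate and `r2` is reported as `NA`.
#'
#' @param angle_set A data frame with columns `angle_deg` and `value`
#'   (positive; ROI medians of one metric).  The protocol uses exactly the
#'   angles 0, 30, 60, 90; other angle sets are accepted but flagged
#'   `out_of_protocol`.
#' @param phi_starts Orientation starts, degrees.
#' @return An object of class `ellipse_fit` with `a`, `b`, `phi_deg` (in
#'   `[0, 180)`), `doa`, `r2`, `out_of_protocol` and the data.
#' @examples
#' df <- tibble::tibble(angle_deg = c(0, 30, 60, 90),
#'                      value = polar_ellipse_r(c(0, 30, 60, 90), 4, 2, 30))
#' fit_ellipse(df)$doa # 2
#' @export
fit_ellipse <- function(angle_set, phi_starts = seq(0, 165, by = 15)) {
  stopifnot(is.data.frame(angle_set),
            all(c("angle_deg", "value") %in% names(angle_set)))
  th <- angle_set$angle_deg
  v <- angle_set$value
  if (any(is.na(v)) || any(v <= 0)) {
    stop("all metric values must be present and positive", call. = FALSE)
  }
  if (length(v) < 4) stop("at least 4 angles are required", call. = FALSE)
  out_of_protocol <- !(length(th) == 4 && setequal(th, c(0, 30, 60, 90)))
  obj <- function(p) {
    r <- polar_ellipse_r(th, exp(p[1]), exp(p[2]), p[3])
    sum((v - r)^2)
  }
  best <- NULL
  for (phi0 in phi_starts) {
    for (init in list(c(log(max(v)), log(min(v)), phi0),
                      c(log(mean(v)), log(mean(v)), phi0))) {
      res <- tryCatch(
        optim(init, obj, method = "Nelder-Mead",
              control = list(reltol = 1e-14, maxit = 2000)),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value)) {
        best <- res
      }
    }
  }
  if (is.null(best)) stop("ellipse fit failed for all starts", call. = FALSE)
  a <- exp(best$par[1])
  b <- exp(best$par[2])
  phi <- best$par[3]
  if (b > a) { # enforce a >= b: swap axes, rotate orientation
    tmp <- a
    a <- b
    b <- tmp
    phi <- phi + 90
  }
  phi <- phi %% 180
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot < .Machine$double.eps^0.5 * sum(v^2)) {
    NA_real_ # degenerate: circle through equal values
  } else {
    1 - best$value / ss_tot
  }
  if (abs(a - b) < 1e-9 * a) phi <- 0 # tie-break for circles
  structure(list(a = a, b = b, phi_deg = phi, doa = a / b, r2 = r2,
                 sse = best$value, out_of_protocol = out_of_protocol,
                 data = tibble::tibble(angle_deg = th, value = v)),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("Polar ellipse fit: a = %.4g, b = %.4g, phi = %.1f deg, DoA = %.3f, R2 = %.3f\n",
              x$a, x$b, x$phi_deg, x$doa, x$r2))
  invisible(x)
}

#' @rdname fit_ellipse
#' @param x An `ellipse_fit` object.
#' @param ... Unused.
#' @export
tidy.ellipse_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "phi_deg"),
                 estimate = c(x$a, x$b, x$phi_deg))
}

#' @rdname fit_ellipse
#' @export
glance.ellipse_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, phi_deg = x$phi_deg, doa = x$doa,
                 r2 = x$r2, out_of_protocol = x$out_of_protocol)
}

#' @rdname fit_ellipse
#' @param object An `ellipse_fit` object.
#' @export
autoplot.ellipse_fit <- function(object, ...) {
  th <- seq(0, 360, by = 2)
  r <- polar_ellipse_r(th, object$a, object$b, object$phi_deg)
  curve <- tibble::tibble(x = r * cos(th * pi / 180),
                          y = r * sin(th * pi / 180))
  pts <- dplyr::bind_rows(
    object$data,
    dplyr::mutate(object$data, angle_deg = .data$angle_deg + 180))
  pts$x <- pts$value * cos(pts$angle_deg * pi / 180)
  pts$y <- pts$value * sin(pts$angle_deg * pi / 180)
  ggplot2::ggplot(curve, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = pts, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Degree-of-anisotropy table across a cohort
#'
#' Fits [fit_ellipse()] to the four per-angle ROI medians of each metric for
#' every subject and compression level, returning one row per
#' subject x metric x compression with the fitted axes, orientation, DoA
#' and R-squared.  Groups with missing or non-positive values are returned
#' with `NA` fits and flagged `missing`.
#'
#' @param scalars A tibble of per-acquisition scalar values with columns
#'   `subject_id`, `metric`, `compression_mm`, `angle_deg`, `value` (the
#'   per-acquisition ROI reduction, see [roi_reduce()]).
#' @return A tibble with columns `subject_id`, `metric`, `compression_mm`,
#'   `a`, `b`, `phi_deg`, `doa`, `r2`, `missing`.
#' @export
doa_table <- function(scalars) {
  stopifnot(all(c("subject_id", "metric", "compression_mm", "angle_deg",
                  "value") %in% names(scalars)))
  scalars |>
    dplyr::group_by(.data$subject_id, .data$metric, .data$compression_mm) |>
    dplyr::group_modify(function(df, key) {
      ok <- sum(!is.na(df$value) & df$value > 0) == 4
      if (!ok) {
        return(tibble::tibble(a = NA_real_, b = NA_real_, phi_deg = NA_real_,
                              doa = NA_real_, r2 = NA_real_, missing = TRUE))
      }
      g <- glance(fit_ellipse(df[, c("angle_deg", "value")]))
      tibble::tibble(a = g$a, b = g$b, phi_deg = g$phi_deg, doa = g$doa,
                     r2 = g$r2, missing = FALSE)
    }) |>
    dplyr::ungroup()
}
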