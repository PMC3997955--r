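#' Relative water content from weight triples
#'
#' `rwc()` computes `100 * (FW - DW) / (TW - DW)` for vectors of fresh,
#' turgid and dry weights. `compute_rwc()` is the data-frame interface: it
#' validates a water-content table and appends an `rwc` column.
#'
#' A turgid weight at or below the dry weight makes the ratio meaningless
#' and is an error (naming the offending plants in the data-frame
#' interface). A fresh weight outside `[DW, TW]` can arise from wiping and
#' weighing variance; it yields a value outside \[0, 100\] which is
#' returned with a warning rather than clipped, so that cell means stay
#' unbiased.
#'
#' @param fresh,turgid,dry Weight vectors (same units, typically g).
#' @return `rwc()`: a numeric vector of percentages.
#' @export
#' @examples
#' rwc(2, 3, 1)          # midpoint: 50
#' rwc(1.8, 2.0, 0.4)    # 87.5
rwc <- function(fresh, turgid, dry) {
  if (any(!is.finite(fresh) | !is.finite(turgid) | !is.finite(dry))) {
    stop("weights must be finite", call. = FALSE)
  }
  if (any(turgid <= dry)) {
    stop("turgid weight must exceed dry weight (TW > DW)", call. = FALSE)
  }
  if (any(fresh > turgid | fresh < dry)) {
    warning("fresh weight outside [dry, turgid] for ",
            sum(fresh > turgid | fresh < dry),
            " record(s); RWC outside [0, 100] returned unclipped",
            call. = FALSE)
  }
  100 * (fresh - dry) / (turgid - dry)
}

#' @rdname rwc
#' @param data A data frame with columns `fresh_weight`, `turgid_weight`,
#'   `dry_weight` (and ideally `cultivar`, `plant_id` for error messages).
#' @return `compute_rwc()`: `data` with an `rwc` column appended.
#' @export
compute_rwc <- function(data) {
  need <- c("fresh_weight", "turgid_weight", "dry_weight")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(data$turgid_weight <= data$dry_weight)
  if (length(bad)) {
    who <- if (all(c("cultivar", "plant_id") %in% names(data))) {
      paste0(data$cultivar[bad], "/plant ", data$plant_id[bad],
             collapse = ", ")
    } else paste("row", paste(bad, collapse = ", "))
    stop("turgid weight <= dry weight for: ", who, call. = FALSE)
  }
  dplyr::mutate(data, rwc = rwc(.data$fresh_weight, .data$turgid_weight,
                                .data$dry_weight))
}

#' Radar-chart layout for the drought-tolerant index
#'
#' The index is the area of a radar chart whose axes alternate the
#' percentage of non-withered plants during drought (D) and the percentage
#' of recovered plants during re-irrigation (R), one D/R pair per sampling
#' day: D1, R1, D3, R3, ..., D15, R15. With 8 sampling days there are 16
#' axes and the equal inner angle is 360/16 = 22.5 degrees.
#'
#' @param days Sampling-day grid (default the odd days 1 to 15).
#' @return A `radar_layout`: list with `days`, `n_axes`, `alpha_deg` and
#'   the axis `ordering` labels.
#' @export
#' @examples
#' radar_layout()
radar_layout <- function(days = seq(1, 15, by = 2)) {
  days <- sort(unique(as.numeric(days)))
  n_axes <- 2L * length(days)
  if (n_axes < 6L) stop("need at least 3 sampling days", call. = FALSE)
  structure(
    list(days = days,
         n_axes = n_axes,
         alpha_deg = 360 / n_axes,
         ordering = as.vector(rbind(paste0("D", days), paste0("R", days)))),
    class = "radar_layout"
  )
}

#' @export
print.radar_layout <- function(x, ...) {
  cat("<radar_layout> ", x$n_axes, " axes, alpha = ", x$alpha_deg,
      " degrees\n  ", paste(x$ordering, collapse = " "), "\n", sep = "")
  invisible(x)
}

check_axes <- function(axes, layout) {
  if (length(axes) != layout$n_axes) {
    stop("expected ", layout$n_axes, " axis values, got ", length(axes),
         call. = FALSE)
  }
  if (any(!is.finite(axes))) stop("axis values must be finite", call. = FALSE)
  if (any(axes < 0)) stop("axis values must be non-negative", call. = FALSE)
  invisible(axes)
}

#' Radar area from a vector of axis values
#'
#' The axis-level core of [compute_dti()]: the polygon area as the sum of
#' the triangle fans between circularly adjacent axes,
#' `1/2 sin(alpha) * sum_k a_k a_{k+1}` (indices mod the axis count).
#'
#' @param axes Numeric vector of non-negative axis values in layout order
#'   (D1, R1, D3, R3, ...).
#' @param layout A [radar_layout()].
#' @return The polygon area.
#' @export
#' @examples
#' dti_area(rep(100, 16))   # maximal polygon: 8 sin(22.5 deg) 1e4
dti_area <- function(axes, layout = radar_layout()) {
  check_axes(axes, layout)
  alpha <- layout$alpha_deg * pi / 180
  0.5 * sin(alpha) * sum(axes * c(axes[-1], axes[1]))
}

#' Independent polygon-area oracle for the radar chart
#'
#' Places vertex k of the radar polygon at polar coordinates
#' (radius = axis value k, angle = k * alpha), converts to Cartesian and
#' applies the shoelace formula. Algebraically identical to the
#' triangle-fan formula used by [compute_dti()]; implemented independently
#' so the two can cross-check each other.
#'
#' @param axes Numeric vector of non-negative axis values in layout order.
#' @param layout A [radar_layout()].
#' @return The polygon area (percent-squared units for percentage axes).
#' @export
#' @examples
#' radar_polygon_area(rep(100, 16))      # regular 16-gon: 8 sin(22.5deg) 1e4
radar_polygon_area <- function(axes, layout = radar_layout()) {
  check_axes(axes, layout)
  theta <- (seq_along(axes) - 1) * layout$alpha_deg * pi / 180
  x <- axes * cos(theta)
  y <- axes * sin(theta)
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Drought-tolerant index from wilting/recovery time courses
#'
#' Computes, per cultivar, the area of the radar polygon whose axes are the
#' interleaved non-withered and recovered percentages:
#' \deqn{DTI = \tfrac{1}{2}\sin\alpha\,(D_1R_1 + R_1D_3 + D_3R_3 + \cdots +
#'   D_{15}R_{15} + R_{15}D_1)}
#' with \eqn{\alpha} the equal inner angle of the chart (22.5 degrees for
#' 16 axes). The polygon is closed by the final \eqn{R_{15} D_1} term. The
#' index does not require the curves to be monotone; any non-negative
#' percentages are accepted.
#'
#' Alongside the raw area (in %^2, of order 10^4), a normalized index
#' `dti_norm` in \[0, 1\] divides by the maximal polygon — all axes at
#' 100% — for a scale-free tolerance score.
#'
#' @param timecourses A data frame in long form with columns `cultivar`,
#'   `day`, `d_pct`, `r_pct`, one row per cultivar x day, days matching the
#'   layout grid.
#' @param layout A [radar_layout()].
#' @return A tibble with one row per cultivar: `cultivar`, `dti`,
#'   `dti_norm`, and an `axes` list-column holding the 16-vector in chart
#'   order.
#' @export
#' @examples
#' tc <- simulate_timecourses(example_panel(n = 3, seed = 2))
#' compute_dti(tc)
compute_dti <- function(timecourses, layout = radar_layout()) {
  need <- c("cultivar", "day", "d_pct", "r_pct")
  miss <- setdiff(need, names(timecourses))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  max_area <- (layout$n_axes / 2) * sin(layout$alpha_deg * pi / 180) * 100^2
  timecourses |>
    dplyr::group_by(.data$cultivar) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$day)
      if (!identical(as.numeric(df$day), layout$days)) {
        stop("cultivar ", key$cultivar, ": days do not match the layout grid (",
             paste(layout$days, collapse = ", "), ")", call. = FALSE)
      }
      axes <- as.vector(rbind(df$d_pct, df$r_pct))
      area <- dti_area(axes, layout)
      tibble::tibble(dti = area, dti_norm = area / max_area,
                     axes = list(stats::setNames(axes, layout$ordering)))
    }) |>
    dplyr::ungroup()
}

#' Rank cultivars by drought-tolerant index
#'
#' Orders cultivars by descending DTI. Tied values share the minimum rank;
#' within ties the rows are ordered by cultivar label so output is
#' deterministic.
#'
#' @param dti_table A data frame with columns `cultivar` and `dti`, e.g.
#'   from [compute_dti()].
#' @return The input ordered by descending `dti` with a `rank` column.
#' @export
#' @examples
#' rank_cultivars(tibble::tibble(cultivar = c("A", "B", "C"),
#'                               dti = c(5, 3, 5)))
rank_cultivars <- function(dti_table) {
  need <- c("cultivar", "dti")
  miss <- setdiff(need, names(dti_table))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(dti_table) < 1) stop("no cultivars to rank", call. = FALSE)
  if (anyDuplicated(dti_table$cultivar)) {
    stop("duplicate cultivar labels", call. = FALSE)
  }
  dti_table |>
    dplyr::mutate(rank = dplyr::min_rank(dplyr::desc(.data$dti))) |>
    dplyr::arrange(dplyr::desc(.data$dti), .data$cultivar)
}
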