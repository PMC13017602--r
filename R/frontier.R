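## Efficiency frontier analysis.
##
## A strategy point is (colonoscopies per 1000, QALYs gained per 1000).
## The frontier is the upper-left concave hull: the strategies yielding
## the most QALYs for a given colonoscopy demand, with non-increasing
## marginal returns.  Near-efficient strategies fall within a vertical
## tolerance below the piecewise-linear frontier (default 1.5
## quality-adjusted months per 1000, i.e. 0.125 QALYs per 1000); the
## strict hull is the default labelling, the tolerance only widens the
## reported frontier band.

#' Identify efficient and near-efficient strategies
#'
#' Flags, for each strategy point: `dominated` (another point needs no
#' more colonoscopies and gains at least as many QALYs, one comparison
#' strict), `on_hull` (vertex of the upper-left concave hull; collinear
#' points on a frontier segment count as vertices; of several points with
#' equal colonoscopy demand only the highest-QALY one is a hull
#' candidate), and `near_efficient` (vertical distance to the
#' interpolated hull at most `tolerance`; beyond the last vertex the
#' hull extends flat).
#'
#' @param points `data.frame`/`data.table` with columns
#'   `colonoscopies_per_1000` and `qalys_gained_per_1000` (a `label`
#'   column is carried through; row order is preserved).
#' @param tolerance near-efficiency band in QALYs per 1000
#'   (default `1.5 / 12`).
#' @return a `crc_frontier`: list with `points` (the input plus
#'   `dominated`, `on_hull`, `near_efficient`, `hull_qalys`), `hull` (the
#'   hull vertices in order), `tolerance`.
#' @examples
#' fr <- find_frontier(reference_outcomes())
#' sum(fr$points$on_hull)
#' @export
find_frontier <- function(points, tolerance = 1.5 / 12) {
  pts <- data.table::as.data.table(points)
  if (!nrow(pts)) stop("no strategy points")
  x <- pts$colonoscopies_per_1000
  y <- pts$qalys_gained_per_1000
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("coordinates must be finite")
  }
  n <- length(x)

  dominated <- vapply(seq_len(n), function(i) {
    any(x <= x[i] & y >= y[i] & (x < x[i] | y > y[i]))
  }, logical(1))

  ## hull over the best point at each distinct colonoscopy level
  cand <- which(!dominated)
  cand <- cand[order(x[cand], -y[cand])]
  cand <- cand[!duplicated(x[cand])]
  hull <- integer()
  for (i in cand) {
    while (length(hull) >= 2L) {
      a <- hull[length(hull) - 1L]
      b <- hull[length(hull)]
      ## drop b when strictly below the chord a -> i (keep collinear)
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross > 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  on_hull <- logical(n)
  on_hull[hull] <- TRUE
  ## a point coinciding exactly with a hull vertex is itself efficient
  key <- paste(x, y)
  on_hull <- on_hull | key %in% key[hull]

  hull_q <- .hull_interp(x, x[hull], y[hull])
  near <- (hull_q - y) <= tolerance + 1e-12

  pts[, "dominated" := dominated]
  pts[, "on_hull" := on_hull]
  pts[, "near_efficient" := near]
  pts[, "hull_qalys" := hull_q]
  structure(list(points = pts,
                 hull = pts[hull, ],
                 tolerance = tolerance),
            class = "crc_frontier")
}

## piecewise-linear hull value at arbitrary budgets; flat beyond the last
## vertex, NA below the first
.hull_interp <- function(budget, hx, hy) {
  if (length(hx) == 1L) {
    out <- rep(hy, length(budget))
    out[budget < hx] <- NA_real_
    return(out)
  }
  out <- stats::approx(hx, hy, xout = pmin(budget, max(hx)),
                       rule = 2, ties = "ordered")$y
  out[budget < min(hx)] <- NA_real_
  out
}

#' Interpolated frontier value at a colonoscopy budget
#'
#' @param fr a `crc_frontier` from [find_frontier()].
#' @param budget colonoscopies per 1000 (at least the cheapest efficient
#'   strategy's demand).
#' @return QALYs gained per 1000 attainable on the frontier at that
#'   budget (linear interpolation; constant beyond the last vertex).
#' @export
frontier_value_at <- function(fr, budget) {
  hx <- fr$hull$colonoscopies_per_1000
  if (any(budget < min(hx))) {
    stop("budget below the cheapest frontier strategy")
  }
  .hull_interp(budget, hx, fr$hull$qalys_gained_per_1000)
}

#' Compare a strategy to a reference strategy
#'
#' @param outcomes an outcome table with `strategy_label` (or `label`),
#'   `colonoscopies_per_1000`, `qalys_gained_per_1000`.
#' @param strategy_label,reference_label labels present in the table.
#' @return one-row `data.table` with the signed percent changes
#'   `qalys_pct` and `colonoscopies_pct` of strategy versus reference
#'   (one decimal).
#' @examples
#' compare_to_reference(reference_outcomes(), "Age_54", "COL_only")
#' @export
compare_to_reference <- function(outcomes, strategy_label,
                                 reference_label) {
  out <- data.table::as.data.table(outcomes)
  lab <- if ("strategy_label" %in% names(out)) out$strategy_label else
    out$label
  i <- match(strategy_label, lab)
  j <- match(reference_label, lab)
  if (is.na(i) || is.na(j)) {
    stop("label not found: ",
         paste(c(strategy_label, reference_label)[c(is.na(i), is.na(j))],
               collapse = ", "))
  }
  data.table::data.table(
    strategy = strategy_label, reference = reference_label,
    qalys_pct = percent_change(out$qalys_gained_per_1000[i],
                               out$qalys_gained_per_1000[j]),
    colonoscopies_pct = percent_change(out$colonoscopies_per_1000[i],
                                       out$colonoscopies_per_1000[j]))
}

#' Published 34-strategy reference outcome table
#'
#' Outcomes (colonoscopies and QALYs gained per 1000 screen-eligible
#' 50-year-olds, and the printed efficiency label) of the 34 efficient-
#' per-family strategies reported by a published Swiss microsimulation
#' analysis of FIT/colonoscopy guidance.  Bundled as a validation fixture
#' for the frontier and comparison tools; the simulation engine's own
#' synthetic calibration does not reproduce these absolute values.
#'
#' @return `data.table` with `strategy_type`, `label`,
#'   `colonoscopies_per_1000`, `qalys_gained_per_1000`, `efficient`.
#' @export
reference_outcomes <- function() {
  data.table::fread(system.file("extdata", "reference_outcomes_34.csv",
                                package = "crcscreen", mustWork = TRUE))
}

#' Plot strategy points and the efficiency frontier
#'
#' @param fr a `crc_frontier`.
#' @param label_hull label hull vertices (requires a `label` column).
#' @return a `ggplot` object.
#' @export
plot_frontier <- function(fr, label_hull = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  pts <- fr$points
  g <- ggplot2::ggplot(pts, ggplot2::aes(
    x = .data$colonoscopies_per_1000, y = .data$qalys_gained_per_1000)) +
    ggplot2::geom_line(data = fr$hull, colour = "black") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$on_hull)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black",
                                            `FALSE` = "grey60"),
                                 name = "efficient") +
    ggplot2::labs(x = "Colonoscopies per 1000",
                  y = "QALYs gained per 1000")
  lab <- intersect(c("label", "strategy_label"), names(pts))
  if (label_hull && length(lab)) {
    g <- g + ggplot2::geom_text(
      data = fr$hull, ggplot2::aes(label = .data[[lab[1]]]),
      vjust = -0.8, size = 2.6)
  }
  g
}
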