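# Aggregation of per-point fields: per-leaf histograms, per-region
# (centroid / left edge / right edge) summaries, day-indexed time series
# and between-day significance tests.

.quantities <- c("chlorophyll", "zenith", "azimuth")

#' Locate the centroid, left-edge and right-edge regions of a leaf
#'
#' Anchors: the labeled point nearest the leaf's mean position (centroid),
#' and the labeled points at minimum / maximum projection on the leaf's
#' second principal axis — the in-plane axis orthogonal to the leaf's long
#' axis, so "left" and "right" are across the blade (ties broken by lowest
#' point index; the axis sign is fixed so its largest-magnitude component
#' is positive, making the left/right assignment deterministic). Each
#' region pools the labeled points within `radius` cm of its anchor.
#'
#' @param cloud a [point_cloud()] with leaf labels.
#' @param leaf_label integer label with >= 3 points.
#' @param radius pooling radius in cm (default 0.25).
#' @return named list of three `leaf_region` objects (`centroid`,
#'   `left_edge`, `right_edge`), each with `leaf_label`, `region`,
#'   `anchor_index`, `point_indices`, `radius`.
#' @export
locate_regions <- function(cloud, leaf_label, radius = 0.25) {
  stopifnot(inherits(cloud, "point_cloud"), radius > 0)
  if (is.null(cloud$leaf_labels)) stop("cloud has no leaf labels")
  idx <- which(cloud$leaf_labels == leaf_label)
  if (length(idx) == 0) {
    stop_phyto("leaf label %d absent from the cloud", leaf_label,
               class = "unknown_label_error")
  }
  if (length(idx) < 3) stop("need at least 3 points with the label")
  pts <- cloud$points[idx, , drop = FALSE]
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  if (max(abs(x)) < 1e-12) {
    stop_phyto("degenerate leaf %d: all points coincident", leaf_label,
               class = "degenerate_leaf_error")
  }
  e <- eigen(crossprod(x), symmetric = TRUE)
  ax2 <- e$vectors[, 2]                      # across-blade axis
  big <- which.max(abs(ax2))
  if (ax2[big] < 0) ax2 <- -ax2
  proj <- as.vector(x %*% ax2)
  d2 <- rowSums(x^2)
  anchor <- c(centroid = idx[which.min(d2)],
              left_edge = idx[which.min(proj)],
              right_edge = idx[which.max(proj)])
  lapply(stats::setNames(names(anchor), names(anchor)), function(reg) {
    a <- cloud$points[anchor[[reg]], ]
    dd <- sqrt(rowSums(sweep(pts, 2, a)^2))
    structure(list(leaf_label = as.integer(leaf_label), region = reg,
                   anchor_index = anchor[[reg]],
                   point_indices = idx[dd <= radius], radius = radius),
              class = "leaf_region")
  })
}

# Per-quantity summary of a vector of per-point values; azimuth statistics
# are circular (vector mean, sqrt(-2 log R) spread).
.summarize_quantity <- function(values, quantity) {
  v <- values[!is.na(values)]
  if (length(v) == 0) return(NULL)
  if (quantity == "azimuth") {
    data.frame(mean = circular_mean(v), sd = circular_sd(v), n = length(v))
  } else {
    data.frame(mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v))
  }
}

#' Per-leaf histogram of a quantity
#'
#' Fixed-width bins spanning the valid (non-`NA`) values of the quantity
#' over the leaf's points; the mean is over valid points only, and circular
#' for azimuth. Field defaults follow common practice for these
#' distributions: 5 degree bins for angles, 1 unit for chlorophyll.
#'
#' @param cloud a [point_cloud()] with leaf labels and the quantity mapped
#'   as an attribute.
#' @param leaf_label integer leaf id.
#' @param quantity one of `"chlorophyll"`, `"zenith"`, `"azimuth"`, or any
#'   attribute name.
#' @param bin_width bin width in the quantity's units; default 5 for
#'   angles, 1 otherwise.
#' @return an object of class `histogram_summary`: `quantity`,
#'   `bin_edges`, `counts` (summing to `n`), `mean`, `n`.
#' @export
leaf_histogram <- function(cloud, leaf_label, quantity,
                           bin_width = if (quantity %in% c("zenith", "azimuth")) 5 else 1) {
  stopifnot(bin_width > 0)
  vals <- cloud_attr(cloud, quantity)
  if (is.null(vals)) stop_phyto("cloud has no attribute '%s'", quantity,
                                class = "missing_attribute_error")
  if (is.null(cloud$leaf_labels)) stop("cloud has no leaf labels")
  v <- vals[cloud$leaf_labels == leaf_label]
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    stop_phyto("no valid '%s' values for leaf %d", quantity, leaf_label,
               class = "empty_histogram_error")
  }
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  m <- if (quantity == "azimuth") circular_mean(v) else mean(v)
  structure(list(quantity = quantity, bin_edges = edges, counts = counts,
                 mean = m, n = length(v)),
            class = "histogram_summary")
}

#' @export
print.histogram_summary <- function(x, ...) {
  cat(sprintf("<histogram_summary> %s: n=%d, mean=%.3f, %d bins [%g, %g]\n",
              x$quantity, x$n, x$mean, length(x$counts),
              min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Histogram as a tidy data frame
#' @param h a `histogram_summary`.
#' @return data frame with `bin_lo`, `bin_hi`, `count`.
#' @export
histogram_df <- function(h) {
  k <- length(h$counts)
  data.frame(bin_lo = h$bin_edges[seq_len(k)],
             bin_hi = h$bin_edges[seq_len(k) + 1],
             count = h$counts)
}

#' Day-indexed per-leaf per-region time series
#'
#' For each day's processed cloud (chlorophyll and angles already mapped),
#' locates the three regions of every requested leaf and summarizes each
#' quantity over the region's valid points. Days are reported sorted; a
#' leaf or region absent on some day is a gap in the output (no row), never
#' a zero. Azimuth means are circular.
#'
#' @param clouds list of processed clouds, one per day.
#' @param days integer day indices (>= 1), parallel to `clouds`; defaults
#'   to `1, 2, ...`.
#' @param leaf_labels leaves to track; default: every nonzero label present
#'   on day 1.
#' @param radius region pooling radius in cm.
#' @param quantities attribute names to summarize.
#' @return data frame with columns `day`, `leaf`, `region`, `quantity`,
#'   `mean`, `sd`, `n`.
#' @export
build_series <- function(clouds, days = seq_along(clouds),
                         leaf_labels = NULL, radius = 0.25,
                         quantities = .quantities) {
  if (length(clouds) == 0) stop("no input clouds")
  stopifnot(length(days) == length(clouds), all(days >= 1))
  ord <- order(days)
  clouds <- clouds[ord]
  days <- days[ord]
  if (is.null(leaf_labels)) {
    labs <- clouds[[1]]$leaf_labels
    if (is.null(labs)) stop("clouds carry no leaf labels")
    leaf_labels <- sort(unique(labs[labs != 0L]))
  }
  rows <- list()
  for (di in seq_along(clouds)) {
    cl <- clouds[[di]]
    for (lab in leaf_labels) {
      regs <- tryCatch(locate_regions(cl, lab, radius),
                       unknown_label_error = function(e) NULL)
      if (is.null(regs)) next                # leaf absent this day: gap
      for (reg in regs) {
        for (q in quantities) {
          vals <- cloud_attr(cl, q)
          if (is.null(vals)) next
          s <- .summarize_quantity(vals[reg$point_indices], q)
          if (is.null(s)) next               # no valid points: gap
          rows[[length(rows) + 1L]] <-
            cbind(data.frame(day = days[di], leaf = lab,
                             region = reg$region, quantity = q), s)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(day = integer(), leaf = integer(),
                      region = character(), quantity = character(),
                      mean = numeric(), sd = numeric(), n = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-day omnibus test of a per-point quantity
#'
#' Kruskal-Wallis rank test of whether the per-point distributions differ
#' across days; chosen over one-way ANOVA because per-point angle and
#' chlorophyll distributions are bounded and typically non-normal. A Welch
#' ANOVA alternative is available via `method = "welch"`. Note that
#' per-point values within a leaf are spatially autocorrelated, so these
#' p-values are descriptive summaries of separation, not independent-sample
#' inference.
#'
#' @param values_by_day named list of numeric vectors, one per day, each
#'   with >= 2 valid values.
#' @param method `"kruskal"` (default) or `"welch"`.
#' @return list with `statistic` (Kruskal-Wallis H, or Welch F), `df`,
#'   `p_value`, `method`.
#' @export
compare_days <- function(values_by_day, method = c("kruskal", "welch")) {
  method <- match.arg(method)
  if (length(values_by_day) < 2) stop("need at least 2 days")
  values_by_day <- lapply(values_by_day, function(v) v[!is.na(v)])
  sizes <- lengths(values_by_day)
  if (any(sizes < 2)) {
    nm <- names(values_by_day)
    if (is.null(nm)) nm <- as.character(seq_along(values_by_day))
    stop_phyto("day '%s' has fewer than 2 valid values",
               nm[which(sizes < 2)[1]], class = "underpowered_day_error")
  }
  if (method == "kruskal") {
    kt <- stats::kruskal.test(values_by_day)
    list(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, method = "kruskal")
  } else {
    g <- factor(rep(seq_along(values_by_day), sizes))
    ow <- stats::oneway.test(unlist(values_by_day) ~ g, var.equal = FALSE)
    list(statistic = unname(ow$statistic),
         df = unname(ow$parameter), p_value = ow$p.value, method = "welch")
  }
}
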