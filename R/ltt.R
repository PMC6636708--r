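#' Lineages-through-time step functions
#'
#' An `ltt_series` records the number of lineages of a dated phylogeny in
#' force at each moment, as a right-continuous-toward-the-present step
#' function on the years-BP axis: `times` is a strictly decreasing vector of
#' event times, `counts[i]` is the number of lineages from `times[i]`
#' (inclusive) until the next event, and the last segment extends to the
#' present, t = 0.  Before the first event the series is 0 — a family
#' contributes no lineages before its root.
#'
#' @param times strictly decreasing event times, years BP.
#' @param counts positive lineage counts, one per event time.
#' @param label series label (family name, or `"sum"`).
#' @return An object of class `"ltt_series"`.
#' @export
ltt_series <- function(times, counts, label = NA_character_) {
  if (length(times) != length(counts) || !length(times))
    stop("`times` and `counts` must be non-empty and of equal length",
         call. = FALSE)
  if (any(diff(times) >= 0))
    stop("`times` must be strictly decreasing (years BP)", call. = FALSE)
  if (any(counts <= 0))
    stop("`counts` must be positive", call. = FALSE)
  if (any(times < 0))
    stop("event times must be >= 0 years BP", call. = FALSE)
  structure(list(times = as.numeric(times), counts = as.numeric(counts),
                 label = as.character(label)),
            class = "ltt_series")
}

#' @export
print.ltt_series <- function(x, ...) {
  cat(sprintf("LTT series%s: %d events, %.6g yr BP -> present, N = %g .. %g\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              length(x$times), x$times[1L], x$counts[1L],
              x$counts[length(x$counts)]))
  invisible(x)
}

#' Evaluate an LTT step function
#'
#' @param series an [ltt_series].
#' @param t numeric vector of times, years BP.
#' @return Lineage count in force at each `t`; 0 before the first event.
#' @export
ltt_at <- function(series, t) {
  # times are decreasing; value at t is the count of the youngest event >= t
  idx <- length(series$times) -
    findInterval(t, rev(series$times), left.open = TRUE)
  out <- numeric(length(t))
  ok <- idx >= 1L
  out[ok] <- series$counts[idx[ok]]
  out
}

#' Build the lineages-through-time series of a dated tree
#'
#' Counts the branches of the phylogeny crossing each time point.  The
#' series starts at the crown root with count equal to the root's degree
#' (2 for a bifurcating root, k for a root polytomy) and ends at the
#' present with the extant tip count.  Simultaneous splits merge into a
#' single step so the function stays single-valued.
#'
#' @param tree a [dated_tree] (or `phylo`) pruned to extant tips.
#' @param label series label; defaults to the tree's family name.
#' @return An [ltt_series].
#' @examples
#' compute_ltt(read_newick("((A:1,B:1):1,C:2);")[[1]])
#' @export
compute_ltt <- function(tree, label = family_name(tree)) {
  n <- ape::Ntip(tree)
  if (n == 1L) {
    warning("single-tip tree: constant LTT with one lineage", call. = FALSE)
    return(ltt_series(root_age(tree), 1, label = label))
  }
  ages <- node_ages(tree)
  internal <- (n + 1L):(n + tree$Nnode)
  degree <- tabulate(tree$edge[, 1L], nbins = n + tree$Nnode)[internal]
  ev <- data.frame(age = ages[internal], add = degree - 1L)
  ev <- stats::aggregate(add ~ age, data = ev, FUN = sum)   # merge ties
  ev <- ev[order(-ev$age), , drop = FALSE]
  counts <- 1 + cumsum(ev$add)
  ltt_series(ev$age, counts, label = label)
}

#' Sum LTT series on the absolute time axis
#'
#' Aligns the series by absolute years BP and adds lineage counts pointwise;
#' a family contributes 0 lineages before its own root age (no stem lineage
#' is imputed for times older than the crown).  Summation is associative and
#' commutative.
#'
#' @param series a list of [ltt_series].
#' @param label label of the summed series.
#' @return An [ltt_series] whose event times are the union of the inputs'.
#' @export
sum_ltt <- function(series, label = "sum") {
  if (!length(series)) stop("empty list of LTT series", call. = FALSE)
  if (inherits(series, "ltt_series")) series <- list(series)
  times <- sort(unique(unlist(lapply(series, `[[`, "times"))),
                decreasing = TRUE)
  counts <- Reduce(`+`, lapply(series, ltt_at, t = times))
  keep <- counts > 0
  ltt_series(times[keep], counts[keep], label = label)
}

# exact integral of the step function over [a, b] (years BP, a < b)
integrate_step <- function(series, a, b) {
  stopifnot(a <= b)
  brks <- c(b, series$times[series$times > a & series$times < b], a)
  brks <- sort(unique(pmin(pmax(brks, a), b)), decreasing = TRUE)
  if (length(brks) < 2L) return(0)
  hi <- brks[-length(brks)]
  lo <- brks[-1L]
  mid <- (hi + lo) / 2
  sum(ltt_at(series, mid) * (hi - lo))
}

#' Average lineage counts over fixed-width time bins
#'
#' Computes the time-weighted mean of the LTT step function over consecutive
#' bins (default 1,000-year "millennial" bins) running from the oldest event
#' down to the present.  Intervals older than the series' first event count
#' as zero lineages; bins lying entirely before the first event are omitted.
#'
#' @param series an [ltt_series].
#' @param bin_width bin width in years (> 0).
#' @return A data frame with columns `mid_bp` (bin midpoint, years BP) and
#'   `mean_n` (time-weighted mean lineage count).
#' @export
millennial_series <- function(series, bin_width = 1000) {
  if (bin_width <= 0) stop("`bin_width` must be > 0", call. = FALSE)
  top <- ceiling(series$times[1L] / bin_width) * bin_width
  edges <- seq(top, 0, by = -bin_width)
  if (edges[length(edges)] > 0) edges <- c(edges, 0)
  hi <- edges[-length(edges)]
  lo <- edges[-1L]
  mean_n <- mapply(function(h, l) integrate_step(series, l, h) / (h - l),
                   hi, lo)
  keep <- lo < series$times[1L]   # drop bins wholly before the root
  data.frame(mid_bp = (hi + lo)[keep] / 2, mean_n = mean_n[keep])
}

#' Overall semi-log diversification rate of an LTT series
#'
#' Ordinary least squares of `ln N` on elapsed time since the first event.
#' With `at = "events"` (default) the regression uses one point per step of
#' the series; `at = "annual"` evaluates the step function on a 1-year grid
#' instead.  The slope estimates the net diversification rate r in yr^-1.
#'
#' @param series an [ltt_series] with at least 3 events.
#' @param at regression point set: `"events"` or `"annual"`.
#' @return A list with `slope` (yr^-1), `intercept`, `r_squared`,
#'   `f_statistic`, `df`, `p_value`, `n_points`, and `constant` (TRUE when
#'   all counts are equal, in which case the slope is 0 and the remaining
#'   diagnostics are undefined).
#' @export
global_rate <- function(series, at = c("events", "annual")) {
  at <- match.arg(at)
  if (length(series$times) < 3L)
    stop("need >= 3 events to fit a global rate", call. = FALSE)
  if (at == "events") {
    x <- series$times[1L] - series$times
    y <- log(series$counts)
  } else {
    grid <- seq(floor(series$times[1L]), 0, by = -1)
    x <- series$times[1L] - grid
    y <- log(ltt_at(series, grid))
  }
  if (length(unique(series$counts)) == 1L) {
    return(list(slope = 0, intercept = log(series$counts[1L]),
                r_squared = NA_real_, f_statistic = NA_real_,
                df = c(1L, length(x) - 2L), p_value = NA_real_,
                n_points = length(x), constant = TRUE))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       f_statistic = unname(sm$fstatistic[1L]),
       df = unname(sm$fstatistic[2:3]),
       p_value = stats::pf(sm$fstatistic[1L], sm$fstatistic[2L],
                           sm$fstatistic[3L], lower.tail = FALSE),
       n_points = length(x), constant = FALSE)
}

#' Write LTT series to TSV
#'
#' Columns `time_bp`, `n_lineages`, `label`, one row per step.
#'
#' @param series an [ltt_series].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ltt_tsv <- function(series, path) {
  df <- data.frame(time_bp = series$times, n_lineages = series$counts,
                   label = series$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
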