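#' Overall net diversification rate
#'
#' Under exponential growth N(t) = N0 e^{rt} from a single ancestor, the net
#' rate implied by a clade of `n_max` extant members after `root_age` years
#' is r = ln(n_max) / root_age (yr^-1).  A monotypic clade gives r = 0.
#'
#' @param n_max extant member count (>= 1); vectorized.
#' @param root_age clade age in years (> 0); vectorized.
#' @return Net diversification rate(s), yr^-1.
#' @examples
#' overall_rate(5, 5500)     # ~0.00029
#' overall_rate(1268, 5230)  # ~0.00137
#' @export
overall_rate <- function(n_max, root_age) {
  if (any(n_max < 1, na.rm = TRUE))
    stop("`n_max` must be >= 1", call. = FALSE)
  if (any(root_age <= 0, na.rm = TRUE))
    stop("`root_age` must be > 0", call. = FALSE)
  log(n_max) / root_age
}

#' Doubling time of a diversification rate
#'
#' t2 = ln(2) / r: the number of years for the clade to double in size at
#' net rate r.
#'
#' @param r_e net diversification rate, yr^-1 (> 0); vectorized.
#' @return Doubling time(s) in years.
#' @examples
#' doubling_time(0.00029)  # ~2390
#' @export
doubling_time <- function(r_e) {
  if (any(r_e <= 0, na.rm = TRUE))
    stop("`r_e` must be > 0 for a finite doubling time", call. = FALSE)
  log(2) / r_e
}

#' Load the packaged family summary table
#'
#' Eighteen language families with extant-language counts from the
#' Ethnologue and Glottolog catalogs, sample sizes of the available
#' phylogenies (where one exists; four trees include dialects), root ages in
#' years, and — for replication tests — the rate and doubling-time values as
#' printed in the source study.  Note the Dravidian row is internally
#' inconsistent in the source (its printed rate does not follow from its
#' printed count and root age); the row is shipped verbatim and flagged by
#' `consistent = FALSE`.
#'
#' @param path optional path to an alternative TSV with the same columns.
#' @return A data frame, one row per family.
#' @export
family_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1.tsv", package = "lingdiv",
                        mustWork = TRUE)
  df <- utils::read.delim(path, na.strings = "NA",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("family", "n_ethnologue", "n_glottolog", "root_age_yr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("family table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if ("r_ethno_printed" %in% names(df)) {
    recomputed <- overall_rate(df$n_ethnologue, df$root_age_yr)
    df$consistent <- abs(recomputed - df$r_ethno_printed) < 5e-5
  }
  df
}

#' Rate table: one estimate per family and catalog
#'
#' Applies [overall_rate()] and [doubling_time()] to each family for each
#' available catalog count.  For replication of printed tables the default
#' convention (`"rounded"`) first rounds the rate to 5 decimal places and
#' then rounds ln(2)/rate to whole years; `"raw"` uses the unrounded rate.
#' Families missing both catalog counts are skipped with a warning.  The
#' result is sorted ascending by each family's Ethnologue rate.
#'
#' @param records data frame as returned by [family_table()].
#' @param convention doubling-time convention, `"rounded"` or `"raw"`.
#' @return Data frame with columns `family`, `catalog`, `n_used`,
#'   `root_age_yr`, `r_e` (unrounded, yr^-1), `r_e_5dp`, `doubling_time_yr`.
#' @export
rate_table <- function(records, convention = c("rounded", "raw")) {
  convention <- match.arg(convention)
  rows <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    counts <- c(ethnologue = suppressWarnings(as.numeric(rec$n_ethnologue)),
                glottolog = suppressWarnings(as.numeric(rec$n_glottolog)))
    counts <- counts[!is.na(counts)]
    if (!length(counts)) {
      warning(sprintf("family '%s': no catalog count; skipped", rec$family),
              call. = FALSE)
      next
    }
    for (cat_name in names(counts)) {
      r <- overall_rate(counts[[cat_name]], rec$root_age_yr)
      r5 <- round(r, 5)
      t2 <- if (convention == "rounded") {
        if (r5 > 0) round(doubling_time(r5)) else NA_real_
      } else {
        if (r > 0) round(doubling_time(r)) else NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        family = rec$family, catalog = cat_name,
        n_used = counts[[cat_name]], root_age_yr = rec$root_age_yr,
        r_e = r, r_e_5dp = r5, doubling_time_yr = t2,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no usable family records", call. = FALSE)
  out <- do.call(rbind, rows)
  eth <- out[out$catalog == "ethnologue", c("family", "r_e")]
  key <- stats::setNames(eth$r_e, eth$family)[out$family]
  key[is.na(key)] <- Inf   # families without an Ethnologue count sort last
  out <- out[order(key, out$family, out$catalog), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize an LTT series to unit time depth and unit size
#'
#' Rescales time as t' = t / root_age (1 at the root, 0 at the present) and
#' lineage counts as N' = N / n_max so families of very different ages and
#' sizes can be compared on a common axis.
#'
#' @param series an [ltt_series] spanning `(root_age, 0]`.
#' @param n_max the family's maximum (extant) size; must be at least the
#'   series' final count — a catalog count below the tree's tip count is a
#'   configuration mistake unless dialect tips were pruned first.
#' @param root_age the family's root age in years.
#' @return An object of class `"normalized_ltt"` with fields `t_prime`
#'   (decreasing, in [0,1]), `n_prime`, `counts` (raw), `n_max`, `root_age`,
#'   `label`.
#' @export
normalize_ltt <- function(series, n_max, root_age) {
  final_n <- series$counts[length(series$counts)]
  if (n_max < final_n)
    stop(sprintf(paste0("n_max (%g) is below the series' final count (%g); ",
                        "catalog count below tree tip count is a ",
                        "configuration mistake unless dialect tips were ",
                        "pruned first"), n_max, final_n), call. = FALSE)
  if (series$times[1L] > root_age * (1 + 1e-9))
    stop("series extends beyond `root_age`", call. = FALSE)
  structure(list(t_prime = series$times / root_age,
                 n_prime = series$counts / n_max,
                 counts = series$counts,
                 n_max = n_max, root_age = root_age,
                 label = series$label),
            class = "normalized_ltt")
}

#' Interval diversification rates over normalized-time bins
#'
#' Splits normalized time t' in [0, 1] into `n_bins` equal bins (ten by
#' default, i.e. consecutive 10% increments of the family's time depth) and
#' computes the interval rate of bin b spanning [t'_hi, t'_lo) as
#' r_b = (ln N(t'_lo) - ln N(t'_hi)) / (dt' * root_age), in yr^-1, where
#' N(.) is the step-function value in force at the bin edge.  The rates
#' telescope exactly: sum_b r_b * dt' * root_age = ln(N_end / N_start).
#'
#' @param norm a `"normalized_ltt"` from [normalize_ltt()].
#' @param root_age root age in years; defaults to the value stored in `norm`.
#' @param n_bins number of bins (>= 2).
#' @return An object of class `"binned_rates"`: a data frame with columns
#'   `bin`, `t_hi`, `t_lo` (normalized edges), `rate` (yr^-1), and
#'   `ln_n_start` (ln N at the bin's older edge), plus attributes `family`
#'   and `root_age`.
#' @export
binned_rates <- function(norm, root_age = norm$root_age, n_bins = 10) {
  if (!inherits(norm, "normalized_ltt"))
    stop("`norm` must come from normalize_ltt()", call. = FALSE)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  raw <- ltt_series(norm$t_prime * root_age, norm$counts, label = norm$label)
  edges <- seq_len(n_bins + 1L)
  t_edges <- seq(1, 0, length.out = n_bins + 1L)
  n_at <- ltt_at(raw, t_edges * root_age)
  if (any(n_at <= 0))
    stop("lineage count is zero at a bin edge; series must span the root",
         call. = FALSE)
  hi <- t_edges[-(n_bins + 1L)]
  lo <- t_edges[-1L]
  rate <- (log(n_at[-1L]) - log(n_at[-(n_bins + 1L)])) / ((hi - lo) * root_age)
  out <- data.frame(bin = seq_len(n_bins), t_hi = hi, t_lo = lo,
                    rate = rate, ln_n_start = log(n_at[-(n_bins + 1L)]))
  attr(out, "family") <- norm$label
  attr(out, "root_age") <- root_age
  class(out) <- c("binned_rates", "data.frame")
  out
}

#' Mean diversification rate with a bootstrap confidence interval
#'
#' Arithmetic mean of per-family rates with a seeded nonparametric bootstrap
#' of the mean (families resampled with replacement, percentile method).
#'
#' @param r_e numeric vector of per-family rates (or a [rate_table()] data
#'   frame, in which case the Ethnologue rows are used).
#' @param reps bootstrap replicates (>= 1000).
#' @param seed integer seed for the bootstrap stream.
#' @param conf confidence level.
#' @return A list with `mean`, `ci` (length-2 percentile interval), `reps`,
#'   `seed`, `n`.
#' @export
mean_rate <- function(r_e, reps = 10000, seed, conf = 0.95) {
  if (is.data.frame(r_e)) r_e <- r_e$r_e[r_e$catalog == "ethnologue"]
  if (length(r_e) < 2L) stop("need >= 2 rate estimates", call. = FALSE)
  if (reps < 1000) stop("`reps` must be >= 1000", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n <- length(r_e)
  boots <- with_local_seed(seed, {
    idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = reps)
    rowMeans(matrix(r_e[idx], nrow = reps))
  })
  alpha <- (1 - conf) / 2
  list(mean = mean(r_e),
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       reps = reps, seed = seed, n = n)
}

# run `expr` under a private RNG stream without touching the caller's state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
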