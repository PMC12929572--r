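# Build the station-day training table and partition it: hold-out station
# selection, stratified tuning sample, station-grouped CV folds.

#' Extract predictor values at station locations
#'
#' Overlays stations onto the harmonized daily stacks and extracts the value
#' of the containing grid cell per feature, producing the long station-day
#' training table. Station-days with missing observed temperature are
#' excluded.
#'
#' @param stacks named list of `raster_stack`s on one shared grid and daily
#'   calendar (static stacks broadcast).
#' @param stations long station table with columns `station_id`, `x`, `y`,
#'   `date`, `ta_obs` and optionally `urban` (see [station_table()]).
#' @return a data frame with `station_id`, `date`, `ta_obs`, `urban` and one
#'   column per feature.
#' @export
extract_station_values <- function(stacks, stations) {
  stopifnot(length(stacks) >= 1)
  grid <- stacks[[1]]$grid
  for (s in stacks) if (!same_grid(s$grid, grid))
    stop_gridta("all stacks must share one grid definition")
  su <- unique(stations[, c("station_id", "x", "y")])
  rc <- point_to_cell(grid, su$x, su$y)
  outside <- is.na(rc$row)
  if (any(outside))
    stop_gridta("stations outside the grid: ",
                paste(su$station_id[outside], collapse = ", "))
  tab <- stations[!is.na(stations$ta_obs), , drop = FALSE]
  idx <- match(tab$station_id, su$station_id)
  row <- rc$row[idx]; col <- rc$col[idx]
  out <- data.frame(station_id = tab$station_id, date = as_date(tab$date),
                    ta_obs = tab$ta_obs)
  out$urban <- if ("urban" %in% names(tab)) tab$urban else NA
  for (f in names(stacks))
    out[[f]] <- stack_value_at(stacks[[f]], out$date, row, col)
  rownames(out) <- NULL
  out
}

#' Select hold-out stations for external validation
#'
#' Repeatedly draws uniform random subsets of `round(frac * n)` stations and
#' compares the observed temperatures of the subset against the remainder
#' with a two-sided Welch two-sample t-test. The first subset with
#' `p < alpha` is returned: a hold-out whose distribution differs from the
#' training data gives a deliberately stricter external test of
#' generalization. The rounding is half-away-from-zero, so 10% of 48
#' stations is 5.
#'
#' @param table a training table with `station_id` and `ta_obs`.
#' @param frac fraction of stations to hold out.
#' @param seed RNG seed for the subset draws.
#' @param alpha qualification threshold on the t-test p-value.
#' @param max_tries maximum subsets drawn before giving up.
#' @return a list of class `partition_spec` with `holdout_station_ids`,
#'   `training_station_ids`, `ttest_p`, `ttest_statistic`,
#'   `n_subsets_tried`, `seed`.
#' @export
select_holdout_stations <- function(table, frac = 0.10, seed = 1L,
                                    alpha = 0.05, max_tries = 1000L) {
  ids <- unique(table$station_id)
  n <- length(ids)
  if (n < 2) stop_gridta("need at least 2 stations")
  k <- round_half_up(frac * n)
  if (k < 1) stop_gridta("frac * n_stations must be >= 1")
  set.seed(seed)
  for (i in seq_len(max_tries)) {
    hold <- sample(ids, k)
    a <- table$ta_obs[table$station_id %in% hold]
    b <- table$ta_obs[!(table$station_id %in% hold)]
    tt <- t.test(a, b, var.equal = FALSE)
    if (is.finite(tt$p.value) && tt$p.value < alpha) {
      return(structure(list(
        holdout_station_ids = sort(hold),
        training_station_ids = sort(setdiff(ids, hold)),
        ttest_p = tt$p.value,
        ttest_statistic = unname(tt$statistic),
        n_subsets_tried = i, seed = seed, frac = frac, alpha = alpha
      ), class = "partition_spec"))
    }
  }
  stop_gridta(
    "no subset of ", k, " stations had t-test p < ", alpha, " within ",
    max_tries, " tries; increase max_tries, or the station series are too ",
    "homogeneous for this hold-out design")
}

#' @export
print.partition_spec <- function(x, ...) {
  cat(sprintf(
    "<partition_spec> %d hold-out / %d training stations (p = %.4g after %d tries)\n",
    length(x$holdout_station_ids), length(x$training_station_ids),
    x$ttest_p, x$n_subsets_tried))
  invisible(x)
}

#' Stratified random sample of a training table
#'
#' Bins rows by observed temperature into `n_bins` equal-width bins and
#' samples `frac` of each bin without replacement. Per-bin counts are floored
#' and the remainder needed to reach `floor(frac * N)` globally is allocated
#' to the largest bins, so the total is exact.
#'
#' @param table training table with `ta_obs`.
#' @param frac sampling fraction in `(0, 1]`.
#' @param n_bins number of equal-width temperature bins.
#' @param seed RNG seed.
#' @return the sampled subset of `table`.
#' @export
stratified_sample <- function(table, frac = 0.5, n_bins = 10, seed = 1L) {
  if (nrow(table) == 0) stop_gridta("empty table")
  if (frac <= 0 || frac > 1) stop_gridta("frac must be in (0, 1]")
  if (frac == 1) return(table)
  set.seed(seed)
  rng <- range(table$ta_obs)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- cut(table$ta_obs, breaks, include.lowest = TRUE, labels = FALSE)
  total <- floor(frac * nrow(table))
  sizes <- tabulate(bin, nbins = n_bins)
  take <- floor(frac * sizes)
  short <- total - sum(take)
  if (short > 0) {
    ord <- order(sizes, decreasing = TRUE)
    ord <- ord[take[ord] < sizes[ord]]
    bump <- rep(ord, length.out = short)
    for (b in bump) take[b] <- take[b] + 1L
  }
  keep <- unlist(lapply(seq_len(n_bins), function(b) {
    rows <- which(bin == b)
    if (length(rows) == 0 || take[b] == 0) return(integer(0))
    sample(rows, min(take[b], length(rows)))
  }), use.names = FALSE)
  table[sort(keep), , drop = FALSE]
}

#' Assign stations to cross-validation folds
#'
#' Deals a random permutation of the stations round-robin into `k` folds, so
#' every observation of a station shares its fold (leave-location-out CV) and
#' fold sizes differ by at most one station.
#'
#' @param station_ids character vector of station ids.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return named integer vector mapping station id to fold in `1..k`.
#' @export
make_station_folds <- function(station_ids, k = 10, seed = 1L) {
  station_ids <- unique(station_ids)
  if (length(station_ids) < k)
    stop_gridta("fewer stations (", length(station_ids), ") than folds (", k, ")")
  set.seed(seed)
  perm <- sample(station_ids)
  folds <- rep(seq_len(k), length.out = length(perm))
  setNames(folds, perm)[station_ids]
}
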