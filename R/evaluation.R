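#' Bundle scan results of replicate datasets for evaluation
#'
#' A *replicate dataset* is one simulation replicate scanned at one
#' sampling generation: its per-window tail counts plus the true window
#' indices of the incompatibility loci (empty for neutral scenarios).
#'
#' @param reps a list; each element is a list with `kappa` (a
#'   `tail_counts` object or integer vector) and `locus_windows`
#'   (1-based integer window indices of the incompatibility loci,
#'   possibly empty), and optionally `generation`.
#' @param scenario scenario label attached to every replicate.
#' @param W window count; inferred from the first replicate if omitted.
#' @return A `scenario_replicates` object.
#' @export
scenario_replicates <- function(reps, scenario = "unnamed", W = NULL) {
  stopifnot(is.list(reps), length(reps) >= 1)
  reps <- lapply(reps, function(r) {
    k <- if (inherits(r$kappa, "tail_counts")) r$kappa$kappa else r$kappa
    list(kappa = as.numeric(k),
         locus_windows = as.integer(r$locus_windows %||% integer(0)),
         generation = r$generation %||% NA_integer_,
         scenario = r$scenario %||% scenario)
  })
  Ws <- vapply(reps, function(r) length(r$kappa), integer(1))
  if (is.null(W)) W <- Ws[1]
  if (!all(Ws == W)) stop("all replicates must share the same window count")
  structure(list(reps = reps, W = as.integer(W)),
            class = "scenario_replicates")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scenario_replicates <- function(x, ...) {
  cat(sprintf("scenario_replicates: %d replicate datasets, %d windows (%s)\n",
              length(x$reps), x$W,
              paste(unique(vapply(x$reps, `[[`, "", "scenario")),
                    collapse = ", ")))
  invisible(x)
}

#' Combine replicate sets
#'
#' @param ... `scenario_replicates` objects on the same window grid.
#' @return A pooled `scenario_replicates`.
#' @export
pool_replicates <- function(...) {
  xs <- list(...)
  stopifnot(all(vapply(xs, inherits, TRUE, "scenario_replicates")))
  W <- unique(vapply(xs, `[[`, integer(1), "W"))
  if (length(W) != 1) stop("window counts differ")
  structure(list(reps = do.call(c, lapply(xs, `[[`, "reps")), W = W),
            class = "scenario_replicates")
}

# windows within d of any locus window (the "true positive" class)
true_class_windows <- function(locus_windows, d, W) {
  if (!length(locus_windows)) return(integer(0))
  sort(unique(unlist(lapply(locus_windows, function(l)
    seq(max(1L, l - d), min(W, l + d))))))
}

#' Classify outlier calls as true or false positives
#'
#' A call at window `i` is a true positive when an incompatibility locus
#' window lies inside its detection region `[i-d, i+d]`; every other
#' call is a false positive.  The true-positive window class therefore
#' has `4d + 2` members (a `2d+1` neighborhood around each of the two
#' loci) when the loci are interior and farther than `2d+1` windows
#' apart; if the neighborhoods overlap or are truncated the class is
#' recomputed and a warning raised.
#'
#' @param calls a data frame from [call_outliers()] (needs a `window`
#'   column).
#' @param locus_windows 1-based window indices of the true loci.
#' @param d neighborhood half-width used for the calls.
#' @param W total window count.
#' @return `calls` with a logical `true_positive` column; attributes
#'   `n_true_class` / `n_false_class` give the window-class sizes.
#' @export
classify_calls <- function(calls, locus_windows, d, W) {
  tc <- true_class_windows(locus_windows, d, W)
  expected <- length(locus_windows) * (2 * d + 1)
  if (length(locus_windows) && length(tc) != expected)
    warning("locus neighborhoods overlap or hit a chromosome end; ",
            "true-positive class recomputed as ", length(tc), " windows")
  calls$true_positive <- calls$window %in% tc
  attr(calls, "n_true_class") <- length(tc)
  attr(calls, "n_false_class") <- as.integer(W) - length(tc)
  calls
}

#' Detection performance of a threshold combination
#'
#' Applies the `{d, thr1, thr2}` calling rule to every replicate dataset
#' and aggregates three metrics: **power**, the fraction of
#' incompatibility loci detected (a locus counts as detected in a
#' replicate when at least one true-positive call covers it; denominator
#' = loci per replicate x replicates); **fpr**, false-positive calls per
#' false-class window per replicate; and **fp_in_outliers**, the
#' fraction of all calls that are false positives (0 when there are no
#' calls).  Neutral replicates (no loci) contribute to `fpr` and
#' `fp_in_outliers` only; `power` is `NA` if no replicate has loci.
#'
#' @param reps a `scenario_replicates` object.
#' @param d,thr1,thr2 the threshold combination.
#' @return A one-row data frame: `d`, `thr1`, `thr2`, `power`, `fpr`,
#'   `fp_in_outliers`, `n_calls`, `resolution_mb` (the `(4d+2)/2`-window
#'   detection region per locus, in Mb).
#' @export
performance <- function(reps, d, thr1, thr2) {
  stopifnot(inherits(reps, "scenario_replicates"))
  W <- reps$W
  n_true <- n_false <- detected <- loci <- 0
  false_class_total <- 0
  ws <- NA_real_
  for (r in reps$reps) {
    kd <- smoothed_counts(r$kappa, d)
    hit <- which(r$kappa > thr1 & kd > thr2)
    tc <- true_class_windows(r$locus_windows, d, W)
    is_true <- hit %in% tc
    n_true <- n_true + sum(is_true)
    n_false <- n_false + sum(!is_true)
    false_class_total <- false_class_total + (W - length(tc))
    loci <- loci + length(r$locus_windows)
    for (l in r$locus_windows)
      detected <- detected + any(abs(hit - l) <= d)
  }
  data.frame(
    d = d, thr1 = thr1, thr2 = thr2,
    power = if (loci > 0) detected / loci else NA_real_,
    fpr = if (false_class_total > 0) n_false / false_class_total else 0,
    fp_in_outliers = if (n_true + n_false > 0)
      n_false / (n_true + n_false) else 0,
    n_calls = n_true + n_false
  )
}

# --- fast full-grid machinery -------------------------------------------
#
# For one replicate and one d, every threshold pair reduces to counting
# windows with kappa > thr1 and kappa_d > thr2.  Binning each window by
# the number of grid values it exceeds turns the whole thr1 x thr2 grid
# into a 2D histogram plus a suffix sum, so per-replicate tables for the
# entire grid cost O(W + |grid|).

suffix2d <- function(h) {
  n1 <- nrow(h)
  n2 <- ncol(h)
  h <- h[n1:1, , drop = FALSE]
  h <- matrix(apply(h, 2, cumsum), n1, n2)
  h <- h[n1:1, n2:1, drop = FALSE]
  h <- t(matrix(apply(h, 1, cumsum), n2, n1))
  h[, n2:1, drop = FALSE]
}

hist2d <- function(a1, a2, n1, n2) {
  # a1, a2 in 0..n1 / 0..n2; cell (i, j) counts windows with a1 == i-?,
  # offset so that suffix sums over >= thresholds work
  h <- matrix(0, n1, n2)
  keep <- a1 >= 1 & a2 >= 1
  if (any(keep))
    h[] <- tabulate((a2[keep] - 1) * n1 + a1[keep], nbins = n1 * n2)
  h
}

rep_grid_tables <- function(kappa, locus_windows, d, thr1_values,
                            thr2_values, W) {
  n1 <- length(thr1_values)
  n2 <- length(thr2_values)
  kd <- smoothed_counts(kappa, d)
  a1 <- findInterval(kappa, thr1_values, left.open = TRUE)  # #{thr1 < kappa}
  a2 <- findInterval(kd, thr2_values, left.open = TRUE)
  tc <- true_class_windows(locus_windows, d, W)
  is_tc <- logical(W)
  is_tc[tc] <- TRUE
  Ttrue <- suffix2d(hist2d(a1[is_tc], a2[is_tc], n1, n2))
  Tfalse <- suffix2d(hist2d(a1[!is_tc], a2[!is_tc], n1, n2))
  det <- matrix(0, n1, n2)
  for (l in locus_windows) {
    nb <- seq(max(1L, l - d), min(W, l + d))
    det <- det + (suffix2d(hist2d(a1[nb], a2[nb], n1, n2)) > 0)
  }
  list(Ttrue = Ttrue, Tfalse = Tfalse, det = det,
       n_loci = length(locus_windows), n_false_class = W - length(tc))
}

precompute_grid <- function(reps, d_values, thr1_values, thr2_values) {
  lapply(reps$reps, function(r)
    lapply(d_values, function(d)
      rep_grid_tables(r$kappa, r$locus_windows, d, thr1_values,
                      thr2_values, reps$W)))
}

grid_metrics <- function(tables, subset, d_values, thr1_values,
                         thr2_values) {
  n1 <- length(thr1_values)
  n2 <- length(thr2_values)
  out <- vector("list", length(d_values))
  for (di in seq_along(d_values)) {
    Ttrue <- Tfalse <- det <- matrix(0, n1, n2)
    loci <- fc <- 0
    for (ri in subset) {
      tb <- tables[[ri]][[di]]
      Ttrue <- Ttrue + tb$Ttrue
      Tfalse <- Tfalse + tb$Tfalse
      det <- det + tb$det
      loci <- loci + tb$n_loci
      fc <- fc + tb$n_false_class
    }
    calls <- Ttrue + Tfalse
    out[[di]] <- list(
      power = if (loci > 0) det / loci else matrix(NA_real_, n1, n2),
      fpr = if (fc > 0) Tfalse / fc else matrix(0, n1, n2),
      fpo = ifelse(calls > 0, Tfalse / pmax(calls, 1), 0),
      n_calls = calls
    )
  }
  out
}

metric_value <- function(power, d, metric) {
  switch(metric,
         power = power,
         power_over_2d1 = power / (2 * d + 1),
         power_over_2d1_sq = power / (2 * d + 1)^2,
         stop("unknown optimizing metric '", metric, "'"))
}

#' Constrained grid search over the calling thresholds
#'
#' Evaluates every `{d, thr1, thr2}` combination on a set of replicate
#' datasets, discards combinations violating the two constraints (a
#' false-positive rate below the Bonferroni ceiling [fpr_ceiling()] and
#' a proportion of false positives among outliers below 5%), and returns
#' the feasible combination maximizing the chosen metric: raw `power`,
#' or the resolution-penalized `power/(2d+1)` or `power/(2d+1)^2`.
#' Exact metric ties are broken, in order, by resolution (smaller `d`),
#' smaller proportion of false positives among outliers, then larger
#' `thr2` (and finally smaller `thr1`, for determinism).
#'
#' @param reps a `scenario_replicates` object.
#' @param metric `"power"`, `"power_over_2d1"` or `"power_over_2d1_sq"`.
#' @param d_values,thr1_values,thr2_values the grid (defaults match the
#'   tuning study: `d` 5..19, `thr1` 400..1000 by 50, `thr2` 0..300 by
#'   20 with `n_b` = 1000).
#' @param constrain apply the two feasibility constraints (default TRUE).
#' @param fp_in_outliers_max ceiling on the proportion of false
#'   positives among outliers.
#' @param tables,subset internal (precomputed tables for
#'   cross-validation).
#' @return A list with `best` (one-row data frame, or `NULL` if no
#'   feasible combination: the `feasible` field then says so) and
#'   `table` (all combinations with their metrics and feasibility).
#' @export
grid_search <- function(reps = NULL, metric = "power_over_2d1",
                        d_values = 5:19,
                        thr1_values = seq(400, 1000, by = 50),
                        thr2_values = seq(0, 300, by = 20),
                        constrain = TRUE, fp_in_outliers_max = 0.05,
                        tables = NULL, subset = NULL) {
  if (is.null(tables)) {
    stopifnot(inherits(reps, "scenario_replicates"))
    tables <- precompute_grid(reps, d_values, thr1_values, thr2_values)
  }
  if (is.null(subset)) subset <- seq_along(tables)
  gm <- grid_metrics(tables, subset, d_values, thr1_values, thr2_values)
  rows <- vector("list", length(d_values))
  n1 <- length(thr1_values)
  n2 <- length(thr2_values)
  ceil1 <- fpr_ceiling(thr1_values)
  for (di in seq_along(d_values)) {
    g <- gm[[di]]
    rows[[di]] <- data.frame(
      d = d_values[di],
      thr1 = rep(thr1_values, times = n2),
      thr2 = rep(thr2_values, each = n1),
      power = as.vector(g$power),
      fpr = as.vector(g$fpr),
      fp_in_outliers = as.vector(g$fpo),
      n_calls = as.vector(g$n_calls),
      feasible = as.vector(g$fpr < matrix(ceil1, n1, n2) &
                             g$fpo < fp_in_outliers_max)
    )
  }
  tab <- do.call(rbind, rows)
  tab$metric <- metric_value(tab$power, tab$d, metric)
  ok <- if (constrain) tab$feasible & !is.na(tab$metric) else
    !is.na(tab$metric)
  if (!any(ok)) {
    return(list(best = NULL, feasible = FALSE, metric = metric,
                table = tab))
  }
  cand <- tab[ok, ]
  cand <- cand[cand$metric == max(cand$metric), ]
  cand <- cand[order(cand$d, cand$fp_in_outliers, -cand$thr2, cand$thr1), ]
  list(best = cand[1, ], feasible = TRUE, metric = metric, table = tab)
}

#' Cross-validate the threshold tuning
#'
#' Repeats, `iters` times: draw a random `train_frac` subset of the
#' replicate datasets (without replacement, stratified by scenario when
#' several are pooled), pick the best feasible `{d, thr1, thr2}` on it by
#' [grid_search()] - also recording every combination whose metric comes
#' within `plateau` (a fraction) of the best - then measure that best
#' combination's performance on the held-out datasets.  The mode of the
#' best-combination distribution is the recommended threshold set; the
#' combination most often found within the plateau is the robust
#' ("better") choice.
#'
#' @inheritParams grid_search
#' @param train_frac fraction of replicate datasets used for tuning.
#' @param iters number of cross-validation iterations.
#' @param plateau relative margin defining "within x% of the best".
#' @param seed optional integer seed.
#' @return A list with `distribution` (data frame of combinations with
#'   `count_best` and `count_plateau`, sorted), `mode` (the modal best
#'   combination), `robust` (most frequent plateau member),
#'   `holdout_mode` (held-out power/fpr/fp-in-outliers of the modal
#'   combination, averaged over the iterations in which it sat on the
#'   plateau), and `holdout` (per-iteration held-out metrics of each
#'   iteration's own best combination).
#' @export
cross_validate <- function(reps, metric = "power_over_2d1",
                           train_frac = 0.25, iters = 100, plateau = 0.05,
                           d_values = 5:19,
                           thr1_values = seq(400, 1000, by = 50),
                           thr2_values = seq(0, 300, by = 20),
                           fp_in_outliers_max = 0.05, seed = NULL) {
  stopifnot(inherits(reps, "scenario_replicates"), length(reps$reps) >= 2)
  if (!is.null(seed)) set.seed(seed)
  D <- length(reps$reps)
  scen <- vapply(reps$reps, `[[`, "", "scenario")
  tables <- precompute_grid(reps, d_values, thr1_values, thr2_values)
  key <- function(d, t1, t2) paste(d, t1, t2)
  counts_best <- counts_plateau <- list()
  bump <- function(lst, k) {
    lst[[k]] <- (lst[[k]] %||% 0) + 1
    lst
  }
  holdout <- vector("list", iters)
  train_sets <- vector("list", iters)
  plateau_sets <- vector("list", iters)
  for (it in seq_len(iters)) {
    train <- unlist(lapply(split(seq_len(D), scen), function(ix) {
      n <- max(1L, round(train_frac * length(ix)))
      ix[sample.int(length(ix), n)]
    }), use.names = FALSE)
    test <- setdiff(seq_len(D), train)
    train_sets[[it]] <- train
    gs <- grid_search(metric = metric, d_values = d_values,
                      thr1_values = thr1_values,
                      thr2_values = thr2_values,
                      fp_in_outliers_max = fp_in_outliers_max,
                      tables = tables, subset = train)
    if (!gs$feasible) next
    b <- gs$best
    counts_best <- bump(counts_best, key(b$d, b$thr1, b$thr2))
    ft <- gs$table[gs$table$feasible & !is.na(gs$table$metric) &
                     gs$table$metric >= (1 - plateau) * b$metric, ]
    pk <- key(ft$d, ft$thr1, ft$thr2)
    plateau_sets[[it]] <- pk
    for (k in pk) counts_plateau <- bump(counts_plateau, k)
    ho <- grid_search(metric = metric, d_values = d_values,
                      thr1_values = thr1_values,
                      thr2_values = thr2_values, constrain = FALSE,
                      tables = tables, subset = test)
    hr <- ho$table
    row <- hr[hr$d == b$d & hr$thr1 == b$thr1 & hr$thr2 == b$thr2, ]
    holdout[[it]] <- cbind(iteration = it, row[, c(
      "d", "thr1", "thr2", "power", "fpr", "fp_in_outliers")])
  }
  all_keys <- union(names(counts_best), names(counts_plateau))
  if (!length(all_keys))
    return(list(distribution = NULL, mode = NULL, robust = NULL,
                holdout_mode = NULL, holdout = NULL,
                message = "no feasible combination in any iteration"))
  parse_key <- function(k) as.numeric(strsplit(k, " ")[[1]])
  dist <- do.call(rbind, lapply(all_keys, function(k) {
    v <- parse_key(k)
    data.frame(d = v[1], thr1 = v[2], thr2 = v[3],
               count_best = counts_best[[k]] %||% 0,
               count_plateau = counts_plateau[[k]] %||% 0)
  }))
  dist <- dist[order(-dist$count_best, -dist$count_plateau), ]
  rownames(dist) <- NULL
  mode_row <- dist[1, ]
  robust_row <- dist[order(-dist$count_plateau, -dist$count_best), ][1, ]
  # held-out performance of the modal combination over the iterations in
  # which it was best or on the plateau
  eval_holdout <- function(cmb) {
    use <- which(vapply(plateau_sets, function(p)
      !is.null(p) && key(cmb$d, cmb$thr1, cmb$thr2) %in% p, TRUE))
    if (!length(use)) return(NULL)
    rows <- lapply(use, function(it) {
      test <- setdiff(seq_len(D), train_sets[[it]])
      ho <- grid_search(metric = metric, d_values = d_values,
                        thr1_values = thr1_values,
                        thr2_values = thr2_values, constrain = FALSE,
                        tables = tables, subset = test)
      hr <- ho$table
      hr[hr$d == cmb$d & hr$thr1 == cmb$thr1 & hr$thr2 == cmb$thr2,
         c("power", "fpr", "fp_in_outliers")]
    })
    m <- colMeans(do.call(rbind, rows), na.rm = TRUE)
    data.frame(d = cmb$d, thr1 = cmb$thr1, thr2 = cmb$thr2,
               power = m["power"], fpr = m["fpr"],
               fp_in_outliers = m["fp_in_outliers"],
               n_iterations = length(use), row.names = NULL)
  }
  list(distribution = dist, mode = mode_row, robust = robust_row,
       holdout_mode = eval_holdout(robust_row),
       holdout = do.call(rbind, holdout))
}

#' Detection-region resolution of a half-width d
#'
#' The detection region of one locus spans `2d + 1` windows; averaged
#' over its two flanks this is conventionally quoted as
#' `(4d + 2) / 2` windows, i.e. `(2d + 1) * window_size`.
#'
#' @param d neighborhood half-width in windows.
#' @param window_size window width in bp.
#' @return Resolution in Mb.
#' @export
resolution_mb <- function(d, window_size = 5e5) {
  (2 * d + 1) * window_size / 1e6
}
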