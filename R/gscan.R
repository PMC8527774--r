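#' Cumulative G profile of an event set
#'
#' For `n` ordered event positions `x_1 < ... < x_n` over an alignment of
#' `L` columns, the cumulative statistic at the i-th event is the difference
#' between its relative occurrence rank and its relative alignment position,
#' `G_i = i/n - x_i/L`, with the sentinel `G_0 = 0` at position 0.  Runs of
#' events denser than the uniform expectation make G rise; evenly spaced
#' events (`x_i = iL/n`) give a flat profile.
#'
#' @param events A `divscan_events` object (see [extract_events()]), or an
#'   integer vector of event positions (then `L` must be given).
#' @param L Alignment length, required when `events` is a bare vector.
#' @return A `divscan_gprofile`: list with `L`, `n`, `x` (positions with the
#'   leading 0) and `G` (values with the leading 0).
#' @examples
#' gp <- g_profile(c(2, 9), L = 10)
#' gp$G  # 0 0.3 0.1
#' @export
g_profile <- function(events, L = NULL) {
  if (inherits(events, "divscan_events")) {
    x <- events$positions
    L <- events$L
  } else {
    x <- sort(as.integer(events))
    if (is.null(L)) stop("L is required when passing bare positions",
                         call. = FALSE)
  }
  n <- length(x)
  if (n == 0L) {
    stop("empty-input error: no events to profile", call. = FALSE)
  }
  if (x[1] < 1L || x[n] > L) {
    stop("event positions must lie in 1..L", call. = FALSE)
  }
  G <- seq_len(n) / n - x / L
  structure(list(L = as.integer(L), n = n,
                 x = c(0L, x), G = c(0, G)),
            class = "divscan_gprofile")
}

#' @export
print.divscan_gprofile <- function(x, ...) {
  cat(sprintf("G profile: n = %d events, L = %d, max G = %.4f\n",
              x$n, x$L, max(x$G)))
  invisible(x)
}

#' Maximal rise of the G profile
#'
#' Returns the maximum of `G_j - G_i` over all ordered index pairs
#' `0 <= i < j <= n`, the scan statistic for a substitution hotspot, together
#' with the arg-max pair.  Ties are broken towards the smallest `i`, then
#' the smallest `j`.  The spanned alignment segment is `(x_i, x_j]`,
#' reported 1-based closed as `[x_i + 1, x_j]`.
#'
#' @param profile A `divscan_gprofile` from [g_profile()].
#' @return List with `delta_g`, indices `i` and `j` (0-based event indices
#'   into the profile including the sentinel), and `segment` (1-based closed
#'   alignment interval).
#' @export
max_delta_g <- function(profile) {
  stopifnot(inherits(profile, "divscan_gprofile"))
  G <- profile$G
  n <- profile$n
  best <- -Inf
  bi <- 0L; bj <- 1L
  min_g <- G[1]        # G_0
  min_i <- 0L
  for (j in seq_len(n)) {
    cand <- G[j + 1L] - min_g
    if (cand > best || (cand == best && min_i < bi)) {
      best <- cand; bi <- min_i; bj <- j
    }
    if (G[j + 1L] < min_g) {
      min_g <- G[j + 1L]; min_i <- j
    }
  }
  list(delta_g = best, i = bi, j = bj,
       segment = c(profile$x[bi + 1L] + 1L, profile$x[bj + 1L]))
}

#' Scan configuration
#'
#' @param n_sims Monte Carlo replicates for the null (default 100000).
#' @param alpha Significance level for calling a hotspot (default 0.05).
#' @param min_events Minimum events in a region for it to be scanned
#'   (default 3).
#' @param min_segment_length Minimum region length in columns (default 10).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param position_universe `"all_columns"` (the null resamples from all
#'   `1..L` alignment columns) or `"mutually_ungapped"` (positions are
#'   re-ranked onto the columns where both sequences are non-gap and the
#'   null resamples from those).
#' @param exact_threshold When the number of distinct arrangements
#'   `choose(L, n)` is at most this, the p-value is computed by exhaustive
#'   enumeration instead of Monte Carlo (default 200000; set to 0 to force
#'   Monte Carlo).
#' @return A `divscan_scancfg` list.
#' @export
scan_config <- function(n_sims = 100000L, alpha = 0.05, min_events = 3L,
                        min_segment_length = 10L, seed = NULL,
                        position_universe = c("all_columns",
                                              "mutually_ungapped"),
                        exact_threshold = 200000) {
  stopifnot(n_sims >= 1, alpha > 0, alpha < 1)
  structure(list(n_sims = as.integer(n_sims), alpha = alpha,
                 min_events = as.integer(min_events),
                 min_segment_length = as.integer(min_segment_length),
                 seed = seed,
                 position_universe = match.arg(position_universe),
                 exact_threshold = exact_threshold),
            class = "divscan_scancfg")
}

#' Monte Carlo p-value for an observed max-deltaG
#'
#' Each replicate draws `n` distinct positions uniformly without replacement
#' from the `L` columns of the position universe, computes the max-deltaG
#' statistic exactly as the observed pipeline does, and the p-value is the
#' add-one estimator `(1 + #\{replicate >= observed\}) / (n_sims + 1)`;
#' ties count as exceedances.  A single seeded generator drives the
#' replicates in replicate-major order, so results are reproducible under a
#' fixed seed.
#'
#' @param observed_delta_g Observed statistic from [max_delta_g()].
#' @param L Number of columns in the position universe.
#' @param n Number of events.
#' @param n_sims Number of Monte Carlo replicates.
#' @param seed Optional integer seed (calls [set.seed()] when non-`NULL`).
#' @return List with `p_value`, `n_sims`, `n_ge` (replicates at or above
#'   the observed value), `null_mean`, `null_sd`, `null_max` and
#'   `method = "mc"`.
#' @export
mc_pvalue <- function(observed_delta_g, L, n, n_sims = 100000L, seed = NULL) {
  if (n > L) stop("infeasible-sample error: n > L", call. = FALSE)
  if (n < 1L) stop("empty-input error: n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r <- mc_null_count(as.integer(L), as.integer(n), as.integer(n_sims),
                     observed_delta_g)
  list(p_value = (1 + r$n_ge) / (n_sims + 1),
       n_sims = as.integer(n_sims), n_ge = r$n_ge,
       null_mean = r$null_mean, null_sd = r$null_sd,
       null_max = r$null_max, method = "mc")
}

#' Exact p-value by exhaustive enumeration
#'
#' Enumerates all `choose(L, n)` arrangements of `n` event positions over
#' `L` columns and returns the exact proportion with max-deltaG at or above
#' the observed value.  Only feasible for small `choose(L, n)`.
#'
#' @inheritParams mc_pvalue
#' @param max_arrangements Refuse to enumerate beyond this many
#'   arrangements (default 200000).
#' @return List with `p_value`, `n_arrangements`, `n_ge` and
#'   `method = "exact"`.
#' @export
exact_pvalue <- function(observed_delta_g, L, n, max_arrangements = 200000) {
  if (n > L) stop("infeasible-sample error: n > L", call. = FALSE)
  if (n < 1L) stop("empty-input error: n must be >= 1", call. = FALSE)
  total <- choose(L, n)
  if (total > max_arrangements) {
    stop("too many arrangements to enumerate: choose(", L, ", ", n, ") = ",
         total, call. = FALSE)
  }
  combos <- utils::combn(L, n)
  inv_n <- 1 / n
  inv_L <- 1 / L
  tol <- 1e-12
  n_ge <- 0L
  for (k in seq_len(ncol(combos))) {
    x <- combos[, k]          # combn emits columns in increasing order
    G <- seq_len(n) * inv_n - x * inv_L
    s <- max(G - cummin(c(0, G[-n])))
    if (s >= observed_delta_g - tol) n_ge <- n_ge + 1L
  }
  list(p_value = n_ge / total, n_arrangements = total, n_ge = n_ge,
       method = "exact")
}

# dispatcher: exhaustive enumeration for small arrangement spaces, Monte
# Carlo otherwise
delta_g_pvalue <- function(observed, L, n, config) {
  if (choose(L, n) <= config$exact_threshold) {
    exact_pvalue(observed, L, n, max_arrangements = config$exact_threshold)
  } else {
    mc_pvalue(observed, L, n, n_sims = config$n_sims)
  }
}

#' Call substitution hotspots by recursive segmentation
#'
#' Computes the max-deltaG statistic on the whole region and its p-value
#' against the resampling null.  If significant at `config$alpha`, the
#' spanned segment is reported as a hotspot and the flanks on either side
#' are re-scanned independently, each with a fresh null of its own event
#' count and length; recursion stops when a region is non-significant, has
#' fewer than `min_events` events, or is shorter than `min_segment_length`
#' columns.  This yields a set of disjoint significant stretches.
#'
#' @param events A `divscan_events` object.
#' @param config A `divscan_scancfg` from [scan_config()].
#' @return A data frame of class `divscan_hotspots` with columns `start`,
#'   `end` (1-based closed alignment columns), `delta_g`, `p_value`,
#'   `n_events`, `depth` and `method`, sorted by `start`.  Empty (zero-row)
#'   when nothing is significant or there are no events.
#' @export
call_hotspots <- function(events, config = scan_config()) {
  stopifnot(inherits(events, "divscan_events"),
            inherits(config, "divscan_scancfg"))
  if (!is.null(config$seed)) set.seed(config$seed)

  empty <- data.frame(start = integer(0), end = integer(0),
                      delta_g = numeric(0), p_value = numeric(0),
                      n_events = integer(0), depth = integer(0),
                      method = character(0), stringsAsFactors = FALSE)

  # optionally re-rank positions onto the mutually ungapped column universe
  to_aln <- identity
  pos <- events$positions
  L <- events$L
  if (config$position_universe == "mutually_ungapped") {
    uni <- events$universe
    rank <- match(pos, uni)
    if (anyNA(rank)) {
      stop("events outside the mutually ungapped universe; indel events ",
           "cannot be scanned under position_universe = 'mutually_ungapped'",
           call. = FALSE)
    }
    pos <- rank
    L <- length(uni)
    to_aln <- function(cols) uni[cols]
  }

  recurse <- function(x, L_reg, offset, depth) {
    n <- length(x)
    if (n < config$min_events || L_reg < config$min_segment_length) {
      return(empty)
    }
    prof <- g_profile(x, L = L_reg)
    m <- max_delta_g(prof)
    if (m$delta_g <= 0) return(empty)
    pv <- delta_g_pvalue(m$delta_g, L_reg, n, config)
    if (pv$p_value > config$alpha) return(empty)
    xi <- prof$x[m$i + 1L]   # position of event i (0 for the sentinel)
    xj <- prof$x[m$j + 1L]
    call <- data.frame(start = offset + xi + 1L, end = offset + xj,
                       delta_g = m$delta_g, p_value = pv$p_value,
                       n_events = m$j - m$i, depth = depth,
                       method = pv$method, stringsAsFactors = FALSE)
    left <- recurse(x[x <= xi], xi, offset, depth + 1L)
    right <- recurse(x[x > xj] - xj, L_reg - xj, offset + xj, depth + 1L)
    rbind(left, call, right)
  }

  calls <- recurse(pos, L, 0L, 0L)
  calls <- calls[order(calls$start), , drop = FALSE]
  rownames(calls) <- NULL
  if (nrow(calls)) {
    calls$start <- as.integer(to_aln(calls$start))
    calls$end <- as.integer(to_aln(calls$end))
  }
  attr(calls, "config") <- config
  attr(calls, "L") <- events$L
  attr(calls, "n") <- events$n
  class(calls) <- c("divscan_hotspots", "data.frame")
  calls
}

#' Plot-ready report of a hotspot scan
#'
#' Combines the G curve and the hotspot calls into plain tables, optionally
#' translating intervals and positions into reference (e.g. promoter)
#' coordinates through a coordinate map.
#'
#' @param calls A `divscan_hotspots` data frame from [call_hotspots()], or
#'   `NULL`/empty for a curve-only report.
#' @param profile A `divscan_gprofile`, or `NULL` when there are no events
#'   (an empty report is returned with a warning).
#' @param coord_map Optional `divscan_coordmap` over the same alignment.
#' @return List of class `divscan_report` with data frames `g_curve`
#'   (`position`, `G`, and `ref_position` when mapped) and `hotspots`
#'   (the calls plus `ref_start`/`ref_end` when mapped).
#' @export
scan_report <- function(calls, profile, coord_map = NULL) {
  if (is.null(profile) || profile$n == 0L) {
    warning("no events: returning an empty report")
    return(structure(list(g_curve = data.frame(position = integer(0),
                                               G = numeric(0)),
                          hotspots = NULL),
                     class = "divscan_report"))
  }
  if (!is.null(coord_map) && length(coord_map$offset) != profile$L) {
    stop("consistency error: coordinate map covers ",
         length(coord_map$offset), " columns but profile has L = ",
         profile$L, call. = FALSE)
  }
  if (!is.null(calls) && nrow(calls) && attr(calls, "L") != profile$L) {
    stop("consistency error: calls and profile have different L",
         call. = FALSE)
  }
  curve <- data.frame(position = profile$x, G = profile$G)
  if (!is.null(coord_map)) {
    curve$ref_position <- c(NA_integer_,
                            coord_map$offset[profile$x[-1]])
  }
  hs <- NULL
  if (!is.null(calls) && nrow(calls)) {
    hs <- as.data.frame(calls)
    if (!is.null(coord_map)) {
      se <- t(vapply(seq_len(nrow(hs)),
                     function(i) map_interval(coord_map, hs$start[i],
                                              hs$end[i]),
                     integer(2)))
      hs$ref_start <- se[, 1]
      hs$ref_end <- se[, 2]
    }
  }
  structure(list(g_curve = curve, hotspots = hs),
            class = "divscan_report")
}

#' @export
print.divscan_report <- function(x, ...) {
  cat(sprintf("Scan report: G curve with %d points\n",
              nrow(x$g_curve)))
  if (is.null(x$hotspots) || !nrow(x$hotspots)) {
    cat("  no significant hotspots\n")
  } else {
    cat(sprintf("  %d hotspot(s):\n", nrow(x$hotspots)))
    print(x$hotspots)
  }
  invisible(x)
}
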