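# The stimulation effect statistic U: the signed z statistic of the
# Wilcoxon signed-rank test on paired pre/post log band powers. Positive U
# means a band-power increase from pre to post. The same statistic applied
# to baseline pseudo-trial pairs quantifies spontaneous band-power
# fluctuation.

#' Wilcoxon signed-rank z statistic (effect U)
#'
#' Computes the signed normal-approximation z statistic of the Wilcoxon
#' signed-rank test on paired samples. Zero differences are discarded
#' (classical Wilcoxon treatment, as in MATLAB's `signrank`); ties in the
#' absolute differences receive mid-ranks with the usual tie correction in
#' the variance. With `continuity = TRUE` a 0.5 continuity correction is
#' applied towards zero (MATLAB's default; at n = 60 the two versions differ
#' by less than 0.06).
#'
#' @param pre,post Paired numeric vectors (pre and post log band power).
#' @param min_pairs Minimum number of non-zero differences required; below
#'   it (but above zero) the cell is unusable and `NA` is returned.
#' @param continuity Apply the continuity correction.
#' @return The z statistic U. All differences zero returns `0` with
#'   attribute `degenerate = TRUE`; fewer than `min_pairs` usable pairs
#'   returns `NA`.
#' @examples
#' effect_U(rep(0, 10), 1:10)  # all increases: (55 - 27.5) / sqrt(96.25)
#' @export
effect_U <- function(pre, post, min_pairs = 10, continuity = FALSE) {
  stopifnot(length(pre) == length(post))
  d <- post - pre
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) return(structure(0, degenerate = TRUE))
  if (n < min_pairs) return(NA_real_)
  r <- rank(abs(d))
  wpos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  num <- wpos - mu
  if (continuity && num != 0) num <- num - 0.5 * sign(num)
  as.numeric(num / sqrt(sigma2))
}

#' Effect matrix U per channel and band for one condition
#'
#' Computes [effect_U()] for every (channel, band) cell of a band-power
#' table, pairing pre and post rows by `pair_id`. Pairs with a missing
#' partner are dropped. Cells with fewer usable pairs than `min_pairs` are
#' `NA`.
#'
#' @param bp_table Long band-power table from [band_power_table()].
#' @param condition `"stimulation"` or `"baseline"`.
#' @param session_id Optional identifier stored on the result.
#' @param min_pairs,continuity Passed to [effect_U()].
#' @return An `effect_matrix`: list with `U` (channels x bands matrix),
#'   `n_pairs` (same shape), `condition`, `session_id`.
#' @export
session_effect <- function(bp_table, condition = c("stimulation", "baseline"),
                           session_id = NULL, min_pairs = 10,
                           continuity = FALSE) {
  condition <- match.arg(condition)
  tb <- bp_table[bp_table$condition == condition, , drop = FALSE]
  if (nrow(tb) == 0L) stopf("no rows for condition '%s'", condition)
  channels <- unique(tb$channel)
  bands <- unique(tb$band)
  U <- matrix(NA_real_, length(channels), length(bands),
              dimnames = list(channels, bands))
  npairs <- matrix(0L, length(channels), length(bands),
                   dimnames = list(channels, bands))
  pre <- tb[tb$role == "pre", , drop = FALSE]
  post <- tb[tb$role == "post", , drop = FALSE]
  key <- function(x) paste(x$channel, x$band, sep = "\r")
  pre_split <- split(pre[c("pair_id", "log_power")], key(pre))
  post_split <- split(post[c("pair_id", "log_power")], key(post))
  for (ch in channels) {
    for (bd in bands) {
      k <- paste(ch, bd, sep = "\r")
      a <- pre_split[[k]]
      b <- post_split[[k]]
      if (is.null(a) || is.null(b)) next
      common <- intersect(a$pair_id, b$pair_id)
      npairs[ch, bd] <- length(common)
      U[ch, bd] <- effect_U(a$log_power[match(common, a$pair_id)],
                            b$log_power[match(common, b$pair_id)],
                            min_pairs = min_pairs, continuity = continuity)
    }
  }
  structure(list(U = U, n_pairs = npairs, condition = condition,
                 session_id = session_id),
            class = "effect_matrix")
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat(sprintf("Effect matrix (%s%s): %d channels x %d bands\n",
              x$condition,
              if (!is.null(x$session_id)) paste0(", session ", x$session_id) else "",
              nrow(x$U), ncol(x$U)))
  cat(sprintf("  U range: [%.3f, %.3f], %d unusable cell(s)\n",
              suppressWarnings(min(x$U, na.rm = TRUE)),
              suppressWarnings(max(x$U, na.rm = TRUE)), sum(is.na(x$U))))
  invisible(x)
}

#' Per-band and overall extrema of an effect matrix
#'
#' Minimum and maximum U across channels, per band and over all cells; the
#' per-session summary compared between stimulation and baseline conditions.
#'
#' @param em An `effect_matrix`.
#' @return Data frame with columns `band` (including `"all"`), `min`, `max`.
#' @export
session_extrema <- function(em) {
  U <- em$U
  per_band <- data.frame(
    band = colnames(U),
    min = apply(U, 2L, function(v) suppressWarnings(min(v, na.rm = TRUE))),
    max = apply(U, 2L, function(v) suppressWarnings(max(v, na.rm = TRUE))),
    stringsAsFactors = FALSE
  )
  all_row <- data.frame(band = "all",
                        min = suppressWarnings(min(U, na.rm = TRUE)),
                        max = suppressWarnings(max(U, na.rm = TRUE)),
                        stringsAsFactors = FALSE)
  out <- rbind(per_band, all_row)
  out$min[!is.finite(out$min)] <- NA_real_
  out$max[!is.finite(out$max)] <- NA_real_
  rownames(out) <- NULL
  out
}

# box-plot adjacent values under the 1.5 x IQR rule
adjacent_values <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- x[x >= q[1] - 1.5 * iqr]
  hi <- x[x <= q[2] + 1.5 * iqr]
  c(lower = min(lo), upper = max(hi))
}

#' Compare stimulation extrema against baseline extrema across sessions
#'
#' For paired per-session extrema (stimulation and baseline conditions of
#' the same sessions), computes (a) the adjacent values of the baseline
#' distribution (whisker ends under the 1.5 x IQR outlier rule), (b) the
#' fraction of sessions whose stimulation maximum exceeds the upper
#' adjacent value of the baseline maxima (resp. minimum below the lower
#' adjacent value of the baseline minima), and (c) a paired t test on the
#' per-session stimulation - baseline differences with Cohen's d for paired
#' samples.
#'
#' @param stim,base Data frames (or lists coercible to them) with one row
#'   per session and columns `min` and `max`, in matching session order.
#' @return List with elements `max` and `min`, each containing `adjacent`,
#'   `exceed_fraction`, `t`, `p`, `cohens_d`, `n`.
#' @export
extrema_comparison <- function(stim, base) {
  stim <- as.data.frame(stim)
  base <- as.data.frame(base)
  if (nrow(stim) != nrow(base)) stopf("stim and base must pair up by session")
  if (nrow(stim) < 3L) stopf("need >= 3 sessions for the extrema comparison")
  one_side <- function(s, b, side) {
    adj <- adjacent_values(b)
    exceed <- if (side == "max") mean(s > adj["upper"]) else mean(s < adj["lower"])
    d <- s - b
    sd_d <- stats::sd(d)
    if (sd_d <= 1e-10 * max(abs(d), 1)) {
      # constant paired difference: t and d are 0 or diverge with its sign
      if (all(abs(d) <= 1e-12)) {
        tt <- list(statistic = 0, p.value = 1)
        cd <- 0
      } else {
        tt <- list(statistic = sign(mean(d)) * Inf, p.value = 0)
        cd <- sign(mean(d)) * Inf
      }
    } else {
      tt <- stats::t.test(s, b, paired = TRUE)
      cd <- mean(d) / sd_d
    }
    list(adjacent = adj, exceed_fraction = unname(exceed),
         t = unname(tt$statistic), p = unname(tt$p.value),
         cohens_d = cd, n = length(s))
  }
  list(max = one_side(stim$max, base$max, "max"),
       min = one_side(stim$min, base$min, "min"))
}

#' Between-session difference in absolute effect
#'
#' The absolute t statistic of a paired t test on the absolute effect |U| of
#' two sessions across all common valid (channel, band) cells, quantifying
#' the overall change in effect magnitude between sessions.
#'
#' @param em1,em2 `effect_matrix` objects for the two sessions.
#' @param cap Value reported when the paired differences have zero variance
#'   but nonzero mean (the t statistic diverges).
#' @return List with `statistic` (|t|), `df`, `n_cells`, `capped`.
#' @export
pair_effect_difference <- function(em1, em2, cap = 1e3) {
  common_ch <- intersect(rownames(em1$U), rownames(em2$U))
  common_bd <- intersect(colnames(em1$U), colnames(em2$U))
  a <- abs(em1$U[common_ch, common_bd, drop = FALSE])
  b <- abs(em2$U[common_ch, common_bd, drop = FALSE])
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) stopf("need >= 3 common valid cells")
  d <- a[ok] - b[ok]
  n <- length(d)
  if (stats::sd(d) <= 1e-10 * max(abs(d), 1)) {
    if (all(abs(d) <= 1e-12)) {
      return(list(statistic = 0, df = n - 1L, n_cells = n, capped = FALSE))
    }
    return(list(statistic = cap, df = n - 1L, n_cells = n, capped = TRUE))
  }
  tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
  list(statistic = unname(abs(tt$statistic)), df = unname(tt$parameter),
       n_cells = n, capped = FALSE)
}
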