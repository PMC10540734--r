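#' Choose the labelling efficiency from incorporation courses
#'
#' The asymptotic labelled fraction achievable in a partial metabolic
#' labelling experiment is estimated as the maximum labelled fraction
#' observed for any protein at any time, plus a small offset, capped
#' at 1.
#'
#' @param courses data.frame with columns `locus`, `time`, `fraction`.
#' @param offset Added to the observed maximum (default 0.01).
#' @return Efficiency in `(0, 1]`.
#' @export
choose_efficiency <- function(courses, offset = 0.01) {
  if (is.null(courses) || !nrow(courses)) stop("no labelling courses")
  if (!any(courses$time > 0)) stop("no positive-time observations")
  min(max(courses$fraction, na.rm = TRUE) + offset, 1)
}

#' Fit a first-order degradation rate to one labelling course
#'
#' Least-squares fit of `f(t) = efficiency * (1 - exp(-k * t))` to the
#' observed labelled fractions, under the assumptions of constant,
#' protein-independent labelling efficiency and equal turnover of
#' heavy and light fractions. The rate is searched over
#' `k in [1e-5, 10]` per hour with a multi-start (log-spaced coarse
#' grid followed by golden-section refinement in the best bracket).
#'
#' @param times Sampling times, hours.
#' @param fractions Observed labelled fractions in `[0, 1]`.
#' @param efficiency Labelling efficiency (see [choose_efficiency()]).
#' @param bounds Search interval for `k`, per hour.
#' @param n_starts Size of the coarse log-spaced grid.
#' @return List of class `degradation_fit`: `k_deg`, `sse`,
#'   `efficiency`, `n`.
#' @export
fit_degradation <- function(times, fractions, efficiency,
                            bounds = c(1e-5, 10), n_starts = 60) {
  ok <- !is.na(times) & !is.na(fractions)
  times <- times[ok]; fractions <- fractions[ok]
  if (!length(times)) stop("no observations")
  if (all(fractions == 0)) stop("no incorporation")
  sse <- function(k) sum((fractions - efficiency * (1 - exp(-k * times)))^2)
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_starts))
  vals <- vapply(grid, sse, 0)
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-12)
  structure(list(k_deg = opt$minimum, sse = opt$objective,
                 efficiency = efficiency, n = length(times)),
            class = "degradation_fit")
}

#' Fit degradation rates for every protein in a course table
#'
#' @param courses data.frame: `locus`, `time`, `fraction`.
#' @param efficiency Labelling efficiency; defaults to
#'   [choose_efficiency()] on the same courses.
#' @param ... Passed to [fit_degradation()].
#' @return data.frame: `locus`, `k_deg`, `sse`, `n`, `efficiency`.
#' @export
fit_degradation_all <- function(courses, efficiency = NULL, ...) {
  if (is.null(efficiency)) efficiency <- choose_efficiency(courses)
  loci <- unique(courses$locus)
  rows <- lapply(loci, function(l) {
    sub <- courses[courses$locus == l, ]
    fit <- fit_degradation(sub$time, sub$fraction, efficiency, ...)
    data.frame(locus = l, k_deg = fit$k_deg, sse = fit$sse, n = fit$n,
               efficiency = efficiency, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Dark-adaptation fold change per protein
#'
#' Fold change of within-timepoint mean abundance between two
#' dark-adaptation timepoints (default the ZT96 vs ZT24 endpoints),
#' with direction labels at the 1.5-fold gate.
#'
#' @param x A `quant_table` in condition `"DA"`.
#' @param from_zt,to_zt Reference and comparison ZTs (hours).
#' @param gate Fold gate for the increasing/decreasing labels.
#' @return data.frame: `locus`, `fold` (to/from), `log2_fold`,
#'   `direction` (`increasing`/`decreasing`/`unchanged`), `flag`.
#' @export
da_fold_change <- function(x, from_zt = 24, to_zt = 96, gate = 1.5) {
  stopifnot(inherits(x, "quant_table"))
  prof <- mean_profiles(x, condition = "DA")
  zts <- as.numeric(colnames(prof))
  if (!from_zt %in% zts || !to_zt %in% zts) {
    stop("requested ZTs not present in the DA table")
  }
  from <- prof[, as.character(from_zt)]
  to <- prof[, as.character(to_zt)]
  fold <- to / from
  flag <- ifelse(from == 0, "zero_reference", "ok")
  fold[from == 0] <- Inf
  direction <- ifelse(fold > gate, "increasing",
                      ifelse(fold < 1 / gate, "decreasing", "unchanged"))
  data.frame(locus = x$features$locus, fold = fold,
             log2_fold = log2(fold), direction = direction, flag = flag,
             stringsAsFactors = FALSE)
}

#' Classify dark-adaptation changes against the proteome average
#'
#' Labels proteins whose absolute log2 fold change exceeds the mean
#' absolute log2 fold change across proteins, and separately whether
#' they pass the 1.5-fold gate.
#'
#' @param folds Output of [da_fold_change()].
#' @return The input with logical columns `above_average` and
#'   `gt_1.5_fold`.
#' @export
classify_da_change <- function(folds) {
  lf <- abs(folds$log2_fold[is.finite(folds$log2_fold)])
  folds$above_average <- abs(folds$log2_fold) > mean(lf)
  folds$gt_1.5_fold <- folds$fold > 1.5 | folds$fold < 1 / 1.5
  folds
}

#' Correlate degradation rates with dark-adaptation fold changes
#'
#' Pearson correlation of per-protein degradation rates against DA
#' fold changes, paired by locus, reported for the full set and with
#' stated, named exclusions (outlier handling is explicit, never
#' automatic). A leave-one-out leverage report helps identify
#' candidate outliers.
#'
#' @param k_degs Named numeric vector of degradation rates, or a
#'   [fit_degradation_all()] data.frame.
#' @param folds Named numeric vector of fold changes, or a
#'   [da_fold_change()] data.frame.
#' @param exclude Character vector of loci to exclude in the secondary
#'   analysis.
#' @return List of class `kdeg_correlation`: `full` and `excluded`
#'   (each `r`, `p`, `n`), `exclusions`, `leverage` (data.frame:
#'   `locus`, `delta_r` on leave-one-out).
#' @export
correlate_kdeg_fold <- function(k_degs, folds, exclude = character()) {
  if (is.data.frame(k_degs)) {
    k_degs <- stats::setNames(k_degs$k_deg, k_degs$locus)
  }
  if (is.data.frame(folds)) folds <- stats::setNames(folds$fold, folds$locus)
  loci <- intersect(names(k_degs), names(folds))
  loci <- loci[is.finite(k_degs[loci]) & is.finite(folds[loci])]
  if (length(loci) < 3) stop("need >= 3 paired finite observations")
  x <- k_degs[loci]; y <- folds[loci]
  ct <- stats::cor.test(x, y)
  full <- list(r = unname(ct$estimate), p = ct$p.value, n = length(loci))
  keep <- !loci %in% exclude
  excluded <- if (sum(keep) >= 3 && any(!keep)) {
    ct2 <- stats::cor.test(x[keep], y[keep])
    list(r = unname(ct2$estimate), p = ct2$p.value, n = sum(keep))
  } else NULL
  leverage <- data.frame(
    locus = loci,
    delta_r = vapply(seq_along(loci), function(i) {
      stats::cor(x[-i], y[-i]) - full$r
    }, 0),
    stringsAsFactors = FALSE
  )
  structure(list(full = full, excluded = excluded, exclusions = exclude,
                 leverage = leverage[order(-abs(leverage$delta_r)), ]),
            class = "kdeg_correlation")
}

#' @export
print.kdeg_correlation <- function(x, ...) {
  cat(sprintf("k_deg vs DA fold: r = %.3f, P = %.3g, n = %d\n",
              x$full$r, x$full$p, x$full$n))
  if (!is.null(x$excluded)) {
    cat(sprintf("excluding %s: r = %.3f, P = %.3g, n = %d\n",
                paste(x$exclusions, collapse = ", "),
                x$excluded$r, x$excluded$p, x$excluded$n))
  }
  invisible(x)
}
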