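#' Cubic polynomial rhythm test for one feature series
#'
#' Fits an ordinary least-squares cubic polynomial
#' `value ~ 1 + t + t^2 + t^3` over all replicate observations (time
#' covariate = raw ZT hours, no wrap-around) and tests it against the
#' intercept-only model by an F-test (df = 3, n - 4). A cubic over one
#' 24 h window can represent one peak and one trough, the waveform
#' expected of a diel rhythm, while tolerating rising or falling
#' baselines that trip up period-detection methods on single-cycle
#' data.
#'
#' @param values Numeric vector of (transformed) abundances.
#' @param zt Numeric vector of ZT hours, same length as `values`.
#' @param null `"intercept"` (default) or `"linear"`: the reference
#'   model of the F-test.
#' @return List with `p` (F-test p-value; 1 by convention for a
#'   zero-variance series), `coefficients` (intercept, t, t^2, t^3),
#'   `fstat`, `df`.
#' @export
polynomial_rhythm_test <- function(values, zt, null = c("intercept", "linear")) {
  null <- match.arg(null)
  ok <- !is.na(values) & !is.na(zt)
  values <- values[ok]; zt <- zt[ok]
  n <- length(values)
  if (n < 5) stop("need at least 5 observations for the cubic fit")
  if (length(unique(zt)) < 2) stop("need at least 2 distinct timepoints")
  if (stats::var(values) == 0) {
    return(list(p = 1, coefficients = c(values[1], 0, 0, 0),
                fstat = 0, df = c(3, n - 4)))
  }
  X <- cbind(1, zt, zt^2, zt^3)
  fit <- stats::lm.fit(X, values)
  rss1 <- sum(fit$residuals^2)
  if (null == "intercept") {
    rss0 <- sum((values - mean(values))^2)
    df1 <- 3
  } else {
    fit0 <- stats::lm.fit(cbind(1, zt), values)
    rss0 <- sum(fit0$residuals^2)
    df1 <- 2
  }
  df2 <- n - 4
  fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  list(p = p, coefficients = stats::setNames(fit$coefficients,
                                             c("(Intercept)", "t", "t2", "t3")),
       fstat = fstat, df = c(df1, df2))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity
#' enforcement; stable under reordering of the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Assign peak and trough timepoints and fold change
#'
#' The peak (trough) time is the timepoint with the maximum (minimum)
#' within-timepoint mean; fold change is max mean / min mean on the
#' normalized, untransformed scale. Ties break toward the earlier ZT.
#'
#' @param means Numeric vector of within-timepoint means.
#' @param zt Numeric vector of the corresponding ZT hours (ascending).
#' @return List with `peak_zt`, `trough_zt`, `fold` and `flag`
#'   (`"ok"`, `"flat"` for a constant series, `"zero_min"` when the
#'   minimum mean is 0 and fold is `Inf`).
#' @export
assign_peak_trough <- function(means, zt) {
  stopifnot(length(means) == length(zt))
  ok <- !is.na(means)
  means <- means[ok]; zt <- zt[ok]
  if (!length(means)) stop("no timepoint means available")
  o <- order(zt)
  means <- means[o]; zt <- zt[o]
  if (max(means) == min(means)) {
    return(list(peak_zt = zt[1], trough_zt = zt[1], fold = 1, flag = "flat"))
  }
  peak <- zt[which.max(means)]
  trough <- zt[which.min(means)]
  if (min(means) == 0) {
    return(list(peak_zt = peak, trough_zt = trough, fold = Inf,
                flag = "zero_min"))
  }
  list(peak_zt = peak, trough_zt = trough,
       fold = max(means) / min(means), flag = "ok")
}

#' Score diel rhythmicity for every feature of a table
#'
#' Combines the cubic polynomial F-test (computed on the
#' arcsinh-transformed scale), BH false discovery adjustment, and the
#' peak/trough/fold assignment (computed on the normalized,
#' untransformed scale). A feature is called rhythmic when
#' `q < fdr` and `fold > fold_threshold`.
#'
#' @param x A normalized, untransformed `quant_table`.
#' @param fdr FDR threshold (default 0.05).
#' @param fold_threshold Fold-change gate (default 1.5).
#' @param condition Condition to analyse (default `"LD"`).
#' @param null Reference model for the F-test (see
#'   [polynomial_rhythm_test()]).
#' @return data.frame with one row per feature: `feature`, `locus`,
#'   `p`, `q`, `fold`, `peak_zt`, `trough_zt`, `rhythmic`, `flag`, and
#'   the cubic coefficients `b0`..`b3`.
#' @export
rhythm_analysis <- function(x, fdr = 0.05, fold_threshold = 1.5,
                            condition = "LD", null = "intercept") {
  stopifnot(inherits(x, "quant_table"))
  if (x$transformed) stop("pass the normalized, untransformed table")
  keep <- x$samples$condition == condition
  if (!any(keep)) stop("no samples in condition ", condition)
  sub <- subset_quant(x, samples = keep)
  trans <- arcsinh_transform(sub)
  zt <- trans$samples$zt

  nfeat <- nrow(trans$abundance)
  p <- numeric(nfeat)
  coefs <- matrix(NA_real_, nfeat, 4)
  complete <- !apply(trans$abundance, 1, anyNA)

  # fast path: one multi-response least-squares fit for complete features
  if (any(complete)) {
    X <- cbind(1, zt, zt^2, zt^3)
    Y <- t(trans$abundance[complete, , drop = FALSE])
    fit <- stats::lm.fit(X, Y)
    res <- as.matrix(fit$residuals)
    rss1 <- colSums(res^2)
    if (null == "intercept") {
      rss0 <- colSums(scale(Y, center = TRUE, scale = FALSE)^2)
      df1 <- 3
    } else {
      fit0 <- stats::lm.fit(cbind(1, zt), Y)
      rss0 <- colSums(as.matrix(fit0$residuals)^2)
      df1 <- 2
    }
    df2 <- length(zt) - 4
    fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
    pc <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
    pc[rss0 == 0] <- 1
    p[complete] <- pc
    coefs[complete, ] <- t(as.matrix(fit$coefficients))
  }
  for (i in which(!complete)) {
    r <- polynomial_rhythm_test(trans$abundance[i, ], zt, null = null)
    p[i] <- r$p
    coefs[i, ] <- r$coefficients
  }

  q <- bh_adjust(p)
  prof <- mean_profiles(sub, condition = condition)
  zts <- as.numeric(colnames(prof))
  pt <- lapply(seq_len(nrow(prof)), function(i) assign_peak_trough(prof[i, ], zts))
  fold <- vapply(pt, `[[`, 0, "fold")
  out <- data.frame(
    feature = sub$features$feature,
    locus = sub$features$locus,
    p = p, q = q, fold = fold,
    peak_zt = vapply(pt, `[[`, 0, "peak_zt"),
    trough_zt = vapply(pt, `[[`, 0, "trough_zt"),
    rhythmic = q < fdr & fold > fold_threshold,
    flag = vapply(pt, `[[`, "", "flag"),
    stringsAsFactors = FALSE
  )
  out$b0 <- coefs[, 1]; out$b1 <- coefs[, 2]
  out$b2 <- coefs[, 3]; out$b3 <- coefs[, 4]
  out
}

#' Pairwise TOST equivalence across timepoints
#'
#' Tests the statistical equivalence of mean abundance across the diel
#' cycle: for every pair of ZTs, two one-sided t-tests of the mean
#' difference against the margins `-eps` and `+eps`; the pair p-value
#' is the larger of the two one-sided p-values, and the feature's
#' equivalence p-value is the maximum over all pairs (the hardest pair
#' to call equivalent). A feature is `equivalent` when that maximum is
#' below `alpha`.
#'
#' @param x An arcsinh-transformed `quant_table` (the margin is on the
#'   transformed scale).
#' @param eps Equivalence margin (default 0.3, transformed scale).
#' @param alpha Significance level (default 0.05).
#' @param condition Condition to analyse (default `"LD"`).
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return data.frame: `feature`, `p_equiv`, `equivalent`, `eps`.
#' @export
tost_equivalence <- function(x, eps = 0.3, alpha = 0.05, condition = "LD",
                             var_equal = TRUE) {
  stopifnot(inherits(x, "quant_table"))
  if (eps <= 0) stop("equivalence margin `eps` must be positive")
  if (!x$transformed) stop("pass the arcsinh-transformed table")
  keep <- x$samples$condition == condition
  s <- x$samples[keep, ]
  ab <- x$abundance[, keep, drop = FALSE]
  zts <- sort(unique(s$zt))
  if (length(zts) < 2) stop("need at least 2 timepoints")
  pairs <- utils::combn(zts, 2)

  tost_pair <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    d <- mean(a) - mean(b)
    if (var_equal) {
      df <- length(a) + length(b) - 2
      sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
      se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    } else {
      va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
      se <- sqrt(va + vb)
      df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    }
    if (se == 0) return(if (abs(d) < eps) 0 else 1)
    # H0: delta <= -eps vs H1: delta > -eps, and H0: delta >= eps
    p_lo <- stats::pt((d + eps) / se, df, lower.tail = FALSE)
    p_hi <- stats::pt((d - eps) / se, df, lower.tail = TRUE)
    max(p_lo, p_hi)
  }

  p_equiv <- apply(ab, 1, function(v) {
    ps <- apply(pairs, 2, function(zp) {
      tost_pair(v[s$zt == zp[1]], v[s$zt == zp[2]])
    })
    if (all(is.na(ps))) NA_real_ else max(ps, na.rm = TRUE)
  })
  data.frame(feature = x$features$feature,
             p_equiv = p_equiv,
             equivalent = !is.na(p_equiv) & p_equiv < alpha,
             eps = eps,
             stringsAsFactors = FALSE)
}
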