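#' Mean-normalize sample columns
#'
#' Scales each sample column so that all column means equal the grand
#' mean of the original column means, removing per-sample loading
#' differences. Column means are computed over available (non-missing)
#' cells. The operation is idempotent.
#'
#' @param x A `quant_table` of raw, non-negative abundances.
#' @return The normalized `quant_table`; scale factors are attached as
#'   attribute `scale_factors`.
#' @export
mean_normalize <- function(x) {
  stopifnot(inherits(x, "quant_table"))
  if (x$transformed) stop("cannot normalize a transformed table")
  cm <- colMeans(x$abundance, na.rm = TRUE)
  if (any(!is.finite(cm)) || any(cm == 0)) {
    stop("all-zero or all-missing sample column(s): ",
         paste(colnames(x$abundance)[!is.finite(cm) | cm == 0], collapse = ", "))
  }
  f <- mean(cm) / cm
  x$abundance <- sweep(x$abundance, 2, f, `*`)
  x$normalized <- TRUE
  attr(x, "scale_factors") <- f
  x
}

#' Inverse hyperbolic sine transform
#'
#' Applies `x -> ln(x + sqrt(x^2 + 1))` to every abundance. Like a log
#' transform for intensity data but defined at zero; used to meet the
#' normality assumption of the rhythm statistics. Guarded against
#' double application via the `transformed` flag.
#'
#' @param x A normalized `quant_table`.
#' @return The transformed `quant_table`.
#' @export
arcsinh_transform <- function(x) {
  stopifnot(inherits(x, "quant_table"))
  if (x$transformed) stop("table is already arcsinh-transformed")
  x$abundance <- asinh(x$abundance)
  x$transformed <- TRUE
  x
}

#' Detect outlier replicates by correlation to the timepoint median
#'
#' For each replicate sample, computes the Pearson correlation of its
#' feature abundances to the per-feature median over all replicates at
#' that timepoint, and flags samples whose squared correlation falls
#' below `r2_threshold`. Features with missing values in any replicate
#' of a timepoint are skipped for that timepoint. A PCA of replicate
#' profiles is attached for QC reporting.
#'
#' @param x A `quant_table`; correlation is scale-invariant, but the
#'   variance-stabilized (arcsinh) scale is recommended.
#' @param r2_threshold Flagging threshold on r^2 (default 0.8).
#' @return data.frame with one row per sample: `key`, `condition`, `zt`,
#'   `replicate`, `r`, `r2`, `flagged`; PCA scores of replicate profiles
#'   as attribute `pca`.
#' @export
detect_outlier_replicates <- function(x, r2_threshold = 0.8) {
  stopifnot(inherits(x, "quant_table"))
  s <- x$samples
  grp <- interaction(s$condition, s$zt, drop = TRUE)
  if (any(table(grp) < 3)) stop("need >= 3 replicates per timepoint")
  r <- rep(NA_real_, nrow(s))
  for (g in levels(grp)) {
    cols <- which(grp == g)
    sub <- x$abundance[, cols, drop = FALSE]
    complete <- stats::complete.cases(sub)
    sub <- sub[complete, , drop = FALSE]
    if (nrow(sub) < 3) stop("too few complete features at timepoint ", g)
    med <- apply(sub, 1, stats::median)
    for (j in seq_along(cols)) {
      sdv <- stats::sd(sub[, j])
      r[cols[j]] <- if (sdv == 0 || stats::sd(med) == 0) NA_real_
        else stats::cor(sub[, j], med)
    }
  }
  out <- data.frame(s, r = r, r2 = r^2,
                    flagged = !is.na(r) & r^2 < r2_threshold,
                    stringsAsFactors = FALSE)
  complete_all <- stats::complete.cases(x$abundance)
  if (sum(complete_all) >= 3) {
    pc <- stats::prcomp(t(x$abundance[complete_all, , drop = FALSE]),
                        center = TRUE, scale. = FALSE)
    attr(out, "pca") <- pc$x[, seq_len(min(3, ncol(pc$x))), drop = FALSE]
  }
  out
}

#' Remove flagged replicate samples
#'
#' @param x A `quant_table`.
#' @param flags Output of [detect_outlier_replicates()], or a character
#'   vector of sample keys to drop.
#' @return The `quant_table` without the flagged samples.
#' @export
remove_outlier_replicates <- function(x, flags) {
  keys <- if (is.data.frame(flags)) flags$key[flags$flagged] else flags
  if (!length(keys)) return(x)
  subset_quant(x, samples = !x$samples$key %in% keys)
}

#' Roll peptides up to protein abundance
#'
#' Protein abundance is the per-sample sum of its unique (non-shared)
#' quantifying peptides. Proteins quantified by fewer than
#' `min_peptides` peptides are dropped and reported.
#'
#' @param x Peptide-level `quant_table` (normalized, untransformed).
#' @param mapping Optional data.frame (`feature`, `locus`); defaults to
#'   the table's own locus metadata.
#' @param min_peptides Minimum quantifying peptides per protein
#'   (default 2).
#' @return A protein-level `quant_table` (feature = locus) with
#'   attributes `dropped` (data.frame: locus, n_peptides) and
#'   `n_peptides` (named vector).
#' @export
rollup_protein <- function(x, mapping = NULL, min_peptides = 2) {
  stopifnot(inherits(x, "quant_table"))
  if (x$transformed) stop("roll up untransformed abundances")
  if (is.null(mapping)) {
    mapping <- x$features[c("feature", "locus")]
  }
  if (!nrow(mapping) || all(is.na(mapping$locus))) stop("empty peptide-locus mapping")
  mapping <- mapping[!is.na(mapping$locus) & nzchar(mapping$locus), , drop = FALSE]
  # shared peptides (multi-locus) are excluded to avoid double counting
  mapping <- mapping[!grepl(";", mapping$locus, fixed = TRUE), , drop = FALSE]
  idx <- match(mapping$feature, rownames(x$abundance))
  mapping <- mapping[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  groups <- split(idx, mapping$locus)
  n_pep <- lengths(groups)
  keep <- n_pep >= min_peptides
  if (!any(keep)) stop("no protein passes the min_peptides threshold")
  ab <- t(vapply(groups[keep], function(i) {
    colSums(x$abundance[i, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(x$abundance))))
  out <- quant_table(ab, locus = names(groups[keep]),
                     normalized = x$normalized, transformed = FALSE)
  attr(out, "dropped") <- data.frame(locus = names(groups[!keep]),
                                     n_peptides = n_pep[!keep],
                                     row.names = NULL,
                                     stringsAsFactors = FALSE)
  attr(out, "n_peptides") <- n_pep[keep]
  out
}
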