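#' Parse sample keys from column names
#'
#' Sample columns follow the dialect `<condition>_ZT<zt>_<replicate>`,
#' e.g. `LD_ZT0_A` or `DA_ZT48_C`. Condition `LD` denotes the entrained
#' light-dark cycle (Zeitgeber times 0-20 h), `DA` prolonged dark
#' adaptation (ZT24-96 h).
#'
#' @param keys Character vector of sample column names.
#' @return A data.frame with columns `key`, `condition`, `zt`
#'   (hours, numeric) and `replicate`.
#' @export
parse_sample_keys <- function(keys) {
  m <- regmatches(keys, regexec("^(LD|DA)_ZT([0-9]+(?:\\.[0-9]+)?)_([A-Za-z0-9]+)$", keys))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) {
    stop("malformed sample key(s): ", paste(keys[bad], collapse = ", "),
         " (expected <condition>_ZT<zt>_<replicate>)")
  }
  out <- data.frame(
    key = keys,
    condition = vapply(m, `[`, "", 2L),
    zt = as.numeric(vapply(m, `[`, "", 3L)),
    replicate = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$key)) {
    stop("duplicate sample key(s): ",
         paste(unique(out$key[duplicated(out$key)]), collapse = ", "))
  }
  out
}

#' Format sample keys from metadata
#'
#' Inverse of [parse_sample_keys()].
#'
#' @param condition,zt,replicate Vectors of equal length (recycled).
#' @return Character vector of sample keys.
#' @export
format_sample_keys <- function(condition, zt, replicate) {
  paste0(condition, "_ZT", format(zt, trim = TRUE, scientific = FALSE), "_", replicate)
}

#' Construct a quantitative feature table
#'
#' The central container of the pipeline: a features x samples abundance
#' matrix with parsed sample metadata. Missing cells are stored as `NA`
#' (never zero-filled); downstream means use available replicates only.
#'
#' @param abundance Numeric matrix, features in rows (rownames are
#'   feature ids), samples in columns (colnames are sample keys in the
#'   `<condition>_ZT<zt>_<replicate>` dialect).
#' @param locus Optional character vector of protein loci per feature
#'   (`NA` allowed). Features mapping to several loci are separated by
#'   `";"` and treated as shared downstream.
#' @param normalized,transformed Logical flags recording the processing
#'   state of the abundances.
#' @return An object of class `quant_table` with elements `abundance`,
#'   `features` (data.frame: `feature`, `locus`), `samples` (see
#'   [parse_sample_keys()]), `normalized`, `transformed`.
#' @export
quant_table <- function(abundance, locus = NULL, normalized = FALSE,
                        transformed = FALSE) {
  if (!is.matrix(abundance) || !is.numeric(abundance)) {
    stop("`abundance` must be a numeric matrix")
  }
  if (is.null(rownames(abundance))) stop("`abundance` must have feature ids as rownames")
  if (is.null(colnames(abundance))) stop("`abundance` must have sample keys as colnames")
  if (anyDuplicated(rownames(abundance))) {
    stop("duplicate feature id(s): ",
         paste(unique(rownames(abundance)[duplicated(rownames(abundance))]),
               collapse = ", "))
  }
  if (!transformed && any(abundance < 0, na.rm = TRUE)) {
    stop("negative abundance(s) in untransformed table")
  }
  samples <- parse_sample_keys(colnames(abundance))
  if (is.null(locus)) locus <- rep(NA_character_, nrow(abundance))
  stopifnot(length(locus) == nrow(abundance))
  structure(
    list(
      abundance = abundance,
      features = data.frame(feature = rownames(abundance),
                            locus = as.character(locus),
                            stringsAsFactors = FALSE),
      samples = samples,
      normalized = isTRUE(normalized),
      transformed = isTRUE(transformed)
    ),
    class = "quant_table"
  )
}

#' @export
print.quant_table <- function(x, ...) {
  cat("quant_table:", nrow(x$abundance), "features x", ncol(x$abundance), "samples\n")
  cat("  conditions:", paste(unique(x$samples$condition), collapse = ", "),
      "| ZTs:", paste(sort(unique(x$samples$zt)), collapse = ", "),
      "| replicates:", paste(sort(unique(x$samples$replicate)), collapse = ", "), "\n")
  cat("  normalized:", x$normalized, "| transformed:", x$transformed, "\n")
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$abundance)

#' Subset a quant_table by features and/or samples
#'
#' @param x A `quant_table`.
#' @param features Character or logical/integer index of features to keep.
#' @param samples Character or logical/integer index of sample keys to keep.
#' @return A `quant_table`.
#' @export
subset_quant <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "quant_table"))
  fi <- if (is.null(features)) seq_len(nrow(x$abundance)) else features
  si <- if (is.null(samples)) seq_len(ncol(x$abundance)) else samples
  ab <- x$abundance[fi, si, drop = FALSE]
  loc <- x$features$locus[match(rownames(ab), x$features$feature)]
  quant_table(ab, locus = loc, normalized = x$normalized,
              transformed = x$transformed)
}

#' Within-timepoint mean profiles
#'
#' Averages replicates at each (condition, ZT), skipping missing cells.
#'
#' @param x A `quant_table`.
#' @param condition Optional condition to restrict to (e.g. `"LD"`).
#' @return Numeric matrix, features x timepoints; columns named by ZT
#'   hour and ordered by increasing ZT.
#' @export
mean_profiles <- function(x, condition = NULL) {
  stopifnot(inherits(x, "quant_table"))
  s <- x$samples
  keep <- if (is.null(condition)) rep(TRUE, nrow(s)) else s$condition == condition
  if (!any(keep)) stop("no samples in condition ", condition)
  zts <- sort(unique(s$zt[keep]))
  out <- vapply(zts, function(z) {
    cols <- which(keep & s$zt == z)
    rowMeans(x$abundance[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(x$abundance)))
  out <- matrix(out, nrow = nrow(x$abundance),
                dimnames = list(x$features$feature, as.character(zts)))
  out
}
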