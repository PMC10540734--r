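#' Read a quantitative table from delimited text
#'
#' Reads TSV (`.tsv`/`.txt`) or CSV (`.csv`) tables with one row per
#' feature and one abundance column per sample. Sample columns are
#' recognised by the `<condition>_ZT<zt>_<replicate>` naming dialect;
#' all other columns are feature metadata.
#'
#' Schemas:
#' \describe{
#'   \item{protein, motif, rna}{columns `feature` (unique id), optional
#'     `locus`, plus sample columns; returns a [quant_table()].}
#'   \item{variant}{phosphopeptide technical variants: columns
#'     `variant_id`, `locus`, `sequence`, `charge`, `missed_cleavages`,
#'     `modifications` (`";"`-separated labels, may be empty),
#'     `positions` (`";"`-separated 1-based phospho positions on the
#'     protein), optional `ambiguous` (logical); returns a
#'     `phospho_variants` object.}
#' }
#'
#' @param path Path to the delimited file.
#' @param schema One of `"protein"`, `"motif"`, `"rna"`, `"variant"`.
#' @param required_samples Optional character vector of sample keys that
#'   must be present; missing ones raise an error listing the absentees.
#' @return A `quant_table` or `phospho_variants` object.
#' @export
read_quant_table <- function(path, schema = c("protein", "motif", "rna", "variant"),
                             required_samples = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  is_sample <- grepl("^(LD|DA)_ZT[0-9]+(\\.[0-9]+)?_[A-Za-z0-9]+$", names(raw))
  if (!any(is_sample)) stop("no sample columns found in ", path)
  if (!is.null(required_samples)) {
    absent <- setdiff(required_samples, names(raw)[is_sample])
    if (length(absent)) {
      stop("missing sample column(s): ", paste(absent, collapse = ", "))
    }
  }
  ab <- as.matrix(raw[is_sample])
  suppress_empty <- function(v) ifelse(v %in% c("", "NA"), NA_character_, v)
  ab <- apply(ab, 2, suppress_empty)
  num <- suppressWarnings(matrix(as.numeric(ab), nrow = nrow(raw),
                                 dimnames = list(NULL, colnames(ab))))
  malformed <- which(is.na(num) & !is.na(ab), arr.ind = TRUE)
  if (nrow(malformed)) {
    coords <- apply(malformed, 1, function(rc) {
      paste0("row ", rc[1], ", column '", colnames(ab)[rc[2]], "'")
    })
    stop("malformed abundance cell(s): ", paste(coords, collapse = "; "))
  }
  if (any(num < 0, na.rm = TRUE)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance at row ", bad[1], ", column '",
         colnames(num)[bad[2]], "'")
  }
  meta <- raw[!is_sample]

  if (schema == "variant") {
    need <- c("variant_id", "locus", "sequence", "charge",
              "missed_cleavages", "modifications", "positions")
    absent <- setdiff(need, names(meta))
    if (length(absent)) stop("variant schema requires column(s): ",
                             paste(absent, collapse = ", "))
    rownames(num) <- meta$variant_id
    return(phospho_variants(
      meta = data.frame(
        variant_id = meta$variant_id,
        locus = meta$locus,
        sequence = meta$sequence,
        charge = as.integer(meta$charge),
        missed_cleavages = as.integer(meta$missed_cleavages),
        modifications = meta$modifications,
        positions = meta$positions,
        ambiguous = if ("ambiguous" %in% names(meta))
          as.logical(meta$ambiguous) else FALSE,
        stringsAsFactors = FALSE
      ),
      abundance = num
    ))
  }

  id_col <- if ("feature" %in% names(meta)) "feature" else names(meta)[1]
  if (is.null(id_col) || !length(meta)) stop("no feature id column found")
  ids <- meta[[id_col]]
  if (anyDuplicated(ids)) {
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rownames(num) <- ids
  locus <- if ("locus" %in% names(meta)) meta$locus else NULL
  quant_table(num, locus = locus)
}

#' Write a quant_table to delimited text
#'
#' Columns are `feature`, `locus`, then sample columns in table order;
#' abundances are serialized at full double precision so that a
#' write/read round trip reproduces values to better than 1e-12
#' relative.
#'
#' @param x A `quant_table`.
#' @param path Output path; `.csv` selects comma separation, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  stopifnot(inherits(x, "quant_table"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # full precision so that read(write(x)) == x to ~1e-12 relative
  ab <- matrix(sprintf("%.17g", x$abundance), nrow = nrow(x$abundance),
               dimnames = dimnames(x$abundance))
  ab[is.na(x$abundance)] <- ""
  out <- data.frame(feature = x$features$feature, locus = x$features$locus,
                    ab, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result set to TSV or JSON
#'
#' @param results A non-empty data.frame of results.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("`results` must be a non-empty data.frame")
  }
  if (format == "tsv") {
    out <- results
    for (j in seq_along(out)) {
      if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
        out[[j]] <- format(out[[j]], digits = 10, trim = TRUE)
      }
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a result set written by [write_results()]
#'
#' @param path Path to a `.tsv` or `.json` result file.
#' @return A data.frame.
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that truncates
#' FASTA headers at the first whitespace so names match locus ids.
#'
#' @param path FASTA file path.
#' @return An `AAStringSet` named by locus.
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}
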