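#' Construct a set of phosphopeptide technical variants
#'
#' A variant is one quantified peptide species: a peptide sequence at a
#' particular charge state, missed-cleavage count and co-modification
#' set, carrying one or more phospho-sites. Label-free quantification
#' reports each such species separately; [merge_variants()] collapses
#' them into phosphopeptide motifs.
#'
#' @param meta data.frame with columns `variant_id` (unique), `locus`,
#'   `sequence`, `charge` (2-4), `missed_cleavages`, `modifications`
#'   (`";"`-separated labels, `""` for none), `positions`
#'   (`";"`-separated 1-based phospho positions on the protein),
#'   `ambiguous` (logical).
#' @param abundance Numeric matrix, one row per variant (rownames =
#'   `variant_id`), sample keys as colnames.
#' @return An object of class `phospho_variants`.
#' @export
phospho_variants <- function(meta, abundance) {
  stopifnot(is.data.frame(meta), is.matrix(abundance))
  need <- c("variant_id", "locus", "sequence", "charge", "missed_cleavages",
            "modifications", "positions")
  absent <- setdiff(need, names(meta))
  if (length(absent)) stop("variant meta requires column(s): ",
                           paste(absent, collapse = ", "))
  if (anyDuplicated(meta$variant_id)) stop("duplicate variant_id")
  if (nrow(meta) != nrow(abundance)) stop("meta/abundance row mismatch")
  if (!"ambiguous" %in% names(meta)) meta$ambiguous <- FALSE
  rownames(abundance) <- meta$variant_id
  samples <- parse_sample_keys(colnames(abundance))
  structure(list(meta = meta, abundance = abundance, samples = samples),
            class = "phospho_variants")
}

#' @export
print.phospho_variants <- function(x, ...) {
  cat("phospho_variants:", nrow(x$meta), "variants x",
      ncol(x$abundance), "samples;",
      length(unique(x$meta$locus)), "loci\n")
  invisible(x)
}

parse_positions <- function(p) {
  lapply(strsplit(as.character(p), ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    sort(as.integer(v))
  })
}

site_key <- function(pos) vapply(pos, paste, "", collapse = "+")

#' Resolve ambiguous phospho-site assignments
#'
#' Variants flagged as having ambiguous site localization are
#' cross-referenced against an independent table of most-probable site
#' predictions, keyed by (peptide sequence, charge, number of residue
#' modifications). When a prediction matches the key, its site
#' assignment replaces the variant's and the variant is flagged
#' `reassigned`; otherwise the variant keeps its assignment and is
#' flagged `unconfirmed`. When several matching predictions disagree,
#' the highest-confidence one wins; ties break toward the original
#' assignment.
#'
#' @param variants A `phospho_variants` object.
#' @param predictions data.frame with columns `sequence`, `charge`,
#'   `n_mods` (modification count including phospho), `positions`
#'   (`";"`-separated), optional `confidence`.
#' @return The `phospho_variants` with updated `positions` and a
#'   `site_flag` column (`original`, `reassigned` or `unconfirmed`).
#' @export
resolve_ambiguous_sites <- function(variants, predictions) {
  stopifnot(inherits(variants, "phospho_variants"))
  m <- variants$meta
  n_mods <- vapply(strsplit(m$modifications, ";", fixed = TRUE),
                   function(v) sum(nzchar(v)), 0L) +
    lengths(parse_positions(m$positions))
  m$site_flag <- "original"
  if (!is.null(predictions) && nrow(predictions)) {
    if (!"confidence" %in% names(predictions)) predictions$confidence <- 1
    pk <- paste(predictions$sequence, predictions$charge, predictions$n_mods,
                sep = "|")
    vk <- paste(m$sequence, m$charge, n_mods, sep = "|")
    for (i in which(m$ambiguous)) {
      hits <- which(pk == vk[i])
      if (!length(hits)) {
        m$site_flag[i] <- "unconfirmed"
        next
      }
      best <- hits[which.max(predictions$confidence[hits])]
      top <- predictions$confidence[hits] == predictions$confidence[best]
      cand <- unique(predictions$positions[hits][top])
      if (length(cand) > 1 && m$positions[i] %in% cand) {
        # tied predictions disagree: keep the original assignment
        m$site_flag[i] <- "original"
      } else if (identical(predictions$positions[best], m$positions[i])) {
        m$site_flag[i] <- "original"
      } else {
        m$positions[i] <- predictions$positions[best]
        m$site_flag[i] <- "reassigned"
      }
    }
  } else {
    m$site_flag[m$ambiguous] <- "unconfirmed"
  }
  variants$meta <- m
  variants
}

#' Merge technical phosphopeptide variants into phosphopeptide motifs
#'
#' Collapses variant redundancy arising from charge states (2+ to 4+),
#' missed cleavages and co-modifications (e.g. oxidation, acetylation)
#' by summing abundances over all variants that share phosphorylation
#' of the same residue set on the same protein. The grouping key is
#' (protein locus, exact set of phospho positions), so a doubly
#' phosphorylated site set is a distinct motif from its singly
#' phosphorylated subsets. Output order is deterministic: by locus,
#' then site key.
#'
#' @param variants A `phospho_variants` object (optionally passed
#'   through [resolve_ambiguous_sites()] first).
#' @param ambiguous `"keep"` (default) retains variants whose ambiguous
#'   sites could not be confirmed; `"drop"` discards them.
#' @param sequences Optional named `AAStringSet` of protein sequences
#'   used to validate phospho positions (within length, residue S/T/Y).
#' @return A list with `motifs` (a [quant_table()] whose feature ids are
#'   `locus:siteKey` and whose `features` carry `locus`, `site_key`,
#'   `n_members`, `member_ids`) and `report` (a `merge_report` list:
#'   `n_in`, `n_motifs`, `n_ambiguous_resolved`, `n_discarded`,
#'   `discarded` data.frame with reasons).
#' @export
merge_variants <- function(variants, ambiguous = c("keep", "drop"),
                           sequences = NULL) {
  ambiguous <- match.arg(ambiguous)
  stopifnot(inherits(variants, "phospho_variants"))
  m <- variants$meta
  ab <- variants$abundance
  if (!"site_flag" %in% names(m)) m$site_flag <- "original"

  pos <- parse_positions(m$positions)
  discard_reason <- rep(NA_character_, nrow(m))
  discard_reason[lengths(pos) == 0] <- "no_sites"
  discard_reason[grepl(";", m$locus, fixed = TRUE) & is.na(discard_reason)] <- "shared"
  if (ambiguous == "drop") {
    discard_reason[m$site_flag == "unconfirmed" & is.na(discard_reason)] <- "unconfirmed"
  }

  if (!is.null(sequences)) {
    sq <- as.character(sequences)
    if (anyDuplicated(names(sq))) {
      dup <- unique(names(sq)[duplicated(names(sq))])
      conflict <- vapply(dup, function(l) length(unique(sq[names(sq) == l])) > 1,
                         TRUE)
      if (any(conflict)) {
        stop("conflicting sequence(s) for locus: ",
             paste(dup[conflict], collapse = ", "))
      }
    }
    for (i in which(is.na(discard_reason))) {
      s <- sq[[m$locus[i]]]
      if (is.null(s) || is.na(s)) next
      if (any(pos[[i]] > nchar(s))) {
        stop("phospho position beyond sequence length for ", m$locus[i])
      }
      res <- substring(s, pos[[i]], pos[[i]])
      if (!all(res %in% c("S", "T", "Y"))) {
        stop("non-S/T/Y phospho residue for ", m$locus[i], " at ",
             paste(pos[[i]][!res %in% c("S", "T", "Y")], collapse = ","))
      }
    }
  }

  keep <- which(is.na(discard_reason))
  if (!length(keep)) stop("no variants left to merge")
  key <- paste(m$locus[keep], site_key(pos[keep]), sep = ":")
  groups <- split(keep, key)
  ord <- order(names(groups))
  groups <- groups[ord]

  motif_ab <- t(vapply(groups, function(idx) {
    colSums(ab[idx, , drop = FALSE], na.rm = FALSE)
  }, numeric(ncol(ab))))
  # a motif sample is NA only when every member is NA there
  all_na <- t(vapply(groups, function(idx) {
    apply(ab[idx, , drop = FALSE], 2, function(v) all(is.na(v)))
  }, logical(ncol(ab))))
  partial <- t(vapply(groups, function(idx) {
    colSums(ab[idx, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(ab))))
  motif_ab[is.na(motif_ab)] <- partial[is.na(motif_ab)]
  motif_ab[all_na] <- NA_real_
  rownames(motif_ab) <- names(groups)

  locus <- vapply(groups, function(idx) m$locus[idx[1]], "")
  motifs <- quant_table(motif_ab, locus = locus)
  motifs$features$site_key <- vapply(groups, function(idx) site_key(pos[idx[1]]), "")
  motifs$features$n_members <- lengths(groups)
  motifs$features$member_ids <- vapply(groups, function(idx) {
    paste(m$variant_id[idx], collapse = ";")
  }, "")

  discarded <- data.frame(
    variant_id = m$variant_id[!is.na(discard_reason)],
    reason = discard_reason[!is.na(discard_reason)],
    stringsAsFactors = FALSE
  )
  report <- structure(list(
    n_in = nrow(m),
    n_motifs = length(groups),
    n_ambiguous_resolved = sum(m$site_flag == "reassigned"),
    n_discarded = nrow(discarded),
    discarded = discarded
  ), class = "merge_report")
  stopifnot(report$n_in == sum(motifs$features$n_members) + report$n_discarded)
  list(motifs = motifs, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat("merge_report:", x$n_in, "variants ->", x$n_motifs, "motifs;",
      x$n_ambiguous_resolved, "reassigned;", x$n_discarded, "discarded\n")
  if (x$n_discarded) print(table(x$discarded$reason))
  invisible(x)
}
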