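#' PCA of temporal mean profiles
#'
#' Rows (features) are observations and ZT columns variables; profiles
#' are zero-centred per feature before an SVD-based decomposition, so
#' the components capture profile shape rather than absolute level.
#' The sign of each component is fixed so that its largest-magnitude
#' loading is positive, making the output deterministic.
#'
#' @param profiles Numeric matrix, features x ZT (e.g. from
#'   [mean_profiles()]).
#' @return List with `scores` (features x PC), `loadings` (ZT x PC),
#'   `variance_fraction` (sums to 1).
#' @export
pca_profiles <- function(profiles) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 3)
  x <- profiles - rowMeans(profiles)
  if (all(abs(x) < .Machine$double.eps * 100)) {
    stop("constant profiles: no variance to decompose")
  }
  sv <- svd(x)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  scores <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k)
  loadings <- sv$v[, 1:k, drop = FALSE]
  # sign convention: largest |loading| of each PC is positive
  for (j in seq_len(k)) {
    s <- sign(loadings[which.max(abs(loadings[, j])), j])
    if (s < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(profiles), paste0("PC", 1:k))
  dimnames(loadings) <- list(colnames(profiles), paste0("PC", 1:k))
  vf <- sv$d[1:k]^2 / sum(sv$d^2)
  list(scores = scores, loadings = loadings,
       variance_fraction = stats::setNames(vf, paste0("PC", 1:k)))
}

#' Cluster temporal profiles with a dynamic hybrid tree cut
#'
#' Profiles are z-scaled per feature, the distance matrix is
#' `1 - Pearson r`, and the dendrogram is built with Ward linkage.
#' Clusters are then formed by a hybrid cut: branches are evaluated
#' top-down from the root, and a branch is split when its merge height
#' exceeds the cut height (joins above the ceiling are never accepted)
#' or when it exceeds `split_factor` times the internal height of its
#' taller child — the branch-separation criterion that adapts the cut
#' to each part of the tree instead of slicing at one fixed height.
#' Branches that survive splitting become clusters; undersized ones
#' (fewer than `min_cluster_size` members) are left unassigned.
#' Clusters are labelled by decreasing size.
#'
#' @param profiles Numeric matrix, features x ZT.
#' @param cut_height Height ceiling on the Ward dendrogram
#'   (default 100; if it exceeds the tree height the whole tree is
#'   eligible and only the separation criterion drives the cut).
#' @param min_cluster_size Minimum members per cluster (default 20).
#' @param split_factor Branch-separation ratio above which a join is
#'   considered to bridge distinct clusters (default 4).
#' @param prefix Cluster label prefix (e.g. `"P"` for proteins, `"PM"`
#'   for phosphopeptide motifs).
#' @return data.frame: `feature`, `cluster` (label or `"unassigned"`);
#'   the `hclust` tree is attached as attribute `tree`.
#' @export
cluster_profiles <- function(profiles, cut_height = 100,
                             min_cluster_size = 20, split_factor = 4,
                             prefix = "C") {
  stopifnot(is.matrix(profiles))
  n <- nrow(profiles)
  if (n < min_cluster_size) {
    warning("fewer features than min_cluster_size: all unassigned")
    return(data.frame(feature = rownames(profiles),
                      cluster = "unassigned", stringsAsFactors = FALSE))
  }
  z <- t(scale(t(profiles)))
  sdz <- apply(profiles, 1, stats::sd)
  z[sdz == 0, ] <- 0
  d <- stats::as.dist(1 - stats::cor(t(z)))
  d[!is.finite(d)] <- 1
  tree <- stats::hclust(d, method = "ward.D2")

  # recursive branch evaluation from the root
  node_height <- function(node) if (node < 0) 0 else tree$height[node]
  members <- function(node) {
    if (node < 0) return(-node)
    c(members(tree$merge[node, 1]), members(tree$merge[node, 2]))
  }
  clusters <- list()
  eval_node <- function(node) {
    if (node < 0) {
      clusters[[length(clusters) + 1]] <<- -node
      return(invisible())
    }
    h <- tree$height[node]
    child_h <- max(node_height(tree$merge[node, 1]),
                   node_height(tree$merge[node, 2]))
    split <- h > cut_height ||
      (h > split_factor * child_h && h > .Machine$double.eps^0.5)
    if (split) {
      eval_node(tree$merge[node, 1])
      eval_node(tree$merge[node, 2])
    } else {
      clusters[[length(clusters) + 1]] <<- members(node)
    }
  }
  eval_node(nrow(tree$merge))

  lab <- rep("unassigned", n)
  sizes <- lengths(clusters)
  ok <- which(sizes >= min_cluster_size)
  ok <- ok[order(-sizes[ok])]
  for (j in seq_along(ok)) lab[clusters[[ok[j]]]] <- paste0(prefix, j)
  out <- data.frame(feature = rownames(profiles), cluster = lab,
                    stringsAsFactors = FALSE)
  attr(out, "tree") <- tree
  out
}

#' Distribution of peak times among rhythmic features
#'
#' @param results A [rhythm_analysis()] data.frame.
#' @param rhythmic_only Restrict to features passing the rhythmicity
#'   call (default TRUE).
#' @param zts Timepoint bins (defaults to the ZTs present).
#' @return data.frame: `zt`, `count`, `fraction` (fractions sum to 1).
#' @export
peak_phase_distribution <- function(results, rhythmic_only = TRUE,
                                    zts = NULL) {
  r <- if (rhythmic_only) results[results$rhythmic, , drop = FALSE] else results
  if (!nrow(r)) stop("no rhythmic features")
  if (is.null(zts)) zts <- sort(unique(results$peak_zt))
  cnt <- vapply(zts, function(z) sum(r$peak_zt == z), 0L)
  data.frame(zt = zts, count = cnt, fraction = cnt / sum(cnt))
}

#' Pair protein peaks with the peaks of their phosphopeptide motifs
#'
#' Joins protein-level and motif-level rhythm results on protein locus
#' and reports, per (protein, motif) pairing, whether the two peak at
#' different timepoints; the summary is the fraction of pairings with
#' differing peaks.
#'
#' @param protein_results,motif_results [rhythm_analysis()] data.frames
#'   (motif results must carry a `locus` column).
#' @param rhythmic_only Restrict both sides to rhythmic features
#'   (default FALSE, i.e. all quantified pairings are reported).
#' @return data.frame of pairings with attribute
#'   `fraction_differing`.
#' @export
pair_protein_phospho <- function(protein_results, motif_results,
                                 rhythmic_only = FALSE) {
  pr <- protein_results
  mo <- motif_results
  if (rhythmic_only) {
    pr <- pr[pr$rhythmic, , drop = FALSE]
    mo <- mo[mo$rhythmic, , drop = FALSE]
  }
  common <- intersect(pr$locus, mo$locus)
  common <- common[!is.na(common)]
  if (!length(common)) stop("no shared loci between protein and motif results")
  mo <- mo[mo$locus %in% common, , drop = FALSE]
  i <- match(mo$locus, pr$locus)
  out <- data.frame(
    locus = mo$locus,
    motif = mo$feature,
    protein_peak_zt = pr$peak_zt[i],
    motif_peak_zt = mo$peak_zt,
    differs = pr$peak_zt[i] != mo$peak_zt,
    stringsAsFactors = FALSE
  )
  attr(out, "fraction_differing") <- mean(out$differs)
  out
}

#' Category enrichment by Fisher's exact or KS-on-loadings test
#'
#' For flat term-to-feature annotations (no ontology structure):
#' `fisher` tests each term's 2x2 membership table (in the feature set
#' of interest x annotated with the term) over the background by a
#' two-sided Fisher's exact test; `ks_on_loadings` compares the
#' absolute PCA loadings (feature scores) of term members against
#' non-members by a two-sample Kolmogorov-Smirnov test, asking whether
#' term members carry systematically higher weight in a component.
#' P-values are BH-adjusted across terms.
#'
#' @param members Character vector: the feature set of interest
#'   (ignored in `ks_on_loadings` mode).
#' @param background Character vector: all eligible features.
#' @param annotation data.frame with columns `term`, `feature`.
#' @param mode `"fisher"` or `"ks_on_loadings"`.
#' @param loadings Named numeric vector of per-feature loading
#'   magnitudes (required for `ks_on_loadings`).
#' @return data.frame: `term`, `n_term`, `k_members` (fisher only),
#'   `statistic`, `p`, `q`.
#' @export
category_enrichment <- function(members, background, annotation,
                                mode = c("fisher", "ks_on_loadings"),
                                loadings = NULL) {
  mode <- match.arg(mode)
  if (mode == "fisher" && length(setdiff(members, background))) {
    stop("`members` must be a subset of `background`")
  }
  annotation <- annotation[annotation$feature %in% background, , drop = FALSE]
  terms <- unique(annotation$term)
  rows <- lapply(terms, function(tm) {
    in_term <- background %in% annotation$feature[annotation$term == tm]
    if (!any(in_term)) {
      warning("term with zero background members skipped: ", tm)
      return(NULL)
    }
    if (mode == "fisher") {
      in_set <- background %in% members
      tab <- table(factor(in_set, c(TRUE, FALSE)),
                   factor(in_term, c(TRUE, FALSE)))
      ft <- stats::fisher.test(tab)
      data.frame(term = tm, n_term = sum(in_term),
                 k_members = sum(in_set & in_term),
                 statistic = unname(ft$estimate), p = ft$p.value,
                 stringsAsFactors = FALSE)
    } else {
      if (is.null(loadings)) stop("`loadings` required for ks_on_loadings")
      lv <- abs(loadings[background])
      if (all(in_term) || !any(in_term)) return(NULL)
      ks <- suppressWarnings(stats::ks.test(lv[in_term], lv[!in_term]))
      data.frame(term = tm, n_term = sum(in_term), k_members = NA_integer_,
                 statistic = unname(ks$statistic), p = ks$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no testable terms")
  out$q <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}
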