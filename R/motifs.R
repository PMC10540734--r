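AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
PAD <- "_"

#' Extract +/-7 sequence windows around phospho-sites
#'
#' Returns the 15-residue window centred on each phospho residue
#' (1-based protein coordinates); positions beyond the termini are
#' padded with `_`, which is excluded from all counting downstream.
#'
#' @param sites data.frame with columns `locus`, `position`; extra
#'   columns are carried through.
#' @param sequences Named `AAStringSet` (or named character vector)
#'   covering all loci.
#' @param flank Residues either side of the site (default 7).
#' @return data.frame: the input columns plus `window` (character,
#'   length `2*flank+1`) and `centre` (the phospho residue).
#' @export
extract_windows <- function(sites, sequences, flank = 7) {
  seqs <- if (is.character(sequences)) sequences
          else stats::setNames(as.character(sequences), names(sequences))
  missing <- setdiff(unique(sites$locus), names(seqs))
  if (length(missing)) {
    stop("sequence(s) missing for locus: ", paste(missing, collapse = ", "))
  }
  win <- character(nrow(sites))
  centre <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- seqs[[sites$locus[i]]]
    p <- sites$position[i]
    if (p < 1 || p > nchar(s)) {
      stop("position ", p, " outside sequence for locus ", sites$locus[i])
    }
    idx <- (p - flank):(p + flank)
    chars <- ifelse(idx >= 1 & idx <= nchar(s),
                    substring(s, idx, idx), PAD)
    win[i] <- paste(chars, collapse = "")
    centre[i] <- substring(s, p, p)
  }
  out <- sites
  out$window <- win
  out$centre <- centre
  out
}

window_matrix <- function(windows, flank = 7) {
  m <- do.call(rbind, strsplit(windows, ""))
  colnames(m) <- as.character(-flank:flank)
  m
}

#' Position-specific binomial residue enrichment (pLogo-style)
#'
#' For every window position (-7..+7, excluding the conditioned
#' phospho position 0) and residue, counts foreground occurrences `k`
#' out of `n` windows with a real (non-pad) residue at that position,
#' takes the background per-position residue frequency `p`, and scores
#' over-representation by the binomial tail `P(X >= k)` and
#' under-representation by `P(X <= k)`, `X ~ Binomial(n, p)`. Height
#' is `-log10` of the tail p-value, signed negative for
#' under-representation; p-values are floored at 1e-300. The
#' significance line is the Bonferroni threshold
#' `-log10(alpha / (20 residues x 15 positions))`.
#'
#' @param foreground,background Character vectors of 15-mer windows
#'   (from [extract_windows()]); the background should contain all
#'   detected sites to avoid detection bias.
#' @param alpha Significance level for the threshold line
#'   (default 0.05).
#' @param flank Window flank (default 7).
#' @return List of class `logo_result`: `heights` (data.frame:
#'   `position`, `residue`, `k`, `n`, `p_bg`, `p_value`, `height`,
#'   `significant`, `flag`), `threshold`.
#' @export
binomial_logo <- function(foreground, background, alpha = 0.05, flank = 7) {
  if (!length(foreground)) stop("empty foreground")
  fg <- window_matrix(foreground, flank)
  bg <- window_matrix(background, flank)
  positions <- setdiff(-flank:flank, 0)
  threshold <- round(-log10(alpha / (length(AA20) * (2 * flank + 1))), 2)
  rows <- vector("list", length(positions) * length(AA20))
  r <- 0
  for (pos in positions) {
    cfg <- fg[, as.character(pos)]
    cbg <- bg[, as.character(pos)]
    cfg <- cfg[cfg != PAD]
    cbg <- cbg[cbg != PAD]
    n <- length(cfg)
    for (res in AA20) {
      r <- r + 1
      k <- sum(cfg == res)
      p_bg <- if (length(cbg)) mean(cbg == res) else 0
      if (n == 0) {
        rows[[r]] <- data.frame(position = pos, residue = res, k = 0L,
                                n = 0L, p_bg = p_bg, p_value = 1,
                                height = 0, flag = "no_observations",
                                stringsAsFactors = FALSE)
        next
      }
      p_over <- stats::pbinom(k - 1, n, p_bg, lower.tail = FALSE)
      p_under <- stats::pbinom(k, n, p_bg)
      if (k / n > p_bg) {
        pv <- max(p_over, 1e-300)
        height <- -log10(pv)
      } else {
        pv <- max(p_under, 1e-300)
        height <- log10(pv)
      }
      rows[[r]] <- data.frame(position = pos, residue = res, k = k, n = n,
                              p_bg = p_bg, p_value = pv, height = height,
                              flag = "ok", stringsAsFactors = FALSE)
    }
  }
  heights <- do.call(rbind, rows)
  heights$significant <- abs(heights$height) >= threshold
  structure(list(heights = heights, threshold = threshold),
            class = "logo_result")
}

#' @export
print.logo_result <- function(x, ...) {
  sig <- x$heights[x$heights$significant, ]
  cat("logo_result: threshold +/-", x$threshold, ";",
      nrow(sig), "significant (position, residue) cells\n")
  if (nrow(sig)) print(utils::head(sig[order(-abs(sig$height)), ], 10),
                       row.names = FALSE)
  invisible(x)
}

#' Grouped-residue binomial enrichment
#'
#' Tests the combined occurrence of a residue group (e.g. the acidic
#' D/E positions of the CK2 consensus) at a set of window positions:
#' success for a window is any group residue at any listed position
#' (pads excluded); the background rate of that event gives the
#' binomial null.
#'
#' @param foreground,background Character vectors of windows.
#' @param group Character vector of residues (e.g. `c("D", "E")`).
#' @param positions Integer positions in -7..+7.
#' @param flank Window flank.
#' @return data.frame: `k`, `n`, `p_bg`, `p_value`, `direction`.
#' @export
grouped_binomial <- function(foreground, background, group, positions,
                             flank = 7) {
  if (!length(group)) stop("empty residue group")
  if (any(positions < -flank | positions > flank)) {
    stop("positions must lie in -", flank, "..+", flank)
  }
  event <- function(wins) {
    m <- window_matrix(wins, flank)
    sub <- m[, as.character(positions), drop = FALSE]
    apply(sub, 1, function(v) any(v %in% group))
  }
  fe <- event(foreground)
  be <- event(background)
  k <- sum(fe); n <- length(fe)
  p_bg <- mean(be)
  p_over <- stats::pbinom(k - 1, n, p_bg, lower.tail = FALSE)
  p_under <- stats::pbinom(k, n, p_bg)
  over <- k / n > p_bg
  data.frame(k = k, n = n, p_bg = p_bg,
             p_value = max(if (over) p_over else p_under, 1e-300),
             direction = if (over) "over" else "under",
             stringsAsFactors = FALSE)
}

#' Kinase-consensus motif classes
#'
#' Declarative stand-ins for kinase target consensus patterns over the
#' +/-7 window (these regex-style classes approximate consensus
#' definitions that dedicated kinase-prediction tools refine):
#' \describe{
#'   \item{proline_directed}{P at +1 (CMGC family: CDK, MAPK, GSK).}
#'   \item{cdk_like}{P at +1 and K/R at +4
#'     (full CDK consensus \[pS/pT\]PXX\[K/R\]).}
#'   \item{acid_directed}{D/E at any of +1..+3 (CK1/CK2-style).}
#'   \item{hydrophobic_directed}{hydrophobic (A/I/L/M/F/V) at both -5
#'     and +4 (SnRK/AMPK-like).}
#' }
#'
#' @param hydrophobic Residue set used for the hydrophobic class.
#' @return Named list of class definitions; each has `name` and
#'   `rules`, a list of `(positions, residues, scope)` where scope
#'   `"any"` requires a hit at some listed position and `"all"` at
#'   every listed position.
#' @export
motif_classes <- function(hydrophobic = c("A", "I", "L", "M", "F", "V")) {
  list(
    proline_directed = list(
      name = "proline_directed",
      rules = list(list(positions = 1, residues = "P", scope = "any"))
    ),
    cdk_like = list(
      name = "cdk_like",
      rules = list(list(positions = 1, residues = "P", scope = "any"),
                   list(positions = 4, residues = c("K", "R"), scope = "any"))
    ),
    acid_directed = list(
      name = "acid_directed",
      rules = list(list(positions = 1:3, residues = c("D", "E"),
                        scope = "any"))
    ),
    hydrophobic_directed = list(
      name = "hydrophobic_directed",
      rules = list(list(positions = c(-5, 4), residues = hydrophobic,
                        scope = "all"))
    )
  )
}

#' Match windows against a motif class
#'
#' @param windows Character vector of 15-mer windows.
#' @param class One element of [motif_classes()].
#' @param flank Window flank.
#' @return Logical vector.
#' @export
match_motif_class <- function(windows, class, flank = 7) {
  m <- window_matrix(windows, flank)
  hit <- rep(TRUE, nrow(m))
  for (rule in class$rules) {
    sub <- m[, as.character(rule$positions), drop = FALSE]
    rh <- if (identical(rule$scope, "all")) {
      apply(sub, 1, function(v) all(v %in% rule$residues))
    } else {
      apply(sub, 1, function(v) any(v %in% rule$residues))
    }
    hit <- hit & rh
  }
  hit
}

#' Phase-specific kinase-consensus enrichment
#'
#' For each peak-phase bin of the rhythmic phosphopeptide motifs and
#' each consensus class, counts class matches among motifs peaking at
#' that ZT and scores them against the class rate in the full detected
#' background (all quantified windows, to avoid detection bias) by a
#' binomial tail test; BH adjustment is applied across all
#' (ZT, class) cells.
#'
#' @param rhythm_results A [rhythm_analysis()] data.frame for the
#'   motifs; only rows with `rhythmic == TRUE` are used.
#' @param windows data.frame from [extract_windows()] with a `feature`
#'   column matching `rhythm_results$feature`.
#' @param background_windows Character vector of all detected windows.
#' @param classes List from [motif_classes()].
#' @return data.frame: `zt`, `class`, `k`, `n`, `p_bg`, `fold`,
#'   `p_value`, `direction`, `q`.
#' @export
phase_motif_enrichment <- function(rhythm_results, windows,
                                   background_windows,
                                   classes = motif_classes()) {
  rh <- rhythm_results[rhythm_results$rhythmic, , drop = FALSE]
  i <- match(rh$feature, windows$feature)
  rh <- rh[!is.na(i), , drop = FALSE]
  win <- windows$window[i[!is.na(i)]]
  if (!nrow(rh)) stop("no rhythmic motifs with windows")
  zts <- sort(unique(rh$peak_zt))
  bg_rate <- vapply(classes, function(cl) {
    mean(match_motif_class(background_windows, cl))
  }, 0)
  rows <- list()
  for (z in zts) {
    at_z <- rh$peak_zt == z
    n <- sum(at_z)
    if (n == 0) {
      warning("no rhythmic motifs peaking at ZT", z, "; skipped")
      next
    }
    for (ci in seq_along(classes)) {
      cl <- classes[[ci]]
      k <- sum(match_motif_class(win[at_z], cl))
      p_bg <- bg_rate[ci]
      over <- k / n > p_bg
      pv <- if (p_bg %in% c(0, 1)) 1
            else if (over) stats::pbinom(k - 1, n, p_bg, lower.tail = FALSE)
            else stats::pbinom(k, n, p_bg)
      rows[[length(rows) + 1]] <- data.frame(
        zt = z, class = cl$name, k = k, n = n, p_bg = p_bg,
        fold = if (p_bg > 0) (k / n) / p_bg else NA_real_,
        p_value = max(pv, 1e-300),
        direction = if (over) "over" else "under",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p_value)
  out
}
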