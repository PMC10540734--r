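#' Specification for a synthetic diel dataset
#'
#' Defines the statistical structure of a simulated label-free diel
#' time course: 6 Zeitgeber times x 5 replicates by default, a
#' controllable fraction of rhythmic features with cosine profiles,
#' multiplicative lognormal replicate noise, per-sample loading
#' factors, and baselines drawn log-uniformly over four decades to
#' emulate the dynamic range of intensity data.
#'
#' @param n_features Number of features (proteins or motifs).
#' @param frac_rhythmic Fraction of features given a cosine rhythm.
#' @param fold Peak/trough fold change of rhythmic features (scalar or
#'   sampler function of n).
#' @param phase Phase sampler: `"uniform"` over `[0, 24)` or a function
#'   of n returning hours.
#' @param cv Replicate noise coefficient of variation (lognormal).
#' @param loading_spread Lognormal sigma of per-sample loading factors.
#' @param zts Sampled Zeitgeber times (hours).
#' @param replicates Replicate labels.
#' @param condition `"LD"` or `"DA"`.
#' @param n_loci Number of protein loci features are assigned to
#'   (several features may share a locus); defaults to one per feature.
#' @param baseline_range log10 range of feature baselines.
#' @param seed Integer seed; identical specs give identical output.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_features = 855, frac_rhythmic = 0.5, fold = 3,
                     phase = "uniform", cv = 0.1, loading_spread = 0.05,
                     zts = c(0, 4, 8, 12, 16, 20),
                     replicates = LETTERS[1:5], condition = "LD",
                     n_loci = n_features, baseline_range = c(3, 7),
                     seed = 1L) {
  if (frac_rhythmic < 0 || frac_rhythmic > 1) {
    stop("`frac_rhythmic` must lie in [0, 1]")
  }
  if (cv <= 0) stop("`cv` must be positive")
  structure(list(n_features = n_features, frac_rhythmic = frac_rhythmic,
                 fold = fold, phase = phase, cv = cv,
                 loading_spread = loading_spread, zts = zts,
                 replicates = replicates, condition = condition,
                 n_loci = n_loci, baseline_range = baseline_range,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

lognormal_noise <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic diel quantification table
#'
#' Noise-free abundance of feature i at time t is
#' `baseline_i * (1 + A_i * cos(2*pi*(t - phi_i)/24))`, with amplitude
#' `A = (fold - 1)/(fold + 1)` so that the max/min ratio of the
#' noise-free means equals the requested peak/trough fold exactly;
#' non-rhythmic features have `A = 0`. Observed cells multiply in
#' lognormal replicate noise (unit mean) and a per-sample loading
#' factor.
#'
#' @param spec A [sim_spec()].
#' @return List with `table` (a [quant_table()]) and `truth`
#'   (data.frame: `feature`, `locus`, `rhythmic`, `phase`, `fold`,
#'   `baseline`).
#' @export
generate_ld_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_features
    ids <- sprintf("f%04d", seq_len(n))
    loci <- sprintf("ostta%05d", sample.int(spec$n_loci, n, replace = TRUE))
    rhythmic <- seq_len(n) <= round(spec$frac_rhythmic * n)
    phase <- if (is.function(spec$phase)) spec$phase(n)
             else stats::runif(n, 0, 24)
    fold <- if (is.function(spec$fold)) spec$fold(n) else rep(spec$fold, n)
    A <- ifelse(rhythmic, (fold - 1) / (fold + 1), 0)
    baseline <- 10^stats::runif(n, spec$baseline_range[1], spec$baseline_range[2])

    keys <- as.vector(outer(spec$zts, spec$replicates, function(z, r) {
      format_sample_keys(spec$condition, z, r)
    }))
    zt_of_col <- rep(spec$zts, times = length(spec$replicates))
    loading <- if (spec$loading_spread > 0) {
      stats::rlnorm(length(keys), 0, spec$loading_spread)
    } else rep(1, length(keys))

    clean <- outer(seq_len(n), zt_of_col, function(i, t) {
      baseline[i] * (1 + A[i] * cos(2 * pi * (t - phase[i]) / 24))
    })
    noise <- matrix(lognormal_noise(n * length(keys), spec$cv),
                    nrow = n)
    ab <- sweep(clean * noise, 2, loading, `*`)
    dimnames(ab) <- list(ids, keys)
    list(
      table = quant_table(ab, locus = loci),
      truth = data.frame(feature = ids, locus = loci, rhythmic = rhythmic,
                         phase = ifelse(rhythmic, phase, NA_real_),
                         fold = ifelse(rhythmic, fold, 1),
                         baseline = baseline, stringsAsFactors = FALSE)
    )
  })
}

#' Split motif abundances into technical phosphopeptide variants
#'
#' Emulates the technical redundancy of phosphopeptide quantification:
#' each motif is observed as 1-6 variants across charge states 2-4,
#' 0-2 missed cleavages and optional oxidation/acetylation
#' co-modifications. Variant abundances are a Dirichlet split of the
#' motif abundance (the split is per variant, constant across samples),
#' so summing the variants of a motif recovers the motif abundance
#' exactly. A configurable fraction of variants carries a deliberately
#' shifted (ambiguous) site assignment together with an
#' alternative-prediction record holding the true sites.
#'
#' @param motif_table A `quant_table` of motif abundances.
#' @param max_variants Maximum variants per motif (1 to this, uniform).
#' @param ambiguous_frac Fraction of variants with shifted sites.
#' @param seed Integer seed.
#' @return List with `variants` (a `phospho_variants`), `predictions`
#'   (data.frame for [resolve_ambiguous_sites()]), and `truth`
#'   (data.frame: `variant_id`, `motif_feature`, `true_positions`).
#' @export
generate_phospho_variants <- function(motif_table, max_variants = 6,
                                      ambiguous_frac = 0, seed = 1L) {
  stopifnot(inherits(motif_table, "quant_table"))
  if (nrow(motif_table$abundance) == 0) stop("empty motif table")
  withr::with_seed(as.integer(seed), {
    n <- nrow(motif_table$abundance)
    n_var <- sample.int(max_variants, n, replace = TRUE)
    meta <- vector("list", n)
    rows <- vector("list", n)
    preds <- vector("list", n)
    truth <- vector("list", n)
    aa <- c("A", "D", "E", "G", "K", "L", "R", "V")
    used <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      k <- n_var[i]
      locus <- motif_table$features$locus[i]
      if (is.na(locus)) locus <- motif_table$features$feature[i]
      n_sites <- sample(1:2, 1)
      # site sets are kept disjoint within a locus so distinct motifs
      # never collapse to the same (locus, site set) key
      taken <- if (!is.null(used[[locus]])) used[[locus]] else integer()
      avail <- setdiff(5:600, c(taken - 1, taken, taken + 1))
      sites <- sort(sample(avail, n_sites))
      used[[locus]] <- c(taken, sites)
      pep <- paste(sample(aa, 12, replace = TRUE), collapse = "")
      w <- stats::rgamma(k, 1)
      w <- w / sum(w)
      ab <- outer(w, motif_table$abundance[i, ])
      charge <- sample(2:4, k, replace = TRUE)
      mc <- sample(0:2, k, replace = TRUE)
      mods <- sample(c("", "oxidation", "acetylation",
                       "oxidation;acetylation"), k, replace = TRUE)
      amb <- stats::runif(k) < ambiguous_frac
      pos_str <- rep(paste(sites, collapse = ";"), k)
      pred <- NULL
      if (any(amb)) {
        shifted <- paste(sites + 1, collapse = ";")
        pos_str[amb] <- shifted
        n_mods <- vapply(strsplit(mods, ";"), function(v) sum(nzchar(v)), 0L) +
          n_sites
        pred <- data.frame(sequence = pep, charge = charge[amb],
                           n_mods = n_mods[amb],
                           positions = paste(sites, collapse = ";"),
                           confidence = 1, stringsAsFactors = FALSE)
      }
      vid <- sprintf("%s_m%d_v%d", locus, i, seq_len(k))
      meta[[i]] <- data.frame(variant_id = vid, locus = locus,
                              sequence = pep, charge = charge,
                              missed_cleavages = mc, modifications = mods,
                              positions = pos_str, ambiguous = amb,
                              stringsAsFactors = FALSE)
      rows[[i]] <- ab
      preds[[i]] <- pred
      truth[[i]] <- data.frame(variant_id = vid,
                               motif_feature = motif_table$features$feature[i],
                               true_positions = paste(sites, collapse = ";"),
                               stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, meta)
    ab <- do.call(rbind, rows)
    colnames(ab) <- colnames(motif_table$abundance)
    rownames(ab) <- meta$variant_id
    predictions <- do.call(rbind, preds)
    list(variants = phospho_variants(meta, ab),
         predictions = predictions,
         truth = do.call(rbind, truth))
  })
}

#' Generate partial metabolic-labelling incorporation courses
#'
#' The labelled fraction of a protein turning over at rate `k` follows
#' `f(t) = efficiency * (1 - exp(-k * t))`, to which multiplicative
#' lognormal noise is applied and the result clipped to `[0, 1]`.
#'
#' @param k_degs Named or unnamed vector of true degradation rates
#'   (per hour, > 0).
#' @param efficiency Labelling efficiency in `[0, 1]`.
#' @param times Sampling times (hours, non-negative, at least one
#'   positive).
#' @param cv Noise coefficient of variation; 0 for noise-free.
#' @param seed Integer seed.
#' @return data.frame: `locus`, `time`, `fraction`.
#' @export
generate_labeling_course <- function(k_degs, efficiency = 0.93,
                                     times = c(0, 6, 12, 24, 48, 72),
                                     cv = 0, seed = 1L) {
  if (any(k_degs <= 0)) stop("degradation rates must be positive")
  if (any(times < 0) || !any(times > 0)) {
    stop("time grid must be non-negative with at least one positive time")
  }
  if (efficiency < 0 || efficiency > 1) stop("efficiency must lie in [0, 1]")
  loci <- names(k_degs)
  if (is.null(loci)) loci <- sprintf("p%03d", seq_along(k_degs))
  withr::with_seed(as.integer(seed), {
    out <- expand.grid(locus = loci, time = times, stringsAsFactors = FALSE)
    k <- k_degs[match(out$locus, loci)]
    f <- efficiency * (1 - exp(-k * out$time))
    if (cv > 0) f <- f * lognormal_noise(length(f), cv)
    out$fraction <- pmin(pmax(f, 0), 1)
    out[order(out$locus, out$time), , drop = FALSE]
  })
}

#' Generate a dark-adaptation decay series
#'
#' Each protein decays exponentially from its starting level at ZT24
#' with its own degradation rate, sampled at ZT 24, 48, 72 and 96 in
#' constant darkness with replicated lognormal noise. This mirrors a
#' proteome that is no longer synthesised in prolonged darkness, so
#' that the dark-adaptation fold change of a protein reflects its
#' turnover rate.
#'
#' @param k_degs Named vector of degradation rates (per hour).
#' @param baselines Starting abundances at ZT24 (recycled).
#' @param zts DA sampling times (hours since the last dawn).
#' @param replicates Replicate labels.
#' @param cv Replicate noise CV.
#' @param seed Integer seed.
#' @return A `quant_table` in condition `"DA"` (feature = locus).
#' @export
generate_da_dataset <- function(k_degs, baselines = 1e5,
                                zts = c(24, 48, 72, 96),
                                replicates = LETTERS[1:5],
                                cv = 0.1, seed = 1L) {
  if (any(k_degs <= 0)) stop("degradation rates must be positive")
  loci <- names(k_degs)
  if (is.null(loci)) loci <- sprintf("p%03d", seq_along(k_degs))
  baselines <- rep_len(baselines, length(k_degs))
  withr::with_seed(as.integer(seed), {
    keys <- as.vector(outer(zts, replicates, function(z, r) {
      format_sample_keys("DA", z, r)
    }))
    zt_of_col <- rep(zts, times = length(replicates))
    clean <- outer(seq_along(k_degs), zt_of_col, function(i, t) {
      baselines[i] * exp(-k_degs[i] * (t - zts[1]))
    })
    noise <- matrix(lognormal_noise(length(clean), cv), nrow = length(k_degs))
    ab <- clean * noise
    dimnames(ab) <- list(loci, keys)
    quant_table(ab, locus = loci)
  })
}

#' Degrade one replicate sample into an outlier
#'
#' Replaces a fraction `severity` of the chosen sample's values by a
#' random permutation of that column, destroying its correlation to
#' the per-timepoint median: at `severity >= 1` the whole column is
#' permuted and the outlier detector's r^2 falls below 0.8.
#' `severity = 0` returns the table unchanged.
#'
#' @param x A `quant_table`.
#' @param sample Sample key of the replicate to degrade.
#' @param severity Fraction of cells permuted, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The modified `quant_table`.
#' @export
inject_outlier_replicate <- function(x, sample, severity = 1, seed = 1L) {
  stopifnot(inherits(x, "quant_table"))
  j <- match(sample, x$samples$key)
  if (is.na(j)) stop("unknown sample: ", sample)
  if (severity == 0) return(x)
  col <- x$abundance[, j]
  if (stats::sd(col, na.rm = TRUE) == 0) {
    stop("constant sample column: outlier undetectable by correlation")
  }
  withr::with_seed(as.integer(seed), {
    n <- length(col)
    pick <- sample.int(n, size = round(min(severity, 1) * n))
    x$abundance[pick, j] <- col[sample(pick)]
  })
  x
}

#' Generate random protein sequences with designated phospho-sites
#'
#' Residues are drawn from a configurable background frequency; each
#' protein carries designated S/T/Y sites. Kinase-consensus context can
#' be planted around a site at stated rates: `plant_sp` puts a proline
#' at +1 (proline-directed consensus), `plant_acidic` puts D/E at every
#' one of +1..+3 (acid-directed consensus).
#'
#' @param n Number of proteins.
#' @param length_range Min/max sequence length (min >= 15 so that a
#'   +/-7 window fits).
#' @param sites_per_protein Designated phospho-sites per protein.
#' @param plant_sp,plant_acidic Planting probabilities in `[0, 1]`.
#' @param background Named residue probability vector (default uniform
#'   over the 20 amino acids).
#' @param seed Integer seed.
#' @return List with `sequences` (an `AAStringSet`) and `sites`
#'   (data.frame: `locus`, `position`, `residue`, `planted`).
#' @export
generate_protein_sequences <- function(n, length_range = c(60, 120),
                                       sites_per_protein = 2,
                                       plant_sp = 0, plant_acidic = 0,
                                       background = NULL, seed = 1L) {
  if (n < 1) stop("`n` must be >= 1")
  if (length_range[1] < 15) stop("minimum sequence length is 15")
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), aa20)
  }
  background <- background[aa20] / sum(background[aa20])
  withr::with_seed(as.integer(seed), {
    loci <- sprintf("ostta%05d", seq_len(n))
    seqs <- character(n)
    sites <- vector("list", n)
    for (i in seq_len(n)) {
      len <- sample(length_range[1]:length_range[2], 1)
      s <- sample(aa20, len, replace = TRUE, prob = background)
      pos <- sort(sample(8:(len - 7), sites_per_protein))
      planted <- logical(sites_per_protein)
      for (k in seq_along(pos)) {
        s[pos[k]] <- sample(c("S", "T"), 1)
        if (stats::runif(1) < plant_sp) {
          s[pos[k] + 1] <- "P"
          planted[k] <- TRUE
        }
        if (stats::runif(1) < plant_acidic) {
          s[pos[k] + 1:3] <- sample(c("D", "E"), 3, replace = TRUE)
          planted[k] <- TRUE
        }
      }
      seqs[i] <- paste(s, collapse = "")
      sites[[i]] <- data.frame(locus = loci[i], position = pos,
                               residue = s[pos], planted = planted,
                               stringsAsFactors = FALSE)
    }
    list(sequences = Biostrings::AAStringSet(stats::setNames(seqs, loci)),
         sites = do.call(rbind, sites))
  })
}
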