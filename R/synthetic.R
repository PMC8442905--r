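# Synthetic-data generators emulating the statistical structure of a plasma
# cfDNA cohort: a tissue reference atlas with planted tissue-specific
# regions, cohorts with tissue-mixture structure and planted DMRs, fragment
# length distributions with nucleosomal peaks, binned CNV profiles, and
# spike-in QC counts. Every generator is deterministic given its seed.

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# Bimodal baseline methylation recentred to the target global mean. Most
# CpGs are near-fully methylated or unmethylated; the high-mode weight is
# set so the raw mixture mean matches the target before recentring.
.baseline_methylation <- function(n, global_mean = 0.755) {
  hi_mean <- 11.5 / 12.5; lo_mean <- 1 / 12.5
  w <- (global_mean - lo_mean) / (hi_mean - lo_mean)
  hi <- stats::rbinom(n, 1L, w) == 1L
  base <- ifelse(hi, stats::rbeta(n, 11.5, 1), stats::rbeta(n, 1, 11.5))
  base <- base + (global_mean - mean(base))
  .clip01(base, eps = 1e-4)
}

#' Generate a synthetic tissue reference atlas with planted specific regions
#'
#' Regions share a bimodal baseline methylation profile across tissues; each
#' tissue receives a disjoint planted set of regions shifted by the effect
#' size away from that baseline (downward where the baseline is high, upward
#' where it is low, with the baseline adjusted to guarantee headroom), so
#' every planted region differs from the other tissues' shared value by
#' exactly `effect`.
#'
#' @param n_tissues Number of tissue groups (>= 2).
#' @param n_regions Number of regions (>= n_tissues).
#' @param effect Planted tissue-specific shift in methylation (0 < effect <= 1).
#' @param seed Integer seed.
#' @param global_mean Target mean methylation of the baseline (default 0.755).
#' @param n_specific Planted regions per tissue (default: 5% of regions,
#'   capped so the sets stay disjoint).
#' @param width Region width in bp used for the synthetic coordinates.
#' @return A `SyntheticAtlasTruth`: `tissue_names`, `region_methylation`
#'   (region x tissue), `specific_regions` (tissue -> region ids), `seed`.
#' @export
make_atlas <- function(n_tissues, n_regions, effect = 0.4, seed = 1,
                       global_mean = 0.755, n_specific = NULL, width = 1000) {
  n_tissues <- .check_count(n_tissues, "n_tissues", min = 2)
  n_regions <- .check_count(n_regions, "n_regions", min = n_tissues)
  effect <- .check_number(effect, "effect", lo = 0, hi = 1)
  set.seed(seed)
  if (is.null(n_specific)) {
    n_specific <- max(2L, min(floor(n_regions / n_tissues), round(0.05 * n_regions)))
  }
  n_specific <- .check_count(n_specific, "n_specific", min = 0)
  if (n_specific * n_tissues > n_regions) stop("planted sets must be disjoint", call. = FALSE)

  base <- .baseline_methylation(n_regions, global_mean)
  ids <- .region_id("chr1", (seq_len(n_regions) - 1L) * width, seq_len(n_regions) * width)
  tissues <- sprintf("tissue_%02d", seq_len(n_tissues))
  planted <- sample.int(n_regions, n_specific * n_tissues)
  split_idx <- split(planted, rep(seq_len(n_tissues), each = n_specific))

  A <- matrix(base, nrow = n_regions, ncol = n_tissues,
              dimnames = list(ids, tissues))
  specific <- stats::setNames(vector("list", n_tissues), tissues)
  if (effect > 0) {
    for (t in seq_len(n_tissues)) {
      idx <- split_idx[[t]]
      up <- base[idx] <= 0.5
      # guarantee headroom for the full shift
      base[idx][up] <- pmin(base[idx][up], 1 - effect)
      base[idx][!up] <- pmax(base[idx][!up], effect)
      A[idx, ] <- base[idx]  # refresh shared baseline after adjustment
      A[idx, t] <- base[idx] + ifelse(up, effect, -effect)
      specific[[t]] <- ids[idx]
    }
  } else {
    for (t in seq_len(n_tissues)) specific[[t]] <- character()
  }
  # headroom adjustment of planted baselines moves the global mean; restore
  # the target by nudging unplanted baseline regions (iterated under clipping)
  unplanted <- setdiff(seq_len(n_regions), planted)
  if (length(unplanted) > 0L) {
    for (it in 1:3) {
      delta <- (global_mean - mean(A)) * n_regions / length(unplanted)
      base[unplanted] <- .clip01(base[unplanted] + delta, eps = 1e-4)
      A[unplanted, ] <- base[unplanted]
    }
  }
  structure(list(tissue_names = tissues, region_methylation = A,
                 specific_regions = specific, baseline = stats::setNames(base, ids),
                 effect = effect, width = width, seed = seed),
            class = "SyntheticAtlasTruth")
}

#' Draw replicate tissue samples around an atlas
#'
#' Per tissue and replicate, region levels are beta-distributed around the
#' tissue mean with the given concentration (matching the noise scale of
#' deep WGBS region-level replicates: sd about 3-5% near the modes).
#'
#' @param atlas A `SyntheticAtlasTruth`.
#' @param n_reps Replicates per tissue (default 3).
#' @param concentration Beta concentration (default 100; larger = tighter).
#' @param seed Integer seed.
#' @return List: `samples` (region x sample matrix), `tissue_labels`.
#' @export
atlas_replicates <- function(atlas, n_reps = 3, concentration = 100, seed = 1) {
  stopifnot(inherits(atlas, "SyntheticAtlasTruth"))
  n_reps <- .check_count(n_reps, "n_reps")
  set.seed(seed)
  A <- atlas$region_methylation
  m <- .clip01(A, eps = 1e-3)
  samples <- matrix(NA_real_, nrow(A), ncol(A) * n_reps)
  labs <- character(ncol(A) * n_reps)
  nm <- character(ncol(A) * n_reps)
  k <- 0L
  for (t in seq_len(ncol(A))) {
    for (r in seq_len(n_reps)) {
      k <- k + 1L
      samples[, k] <- stats::rbeta(nrow(A), m[, t] * concentration,
                                   (1 - m[, t]) * concentration)
      labs[k] <- colnames(A)[t]
      nm[k] <- sprintf("%s_rep%d", colnames(A)[t], r)
    }
  }
  dimnames(samples) <- list(rownames(A), nm)
  list(samples = samples, tissue_labels = labs)
}

#' Generate a synthetic cfDNA cohort with planted DMRs
#'
#' Each sample's expected window methylation is `A %*% x_true` for a
#' Dirichlet-drawn tissue mixture `x_true`; samples of each non-reference
#' group additionally receive a planted, disjoint set of group-specific DMR
#' shifts (alternating hyper/hypo) restricted to that group's regulatory
#' window class. Windows map 1:1 to atlas regions; even-indexed windows are
#' declared "enhancer" and odd-indexed "promoter" in the generated
#' annotations. Observed per-CpG counts are binomial draws at
#' Poisson-distributed coverage; with `noise_free = TRUE` the emitted counts
#' are the (fractional) expected values so window levels equal `A %*% x_true`
#' exactly.
#'
#' @param atlas A `SyntheticAtlasTruth`; its regions are the cohort windows.
#' @param group_sizes Named integer vector, e.g. `c(control = 20, cancer = 20)`;
#'   the first group is the reference (no planted DMRs).
#' @param dmr_effect Planted DMR shift (0 disables planting).
#' @param n_dmrs Planted windows per non-reference group (default 200).
#' @param coverage Mean reads per CpG (> 0).
#' @param seed Integer seed.
#' @param n_cpgs_per_window CpG sites per window (default 5).
#' @param dirichlet_conc Concentration of the tissue-mixture prior (default
#'   150, giving a between-patient SD of roughly 2-3% for a 10-20%
#'   component, the scale reported for healthy cfDNA tissue contributions;
#'   between-patient variability is exposed as this parameter).
#' @param admixture Optional list(group=, tissue=, fraction=) adding a fixed
#'   tissue admixture to one group's mixtures (e.g. tumor fraction).
#' @param dmr_classes Regulatory class per non-reference group, recycled
#'   (default alternates "enhancer", "promoter").
#' @param noise_free Emit expected (fractional) counts instead of draws.
#' @return A list: `calls` (named list of per-sample CpG call tables),
#'   `truth` (`SyntheticCohortTruth`), `annotations` (enhancer/promoter
#'   `GRanges`), `expected_levels` (sample x window), `window_ids`.
#' @export
make_cohort <- function(atlas, group_sizes = c(control = 20, cancer = 20),
                        dmr_effect = 0.15, n_dmrs = 200, coverage = 10,
                        seed = 1, n_cpgs_per_window = 5, dirichlet_conc = 150,
                        admixture = NULL, dmr_classes = NULL, noise_free = FALSE) {
  stopifnot(inherits(atlas, "SyntheticAtlasTruth"))
  if (coverage <= 0) stop("`coverage` must be > 0", call. = FALSE)
  if (is.null(names(group_sizes)) || any(names(group_sizes) == "")) {
    stop("group_sizes must be named", call. = FALSE)
  }
  set.seed(seed)
  A <- atlas$region_methylation
  n_regions <- nrow(A); n_tissues <- ncol(A)
  ids <- rownames(A)
  width <- atlas$width
  starts <- (seq_len(n_regions) - 1L) * width

  # 1:1 window-to-region mapping; alternate enhancer/promoter labels
  is_enh <- (seq_len(n_regions) - 1L) %% 2L == 0L
  annotations <- list(
    enhancers = .gr0("chr1", starts[is_enh], starts[is_enh] + width),
    promoters = .gr0("chr1", starts[!is_enh], starts[!is_enh] + width)
  )

  groups <- names(group_sizes)
  samples <- unlist(lapply(groups, function(g) {
    sprintf("%s_%02d", g, seq_len(group_sizes[[g]]))
  }))
  labels <- stats::setNames(rep(groups, group_sizes), samples)

  # planted group-specific DMRs, disjoint across groups
  planted <- list()
  if (length(groups) > 1L && dmr_effect > 0 && n_dmrs > 0) {
    if (is.null(dmr_classes)) {
      dmr_classes <- rep_len(c("enhancer", "promoter"), length(groups) - 1L)
    } else {
      dmr_classes <- rep_len(dmr_classes, length(groups) - 1L)
    }
    used <- integer()
    for (gi in seq_along(groups[-1L])) {
      g <- groups[-1L][gi]
      pool <- which(if (dmr_classes[gi] == "enhancer") is_enh else !is_enh)
      pool <- setdiff(pool, used)
      if (length(pool) < n_dmrs) stop("not enough windows to plant DMRs", call. = FALSE)
      idx <- sample(pool, n_dmrs)
      used <- c(used, idx)
      sgn <- rep_len(c(1, -1), n_dmrs)
      planted[[paste0(g, "_vs_", groups[1L])]] <- data.table::data.table(
        window = ids[idx], effect = sgn * dmr_effect, class = dmr_classes[gi])
    }
  }

  x_true <- .rdirichlet(length(samples), rep(dirichlet_conc / n_tissues, n_tissues))
  dimnames(x_true) <- list(samples, colnames(A))
  if (!is.null(admixture)) {
    gs <- labels == admixture$group
    x_true[gs, ] <- x_true[gs, , drop = FALSE] * (1 - admixture$fraction)
    x_true[gs, admixture$tissue] <- x_true[gs, admixture$tissue] + admixture$fraction
  }

  expected <- x_true %*% t(A)  # sample x window
  for (key in names(planted)) {
    g <- sub("_vs_.*$", "", key)
    pd <- planted[[key]]
    gi <- which(labels == g)
    j <- match(pd$window, ids)
    expected[gi, j] <- sweep(expected[gi, j, drop = FALSE], 2L, pd$effect, `+`)
  }
  expected <- .clip01(expected)

  offs <- as.integer(round((seq_len(n_cpgs_per_window) - 0.5) / n_cpgs_per_window * width))
  calls <- stats::setNames(vector("list", length(samples)), samples)
  for (s in samples) {
    p <- rep(expected[s, ], each = n_cpgs_per_window)
    pos <- rep(starts, each = n_cpgs_per_window) + rep(offs, times = n_regions)
    if (noise_free) {
      depth <- rep(1e6, length(p))
      meth <- p * depth
    } else {
      depth <- stats::rpois(length(p), coverage)
      meth <- stats::rbinom(length(p), depth, p)
    }
    calls[[s]] <- data.table::data.table(
      chrom = "chr1", start = pos, end = pos + 1L,
      n_meth = meth, n_unmeth = depth - meth)
  }

  truth <- structure(list(sample_labels = labels, true_contributions = x_true,
                          planted_dmrs = planted, coverage_model = coverage,
                          dirichlet_conc = dirichlet_conc, seed = seed),
                     class = "SyntheticCohortTruth")
  list(calls = calls, truth = truth, annotations = annotations,
       expected_levels = expected, window_ids = ids)
}

#' Generate synthetic cfDNA fragment lengths
#'
#' Mixture model reproducing the nucleosomal cfDNA length distribution: a
#' dominant narrow peak at `main_peak_bp` (167 bp), a comb of narrow peaks
#' at `main_peak_bp - k * periodicity_bp` (k = 1..6) with geometrically
#' decaying weights, a broad secondary peak at `secondary_peak_bp` (~320
#' bp), plus broad short and long background components. `group_shift` moves
#' that fraction of probability mass from the long components (secondary
#' peak and long background) to the short background, emulating the
#' short-fragment enrichment of cancer cfDNA.
#'
#' @param n_fragments Number of fragments (> 0).
#' @param main_peak_bp Dominant peak (default 167; must lie in \[50, 600\]).
#' @param secondary_peak_bp Secondary peak (default 320).
#' @param periodicity_bp Sub-peak spacing (default 10).
#' @param group_shift Probability mass moved long -> short (default 0).
#' @param seed Integer seed.
#' @return Integer vector of fragment lengths.
#' @export
make_fragments <- function(n_fragments, main_peak_bp = 167, secondary_peak_bp = 320,
                           periodicity_bp = 10, group_shift = 0, seed = 1) {
  n_fragments <- .check_count(n_fragments, "n_fragments")
  main_peak_bp <- .check_number(main_peak_bp, "main_peak_bp", 50, 600)
  secondary_peak_bp <- .check_number(secondary_peak_bp, "secondary_peak_bp", 50, 600)
  periodicity_bp <- .check_count(periodicity_bp, "periodicity_bp")
  group_shift <- .check_number(group_shift, "group_shift", 0, 0.3)
  set.seed(seed)

  comb_k <- 1:6
  comb_w <- 0.5^comb_k; comb_w <- 0.13 * comb_w / sum(comb_w)
  w <- c(main = 0.50, stats::setNames(comb_w, paste0("comb", comb_k)),
         secondary = 0.17, long_bg = 0.10, short_bg = 0.10)
  # shift mass long -> short, proportionally from the long components
  long_comp <- c("secondary", "long_bg")
  take <- group_shift * w[long_comp] / sum(w[long_comp])
  w[long_comp] <- w[long_comp] - take
  w["short_bg"] <- w["short_bg"] + group_shift

  comp <- sample(names(w), n_fragments, replace = TRUE, prob = w)
  lens <- numeric(n_fragments)
  lens[comp == "main"] <- stats::rnorm(sum(comp == "main"), main_peak_bp, 3)
  for (k in comb_k) {
    ck <- comp == paste0("comb", k)
    lens[ck] <- stats::rnorm(sum(ck), main_peak_bp - k * periodicity_bp, 1.5)
  }
  lens[comp == "secondary"] <- stats::rnorm(sum(comp == "secondary"), secondary_peak_bp, 25)
  lens[comp == "long_bg"] <- stats::runif(sum(comp == "long_bg"), 330, 500)
  lens[comp == "short_bg"] <- stats::runif(sum(comp == "short_bg"), 80, 150)
  pmin(pmax(as.integer(round(lens)), 30L), 700L)
}

#' Generate a synthetic binned CNV read-count profile
#'
#' Poisson counts per fixed-width bin with mean `depth * copy_ratio` inside
#' the given segments and `depth` elsewhere. Segments must not overlap.
#'
#' @param segments `NULL` (flat profile) or a data.frame with chrom, start,
#'   end, copy_ratio (> 0).
#' @param depth Mean count per bin.
#' @param seed Integer seed.
#' @param bin_size Bin width in bp (default 100 kb).
#' @param chrom_length Length of the synthetic chromosome (default 50 Mb).
#' @param chrom Chromosome name.
#' @return Bin table (chrom, start, end, mappability, blacklist, count,
#'   true_ratio) compatible with [bin_and_filter()].
#' @export
make_cnv_profile <- function(segments = NULL, depth = 500, seed = 1,
                             bin_size = 1e5, chrom_length = 5e7, chrom = "chr1") {
  depth <- .check_number(depth, "depth", lo = 1e-9)
  set.seed(seed)
  starts <- seq(0, chrom_length - bin_size, by = bin_size)
  ratio <- rep(1, length(starts))
  if (!is.null(segments) && nrow(segments) > 0L) {
    seg <- data.table::as.data.table(segments)
    stopifnot(all(c("chrom", "start", "end", "copy_ratio") %in% names(seg)))
    if (any(seg$copy_ratio <= 0)) stop("copy_ratio must be > 0", call. = FALSE)
    data.table::setorder(seg, chrom, start)
    if (any(seg[, start < data.table::shift(end, fill = -1), by = chrom]$V1)) {
      stop("segments must not overlap", call. = FALSE)
    }
    mid <- starts + bin_size / 2
    for (r in seq_len(nrow(seg))) {
      inside <- seg$chrom[r] == chrom & mid >= seg$start[r] & mid < seg$end[r]
      ratio[inside] <- seg$copy_ratio[r]
    }
  }
  data.table::data.table(
    chrom = chrom, start = as.integer(starts), end = as.integer(starts + bin_size),
    mappability = 100, blacklist = FALSE,
    count = stats::rpois(length(starts), depth * ratio),
    true_ratio = ratio)
}

#' Generate spike-in control call tables
#'
#' Binomial converted-call counts at the stated conversion rate for the
#' methylated control (CpG-methylated lambda DNA analogue) and at the stated
#' false-positive rate for the unmodified control, spread over a fixed set
#' of synthetic control positions.
#'
#' @param n_meth_calls Total calls at methylated-control CpGs.
#' @param conv True 5mC conversion rate in \[0, 1\].
#' @param n_unmod_calls Total calls at unmodified-control cytosines.
#' @param fpr True false-positive (spurious conversion) rate in \[0, 1\].
#' @param seed Integer seed.
#' @param n_sites Synthetic control positions per table (default 50).
#' @return List with `meth_control` and `unmod_control` call tables.
#' @export
make_spikein <- function(n_meth_calls, conv = 0.97, n_unmod_calls = n_meth_calls,
                         fpr = 0.0028, seed = 1, n_sites = 50) {
  n_meth_calls <- .check_count(n_meth_calls, "n_meth_calls")
  n_unmod_calls <- .check_count(n_unmod_calls, "n_unmod_calls")
  conv <- .check_fraction(conv, "conv")
  fpr <- .check_fraction(fpr, "fpr")
  set.seed(seed)
  spread <- function(total, rate, chrom) {
    per <- diff(round(seq(0, total, length.out = n_sites + 1L)))
    converted <- stats::rbinom(n_sites, per, rate)
    data.table::data.table(chrom = chrom, start = seq_len(n_sites) * 100L,
                           end = seq_len(n_sites) * 100L + 1L,
                           n_meth = converted, n_unmeth = per - converted)
  }
  list(meth_control = spread(n_meth_calls, conv, "lambda_meth"),
       unmod_control = spread(n_unmod_calls, fpr, "unmod_2kb"))
}

#' Generate a multimodal cohort with complementary modality signals
#'
#' Three feature matrices (methylation-, tissue- and fragmentation-like)
#' over the same three-class cohort, where modality m carries signal for
#' exactly one class (its informative features are shifted for that class
#' only). No single modality can separate the other two classes, but the
#' three together identify every class — the constructive setting for
#' testing probability-averaging integration.
#'
#' @param n_per_group Samples per class (default 10).
#' @param n_features Features per modality (default 10).
#' @param n_informative Shifted features per modality (default 3).
#' @param effect Shift size in units of the noise SD (default 2).
#' @param noise_sd Feature noise SD (default 1).
#' @param seed Integer seed.
#' @param classes Class labels; the first is the control class.
#' @return List: `modalities` (named list of 3 sample-by-feature matrices),
#'   `labels`.
#' @export
make_multimodal_cohort <- function(n_per_group = 10, n_features = 10,
                                   n_informative = 3, effect = 2, noise_sd = 1,
                                   seed = 1,
                                   classes = c("control", "HCC", "PDAC")) {
  n_per_group <- .check_count(n_per_group, "n_per_group", min = 2)
  stopifnot(length(classes) == 3L)
  set.seed(seed)
  n <- 3L * n_per_group
  labels <- rep(classes, each = n_per_group)
  samples <- sprintf("%s_%02d", labels, rep(seq_len(n_per_group), times = 3L))
  modality_names <- c("methylation", "tissue", "fragmentation")
  mods <- stats::setNames(vector("list", 3L), modality_names)
  for (m in 1:3) {
    x <- matrix(stats::rnorm(n * n_features, sd = noise_sd), n, n_features,
                dimnames = list(samples, sprintf("f%02d", seq_len(n_features))))
    x[labels == classes[m], seq_len(n_informative)] <-
      x[labels == classes[m], seq_len(n_informative)] + effect * noise_sd
    mods[[m]] <- x
  }
  list(modalities = mods, labels = stats::setNames(labels, samples))
}
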