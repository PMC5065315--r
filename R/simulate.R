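# Synthetic-data generators. Every generator is seeded and returns its ground
# truth in a separate container, so downstream code can never read it by
# accident.

#' Configuration for a simulated spike-in ChIP-seq experiment
#'
#' Collects and validates the design of a two-genome (target + spike-in)
#' calibrated ChIP-seq simulation. Defaults mirror a typical calibrated
#' Polycomb ChIP-seq design: biological triplicates in two conditions
#' (untreated `UNT` vs treated `OHT`) with a spike:target cell ratio of 0.25
#' (e.g. 1.25e7 spike cells added to 5e7 target cells).
#'
#' @param n_intervals Number of target-genome intervals (peaks).
#' @param interval_length_bp Interval length(s) in bp; scalar or a vector of
#'   length `n_intervals`.
#' @param n_replicates Biological replicates per condition.
#' @param conditions Ordered condition labels; the first is the reference.
#' @param ip_efficiency Fraction of chromatin captured per sample: a scalar, a
#'   vector named by condition, or one value per sample (all samples of
#'   condition 1 first, in replicate order).
#' @param spike_cell_fraction True spike:target cell ratio per sample (same
#'   shapes as `ip_efficiency`). Default 0.25.
#' @param depth Relative sequencing depth per sample (same shapes as
#'   `ip_efficiency`).
#' @param affected_fraction Proportion of intervals carrying a true condition
#'   effect, in \[0, 1\].
#' @param effect_log2fc True log2 fold change (condition 2 vs condition 1) at
#'   affected intervals; scalar, or one value per affected interval.
#' @param nb_dispersion Negative-binomial dispersion `phi` of interval counts
#'   (variance `mu + phi * mu^2`); `0` gives Poisson counts exactly.
#' @param base_enrichment Mean IP signal per interval in the reference
#'   condition at unit efficiency and depth; scalar or per-interval vector.
#' @param spike_library_scale,input_library_scale Expected spike-IP reads at
#'   unit spike fraction/efficiency/depth, and expected target-input reads at
#'   unit depth. Only set these to change the absolute size of the simulated
#'   libraries.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   simulation bit-for-bit.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(n_intervals = 2000,
                       interval_length_bp = 1000,
                       n_replicates = 3,
                       conditions = c("UNT", "OHT"),
                       ip_efficiency = 1,
                       spike_cell_fraction = 0.25,
                       depth = 1,
                       affected_fraction = 0,
                       effect_log2fc = -1,
                       nb_dispersion = 0.05,
                       base_enrichment = 100,
                       spike_library_scale = 4e6,
                       input_library_scale = 1e6,
                       seed = 1L) {
  n_intervals <- check_count(n_intervals, "n_intervals", min = 1L)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1L)
  if (!is.character(conditions) || length(conditions) != 2L ||
      anyDuplicated(conditions)) {
    stop("'conditions' must be two distinct labels", call. = FALSE)
  }
  check_scalar_number(affected_fraction, "affected_fraction", min = 0)
  if (affected_fraction > 1) {
    stop("'affected_fraction' must be in [0, 1]", call. = FALSE)
  }
  check_scalar_number(nb_dispersion, "nb_dispersion", min = 0)
  check_scalar_number(spike_library_scale, "spike_library_scale", positive = TRUE)
  check_scalar_number(input_library_scale, "input_library_scale", positive = TRUE)
  if (any(!is.finite(interval_length_bp)) || any(interval_length_bp <= 0)) {
    stop("'interval_length_bp' must be positive", call. = FALSE)
  }
  if (any(!is.finite(base_enrichment)) || any(base_enrichment <= 0)) {
    stop("'base_enrichment' must be positive", call. = FALSE)
  }
  if (any(!is.finite(effect_log2fc))) {
    stop("'effect_log2fc' must be finite", call. = FALSE)
  }
  for (nm in c("ip_efficiency", "spike_cell_fraction", "depth")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("'%s' must be positive and finite", nm), call. = FALSE)
    }
  }
  structure(
    list(n_intervals = n_intervals,
         interval_length_bp = interval_length_bp,
         n_replicates = n_replicates,
         conditions = conditions,
         ip_efficiency = ip_efficiency,
         spike_cell_fraction = spike_cell_fraction,
         depth = depth,
         affected_fraction = affected_fraction,
         effect_log2fc = effect_log2fc,
         nb_dispersion = nb_dispersion,
         base_enrichment = base_enrichment,
         spike_library_scale = spike_library_scale,
         input_library_scale = input_library_scale,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a two-genome calibrated ChIP-seq experiment
#'
#' Draws per-interval IP fragment counts for every sample of a two-condition,
#' replicated, spike-in ChIP-seq design, along with per-library read totals
#' for the target genome, the spike genome, and matched input libraries.
#'
#' The count model is a Gamma-Poisson (negative binomial) mixture: interval
#' `i` in sample `s` has mean
#' `base_enrichment[i] * effect(condition_s, i) * ip_efficiency[s] * depth[s]`
#' and variance `mu + phi * mu^2`; `nb_dispersion = 0` gives Poisson counts.
#' Spike-in IP totals are Poisson with mean proportional to
#' `spike_cell_fraction * ip_efficiency * depth`; matched input totals reflect
#' `spike_cell_fraction` and `depth` only (input measures chromatin
#' composition, not capture), so the spike-to-target input ratio recovers the
#' per-sample spike cell fraction.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#' \describe{
#'   \item{libraries}{Per-sample read totals (`sample_id`, `condition`,
#'     `replicate`, `n_target_ip`, `n_spike_ip`, `n_target_input`,
#'     `n_spike_input`).}
#'   \item{counts}{A raw-count [signal_table()].}
#'   \item{truth}{A `ground_truth` object: per-interval true means, affected
#'     flags and true log2FC, plus per-sample efficiency/spike-fraction/depth.
#'     Kept separate so analysis code never touches it.}
#' }
#' @examples
#' sim <- simulate_experiment(sim_config(n_intervals = 50, seed = 7))
#' sim$counts
#' head(sim$truth$intervals)
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("'config' must be created by sim_config()", call. = FALSE)
  }
  cfg <- config
  samples <- data.frame(
    sample_id = paste0(rep(cfg$conditions, each = cfg$n_replicates), "_rep",
                       rep(seq_len(cfg$n_replicates), times = 2L)),
    condition = rep(cfg$conditions, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), times = 2L),
    stringsAsFactors = FALSE
  )
  eff <- resolve_per_sample(cfg$ip_efficiency, "ip_efficiency", samples)
  spike <- resolve_per_sample(cfg$spike_cell_fraction, "spike_cell_fraction",
                              samples)
  depth <- resolve_per_sample(cfg$depth, "depth", samples)

  n <- cfg$n_intervals
  len <- rep(cfg$interval_length_bp, length.out = n)
  base <- rep(cfg$base_enrichment, length.out = n)
  # Intervals laid head-to-tail on one synthetic contig with 10 kb spacing.
  gap <- 10000L
  starts <- cumsum(c(0L, (len + gap)[-n]))
  intervals <- data.frame(
    chrom = "chrS",
    start = as.integer(starts),
    end = as.integer(starts + len),
    id = sprintf("iv_%05d", seq_len(n)),
    stringsAsFactors = FALSE
  )

  out <- with_seed(cfg$seed, {
    n_affected <- round(cfg$affected_fraction * n)
    affected_idx <- if (n_affected > 0) sort(sample.int(n, n_affected)) else integer(0)
    true_lfc <- numeric(n)
    if (n_affected > 0) {
      true_lfc[affected_idx] <- rep(cfg$effect_log2fc, length.out = n_affected)
    }
    mult <- cbind(1, 2^true_lfc)  # effect multiplier per condition
    colnames(mult) <- cfg$conditions

    counts <- matrix(0, nrow = n, ncol = nrow(samples))
    for (s in seq_len(nrow(samples))) {
      mu <- base * mult[, samples$condition[s]] * eff[s] * depth[s]
      counts[, s] <- if (cfg$nb_dispersion > 0) {
        rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
      } else {
        rpois(n, lambda = mu)
      }
    }
    libraries <- data.frame(
      samples,
      n_target_ip = as.numeric(colSums(counts)),
      n_spike_ip = rpois(nrow(samples),
                         cfg$spike_library_scale * spike * eff * depth),
      n_target_input = rpois(nrow(samples), cfg$input_library_scale * depth),
      n_spike_input = rpois(nrow(samples),
                            cfg$input_library_scale * spike * depth),
      stringsAsFactors = FALSE
    )
    list(counts = counts, libraries = libraries,
         affected_idx = affected_idx, true_lfc = true_lfc, mult = mult)
  })

  table <- signal_table(
    out$counts, intervals,
    samples = data.frame(samples,
                         library_size = out$libraries$n_target_ip,
                         stringsAsFactors = FALSE),
    calibrated = FALSE, units = "counts"
  )
  truth <- structure(
    list(
      intervals = data.frame(
        id = intervals$id,
        base_enrichment = base,
        affected = seq_len(n) %in% out$affected_idx,
        true_log2fc = out$true_lfc,
        true_mean_ref = base,
        true_mean_alt = base * out$mult[, 2L],
        stringsAsFactors = FALSE
      ),
      samples = data.frame(
        sample_id = samples$sample_id,
        ip_efficiency = eff,
        spike_cell_fraction = spike,
        depth = depth,
        stringsAsFactors = FALSE
      )
    ),
    class = "ground_truth"
  )
  list(libraries = out$libraries, counts = table, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d intervals (%d affected), %d samples\n",
              nrow(x$intervals), sum(x$intervals$affected), nrow(x$samples)))
  invisible(x)
}

#' Simulate paired RYBP/CBX7 signal-profile matrices
#'
#' Generates binned signal profiles for two planted classes of Polycomb
#' target sites: both classes carry high variant-PRC1 (RYBP-like) signal;
#' one class is depleted of canonical-PRC1 (CBX7-like) signal
#' ("variant-enriched") while the other is CBX7-enriched ("shared"). The two
#' CBX7 class means are separated by `separation` noise standard deviations,
#' so `separation = 0` makes the classes distributionally identical and the
#' labels unrecoverable by construction.
#'
#' @param n_sites Number of sites (>= 2).
#' @param bins Number of bins per profile (>= 1).
#' @param separation Class-mean separation in units of the per-bin noise SD;
#'   must be >= 0.
#' @param seed Integer seed.
#' @param prop_variant Proportion of sites in the variant-enriched class.
#' @param noise_sd Per-bin Gaussian noise SD.
#' @param rybp_level,cbx7_level Baseline per-bin signal of the RYBP track
#'   (both classes) and of the CBX7 track in the depleted class.
#' @return A list: `rybp` and `cbx7` (`n_sites x bins` matrices, rows named
#'   `site_...`) and `truth` (data frame of site id and true class,
#'   `"variant_enriched"` or `"shared"`).
#' @examples
#' pr <- simulate_profiles(n_sites = 20, bins = 5, separation = 8, seed = 1)
#' table(pr$truth$class)
#' @export
simulate_profiles <- function(n_sites, bins, separation, seed = 1L,
                              prop_variant = 0.5, noise_sd = 1,
                              rybp_level = 5, cbx7_level = 1) {
  n_sites <- check_count(n_sites, "n_sites", min = 2L)
  bins <- check_count(bins, "bins", min = 1L)
  check_scalar_number(separation, "separation", min = 0)
  check_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  with_seed(seed, {
    n_var <- round(prop_variant * n_sites)
    class <- rep("shared", n_sites)
    class[sample.int(n_sites, n_var)] <- "variant_enriched"
    cbx7_mean <- ifelse(class == "variant_enriched",
                        cbx7_level, cbx7_level + separation * noise_sd)
    rybp <- matrix(rybp_level, n_sites, bins) +
      matrix(rnorm(n_sites * bins, sd = noise_sd), n_sites, bins)
    cbx7 <- matrix(cbx7_mean, n_sites, bins) +
      matrix(rnorm(n_sites * bins, sd = noise_sd), n_sites, bins)
    ids <- sprintf("site_%04d", seq_len(n_sites))
    dimnames(rybp) <- dimnames(cbx7) <-
      list(ids, sprintf("bin_%03d", seq_len(bins)))
    list(rybp = rybp, cbx7 = cbx7,
         truth = data.frame(site_id = ids, class = class,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a toy structure with crosslinks of known geometry
#'
#' Places `n_residues` C-alpha coordinates uniformly in a cubic box and samples
#' `n_links` distinct residue pairs as crosslinks. Confidence scores are drawn
#' so that a configurable fraction of links falls at or below the score
#' threshold (and would be removed by [filter_crosslinks()]); true pair
#' distances are returned in the truth channel.
#'
#' @param n_residues Number of residues (>= 2).
#' @param n_links Number of crosslinks; at most `n_residues*(n_residues-1)/2`.
#' @param seed Integer seed.
#' @param protein Protein label attached to the links.
#' @param chain Chain identifier of the structure.
#' @param box_size Edge length of the coordinate box in Angstrom.
#' @param frac_low_confidence Fraction of links given scores at or below
#'   `score_threshold`.
#' @param score_threshold Confidence threshold the low-score subset straddles.
#' @return A list: `structure` (a `structure_coords` data frame), `links`
#'   (crosslink data frame with `protein_a`, `residue_a`, `protein_b`,
#'   `residue_b`, `score`) and `truth` (per-link true distance in Angstrom).
#' @export
simulate_structure_and_crosslinks <- function(n_residues, n_links, seed = 1L,
                                              protein = "protA", chain = "A",
                                              box_size = 60,
                                              frac_low_confidence = 0.3,
                                              score_threshold = 15) {
  n_residues <- check_count(n_residues, "n_residues", min = 2L)
  n_links <- check_count(n_links, "n_links", min = 0L)
  max_links <- n_residues * (n_residues - 1) / 2
  if (n_links > max_links) {
    stop(sprintf("n_links (%d) exceeds the number of residue pairs (%d)",
                 n_links, max_links), call. = FALSE)
  }
  with_seed(seed, {
    xyz <- matrix(runif(3 * n_residues, 0, box_size), ncol = 3)
    structure_df <- structure_coords(
      chain = rep(chain, n_residues),
      residue = seq_len(n_residues),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      source = "synthetic"
    )
    if (n_links > 0) {
      pairs <- which(upper.tri(diag(n_residues)), arr.ind = TRUE)
      sel <- pairs[sample.int(nrow(pairs), n_links), , drop = FALSE]
      d <- sqrt(rowSums((xyz[sel[, 1], , drop = FALSE] -
                           xyz[sel[, 2], , drop = FALSE])^2))
      n_low <- round(frac_low_confidence * n_links)
      score <- runif(n_links, score_threshold + 0.5, score_threshold + 25)
      if (n_low > 0) {
        score[sample.int(n_links, n_low)] <- runif(n_low, 0, score_threshold)
      }
      links <- data.frame(
        protein_a = protein, residue_a = as.integer(sel[, 1]),
        protein_b = protein, residue_b = as.integer(sel[, 2]),
        score = score, stringsAsFactors = FALSE
      )
      truth <- data.frame(residue_a = as.integer(sel[, 1]),
                          residue_b = as.integer(sel[, 2]),
                          true_distance = d)
    } else {
      links <- data.frame(protein_a = character(0), residue_a = integer(0),
                          protein_b = character(0), residue_b = integer(0),
                          score = numeric(0), stringsAsFactors = FALSE)
      truth <- data.frame(residue_a = integer(0), residue_b = integer(0),
                          true_distance = numeric(0))
    }
    list(structure = structure_df, links = links, truth = truth)
  })
}
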