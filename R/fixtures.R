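#' Synthetic benchmark configuration
#'
#' The generator emulates the statistical shape of spectral-library
#' training data: many structures, a binary fingerprint per structure,
#' multiple replicate spectra per structure with highly variable replicate
#' counts (a truncated geometric mimics the observed 3-to-85 spread), and
#' fragment peaks statistically linked to fingerprint labels — each label
#' owns a small set of characteristic fragment masses that appear in the
#' spectra of structures carrying the label. It does not emulate real
#' fragmentation chemistry, isotope patterns or adduct diversity.
#'
#' @param n_structures number of structures.
#' @param n_labels number of fingerprint labels.
#' @param replicate_mean mean of the (truncated, >= 1) geometric replicate-
#'   count distribution.
#' @param replicate_max truncation point of the replicate count.
#' @param fragments_per_label characteristic fragment masses per label.
#' @param peak_mass_range numeric length-2, fragment mass range in Da.
#' @param label_prevalence numeric length-2, per-label prevalence range.
#' @param n_background_peaks structure-specific background peaks per
#'   spectrum.
#' @param peak_presence_prob probability that a characteristic peak of a
#'   positive label appears in a given clean spectrum.
#' @param noise list of [simulate_noise()] parameters applied to replicate
#'   spectra (`drop_fraction`, `intensity_jitter_sd`, `n_noise_peaks`,
#'   `noise_intensity_quantile`).
#' @param seed mandatory integer seed.
#' @return object of class `fixture_config`.
#' @export
fixture_config <- function(n_structures = 300L, n_labels = 40L,
                           replicate_mean = 5, replicate_max = 100L,
                           fragments_per_label = 3L,
                           peak_mass_range = c(50, 500),
                           label_prevalence = c(0.15, 0.5),
                           n_background_peaks = 6L,
                           peak_presence_prob = 0.95,
                           noise = list(drop_fraction = 0.2,
                                        intensity_jitter_sd = 0.3,
                                        n_noise_peaks = NULL,
                                        noise_intensity_quantile = 0.25),
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_structures >= 2, n_labels >= 1, replicate_mean >= 1,
            length(peak_mass_range) == 2, diff(peak_mass_range) > 0,
            all(label_prevalence > 0), all(label_prevalence <= 1))
  structure(list(n_structures = as.integer(n_structures),
                 n_labels = as.integer(n_labels),
                 replicate_mean = replicate_mean,
                 replicate_max = as.integer(replicate_max),
                 fragments_per_label = as.integer(fragments_per_label),
                 peak_mass_range = peak_mass_range,
                 label_prevalence = label_prevalence,
                 n_background_peaks = as.integer(n_background_peaks),
                 peak_presence_prob = peak_presence_prob,
                 noise = noise, seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate a synthetic fingerprint matrix
#'
#' Each label's prevalence is drawn uniformly from the configured range;
#' structure memberships are independent Bernoulli draws.
#'
#' @param cfg a [fixture_config()].
#' @return a [fingerprint_matrix()] over `cfg$n_structures` structures.
#' @export
generate_fingerprints <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  withr::with_seed(cfg$seed, {
    prev <- stats::runif(cfg$n_labels, cfg$label_prevalence[1],
                         cfg$label_prevalence[2])
    m <- vapply(prev, function(p) stats::rbinom(cfg$n_structures, 1, p),
                integer(cfg$n_structures))
    m <- matrix(m, nrow = cfg$n_structures)
  })
  rownames(m) <- sprintf("STRUCT%05d", seq_len(cfg$n_structures))
  colnames(m) <- sprintf("LABEL%04d", seq_len(cfg$n_labels))
  fingerprint_matrix(m)
}

# one characteristic mass set per label, drawn once per fixture
label_fragment_masses <- function(cfg) {
  withr::with_seed(cfg$seed + 1L, {
    matrix(stats::runif(cfg$n_labels * cfg$fragments_per_label,
                        cfg$peak_mass_range[1], cfg$peak_mass_range[2]),
           nrow = cfg$n_labels)
  })
}

#' Generate replicate spectra for a synthetic fingerprint matrix
#'
#' Every structure gets a clean template spectrum containing (with
#' probability `peak_presence_prob` each) the characteristic peaks of its
#' positive labels plus structure-specific background peaks, and a
#' replicate count drawn from the truncated geometric distribution.
#' Replicates are degraded with [simulate_noise()] using masses pooled from
#' the whole fixture as the noise-peak pool.
#'
#' @param fp [generate_fingerprints()] output.
#' @param cfg the same [fixture_config()].
#' @param clean skip the noise model (single clean spectrum per structure).
#' @return list with `spectra` (all replicates), `replicate_counts` (named
#'   per structure) and `fragment_masses` (n_labels x fragments_per_label).
#' @export
generate_spectra <- function(fp, cfg, clean = FALSE) {
  stopifnot(inherits(fp, "fingerprint_matrix"),
            inherits(cfg, "fixture_config"))
  frag <- label_fragment_masses(cfg)
  peak_pool <- as.numeric(frag)
  spectra <- list()
  withr::with_seed(cfg$seed + 2L, {
    # truncated geometric on {1, 2, ...} with the configured mean
    pgeo <- 1 / cfg$replicate_mean
    reps <- pmin(1L + stats::rgeom(cfg$n_structures, pgeo), cfg$replicate_max)
    if (clean) reps <- rep(1L, cfg$n_structures)
    seeds <- sample.int(2^30, cfg$n_structures * max(reps) + cfg$n_structures)
    for (i in seq_len(cfg$n_structures)) {
      key <- fp$structures[i]
      pos <- which(fp$values[i, ] == 1)
      char_mz <- as.numeric(frag[pos, , drop = FALSE])
      present <- stats::runif(length(char_mz)) < cfg$peak_presence_prob
      char_mz <- char_mz[present]
      char_int <- stats::runif(length(char_mz), 0.3, 1)
      bg_mz <- stats::runif(cfg$n_background_peaks, cfg$peak_mass_range[1],
                            cfg$peak_mass_range[2])
      bg_int <- stats::runif(cfg$n_background_peaks, 0.01, 0.2)
      mz <- c(char_mz, bg_mz); intensity <- c(char_int, bg_int)
      if (!length(mz)) { mz <- bg_mz[1]; intensity <- 1 }
      precursor <- cfg$peak_mass_range[2] + stats::runif(1, 1, 50)
      template <- spectrum(mz, intensity / max(intensity),
                           precursor_mz = precursor, structure_key = key,
                           compound_id = key, adduct = "[M+H]+",
                           collision_energy = "ramp",
                           instrument = "synthetic-qtof")
      for (r in seq_len(reps[i])) {
        s <- if (clean) template else
          simulate_noise(template, peak_pool = peak_pool,
                         drop_fraction = cfg$noise$drop_fraction,
                         intensity_jitter_sd = cfg$noise$intensity_jitter_sd,
                         n_noise_peaks = cfg$noise$n_noise_peaks,
                         noise_intensity_quantile =
                           cfg$noise$noise_intensity_quantile,
                         seed = seeds[(i - 1L) * max(reps) + r])
        s$compound_id <- sprintf("%s.rep%02d", key, r)
        s$collision_energy <- as.character(10 * r)
        spectra[[length(spectra) + 1L]] <- s
      }
    }
  })
  list(spectra = spectra,
       replicate_counts = stats::setNames(reps, fp$structures),
       fragment_masses = frag)
}

#' Generate a full desk-scale benchmark
#'
#' Structure-disjoint train/eval split, merged compound records with
#' replicate sample weights, and one candidate set per evaluation structure
#' containing the true fingerprint plus decoys at a fixed Hamming distance
#' (bit-flip decoys keep the test path free of cheminformatics
#' dependencies).
#'
#' @param cfg a [fixture_config()].
#' @param eval_fraction fraction of structures held out for evaluation.
#' @param n_candidates candidates per evaluation query (incl. the truth).
#' @param decoy_bits Hamming distance of each decoy from the truth.
#' @param clean generate clean single spectra instead of noisy replicates.
#' @return list with `train_records`, `eval_records` (lists of
#'   `compound_record`, merged, weighted), `fingerprints` (full
#'   [fingerprint_matrix()]), `candidates` (list of [candidate_set()]),
#'   `spectra` (raw replicates) and `fragment_masses`.
#' @export
generate_benchmark <- function(cfg, eval_fraction = 0.2, n_candidates = 10L,
                               decoy_bits = 5L, clean = FALSE) {
  stopifnot(inherits(cfg, "fixture_config"))
  fp <- generate_fingerprints(cfg)
  gen <- generate_spectra(fp, cfg, clean = clean)
  records <- merge_spectra(gen$spectra)
  weights <- compute_sample_weights(gen$replicate_counts)
  records <- lapply(records, function(r) {
    r$sample_weight <- weights[[r$structure_key]]
    r
  })
  n_eval <- max(1L, round(eval_fraction * cfg$n_structures))
  withr::with_seed(cfg$seed + 3L, {
    eval_keys <- sample(fp$structures, n_eval)
    keys <- vapply(records, `[[`, character(1), "structure_key")
    train_records <- records[!(keys %in% eval_keys)]
    eval_records <- records[keys %in% eval_keys]
    eval_records <- lapply(eval_records, function(r) {
      r$dataset_tag <- "eval"; r
    })
    candidates <- lapply(eval_keys, function(key) {
      truth <- fp$values[key, ]
      fps <- matrix(truth, n_candidates, cfg$n_labels, byrow = TRUE)
      for (j in seq_len(n_candidates - 1L)) {
        flip <- sample.int(cfg$n_labels, min(decoy_bits, cfg$n_labels))
        fps[j + 1L, flip] <- 1L - fps[j + 1L, flip]
      }
      colnames(fps) <- fp$labels
      rownames(fps) <- c(key, sprintf("%s.decoy%02d", key,
                                      seq_len(n_candidates - 1L)))
      candidate_set(query_id = key, fingerprints = fps, correct_key = key)
    })
  })
  list(train_records = train_records, eval_records = eval_records,
       fingerprints = fp, candidates = candidates,
       spectra = gen$spectra, fragment_masses = gen$fragment_masses)
}
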