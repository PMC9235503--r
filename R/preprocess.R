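#' Merge replicate spectra into compound records
#'
#' The learning methods consume a *compound*: either a single spectrum or a
#' merge of several spectra of the same structure measured on the same
#' instrument with the same adduct. Merging pools all peaks of a group and
#' agglomerates peaks closer than `ppm` parts-per-million; a merged peak
#' takes the intensity-weighted mean m/z and the maximum intensity of its
#' members.
#'
#' @param spectra list of [spectrum()] objects; every spectrum must carry
#'   `structure_key`, `instrument` and `adduct`.
#' @param group_by metadata fields defining a merge group.
#' @param ppm peak agglomeration tolerance in parts per million.
#' @param precursor_tol maximum spread of precursor m/z within a group (Da).
#' @return list of `compound_record` objects: one per group, each holding a
#'   merged `spectrum`, the structure key, the number of source spectra
#'   (`n_merged`) and a `dataset_tag` (default `"main"`).
#' @export
merge_spectra <- function(spectra,
                          group_by = c("structure", "instrument", "adduct"),
                          ppm = 10, precursor_tol = 0.05) {
  stopifnot(length(spectra) > 0)
  keyparts <- lapply(spectra, function(s) {
    parts <- character()
    if ("structure" %in% group_by) parts <- c(parts, s$structure_key)
    if ("instrument" %in% group_by) parts <- c(parts, as.character(s$instrument))
    if ("adduct" %in% group_by) parts <- c(parts, s$adduct)
    paste(parts, collapse = "||")
  })
  groups <- split(spectra, unlist(keyparts))
  out <- lapply(groups, function(grp) {
    prec <- vapply(grp, `[[`, numeric(1), "precursor_mz")
    if (diff(range(prec)) > precursor_tol)
      stop("conflicting precursor masses in group '",
           grp[[1]]$structure_key, "': ",
           paste(format(range(prec)), collapse = " .. "))
    first <- grp[[1]]
    if (length(grp) == 1L) {
      merged <- first
    } else {
      mz <- unlist(lapply(grp, `[[`, "mz"))
      intensity <- unlist(lapply(grp, `[[`, "intensity"))
      pk <- agglomerate_peaks(mz, intensity, ppm)
      ces <- unique(stats::na.omit(vapply(grp, `[[`, character(1),
                                          "collision_energy")))
      merged <- spectrum(pk$mz, pk$intensity,
                         precursor_mz = mean(prec),
                         structure_key = first$structure_key,
                         compound_id = paste0(first$structure_key, ":merged"),
                         adduct = first$adduct,
                         collision_energy = if (length(ces))
                           paste(ces, collapse = ",") else NA_character_,
                         instrument = first$instrument,
                         tolerance = Inf)
    }
    compound_record(merged, n_merged = length(grp))
  })
  unname(out)
}

# single linkage within a ppm window on the sorted mass axis; merged mz is
# the intensity-weighted mean, merged intensity the maximum (robust to the
# same fragment being split across replicates)
agglomerate_peaks <- function(mz, intensity, ppm) {
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  # (1 + 1e-9) slack keeps exactly-at-tolerance pairs on the merge side
  gap <- diff(mz) > mz[-length(mz)] * ppm * 1e-6 * (1 + 1e-9)
  grp <- cumsum(c(TRUE, gap))
  list(mz = as.numeric(tapply(mz * intensity, grp, sum) /
                         tapply(intensity, grp, sum)),
       intensity = as.numeric(tapply(intensity, grp, max)))
}

#' Wrap raw spectra as unmerged compound records
#'
#' The unmerged counterpart of [merge_spectra()]: every spectrum becomes its
#' own compound (the treatment of the large replicate-rich training
#' dataset), weighted by the reciprocal square root of its structure's
#' replicate count so heavily re-measured structures do not dominate.
#'
#' @param spectra list of [spectrum()] objects.
#' @param dataset_tag tag applied to all records (default `"additional"`).
#' @return list of `compound_record`s, one per spectrum.
#' @export
unmerged_records <- function(spectra, dataset_tag = "additional") {
  keys <- vapply(spectra, `[[`, character(1), "structure_key")
  w <- compute_sample_weights(table(keys))
  lapply(spectra, function(s)
    compound_record(s, dataset_tag = dataset_tag,
                    sample_weight = w[[s$structure_key]]))
}

#' Construct a compound record
#'
#' @param spec a merged or single [spectrum()].
#' @param molecular_formula named integer vector of element counts, or NULL.
#' @param dataset_tag one of `"main"`, `"additional"`, `"eval"`.
#' @param sample_weight positive training weight (see
#'   [compute_sample_weights()]).
#' @param n_merged number of source spectra merged into this record.
#' @return object of class `compound_record`.
#' @export
compound_record <- function(spec, molecular_formula = NULL,
                            dataset_tag = "main", sample_weight = 1,
                            n_merged = 1L) {
  stopifnot(inherits(spec, "fpkit_spectrum"), sample_weight > 0)
  if (!is.null(molecular_formula)) {
    mf <- unlist(molecular_formula)
    if (any(mf < 0) || any(mf != round(mf)))
      stop("molecular formula counts must be non-negative integers")
  }
  structure(
    list(spectrum = spec, structure_key = spec$structure_key,
         compound_id = spec$compound_id,
         molecular_formula = molecular_formula,
         dataset_tag = match.arg(dataset_tag, c("main", "additional", "eval")),
         sample_weight = sample_weight, n_merged = as.integer(n_merged)),
    class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record %s> structure %s, %d peaks, %d merged, tag=%s, w=%.4f\n",
              x$compound_id, x$structure_key, length(x$spectrum$mz),
              x$n_merged, x$dataset_tag, x$sample_weight))
  invisible(x)
}

#' Replicate-count sample weights
#'
#' Spectral libraries hold wildly different numbers of replicate spectra per
#' structure (85 for some structures, 3 for others). To keep heavily
#' re-measured structures from dominating training while still crediting the
#' extra information, each structure is weighted by the reciprocal of the
#' square root of its occurrence count.
#'
#' @param replicate_counts named integer vector, structure_key -> count >= 1.
#' @return named numeric vector of weights `1/sqrt(count)`, in (0, 1].
#' @export
compute_sample_weights <- function(replicate_counts) {
  counts <- unlist(replicate_counts)
  if (any(counts < 1)) stop("replicate counts must be >= 1")
  w <- 1 / sqrt(counts)
  names(w) <- names(replicate_counts)
  w
}

#' Spectrum cleanup before binned featurization
#'
#' Drops peaks below a relative-intensity floor and keeps at most the
#' `max_peaks` most intense peaks (ties broken by lower m/z kept first).
#'
#' @param s a [spectrum()].
#' @param min_rel_intensity relative intensity floor (fraction of base peak).
#' @param max_peaks maximum number of peaks retained.
#' @return a cleaned `spectrum`.
#' @export
remove_noise_peaks <- function(s, min_rel_intensity = 0.001, max_peaks = 500L) {
  stopifnot(inherits(s, "fpkit_spectrum"))
  if (!length(s$mz)) return(s)
  rel <- s$intensity / max(s$intensity)
  keep <- which(rel >= min_rel_intensity)
  if (length(keep) > max_peaks)
    keep <- keep[order(-s$intensity[keep], s$mz[keep])[seq_len(max_peaks)]]
  keep <- sort(keep)
  s$mz <- s$mz[keep]; s$intensity <- s$intensity[keep]
  s
}

#' Binned feature vector for the spectrum DNN
#'
#' A spectrum is turned into two concatenated sparse bin vectors: the raw
#' m/z axis and the precursor-difference axis (precursor m/z minus each
#' fragment m/z, which aligns neutral losses across precursors). Bin index
#' is `floor(m / bin_width)`; the bin value is the square root of relative
#' intensity (intensities are first scaled so the base peak is 1), and
#' colliding peaks keep the maximum.
#'
#' @param s a [spectrum()].
#' @param bin_width bin width in Da (default 0.005).
#' @param max_mass upper end of each axis in Da; peaks above it are dropped
#'   with a warning.
#' @return a length `2 * ceiling(max_mass / bin_width)` sparse vector
#'   ([Matrix::sparseVector]); first half raw m/z bins, second half
#'   precursor-difference bins.
#' @export
bin_spectrum_features <- function(s, bin_width = 0.005, max_mass = 1000) {
  stopifnot(inherits(s, "fpkit_spectrum"), bin_width > 0)
  nbins <- as.integer(ceiling(max_mass / bin_width))
  mz <- s$mz; intensity <- s$intensity
  if (length(mz) && max(intensity) > 0) intensity <- intensity / max(intensity)
  over <- mz > max_mass
  if (any(over)) {
    warning(sum(over), " peak(s) above max_mass ", max_mass, " Da dropped")
    mz <- mz[!over]; intensity <- intensity[!over]
  }
  val <- sqrt(intensity)
  i1 <- pmin(nbins - 1L, as.integer(floor(mz / bin_width))) + 1L
  dmz <- s$precursor_mz - mz
  ok2 <- dmz >= 0 & dmz <= max_mass
  i2 <- nbins + pmin(nbins - 1L,
                     as.integer(floor(dmz[ok2] / bin_width))) + 1L
  idx <- c(i1, i2); v <- c(val, val[ok2])
  if (anyDuplicated(idx)) {
    agg <- tapply(v, idx, max)   # collision rule: maximum
    idx <- as.integer(names(agg)); v <- as.numeric(agg)
  }
  ord <- order(idx)
  Matrix::sparseVector(x = v[ord], i = idx[ord], length = 2L * nbins)
}

#' Normalized molecular-formula feature vector
#'
#' Element counts divided elementwise by the per-element standard deviation
#' estimated on the training set. Elements whose training standard deviation
#' is zero carry no information and are dropped from the vector.
#'
#' @param formula named integer vector of element counts (e.g.
#'   `c(C = 6, H = 12, O = 6)`).
#' @param element_order character vector fixing the feature order.
#' @param stds named numeric vector of per-element training standard
#'   deviations, aligned with `element_order`.
#' @return dense numeric vector over `element_order` entries with
#'   `stds > 0`.
#' @export
formula_feature_vector <- function(formula, element_order, stds) {
  mf <- unlist(formula)
  unknown <- setdiff(names(mf), element_order)
  if (length(unknown))
    stop("element(s) outside the training alphabet: ",
         paste(unknown, collapse = ", "))
  stds <- stds[element_order]
  counts <- stats::setNames(numeric(length(element_order)), element_order)
  counts[names(mf)] <- mf
  keep <- !is.na(stds) & stds > 0
  counts[keep] / stds[keep]
}

#' Per-element standard deviations of a formula table
#'
#' @param formulas list of named element-count vectors (training set).
#' @param element_order feature order; default the union of elements seen.
#' @return list with `element_order` and `stds` for
#'   [formula_feature_vector()].
#' @export
formula_feature_stats <- function(formulas, element_order = NULL) {
  if (is.null(element_order))
    element_order <- sort(unique(unlist(lapply(formulas, names))))
  m <- vapply(formulas, function(f) {
    x <- stats::setNames(numeric(length(element_order)), element_order)
    f <- unlist(f); x[names(f)] <- f; x
  }, numeric(length(element_order)))
  m <- matrix(m, nrow = length(element_order))
  list(element_order = element_order,
       stds = stats::setNames(apply(m, 1, stats::sd), element_order))
}
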