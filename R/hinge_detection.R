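# Hinge calling: min-max normalization of the deformation and fluctuation
# tracks, superposition, region detection (high deformation AND low
# fluctuation), and the secondary-structure exclusion that nominates
# mutable candidate residues.

#' Min-max normalize a residue profile
#'
#' Maps the smallest value to 0 and the largest to 1; a monotone
#' transform, so residue ranking is preserved. Normalizing both the
#' deformation-energy and fluctuation tracks puts them on a common scale
#' so they can be superposed and thresholded jointly.
#'
#' @param profile raw `residue_profile` with at least two distinct values.
#' @return `residue_profile` with normalization `"minmax"`.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "residue_profile"))
  v <- profile$values
  rng <- range(v)
  if (diff(rng) <= 0) {
    stop("cannot min-max normalize a constant profile")
  }
  residue_profile((v - rng[1]) / diff(rng), profile$labels, units = "1",
                  normalization = "minmax",
                  provenance = paste(profile$provenance, "(minmax)"))
}

#' Find hinge regions from superposed normalized profiles
#'
#' A residue qualifies when its normalized deformation energy is at least
#' `tau_def` AND its normalized fluctuation is at most `tau_fluct` -- the
#' signature of a pivot: locally strained but barely displaced.
#' Qualifying residues are merged into contiguous regions; runs of at most
#' `max_gap` non-qualifying residues between qualifying ones are bridged.
#'
#' @param def_norm,fluct_norm min-max normalized `residue_profile`s over
#'   the same residues.
#' @param tau_def qualification threshold on normalized deformation
#'   (default 0.4).
#' @param tau_fluct qualification ceiling on normalized fluctuation
#'   (default 0.25).
#' @param max_gap largest bridged run of non-qualifying residues
#'   (default 1).
#' @return data frame of regions: `start`, `end` (mature residue labels,
#'   inclusive), `start_idx`, `end_idx` (bead indices), `n_qualifying`.
#' @export
find_hinge_regions <- function(def_norm, fluct_norm, tau_def = 0.4,
                               tau_fluct = 0.25, max_gap = 1L) {
  stopifnot(inherits(def_norm, "residue_profile"),
            inherits(fluct_norm, "residue_profile"),
            def_norm$normalization == "minmax",
            fluct_norm$normalization == "minmax")
  if (length(def_norm$values) != length(fluct_norm$values)) {
    stop("profile length mismatch: ", length(def_norm$values), " vs ",
         length(fluct_norm$values))
  }
  qual <- def_norm$values >= tau_def & fluct_norm$values <= tau_fluct
  regions_from_mask(qual, def_norm$labels, max_gap)
}

regions_from_mask <- function(qual, labels, max_gap) {
  empty <- data.frame(start = integer(), end = integer(),
                      start_idx = integer(), end_idx = integer(),
                      n_qualifying = integer())
  idx <- which(qual)
  if (!length(idx)) return(empty)
  # merge qualifying residues whose index gap leaves <= max_gap
  # non-qualifying residues between them
  brk <- which(diff(idx) > max_gap + 1L)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  data.frame(
    start = labels$resno[starts], end = labels$resno[ends],
    start_idx = starts, end_idx = ends,
    n_qualifying = vapply(seq_along(starts), function(r)
      sum(qual[starts[r]:ends[r]]), integer(1))
  )
}

#' Exclude secondary-structure residues from hinge regions
#'
#' Residues inside helix or sheet spans are poor mutation candidates
#' (mutating them risks misfolding), so they are removed from the region
#' residues; what remains are the candidate residues. Regions entirely
#' inside secondary structure are retained in the report as
#' detected-but-excluded.
#'
#' @param regions region data frame from [find_hinge_regions()].
#' @param sse_spans data frame `kind`, `chain`, `start`, `end` in the same
#'   (mature) numbering as the region labels, or NULL/empty for none.
#' @param labels bead labels of the underlying model.
#' @return list with `candidates` (integer mature residue numbers, in
#'   sequence order), `excluded` (region residues inside SSE) and
#'   `empty_regions` (row indices of regions fully removed).
#' @export
exclude_secondary_structure <- function(regions, sse_spans, labels) {
  region_res <- integer()
  for (r in seq_len(nrow(regions))) {
    region_res <- c(region_res,
                    labels$resno[regions$start_idx[r]:regions$end_idx[r]])
  }
  region_res <- sort(unique(region_res))
  in_sse <- rep(FALSE, length(region_res))
  if (!is.null(sse_spans) && NROW(sse_spans) > 0) {
    for (s in seq_len(nrow(sse_spans))) {
      in_sse <- in_sse | (region_res >= sse_spans$start[s] &
                            region_res <= sse_spans$end[s])
    }
  }
  empty <- vapply(seq_len(nrow(regions)), function(r) {
    rr <- labels$resno[regions$start_idx[r]:regions$end_idx[r]]
    all(rr %in% region_res[in_sse])
  }, logical(1))
  list(candidates = region_res[!in_sse], excluded = region_res[in_sse],
       empty_regions = which(empty))
}

#' Full hinge report for one mode
#'
#' Convenience wrapper running normalization, region finding and the
#' secondary-structure exclusion, and attaching a threshold-free combined
#' score S_i = def_norm_i * (1 - fluct_norm_i) so rankings can be
#' inspected independently of the thresholds.
#'
#' @param model `calpha_model` with force constants.
#' @param modes `mode_set`.
#' @param mode_index internal mode to analyse (default: first internal
#'   mode).
#' @inheritParams find_hinge_regions
#' @return object of class `hinge_report`: list with `mode_index`,
#'   `def_norm`, `fluct_norm`, `score`, `regions`, `candidates`,
#'   `excluded`, `empty_regions`, `thresholds`, and a per-residue `table`
#'   (label, def_norm, fluct_norm, S, qualifying, in_region, in_sse,
#'   candidate).
#' @export
hinge_report <- function(model, modes, mode_index = NULL, tau_def = 0.4,
                         tau_fluct = 0.25, max_gap = 1L) {
  if (is.null(mode_index)) mode_index <- first_internal_mode(modes)
  check_internal_mode(modes, mode_index)
  def_norm <- normalize_profile(deformation_energy(model, modes, mode_index))
  fl <- mode_fluctuation(modes, mode_index, labels = model$labels)
  fluct_norm <- normalize_profile(fl)
  regions <- find_hinge_regions(def_norm, fluct_norm, tau_def, tau_fluct,
                                max_gap)
  excl <- exclude_secondary_structure(regions, model$sse_spans,
                                      model$labels)
  score <- def_norm$values * (1 - fluct_norm$values)

  resno <- model$labels$resno
  qual <- def_norm$values >= tau_def & fluct_norm$values <= tau_fluct
  in_region <- rep(FALSE, length(resno))
  for (r in seq_len(nrow(regions))) {
    in_region[regions$start_idx[r]:regions$end_idx[r]] <- TRUE
  }
  tab <- data.frame(
    resno = resno, resname = model$labels$resname,
    def_norm = def_norm$values, fluct_norm = fluct_norm$values,
    score = score, qualifying = qual, in_region = in_region,
    in_sse = model$in_sse, candidate = resno %in% excl$candidates)

  structure(
    list(mode_index = mode_index, def_norm = def_norm,
         fluct_norm = fluct_norm, score = score, regions = regions,
         candidates = excl$candidates, excluded = excl$excluded,
         empty_regions = excl$empty_regions,
         thresholds = list(tau_def = tau_def, tau_fluct = tau_fluct,
                           max_gap = max_gap),
         table = tab),
    class = "hinge_report"
  )
}

#' @export
print.hinge_report <- function(x, ...) {
  cat("<hinge_report> mode ", x$mode_index, ": ", nrow(x$regions),
      " regions, ", length(x$candidates), " candidate residues",
      " (tau_def = ", x$thresholds$tau_def,
      ", tau_fluct = ", x$thresholds$tau_fluct,
      ", max_gap = ", x$thresholds$max_gap, ")\n", sep = "")
  if (length(x$candidates)) {
    cat("  candidates:", paste(x$candidates, collapse = " "), "\n")
  }
  invisible(x)
}
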