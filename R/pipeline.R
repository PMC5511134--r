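# Pipeline orchestration: a validated flat config drives the full
# analysis (structure -> ENM -> modes -> profiles -> hinge report ->
# H-bond persistence -> optional trajectory PCA) and writes delimited
# tables, a JSON report and a run manifest to an output directory.

pipeline_defaults <- function() {
  list(
    structure = NULL,        # path to a PDB file (required unless a
                             # structure object is passed directly)
    trajectory = NULL,       # optional multi-model PDB path
    sse_override = NULL,     # optional SSE table path
    chain = NULL,
    numbering_offset = 0L,
    k_bond = 1000, gamma_sse = 5, c_dist = 1e4, k_ss = 500,
    r_cut = 15, r_bridge = 5.5,
    zero_tol = 1e-9,
    mode = NULL,             # NULL = first internal mode ("mode 7")
    amplitude = NULL,        # NULL = calibrate to max_rmsd
    max_rmsd = 2.0,
    n_frames = 21L,
    tau_def = 0.4, tau_fluct = 0.25, max_gap = 1L,
    hbond_cutoff = 3.2,
    pca_k = 3L,
    out = NULL,              # output directory (required by run_pipeline)
    seed = 1L
  )
}

numeric_keys <- function() {
  c("numbering_offset", "k_bond", "gamma_sse", "c_dist", "k_ss", "r_cut",
    "r_bridge", "zero_tol", "mode", "amplitude", "max_rmsd", "n_frames",
    "tau_def", "tau_fluct", "max_gap", "hbond_cutoff", "pca_k", "seed")
}

positive_keys <- function() {
  c("k_bond", "gamma_sse", "c_dist", "k_ss", "r_cut", "r_bridge",
    "zero_tol", "max_rmsd", "hbond_cutoff")
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; unknown keys, malformed
#' values and out-of-range parameters are all collected and reported
#' together (not just the first). Missing keys take documented defaults;
#' malformed values are never silently replaced by defaults.
#'
#' @param config path to a YAML config file, or a named list of settings.
#'   Keys and defaults: see `hingescan:::pipeline_defaults()` and the
#'   parameter documentation of [ff_params()], [hinge_report()],
#'   [mode_trajectory()], [detect_hbonds()] and [traj_pca()].
#' @return the fully defaulted config list (class `pipeline_config`), or
#'   an error listing every violation.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- tryCatch(yaml::read_yaml(config), error = function(e)
      stop("config file not parseable as YAML: ", conditionMessage(e)))
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  problems <- character()

  unknown <- setdiff(names(config), names(defaults))
  for (key in unknown) {
    near <- names(defaults)[which.min(adist(key, names(defaults)))]
    problems <- c(problems, sprintf(
      "unknown key '%s' (nearest valid key: '%s')", key, near))
  }
  config <- config[setdiff(names(config), unknown)]

  for (key in intersect(names(config), numeric_keys())) {
    v <- config[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      problems <- c(problems, sprintf("key '%s' must be a finite number", key))
    }
  }
  merged <- modifyList(defaults, config, keep.null = TRUE)
  chk <- function(cond, msg) if (isTRUE(cond)) problems <<- c(problems, msg)
  for (key in positive_keys()) {
    v <- merged[[key]]
    if (is.numeric(v) && length(v) == 1L && is.finite(v)) {
      chk(v <= 0, sprintf("key '%s' must be positive (got %g)", key, v))
    }
  }
  if (is.numeric(merged$tau_def)) {
    chk(merged$tau_def < 0 || merged$tau_def > 1, "key 'tau_def' must lie in [0, 1]")
  }
  if (is.numeric(merged$tau_fluct)) {
    chk(merged$tau_fluct < 0 || merged$tau_fluct > 1, "key 'tau_fluct' must lie in [0, 1]")
  }
  if (is.numeric(merged$max_gap)) chk(merged$max_gap < 0, "key 'max_gap' must be >= 0")
  if (is.numeric(merged$n_frames)) chk(merged$n_frames < 3, "key 'n_frames' must be >= 3")
  if (is.numeric(merged$pca_k)) chk(merged$pca_k < 1, "key 'pca_k' must be >= 1")
  if (!is.null(merged$amplitude) && is.numeric(merged$amplitude)) {
    chk(merged$amplitude < 0, "key 'amplitude' must be non-negative")
  }

  if (length(problems)) {
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  class(merged) <- c("pipeline_config", "list")
  merged
}

#' Run the full hinge-detection pipeline
#'
#' Orchestrates: structure reading, C-alpha extraction, force-constant
#' construction, normal-mode solution, fluctuation/deformation profiling
#' of the analysis mode, hinge-region calling with secondary-structure
#' exclusion, candidate hydrogen-bond detection and persistence along the
#' mode trajectory, and (when a trajectory is supplied) superposition +
#' PCA with per-residue contributions. Writes tab-separated tables, a
#' JSON hinge report, the mode trajectory as multi-model PDB, and a run
#' manifest echoing the fully defaulted config, to `config$out`.
#'
#' Identical config + seed produce byte-identical reports.
#'
#' @param config a `pipeline_config` from [validate_config()], a config
#'   list/YAML path (validated on the way in).
#' @param struct optionally a pre-built `structure`, bypassing
#'   `config$structure`.
#' @return invisibly, a list with the in-memory results: `model`,
#'   `modes`, `report` (`hinge_report`), `hbonds`, `persistence`,
#'   `pca` (or NULL), `files` (paths written).
#' @export
run_pipeline <- function(config = list(), struct = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (is.null(config$out)) stop("config key 'out' (output directory) is required")
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.null(struct)) {
    if (is.null(config$structure)) {
      stop("config key 'structure' (input PDB) is required")
    }
    struct <- stage("read_structure",
                    read_pdb(config$structure, chain = config$chain,
                             sse_override = config$sse_override))
  }
  nmap <- numbering_map(chain = config$chain,
                        offset = config$numbering_offset)
  model <- stage("extract_calpha", extract_calpha(struct, nmap))
  model <- stage("force_constants", build_force_constants(
    model, ff_params(k_bond = config$k_bond, gamma_sse = config$gamma_sse,
                     c_dist = config$c_dist, k_ss = config$k_ss,
                     r_cut = config$r_cut, r_bridge = config$r_bridge)))
  hess <- stage("hessian", build_hessian(model))
  modes <- stage("modes", compute_modes(hess, zero_tol = config$zero_tol))
  mode_idx <- if (is.null(config$mode)) first_internal_mode(modes) else
    as.integer(config$mode)

  report <- stage("hinge_report", hinge_report(
    model, modes, mode_index = mode_idx, tau_def = config$tau_def,
    tau_fluct = config$tau_fluct, max_gap = config$max_gap))

  traj <- stage("mode_trajectory", mode_trajectory(
    model, modes, mode_idx, amplitude = config$amplitude,
    n_frames = config$n_frames, max_rmsd = config$max_rmsd))

  cand_pdb <- model$labels$pdb_resno[model$labels$resno %in% report$candidates]
  hbonds <- stage("hbond_detect", if (length(cand_pdb)) {
    detect_hbonds(struct, residues = cand_pdb,
                  cutoff = config$hbond_cutoff, numbering = nmap)
  } else empty_hbond_table())
  persistence <- stage("hbond_persistence", if (nrow(hbonds)) {
    vapply(seq_len(nrow(hbonds)), function(b)
      hbond_persistence(struct, hbonds[b, ], traj, model,
                        cutoff = config$hbond_cutoff)$persistence,
      numeric(1))
  } else numeric(0))
  if (nrow(hbonds)) hbonds$persistence <- persistence

  pca <- NULL
  if (!is.null(config$trajectory)) {
    user_traj <- stage("read_trajectory",
                       read_trajectory_pdb(config$trajectory,
                                           chain = config$chain))
    aligned <- stage("superpose", superpose(user_traj))
    pca <- stage("pca", traj_pca(aligned, k = config$pca_k))
  }

  files <- stage("write_outputs", write_pipeline_outputs(
    config, model, modes, mode_idx, report, traj, hbonds, pca))

  invisible(list(model = model, modes = modes, mode_index = mode_idx,
                 report = report, trajectory = traj, hbonds = hbonds,
                 persistence = persistence, pca = pca, files = files))
}

write_pipeline_outputs <- function(config, model, modes, mode_idx, report,
                                   traj, hbonds, pca) {
  out <- config$out
  p <- function(f) file.path(out, f)
  write_tsv <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p(f)
  }
  files <- c(
    modes = write_tsv(mode_table(modes), "modes.tsv"),
    residues = write_tsv(report$table, "residue_table.tsv"),
    hbonds = write_tsv(as.data.frame(hbonds), "hbonds.tsv")
  )
  traj_path <- p("mode_trajectory.pdb")
  write_trajectory_pdb(traj, traj_path, labels = model$labels)
  files["trajectory"] <- traj_path

  report_json <- list(
    mode = mode_idx,
    thresholds = report$thresholds,
    n_regions = nrow(report$regions),
    regions = report$regions,
    candidates = report$candidates,
    excluded = report$excluded,
    hbonds = as.data.frame(hbonds),
    collectivity = collectivity(modes, mode_idx)
  )
  jp <- p("hinge_report.json")
  jsonlite::write_json(report_json, jp, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  files["report"] <- jp

  if (!is.null(pca)) {
    files["pca_eigenvalues"] <- write_tsv(
      data.frame(pc = seq_along(pca$values), eigenvalue = pca$values),
      "pca_eigenvalues.tsv")
    contrib <- as.data.frame(pca$contributions)
    names(contrib) <- paste0("PC", seq_len(ncol(contrib)))
    files["pca_contributions"] <- write_tsv(
      cbind(resno = model$labels$resno, contrib), "pca_contributions.tsv")
  }

  manifest <- list(
    package = "hingescan",
    version = as.character(utils::packageVersion("hingescan")),
    config = unclass(config),
    n_beads = nrow(model$xyz),
    n_rigid_modes = sum(modes$rigid),
    analysis_mode = mode_idx,
    outputs = as.list(files)
  )
  mp <- p("manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  files["manifest"] <- mp
  files
}
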