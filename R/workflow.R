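# End-to-end workflow: ensemble -> reaction coordinates -> free-energy
# landscape -> basins -> per-basin fingerprints -> hotspots ->
# pre-reaction-state statistics -> optional tunnel/pocket metrics.

#' Validate a workflow configuration
#'
#' A configuration is a named list (or a YAML file with the same
#' structure):
#'
#' * `input`: either `list(pdb = <path>)` or
#'   `list(synthetic = list(...))` with [ensemble_spec()] arguments;
#' * `selections`: `ligand`, `acceptor_O`, `anomeric_C`, `catalytic_N`
#'   (required) and optionally `analysis` (reaction-coordinate
#'   selection, default `"name CA"`);
#' * `fel`: optional `bins` (length 2), `temperature_K`,
#'   `min_separation_bins`;
#' * `contacts`: optional [contact_config()] overrides;
#' * `prs`: optional `threshold`;
#' * `tunnel`: optional `profile_csv` and `cost_scale`;
#' * `pocket`: optional `seed_point`, `grid_spacing`, `probe_radius`;
#' * `output_dir`: where stage artifacts are written (optional);
#' * `seed`: integer seed for the synthetic input.
#'
#' Defaults are filled in and returned, so the resolved configuration is
#' part of the run's provenance.
#'
#' @param config Named list or path to a YAML file.
#' @return The resolved configuration list.
#' @export
validate_workflow_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML path.")
  if (is.null(config$input)) abort("Config field missing: `input`.")
  if (is.null(config$input$pdb) && is.null(config$input$synthetic)) {
    abort("Config field `input` needs either `pdb` or `synthetic`.")
  }
  if (!is.null(config$input$pdb) && !file.exists(config$input$pdb)) {
    abort(paste0("Config `input$pdb` does not exist: ", config$input$pdb))
  }
  sel <- config$selections
  if (is.null(sel)) abort("Config field missing: `selections`.")
  for (f in c("ligand", "acceptor_O", "anomeric_C", "catalytic_N")) {
    if (is.null(sel[[f]])) {
      abort(paste0("Config field missing: `selections$", f, "`."))
    }
  }
  sel$analysis <- sel$analysis %||% "name CA"
  config$selections <- sel
  fel <- config$fel %||% list()
  fel$bins <- as.numeric(unlist(fel$bins %||% c(40, 40)))
  fel$temperature_K <- fel$temperature_K %||% 300
  fel$min_separation_bins <- fel$min_separation_bins %||% 2
  config$fel <- fel
  config$contacts <- config$contacts %||% list()
  config$prs <- config$prs %||% list()
  config$prs$threshold <- config$prs$threshold %||% 3.5
  config$hotspots <- config$hotspots %||% list()
  config$hotspots$min_frequency <- config$hotspots$min_frequency %||% 0.5
  config$seed <- config$seed %||% 1
  config
}

#' Run the full analysis workflow
#'
#' Executes the pipeline stages in fixed order with fail-fast semantics:
#' load or generate the ensemble, compute RMSD/Rg reaction coordinates,
#' build the free-energy landscape, locate basins and representative
#' frames, compute per-basin interaction fingerprints, select hotspot
#' residues, compute pre-reaction-state statistics, and (when
#' configured) tunnel and pocket metrics. With a fixed config and seed
#' the report is identical run to run.
#'
#' @param config See [validate_workflow_config()].
#' @return A `ps_workflow_report`: list with the resolved config and its
#'   hash, the per-stage results (`fel_summary`, `basins`,
#'   `fingerprints`, `hotspots`, `prs`, `tunnel`, `pocket`) and paths of
#'   written artifacts.
#' @export
run_workflow <- function(config) {
  config <- validate_workflow_config(config)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  artifacts <- character(0)

  # Stage 1: ensemble
  if (!is.null(config$input$pdb)) {
    ens <- read_multimodel_pdb(config$input$pdb)
  } else {
    spec <- do.call(
      ensemble_spec,
      c(config$input$synthetic, list(seed = config$seed))
    )
    ens <- generate_two_basin_ensemble(spec)$ensemble
  }
  sel <- config$selections
  # Pre-run selection resolution (fail before any heavy stage).
  for (f in c("ligand", "acceptor_O", "anomeric_C", "catalytic_N",
    "analysis"
  )) {
    s <- resolve_selection(ens$topology, sel[[f]])
    if (s$empty) {
      abort(paste0("Selection `", f, "` ('", sel[[f]], "') matches no atoms."))
    }
  }

  # Stage 2: reaction coordinates
  x <- rmsd_series(ens, selection = sel$analysis, reference = 1)
  y <- rg_series(ens, selection = sel$analysis)

  # Stage 3: free-energy landscape
  fel <- compute_fel(x, y,
    bins = config$fel$bins,
    temperature_K = config$fel$temperature_K
  )

  # Stage 4: basins + representatives
  basins <- find_minima(fel,
    min_separation_bins = config$fel$min_separation_bins
  )
  basins <- representative_frames(basins, fel)

  # Stage 5: per-basin fingerprints (frames of each basin bin)
  cc <- do.call(contact_config, config$contacts)
  fps <- list()
  for (r in seq_len(min(nrow(basins), 4))) {
    fps[[paste0("basin_", r)]] <- fingerprint(
      ens, sel$ligand,
      frames = basins$members[[r]], config = cc,
      scope = paste0("basin_", r)
    )
  }

  # Stage 6: hotspots
  hotspots <- select_hotspots(fps,
    min_frequency = config$hotspots$min_frequency,
    require_all_basins = TRUE
  )

  # Stage 7: pre-reaction-state statistics
  prs <- prs_population(ens,
    acceptor_O = sel$acceptor_O, anomeric_C = sel$anomeric_C,
    catalytic_N = sel$catalytic_N, threshold = config$prs$threshold
  )

  # Stage 8: optional tunnel / pocket metrics
  tunnel <- NULL
  if (!is.null(config$tunnel$profile_csv)) {
    prof <- read_tunnel_profile_csv(config$tunnel$profile_csv)
    tunnel <- tunnel_metrics(prof,
      cost_scale = config$tunnel$cost_scale %||% 1
    )
  }
  pocket <- NULL
  if (!is.null(config$pocket$seed_point)) {
    pocket <- pocket_metrics(ens,
      seed_point = unlist(config$pocket$seed_point),
      grid_spacing = config$pocket$grid_spacing %||% 0.5,
      probe_radius = config$pocket$probe_radius %||% 1.4
    )
  }

  if (!is.null(out_dir)) {
    artifacts <- c(
      fel = write_fel_tsv(fel, file.path(out_dir, "fel.tsv")),
      basins = {
        p <- file.path(out_dir, "basins.json")
        jsonlite::write_json(
          dplyr::select(basins, -"members"), p,
          auto_unbox = TRUE, digits = NA
        )
        p
      },
      hotspots = {
        p <- file.path(out_dir, "hotspots.tsv")
        utils::write.table(
          dplyr::select(
            as.data.frame(hotspots),
            -dplyr::any_of("supporting_types")
          ),
          p, sep = "\t", row.names = FALSE, quote = FALSE
        )
        p
      },
      prs = {
        p <- file.path(out_dir, "prs.json")
        jsonlite::write_json(
          as.list(glance(prs)), p, auto_unbox = TRUE, digits = NA
        )
        p
      }
    )
    for (nm in names(fps)) {
      p <- file.path(out_dir, paste0("ifp_", nm, ".tsv"))
      write_ifp_tsv(fps[[nm]], p)
      artifacts <- c(artifacts, setNames(p, paste0("ifp_", nm)))
    }
  }

  report <- structure(
    list(
      config = config,
      config_hash = rlang::hash(config),
      n_frames = n_frames(ens),
      fel_summary = glance(fel),
      basins = basins,
      fingerprints = fps,
      hotspots = hotspots,
      prs = glance(prs),
      prs_distances = tidy(prs),
      tunnel = tunnel,
      pocket = pocket,
      artifacts = artifacts
    ),
    class = "ps_workflow_report"
  )
  report
}

#' @export
print.ps_workflow_report <- function(x, ...) {
  cat(
    "<ps_workflow_report> config hash ", x$config_hash, "\n  ",
    x$n_frames, " frames; ", nrow(x$basins), " basins; ",
    nrow(x$hotspots), " hotspot residues; PRS fraction ",
    signif(x$prs$prs_fraction, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Content hash of a workflow report
#'
#' Deterministic hash of the report's scientific content (everything
#' except file paths), for run-to-run reproducibility checks.
#'
#' @param report A `ps_workflow_report`.
#' @return Character hash.
#' @export
report_content_hash <- function(report) {
  core <- report[setdiff(names(report), "artifacts")]
  rlang::hash(core)
}
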