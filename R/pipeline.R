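#' Load a pipeline configuration from YAML
#'
#' @param path YAML file path.
#' @return The configuration list, validated by [validate_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' A configuration names either an `input` census file or a `simulation`
#' block (exactly one of the two), plus optional `basis`, `group_by`,
#' `out_dir`, `seed` and `cycling` entries. Validation happens before any
#' computation.
#'
#' @param config a configuration list.
#' @return The configuration, with defaults filled in.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulation)
  if (has_input == has_sim)
    stop("config must contain exactly one of `input` (census file path) ",
         "or `simulation` (simulation block)", call. = FALSE)
  if (has_input && (!is.character(config$input) || length(config$input) != 1L))
    stop("`input` must be a single file path", call. = FALSE)
  config$basis <- match.arg(config$basis %||% "sown", c("sown", "viable"))
  config$group_by <- config$group_by %||%
    c("species", "treatment", "temperature_C")
  if (!all(config$group_by %in% c("species", "treatment", "temperature_C")))
    stop("`group_by` entries must be among species, treatment, temperature_C",
         call. = FALSE)
  config$out_dir <- config$out_dir %||% "."
  config$seed <- as.integer(config$seed %||% 1L)
  if (!is.null(config$cycling) && !is.list(config$cycling))
    stop("`cycling` must be a block of run_burial() arguments", call. = FALSE)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build model objects from a simulation config block
.sim_objects <- function(sim, seed) {
  thermal <- do.call(thermal_model, sim$thermal %||% list())
  des_args <- sim$design %||% list()
  if (is.null(des_args$rng_seed)) des_args$rng_seed <- seed
  if (!is.null(des_args$temperatures_C))
    des_args$temperatures_C <- unlist(des_args$temperatures_C)
  design <- do.call(simulation_design, des_args)
  state <- dormancy_state(sim$dormancy_level %||% 0.5,
                          sim$pd_type %||% 3L)
  extra <- sim[names(sim) %in% c("kappa", "leak", "dead_frac", "T_range",
                                 "T_mid", "gmax_gamma", "gmax_floor")]
  if (!is.null(extra$T_range)) extra$T_range <- unlist(extra$T_range)
  list(design = design, thermal = thermal, state = state, extra = extra,
       treatment = sim$treatment %||% "simulated",
       species = sim$species %||% "synthetic")
}

#' Run the full analysis pipeline
#'
#' Loads census data (or simulates it), writes a per-replicate index table
#' and group summaries, optionally runs a burial/cycling simulation, and
#' records provenance (the full configuration, its MD5 hash, the seed and
#' the package version). All randomness is routed through `config$seed`.
#' On any stage error, files already written by this run are removed and
#' the error is re-thrown, so partial output never survives.
#'
#' @param config configuration list (see [validate_config()]) or a YAML
#'   file path.
#' @return Invisibly, a named list of the written file paths
#'   (`indices`, `summary`, optionally `burial` and `correlation`, and
#'   `provenance`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    indices = file.path(config$out_dir, "indices.csv"),
    summary = file.path(config$out_dir, "summary.csv")
  )
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    if (!is.null(config$input)) {
      trialsets <- read_counts(config$input)
    } else {
      so <- .sim_objects(config$simulation, config$seed)
      trialsets <- do.call(simulate_trialset,
                           c(list(so$design, so$thermal, so$state,
                                  treatment = so$treatment,
                                  species = so$species),
                             so$extra))
    }
    idx <- replicate_indices(trialsets, basis = config$basis)
    utils::write.csv(idx, paths$indices, row.names = FALSE)
    written <- c(written, paths$indices)
    summ <- summarize_trialsets(trialsets, group_by = config$group_by,
                                warn_excluded = FALSE)
    utils::write.csv(summ, paths$summary, row.names = FALSE)
    written <- c(written, paths$summary)

    if (!is.null(config$cycling)) {
      cyc <- config$cycling
      so <- .sim_objects(config$simulation %||% list(), config$seed)
      series <- do.call(run_burial,
                        c(list(so$design, so$thermal,
                               pd_type = cyc$pd_type %||% 3L,
                               n_months = cyc$n_months %||% 12L,
                               d_mean = cyc$d_mean %||% 0.5,
                               d_amp = cyc$d_amp %||% 0.4,
                               phase = cyc$phase %||% 0,
                               assay_temperature =
                                 cyc$assay_temperature %||% 20,
                               basis = config$basis,
                               species = so$species),
                          so$extra))
      paths$burial <- file.path(config$out_dir, "burial.csv")
      utils::write.csv(as.data.frame(series), paths$burial, row.names = FALSE)
      written <- c(written, paths$burial)
      corr <- cycling_correlation(series)
      paths$correlation <- file.path(config$out_dir, "correlation.json")
      jsonlite::write_json(corr, paths$correlation, auto_unbox = TRUE,
                           digits = NA)
      written <- c(written, paths$correlation)
    }

    paths$provenance <- file.path(config$out_dir, "provenance.json")
    cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                 null = "null")
    tmp <- tempfile(fileext = ".json")
    writeLines(cfg_json, tmp)
    prov <- list(
      package = "germsync",
      version = as.character(utils::packageVersion("germsync")),
      seed = config$seed,
      rng = "base R Mersenne-Twister, per-replicate derived substreams",
      config_md5 = unname(tools::md5sum(tmp)),
      config = config
    )
    unlink(tmp)
    jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE,
                         digits = NA, null = "null")
    written <- c(written, paths$provenance)
    invisible(paths)
  }, error = on_fail)
}
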