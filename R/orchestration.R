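# End-to-end pipeline: synthetic study (or CSV input) -> per-school fits ->
# goodness of fit -> meta-analysis -> selection tables, with a manifest for
# reproducibility and resumption.

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order, writing per-school fit JSONs, GOF
#' CSVs, the meta-analysis table and pooled selection tables plus a run
#' manifest (seed, configuration hash, stage completion) under `out_dir`.
#' Per-school estimation failures are logged and skipped, never fatal.
#' With `resume = TRUE`, stages already recorded in the manifest are not
#' recomputed.
#'
#' @param config a configuration list or the path of a YAML file with
#'   optional blocks `synth` (arguments of [synth_config()]), `estimation`
#'   (arguments of [estimate_options()]), `model` (`effects`, `behaviors`),
#'   `gof` (`R`), `tables` (`behaviors`).
#' @param out_dir output directory.
#' @param seed master seed (overrides the config's).
#' @param stages subset of `c("synth", "estimate", "gof", "meta", "tables")`.
#' @param resume skip stages already completed in `out_dir`'s manifest.
#' @return `out_dir`, invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = "coevonet_run",
                         seed = NULL,
                         stages = c("synth", "estimate", "gof", "meta", "tables"),
                         resume = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a list or a YAML path")
  stages <- match.arg(stages, c("synth", "estimate", "gof", "meta", "tables"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  synth_args <- config$synth %||% list()
  if (!is.null(seed)) synth_args$seed <- seed
  cfg <- do.call(synth_config, synth_args)
  config_hash <- rlang::hash(list(cfg[setdiff(names(cfg), "seed")],
                                  config$estimation, config$model,
                                  config$gof, config$tables))

  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else {
    list(seed = cfg$seed, config_hash = config_hash,
         package_version = as.character(utils::packageVersion("coevonet")),
         stages = character(0), excluded_schools = character(0))
  }
  if (resume && !identical(manifest$config_hash, config_hash))
    abort("manifest in out_dir was produced with a different configuration")
  done <- function(stage) resume && stage %in% manifest$stages
  save_manifest <- function() jsonlite::write_json(
    manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  study <- NULL
  get_study <- function() {
    if (is.null(study)) study <<- generate_study(cfg)
    study
  }

  if ("synth" %in% stages && !done("synth")) {
    generate_study(cfg, out_dir = file.path(out_dir, "panels"))
    manifest$stages <- union(manifest$stages, "synth")
    save_manifest()
  }

  fits <- list()
  fit_dir <- file.path(out_dir, "fits")
  if (any(c("estimate", "gof", "meta", "tables") %in% stages)) {
    study <- get_study()
    if ("estimate" %in% stages && !done("estimate")) {
      dir.create(fit_dir, showWarnings = FALSE)
      opts <- do.call(estimate_options, config$estimation %||% list())
      model_args <- config$model %||% list()
      for (k in seq_along(study$panels)) {
        p <- study$panels[[k]]
        fit <- tryCatch({
          spec <- model_spec(p, effects = model_args$effects %||% cfg$effects,
                             behaviors = model_args$behaviors %||% cfg$behaviors)
          f <- estimate_school(p, spec, opts,
                               seed = .school_seed(cfg$seed, 10000 + k))
          inform(sprintf("school %s: max |t| = %.3f, overall = %.3f%s",
                         p$school_id, max(abs(f$t_ratios)), f$overall_ratio,
                         if (f$converged) "" else " (not converged)"))
          f
        }, error = function(e) {
          warn(sprintf("school %s failed: %s", p$school_id, conditionMessage(e)))
          NULL
        })
        if (!is.null(fit)) {
          fits[[p$school_id]] <- fit
          write_fit_json(fit, file.path(fit_dir, paste0(p$school_id, ".json")))
        }
      }
      saveRDS(fits, file.path(out_dir, "fits.rds"))
      manifest$excluded_schools <- setdiff(
        vapply(study$panels, function(p) p$school_id, character(1)),
        names(Filter(function(f) f$converged, fits)))
      manifest$stages <- union(manifest$stages, "estimate")
      save_manifest()
    } else if (file.exists(file.path(out_dir, "fits.rds"))) {
      fits <- readRDS(file.path(out_dir, "fits.rds"))
    }
  }

  if ("gof" %in% stages && !done("gof") && length(fits)) {
    study <- get_study()
    gof_dir <- file.path(out_dir, "gof")
    dir.create(gof_dir, showWarnings = FALSE)
    gof_cfg <- config$gof %||% list()
    R <- gof_cfg$R %||% 100
    for (sid in names(fits)) {
      p <- study$panels[[which(vapply(study$panels, function(q)
        q$school_id == sid, logical(1)))]]
      g <- saom_gof(fits[[sid]], p, R = R,
                    in_cap = gof_cfg$in_cap %||% 7,
                    out_cap = gof_cfg$out_cap %||% 7,
                    seed = .school_seed(cfg$seed, 20000 + match(sid, names(fits))))
      write_gof_csv(g, file.path(gof_dir, paste0(sid, "_gof.csv")))
    }
    manifest$stages <- union(manifest$stages, "gof")
    save_manifest()
  }

  if ("meta" %in% stages && !done("meta") && length(fits) >= 2) {
    study <- get_study()
    meta <- tryCatch(meta_analyze(fits, study$metadata), error = function(e) {
      warn(sprintf("meta-analysis skipped: %s", conditionMessage(e)))
      NULL
    })
    if (!is.null(meta)) {
      write.csv(tidy(meta), file.path(out_dir, "meta_analysis.csv"),
                row.names = FALSE)
      manifest$stages <- union(manifest$stages, "meta")
      save_manifest()
    }
  }

  if ("tables" %in% stages && !done("tables") && length(fits) >= 2) {
    beh <- (config$tables %||% list())$behaviors %||%
      intersect(cfg$behaviors, .beh_dims)
    for (b in beh) {
      tabs <- tryCatch(selection_tables(fits, b), error = function(e) NULL)
      if (is.null(tabs)) next
      out <- dplyr::bind_rows(lapply(tabs, tidy))
      write.csv(out, file.path(out_dir, sprintf("selection_table_%s.csv", b)),
                row.names = FALSE)
    }
    manifest$stages <- union(manifest$stages, "tables")
    save_manifest()
  }

  invisible(out_dir)
}
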