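# Orchestration: a config-driven run over a multi-species occurrence file
# (filter -> extract -> envelope + maxent -> project all scenarios -> risk
# and richness), with per-species isolation, structured logging and a
# checksummed artifact manifest; plus a demo that builds a full synthetic
# world and runs everything.

#' Read and write GCM delta manifests
#'
#' A set of anomaly fields on disk is described by a manifest CSV with
#' columns `gcm_id`, `ssp`, `period`, `variable`, `path` (relative to the
#' manifest), `mode` (`add` for temperature, `ratio` for precipitation).
#'
#' @param deltas List of [delta_field()]s (for writing).
#' @param dir Directory for the anomaly GeoTIFFs.
#' @param manifest Manifest CSV path.
#' @return `write_delta_manifest`: the manifest path, invisibly;
#'   `read_delta_manifest`: a list of [delta_field()]s.
#' @export
write_delta_manifest <- function(deltas, dir,
                                 manifest = file.path(dir, "delta_manifest.csv")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (d in deltas) {
    tag <- gsub("[^A-Za-z0-9._-]+", "_", delta_label(d))
    for (v in CLIMATE_VARIABLES) {
      fn <- sprintf("delta_%s_%s.tif", tag, v)
      write_raster(d$grids[[v]], file.path(dir, fn))
      rows[[length(rows) + 1]] <- data.frame(
        gcm_id = d$gcm_id, ssp = d$ssp, period = d$period, variable = v,
        path = fn, mode = if (v %in% TEMP_VARIABLES) "add" else "ratio"
      )
    }
  }
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_delta_manifest
#' @export
read_delta_manifest <- function(manifest) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("gcm_id", "ssp", "period", "variable", "path")
  if (!all(need %in% names(tab))) {
    stop_pn("delta manifest needs columns %s", paste(need, collapse = ", "))
  }
  base <- dirname(manifest)
  keys <- unique(tab[, c("gcm_id", "ssp", "period")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- tab$gcm_id == keys$gcm_id[i] & tab$ssp == keys$ssp[i] &
      tab$period == keys$period[i]
    grids <- Map(function(p, v) read_raster(file.path(base, p), variable = v),
                 tab$path[sel], tab$variable[sel])
    delta_field(keys$gcm_id[i], keys$ssp[i], keys$period[i], unname(grids))
  })
}

#' Read and write host volume manifests
#'
#' Manifest CSV columns: `host_species`, `path` (GeoTIFF of m3 per cell,
#' relative to the manifest).
#'
#' @param host_grids Named list of host volume [climate_grid()]s.
#' @param dir Directory for the volume GeoTIFFs.
#' @param manifest Manifest CSV path.
#' @return `write_host_manifest`: the manifest path, invisibly;
#'   `read_host_manifest`: a named list of grids.
#' @export
write_host_manifest <- function(host_grids, dir,
                                manifest = file.path(dir, "host_manifest.csv")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(host_grids), function(h) {
    fn <- sprintf("host_%s.tif", gsub("[^A-Za-z0-9._-]+", "_", h))
    write_raster(host_grids[[h]], file.path(dir, fn))
    data.frame(host_species = h, path = fn)
  })
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_host_manifest
#' @export
read_host_manifest <- function(manifest) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("host_species", "path") %in% names(tab))) {
    stop_pn("host manifest needs columns host_species, path")
  }
  base <- dirname(manifest)
  grids <- lapply(seq_len(nrow(tab)), function(i) {
    read_raster(file.path(base, tab$path[i]), variable = tab$host_species[i])
  })
  names(grids) <- tab$host_species
  grids
}

#' Pipeline run configuration
#'
#' Bundles the input paths, thresholds and switches of a full run. All
#' referenced paths are checked at construction, before any work starts.
#' Defaults mirror the package's standard settings: 10-km thinning, a
#' 30-record modelling gate, 10,000 background points, and a regularization
#' multiplier of 1.
#'
#' @param occurrences Occurrence CSV (may hold several species).
#' @param landmask Land mask GeoTIFF.
#' @param baseline_manifest Baseline stack manifest CSV ([write_stack()]).
#' @param out_dir Output directory (created if missing).
#' @param delta_manifest Optional GCM delta manifest CSV.
#' @param host_manifest Optional host volume manifest CSV.
#' @param pest_hosts Optional pest-to-host CSV.
#' @param cell_km,min_records,background_m,reg_multiplier Thresholds.
#' @param models Model set to fit: subset of `c("envelope", "maxent")`.
#' @param risk_rule Mask used for risk accounting: `"envelope"` (class not
#'   unsuitable; default) or `"maxent"` (logistic at least the 10th
#'   percentile of presence predictions).
#' @param seed Integer seed driving every random stage.
#' @param maxent_tol,maxent_max_iter Solver settings for the per-species
#'   fits.
#' @return A `run_config` list.
#' @export
run_config <- function(occurrences, landmask, baseline_manifest, out_dir,
                       delta_manifest = NULL, host_manifest = NULL,
                       pest_hosts = NULL,
                       cell_km = 10, min_records = 30, background_m = 10000,
                       reg_multiplier = 1,
                       models = c("envelope", "maxent"),
                       risk_rule = c("envelope", "maxent"),
                       seed = 1, maxent_tol = 1e-4, maxent_max_iter = 1000) {
  risk_rule <- match.arg(risk_rule)
  models <- match.arg(models, several.ok = TRUE)
  paths <- c(occurrences = occurrences, landmask = landmask,
             baseline_manifest = baseline_manifest,
             delta_manifest = delta_manifest, host_manifest = host_manifest,
             pest_hosts = pest_hosts)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_pn("run_config: missing input file(s): %s",
            paste(sprintf("%s (%s)", names(missing), missing), collapse = "; "))
  }
  if (risk_rule == "maxent" && !("maxent" %in% models)) {
    stop_pn("risk_rule 'maxent' requires the maxent model to be fitted")
  }
  structure(
    list(
      occurrences = occurrences, landmask = landmask,
      baseline_manifest = baseline_manifest, out_dir = out_dir,
      delta_manifest = delta_manifest, host_manifest = host_manifest,
      pest_hosts = pest_hosts,
      cell_km = cell_km, min_records = min_records,
      background_m = background_m, reg_multiplier = reg_multiplier,
      models = models, risk_rule = risk_rule, seed = as.integer(seed),
      maxent_tol = maxent_tol, maxent_max_iter = maxent_max_iter
    ),
    class = "run_config"
  )
}

pipeline_log <- function(log_path, stage, species, detail) {
  line <- sprintf("stage=%s species=%s %s", stage, species, detail)
  cat(line, "\n", file = log_path, append = TRUE)
  message(line)
}

#' Run the full pipeline for every species in an occurrence file
#'
#' For each species: occurrence screen (with a JSON audit report), climate
#' extraction, envelope and/or maximum-entropy fits, projection onto the
#' baseline and every scenario in the delta manifest, and (when host data
#' are supplied) volume-at-risk summaries. Envelope suitability masks of
#' all modelled species are stacked into per-scenario richness maps and a
#' richness-change map against the baseline. Species failing the
#' minimum-record gate are reported as skipped; a failure in one species is
#' logged and does not stop the others. Every artifact is listed, with an
#' MD5 checksum, in `manifest.json` (the run log, which contains timings,
#' is excluded from checksumming).
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return A `run_result` list: per-species status, the artifact manifest,
#'   and the aggregated risk table.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  logf <- if (quiet) {
    function(...) cat(sprintf("stage=%s species=%s %s\n", ...),
                      file = log_path, append = TRUE)
  } else {
    function(...) pipeline_log(log_path, ...)
  }

  occ <- read_occurrences(config$occurrences)
  landmask <- read_raster(config$landmask, variable = "LAND")
  baseline <- read_stack(config$baseline_manifest)
  deltas <- if (!is.null(config$delta_manifest)) {
    read_delta_manifest(config$delta_manifest)
  } else {
    list()
  }
  scenarios <- c(
    stats::setNames(list(baseline), baseline$label),
    scenario_matrix(baseline, deltas)
  )
  host_grids <- if (!is.null(config$host_manifest)) {
    read_host_manifest(config$host_manifest)
  } else {
    NULL
  }
  pest_hosts <- if (!is.null(config$pest_hosts)) {
    read_pest_hosts(config$pest_hosts)
  } else {
    NULL
  }
  background <- draw_background(landmask, baseline, m = config$background_m,
                                seed = config$seed)

  species_list <- sort(unique(occ$species))
  status <- stats::setNames(rep("ok", length(species_list)), species_list)
  risk_rows <- list()
  env_masks <- list() # per scenario, per species: binary envelope masks

  safe_name <- function(s) gsub("[^A-Za-z0-9._-]+", "_", s)

  for (sp in species_list) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      sp_dir <- file.path(out_dir, safe_name(sp))
      dir.create(sp_dir, showWarnings = FALSE, recursive = TRUE)
      filt <- filter_occurrences(occ[occ$species == sp, , drop = FALSE],
                                 landmask, cell_km = config$cell_km,
                                 min_records = config$min_records)
      write_filter_report(filt$report, file.path(sp_dir, "filter_report.json"))
      write_occurrences(filt$records, file.path(sp_dir, "occurrences_filtered.csv"))
      logf("filter", sp, sprintf(
        "input=%d survivors=%d modelled=%s",
        filt$report$input, filt$report$after_thinning, filt$report$modelled
      ))
      if (!filt$report$modelled) {
        status[sp] <- "skipped"
      } else {
        clim <- extract_climate(baseline, filt$records$lon, filt$records$lat)
        keep <- stats::complete.cases(clim)
        clim <- clim[keep, , drop = FALSE]
        logf("extract", sp, sprintf("points=%d", nrow(clim)))

        env <- NULL
        if ("envelope" %in% config$models) {
          env <- fit_envelope(clim)
          write_envelope(env, file.path(sp_dir, "envelope.json"))
        }
        mx <- NULL
        if ("maxent" %in% config$models) {
          mx <- withCallingHandlers(
            fit_maxent(clim, background,
                       reg_multiplier = config$reg_multiplier,
                       tol = config$maxent_tol,
                       max_iter = config$maxent_max_iter),
            warning = function(w) {
              logf("maxent", sp, sprintf("warning=%s", conditionMessage(w)))
              invokeRestart("muffleWarning")
            }
          )
          write_maxent(mx, file.path(sp_dir, "maxent.json"))
          logf("maxent", sp, sprintf(
            "auc=%.4f active=%d", evaluate_auc(mx, clim, background),
            sum(mx$weights != 0)
          ))
        }
        mx_threshold <- if (!is.null(mx)) {
          stats::quantile(predict(mx, clim, type = "logistic"), 0.10,
                          names = FALSE, type = 7)
        } else {
          NA_real_
        }

        for (sc in names(scenarios)) {
          st <- scenarios[[sc]]
          sc_tag <- safe_name(sc)
          suit_mask <- NULL
          if (!is.null(env)) {
            em <- map_envelope(env, st)
            write_raster(em$class, file.path(
              sp_dir, sprintf("envelope_class_%s.tif", sc_tag)
            ))
            write_raster(em$score, file.path(
              sp_dir, sprintf("envelope_score_%s.tif", sc_tag)
            ))
            mask_vals <- em$class$values
            mask_vals[!is.na(mask_vals)] <-
              as.numeric(mask_vals[!is.na(mask_vals)] > 0)
            suit_env <- climate_grid(mask_vals, em$class$geometry, sp,
                                     units = "mask")
            env_masks[[sc]][[sp]] <- suit_env
            if (config$risk_rule == "envelope") suit_mask <- suit_env
          }
          if (!is.null(mx)) {
            mm <- map_maxent(mx, st, type = "logistic")
            write_raster(mm, file.path(
              sp_dir, sprintf("maxent_logistic_%s.tif", sc_tag)
            ))
            if (config$risk_rule == "maxent") {
              mv <- mm$values
              mv[!is.na(mv)] <- as.numeric(mv[!is.na(mv)] >= mx_threshold)
              suit_mask <- climate_grid(mv, mm$geometry, sp, units = "mask")
            }
          }
          if (!is.null(suit_mask) && !is.null(host_grids) &&
              !is.null(pest_hosts) && sp %in% pest_hosts$pest_species) {
            hosts <- hosts_for_pest(pest_hosts, sp, host_grids)
            rs <- volume_at_risk(suit_mask, hosts, pest_species = sp,
                                 scenario = sc, rule = config$risk_rule)
            write_risk_summary(rs, file.path(
              sp_dir, sprintf("risk_%s.json", sc_tag)
            ))
            risk_rows[[length(risk_rows) + 1]] <- as.data.frame(rs)
            logf("risk", sp, sprintf(
              "scenario=%s volume_m3=%.6g area_km2=%.6g",
              sc, rs$volume_at_risk, rs$area_km2
            ))
          }
        }
      }
      TRUE
    }, error = function(e) {
      status[sp] <<- paste0("failed: ", conditionMessage(e))
      logf("error", sp, sprintf("message=%s", conditionMessage(e)))
      FALSE
    })
    logf("done", sp, sprintf(
      "status=%s elapsed_s=%.1f", status[sp], proc.time()[["elapsed"]] - t0
    ))
  }

  risk_table <- if (length(risk_rows)) do.call(rbind, risk_rows) else NULL
  if (!is.null(risk_table)) {
    utils::write.csv(risk_table, file.path(out_dir, "risk_summaries.csv"),
                     row.names = FALSE)
  }

  richness <- list()
  change_summary <- NULL
  if (length(env_masks) && length(env_masks[[1]])) {
    for (sc in names(env_masks)) {
      rg <- stack_richness(unname(env_masks[[sc]]),
                           labels = names(env_masks[[sc]]), scenario = sc)
      write_raster(rg, file.path(
        out_dir, sprintf("richness_%s.tif", safe_name(sc))
      ))
      richness[[sc]] <- rg
    }
    base_sc <- baseline$label
    futures <- setdiff(names(richness), base_sc)
    if (length(futures)) {
      rows <- lapply(futures, function(sc) {
        ch <- richness_change(richness[[base_sc]], richness[[sc]])
        write_raster(ch, file.path(
          out_dir, sprintf("richness_change_%s.tif", safe_name(sc))
        ))
        gain <- area_with_change(ch, k = 1)
        data.frame(scenario = sc, gain_ge1_cells = gain$cells,
                   gain_ge1_km2 = gain$km2)
      })
      change_summary <- do.call(rbind, rows)
      utils::write.csv(change_summary,
                       file.path(out_dir, "richness_change_summary.csv"),
                       row.names = FALSE)
    }
  }

  files <- setdiff(
    list.files(out_dir, recursive = TRUE),
    c("run.log", "manifest.json")
  )
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- data.frame(path = files, md5 = unname(sums),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$path), , drop = FALSE]
  write_json_file(
    list(seed = config$seed, species = as.list(status),
         files = manifest),
    file.path(out_dir, "manifest.json")
  )

  structure(
    list(status = status, manifest = manifest, risk_table = risk_table,
         richness = richness, change_summary = change_summary,
         out_dir = out_dir),
    class = "run_result"
  )
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %d species (%d ok, %d skipped, %d failed); %d artifacts in %s\n",
              length(x$status), sum(x$status == "ok"),
              sum(x$status == "skipped"),
              sum(startsWith(x$status, "failed")),
              nrow(x$manifest), x$out_dir))
  invisible(x)
}

#' Exit code of a pipeline run
#'
#' 0 if every species succeeded, 2 if some were skipped (below the record
#' gate) but none failed, 1 if any species failed.
#'
#' @param result A [run_pipeline()] result.
#' @return Integer exit code.
#' @export
run_exit_code <- function(result) {
  if (any(startsWith(result$status, "failed"))) return(1L)
  if (any(result$status == "skipped")) return(2L)
  0L
}

#' End-to-end demonstration on a synthetic world
#'
#' Builds a complete synthetic study system — a 100 x 100 climate world
#' with land mask, a cold-limited and a warm-limited species (200 records
#' each, plus records violating every metadata filter), host volume
#' surfaces, two GCM anomaly fields and their composite for SSP2-4.5
#' 2041-2070 — writes every input to disk, and runs [run_pipeline()] over
#' it. Prints a summary of host volume at risk under current versus future
#' climate and the projected richness change.
#'
#' @param seed Integer seed; the entire run is reproducible from it.
#' @param out_dir Output directory (default: under `tempdir()`).
#' @param n_rows,n_cols World size.
#' @param n_records Clean occurrence records per species.
#' @param background_m Background sample size.
#' @param quiet Suppress progress messages.
#' @return The [run_pipeline()] result, invisibly.
#' @export
demo_run <- function(seed = 7, out_dir = file.path(tempdir(), "pestniche_demo"),
                     n_rows = 100, n_cols = 100, n_records = 200,
                     background_m = 10000, quiet = FALSE) {
  in_dir <- file.path(out_dir, "inputs")
  run_dir <- file.path(out_dir, "run")
  dir.create(in_dir, showWarnings = FALSE, recursive = TRUE)

  cfg <- synthetic_world_config(n_rows = n_rows, n_cols = n_cols, seed = seed)
  world <- make_climate_stack(cfg)
  write_raster(world$landmask, file.path(in_dir, "landmask.tif"))
  stack_manifest <- write_stack(world$stack, in_dir)

  land_climate <- stack_cell_table(world$stack)
  q <- function(v, p) stats::quantile(land_climate[[v]], p, names = FALSE)
  wide <- vapply(CLIMATE_VARIABLES, function(v) {
    3 * stats::sd(land_climate[[v]]) + 1e-6
  }, numeric(1))
  centre_mid <- vapply(CLIMATE_VARIABLES, function(v) q(v, 0.5), numeric(1))
  cold_niche <- true_niche(
    centre = replace(centre_mid, "MAT", q("MAT", 0.2)),
    spread = replace(wide, "MAT", 2.5),
    max_occurrence_rate = 0.9
  )
  warm_niche <- true_niche(
    centre = replace(centre_mid, "MAT", q("MAT", 0.8)),
    spread = replace(wide, "MAT", 2.5),
    max_occurrence_rate = 0.9
  )
  species <- c(cold = "Synthetica frigida", warm = "Synthetica calida")
  occ <- rbind(
    sample_species(world$stack, cold_niche, n_records,
                   seed = derive_seed(seed, "cold"), species = species[["cold"]]),
    sample_species(world$stack, warm_niche, n_records,
                   seed = derive_seed(seed, "warm"), species = species[["warm"]])
  )
  occ <- inject_dirty_records(occ, n_missing_coords = 10, n_geo_issue = 8,
                              n_pre1951 = 6, n_fossil = 4,
                              seed = derive_seed(seed, "dirty"))
  occ_path <- file.path(in_dir, "occurrences.csv")
  write_occurrences(occ, occ_path)

  # host trees occupy broader climate ranges than their pests and extend
  # poleward of the pests' current envelopes, so warming can open new host
  # area (the northward-shift pattern)
  picea_niche <- true_niche(
    centre = replace(centre_mid, "MAT", q("MAT", 0.35)),
    spread = replace(wide, "MAT", 6)
  )
  pinus_niche <- true_niche(
    centre = replace(centre_mid, "MAT", q("MAT", 0.65)),
    spread = replace(wide, "MAT", 6)
  )
  hosts <- list(
    "Picea synthetica" = make_host_volume(
      world$stack, picea_niche, total_volume = 150e6,
      seed = derive_seed(seed, "host1"), host_species = "Picea synthetica"
    ),
    "Pinus synthetica" = make_host_volume(
      world$stack, pinus_niche, total_volume = 120e6,
      seed = derive_seed(seed, "host2"), host_species = "Pinus synthetica"
    )
  )
  host_manifest <- write_host_manifest(hosts, in_dir)
  ph_path <- file.path(in_dir, "pest_hosts.csv")
  utils::write.csv(
    data.frame(
      pest_species = unname(species),
      host_species = c("Picea synthetica", "Pinus synthetica")
    ),
    ph_path, row.names = FALSE
  )

  deltas <- list(
    make_gcm_delta(world$stack, "GCM-A", warming = 3.0, precip_ratio = 1.05,
                   seed = seed),
    make_gcm_delta(world$stack, "GCM-B", warming = 2.5, precip_ratio = 0.95,
                   seed = seed)
  )
  deltas <- c(deltas, list(composite_delta(deltas)))
  delta_manifest <- write_delta_manifest(deltas, in_dir)

  config <- run_config(
    occurrences = occ_path, landmask = file.path(in_dir, "landmask.tif"),
    baseline_manifest = stack_manifest, out_dir = run_dir,
    delta_manifest = delta_manifest, host_manifest = host_manifest,
    pest_hosts = ph_path, background_m = background_m, seed = seed
  )
  result <- run_pipeline(config, quiet = quiet)

  if (!quiet && !is.null(result$risk_table)) {
    cat("\nHost volume at risk (m3) by species and scenario:\n")
    wide_tab <- stats::reshape(
      result$risk_table[, c("pest_species", "scenario", "volume_at_risk")],
      idvar = "pest_species", timevar = "scenario", direction = "wide"
    )
    names(wide_tab) <- sub("^volume_at_risk\\.", "", names(wide_tab))
    print(wide_tab, row.names = FALSE)
    if (!is.null(result$change_summary)) {
      cat("\nArea with projected envelope-richness gain >= 1 species:\n")
      print(result$change_summary, row.names = FALSE)
    }
  }
  invisible(result)
}
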