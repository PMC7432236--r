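#' Run the full exposure-mapping pipeline on a synthetic scene
#'
#' Orchestrates scene generation, band combination, variogram fitting,
#' grid kriging, diurnal profiling, per-cell temporalization, population
#' allocation, person-hours, calibrated indoor and uplink distributions,
#' Monte-Carlo aggregation and map writing, all under one run-level seed.
#' A fixed seed makes every output file byte-identical across runs.
#'
#' @param config a [scene_config()] (its `seed` is overridden by `seed`).
#' @param seed run-level integer seed.
#' @param out_dir output directory; `NULL` skips writing.
#' @param n_points drive-test locations.
#' @param n_nodes,n_days monitoring-network shape.
#' @param n_cell samples per cell distribution (temporal and aggregated).
#' @param n_building samples per building indoor distribution.
#' @param tf transfer functions, see [sar_transfer_functions()].
#' @param budgets time budgets, see [time_budget()].
#' @param usage uplink usage, see [uplink_usage()].
#' @param fit_cell_distributions fit gamma/normal families per cell
#'   (slower; default `FALSE`).
#' @return list with every intermediate product: `scene`, `variogram`,
#'   `estimates`, `profiles`, `cell_fields`, `buildings`, `ph`, `indoor`,
#'   `uplink`, `cells`, `contributions`, `out_dir`.
#' @export
run_all <- function(config = scene_config(), seed = 1L, out_dir = NULL,
                    n_points = 400, n_nodes = 10, n_days = 7,
                    n_cell = 20000, n_building = 2000,
                    tf = sar_transfer_functions(),
                    budgets = time_budget(),
                    usage = uplink_usage(),
                    fit_cell_distributions = FALSE) {
  config$seed <- as.integer(seed)
  scene <- simulate_scene(config, n_points = n_points, n_nodes = n_nodes,
                          n_days = n_days)
  grid <- scene$district$grid

  # outdoor surface: RSS-combined bands, log-domain local kriging
  meas <- combine_bands(scene$measurements)
  vg <- fit_variogram(meas)
  estimates <- krige_grid(meas, grid, vg)

  # diurnal profiles per monitoring band
  bands <- config$diurnal_params$bands
  profiles <- stats::setNames(
    lapply(bands, function(b) build_profile(scene$sensors, b)), bands)

  # per-cell time-varying field distributions
  cell_fields <- stats::setNames(vector("list", nrow(grid)), grid$cell_id)
  for (i in seq_len(nrow(grid))) {
    cell_fields[[i]] <- temporalize_cell(
      estimates[i, ], profiles, n = n_cell,
      seed = stage_seed(seed, "temporal") + i,
      fit = fit_cell_distributions)
  }

  # population geoprocessing
  buildings <- allocate_population(scene$district$buildings,
                                  scene$district$zones,
                                  scene$district$occupational_total)
  ph <- person_hours(buildings, grid, budgets)

  # building cell assignment and outdoor field at each building
  bld_cell <- vapply(seq_len(nrow(buildings)), function(i) {
    c0 <- rect_centroid(rect_from_row(buildings, i))
    hit <- grid$cell_id[c0[["x"]] >= grid$xmin & c0[["x"]] < grid$xmax &
                          c0[["y"]] >= grid$ymin & c0[["y"]] < grid$ymax]
    if (length(hit) == 0) NA_character_ else hit[1]
  }, character(1))
  outdoor_by_building <- stats::setNames(lapply(seq_len(nrow(buildings)), function(i) {
    if (is.na(bld_cell[i])) return(0)
    cell_fields[[bld_cell[i]]]$samples
  }), buildings$building_id)

  indoor <- indoor_profiles(buildings, outdoor_by_building, tf = tf,
                            n = n_building, seed = seed)
  uplink <- uplink_profiles(usage, n = n_cell, seed = seed)

  # assemble per-cell components weighted by person-hours
  tissues <- c("whole_body", "whole_brain")
  cells <- stats::setNames(vector("list", nrow(grid)), grid$cell_id)
  cell_ph <- stats::setNames(numeric(nrow(grid)), grid$cell_id)
  for (i in seq_len(nrow(grid))) {
    cid <- grid$cell_id[i]
    comp <- list()
    # outdoor components per age group
    out_ph <- ph[ph$microenv == "outdoor" & ph$cell_id %in% cid, , drop = FALSE]
    out_sar <- lapply(tissues, function(ts) {
      list(indoor = 0,
           outdoor = field_to_sar(cell_fields[[cid]]$samples, tf, ts, "adult"))
    })
    names(out_sar) <- tissues
    for (g in unique(out_ph$group)) {
      age <- if (g == "resident_child") "child" else "adult"
      comp[[length(comp) + 1]] <- list(
        ph = sum(out_ph$person_hours[out_ph$group == g]),
        age = age, pools = out_sar)
    }
    # building components (home, office) for buildings in this cell
    b_ph <- ph[ph$unit_type == "building" & ph$cell_id %in% cid, , drop = FALSE]
    for (r in seq_len(nrow(b_ph))) {
      bid <- b_ph$unit_id[r]
      age <- if (b_ph$group[r] == "resident_child") "child" else "adult"
      pools <- lapply(tissues, function(ts) {
        d <- indoor[[bid]][[ts]][[age]]
        list(indoor = d$indoor, outdoor = d$outdoor)
      })
      names(pools) <- tissues
      comp[[length(comp) + 1]] <- list(ph = b_ph$person_hours[r], age = age,
                                       pools = pools)
    }
    cells[[cid]] <- aggregate_cell(comp, uplink, n_total = n_cell,
                                   seed = stage_seed(seed, "aggregate") + i)
    cell_ph[cid] <- sum(out_ph$person_hours) + sum(b_ph$person_hours)
  }

  nonempty <- names(cells)[vapply(cells, function(cl) !isTRUE(cl$empty), logical(1))]
  contributions <- if (length(nonempty) > 0) {
    contribution_curves(cells[nonempty], cell_ph[nonempty])
  } else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_scene(scene, file.path(out_dir, "scene"))
    utils::write.csv(estimates, file.path(out_dir, "estimates.csv"),
                     row.names = FALSE)
    prof_tab <- do.call(rbind, lapply(profiles, function(p) {
      data.frame(band = p$band, hour = 0:23, eta = p$eta_hour,
                 n = p$n_samples_hour)
    }))
    utils::write.csv(prof_tab, file.path(out_dir, "profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(ph, file.path(out_dir, "person_hours.csv"),
                     row.names = FALSE)
    write_maps(cells, grid, file.path(out_dir, "maps"),
               contributions = contributions)
  }

  list(scene = scene, variogram = vg, estimates = estimates,
       profiles = profiles, cell_fields = cell_fields,
       buildings = buildings, ph = ph, indoor = indoor, uplink = uplink,
       cells = cells, cell_ph = cell_ph, contributions = contributions,
       out_dir = out_dir)
}
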