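# SAR conversion and Monte-Carlo fusion of outdoor, indoor and uplink
# exposure distributions into per-cell percentile maps.

#' Default SAR transfer-function tables
#'
#' Reference SAR values per tissue, age group and exposure mode: uplink
#' modes (`voice`, `data`) in mW/kg per watt emitted by the device,
#' `downlink` in mW/kg per W/m2 of incident plane-wave power density. The
#' uplink entries are solved at run time by the calibrated uplink mode; the
#' downlink entries are documented placeholders chosen so that ambient
#' downlink dose at typical urban field strengths sits about an order of
#' magnitude below the indoor-source dose, reproducing the observed source
#' ranking (indoor > outdoor > mobile). Absolute downlink dosimetry is
#' configuration, not a package constant.
#'
#' @param downlink_wb,downlink_wbr downlink entries, (mW/kg)/(W/m2).
#' @param voice,data uplink entries, (mW/kg)/W.
#' @return nested list `[[tissue]][[age]][[mode]]`, each entry
#'   `list(value, unit)`.
#' @export
sar_transfer_functions <- function(downlink_wb = 100, downlink_wbr = 80,
                                   voice = 1, data = 1) {
  entry <- function(v, unit) list(value = v, unit = unit)
  per_age <- function(dl) list(
    child = list(voice = entry(voice, "mW/kg per W"),
                 data = entry(data, "mW/kg per W"),
                 downlink = entry(dl, "mW/kg per W/m2")),
    adult = list(voice = entry(voice, "mW/kg per W"),
                 data = entry(data, "mW/kg per W"),
                 downlink = entry(dl, "mW/kg per W/m2"))
  )
  list(whole_body = per_age(downlink_wb),
       whole_brain = per_age(downlink_wbr))
}

tf_entry <- function(tf, tissue, age, mode) {
  e <- tf[[tissue]][[age]][[mode]]
  if (is.null(e)) {
    stop_rfemap(sprintf("missing transfer function %s/%s/%s",
                        tissue, age, mode), "configuration_error")
  }
  e
}

#' Convert electric-field strength to tissue SAR
#'
#' Uses the plane-wave power density `S = E^2 / Z0` with the free-space
#' impedance `Z0 = 377` ohm, then `SAR = tf * S` with the downlink transfer
#' function of the requested tissue and age group.
#'
#' @param E field strength(s), V/m, >= 0.
#' @param tf transfer functions from [sar_transfer_functions()].
#' @param tissue,age group selectors.
#' @return SAR value(s), mW/kg.
#' @export
field_to_sar <- function(E, tf = sar_transfer_functions(),
                         tissue = "whole_body", age = "adult") {
  if (any(E < 0)) stop_rfemap("field strength must be >= 0", "invalid_input")
  t <- tf_entry(tf, tissue, age, "downlink")$value
  t * E^2 / 377
}

# Percentile grid of the aggregated maps: vigintiles plus the 99th.
agg_probs <- function() {
  p <- c(seq(5, 100, by = 5), 99) / 100
  sort(p)
}

#' Aggregate exposure components of one grid cell
#'
#' Fuses the cell's exposure components (the time-varying outdoor
#' distribution, and home/office distributions of the intersecting
#' buildings) into one Monte-Carlo distribution per tissue. The total
#' sample budget (default 20,000) is apportioned across components
#' proportionally to their person-hours; every sample receives an
#' age-matched uplink draw on top (mobile-phone exposure is cumulative with
#' ambient exposure). Pooled samples are summarized into 20 percentiles
#' (P5...P100, with P99 added), mean and SD, and value-weighted per-source
#' shares (indoor / outdoor / mobile) per percentile bin.
#'
#' @param components list of components; each is a list with `ph`
#'   (person-hours weight), `age` (`"child"`/`"adult"`), and `pools`: a list
#'   by tissue of `list(indoor =, outdoor =)` sample vectors (mW/kg; either
#'   may be a scalar 0).
#' @param uplink uplink distributions from [uplink_profiles()]
#'   (`[[age]][[tissue]]`).
#' @param n_total total samples per tissue (default 20000).
#' @param seed integer seed.
#' @param tissues tissues to aggregate.
#' @return object of class `aggregated_cell`: per tissue `percentiles`
#'   (named, non-decreasing), `mean`, `sd`, `shares` (matrix percentile x
#'   source), and the pooled `samples` with per-sample source parts.
#' @export
aggregate_cell <- function(components, uplink, n_total = 20000, seed = 1L,
                           tissues = c("whole_body", "whole_brain")) {
  ph <- vapply(components, function(cp) cp$ph, numeric(1))
  if (length(components) == 0 || sum(ph) <= 0) {
    return(structure(list(empty = TRUE), class = "aggregated_cell"))
  }
  set.seed(as.integer(seed))
  counts <- largest_remainder(n_total, ph)
  out <- list(empty = FALSE)
  for (tissue in tissues) {
    ind <- outd <- mob <- numeric(0)
    for (k in seq_along(components)) {
      nk <- counts[k]
      if (nk == 0) next
      cp <- components[[k]]
      pool <- cp$pools[[tissue]]
      draw <- function(v) {
        if (length(v) == 1) rep(v, nk) else v[sample.int(length(v), nk, replace = TRUE)]
      }
      ind <- c(ind, draw(pool$indoor %||% 0))
      outd <- c(outd, draw(pool$outdoor %||% 0))
      up <- uplink[[cp$age]][[tissue]]
      mob <- c(mob, up[sample.int(length(up), nk, replace = TRUE)])
    }
    total <- ind + outd + mob
    probs <- agg_probs()
    q <- stats::quantile(total, probs = probs, type = 7, names = FALSE)
    names(q) <- sprintf("P%g", probs * 100)
    # value-weighted source shares per percentile bin
    shares <- matrix(NA_real_, length(probs), 3,
                     dimnames = list(names(q), c("indoor", "outdoor", "mobile")))
    bin <- findInterval(total, q, left.open = TRUE) + 1L  # 1..len(probs)+?
    bin[bin > length(probs)] <- length(probs)
    for (p in seq_along(probs)) {
      idx <- bin == p
      if (!any(idx)) next
      tt <- sum(total[idx])
      if (tt <= 0) next
      shares[p, ] <- c(sum(ind[idx]), sum(outd[idx]), sum(mob[idx])) / tt
    }
    out[[tissue]] <- list(
      percentiles = q, mean = mean(total), sd = stats::sd(total),
      shares = shares,
      samples = data.frame(total = total, indoor = ind, outdoor = outd,
                           mobile = mob)
    )
  }
  structure(out, class = "aggregated_cell")
}

#' District-wide contribution curves per percentile
#'
#' Pools the per-cell aggregated samples, weighting each cell by its total
#' person-hours, and computes the value-weighted share of each source class
#' (indoor / outdoor / mobile) within each percentile bin of the pooled
#' distribution.
#'
#' @param cells named list of [aggregate_cell()] results.
#' @param cell_ph named numeric of total person-hours per cell (same names);
#'   default equal weights.
#' @param tissues tissues to summarize.
#' @return data frame: `tissue`, `percentile`, `source`, `share`.
#' @export
contribution_curves <- function(cells, cell_ph = NULL,
                                tissues = c("whole_body", "whole_brain")) {
  keep <- vapply(cells, function(cl) !isTRUE(cl$empty), logical(1))
  cells <- cells[keep]
  if (length(cells) == 0) stop_rfemap("no aggregated cells", "invalid_input")
  if (is.null(cell_ph)) {
    cell_ph <- stats::setNames(rep(1, length(cells)), names(cells))
  }
  rows <- list()
  probs <- agg_probs()
  for (tissue in tissues) {
    tot <- unlist(lapply(cells, function(cl) cl[[tissue]]$samples$total))
    ind <- unlist(lapply(cells, function(cl) cl[[tissue]]$samples$indoor))
    outd <- unlist(lapply(cells, function(cl) cl[[tissue]]$samples$outdoor))
    mob <- unlist(lapply(cells, function(cl) cl[[tissue]]$samples$mobile))
    w <- unlist(lapply(names(cells), function(id) {
      n <- nrow(cells[[id]][[tissue]]$samples)
      rep(cell_ph[[id]] / n, n)
    }))
    q <- weighted_quantile(tot, w, probs)
    bin <- findInterval(tot, q, left.open = TRUE) + 1L
    bin[bin > length(probs)] <- length(probs)
    for (p in seq_along(probs)) {
      idx <- bin == p
      denom <- sum(w[idx] * tot[idx])
      sh <- if (denom > 0) {
        c(sum(w[idx] * ind[idx]), sum(w[idx] * outd[idx]),
          sum(w[idx] * mob[idx])) / denom
      } else c(NA_real_, NA_real_, NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        tissue = tissue, percentile = probs[p] * 100,
        source = c("indoor", "outdoor", "mobile"), share = sh,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write aggregated maps and tables
#'
#' Writes one CSV per tissue with the full per-cell percentile table, a
#' GeoJSON FeatureCollection of grid cells carrying P50 / mean / SD per
#' tissue (empty cells carry nulls), and a contributions CSV. All formats
#' are plain text.
#'
#' @param cells named list of [aggregate_cell()] results (names are cell
#'   ids).
#' @param grid analysis grid from [make_grid()].
#' @param dir output directory.
#' @param contributions optional [contribution_curves()] table.
#' @param tissues tissues to write.
#' @return `dir`, invisibly.
#' @export
write_maps <- function(cells, grid, dir, contributions = NULL,
                       tissues = c("whole_body", "whole_brain")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  probs <- agg_probs()
  pn <- sprintf("P%g", probs * 100)
  for (tissue in tissues) {
    rows <- lapply(grid$cell_id, function(id) {
      cl <- cells[[id]]
      base <- grid[grid$cell_id == id,
                   c("cell_id", "x_center", "y_center"), drop = FALSE]
      if (is.null(cl) || isTRUE(cl$empty)) {
        stats <- as.list(stats::setNames(rep(NA_real_, length(pn) + 2),
                                         c(pn, "mean", "sd")))
      } else {
        st <- cl[[tissue]]
        stats <- c(as.list(st$percentiles), list(mean = st$mean, sd = st$sd))
        names(stats) <- c(pn, "mean", "sd")
      }
      cbind(base, as.data.frame(stats, check.names = FALSE))
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(dir, sprintf("cells_%s.csv", tissue)),
                     row.names = FALSE, na = "")
  }
  gj <- grid[, c("xmin", "ymin", "xmax", "ymax", "cell_id")]
  for (tissue in tissues) {
    p50 <- mn <- sdv <- rep(NA_real_, nrow(grid))
    for (i in seq_len(nrow(grid))) {
      cl <- cells[[grid$cell_id[i]]]
      if (!is.null(cl) && !isTRUE(cl$empty)) {
        p50[i] <- cl[[tissue]]$percentiles[["P50"]]
        mn[i] <- cl[[tissue]]$mean
        sdv[i] <- cl[[tissue]]$sd
      }
    }
    gj[[paste0(tissue, "_P50")]] <- p50
    gj[[paste0(tissue, "_mean")]] <- mn
    gj[[paste0(tissue, "_sd")]] <- sdv
  }
  write_geojson_rects(gj, file.path(dir, "cells.geojson"))
  if (!is.null(contributions)) {
    utils::write.csv(contributions, file.path(dir, "contributions.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
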