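# Census population allocation to buildings by housing-surface ratio, and
# person-hours per microenvironment.

#' Classify buildings into a typology from their declared use
#'
#' Maps the cadastral declared-use attribute to a typology
#' (`residential` / `office` / `mixed`), derives the residential floor-area
#' share (`res_share`: 1 for residential, 0 for office, the declared share
#' for mixed), and computes `housing_area` and `office_area` as footprint
#' area x floor count x share. Unknown use codes default to residential
#' with a warning — the conservative choice for residential exposure.
#'
#' @param buildings data frame with `xmin`, `ymin`, `xmax`, `ymax`,
#'   `floors`, `use`, and `res_share` for mixed buildings.
#' @return the data frame with `typology`, `res_share`, `housing_area`,
#'   `office_area` columns filled.
#' @export
classify_buildings <- function(buildings) {
  use <- buildings$use
  typ <- ifelse(use == "dwelling", "residential",
         ifelse(use == "office", "office",
         ifelse(use == "mixed", "mixed", NA)))
  if (any(is.na(typ))) {
    warning(sprintf("%d building(s) with unknown use defaulted to residential",
                    sum(is.na(typ))))
    typ[is.na(typ)] <- "residential"
  }
  share <- ifelse(typ == "residential", 1,
           ifelse(typ == "office", 0, buildings$res_share))
  if (any(typ == "mixed" & (is.na(share) | share < 0 | share > 1))) {
    stop_rfemap("mixed buildings need res_share in [0, 1]", "invalid_config")
  }
  fa <- (buildings$xmax - buildings$xmin) *
    (buildings$ymax - buildings$ymin) * buildings$floors
  buildings$typology <- typ
  buildings$res_share <- share
  buildings$housing_area <- fa * share
  buildings$office_area <- fa * (1 - share)
  buildings
}

#' Allocate census populations to buildings by surface ratio
#'
#' The residential population of building *i* is
#' `P_i = sum_j (S_ij / S_j) * P_j` over the zones *j* it intersects, where
#' `S_ij` is the building's housing area inside zone *j* and `S_j` the
#' zone's total housing area — computed separately per age class. The
#' occupational population is allocated analogously over office areas from
#' the district-level aggregate. Intersection slivers below 0.5 m2 are
#' dropped; populated zones with zero housing area are reported as
#' unallocated.
#'
#' @param buildings classified buildings (see [classify_buildings()]).
#' @param zones zone data frame with `zone_id`, rectangle bounds,
#'   `housing_area`, `pop_child`, `pop_adult`.
#' @param occupational_total district-level occupational population.
#' @return buildings with `P_child`, `P_adult`, `P_occ` columns; attribute
#'   `unallocated` lists zones whose population could not be assigned.
#' @export
allocate_population <- function(buildings, zones, occupational_total = 0) {
  nb <- nrow(buildings)
  P_child <- P_adult <- rep(0, nb)
  unallocated <- character(0)
  for (j in seq_len(nrow(zones))) {
    zj <- rect_from_row(zones, j)
    S_j <- zones$housing_area[j]
    if (S_j <= 0) {
      if (zones$pop_child[j] + zones$pop_adult[j] > 0) {
        warning(sprintf("zone %s populated but has no housing area; %d person(s) unallocated",
                        zones$zone_id[j], zones$pop_child[j] + zones$pop_adult[j]))
        unallocated <- c(unallocated, zones$zone_id[j])
      }
      next
    }
    for (i in seq_len(nb)) {
      if (buildings$housing_area[i] <= 0) next
      bi <- rect_from_row(buildings, i)
      a <- rect_intersection_area(bi, zj)
      if (a < 0.5) next  # sliver cutoff, m2
      S_ij <- buildings$housing_area[i] * a / rect_area(bi)
      P_child[i] <- P_child[i] + S_ij / S_j * zones$pop_child[j]
      P_adult[i] <- P_adult[i] + S_ij / S_j * zones$pop_adult[j]
    }
  }
  office_tot <- sum(buildings$office_area)
  P_occ <- if (office_tot > 0) {
    occupational_total * buildings$office_area / office_tot
  } else rep(0, nb)
  buildings$P_child <- P_child
  buildings$P_adult <- P_adult
  buildings$P_occ <- P_occ
  attr(buildings, "unallocated") <- unallocated
  buildings
}

#' Default daily time budgets per population group
#'
#' Hours per day spent in each microenvironment, summing to 24 per group.
#' Residential groups spend about 90% of the day at home; the occupational
#' group adds office time. The occupational group's home hours are assumed
#' to fall outside the study area (residences are represented by the
#' residential groups) and are not localized by [person_hours()].
#'
#' @return named list of `c(home, office, outdoor)` hour vectors.
#' @export
time_budget <- function() {
  list(
    resident_child = c(home = 21.5, office = 0, outdoor = 2.5),
    resident_adult = c(home = 21.5, office = 0, outdoor = 2.5),
    worker = c(home = 16, office = 6, outdoor = 2)
  )
}

#' Person-hours per building and grid cell
#'
#' Person-hours are population counts times the hours spent in the
#' microenvironment. Home and office person-hours are attached to
#' buildings; outdoor person-hours accumulate in the grid cell containing
#' each building's centroid (residents and workers both contribute their
#' outdoor hours there). The worker group's home hours are not localized
#' (see [time_budget()]).
#'
#' @param buildings allocated buildings (see [allocate_population()]).
#' @param grid analysis grid from [make_grid()].
#' @param budgets time budgets, see [time_budget()]; each group must sum to
#'   24 h.
#' @return data frame: `unit_type` (`building` / `cell`), `unit_id`,
#'   `cell_id` (containing cell), `group`, `microenv`, `person_hours`.
#' @export
person_hours <- function(buildings, grid, budgets = time_budget()) {
  for (g in names(budgets)) {
    if (abs(sum(budgets[[g]]) - 24) > 1e-9) {
      stop_rfemap(sprintf("time budget of group %s does not sum to 24 h", g),
                  "invalid_config")
    }
  }
  cell_of <- function(x, y) {
    hit <- grid$cell_id[x >= grid$xmin & x < grid$xmax &
                          y >= grid$ymin & y < grid$ymax]
    if (length(hit) == 0) NA_character_ else hit[1]
  }
  rows <- list()
  add <- function(unit_type, unit_id, cell_id, group, microenv, ph) {
    if (ph <= 0) return()
    rows[[length(rows) + 1]] <<- data.frame(
      unit_type = unit_type, unit_id = unit_id, cell_id = cell_id,
      group = group, microenv = microenv, person_hours = ph,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(buildings))) {
    c0 <- rect_centroid(rect_from_row(buildings, i))
    cid <- cell_of(c0[["x"]], c0[["y"]])
    bid <- buildings$building_id[i]
    add("building", bid, cid, "resident_child", "home",
        buildings$P_child[i] * budgets$resident_child[["home"]])
    add("building", bid, cid, "resident_adult", "home",
        buildings$P_adult[i] * budgets$resident_adult[["home"]])
    add("building", bid, cid, "worker", "office",
        buildings$P_occ[i] * budgets$worker[["office"]])
    add("cell", cid, cid, "resident_child", "outdoor",
        buildings$P_child[i] * budgets$resident_child[["outdoor"]])
    add("cell", cid, cid, "resident_adult", "outdoor",
        buildings$P_adult[i] * budgets$resident_adult[["outdoor"]])
    add("cell", cid, cid, "worker", "outdoor",
        buildings$P_occ[i] * budgets$worker[["outdoor"]])
  }
  if (length(rows) == 0) {
    return(data.frame(unit_type = character(0), unit_id = character(0),
                      cell_id = character(0), group = character(0),
                      microenv = character(0), person_hours = numeric(0)))
  }
  out <- do.call(rbind, rows)
  # collapse outdoor rows per (cell, group)
  agg <- stats::aggregate(
    person_hours ~ unit_type + unit_id + cell_id + group + microenv,
    data = out, FUN = sum)
  agg[order(agg$unit_type, agg$unit_id, agg$group, agg$microenv), ,
      drop = FALSE]
}
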