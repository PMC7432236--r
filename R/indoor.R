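# Indoor exposure: building penetration of the outdoor field, calibrated
# indoor source distributions, and per-building exposure profiles.

#' Building penetration loss parameters
#'
#' @param loss_db penetration loss in dB (>= 0). The default 9.5 dB is the
#'   literature mean for the 900 MHz-equivalent band.
#' @return object of class `penetration_params`.
#' @export
penetration_params <- function(loss_db = 9.5) {
  if (loss_db < 0) stop_rfemap("penetration loss must be >= 0 dB", "invalid_config")
  structure(list(loss_db = loss_db), class = "penetration_params")
}

#' Attenuate an outdoor field by building penetration loss
#'
#' `V_I = V_O * 10^(-dB / 20)`.
#'
#' @param V_O outdoor field strength(s), V/m, >= 0.
#' @param params a [penetration_params()].
#' @return indoor field strength(s), V/m.
#' @export
penetrate <- function(V_O, params = penetration_params()) {
  if (any(V_O < 0)) stop_rfemap("field strength must be >= 0", "invalid_input")
  V_O * 10^(-params$loss_db / 20)
}

#' Calibration table for indoor source exposure profiles
#'
#' Mean and standard deviation of the indoor exposure profiles (SAR, mW/kg)
#' used by the calibrated (surrogate-free) indoor mode: combined WLAN access
#' point + femtocell exposure (child-derived, applied to adults as a
#' conservative choice) and Wi-Fi-use exposure per age group and tissue.
#'
#' @return data frame: `source`, `tissue`, `age`, `mean`, `sd`.
#' @export
indoor_calibration <- function() {
  data.frame(
    source = c("wlan_femtocell", "wlan_femtocell",
               "wifi", "wifi", "wifi", "wifi"),
    tissue = c("whole_body", "whole_brain",
               "whole_body", "whole_body", "whole_brain", "whole_brain"),
    age = c("all", "all", "adult", "child", "adult", "child"),
    mean = c(2.4e-1, 6.7e-2, 3.6e-5, 4.3e-5, 4.9e-5, 5.0e-5),
    sd = c(1.7e-1, 4.9e-2, 4.2e-5, 5.1e-5, 5.7e-5, 5.9e-5),
    stringsAsFactors = FALSE
  )
}

# Lognormal parameters matching a target mean and standard deviation.
lnorm_moment_match <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

indoor_source_params <- function(source, tissue, age) {
  tab <- indoor_calibration()
  row <- tab[tab$source == source & tab$tissue == tissue &
               (tab$age == age | tab$age == "all"), , drop = FALSE]
  if (nrow(row) == 0) {
    stop_rfemap(sprintf("no indoor calibration for %s/%s/%s",
                        source, tissue, age), "configuration_error")
  }
  lnorm_moment_match(row$mean[1], row$sd[1])
}

#' Per-building indoor exposure distributions
#'
#' Draws `n` Monte-Carlo SAR samples per building, tissue and age group,
#' combining (a) WLAN + femtocell exposure — either lognormals
#' moment-matched to the calibration table (default) or the trained low-rank
#' surrogate evaluated at random source/occupant positions — (b) Wi-Fi-use
#' exposure from the calibrated distribution, and (c) the outdoor field
#' after building penetration loss, converted to SAR. Per-sample totals are
#' stored together with their source-class parts (`indoor` = in-building
#' sources, `outdoor` = penetrated ambient field), so contribution
#' accounting stays exact.
#'
#' @param buildings data frame with at least `building_id`.
#' @param outdoor_field named list (by `building_id`) of outdoor field
#'   sample vectors (V/m) at each building, or a single numeric vector /
#'   scalar recycled for all buildings.
#' @param tf transfer functions from [sar_transfer_functions()].
#' @param mode `"calibrated"` or `"surrogate"`.
#' @param surrogate an [lra_fit()] model (surrogate mode); predictions are
#'   taken as whole-body SAR, whole-brain values are scaled by the
#'   calibration-table tissue ratio.
#' @param room a [room_spec()] providing the surrogate input domain.
#' @param penetration a [penetration_params()].
#' @param n samples per building/tissue/age.
#' @param seed integer seed.
#' @param tissues,ages groups to generate.
#' @return nested list `[[building_id]][[tissue]][[age]]`, each a list with
#'   `total`, `indoor`, `outdoor` sample vectors (mW/kg).
#' @export
indoor_profiles <- function(buildings, outdoor_field, tf = sar_transfer_functions(),
                            mode = c("calibrated", "surrogate"),
                            surrogate = NULL, room = room_spec(),
                            penetration = penetration_params(),
                            n = 2000, seed = 1L,
                            tissues = c("whole_body", "whole_brain"),
                            ages = c("child", "adult")) {
  mode <- match.arg(mode)
  if (mode == "surrogate" && is.null(surrogate)) {
    stop_rfemap("surrogate mode needs a trained lra model", "configuration_error")
  }
  set.seed(stage_seed(seed, "indoor"))
  ids <- as.character(buildings$building_id)
  if (!is.list(outdoor_field)) {
    outdoor_field <- stats::setNames(rep(list(outdoor_field), length(ids)), ids)
  }
  tab <- indoor_calibration()
  wb_mean <- tab$mean[tab$source == "wlan_femtocell" & tab$tissue == "whole_body"]
  wbr_mean <- tab$mean[tab$source == "wlan_femtocell" & tab$tissue == "whole_brain"]

  out <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    V_I <- penetrate(outdoor_field[[id]], penetration)
    per_tissue <- list()
    for (tissue in tissues) {
      per_age <- list()
      if (mode == "calibrated") {
        p <- indoor_source_params("wlan_femtocell", tissue, "all")
        wlan <- stats::rlnorm(n, p$meanlog, p$sdlog)
      } else {
        b <- room$bounds
        Xs <- sapply(seq_len(nrow(b)), function(i) stats::runif(n, b[i, 1], b[i, 2]))
        wb <- pmax(0, as.numeric(lra_predict(surrogate, Xs)))
        wlan <- if (tissue == "whole_body") wb else wb * (wbr_mean / wb_mean)
      }
      for (age in ages) {
        pw <- indoor_source_params("wifi", tissue, age)
        wifi <- stats::rlnorm(n, pw$meanlog, pw$sdlog)
        VI_s <- if (length(V_I) >= n) V_I[seq_len(n)] else
          V_I[sample.int(length(V_I), n, replace = TRUE)]
        pen_sar <- field_to_sar(VI_s, tf, tissue = tissue, age = age)
        indoor_part <- wlan + wifi
        per_age[[age]] <- list(
          total = indoor_part + pen_sar,
          indoor = indoor_part,
          outdoor = pen_sar
        )
      }
      per_tissue[[tissue]] <- per_age
    }
    out[[id]] <- per_tissue
  }
  out
}
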