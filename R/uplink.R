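# Mobile-phone (near-field, uplink) SAR dose model.

#' Uplink usage parameters
#'
#' Usage and network parameters of the uplink dose model: fractions of 3G
#' connections, voice-call and data-traffic users, daily voice-call
#' duration, daily data volume, mean transmitted powers and network
#' connection speed. Defaults describe a typical urban 3G usage pattern.
#'
#' @param p3G fraction of 3G connections in `[0, 1]`.
#' @param p_v,p_d fractions of voice-call and data-traffic users.
#' @param t voice-call duration, s/day.
#' @param V_d data volume, bits/day.
#' @param Pbar_v,Pbar_d mean transmitted powers, W.
#' @param Tbar network connection speed, bits/s.
#' @return object of class `uplink_usage`.
#' @export
uplink_usage <- function(p3G = 0.8, p_v = 0.9, p_d = 0.7,
                         t = 120, V_d = 1.6e9,
                         Pbar_v = 0.2, Pbar_d = 0.1, Tbar = 5e6) {
  vals <- c(p3G = p3G, p_v = p_v, p_d = p_d, t = t, V_d = V_d,
            Pbar_v = Pbar_v, Pbar_d = Pbar_d, Tbar = Tbar)
  if (any(vals < 0)) stop_rfemap("usage parameters must be >= 0", "invalid_usage")
  if (any(c(p3G, p_v, p_d) > 1)) {
    stop_rfemap("usage fractions must be <= 1", "invalid_usage")
  }
  if (V_d > 0 && Tbar <= 0) {
    stop_rfemap("connection speed must be > 0 when data volume > 0",
                "invalid_usage")
  }
  structure(as.list(vals), class = "uplink_usage")
}

#' Daily time-averaged uplink SAR dose
#'
#' Evaluates the uplink dose model exactly as formulated:
#' \deqn{E_{tel} = \frac{0.25\, p_{3G}}{24 \times 3600}\, t\, SAR_v\, p_v\,
#'   \bar P_v + \frac{0.25}{24 \times 3600}\, p_{3G}\, V_d\, SAR_d\, p_d\,
#'   \frac{\bar P_d}{\bar T}}
#' with `SAR_v`, `SAR_d` the reference SAR per watt for voice and data mode
#' of the requested tissue and age group. The leading 0.25 factor is kept in
#' both terms by default; `include_quarter_factor = FALSE` drops it for
#' sensitivity analysis.
#'
#' @param usage an [uplink_usage()].
#' @param tf transfer functions from [sar_transfer_functions()].
#' @param tissue `"whole_body"` or `"whole_brain"`.
#' @param age `"child"` or `"adult"`.
#' @param include_quarter_factor keep the 0.25 factor (default `TRUE`).
#' @return list `E_tel` (mW/kg, time-averaged over the day), plus the
#'   separate `voice` and `data` terms.
#' @export
uplink_sar <- function(usage, tf = sar_transfer_functions(),
                       tissue = "whole_body", age = "adult",
                       include_quarter_factor = TRUE) {
  stopifnot(inherits(usage, "uplink_usage"))
  sar_v <- tf_entry(tf, tissue, age, "voice")$value
  sar_d <- tf_entry(tf, tissue, age, "data")$value
  q <- if (include_quarter_factor) 0.25 else 1
  day <- 24 * 3600
  voice <- q * usage$p3G / day * usage$t * sar_v * usage$p_v * usage$Pbar_v
  data <- if (usage$V_d > 0) {
    q / day * usage$p3G * usage$V_d * sar_d * usage$p_d * usage$Pbar_d / usage$Tbar
  } else 0
  list(E_tel = voice + data, voice = voice, data = data)
}

#' Calibration table for mobile-phone exposure profiles
#'
#' Mean and median (P50) of the mobile-phone use exposure profiles
#' (SAR, mW/kg) per tissue and age group, used to calibrate the uplink
#' Monte-Carlo mode.
#'
#' @return data frame: `tissue`, `age`, `mean`, `p50`.
#' @export
uplink_calibration <- function() {
  data.frame(
    tissue = c("whole_body", "whole_body", "whole_brain", "whole_brain"),
    age = c("adult", "child", "adult", "child"),
    mean = c(6.3e-3, 3.5e-3, 3.6e-3, 8.4e-4),
    p50 = c(2.0e-3, 8.3e-4, 1.3e-3, 2.9e-4),
    stringsAsFactors = FALSE
  )
}

# Solve the calibrated-mode parameters for one tissue/age: the reference SAR
# (same value for voice and data mode) that makes the deterministic dose
# equal the target median, and the sdlog of the shared lognormal usage
# intensity that reproduces the target mean/median ratio
# (mean = median * exp(sdlog^2 / 2) for a lognormal).
calibrate_uplink <- function(usage, tissue, age,
                             calibration = uplink_calibration(),
                             include_quarter_factor = TRUE) {
  row <- calibration[calibration$tissue == tissue & calibration$age == age, ]
  if (nrow(row) == 0) {
    stop_rfemap("no uplink calibration for this tissue/age", "configuration_error")
  }
  tf1 <- sar_transfer_functions()
  tf1[[tissue]][[age]][["voice"]]$value <- 1
  tf1[[tissue]][[age]][["data"]]$value <- 1
  unit_dose <- uplink_sar(usage, tf1, tissue, age,
                          include_quarter_factor = include_quarter_factor)$E_tel
  if (unit_dose <= 0) stop_rfemap("degenerate usage: zero dose", "invalid_usage")
  list(
    sar_ref = row$p50 / unit_dose,
    sdlog = sqrt(2 * log(row$mean / row$p50)),
    median = row$p50, mean = row$mean
  )
}

#' Per-group uplink exposure distributions
#'
#' Draws `n` Monte-Carlo uplink dose samples per age group and tissue. Usage
#' behaviour is identical across groups; only the age-specific SAR transfer
#' functions differ. In the default calibrated mode the spread of usage and
#' transfer-function parameters is represented by a shared lognormal
#' intensity factor, with the reference SAR solved so that the dose-model
#' median and mean match the calibration table (see
#' [uplink_calibration()]).
#'
#' @param usage an [uplink_usage()].
#' @param n samples per group/tissue.
#' @param seed integer seed.
#' @param tissues,ages groups to generate.
#' @param spread_sdlog override the calibrated lognormal spread (0 collapses
#'   the distribution to the deterministic dose-model value).
#' @param calibration calibration table, see [uplink_calibration()].
#' @param include_quarter_factor see [uplink_sar()].
#' @return nested list `[[age]][[tissue]]` of sample vectors (mW/kg).
#' @export
uplink_profiles <- function(usage = uplink_usage(), n = 20000, seed = 1L,
                            tissues = c("whole_body", "whole_brain"),
                            ages = c("child", "adult"),
                            spread_sdlog = NULL,
                            calibration = uplink_calibration(),
                            include_quarter_factor = TRUE) {
  set.seed(stage_seed(seed, "uplink"))
  out <- list()
  for (age in ages) {
    per_tissue <- list()
    for (tissue in tissues) {
      cal <- calibrate_uplink(usage, tissue, age, calibration,
                              include_quarter_factor)
      tf <- sar_transfer_functions()
      tf[[tissue]][[age]][["voice"]]$value <- cal$sar_ref
      tf[[tissue]][[age]][["data"]]$value <- cal$sar_ref
      base <- uplink_sar(usage, tf, tissue, age,
                         include_quarter_factor = include_quarter_factor)$E_tel
      s <- spread_sdlog %||% cal$sdlog
      per_tissue[[tissue]] <- if (s > 0) {
        base * exp(stats::rnorm(n, 0, s))
      } else rep(base, n)
    }
    out[[age]] <- per_tissue
  }
  out
}
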