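#' Generate a synthetic plate of OD growth curves
#'
#' Emulates a 24-h plate-reader run: for each strain, logistic growth curves
#' sampled every 10 minutes (145 points by default) with i.i.d. Gaussian
#' measurement noise floored at zero, laid out over randomised wells with a
#' fixed number of replicates per strain.
#'
#' @param true_params data frame with one row per strain: `strain_id`, `K`,
#'   `r`, `N0` (OD units and per hour), optionally `media_id`.
#' @param replicates wells per strain.
#' @param od_noise_sd Gaussian measurement noise SD, OD units.
#' @param seed RNG seed; fixed seed gives identical output.
#' @param interval_min sampling interval, minutes.
#' @param duration_h run length, hours.
#' @return list with `plate` (long data frame `time_h`, `well`, `od`) and
#'   `map` (`well`, `strain_id`, `media_id`, `replicate`).
#' @export
gen_od_curves <- function(true_params, replicates = 5, od_noise_sd = 0.01,
                          seed = 1, interval_min = 10, duration_h = 24) {
  stopifnot(all(c("strain_id", "K", "r", "N0") %in% names(true_params)))
  if (!"media_id" %in% names(true_params)) true_params$media_id <- "fresh"
  set.seed(seed)
  times <- seq(0, duration_h, by = interval_min / 60)
  n_wells <- nrow(true_params) * replicates
  all_wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
  if (n_wells > length(all_wells))
    stop("layout needs more than 96 wells")
  wells <- sample(all_wells, n_wells)  # randomised plate layout
  map <- data.frame(
    well = wells,
    strain_id = rep(true_params$strain_id, each = replicates),
    media_id = rep(true_params$media_id, each = replicates),
    replicate = rep(seq_len(replicates), times = nrow(true_params)),
    stringsAsFactors = FALSE)
  plate <- do.call(rbind, lapply(seq_len(n_wells), function(i) {
    p <- true_params[match(map$strain_id[i], true_params$strain_id), ]
    od <- logistic_od(times, p$K, p$r, p$N0)
    if (od_noise_sd > 0) od <- pmax(od + rnorm(length(od), 0, od_noise_sd), 0)
    data.frame(time_h = times, well = map$well[i], od = od,
               stringsAsFactors = FALSE)
  }))
  rownames(plate) <- NULL
  list(plate = plate, map = map)
}

#' Simulate two-gate flow-cytometry event counts
#'
#' Draws gated event counts for an *E. coli*/yeast co-culture from a
#' two-category multinomial over a fixed number of events (at most 100,000
#' events per sample on the instrument this emulates). Only relative
#' frequencies are informative, mirroring cytometry's relative-abundance
#' readout.
#'
#' @param true_freq_E true relative frequency of *E. coli*, in \[0, 1\].
#' @param events number of recorded events (`>= 1`, capped at 100,000).
#' @param seed optional RNG seed.
#' @return list with `count_E`, `count_Y` (summing to `events`) and the
#'   estimated `freq_E = count_E / events`.
#' @export
gen_flow_counts <- function(true_freq_E, events = 1e5, seed = NULL) {
  stopifnot(true_freq_E >= 0, true_freq_E <= 1, events >= 1)
  events <- min(as.integer(events), 100000L)
  if (!is.null(seed)) set.seed(seed)
  counts <- rmultinom(1, size = events, prob = c(true_freq_E, 1 - true_freq_E))
  list(count_E = counts[1], count_Y = counts[2],
       freq_E = counts[1] / events)
}

#' Simulate a CFU spot count
#'
#' Colony count from spotting a diluted sample on a selection plate,
#' modelled as Poisson with mean `density * volume * dilution`.
#'
#' @param density cell density of the culture, cells/mL (`>= 0`).
#' @param spot_volume_ul spotted volume, microlitres (20 by default).
#' @param dilution dilution factor applied before spotting, in (0, 1\].
#' @param seed optional RNG seed.
#' @return integer colony count.
#' @export
#' @examples
#' expected_cfu(10)  # 0.2 colonies expected: below the detection regime
gen_cfu_counts <- function(density, spot_volume_ul = 20, dilution = 1,
                           seed = NULL) {
  stopifnot(density >= 0, spot_volume_ul > 0, dilution > 0, dilution <= 1)
  if (!is.null(seed)) set.seed(seed)
  rpois(1, expected_cfu(density, spot_volume_ul, dilution))
}

#' @rdname gen_cfu_counts
#' @export
expected_cfu <- function(density, spot_volume_ul = 20, dilution = 1) {
  density * (spot_volume_ul / 1000) * dilution
}

#' Generate replicated competition frequency trajectories
#'
#' Runs the deterministic serial-transfer (or delayed-invader) dynamics once
#' and observes the daily end-of-cycle states independently for each
#' replicate, through two-gate cytometry counts (E vs Y) or per-species
#' Poisson CFU counts. Replicates therefore differ only in observation
#' noise, matching a model in which day-to-day dynamics are deterministic
#' and all noise is sampling noise.
#'
#' @param community an [lv_community()].
#' @param n_replicates replicate cultures observed.
#' @param observation `"flow"` (E vs Y gate counts), `"cfu"` (Poisson spot
#'   counts for all three species) or `"none"` (true values, noise-free).
#' @param invade run [simulate_invasion()] instead of a plain serial
#'   transfer.
#' @param n_cycles,dilution_factor,equilibration_cycles,invader_N0 protocol
#'   settings (see [simulate_serial_transfer()] and [simulate_invasion()]).
#' @param events flow events per sample.
#' @param cfu_dilution dilution applied before CFU spotting.
#' @param seed RNG seed for the observation layer.
#' @return data frame with one row per replicate x cycle: true populations
#'   (`N_E`, `N_Y`, `N_B`, cells/mL at cycle end), observed counts and
#'   observed relative frequencies (`freq_E`, `freq_Y`, `freq_B`; for flow,
#'   frequencies are within the E+Y gates and `freq_B` is `NA`).
#' @export
gen_competition_series <- function(community, n_replicates = 5,
                                   observation = c("flow", "cfu", "none"),
                                   invade = FALSE, n_cycles = 7,
                                   dilution_factor = 2^-10,
                                   equilibration_cycles = 3,
                                   invader_N0 = community$B$N0,
                                   events = 1e5, cfu_dilution = 1e-5,
                                   seed = 1) {
  observation <- match.arg(observation)
  traj <- if (invade) {
    simulate_invasion(community, invader_N0 = invader_N0,
                      equilibration_cycles = equilibration_cycles,
                      total_cycles = n_cycles,
                      dilution_factor = dilution_factor, grid_by = 1)
  } else {
    simulate_serial_transfer(community, n_cycles = n_cycles,
                             dilution_factor = dilution_factor, grid_by = 1)
  }
  df <- as.data.frame(traj)
  # end-of-cycle states (sampled daily, before dilution)
  ends <- do.call(rbind, lapply(split(df, df$cycle), function(x) x[nrow(x), ]))
  set.seed(seed)
  rows <- list()
  for (rep_i in seq_len(n_replicates)) {
    for (k in seq_len(nrow(ends))) {
      s <- ends[k, ]
      tot <- s$N_E + s$N_Y + s$N_B
      row <- data.frame(replicate = rep_i, cycle = s$cycle,
                        N_E = s$N_E, N_Y = s$N_Y, N_B = s$N_B)
      if (observation == "flow") {
        ey <- s$N_E + s$N_Y
        fE <- if (ey > 0) s$N_E / ey else 0
        obs <- gen_flow_counts(fE, events = events)
        row$count_E <- obs$count_E
        row$count_Y <- obs$count_Y
        row$count_B <- NA_integer_
        row$freq_E <- obs$freq_E
        row$freq_Y <- 1 - obs$freq_E
        row$freq_B <- NA_real_
      } else if (observation == "cfu") {
        cE <- gen_cfu_counts(s$N_E, dilution = cfu_dilution)
        cY <- gen_cfu_counts(s$N_Y, dilution = cfu_dilution)
        cB <- gen_cfu_counts(s$N_B, dilution = cfu_dilution)
        ctot <- cE + cY + cB
        row$count_E <- cE; row$count_Y <- cY; row$count_B <- cB
        if (ctot > 0) {
          row$freq_E <- cE / ctot; row$freq_Y <- cY / ctot
          row$freq_B <- cB / ctot
        } else {
          row$freq_E <- row$freq_Y <- row$freq_B <- NA_real_
        }
      } else {
        row$count_E <- row$count_Y <- row$count_B <- NA_integer_
        if (tot > 0) {
          row$freq_E <- s$N_E / tot; row$freq_Y <- s$N_Y / tot
          row$freq_B <- s$N_B / tot
        } else {
          row$freq_E <- row$freq_Y <- row$freq_B <- NA_real_
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "introduction_cycle") <- attr(traj, "introduction_cycle")
  out
}
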