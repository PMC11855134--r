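#' Default 26-treatment oryzalin design
#'
#' The concentration x exposure grid of the tissue-culture experiment the
#' simulator emulates: 26 distinct treatments over 10 oryzalin
#' concentrations (0--100 micromolar) and exposures of 10--36 hours, denser
#' at the doses where the ploidy response turns over. Includes the untreated
#' control, the low-dose/short-exposure cells that yield only diploids, the
#' extreme 100 uM / 10 h cell dominated by mixoploids, and the
#' 40--80 uM x 18--36 h block where tetraploid conversion is highest.
#'
#' @return Data frame with columns `concentration_uM` and `exposure_h`,
#'   26 rows, all pairs distinct.
#' @examples
#' g <- default_treatment_grid()
#' nrow(g)  # 26
#' @export
default_treatment_grid <- function() {
  # The named cells from the source experiment plus fill-ins chosen so the
  # design covers the whole 0-100 uM x 10-36 h envelope the optimizer later
  # searches: every corner of that rectangle has observed outcomes, so the
  # fitted classifiers interpolate rather than extrapolate.
  cells <- list(
    `0`   = c(24, 36),
    `2`   = c(12, 24),
    `5`   = c(12, 36),
    `8`   = c(12, 24),
    `10`  = c(10, 12, 24),
    `20`  = c(12, 18, 36),
    `40`  = c(18, 24, 36),
    `60`  = c(18, 24, 36),
    `80`  = c(18, 24),
    `100` = c(10, 12, 24, 36)
  )
  conc <- rep(as.numeric(names(cells)), lengths(cells))
  grid <- data.frame(concentration_uM = conc,
                     exposure_h = unlist(cells, use.names = FALSE))
  rownames(grid) <- NULL
  grid
}

#' Dose-response model parameters
#'
#' Parameters of the three-class generative model behind the simulator.
#' A latent conversion score s = b0 + b1*log(1+C) + b2*t + b3*log(1+C)*t
#' drives a decreasing diploid logistic P(diploid) = 1/(1+exp(s)): explants
#' escape the diploid state once dose and exposure are sufficient. Among
#' converted explants, the completed-doubling (tetraploid) fraction is a
#' unimodal exponential-power bump in (log-dose, time) centred on the
#' treatment optimum, multiplied by a saturating exposure factor
#' 1 - exp(-(t/tau)^4): exposures much shorter than a cell cycle leave
#' chimeric mixoploids rather than uniform tetraploids. The saturation
#' scale grows with dose beyond the optimum,
#' tau = time_sat * (1 + sat_dose_gain * max(0, log-dose excess)^2):
#' antimitotic arrest deepens at high doses, so completing a uniform
#' doubling takes longer and high-dose cells at short or intermediate
#' exposures stay chimeric. Tetraploid purity therefore falls off on all
#' sides of the optimum, which is what makes it identifiable. Mixoploid
#' takes the remaining probability, and is guaranteed at least
#' `mixoploid_floor` of
#' the converted mass.
#'
#' @param intercept,logdose_weight,time_weight,interaction_weight
#'   Coefficients of the latent conversion score (dimensionless; dose enters
#'   as log(1 + concentration)).
#' @param peak_conc,peak_time Location of the tetraploid optimum
#'   (micromolar, hours).
#' @param conc_decay Decay rate of the tetraploid bump per unit
#'   |log(1+C) - log(1+peak_conc)|^1.5 (must be > 0).
#' @param time_decay Decay rate per unit |t - peak_time|^1.5 (must be > 0).
#' @param amplitude Maximum tetraploid fraction among converted explants,
#'   in (0, 1].
#' @param time_sat Exposure scale (hours) of the completed-doubling
#'   saturation factor at and below the optimal dose.
#' @param sat_dose_gain Growth rate of the saturation scale per squared
#'   unit of log-dose above the optimum (dimensionless, >= 0).
#' @param mixoploid_floor Minimum mixoploid fraction among converted
#'   explants, in \[0, 1).
#' @return An object of class `dose_response_params`.
#' @export
dose_response_params <- function(intercept = -15.5,
                                 logdose_weight = 6,
                                 time_weight = 0.01,
                                 interaction_weight = 0.01,
                                 peak_conc = 33,
                                 peak_time = 18,
                                 conc_decay = 0.1,
                                 time_decay = 0.0028,
                                 amplitude = 0.96,
                                 time_sat = 12,
                                 sat_dose_gain = 0.95,
                                 mixoploid_floor = 0.02) {
  check_number(conc_decay, "conc_decay", lower = 1e-12)
  check_number(time_decay, "time_decay", lower = 1e-12)
  check_number(amplitude, "amplitude", lower = 1e-12, upper = 1)
  check_number(time_sat, "time_sat", lower = 1e-12)
  check_number(sat_dose_gain, "sat_dose_gain", lower = 0)
  check_number(mixoploid_floor, "mixoploid_floor", lower = 0, upper = 1 - 1e-9)
  check_number(peak_conc, "peak_conc", lower = 0, upper = 100)
  check_number(peak_time, "peak_time", lower = 0, upper = 48)
  for (nm in c("intercept", "logdose_weight", "time_weight",
               "interaction_weight")) {
    check_number(get(nm), nm)
  }
  structure(
    list(intercept = intercept, logdose_weight = logdose_weight,
         time_weight = time_weight, interaction_weight = interaction_weight,
         peak_conc = peak_conc, peak_time = peak_time,
         conc_decay = conc_decay, time_decay = time_decay,
         amplitude = amplitude, time_sat = time_sat,
         sat_dose_gain = sat_dose_gain,
         mixoploid_floor = mixoploid_floor),
    class = "dose_response_params"
  )
}

#' Class probabilities of a treatment
#'
#' Evaluates the generative dose-response model: the probability that an
#' explant treated at the given oryzalin concentration and exposure time
#' ends up diploid, mixoploid, or tetraploid. Vectorized over treatments.
#'
#' @param concentration Oryzalin concentration(s), micromolar, in \[0, 100\].
#' @param exposure Exposure time(s), hours, in \[0, 48\].
#' @param params A [dose_response_params()] object.
#' @return Numeric matrix, one row per treatment, columns
#'   `diploid`, `mixoploid`, `tetraploid`; rows sum to 1.
#' @examples
#' class_probabilities(33, 18)          # tetraploid-dominated optimum
#' class_probabilities(0, 24)           # untreated control: diploid
#' class_probabilities(100, 10)         # extreme dose, short pulse: mixoploid
#' @export
class_probabilities <- function(concentration, exposure,
                                params = dose_response_params()) {
  stopifnot(inherits(params, "dose_response_params"))
  if (length(concentration) != length(exposure)) {
    stop("concentration and exposure differ in length", call. = FALSE)
  }
  if (anyNA(concentration) || anyNA(exposure) ||
      any(concentration < 0) || any(concentration > 100)) {
    stop("concentration out of bounds [0, 100] uM", call. = FALSE)
  }
  if (any(exposure < 0) || any(exposure > 48)) {
    stop("exposure out of bounds [0, 48] h", call. = FALSE)
  }
  L <- log1p(concentration)
  score <- params$intercept + params$logdose_weight * L +
    params$time_weight * exposure + params$interaction_weight * L * exposure
  p_di <- 1 / (1 + exp(score))
  g <- params$amplitude *
    exp(-params$conc_decay * abs(L - log1p(params$peak_conc))^1.5 -
          params$time_decay * abs(exposure - params$peak_time)^1.5) *
    (1 - exp(-(exposure / (params$time_sat *
                             (1 + params$sat_dose_gain *
                                pmax(0, L - log1p(params$peak_conc))^2)))^4))
  g <- pmin(g, 1 - params$mixoploid_floor)
  out <- cbind(diploid = p_di,
               mixoploid = (1 - p_di) * (1 - g),
               tetraploid = (1 - p_di) * g)
  rownames(out) <- NULL
  out
}

#' Simulate a ploidy-induction experiment
#'
#' Draws an independent ploidy outcome for every explant of a replicated
#' design: `replicates` culture vessels per treatment, `explants` explants
#' per vessel, each explant's class sampled from [class_probabilities()].
#'
#' @param grid Data frame of treatments (`concentration_uM`, `exposure_h`);
#'   defaults to [default_treatment_grid()].
#' @param replicates Replicates per treatment (default 4).
#' @param explants Explants per replicate (default 4).
#' @param params A [dose_response_params()] object.
#' @param seed Integer seed; identical seeds give identical records.
#' @return Data frame with one row per explant: `concentration_uM`,
#'   `exposure_h`, `replicate`, `explant`, `ploidy`.
#' @examples
#' rec <- simulate_experiment(seed = 1)
#' nrow(rec)  # 26 treatments x 4 replicates x 4 explants = 416
#' @export
simulate_experiment <- function(grid = default_treatment_grid(),
                                replicates = 4, explants = 4,
                                params = dose_response_params(),
                                seed = 1L) {
  check_seed(seed)
  check_number(replicates, "replicates", lower = 1)
  check_number(explants, "explants", lower = 1)
  replicates <- as.integer(replicates)
  explants <- as.integer(explants)
  probs <- class_probabilities(grid$concentration_uM, grid$exposure_h, params)
  per_treat <- replicates * explants
  n <- nrow(grid) * per_treat
  rec <- data.frame(
    concentration_uM = rep(grid$concentration_uM, each = per_treat),
    exposure_h = rep(grid$exposure_h, each = per_treat),
    replicate = rep(rep(seq_len(replicates), each = explants), nrow(grid)),
    explant = rep(seq_len(explants), replicates * nrow(grid))
  )
  rec$ploidy <- with_seed(seed, {
    unlist(lapply(seq_len(nrow(grid)), function(i) {
      sample(PLOIDY_CLASSES, per_treat, replace = TRUE, prob = probs[i, ])
    }), use.names = FALSE)
  })
  rec
}

#' Assemble a class-balanced dataset from simulated records
#'
#' Subsamples explant-level records to equal per-class counts, the format
#' the classifiers are trained on (default 24 per class, 72 rows).
#'
#' @param records Data frame from [simulate_experiment()] (or any frame with
#'   `concentration_uM`, `exposure_h`, `ploidy`).
#' @param per_class Instances to keep per ploidy class (default 24).
#' @param seed Integer seed for the subsampling.
#' @return A [ploidy_dataset()] with `3 * per_class` rows.
#' @export
assemble_balanced_dataset <- function(records, per_class = 24, seed = 1L) {
  check_seed(seed)
  check_number(per_class, "per_class", lower = 0)
  per_class <- as.integer(per_class)
  if (per_class == 0L) {
    return(structure(
      list(features = matrix(numeric(0), ncol = 2,
                             dimnames = list(NULL, c("concentration_uM",
                                                     "exposure_h"))),
           labels = factor(character(0), levels = PLOIDY_CLASSES)),
      class = "ploidy_dataset"
    ))
  }
  idx <- with_seed(seed, {
    unlist(lapply(PLOIDY_CLASSES, function(cl) {
      rows <- which(records$ploidy == cl)
      if (length(rows) < per_class) {
        stop(sprintf("class %s has only %d record(s); %d required",
                     dQuote(cl), length(rows), per_class), call. = FALSE)
      }
      sort(sample(rows, per_class))
    }), use.names = FALSE)
  })
  ploidy_dataset(records[idx, c("concentration_uM", "exposure_h")],
                 records$ploidy[idx])
}
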