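## Per-metal log-normal exposure scales (meanlog of mg/L water, mg/kg soil)
## and blood levels (ug/mL), chosen as realistic urban background ranges.
METAL_PARAMS <- list(
  zn = list(water_meanlog = log(0.25),  soil_meanlog = log(60),
            blood_meanlog = log(0.9)),
  cr = list(water_meanlog = log(0.010), soil_meanlog = log(30),
            blood_meanlog = log(0.001)),
  cu = list(water_meanlog = log(0.050), soil_meanlog = log(25),
            blood_meanlog = log(1.0)),
  pb = list(water_meanlog = log(0.005), soil_meanlog = log(20),
            blood_meanlog = log(0.0002)))

#' Configuration of a synthetic cohort
#'
#' Defaults mirror the study conditions the method targets: 242 children
#' and teenagers, 54 boys (mean age 11.7) and 188 girls (mean age 10.4),
#' log-normal environmental metal concentrations, and a planted smooth
#' monotone mapping from exposure and physiology to clearance (higher
#' exposure, lower clearance, higher retention).  Soil feeds only the
#' long-term latent component; water feeds both.
#'
#' @param n cohort size (default 242, at least 10).
#' @param n_male number of boys; defaults to the study's sex ratio
#'   (54 boys of 242) scaled to \code{n}.
#' @param mean_age_male,mean_age_female mean ages in years (defaults 11.7
#'   and 10.4); ages are drawn around these with spread \code{age_sd} and
#'   rounded to whole years within 5..17.
#' @param age_sd age spread in years (default 2.2).
#' @param sdlog_env log-scale spread of the water and soil concentration
#'   distributions (default 0.45).
#' @param noise_sd standard deviation of Gaussian observation noise added
#'   to the retention target (default 0.02; must be < 0.5).
#' @param missing_rate fraction of metal-specific exposure fields blanked
#'   at random (default 0), emulating per-metal dataset attrition.
#' @param mapping named list of planted-mapping coefficients: standardised
#'   log-water and log-soil exposure, age, sex and body-size terms of the
#'   latent index, the logistic \code{slope}, the clearance \code{floor}
#'   (fraction of \code{cl_max} that even the most exposed subject clears)
#'   and \code{cl_max} in mL/min.  The defaults are calibrated so the
#'   planted retention spans roughly (0.02, 0.99) over a default cohort.
#' @param seed integer seed (required).
#' @return object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n = 242, n_male = NULL, mean_age_male = 11.7,
                          mean_age_female = 10.4, age_sd = 2.2,
                          sdlog_env = 0.45, noise_sd = 0.02,
                          missing_rate = 0,
                          mapping = list(water = 0.85, soil = 0.08,
                                         age = -0.30, sex = -0.20,
                                         size = 0.35, slope = 3,
                                         floor = 0.04, cl_max = 5),
                          seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (n < 10L) stop("infeasible config: n must be at least 10", call. = FALSE)
  ## study sex ratio (54 boys of 242) scaled to the requested size
  if (is.null(n_male)) n_male <- round(n * 54 / 242)
  if (noise_sd < 0 || noise_sd >= 0.5)
    stop("infeasible config: noise_sd must lie in [0, 0.5)", call. = FALSE)
  if (n_male < 0L || n_male > n)
    stop("'n_male' must lie between 0 and n", call. = FALSE)
  stopifnot(age_sd > 0, sdlog_env > 0, missing_rate >= 0, missing_rate < 1,
            is.list(mapping), mapping$cl_max > 0, mapping$floor >= 0,
            mapping$slope > 0)
  structure(list(n = as.integer(n), n_male = as.integer(n_male),
                 mean_age_male = mean_age_male,
                 mean_age_female = mean_age_female, age_sd = age_sd,
                 sdlog_env = sdlog_env, noise_sd = noise_sd,
                 missing_rate = missing_rate, mapping = mapping,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a cohort with planted ground truth
#'
#' Generates a seeded synthetic cohort in the cohort CSV schema.  For each
#' metal a latent clearance is a scaled logistic of a linear index of
#' log-exposures, age, sex and body size; blood, urine and diuresis are
#' then back-solved through the Reberg formula so that the retention
#' pipeline recomputes the planted clearance exactly.  The observed
#' retention target is the planted retention plus Gaussian noise, clipped
#' into (0;1).
#'
#' @param config a [cohort_config()].
#' @return data.frame in the cohort CSV schema with one \code{*_retention}
#'   column per metal; the noise-free truth (clearance and retention per
#'   metal) is attached as \code{attr(, "truth")}.
#' @examples
#' coh <- simulate_cohort(cohort_config(n = 50, seed = 42))
#' range(coh$zn_retention)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  local_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n
  sex <- c(rep(1L, cfg$n_male), rep(0L, n - cfg$n_male))
  mean_age <- ifelse(sex == 1L, cfg$mean_age_male, cfg$mean_age_female)
  age <- pmin(pmax(round(stats::rnorm(n, mean_age, cfg$age_sd)), 5L), 17L)
  height <- 80 + 6.2 * age + stats::rnorm(n, 0, 6)
  bmi <- stats::rnorm(n, 17.5 + 0.3 * (age - 10), 1.8)
  weight <- pmax(bmi * (height / 100)^2, 12)
  body_area <- sqrt(weight * height / 3600)      # Mosteller BSA, m2
  diuresis <- pmin(pmax(stats::rnorm(n, 1400, 250), 600), 2500)

  out <- data.frame(
    participant_code = sprintf("S%04d", seq_len(n)),
    weight_kg = round(weight, 1), height_cm = round(height, 1),
    body_area_m2 = body_area, age_years = age, sex = sex,
    diuresis_ml = round(diuresis),
    stringsAsFactors = FALSE)
  ## rounded physiology feeds the back-solve so the pipeline round-trips
  body_area <- out$body_area_m2
  diuresis <- out$diuresis_ml

  truth <- data.frame(participant_code = out$participant_code)
  z_size <- as.vector(scale(body_area))
  z_age <- (age - 11) / 3
  for (metal in METALS) {
    p <- METAL_PARAMS[[metal]]
    water <- stats::rlnorm(n, p$water_meanlog, cfg$sdlog_env)
    soil <- stats::rlnorm(n, p$soil_meanlog, cfg$sdlog_env)
    blood <- stats::rlnorm(n, p$blood_meanlog, 0.3)
    z_w <- (log(water) - p$water_meanlog) / cfg$sdlog_env
    z_s <- (log(soil) - p$soil_meanlog) / cfg$sdlog_env
    ## planted index: exposure raises retention, size/age raise clearance;
    ## standardised so the logistic slope is the same for every metal
    mp <- cfg$mapping
    eta <- mp$water * z_w + mp$soil * z_s + mp$age * z_age +
      mp$sex * sex + mp$size * z_size
    eta <- eta / series_sd(eta, "population")
    clearance <- mp$cl_max *
      (mp$floor + (1 - mp$floor) * stats::plogis(-mp$slope * eta))
    sigma <- series_sd(clearance, "population")
    r_true <- retention_from_clearance(clearance, sigma)
    ## back-solve urine through the Reberg formula
    urine <- clearance * blood * MINUTES_PER_DAY * body_area / diuresis
    r_obs <- r_true + stats::rnorm(n, 0, cfg$noise_sd)
    r_obs <- pmin(pmax(r_obs, 1e-4), 1 - 1e-4)
    out[[paste0(metal, "_blood_ugml")]] <- blood
    out[[paste0(metal, "_urine_ugml")]] <- urine
    out[[paste0(metal, "_water_mgl")]] <- water
    out[[paste0(metal, "_soil_mgkg")]] <- soil
    out[[paste0(metal, "_retention")]] <- r_obs
    truth[[paste0(metal, "_clearance")]] <- clearance
    truth[[paste0(metal, "_retention_true")]] <- r_true
    truth[[paste0(metal, "_sigma")]] <- sigma
    if (cfg$missing_rate > 0) {
      drop_idx <- which(stats::runif(n) < cfg$missing_rate)
      for (col in paste0(metal, c("_water_mgl", "_soil_mgkg", "_retention")))
        out[[col]][drop_idx] <- NA
    }
  }
  attr(out, "truth") <- truth
  out
}

#' Tiny hand-checkable worked cohort
#'
#' Eight fixed-constant records for one metal (zinc) whose clearances come
#' out to the integers \{0, 1, 1, 2, 2, 3, 3, 4\} by construction
#' (diuresis 1440 mL, body-area correction 1, blood 1 ug/mL, so clearance
#' equals the urine concentration).  The series has population variance
#' 1.5, so every retention value has the closed form \eqn{e^{-CL^2/3}};
#' the first record (no excretion) has retention exactly 1.  The fixture
#' is deterministic and byte-stable across runs.
#'
#' @return data.frame in the cohort CSV schema (zinc columns only).
#' @export
worked_fixture <- function() {
  cl <- c(0, 1, 1, 2, 2, 3, 3, 4)
  data.frame(
    participant_code = sprintf("W%d", 1:8),
    weight_kg = 36, height_cm = 100, body_area_m2 = 1,
    age_years = c(8L, 9L, 10L, 11L, 12L, 13L, 14L, 15L),
    sex = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
    diuresis_ml = 1440,
    zn_blood_ugml = 1, zn_urine_ugml = cl,
    zn_water_mgl = seq(0.1, 0.8, by = 0.1),
    zn_soil_mgkg = seq(10, 80, by = 10),
    stringsAsFactors = FALSE)
}
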