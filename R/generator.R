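#' Configuration for the synthetic EHR cohort generator
#'
#' Builds and validates the parameter set controlling [generate_cohort()].
#' Defaults reproduce the published baseline moments of the HU-resistant
#' (HU-RES, n = 733) and non-resistant (NON-RES, n = 571) groups of a
#' real-world polycythemia vera cohort (n = 1304); variables whose group
#' moments were not published (RBC, PLT, lymphocytes, weight, time from
#' diagnosis to treatment) carry invented but clinically plausible defaults
#' and are flagged as such below.
#'
#' @param n_patients number of patients to simulate.
#' @param resistant_fraction marginal probability of HU resistance
#'   (default 733/1304).
#' @param group_moments named list; one entry per continuous baseline
#'   variable, each a list with elements `res = c(mean, sd)`,
#'   `non = c(mean, sd)`, and truncation bounds `lower`, `upper`.
#'   See `default_group_moments()` for the defaults and their provenance.
#' @param interaction_effect log-odds added to the resistance linear predictor
#'   for patients in the high-RDW / low-HGB quadrant
#'   (RDW >= `rdw_threshold` and HGB < `hgb_threshold`).
#' @param baseline_logit intercept of the resistance model; `NULL` (default)
#'   means `qlogis(resistant_fraction)`.
#' @param discrimination_scale multiplier on the lab-driven part of the
#'   resistance linear predictor; 1 (default) makes labs discriminate between
#'   groups exactly as strongly as the configured group moments imply, 0
#'   removes all lab information.
#' @param rdw_threshold,hgb_threshold thresholds (RDW %, HGB g/dL) defining
#'   the planted interaction quadrant; defaults 17 and 15.5.
#' @param event_window_days integer vector `c(start, end)`: half-open
#'   post-index window (days) in which resistance manifests; default
#'   `c(183, 274)`, i.e. months 6-9 at 30.44 days/month.
#' @param followup_days follow-up span after the index date (default 365).
#' @param pre_index_days documented history span before the index date
#'   (default 183).
#' @param factor_loadings named numeric vector of loadings of each lab on a
#'   single latent myeloproliferation factor, inducing the co-elevation of
#'   WBC/ANC/RBC/RDW seen clinically; invented defaults, documented in the
#'   package vignette.
#' @param gender_female,te_history_prob length-2 named vectors (`res`, `non`)
#'   of female proportion and thromboembolism-history prevalence per group.
#' @param phlebotomy_rate length-2 named vector (`res`, `non`): mean
#'   annualized pre-index phlebotomy rate per group.
#' @param phlebotomy_shape gamma shape of the patient-level phlebotomy rate
#'   (overdispersion; invented default 0.35).
#' @param seed integer seed making the cohort fully reproducible.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [resistance_probability()]
#' @export
cohort_config <- function(n_patients = 1304L,
                          resistant_fraction = 733 / 1304,
                          group_moments = default_group_moments(),
                          interaction_effect = 1.0,
                          baseline_logit = NULL,
                          discrimination_scale = 1,
                          rdw_threshold = 17,
                          hgb_threshold = 15.5,
                          event_window_days = c(183L, 274L),
                          followup_days = 365L,
                          pre_index_days = 183L,
                          factor_loadings = default_factor_loadings(),
                          gender_female = c(res = 0.419, non = 0.574),
                          te_history_prob = c(res = 0.146, non = 0.163),
                          phlebotomy_rate = c(res = 0.74, non = 0.28),
                          phlebotomy_shape = 0.35,
                          seed = 1L) {
  if (!is.finite(resistant_fraction) ||
      resistant_fraction < 0 || resistant_fraction > 1)
    stop("invalid cohort_config field 'resistant_fraction': must lie in [0, 1]",
         call. = FALSE)
  cfg <- list(
    n_patients = as.integer(n_patients),
    resistant_fraction = resistant_fraction,
    group_moments = group_moments,
    interaction_effect = interaction_effect,
    baseline_logit = if (is.null(baseline_logit)) qlogis(resistant_fraction) else baseline_logit,
    discrimination_scale = discrimination_scale,
    rdw_threshold = rdw_threshold,
    hgb_threshold = hgb_threshold,
    event_window_days = as.integer(event_window_days),
    followup_days = as.integer(followup_days),
    pre_index_days = as.integer(pre_index_days),
    factor_loadings = factor_loadings,
    gender_female = gender_female,
    te_history_prob = te_history_prob,
    phlebotomy_rate = phlebotomy_rate,
    phlebotomy_shape = phlebotomy_shape,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Default group-wise baseline moments
#'
#' Mean/SD pairs per outcome group (`res` = HU-resistant, `non` =
#' non-resistant) for each continuous baseline variable, with truncation
#' bounds. Values for age, HCT, HGB, RDW, WBC, ANC are the published group
#' moments of the 1304-patient modelling cohort; RBC, lymphocytes, PLT,
#' weight and `time_dx_to_tx` were not published per group and are invented,
#' clinically plausible stand-ins (marked "invented").
#'
#' @return named list usable as `group_moments` in [cohort_config()].
#' @export
default_group_moments <- function() {
  list(
    age_at_index  = list(res = c(68.4, 11.2), non = c(71.2, 10.8), lower = 18,  upper = 100),
    HCT           = list(res = c(49.0, 7.40), non = c(47.2, 7.37), lower = 0,   upper = 100),
    HGB           = list(res = c(15.6, 2.61), non = c(15.4, 2.49), lower = 0,   upper = Inf),
    RDW           = list(res = c(18.1, 3.22), non = c(17.1, 3.05), lower = 0,   upper = Inf),
    WBC           = list(res = c(13.1, 9.02), non = c(11.1, 6.36), lower = 0.5, upper = Inf),
    ANC           = list(res = c(9.58, 6.00), non = c(8.36, 5.58), lower = 0.2, upper = Inf),
    # invented: not published per group
    RBC           = list(res = c(6.10, 1.00), non = c(5.80, 1.00), lower = 1,   upper = Inf),
    lymphocytes   = list(res = c(1.75, 0.75), non = c(1.70, 0.75), lower = 0.2, upper = Inf),
    PLT           = list(res = c(455, 185),   non = c(420, 175),   lower = 20,  upper = Inf),
    weight        = list(res = c(86, 19),     non = c(84, 19),     lower = 35,  upper = 200),
    time_dx_to_tx = list(res = c(450, 380),   non = c(380, 340),   lower = 1,   upper = Inf)
  )
}

#' @rdname default_group_moments
#' @export
default_factor_loadings <- function() {
  c(age_at_index = 0, HCT = 0.5, HGB = 0.2, RDW = 0.35, WBC = 0.6,
    ANC = 0.6, RBC = 0.5, lymphocytes = 0.1, PLT = 0.3, weight = 0,
    time_dx_to_tx = 0)
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid cohort_config field '%s': %s", field, msg), call. = FALSE)
  }
  if (!is.finite(cfg$n_patients) || cfg$n_patients <= 0L)
    fail("n_patients", "must be a positive integer")
  if (!is.finite(cfg$resistant_fraction) ||
      cfg$resistant_fraction < 0 || cfg$resistant_fraction > 1)
    fail("resistant_fraction", "must lie in [0, 1]")
  if (length(cfg$event_window_days) != 2L ||
      cfg$event_window_days[1] >= cfg$event_window_days[2])
    fail("event_window_days", "must be c(start, end) with start < end")
  if (cfg$event_window_days[2] > cfg$followup_days)
    fail("event_window_days", "window end must not exceed followup_days")
  if (cfg$followup_days <= 0L) fail("followup_days", "must be positive")
  if (cfg$pre_index_days <= 0L) fail("pre_index_days", "must be positive")
  for (v in names(cfg$group_moments)) {
    gm <- cfg$group_moments[[v]]
    for (g in c("res", "non")) {
      if (length(gm[[g]]) != 2L || !all(is.finite(gm[[g]])))
        fail("group_moments", sprintf("'%s' group '%s' needs finite c(mean, sd)", v, g))
      if (gm[[g]][2] < 0)
        fail("group_moments", sprintf("'%s' group '%s' has sd < 0", v, g))
    }
    if (gm$lower >= gm$upper)
      fail("group_moments", sprintf("'%s' bounds must satisfy lower < upper", v))
  }
  miss <- setdiff(names(cfg$group_moments), names(cfg$factor_loadings))
  if (length(miss))
    fail("factor_loadings", paste("missing loadings for:", paste(miss, collapse = ", ")))
  invisible(cfg)
}

## ---- truncated-normal machinery ------------------------------------------

# mean and sd of N(mu, sigma) truncated to [a, b]
trunc_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  pa <- dnorm(al); pb <- dnorm(be)
  alpa <- if (is.finite(al)) al * pa else 0   # x * phi(x) -> 0 at +-Inf
  bepb <- if (is.finite(be)) be * pb else 0
  m <- mu + sigma * (pa - pb) / Z
  v <- sigma^2 * (1 + (alpa - bepb) / Z - ((pa - pb) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# underlying normal parameters whose truncation to [a, b] has the target
# mean/sd; identity when truncation is negligible
trunc_match <- function(target_mean, target_sd, a, b) {
  if (target_sd == 0) return(c(mu = target_mean, sigma = 0))
  za <- (a - target_mean) / target_sd
  zb <- (b - target_mean) / target_sd
  if (za < -6 && zb > 6) return(c(mu = target_mean, sigma = target_sd))
  obj <- function(par) {
    m <- trunc_moments(par[1], exp(par[2]), a, b)
    (m[1] - target_mean)^2 / target_sd^2 + (m[2] - target_sd)^2 / target_sd^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# map standard-normal draws u to the truncated normal via the percentile map
rtrunc_from_z <- function(u, mu, sigma, a, b) {
  if (sigma == 0) return(rep(mu, length(u)))
  pa <- pnorm(a, mu, sigma)
  pb <- pnorm(b, mu, sigma)
  qnorm(pa + pnorm(u) * (pb - pa), mu, sigma)
}

# log density of the truncated normal (for the likelihood-ratio posterior)
dtrunc_log <- function(x, mu, sigma, a, b) {
  Z <- pnorm(b, mu, sigma) - pnorm(a, mu, sigma)
  ifelse(x < a | x > b, -Inf, dnorm(x, mu, sigma, log = TRUE) - log(Z))
}

# latent standard-normal score of x under the group's truncated marginal
# (inverse of the percentile map used in generation)
ztrunc <- function(x, mu, sigma, a, b) {
  pa <- pnorm(a, mu, sigma)
  pb <- pnorm(b, mu, sigma)
  p <- (pnorm(x, mu, sigma) - pa) / (pb - pa)
  qnorm(pmin(pmax(p, 1e-12), 1 - 1e-12))
}

# log density of the one-factor Gaussian copula at latent scores U (n x p),
# relative to independence: log c(u) = log mvn(u; 0, L L' + D) - sum log phi(u)
log_copula <- function(U, loadings) {
  d <- 1 - loadings^2
  keep <- loadings != 0
  if (!any(keep)) return(numeric(nrow(U)))
  U <- U[, keep, drop = FALSE]
  lam <- loadings[keep]; d <- d[keep]
  denom <- 1 + sum(lam^2 / d)
  q <- rowSums(sweep(U^2, 2, d, "/")) -
    (as.vector(U %*% (lam / d)))^2 / denom
  logdet <- log(denom) + sum(log(d))
  -0.5 * (q + logdet + ncol(U) * log(2 * pi)) -
    rowSums(dnorm(U, log = TRUE))
}

# per-variable underlying parameters for both groups, cached on the config
trunc_params <- function(cfg) {
  lapply(cfg$group_moments, function(gm) {
    list(res = trunc_match(gm$res[1], gm$res[2], gm$lower, gm$upper),
         non = trunc_match(gm$non[1], gm$non[2], gm$lower, gm$upper),
         lower = gm$lower, upper = gm$upper)
  })
}

## ---- resistance model -----------------------------------------------------

# lab-driven log likelihood ratio (resistant vs non-resistant) for one or
# more patients given as a data.frame of baseline fields
lab_llr <- function(records, cfg, tp = trunc_params(cfg)) {
  llr <- numeric(nrow(records))
  vars <- names(cfg$group_moments)
  Ur <- Un <- matrix(0, nrow(records), length(vars),
                     dimnames = list(NULL, vars))
  for (v in vars) {
    if (!v %in% names(records) || anyNA(records[[v]]))
      stop(sprintf("resistance model requires field '%s'", v), call. = FALSE)
    p <- tp[[v]]
    llr <- llr +
      dtrunc_log(records[[v]], p$res[1], p$res[2], p$lower, p$upper) -
      dtrunc_log(records[[v]], p$non[1], p$non[2], p$lower, p$upper)
    Ur[, v] <- ztrunc(records[[v]], p$res[1], p$res[2], p$lower, p$upper)
    Un[, v] <- ztrunc(records[[v]], p$non[1], p$non[2], p$lower, p$upper)
  }
  # dependence correction: the labs co-vary through the latent factor, so the
  # exact likelihood ratio carries the copula density at each group's scores
  lam <- cfg$factor_loadings[vars]
  llr <- llr + log_copula(Ur, lam) - log_copula(Un, lam)
  # pre-index phlebotomy burden: negative-binomial (gamma-Poisson) count
  if (!"annualized_phlebotomy_count" %in% names(records) ||
      anyNA(records$annualized_phlebotomy_count))
    stop("resistance model requires field 'annualized_phlebotomy_count'", call. = FALSE)
  k <- round(records$annualized_phlebotomy_count * cfg$pre_index_days / 365)
  expo <- cfg$pre_index_days / 365
  llr <- llr +
    dnbinom(k, size = cfg$phlebotomy_shape, mu = cfg$phlebotomy_rate["res"] * expo, log = TRUE) -
    dnbinom(k, size = cfg$phlebotomy_shape, mu = cfg$phlebotomy_rate["non"] * expo, log = TRUE)
  # binary covariates
  if (!"gender" %in% names(records) || anyNA(records$gender))
    stop("resistance model requires field 'gender'", call. = FALSE)
  fem <- records$gender == "female"
  llr <- llr + ifelse(fem,
                      log(cfg$gender_female["res"] / cfg$gender_female["non"]),
                      log((1 - cfg$gender_female["res"]) / (1 - cfg$gender_female["non"])))
  if (!"te_history" %in% names(records) || anyNA(records$te_history))
    stop("resistance model requires field 'te_history'", call. = FALSE)
  llr + ifelse(records$te_history,
               log(cfg$te_history_prob["res"] / cfg$te_history_prob["non"]),
               log((1 - cfg$te_history_prob["res"]) / (1 - cfg$te_history_prob["non"])))
}

#' Probability of hydroxyurea resistance under the generative model
#'
#' Logistic model: `baseline_logit` plus `discrimination_scale` times the
#' log-likelihood ratio of the patient's baseline profile under the two
#' configured group distributions, plus `interaction_effect` if the patient
#' lies in the high-RDW / low-HGB quadrant (RDW >= `rdw_threshold` and
#' HGB < `hgb_threshold`). With `discrimination_scale = 0` and
#' `interaction_effect = 0` every patient has probability
#' `plogis(baseline_logit)`.
#'
#' @param record a one-row data.frame (or a data.frame of several patients)
#'   with the baseline fields named in `config$group_moments` plus
#'   `annualized_phlebotomy_count`, `gender`, `te_history`.
#' @param config a [cohort_config()].
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
resistance_probability <- function(record, config) {
  stopifnot(inherits(config, "cohort_config"))
  record <- as.data.frame(record)
  eta <- rep(config$baseline_logit, nrow(record))
  if (config$discrimination_scale != 0)
    eta <- eta + config$discrimination_scale * lab_llr(record, config)
  else
    lab_llr(record, config)  # still enforce the missing-field contract
  if (config$interaction_effect != 0) {
    if (!all(c("RDW", "HGB") %in% names(record)) || anyNA(record$RDW) || anyNA(record$HGB))
      stop("resistance model requires fields 'RDW' and 'HGB'", call. = FALSE)
    q1 <- record$RDW >= config$rdw_threshold & record$HGB < config$hgb_threshold
    eta <- eta + config$interaction_effect * as.numeric(q1)
  }
  unname(plogis(eta))
}

## ---- cohort generation ----------------------------------------------------

#' Generate a synthetic EHR-like polycythemia vera cohort
#'
#' Draws `n_patients` baseline records from a two-group mixture with the
#' configured group moments (moment-matched truncated normals correlated by a
#' single latent myeloproliferation factor), assigns the resistance outcome
#' through [resistance_probability()], and lays out a per-patient event
#' timeline: the PV diagnosis, two hydroxyurea prescriptions (day 0 = index
#' and ~day 90), serial laboratory panels every 6 weeks from 6 months before
#' to 12 months after the index, pre-index phlebotomies, and -- for resistant
#' patients -- a planted resistance manifestation (phlebotomy, uncontrolled
#' hematocrit, or combined leukocytosis/thrombocytosis) inside the configured
#' post-index event window.
#'
#' @param config a [cohort_config()].
#' @return a list of class `pv_cohort` with elements
#'   \describe{
#'     \item{patients}{data.frame, one row per patient: demographics and
#'       pre-index baseline features (see the package vignette for the schema).}
#'     \item{events}{data.frame in long format: `patient_id`, `day_offset`
#'       (integer days relative to the index date, negative = pre-index),
#'       `kind`, `analyte`, `value`; sorted by patient and day.}
#'     \item{outcome}{data.frame of ground truth: `patient_id`, `resistant`,
#'       `criterion`, `event_day` (day of the planted manifestation, or the
#'       follow-up end for censored patients).}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 50, seed = 7))
#' table(coh$outcome$resistant)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  local_seed(config$seed)
  n <- config$n_patients
  tp <- trunc_params(config)

  ## initial mixture component (determines which group's moments are drawn)
  comp <- runif(n) < config$resistant_fraction  # TRUE = resistant component

  ## latent myeloproliferation factor + idiosyncratic noise -> labs
  z <- rnorm(n)
  patients <- data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                         stringsAsFactors = FALSE)
  for (v in names(config$group_moments)) {
    lam <- config$factor_loadings[[v]]
    u <- lam * z + sqrt(1 - lam^2) * rnorm(n)
    p <- tp[[v]]
    x <- numeric(n)
    x[comp]  <- rtrunc_from_z(u[comp],  p$res[1], p$res[2], p$lower, p$upper)
    x[!comp] <- rtrunc_from_z(u[!comp], p$non[1], p$non[2], p$lower, p$upper)
    patients[[v]] <- x
  }
  patients$time_dx_to_tx <- as.integer(pmax(1, round(patients$time_dx_to_tx)))
  patients$gender <- ifelse(
    runif(n) < ifelse(comp, config$gender_female["res"], config$gender_female["non"]),
    "female", "male")
  patients$te_history <- runif(n) <
    ifelse(comp, config$te_history_prob["res"], config$te_history_prob["non"])

  ## pre-index phlebotomy burden: gamma rate, Poisson realization
  rate <- rgamma(n, shape = config$phlebotomy_shape,
                 scale = ifelse(comp, config$phlebotomy_rate["res"],
                                config$phlebotomy_rate["non"]) / config$phlebotomy_shape)
  expo <- config$pre_index_days / 365
  phleb_n <- rpois(n, rate * expo)
  patients$annualized_phlebotomy_count <- phleb_n * 365 / config$pre_index_days
  patients$NLR <- patients$ANC / patients$lymphocytes

  ## outcome assignment through the resistance model
  pr <- resistance_probability(patients, config)
  resistant <- runif(n) < pr

  ## planted manifestation for resistant patients
  w <- config$event_window_days
  crit <- rep("none", n)
  event_day <- rep(config$followup_days, n)
  if (any(resistant)) {
    k <- sum(resistant)
    crit[resistant] <- sample(c("phlebotomy_in_window", "hct_uncontrolled",
                                "myeloproliferation_uncontrolled"),
                              k, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    event_day[resistant] <- sample(seq.int(w[1], w[2] - 1L), k, replace = TRUE)
  }

  events <- build_timelines(patients, phleb_n, resistant, crit, event_day, config)

  out <- list(patients = order_patient_columns(patients),
              events = events,
              outcome = data.frame(patient_id = patients$patient_id,
                                   resistant = resistant,
                                   criterion = crit,
                                   event_day = as.integer(event_day),
                                   stringsAsFactors = FALSE),
              config = config)
  class(out) <- "pv_cohort"
  out
}

order_patient_columns <- function(patients) {
  first <- c("patient_id", "gender", "age_at_index", "te_history", "weight",
             "time_dx_to_tx", "annualized_phlebotomy_count")
  labs <- c("RBC", "HCT", "HGB", "RDW", "WBC", "ANC", "lymphocytes", "PLT", "NLR")
  patients[, c(first, labs)]
}

# controlled post-index values under effective hydroxyurea (kept strictly
# clear of every labeling trigger so that the ground-truth flag is
# recoverable from the timeline)
controlled_lab <- function(n, analyte) {
  switch(analyte,
    HCT = pmin(rnorm(n, 42, 1.5), 44.4),
    WBC = pmax(pmin(rnorm(n, 7, 1.5), 9.8), 1),
    PLT = pmax(pmin(rnorm(n, 300, 50), 398), 50))
}

build_timelines <- function(patients, phleb_n, resistant, crit, event_day, config) {
  n <- nrow(patients)
  pre <- config$pre_index_days
  fup <- config$followup_days
  lab_days <- seq.int(-pre, fup, by = 42L)
  if (max(lab_days) < fup) lab_days <- c(lab_days, fup)
  pre_days <- lab_days[lab_days < 0L]
  post_days <- lab_days[lab_days >= 0L]
  base_analytes <- c("RBC", "HCT", "HGB", "RDW", "WBC", "ANC", "lymphocytes", "PLT")

  per_patient <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- patients$patient_id[i]
    ev <- list()
    add <- function(day, kind, analyte = NA_character_, value = NA_real_) {
      ev[[length(ev) + 1L]] <<- list(day = as.integer(day), kind = kind,
                                     analyte = analyte, value = value)
    }
    dx_day <- -as.integer(patients$time_dx_to_tx[i])
    add(dx_day, "pv_diagnosis")
    add(0L, "hu_prescription")
    add(90L, "hu_prescription")
    if (patients$te_history[i]) add(-100L, "te_event")
    ## pre-index serial labs: monitoring analytes, baseline panel at the most
    ## recent pre-index draw (so features derived from the timeline equal the
    ## baseline record)
    for (d in pre_days[-length(pre_days)]) {
      add(d, "lab", "HCT", controlled_lab(1, "HCT") + 5)
      add(d, "lab", "WBC", controlled_lab(1, "WBC") + 3)
    }
    last_pre <- pre_days[length(pre_days)]
    for (a in base_analytes) add(last_pre, "lab", a, patients[[a]][i])
    ## pre-index phlebotomies
    if (phleb_n[i] > 0L)
      for (d in sort(sample.int(pre, phleb_n[i], replace = TRUE) - pre - 1L))
        add(d, "phlebotomy")
    ## post-index monitoring under hydroxyurea
    for (d in post_days) {
      add(d, "lab", "HCT", controlled_lab(1, "HCT"))
      add(d, "lab", "WBC", controlled_lab(1, "WBC"))
      add(d, "lab", "PLT", controlled_lab(1, "PLT"))
    }
    ## planted resistance manifestation
    if (resistant[i]) {
      d <- event_day[i]
      if (crit[i] == "phlebotomy_in_window") {
        add(d, "phlebotomy")
      } else if (crit[i] == "hct_uncontrolled") {
        add(d, "lab", "HCT", runif(1, 45.5, 54))
      } else {
        add(d, "lab", "WBC", runif(1, 10.5, 18))
        add(d, "lab", "PLT", runif(1, 410, 700))
      }
    }
    df <- data.frame(
      patient_id = pid,
      day_offset = vapply(ev, `[[`, integer(1), "day"),
      kind = vapply(ev, `[[`, character(1), "kind"),
      analyte = vapply(ev, `[[`, character(1), "analyte"),
      value = vapply(ev, `[[`, numeric(1), "value"),
      stringsAsFactors = FALSE)
    per_patient[[i]] <- df[order(df$day_offset, method = "radix"), ]
  }
  ev <- do.call(rbind, per_patient)
  rownames(ev) <- NULL
  ev
}

#' @export
print.pv_cohort <- function(x, ...) {
  cat(sprintf("Synthetic PV cohort: %d patients, %d events\n",
              nrow(x$patients), nrow(x$events)))
  cat(sprintf("  resistant: %d (%.1f%%)   seed: %d\n",
              sum(x$outcome$resistant),
              100 * mean(x$outcome$resistant), x$config$seed))
  invisible(x)
}

# seed the RNG for the calling frame, restoring the previous state on exit
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = envir)
  set.seed(seed)
  invisible(NULL)
}
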