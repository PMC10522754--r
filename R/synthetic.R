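# Seeded generator of synthetic surveillance cohorts with the statistical
# structure the analysis pipeline assumes: 6-monthly visits, log-normal
# marker set-points with multiplicative measurement noise, prediagnostic
# marker rises timed by log-normal lead-time distributions, morphological
# feature emergence, and stage-dependent postdiagnosis survival.

#' Configuration of the synthetic cohort generator
#'
#' Defaults encode the published frequencies of the motivating 100-case
#' surveillance series: an even split of IPMN-derived and concomitant
#' carcinomas; the clinical-stage distribution per type; CA19-9 aberrant-
#' elevation probabilities conditional on type and stage stratum (23% / 71%
#' in stage 0-II / III-IV of derived carcinomas, 41% / 100% in concomitant);
#' in-window CA19-9 availability (47/50 and 42/50 per type, so 11% of cases
#' lack data in the final year); HbA1c elevation in 3%, enzyme elevation in
#' 16% / 20%; high-risk stigmata in 86% / 16%; at least one worrisome
#' feature or stigma in all derived and 49/50 concomitant cases; log-normal
#' lead-time distributions matched to the printed median/IQR anchors; and a
#' median 5.7-year (range 0.5-25.6) follow-up to diagnosis.
#'
#' Intended labels (pattern, elevations, stigmata) are assigned by
#' variance-controlled quota within each (type, stage-stratum) cell —
#' `floor(n p)` cases plus a Bernoulli remainder, positions randomised — so
#' that a simulated cohort reproduces the target prevalences the way a fixed
#' published cohort does, rather than with full binomial noise.
#'
#' @param n_carcinoma Number of carcinoma cases.
#' @param prop_derived Proportion of IPMN-derived (vs concomitant) cases.
#' @param n_noncancer Number of carcinoma-free surveillance patients.
#' @param visit_interval_days,visit_jitter_sd_days Surveillance cadence.
#' @param followup_meanlog,followup_sdlog,followup_range_years Log-normal
#'   time from baseline to carcinoma diagnosis, truncated to the range.
#' @param stage_probs Clinical-stage distribution per carcinoma type.
#' @param p_ca19_9_available Probability of CA19-9 data within the final
#'   prediagnostic year, per type.
#' @param p_aberrant Aberrant-elevation probability per type and stage
#'   stratum (`early` = stage 0-II, `late` = III-IV), among cases with
#'   in-window data.
#' @param p_high_to_high Probability of the high-to-high pattern among
#'   non-aberrant cases with in-window data, per type.
#' @param p_hba1c,p_enzyme,p_hrs,p_any_wf_or_hrs Prevalence parameters (per
#'   type where vectors).
#' @param ca19_9_lead,wf_lead Median/quartile anchors (years) of the
#'   log-normal lead-time distributions, per type.
#' @param marker_cv Multiplicative measurement noise (log-sd) of marker
#'   series.
#' @param ca19_9_setpoint,ca19_9_high_setpoint,p_amylase_setpoint,lipase_setpoint,amylase_setpoint
#'   Log-normal set-point parameters `c(meanlog, sdlog)`.
#' @param hba1c_mean_pct,hba1c_sd_pct,hba1c_noise_mmol HbA1c set-point (NGSP
#'   %) and measurement noise (mmol/mol).
#' @param lewis_negative_fraction Fraction of carcinoma cases that are
#'   Lewis-antigen negative (drawn among low-to-low cases).
#' @param ca19_9_detection_limit Assay detection limit, U/mL.
#' @param p_acute_pancreatitis Probability of a prediagnostic acute
#'   pancreatitis event, per type.
#' @param survival_median_years Median postdiagnosis survival per clinical
#'   stage (exponential model).
#' @param censor_range_years Administrative censoring window after
#'   diagnosis (uniform).
#' @param age_mean,age_sd,age_range,p_male,p_smoking,bmi_mean,bmi_sd,diabetes_probs,p_family_history,ipmn_type_probs,p_head_location
#'   Baseline covariate distributions.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_carcinoma = 100,
    prop_derived = 0.5,
    n_noncancer = 0,
    visit_interval_days = 182.6,
    visit_jitter_sd_days = 15,
    followup_meanlog = log(5.7),
    followup_sdlog = 0.9,
    followup_range_years = c(0.6, 25.6),
    stage_probs = list(
      ipmn_derived = c(`0` = 18, I = 10, II = 15, III = 5, IV = 2) / 50,
      concomitant_pdac = c(`0` = 1, I = 8, II = 27, III = 6, IV = 8) / 50),
    p_ca19_9_available = c(ipmn_derived = 47 / 50, concomitant_pdac = 42 / 50),
    p_aberrant = list(
      ipmn_derived = c(early = 0.23, late = 0.71),
      concomitant_pdac = c(early = 0.41, late = 1.00)),
    p_high_to_high = c(ipmn_derived = 10 / 33, concomitant_pdac = 2 / 17),
    p_hba1c = 0.03,
    p_enzyme = c(ipmn_derived = 0.16, concomitant_pdac = 0.20),
    p_hrs = c(ipmn_derived = 0.86, concomitant_pdac = 0.16),
    p_any_wf_or_hrs = c(ipmn_derived = 1.0, concomitant_pdac = 49 / 50),
    ca19_9_lead = list(
      ipmn_derived = c(median = 0.4, q1 = 0.1, q3 = 0.5),
      concomitant_pdac = c(median = 0.1, q1 = 0.1, q3 = 0.7)),
    wf_lead = list(
      ipmn_derived = c(median = 1.6, q1 = 0.7, q3 = 3.7),
      concomitant_pdac = c(median = 0.2, q1 = 0.1, q3 = 1.9)),
    marker_cv = 0.2,
    ca19_9_setpoint = c(meanlog = log(9), sdlog = 0.45),
    ca19_9_high_setpoint = c(meanlog = log(70), sdlog = 0.3),
    p_amylase_setpoint = c(meanlog = log(28), sdlog = 0.4),
    lipase_setpoint = c(meanlog = log(40), sdlog = 0.4),
    amylase_setpoint = c(meanlog = log(80), sdlog = 0.4),
    hba1c_mean_pct = 6.0,
    hba1c_sd_pct = 0.4,
    hba1c_noise_mmol = 0.7,
    lewis_negative_fraction = 0.08,
    ca19_9_detection_limit = 2,
    p_acute_pancreatitis = c(ipmn_derived = 0.04, concomitant_pdac = 0.06),
    survival_median_years = c(`0` = 10, I = 6, II = 2.5, III = 1.2, IV = 0.7),
    censor_range_years = c(1, 8),
    age_mean = 70.9, age_sd = 8.7, age_range = c(43, 88),
    p_male = 0.58, p_smoking = 0.53,
    bmi_mean = 21.9, bmi_sd = 3.3,
    diabetes_probs = c(absent = 0.51, recent_onset_lt2y = 0.09,
                       unknown_onset = 0.03, long_standing_ge2y = 0.37),
    p_family_history = 0.07,
    ipmn_type_probs = c(branch_duct = 0.80, main_duct = 0.06, mixed = 0.14),
    p_head_location = c(ipmn_derived = 27 / 50, concomitant_pdac = 24 / 50)) {
  cfg <- as.list(environment())
  probs <- c(cfg$prop_derived, cfg$p_ca19_9_available,
             unlist(cfg$p_aberrant), cfg$p_high_to_high, cfg$p_hba1c,
             cfg$p_enzyme, cfg$p_hrs, cfg$p_any_wf_or_hrs,
             cfg$lewis_negative_fraction, cfg$p_acute_pancreatitis)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (any(unlist(cfg$survival_median_years) <= 0))
    stop("survival medians must be positive", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

# log-normal parameters matched to a printed median and IQR
lnorm_from_quartiles <- function(anchors) {
  meanlog <- log(anchors[["median"]])
  sdlog <- (log(anchors[["q3"]]) - log(anchors[["q1"]])) / (2 * qnorm(0.75))
  c(meanlog = meanlog, sdlog = max(sdlog, 0.05))
}

rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- rlnorm(50, meanlog, sdlog)
    x <- x[x >= lo & x <= hi]
    out[i] <- if (length(x)) x[1] else min(max(rlnorm(1, meanlog, sdlog), lo), hi)
  }
  out
}

# integer cell counts with expectations n * probs (largest-remainder rounding,
# randomised ties via a tiny jitter)
quota_counts <- function(n, probs) {
  exp <- n * probs / sum(probs)
  k <- floor(exp)
  rem <- n - sum(k)
  if (rem > 0) {
    frac <- exp - k + runif(length(exp)) * 1e-9
    k[order(frac, decreasing = TRUE)[seq_len(rem)]] <- k[order(
      frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  k
}

# sample() that never falls into the length-1 sample.int trap
resample <- function(x, k) x[sample.int(length(x), k)]

# pick round(n*p) +/- Bernoulli-remainder members of ids, uniformly at random
quota_pick <- function(ids, p) {
  n <- length(ids)
  if (!n || p <= 0) return(ids[0])
  target <- n * p
  k <- floor(target) + (runif(1) < target - floor(target))
  k <- min(k, n)
  if (k == 0) return(ids[0])
  resample(ids, k)
}

visit_schedule <- function(end_day, interval, jitter_sd) {
  days <- 0
  repeat {
    nxt <- days[length(days)] + max(30, rnorm(1, interval, jitter_sd))
    if (nxt >= end_day - 30) break
    days <- c(days, nxt)
  }
  round(days)
}

#' Generate a synthetic surveillance cohort
#'
#' Draws a full cohort — patients, labs, imaging, events — from a
#' [cohort_config()], together with the ground-truth labels each case was
#' generated with. The output passes [validate_cohort()] and is byte-stable
#' under a fixed seed.
#'
#' Each carcinoma case receives an intended CA19-9 trajectory pattern,
#' marker elevation flags, and feature-emergence times; marker series are
#' calibrated so that the classification rules trigger at the intended
#' times (an elevated measurement is documented exactly at the drawn onset,
#' emulating a symptom- or finding-prompted interim test).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; all randomness derives from it.
#' @return A list: `cohort` (a [surveillance_cohort()]) and `truth` (tibble
#'   of per-patient generating labels).
#' @export
generate_cohort <- function(config = cohort_config(), seed) {
  stopifnot(inherits(config, "cohort_config"), !missing(seed))
  withr::with_seed(as.integer(seed), generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_c <- cfg$n_carcinoma
  n_derived <- round(n_c * cfg$prop_derived)
  type <- c(rep("ipmn_derived", n_derived),
            rep("concomitant_pdac", n_c - n_derived))

  # clinical stage: quota per type
  stage <- character(n_c)
  for (ty in unique(type)) {
    idx <- which(type == ty)
    k <- quota_counts(length(idx), cfg$stage_probs[[ty]])
    stage[idx] <- sample(rep(STAGE_LEVELS, k))
  }
  stratum <- ifelse(stage %in% c("0", "I", "II"), "early", "late")

  # in-window CA19-9 availability, then intended trajectory pattern
  available <- logical(n_c)
  for (ty in unique(type)) {
    idx <- which(type == ty)
    available[quota_pick(idx, cfg$p_ca19_9_available[[ty]])] <- TRUE
  }
  pattern <- ifelse(available, "low_to_low", "insufficient_data")
  for (ty in unique(type)) for (st in c("early", "late")) {
    idx <- which(type == ty & stratum == st & available)
    pattern[quota_pick(idx, cfg$p_aberrant[[ty]][[st]])] <- "aberrant_elevation"
  }
  for (ty in unique(type)) {
    idx <- which(type == ty & available & pattern != "aberrant_elevation")
    pattern[quota_pick(idx, cfg$p_high_to_high[[ty]])] <- "high_to_high"
  }

  lewis <- logical(n_c)
  l2l <- which(pattern == "low_to_low")
  n_lewis <- min(length(l2l), round(cfg$lewis_negative_fraction * n_c))
  if (n_lewis > 0) lewis[resample(l2l, n_lewis)] <- TRUE

  hba1c_pos <- seq_len(n_c) %in% quota_pick(which(available), cfg$p_hba1c * n_c /
                                              max(sum(available), 1))
  enzyme_pos <- logical(n_c)
  for (ty in unique(type)) {
    idx <- which(type == ty & available)
    # quota computed on the full type size so the per-100 count matches
    target_k <- cfg$p_enzyme[[ty]] * sum(type == ty)
    enzyme_pos[quota_pick(idx, min(1, target_k / max(length(idx), 1)))] <- TRUE
  }
  enzyme_analyte <- ifelse(enzyme_pos,
                           sample(c("p_amylase", "lipase"), n_c, replace = TRUE),
                           NA_character_)

  hrs <- logical(n_c)
  for (ty in unique(type)) {
    idx <- which(type == ty)
    hrs[quota_pick(idx, cfg$p_hrs[[ty]])] <- TRUE
  }
  any_wf <- rep(TRUE, n_c)
  for (ty in unique(type)) {
    idx <- which(type == ty)
    n_neg <- length(idx) - round(length(idx) * cfg$p_any_wf_or_hrs[[ty]])
    if (n_neg > 0) {
      # the all-negative case must have no stigma and no marker-borne WF
      cand <- idx[!hrs[idx] & pattern[idx] %in%
                    c("low_to_low", "insufficient_data")]
      if (length(cand)) any_wf[resample(cand, min(n_neg, length(cand)))] <- FALSE
    }
  }
  ap_event <- logical(n_c)
  for (ty in unique(type)) {
    idx <- which(type == ty & any_wf)
    ap_event[quota_pick(idx, cfg$p_acute_pancreatitis[[ty]])] <- TRUE
  }

  # follow-up to diagnosis and lead times
  fu_rng <- cfg$followup_range_years
  t_dx <- rlnorm_trunc(n_c, cfg$followup_meanlog, cfg$followup_sdlog,
                       fu_rng[1], fu_rng[2])
  # an elevated-at-baseline pattern is only observable when the baseline
  # measurement predates the 1-year window
  t_dx[pattern == "high_to_high"] <- pmax(t_dx[pattern == "high_to_high"], 1.2)
  ca_lead <- rep(NA_real_, n_c)
  wf_lead <- rep(NA_real_, n_c)
  for (ty in unique(type)) {
    idx <- which(type == ty)
    ab <- idx[pattern[idx] == "aberrant_elevation"]
    if (length(ab)) {
      pr <- lnorm_from_quartiles(cfg$ca19_9_lead[[ty]])
      ca_lead[ab] <- pmin(rlnorm_trunc(length(ab), pr[1], pr[2], 0.02, 0.95),
                          t_dx[ab] - 0.1)
    }
    pr <- lnorm_from_quartiles(cfg$wf_lead[[ty]])
    wf_lead[idx] <- pmin(rlnorm_trunc(length(idx), pr[1], pr[2], 0.05, 24),
                         t_dx[idx] - 0.05)
  }

  origin <- as.Date("2005-01-01")
  baseline_date <- origin + sample.int(3000, n_c, replace = TRUE)

  # morphological realisation choices
  wf_item <- sample(c("mpd", "size", "nodule"), n_c, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
  hrs_item <- ifelse(type == "ipmn_derived",
                     sample(c("mpd10", "nodule5"), n_c, TRUE, c(0.7, 0.3)),
                     sample(c("mpd10", "nodule5"), n_c, TRUE, c(0.2, 0.8)))

  pats <- vector("list", n_c); labs <- vector("list", n_c)
  imgs <- vector("list", n_c); evts <- vector("list", n_c)
  truth <- vector("list", n_c)
  for (i in seq_len(n_c)) {
    sim <- simulate_case(
      pid = sprintf("P%04d", i), cfg = cfg,
      baseline_date = baseline_date[i], t_dx = t_dx[i],
      type = type[i], stage = stage[i], pattern = pattern[i],
      available = available[i], lewis = lewis[i],
      hba1c_pos = hba1c_pos[i], enzyme_pos = enzyme_pos[i],
      enzyme_analyte = enzyme_analyte[i],
      hrs = hrs[i], any_wf = any_wf[i], ap_event = ap_event[i],
      ca_lead = ca_lead[i], wf_lead = wf_lead[i],
      wf_item = wf_item[i], hrs_item = hrs_item[i])
    pats[[i]] <- sim$patient; labs[[i]] <- sim$labs
    imgs[[i]] <- sim$imaging; evts[[i]] <- sim$events
    truth[[i]] <- sim$truth
  }

  # carcinoma-free surveillance patients
  if (cfg$n_noncancer > 0) {
    for (j in seq_len(cfg$n_noncancer)) {
      i <- n_c + j
      sim <- simulate_noncancer(sprintf("P%04d", i), cfg,
                                origin + sample.int(3000, 1))
      pats[[i]] <- sim$patient; labs[[i]] <- sim$labs
      imgs[[i]] <- sim$imaging; evts[[i]] <- sim$events
      truth[[i]] <- sim$truth
    }
  }

  cohort <- surveillance_cohort(bind_rows(pats), bind_rows(labs),
                                bind_rows(imgs), bind_rows(evts))
  list(cohort = cohort, truth = bind_rows(truth))
}

draw_covariates <- function(cfg) {
  age <- min(max(rnorm(1, cfg$age_mean, cfg$age_sd), cfg$age_range[1]),
             cfg$age_range[2])
  list(age = round(age, 1),
       sex = if (runif(1) < cfg$p_male) "male" else "female",
       ipmn_type = sample(names(cfg$ipmn_type_probs), 1,
                          prob = cfg$ipmn_type_probs),
       smoking = if (runif(1) < cfg$p_smoking) "past_current" else "never",
       bmi = round(max(rnorm(1, cfg$bmi_mean, cfg$bmi_sd), 14), 1),
       diabetes = sample(names(cfg$diabetes_probs), 1,
                         prob = cfg$diabetes_probs),
       fh = runif(1) < cfg$p_family_history)
}

simulate_case <- function(pid, cfg, baseline_date, t_dx, type, stage,
                          pattern, available, lewis, hba1c_pos, enzyme_pos,
                          enzyme_analyte, hrs, any_wf, ap_event,
                          ca_lead, wf_lead, wf_item, hrs_item) {
  dx_day <- round(t_dx * DAYS_PER_YEAR)
  visit_days <- c(visit_schedule(dx_day, cfg$visit_interval_days,
                                 cfg$visit_jitter_sd_days), dx_day)
  cv <- cfg$marker_cv

  ## ---- CA19-9 -------------------------------------------------------------
  ca_days <- visit_days
  t_elev_day <- NA_real_
  if (pattern == "aberrant_elevation") {
    t_elev_day <- round(dx_day - ca_lead * DAYS_PER_YEAR)
    ca_days <- sort(unique(c(ca_days, t_elev_day)))
  }
  if (!available) ca_days <- ca_days[ca_days <= dx_day - 1.05 * DAYS_PER_YEAR]
  if (lewis) {
    ca_val <- runif(length(ca_days), 0.3, 0.95) * cfg$ca19_9_detection_limit
  } else if (pattern == "high_to_high") {
    sp <- max(rlnorm(1, cfg$ca19_9_high_setpoint[1],
                     cfg$ca19_9_high_setpoint[2]), 55)
    ca_val <- sp * exp(rnorm(length(ca_days), 0, cv))
    while (length(ca_val) && ca_val[1] <= 37 * 1.05) {
      ca_val[1] <- sp * exp(rnorm(1, 0, cv))
    }
    # a persistently elevated set-point fluctuates without ever doubling its
    # own running reference
    if (length(ca_val) > 1) {
      for (k in 2:length(ca_val)) {
        ca_val[k] <- min(ca_val[k], 1.8 * mean(ca_val[seq_len(k - 1)]))
      }
    }
  } else {
    sp <- min(rlnorm(1, cfg$ca19_9_setpoint[1], cfg$ca19_9_setpoint[2]), 20)
    ca_val <- sp * exp(rnorm(length(ca_days), 0, cv))
    if (pattern == "aberrant_elevation") {
      prior <- ca_days < t_elev_day
      ref <- if (any(prior)) mean(ca_val[prior]) else sp
      spike0 <- max(runif(1, 1.3, 3) * 37, 2.2 * ref)
      g <- runif(1, 0.5, 2)
      post <- ca_days >= t_elev_day
      ca_val[post] <- spike0 *
        exp(g * (ca_days[post] - t_elev_day) / DAYS_PER_YEAR) *
        exp(rnorm(sum(post), 0, 0.05))
      ca_val[which(post)[1]] <- spike0
    }
  }

  ## ---- HbA1c (stored as NGSP %) ------------------------------------------
  hb_days <- visit_days
  hb_sp <- min(max(rnorm(1, cfg$hba1c_mean_pct, cfg$hba1c_sd_pct), 5.2), 7.5)
  hb_val <- hb_sp + rnorm(length(hb_days), 0, cfg$hba1c_noise_mmol / 10.93)
  if (hba1c_pos) {
    t_h <- round(dx_day - runif(1, 0.05, min(0.8, t_dx - 0.05)) * DAYS_PER_YEAR)
    rise <- runif(1, 6, 15) / 10.93
    hb_val[hb_days >= t_h] <- hb_val[hb_days >= t_h] + rise
  }

  ## ---- pancreatic enzymes and total amylase ------------------------------
  enz <- function(par) {
    sp <- rlnorm(1, par[1], par[2])
    list(sp = sp, val = sp * exp(rnorm(length(visit_days), 0, cv)))
  }
  pam <- enz(cfg$p_amylase_setpoint)
  lip <- enz(cfg$lipase_setpoint)
  amy <- enz(cfg$amylase_setpoint)
  enz_days <- list(p_amylase = visit_days, lipase = visit_days)
  enz_vals <- list(p_amylase = pam$val, lipase = lip$val)
  if (enzyme_pos) {
    t_e <- round(dx_day - runif(1, 0.05, min(0.9, t_dx - 0.05)) * DAYS_PER_YEAR)
    uln <- if (enzyme_analyte == "p_amylase") 50 else 60
    d <- enz_days[[enzyme_analyte]]; v <- enz_vals[[enzyme_analyte]]
    if (!t_e %in% d) {
      sp <- if (enzyme_analyte == "p_amylase") pam$sp else lip$sp
      d <- c(d, t_e); v <- c(v, sp * exp(rnorm(1, 0, cv)))
      o <- order(d); d <- d[o]; v <- v[o]
    }
    at <- which(d == t_e)[1]
    ref <- if (at > 1) mean(v[seq_len(at - 1)]) else v[at]
    v[at] <- max(3.5 * uln, 2.2 * ref)
    enz_days[[enzyme_analyte]] <- d; enz_vals[[enzyme_analyte]] <- v
  }

  ## ---- imaging ------------------------------------------------------------
  s0 <- min(rlnorm(1, log(18), 0.25), 28)
  mpd0 <- runif(1, 1.5, 4.4)
  t_any_day <- round(dx_day - wf_lead * DAYS_PER_YEAR)
  # morphological WF: all derived cases; concomitant cases that need one for
  # the any-WF guarantee (no stigma and no CA19-9 above the ULN)
  morph_wf <- any_wf &&
    (type == "ipmn_derived" ||
       (!hrs && pattern %in% c("low_to_low", "insufficient_data")))
  t_wf_day <- if (morph_wf) t_any_day else NA_real_
  t_hrs_day <- if (hrs) {
    if (type == "ipmn_derived" && morph_wf) {
      round(t_any_day + runif(1, 0.2, 0.8) * (dx_day - t_any_day))
    } else t_any_day
  } else NA_real_
  img_days <- sort(unique(c(visit_days,
                            t_wf_day[!is.na(t_wf_day)],
                            t_hrs_day[!is.na(t_hrs_day)])))
  size <- s0 + rnorm(length(img_days), 0, 0.3)
  mpd <- pmax(mpd0 + rnorm(length(img_days), 0, 0.15), 0.5)
  nod <- rep("absent", length(img_days))
  if (morph_wf) {
    on <- img_days >= t_wf_day
    if (wf_item == "mpd") mpd[on] <- runif(1, 5.5, 8.5) +
        rnorm(sum(on), 0, 0.2)
    if (wf_item == "size") size[on] <- runif(1, 31, 40) +
        rnorm(sum(on), 0, 0.3)
    if (wf_item == "nodule") nod[on] <- "present_lt5mm_enhancing"
  }
  if (hrs) {
    on <- img_days >= t_hrs_day
    if (hrs_item == "mpd10") mpd[on] <- runif(1, 10.5, 14) +
        rnorm(sum(on), 0, 0.2)
    if (hrs_item == "nodule5") nod[on] <- "present_ge5mm_enhancing"
  }
  mpd <- round(pmin(pmax(mpd, 0.5), 20), 1)
  size <- round(pmin(pmax(size, 3), 120), 1)
  modality <- sample(MODALITIES, length(img_days), TRUE,
                     prob = c(0.6, 0.2, 0.15, 0.05))
  solid <- img_days == dx_day & type == "concomitant_pdac"

  ## ---- events, diagnosis, survival ---------------------------------------
  ev_days <- numeric(0); ev_kind <- character(0)
  if (ap_event) {
    ev_days <- c(ev_days, round(runif(1, 0.2, 0.9) * dx_day))
    ev_kind <- c(ev_kind, "acute_pancreatitis")
  }
  med <- cfg$survival_median_years[[stage]]
  surv_y <- rexp(1, rate = log(2) / med)
  cens_y <- runif(1, cfg$censor_range_years[1], cfg$censor_range_years[2])
  dead <- surv_y <= cens_y
  last_day <- dx_day + round(min(surv_y, cens_y) * DAYS_PER_YEAR)

  cov <- draw_covariates(cfg)
  location <- if (runif(1) < cfg$p_head_location[[type]]) "head" else
    "body_tail"

  patient <- tibble(
    patient_id = pid, baseline_date = baseline_date,
    age_at_baseline = cov$age, sex = cov$sex, ipmn_type = cov$ipmn_type,
    smoking = cov$smoking, bmi = cov$bmi, diabetes = cov$diabetes,
    family_history_pc = cov$fh,
    dx_date = baseline_date + dx_day, carcinoma_type = type,
    clinical_stage = stage, pathological_stage = NA_character_,
    location = location, last_date = baseline_date + last_day,
    status = if (dead) "dead" else "alive_censored")

  lab_tbl <- function(days, analyte, values, unit, det = NA_real_) {
    if (!length(days)) return(NULL)
    tibble(patient_id = pid, date = baseline_date + days, analyte = analyte,
           value = round(values, 1), unit = unit, detection_limit = det)
  }
  labs <- bind_rows(
    lab_tbl(ca_days, "ca19_9", ca_val, "U/mL", cfg$ca19_9_detection_limit),
    lab_tbl(hb_days, "hba1c", hb_val, "%"),
    lab_tbl(enz_days$p_amylase, "p_amylase", enz_vals$p_amylase, "U/L"),
    lab_tbl(enz_days$lipase, "lipase", enz_vals$lipase, "U/L"),
    lab_tbl(visit_days, "amylase", amy$val, "U/L"))

  imaging <- tibble(
    patient_id = pid, date = baseline_date + img_days, modality = modality,
    cyst_size_mm = size, mpd_diameter_mm = mpd, mural_nodule = nod,
    thickened_enhanced_wall = FALSE,
    abrupt_caliber_change_with_atrophy = FALSE,
    lymphadenopathy = FALSE, solid_mass_detected = solid)

  events <- if (length(ev_days)) {
    tibble(patient_id = pid, date = baseline_date + ev_days, kind = ev_kind)
  } else empty_events()

  truth <- tibble(
    patient_id = pid, group = "carcinoma", carcinoma_type = type,
    clinical_stage = stage, ca19_9_available = available,
    pattern_intended = pattern, ca19_9_lead_years = ca_lead,
    hba1c_intended = hba1c_pos, enzyme_intended = enzyme_pos,
    enzyme_analyte_intended = enzyme_analyte, hrs_intended = hrs,
    any_wf_or_hrs_intended = any_wf, wf_lead_years = wf_lead,
    lewis_negative = lewis, followup_to_dx_years = t_dx)

  list(patient = patient, labs = labs, imaging = imaging, events = events,
       truth = truth)
}

simulate_noncancer <- function(pid, cfg, baseline_date) {
  fu_rng <- cfg$followup_range_years
  t_fu <- rlnorm_trunc(1, cfg$followup_meanlog, cfg$followup_sdlog,
                       fu_rng[1], fu_rng[2])
  end_day <- round(t_fu * DAYS_PER_YEAR)
  visit_days <- c(visit_schedule(end_day, cfg$visit_interval_days,
                                 cfg$visit_jitter_sd_days), end_day)
  cv <- cfg$marker_cv
  sp <- min(rlnorm(1, cfg$ca19_9_setpoint[1], cfg$ca19_9_setpoint[2]), 20)
  hb_sp <- min(max(rnorm(1, cfg$hba1c_mean_pct, cfg$hba1c_sd_pct), 5.2), 7.5)
  pam_sp <- rlnorm(1, cfg$p_amylase_setpoint[1], cfg$p_amylase_setpoint[2])
  lip_sp <- rlnorm(1, cfg$lipase_setpoint[1], cfg$lipase_setpoint[2])
  cov <- draw_covariates(cfg)
  n <- length(visit_days)
  patient <- tibble(
    patient_id = pid, baseline_date = baseline_date,
    age_at_baseline = cov$age, sex = cov$sex, ipmn_type = cov$ipmn_type,
    smoking = cov$smoking, bmi = cov$bmi, diabetes = cov$diabetes,
    family_history_pc = cov$fh, dx_date = as.Date(NA),
    carcinoma_type = NA_character_, clinical_stage = NA_character_,
    pathological_stage = NA_character_, location = NA_character_,
    last_date = baseline_date + end_day, status = "alive_censored")
  labs <- bind_rows(
    tibble(patient_id = pid, date = baseline_date + visit_days,
           analyte = "ca19_9", value = round(sp * exp(rnorm(n, 0, cv)), 1),
           unit = "U/mL", detection_limit = cfg$ca19_9_detection_limit),
    tibble(patient_id = pid, date = baseline_date + visit_days,
           analyte = "hba1c",
           value = round(hb_sp + rnorm(n, 0, cfg$hba1c_noise_mmol / 10.93), 1),
           unit = "%", detection_limit = NA_real_),
    tibble(patient_id = pid, date = baseline_date + visit_days,
           analyte = "p_amylase", value = round(pam_sp * exp(rnorm(n, 0, cv)), 1),
           unit = "U/L", detection_limit = NA_real_),
    tibble(patient_id = pid, date = baseline_date + visit_days,
           analyte = "lipase", value = round(lip_sp * exp(rnorm(n, 0, cv)), 1),
           unit = "U/L", detection_limit = NA_real_))
  imaging <- tibble(
    patient_id = pid, date = baseline_date + visit_days,
    modality = sample(MODALITIES, n, TRUE, prob = c(0.6, 0.2, 0.15, 0.05)),
    cyst_size_mm = round(min(rlnorm(1, log(16), 0.25), 28) +
                           rnorm(n, 0, 0.3), 1),
    mpd_diameter_mm = round(pmax(runif(1, 1.5, 4.4) + rnorm(n, 0, 0.15),
                                 0.5), 1),
    mural_nodule = "absent", thickened_enhanced_wall = FALSE,
    abrupt_caliber_change_with_atrophy = FALSE, lymphadenopathy = FALSE,
    solid_mass_detected = FALSE)
  truth <- tibble(
    patient_id = pid, group = "noncancer", carcinoma_type = NA_character_,
    clinical_stage = NA_character_, ca19_9_available = TRUE,
    pattern_intended = NA_character_, ca19_9_lead_years = NA_real_,
    hba1c_intended = FALSE, enzyme_intended = FALSE,
    enzyme_analyte_intended = NA_character_, hrs_intended = FALSE,
    any_wf_or_hrs_intended = FALSE, wf_lead_years = NA_real_,
    lewis_negative = FALSE, followup_to_dx_years = NA_real_)
  list(patient = patient, labs = labs, imaging = imaging,
       events = empty_events(), truth = truth)
}
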