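# Independent brute-force oracles. These deliberately re-derive each rule
# with plain loops and repeated recomputation, sharing no code with the
# package implementation.

DPY <- 365.25

# --- CA19-9 trajectory rule, evaluated point by point ------------------------
oracle_classify_ca199 <- function(days, values, dx_day, uln = 37,
                                  window_years = 1) {
  keep <- !is.na(values) & days <= dx_day
  days <- days[keep]; values <- values[keep]
  o <- order(days); days <- days[o]; values <- values[o]
  n <- length(days)
  in_win <- function(i) days[i] > dx_day - window_years * DPY & days[i] <= dx_day
  if (n == 0 || !any(sapply(seq_len(n), in_win))) {
    return(list(pattern = "insufficient_data", first_day = NA))
  }
  cumavg <- function(i) if (i == 1) NA else mean(values[1:(i - 1)])
  qualifies <- function(i) {
    if (!in_win(i) || values[i] <= uln) return(FALSE)
    first_doc <- all(values[seq_len(i - 1)] <= uln) || i == 1
    ca <- cumavg(i)
    doubles <- !is.na(ca) && values[i] >= 2 * ca
    first_doc || doubles
  }
  for (i in seq_len(n)) {
    if (qualifies(i)) {
      return(list(pattern = "aberrant_elevation", first_day = days[i]))
    }
  }
  if (all(values <= uln)) return(list(pattern = "low_to_low", first_day = NA))
  dbl_in_win <- FALSE
  for (i in seq_len(n)) {
    ca <- cumavg(i)
    if (in_win(i) && !is.na(ca) && values[i] >= 2 * ca) dbl_in_win <- TRUE
  }
  if (values[1] > uln && !dbl_in_win) {
    return(list(pattern = "high_to_high", first_day = NA))
  }
  list(pattern = "residual_unclassified", first_day = NA)
}

# --- Fisher's exact test by full hypergeometric enumeration ------------------
oracle_fisher_2x2 <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- sapply(support, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  })
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- Wilcoxon rank-sum by full permutation enumeration -----------------------
oracle_wilcoxon_perm <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2  # Mann-Whitney U for x
  mu <- nx * ny / 2
  combos <- utils::combn(nx + ny, nx)
  stats <- apply(combos, 2, function(idx) {
    sum(ranks[idx]) - nx * (nx + 1) / 2
  })
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# --- morphology predicates, evaluated independently per visit ----------------
oracle_features_at <- function(visit_day, imaging, ca199, events, location,
                               uln = 37) {
  im <- imaging[imaging$day <= visit_day, , drop = FALSE]
  wf <- character(0); hrs <- character(0)
  if (nrow(im)) {
    cur <- im[nrow(im), ]
    if (!is.na(cur$cyst_size_mm) && cur$cyst_size_mm >= 30) {
      wf <- c(wf, "size_ge_30mm")
    }
    if (!is.na(cur$mural_nodule) &&
        cur$mural_nodule == "present_lt5mm_enhancing") {
      wf <- c(wf, "nodule_lt5mm_enhancing")
    }
    if (isTRUE(cur$thickened_enhanced_wall)) wf <- c(wf, "thickened_wall")
    if (!is.na(cur$mpd_diameter_mm) && cur$mpd_diameter_mm >= 5 &&
        cur$mpd_diameter_mm < 10) {
      wf <- c(wf, "mpd_5_to_9.9mm")
    }
    if (isTRUE(cur$abrupt_caliber_change_with_atrophy)) {
      wf <- c(wf, "abrupt_caliber_change_atrophy")
    }
    if (isTRUE(cur$lymphadenopathy)) wf <- c(wf, "lymphadenopathy")
    for (j in seq_len(nrow(im) - 1)) {
      ok <- im$day[nrow(im)] - im$day[j] <= 2 * DPY &&
        im$day[j] < im$day[nrow(im)] &&
        im$cyst_size_mm[nrow(im)] - im$cyst_size_mm[j] > 5
      if (isTRUE(ok)) wf <- union(wf, "growth_gt_5mm_per_2y")
    }
    if (!is.na(cur$mural_nodule) &&
        cur$mural_nodule == "present_ge5mm_enhancing") {
      hrs <- c(hrs, "enhancing_nodule_ge_5mm")
    }
    if (!is.na(cur$mpd_diameter_mm) && cur$mpd_diameter_mm >= 10) {
      hrs <- c(hrs, "mpd_ge_10mm")
    }
  }
  ca <- ca199[ca199$day <= visit_day, , drop = FALSE]
  if (nrow(ca) && ca$value[nrow(ca)] > uln) wf <- c(wf, "ca19_9_gt_37")
  ap <- events[events$kind == "acute_pancreatitis" &
                 events$day <= visit_day, , drop = FALSE]
  if (nrow(ap)) wf <- c(wf, "acute_pancreatitis")
  oj <- events[events$kind == "obstructive_jaundice" &
                 events$day <= visit_day, , drop = FALSE]
  if (nrow(oj) && !is.na(location) && location == "head") {
    hrs <- c(hrs, "obstructive_jaundice_head_lesion")
  }
  list(wf = sort(unique(wf)), hrs = sort(unique(hrs)))
}

# --- Kaplan-Meier with no censoring = empirical survival ---------------------
oracle_ecdf_surv <- function(times, at) {
  sapply(at, function(t) mean(times > t))
}

# --- log-rank O-E by direct tabulation ---------------------------------------
oracle_logrank_oe <- function(time, event, group) {
  gs <- sort(unique(group))
  oe <- setNames(numeric(length(gs)), gs)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    d <- sum(event == 1 & time == t)
    for (g in gs) {
      n_g <- sum(at_risk & group == g)
      d_g <- sum(event == 1 & time == t & group == g)
      oe[g] <- oe[g] + d_g - d * n_g / sum(at_risk)
    }
  }
  oe
}
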