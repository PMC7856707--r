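# Packaged name pools (no external downloads). The first block of each
# pool is reserved for surgical patients, the remainder for the
# non-surgical ICU population, so the two groups cannot collide on
# surname + forename. The surgical pool deliberately includes hyphenated
# and apostrophe forms: punctuation variants are a known source of
# duplicate linkage keys, and normalization must absorb them.
surname_pool <- c(
  "SMITH", "JONES", "WILLIAMS", "BROWN", "WILSON", "TAYLOR", "JOHNSON",
  "WHITE", "MARTIN", "ANDERSON", "THOMPSON", "NGUYEN", "THOMAS", "WALKER",
  "HARRIS", "LEE", "RYAN", "ROBINSON", "KELLY", "KING", "DAVIS", "WRIGHT",
  "EVANS", "ROBERTS", "GREEN", "HALL", "WOOD", "JACKSON", "CLARKE", "PATEL",
  "KHAN", "LEWIS", "JAMES", "PHILLIPS", "MASON", "MITCHELL", "ROSE", "DAVIES",
  "RODRIGUEZ", "COX", "ALEXANDER", "GARDEN", "CAMPBELL", "JOHNSTON", "MOORE",
  "SINGH", "SCOTT", "YOUNG", "ALLEN", "HILL", "O'BRIEN", "O'CONNOR",
  "MCDONALD", "SMITH-JONES", "TAYLOR-WOOD", "DE LA CRUZ", "VAN DER BERG",
  "ST CLAIR", "NG", "LIU", "CHEN", "WANG", "KUMAR", "TRAN", "PAPADOPOULOS",
  "KOVACS", "SILVA", "ROSSI", "MULLER", "SCHMIDT", "IVANOV", "DUBOIS",
  "FERRARI", "YAMAMOTO", "SATO", "KIM", "PARK", "ALI", "HUSSEIN", "ABDULLAH",
  "COHEN", "LEVI", "MURPHY", "BYRNE", "WALSH", "DOYLE", "BRENNAN", "LYNCH",
  "BURKE", "CARROLL", "DUNNE", "FLYNN", "KENNEDY", "MAGUIRE", "NOLAN",
  "QUINN", "REILLY", "SHEEHAN", "SWEENEY", "WHELAN",
  # -- non-surgical pool from here --
  "ADAMS", "BAKER", "BARNES", "BELL", "BENNETT", "BUTLER", "CARTER",
  "COLLINS", "COOK", "COOPER", "CRUZ", "DIAZ", "EDWARDS", "FISHER",
  "FOSTER", "GARCIA", "GIBSON", "GRANT", "GRAY", "HAMILTON", "HAYES",
  "HENDERSON", "HOWARD", "HUGHES", "HUNT", "JENKINS", "KNIGHT", "LANE",
  "LONG", "MARSHALL", "MILLS", "MORGAN", "MORRIS", "MURRAY", "OWEN",
  "PALMER", "PARKER", "PEARSON", "PERRY", "POWELL")

forename_pool_m <- c(
  "JOHN", "DAVID", "PETER", "MICHAEL", "JAMES", "ROBERT", "WILLIAM",
  "ANDREW", "STEPHEN", "PAUL", "MARK", "GEOFFREY", "IAN", "BRIAN", "KEVIN",
  "GREGORY", "ANTHONY", "COLIN", "BARRY", "NEIL", "WAYNE", "CRAIG", "SHANE",
  "TREVOR", "ALAN", "BRUCE", "NOEL", "TERENCE", "RONALD", "FRANCIS",
  "JO", "LI", "MINH", "RAJ", "OMAR", "CARLOS", "HENRI", "STEFAN", "PIETRO",
  "TOMAS",
  # -- non-surgical pool from here --
  "ADAM", "BENJAMIN", "CHARLES", "DANIEL", "EDWARD", "FREDERICK", "GEORGE",
  "HENRY", "ISAAC", "JOSEPH", "KENNETH", "LAWRENCE", "MATTHEW", "NICHOLAS",
  "OSCAR", "PATRICK", "RICHARD", "SAMUEL", "TIMOTHY", "VINCENT")

forename_pool_f <- c(
  "MARGARET", "SUSAN", "HELEN", "ELIZABETH", "PATRICIA", "JENNIFER",
  "CHRISTINE", "KAREN", "SANDRA", "JULIE", "ROBYN", "CHERYL", "WENDY",
  "DIANNE", "PAMELA", "JUDITH", "CAROL", "JANET", "HEATHER", "LORRAINE",
  "KERRY", "NARELLE", "LEANNE", "SHARON", "DEBORAH", "KATHLEEN", "MAREE",
  "JOAN", "BEVERLEY", "DENISE",
  "AN", "MEI", "PRIYA", "FATIMA", "MARIA", "ELENA", "INGRID", "SOFIA",
  "HANA", "AMIRA",
  # -- non-surgical pool from here --
  "ALICE", "BARBARA", "CATHERINE", "DOROTHY", "EMILY", "FRANCES", "GRACE",
  "HANNAH", "IRENE", "JESSICA", "KATE", "LAURA", "MARION", "NANCY",
  "OLIVIA", "PAULA", "RACHEL", "SARAH", "TERESA", "VALERIE")

# completed years between dob and a reference date
age_at <- function(dob, ref) {
  d <- as.POSIXlt(dob)
  r <- as.POSIXlt(ref)
  (r$year - d$year) - ((r$mon < d$mon) | (r$mon == d$mon & r$mday < d$mday))
}

add_years <- function(date, k) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year + k
  as.Date(lt)  # Feb 29 in a non-leap year normalizes to Mar 1
}

# dob uniform over the dates giving exactly `age` completed years at `ref`
dob_for_age <- function(age, ref) {
  hi <- add_years(ref, -age)            # youngest dob with this age
  lo <- add_years(ref, -(age + 1L)) + 1 # oldest
  span <- as.integer(hi - lo)
  lo + vapply(span, function(s) sample.int(s + 1L, 1L) - 1L, integer(1))
}

# single-character substitution at a random position
typo_name <- function(x) {
  vapply(x, function(nm) {
    if (is.na(nm) || nchar(nm) < 1) return(nm)
    pos <- sample.int(nchar(nm), 1)
    repl <- sample(LETTERS, 1)
    while (repl == toupper(substr(nm, pos, pos))) repl <- sample(LETTERS, 1)
    paste0(substr(nm, 1, pos - 1), repl, substr(nm, pos + 1, nchar(nm)))
  }, character(1), USE.NAMES = FALSE)
}

typo_digits <- function(x) {
  vapply(x, function(d) {
    if (is.na(d) || nchar(d) < 1) return(d)
    pos <- sample.int(nchar(d), 1)
    repl <- sample(0:9, 1)
    while (as.character(repl) == substr(d, pos, pos)) repl <- sample(0:9, 1)
    paste0(substr(d, 1, pos - 1), repl, substr(d, pos + 1, nchar(d)))
  }, character(1), USE.NAMES = FALSE)
}

# single-digit error in the DDMMYYYY rendering, resampled until the
# perturbed string is a valid calendar date different from the original
typo_date <- function(d) {
  as.Date(vapply(format(d, "%d%m%Y"), function(s) {
    repeat {
      cand <- typo_digits(s)
      parsed <- as.Date(cand, format = "%d%m%Y")
      if (!is.na(parsed)) return(format(parsed, "%Y-%m-%d"))
    }
  }, character(1), USE.NAMES = FALSE))
}

#' Cohort parameters for the synthetic dual registry
#'
#' Defaults reproduce the emulated registry population: 1283 surgical
#' procedures over April 2017 to December 2018 and enough non-surgical ICU
#' admissions to total about 5179 ICU episodes. Matchable ("clean")
#' patients draw their covariates from the matched-cohort summaries (age
#' mean 63.5, sd 12.7; 77.3% male; 22.0% urgent; procedure mix 56.6% CABG,
#' 15.1% valve, 7.5% combined, 20.1% other; 30-day risk of death median
#' 1.08%), while hard-to-match patients draw from the unmatched-cohort
#' summaries (age 53.6 sd 15.1; 80.5% male; 58.5% urgent; 26.8/17.1/4.9/
#' 51.2% procedure mix; risk median 7.50%). Risk of death is log-normal
#' with the log-scale spread chosen to reproduce the reported IQRs.
#'
#' @param n_surgery Number of surgical procedures.
#' @param n_icu_nonsurgical Number of non-surgical ICU admissions
#'   (default: 5179 minus the expected surgical ICU episodes).
#' @param age_mean_clean,age_sd_clean,age_mean_hard,age_sd_hard Age
#'   distributions (years) by stratum.
#' @param p_male_clean,p_male_hard Proportion male by stratum.
#' @param p_urgent_clean,p_urgent_hard Proportion urgent/emergent.
#' @param proc_probs_clean,proc_probs_hard Named probabilities over
#'   `CABG`, `valve`, `CABG+valve`, `other` (normalized internally).
#' @param risk_median_clean,risk_sdlog_clean,risk_median_hard,risk_sdlog_hard
#'   Log-normal risk-of-death parameters (medians as fractions).
#' @param start_date,end_date Procedure-date window (ISO strings or Dates).
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_surgery = 1283L,
                          n_icu_nonsurgical = 3842L,
                          age_mean_clean = 63.5, age_sd_clean = 12.7,
                          age_mean_hard = 53.6, age_sd_hard = 15.1,
                          p_male_clean = 0.773, p_male_hard = 0.805,
                          p_urgent_clean = 0.220, p_urgent_hard = 0.585,
                          proc_probs_clean = c(CABG = 0.566, valve = 0.151,
                                               `CABG+valve` = 0.0749,
                                               other = 0.201),
                          proc_probs_hard = c(CABG = 0.268, valve = 0.171,
                                              `CABG+valve` = 0.049,
                                              other = 0.512),
                          risk_median_clean = 0.0108, risk_sdlog_clean = 0.85,
                          risk_median_hard = 0.0750, risk_sdlog_hard = 1.77,
                          start_date = "2017-04-01", end_date = "2018-12-31") {
  p <- list(n_surgery = as.integer(n_surgery),
            n_icu_nonsurgical = as.integer(n_icu_nonsurgical),
            age_mean_clean = age_mean_clean, age_sd_clean = age_sd_clean,
            age_mean_hard = age_mean_hard, age_sd_hard = age_sd_hard,
            p_male_clean = p_male_clean, p_male_hard = p_male_hard,
            p_urgent_clean = p_urgent_clean, p_urgent_hard = p_urgent_hard,
            proc_probs_clean = proc_probs_clean / sum(proc_probs_clean),
            proc_probs_hard = proc_probs_hard / sum(proc_probs_hard),
            risk_median_clean = risk_median_clean,
            risk_sdlog_clean = risk_sdlog_clean,
            risk_median_hard = risk_median_hard,
            risk_sdlog_hard = risk_sdlog_hard,
            start_date = as.Date(start_date), end_date = as.Date(end_date))
  probs <- unlist(p[c("p_male_clean", "p_male_hard",
                      "p_urgent_clean", "p_urgent_hard")])
  if (any(probs < 0 | probs > 1)) stop("proportions must lie in [0, 1]",
                                       call. = FALSE)
  if (p$n_surgery < 1 || p$n_icu_nonsurgical < 0) {
    stop("cohort sizes must be positive", call. = FALSE)
  }
  structure(p, class = "cohort_params")
}

#' Error model for the synthetic dual registry
#'
#' Controls the data pathologies injected into the ICU copy of each
#' episode. Defaults are calibrated to the emulated registries: 47/5179 ICU
#' records with names and MRN blanked (SLK retained), 10/1283 surgical
#' procedures with no ICU episode at all, and 31/1273 whose ICU admission
#' precedes the procedure by more than 2 days. Typographical errors are
#' single-character (names) or single-digit (MRN, dates) substitutions.
#' `p_date_typo` applies per administrative date field (hospital
#' admission/discharge and ICU discharge on the ICU side); the ICU
#' admission date itself is never perturbed — it anchors the episode and
#' the emulated registries' date mismatches sat in the other date fields.
#' Date-of-birth errors get their own rate because they corrupt the
#' SLK-581 while administrative-date errors do not.
#'
#' Independent single-digit slips alone cannot reproduce the observed
#' failure pattern of staged matching, which loses records to errors in
#' *multiple* fields at once (mis-assigned stays, transfer confusion):
#' `p_multi_error` is the rate of that correlated process, under which
#' each administrative date field of the affected ICU record is corrupted
#' with high probability (0.85 per field). With every rate zero the two
#' registries agree exactly on all shared fields.
#'
#' @param p_missing_identity Fraction of ICU records with surname,
#'   forename and MRN blanked.
#' @param p_no_icu Fraction of surgery records with no ICU episode.
#' @param p_preop_icu Fraction (of the remainder) whose ICU admission
#'   precedes the procedure by more than the caliper.
#' @param p_name_typo Per name field (surname, forename) substitution rate.
#' @param p_dob_typo Per-record date-of-birth digit-error rate.
#' @param p_mrn_typo Per-record MRN digit-error rate.
#' @param p_date_typo Per administrative date field digit-error rate.
#' @param p_multi_error Per-record rate of correlated multi-field
#'   administrative-date corruption.
#' @param p_extra_icu Rate of an additional later ICU episode in the same
#'   hospital stay.
#' @param icu_delay_probs Probabilities of a 0-, 1- or 2-day delay from
#'   procedure to ICU admission.
#' @return An object of class `error_model`.
#' @export
error_model <- function(p_missing_identity = 47 / 5179,
                        p_no_icu = 10 / 1283,
                        p_preop_icu = 31 / 1273,
                        p_name_typo = 0.02,
                        p_dob_typo = 0.018,
                        p_mrn_typo = 0.01,
                        p_date_typo = 0.02,
                        p_multi_error = 0.055,
                        p_extra_icu = 0.05,
                        icu_delay_probs = c(`0` = 0.80, `1` = 0.15,
                                            `2` = 0.05)) {
  e <- list(p_missing_identity = p_missing_identity, p_no_icu = p_no_icu,
            p_preop_icu = p_preop_icu, p_name_typo = p_name_typo,
            p_dob_typo = p_dob_typo, p_mrn_typo = p_mrn_typo,
            p_date_typo = p_date_typo, p_multi_error = p_multi_error,
            p_extra_icu = p_extra_icu,
            icu_delay_probs = icu_delay_probs / sum(icu_delay_probs))
  rates <- unlist(e[setdiff(names(e), "icu_delay_probs")])
  if (any(rates < 0 | rates > 1)) {
    stop("error rates must lie in [0, 1]", call. = FALSE)
  }
  structure(e, class = "error_model")
}

#' An error-free model (all rates zero)
#'
#' Convenience constructor for the noiseless condition under which the two
#' registries agree exactly and every surgery record has one matching ICU
#' episode, so every strategy should recover the gold standard in full.
#'
#' @return An `error_model` with every rate 0.
#' @export
error_model_zero <- function() {
  error_model(p_missing_identity = 0, p_no_icu = 0, p_preop_icu = 0,
              p_name_typo = 0, p_dob_typo = 0, p_mrn_typo = 0,
              p_date_typo = 0, p_multi_error = 0, p_extra_icu = 0)
}

#' Generate a paired synthetic surgery/ICU registry with gold standard
#'
#' Builds a surgical cohort with per-stratum covariates, gives each
#' patient a hospital stay and (unless planted otherwise) a post-operative
#' ICU episode starting 0-2 days after the procedure, adds non-surgical
#' ICU admissions drawn from a disjoint name/MRN pool, and then corrupts
#' the ICU copy of each episode according to the error model. The SLK-581
#' on ICU records is always built from the identity *as recorded in the
#' ICU registry* (after typos), so key errors arise from upstream
#' name/date-of-birth errors and never by direct injection; identity
#' blanking happens after key construction, so blanked records keep their
#' key. Hard-to-match patients (those planted with no ICU episode or a
#' pre-operative ICU admission) draw their covariates from the
#' unmatched-cohort distributions.
#'
#' The gold standard maps each eligible surgery record to its
#' post-operative ICU episode; planted no-ICU and pre-operative-ICU
#' records have no gold partner and are labelled `hard`.
#'
#' @param params A [cohort_params()].
#' @param errors An [error_model()].
#' @param seed Integer seed; identical `(params, errors, seed)` give
#'   byte-identical registries.
#' @return A list with elements `surgery`, `icu` (registry data frames)
#'   and `gold` (`surgery_id`, `icu_id` — `NA` when no true partner —
#'   and `stratum`).
#' @export
generate_registries <- function(params = cohort_params(),
                                errors = error_model(),
                                seed = 1L) {
  stopifnot(inherits(params, "cohort_params"), inherits(errors, "error_model"))
  set.seed(seed)
  n <- params$n_surgery

  ## -- pathology / stratum assignment ------------------------------------
  no_icu <- stats::runif(n) < errors$p_no_icu
  preop <- !no_icu & stats::runif(n) < errors$p_preop_icu
  hard <- no_icu | preop
  pick <- function(clean_val, hard_val) ifelse(hard, hard_val, clean_val)

  ## -- covariates by stratum ---------------------------------------------
  sex <- ifelse(stats::runif(n) < pick(params$p_male_clean, params$p_male_hard),
                "M", "F")
  age <- round(stats::rnorm(n, pick(params$age_mean_clean, params$age_mean_hard),
                            pick(params$age_sd_clean, params$age_sd_hard)))
  age <- pmin(pmax(age, 18L), 95L)
  urgency <- ifelse(
    stats::runif(n) < pick(params$p_urgent_clean, params$p_urgent_hard),
    "urgent", "elective")
  proc_levels <- names(params$proc_probs_clean)
  ptype <- character(n)
  ptype[!hard] <- sample(proc_levels, sum(!hard), replace = TRUE,
                         prob = params$proc_probs_clean)
  ptype[hard] <- sample(proc_levels, sum(hard), replace = TRUE,
                        prob = params$proc_probs_hard)
  risk <- stats::rlnorm(n,
                        meanlog = log(pick(params$risk_median_clean,
                                           params$risk_median_hard)),
                        sdlog = pick(params$risk_sdlog_clean,
                                     params$risk_sdlog_hard))
  risk <- pmin(risk, 0.97)

  ## -- identity -----------------------------------------------------------
  surg_surnames <- surname_pool[1:100]
  surname <- sample(surg_surnames, n, replace = TRUE)
  forename <- character(n)
  forename[sex == "M"] <- sample(forename_pool_m[1:40], sum(sex == "M"),
                                 replace = TRUE)
  forename[sex == "F"] <- sample(forename_pool_f[1:40], sum(sex == "F"),
                                 replace = TRUE)
  mrn_all <- sprintf("%07d", sample(1000000:9999999,
                                    n + params$n_icu_nonsurgical))
  mrn <- mrn_all[seq_len(n)]

  ## -- episode dates -------------------------------------------------------
  date_pool <- seq(params$start_date, params$end_date, by = "day")
  proc_date <- sample(date_pool, n, replace = TRUE)
  adm_lead <- ifelse(urgency == "urgent",
                     sample(0:2, n, replace = TRUE),
                     sample(0:14, n, replace = TRUE))
  hosp_adm <- proc_date - adm_lead
  delay <- sample(0:2, n, replace = TRUE, prob = errors$icu_delay_probs)
  icu_adm <- proc_date + delay
  preop_lead <- sample(3:10, n, replace = TRUE)
  icu_adm[preop] <- proc_date[preop] - preop_lead[preop]
  hosp_adm[preop] <- icu_adm[preop] - sample(0:2, sum(preop), replace = TRUE)
  icu_los <- sample(1:5, n, replace = TRUE)
  icu_dis <- icu_adm + icu_los
  icu_dis[preop] <- proc_date[preop] + icu_los[preop]

  extra <- !no_icu & stats::runif(n) < errors$p_extra_icu
  icu2_adm <- icu_dis + sample(2:20, n, replace = TRUE)
  icu2_dis <- icu2_adm + sample(1:5, n, replace = TRUE)

  last_icu_dis <- icu_dis
  last_icu_dis[extra] <- icu2_dis[extra]
  hosp_dis <- last_icu_dis + sample(2:14, n, replace = TRUE)
  hosp_dis[no_icu] <- proc_date[no_icu] + sample(2:14, sum(no_icu),
                                                 replace = TRUE)

  dob <- dob_for_age(age, hosp_adm)
  age <- age_at(dob, hosp_adm)   # identical on both sides by construction

  ## -- identifiability guarantee -------------------------------------------
  # No two episodes may share the admission-insensitive five-field
  # signature (ICU discharge, hospital adm/dis, age, sex): within the
  # caliper the admission date cannot discriminate, so an exact duplicate
  # (including two surgical patients whose episodes differ only in the
  # post-operative delay) makes the gold pairing unrecoverable from
  # deidentified fields even on error-free data. Duplicated surgical
  # signatures get a resampled post-ICU stay.
  sig <- function(icu_d, hosp_a, hosp_d, ag, sx) {
    paste(icu_d, hosp_a, hosp_d, ag, sx, sep = "|")
  }
  surg_sig <- sig(icu_dis, hosp_adm, hosp_dis, age, sex)
  surg_sig[no_icu] <- NA
  for (iter in 1:25) {
    dup <- !is.na(surg_sig) & duplicated(surg_sig, incomparables = NA)
    if (!any(dup)) break
    hosp_dis[dup] <- last_icu_dis[dup] + sample(2:14, sum(dup), replace = TRUE)
    surg_sig <- sig(icu_dis, hosp_adm, hosp_dis, age, sex)
    surg_sig[no_icu] <- NA
  }
  extra_sig <- rep(NA_character_, n)
  extra_sig[extra] <- sig(icu2_dis[extra], hosp_adm[extra],
                          hosp_dis[extra], age[extra], sex[extra])
  for (iter in 1:25) {
    clash <- extra & extra_sig %in% stats::na.omit(surg_sig)
    if (!any(clash)) break
    icu2_adm[clash] <- icu_dis[clash] + sample(2:20, sum(clash), replace = TRUE)
    icu2_dis[clash] <- icu2_adm[clash] + sample(1:5, sum(clash), replace = TRUE)
    extra_sig[clash] <- sig(icu2_dis[clash], hosp_adm[clash],
                            hosp_dis[clash], age[clash], sex[clash])
  }
  taken_sig <- c(stats::na.omit(surg_sig), stats::na.omit(extra_sig))

  surgery <- data.frame(
    record_id = sprintf("S%04d", seq_len(n)),
    surname = surname, forename = forename, mrn = mrn, dob = dob, sex = sex,
    procedure_date = proc_date, hosp_adm_date = hosp_adm,
    hosp_dis_date = hosp_dis,
    icu_dis_date = as.Date(ifelse(!hard, icu_dis, NA), origin = "1970-01-01"),
    age = age, urgency = urgency, procedure_type = ptype,
    risk_of_death = round(risk, 5), stringsAsFactors = FALSE)
  class(surgery) <- c("surgery_registry", "data.frame")

  ## -- ICU episode rows (true values) --------------------------------------
  ep <- function(owner, surname, forename, mrn, dob, sex, icu_adm, icu_dis,
                 hosp_adm, hosp_dis) {
    data.frame(owner = owner, surname = surname, forename = forename,
               mrn = mrn, dob = dob, sex = sex, icu_adm_date = icu_adm,
               icu_dis_date = icu_dis, hosp_adm_date = hosp_adm,
               hosp_dis_date = hosp_dis, stringsAsFactors = FALSE)
  }
  has_ep <- !no_icu
  rows <- list(
    ep(surgery$record_id[has_ep], surname[has_ep], forename[has_ep],
       mrn[has_ep], dob[has_ep], sex[has_ep], icu_adm[has_ep],
       icu_dis[has_ep], hosp_adm[has_ep], hosp_dis[has_ep]))
  if (any(extra)) {
    rows <- c(rows, list(
      ep(NA_character_, surname[extra], forename[extra], mrn[extra],
         dob[extra], sex[extra], icu2_adm[extra], icu2_dis[extra],
         hosp_adm[extra], hosp_dis[extra])))
  }

  ## -- non-surgical ICU admissions (disjoint name/MRN pool) ----------------
  m <- params$n_icu_nonsurgical
  if (m > 0) {
    ns_sex <- ifelse(stats::runif(m) < 0.58, "M", "F")
    ns_age <- pmin(pmax(round(stats::rnorm(m, 62, 17)), 16L), 99L)
    ns_surname <- sample(surname_pool[101:length(surname_pool)], m,
                         replace = TRUE)
    ns_forename <- character(m)
    ns_forename[ns_sex == "M"] <-
      sample(forename_pool_m[41:length(forename_pool_m)],
             sum(ns_sex == "M"), replace = TRUE)
    ns_forename[ns_sex == "F"] <-
      sample(forename_pool_f[41:length(forename_pool_f)],
             sum(ns_sex == "F"), replace = TRUE)
    ns_mrn <- mrn_all[n + seq_len(m)]
    # Medical/non-surgical stays are long-tailed: many direct ICU admissions
    # but a heavy tail of ward deterioration before ICU and long recovery
    # after, unlike the tight post-operative cardiac pattern.
    ns_icu_adm <- sample(date_pool, m, replace = TRUE)
    ns_stay <- function(idx) {
      k <- length(idx)
      lead <- pmin(stats::rgeom(k, 0.2), 30L)
      los <- pmin(pmax(round(stats::rlnorm(k, log(3), 1.0)), 1L), 60L)
      post <- pmin(round(stats::rlnorm(k, log(7), 0.9)), 60L)
      list(hosp_adm = ns_icu_adm[idx] - lead,
           icu_dis = ns_icu_adm[idx] + los,
           hosp_dis = ns_icu_adm[idx] + los + post)
    }
    st <- ns_stay(seq_len(m))
    ns_hosp_adm <- st$hosp_adm
    ns_icu_dis <- st$icu_dis
    ns_hosp_dis <- st$hosp_dis
    for (iter in 1:25) {
      clash <- which(sig(ns_icu_dis, ns_hosp_adm, ns_hosp_dis,
                         ns_age, ns_sex) %in% taken_sig)
      if (!length(clash)) break
      st <- ns_stay(clash)
      ns_hosp_adm[clash] <- st$hosp_adm
      ns_icu_dis[clash] <- st$icu_dis
      ns_hosp_dis[clash] <- st$hosp_dis
    }
    ns_dob <- dob_for_age(ns_age, ns_hosp_adm)
    rows <- c(rows, list(
      ep(NA_character_, ns_surname, ns_forename, ns_mrn, ns_dob, ns_sex,
         ns_icu_adm, ns_icu_dis, ns_hosp_adm, ns_hosp_dis)))
  }
  icu <- do.call(rbind, rows)

  ## -- error processes on the ICU copy --------------------------------------
  k <- nrow(icu)
  hosp_adm_true <- icu$hosp_adm_date
  tn1 <- stats::runif(k) < errors$p_name_typo
  tn2 <- stats::runif(k) < errors$p_name_typo
  tdob <- stats::runif(k) < errors$p_dob_typo
  tmrn <- stats::runif(k) < errors$p_mrn_typo
  if (any(tn1)) icu$surname[tn1] <- typo_name(icu$surname[tn1])
  if (any(tn2)) icu$forename[tn2] <- typo_name(icu$forename[tn2])
  if (any(tdob)) icu$dob[tdob] <- typo_date(icu$dob[tdob])
  if (any(tmrn)) icu$mrn[tmrn] <- typo_digits(icu$mrn[tmrn])
  multi <- stats::runif(k) < errors$p_multi_error
  for (col in c("icu_dis_date", "hosp_adm_date", "hosp_dis_date")) {
    td <- stats::runif(k) < errors$p_date_typo
    td <- td | (multi & stats::runif(k) < 0.85)
    if (any(td)) icu[[col]][td] <- typo_date(icu[[col]][td])
  }
  icu$age <- age_at(icu$dob, hosp_adm_true)
  icu$slk <- build_slk(icu$surname, icu$forename, icu$dob, icu$sex)
  icu$slk[is.na(icu$slk)] <- ""
  blank <- stats::runif(k) < errors$p_missing_identity
  icu$surname[blank] <- ""
  icu$forename[blank] <- ""
  icu$mrn[blank] <- ""

  ## -- shuffle episode order, assign ids, build gold standard ---------------
  perm <- sample.int(k)
  icu <- icu[perm, , drop = FALSE]
  icu$record_id <- sprintf("I%05d", seq_len(k))
  gold_map <- icu$record_id[match(surgery$record_id, icu$owner)]
  gold_map[hard] <- NA_character_
  icu$owner <- NULL
  icu <- icu[icu_columns]
  rownames(icu) <- NULL
  class(icu) <- c("icu_registry", "data.frame")

  gold <- data.frame(surgery_id = surgery$record_id,
                     icu_id = gold_map,
                     stratum = ifelse(hard, "hard", "clean"),
                     stringsAsFactors = FALSE)
  list(surgery = surgery, icu = icu, gold = gold)
}
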