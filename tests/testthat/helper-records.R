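# One-row record builders for hand-constructed linkage scenarios.

make_surgery <- function(record_id = "S1", surname = "CITIZEN",
                         forename = "JOHN", mrn = "1234567",
                         dob = as.Date("1955-03-10"), sex = "M",
                         procedure_date = as.Date("2018-06-10"),
                         hosp_adm_date = procedure_date - 2,
                         hosp_dis_date = procedure_date + 12,
                         icu_dis_date = procedure_date + 3,
                         age = 63L, urgency = "elective",
                         procedure_type = "CABG", risk_of_death = 0.011) {
  data.frame(record_id = record_id, surname = surname, forename = forename,
             mrn = mrn, dob = dob, sex = sex,
             procedure_date = procedure_date, hosp_adm_date = hosp_adm_date,
             hosp_dis_date = hosp_dis_date, icu_dis_date = icu_dis_date,
             age = age, urgency = urgency, procedure_type = procedure_type,
             risk_of_death = risk_of_death, stringsAsFactors = FALSE)
}

# By default the ICU record mirrors a surgery record built with the same
# arguments: admission on the procedure date, same stay, SLK built from
# the same identity.
make_icu <- function(record_id = "I1", surname = "CITIZEN",
                     forename = "JOHN", mrn = "1234567",
                     dob = as.Date("1955-03-10"), sex = "M",
                     icu_adm_date = as.Date("2018-06-10"),
                     icu_dis_date = icu_adm_date + 3,
                     hosp_adm_date = icu_adm_date - 2,
                     hosp_dis_date = icu_adm_date + 12,
                     age = 63L,
                     slk = build_slk(surname, forename, dob, sex)) {
  slk[is.na(slk)] <- ""
  data.frame(record_id = record_id, surname = surname, forename = forename,
             mrn = mrn, dob = dob, sex = sex, slk = slk,
             icu_adm_date = icu_adm_date, icu_dis_date = icu_dis_date,
             hosp_adm_date = hosp_adm_date, hosp_dis_date = hosp_dis_date,
             age = age, stringsAsFactors = FALSE)
}

rbind_records <- function(...) do.call(rbind, list(...))

# small cohort for fast generator-based tests
small_params <- function(n_surgery = 150L, n_icu_nonsurgical = 400L, ...) {
  cohort_params(n_surgery = n_surgery, n_icu_nonsurgical = n_icu_nonsurgical,
                ...)
}
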