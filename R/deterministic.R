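stage_fields_all <- c("SLK", "ICUAdmDt", "ICUDisDt", "HospAdmDt",
                      "HospDisDt", "Age", "Sex")
stage_date_fields <- c("ICUAdmDt", "ICUDisDt", "HospAdmDt", "HospDisDt")

# The two shipped stage hierarchies. The right-hand plan uses the six
# non-identifying variables over 9 sequential stages; the left-hand plan
# adds SLK-581 and runs 12 stages. ICUAdmDt on the surgery side is the
# procedure date. Stage 1 of each plan requires exact agreement; every
# later stage applies the loosened +/-2 day / +/-2 year criteria.
shipped_plans <- function() {
  s2 <- list(
    c("ICUAdmDt", "ICUDisDt", "HospAdmDt", "HospDisDt", "Age", "Sex"),
    c("ICUAdmDt", "ICUDisDt", "HospAdmDt", "HospDisDt", "Age"),
    c("ICUAdmDt", "ICUDisDt", "HospAdmDt", "HospDisDt", "Sex"),
    c("ICUAdmDt", "ICUDisDt", "HospAdmDt", "Age", "Sex"),
    c("ICUAdmDt", "ICUDisDt", "HospDisDt", "Age", "Sex"),
    c("ICUAdmDt", "HospAdmDt", "HospDisDt", "Age", "Sex"),
    c("ICUDisDt", "HospAdmDt", "HospDisDt", "Age", "Sex"),
    c("ICUAdmDt", "ICUDisDt", "HospAdmDt", "HospDisDt"),
    c("ICUAdmDt", "ICUDisDt", "HospAdmDt"))
  s4 <- list(
    c("SLK", "ICUAdmDt", "ICUDisDt", "HospAdmDt", "HospDisDt", "Age", "Sex"),
    c("SLK", "ICUAdmDt", "ICUDisDt", "HospAdmDt"),
    c("SLK", "ICUAdmDt", "ICUDisDt"),
    c("SLK", "ICUAdmDt"),
    c("ICUAdmDt", "ICUDisDt", "HospAdmDt", "HospDisDt", "Age", "Sex"),
    c("ICUAdmDt", "ICUDisDt", "HospAdmDt", "HospDisDt", "Age"),
    c("ICUAdmDt", "ICUDisDt", "HospAdmDt", "HospDisDt", "Sex"),
    c("SLK", "ICUAdmDt", "ICUDisDt", "HospAdmDt", "HospDisDt", "Sex"),
    c("SLK", "ICUAdmDt", "ICUDisDt", "HospAdmDt", "Age", "Sex"),
    c("SLK", "ICUAdmDt", "ICUDisDt", "HospDisDt", "Age", "Sex"),
    c("SLK", "ICUAdmDt", "HospAdmDt", "HospDisDt", "Age", "Sex"),
    c("SLK", "ICUDisDt", "HospAdmDt", "HospDisDt", "Age", "Sex"))
  list(strategy2 = s2, strategy4 = s4)
}

#' Staged deterministic matching plans
#'
#' Returns one of the two shipped sequential matching hierarchies:
#' `"strategy2"` (9 stages over the six non-identifying variables — ICU
#' admission/procedure date, ICU discharge date, hospital admission and
#' discharge dates, age, sex) or `"strategy4"` (the same variables plus
#' SLK-581, 12 stages). Stage 1 requires exact agreement on every field;
#' all later stages apply the configured tolerances.
#'
#' A custom plan can be built by passing a list of character vectors as
#' `stages` (field names from `SLK, ICUAdmDt, ICUDisDt, HospAdmDt,
#' HospDisDt, Age, Sex`) together with a logical `tolerant` vector.
#'
#' @param name `"strategy2"` or `"strategy4"` (ignored when `stages` given,
#'   except as the plan label).
#' @param stages Optional list of field vectors for a custom plan.
#' @param tolerant Optional logical vector, one flag per stage; default:
#'   stage 1 exact, later stages tolerant.
#' @return An object of class `stage_plan`.
#' @export
stage_plan <- function(name = c("strategy2", "strategy4"),
                       stages = NULL, tolerant = NULL) {
  if (is.null(stages)) {
    name <- match.arg(name)
    stages <- shipped_plans()[[name]]
  } else {
    name <- if (length(name)) name[1] else "custom"
  }
  if (!length(stages)) stop("a plan needs at least one stage", call. = FALSE)
  for (f in stages) {
    bad <- setdiff(f, stage_fields_all)
    if (length(bad)) stop("unknown stage field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (!length(f)) stop("empty stage field set", call. = FALSE)
  }
  if (is.null(tolerant)) tolerant <- c(FALSE, rep(TRUE, length(stages) - 1))
  stopifnot(length(tolerant) == length(stages))
  specs <- lapply(seq_along(stages), function(k) {
    list(stage_number = k, required_fields = stages[[k]], tolerant = tolerant[k])
  })
  structure(list(name = name, stages = specs), class = "stage_plan")
}

#' @export
print.stage_plan <- function(x, ...) {
  cat(sprintf("Stage plan '%s' (%d stages)\n", x$name, length(x$stages)))
  for (st in x$stages) {
    cat(sprintf("  %2d. %s%s\n", st$stage_number,
                paste(st$required_fields, collapse = " "),
                if (st$tolerant) "  [+/- tolerance]" else "  [exact]"))
  }
  invisible(x)
}

# Comparison frames for staged matching. Surgery-side ICUAdmDt is the
# procedure date; surgery-side ICUDisDt is the recorded post-operative ICU
# discharge (may be NA, in which case any stage requiring it fails).
surgery_stage_side <- function(surgery) {
  slk <- if (!is.null(surgery$slk)) surgery$slk else
    build_slk(surgery$surname, surgery$forename, surgery$dob, surgery$sex)
  slk[is.na(slk)] <- ""
  data.frame(record_id = surgery$record_id, SLK = slk,
             ICUAdmDt = surgery$procedure_date,
             ICUDisDt = surgery$icu_dis_date,
             HospAdmDt = surgery$hosp_adm_date,
             HospDisDt = surgery$hosp_dis_date,
             Age = surgery$age, Sex = surgery$sex,
             stringsAsFactors = FALSE)
}

icu_stage_side <- function(icu) {
  slk <- icu$slk
  slk[is.na(slk)] <- ""
  data.frame(record_id = icu$record_id, SLK = slk,
             ICUAdmDt = icu$icu_adm_date,
             ICUDisDt = icu$icu_dis_date,
             HospAdmDt = icu$hosp_adm_date,
             HospDisDt = icu$hosp_dis_date,
             Age = icu$age, Sex = icu$sex,
             stringsAsFactors = FALSE)
}

# Vectorized agreement over aligned row subsets of the two stage frames.
# A field missing on either side fails the stage for that pair.
# ICUAdmDt is a cross-field comparison (ICU admission date vs procedure
# date) with an intrinsic 0-2 day post-operative offset, so it always
# carries at least the caliper; the exact/loosened distinction applies to
# the fields where both registries record the same quantity.
stage_agree_rows <- function(s, i, fields, tolerant, cfg) {
  ok <- rep(TRUE, nrow(s))
  dtol <- if (tolerant) cfg$date_tolerance_days else 0L
  atol <- if (tolerant) cfg$age_tolerance_years else 0L
  for (f in fields) {
    fi <- if (f %in% stage_date_fields) {
      tol_f <- if (f == "ICUAdmDt") max(dtol, cfg$caliper_days) else dtol
      delta <- as.integer(i[[f]] - s[[f]])
      !is.na(delta) & abs(delta) <= tol_f
    } else if (f == "Age") {
      delta <- i$Age - s$Age
      !is.na(delta) & abs(delta) <= atol
    } else if (f == "Sex") {
      !is.na(s$Sex) & !is.na(i$Sex) & s$Sex == i$Sex
    } else { # SLK
      slk_agree(s$SLK, i$SLK) == "agree"
    }
    ok <- ok & fi
  }
  ok
}

# Total discrepancy of an agreeing pair over the stage's fields: days for
# date fields, years for age; agreeing sex/SLK contribute 0. Used to
# resolve within-stage ambiguity by closest agreement.
stage_discrepancy_rows <- function(s, i, fields) {
  d <- numeric(nrow(s))
  for (f in fields) {
    if (f %in% stage_date_fields) {
      d <- d + abs(as.integer(i[[f]] - s[[f]]))
    } else if (f == "Age") {
      d <- d + abs(i$Age - s$Age)
    }
  }
  d
}

#' Does a record pair agree at one matching stage?
#'
#' A pair agrees when every field the stage requires agrees: date fields
#' exactly, or within the configured \eqn{\pm} day tolerance at a loosened
#' stage; age exactly or within the year tolerance; sex exactly; SLK-581
#' by exact key comparison. `ICUAdmDt` compares the ICU admission date
#' with the procedure date, a cross-field comparison with an intrinsic
#' post-operative offset, so it always allows at least the caliper (2
#' days) even at the tight first stage. A field missing on either side
#' fails the stage.
#'
#' @param s One-row surgery registry data frame.
#' @param i One-row ICU registry data frame.
#' @param stage A single stage spec from a [stage_plan()] (a list with
#'   `required_fields` and `tolerant`).
#' @param cfg A [link_config()] supplying the tolerances.
#' @return `TRUE` or `FALSE`.
#' @export
stage_agree <- function(s, i, stage, cfg = link_config()) {
  stopifnot(nrow(s) == 1, nrow(i) == 1)
  stage_agree_rows(surgery_stage_side(s), icu_stage_side(i),
                   stage$required_fields, isTRUE(stage$tolerant), cfg)
}

# Candidate generation for one stage: block on ICUAdmDt if the stage uses
# it, else the first required date field, else the SLK. Date blocking joins
# the surgery-side date expanded by the stage tolerance.
stage_candidates <- function(s, i, fields, tolerant, cfg) {
  dates_here <- intersect(stage_date_fields, fields)
  block <- if ("ICUAdmDt" %in% fields) "ICUAdmDt"
           else if (length(dates_here)) dates_here[1]
           else "SLK"
  if (block == "SLK") {
    s_ok <- which(s$SLK != "")
    i_ok <- which(i$SLK != "")
    cand <- merge(data.frame(s_idx = s_ok, key = s$SLK[s_ok]),
                  data.frame(i_idx = i_ok, key = i$SLK[i_ok]), by = "key")
  } else {
    tol <- if (tolerant) cfg$date_tolerance_days else 0L
    if (block == "ICUAdmDt") tol <- max(tol, cfg$caliper_days)
    offsets <- seq(-tol, tol)
    s_ok <- which(!is.na(s[[block]]))
    i_ok <- which(!is.na(i[[block]]))
    s_exp <- data.frame(
      s_idx = rep(s_ok, each = length(offsets)),
      key = as.integer(rep(s[[block]][s_ok], each = length(offsets))) +
            rep(offsets, length(s_ok)))
    cand <- merge(s_exp,
                  data.frame(i_idx = i_ok, key = as.integer(i[[block]][i_ok])),
                  by = "key")
  }
  cand[c("s_idx", "i_idx")]
}

#' Sequential staged deterministic linkage
#'
#' Runs the plan's stages in order over the records not yet matched. At
#' each stage all agreeing (surgery, ICU) pairs are formed; a pair is
#' accepted only when it is unambiguously the best at that stage: for both
#' of its records it must be the unique agreeing pair of strictly smallest
#' total discrepancy (summed day/year differences over the stage's
#' fields). A record whose agreeing counterparts tie — in particular, two
#' records identical in every stage field — is deferred, not dropped: it
#' stays available for later (more discriminating or differently
#' composed) stages. A record accepted at stage *k* is excluded from every
#' later stage, and the result is one-to-one overall; per-pair provenance
#' records the accepting stage.
#'
#' @param surgery Surgery registry data frame.
#' @param icu ICU registry data frame.
#' @param plan A [stage_plan()].
#' @param cfg A [link_config()] supplying the loosened-stage tolerances.
#' @return A `linkage_result` whose `pairs$stage` records the accepting
#'   stage number.
#' @export
run_stages <- function(surgery, icu, plan, cfg = link_config()) {
  stopifnot(inherits(plan, "stage_plan"),
            !anyDuplicated(surgery$record_id), !anyDuplicated(icu$record_id))
  s <- surgery_stage_side(surgery)
  i <- icu_stage_side(icu)
  s_free <- rep(TRUE, nrow(s))
  i_free <- rep(TRUE, nrow(i))
  acc <- list()

  for (st in plan$stages) {
    if (!any(s_free) || !any(i_free)) break
    s_idx_map <- which(s_free)
    i_idx_map <- which(i_free)
    s_sub <- s[s_idx_map, , drop = FALSE]
    i_sub <- i[i_idx_map, , drop = FALSE]
    cand <- stage_candidates(s_sub, i_sub, st$required_fields,
                             isTRUE(st$tolerant), cfg)
    if (!nrow(cand)) next
    ok <- stage_agree_rows(s_sub[cand$s_idx, , drop = FALSE],
                           i_sub[cand$i_idx, , drop = FALSE],
                           st$required_fields, isTRUE(st$tolerant), cfg)
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) next
    # accept a pair only if it is the strict closest-agreement minimum for
    # both of its records; ties (e.g. exact twins) defer to later stages
    D <- stage_discrepancy_rows(s_sub[cand$s_idx, , drop = FALSE],
                                i_sub[cand$i_idx, , drop = FALSE],
                                st$required_fields)
    min_s <- stats::ave(D, cand$s_idx, FUN = min)
    min_i <- stats::ave(D, cand$i_idx, FUN = min)
    at_min_s <- D == min_s
    at_min_i <- D == min_i
    n_min_s <- stats::ave(at_min_s, cand$s_idx, FUN = sum)
    n_min_i <- stats::ave(at_min_i, cand$i_idx, FUN = sum)
    uniq <- at_min_s & at_min_i & n_min_s == 1 & n_min_i == 1
    cand <- cand[uniq, , drop = FALSE]
    if (!nrow(cand)) next
    sg <- s_idx_map[cand$s_idx]
    ig <- i_idx_map[cand$i_idx]
    acc[[length(acc) + 1]] <- data.frame(
      surgery_id = s$record_id[sg], icu_id = i$record_id[ig],
      method = plan$name, stage = st$stage_number, stringsAsFactors = FALSE)
    s_free[sg] <- FALSE
    i_free[ig] <- FALSE
  }

  pairs <- if (length(acc)) do.call(rbind, acc) else
    data.frame(surgery_id = character(), icu_id = character(),
               method = character(), stage = integer(), stringsAsFactors = FALSE)
  linkage_result(pairs, s$record_id, i$record_id, plan$name)
}
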