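# EMR-driven cohort construction: labeling pathways and exclusion filters.
# The labels mirror clinical practice for sickle cell admissions: ACS is a
# new pulmonary infiltrate on chest imaging together with fever or
# respiratory symptoms; an infiltrate or consolidation without the full
# symptom picture is a complicated vaso-occlusive crisis; an uncomplicated
# VOC (clean imaging, no scarring) is acoustically healthy-like and joins
# the healthy pool.

#' Chest-imaging findings that lower sound transmission
#' @export
ATTENUATING_FINDINGS <- c("pleural_effusion", "consolidation", "scarring",
                          "infiltrate")

#' Findings with no expected effect on sound transmission
#' @export
NON_ATTENUATING_FINDINGS <- c("atelectasis", "cardiomegaly",
                              "vascular_congestion", "hyperinflation",
                              "clear")

#' Findings with a mixed effect on sound transmission
#'
#' Ground-glass opacity can be predominantly interstitial (little effect)
#' or more consolidative (attenuating), so its acoustic effect varies by
#' subject.
#' @export
MIXED_FINDINGS <- c("ground_glass_opacity")

finding_vocabulary <- function() {
  c(ATTENUATING_FINDINGS, NON_ATTENUATING_FINDINGS, MIXED_FINDINGS)
}

check_findings <- function(findings) {
  findings <- findings[nzchar(findings)]
  unknown <- setdiff(findings, finding_vocabulary())
  if (length(unknown) > 0) {
    stop("unknown finding name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  findings
}

#' EMR-style subject record
#'
#' @param subject_id identifier
#' @param bmi body-mass index in kg/m^2 (> 0)
#' @param stethoscope recording device: `eko`, `littmann`, or `other`
#' @param cxr_performed was chest imaging performed
#' @param cxr_findings character vector of finding names from the
#'   configured vocabulary (empty for clean imaging)
#' @param fever,respiratory_symptoms,chest_pain symptom flags
#' @param voc_admission admitted for a vaso-occlusive crisis
#' @param scarring known pulmonary scarring
#' @return an object of class `subject_record`
#' @export
subject_record <- function(subject_id, bmi, stethoscope = "eko",
                           cxr_performed = FALSE, cxr_findings = character(),
                           fever = FALSE, respiratory_symptoms = FALSE,
                           chest_pain = FALSE, voc_admission = FALSE,
                           scarring = FALSE) {
  check_that(is.numeric(bmi) && bmi > 0, "bmi", "must be > 0")
  check_that(stethoscope %in% c("eko", "littmann", "other"), "stethoscope",
             "must be eko, littmann or other")
  cxr_findings <- check_findings(cxr_findings)
  structure(
    list(subject_id = subject_id, bmi = bmi, stethoscope = stethoscope,
         cxr_performed = cxr_performed, cxr_findings = cxr_findings,
         fever = fever, respiratory_symptoms = respiratory_symptoms,
         chest_pain = chest_pain, voc_admission = voc_admission,
         scarring = scarring),
    class = "subject_record"
  )
}

#' Assign a study label to a subject
#'
#' The labeling pathway, in priority order:
#' \itemize{
#'   \item \strong{acs}: infiltrate-bearing imaging together with fever or
#'     respiratory symptoms (the clinical ACS definition);
#'   \item \strong{voc_complicated}: infiltrate or consolidation present
#'     without the full symptom set — excluded from the healthy pool;
#'   \item \strong{voc_uncomplicated}: VOC admission with clean or no
#'     imaging and no scarring — acoustically healthy-like, eligible for
#'     the healthy pool;
#'   \item \strong{healthy}: no infiltrate, consolidation or scarring.
#' }
#' Scarring alone never yields a healthy label (it attenuates sound
#' transmission); such subjects are labeled `voc_complicated` if admitted
#' for VOC and `excluded` otherwise.
#'
#' @param rec a [subject_record()]
#' @param symptom_rule how the ACS symptom requirement combines fever and
#'   respiratory symptoms: `"or"` (default) or `"and"`
#' @param followup_label optional later clinical diagnosis that overrides
#'   the admission pathway (supports retrospective reclassification of a
#'   complicated VOC that developed into ACS); default `NULL` = off
#' @return list with `label` (one of `healthy`, `acs`, `voc_uncomplicated`,
#'   `voc_complicated`, `excluded`) and `exclusion_reason` (non-`NA` iff
#'   excluded)
#' @export
classify_subject <- function(rec, symptom_rule = c("or", "and"),
                             followup_label = NULL) {
  stopifnot(inherits(rec, "subject_record"))
  symptom_rule <- match.arg(symptom_rule)
  if (!is.null(followup_label)) {
    check_that(followup_label %in% STUDY_LABELS, "followup_label",
               "must be a study label")
    return(list(label = followup_label, exclusion_reason = NA_character_))
  }
  findings <- check_findings(rec$cxr_findings)
  has_infiltrate <- any(c("infiltrate", "consolidation") %in% findings)
  symptoms <- if (symptom_rule == "or") {
    rec$fever || rec$respiratory_symptoms
  } else {
    rec$fever && rec$respiratory_symptoms
  }
  has_scarring <- rec$scarring || "scarring" %in% findings

  label <- if (has_infiltrate && symptoms) {
    "acs"
  } else if (has_infiltrate) {
    "voc_complicated"
  } else if (has_scarring) {
    # never healthy; scarring attenuates transmission
    if (rec$voc_admission) "voc_complicated" else "excluded"
  } else if (rec$voc_admission) {
    "voc_uncomplicated"
  } else {
    "healthy"
  }
  list(label = label,
       exclusion_reason = if (label == "excluded") {
         "pulmonary scarring outside a VOC admission"
       } else NA_character_)
}

#' Apply the technical exclusion filters to a roster
#'
#' Drops subjects with BMI strictly greater than 30 (excess soft tissue
#' damps the transmitted chirp below a usable amplitude; BMI exactly 30 is
#' retained) and subjects recorded with any stethoscope other than the Eko
#' (different devices have incompatible response dynamics, which would bias
#' a quantitative comparison). Order-preserving and idempotent.
#'
#' @param records list of [subject_record()]s
#' @return list with `retained` (list of records) and `exclusion_log`
#'   (data.frame subject_id, reason; one row per dropped record)
#' @export
apply_exclusions <- function(records) {
  reasons <- vapply(records, function(r) {
    if (r$bmi > 30) {
      sprintf("BMI %.1f > 30", r$bmi)
    } else if (r$stethoscope != "eko") {
      sprintf("recorded with %s stethoscope", r$stethoscope)
    } else {
      NA_character_
    }
  }, character(1))
  keep <- is.na(reasons)
  log <- data.frame(
    subject_id = vapply(records[!keep], `[[`, character(1), "subject_id"),
    reason = reasons[!keep], stringsAsFactors = FALSE)
  list(retained = records[keep], exclusion_log = log)
}

#' Acoustic effect class of a chest-imaging finding
#'
#' Pleural effusion, consolidation, infiltrate and scarring are expected to
#' lower sound transmission through the affected lung; ground-glass opacity
#' is mixed (subject-dependent); the remaining vocabulary has no expected
#' effect.
#'
#' @param finding a finding name from the configured vocabulary
#' @param attenuating,non_attenuating,mixed the vocabulary lists
#'   (configurable)
#' @return one of `"attenuating"`, `"non_attenuating"`, `"mixed"`
#' @export
finding_attenuation_class <- function(finding,
                                      attenuating = ATTENUATING_FINDINGS,
                                      non_attenuating = NON_ATTENUATING_FINDINGS,
                                      mixed = MIXED_FINDINGS) {
  if (finding %in% attenuating) return("attenuating")
  if (finding %in% mixed) return("mixed")
  if (finding %in% non_attenuating) return("non_attenuating")
  stop("unknown finding name: ", finding, call. = FALSE)
}

#' Read subject records from CSV
#'
#' Expects columns matching the [subject_record()] fields, with
#' `cxr_findings` semicolon-joined.
#'
#' @param path CSV file path
#' @return list of [subject_record()]s
#' @export
read_subject_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    findings <- if (is.na(df$cxr_findings[i]) || !nzchar(df$cxr_findings[i])) {
      character()
    } else {
      strsplit(df$cxr_findings[i], ";")[[1]]
    }
    subject_record(
      subject_id = df$subject_id[i], bmi = df$bmi[i],
      stethoscope = df$stethoscope[i],
      cxr_performed = isTRUE(as.logical(df$cxr_performed[i])),
      cxr_findings = findings,
      fever = isTRUE(as.logical(df$fever[i])),
      respiratory_symptoms = isTRUE(as.logical(df$respiratory_symptoms[i])),
      chest_pain = isTRUE(as.logical(df$chest_pain[i])),
      voc_admission = isTRUE(as.logical(df$voc_admission[i])),
      scarring = isTRUE(as.logical(df$scarring[i])))
  })
}
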