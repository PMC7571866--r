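subj <- function(id = "S1", bmi = 24, ...) subject_record(id, bmi, ...)

test_that("the labeling pathway assigns each clinical picture its label", {
  # infiltrate + symptoms = ACS
  expect_equal(classify_subject(subj(cxr_performed = TRUE,
                                     cxr_findings = "infiltrate",
                                     fever = TRUE,
                                     respiratory_symptoms = TRUE))$label,
               "acs")
  # infiltrate without symptoms = complicated VOC
  expect_equal(classify_subject(subj(cxr_performed = TRUE,
                                     cxr_findings = "infiltrate"))$label,
               "voc_complicated")
  expect_equal(classify_subject(subj(cxr_performed = TRUE,
                                     cxr_findings = "consolidation",
                                     fever = FALSE))$label,
               "voc_complicated")
  # VOC admission with clean imaging = uncomplicated, healthy-pool eligible
  expect_equal(classify_subject(subj(voc_admission = TRUE))$label,
               "voc_uncomplicated")
  # no findings, no admission = healthy
  expect_equal(classify_subject(subj())$label, "healthy")
  # scarring is never healthy
  expect_equal(classify_subject(subj(scarring = TRUE,
                                     voc_admission = TRUE))$label,
               "voc_complicated")
  out <- classify_subject(subj(scarring = TRUE))
  expect_equal(out$label, "excluded")
  expect_false(is.na(out$exclusion_reason))
  # stricter symptom rule demands fever AND respiratory symptoms
  expect_equal(classify_subject(subj(cxr_findings = "infiltrate",
                                     fever = TRUE),
                                symptom_rule = "and")$label,
               "voc_complicated")
  # retrospective follow-up diagnosis overrides the admission pathway
  expect_equal(classify_subject(subj(cxr_findings = "infiltrate"),
                                followup_label = "acs")$label, "acs")
})

test_that("classification is total and safe over random records", {
  set.seed(30)
  vocab <- c(ATTENUATING_FINDINGS, NON_ATTENUATING_FINDINGS, MIXED_FINDINGS)
  for (i in 1:200) {
    r <- subject_record(
      sprintf("R%d", i), bmi = runif(1, 16, 40),
      stethoscope = sample(c("eko", "littmann", "other"), 1),
      cxr_performed = sample(c(TRUE, FALSE), 1),
      cxr_findings = sample(vocab, sample(0:3, 1)),
      fever = sample(c(TRUE, FALSE), 1),
      respiratory_symptoms = sample(c(TRUE, FALSE), 1),
      voc_admission = sample(c(TRUE, FALSE), 1),
      scarring = sample(c(TRUE, FALSE), 1))
    out <- classify_subject(r)
    expect_true(out$label %in% c(STUDY_LABELS, "excluded"))
    expect_equal(is.na(out$exclusion_reason), out$label != "excluded")
    # safety: nothing with infiltrate/consolidation/scarring is healthy
    if (out$label %in% c("healthy", "voc_uncomplicated")) {
      expect_false(any(c("infiltrate", "consolidation", "scarring")
                       %in% r$cxr_findings))
      expect_false(r$scarring)
    }
  }
})

test_that("an 11-subject ACS roster with 3 above BMI 30 retains 8", {
  roster <- c(
    lapply(1:3, function(i) subj(sprintf("A%d", i), bmi = 30 + i)),
    lapply(4:11, function(i) subj(sprintf("A%d", i), bmi = 22 + i %% 5)))
  out <- apply_exclusions(roster)
  expect_length(out$retained, 8)
  expect_equal(nrow(out$exclusion_log), 3)
  expect_true(all(grepl("BMI", out$exclusion_log$reason)))
})

test_that("exclusion boundaries and devices behave as documented", {
  # BMI exactly 30 is retained (the rule is strictly greater)
  out <- apply_exclusions(list(subj(bmi = 30), subj(bmi = 30.1)))
  expect_length(out$retained, 1)
  expect_equal(out$retained[[1]]$bmi, 30)
  # non-Eko devices are all dropped and logged
  littmann <- lapply(1:4, function(i)
    subj(sprintf("L%d", i), stethoscope = "littmann"))
  out2 <- apply_exclusions(littmann)
  expect_length(out2$retained, 0)
  expect_equal(nrow(out2$exclusion_log), 4)
  # idempotent and order-preserving
  mixed <- c(littmann[1], list(subj("K1"), subj("K2", bmi = 35), subj("K3")))
  once <- apply_exclusions(mixed)
  twice <- apply_exclusions(once$retained)
  expect_identical(once$retained, twice$retained)
  expect_identical(vapply(once$retained, `[[`, character(1), "subject_id"),
                   c("K1", "K3"))
})

test_that("findings map to their acoustic effect classes", {
  expect_equal(finding_attenuation_class("consolidation"), "attenuating")
  expect_equal(finding_attenuation_class("pleural_effusion"), "attenuating")
  expect_equal(finding_attenuation_class("scarring"), "attenuating")
  expect_equal(finding_attenuation_class("ground_glass_opacity"), "mixed")
  expect_equal(finding_attenuation_class("atelectasis"), "non_attenuating")
  expect_error(finding_attenuation_class("pneumothorax_misnamed"),
               "unknown finding")
  expect_error(subject_record("X", 22, cxr_findings = "bogus_finding"),
               "unknown finding")
})

test_that("subject CSV round-trips through the record constructor", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(
    subject_id = c("P1", "P2"), bmi = c(24, 33),
    stethoscope = c("eko", "littmann"), cxr_performed = c(TRUE, FALSE),
    cxr_findings = c("infiltrate;consolidation", ""),
    fever = c(TRUE, FALSE), respiratory_symptoms = c(TRUE, FALSE),
    chest_pain = FALSE, voc_admission = FALSE, scarring = FALSE),
    tmp, row.names = FALSE)
  recs <- read_subject_csv(tmp)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$cxr_findings, c("infiltrate", "consolidation"))
  expect_equal(classify_subject(recs[[1]])$label, "acs")
  expect_length(apply_exclusions(recs)$retained, 1)
})
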