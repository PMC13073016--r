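#!/usr/bin/env Rscript
# Regenerates the bundled instrument configurations and the published
# consensus table under inst/extdata/ from the published medians.
# Run from the repository root: Rscript tools/make-instruments.R

library(jsonlite)

grid4 <- c(0, 0.33, 0.67, 1)
grid3 <- c(0, 0.5, 1)

opt <- function(labels, values) {
  lapply(seq_along(labels), function(i) {
    list(label = labels[i], severity_rank = i - 1L, value = values[i])
  })
}

# item catalogue; severity_rank 0 is always the clinically optimal answer
# (note the trough-satisfaction options are listed worst-first in the source
# questionnaire; here they are encoded in clinical direction)
items <- list(
  trough_sat = list(
    id = "trough_sat",
    text = "Based on the patient's needs and the current prophylaxis regimen, how satisfactory is the obtained trough level?",
    scale_size = 4L,
    options = opt(c("Very satisfactory", "Quite satisfactory",
                    "Not very satisfactory", "Not at all satisfactory"), grid4),
    bucketing_rule = "trough_satisfaction"
  ),
  abr = list(
    id = "abr",
    text = "What is the annualized bleeding rate (ABR)?",
    scale_size = 4L,
    options = opt(c("Total ABR 0", "Total ABR 1-2", "Total ABR 3-4",
                    "Total ABR >= 5"), grid4),
    bucketing_rule = "abr"
  ),
  pj_count = list(
    id = "pj_count",
    text = "How many Problem Joints (PJs) does the patient currently present with?",
    scale_size = 4L,
    options = opt(c("None", "1", "2-3", ">= 4"), grid4),
    bucketing_rule = "pj_count"
  ),
  pj_trend = list(
    id = "pj_trend",
    text = "Since the start of the current treatment, the PJs have",
    scale_size = 3L,
    options = opt(c("Absent or decreased", "Remained stable", "Increased"), grid3),
    bucketing_rule = "pj_trend"
  ),
  tj_count = list(
    id = "tj_count",
    text = "How many Target Joints (TJs) does the patient currently present with?",
    scale_size = 3L,
    options = opt(c("None", "1", ">= 2"), grid3),
    bucketing_rule = "tj_count"
  ),
  tj_trend = list(
    id = "tj_trend",
    text = "Since the start of the current treatment, the TJs have",
    scale_size = 3L,
    options = opt(c("Absent or decreased", "Remained stable", "Increased"), grid3),
    bucketing_rule = "tj_trend"
  ),
  hjhs_change = list(
    id = "hjhs_change",
    text = "Since the last assessment, how has the clinical evaluation of the patient's joint status changed?",
    scale_size = 3L,
    options = opt(c("Improved or remained approximately unchanged (at most +1 point)",
                    "Moderately worsened (+2/+3 points)",
                    "Significantly worsened (+4 points)"), grid3),
    bucketing_rule = "hjhs_delta"
  ),
  headus_change = list(
    id = "headus_change",
    text = "Since the last assessment, how has the ultrasound evaluation of the patient's joint status changed?",
    scale_size = 3L,
    options = opt(c("Improved or remained unchanged",
                    "Moderately worsened (+1 point)",
                    "Significantly worsened (+2 points or more)"), grid3),
    bucketing_rule = "headus_delta"
  ),
  ajbr = list(
    id = "ajbr",
    text = "What is the annualized joint bleeding rate (AJBR)?",
    scale_size = 4L,
    options = opt(c("Total AJBR 0", "Total AJBR 1", "Total AJBR 2",
                    "Total AJBR >= 3"), grid4),
    bucketing_rule = "ajbr"
  ),
  adherence = list(
    id = "adherence",
    text = "How would you rate your patient's adherence to the prophylactic treatment?",
    scale_size = 3L,
    options = opt(c("Very satisfactory (>90%)",
                    "Satisfactory (between 80% and 90%)",
                    "Poorly satisfactory (<80%)"), grid3),
    bucketing_rule = "adherence"
  ),
  qol_current = list(
    id = "qol_current",
    text = "How would you assess your patient's current Quality of Life (QoL)?",
    scale_size = 4L,
    options = opt(c("Very satisfactory (5-6 points)",
                    "Moderately satisfactory (7-11 points)",
                    "Poorly satisfactory (12-18 points)",
                    "Not at all satisfactory (19-25 points)"), grid4),
    bucketing_rule = "lss_current"
  ),
  qol_change = list(
    id = "qol_change",
    text = "Since the last assessment, how would you evaluate your patient's Quality of Life (QoL)?",
    scale_size = 3L,
    options = opt(c("Improved or remained unchanged",
                    "Slightly worsened (+1/+2 points)",
                    "Significantly worsened (+3 points or more)"), grid3),
    bucketing_rule = "lss_change"
  )
)

with_weight <- function(id, w) {
  it <- items[[id]]
  list(id = it$id, text = it$text, scale_size = it$scale_size,
       weight_pct = w, options = it$options, bucketing_rule = it$bucketing_rule)
}

domain <- function(name, W, item_weights) {
  list(id = name, name = name, weight_pct = W,
       items = mapply(with_weight, names(item_weights), unname(item_weights),
                      SIMPLIFY = FALSE, USE.NAMES = FALSE))
}

joint_prophylaxis <- c("pj_count", "pj_trend", "tj_count", "tj_trend",
                       "hjhs_change", "headus_change", "ajbr")
joint_on_demand <- c("pj_count", "tj_count", "hjhs_change", "headus_change", "ajbr")
adhqol_prophylaxis <- c("adherence", "qol_current", "qol_change")

configs <- list(
  haemophilia_B_prophylaxis = list(
    disease = "B", setting = "prophylaxis",
    provenance = "Published round-2 consensus medians (haemophilia B, prophylaxis)",
    domains = list(
      domain("pharmacokinetics", 18, c(trough_sat = 100)),
      domain("bleeding_episodes", 32, c(abr = 100)),
      domain("joint_health", 27, setNames(c(13, 13, 13, 14, 15, 19, 13),
                                          joint_prophylaxis)),
      domain("adherence_qol", 23, setNames(c(32, 32, 36), adhqol_prophylaxis))
    )
  ),
  haemophilia_A_prophylaxis = list(
    disease = "A", setting = "prophylaxis",
    provenance = "Published round-2 consensus medians (haemophilia A, prophylaxis)",
    domains = list(
      domain("pharmacokinetics", 19, c(trough_sat = 100)),
      domain("bleeding_episodes", 31, c(abr = 100)),
      domain("joint_health", 29, setNames(c(11, 15, 12, 17, 15, 17, 13),
                                          joint_prophylaxis)),
      domain("adherence_qol", 21, setNames(c(33, 32, 35), adhqol_prophylaxis))
    )
  ),
  haemophilia_B_on_demand = list(
    disease = "B", setting = "on_demand",
    provenance = "Published round-2 consensus medians (haemophilia B, on-demand)",
    domains = list(
      domain("bleeding_episodes", 40, c(abr = 100)),
      domain("joint_health", 35, setNames(c(18, 19, 20, 26, 17), joint_on_demand)),
      domain("adherence_qol", 25, c(qol_current = 100))
    )
  ),
  haemophilia_A_on_demand = list(
    disease = "A", setting = "on_demand",
    provenance = "Published round-2 consensus medians (haemophilia A, on-demand)",
    domains = list(
      domain("bleeding_episodes", 38, c(abr = 100)),
      domain("joint_health", 37, setNames(c(18, 19, 23, 22, 18), joint_on_demand)),
      domain("adherence_qol", 25, c(qol_current = 100))
    )
  )
)

dir.create("inst/extdata/instruments", recursive = TRUE, showWarnings = FALSE)
for (nm in names(configs)) {
  path <- file.path("inst/extdata/instruments", paste0(nm, ".json"))
  write_json(configs[[nm]], path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cat("wrote", path, "\n")
}

# published per-slot consensus medians and IQRs (domain level and, for
# multi-item domains, item level) — 44 entries in total
cons <- local({
  row <- function(disease, setting, scope, slot, med, iqr) {
    data.frame(disease = disease, setting = setting, scope = scope,
               slot_id = slot, median_pct = med, iqr = iqr,
               stringsAsFactors = FALSE)
  }
  dnames4 <- c("pharmacokinetics", "bleeding_episodes", "joint_health",
               "adherence_qol")
  dnames3 <- c("bleeding_episodes", "joint_health", "adherence_qol")
  rbind(
    row("B", "prophylaxis", "domain", dnames4, c(18, 32, 27, 23), c(4, 2, 3, 6)),
    row("A", "prophylaxis", "domain", dnames4, c(19, 31, 29, 21),
        c(5.5, 4.5, 4.75, 3.25)),
    row("B", "on_demand", "domain", dnames3, c(40, 35, 25), c(0, 2, 6)),
    row("A", "on_demand", "domain", dnames3, c(38, 37, 25), c(5.5, 2.5, 6)),
    row("B", "prophylaxis", "items:joint_health", joint_prophylaxis,
        c(13, 13, 13, 14, 15, 19, 13), c(2, 2, 5, 1, 3, 3, 4)),
    row("B", "prophylaxis", "items:adherence_qol", adhqol_prophylaxis,
        c(32, 32, 36), c(5, 1, 2)),
    row("A", "prophylaxis", "items:joint_health", joint_prophylaxis,
        c(11, 15, 12, 17, 15, 17, 13), c(5.25, 3, 3.25, 4.25, 3.5, 3.5, 5)),
    row("A", "prophylaxis", "items:adherence_qol", adhqol_prophylaxis,
        c(33, 32, 35), c(4, 3.75, 1.75)),
    row("B", "on_demand", "items:joint_health", joint_on_demand,
        c(18, 19, 20, 26, 17), c(1, 3, 4, 3, 5)),
    row("A", "on_demand", "items:joint_health", joint_on_demand,
        c(18, 19, 23, 22, 18), c(3.25, 2.75, 5.25, 4, 7))
  )
})
stopifnot(nrow(cons) == 44L)
write.csv(cons, "inst/extdata/published_consensus.csv", row.names = FALSE)
cat("wrote inst/extdata/published_consensus.csv (", nrow(cons), "entries )\n")
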