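# Endpoint identifiers modeled by the life table (order used in outputs).
CVD_ENDPOINTS <- c(
  "coronary_heart_disease", "heart_failure", "valvular_heart_disease",
  "other_cardiac", "stroke"
)
SC_ENDPOINTS <- c("lung_cancer", "breast_cancer", "esophageal_cancer")
MODELED_ENDPOINTS <- c(CVD_ENDPOINTS, SC_ENDPOINTS)
OTHER_CAUSE <- "all_other_causes"

# DoseSummary metric columns in the cohort schema.
DOSE_METRICS <- c(
  "whole_heart", "left_ventricle", "aortic_valve", "mitral_valve",
  "tricuspid_valve", "carotid_arteries", "lungs", "breast", "esophagus",
  "normal_tissue"
)
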