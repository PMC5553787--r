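# Shared fixtures, built in code at load time.

LEX <- default_lexicon()

# Hand-written two-patient extraction + patient tables with known answers.
# P1 LAD: two Xience stents (28+10 mm, diameters 3.0/2.5), balloon, TVR at
#   day 400. P1 RCA: one Nobori, no event, censored by last contact day 500.
# P2 LAD: one Cypher, no event, last contact beyond the 730-day window.
toy_extraction <- function() {
  data.frame(
    report_id = c("r1", "r1", "r1", "r2"),
    patient_id = c("p1", "p1", "p1", "p2"),
    procedure_date = c("2011-01-01", "2011-01-01", "2011-01-01", "2012-06-01"),
    vessel = c("LAD", "LAD", "RCA", "LAD"),
    brand_family = c("Xience family", "Xience family", "Nobori", "Cypher"),
    device_class = c("DES", "DES", "DES", "DES"),
    generation = c("second", "second", "second", "first"),
    polymer = c("durable", "durable", "biodegradable", "none"),
    stent_class = c("DES2-DP", "DES2-DP", "DES2-BP", "DES1"),
    diameter_mm = c(3.0, 2.5, 2.75, 3.5),
    length_mm = c(28, 10, 18, 23),
    char_start = NA_integer_, char_end = NA_integer_,
    noncompliant_balloon = c(TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

toy_patients <- function() {
  list(
    demographics = data.frame(
      patient_id = c("p1", "p2"),
      birth_date = c("1951-01-01", "1940-06-01"),
      sex = c("M", "F"),
      last_contact = c("2012-05-15", "2014-12-31"),  # p1: day 500
      stringsAsFactors = FALSE),
    diagnoses = data.frame(
      patient_id = c("p1", "p2"),
      code = c("I10", "E11.9"),
      date = c("2010-06-01", "2012-01-01"),
      stringsAsFactors = FALSE),
    prescriptions = data.frame(
      patient_id = c("p1", "p1", "p2"),
      drug_class = c("aspirin", "clopidogrel", "aspirin"),
      start = c("2011-01-01", "2011-01-01", "2012-06-01"),
      end = c("2012-06-01", "2011-11-01", "2013-06-01"),
      stringsAsFactors = FALSE),
    procedures = data.frame(
      patient_id = c("p1", "p1", "p1", "p2"),
      date = c("2011-01-01", "2011-01-01", "2012-02-05", "2012-06-01"),
      vessel = c("LAD", "RCA", "LAD", "LAD"),
      approach = c("radial", "radial", "femoral", "femoral"),
      emergent = c(FALSE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE))
}

# Small rendered corpus with lexicon-covered noise only, cached per options.
clean_synthetic <- function(n_patients = 100, seed = 42, typo_rate = 0,
                            variant_rate = 0.3, decoy_rate = 0.2) {
  cfg <- generator_config(n_patients = n_patients, seed = seed,
                          variant_rate = variant_rate, typo_rate = typo_rate,
                          decoy_rate = decoy_rate)
  truth <- generate_cohort(cfg)
  list(truth = truth, corpus = render_reports(truth), config = cfg)
}

# Independent log-rank oracle: explicit observed-minus-expected sums over the
# risk sets, no survival-package calls.
logrank_by_hand <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

pair_frac_recalled <- function(pred, gold, report_ids) {
  cc <- confusion_counts(pred, gold, report_ids = report_ids)
  metrics(cc)
}
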