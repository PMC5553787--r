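#' Default warehouse configuration
#'
#' Drug-class membership and derivation rules used when assembling vessel
#' episodes. Drug classes are plain labels matched against the prescription
#' table's `drug_class` column, so sites can remap them without code changes.
#' The follow-up window is 730 days (2 years) and "DAPT over 12 months"
#' means at least 365 days of overlapping aspirin and P2Y12 coverage.
#'
#' @return A named list of configuration values.
#' @export
warehouse_config <- function() {
  list(window_days = 730,
       dapt_over_days = 365,
       htn_code = "I10",
       dm_code_prefix = "E11",
       antihypertensive = c("acei", "arb", "beta_blocker", "ccb",
                            "thiazide", "diuretic"),
       aspirin = "aspirin",
       p2y12 = c("clopidogrel", "prasugrel", "ticagrelor"),
       antidiabetic = c("metformin", "sulfonylurea", "insulin",
                        "dpp4_inhibitor"))
}

as_date <- function(x) if (inherits(x, "Date")) x else as.Date(x)

#' Derive the hypertension covariate
#'
#' True iff the ICD-10 code I10 was assigned on or before the index date, or
#' at least one antihypertensive-class prescription started on or before it.
#'
#' @param diagnoses Data.frame with `code`, `date` (this patient's rows).
#' @param prescriptions Data.frame with `drug_class`, `start`.
#' @param index_date Index PCI date.
#' @param config See [warehouse_config()].
#' @return Logical scalar.
#' @export
derive_hypertension <- function(diagnoses, prescriptions, index_date,
                                config = warehouse_config()) {
  index_date <- as_date(index_date)
  by_code <- nrow(diagnoses) > 0 &&
    any(diagnoses$code == config$htn_code & as_date(diagnoses$date) <= index_date)
  by_drug <- nrow(prescriptions) > 0 &&
    any(prescriptions$drug_class %in% config$antihypertensive &
          as_date(prescriptions$start) <= index_date)
  isTRUE(by_code) || isTRUE(by_drug)
}

#' Derive the diabetes covariate (simplified code-or-drug phenotype)
#'
#' True iff a type 2 diabetes diagnosis code (prefix E11) was assigned on or
#' before the index date, or at least one antidiabetic prescription started
#' on or before it. This is a deliberately simple phenotype; the rule's code
#' prefix and drug classes are configurable.
#'
#' @inheritParams derive_hypertension
#' @return Logical scalar.
#' @export
derive_diabetes <- function(diagnoses, prescriptions, index_date,
                            config = warehouse_config()) {
  index_date <- as_date(index_date)
  by_code <- nrow(diagnoses) > 0 &&
    any(startsWith(diagnoses$code, config$dm_code_prefix) &
          as_date(diagnoses$date) <= index_date)
  by_drug <- nrow(prescriptions) > 0 &&
    any(prescriptions$drug_class %in% config$antidiabetic &
          as_date(prescriptions$start) <= index_date)
  isTRUE(by_code) || isTRUE(by_drug)
}

union_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  keep_s <- numeric(); keep_e <- numeric()
  for (i in seq_along(start)) {
    if (length(keep_s) && start[i] <= keep_e[length(keep_e)]) {
      keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], end[i])
    } else {
      keep_s <- c(keep_s, start[i]); keep_e <- c(keep_e, end[i])
    }
  }
  list(start = keep_s, end = keep_e)
}

#' Derive dual antiplatelet therapy duration
#'
#' DAPT days are the total number of post-index days on which an
#' aspirin-class and a P2Y12-inhibitor prescription interval overlap.
#'
#' @param prescriptions Data.frame with `drug_class`, `start`, `end`.
#' @param index_date Index PCI date.
#' @param config See [warehouse_config()].
#' @return List with `dapt_days` and `over_12mo` (`dapt_days >= 365`).
#' @export
derive_dapt <- function(prescriptions, index_date,
                        config = warehouse_config()) {
  index_date <- as_date(index_date)
  clip <- function(classes) {
    p <- prescriptions[prescriptions$drug_class %in% classes, , drop = FALSE]
    if (nrow(p) == 0) return(NULL)
    s <- pmax(as.numeric(as_date(p$start) - index_date), 0)
    e <- as.numeric(as_date(p$end) - index_date)
    keep <- e > s
    if (!any(keep)) return(NULL)
    union_intervals(s[keep], e[keep])
  }
  a <- clip(config$aspirin)
  b <- clip(config$p2y12)
  days <- 0
  if (!is.null(a) && !is.null(b)) {
    for (i in seq_along(a$start)) {
      lo <- pmax(a$start[i], b$start); hi <- pmin(a$end[i], b$end)
      days <- days + sum(pmax(hi - lo, 0))
    }
  }
  list(dapt_days = days, over_12mo = days >= config$dapt_over_days)
}

#' Derive the target vessel revascularization outcome for one episode
#'
#' TVR is a repeat PCI on the same target vessel category within the
#' follow-up window after the index procedure. Without such a repeat the
#' episode is censored at the earlier of last contact and the window.
#'
#' @param index_date Index PCI date.
#' @param repeat_dates Dates of subsequent PCI procedures on the same vessel
#'   category (excluding the index itself). A repeat dated before the index
#'   is a data-integrity error.
#' @param last_contact Date of last known contact.
#' @param window_days Follow-up window (default 730 = 2 years).
#' @return List with `tvr_event` (logical) and `followup_days`.
#' @export
derive_tvr <- function(index_date, repeat_dates, last_contact,
                       window_days = 730) {
  index_date <- as_date(index_date)
  repeat_dates <- as_date(repeat_dates)
  if (length(repeat_dates) && any(repeat_dates < index_date))
    stop("data-integrity error: repeat procedure dated before the index PCI")
  gap <- sort(as.numeric(repeat_dates - index_date))
  gap <- gap[gap > 0]
  censor_at <- min(as.numeric(as_date(last_contact) - index_date), window_days)
  if (length(gap) && gap[1] <= window_days)
    list(tvr_event = TRUE, followup_days = gap[1])
  else
    list(tvr_event = FALSE, followup_days = censor_at)
}

brand_label_at <- function(brands, granularity, lexicon) {
  s <- lexicon[lexicon$kind == "stent", ]
  i <- match(brands, s$category)
  if (anyNA(i)) stop("unknown brand family: ",
                     paste(brands[is.na(i)], collapse = ", "))
  switch(granularity,
         class = stent_class_label(s$device_class[i], s$generation[i], s$polymer[i]),
         generation = ifelse(s$device_class[i] == "BMS", "BMS",
                             paste0("DES-", s$generation[i])),
         polymer = ifelse(s$generation[i] == "second", s$polymer[i],
                          ifelse(s$device_class[i] == "BMS", "BMS", "DES1")),
         brand = brands,
         stop("unknown granularity: ", granularity))
}

#' Flag vessels treated with more than one stent category
#'
#' Prior to each comparison, vessels whose stent records span more than one
#' category at the comparison's granularity (e.g. both a durable- and a
#' biodegradable-polymer stent) are excluded from analysis. The exclusion is
#' comparison-specific: the generation comparison works at
#' generation granularity, the polymer comparison at polymer granularity.
#'
#' @param cohort A cohort table from [build_warehouse()].
#' @param granularity One of `"class"`, `"generation"`, `"polymer"`, `"brand"`.
#' @param lexicon A `pci_lexicon` (maps brand families to classifications).
#' @return The cohort with `excluded` / `exclude_reason` updated; previously
#'   excluded rows stay excluded.
#' @export
apply_exclusions <- function(cohort,
                             granularity = c("class", "generation",
                                             "polymer", "brand"),
                             lexicon = default_lexicon()) {
  granularity <- match.arg(granularity)
  mixed <- vapply(strsplit(cohort$brands_present, ";", fixed = TRUE),
                  function(b) {
                    length(unique(brand_label_at(b, granularity, lexicon))) > 1
                  }, logical(1))
  cohort$excluded <- cohort$excluded | mixed
  cohort$exclude_reason <- ifelse(
    mixed & !nzchar(cohort$exclude_reason), "mixed-category",
    cohort$exclude_reason)
  cohort
}

warehouse_columns <- c(
  "patient_id", "vessel", "index_date", "stent_class", "brands_present",
  "n_stents", "total_length_mm", "mean_diameter_mm", "balloon_used",
  "approach", "emergent", "age", "sex", "hypertension", "diabetes",
  "dapt_days", "dapt_over_12mo", "followup_days", "tvr_event",
  "excluded", "exclude_reason")

#' Assemble the vessel-level analysis warehouse
#'
#' One row per (patient, vessel category, index procedure), where the index
#' procedure is the first stent-implanting PCI for that patient-vessel in
#' the extraction. Per-episode stent aggregates (count, total length, mean
#' diameter, balloon flag) come from that vessel's extracted records at the
#' index date; outcome and covariates are derived from the patient tables.
#' Deterministic: identical inputs yield an identical table.
#'
#' @param extraction Extraction data.frame from [parse_corpus()] (or read
#'   back from its CSV), with `patient_id` and `procedure_date` present.
#' @param patients List with data.frames `demographics` (`patient_id`,
#'   `birth_date`, `sex`, `last_contact`), `diagnoses` (`patient_id`, `code`,
#'   `date`), `prescriptions` (`patient_id`, `drug_class`, `start`, `end`),
#'   `procedures` (`patient_id`, `date`, `vessel`, `approach`, `emergent`).
#' @param config See [warehouse_config()].
#' @param lexicon A `pci_lexicon`.
#' @return A `cohort_table` data.frame (see package docs for the schema).
#'   Extraction rows whose patient has no demographics row are dropped; the
#'   dropped count is attribute `"orphans"`.
#' @export
build_warehouse <- function(extraction, patients, config = warehouse_config(),
                            lexicon = default_lexicon()) {
  ex <- as.data.frame(extraction)
  if (nrow(ex) == 0) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(warehouse_columns)),
                         stringsAsFactors = FALSE)
    names(out) <- warehouse_columns
    return(structure(out, class = c("cohort_table", "data.frame"),
                     orphans = 0L))
  }
  dem <- patients$demographics
  orphan <- !(ex$patient_id %in% dem$patient_id)
  ex <- ex[!orphan, , drop = FALSE]
  ex$procedure_date <- as_date(ex$procedure_date)
  key <- paste(ex$patient_id, ex$vessel, sep = "\r")
  index_date <- as.Date(tapply(as.numeric(ex$procedure_date), key, min),
                        origin = "1970-01-01")
  keys <- sort(unique(key))

  rows <- lapply(keys, function(k) {
    sel <- key == k & ex$procedure_date == index_date[k]
    e <- ex[sel, , drop = FALSE]
    pid <- e$patient_id[1]; vessel <- e$vessel[1]; idx <- index_date[k]
    d <- dem[dem$patient_id == pid, ][1, ]
    dx <- patients$diagnoses[patients$diagnoses$patient_id == pid, , drop = FALSE]
    rx <- patients$prescriptions[patients$prescriptions$patient_id == pid, , drop = FALSE]
    pr <- patients$procedures[patients$procedures$patient_id == pid, , drop = FALSE]
    same_vessel <- !is.na(pr$vessel) & pr$vessel == vessel
    idx_proc <- pr[same_vessel & as_date(pr$date) == idx, , drop = FALSE]
    repeats <- pr[same_vessel & as_date(pr$date) > idx, "date"]
    tvr <- derive_tvr(idx, repeats, d$last_contact, config$window_days)
    dapt <- derive_dapt(rx, idx, config)
    classes <- unique(e$stent_class)
    data.frame(
      patient_id = pid, vessel = vessel, index_date = as.character(idx),
      stent_class = if (length(classes) == 1) classes else "mixed",
      brands_present = paste(sort(unique(e$brand_family)), collapse = ";"),
      n_stents = nrow(e),
      total_length_mm = sum(e$length_mm),
      mean_diameter_mm = mean(e$diameter_mm),
      balloon_used = any(e$noncompliant_balloon),
      approach = if (nrow(idx_proc)) idx_proc$approach[1] else NA_character_,
      emergent = if (nrow(idx_proc)) isTRUE(idx_proc$emergent[1]) else FALSE,
      age = floor(as.numeric(idx - as_date(d$birth_date)) / 365.25),
      sex = d$sex,
      hypertension = derive_hypertension(dx, rx, idx, config),
      diabetes = derive_diabetes(dx, rx, idx, config),
      dapt_days = dapt$dapt_days,
      dapt_over_12mo = dapt$over_12mo,
      followup_days = tvr$followup_days,
      tvr_event = tvr$tvr_event,
      excluded = FALSE, exclude_reason = "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$vessel), warehouse_columns]
  rownames(out) <- NULL
  structure(out, class = c("cohort_table", "data.frame"),
            orphans = sum(orphan))
}

#' Write a cohort table with provenance
#'
#' Writes the warehouse CSV (fixed column order, default float formatting,
#' so re-running on identical inputs is byte-identical) and a provenance
#' JSON next to it.
#'
#' @param cohort A `cohort_table`.
#' @param path CSV output path; provenance goes to `<path>.provenance.json`.
#' @param provenance Optional named list merged into the provenance record.
#' @return `path`, invisibly.
#' @export
write_warehouse <- function(cohort, path, provenance = list()) {
  utils::write.csv(as.data.frame(cohort)[, warehouse_columns], path,
                   row.names = FALSE)
  prov <- c(list(n_episodes = nrow(cohort),
                 n_excluded = sum(cohort$excluded),
                 orphans = attr(cohort, "orphans"),
                 columns = warehouse_columns), provenance)
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a cohort table written by [write_warehouse()]
#'
#' @param path CSV path.
#' @return A `cohort_table`.
#' @export
read_warehouse <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(exclude_reason = "character"))
  out$exclude_reason[is.na(out$exclude_reason)] <- ""
  structure(out, class = c("cohort_table", "data.frame"))
}
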