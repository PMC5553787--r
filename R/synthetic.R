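default_brand_mix <- c(
  "Vision" = 0.02, "Genoss" = 0.01, "Coroflex Blue" = 0.01, "Zeta" = 0.01,
  "Cypher" = 0.05, "Coroflex Please" = 0.02, "Taxus" = 0.05,
  "Resolute family" = 0.17, "Promus family" = 0.20, "Xience family" = 0.17,
  "Endeavor" = 0.03,
  "Biomatrix" = 0.08, "Desyne" = 0.02, "Nobori" = 0.14, "Orsiro" = 0.02)

# Non-lexicon filler emulating mixed English/Korean report prose; includes
# Hangul tokens so decoys exercise the non-Latin path.
decoy_tokens <- c(
  "good distal flow", "TIMI III flow noted", "no dissection",
  "mild residual stenosis", "successful deployment",
  "\uc2dc\uc220 \uacbd\uacfc \uc591\ud638",           # procedure course favorable
  "\ud611\ucc29 \ubcd1\ubcc0",                        # stenotic lesion
  "\uc7ac\ud611\ucc29 \uc18c\uacac \uc5c6\uc74c")     # no restenosis finding

#' Configuration for the synthetic corpus/cohort generator
#'
#' Defaults echo the magnitudes of a real-world PCI warehouse: about 1.5
#' treated vessels and one report per patient, ~1.25 stents per vessel,
#' stent diameter ~3.0 mm and per-stent length ~24 mm, a ~5% two-year TVR
#' fraction (baseline hazard 7e-5 events/day), covariate prevalences of 71%
#' male, 46% hypertension, 20% diabetes, 61% DAPT beyond 12 months, 81%
#' femoral approach, and hazard-ratio defaults matching the adjusted
#' estimates the package's analyses are designed to detect (second- vs
#' first-generation 0.423, hypertension 3.469, diabetes 2.100, emergent
#' 3.270, DAPT>12mo 0.389, age 0.978/year).
#'
#' @param n_patients Number of patients (one report each).
#' @param seed Seed fixing every generator output byte-identically.
#' @param ... Overrides for any config field (see the function body for the
#'   full list): `brand_mix`, `vessels_per_patient`, `stents_per_vessel`,
#'   `diameter_mean`, `diameter_sd`, `length_mean`, `length_sd`,
#'   `balloon_rate`, `variant_rate`, `typo_rate`, `decoy_rate`,
#'   `disagreement_rate`, `baseline_rate`, `log_hr`, `censoring`
#'   (`"uniform"` or `"fixed"`), `window_days`, prevalence fields
#'   (`p_male`, `p_htn`, `p_dm`, `p_dapt12`, `p_emergent`, `p_radial`),
#'   `age_mean`, `age_sd`.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 300, seed = 1, ...) {
  cfg <- list(
    n_patients = n_patients, seed = seed,
    vessels_per_patient = c(`1` = 0.6, `2` = 0.3, `3` = 0.1),
    stents_per_vessel = c(`1` = 0.8, `2` = 0.15, `3` = 0.05),
    brand_mix = default_brand_mix,
    diameter_mean = 3.0, diameter_sd = 0.35,
    length_mean = 24, length_sd = 8,
    balloon_rate = 0.5,
    variant_rate = 0.1, typo_rate = 0, decoy_rate = 0.2,
    disagreement_rate = 0.039,
    baseline_rate = 7e-5,
    log_hr = c(second_gen = log(0.423), hypertension = log(3.469),
               diabetes = log(2.100), emergent = log(3.270),
               dapt_over_12mo = log(0.389), age_c = log(0.978)),
    censoring = "uniform", window_days = 730,
    p_male = 0.71, p_htn = 0.46, p_dm = 0.20, p_dapt12 = 0.61,
    p_emergent = 0.15, p_radial = 0.19,
    age_mean = 62.75, age_sd = 11.77)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  bad <- character()
  ok_prob <- function(p) abs(sum(p) - 1) < 1e-8 && all(p >= 0)
  if (!ok_prob(cfg$vessels_per_patient)) bad <- c(bad, "vessels_per_patient")
  if (!ok_prob(cfg$stents_per_vessel)) bad <- c(bad, "stents_per_vessel")
  if (!ok_prob(cfg$brand_mix)) bad <- c(bad, "brand_mix")
  for (r in c("balloon_rate", "variant_rate", "typo_rate", "decoy_rate",
              "disagreement_rate", "p_male", "p_htn", "p_dm", "p_dapt12",
              "p_emergent", "p_radial"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1) bad <- c(bad, r)
  for (r in c("n_patients", "baseline_rate", "window_days", "diameter_mean",
              "length_mean"))
    if (cfg[[r]] <= 0) bad <- c(bad, r)
  if (!cfg$censoring %in% c("uniform", "fixed")) bad <- c(bad, "censoring")
  if (length(bad)) stop("invalid generator config field(s): ",
                        paste(unique(bad), collapse = ", "))
  structure(cfg, class = "generator_config")
}

sample_int <- function(n, probs) {
  as.integer(sample(names(probs), n, replace = TRUE, prob = probs))
}

#' Generate a synthetic PCI cohort with known ground truth
#'
#' Draws patients, their treated-vessel episodes (brand, stent dimensions,
#' balloon use), covariates, and event/censoring times under an exponential
#' baseline hazard multiplied by `exp(linear predictor)` with the config's
#' log hazard ratios. Emits the longitudinal patient tables the warehouse
#' consumes (demographics, diagnoses, prescriptions, procedures) together
#' with the generator-side truth. Fully deterministic under the config seed.
#'
#' @param config A `generator_config`.
#' @return A list of class `synthetic_truth`: `episodes` (one row per treated
#'   vessel with covariates and true/observed event data), `stents` (one row
#'   per implanted stent), `patients` (the four warehouse input tables), and
#'   `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  lex <- default_lexicon()
  stent_tab <- lex[lex$kind == "stent", ]
  origin <- as.Date("2010-02-01")

  dem <- list(); dx <- list(); rx <- list(); pr <- list()
  eps <- list(); stents <- list()
  for (i in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%05d", i)
    rid <- sprintf("R%05d", i)
    age <- pmin(pmax(round(stats::rnorm(1, cfg$age_mean, cfg$age_sd)), 25), 95)
    sex <- if (stats::runif(1) < cfg$p_male) "M" else "F"
    index <- origin + sample.int(1700, 1)
    birth <- index - round(age * 365.25) - 180
    htn <- stats::runif(1) < cfg$p_htn
    dm <- stats::runif(1) < cfg$p_dm
    dapt12 <- stats::runif(1) < cfg$p_dapt12
    dapt_days <- if (dapt12) sample(365:730, 1) else sample(30:364, 1)
    emergent <- stats::runif(1) < cfg$p_emergent
    approach <- if (stats::runif(1) < cfg$p_radial) "radial" else "femoral"
    cens_day <- if (cfg$censoring == "fixed") cfg$window_days
                else max(1L, as.integer(ceiling(stats::runif(1, 0, cfg$window_days))))

    if (htn) {
      if (stats::runif(1) < 0.5)
        dx[[length(dx) + 1]] <- data.frame(patient_id = pid, code = "I10",
                                           date = as.character(index - 30))
      else
        rx[[length(rx) + 1]] <- data.frame(patient_id = pid, drug_class = "arb",
                                           start = as.character(index - 60),
                                           end = as.character(index + 365))
    }
    if (dm) {
      if (stats::runif(1) < 0.5)
        dx[[length(dx) + 1]] <- data.frame(patient_id = pid, code = "E11.9",
                                           date = as.character(index - 90))
      else
        rx[[length(rx) + 1]] <- data.frame(patient_id = pid,
                                           drug_class = "metformin",
                                           start = as.character(index - 120),
                                           end = as.character(index + 365))
    }
    rx[[length(rx) + 1]] <- data.frame(patient_id = pid, drug_class = "aspirin",
                                       start = as.character(index),
                                       end = as.character(index + 900))
    rx[[length(rx) + 1]] <- data.frame(patient_id = pid,
                                       drug_class = "clopidogrel",
                                       start = as.character(index),
                                       end = as.character(index + dapt_days))

    n_vessels <- sample_int(1, cfg$vessels_per_patient)
    vessels <- sample(vessel_categories(), n_vessels)
    for (v in vessels) {
      brand <- sample(names(cfg$brand_mix), 1, prob = cfg$brand_mix)
      cls <- stent_tab[match(brand, stent_tab$category), ]
      n_st <- sample_int(1, cfg$stents_per_vessel)
      dia <- round(pmin(pmax(stats::rnorm(n_st, cfg$diameter_mean,
                                          cfg$diameter_sd), 2.0), 4.5), 1)
      len <- round(pmin(pmax(stats::rnorm(n_st, cfg$length_mean,
                                          cfg$length_sd), 8), 48))
      balloon <- stats::runif(1) < cfg$balloon_rate
      cov <- c(second_gen = as.numeric(cls$generation == "second"),
               biodegradable = as.numeric(cls$polymer == "biodegradable"),
               hypertension = as.numeric(htn), diabetes = as.numeric(dm),
               emergent = as.numeric(emergent),
               dapt_over_12mo = as.numeric(dapt12),
               age_c = age - 63, male = as.numeric(sex == "M"))
      lp <- sum(cfg$log_hr * cov[names(cfg$log_hr)])
      t_day <- max(1L, as.integer(ceiling(stats::rexp(1, cfg$baseline_rate * exp(lp)))))
      horizon <- min(cens_day, cfg$window_days)
      event <- t_day <= horizon
      time_obs <- if (event) t_day else horizon
      pr[[length(pr) + 1]] <- data.frame(patient_id = pid,
                                         date = as.character(index),
                                         vessel = v, approach = approach,
                                         emergent = emergent)
      if (event)
        pr[[length(pr) + 1]] <- data.frame(patient_id = pid,
                                           date = as.character(index + t_day),
                                           vessel = v, approach = "femoral",
                                           emergent = FALSE)
      eps[[length(eps) + 1]] <- data.frame(
        report_id = rid, patient_id = pid, vessel = v,
        index_date = as.character(index), brand_family = brand,
        device_class = cls$device_class, generation = cls$generation,
        polymer = cls$polymer,
        stent_class = stent_class_label(cls$device_class, cls$generation,
                                        cls$polymer),
        n_stents = n_st, total_length_mm = sum(len),
        mean_diameter_mm = mean(dia), balloon_used = balloon,
        age = age, sex = sex, hypertension = htn, diabetes = dm,
        dapt_days = dapt_days, dapt_over_12mo = dapt12,
        emergent = emergent, approach = approach,
        event_day = t_day, censor_day = cens_day,
        time_days = time_obs, tvr_event = event,
        stringsAsFactors = FALSE)
      stents[[length(stents) + 1]] <- data.frame(
        report_id = rid, vessel = v, brand_family = brand,
        diameter_mm = dia, length_mm = len, balloon = balloon,
        stringsAsFactors = FALSE)
    }
    dem[[length(dem) + 1]] <- data.frame(
      patient_id = pid, birth_date = as.character(birth), sex = sex,
      last_contact = as.character(index + cens_day), stringsAsFactors = FALSE)
  }
  empty_dx <- data.frame(patient_id = character(), code = character(),
                         date = character(), stringsAsFactors = FALSE)
  structure(list(
    episodes = do.call(rbind, eps),
    stents = do.call(rbind, stents),
    patients = list(
      demographics = do.call(rbind, dem),
      diagnoses = if (length(dx)) do.call(rbind, dx) else empty_dx,
      prescriptions = do.call(rbind, rx),
      procedures = do.call(rbind, pr)),
    config = cfg), class = "synthetic_truth")
}

title_case <- function(x) gsub("\\b([a-z])", "\\U\\1", x, perl = TRUE)

# Insert a non-lexicon digraph so the mangled form cannot match any term.
mangle <- function(s) paste0(substr(s, 1, 2), "zq", substr(s, 3, nchar(s)))

surface_form <- function(canonical, category, kind, lexicon, variant_rate) {
  if (stats::runif(1) < variant_rate) {
    forms <- lexicon$term[lexicon$kind == kind & lexicon$category == category]
    sample(forms, 1)
  } else canonical
}

#' Render a synthetic truth as a free-text report corpus
#'
#' Each report gets one `<vessel term>:` header per treated vessel followed
#' by one body line per stent (`<brand> <diameter>/<length>mm`, with the
#' space-before-"mm" dialect appearing at random) and, when a non-compliant
#' balloon was used, an "HP"/balloon-brand line. Surface forms are sampled
#' from registered lexicon variants at `variant_rate`; unregistered typos
#' are injected into headers and stent names at `typo_rate`; decoy
#' lines/tokens (including Hangul filler) at `decoy_rate`. The gold standard
#' is unaffected by noise. Deterministic under the config seed.
#'
#' @param truth A `synthetic_truth` from [generate_cohort()].
#' @param config Defaults to the truth's own config; pass a modified config
#'   to re-render the same truth at different noise rates.
#' @param lexicon A `pci_lexicon`.
#' @return A corpus data.frame (`report_id`, `patient_id`, `procedure_date`,
#'   `text`) usable by [parse_corpus()].
#' @export
render_reports <- function(truth, config = truth$config,
                           lexicon = default_lexicon()) {
  set.seed(config$seed + 1L)
  canon_vessel <- c(LAD = "LAD", LCx = "LCx", LM = "LM", RCA = "RCA")
  stent_tab <- lexicon[lexicon$kind == "stent", ]
  canon_stent <- vapply(unique(stent_tab$category), function(b)
    stent_tab$term[stent_tab$category == b][1], character(1))
  balloon_terms <- lexicon$term[lexicon$kind == "balloon"]
  ep <- truth$episodes
  texts <- vapply(unique(ep$report_id), function(rid) {
    rows <- ep[ep$report_id == rid, , drop = FALSE]
    st <- truth$stents[truth$stents$report_id == rid, , drop = FALSE]
    lines <- character()
    if (stats::runif(1) < config$decoy_rate)
      lines <- c(lines, sample(decoy_tokens, 1))
    for (j in seq_len(nrow(rows))) {
      v <- rows$vessel[j]
      header <- surface_form(canon_vessel[[v]], v, "vessel", lexicon,
                             config$variant_rate)
      header <- toupper(header)
      if (stats::runif(1) < config$typo_rate) header <- mangle(header)
      lines <- c(lines, paste0(header, ":"))
      vs <- st[st$vessel == v, , drop = FALSE]
      for (s in seq_len(nrow(vs))) {
        nm <- surface_form(canon_stent[[vs$brand_family[s]]],
                           vs$brand_family[s], "stent", lexicon,
                           config$variant_rate)
        nm <- title_case(nm)
        if (stats::runif(1) < config$typo_rate) nm <- mangle(nm)
        unit <- if (stats::runif(1) < 0.3) " mm" else "mm"
        line <- sprintf("  %s %.1f/%g%s", nm, vs$diameter_mm[s],
                        vs$length_mm[s], unit)
        if (stats::runif(1) < config$decoy_rate)
          line <- paste(line, sample(decoy_tokens, 1))
        lines <- c(lines, line)
      }
      if (rows$balloon_used[j]) {
        btok <- if (stats::runif(1) < 0.5) "HP"
                else title_case(sample(balloon_terms, 1))
        lines <- c(lines, sprintf("  post-dilation with %s %.1f/%gmm",
                                  btok, 3.5, 8))
      }
      if (stats::runif(1) < config$decoy_rate)
        lines <- c(lines, paste(" ", sample(decoy_tokens, 1)))
    }
    paste(lines, collapse = "\n")
  }, character(1))
  first <- ep[!duplicated(ep$report_id), c("report_id", "patient_id", "index_date")]
  data.frame(report_id = first$report_id, patient_id = first$patient_id,
             procedure_date = first$index_date, text = unname(texts),
             stringsAsFactors = FALSE)
}

#' Export the generator's gold-standard pair annotations
#'
#' @param truth A `synthetic_truth`.
#' @param path Optional CSV path; when given the gold table is also written.
#' @return Data.frame with `report_id`, `vessel`, `stent_class`,
#'   `brand_family` \u2014 one row per true (vessel, stent) pair, directly usable
#'   as the gold input of the evaluation functions via [to_pair_set()].
#' @export
export_gold <- function(truth, path = NULL) {
  g <- unique(truth$episodes[, c("report_id", "vessel", "stent_class",
                                 "brand_family")])
  g <- g[order(g$report_id, g$vessel, g$stent_class), , drop = FALSE]
  rownames(g) <- NULL
  if (!is.null(path)) utils::write.csv(g, path, row.names = FALSE)
  g
}

#' Simulate independent extractor outputs with a known disagreement rate
#'
#' Emulates three extraction scripts that agree on most descriptions:
#' starting from the gold pair set, each pair is, with probability `rate`,
#' dropped from exactly one randomly chosen extractor's output. Such a pair
#' is asserted by 2 of 3 extractors and therefore lands in the disputed
#' queue of [consensus_merge()], so the expected disputed fraction equals
#' `rate`.
#'
#' @param gold Gold data.frame from [export_gold()].
#' @param rate Per-description disagreement probability.
#' @param seed Seed.
#' @return List of three pair-set data.frames (category granularity).
#' @export
make_extractor_outputs <- function(gold, rate, seed = 1) {
  set.seed(seed)
  base <- to_pair_set(gold, "category")
  flip <- stats::runif(nrow(base)) < rate
  who <- sample.int(3, nrow(base), replace = TRUE)
  lapply(1:3, function(e) base[!(flip & who == e), , drop = FALSE])
}

#' Convert generator truth to the extraction-table schema
#'
#' Produces the table [parse_corpus()] would emit on a noise-free rendering
#' of the truth, bypassing text rendering and parsing. Useful for exercising
#' the warehouse and survival stages directly against known inputs.
#'
#' @param truth A `synthetic_truth`.
#' @return An extraction data.frame (see [parse_corpus()]).
#' @export
truth_extraction <- function(truth) {
  lex <- default_lexicon()
  s <- merge(truth$stents,
             truth$episodes[, c("report_id", "vessel", "patient_id",
                                "index_date", "balloon_used")],
             by = c("report_id", "vessel"))
  tab <- lex[lex$kind == "stent", ]
  i <- match(s$brand_family, tab$category)
  out <- data.frame(report_id = s$report_id, patient_id = s$patient_id,
                    procedure_date = s$index_date, vessel = s$vessel,
                    brand_family = s$brand_family,
                    device_class = tab$device_class[i],
                    generation = tab$generation[i], polymer = tab$polymer[i],
                    stent_class = stent_class_label(tab$device_class[i],
                                                    tab$generation[i],
                                                    tab$polymer[i]),
                    diameter_mm = s$diameter_mm, length_mm = s$length_mm,
                    char_start = NA_integer_, char_end = NA_integer_,
                    noncompliant_balloon = s$balloon_used,
                    stringsAsFactors = FALSE)
  out <- out[order(out$report_id, out$vessel), ]
  rownames(out) <- NULL
  out
}

#' Simulate a minimal proportional-hazards cohort
#'
#' One binary exposure with the given prevalence and log hazard ratio, plus
#' `n_null` standard-normal covariates with zero effect; exponential baseline
#' hazard; administrative censoring at `window_days`.
#'
#' @param n Number of episodes.
#' @param log_hr True log hazard ratio of the exposure.
#' @param prevalence Exposure prevalence.
#' @param baseline_rate Baseline hazard (events/day).
#' @param window_days Administrative censoring time.
#' @param n_null Number of null covariates (`z1..zk`).
#' @param seed Seed.
#' @return Data.frame with `time`, `event`, `exposure`, `z1..zk`.
#' @export
simulate_ph_cohort <- function(n, log_hr, prevalence, baseline_rate = 7e-5,
                               window_days = 730, n_null = 3, seed = 1) {
  set.seed(seed)
  exposure <- stats::rbinom(n, 1, prevalence)
  z <- matrix(stats::rnorm(n * n_null), n, n_null,
              dimnames = list(NULL, paste0("z", seq_len(n_null))))
  t <- stats::rexp(n, baseline_rate * exp(log_hr * exposure))
  d <- data.frame(time = pmin(t, window_days), event = as.integer(t <= window_days),
                  exposure = exposure)
  cbind(d, as.data.frame(z))
}

#' Write a synthetic corpus, patient tables and gold standard to disk
#'
#' Produces the on-disk layout the command-line interface consumes:
#' `corpus/<report_id>.txt` plus `corpus/manifest.csv`, `patients/*.csv`,
#' `gold.csv`, `truth.csv` and `config.json`.
#'
#' @param truth A `synthetic_truth`.
#' @param corpus Output of [render_reports()] on that truth.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(truth, corpus, dir) {
  dir.create(file.path(dir, "corpus"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "patients"), showWarnings = FALSE)
  for (i in seq_len(nrow(corpus)))
    writeLines(corpus$text[i],
               file.path(dir, "corpus", paste0(corpus$report_id[i], ".txt")),
               useBytes = TRUE)
  utils::write.csv(corpus[, c("report_id", "patient_id", "procedure_date")],
                   file.path(dir, "corpus", "manifest.csv"), row.names = FALSE)
  for (nm in names(truth$patients))
    utils::write.csv(truth$patients[[nm]],
                     file.path(dir, "patients", paste0(nm, ".csv")),
                     row.names = FALSE)
  export_gold(truth, file.path(dir, "gold.csv"))
  utils::write.csv(truth$episodes, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- unclass(truth$config)
  cfg$log_hr <- as.list(cfg$log_hr)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
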