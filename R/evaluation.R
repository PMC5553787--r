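#' Stent labels forming the comparison universe
#'
#' At `"category"` granularity the labels are the four stent classes
#' (BMS, DES1, DES2-DP, DES2-BP) — the level at which extraction was
#' validated. `"brand"` granularity uses brand families instead.
#'
#' @param granularity `"category"` or `"brand"`.
#' @param lexicon A `pci_lexicon`; needed for brand granularity.
#' @return Character vector of stent labels.
#' @export
pair_labels <- function(granularity = c("category", "brand"),
                        lexicon = default_lexicon()) {
  granularity <- match.arg(granularity)
  if (granularity == "category") stent_class_labels()
  else sort(unique(lexicon$category[lexicon$kind == "stent"]))
}

#' Reduce extraction output to vessel-stent pair assertions
#'
#' The unit of extraction validation: the set of distinct
#' (vessel category, stent label) pairs asserted for each report. Duplicate
#' records (two same-class stents in one vessel) collapse to one pair.
#'
#' @param x A `procedure_record`, an extraction data.frame from
#'   [parse_corpus()], or any data.frame with `report_id`, `vessel` and the
#'   label source columns.
#' @param granularity `"category"` (stent class) or `"brand"` (brand family).
#' @return A data.frame with columns `report_id`, `vessel`, `stent_label`,
#'   one row per distinct pair.
#' @export
to_pair_set <- function(x, granularity = c("category", "brand")) {
  granularity <- match.arg(granularity)
  df <- if (inherits(x, "procedure_record")) {
    if (nrow(x$records) == 0)
      data.frame(report_id = character(), vessel = character(),
                 stent_class = character(), brand_family = character())
    else cbind(report_id = x$report_id, x$records)
  } else as.data.frame(x)
  lab <- if (granularity == "category") df$stent_class else df$brand_family
  out <- unique(data.frame(report_id = as.character(df$report_id),
                           vessel = df$vessel, stent_label = lab,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(out$report_id, out$vessel, out$stent_label), , drop = FALSE]
}

pair_key <- function(df) paste(df$report_id, df$vessel, df$stent_label, sep = "\r")

check_universe <- function(pairs, report_ids, labels, what) {
  if (nrow(pairs) == 0) return(invisible())
  if (!all(pairs$report_id %in% report_ids))
    stop(what, ": pair set contains report ids outside the comparison set")
  if (!all(pairs$vessel %in% vessel_categories()) ||
      !all(pairs$stent_label %in% labels))
    stop(what, ": pair set contains labels outside the declared universe")
  invisible()
}

#' Pair-level confusion counts against a gold standard
#'
#' The negative universe is, per report, the full cross-product of the four
#' vessel categories with the stent labels under comparison; a pair absent
#' from both the prediction and the gold standard is a true negative. With
#' category granularity the per-report universe has 16 slots.
#'
#' @param predicted,gold Pair-set data.frames (see [to_pair_set()]).
#' @param report_ids All report ids in the comparison (reports with no pairs
#'   still contribute true negatives).
#' @param labels Stent labels of the universe (default category labels).
#' @return A list of class `confusion_counts` with `TP`, `FP`, `FN`, `TN`,
#'   `n_slots`.
#' @export
confusion_counts <- function(predicted, gold,
                             report_ids = union(predicted$report_id, gold$report_id),
                             labels = pair_labels("category")) {
  check_universe(predicted, report_ids, labels, "predicted")
  check_universe(gold, report_ids, labels, "gold")
  p <- unique(pair_key(predicted)); g <- unique(pair_key(gold))
  n_slots <- length(unique(report_ids)) * length(vessel_categories()) * length(labels)
  tp <- length(intersect(p, g))
  fp <- length(setdiff(p, g))
  fn <- length(setdiff(g, p))
  tn <- n_slots - tp - fp - fn
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn, n_slots = n_slots),
            class = "confusion_counts")
}

safe_div <- function(num, den) if (den > 0) num / den else NA_real_

#' Agreement metrics from confusion counts
#'
#' Sensitivity (recall), specificity, positive and negative predictive value,
#' and the F-measure (harmonic mean of PPV and sensitivity). A metric whose
#' denominator is zero is returned as `NA` (undefined), never as 0 or 1.
#'
#' @param counts A `confusion_counts` object or a list with `TP`, `FP`, `FN`,
#'   `TN`.
#' @return A list of class `agreement_result` with `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `f_measure`.
#' @export
metrics <- function(counts) {
  sens <- safe_div(counts$TP, counts$TP + counts$FN)
  spec <- safe_div(counts$TN, counts$TN + counts$FP)
  ppv <- safe_div(counts$TP, counts$TP + counts$FP)
  npv <- safe_div(counts$TN, counts$TN + counts$FN)
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
                 f_measure = f_measure(ppv, sens)),
            class = "agreement_result")
}

#' Harmonic mean of precision and recall
#'
#' @param ppv Positive predictive value (precision).
#' @param sensitivity Recall.
#' @return The F-measure, or `NA` when undefined.
#' @export
f_measure <- function(ppv, sensitivity) {
  if (is.na(ppv) || is.na(sensitivity) || (ppv + sensitivity) == 0)
    return(NA_real_)
  2 * ppv * sensitivity / (ppv + sensitivity)
}

# Binary presence vector of a pair collection over the full slot universe.
slot_vector <- function(pairs, report_ids, labels) {
  slots <- expand.grid(report_id = unique(report_ids),
                       vessel = vessel_categories(),
                       stent_label = labels, stringsAsFactors = FALSE)
  pair_key(slots) %in% pair_key(pairs)
}

#' Cohen's kappa between two extractor outputs
#'
#' Each (report, vessel, stent label) slot of the comparison universe is a
#' binary present/absent rating by each extractor, pooled over reports.
#' Kappa = (p_o - p_e) / (1 - p_e), with chance agreement p_e computed from
#' each rater's marginal present/absent frequencies.
#'
#' @param a,b Pair-set data.frames from two extractors over the same reports.
#' @param report_ids All report ids rated by both.
#' @param labels Stent labels of the universe.
#' @return Kappa in `[-1, 1]`, or `NA` when both raters are constant
#'   (p_e = 1, chance-corrected agreement undefined).
#' @export
cohen_kappa <- function(a, b, report_ids = union(a$report_id, b$report_id),
                        labels = pair_labels("category")) {
  check_universe(a, report_ids, labels, "a")
  check_universe(b, report_ids, labels, "b")
  va <- slot_vector(a, report_ids, labels)
  vb <- slot_vector(b, report_ids, labels)
  po <- mean(va == vb)
  pa <- mean(va); pb <- mean(vb)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Three-way consensus merge of extractor outputs
#'
#' A pair is accepted into the warehouse only when all three extractors
#' assert it (unanimity); a pair asserted by one or two of the three is
#' disputed and queued for manual adjudication. The merge is invariant to
#' the order of its three inputs.
#'
#' @param x,y,z Pair-set data.frames from the three extractors.
#' @return A list of class `consensus_outcome`: `accepted` (pairs present in
#'   all three), `disputed` (pairs present in one or two, with `n_asserting`),
#'   and `adjudicated` (initially empty; see [apply_adjudication()]).
#' @export
consensus_merge <- function(x, y, z) {
  all_pairs <- unique(rbind(x[, c("report_id", "vessel", "stent_label")],
                            y[, c("report_id", "vessel", "stent_label")],
                            z[, c("report_id", "vessel", "stent_label")]))
  k <- pair_key(all_pairs)
  n <- (k %in% pair_key(x)) + (k %in% pair_key(y)) + (k %in% pair_key(z))
  accepted <- all_pairs[n == 3L, , drop = FALSE]
  disputed <- all_pairs[n < 3L, , drop = FALSE]
  disputed$n_asserting <- n[n < 3L]
  ord <- function(d) { d <- d[order(d$report_id, d$vessel, d$stent_label), ,
                              drop = FALSE]; rownames(d) <- NULL; d }
  structure(list(accepted = ord(accepted), disputed = ord(disputed),
                 adjudicated = NULL),
            class = "consensus_outcome")
}

#' Write the disputed queue as an adjudication CSV
#'
#' Columns: `report_id`, `vessel`, `stent_label`, `n_asserting`, `verdict`
#' (to be filled in as `present` or `absent`), `adjudicator`, `note`.
#'
#' @param outcome A `consensus_outcome`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_disputed <- function(outcome, path) {
  d <- outcome$disputed
  d$verdict <- character(nrow(d))
  d$adjudicator <- character(nrow(d))
  d$note <- character(nrow(d))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Fold manual adjudications back into a consensus outcome
#'
#' @param outcome A `consensus_outcome`.
#' @param adjudications Data.frame (or CSV path) with `report_id`, `vessel`,
#'   `stent_label`, `verdict` in `{present, absent}`. Every row must refer to
#'   a disputed pair; unknown pairs are an error.
#' @return The outcome with `adjudicated` filled in; the final merged pair
#'   set is `accepted` plus the adjudicated-present pairs (see
#'   [final_pairs()]).
#' @export
apply_adjudication <- function(outcome, adjudications) {
  if (is.character(adjudications))
    adjudications <- utils::read.csv(adjudications, stringsAsFactors = FALSE)
  stopifnot(all(c("report_id", "vessel", "stent_label", "verdict") %in%
                  names(adjudications)))
  if (!all(adjudications$verdict %in% c("present", "absent")))
    stop("verdict must be 'present' or 'absent'")
  unknown <- !(pair_key(adjudications) %in% pair_key(outcome$disputed))
  if (any(unknown))
    stop("adjudication refers to pair(s) not in the disputed queue: ",
         paste(pair_key(adjudications)[unknown], collapse = "; "))
  outcome$adjudicated <- adjudications
  outcome
}

#' Final merged pair set after consensus and adjudication
#'
#' @param outcome A `consensus_outcome`, after [apply_adjudication()] if any
#'   pairs were disputed.
#' @return Pair-set data.frame: unanimous pairs plus adjudicated-present ones.
#' @export
final_pairs <- function(outcome) {
  out <- outcome$accepted
  if (!is.null(outcome$adjudicated)) {
    keep <- outcome$adjudicated[outcome$adjudicated$verdict == "present",
                                c("report_id", "vessel", "stent_label")]
    out <- unique(rbind(out, keep))
  }
  out <- out[order(out$report_id, out$vessel, out$stent_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f  F %.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv, x$f_measure))
  invisible(x)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d (universe %d slots)\n",
              x$TP, x$FP, x$FN, x$TN, x$n_slots))
  invisible(x)
}
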