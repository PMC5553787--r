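#' Segment a report into vessel-section candidates
#'
#' PCI procedure reports are semi-structured: each treated vessel is
#' introduced by a header line of the form `<vessel term>:` and described in
#' the lines that follow. A line is a header candidate when it contains a
#' colon and its pre-colon text is at most `max_header_chars` characters
#' (guarding against prose sentences containing colons). Only the first colon
#' on a line delimits the header. The section body runs from just after the
#' colon to the start of the next header line (multi-line bodies allowed).
#'
#' @param text Raw report text.
#' @param max_header_chars Longest pre-colon text still treated as a header.
#' @return A data.frame with one row per candidate: `header_raw`, `header`
#'   (normalized), `body` (the exact substring of `text`), and the 0-based
#'   half-open character offsets `body_start`, `sec_start`, `sec_end`.
#'   A document with no colon lines yields zero rows.
#' @export
segment_sections <- function(text, max_header_chars = 40) {
  empty <- data.frame(header_raw = character(), header = character(),
                      body = character(), body_start = integer(),
                      sec_start = integer(), sec_end = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0) return(empty)
  line_start <- cumsum(c(0L, nchar(lines[-length(lines)], type = "chars") + 1L))
  colon <- regexpr(":", lines, fixed = TRUE)
  is_header <- colon > 0L & (colon - 1L) <= max_header_chars
  idx <- which(is_header)
  if (length(idx) == 0) return(empty)
  next_start <- c(line_start[idx][-1], nchar(text, type = "chars"))
  out <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    body_start <- line_start[i] + colon[i]      # 0-based, just past the colon
    body <- substr(text, body_start + 1L, next_start[k])
    data.frame(header_raw = substr(lines[i], 1L, colon[i] - 1L),
               header = normalize_token(substr(lines[i], 1L, colon[i] - 1L)),
               body = body, body_start = body_start,
               sec_start = line_start[i], sec_end = next_start[k],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Resolve section headers to vessel categories
#'
#' @param candidates Output of [segment_sections()].
#' @param lexicon A `pci_lexicon`.
#' @return A list with `sections` (the candidates whose header is a
#'   registered vessel form, plus a `vessel` column) and `unmatched`
#'   (normalized headers that matched no vessel category).
#' @export
resolve_vessels <- function(candidates, lexicon) {
  if (nrow(candidates) == 0)
    return(list(sections = cbind(candidates, vessel = character()),
                unmatched = character()))
  vessel <- lookup_vessel(lexicon, candidates$header)
  sections <- candidates[!is.na(vessel), , drop = FALSE]
  sections$vessel <- vessel[!is.na(vessel)]
  rownames(sections) <- NULL
  list(sections = sections, unmatched = candidates$header[is.na(vessel)])
}

dimension_pattern <- "([0-9]+(?:\\.[0-9]+)?)\\s*/\\s*([0-9]+(?:\\.[0-9]+)?)\\s*mm"

empty_stent_records <- function() {
  data.frame(vessel = character(), brand_family = character(),
             device_class = character(), generation = character(),
             polymer = character(), stent_class = character(),
             diameter_mm = numeric(), length_mm = numeric(),
             char_start = integer(), char_end = integer(),
             stringsAsFactors = FALSE)
}

#' Extract stent dimension strings from a section body
#'
#' Matches `<diameter>/<length>mm`: two numbers (integer or decimal)
#' separated by a slash and followed by "mm", with optional whitespace before
#' the unit and around the slash.
#'
#' @param body Section body text.
#' @return A data.frame with `diameter_mm`, `length_mm` and `pos` (0-based
#'   match start within `body`), in order of appearance; zero rows when
#'   nothing matches.
#' @export
#' @examples
#' extract_dimensions("Xience 3.0/28mm deployed")
extract_dimensions <- function(body) {
  m <- gregexpr(dimension_pattern, body, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(diameter_mm = numeric(), length_mm = numeric(),
                      pos = integer()))
  txt <- regmatches(body, list(m))[[1]]
  data.frame(
    diameter_mm = as.numeric(sub(dimension_pattern, "\\1", txt, perl = TRUE)),
    length_mm   = as.numeric(sub(dimension_pattern, "\\2", txt, perl = TRUE)),
    pos = as.integer(m) - 1L)
}

term_regex <- function(term) {
  esc <- gsub("([^[:alnum:] ])", "\\\\\\1", term)
  paste0("\\b", gsub(" ", "\\\\s+", esc), "\\b")
}

# All word-boundary matches of the lexicon's terms of a given kind in `body`,
# keeping only maximal matches (a hit contained in a longer hit is dropped,
# so "xience" inside "xience prime" counts once).
match_terms <- function(body, lexicon, kind) {
  low <- tolower(body)
  terms <- lexicon[lexicon$kind == kind, , drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(terms))) {
    m <- gregexpr(term_regex(terms$term[i]), low, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    hits[[length(hits) + 1L]] <- data.frame(
      start = as.integer(m) - 1L,
      end = as.integer(m) - 1L + attr(m, "match.length"),
      term = terms$term[i], category = terms$category[i],
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(), end = integer(),
                      term = character(), category = character()))
  h <- do.call(rbind, hits)
  h <- h[order(h$start, -(h$end - h$start)), , drop = FALSE]
  len <- h$end - h$start
  contained <- vapply(seq_len(nrow(h)), function(i) {
    any(h$start <= h$start[i] & h$end >= h$end[i] & len > len[i])
  }, logical(1))
  h <- h[!contained, , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Extract complete stent records from one vessel section
#'
#' Stent-name matches are paired with dimension tuples by proximity: each
#' name, in textual order, takes the nearest unused dimension after it, or
#' failing that the nearest unused one before it. Only complete
#' (name, diameter, length) triples become records — a name without a
#' pairable dimension (or a dimension without a name) yields no record,
#' mirroring the rule that a missing variable means no stent was inserted.
#'
#' @param section One row of resolved sections (with `vessel`, `body`,
#'   `body_start`).
#' @param lexicon A `pci_lexicon`.
#' @return A data.frame of stent records (possibly zero rows) with columns
#'   `vessel`, `brand_family`, `device_class`, `generation`, `polymer`,
#'   `stent_class`, `diameter_mm`, `length_mm`, `char_start`, `char_end`
#'   (document offsets of the stent name), plus attribute `"dropped"` with
#'   the count of unpairable names.
#' @export
extract_stents <- function(section, lexicon) {
  empty <- empty_stent_records()
  names_hit <- match_terms(section$body, lexicon, "stent")
  dims <- extract_dimensions(section$body)
  if (nrow(names_hit) == 0) return(structure(empty, dropped = 0L))
  used <- rep(FALSE, nrow(dims))
  rows <- list(); dropped <- 0L
  for (i in seq_len(nrow(names_hit))) {
    cand_after <- which(!used & dims$pos >= names_hit$end[i])
    cand_before <- which(!used & dims$pos < names_hit$start[i])
    j <- if (length(cand_after)) cand_after[which.min(dims$pos[cand_after])]
         else if (length(cand_before)) cand_before[which.max(dims$pos[cand_before])]
         else NA_integer_
    if (is.na(j)) { dropped <- dropped + 1L; next }
    used[j] <- TRUE
    cls <- lookup_stent(lexicon, names_hit$term[i])
    rows[[length(rows) + 1L]] <- data.frame(
      vessel = section$vessel, brand_family = cls$brand_family,
      device_class = cls$device_class, generation = cls$generation,
      polymer = cls$polymer, stent_class = cls$stent_class,
      diameter_mm = dims$diameter_mm[j], length_mm = dims$length_mm[j],
      char_start = section$body_start + names_hit$start[i],
      char_end = section$body_start + names_hit$end[i],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  structure(out, dropped = dropped)
}

#' Detect use of a non-compliant (high-pressure) balloon in a section
#'
#' True iff the standalone token "HP" (word boundaries required, so "CHPX"
#' does not trigger) or any registered balloon brand name occurs in the
#' section body.
#'
#' @param body Section body text.
#' @param lexicon A `pci_lexicon`.
#' @return Logical scalar.
#' @export
detect_noncompliant_balloon <- function(body, lexicon) {
  if (grepl("\\bhp\\b", tolower(body), perl = TRUE)) return(TRUE)
  nrow(match_terms(body, lexicon, "balloon")) > 0
}

#' Parse one PCI report into a procedure record
#'
#' Runs the full extraction: section segmentation, vessel-header resolution,
#' stent-name and dimension matching with proximity pairing, the
#' three-variable completeness rule, and balloon detection. Pure function of
#' `(doc, lexicon)`: identical input yields identical output. An unparseable
#' report (no sections) yields an empty record and a logged note, never an
#' error.
#'
#' @param doc A list or one-row data.frame with `report_id`, `text`, and
#'   optionally `patient_id`, `procedure_date`.
#' @param lexicon A `pci_lexicon`.
#' @return A `procedure_record`: list with `report_id`, `patient_id`,
#'   `procedure_date`, `sections` (resolved sections with a per-vessel
#'   `noncompliant_balloon` flag), `records` (stent records),
#'   `unparsed_headers`, and `log` (character vector of parse notes).
#' @export
parse_report <- function(doc, lexicon) {
  stopifnot(!is.null(doc$report_id), !is.null(doc$text))
  log <- character()
  cands <- segment_sections(doc$text)
  if (nrow(cands) == 0)
    log <- c(log, "unparseable report: no section headers found")
  res <- resolve_vessels(cands, lexicon)
  sections <- res$sections
  balloon <- logical(nrow(sections))
  recs <- list()
  for (i in seq_len(nrow(sections))) {
    r <- extract_stents(sections[i, ], lexicon)
    if (attr(r, "dropped") > 0)
      log <- c(log, sprintf("section '%s': %d stent name(s) without pairable dimensions",
                            sections$header[i], attr(r, "dropped")))
    balloon[i] <- detect_noncompliant_balloon(sections$body[i], lexicon)
    recs[[i]] <- r
  }
  records <- if (length(recs)) do.call(rbind, recs) else empty_stent_records()
  if (nrow(sections)) sections$noncompliant_balloon <- balloon
  if (nrow(records)) {
    bmap <- tapply(balloon, sections$vessel, any)
    records$noncompliant_balloon <- unname(bmap[records$vessel])
    rownames(records) <- NULL
  } else {
    records$noncompliant_balloon <- logical(0)
  }
  if (any(records$diameter_mm >= records$length_mm))
    log <- c(log, "atypical dimensions: diameter >= length in some record(s)")
  structure(list(report_id = doc$report_id,
                 patient_id = if (is.null(doc$patient_id)) NA_character_ else doc$patient_id,
                 procedure_date = if (is.null(doc$procedure_date)) NA_character_ else doc$procedure_date,
                 sections = sections, records = records,
                 unparsed_headers = res$unmatched, log = log),
            class = "procedure_record")
}

#' @export
print.procedure_record <- function(x, ...) {
  cat("<procedure_record>", x$report_id, "-", nrow(x$records),
      "stent record(s) across", nrow(x$sections), "vessel section(s)\n")
  if (nrow(x$records)) print(x$records)
  if (length(x$unparsed_headers))
    cat("unparsed headers:", paste(x$unparsed_headers, collapse = ", "), "\n")
  invisible(x)
}

#' Parse a corpus of reports into an extraction table
#'
#' @param corpus A data.frame with columns `report_id`, `text` and optionally
#'   `patient_id`, `procedure_date` (see [read_corpus()]).
#' @param lexicon A `pci_lexicon`.
#' @return A data.frame, one row per extracted stent record:
#'   `report_id`, `patient_id`, `procedure_date`, `vessel`, `brand_family`,
#'   `device_class`, `generation`, `polymer`, `stent_class`, `diameter_mm`,
#'   `length_mm`, `noncompliant_balloon`, `char_start`, `char_end`. The parse
#'   log is attached as attribute `"log"`.
#' @export
parse_corpus <- function(corpus, lexicon) {
  stopifnot(all(c("report_id", "text") %in% names(corpus)))
  logs <- character()
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    rec <- parse_report(corpus[i, ], lexicon)
    if (length(rec$log))
      logs <<- c(logs, paste0(rec$report_id, ": ", rec$log))
    r <- rec$records
    if (nrow(r) == 0) return(NULL)
    cbind(data.frame(report_id = rec$report_id, patient_id = rec$patient_id,
                     procedure_date = rec$procedure_date,
                     stringsAsFactors = FALSE),
          r)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(report_id = character(), patient_id = character(),
               procedure_date = character(), vessel = character(),
               brand_family = character(), device_class = character(),
               generation = character(), polymer = character(),
               stent_class = character(), diameter_mm = numeric(),
               length_mm = numeric(), char_start = integer(),
               char_end = integer(), noncompliant_balloon = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, log = logs)
}

#' Read a report corpus from a directory plus manifest
#'
#' The corpus layout is one UTF-8 `.txt` file per report, named
#' `<report_id>.txt`, alongside a manifest CSV with columns `report_id`,
#' `patient_id`, `procedure_date` (ISO-8601).
#'
#' @param dir Directory containing the `.txt` files.
#' @param manifest Path to the manifest CSV (default `manifest.csv` in `dir`).
#' @return A corpus data.frame usable by [parse_corpus()].
#' @export
read_corpus <- function(dir, manifest = file.path(dir, "manifest.csv")) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("report_id", "patient_id", "procedure_date") %in% names(man)))
  man$text <- vapply(man$report_id, function(id) {
    paste(readLines(file.path(dir, paste0(id, ".txt")), encoding = "UTF-8",
                    warn = FALSE), collapse = "\n")
  }, character(1))
  man
}

#' Write an extraction table to CSV
#'
#' @param extraction Output of [parse_corpus()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_extraction <- function(extraction, path) {
  utils::write.csv(as.data.frame(extraction), path, row.names = FALSE)
  invisible(path)
}
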