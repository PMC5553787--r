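test_that("section segmentation follows the newline-to-colon rule", {
  s <- segment_sections("LAD:\n Xience 3.0/28mm\nRCA:\n Nobori 2.5/18mm")
  expect_identical(s$header, c("lad", "rca"))
  expect_match(s$body[1], "Xience")
  expect_match(s$body[2], "Nobori")
  expect_identical(nrow(segment_sections("no colons here")), 0L)
  expect_identical(nrow(segment_sections("")), 0L)
  one <- segment_sections("OM: Promus 2.75/24mm")
  expect_identical(one$header, "om")
  expect_identical(trimws(one$body), "Promus 2.75/24mm")
  # only the first colon delimits; long pre-colon prose is not a header
  s2 <- segment_sections("LAD: note: staged\nthis sentence is far longer than forty characters before: colon")
  expect_identical(s2$header, "lad")
  expect_match(s2$body, "note: staged")
})

test_that("section offsets are 0-based, in-document, ordered and non-overlapping", {
  txt <- "preamble line\nLAD:\n Xience 3.0/28mm\nOM:\n Nobori 2.5/18mm"
  s <- segment_sections(txt)
  expect_true(all(s$sec_start >= 0 & s$sec_end <= nchar(txt)))
  expect_true(all(diff(s$sec_start) > 0))
  expect_true(all(s$sec_end[-nrow(s)] <= s$sec_start[-1]))
  # body is the exact substring at its offsets
  for (i in seq_len(nrow(s)))
    expect_identical(substr(txt, s$body_start[i] + 1, s$sec_end[i]), s$body[i])
})

test_that("vessel resolution keeps matches and reports the rest", {
  cands <- segment_sections("LAD:\n x\nFindings:\n y\nD1:\n z\nOM:\n w")
  res <- resolve_vessels(cands, LEX)
  expect_identical(res$sections$vessel, c("LAD", "LAD", "LCx"))
  expect_identical(res$unmatched, "findings")
  empty <- resolve_vessels(segment_sections(""), LEX)
  expect_identical(nrow(empty$sections), 0L)
  expect_identical(empty$unmatched, character(0))
})

test_that("dimension extraction accepts the documented dialects only", {
  d <- extract_dimensions("Xience 3.0/28mm deployed")
  expect_equal(d$diameter_mm, 3.0)
  expect_equal(d$length_mm, 28)
  d2 <- extract_dimensions("2.75/24 mm then 3.5/12mm")
  expect_equal(d2$diameter_mm, c(2.75, 3.5))
  expect_equal(d2$length_mm, c(24, 12))
  expect_true(all(diff(d2$pos) > 0))
  expect_identical(nrow(extract_dimensions("inflated to 14 atm")), 0L)
  expect_identical(nrow(extract_dimensions("")), 0L)
})

test_that("only complete name-diameter-length triples become stent records", {
  sec <- function(body, vessel = "LAD")
    data.frame(vessel = vessel, body = body, body_start = 0L,
               stringsAsFactors = FALSE)
  r <- extract_stents(sec("Xience 3.0/28mm"), LEX)
  expect_identical(nrow(r), 1L)
  expect_identical(r$brand_family, "Xience family")
  # missing dimensions: no record at all
  r2 <- extract_stents(sec("Nobori"), LEX)
  expect_identical(nrow(r2), 0L)
  expect_identical(attr(r2, "dropped"), 1L)
  # dimensions without a name: no record
  expect_identical(nrow(extract_stents(sec("ballooned 3.0/20mm"), LEX)), 0L)
  # two names, two dimensions, paired in order
  r3 <- extract_stents(sec("Promus 2.75/24mm, Promus 2.5/18mm", "LCx"), LEX)
  expect_identical(nrow(r3), 2L)
  expect_equal(r3$diameter_mm, c(2.75, 2.5))
  # dimension before the name is used when none follows
  r4 <- extract_stents(sec("3.0/28mm Xience deployed"), LEX)
  expect_equal(r4$length_mm, 28)
  # family-member spelling counts once, not once per nested term
  r5 <- extract_stents(sec("Xience Prime 3.0/28mm"), LEX)
  expect_identical(nrow(r5), 1L)
})

test_that("non-compliant balloon detection needs word boundaries or a brand", {
  expect_true(detect_noncompliant_balloon("post-dilated with HP 3.5/8mm", LEX))
  expect_true(detect_noncompliant_balloon("NC Trek 3.0/12mm used", LEX))
  expect_false(detect_noncompliant_balloon("Xience 3.0/28mm", LEX))
  expect_false(detect_noncompliant_balloon("CHPX catheter", LEX))
})

test_that("parse_report composes the steps and is deterministic", {
  doc <- list(report_id = "r9",
              text = "LAD:\n Xience 3.0/28mm\nRCA:\n Nobori 2.5/18mm\n HP 3.5/8mm")
  a <- parse_report(doc, LEX)
  b <- parse_report(doc, LEX)
  expect_identical(a, b)
  ps <- to_pair_set(a)
  expect_identical(ps$stent_label, c("DES2-DP", "DES2-BP"))
  expect_true(a$records$noncompliant_balloon[a$records$vessel == "RCA"])
  expect_false(a$records$noncompliant_balloon[a$records$vessel == "LAD"])
  # unparseable report: empty record plus a note, no error
  bad <- parse_report(list(report_id = "r0", text = "plain prose"), LEX)
  expect_identical(nrow(bad$records), 0L)
  expect_match(bad$log, "unparseable")
  # diagnostic-only report: sections but no stent records
  diag <- parse_report(list(report_id = "r1",
                            text = "LAD:\n 40% stenosis, no intervention"), LEX)
  expect_identical(nrow(diag$sections), 1L)
  expect_identical(nrow(diag$records), 0L)
})

test_that("extracted records never carry a missing field", {
  syn <- clean_synthetic(n_patients = 60, seed = 9, typo_rate = 0.2)
  ex <- parse_corpus(syn$corpus, LEX)
  core <- c("report_id", "vessel", "brand_family", "stent_class",
            "diameter_mm", "length_mm", "noncompliant_balloon")
  expect_false(anyNA(ex[, core]))
  expect_true(all(ex$diameter_mm > 0 & ex$length_mm > 0))
})

test_that("round trip: lexicon-covered noise leaves extraction equal to truth", {
  syn <- clean_synthetic(n_patients = 80, seed = 3)
  ex <- parse_corpus(syn$corpus, LEX)
  pred <- to_pair_set(ex)
  gold <- to_pair_set(export_gold(syn$truth))
  # per-report equality, not just aggregate counts
  expect_identical(pair_frac_recalled(pred, gold, syn$corpus$report_id)$sensitivity, 1)
  expect_identical(nrow(pred), nrow(gold))
  expect_setequal(paste(pred$report_id, pred$vessel, pred$stent_label),
                  paste(gold$report_id, gold$vessel, gold$stent_label))
  # brand-granularity truth also round-trips
  predb <- to_pair_set(ex, "brand")
  goldb <- to_pair_set(export_gold(syn$truth), "brand")
  expect_setequal(paste(predb$report_id, predb$vessel, predb$stent_label),
                  paste(goldb$report_id, goldb$vessel, goldb$stent_label))
})

test_that("unregistered-typo noise degrades recall monotonically at perfect precision", {
  rates <- c(0, 0.2, 0.5, 1)
  cfg0 <- generator_config(n_patients = 60, seed = 21, variant_rate = 0.1,
                           decoy_rate = 0.2)
  truth <- generate_cohort(cfg0)
  gold <- to_pair_set(export_gold(truth))
  recalls <- numeric(length(rates))
  for (k in seq_along(rates)) {
    cfg <- generator_config(n_patients = 60, seed = 21, variant_rate = 0.1,
                            decoy_rate = 0.2, typo_rate = rates[k])
    corpus <- render_reports(truth, cfg)
    pred <- to_pair_set(parse_corpus(corpus, LEX))
    m <- pair_frac_recalled(pred, gold, corpus$report_id)
    recalls[k] <- m$sensitivity
    if (nrow(pred) > 0) expect_identical(m$ppv, 1)
  }
  expect_true(all(diff(recalls) <= 0))
  expect_identical(recalls[1], 1)
  # destructive limit: everything mangled, recall zero, precision undefined
  cfg1 <- generator_config(n_patients = 60, seed = 21, variant_rate = 0.1,
                           decoy_rate = 0.2, typo_rate = 1)
  pred1 <- to_pair_set(parse_corpus(render_reports(truth, cfg1), LEX))
  m1 <- pair_frac_recalled(pred1, gold, export_gold(truth)$report_id)
  expect_identical(m1$sensitivity, 0)
  expect_true(is.na(m1$ppv))
})

test_that("corpus directory round-trips through the manifest layout", {
  syn <- clean_synthetic(n_patients = 10, seed = 2)
  dir <- withr::local_tempdir()
  write_synthetic(syn$truth, syn$corpus, dir)
  back <- read_corpus(file.path(dir, "corpus"))
  expect_identical(back$report_id, syn$corpus$report_id)
  expect_identical(back$text, syn$corpus$text)
  ex1 <- parse_corpus(back, LEX)
  ex2 <- parse_corpus(syn$corpus, LEX)
  expect_identical(as.data.frame(ex1), as.data.frame(ex2))
})
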