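#' Coronary vessel categories
#'
#' The four target-vessel categories used throughout the package. Every
#' vessel surface form in a lexicon maps to exactly one of these.
#'
#' @return Character vector `c("LAD", "LCx", "LM", "RCA")`.
#' @export
vessel_categories <- function() c("LAD", "LCx", "LM", "RCA")

#' Stent category labels at "category" granularity
#'
#' Bare-metal stents, first-generation drug-eluting stents, and
#' second-generation DES split by polymer (durable vs biodegradable).
#'
#' @return Character vector of the four class labels.
#' @export
stent_class_labels <- function() c("BMS", "DES1", "DES2-DP", "DES2-BP")

#' Derive the stent class label from the classification triple
#'
#' @param device_class "BMS" or "DES".
#' @param generation "none", "first" or "second".
#' @param polymer "none", "durable" or "biodegradable".
#' @return One of [stent_class_labels()]. Vectorized.
#' @export
stent_class_label <- function(device_class, generation, polymer) {
  out <- character(length(device_class))
  out[device_class == "BMS"] <- "BMS"
  out[device_class == "DES" & generation == "first"] <- "DES1"
  out[device_class == "DES" & generation == "second" & polymer == "durable"] <- "DES2-DP"
  out[device_class == "DES" & generation == "second" & polymer == "biodegradable"] <- "DES2-BP"
  if (any(out == ""))
    stop("unclassifiable (device_class, generation, polymer) combination")
  out
}

#' Normalize a surface form for lexicon lookup
#'
#' Case-folds, strips surrounding whitespace and punctuation, and collapses
#' internal whitespace runs to a single space. Internal punctuation (as in
#' "lm-lad") is preserved. Idempotent; the empty string maps to itself.
#'
#' @param raw Character vector of raw tokens.
#' @return Character vector of normalized tokens.
#' @export
#' @examples
#' normalize_token("  LAD ")          # "lad"
#' normalize_token("Coroflex  Blue")  # "coroflex blue"
normalize_token <- function(raw) {
  x <- tolower(as.character(raw))
  x <- gsub("\\s+", " ", x)
  x <- gsub("^[[:space:][:punct:]]+", "", x)
  x <- gsub("[[:space:][:punct:]]+$", "", x)
  x
}

lexicon_columns <- c("term", "kind", "category", "device_class",
                     "generation", "polymer")

validate_lexicon <- function(df) {
  stopifnot(is.data.frame(df), all(lexicon_columns %in% names(df)))
  df <- df[, lexicon_columns]
  df$term <- normalize_token(df$term)
  if (anyDuplicated(df$term))
    stop("lexicon terms must be unique after normalization: ",
         paste(df$term[duplicated(df$term)], collapse = ", "))
  if (!all(df$kind %in% c("vessel", "stent", "balloon")))
    stop("lexicon kind must be vessel, stent or balloon")
  v <- df[df$kind == "vessel", ]
  if (!all(v$category %in% vessel_categories()))
    stop("vessel category must be one of ", paste(vessel_categories(), collapse = ", "))
  s <- df[df$kind == "stent", ]
  bad <- (s$polymer != "none") != (s$generation == "second")
  if (any(bad))
    stop("stent rows must have a polymer iff second-generation: ",
         paste(s$term[bad], collapse = ", "))
  bad <- (s$generation == "none") != (s$device_class == "BMS")
  if (any(bad))
    stop("generation 'none' is reserved for BMS: ", paste(s$term[bad], collapse = ", "))
  # one classification per brand family
  key <- unique(s[, c("category", "device_class", "generation", "polymer")])
  if (anyDuplicated(key$category))
    stop("a brand family has more than one (class, generation, polymer) assignment")
  structure(df, class = c("pci_lexicon", "data.frame"))
}

#' Read a term lexicon from a delimited file
#'
#' The file is pipe-delimited UTF-8 with a header row and columns
#' `term|kind|category|device_class|generation|polymer`. `kind` is one of
#' `vessel`, `stent`, `balloon`; `category` holds the vessel category for
#' vessels and the brand family for stents.
#'
#' @param path File path.
#' @return A `pci_lexicon` (a validated data.frame).
#' @export
read_lexicon <- function(path) {
  df <- utils::read.table(path, sep = "|", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          encoding = "UTF-8", na.strings = character())
  validate_lexicon(df)
}

#' Write a term lexicon to a delimited file
#'
#' @param lexicon A `pci_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(as.data.frame(lexicon), path, sep = "|", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The default vessel/stent/balloon lexicon
#'
#' Loads the lexicon shipped with the package: the four vessel categories
#' with their branch terms, the stent brand families with their device
#' class / generation / polymer assignments, common family-member spellings,
#' and a small set of non-compliant balloon brand names.
#'
#' Endeavor is classified as a second-generation durable-polymer DES by
#' default; `endeavor_first_gen = TRUE` reclassifies it as first-generation
#' (the convention of some registries).
#'
#' @param endeavor_first_gen Reclassify Endeavor as first-generation DES.
#' @return A `pci_lexicon`.
#' @export
default_lexicon <- function(endeavor_first_gen = FALSE) {
  path <- system.file("extdata", "lexicon_default.tsv", package = "pcidw")
  lex <- read_lexicon(path)
  if (endeavor_first_gen) {
    i <- lex$kind == "stent" & lex$category == "Endeavor"
    lex$generation[i] <- "first"
    lex$polymer[i] <- "none"
    lex <- validate_lexicon(as.data.frame(lex))
  }
  lex
}

#' Look up a vessel category
#'
#' @param lexicon A `pci_lexicon`.
#' @param token A normalized token (see [normalize_token()]).
#' @return The vessel category label, or `NA_character_` if the token is not
#'   a registered vessel form.
#' @export
#' @examples
#' lex <- default_lexicon()
#' lookup_vessel(lex, "om")   # "LCx"
#' lookup_vessel(lex, "pda")  # "RCA"
lookup_vessel <- function(lexicon, token) {
  i <- match(token, lexicon$term)
  out <- ifelse(!is.na(i) & lexicon$kind[i] == "vessel",
                lexicon$category[i], NA_character_)
  unname(out)
}

#' Look up a stent brand family and its classification
#'
#' @param lexicon A `pci_lexicon`.
#' @param token A normalized token.
#' @return A one-row data.frame with columns `brand_family`, `device_class`,
#'   `generation`, `polymer`, `stent_class`; or `NULL` if unregistered.
#' @export
#' @examples
#' lex <- default_lexicon()
#' lookup_stent(lex, "nobori")$stent_class  # "DES2-BP"
lookup_stent <- function(lexicon, token) {
  i <- match(token, lexicon$term)
  if (is.na(i) || lexicon$kind[i] != "stent") return(NULL)
  row <- lexicon[i, ]
  data.frame(brand_family = row$category,
             device_class = row$device_class,
             generation = row$generation,
             polymer = row$polymer,
             stent_class = stent_class_label(row$device_class, row$generation,
                                             row$polymer),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Register a spelling or abbreviation variant
#'
#' Adds `variant` (after normalization) as a new surface form of an already
#' registered target. `target` may be a vessel category, a stent brand
#' family, a balloon label, or any registered surface form of one of those.
#'
#' @param lexicon A `pci_lexicon`.
#' @param variant New surface form.
#' @param target Existing category/brand label or registered term.
#' @return The extended lexicon. Registering a variant that already resolves
#'   to the same target is a no-op; to a different target, an error.
#' @export
register_variant <- function(lexicon, variant, target) {
  v <- normalize_token(variant)
  if (v == "") stop("variant normalizes to the empty string")
  tmpl <- lexicon[lexicon$category == target, ]
  if (nrow(tmpl) == 0) tmpl <- lexicon[lexicon$term == normalize_token(target), ]
  if (nrow(tmpl) == 0) stop("target not registered: ", target)
  tmpl <- tmpl[1, ]
  j <- match(v, lexicon$term)
  if (!is.na(j)) {
    if (lexicon$category[j] == tmpl$category && lexicon$kind[j] == tmpl$kind)
      return(lexicon)
    stop(sprintf("conflict: '%s' already maps to %s (%s)",
                 v, lexicon$category[j], lexicon$kind[j]))
  }
  tmpl$term <- v
  validate_lexicon(rbind(as.data.frame(lexicon), as.data.frame(tmpl)))
}
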