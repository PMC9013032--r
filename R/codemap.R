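#' The 30-category Elixhauser comorbidity registry
#'
#' Ordered short names of the 30 Elixhauser comorbidity categories used as
#' the default registry. The order is fixed so that comorbidity feature
#' vectors and model coefficients are positionally stable. The default set
#' follows the HCUP ICD-10-CM comorbidity software naming (hypertension is
#' split into uncomplicated `HTN` and complicated `HTNCX`; there is no
#' cardiac-arrhythmia category).
#'
#' @return Character vector of length 30 with unique category short names.
#' @export
#' @examples
#' length(elix_registry())  # 30
elix_registry <- function() {
  c("CHF", "VALVE", "PULMCIRC", "PERIVASC", "HTN", "HTNCX", "PARA",
    "NEURO", "CHRNLUNG", "DM", "DMCX", "HYPOTHY", "RENLFAIL", "LIVER",
    "ULCER", "AIDS", "LYMPH", "METS", "TUMOR", "ARTH", "COAG", "OBESE",
    "WGHTLOSS", "LYTES", "BLDLOSS", "ANEMDEF", "ALCOHOL", "DRUG",
    "PSYCH", "DEPRESS")
}

N_BODY_SYSTEMS <- 18L

icd10_pattern <- "^[A-Z][0-9]{2}[0-9A-Z]{0,4}$"

#' Normalize an ICD-10-CM diagnosis code
#'
#' Strips surrounding whitespace, removes the dot, and upper-cases the code,
#' yielding the canonical dotless form used as the lookup key everywhere in
#' the package. Normalization is idempotent. Codes whose normalized form
#' does not match the ICD-10-CM syntax (a letter, two digits, then up to
#' four alphanumerics) are flagged rather than silently passed through.
#'
#' @param x character vector of raw codes.
#' @param strict if `TRUE`, invalid codes are a fatal error; otherwise they
#'   become `NA` with a warning.
#' @return Character vector of canonical codes (`NA` for invalid entries
#'   unless `strict`).
#' @export
#' @examples
#' normalize_code("e87.70")   # "E8770"
#' normalize_code("  i10 ")   # "I10"
normalize_code <- function(x, strict = FALSE) {
  out <- toupper(gsub(".", "", trimws(as.character(x)), fixed = TRUE))
  bad <- !is.na(out) & !grepl(icd10_pattern, out)
  bad <- bad | is.na(out) | out == ""
  if (any(bad)) {
    shown <- utils::head(unique(x[bad]), 5)
    msg <- paste0("invalid ICD-10-CM code(s): ",
                  paste(sQuote(shown), collapse = ", "))
    if (strict) stop_fatal(msg)
    warning(msg, call. = FALSE)
    out[bad] <- NA_character_
  }
  out
}

#' Construct a reference-map object
#'
#' Bundles the four lookup tables that turn ICD-10-CM codes into model-ready
#' categories: body system (1-18), CC/MCC status, Elixhauser comorbidity
#' categories, and POA-reporting exemption. Most users will call
#' [load_reference_maps()] (files) or [generate_reference_maps()]
#' (synthetic) instead of this constructor.
#'
#' @param body_system named integer vector; names are canonical codes,
#'   values in 1..18.
#' @param ccmcc named character vector over codes with values `"CC"` or
#'   `"MCC"`; any code absent from this table is implicitly `"NONE"`.
#' @param elixhauser data.frame with columns `code`, `category`; a code may
#'   appear on several rows for different categories.
#' @param poa_exempt character vector of POA-exempt codes.
#' @param version_label free-text label recorded in every downstream report
#'   (severity models should be refreshed when the underlying code maps
#'   change, so provenance matters).
#' @param registry category registry, default [elix_registry()].
#' @return An object of class `reference_maps`.
#' @export
reference_maps <- function(body_system = integer(), ccmcc = character(),
                           elixhauser = data.frame(code = character(),
                                                   category = character()),
                           poa_exempt = character(),
                           version_label = "unversioned",
                           registry = elix_registry()) {
  if (length(registry) != length(unique(registry))) {
    stop_fatal("Elixhauser registry names must be unique")
  }
  body_system <- as.integer(body_system) |>
    stats::setNames(names(body_system))
  check_codes <- function(codes, what) {
    bad <- codes[!grepl(icd10_pattern, codes)]
    if (length(bad)) {
      stop_fatal(what, ": non-canonical code(s) ",
                 paste(sQuote(utils::head(bad, 5)), collapse = ", "))
    }
  }
  check_codes(names(body_system), "body_system")
  check_codes(names(ccmcc), "ccmcc")
  check_codes(elixhauser$code, "elixhauser")
  check_codes(poa_exempt, "poa_exempt")
  if (length(body_system) &&
      (any(body_system < 1L) || any(body_system > N_BODY_SYSTEMS))) {
    stop_fatal("body system values must be integers in [1, ",
               N_BODY_SYSTEMS, "]")
  }
  if (length(ccmcc) && !all(ccmcc %in% c("CC", "MCC"))) {
    stop_fatal("CC/MCC levels must be 'CC' or 'MCC'")
  }
  if (nrow(elixhauser) && !all(elixhauser$category %in% registry)) {
    bad <- setdiff(unique(elixhauser$category), registry)
    stop_fatal("unknown Elixhauser categories: ",
               paste(sQuote(bad), collapse = ", "))
  }
  structure(
    list(body_system = body_system,
         ccmcc = ccmcc,
         elixhauser = unique(elixhauser[c("code", "category")]),
         poa_exempt = unique(poa_exempt),
         version_label = version_label,
         registry = registry),
    class = "reference_maps")
}

#' @export
print.reference_maps <- function(x, ...) {
  cat("<reference_maps> ", x$version_label, "\n",
      "  body-system codes: ", length(x$body_system), "\n",
      "  CC/MCC codes:      ", length(x$ccmcc), "\n",
      "  Elixhauser rows:   ", nrow(x$elixhauser),
      " (", length(unique(x$elixhauser$category)), " categories)\n",
      "  POA-exempt codes:  ", length(x$poa_exempt), "\n", sep = "")
  invisible(x)
}

#' Look up codes in a reference map
#'
#' Vectorized lookups. Codes absent from a table resolve to the neutral
#' value (`NA` body system, `"NONE"` CC/MCC status, empty category set,
#' not exempt) and never raise.
#'
#' @param maps a `reference_maps` object.
#' @param codes character vector of canonical codes.
#' @return `body_system_of`: integer vector (NA when unmapped);
#'   `ccmcc_of`: character vector over `{"NONE","CC","MCC"}`;
#'   `is_poa_exempt`: logical vector; `elix_of`: character vector of
#'   categories for a single code.
#' @export
body_system_of <- function(maps, codes) {
  unname(maps$body_system[match(codes, names(maps$body_system))])
}

#' @rdname body_system_of
#' @export
ccmcc_of <- function(maps, codes) {
  out <- unname(maps$ccmcc[match(codes, names(maps$ccmcc))])
  out[is.na(out)] <- "NONE"
  out
}

#' @rdname body_system_of
#' @export
is_poa_exempt <- function(maps, codes) {
  codes %in% maps$poa_exempt
}

#' @rdname body_system_of
#' @param code a single canonical code (for `elix_of`).
#' @export
elix_of <- function(maps, code) {
  stopifnot(length(code) == 1L)
  maps$elixhauser$category[maps$elixhauser$code == code]
}

# Tolerant reader for one two/three-column mapping file. Accepts an
# optional header row and dotted or dotless codes; collects malformed
# codes with their line numbers and reports them all at once.
read_map_file <- function(path, cols) {
  if (!file.exists(path)) stop_fatal("mapping file not found: ", path)
  raw <- tryCatch(
    utils::read.csv(path, header = FALSE, colClasses = "character",
                    strip.white = TRUE, blank.lines.skip = TRUE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                         cols))
    attr(out, "line") <- integer()
    return(out)
  }
  if (ncol(raw) < length(cols)) {
    stop_fatal(path, ": expected ", length(cols), " column(s), found ",
               ncol(raw))
  }
  raw <- raw[seq_along(cols)]
  names(raw) <- cols
  line <- seq_len(nrow(raw))
  # header detection: first row's code field must normalize to a valid code
  first <- suppressWarnings(normalize_code(raw$code[1]))
  if (is.na(first)) {
    raw <- raw[-1, , drop = FALSE]
    line <- line[-1]
  }
  norm <- suppressWarnings(normalize_code(raw$code))
  if (anyNA(norm)) {
    bad <- which(is.na(norm))
    stop_fatal(path, ": malformed code(s) at line(s) ",
               paste(line[bad], collapse = ", "), ": ",
               paste(sQuote(utils::head(raw$code[bad], 10)), collapse = ", "))
  }
  raw$code <- norm
  keep <- !duplicated(raw)             # identical duplicate rows collapse
  out <- raw[keep, , drop = FALSE]
  attr(out, "line") <- line[keep]
  out
}

# Fatal when a code maps to conflicting values in a single-valued table.
check_conflicts <- function(df, path) {
  dup <- unique(df$code[duplicated(df$code)])
  if (length(dup)) {
    stop_fatal(path, ": conflicting duplicate rows for code(s) ",
               paste(sQuote(utils::head(dup, 10)), collapse = ", "))
  }
  df
}

#' Load the four reference mapping tables from delimited files
#'
#' Reads the canonical comma-delimited layouts (an optional header row and
#' dotted or dotless codes are tolerated):
#' * `body_systems`: columns `code,body_system` with body system in 1-18;
#' * `ccmcc`: columns `code,level` with level `CC` or `MCC`;
#' * `elixhauser`: columns `code,category` (a code may appear on multiple
#'   rows for different categories);
#' * `poa_exempt`: a single `code` column.
#'
#' Malformed codes are reported with their line numbers; duplicate rows
#' with conflicting values are fatal, identical duplicates are collapsed.
#'
#' @param body_systems,ccmcc,elixhauser,poa_exempt file paths.
#' @param version_label provenance label stored on the result.
#' @param registry Elixhauser category registry (default [elix_registry()]).
#' @return A [reference_maps] object.
#' @export
load_reference_maps <- function(body_systems, ccmcc, elixhauser, poa_exempt,
                                version_label = "unversioned",
                                registry = elix_registry()) {
  bs <- check_conflicts(read_map_file(body_systems,
                                      c("code", "body_system")),
                        body_systems)
  bs_val <- suppressWarnings(as.integer(bs$body_system))
  if (anyNA(bs_val) && nrow(bs)) {
    stop_fatal(body_systems, ": non-integer body system value(s)")
  }
  cc <- check_conflicts(read_map_file(ccmcc, c("code", "level")), ccmcc)
  if (nrow(cc) && !all(cc$level %in% c("CC", "MCC"))) {
    stop_fatal(ccmcc, ": level must be CC or MCC, got ",
               paste(sQuote(setdiff(unique(cc$level), c("CC", "MCC"))),
                     collapse = ", "))
  }
  el <- read_map_file(elixhauser, c("code", "category"))
  ex <- read_map_file(poa_exempt, "code")
  reference_maps(
    body_system = stats::setNames(bs_val, bs$code),
    ccmcc = stats::setNames(cc$level, cc$code),
    elixhauser = el[c("code", "category")],
    poa_exempt = ex$code,
    version_label = version_label,
    registry = registry)
}

#' Write a reference-map object back to its canonical files
#'
#' Inverse of [load_reference_maps()]: writes `body_systems.csv`,
#' `ccmcc.csv`, `elixhauser.csv` and `poa_exempt.csv` (with headers) into
#' `dir`. Reloading the written files reproduces identical lookup
#' behaviour for every code.
#'
#' @param maps a `reference_maps` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_reference_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("body_systems.csv", "ccmcc.csv",
                            "elixhauser.csv", "poa_exempt.csv"))
  utils::write.csv(
    data.frame(code = names(maps$body_system),
               body_system = unname(maps$body_system)),
    paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(code = names(maps$ccmcc), level = unname(maps$ccmcc)),
    paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(maps$elixhauser, paths[3], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(code = maps$poa_exempt), paths[4],
                   row.names = FALSE, quote = FALSE)
  invisible(stats::setNames(paths, c("body_systems", "ccmcc",
                                     "elixhauser", "poa_exempt")))
}
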