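#' Bundle encounters and their diagnoses into an encounter set
#'
#' The package stores encounter-level data relationally: one row per
#' encounter plus a long table of coded diagnoses. This mirrors how
#' administrative claims extracts are laid out and lets feature
#' construction vectorize over hundreds of thousands of rows.
#'
#' @param encounters data.frame with columns `encounter_id`, `age`, `sex`,
#'   `race`, `facility`, `discharge_month`, `admit_soi`, `discharge_soi`
#'   and optional logicals `cds_reviewed`, `cds_queried`.
#' @param diagnoses data.frame with columns `encounter_id`, `code`
#'   (canonical ICD-10-CM), `poa` (one of `Y`, `N`, `U`, `W`, `1`, or
#'   blank) and `position` (`"principal"` or `"secondary"`). Encounters
#'   with no diagnoses are legal; encounters with diagnoses must have
#'   exactly one principal code.
#' @param truth optional data.frame of latent simulation truth (see
#'   [generate_encounters()]).
#' @return An object of class `encounter_set`.
#' @export
encounter_set <- function(encounters, diagnoses, truth = NULL) {
  req <- c("encounter_id", "age", "admit_soi", "discharge_soi")
  miss <- setdiff(req, names(encounters))
  if (length(miss)) {
    stop_fatal("encounters missing column(s): ", paste(miss, collapse = ", "))
  }
  for (col in c("sex", "race", "facility", "discharge_month",
                "cds_reviewed", "cds_queried")) {
    if (!col %in% names(encounters)) encounters[[col]] <- NA
  }
  if (anyDuplicated(encounters$encounter_id)) {
    stop_fatal("duplicate encounter_id values")
  }
  if (!all(encounters$admit_soi %in% 1:4) ||
      !all(encounters$discharge_soi %in% 1:4)) {
    stop_fatal("admit_soi and discharge_soi must be in {1,2,3,4}")
  }
  if (any(encounters$age < 18)) {
    stop_fatal("cohort is restricted to adult inpatients (age >= 18)")
  }
  miss <- setdiff(c("encounter_id", "code", "poa", "position"),
                  names(diagnoses))
  if (length(miss)) {
    stop_fatal("diagnoses missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(diagnoses)) {
    if (!all(diagnoses$position %in% c("principal", "secondary"))) {
      stop_fatal("diagnosis position must be 'principal' or 'secondary'")
    }
    if (!all(diagnoses$poa %in% c("Y", "N", "U", "W", "1", ""))) {
      stop_fatal("POA flags must be one of Y, N, U, W, 1, or blank")
    }
    if (!all(diagnoses$encounter_id %in% encounters$encounter_id)) {
      stop_fatal("diagnoses reference unknown encounter_id values")
    }
    n_principal <- table(factor(
      diagnoses$encounter_id[diagnoses$position == "principal"],
      levels = unique(diagnoses$encounter_id)))
    if (any(n_principal != 1L)) {
      stop_fatal("each encounter with diagnoses needs exactly one ",
                 "principal diagnosis")
    }
  }
  structure(list(encounters = encounters, diagnoses = diagnoses,
                 truth = truth),
            class = "encounter_set")
}

#' @export
print.encounter_set <- function(x, ...) {
  cat("<encounter_set> ", nrow(x$encounters), " encounters, ",
      nrow(x$diagnoses), " coded diagnoses",
      if (!is.null(x$truth)) " (latent truth attached)", "\n", sep = "")
  invisible(x)
}

#' Subset an encounter set by encounter id
#'
#' @param encset an `encounter_set`.
#' @param ids encounter ids to keep.
#' @return A new `encounter_set` restricted to `ids` (diagnoses and latent
#'   truth follow).
#' @export
subset_encounters <- function(encset, ids) {
  keep_e <- encset$encounters$encounter_id %in% ids
  keep_d <- encset$diagnoses$encounter_id %in% ids
  truth <- encset$truth
  if (!is.null(truth)) {
    truth <- truth[truth$encounter_id %in% ids, , drop = FALSE]
  }
  encounter_set(encset$encounters[keep_e, , drop = FALSE],
                encset$diagnoses[keep_d, , drop = FALSE],
                truth = truth)
}

#' Select diagnosis codes by phase
#'
#' Discharge severity uses every coded diagnosis. Admission severity uses
#' only the diagnoses present on admission -- POA flag in `admit_poa`
#' (default `Y` and `W`, the flags CMS treats as present for payment) --
#' plus any code on the POA-reporting-exempt list regardless of its flag.
#' The admission selection is always a subset of the discharge selection.
#'
#' @param diagnoses diagnoses data.frame (see [encounter_set()]).
#' @param phase `"discharge"` or `"admission"`.
#' @param maps a [reference_maps] object (used for the exempt list).
#' @param admit_poa POA flag values counted as present on admission.
#' @return The selected rows of `diagnoses`.
#' @export
select_codes <- function(diagnoses, phase = c("discharge", "admission"),
                         maps, admit_poa = c("Y", "W")) {
  phase <- match.arg(phase)
  if (phase == "discharge") return(diagnoses)
  keep <- diagnoses$poa %in% admit_poa | is_poa_exempt(maps, diagnoses$code)
  diagnoses[keep, , drop = FALSE]
}

#' Body-system CC/MCC ordinal indicators
#'
#' Collapses a set of coded diagnoses into one 3-level ordinal severity
#' indicator per body system: level 0 when no diagnosis falls in the
#' system, level 1 when at least one does but none is a CC or MCC code,
#' level 2 when at least one CC or MCC code falls in the system. Codes
#' without a body-system mapping contribute nothing (a warning counts
#' them); the order of the diagnosis list is irrelevant.
#'
#' @param diagnoses diagnoses data.frame.
#' @param maps a [reference_maps] object.
#' @param encounter_ids row universe of the result; defaults to the ids
#'   present in `diagnoses`. Ids without diagnoses get an all-zero row.
#' @return Integer matrix, one row per encounter id, 18 columns
#'   (`bs01`..`bs18`), entries in {0,1,2}.
#' @export
body_system_levels <- function(diagnoses, maps,
                               encounter_ids = unique(diagnoses$encounter_id)) {
  n <- length(encounter_ids)
  out <- matrix(0L, n, N_BODY_SYSTEMS,
                dimnames = list(encounter_ids,
                                sprintf("bs%02d", seq_len(N_BODY_SYSTEMS))))
  if (!nrow(diagnoses) || !n) return(out)
  sys <- body_system_of(maps, diagnoses$code)
  unmapped <- sum(is.na(sys))
  if (unmapped > 0) {
    warning(unmapped, " diagnosis code(s) without a body-system mapping ",
            "were ignored", call. = FALSE)
  }
  ei <- match(diagnoses$encounter_id, encounter_ids)
  keep <- !is.na(sys) & !is.na(ei)
  if (!any(keep)) return(out)
  sev <- 1L + as.integer(ccmcc_of(maps, diagnoses$code[keep]) != "NONE")
  idx <- cbind(ei[keep], sys[keep])
  # assign in increasing severity so the per-cell maximum lands last
  o <- order(sev)
  out[idx[o, , drop = FALSE]] <- sev[o]
  out
}

#' Elixhauser comorbidity flags
#'
#' One binary flag per registry category: 1 when at least one
#' secondary-position diagnosis maps to the category. The principal
#' diagnosis is excluded -- Elixhauser comorbidities are by construction
#' conditions coexisting with, not causing, the admission.
#'
#' @inheritParams body_system_levels
#' @return Integer matrix, one row per encounter id, 30 columns named by
#'   the registry, entries in {0,1}.
#' @export
elixhauser_flags <- function(diagnoses, maps,
                             encounter_ids = unique(diagnoses$encounter_id)) {
  registry <- maps$registry
  n <- length(encounter_ids)
  out <- matrix(0L, n, length(registry),
                dimnames = list(encounter_ids, registry))
  if (!nrow(diagnoses) || !n) return(out)
  sec <- diagnoses[diagnoses$position == "secondary", c("encounter_id", "code")]
  if (!nrow(sec)) return(out)
  hit <- merge(sec, maps$elixhauser, by = "code")
  if (!nrow(hit)) return(out)
  ei <- match(hit$encounter_id, encounter_ids)
  ci <- match(hit$category, registry)
  keep <- !is.na(ei) & !is.na(ci)
  out[cbind(ei[keep], ci[keep])] <- 1L
  out
}

#' Build the severity feature set for one phase
#'
#' Composes [select_codes()] with [body_system_levels()] and
#' [elixhauser_flags()] for every encounter in the set. Deterministic:
#' identical inputs always give identical features.
#'
#' @param encset an [encounter_set()].
#' @param maps a [reference_maps] object.
#' @param phase `"discharge"` or `"admission"`.
#' @param admit_poa passed to [select_codes()].
#' @return An object of class `severity_features`: a list with `phase`,
#'   `body` (n x 18 ordinal matrix) and `elix` (n x 30 flag matrix), rows
#'   aligned with `encset$encounters`.
#' @export
build_features <- function(encset, maps,
                           phase = c("discharge", "admission"),
                           admit_poa = c("Y", "W")) {
  phase <- match.arg(phase)
  ids <- encset$encounters$encounter_id
  sel <- select_codes(encset$diagnoses, phase, maps, admit_poa = admit_poa)
  structure(list(phase = phase,
                 body = body_system_levels(sel, maps, encounter_ids = ids),
                 elix = elixhauser_flags(sel, maps, encounter_ids = ids),
                 registry = maps$registry),
            class = "severity_features")
}

#' @export
print.severity_features <- function(x, ...) {
  cat("<severity_features> phase=", x$phase, ", n=", nrow(x$body),
      ", 18 body-system levels + ", ncol(x$elix),
      " comorbidity flags\n", sep = "")
  invisible(x)
}

#' Binarize a 4-level severity-of-illness value
#'
#' Minor and moderate severity (SOI 1 or 2) collapse to the low class (0);
#' major and extreme (SOI 3 or 4) to the high class (1). This binary
#' response is what the severity models predict.
#'
#' @param soi integer vector with values in {1,2,3,4}.
#' @return Integer vector of 0 (low) / 1 (high).
#' @export
#' @examples
#' binarize_outcome(c(1, 2, 3, 4))  # 0 0 1 1
binarize_outcome <- function(soi) {
  if (anyNA(soi) || !all(soi %in% 1:4)) {
    stop_fatal("SOI values must be in {1,2,3,4}")
  }
  as.integer(soi >= 3)
}

# ---- encounter file IO -----------------------------------------------------

#' Read and write encounter files
#'
#' Two plain-text layouts are supported. The CSV layout holds one row per
#' encounter with the diagnosis list packed into a single `diagnoses`
#' column as pipe-separated `code;poa;position` triples. The JSON-lines
#' layout holds one JSON object per line with a `diagnoses` array.
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"`; guessed from the extension by
#'   default.
#' @return `read_encounters`: an [encounter_set()]. `write_encounters`:
#'   the path, invisibly.
#' @export
read_encounters <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  if (!file.exists(path)) stop_fatal("encounter file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character")
    dx_col <- df$diagnoses
    df$diagnoses <- NULL
    enc <- coerce_encounter_cols(df)
    dx <- unpack_dx(enc$encounter_id, dx_col)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON)
    enc <- coerce_encounter_cols(do.call(
      rbind,
      lapply(recs, function(r) {
        r <- r[setdiff(names(r), "diagnoses")]
        r[vapply(r, is.null, logical(1))] <- NA
        as.data.frame(r, stringsAsFactors = FALSE)
      })))
    dx <- do.call(rbind, lapply(recs, function(r) {
      d <- r$diagnoses
      if (is.null(d) || NROW(d) == 0) return(NULL)
      data.frame(encounter_id = r$encounter_id, code = d$code,
                 poa = d$poa, position = d$position,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(dx)) {
      dx <- data.frame(encounter_id = character(), code = character(),
                       poa = character(), position = character())
    }
  }
  encounter_set(enc, dx)
}

coerce_encounter_cols <- function(df) {
  for (col in c("age", "admit_soi", "discharge_soi")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("cds_reviewed", "cds_queried")) {
    if (col %in% names(df)) {
      v <- df[[col]]
      df[[col]] <- ifelse(v %in% c("TRUE", "true", "1", TRUE), TRUE,
                          ifelse(v %in% c("FALSE", "false", "0", FALSE),
                                 FALSE, NA))
    }
  }
  df
}

unpack_dx <- function(ids, packed) {
  packed[is.na(packed)] <- ""
  per <- strsplit(packed, "|", fixed = TRUE)
  n_dx <- lengths(per)
  flat <- unlist(per, use.names = FALSE)
  if (!length(flat)) {
    return(data.frame(encounter_id = character(), code = character(),
                      poa = character(), position = character()))
  }
  parts <- strsplit(flat, ";", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop_fatal("malformed diagnosis triple(s): ",
               paste(sQuote(utils::head(flat[bad], 5)), collapse = ", "))
  }
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  data.frame(encounter_id = rep(ids, n_dx), code = m[, 1],
             poa = m[, 2], position = m[, 3], stringsAsFactors = FALSE)
}

#' @rdname read_encounters
#' @param encset an [encounter_set()] to write.
#' @export
write_encounters <- function(encset, path,
                             format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  enc <- encset$encounters
  dx <- encset$diagnoses
  if (format == "csv") {
    triple <- paste(dx$code, dx$poa, dx$position, sep = ";")
    packed <- vapply(split(triple, factor(dx$encounter_id,
                                          levels = enc$encounter_id)),
                     paste, character(1), collapse = "|")
    out <- enc
    out$diagnoses <- unname(packed)
    utils::write.csv(out, path, row.names = FALSE, na = "")
  } else {
    dx_split <- split(dx[c("code", "poa", "position")],
                      factor(dx$encounter_id, levels = enc$encounter_id))
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(enc))) {
      rec <- as.list(enc[i, , drop = FALSE])
      rec$diagnoses <- dx_split[[i]]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                  dataframe = "rows", digits = NA), con)
    }
  }
  invisible(path)
}
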