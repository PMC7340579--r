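#' Read a deposit metrics table
#'
#' Reads a per-deposit CSV/TSV of archive metadata and validation metrics
#' into the internal deposit representation. Rows failing range checks
#' (non-positive resolution, percentages outside \[0, 100\], malformed
#' dates, duplicated accessions) are dropped and reported in the
#' `"rejected"` attribute of the result; metric absence is encoded as `NA`,
#' never as zero.
#'
#' @param path Path to a CSV (or TSV, by file extension) file. Missing
#'   values must be encoded as empty cells (or `NA`).
#' @param schema Optional column-name mapping from internal names to the
#'   file's column names, as a named character vector / list or a path to a
#'   YAML file holding one. Internal names: `pdb_id`, `deposition_date`,
#'   `resolution`, `molecule_class`, `structural_genomics`, `journal_raw`,
#'   `issn`, `clashscore`, `rama_outliers`, `rota_outliers`,
#'   `rsrz_outliers`, `r_free`, `r_work`. Unmapped names are looked up
#'   verbatim.
#'
#' @details The mandatory columns are `pdb_id`, `deposition_date`,
#' `resolution`, and `molecule_class`; their absence is an error. Metric
#' columns are optional and filled with `NA` when absent. Deposition dates
#' may be full dates (`YYYY-MM-DD`) or bare years; bare years are
#' canonicalized to January 1 of that year, so year-precision data treats
#' same-year deposits as contemporaneous. Ramachandran and Rotamer cells of
#' nucleic-acid-only deposits are forced to `NA` and treated as
#' inapplicable (not missing) downstream.
#'
#' @return A tibble of deposits with one row per accepted input row,
#'   columns as listed above plus `deposition_year`, and attribute
#'   `rejected` (tibble with `row`, `pdb_id`, `reason`).
#' @seealso [write_deposit_table()], [clean_journal_names()]
#' @export
read_deposit_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("deposit table not found: ", path)
  schema <- load_schema(schema)

  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = c("", "NA"), progress = FALSE,
                           show_col_types = FALSE)

  internal <- c("pdb_id", "deposition_date", "resolution", "molecule_class",
                "structural_genomics", "journal_raw", "issn", .imputable_cols)
  file_col <- function(name) {
    if (!is.null(schema[[name]])) as.character(schema[[name]]) else name
  }
  mandatory <- c("pdb_id", "deposition_date", "resolution", "molecule_class")
  missing_mand <- mandatory[!vapply(mandatory, function(n) file_col(n) %in% names(raw), logical(1))]
  if (length(missing_mand)) {
    stop("mandatory column(s) absent from ", path, ": ",
         paste(vapply(missing_mand, file_col, character(1)), collapse = ", "))
  }

  out <- tibble::tibble(.rows = nrow(raw))
  for (name in internal) {
    fc <- file_col(name)
    out[[name]] <- if (fc %in% names(raw)) raw[[fc]] else NA_character_
  }
  parse_deposits(out)
}

load_schema <- function(schema) {
  if (is.null(schema)) return(list())
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    schema <- yaml::read_yaml(schema)
    if (!is.null(schema$columns)) schema <- schema$columns
  }
  as.list(schema)
}

## Coerce the all-character frame, apply per-row validation, split accepted
## from rejected.
parse_deposits <- function(df) {
  n <- nrow(df)
  reasons <- character(n)
  note <- function(bad, why) {
    bad <- which(bad & !nzchar(reasons))
    reasons[bad] <<- why
  }

  date_parsed <- parse_deposit_date(df$deposition_date)
  num <- function(x) suppressWarnings(as.numeric(x))

  resolution <- num(df$resolution)
  mol <- normalize_molecule_class(df$molecule_class)
  sg <- parse_flag(df$structural_genomics)

  note(is.na(df$pdb_id) | nchar(trimws(df$pdb_id)) != 4, "pdb_id absent or not 4 characters")
  note(is.na(date_parsed$date), "unparseable deposition date")
  note(is.na(resolution) | resolution <= 0, "resolution absent or not positive")
  note(is.na(mol), "unrecognized molecule class")

  metrics <- lapply(.imputable_cols, function(m) num(df[[m]]))
  names(metrics) <- .imputable_cols
  for (m in .imputable_cols) {
    present_raw <- !is.na(df[[m]])
    bad_numeric <- present_raw & is.na(metrics[[m]])
    rng <- .metric_ranges[[m]]
    out_of_range <- !is.na(metrics[[m]]) & (metrics[[m]] < rng[1] | metrics[[m]] > rng[2])
    if (m %in% c("r_free", "r_work")) {
      out_of_range <- out_of_range | (!is.na(metrics[[m]]) & metrics[[m]] == 0)
    }
    note(bad_numeric, paste0(m, " not numeric"))
    note(out_of_range, paste0(m, " outside legal range"))
  }

  pdb_id <- toupper(trimws(df$pdb_id))
  dup <- duplicated(pdb_id) & !is.na(pdb_id)
  note(dup, "duplicate pdb_id")

  keep <- !nzchar(reasons)
  rejected <- tibble::tibble(row = which(!keep),
                             pdb_id = pdb_id[!keep],
                             reason = reasons[!keep])

  res <- tibble::tibble(
    pdb_id = pdb_id[keep],
    deposition_date = date_parsed$date[keep],
    deposition_year = date_parsed$year[keep],
    resolution = resolution[keep],
    molecule_class = mol[keep],
    structural_genomics = sg[keep],
    journal_raw = as.character(df$journal_raw)[keep],
    issn = as.character(df$issn)[keep]
  )
  for (m in .imputable_cols) res[[m]] <- metrics[[m]][keep]

  ## Rama/Rota are inapplicable for nucleic-acid-only deposits
  na_rows <- res$molecule_class == "nucleic_acid"
  res$rama_outliers[na_rows] <- NA_real_
  res$rota_outliers[na_rows] <- NA_real_

  attr(res, "rejected") <- rejected
  res
}

parse_deposit_date <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  date <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x) & !is.na(x)
  if (any(full)) {
    date[full] <- as.Date(suppressWarnings(
      strptime(x[full], format = "%Y-%m-%d", tz = "UTC")))
  }
  yr_only <- grepl("^\\d{4}$", x) & !is.na(x)
  if (any(yr_only)) date[yr_only] <- as.Date(paste0(x[yr_only], "-01-01"))
  list(date = date, year = as.integer(format(date, "%Y")))
}

normalize_molecule_class <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("nucleic acid", "nucleic-acid", "na", "nucleicacid")] <- "nucleic_acid"
  x[x %in% c("protein-nucleic acid complex", "protein_nucleic_acid")] <- "complex"
  x[!x %in% .molecule_classes] <- NA_character_
  x
}

parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(FALSE, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out
}

#' Write a deposit table
#'
#' Inverse of [read_deposit_table()] under the default schema: present
#' values round-trip exactly and missing cells are written empty.
#'
#' @param deposits Deposit tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_deposit_table <- function(deposits, path) {
  out <- deposits
  out$deposition_date <- format(out$deposition_date, "%Y-%m-%d")
  out$deposition_year <- NULL
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Classify a deposit by its polymer composition
#'
#' Maps the declared polymer types of a deposit to the molecule class used
#' by the scoring populations. Protein-only compositions are `"protein"`,
#' nucleic-acid-only are `"nucleic_acid"`, and mixed compositions are
#' `"complex"` -- complexes are scored within the protein group because all
#' five quality metrics can be computed for them.
#'
#' @param entity_composition Character vector of polymer types present in
#'   one deposit (e.g. `c("protein", "DNA")`). Recognized nucleic-acid
#'   types: `DNA`, `RNA`, `DNA/RNA hybrid`, `nucleic_acid`.
#' @return One of `"protein"`, `"nucleic_acid"`, `"complex"`.
#' @export
classify_molecule <- function(entity_composition) {
  types <- tolower(trimws(entity_composition))
  types <- types[nzchar(types) & !is.na(types)]
  if (!length(types)) stop("no polymer type declared")
  nucleic <- types %in% c("dna", "rna", "dna/rna hybrid", "hybrid", "nucleic_acid", "nucleic acid")
  protein <- types %in% c("protein", "polypeptide", "polypeptide(l)", "polypeptide(d)", "peptide")
  if (any(!nucleic & !protein)) {
    stop("unrecognized polymer type(s): ",
         paste(unique(entity_composition[!nucleic & !protein]), collapse = ", "))
  }
  if (any(protein) && any(nucleic)) "complex"
  else if (any(protein)) "protein"
  else "nucleic_acid"
}

#' Normalize a raw journal string
#'
#' Case-folds to upper case, replaces punctuation with spaces, and
#' collapses whitespace, so that trivially different spellings of the same
#' venue ("FEBS J.", "Febs J") collapse to one key. Absent strings map to
#' [TO_BE_PUBLISHED].
#'
#' @param x Character vector of raw venue strings.
#' @return Character vector of normalized names.
#' @export
normalize_journal <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", trimws(x))
  x[is.na(x) | !nzchar(x) | x == toupper(TO_BE_PUBLISHED)] <- TO_BE_PUBLISHED
  x
}

#' Read a journal alias map
#'
#' @param path CSV with columns `raw`, `canonical`, and optionally `issn`.
#' @return A tibble with normalized `raw` keys.
#' @export
read_alias_map <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE)
  if (!all(c("raw", "canonical") %in% names(df))) {
    stop("alias map needs columns raw, canonical")
  }
  if (is.null(df$issn)) df$issn <- NA_character_
  df$raw <- normalize_journal(df$raw)
  df <- df[!duplicated(df$raw), , drop = FALSE]
  tibble::as_tibble(df)
}

#' Attach canonical journal names to deposits
#'
#' Normalizes raw primary-citation strings and resolves them through an
#' optional alias map. Unmapped strings pass through in normalized form, so
#' cleaning is total; absent citations become [TO_BE_PUBLISHED]. The
#' operation is idempotent: canonical names are fixed points of the
#' cleaning.
#'
#' @param records Deposit tibble with a `journal_raw` column.
#' @param alias_map Optional alias tibble from [read_alias_map()] (or
#'   `NULL` for normalization-only mode).
#' @return `records` with columns `journal` (canonical name) and, when the
#'   alias map supplies one, an updated `issn`.
#' @export
clean_journal_names <- function(records, alias_map = NULL) {
  raw <- if ("journal" %in% names(records)) records$journal else records$journal_raw
  key <- normalize_journal(raw)
  canonical <- key
  issn <- if ("issn" %in% names(records)) records$issn else rep(NA_character_, nrow(records))

  if (!is.null(alias_map) && nrow(alias_map)) {
    ## canonical names must be fixed points: add identity entries for them
    ids <- tibble::tibble(raw = normalize_journal(alias_map$canonical),
                          canonical = alias_map$canonical,
                          issn = alias_map$issn)
    map <- rbind(alias_map[, c("raw", "canonical", "issn")], ids)
    map <- map[!duplicated(map$raw), , drop = FALSE]
    hit <- match(key, map$raw)
    found <- !is.na(hit)
    canonical[found] <- map$canonical[hit[found]]
    map_issn <- map$issn[hit[found]]
    issn[found] <- ifelse(is.na(map_issn), issn[found], map_issn)
  }
  records$journal <- canonical
  records$issn <- issn
  records
}

#' Read a journal bibliometrics table
#'
#' Reads per-journal, per-year impact indicators: IPP (impact per
#' publication, a 3-year citation average) and SNIP (its field-normalized
#' variant). Rows with malformed or negative values are rejected and
#' reported in the `"rejected"` attribute; duplicated `(issn, year)` pairs
#' are an error.
#'
#' @param path CSV with columns `issn`, `year`, `ipp`, `snip`.
#' @return Tibble of bibliometric records.
#' @export
read_bibliometrics <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE)
  need <- c("issn", "year", "ipp", "snip")
  if (!all(need %in% names(df))) {
    stop("bibliometrics table needs columns: ", paste(need, collapse = ", "))
  }
  year <- suppressWarnings(as.integer(df$year))
  ipp <- suppressWarnings(as.numeric(df$ipp))
  snip <- suppressWarnings(as.numeric(df$snip))
  bad <- is.na(df$issn) | is.na(year) |
    is.na(ipp) | is.na(snip) | ipp < 0 | snip < 0
  rejected <- tibble::tibble(row = which(bad),
                             issn = df$issn[bad],
                             reason = "malformed or negative value")
  out <- tibble::tibble(issn = df$issn[!bad], year = year[!bad],
                        ipp = ipp[!bad], snip = snip[!bad])
  if (anyDuplicated(out[, c("issn", "year")])) {
    stop("duplicate (issn, year) in bibliometrics table")
  }
  attr(out, "rejected") <- rejected
  out
}
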