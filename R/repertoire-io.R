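# AIRR Rearrangement TSV ingestion, filtering, and configuration files.

MANDATORY_COLUMNS <- c("sequence_id", "v_call", "j_call", "junction",
                       "duplicate_count", "productive")

#' Default AIRR Rearrangement column mapping
#'
#' Maps the internal field names to AIRR Community Rearrangement schema
#' column names. `sample_id`, `population_label` and `isotype` are extension
#' columns (the schema reserves no names for them); override entries to
#' adapt to other dialects, e.g.
#' `airr_column_map(duplicate_count = "umi_count")`.
#'
#' @param ... Named overrides, `internal_name = "file_column"`.
#' @return Named character vector mapping internal names to file columns.
#' @export
airr_column_map <- function(...) {
  map <- c(sequence_id = "sequence_id", v_call = "v_call", d_call = "d_call",
           j_call = "j_call", junction = "junction",
           junction_aa = "junction_aa", duplicate_count = "duplicate_count",
           productive = "productive", v_identity = "v_identity",
           sample_id = "sample_id", population_label = "population_label",
           isotype = "isotype")
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(map))
    if (length(bad)) stop("unknown column_map field(s): ",
                          paste(bad, collapse = ", "))
    map[names(overrides)] <- overrides
  }
  map
}

POPULATION_LEVELS <- c("FM", "GC", "MZ", "MZ27pos", "MZ27neg", "SM", "MO",
                       "DN", "TR", "CD5pos", "CD5neg", "OTHER")

parse_logical_column <- function(x) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("T", "TRUE", "1", "YES")] <- TRUE
  out[up %in% c("F", "FALSE", "0", "NO")] <- FALSE
  out
}

#' Read an AIRR rearrangement table
#'
#' Reads a tab-separated rearrangement table (header row required) into a
#' data frame of annotated IGH rearrangements. Rows violating record
#' invariants (`duplicate_count` < 1, unparseable `productive`, germline
#' identity outside \[0,100\], duplicated `sequence_id`) are dropped from
#' the result but reported via the `"rejected"` attribute and a warning —
#' never silently.
#'
#' Derived columns added on read: `cdr3_aa` (junction_aa minus the flanking
#' C/W residues, translated from `junction` when `junction_aa` is absent),
#' `v_gene`/`j_gene` (allele- and multi-call-stripped, see
#' [strip_allele()]), and `v_identity_pct`.
#'
#' @param path Path to the TSV file.
#' @param column_map Named mapping from internal field names to file column
#'   names; see [airr_column_map()].
#' @param v_identity_scale `"percent"` (default) or `"fraction"`: the scale
#'   the file's `v_identity` column uses.
#' @return Data frame of records in file order, with attribute `"rejected"`
#'   (data frame with `row`, `sequence_id`, `reason`).
#' @export
read_rearrangements <- function(path, column_map = airr_column_map(),
                                v_identity_scale = c("percent", "fraction")) {
  v_identity_scale <- match.arg(v_identity_scale)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), quote = "")
  missing <- setdiff(unname(column_map[MANDATORY_COLUMNS]), names(raw))
  if (length(missing))
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("empty rearrangement table: ", path)
    out <- empty_rearrangements()
    attr(out, "rejected") <- data.frame(row = integer(), sequence_id =
                                          character(), reason = character())
    return(out)
  }
  pull <- function(field, default = NA_character_) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]]
    else rep(default, nrow(raw))
  }
  rec <- data.frame(
    sequence_id = pull("sequence_id"),
    sample_id = pull("sample_id", "sample1"),
    population_label = pull("population_label", "OTHER"),
    isotype = pull("isotype", "IGHM"),
    v_call = pull("v_call"),
    d_call = pull("d_call"),
    j_call = pull("j_call"),
    junction = toupper(pull("junction")),
    junction_aa = pull("junction_aa"),
    v_identity_pct = suppressWarnings(as.numeric(pull("v_identity"))),
    duplicate_count = suppressWarnings(as.integer(pull("duplicate_count"))),
    productive = parse_logical_column(pull("productive")),
    stringsAsFactors = FALSE
  )
  if (v_identity_scale == "fraction")
    rec$v_identity_pct <- rec$v_identity_pct * 100
  need_aa <- is.na(rec$junction_aa)
  if (any(need_aa))
    rec$junction_aa[need_aa] <- translate_nt(rec$junction[need_aa])
  rec$cdr3_aa <- junction_aa_to_cdr3(rec$junction_aa)
  rec$v_gene <- strip_allele(rec$v_call)
  rec$j_gene <- strip_allele(rec$j_call)

  reason <- rep(NA_character_, nrow(rec))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(is.na(rec$sequence_id), "missing_sequence_id")
  flag(is.na(rec$junction) | !nzchar(rec$junction), "missing_junction")
  flag(is.na(rec$duplicate_count) | rec$duplicate_count < 1L,
       "invalid_duplicate_count")
  flag(is.na(rec$productive), "invalid_productive")
  flag(!is.na(rec$v_identity_pct) &
         (rec$v_identity_pct < 0 | rec$v_identity_pct > 100),
       "v_identity_out_of_range")
  flag(duplicated(rec$sequence_id), "duplicate_sequence_id")
  rejected <- data.frame(row = which(!is.na(reason)),
                         sequence_id = rec$sequence_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    warning(nrow(rejected), " row(s) rejected on read (see attr 'rejected'): ",
            paste(unique(rejected$reason), collapse = ", "))
  out <- rec[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

empty_rearrangements <- function() {
  data.frame(sequence_id = character(), sample_id = character(),
             population_label = character(), isotype = character(),
             v_call = character(), d_call = character(), j_call = character(),
             junction = character(), junction_aa = character(),
             v_identity_pct = numeric(), duplicate_count = integer(),
             productive = logical(), cdr3_aa = character(),
             v_gene = character(), j_gene = character(),
             stringsAsFactors = FALSE)
}

#' Write a rearrangement table as AIRR TSV
#'
#' Inverse of [read_rearrangements()]: writes the standard AIRR column
#' names (booleans as `T`/`F`), so a read–write–read round trip reproduces
#' every field value.
#'
#' @param records Data frame as returned by [read_rearrangements()].
#' @param path Output file path.
#' @param extra_columns Additional column names of `records` to carry along
#'   (e.g. analysis results); defaults to every non-derived extra column.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(records, path, extra_columns = NULL) {
  map <- airr_column_map()
  out <- data.frame(row.names = seq_len(nrow(records)))
  internal <- c("sequence_id", "sample_id", "population_label", "isotype",
                "v_call", "d_call", "j_call", "junction", "junction_aa",
                "v_identity_pct", "duplicate_count", "productive")
  file_col <- c(map[c("sequence_id", "sample_id", "population_label",
                      "isotype", "v_call", "d_call", "j_call", "junction",
                      "junction_aa")], map[["v_identity"]],
                map[["duplicate_count"]], map[["productive"]])
  for (i in seq_along(internal)) {
    v <- records[[internal[i]]]
    if (is.logical(v)) v <- ifelse(v, "T", "F")
    out[[file_col[i]]] <- v
  }
  if (is.null(extra_columns))
    extra_columns <- setdiff(names(records), c(internal, "cdr3_aa",
                                               "v_gene", "j_gene"))
  for (col in extra_columns) {
    v <- records[[col]]
    if (is.logical(v)) v <- ifelse(v, "T", "F")
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Strip allele designation (and secondary calls) from an IMGT call
#'
#' `"IGHV1-69*01"` becomes `"IGHV1-69"`. Multiple comma-separated calls are
#' resolved by taking the first listed call. Input without `"*"` is
#' returned unchanged.
#'
#' @param call Character vector of IMGT allele calls.
#' @return Gene-level call strings.
#' @export
strip_allele <- function(call) {
  out <- sub("\\*.*$", "", trimws(sub(",.*$", "", call)))
  out[is.na(call)] <- NA_character_
  out
}

#' IGHV/IGHJ family of a gene-level call
#'
#' The family is the token between the locus-segment prefix (e.g. `IGHV`)
#' and the first `-`: `"IGHV1-69"` maps to `"IGHV1"`.
#'
#' @param gene Character vector of gene-level calls.
#' @return Family names.
#' @export
ighv_family <- function(gene) {
  sub("^([A-Z]+[0-9]+).*$", "\\1", gene)
}

#' Record filter criteria
#'
#' Encodes the study design filter: productive rearrangements of the IGHV1
#' subgroup captured with mu or gamma constant-region primers.
#'
#' @param require_productive Keep only productive rearrangements.
#' @param allowed_v_families Non-empty character set of IGHV family names.
#' @param allowed_isotypes Non-empty character set of isotypes.
#' @return Object of class `filter_criteria`.
#' @export
filter_criteria <- function(require_productive = TRUE,
                            allowed_v_families = "IGHV1",
                            allowed_isotypes = c("IGHM", "IGHG")) {
  if (!length(allowed_v_families) || !length(allowed_isotypes))
    stop("allowed_v_families and allowed_isotypes must be non-empty")
  structure(list(require_productive = isTRUE(require_productive),
                 allowed_v_families = allowed_v_families,
                 allowed_isotypes = allowed_isotypes),
            class = "filter_criteria")
}

#' Filter rearrangement records
#'
#' Applies a [filter_criteria()] to a record table. Each rejected record is
#' tallied under the first criterion it fails (precedence: productive,
#' V family, isotype), so kept + tallied always equals the input size.
#'
#' @param records Rearrangement data frame.
#' @param criteria A [filter_criteria()] object.
#' @return Kept records, with attribute `"rejection_tally"` (named integer
#'   vector over `productive`, `family`, `isotype`).
#' @export
filter_records <- function(records, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  reason <- rep(NA_character_, nrow(records))
  if (criteria$require_productive)
    reason[!records$productive] <- "productive"
  fam <- ighv_family(records$v_gene)
  reason[is.na(reason) & !(fam %in% criteria$allowed_v_families)] <- "family"
  reason[is.na(reason) &
           !(records$isotype %in% criteria$allowed_isotypes)] <- "isotype"
  tally <- c(productive = sum(reason == "productive", na.rm = TRUE),
             family = sum(reason == "family", na.rm = TRUE),
             isotype = sum(reason == "isotype", na.rm = TRUE))
  out <- records[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejection_tally") <- tally
  out
}

#' Read a pipeline configuration file
#'
#' YAML file holding (any of) `filter`, `column_map`, `similarity_groups`,
#' `clan_table`, `subsets`, `clustering`, `shm`, and `simulation` sections.
#' Absent sections fall back to package defaults.
#'
#' @param path Path to a YAML file.
#' @return Named list (class `stereorep_config`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration file is not a YAML mapping: ", path)
  structure(cfg, class = c("stereorep_config", "list"))
}
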