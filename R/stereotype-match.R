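# Assignment of VH CDR3 sequences to CLL major stereotyped subsets.
#
# A sequence belongs to a subset when its CDR3 has the subset's length, its
# IGHV gene belongs to the subset's phylogenetic clan, and the CDR3 window at
# the subset's pattern offset reaches >= 50% amino-acid identity and >= 70%
# amino-acid similarity (physicochemical-group agreement) to the consensus
# pattern.

#' Default amino-acid similarity groups
#'
#' A standard physicochemical partition of the 20 amino acids:
#' small/aliphatic (G,A,V,L,I), aromatic (F,Y,W), sulfur-containing (C,M),
#' hydroxyl (S,T), basic (K,R,H), acidic/amide (D,E,N,Q), and proline.
#' The published stereotypy algorithm's exact classes are not reproduced in
#' the primary sources, so the partition is configurable.
#'
#' @return Named list of character vectors partitioning the 20 amino acids.
#' @export
default_similarity_groups <- function() {
  list(aliphatic = c("G", "A", "V", "L", "I"),
       aromatic = c("F", "Y", "W"),
       sulfur = c("C", "M"),
       hydroxyl = c("S", "T"),
       basic = c("K", "R", "H"),
       acid_amide = c("D", "E", "N", "Q"),
       proline = "P")
}

#' Validate a similarity-group partition
#'
#' @param groups Named list of character vectors.
#' @return `groups`, invisibly; errors unless every one of the 20 standard
#'   amino acids appears in exactly one group.
#' @export
validate_similarity_groups <- function(groups) {
  all_aa <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_aa))
    stop("similarity groups overlap: ",
         paste(unique(all_aa[duplicated(all_aa)]), collapse = ", "))
  missing <- setdiff(AA_ALPHABET, all_aa)
  if (length(missing))
    stop("similarity groups do not cover: ", paste(missing, collapse = ", "))
  extra <- setdiff(all_aa, AA_ALPHABET)
  if (length(extra))
    stop("similarity groups contain non-standard residues: ",
         paste(extra, collapse = ", "))
  invisible(groups)
}

# residue -> group-id lookup vector
group_lookup <- function(groups) {
  validate_similarity_groups(groups)
  lut <- rep(seq_along(groups), lengths(groups))
  names(lut) <- unlist(groups, use.names = FALSE)
  lut
}

check_aa_pair <- function(a, b) {
  if (length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b))
    stop("aa comparison requires two single non-missing strings")
  if (nchar(a) != nchar(b))
    stop("non-comparable CDR3s: lengths differ (", nchar(a), " vs ",
         nchar(b), ")")
  if (nchar(a) == 0L) stop("empty amino-acid string")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  bad <- which(!(ca %in% AA_ALPHABET) | !(cb %in% AA_ALPHABET))
  if (length(bad))
    stop("invalid residue at position ", bad[1], ": '", ca[bad[1]], "'/'",
         cb[bad[1]], "'")
  list(a = ca, b = cb)
}

#' Amino-acid identity between equal-length sequences
#'
#' @param a,b Amino-acid strings of equal positive length.
#' @return Fraction of positions with identical residues, in \[0,1\].
#' @export
aa_identity <- function(a, b) {
  p <- check_aa_pair(a, b)
  mean(p$a == p$b)
}

#' Amino-acid similarity between equal-length sequences
#'
#' A position counts as similar when the residues are identical or belong
#' to the same physicochemical group, so similarity is always at least the
#' identity.
#'
#' @param a,b Amino-acid strings of equal positive length.
#' @param groups Similarity partition, see [default_similarity_groups()].
#' @return Fraction of similar positions, in \[0,1\].
#' @export
aa_similarity <- function(a, b, groups = default_similarity_groups()) {
  p <- check_aa_pair(a, b)
  lut <- group_lookup(groups)
  mean(lut[p$a] == lut[p$b])
}

#' Default IGHV clan table
#'
#' Standard phylogenetic clan assignment of the human IGHV families:
#' clan I = IGHV1/IGHV5/IGHV7, clan II = IGHV2/IGHV4/IGHV6,
#' clan III = IGHV3. Editable reference data: pass a modified copy to the
#' matching functions to override.
#'
#' @return Named character vector, family -> clan.
#' @export
default_clan_table <- function() {
  c(IGHV1 = "I", IGHV5 = "I", IGHV7 = "I",
    IGHV2 = "II", IGHV4 = "II", IGHV6 = "II",
    IGHV3 = "III")
}

#' Clan of an IGHV gene
#'
#' @param v_gene Gene-level IGHV call (e.g. `"IGHV1-69"`). Direct gene
#'   entries in `clans` take precedence over the family entry.
#' @param clans Clan table, family or gene -> clan.
#' @return Clan label.
#' @export
ighv_clan <- function(v_gene, clans = default_clan_table()) {
  if (v_gene %in% names(clans)) return(unname(clans[[v_gene]]))
  fam <- ighv_family(v_gene)
  if (!fam %in% names(clans))
    stop("IGHV gene not covered by the clan table: ", v_gene)
  unname(clans[[fam]])
}

#' Define a CLL stereotyped subset
#'
#' @param subset_id Subset label, e.g. `"#12"`.
#' @param cdr3_length_aa Required CDR3 length (amino acids).
#' @param pattern Amino-acid consensus pattern.
#' @param pattern_offset 0-based start of the pattern within the CDR3.
#' @param clan IGHV clan (`"I"`, `"II"` or `"III"`).
#' @param typical_v_genes Gene-level IGHV genes characteristically used by
#'   CLL clones of this subset.
#' @param min_identity Minimum window identity (default 0.5).
#' @param min_similarity Minimum window similarity (default 0.7).
#' @param clans Clan table used to check `typical_v_genes` consistency.
#' @return Object of class `subset_definition`.
#' @export
subset_definition <- function(subset_id, cdr3_length_aa, pattern,
                              pattern_offset = 0L, clan = "I",
                              typical_v_genes = character(),
                              min_identity = 0.5, min_similarity = 0.7,
                              clans = default_clan_table()) {
  stopifnot(is.character(subset_id), nzchar(subset_id),
            cdr3_length_aa >= 1, nchar(pattern) >= 1, pattern_offset >= 0)
  if (pattern_offset + nchar(pattern) > cdr3_length_aa)
    stop("pattern (offset ", pattern_offset, ", length ", nchar(pattern),
         ") does not fit in a CDR3 of length ", cdr3_length_aa)
  if (min_identity > min_similarity)
    stop("min_identity must not exceed min_similarity")
  if (!clan %in% c("I", "II", "III")) stop("clan must be I, II or III")
  bad <- strsplit(pattern, "")[[1]]
  bad <- setdiff(bad, AA_ALPHABET)
  if (length(bad))
    stop("pattern contains non-standard residues: ",
         paste(unique(bad), collapse = ", "))
  for (g in typical_v_genes)
    if (!identical(ighv_clan(g, clans), clan))
      stop("typical gene ", g, " is not in clan ", clan)
  structure(list(subset_id = subset_id,
                 cdr3_length_aa = as.integer(cdr3_length_aa),
                 pattern = pattern,
                 pattern_offset = as.integer(pattern_offset),
                 clan = clan,
                 typical_v_genes = typical_v_genes,
                 min_identity = min_identity,
                 min_similarity = min_similarity),
            class = "subset_definition")
}

#' Read subset definitions from a configuration list or YAML file
#'
#' @param x A `stereorep_config`/list with a `subsets` entry, a list of
#'   subset mappings, or a path to a YAML file.
#' @return List of [subset_definition()] objects.
#' @export
read_subset_definitions <- function(x) {
  if (is.character(x)) x <- read_config(x)
  subs <- if (!is.null(x$subsets)) x$subsets else x
  lapply(subs, function(s) {
    if (is.null(s$pattern))
      stop("subset ", s$subset_id %||% "?", " has no consensus pattern; ",
           "fill the template from the published subset definitions")
    subset_definition(subset_id = s$subset_id,
                      cdr3_length_aa = s$cdr3_length_aa,
                      pattern = s$pattern,
                      pattern_offset = s$pattern_offset %||% 0L,
                      clan = s$clan %||% "I",
                      typical_v_genes = as.character(s$typical_v_genes %||%
                                                       character()),
                      min_identity = s$min_identity %||% 0.5,
                      min_similarity = s$min_similarity %||% 0.7)
  })
}

#' Typical vs non-typical IGHV usage
#'
#' A stereotype-assigned rearrangement is "typical" when it uses one of the
#' IGHV genes characteristically found in CLL clones of its subset, and
#' "non-typical" when it uses a different (clan-consistent) gene.
#'
#' @param v_gene Gene-level IGHV call.
#' @param subset A [subset_definition()] with non-empty `typical_v_genes`.
#' @return Logical.
#' @export
classify_typical <- function(v_gene, subset) {
  if (!length(subset$typical_v_genes))
    stop("subset ", subset$subset_id, " has an empty typical_v_genes set")
  v_gene %in% subset$typical_v_genes
}

#' Assign one CDR3 to a stereotyped subset
#'
#' A subset is a candidate iff the CDR3 length equals the subset length,
#' the IGHV gene's clan equals the subset clan, and the pattern window of
#' the CDR3 reaches the subset's identity and similarity thresholds
#' against the consensus. Ties across candidates are broken by highest
#' similarity, then highest identity, then lexicographically smallest
#' subset id; all candidates are recorded.
#'
#' @param cdr3_aa CDR3 amino-acid string.
#' @param v_gene Gene-level IGHV call.
#' @param defs List of [subset_definition()] objects.
#' @param clans Clan table.
#' @param groups Similarity groups.
#' @param full_cdr3 If `TRUE`, compare the full CDR3 instead of the pattern
#'   window (requires full-length patterns at offset 0).
#' @return List with `subset_id` (`NA` if none), `identity`, `similarity`,
#'   `typical`, `ambiguous_candidates`.
#' @export
assign_subset <- function(cdr3_aa, v_gene, defs,
                          clans = default_clan_table(),
                          groups = default_similarity_groups(),
                          full_cdr3 = FALSE) {
  stopifnot(length(defs) >= 1)
  none <- list(subset_id = NA_character_, identity = NA_real_,
               similarity = NA_real_, typical = NA,
               ambiguous_candidates = character())
  if (is.na(cdr3_aa) || !nzchar(cdr3_aa)) return(none)
  clan <- ighv_clan(v_gene, clans)  # errors for unknown genes
  lut <- group_lookup(groups)
  eps <- 1e-9
  cand <- list()
  for (d in defs) {
    if (nchar(cdr3_aa) != d$cdr3_length_aa) next
    if (!identical(clan, d$clan)) next
    if (full_cdr3) {
      if (d$pattern_offset != 0L || nchar(d$pattern) != d$cdr3_length_aa)
        stop("full_cdr3 comparison requires a full-length pattern at ",
             "offset 0 (subset ", d$subset_id, ")")
      window <- cdr3_aa
    } else {
      window <- substr(cdr3_aa, d$pattern_offset + 1L,
                       d$pattern_offset + nchar(d$pattern))
    }
    id <- aa_identity(window, d$pattern)
    ca <- strsplit(window, "", fixed = TRUE)[[1]]
    cb <- strsplit(d$pattern, "", fixed = TRUE)[[1]]
    sim <- mean(lut[ca] == lut[cb])
    if (id >= d$min_identity - eps && sim >= d$min_similarity - eps)
      cand[[length(cand) + 1L]] <- list(def = d, identity = id,
                                        similarity = sim)
  }
  if (!length(cand)) return(none)
  ids <- vapply(cand, function(x) x$def$subset_id, character(1))
  sims <- vapply(cand, function(x) x$similarity, numeric(1))
  idents <- vapply(cand, function(x) x$identity, numeric(1))
  ord <- order(-sims, -idents, ids)
  best <- cand[[ord[1]]]
  list(subset_id = best$def$subset_id,
       identity = best$identity,
       similarity = best$similarity,
       typical = classify_typical(v_gene, best$def),
       ambiguous_candidates = if (length(cand) > 1L) ids[ord] else character())
}

#' Scan a rearrangement table for stereotyped subsets
#'
#' Applies [assign_subset()] to every record and appends the columns
#' `subset_id`, `stereo_identity`, `stereo_similarity`, `stereo_typical`
#' and `stereo_ambiguous` (comma-separated candidate list).
#'
#' @inheritParams assign_subset
#' @param records Rearrangement data frame with `cdr3_aa` and `v_gene`.
#' @return `records` with assignment columns appended.
#' @export
assign_stereotypes <- function(records, defs,
                               clans = default_clan_table(),
                               groups = default_similarity_groups(),
                               full_cdr3 = FALSE) {
  n <- nrow(records)
  subset_id <- character(n); identity <- numeric(n)
  similarity <- numeric(n); typical <- logical(n); ambig <- character(n)
  for (i in seq_len(n)) {
    a <- assign_subset(records$cdr3_aa[i], records$v_gene[i], defs,
                       clans = clans, groups = groups, full_cdr3 = full_cdr3)
    subset_id[i] <- a$subset_id
    identity[i] <- a$identity
    similarity[i] <- a$similarity
    typical[i] <- a$typical
    ambig[i] <- paste(a$ambiguous_candidates, collapse = ",")
  }
  records$subset_id <- subset_id
  records$stereo_identity <- identity
  records$stereo_similarity <- similarity
  records$stereo_typical <- typical
  records$stereo_ambiguous <- ambig
  records
}
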