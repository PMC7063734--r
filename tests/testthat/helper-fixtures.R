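# Fixtures are built in code: small record tables, synthetic subset
# definitions, and independent oracles used to cross-check the
# implementation.

toy_records <- function(junctions,
                        v_call = "IGHV1-69*01",
                        j_call = "IGHJ6*01",
                        sequence_id = sprintf("s%03d", seq_along(junctions)),
                        duplicate_count = rep(1L, length(junctions)),
                        isotype = "IGHM",
                        population_label = "FM",
                        sample_id = "t1",
                        productive = TRUE,
                        v_identity_pct = 100) {
  n <- length(junctions)
  rec <- data.frame(
    sequence_id = sequence_id,
    sample_id = rep_len(sample_id, n),
    population_label = rep_len(population_label, n),
    isotype = rep_len(isotype, n),
    v_call = rep_len(v_call, n),
    d_call = NA_character_,
    j_call = rep_len(j_call, n),
    junction = junctions,
    v_identity_pct = rep_len(v_identity_pct, n),
    duplicate_count = rep_len(duplicate_count, n),
    productive = rep_len(productive, n),
    stringsAsFactors = FALSE)
  rec$junction_aa <- translate_nt(rec$junction)
  rec$cdr3_aa <- ifelse(is.na(rec$junction_aa), NA,
                        substr(rec$junction_aa, 2,
                               nchar(rec$junction_aa) - 1))
  rec$v_gene <- strip_allele(rec$v_call)
  rec$j_gene <- strip_allele(rec$j_call)
  rec
}

# two synthetic subset definitions used across the suite (CDR3 lengths 13
# and 16, i.e. junction lengths 45 and 54)
toy_defs <- function() {
  list(subset_definition("#S1", cdr3_length_aa = 13, pattern = "ARDANGMDV",
                         pattern_offset = 2, clan = "I",
                         typical_v_genes = "IGHV1-69"),
       subset_definition("#S2", cdr3_length_aa = 16,
                         pattern = "GYDSSGYWLDP", pattern_offset = 3,
                         clan = "I",
                         typical_v_genes = c("IGHV1-2", "IGHV1-18")))
}

# background junction lengths disjoint from toy_defs() CDR3 lengths
toy_background_lengths <- function() {
  len <- setdiff(seq(36L, 66L, by = 3L), c(45L, 54L))
  stats::setNames(rep(1 / length(len), length(len)), len)
}

random_aa_string <- function(n) {
  paste(sample(stereorep:::AA_ALPHABET, n, replace = TRUE), collapse = "")
}

random_nt_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent single-linkage oracle: boolean transitive closure of the
# adjacency matrix d <= threshold
oracle_components <- function(seqs, threshold) {
  m <- length(seqs)
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = m, byrow = TRUE)
  D <- matrix(0, m, m)
  for (j in seq_len(ncol(chars))) D <- D + outer(chars[, j], chars[, j], "!=")
  A <- (D / ncol(chars)) <= threshold + 1e-12
  reach <- A
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(m)
  next_id <- 0L
  for (i in seq_len(m)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[reach[i, ]] <- next_id
    }
  }
  comp
}

# canonical form of a clustering: sorted list of sorted member id sets
membership_sets <- function(ids, labels) {
  s <- lapply(split(ids, labels), sort)
  unname(s[order(vapply(s, `[`, character(1), 1))])
}

write_airr_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
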