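# Synthetic annotated repertoires with planted ground truth: multinomial
# V/J usage over the IGHV1 family, codon-aware junctions (2nd-CYS ... J-TRP,
# no stop codons), clonal lineages whose within-clone divergence sits below
# the planted threshold window and between-clone divergence above it,
# stereotyped spike-in clones at controlled identity/similarity, planted SHM
# levels, and mRNA duplicate counts.

STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, STOP_CODONS)
}

#' Default gene-usage weights for the simulator
#'
#' Multinomial usage over the functional IGHV1-family genes, skewed toward
#' IGHV1-69/IGHV1-2/IGHV1-18 as in adult repertoires, and over IGHJ1-6
#' dominated by IGHJ4/IGHJ6.
#'
#' @return Named numeric weight vector summing to 1.
#' @name simulator_defaults
NULL

#' @rdname simulator_defaults
#' @export
default_v_gene_usage <- function() {
  w <- c("IGHV1-2" = 0.18, "IGHV1-3" = 0.06, "IGHV1-8" = 0.10,
         "IGHV1-18" = 0.16, "IGHV1-24" = 0.06, "IGHV1-45" = 0.04,
         "IGHV1-46" = 0.12, "IGHV1-58" = 0.05, "IGHV1-69" = 0.23)
  w / sum(w)
}

#' @rdname simulator_defaults
#' @export
default_j_gene_usage <- function() {
  w <- c(IGHJ1 = 0.02, IGHJ2 = 0.03, IGHJ3 = 0.06, IGHJ4 = 0.45,
         IGHJ5 = 0.08, IGHJ6 = 0.36)
  w / sum(w)
}

#' @rdname simulator_defaults
#' @export
default_junction_lengths <- function() {
  len <- seq(36L, 66L, by = 3L)
  w <- stats::dnorm(len, mean = 48, sd = 7)
  stats::setNames(w / sum(w), len)
}

#' Simulation configuration
#'
#' Parameters of the synthetic repertoire. Defaults encode a
#' mu-dominated, moderately mutated adult IGHV1 repertoire at desk scale;
#' `within_clone_divergence` (d1) and `between_clone_min_divergence` (d2)
#' bracket the planted threshold window.
#'
#' @param seed Integer seed; generation is fully reproducible.
#' @param n_background_clones Number of non-stereotyped clones.
#' @param clone_size `list(name = "geometric", mean = 1.5)` (shifted
#'   geometric, minimum 1) or `list(name = "fixed", size = k)`.
#' @param v_gene_usage,j_gene_usage Named weight vectors.
#' @param junction_lengths Named weight vector over junction lengths
#'   (nucleotides, multiples of 3).
#' @param within_clone_divergence d1: maximum within-clone junction
#'   distance.
#' @param between_clone_min_divergence d2: minimum between-clone junction
#'   distance within a partition (d1 < d2).
#' @param shm_mutated_fraction Fraction of sequences planted as mutated.
#' @param shm_identity_range_mutated Percent-identity interval for mutated
#'   sequences (default \[92, 98.9\]); unmutated draw from \[99, 100\].
#' @param spikes List of spike specs:
#'   `list(subset_id =, n_clones =, typical_fraction = 1, identity_level =
#'   1, similarity_level = 1)`.
#' @param isotype_weights,population_weights Named weight vectors.
#' @param duplicate_count `list(name = "zeta", exponent = 2.5, max = 1000)`:
#'   heavy-tailed mRNA molecule counts.
#' @param sample_id Sample label stamped on every record.
#' @param emit_v_sequences If `TRUE`, emit mutated full V sequences (column
#'   `v_sequence`) against the germline reference instead of only the
#'   identity annotation.
#' @param max_retries Rejection-sampling budget per founder.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_background_clones = 300L,
                              clone_size = list(name = "geometric",
                                                mean = 1.5),
                              v_gene_usage = default_v_gene_usage(),
                              j_gene_usage = default_j_gene_usage(),
                              junction_lengths = default_junction_lengths(),
                              within_clone_divergence = 0.05,
                              between_clone_min_divergence = 0.40,
                              shm_mutated_fraction = 0.25,
                              shm_identity_range_mutated = c(92, 98.9),
                              spikes = list(),
                              isotype_weights = c(IGHM = 0.8, IGHG = 0.2),
                              population_weights = c(FM = 0.3, GC = 0.2,
                                                     MZ = 0.2, SM = 0.15,
                                                     TR = 0.15),
                              duplicate_count = list(name = "zeta",
                                                     exponent = 2.5,
                                                     max = 1000L),
                              sample_id = "sim1",
                              emit_v_sequences = FALSE,
                              max_retries = 1000L) {
  if (within_clone_divergence >= between_clone_min_divergence)
    stop("within_clone_divergence (d1) must be < between_clone_min_",
         "divergence (d2)")
  lens <- as.integer(names(junction_lengths))
  if (any(lens %% 3L != 0L) || any(lens < 9L))
    stop("junction lengths must be multiples of 3 and >= 9")
  for (s in spikes) {
    if (is.null(s$subset_id) || is.null(s$n_clones))
      stop("each spike needs subset_id and n_clones")
    if ((s$identity_level %||% 1) > (s$similarity_level %||% 1))
      stop("spike identity_level must not exceed similarity_level")
  }
  structure(list(seed = as.integer(seed),
                 n_background_clones = as.integer(n_background_clones),
                 clone_size = clone_size,
                 v_gene_usage = v_gene_usage / sum(v_gene_usage),
                 j_gene_usage = j_gene_usage / sum(j_gene_usage),
                 junction_lengths = junction_lengths / sum(junction_lengths),
                 within_clone_divergence = within_clone_divergence,
                 between_clone_min_divergence = between_clone_min_divergence,
                 shm_mutated_fraction = shm_mutated_fraction,
                 shm_identity_range_mutated = shm_identity_range_mutated,
                 spikes = spikes,
                 isotype_weights = isotype_weights / sum(isotype_weights),
                 population_weights =
                   population_weights / sum(population_weights),
                 duplicate_count = duplicate_count,
                 sample_id = sample_id,
                 emit_v_sequences = isTRUE(emit_v_sequences),
                 max_retries = as.integer(max_retries)),
            class = "simulation_config")
}

#' Deterministic synthetic germline V reference
#'
#' A stand-in for a real germline database: one random (but fixed)
#' 300-nucleotide sequence per IGHV1-family gene, for exercising germline
#' identity computation end to end. Synthetic — not real germline genes.
#'
#' @param genes Gene-level names (default: the simulator's V genes).
#' @param length_nt Sequence length.
#' @return Named character vector of sequences.
#' @export
synthetic_germline_reference <- function(genes = names(default_v_gene_usage()),
                                         length_nt = 300L) {
  with_seed(104729L, {
    out <- vapply(sort(genes), function(g)
      paste(sample(c("A", "C", "G", "T"), length_nt, replace = TRUE),
            collapse = ""), character(1))
    out[genes]
  })
}

#' Write a named sequence set as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

random_junction <- function(length_nt) {
  n_mid <- length_nt / 3L - 2L
  paste0(sample(c("TGT", "TGC"), 1L),
         paste(sample(sense_codons(), n_mid, replace = TRUE), collapse = ""),
         "TGG")
}

# k substitutions in the interior codons (flanking C/W codons untouched),
# resampled until the junction stays stop-free
mutate_junction <- function(junction, k) {
  if (k == 0L) return(junction)
  L <- nchar(junction)
  interior <- seq.int(4L, L - 3L)
  bases <- c("A", "C", "G", "T")
  for (attempt in 1:100) {
    chars <- strsplit(junction, "", fixed = TRUE)[[1]]
    pos <- sample(interior, k)
    for (p in pos)
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    out <- paste(chars, collapse = "")
    aa <- translate_nt(out)
    if (!grepl("*", aa, fixed = TRUE)) return(out)
  }
  stop("could not place ", k, " substitutions without a stop codon")
}

reverse_translate <- function(aa) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(AA_TO_CODON[chars], collapse = "")
}

# CDR3 hitting the requested window identity/similarity against a subset
# consensus: round(identity*w) positions kept, round(similarity*w) -
# round(identity*w) positions swapped within their similarity group, the
# rest swapped across groups; non-window positions are random residues
spike_cdr3 <- function(def, identity_level, similarity_level, groups) {
  lut <- group_lookup(groups)
  pat <- strsplit(def$pattern, "", fixed = TRUE)[[1]]
  w <- length(pat)
  n_eq <- round(identity_level * w)
  n_sim <- round(similarity_level * w) - n_eq
  n_diff <- w - n_eq - n_sim
  multi_group <- which(vapply(pat, function(r)
    sum(lut == lut[[r]]) > 1L, logical(1)))
  if (n_sim > length(multi_group))
    stop("subset ", def$subset_id, ": cannot plant ", n_sim,
         " same-group substitutions; pattern has only ",
         length(multi_group), " positions in multi-residue groups")
  sim_pos <- if (n_sim > 0L) sample(multi_group, n_sim) else integer()
  diff_pos <- if (n_diff > 0L) sample(setdiff(seq_len(w), sim_pos), n_diff)
              else integer()
  out <- pat
  for (p in sim_pos) {
    same <- setdiff(names(lut)[lut == lut[[pat[p]]]], pat[p])
    out[p] <- sample(same, 1L)
  }
  for (p in diff_pos) {
    other <- names(lut)[lut != lut[[pat[p]]]]
    out[p] <- sample(other, 1L)
  }
  window <- paste(out, collapse = "")
  n_flank <- def$cdr3_length_aa - w
  left <- def$pattern_offset
  right <- n_flank - left
  paste0(paste(sample(AA_ALPHABET, left, replace = TRUE), collapse = ""),
         window,
         paste(sample(AA_ALPHABET, right, replace = TRUE), collapse = ""))
}

draw_clone_size <- function(spec, n) {
  switch(spec$name,
         geometric = 1L + stats::rgeom(n, prob = 1 / spec$mean),
         fixed = rep(as.integer(spec$size), n),
         stop("unknown clone size distribution: ", spec$name))
}

draw_duplicate_counts <- function(spec, n) {
  switch(spec$name,
         zeta = {
           k <- seq_len(spec$max)
           sample(k, n, replace = TRUE, prob = k^(-spec$exponent))
         },
         fixed = rep(as.integer(spec$value), n),
         stop("unknown duplicate count distribution: ", spec$name))
}

#' Generate a synthetic annotated repertoire with ground truth
#'
#' Background clones are built from stop-free founder junctions (2nd-CYS
#' first codon, J-TRP last codon) drawn per V/J/length partition with
#' rejection sampling so that founders sit at least `d2 + d1` apart, and
#' members drift at most `floor(d1 * L / 2)` substitutions from their
#' founder — realized within-clone pairwise distances are therefore <= d1
#' and between-clone distances >= d2. Spike clones embed a subset
#' consensus window at the configured identity/similarity levels and use a
#' typical IGHV gene with the configured probability. Fully reproducible
#' for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @param subset_defs List of [subset_definition()] covering every spiked
#'   subset id.
#' @param groups Similarity groups used for spike construction.
#' @return List with `records` (rearrangement data frame in the
#'   [read_rearrangements()] schema) and `truth` (data frame per sequence:
#'   `sequence_id`, `clone_id`, `subset_id`, `typical`,
#'   `n_planted_substitutions`; attributes `d1`, `d2`,
#'   `d1_realized`, `d2_realized`).
#' @export
generate_repertoire <- function(config, subset_defs = list(),
                                groups = default_similarity_groups()) {
  stopifnot(inherits(config, "simulation_config"))
  def_ids <- vapply(subset_defs, `[[`, character(1), "subset_id")
  for (s in config$spikes)
    if (!s$subset_id %in% def_ids)
      stop("spike subset ", s$subset_id, " has no definition")
  with_seed(config$seed, generate_repertoire_impl(config, subset_defs,
                                                  def_ids, groups))
}

generate_repertoire_impl <- function(config, subset_defs, def_ids, groups) {
  d1 <- config$within_clone_divergence
  d2 <- config$between_clone_min_divergence
  founders <- new.env(parent = emptyenv())  # population|partition -> junctions
  clones <- list()
  pops <- names(config$population_weights)

  # clustering runs per sample and population, so founder separation is
  # enforced within (population, V, J, length); populations are drawn per
  # clone and inherited by members
  add_founder <- function(pop, v, j, junction) {
    key <- paste(pop, v, j, nchar(junction), sep = "|")
    existing <- get0(key, envir = founders, ifnotfound = character())
    min_sep <- (d2 + d1) * nchar(junction)
    ok <- all(vapply(existing, function(e)
      sum(strsplit(e, "")[[1]] != strsplit(junction, "")[[1]]) >= min_sep,
      logical(1)))
    if (ok) assign(key, c(existing, junction), envir = founders)
    ok
  }

  # background clones
  lens <- as.integer(names(config$junction_lengths))
  for (i in seq_len(config$n_background_clones)) {
    placed <- FALSE
    for (try in seq_len(config$max_retries)) {
      pop <- sample(pops, 1L, prob = config$population_weights)
      v <- sample(names(config$v_gene_usage), 1L,
                  prob = config$v_gene_usage)
      j <- sample(names(config$j_gene_usage), 1L,
                  prob = config$j_gene_usage)
      L <- sample(lens, 1L, prob = config$junction_lengths)
      junction <- random_junction(L)
      if (add_founder(pop, v, j, junction)) { placed <- TRUE; break }
    }
    if (!placed)
      stop("founder rejection budget exceeded; use longer junctions or ",
           "fewer clones")
    clones[[length(clones) + 1L]] <- list(
      clone_id = sprintf("bg%05d", i), v_gene = v, j_gene = j,
      population = pop, founder = junction, subset_id = NA_character_,
      typical = NA)
  }

  # stereotyped spike clones
  for (s in config$spikes) {
    def <- subset_defs[[match(s$subset_id, def_ids)]]
    typical_fraction <- s$typical_fraction %||% 1
    id_level <- s$identity_level %||% 1
    sim_level <- s$similarity_level %||% 1
    non_typical_pool <- setdiff(names(config$v_gene_usage),
                                def$typical_v_genes)
    for (i in seq_len(s$n_clones)) {
      placed <- FALSE
      for (try in seq_len(config$max_retries)) {
        pop <- sample(pops, 1L, prob = config$population_weights)
        typical <- stats::runif(1) < typical_fraction
        v <- if (typical) sample(def$typical_v_genes, 1L)
             else sample(non_typical_pool, 1L)
        j <- sample(names(config$j_gene_usage), 1L,
                    prob = config$j_gene_usage)
        cdr3 <- spike_cdr3(def, id_level, sim_level, groups)
        junction <- paste0("TGT", reverse_translate(cdr3), "TGG")
        if (add_founder(pop, v, j, junction)) { placed <- TRUE; break }
      }
      if (!placed)
        stop("spike founder rejection budget exceeded for subset ",
             s$subset_id, "; same-subset clones need distinct ",
             "(population, V, J) slots")
      clones[[length(clones) + 1L]] <- list(
        clone_id = sprintf("spk_%s_%03d", gsub("#", "", def$subset_id), i),
        v_gene = v, j_gene = j, population = pop, founder = junction,
        subset_id = def$subset_id, typical = typical)
    }
  }

  # expand clones into member sequences
  n_clones <- length(clones)
  sizes <- draw_clone_size(config$clone_size, n_clones)
  rows <- list()
  for (ci in seq_len(n_clones)) {
    cl <- clones[[ci]]
    L <- nchar(cl$founder)
    max_drift <- if (is.na(cl$subset_id)) floor(d1 * L / 2) else 0L
    for (mi in seq_len(sizes[ci])) {
      junction <- if (mi == 1L || max_drift == 0L) cl$founder
                  else mutate_junction(cl$founder,
                                       sample.int(max_drift, 1L))
      rows[[length(rows) + 1L]] <- list(clone_id = cl$clone_id,
                                        v_gene = cl$v_gene,
                                        j_gene = cl$j_gene,
                                        population = cl$population,
                                        junction = junction,
                                        subset_id = cl$subset_id,
                                        typical = cl$typical)
    }
  }
  n <- length(rows)
  rec <- data.frame(
    sequence_id = sprintf("sim%06d", seq_len(n)),
    sample_id = config$sample_id,
    population_label = vapply(rows, `[[`, character(1), "population"),
    isotype = sample(names(config$isotype_weights), n, replace = TRUE,
                     prob = config$isotype_weights),
    v_call = paste0(vapply(rows, `[[`, character(1), "v_gene"), "*01"),
    d_call = NA_character_,
    j_call = paste0(vapply(rows, `[[`, character(1), "j_gene"), "*01"),
    junction = vapply(rows, `[[`, character(1), "junction"),
    stringsAsFactors = FALSE)
  rec$junction_aa <- translate_nt(rec$junction)
  rec$cdr3_aa <- junction_aa_to_cdr3(rec$junction_aa)
  rec$v_gene <- strip_allele(rec$v_call)
  rec$j_gene <- strip_allele(rec$j_call)

  # planted SHM levels
  mutated <- stats::runif(n) < config$shm_mutated_fraction
  rng <- config$shm_identity_range_mutated
  target <- ifelse(mutated, stats::runif(n, rng[1], rng[2]),
                   stats::runif(n, 99, 100))
  n_sub <- rep(NA_integer_, n)
  if (config$emit_v_sequences) {
    germ <- synthetic_germline_reference(names(config$v_gene_usage))
    vlen <- nchar(germ[[1]])
    bases <- c("A", "C", "G", "T")
    vseq <- character(n)
    for (i in seq_len(n)) {
      g <- germ[[rec$v_gene[i]]]
      k <- round((100 - target[i]) / 100 * vlen)
      chars <- strsplit(g, "", fixed = TRUE)[[1]]
      if (k > 0) {
        pos <- sample.int(vlen, k)
        for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
      }
      vseq[i] <- paste(chars, collapse = "")
      n_sub[i] <- k
      target[i] <- 100 * (1 - k / vlen)
    }
    rec$v_sequence <- vseq
  }
  rec$v_identity_pct <- target
  rec$duplicate_count <- draw_duplicate_counts(config$duplicate_count, n)
  rec$productive <- TRUE

  truth <- data.frame(
    sequence_id = rec$sequence_id,
    clone_id = vapply(rows, `[[`, character(1), "clone_id"),
    subset_id = vapply(rows, `[[`, character(1), "subset_id"),
    typical = vapply(rows, function(r) as.logical(r$typical), logical(1)),
    n_planted_substitutions = n_sub,
    stringsAsFactors = FALSE)
  attr(truth, "d1") <- d1
  attr(truth, "d2") <- d2
  win <- realized_divergence_window(rec, truth)
  attr(truth, "d1_realized") <- win[1]
  attr(truth, "d2_realized") <- win[2]
  list(records = rec, truth = truth)
}

# max within-clone and min between-clone pairwise distance, within the
# (sample, population, V, J, length) strata that clustering compares
realized_divergence_window <- function(rec, truth) {
  within_max <- 0; between_min <- Inf
  parts <- list()
  for (g in unique(rec$population_label))
    parts <- c(parts,
               partition_records(rec[rec$population_label == g, ,
                                     drop = FALSE]))
  for (p in parts) {
    if (nrow(p) < 2L) next
    D <- hamming_matrix(p$junction)
    cl <- truth$clone_id[match(p$sequence_id, truth$sequence_id)]
    same <- outer(cl, cl, "==")
    diag(same) <- NA
    if (any(same, na.rm = TRUE))
      within_max <- max(within_max, max(D[which(same)]))
    if (any(!same, na.rm = TRUE))
      between_min <- min(between_min, min(D[which(!same)]))
  }
  c(within_max, between_min)
}

#' Write the ground-truth sidecar table
#'
#' @param truth Truth data frame from [generate_repertoire()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$typical <- ifelse(is.na(out$typical), "", ifelse(out$typical, "T", "F"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Label-invariant agreement between two clusterings of the same items;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param x,y Cluster label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (abs(maximum - expected) < 1e-12) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Score pipeline predictions against planted ground truth
#'
#' @param predicted Annotated records (after [assign_stereotypes()] and,
#'   optionally, [infer_clones()]) with `sequence_id`, `subset_id`, and
#'   optionally `clone_id`.
#' @param truth Truth data frame from [generate_repertoire()].
#' @param threshold Optional threshold value (or [find_threshold()] result)
#'   to check against the planted (d1, d2) window.
#' @return List with `sensitivity` (spiked sequences assigned their planted
#'   subset), `specificity` (background assigned none), `ari` (clone
#'   partition agreement, `NA` when `predicted` has no `clone_id`), and
#'   `threshold_in_window`.
#' @export
evaluate_recovery <- function(predicted, truth, threshold = NULL) {
  if (!setequal(predicted$sequence_id, truth$sequence_id))
    stop("predicted and truth sequence_id sets differ")
  m <- match(truth$sequence_id, predicted$sequence_id)
  pred_subset <- predicted$subset_id[m]
  spiked <- !is.na(truth$subset_id)
  sensitivity <- if (any(spiked))
    mean(!is.na(pred_subset[spiked]) &
           pred_subset[spiked] == truth$subset_id[spiked])
  else NA_real_
  specificity <- if (any(!spiked)) mean(is.na(pred_subset[!spiked]))
                 else NA_real_
  ari <- if (!is.null(predicted$clone_id))
    adjusted_rand_index(predicted$clone_id[m], truth$clone_id)
  else NA_real_
  tw <- NA
  if (!is.null(threshold)) {
    val <- if (inherits(threshold, "distance_threshold")) threshold$value
           else threshold
    tw <- val > attr(truth, "d1") && val < attr(truth, "d2")
  }
  list(sensitivity = sensitivity, specificity = specificity, ari = ari,
       threshold_in_window = tw)
}
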