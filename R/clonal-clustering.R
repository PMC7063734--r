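# Clonal family inference: V/J/junction-length partitions, distance-to-
# nearest threshold detection, single-linkage clustering, representatives.

#' Normalized Hamming distance between equal-length nucleotide strings
#'
#' 0 means 100% identity, 1 means 0% identity.
#'
#' @param a,b Nucleotide strings of equal positive length.
#' @return Fraction of mismatching positions.
#' @export
normalized_hamming <- function(a, b) {
  if (is.na(a) || is.na(b)) stop("missing sequence")
  if (nchar(a) != nchar(b))
    stop("sequences from different partitions: lengths differ (",
         nchar(a), " vs ", nchar(b), ")")
  if (nchar(a) == 0L) stop("empty sequence")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(ca != cb)
}

# full pairwise normalized Hamming matrix for a character vector of
# equal-length sequences; column-wise accumulation keeps it vectorized
hamming_matrix <- function(seqs) {
  m <- length(seqs)
  L <- nchar(seqs[1])
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = m, byrow = TRUE)
  D <- matrix(0, m, m)
  for (j in seq_len(L)) {
    cj <- chars[, j]
    D <- D + outer(cj, cj, "!=")
  }
  D / L
}

#' Partition records by V gene, J gene and junction length
#'
#' Gene-level calls (allele stripped) are used, so records differing only
#' in allele suffix share a partition.
#'
#' @param records Rearrangement data frame.
#' @return Named list of data frames, keyed `"v|j|length"`, with attribute
#'   `"keys"` (data frame of `v_gene`, `j_gene`, `junction_length_nt`).
#' @export
partition_records <- function(records) {
  if (nrow(records) == 0L) {
    out <- list()
    attr(out, "keys") <- data.frame(v_gene = character(),
                                    j_gene = character(),
                                    junction_length_nt = integer())
    return(out)
  }
  len <- nchar(records$junction)
  key <- paste(records$v_gene, records$j_gene, len, sep = "|")
  idx <- split(seq_len(nrow(records)), key)
  out <- lapply(idx, function(i) records[i, , drop = FALSE])
  parts <- strsplit(names(out), "|", fixed = TRUE)
  attr(out, "keys") <- data.frame(
    v_gene = vapply(parts, `[`, character(1), 1L),
    j_gene = vapply(parts, `[`, character(1), 2L),
    junction_length_nt = as.integer(vapply(parts, `[`, character(1), 3L)),
    row.names = names(out), stringsAsFactors = FALSE)
  out
}

#' Distance-to-nearest distribution
#'
#' For every record in every multi-member partition, the minimum normalized
#' Hamming distance of its junction to any other junction in the same
#' partition. Singleton partitions contribute nothing. This distribution is
#' typically bimodal — clonally related pairs near 0, unrelated pairs far
#' out — and its valley sets the clustering threshold.
#'
#' @param partitions Output of [partition_records()].
#' @return Numeric vector of distances (empty, with a warning, when no
#'   partition has two or more members).
#' @export
nearest_neighbor_distances <- function(partitions) {
  out <- unlist(lapply(partitions, function(p) {
    m <- nrow(p)
    if (m < 2L) return(numeric())
    D <- hamming_matrix(p$junction)
    diag(D) <- Inf
    apply(D, 1L, min)
  }), use.names = FALSE)
  if (!length(out))
    warning("no partition with >= 2 members; no distances to report")
  out
}

#' Find a clustering threshold from the distance-to-nearest distribution
#'
#' Smooths the distances with a Gaussian kernel density estimate on
#' \[0,1\], detects modes (local maxima merged unless the density drops
#' below half the smaller peak between them), and returns the location of
#' the density minimum between the two largest modes. When fewer than two
#' modes are detected the configured fallback value is returned and the
#' method is reported as `"fixed"`.
#'
#' @param distances Numeric vector of distance-to-nearest values.
#' @param bandwidth Kernel standard deviation on the \[0,1\] axis.
#' @param grid_n Number of evaluation grid points.
#' @param min_distances Minimum sample size required.
#' @param min_mode_height Minimum mode height as a fraction of the global
#'   density maximum; lower local maxima (stray outliers, tail wiggles)
#'   are not counted as modes.
#' @param fallback Threshold used when no valley can be found.
#' @return Object of class `distance_threshold`: `value`, `method`
#'   (`"density_valley"` or `"fixed"`), `n`, and the `density` estimate.
#' @export
find_threshold <- function(distances, bandwidth = 0.02, grid_n = 512,
                           min_distances = 50, min_mode_height = 0.05,
                           fallback = 0.15) {
  distances <- distances[!is.na(distances)]
  if (length(distances) < min_distances)
    stop("only ", length(distances), " distances (need >= ", min_distances,
         "); use a fixed threshold instead")
  fixed <- function(dens) structure(list(value = fallback, method = "fixed",
                                         n = length(distances),
                                         density = dens),
                                    class = "distance_threshold")
  if (length(unique(distances)) == 1L) return(fixed(NULL))
  dens <- stats::density(distances, bw = bandwidth, from = 0, to = 1,
                         n = grid_n)
  y <- dens$y; x <- dens$x; n <- length(y)
  ypad <- c(-Inf, y, -Inf)
  is_max <- which(ypad[2:(n + 1)] > ypad[1:n] &
                    ypad[2:(n + 1)] >= ypad[3:(n + 2)])
  is_max <- is_max[y[is_max] >= min_mode_height * max(y)]
  if (length(is_max) < 2L) return(fixed(dens))
  # merge peaks not separated by a drop below half the smaller peak
  peaks <- is_max[order(x[is_max])]
  repeat {
    if (length(peaks) < 2L) break
    merged <- FALSE
    for (k in seq_len(length(peaks) - 1L)) {
      i <- peaks[k]; j <- peaks[k + 1L]
      valley <- min(y[i:j])
      if (valley > 0.5 * min(y[i], y[j])) {
        drop <- if (y[i] >= y[j]) k + 1L else k
        peaks <- peaks[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  if (length(peaks) < 2L) return(fixed(dens))
  top2 <- sort(peaks[order(-y[peaks])][1:2])
  seg <- seq(top2[1], top2[2])
  value <- x[seg[which.min(y[seg])]]
  structure(list(value = min(max(value, 0), 1), method = "density_valley",
                 n = length(distances), density = dens),
            class = "distance_threshold")
}

#' @export
print.distance_threshold <- function(x, ...) {
  cat("distance threshold:", format(x$value, digits = 4),
      sprintf("(method = %s, n = %d)\n", x$method, x$n))
  invisible(x)
}

# single-linkage components under d <= threshold, via union-find
single_linkage_components <- function(D, threshold) {
  m <- nrow(D)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  eps <- 1e-12
  for (i in seq_len(m - 1L))
    for (j in seq.int(i + 1L, m))
      if (D[i, j] <= threshold + eps) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
  vapply(seq_len(m), find, integer(1))
}

#' Cluster partitions into clonal families
#'
#' Within each V/J/length partition, two rearrangements join the same
#' clonal family when their junction distance is at most the threshold
#' (single-linkage transitive closure). Clone ids are deterministic:
#' partition key plus the smallest member `sequence_id`.
#'
#' @param partitions Output of [partition_records()].
#' @param threshold Numeric in \[0,1\] or a [find_threshold()] result.
#' @return List of clone families: `clone_id`, `v_gene`, `j_gene`,
#'   `junction_length_nt`, `member_ids`.
#' @export
cluster_clones <- function(partitions, threshold) {
  if (inherits(threshold, "distance_threshold")) threshold <- threshold$value
  stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 1)
  keys <- attr(partitions, "keys")
  fams <- list()
  for (key in names(partitions)) {
    p <- partitions[[key]]
    m <- nrow(p)
    comp <- if (m == 1L) 1L
            else single_linkage_components(hamming_matrix(p$junction),
                                           threshold)
    for (cid in unique(comp)) {
      ids <- sort(p$sequence_id[comp == cid])
      fams[[length(fams) + 1L]] <- list(
        clone_id = paste(key, ids[1], sep = "|"),
        v_gene = keys[key, "v_gene"],
        j_gene = keys[key, "j_gene"],
        junction_length_nt = keys[key, "junction_length_nt"],
        member_ids = ids)
    }
  }
  fams[order(vapply(fams, `[[`, character(1), "clone_id"))]
}

#' Pick the clonal representative
#'
#' The member with the highest number of sequenced mRNA molecules
#' (`duplicate_count`); ties broken by lexicographically smallest
#' `sequence_id`.
#'
#' @param family A clone family from [cluster_clones()].
#' @param records Rearrangement data frame covering the members.
#' @return The representative `sequence_id`.
#' @export
select_representative <- function(family, records) {
  idx <- match(family$member_ids, records$sequence_id)
  if (anyNA(idx)) stop("clone members missing from records: ",
                       paste(family$member_ids[is.na(idx)], collapse = ", "))
  counts <- records$duplicate_count[idx]
  ids <- family$member_ids
  ids[order(-counts, ids)][1]
}

#' Infer clonal families across a repertoire
#'
#' High-level driver: partitions records by V gene, J gene and junction
#' length, computes one distance threshold per `group_by` stratum (the
#' study computed one per sample and B-cell subpopulation) from the
#' distance-to-nearest distribution, clusters with single linkage, and
#' selects representatives.
#'
#' @param records Rearrangement data frame.
#' @param threshold Optional fixed threshold overriding detection.
#' @param group_by Columns defining the per-threshold strata (default
#'   `sample_id` + `population_label`); `NULL` for one global threshold.
#' @param bandwidth,min_distances,fallback Passed to [find_threshold()].
#' @return `records` with `clone_id` and `is_representative` columns,
#'   plus attributes `"thresholds"` (data frame: group, value, method,
#'   n_distances) and `"clones"` (the clone family list).
#' @export
infer_clones <- function(records, threshold = NULL,
                         group_by = c("sample_id", "population_label"),
                         bandwidth = 0.02, min_distances = 50,
                         fallback = 0.15) {
  if (nrow(records) == 0L) {
    records$clone_id <- character(0)
    records$is_representative <- logical(0)
    attr(records, "thresholds") <- data.frame(group = character(),
                                              value = numeric(),
                                              method = character(),
                                              n_distances = integer())
    attr(records, "clones") <- list()
    return(records)
  }
  grp <- if (is.null(group_by)) rep("all", nrow(records))
         else do.call(paste, c(records[group_by], sep = "/"))
  records$clone_id <- NA_character_
  records$is_representative <- FALSE
  thresholds <- list()
  clones <- list()
  for (g in sort(unique(grp))) {
    sub <- records[grp == g, , drop = FALSE]
    parts <- partition_records(sub)
    if (!is.null(threshold)) {
      th <- structure(list(value = threshold, method = "fixed",
                           n = NA_integer_, density = NULL),
                      class = "distance_threshold")
    } else {
      nn <- suppressWarnings(nearest_neighbor_distances(parts))
      th <- if (length(nn) < min_distances)
        structure(list(value = fallback, method = "fixed", n = length(nn),
                       density = NULL), class = "distance_threshold")
      else find_threshold(nn, bandwidth = bandwidth,
                          min_distances = min_distances, fallback = fallback)
    }
    fams <- cluster_clones(parts, th)
    for (f in fams) {
      rep_id <- select_representative(f, sub)
      records$clone_id[match(f$member_ids, records$sequence_id)] <-
        paste(g, f$clone_id, sep = "/")
      records$is_representative[match(rep_id, records$sequence_id)] <- TRUE
    }
    thresholds[[g]] <- data.frame(group = g, value = th$value,
                                  method = th$method,
                                  n_distances = th$n %||% NA_integer_,
                                  stringsAsFactors = FALSE)
    clones[[g]] <- fams
  }
  attr(records, "thresholds") <- do.call(rbind, c(thresholds,
                                                  make.row.names = FALSE))
  attr(records, "clones") <- clones
  records
}
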