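# Somatic hypermutation status from germline V identity.

#' Percent identity of an observed V segment to its germline gene
#'
#' Substitution-only model: the sequences must be pre-aligned and of equal
#' length (indel-containing input is rejected). Positions where either
#' sequence carries an ambiguity character (anything other than A/C/G/T)
#' are excluded from both numerator and denominator.
#'
#' @param observed_v,germline_v Nucleotide strings of equal length.
#' @return Percent identity in \[0,100\].
#' @export
germline_identity <- function(observed_v, germline_v) {
  if (nchar(observed_v) != nchar(germline_v))
    stop("length mismatch (", nchar(observed_v), " vs ", nchar(germline_v),
         "): indel-containing input is unsupported")
  if (nchar(observed_v) == 0L) stop("empty sequence")
  a <- strsplit(toupper(observed_v), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(germline_v), "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  informative <- a %in% acgt & b %in% acgt
  if (!any(informative))
    stop("no informative (unambiguous) positions")
  100 * mean(a[informative] == b[informative])
}

#' Mutational status at a germline-identity cutoff
#'
#' A rearrangement is called unmutated when its germline identity is at
#' least `100 - cutoff_pct` percent (boundary inclusive, consistent with
#' the GI >= 98% convention used for CLL). The default 1% cutoff is the
#' stricter convention used for normal-repertoire stereotyped sequences;
#' pass `cutoff_pct = 2` for the CLL convention.
#'
#' @param v_identity_pct Numeric vector of percent identities in \[0,100\].
#' @param cutoff_pct Positive percent-difference cutoff (default 1).
#' @return Character vector, `"unmutated"` or `"mutated"`.
#' @export
mutation_status <- function(v_identity_pct, cutoff_pct = 1.0) {
  stopifnot(cutoff_pct > 0,
            all(is.na(v_identity_pct) |
                  (v_identity_pct >= 0 & v_identity_pct <= 100)))
  ifelse(v_identity_pct >= 100 - cutoff_pct - 1e-9, "unmutated", "mutated")
}

#' Read a germline V reference FASTA
#'
#' @param path Path to a FASTA file of germline V sequences, names matching
#'   allele or gene calls.
#' @return Named character vector of uppercase sequences.
#' @export
read_germline_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Annotate SHM status on a rearrangement table
#'
#' Uses the annotator-provided `v_identity_pct` column when present;
#' otherwise recomputes identity from a `v_sequence` column against the
#' germline reference (matched by gene-level `v_gene`, falling back to
#' `v_call`). Appends `shm_status` and `shm_cutoff` columns.
#'
#' @param records Rearrangement data frame.
#' @param cutoff_pct Percent cutoff, see [mutation_status()].
#' @param germline Optional named vector from [read_germline_fasta()].
#' @return `records` with `shm_status`/`shm_cutoff` appended.
#' @export
annotate_shm <- function(records, cutoff_pct = 1.0, germline = NULL) {
  ident <- records$v_identity_pct
  needs <- is.na(ident)
  if (any(needs)) {
    if (is.null(germline) || is.null(records$v_sequence))
      stop("records lack v_identity_pct; supply a germline reference and ",
           "a v_sequence column to recompute it")
    for (i in which(needs)) {
      g <- germline[[records$v_gene[i]]] %||% germline[[records$v_call[i]]]
      if (is.null(g)) stop("no germline sequence for ", records$v_call[i])
      obs <- records$v_sequence[i]
      ident[i] <- germline_identity(obs, substr(g, 1L, nchar(obs)))
    }
  }
  records$v_identity_pct <- ident
  records$shm_status <- mutation_status(ident, cutoff_pct)
  records$shm_cutoff <- cutoff_pct
  records
}
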