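# Cohort statistics over a table of pathogenic SNVs: input exclusion
# filters, per-substitution repairability counts, the synonymous-only
# fraction among repairable transitions, and the amino-acid substitution
# matrix for transversion-derived variants, together with the PAM-free
# codon-degeneracy enumeration used as its theoretical upper bound.

.DEFAULT_COHORT_MAPPING <- list(id = "id", chrom = "chrom", ref = "ref_base",
                                var = "var_base", sequence = "sequence",
                                snv_pos = "snv_pos",
                                frame_offset = "frame_offset")

#' Apply cohort exclusion filters
#'
#' Keeps single-nucleotide substitutions on non-mitochondrial chromosomes
#' with a usable variant-bearing sequence and frame. Insertions, deletions
#' and multi-nucleotide variants (allele length != 1) are excluded, as are
#' mitochondrial records (the standard nuclear code does not apply there)
#' and records whose sequence/position/frame fields are unusable.
#'
#' @param records data frame of raw variant records.
#' @param mapping named list mapping the roles id, chrom, ref, var, sequence,
#'   snv_pos, frame_offset to column names of `records`; chrom is optional
#'   (records then cannot be excluded as mitochondrial).
#' @return list with `records` (a list of [snv_record()]) and `excluded`
#'   (named counts: indel_or_mnv, mitochondrial, invalid).
#' @export
apply_exclusion_filters <- function(records,
                                    mapping = .DEFAULT_COHORT_MAPPING) {
  mapping <- utils::modifyList(.DEFAULT_COHORT_MAPPING, mapping)
  need <- setdiff(unlist(mapping[c("ref", "var", "sequence", "snv_pos")]),
                  names(records))
  if (length(need))
    stop(sprintf("variant table lacks required column(s): %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  has_chrom <- mapping$chrom %in% names(records)
  has_id <- mapping$id %in% names(records)
  has_frame <- mapping$frame_offset %in% names(records)
  excluded <- c(indel_or_mnv = 0L, mitochondrial = 0L, invalid = 0L)
  kept <- list()
  for (i in seq_len(nrow(records))) {
    row <- records[i, , drop = FALSE]
    ref <- toupper(as.character(row[[mapping$ref]]))
    var <- toupper(as.character(row[[mapping$var]]))
    if (is.na(ref) || is.na(var) || nchar(ref) != 1 || nchar(var) != 1 ||
        !ref %in% c("A", "C", "G", "T") || !var %in% c("A", "C", "G", "T")) {
      excluded["indel_or_mnv"] <- excluded["indel_or_mnv"] + 1L
      next
    }
    if (has_chrom) {
      chrom <- sub("^chr", "", as.character(row[[mapping$chrom]]),
                   ignore.case = TRUE)
      if (toupper(chrom) %in% c("M", "MT")) {
        excluded["mitochondrial"] <- excluded["mitochondrial"] + 1L
        next
      }
    }
    rec <- tryCatch(
      snv_record(id = if (has_id) as.character(row[[mapping$id]]) else
                   as.character(i),
                 sequence = as.character(row[[mapping$sequence]]),
                 snv_pos = as.integer(row[[mapping$snv_pos]]),
                 ref_base = ref, var_base = var,
                 frame_offset = if (has_frame)
                   as.integer(row[[mapping$frame_offset]]) else 0L),
      error = function(e) NULL)
    if (is.null(rec)) {
      excluded["invalid"] <- excluded["invalid"] + 1L
      next
    }
    kept[[length(kept) + 1]] <- rec
  }
  list(records = kept, excluded = excluded)
}

.aa_of_codon_at <- function(sequence, pos, frame_offset) {
  start <- .codon_start_at(pos, frame_offset, nchar(sequence))
  if (is.na(start)) return(list(codon = NA_character_, aa = NA_character_))
  codon <- substr(sequence, start, start + 2)
  list(codon = codon, aa = unname(Biostrings::GENETIC_CODE[codon]))
}

#' Summarize repairability over a cohort of SNV records
#'
#' Runs [find_corrections()] for every record. A record counts as repairable
#' when at least one major-window correction exists; it is synonymous-only
#' when repairable without any major-window precise correction. Records
#' rescued only through minor-window matches are tallied separately and do
#' not count as repairable. For transversions, occurrences and repairs are
#' additionally keyed by the (reference AA, variant AA) substitution derived
#' from the reading frame.
#'
#' @param records list of [snv_record()] (e.g. from
#'   [apply_exclusion_filters()]).
#' @param registry an `editor_registry`.
#' @param excluded optional exclusion counts to carry into the summary.
#' @return object of class `cohort_summary`.
#' @export
summarize_cohort <- function(records, registry = builtin_registry(),
                             excluded = c(indel_or_mnv = 0L,
                                          mitochondrial = 0L, invalid = 0L)) {
  n_total <- length(records)
  is_tr <- logical(n_total)
  repairable <- logical(n_total)
  has_precise <- logical(n_total)
  minor_only <- logical(n_total)
  aa_key <- character(n_total)
  per_record <- vector("list", n_total)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    is_tr[i] <- is_transition(rec$ref_base, rec$var_base)
    cs <- find_corrections(rec, registry, include_minor = TRUE)
    df <- as.data.frame(cs)
    per_record[[i]] <- df
    major <- df[df$window == "major", , drop = FALSE]
    repairable[i] <- nrow(major) > 0
    has_precise[i] <- any(major$scenario == "precise")
    minor_only[i] <- nrow(df) > 0 && nrow(major) == 0
    ref_seq <- rec$sequence
    substr(ref_seq, rec$snv_pos, rec$snv_pos) <- rec$ref_base
    ref_aa <- .aa_of_codon_at(ref_seq, rec$snv_pos, rec$frame_offset)$aa
    var_aa <- .aa_of_codon_at(rec$sequence, rec$snv_pos,
                              rec$frame_offset)$aa
    aa_key[i] <- if (is.na(ref_aa) || is.na(var_aa)) NA_character_ else
      paste0(ref_aa, ">", var_aa)
  }
  tv <- !is_tr
  keys <- sort(unique(aa_key[tv & !is.na(aa_key)]))
  aa_matrix <- data.frame(
    ref_aa = sub(">.*", "", keys), var_aa = sub(".*>", "", keys),
    n_occurrences = vapply(keys, function(k)
      sum(aa_key == k & tv, na.rm = TRUE), integer(1)),
    n_repairable = vapply(keys, function(k)
      sum(aa_key == k & tv & repairable, na.rm = TRUE), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    n_total = n_total,
    n_transitions = sum(is_tr),
    n_transversions = sum(tv),
    n_transitions_repairable = sum(is_tr & repairable),
    n_transitions_synonymous_only = sum(is_tr & repairable & !has_precise),
    n_transversions_repairable = sum(tv & repairable),
    n_minor_only = sum(minor_only),
    aa_substitution_matrix = aa_matrix,
    excluded = excluded,
    per_record = per_record
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d SNVs: %d transitions, %d transversions\n",
              x$n_total, x$n_transitions, x$n_transversions))
  if (x$n_transitions > 0)
    cat(sprintf("  transitions repairable: %d (%.1f%%), of which synonymous-only: %d (%.1f%% of repairable)\n",
                x$n_transitions_repairable,
                100 * x$n_transitions_repairable / x$n_transitions,
                x$n_transitions_synonymous_only,
                if (x$n_transitions_repairable > 0)
                  100 * x$n_transitions_synonymous_only /
                    x$n_transitions_repairable else 0))
  if (x$n_transversions > 0)
    cat(sprintf("  transversions repairable (synonymous corrections): %d (%.1f%%)\n",
                x$n_transversions_repairable,
                100 * x$n_transversions_repairable / x$n_transversions))
  cat(sprintf("  minor-window-only matches (not counted as repairable): %d\n",
              x$n_minor_only))
  if (sum(x$excluded) > 0)
    cat(sprintf("  excluded upstream: %s\n",
                paste(names(x$excluded), x$excluded, sep = "=",
                      collapse = ", ")))
  invisible(x)
}

.CHEMISTRIES <- list(c("C", "T"), c("A", "G"), c("G", "A"), c("T", "C"))
.TRANSVERSION_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                               C = c("A", "G"), T = c("A", "G"))

# Can some one-chemistry transition edit of var_codon restore ref_aa?
# Achievable edit sets are the source-base positions inside a contiguous
# interval of codon positions (an activity window truncates the codon to an
# interval; every source base inside it converts).
.codon_recoverable <- function(var_codon, ref_aa) {
  bases <- strsplit(var_codon, "")[[1]]
  for (chem in .CHEMISTRIES) {
    src_pos <- which(bases == chem[1])
    if (length(src_pos) == 0) next
    for (a in 1:3) for (b in a:3) {
      conv <- src_pos[src_pos >= a & src_pos <= b]
      if (length(conv) == 0) next
      edited <- bases
      edited[conv] <- chem[2]
      if (unname(Biostrings::GENETIC_CODE[paste(edited, collapse = "")]) ==
          ref_aa)
        return(TRUE)
    }
  }
  FALSE
}

#' Codon-level recoverability of transversion-derived AA substitutions
#'
#' PAM-free exhaustive enumeration: every sense codon is subjected to each of
#' its nine single-base transversions; a (reference AA, variant AA) pair is
#' recoverable when for at least one such codon pair some one-chemistry
#' transition edit set (all source bases within a contiguous stretch of the
#' codon, mimicking an activity window) restores the reference amino acid.
#' This is the theoretical upper bound on what placement-constrained editing
#' can rescue: PAM and window constraints can only shrink the set.
#'
#' @return data frame with columns ref_aa, var_aa, recoverable, one row per
#'   transversion-reachable amino-acid substitution (ref_aa != var_aa;
#'   variant stop codons are included as '*').
#' @examples
#' tab <- recoverable_substitution_table()
#' subset(tab, ref_aa == "I" & var_aa == "M")$recoverable  # TRUE
#' @export
recoverable_substitution_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  res <- new.env(parent = emptyenv())
  for (codon in sense) {
    ref_aa <- unname(gc[codon])
    bases <- strsplit(codon, "")[[1]]
    for (p in 1:3) for (alt in .TRANSVERSION_PARTNERS[[bases[p]]]) {
      vb <- bases
      vb[p] <- alt
      var_codon <- paste(vb, collapse = "")
      var_aa <- unname(gc[var_codon])
      if (var_aa == ref_aa) next
      key <- paste0(ref_aa, ">", var_aa)
      prev <- if (is.null(res[[key]])) FALSE else res[[key]]
      if (!prev) res[[key]] <- .codon_recoverable(var_codon, ref_aa)
    }
  }
  keys <- sort(ls(res))
  data.frame(ref_aa = sub(">.*", "", keys), var_aa = sub(".*>", "", keys),
             recoverable = vapply(keys, function(k) res[[k]], logical(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
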