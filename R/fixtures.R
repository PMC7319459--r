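# Synthetic SNV fixture generator. Each record is a random coding sequence
# (sense codons, no internal stops) with a codon-aligned cassette implanted
# at a random position. The cassette fixes the protospacer, PAM and activity
# window content of one planted editor placement, so the intended correction
# scenario is guaranteed by construction; incidental additional corrections
# arising from the random flanks are allowed, the ground truth is "the
# planted correction exists", not "it is unique".

# Cassettes are codon-aligned. snv_off is 1-based within the cassette
# (after the guard for plus-strand cassettes). The 9-nt guard preceding the
# plus-strand CBE cassettes pins the sequence immediately 5' of the
# protospacer so that no chance PAM can yield an unplanned precise
# correction there; the analysis of in-cassette PAM geometry rules out the
# rest, which keeps planted multiple-bases records free of precise hits.
.FIXTURE_TEMPLATES <- list(
  precise = list(
    guard = "GAAGAAGAA", cassette = "GCCACATTAGAAGATTTTTTAGGA",
    snv_off = 5L, ref = "T", var = "C", editor = "BE3", strand = "+"),
  multiple_bases_synonymous = list(
    guard = "GAAGAAGAA", cassette = "GCCACTCTAGAAGATTTTTTAGGA",
    snv_off = 5L, ref = "T", var = "C", editor = "BE3", strand = "+"),
  on_target_synonymous = list(
    guard = "", cassette = "GTCCAGGAAGACGAAGATTTAGGAAAA",
    snv_off = 22L, ref = "C", var = "G", editor = "BE3", strand = "-"),
  bystander_synonymous = list(
    guard = "", cassette = "GTCCAGGAAGACGAAGACGGCTTTAAA",
    snv_off = 24L, ref = "A", var = "T", editor = "ABE 7.10*", strand = "-"),
  unrepairable = list(
    guard = "", cassette = "GAC",
    snv_off = 2L, ref = "C", var = "A", editor = NA_character_,
    strand = NA_character_)
)

.SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

#' Generate a synthetic SNV cohort with known ground truth
#'
#' Produces `n_records` variant-bearing coding sequences whose intended
#' correction scenario is planted by construction: a transition SNV with a
#' clean BE3 window (precise), the multi-C window that co-edits a synonymous
#' bystander (multiple bases synonymous), an R>G transversion rescued
#' on-target by a minus-strand CBE, an L>F transversion rescued by a
#' bystander edit through an ABE minor-window match, or an A>D transversion
#' that no transition chemistry can rescue at the codon level
#' (unrepairable, [find_corrections()] is provably empty for it).
#'
#' @param n_records number of records.
#' @param scenario_mix named proportions over the five classes; must sum
#'   to 1.
#' @param seed integer seed; generation is reproducible.
#' @param cds_length sequence length in nt, a multiple of 3, >= 60 so every
#'   cassette fits.
#' @param editor_pool editor names (or aliases) whose PAMs may be planted;
#'   a scenario whose planted editor is not in the pool raises an error
#'   naming the class.
#' @return list with `records` (list of [snv_record()]) and `labels`
#'   (data frame: id, scenario, editor, strand).
#' @examples
#' fx <- generate_fixture(10, c(precise = 1), seed = 7)
#' fx$labels$scenario
#' @export
generate_fixture <- function(n_records,
                             scenario_mix = c(precise = 0.2,
                                              multiple_bases_synonymous = 0.2,
                                              on_target_synonymous = 0.2,
                                              bystander_synonymous = 0.2,
                                              unrepairable = 0.2),
                             seed = 1L, cds_length = 120L,
                             editor_pool = c("BE3", "ABE 7.10*")) {
  stopifnot(n_records >= 1)
  if (cds_length %% 3 != 0 || cds_length < 60)
    stop("cds_length must be a multiple of 3 and at least 60", call. = FALSE)
  bad <- setdiff(names(scenario_mix), names(.FIXTURE_TEMPLATES))
  if (length(bad))
    stop(sprintf("unknown scenario class: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (abs(sum(scenario_mix) - 1) > 1e-8)
    stop("scenario_mix proportions must sum to 1", call. = FALSE)
  reg <- builtin_registry()
  pool <- unique(unlist(lapply(editor_pool, function(nm)
    lookup_editor(reg, nm)$name)))
  for (sc in names(scenario_mix)[scenario_mix > 0]) {
    planted <- .FIXTURE_TEMPLATES[[sc]]$editor
    if (!is.na(planted) && !planted %in% pool)
      stop(sprintf("scenario '%s' needs editor '%s', not in editor_pool",
                   sc, planted), call. = FALSE)
  }
  # largest-remainder apportionment of n_records over the classes
  raw <- scenario_mix * n_records
  counts <- floor(raw)
  rem <- n_records - sum(counts)
  if (rem > 0) {
    o <- order(raw - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }
  scenarios <- rep(names(counts), counts)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)

  n_codons <- cds_length %/% 3
  records <- vector("list", n_records)
  labels <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    sc <- scenarios[i]
    tp <- .FIXTURE_TEMPLATES[[sc]]
    insert <- paste0(tp$guard, tp$cassette)
    ins_codons <- nchar(insert) %/% 3
    slot <- sample.int(n_codons - ins_codons + 1, 1)
    codons <- sample(.SENSE_CODONS, n_codons, replace = TRUE)
    seq_str <- paste(codons, collapse = "")
    at <- (slot - 1) * 3 + 1
    substr(seq_str, at, at + nchar(insert) - 1) <- insert
    snv_pos <- at + nchar(tp$guard) + tp$snv_off - 1
    id <- sprintf("fx%04d_%s", i, sc)
    records[[i]] <- snv_record(id, seq_str, snv_pos, tp$ref, tp$var,
                               frame_offset = 0)
    labels[[i]] <- data.frame(id = id, scenario = sc,
                              editor = tp$editor, strand = tp$strand,
                              stringsAsFactors = FALSE)
  }
  list(records = records, labels = do.call(rbind, labels))
}

#' Write a fixture as batch and label TSVs
#'
#' @param fixture a [generate_fixture()] result.
#' @param records_path output TSV of batch rows (id, sequence, snv_pos,
#'   ref_base, var_base, frame_offset).
#' @param labels_path optional output TSV of ground-truth labels.
#' @export
write_fixture_tsv <- function(fixture, records_path, labels_path = NULL) {
  df <- do.call(rbind, lapply(fixture$records, function(r)
    data.frame(id = r$id, sequence = r$sequence, snv_pos = r$snv_pos,
               ref_base = r$ref_base, var_base = r$var_base,
               frame_offset = r$frame_offset, stringsAsFactors = FALSE)))
  utils::write.table(df, records_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(labels_path))
    utils::write.table(fixture$labels, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(records_path)
}
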