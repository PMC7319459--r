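# Correction-scenario classification. A precise correction requires the
# edited DNA to equal the reference allele sequence; synonymous corrections
# require the translated protein (over the whole in-frame sequence) to equal
# the reference protein while the DNA differs. The synonymous family splits
# by what happened at the SNV itself: corrected with extra bystander changes
# (multiple bases), converted to a third base encoding the reference amino
# acid (on-target), or untouched while a bystander edit rescues the codon
# (bystander).

.SCENARIOS <- c("precise", "multiple_bases_synonymous",
                "on_target_synonymous", "bystander_synonymous", "none")

#' Classify an edit outcome against the reference allele
#'
#' Decision order: (1) edited DNA equals the reference sequence -> precise;
#' otherwise, if the edited protein equals the reference protein: (2) SNV
#' restored to the reference base but bystanders differ -> multiple bases
#' synonymous, (3) SNV converted to a base that is neither variant nor
#' reference -> on-target synonymous, (4) SNV still the variant base ->
#' bystander synonymous; otherwise -> none. The protein comparison spans the
#' full in-frame translation, so an edit that damages a neighboring codon
#' disqualifies the placement.
#'
#' @param outcome an [simulate_edit()] result.
#' @param snv the [snv_record()] it derives from.
#' @return object of class `correction_result`.
#' @export
classify_outcome <- function(outcome, snv) {
  stopifnot(inherits(outcome, "edit_outcome"), inherits(snv, "snv_record"))
  S <- snv$sequence
  p <- snv$snv_pos
  reference <- S
  substr(reference, p, p) <- snv$ref_base
  edited <- outcome$edited_sequence
  if (nchar(edited) != nchar(S))
    stop("edited sequence length differs from the input", call. = FALSE)
  ref_prot <- translate_cds(reference, snv$frame_offset)
  var_prot <- translate_cds(S, snv$frame_offset)
  ed_prot <- translate_cds(edited, snv$frame_offset)
  snv_after <- substr(edited, p, p)
  scenario <- if (edited == reference) {
    "precise"
  } else if (ed_prot == ref_prot) {
    if (snv_after == snv$ref_base) "multiple_bases_synonymous"
    else if (snv_after != snv$var_base) "on_target_synonymous"
    else "bystander_synonymous"
  } else "none"
  structure(list(outcome = outcome, scenario = scenario,
                 reference_sequence = reference,
                 edited_protein = ed_prot, reference_protein = ref_prot,
                 variant_protein = var_prot,
                 snv_base_after_edit = snv_after),
            class = "correction_result")
}

#' Find all base-editing corrections for an SNV
#'
#' Runs the full pipeline — placement enumeration, deterministic edit
#' simulation, classification — and keeps every result whose scenario is not
#' `none`, precise corrections first. Placements that reach the SNV only
#' through a minor activity window are carried with their
#' `minor_window_match` flag (set `include_minor = FALSE` to drop them).
#'
#' @param snv an [snv_record()].
#' @param registry an `editor_registry`; defaults to the built-in repository.
#' @param include_minor keep minor-window SNV matches?
#' @return object of class `correction_set`.
#' @examples
#' reg <- builtin_registry()
#' snv <- snv_record("ex", paste0("GAAGAAGAAGCCACTCTAGAAGATTTTTTAGGAGAAGAA"),
#'                   14, "T", "C", 0)
#' find_corrections(snv, reg)
#' @export
find_corrections <- function(snv, registry = builtin_registry(),
                             include_minor = TRUE) {
  pls <- enumerate_placements(snv, registry)
  if (!include_minor) pls <- pls[pls$window == "major", , drop = FALSE]
  results <- list()
  for (i in seq_len(nrow(pls))) {
    out <- simulate_edit(pls[i, ], snv, registry)
    res <- classify_outcome(out, snv)
    if (res$scenario != "none") results[[length(results) + 1]] <- res
  }
  precise <- vapply(results, function(r) r$scenario == "precise", logical(1))
  results <- c(results[precise], results[!precise])
  structure(list(snv = snv, results = results), class = "correction_set")
}

#' @export
length.correction_set <- function(x) length(x$results)

#' Correction results as a data frame
#'
#' One row per correction with the serialization columns: id, editor, strand,
#' protospacer interval, observed PAM, SNV distance from PAM, window
#' (major/minor), scenario, edited protospacer-strand sequence over the major
#' window, and the number of bystander changes (changed positions other than
#' the SNV).
#'
#' @param x a `correction_set`.
#' @param ... unused.
#' @export
as.data.frame.correction_set <- function(x, ...) {
  empty <- data.frame(id = character(), editor = character(),
                      strand = character(), protospacer = character(),
                      pam = character(), snv_distance_from_pam = integer(),
                      window = character(), scenario = character(),
                      edited_window_sequence = character(),
                      bystander_count = integer(),
                      minor_bystander_flag = logical(),
                      stringsAsFactors = FALSE)
  if (length(x$results) == 0) return(empty)
  do.call(rbind, lapply(x$results, function(r) {
    pl <- r$outcome$placement
    ed_seq <- r$outcome$edited_sequence
    snv <- x$snv
    reg_ed <- pl$editor
    # edited major-window sequence on the protospacer strand
    span_seq <- substr(ed_seq, pl$proto_start, pl$proto_end)
    if (pl$strand == "-") span_seq <- reverse_complement(span_seq)
    data.frame(id = snv$id, editor = reg_ed, strand = pl$strand,
               protospacer = sprintf("%d-%d", pl$proto_start, pl$proto_end),
               pam = pl$pam_site, snv_distance_from_pam = pl$dist,
               window = pl$window, scenario = r$scenario,
               edited_window_sequence = span_seq,
               bystander_count = sum(r$outcome$changed_positions !=
                                       snv$snv_pos),
               minor_bystander_flag = r$outcome$minor_bystander_flag,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.correction_set <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("SNV %s: %s>%s at position %d (%s)\n", x$snv$id, x$snv$ref_base,
              x$snv$var_base, x$snv$snv_pos,
              if (is_transition(x$snv$ref_base, x$snv$var_base)) "transition"
              else "transversion"))
  if (nrow(df) == 0) {
    cat("no correction found\n")
    return(invisible(x))
  }
  prec <- df[df$scenario == "precise", , drop = FALSE]
  syn <- df[df$scenario != "precise", , drop = FALSE]
  cat(sprintf("Precise corrections: %d\n", nrow(prec)))
  if (nrow(prec)) print(prec, row.names = FALSE)
  cat(sprintf("Synonymous corrections: %d\n", nrow(syn)))
  if (nrow(syn)) print(syn, row.names = FALSE)
  if (any(df$window == "minor"))
    cat("note: minor-window matches present; minor editing may occur at lower efficiency\n")
  invisible(x)
}
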