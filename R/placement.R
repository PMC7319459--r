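# Placement search and deterministic edit simulation. A placement is a
# (editor, strand, protospacer start) triple whose PAM matches the sequence
# and whose major or minor activity window covers the SNV. Simulation
# converts every target base inside the major window on the protospacer
# strand; minor windows are flagged, never edited.

#' Construct an SNV record
#'
#' The sequence carries the VARIANT allele; `snv_pos` is the 1-based position
#' of the variant base within it. Supply at least (max gRNA length + max PAM
#' length) flanking bases on each side of the SNV when possible, otherwise
#' the placement scan is truncated at the sequence ends.
#'
#' @param id record identifier.
#' @param sequence DNA string over A/C/G/T containing the variant base.
#' @param snv_pos 1-based position of the variant within `sequence`.
#' @param ref_base,var_base single reference / variant bases on the given
#'   strand; `sequence[snv_pos]` must equal `var_base`.
#' @param frame_offset 0, 1 or 2: bases before the first complete codon.
#' @return object of class `snv_record`.
#' @export
snv_record <- function(id, sequence, snv_pos, ref_base, var_base,
                       frame_offset = 0) {
  sequence <- normalize_dna(sequence)
  ref_base <- normalize_dna(ref_base, what = "ref_base")
  var_base <- normalize_dna(var_base, what = "var_base")
  snv_pos <- as.integer(snv_pos)
  frame_offset <- as.integer(frame_offset)
  if (nchar(ref_base) != 1 || nchar(var_base) != 1)
    stop("ref_base and var_base must be single bases", call. = FALSE)
  if (ref_base == var_base)
    stop("ref_base and var_base must differ", call. = FALSE)
  if (is.na(snv_pos) || snv_pos < 1 || snv_pos > nchar(sequence))
    stop("snv_pos outside the sequence", call. = FALSE)
  if (substr(sequence, snv_pos, snv_pos) != var_base)
    stop(sprintf("sequence position %d is '%s', not the stated variant base '%s'",
                 snv_pos, substr(sequence, snv_pos, snv_pos), var_base),
         call. = FALSE)
  if (!frame_offset %in% 0:2)
    stop("frame_offset must be 0, 1 or 2", call. = FALSE)
  structure(list(id = as.character(id), sequence = sequence,
                 snv_pos = snv_pos, ref_base = ref_base, var_base = var_base,
                 frame_offset = frame_offset),
            class = "snv_record")
}

#' Is a substitution a transition?
#'
#' @param ref_base,var_base single bases.
#' @return TRUE for purine<->purine or pyrimidine<->pyrimidine substitutions.
#' @export
is_transition <- function(ref_base, var_base) {
  purine <- c("A", "G")
  (ref_base %in% purine) == (var_base %in% purine)
}

# Sense-strand coordinates of a distance-from-PAM interval [lo, hi] for a
# placement whose protospacer starts at `start` (sense coordinates).
.window_span <- function(start, grna_length, pam_side, strand, lo, hi) {
  if ((strand == "+") == (pam_side == "three_prime")) {
    # distances count down the sense coordinate axis
    c(start + grna_length - hi, start + grna_length - lo)
  } else {
    c(start + lo - 1, start + hi - 1)
  }
}

# Distance from PAM of sense position p for the same placement.
.pam_distance <- function(p, start, grna_length, pam_side, strand) {
  if ((strand == "+") == (pam_side == "three_prime"))
    start + grna_length - p
  else
    p - start + 1
}

# PAM location (sense coordinates) for a protospacer starting at `start`.
.pam_span <- function(start, grna_length, pam_len, pam_side, strand) {
  if ((strand == "+") == (pam_side == "three_prime"))
    c(start + grna_length, start + grna_length + pam_len - 1)
  else
    c(start - pam_len, start - 1)
}

#' Enumerate guide placements covering an SNV
#'
#' For every editor in the registry, both strands, and every protospacer
#' start for which (i) the PAM site matches on the protospacer strand,
#' (ii) the SNV lies inside the major or a minor activity window and
#' (iii) protospacer and PAM fit within the sequence, a placement is emitted.
#' All editors are tried regardless of the substitution type: the window/PAM
#' criteria are purely positional, which is what enables on-target and
#' bystander rescues of transversions. A protospacer or PAM running past a
#' sequence end is skipped, not padded.
#'
#' @param snv an [snv_record()].
#' @param registry an `editor_registry`.
#' @return data frame of class `guide_placements`, ordered by registry order,
#'   strand (+ before -) and protospacer start, with columns editor, strand,
#'   proto_start, proto_end, pam_start, pam_end, pam_site (protospacer-strand
#'   PAM text), window ("major"/"minor") and dist (SNV distance from PAM).
#' @export
enumerate_placements <- function(snv, registry) {
  stopifnot(inherits(snv, "snv_record"), inherits(registry, "editor_registry"))
  S <- snv$sequence
  n <- nchar(S)
  p <- snv$snv_pos
  rows <- list()
  for (ed in registry$editors) {
    L <- ed$grna_length
    m <- nchar(ed$pam)
    major <- ed$major_window[1]:ed$major_window[2]
    minor <- unlist(lapply(ed$minor_windows, function(w) w[1]:w[2]))
    dists <- c(major, minor)
    labels <- c(rep("major", length(major)), rep("minor", length(minor)))
    for (strand in c("+", "-")) {
      down <- (strand == "+") == (ed$pam_side == "three_prime")
      # protospacer start placing the SNV at distance d
      starts <- if (down) p - L + dists else p - dists + 1
      keep <- starts >= 1 & starts + L - 1 <= n
      if (!any(keep)) next
      st <- starts[keep]
      lab <- labels[keep]
      d <- dists[keep]
      pam_start <- if (down) st + L else st - m
      pam_end <- pam_start + m - 1
      ok <- pam_start >= 1 & pam_end <= n
      if (!any(ok)) next
      st <- st[ok]; lab <- lab[ok]; d <- d[ok]
      pam_start <- pam_start[ok]; pam_end <- pam_end[ok]
      pam_seq <- substring(S, pam_start, pam_end)
      if (strand == "-") pam_seq <- reverse_complement(pam_seq)
      hit <- iupac_match(ed$pam, pam_seq)
      if (!any(hit)) next
      rows[[length(rows) + 1]] <- data.frame(
        editor = ed$name, strand = strand,
        proto_start = st[hit], proto_end = st[hit] + L - 1,
        pam_start = pam_start[hit], pam_end = pam_end[hit],
        pam_site = pam_seq[hit], window = lab[hit], dist = d[hit],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(editor = character(), strand = character(),
               proto_start = integer(), proto_end = integer(),
               pam_start = integer(), pam_end = integer(),
               pam_site = character(), window = character(),
               dist = integer(), stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("editor", "strand", "proto_start")]), ,
             drop = FALSE]
  ed_order <- vapply(registry$editors, function(e) e$name, character(1))
  o <- order(match(out$editor, ed_order),
             match(out$strand, c("+", "-")), out$proto_start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("guide_placements", "data.frame")
  out
}

#' Simulate the outcome of a base-editing placement
#'
#' Deterministic all-or-nothing major-window editing: every source base
#' (C for CBEs, A for ABEs, on the protospacer strand) inside the major
#' activity window is converted, respecting an editor's 5' context rule.
#' Minus-strand edits are reported in sense coordinates as the complementary
#' conversion (a C>T chemistry on the minus strand appears as G>A). Source
#' bases inside minor windows are left unchanged but raise
#' `minor_bystander_flag`; a placement that reaches the SNV only through a
#' minor window is marked `minor_window_match`.
#'
#' @param placement one row of [enumerate_placements()] output (or an
#'   equivalent list).
#' @param snv the [snv_record()] the placement was derived from.
#' @param registry the registry holding the placement's editor.
#' @return object of class `edit_outcome`: the placement, the edited sense
#'   sequence, the 1-based changed positions and the minor-window flags.
#' @export
simulate_edit <- function(placement, snv, registry) {
  pl <- as.list(placement)
  if (is.data.frame(placement)) {
    stopifnot(nrow(placement) == 1)
    pl <- lapply(placement, `[[`, 1)
  }
  ed <- lookup_editor(registry, pl$editor)
  S <- snv$sequence
  if (pl$proto_start < 1 || pl$proto_end > nchar(S) ||
      snv$snv_pos < pl$proto_start || snv$snv_pos > pl$proto_end)
    stop("placement does not cover the SNV of this record", call. = FALSE)
  strand <- pl$strand
  src <- substr(ed$conversion, 1, 1)
  dst <- substr(ed$conversion, 3, 3)
  if (strand == "-") {
    src <- .complement_base(src)
    dst <- .complement_base(dst)
  }
  span <- .window_span(pl$proto_start, ed$grna_length, ed$pam_side, strand,
                       ed$major_window[1], ed$major_window[2])
  pos <- span[1]:span[2]
  pos <- pos[pos >= 1 & pos <= nchar(S)]
  bases <- substring(S, pos, pos)
  hit <- bases == src
  if (!is.na(ed$context_5prime) && any(hit)) {
    # 5'-adjacent base on the protospacer strand
    ctx_pos <- if (strand == "+") pos - 1 else pos + 1
    ctx_need <- if (strand == "+") ed$context_5prime else
      .complement_base(ed$context_5prime)
    in_seq <- ctx_pos >= 1 & ctx_pos <= nchar(S)
    ctx_ok <- in_seq & substring(S, ctx_pos, ctx_pos) == ctx_need
    hit <- hit & ctx_ok
  }
  changed <- pos[hit]
  edited <- S
  for (q in changed) substr(edited, q, q) <- dst
  minor_flag <- FALSE
  for (w in ed$minor_windows) {
    sp <- .window_span(pl$proto_start, ed$grna_length, ed$pam_side, strand,
                       w[1], w[2])
    mp <- sp[1]:sp[2]
    mp <- mp[mp >= 1 & mp <= nchar(S)]
    if (any(substring(S, mp, mp) == src)) minor_flag <- TRUE
  }
  structure(list(placement = pl, edited_sequence = edited,
                 changed_positions = changed,
                 minor_bystander_flag = minor_flag,
                 minor_window_match = identical(pl$window, "minor")),
            class = "edit_outcome")
}
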