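# Independent brute-force oracle for the placement search: slides every
# protospacer start on both strands and applies the PAM / window criteria
# directly, with its own IUPAC table and complement code. Deliberately
# written as plain loops so it shares no code path with the package.

ORACLE_IUPAC <- list(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                     S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                     D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_iupac_match <- function(pattern, site) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(site, "")[[1]]
  if (length(p) != length(s)) return(FALSE)
  for (k in seq_along(p))
    if (!grepl(s[k], ORACLE_IUPAC[[p[k]]], fixed = TRUE)) return(FALSE)
  TRUE
}

# distance from PAM of sense position p, for a protospacer at sense
# coordinates i..i+L-1: the protospacer base adjacent to the PAM is
# distance 1
oracle_distance <- function(p, i, L, pam_side, strand) {
  pam_adjacent <- if (pam_side == "three_prime") {
    if (strand == "+") i + L - 1 else i
  } else {
    if (strand == "+") i else i + L - 1
  }
  abs(p - pam_adjacent) + 1
}

oracle_placements <- function(snv, registry) {
  S <- snv$sequence
  n <- nchar(S)
  p <- snv$snv_pos
  rows <- list()
  for (ed in registry$editors) {
    L <- ed$grna_length
    m <- nchar(ed$pam)
    for (strand in c("+", "-")) {
      for (i in seq_len(n)) {
        if (i + L - 1 > n) next
        if (p < i || p > i + L - 1) next
        pam_downstream_on_sense <-
          (strand == "+") == (ed$pam_side == "three_prime")
        if (pam_downstream_on_sense) {
          ps <- i + L; pe <- i + L + m - 1
        } else {
          ps <- i - m; pe <- i - 1
        }
        if (ps < 1 || pe > n) next
        pam_text <- substr(S, ps, pe)
        if (strand == "-") pam_text <- oracle_revcomp(pam_text)
        if (!oracle_iupac_match(ed$pam, pam_text)) next
        d <- oracle_distance(p, i, L, ed$pam_side, strand)
        win <- NULL
        if (d >= ed$major_window[1] && d <= ed$major_window[2]) {
          win <- "major"
        } else {
          for (w in ed$minor_windows)
            if (d >= w[1] && d <= w[2]) win <- "minor"
        }
        if (is.null(win)) next
        rows[[length(rows) + 1]] <- data.frame(
          editor = ed$name, strand = strand, proto_start = i,
          window = win, dist = d, pam_site = pam_text,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(editor = character(), strand = character(),
                      proto_start = integer(), window = character(),
                      dist = integer(), pam_site = character()))
  do.call(rbind, rows)
}

placement_key <- function(df) {
  if (nrow(df) == 0) return(character())
  sort(sprintf("%s|%s|%d|%s|%d|%s", df$editor, df$strand, df$proto_start,
               df$window, df$dist, df$pam_site))
}

# small but structurally diverse registry: 3' NGG, degenerate 3' PAMs,
# 21-nt Sa guide, 5' Cas12a PAM, ABE chemistry, TC-context CBE
oracle_registry <- function() {
  reg <- builtin_registry()
  editor_registry(lapply(
    c("BE3", "VQR-BE3", "SaBE3", "Cas12a-BE", "ABE 7.10*", "eA3A-BE3"),
    function(nm) lookup_editor(reg, nm)))
}

random_snv <- function(id = "r", min_len = 60, max_len = 100) {
  n <- sample(min_len:max_len, 1)
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
             collapse = "")
  pos <- sample(seq_len(n), 1)
  var <- substr(s, pos, pos)
  ref <- sample(setdiff(c("A", "C", "G", "T"), var), 1)
  snv_record(id, s, pos, ref, var, frame_offset = sample(0:2, 1))
}

# all edit outcomes (placements x simulation) as comparable keys, mapped to
# a canonical strand-independent form for the symmetry test
outcome_keys <- function(snv, registry) {
  pls <- enumerate_placements(snv, registry)
  n <- nchar(snv$sequence)
  vapply(seq_len(nrow(pls)), function(i) {
    out <- simulate_edit(pls[i, ], snv, registry)
    pl <- out$placement
    sprintf("%s|%s|%d-%d|%s|%s", pl$editor, pl$strand, pl$proto_start,
            pl$proto_end, pl$window, out$edited_sequence)
  }, character(1))
}

mirror_snv <- function(snv) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- nchar(snv$sequence)
  snv_record(snv$id, reverse_complement(snv$sequence), n - snv$snv_pos + 1,
             comp[[snv$ref_base]], comp[[snv$var_base]], snv$frame_offset)
}

# keys of the mirrored record mapped back into the original frame
mirrored_outcome_keys <- function(snv, registry) {
  m <- mirror_snv(snv)
  pls <- enumerate_placements(m, registry)
  n <- nchar(snv$sequence)
  vapply(seq_len(nrow(pls)), function(i) {
    out <- simulate_edit(pls[i, ], m, registry)
    pl <- out$placement
    strand <- if (pl$strand == "+") "-" else "+"
    sprintf("%s|%s|%d-%d|%s|%s", pl$editor, strand,
            n - pl$proto_end + 1, n - pl$proto_start + 1, pl$window,
            reverse_complement(out$edited_sequence))
  }, character(1))
}
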