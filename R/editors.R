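# Base-editor registry: machine-readable descriptions of published cytosine
# and adenine base editors (conversion chemistry, PAM, orientation, gRNA
# length, major/minor activity windows, sequence-context rule), plus a
# validating parser for user-defined editors (JSON or TSV).

#' Construct a base editor description
#'
#' Activity windows are inclusive distance-from-PAM intervals: the protospacer
#' base adjacent to the PAM is distance 1. For `pam_side = "three_prime"`
#' (type II Cas, PAM downstream of the protospacer) distance d corresponds to
#' 5'-counted protospacer position `grna_length - d + 1`; for
#' `pam_side = "five_prime"` (type V, e.g. Cas12a, distances counted downstream
#' away from the PAM) it corresponds to position d. With that convention a
#' canonical 20-nt CBE window of 13-17 covers protospacer positions 4-8.
#'
#' @param name canonical editor name.
#' @param conversion `"C>T"` (CBE) or `"A>G"` (ABE); the chemistry on the
#'   protospacer strand. `"C to T"`/unicode-arrow spellings are accepted.
#' @param pam IUPAC PAM pattern, e.g. `"NGG"`, `"TTTV"`.
#' @param pam_side `"three_prime"` (PAM downstream) or `"five_prime"`.
#' @param grna_length protospacer length in nt (20 typical, 21 for Sa guides).
#' @param major_window integer `c(lo, hi)` distance-from-PAM interval where
#'   every target base is deterministically deaminated.
#' @param minor_windows list of `c(lo, hi)` intervals of weak residual
#'   activity; reported as flags, never simulated as edits.
#' @param context_5prime optional single base that must precede a target base
#'   on the protospacer strand for conversion (e.g. "T" for eA3A's TC rule).
#' @param aliases other published construct names sharing these parameters.
#' @param notes free-text caveats.
#' @return object of class `base_editor`.
#' @export
base_editor <- function(name, conversion, pam, pam_side = "three_prime",
                        grna_length = 20L, major_window,
                        minor_windows = list(), context_5prime = NA_character_,
                        aliases = character(), notes = "") {
  ed <- structure(list(
    name = as.character(name),
    aliases = as.character(aliases),
    conversion = .normalize_conversion(conversion),
    pam = normalize_dna(pam, pattern = TRUE, what = "pam"),
    pam_side = as.character(pam_side),
    grna_length = as.integer(grna_length),
    major_window = as.integer(major_window),
    minor_windows = lapply(minor_windows, as.integer),
    context_5prime = as.character(context_5prime),
    notes = as.character(notes)
  ), class = "base_editor")
  validate_editor(ed)
}

.normalize_conversion <- function(x) {
  x <- gsub("→", ">", as.character(x))
  x <- toupper(gsub("[[:space:]]*TO[[:space:]]*", ">", toupper(x)))
  x <- gsub(" ", "", x)
  x
}

.check_window <- function(w, grna_length, field, name) {
  if (length(w) != 2 || any(is.na(w)))
    stop(sprintf("editor '%s': %s must be two integers", name, field),
         call. = FALSE)
  if (w[1] < 1)
    stop(sprintf("editor '%s': %s lower bound %d is below 1 (distance from PAM starts at 1)",
                 name, field, w[1]), call. = FALSE)
  if (w[1] > w[2])
    stop(sprintf("editor '%s': %s has lo > hi", name, field), call. = FALSE)
  if (w[2] > grna_length)
    stop(sprintf("editor '%s': %s extends beyond the %d-nt protospacer",
                 name, field, grna_length), call. = FALSE)
  invisible(w)
}

#' Validate a base editor description
#'
#' Checks the field invariants: known conversion chemistry, IUPAC-only PAM,
#' valid PAM side, windows within the protospacer with lo <= hi, and minor
#' windows disjoint from the major window. Errors name the offending field.
#'
#' @param editor a `base_editor`.
#' @return the editor, invisibly unchanged, if valid.
#' @export
validate_editor <- function(editor) {
  nm <- editor$name
  if (!nzchar(nm)) stop("editor name must be non-empty", call. = FALSE)
  if (!editor$conversion %in% c("C>T", "A>G"))
    stop(sprintf("editor '%s': conversion must be C>T or A>G", nm),
         call. = FALSE)
  if (!editor$pam_side %in% c("three_prime", "five_prime"))
    stop(sprintf("editor '%s': pam_side must be three_prime or five_prime", nm),
         call. = FALSE)
  if (is.na(editor$grna_length) || editor$grna_length < 1)
    stop(sprintf("editor '%s': grna_length must be a positive integer", nm),
         call. = FALSE)
  # PAM alphabet is enforced by normalize_dna(pattern = TRUE) at construction;
  # re-check here so hand-built lists go through the same gate.
  normalize_dna(editor$pam, pattern = TRUE, what = sprintf("pam of '%s'", nm))
  .check_window(editor$major_window, editor$grna_length, "major_window", nm)
  maj <- editor$major_window[1]:editor$major_window[2]
  for (w in editor$minor_windows) {
    .check_window(w, editor$grna_length, "minor_window", nm)
    if (length(intersect(w[1]:w[2], maj)))
      stop(sprintf("editor '%s': minor_window %d-%d overlaps the major window",
                   nm, w[1], w[2]), call. = FALSE)
  }
  if (!is.na(editor$context_5prime) &&
      !editor$context_5prime %in% c("A", "C", "G", "T"))
    stop(sprintf("editor '%s': context_5prime must be a single DNA base", nm),
         call. = FALSE)
  invisible(editor)
}

#' Build an editor registry
#'
#' @param editors list of `base_editor` objects; names (including aliases)
#'   must be unique across the registry.
#' @return object of class `editor_registry`.
#' @export
editor_registry <- function(editors) {
  for (ed in editors) {
    if (!inherits(ed, "base_editor"))
      stop("all registry entries must be base_editor objects", call. = FALSE)
    validate_editor(ed)
  }
  all_names <- unlist(lapply(editors, function(e) c(e$name, e$aliases)))
  if (anyDuplicated(all_names))
    stop(sprintf("duplicate editor name: %s",
                 all_names[duplicated(all_names)][1]), call. = FALSE)
  structure(list(editors = editors), class = "editor_registry")
}

#' @export
length.editor_registry <- function(x) length(x$editors)

#' Look up an editor by name or alias
#'
#' Rows of the built-in repository that group several published constructs
#' with identical parameters (e.g. BE1/BE2/BE3/HF-BE3/BE4(max)/BE4-Gam) are a
#' single entry; any of the construct names resolves to it.
#'
#' @param registry an `editor_registry`.
#' @param name editor name or alias.
#' @return the matching `base_editor`, or an error if absent.
#' @export
lookup_editor <- function(registry, name) {
  for (ed in registry$editors)
    if (name == ed$name || name %in% ed$aliases) return(ed)
  stop(sprintf("no editor named '%s' in the registry", name), call. = FALSE)
}

# Table-driven definition of the built-in repository. Windows are
# distance-from-PAM, transcribed verbatim from the published properties.
# minor: ";"-separated intervals. len 21 marks Sa-type 21-nt gRNAs.
.BUILTIN_EDITORS <- list(
  list("BE3", c("BE1", "BE2", "HF-BE3", "BE4(max)", "BE4-Gam"), "C>T", "NGG",
       "three_prime", 20, "13-17", "10-12;18-19", NA,
       "BE1/BE2/BE3/HF-BE3/BE4(max)/BE4-Gam share parameters; one entry"),
  list("YE1-BE3", character(), "C>T", "NGG", "three_prime", 20, "14-16", "17",
       NA, ""),
  list("YEE-BE3", character(), "C>T", "NGG", "three_prime", 20, "15-15", "16",
       NA, ""),
  list("VQR-BE3", character(), "C>T", "NGAN", "three_prime", 20, "10-17", "",
       NA, ""),
  list("VRER-BE3", character(), "C>T", "NGCG", "three_prime", 20, "11-18", "",
       NA, ""),
  list("SaBE3", c("SaBE4", "SaBE4-Gam"), "C>T", "NNGRRT", "three_prime", 21,
       "10-19", "", NA, "21nt gRNA"),
  list("Sa(KKH)-BE3", character(), "C>T", "NNNRRT", "three_prime", 21,
       "10-19", "", NA, "21nt gRNA"),
  list("Cas12a-BE", character(), "C>T", "TTTV", "five_prime", 20, "10-12",
       "8-9;13", NA, "type V; windows counted downstream of the 5' PAM"),
  list("Target-AID", character(), "C>T", "NGG", "three_prime", 20, "17-19",
       "13-16", NA, ""),
  list("Target-AID-NG", character(), "C>T", "NG", "three_prime", 20, "17-19",
       "13-16", NA, ""),
  list("xBE3", character(), "C>T", "NG", "three_prime", 20, "13-17",
       "10-12;18-19", NA, ""),
  list("eA3A-BE3", character(), "C>T", "NGG", "three_prime", 20, "13-17",
       "10-12;18-19", "T", "converts C only when preceded 5' by T (TC context)"),
  list("BE-PLUS", character(), "C>T", "NGG", "three_prime", 20, "7-17", "5-6",
       NA, ""),
  list("CP-CBEmax", c("CP-CBEmax variants"), "C>T", "NGG", "three_prime", 20,
       "12-17", "10-11", NA,
       "may exhibit editing upstream of the protospacer (not modeled)"),
  list("evoAPOBEC1-BE4max", character(), "C>T", "NGG", "three_prime", 20,
       "13-18", "19-20;9-12", NA, ""),
  list("evoFERNY-BE4max", character(), "C>T", "NGG", "three_prime", 20,
       "13-18", "19-20", NA, ""),
  list("evoCDA1-BE4max", character(), "C>T", "NGG", "three_prime", 20,
       "9-20", "7-8", NA,
       "may exhibit editing upstream of the protospacer (not modeled)"),
  list("ABE 7.9", character(), "A>G", "NGG", "three_prime", 20, "13-16",
       "12;17", NA, ""),
  list("ABE 7.10", character(), "A>G", "NGG", "three_prime", 20, "14-17", "13",
       NA, ""),
  list("ABE 7.10*", character(), "A>G", "NGG", "three_prime", 20, "13-17",
       "12;18-19", NA, ""),
  list("xABE", c("NG-ABEmax"), "A>G", "NG", "three_prime", 20, "14-17", "13",
       NA, "xABE/NG-ABEmax share parameters; one entry"),
  list("ABESa", character(), "A>G", "NNGRRT", "three_prime", 21, "10-16", "",
       NA, "21nt gRNA"),
  list("Sa(KKH)-ABE", character(), "A>G", "NGA", "three_prime", 21, "10-16",
       "", NA,
       "21nt gRNA; PAM as published even though it may look swapped with VQR-ABE"),
  list("VRER-ABE", character(), "A>G", "NGCG", "three_prime", 20, "15-17",
       "13-14", NA, ""),
  list("VQR-ABE", character(), "A>G", "NNNRRT", "three_prime", 20, "15-17",
       "13-14", NA,
       "PAM as published even though it may look swapped with Sa(KKH)-ABE"),
  list("CP-ABEmax", c("CP-ABEmax variants"), "A>G", "NGG", "three_prime", 20,
       "14-17", "7-13", NA, "")
)

.parse_windows <- function(x) {
  if (is.na(x) || !nzchar(x)) return(list())
  lapply(strsplit(x, ";")[[1]], function(iv) {
    parts <- as.integer(strsplit(iv, "-")[[1]])
    if (length(parts) == 1) parts <- c(parts, parts)
    parts
  })
}

#' The built-in base-editor repository
#'
#' Returns the registry of 26 published base editors (17 CBEs, 9 ABEs) with
#' their PAMs, gRNA lengths and distance-from-PAM activity windows. Constructs
#' sharing all parameters form a single aliased entry.
#'
#' @return an `editor_registry` of 26 entries.
#' @examples
#' reg <- builtin_registry()
#' length(reg)
#' lookup_editor(reg, "VQR-BE3")$pam
#' @export
builtin_registry <- function() {
  eds <- lapply(.BUILTIN_EDITORS, function(r) {
    base_editor(name = r[[1]], aliases = r[[2]], conversion = r[[3]],
                pam = r[[4]], pam_side = r[[5]], grna_length = r[[6]],
                major_window = .parse_windows(r[[7]])[[1]],
                minor_windows = .parse_windows(r[[8]]),
                context_5prime = if (is.na(r[[9]])) NA_character_ else r[[9]],
                notes = r[[10]])
  })
  editor_registry(eds)
}

.fmt_windows <- function(ws) {
  if (length(ws) == 0) return("")
  paste(vapply(ws, function(w)
    if (w[1] == w[2]) as.character(w[1]) else paste0(w[1], "-", w[2]),
    character(1)), collapse = ";")
}

#' Registry as a data frame
#'
#' One row per editor with windows in "lo-hi" notation (";"-separated minors)
#' and aliases "|"-separated; the format written by [write_editors()] and read
#' back by [load_custom_editors()].
#'
#' @param x an `editor_registry`.
#' @param ... unused.
#' @export
as.data.frame.editor_registry <- function(x, ...) {
  do.call(rbind, lapply(x$editors, function(e) {
    data.frame(name = e$name,
               aliases = paste(e$aliases, collapse = "|"),
               conversion = e$conversion,
               pam = e$pam,
               pam_side = e$pam_side,
               grna_length = e$grna_length,
               major_window = .fmt_windows(list(e$major_window)),
               minor_windows = .fmt_windows(e$minor_windows),
               context_5prime = ifelse(is.na(e$context_5prime), "",
                                       e$context_5prime),
               notes = e$notes,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.editor_registry <- function(x, ...) {
  df <- as.data.frame(x)
  n_cbe <- sum(df$conversion == "C>T")
  cat(sprintf("Base editor registry: %d editors (%d CBE, %d ABE)\n",
              nrow(df), n_cbe, nrow(df) - n_cbe))
  print(df[, c("name", "conversion", "pam", "pam_side", "grna_length",
               "major_window", "minor_windows")], row.names = FALSE)
  invisible(x)
}

.editor_from_record <- function(rec) {
  need <- c("name", "conversion", "pam", "pam_side", "grna_length",
            "major_window")
  missing <- setdiff(need, names(rec)[!vapply(rec, function(v)
    is.null(v) || (length(v) == 1 && is.na(v)), logical(1))])
  if (length(missing))
    stop(sprintf("editor definition missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  to_windows <- function(v) {
    if (is.null(v)) return(list())
    if (is.character(v)) return(.parse_windows(v))
    if (is.numeric(v)) return(list(as.integer(v)))
    lapply(v, as.integer)
  }
  aliases <- rec$aliases
  if (is.character(aliases) && length(aliases) == 1)
    aliases <- strsplit(aliases, "|", fixed = TRUE)[[1]]
  ctx <- rec$context_5prime
  if (is.null(ctx) || (is.character(ctx) && !nzchar(ctx))) ctx <- NA_character_
  base_editor(name = rec$name,
              aliases = if (is.null(aliases)) character() else
                aliases[nzchar(aliases)],
              conversion = rec$conversion, pam = rec$pam,
              pam_side = rec$pam_side, grna_length = rec$grna_length,
              major_window = to_windows(rec$major_window)[[1]],
              minor_windows = to_windows(rec$minor_windows),
              context_5prime = ctx,
              notes = if (is.null(rec$notes) || is.na(rec$notes)) "" else
                rec$notes)
}

#' Load user-defined editors
#'
#' Reads editor definitions from a JSON array of objects or a TSV with the
#' columns produced by [write_editors()] (minor windows optional,
#' ";"-separated "lo-hi" intervals). Every editor passes the same validator as
#' the built-in repository; merging with the built-ins is the caller's choice.
#'
#' @param source path to a .json or .tsv/.txt file, or a data frame / list of
#'   records already in memory.
#' @param format "auto" (by extension), "json" or "tsv".
#' @return an `editor_registry` of the validated editors.
#' @export
load_custom_editors <- function(source, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (is.character(source) && length(source) == 1) {
    if (format == "auto")
      format <- if (grepl("\\.json$", source, ignore.case = TRUE)) "json"
        else "tsv"
    records <- if (format == "json") {
      jsonlite::fromJSON(source, simplifyDataFrame = FALSE)
    } else {
      df <- utils::read.delim(source, stringsAsFactors = FALSE,
                              colClasses = "character")
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
    }
  } else if (is.data.frame(source)) {
    records <- lapply(seq_len(nrow(source)), function(i)
      as.list(source[i, , drop = FALSE]))
  } else {
    records <- source
    if (!is.null(names(records)) && "name" %in% names(records))
      records <- list(records)
  }
  editor_registry(lapply(records, .editor_from_record))
}

#' Write a registry to disk
#'
#' @param registry an `editor_registry`.
#' @param path output file.
#' @param format "json" or "tsv"; [load_custom_editors()] round-trips both.
#' @export
write_editors <- function(registry, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  df <- as.data.frame(registry)
  if (format == "json") {
    recs <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
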